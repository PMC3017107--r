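test_that("lift_to_3d follows the circle cross-section with the side sign convention", {
  cfg <- spatial_config()
  # equator: |z| = r, signed by side
  expect_equal(lift_to_3d(0, 0, "left", cfg)$z, 0.05)
  expect_equal(lift_to_3d(0, 0, "right", cfg)$z, -0.05)
  # 3-4-5 triangle: sqrt(0.05^2 - 0.03^2) = 0.04
  expect_equal(lift_to_3d(0.1, 0.03, "right", cfg)$z, -0.04)
  # midline neurons always have z = 0, even on the dorsal line (dv = r)
  expect_equal(lift_to_3d(0.2, 0.05, "midline", cfg)$z, 0)
  # x and y pass through
  out <- lift_to_3d(0.7, -0.02, "left", cfg)
  expect_equal(c(out$x, out$y), c(0.7, -0.02))
})

test_that("lift_to_3d clamps over-radius coordinates and rejects non-finite input", {
  cfg <- spatial_config()
  # tiny digitization overshoot: silent clamp to the radius, z = 0
  expect_silent(out <- lift_to_3d(0, 0.05 + 1e-8, "left", cfg))
  expect_equal(out$z, 0)
  expect_equal(out$y, 0.05)
  # gross overshoot: warning + clamp
  expect_warning(out2 <- lift_to_3d(0, 0.2, "left", cfg), "clamp")
  expect_equal(out2$z, 0)
  expect_error(lift_to_3d(NA_real_, 0, "left", cfg), "non-finite")
  expect_error(lift_to_3d(0, 0, "up", cfg), "side")
})

test_that("lift_to_3d round-trip: y^2 + z^2 = r^2 for non-midline neurons", {
  cfg <- spatial_config()
  set.seed(11)
  dv <- runif(200, -0.05, 0.05)
  side <- sample(c("left", "right"), 200, replace = TRUE)
  out <- lift_to_3d(runif(200, 0, 1.2), dv, side, cfg)
  expect_true(all(abs(out$y^2 + out$z^2 - 0.05^2) < 1e-9))
})

test_that("neuron CSV loader populates 3D positions and validates input", {
  cfg <- spatial_config()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,ap_mm,dv_mm,side,birth_time_min",
               "AVAL,0.1,0.0,left,290",
               "AVAR,0.1,0.0,right,295",
               "M1,0.5,0.02,midline,900"), f)
  nn <- load_neuron_table(f, cfg)
  expect_equal(nrow(nn), 3)
  expect_equal(nn$birth_time, c(290, 295, 900))
  expect_equal(nn$z, c(0.05, -0.05, 0))

  fdup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,ap_mm,dv_mm,side,birth_time_min",
               "AVAL,0.1,0,left,290", "AVAL,0.2,0,right,300"), fdup)
  expect_error(load_neuron_table(fdup, cfg), "AVAL")

  fmiss <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,ap_mm,side,birth_time_min", "AVAL,0.1,left,290"), fmiss)
  expect_error(load_neuron_table(fmiss, cfg), "dv_mm")

  fbad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,ap_mm,dv_mm,side,birth_time_min",
               "AVAL,0.1,0,left,290", "AVAR,0.1,x,right,295"), fbad)
  expect_error(load_neuron_table(fbad, cfg), "line.*2")
})

test_that("edge loader collapses duplicate pairs and upgrades to combination", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pre,post,synapse_kind,directedness",
               "A,B,gap,bi",
               "B,A,chemical,uni",     # same pair: gap + chemical -> combination
               "A,C,chemical,uni",
               "C,A,chemical,uni",     # reciprocal chemical -> one bi link
               "B,C,chemical,uni"), f)
  e <- load_edge_table(f)
  expect_equal(nrow(e), 3)
  ab <- e[e$pre %in% c("A", "B") & e$post %in% c("A", "B"), ]
  expect_equal(ab$synapse_kind, "combination")
  expect_equal(ab$directedness, "bi")
  ac <- e[(e$pre == "A" & e$post == "C") | (e$pre == "C" & e$post == "A"), ]
  expect_equal(ac$directedness, "bi")
  expect_equal(e[e$pre == "B" & e$post == "C", "directedness"], "uni")
})

test_that("connectome validation rejects inconsistent input", {
  nn <- data.frame(id = c("A", "B"), birth_time = c(1, 2))
  expect_error(
    connectome(nn, data.frame(pre = "A", post = "Z",
                              synapse_kind = "chemical",
                              directedness = "uni")), "Z")
  expect_error(
    connectome(nn, data.frame(pre = "A", post = "A",
                              synapse_kind = "chemical",
                              directedness = "uni")), "self-loop")
  expect_error(
    connectome(nn, data.frame(pre = "A", post = "B",
                              synapse_kind = "gap",
                              directedness = "uni")), "bidirectional")
  expect_error(
    connectome(nn, data.frame(pre = c("A", "B"), post = c("B", "A"),
                              synapse_kind = "chemical",
                              directedness = "uni")), "duplicate")
})

test_that("apply_exclusions removes neurons with incident edges, self-loops, and is idempotent", {
  nn <- data.frame(id = c("A", "B", "C", "D", "E"),
                   birth_time = c(1, 2, 3, 4, 5))
  ee <- data.frame(pre = c("A", "A", "B", "C", "E"),
                   post = c("B", "C", "C", "D", "E"),
                   synapse_kind = "chemical", directedness = "uni")
  raw <- list(neurons = nn, connections = ee, config = spatial_config())
  out <- suppressMessages(apply_exclusions(raw, "A"))
  expect_equal(nrow(out$neurons), 4)       # A gone
  expect_equal(nrow(out$connections), 2)   # A's 2 edges and the E self-loop gone
  # idempotent
  again <- apply_exclusions(out, "A") |> suppressMessages() |> suppressWarnings()
  expect_identical(again$neurons, out$neurons)
  expect_identical(again$connections, out$connections)
  # unknown id warns, does not error
  expect_warning(suppressMessages(apply_exclusions(out, "ZZ")), "ZZ")
  # empty exclusion set on a clean connectome is the identity
  clean <- apply_exclusions(out)
  expect_identical(clean$connections, out$connections)
})

test_that("stage_network induces on births <= t and is monotone", {
  con <- mini_connectome(
    data.frame(pre = c("A", "B"), post = c("B", "C")),
    c(A = 100, B = 200, C = 300))
  expect_equal(nrow(stage_network(con, 50)$neurons), 0)
  s <- stage_network(con, 250)
  expect_setequal(s$neurons$id, c("A", "B"))
  expect_equal(nrow(s$connections), 1)
  expect_equal(nrow(stage_network(con, 300)$connections), 2)
  # inclusive cutoff
  expect_true("B" %in% stage_network(con, 200)$neurons$id)
  # monotonicity on a synthetic network
  sim <- generate_connectome(generator_config(n_neurons = 60,
                                              n_connections = 200, seed = 5))
  ts <- c(400, 600, 840, 2000, 2700)
  prev <- stage_network(sim$connectome, ts[1])
  for (t in ts[-1]) {
    cur <- stage_network(sim$connectome, t)
    expect_true(all(prev$neurons$id %in% cur$neurons$id))
    expect_true(all(pair_ids(prev) %in% pair_ids(cur)))
    prev <- cur
  }
})

test_that("degree counts arcs after expanding bidirectional links", {
  # 2 uni outgoing + 1 bi = 2 + 2 = 4
  con <- mini_connectome(
    data.frame(pre = c("H", "H", "H"), post = c("A", "B", "C"),
               synapse_kind = c("chemical", "chemical", "gap"),
               directedness = c("uni", "uni", "bi")),
    c(H = 1, A = 2, B = 3, C = 4, I = 5))
  expect_equal(neuron_degree(con, "H"), 4L)
  expect_equal(neuron_degree(con, "I"), 0L)   # isolated
  expect_error(neuron_degree(con, "nope"), "unknown")
  # handshake identity: sum of degrees = 2 x number of arcs
  n_arcs <- sum(ifelse(con$connections$directedness == "bi", 2L, 1L))
  expect_equal(sum(neuron_degree(con)), 2L * n_arcs)
})

test_that("write/reload round-trips a connectome field-for-field", {
  con <- toy_connectome()
  dir <- withr::local_tempdir()
  paths <- write_connectome(con, dir)
  re <- read_connectome(paths["neurons"], paths["edges"])
  expect_equal(re$neurons[order(re$neurons$id), ],
               con$neurons[order(con$neurons$id), ],
               ignore_attr = TRUE)
  ek <- function(x) {
    e <- x$connections
    o <- order(e$pre, e$post)
    e[o, c("pre", "post", "synapse_kind", "directedness")]
  }
  expect_equal(ek(re), ek(con), ignore_attr = TRUE)
})

test_that("GraphML export writes a loadable graph with neuron attributes", {
  con <- toy_connectome()
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(con, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 5)
  expect_true("birth_time" %in% igraph::vertex_attr_names(g))
  # directed expansion: 2 uni + 2 bi links -> 6 arcs
  expect_equal(igraph::ecount(g), 6)
})
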