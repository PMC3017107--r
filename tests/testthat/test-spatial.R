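pos345 <- matrix(c(0, 0, 0,
                   0.3, 0.4, 0,
                   0.3, 0, 0.4), byrow = TRUE, nrow = 3,
                 dimnames = list(c("A", "B", "C"), NULL))

test_that("connection lengths are Euclidean, symmetric, and fail on missing positions", {
  con <- mini_connectome(data.frame(pre = c("A", "A"), post = c("B", "C")),
                         c(A = 1, B = 2, C = 3), pos = pos345)
  expect_equal(connection_lengths(con), c(0.5, 0.5))
  expect_equal(connection_length(con, "A", "B"),
               connection_length(con, "B", "A"))
  expect_equal(connection_length(con, "B", "B"), 0)
  nopos <- mini_connectome(data.frame(pre = "A", post = "B"),
                           c(A = 1, B = 2))
  expect_error(connection_lengths(nopos), "A")
})

test_that("length classes follow the 0.36/0.84 mm thresholds with half-open bins", {
  expect_equal(classify_length(c(0.20, 0.50, 1.00)),
               c("short", "medium", "long"))
  # boundaries: short bound goes to medium, long bound goes to long
  expect_equal(classify_length(c(0, 0.36, 0.84, 1.2, 5)),
               c("short", "medium", "long", "long", "long"))
  expect_error(classify_length(-0.1), "non-negative")
  # classes partition any input: counts sum to the total
  set.seed(8)
  d <- runif(300, 0, 2)
  expect_equal(sum(table(classify_length(d))), 300)
  # monotone short -> medium -> long as d increases
  cls <- classify_length(sort(d))
  expect_true(all(diff(match(cls, c("short", "medium", "long"))) >= 0))
})

test_that("appearance curves use adult lengths and both-born semantics", {
  # single short pair born at (300, 900)
  con <- mini_connectome(data.frame(pre = "A", post = "B"),
                         c(A = 300, B = 900),
                         pos = matrix(c(0, 0, 0, 0.1, 0, 0), byrow = TRUE,
                                      nrow = 2,
                                      dimnames = list(c("A", "B"), NULL)))
  cur <- suppressWarnings(appearance_curves(con, c(800, 2000)))
  expect_equal(cur$short, c(0, 100))
  expect_false("long" %in% names(cur))   # no adult long pairs -> omitted
  expect_warning(expect_warning(appearance_curves(con, c(800)), "long"),
                 "medium")
  # final stage reaches 100% in every class on synthetic data
  sim <- generate_connectome(generator_config(n_neurons = 80,
                                              n_connections = 400, seed = 2))
  cur2 <- appearance_curves(sim$connectome, c(500, 840, 2700))
  for (col in setdiff(names(cur2), "stage_time")) {
    expect_true(all(diff(cur2[[col]]) >= 0))
    expect_equal(cur2[[col]][3], 100)
  }
})

test_that("synapse breakdown cross-tabulates kind x class x phase", {
  pos <- matrix(c(0, 0, 0,
                  0.1, 0, 0,
                  1.0, 0, 0,
                  0.2, 0, 0,
                  1.1, 0, 0), byrow = TRUE, nrow = 5,
                dimnames = list(c("O", "S1", "L1", "S2", "L2"), NULL))
  con <- mini_connectome(
    data.frame(pre = c("O", "O", "O", "O"),
               post = c("S1", "L1", "S2", "L2"),
               synapse_kind = c("gap", "gap", "chemical", "combination"),
               directedness = c("bi", "bi", "uni", "bi")),
    c(O = 100, S1 = 200, L1 = 900, S2 = 300, L2 = 400), pos = pos)
  bd <- synapse_breakdown(con)
  # partition: counts sum to total connections
  expect_equal(sum(bd$counts$n), 4)
  # electrically coupled long links: gap/long/late + combination/long/early
  long_row <- bd$by_class[bd$by_class$length_class == "long", ]
  expect_equal(long_row$pct_electrical, 100)
  expect_equal(long_row$n, 2)
  g <- bd$counts
  expect_equal(g$n[g$synapse_kind == "gap" & g$length_class == "long" &
                   g$phase == "late"], 1)
  expect_equal(g$n[g$synapse_kind == "combination" & g$length_class == "long" &
                   g$phase == "early"], 1)
  # all-chemical network: gap and combination rows all zero
  chem <- mini_connectome(
    data.frame(pre = "O", post = "S1"),
    c(O = 100, S1 = 200), pos = pos[1:2, , drop = FALSE])
  bd2 <- synapse_breakdown(chem)
  expect_equal(sum(bd2$counts$n[bd2$counts$synapse_kind != "chemical"]), 0)
})

test_that("region connectivity is endpoint-weighted with a link-level variant", {
  nn <- data.frame(id = c("a", "b", "c"), birth_time = 1:3,
                   region = c("head", "head", "tail"))
  con <- connectome(nn, data.frame(pre = c("a", "a"), post = c("b", "c"),
                                   synapse_kind = "chemical",
                                   directedness = "uni"))
  rc <- region_connectivity(con)
  expect_equal(unname(rc["head"]), 2 / 3)
  expect_equal(unname(rc["tail"]), 0)
  expect_equal(unname(region_connectivity(con, "link")["head"]), 1 / 2)
  # single-region network: fraction 1
  one <- connectome(data.frame(id = c("a", "b"), birth_time = 1:2,
                               region = "head"),
                    data.frame(pre = "a", post = "b",
                               synapse_kind = "chemical",
                               directedness = "uni"))
  expect_equal(unname(region_connectivity(one)["head"]), 1)
  # bipartite head-tail: both fractions 0
  bip <- connectome(data.frame(id = c("a", "b"), birth_time = 1:2,
                               region = c("head", "tail")),
                    data.frame(pre = "a", post = "b",
                               synapse_kind = "chemical",
                               directedness = "uni"))
  expect_equal(unname(region_connectivity(bip)), c(0, 0))
})

test_that("circuit curves assign spanning pairs to both circuits", {
  nn <- data.frame(id = c("a", "b", "c", "d"), birth_time = c(100, 200, 900, 1000),
                   circuits = c("X", "X", "X;Y", "Y"))
  con <- connectome(nn, data.frame(pre = c("a", "c"), post = c("b", "d"),
                                   synapse_kind = "chemical",
                                   directedness = "uni"))
  cur <- circuit_curves(con, c(840, 2700))
  # X pairs: a-b (born by 840) and c-d via c's X membership (late) -> 50%, 100%
  expect_equal(cur$X, c(50, 100))
  # Y pairs: only c-d -> 0%, 100%
  expect_equal(cur$Y, c(0, 100))
  # a neuron with an empty circuit set triggers a warning and joins nothing
  nn2 <- nn; nn2$circuits[1] <- ""
  con2 <- connectome(nn2, con$connections)
  expect_warning(cur2 <- circuit_curves(con2, c(2700)), "empty circuit")
  expect_equal(cur2$X, 100)
})

test_that("degree-length correlations need variance and track planted structure", {
  pos <- matrix(c(0, 0, 0, 0.1, 0, 0, 0.2, 0, 0), byrow = TRUE, nrow = 3,
                dimnames = list(c("a", "b", "c"), NULL))
  allshort <- mini_connectome(
    data.frame(pre = c("a", "a", "b"), post = c("b", "c", "c")),
    c(a = 1, b = 2, c = 3), pos = pos)
  expect_error(degree_length_correlations(allshort), "variance")
  # null with class independent of degree: permuting identities detaches
  # lengths from the fixed degree sequence
  base <- generate_connectome(
    generator_config(n_neurons = 200, n_connections = 2000,
                     hub_early_bias = 0, long_range_early_bias = 0,
                     seed = 19))$connectome
  rs <- vapply(1:20, function(s) {
    degree_length_correlations(shuffle_identities(base, s))
  }, numeric(2))
  expect_lt(abs(mean(rs["r_short", ])), 0.1)
  expect_lt(abs(mean(rs["r_long", ])), 0.1)
})
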