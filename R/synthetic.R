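#' Synthetic-connectome generator configuration
#'
#' Parameters of the seeded generator in [generate_connectome()]. The
#' defaults emulate the structure of the adult hermaphrodite nervous system
#' at the scale the analyses assume: 279 neurons with 2,990 links on a
#' 1.2 mm body cylinder of 50 µm radius; two birth bursts (embryonic
#' 350-750 min, post-embryonic 900-2700 min, hatching at 840 min); axial
#' clustering into head/body/tail; bilateral left/right pairs born within
#' ten minutes of each other; distance-dependent connectivity with planted
#' early-born-hub and early-long-range effects.
#'
#' @param n_neurons Number of neurons (default 279).
#' @param region_weights Named proportions for `head`/`body`/`tail` summing
#'   to 1 (default 0.5/0.3/0.2, head-dominated as in the worm).
#' @param body_length Body length in mm (default 1.2).
#' @param body_radius Body radius in mm (default 0.05).
#' @param embryonic_window,postembryonic_window Birth-time windows in
#'   minutes; embryonic must end before post-embryonic starts.
#' @param embryonic_fraction Proportion of neurons born in the embryonic
#'   window (default 0.7).
#' @param bilateral_fraction Proportion of neurons belonging to a
#'   left/right bilateral pair (default 0.7).
#' @param bilateral_time_jitter Maximum within-pair birth-time difference in
#'   minutes (default 10).
#' @param n_connections Number of links sampled (default 2990).
#' @param hub_early_bias Coefficient >= 0 of the planted early-birth ->
#'   high-degree effect: pair weight is multiplied by
#'   `exp(hub_early_bias * earliness_i * earliness_j)` where earliness is
#'   `(latest stage time - birth time)` rescaled to `[0, 1]` (default 1.5).
#' @param long_range_early_bias Additive weight >= 0 given to pairs longer
#'   than the long-class threshold whose endpoints are both embryonic
#'   (default 2, which leaves roughly a tenth of all links long — near the
#'   real worm's class mix — with a strong embryonic excess).
#' @param gap_fraction,combination_fraction Proportions of links that are
#'   pure gap junctions and gap+chemical combinations (defaults 0.225 and
#'   0.126, as in the real link table); the rest are chemical.
#' @param chemical_bi_fraction Proportion of chemical links that are
#'   reciprocal, hence bidirectional (default 0.18).
#' @param distance_decay Length scale lambda (mm) of the baseline
#'   connection-probability decay `exp(-d / lambda)` (default 0.25).
#' @param seed Integer RNG seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_neurons = 279,
                             region_weights = c(head = 0.5, body = 0.3,
                                                tail = 0.2),
                             body_length = 1.2,
                             body_radius = 0.05,
                             embryonic_window = c(350, 750),
                             postembryonic_window = c(900, 2700),
                             embryonic_fraction = 0.7,
                             bilateral_fraction = 0.7,
                             bilateral_time_jitter = 10,
                             n_connections = 2990,
                             hub_early_bias = 1.5,
                             long_range_early_bias = 2,
                             gap_fraction = 0.225,
                             combination_fraction = 0.126,
                             chemical_bi_fraction = 0.18,
                             distance_decay = 0.25,
                             seed = 1L) {
  stopifnot(n_neurons >= 2, body_length > 0, body_radius > 0,
            length(embryonic_window) == 2L, length(postembryonic_window) == 2L,
            diff(embryonic_window) > 0, diff(postembryonic_window) > 0,
            embryonic_window[2] < postembryonic_window[1],
            embryonic_fraction >= 0, embryonic_fraction <= 1,
            bilateral_fraction >= 0, bilateral_fraction <= 1,
            bilateral_time_jitter >= 0,
            hub_early_bias >= 0, long_range_early_bias >= 0,
            gap_fraction >= 0, combination_fraction >= 0,
            gap_fraction + combination_fraction <= 1,
            chemical_bi_fraction >= 0, chemical_bi_fraction <= 1,
            distance_decay > 0)
  if (!setequal(names(region_weights), c("head", "body", "tail")) ||
      abs(sum(region_weights) - 1) > 1e-9 || any(region_weights < 0)) {
    stop("`region_weights` must be named head/body/tail proportions summing to 1")
  }
  if (n_connections > n_neurons * (n_neurons - 1) / 2) {
    stop("`n_connections` exceeds the number of distinct neuron pairs")
  }
  structure(
    list(n_neurons = as.integer(n_neurons),
         region_weights = region_weights[c("head", "body", "tail")],
         body_length = body_length, body_radius = body_radius,
         embryonic_window = embryonic_window,
         postembryonic_window = postembryonic_window,
         embryonic_fraction = embryonic_fraction,
         bilateral_fraction = bilateral_fraction,
         bilateral_time_jitter = bilateral_time_jitter,
         n_connections = as.integer(n_connections),
         hub_early_bias = hub_early_bias,
         long_range_early_bias = long_range_early_bias,
         gap_fraction = gap_fraction,
         combination_fraction = combination_fraction,
         chemical_bi_fraction = chemical_bi_fraction,
         distance_decay = distance_decay,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

with_rng_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic connectome with planted effects
#'
#' Draws neurons on a cylindrical body with head/body/tail axial clusters,
#' two-burst birth times, mirrored bilateral pairs, and samples exactly
#' `n_connections` links without replacement from pair weights
#' `exp(-d/lambda) * exp(hub_early_bias * e_i * e_j) + long_range_early_bias
#' * [d >= long threshold and both endpoints embryonic]`, where `e` is the
#' earliness score. Both bias terms are planted effects the analysis
#' pipeline should recover; with both biases 0 the generator is a pure
#' distance-decay spatial network.
#'
#' @param config A [generator_config()].
#' @param spatial A [spatial_config()] supplying hatch time and stage times
#'   (the long-length threshold comes from `classifier`).
#' @param classifier A [length_classifier()] defining the long threshold
#'   used by the planted long-range effect.
#' @return A list with elements `connectome` (a [connectome()]) and `truth`
#'   (the planted ground truth: per-neuron earliness and intended hub
#'   status, the sampled pairs' generation-time length classes, and the bias
#'   coefficients used).
#' @examples
#' sim <- generate_connectome(generator_config(n_neurons = 60,
#'                                             n_connections = 150, seed = 3))
#' sim$connectome
#' @export
generate_connectome <- function(config = generator_config(),
                                spatial = spatial_config(),
                                classifier = length_classifier()) {
  stopifnot(inherits(config, "generator_config"),
            inherits(spatial, "spatial_config"),
            inherits(classifier, "length_classifier"))
  with_rng_seed(config$seed, {
    n <- config$n_neurons
    L <- config$body_length
    r <- config$body_radius
    jit <- config$bilateral_time_jitter

    # build pairing units: bilateral pairs share position/region/timing base
    n_pairs <- floor(config$bilateral_fraction * n / 2)
    n_single <- n - 2L * n_pairs
    n_units <- n_pairs + n_single
    unit_region <- sample(c("head", "body", "tail"), n_units, replace = TRUE,
                          prob = config$region_weights)
    # axial layout: head = anterior 20%, tail = posterior 15%, body between
    unit_ap <- numeric(n_units)
    for (reg in c("head", "body", "tail")) {
      idx <- which(unit_region == reg)
      rng <- switch(reg, head = c(0, 0.2), body = c(0.2, 0.85),
                    tail = c(0.85, 1))
      unit_ap[idx] <- runif(length(idx), rng[1] * L, rng[2] * L)
    }
    unit_dv <- runif(n_units, -0.9 * r, 0.9 * r)
    emb <- runif(n_units) < config$embryonic_fraction
    win <- function(is_emb) if (is_emb) config$embryonic_window
           else config$postembryonic_window
    unit_birth <- vapply(emb, function(e) {
      w <- win(e)
      runif(1, w[1], max(w[1], w[2] - jit))
    }, numeric(1))

    pair_units <- seq_len(n_pairs)
    single_units <- if (n_single > 0) n_pairs + seq_len(n_single) else integer()
    id <- character(n)
    side <- character(n)
    ap <- dv <- birth <- numeric(n)
    unit_of <- integer(n)
    partner <- rep(NA_character_, n)
    k <- 0L
    for (u in pair_units) {
      base <- sprintf("SN%03d", u)
      off <- runif(1, 0, jit)
      for (s in c("L", "R")) {
        k <- k + 1L
        id[k] <- paste0(base, s)
        side[k] <- if (s == "L") "left" else "right"
        ap[k] <- unit_ap[u]; dv[k] <- unit_dv[u]
        birth[k] <- unit_birth[u] + if (s == "L") 0 else off
        unit_of[k] <- u
      }
      partner[k - 1L] <- id[k]
      partner[k] <- id[k - 1L]
    }
    for (u in single_units) {
      k <- k + 1L
      id[k] <- sprintf("SN%03dM", u)
      side[k] <- "midline"
      ap[k] <- unit_ap[u]; dv[k] <- unit_dv[u]
      birth[k] <- unit_birth[u]
      unit_of[k] <- u
    }

    cfg3d <- spatial_config(body_radius = r, hatch_time = spatial$hatch_time,
                            stage_times = spatial$stage_times)
    pos <- lift_to_3d(ap, dv, side, cfg3d)

    # neuron types: sensory/inter/motor with occasional polymodal motor+inter;
    # motor neurons skew post-embryonic as in the ventral cord classes
    type_pool <- c("sensory", "inter", "motor", "motor;inter")
    p_emb <- c(0.40, 0.40, 0.12, 0.08)
    p_post <- c(0.15, 0.20, 0.55, 0.10)
    unit_emb <- emb[unit_of]
    ntype <- ifelse(unit_emb,
                    sample(type_pool, n, replace = TRUE, prob = p_emb),
                    sample(type_pool, n, replace = TRUE, prob = p_post))
    # keep bilateral partners the same type
    for (u in pair_units) {
      members <- which(unit_of == u)
      ntype[members] <- ntype[members[1]]
    }
    circuit_of <- c(head = "head_sensory;nerve_ring", body = "locomotion_vnc",
                    tail = "tail_sensory")
    circuits <- unname(circuit_of[unit_region[unit_of]])

    neurons <- normalize_neurons(data.frame(
      id = id, neuron_class = substr(id, 1, 5),
      ap_mm = ap, dv_mm = pos$y, side = side, birth_time = birth,
      x = pos$x, y = pos$y, z = pos$z,
      neuron_type = ntype, region = unit_region[unit_of],
      circuits = circuits, bilateral_partner = partner,
      stringsAsFactors = FALSE
    ))

    # pair weights
    T_last <- max(cfg3d$stage_times)
    e0 <- config$embryonic_window[1]
    earl <- pmin(pmax((T_last - birth) / (T_last - e0), 0), 1)
    ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    jj <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
    d <- sqrt((pos$x[ii] - pos$x[jj])^2 + (pos$y[ii] - pos$y[jj])^2 +
              (pos$z[ii] - pos$z[jj])^2)
    both_emb <- (birth[ii] < cfg3d$hatch_time) & (birth[jj] < cfg3d$hatch_time)
    w <- exp(-d / config$distance_decay) *
      exp(config$hub_early_bias * earl[ii] * earl[jj]) +
      config$long_range_early_bias * (d >= classifier$long_min & both_emb)
    if (sum(w > 0) < config$n_connections) {
      stop("only ", sum(w > 0), " neuron pairs have positive weight but ",
           config$n_connections, " connections requested; increase ",
           "`distance_decay` or reduce `n_connections`")
    }
    picked <- sample.int(length(w), config$n_connections, prob = w)

    m <- config$n_connections
    kind <- sample(KIND_LEVELS, m, replace = TRUE,
                   prob = c(config$gap_fraction,
                            1 - config$gap_fraction - config$combination_fraction,
                            config$combination_fraction))
    dir <- ifelse(kind == "chemical",
                  ifelse(runif(m) < config$chemical_bi_fraction, "bi", "uni"),
                  "bi")
    edges <- data.frame(pre = id[ii[picked]], post = id[jj[picked]],
                        synapse_kind = kind, directedness = dir,
                        stringsAsFactors = FALSE)

    truth <- list(
      neurons = data.frame(id = id, earliness = earl,
                           intended_hub = earl >= quantile(earl, 0.9),
                           stringsAsFactors = FALSE),
      pairs = data.frame(pre = id[ii[picked]], post = id[jj[picked]],
                         length_mm = d[picked],
                         length_class = classify_length(d[picked], classifier),
                         both_embryonic = both_emb[picked],
                         stringsAsFactors = FALSE),
      hub_early_bias = config$hub_early_bias,
      long_range_early_bias = config$long_range_early_bias,
      seed = config$seed
    )

    con <- connectome(neurons, edges, cfg3d,
                      provenance = sprintf("synthetic (seed %d)", config$seed))
    list(connectome = con, truth = truth)
  })
}

#' Write a synthetic connectome fixture to disk
#'
#' Emits `neurons.csv` and `edges.csv` in the loader dialect (reloads
#' round-trip exactly) plus, when planted truth is supplied, a
#' `truth.json` sidecar.
#'
#' @param con A `connectome`.
#' @param dir Output directory.
#' @param truth Optional planted-truth list from [generate_connectome()].
#' @return Invisibly, the file paths written.
#' @export
write_fixture <- function(con, dir, truth = NULL) {
  paths <- write_connectome(con, dir)
  if (!is.null(truth)) {
    tfile <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, tfile, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    paths <- c(paths, truth = tfile)
  }
  invisible(paths)
}
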