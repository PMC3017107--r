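#' Identity-shuffle null model
#'
#' Keeps the graph fixed (edge structure, synapse kinds, directedness — the
#' degree sequence is exactly preserved) and permutes whole neuron identity
#' bundles uniformly at random across the nodes. An identity bundle is
#' everything that ties a neuron to space and time: 2D and 3D position,
#' side, birth time, region, neuron type, class and circuit memberships.
#' Attributes are permuted together, never independently, so the coupling
#' between where a neuron sits and when it is born survives the shuffle;
#' only its assignment to a network node is randomized. Bilateral-partner
#' annotations are dropped (partnership is an identity-pair property that a
#' single-node permutation cannot preserve).
#'
#' @param con A `connectome`.
#' @param seed Integer RNG seed (same seed, same shuffle).
#' @return A `connectome` with permuted identities.
#' @export
shuffle_identities <- function(con, seed) {
  stopifnot(inherits(con, "connectome"))
  with_rng_seed(seed, {
    nn <- con$neurons
    perm <- sample.int(nrow(nn))
    bundle <- c("neuron_class", "ap_mm", "dv_mm", "side", "birth_time",
                "x", "y", "z", "neuron_type", "region", "circuits")
    nn[, bundle] <- nn[perm, bundle]
    nn$bilateral_partner <- NA_character_
    connectome(nn, con$connections, con$config,
               provenance = paste0(con$provenance, " [identity shuffle]"))
  })
}

#' Metric ensemble over identity shuffles
#'
#' Applies a scalar metric to `n_trials` independent identity shuffles of
#' the connectome and summarizes the trial values. Trial seeds are derived
#' deterministically from the master seed, so the whole ensemble is
#' reproducible. A metric that fails on some trial is recorded as missing
#' and the ensemble is flagged.
#'
#' @param metric A function `connectome -> single number`.
#' @param con A `connectome`.
#' @param n_trials Number of shuffled trials (default 20).
#' @param seed Master integer seed.
#' @param metric_name Label stored in the result.
#' @return A list of class `ensemble_result`: `metric_name`, `trial_values`,
#'   `n_trials`, `mean`, `sd` (sample, n-1 denominator), `seed`, `flagged`.
#' @export
ensemble <- function(metric, con, n_trials = 20, seed = 1L,
                     metric_name = deparse(substitute(metric))) {
  stopifnot(is.function(metric), inherits(con, "connectome"), n_trials >= 1)
  trial_seeds <- with_rng_seed(seed,
                               sample.int(.Machine$integer.max, n_trials))
  vals <- vapply(trial_seeds, function(s) {
    out <- tryCatch(metric(shuffle_identities(con, s)),
                    error = function(e) NA_real_)
    if (length(out) != 1L || !is.numeric(out)) NA_real_ else as.numeric(out)
  }, numeric(1))
  flagged <- anyNA(vals)
  if (flagged) {
    warning("metric failed on ", sum(is.na(vals)), " of ", n_trials,
            " trials; ensemble flagged")
  }
  structure(
    list(metric_name = metric_name, trial_values = vals,
         n_trials = n_trials, mean = mean(vals, na.rm = TRUE),
         sd = sd(vals[!is.na(vals)]), seed = seed, flagged = flagged),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("Ensemble '", x$metric_name, "': mean ", signif(x$mean, 4),
      " (sd ", signif(x$sd, 4), ") over ", x$n_trials, " trials",
      if (x$flagged) " [FLAGGED: failed trials]" else "", "\n", sep = "")
  invisible(x)
}

#' One-sample t-test of an ensemble against an observed value
#'
#' Tests whether the null-ensemble trial values are consistent with the
#' observed statistic: `t = (observed - mean) / (sd / sqrt(n))` with
#' `n - 1` degrees of freedom. The orientation (ensemble sample vs observed
#' reference) only flips the sign of t; `|t|` and the two-sided p are
#' identical either way.
#'
#' @param observed The observed scalar.
#' @param ens An `ensemble_result` (or anything with `mean`, `sd`,
#'   `n_trials`).
#' @param sides `"two"` (default) or `"one"` (one-sided in the direction of
#'   the observed deviation).
#' @return Named numeric vector `c(t, df, p)`.
#' @examples
#' ens <- list(mean = 2, sd = 1, n_trials = 3)
#' one_sample_ttest(4, ens)  # t = 3.464, df = 2
#' @export
one_sample_ttest <- function(observed, ens, sides = c("two", "one")) {
  sides <- match.arg(sides)
  stopifnot(is.numeric(observed), length(observed) == 1L,
            ens$n_trials >= 2)
  if (!is.finite(ens$sd) || ens$sd <= 0) {
    stop("degenerate ensemble: sd must be positive")
  }
  df <- ens$n_trials - 1
  t <- (observed - ens$mean) / (ens$sd / sqrt(ens$n_trials))
  p <- if (sides == "two") 2 * pt(-abs(t), df) else pt(-abs(t), df)
  c(t = t, df = df, p = p)
}

#' Erdős–Rényi G(n, m) random connectome
#'
#' Exactly `n_links` distinct unordered node pairs chosen uniformly without
#' replacement; no self-loops. This is the topology-only baseline that
#' matches a network on node and link counts but not on its degree
#' distribution. Nodes carry no spatial or temporal annotation; links are
#' bidirectional.
#'
#' @param n_nodes Number of nodes.
#' @param n_links Number of links, `0 <= n_links <= n_nodes*(n_nodes-1)/2`.
#' @param seed Integer RNG seed.
#' @return A topology-only `connectome`.
#' @export
erdos_renyi <- function(n_nodes, n_links, seed) {
  stopifnot(n_nodes >= 1)
  max_links <- n_nodes * (n_nodes - 1) / 2
  if (n_links < 0 || n_links > max_links) {
    stop("`n_links` must be between 0 and n_nodes*(n_nodes-1)/2 = ",
         max_links)
  }
  ids <- sprintf("v%03d", seq_len(n_nodes))
  with_rng_seed(seed, {
    g <- igraph::sample_gnm(n_nodes, n_links, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- data.frame(pre = ids[el[, 1]], post = ids[el[, 2]],
                        synapse_kind = rep("chemical", nrow(el)),
                        directedness = rep("bi", nrow(el)),
                        stringsAsFactors = FALSE)
    neurons <- data.frame(id = ids, birth_time = 0,
                          stringsAsFactors = FALSE)
    connectome(neurons, edges,
               provenance = sprintf("Erdos-Renyi G(%d, %d), seed %d",
                                    n_nodes, n_links, seed))
  })
}
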