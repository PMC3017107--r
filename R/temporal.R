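#' Birth-time differences of connected neurons
#'
#' One value `|birth(pre) - birth(post)|` per link (links counted once,
#' regardless of directedness). The distribution of these differences
#' measures the time window available for the two partners to meet.
#'
#' @param con A `connectome`.
#' @return Numeric vector of absolute birth-time differences (minutes), one
#'   per connection; empty for an edgeless connectome.
#' @export
birth_time_differences <- function(con) {
  stopifnot(inherits(con, "connectome"))
  bt <- setNames(con$neurons$birth_time, con$neurons$id)
  abs(bt[con$connections$pre] - bt[con$connections$post])
}

#' Equal-width histogram with per-bin means
#'
#' Bins `values` into `n_bins` equal-width bins spanning `[0, max(values)]`;
#' all bins are half-open `[lo, hi)` except the last, which is right-closed.
#' Besides counts, the mean of the in-bin values is reported per bin (NA for
#' empty bins, so empty bins cannot masquerade as zero-mean bins). If every
#' value is 0 the histogram degenerates to a single `[0, 0]` bin.
#'
#' @param values Non-empty numeric vector of non-negative values.
#' @param n_bins Number of bins (default 10).
#' @return A list of class `binned_histogram` with `bin_edges` (length
#'   `n_bins + 1`), `counts` and `bin_means`.
#' @export
binned_histogram <- function(values, n_bins = 10) {
  stopifnot(length(values) > 0, n_bins >= 1, all(is.finite(values)),
            all(values >= 0))
  mx <- max(values)
  if (mx == 0) {
    return(structure(list(bin_edges = c(0, 0), counts = length(values),
                          bin_means = 0), class = "binned_histogram"))
  }
  edges <- seq(0, mx, length.out = n_bins + 1)
  idx <- pmin(findInterval(values, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  means <- rep(NA_real_, n_bins)
  occupied <- sort(unique(idx))
  means[occupied] <- vapply(occupied, function(b) mean(values[idx == b]),
                            numeric(1))
  structure(list(bin_edges = edges, counts = counts, bin_means = means),
            class = "binned_histogram")
}

#' @export
print.binned_histogram <- function(x, ...) {
  df <- data.frame(lo = x$bin_edges[-length(x$bin_edges)],
                   hi = x$bin_edges[-1], count = x$counts,
                   bin_mean = x$bin_means)
  print(df, row.names = FALSE)
  invisible(x)
}

is_embryonic <- function(con, hatch_time) {
  setNames(con$neurons$birth_time < hatch_time, con$neurons$id)
}

#' Within-phase connection fractions
#'
#' Neurons divide into the embryonic phase (`birth_time < hatch_time`) and
#' the post-embryonic phase (`birth_time >= hatch_time`). For each phase the
#' fraction of connections its neurons make that stay within the phase is
#' reported. In the default endpoint-weighted method, every connection
#' contributes once per endpoint in the phase, and the fraction is the
#' proportion of those contributions whose partner is also in the phase —
#' this reads the fraction as "of the connections made by phase-X neurons,
#' how many are to phase-X partners". The `"link"` method instead counts
#' each connection once: within-phase links over links touching the phase.
#'
#' @param con A `connectome`.
#' @param hatch_time Hatching time in minutes (default from the connectome's
#'   configuration).
#' @param method `"endpoint"` (default) or `"link"`.
#' @return Named numeric vector `c(embryonic_within, postembryonic_within)`;
#'   a phase with no neurons yields `NA` for its fraction.
#' @export
phase_fractions <- function(con, hatch_time = con$config$hatch_time,
                            method = c("endpoint", "link")) {
  stopifnot(inherits(con, "connectome"))
  method <- match.arg(method)
  emb <- is_embryonic(con, hatch_time)
  e <- con$connections
  frac_for <- function(in_phase) {
    if (!any(in_phase)) return(NA_real_)
    p <- in_phase[e$pre]; q <- in_phase[e$post]
    if (method == "endpoint") {
      contrib <- sum(p) + sum(q)            # endpoints in phase
      within <- sum(p & q) * 2              # both endpoints in phase
    } else {
      contrib <- sum(p | q)
      within <- sum(p & q)
    }
    if (contrib == 0) return(NA_real_)
    within / contrib
  }
  c(embryonic_within = frac_for(emb),
    postembryonic_within = frac_for(!emb))
}

#' Pearson correlation of degree with birth time
#'
#' An early-born-hub effect shows up as a negative correlation: neurons born
#' earlier have had longer to accumulate connections.
#'
#' @param con A `connectome` with at least 3 neurons.
#' @return Pearson's r.
#' @export
degree_birth_correlation <- function(con) {
  stopifnot(inherits(con, "connectome"))
  if (nrow(con$neurons) < 3) stop("need at least 3 neurons")
  deg <- neuron_degree(con)
  bt <- con$neurons$birth_time
  if (sd(deg) == 0) stop("degree has zero variance")
  if (sd(bt) == 0) stop("birth time has zero variance")
  cor(as.numeric(deg), bt)
}

#' Hub report: high-degree neurons and their birth phases
#'
#' Lists the neurons whose degree meets the threshold, the fraction of them
#' born before hatching, and for each the number of "late-forming
#' neighbours" — connected partners born at or after `hatch_time`.
#'
#' @param con A `connectome`.
#' @param degree_threshold Non-negative integer degree cutoff.
#' @param hatch_time Hatching time in minutes.
#' @param comparator `">="` (degree at or above threshold, default) or
#'   `">"` (strictly above); reported thresholds in the source literature
#'   mix both readings, so the comparator is explicit.
#' @return A list of class `hub_report`: `degree_threshold`, `comparator`,
#'   `n_at_or_above`, `fraction_born_before`, and `neurons` (a data frame
#'   with `id`, `degree`, `birth_time`, `n_late_neighbors`).
#' @export
hub_report <- function(con, degree_threshold,
                       hatch_time = con$config$hatch_time,
                       comparator = c(">=", ">")) {
  stopifnot(inherits(con, "connectome"), degree_threshold >= 0)
  comparator <- match.arg(comparator)
  deg <- neuron_degree(con)
  sel <- if (comparator == ">=") deg >= degree_threshold
         else deg > degree_threshold
  ids <- names(deg)[sel]
  bt <- setNames(con$neurons$birth_time, con$neurons$id)
  e <- con$connections
  late <- bt >= hatch_time
  n_late <- vapply(ids, function(id) {
    nbr <- c(e$post[e$pre == id], e$pre[e$post == id])
    sum(late[nbr])
  }, integer(1))
  df <- data.frame(id = ids, degree = as.integer(deg[ids]),
                   birth_time = unname(bt[ids]),
                   n_late_neighbors = unname(n_late),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$degree, df$id), , drop = FALSE]
  rownames(df) <- NULL
  structure(
    list(degree_threshold = degree_threshold, comparator = comparator,
         n_at_or_above = nrow(df),
         fraction_born_before = if (nrow(df) > 0)
           mean(df$birth_time < hatch_time) else NA_real_,
         neurons = df),
    class = "hub_report"
  )
}

#' @export
print.hub_report <- function(x, ...) {
  cat("Hub report (degree ", x$comparator, " ", x$degree_threshold, "): ",
      x$n_at_or_above, " neuron(s), ",
      if (is.na(x$fraction_born_before)) "no" else
        sprintf("%.1f%%", 100 * x$fraction_born_before),
      " born before hatching\n", sep = "")
  invisible(x)
}

#' Birth-time differences of bilateral pairs
#'
#' Bilateral left/right mirror pairs (e.g. AVAL/AVAR) are expected to be
#' born nearly simultaneously; this reports the within-pair birth-time
#' difference for every annotated pair. Asymmetric annotations (A names B
#' but B does not name A) are an error.
#'
#' @param con A `connectome`.
#' @return Data frame with one row per unordered pair: `id_a`, `id_b`,
#'   `delta_min`.
#' @export
bilateral_timing <- function(con) {
  stopifnot(inherits(con, "connectome"))
  nn <- con$neurons
  has <- !is.na(nn$bilateral_partner) & nzchar(nn$bilateral_partner)
  empty <- data.frame(id_a = character(), id_b = character(),
                      delta_min = numeric())
  if (!any(has)) return(empty)
  partner <- setNames(nn$bilateral_partner, nn$id)
  for (id in nn$id[has]) {
    p <- partner[[id]]
    if (!p %in% nn$id || is.na(partner[p]) || !nzchar(partner[p]) ||
        partner[[p]] != id) {
      stop("asymmetric bilateral annotation between '", id, "' and '", p, "'")
    }
  }
  bt <- setNames(nn$birth_time, nn$id)
  a <- nn$id[has]; b <- partner[a]
  first <- a < b
  out <- data.frame(id_a = a[first], id_b = unname(b[first]),
                    delta_min = abs(bt[a[first]] - bt[b[first]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cumulative growth curves per neuron type
#'
#' For each neuron type (`sensory`, `inter`, `motor`) and additionally for
#' exclusive motor neurons (motor and nothing else), the percentage of that
#' type's adult count born by each stage time. A polymodal neuron (e.g.
#' motor + inter) counts in each of its types but not in the exclusive-motor
#' curve.
#'
#' @param con A `connectome` with `neuron_type` populated.
#' @param stage_times Stage cutoffs in minutes (default from the
#'   connectome's configuration).
#' @return Data frame with columns `stage_time` and one percentage column
#'   per type; types with zero adult members are omitted with a warning.
#' @export
type_growth_curves <- function(con, stage_times = con$config$stage_times) {
  stopifnot(inherits(con, "connectome"))
  types <- split_set(con$neurons$neuron_type)
  bt <- con$neurons$birth_time
  member <- list(
    sensory = vapply(types, function(v) "sensory" %in% v, logical(1)),
    inter = vapply(types, function(v) "inter" %in% v, logical(1)),
    motor = vapply(types, function(v) "motor" %in% v, logical(1)),
    exclusive_motor = vapply(types, function(v) identical(v, "motor"),
                             logical(1))
  )
  out <- data.frame(stage_time = stage_times)
  for (ty in names(member)) {
    sel <- member[[ty]]
    if (!any(sel)) {
      warning("no adult neurons of type '", ty, "'; curve omitted")
      next
    }
    out[[ty]] <- vapply(stage_times,
                        function(t) 100 * sum(bt[sel] <= t) / sum(sel),
                        numeric(1))
  }
  out
}
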