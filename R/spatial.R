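#' Soma-to-soma connection lengths
#'
#' The length of a connection is the Euclidean distance between the two
#' soma positions in 3D — not an axon trajectory length, and independent of
#' where along the wire the synapse sits.
#'
#' @param con A `connectome` with `x`, `y`, `z` populated.
#' @return Numeric vector of lengths (mm), one per connection, in table
#'   order.
#' @export
connection_lengths <- function(con) {
  stopifnot(inherits(con, "connectome"))
  nn <- con$neurons
  miss <- nn$id[!is.finite(nn$x) | !is.finite(nn$y) | !is.finite(nn$z)]
  e <- con$connections
  used <- union(e$pre, e$post)
  bad <- intersect(miss, used)
  if (length(bad) > 0L) {
    stop("missing 3D position for neuron(s): ", paste(bad, collapse = ", "))
  }
  idx <- setNames(seq_len(nrow(nn)), nn$id)
  i <- idx[e$pre]; j <- idx[e$post]
  sqrt((nn$x[i] - nn$x[j])^2 + (nn$y[i] - nn$y[j])^2 + (nn$z[i] - nn$z[j])^2)
}

#' Length of a single connection
#'
#' @param con A `connectome`.
#' @param pre,post Neuron ids of the two endpoints.
#' @return Length in mm (symmetric in its endpoints).
#' @export
connection_length <- function(con, pre, post) {
  stopifnot(inherits(con, "connectome"))
  nn <- con$neurons
  for (id in c(pre, post)) {
    row <- nn[nn$id == id, , drop = FALSE]
    if (nrow(row) == 0L) stop("unknown neuron id: ", id)
    if (!all(is.finite(c(row$x, row$y, row$z)))) {
      stop("missing 3D position for neuron: ", id)
    }
  }
  a <- nn[nn$id == pre, ]; b <- nn[nn$id == post, ]
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
}

#' Classify a connection length as short, medium or long
#'
#' With the default classifier: short means `d < 0.36` mm, long means
#' `d >= 0.84` mm, medium is the band between. Class bins are half-open
#' `[lo, hi)`, so the long boundary itself is long. Lengths beyond the
#' binned range are long (the classifier is total on `d >= 0`).
#'
#' @param d Numeric vector of non-negative lengths (mm).
#' @param classifier A [length_classifier()].
#' @return Character vector in `c("short", "medium", "long")`.
#' @examples
#' classify_length(c(0.20, 0.50, 1.00))
#' @export
classify_length <- function(d, classifier = length_classifier()) {
  stopifnot(inherits(classifier, "length_classifier"))
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("lengths must be finite and non-negative")
  }
  ifelse(d < classifier$short_max, "short",
         ifelse(d >= classifier$long_min, "long", "medium"))
}

#' Per-class connection-pair appearance curves
#'
#' For each stage time `t` and length class `c`, the percentage of the
#' adult class-`c` connection pairs whose two endpoints have both been born
#' by `t`. Lengths are always the adult soma-to-soma lengths; presence at a
#' stage says only that both neurons exist, not that the synapse has formed.
#'
#' @param con The adult `connectome` (positions and birth times populated).
#' @param stage_times Stage cutoffs in minutes.
#' @param classifier A [length_classifier()].
#' @return Data frame with columns `stage_time`, then one percentage column
#'   per length class (plus `all`); classes with zero adult pairs are
#'   omitted with a warning.
#' @export
appearance_curves <- function(con, stage_times = con$config$stage_times,
                              classifier = length_classifier()) {
  stopifnot(inherits(con, "connectome"))
  len <- connection_lengths(con)
  cls <- classify_length(len, classifier)
  bt <- setNames(con$neurons$birth_time, con$neurons$id)
  e <- con$connections
  born_by <- function(t) bt[e$pre] <= t & bt[e$post] <= t
  out <- data.frame(stage_time = stage_times)
  for (cl in c("short", "medium", "long")) {
    sel <- cls == cl
    if (!any(sel)) {
      warning("no adult connection pairs in class '", cl, "'; curve omitted")
      next
    }
    out[[cl]] <- vapply(stage_times,
                        function(t) 100 * sum(born_by(t) & sel) / sum(sel),
                        numeric(1))
  }
  out$all <- vapply(stage_times,
                    function(t) 100 * sum(born_by(t)) / nrow(e), numeric(1))
  out
}

#' Synapse-kind by length-class by phase contingency table
#'
#' Counts connections by synapse kind (gap / chemical / combination),
#' length class (short / medium / long) and phase ("early" = both endpoints
#' born before `hatch_time`, "late" otherwise), with derived percentages.
#' The electrically-coupled aggregate counts gap plus combination junctions.
#'
#' @param con A `connectome`.
#' @param classifier A [length_classifier()].
#' @param hatch_time Hatching time in minutes.
#' @return A list of class `synapse_breakdown` with `counts` (the full
#'   contingency data frame), `by_class` (per length class: counts and the
#'   electrically-coupled percentage) and `early_fraction_by_coupling`
#'   (fraction of electrically vs chemically coupled links that are early).
#' @export
synapse_breakdown <- function(con, classifier = length_classifier(),
                              hatch_time = con$config$hatch_time) {
  stopifnot(inherits(con, "connectome"))
  e <- con$connections
  len <- connection_lengths(con)
  cls <- factor(classify_length(len, classifier),
                levels = c("short", "medium", "long"))
  bt <- setNames(con$neurons$birth_time, con$neurons$id)
  early <- factor(ifelse(bt[e$pre] < hatch_time & bt[e$post] < hatch_time,
                         "early", "late"), levels = c("early", "late"))
  kind <- factor(e$synapse_kind, levels = KIND_LEVELS)
  counts <- as.data.frame(table(synapse_kind = kind, length_class = cls,
                                phase = early), stringsAsFactors = FALSE)
  names(counts)[names(counts) == "Freq"] <- "n"

  coupled <- kind %in% c("gap", "combination")
  by_class <- do.call(rbind, lapply(levels(cls), function(cl) {
    sel <- cls == cl
    data.frame(length_class = cl, n = sum(sel),
               n_electrical = sum(sel & coupled),
               pct_electrical = if (any(sel))
                 100 * sum(sel & coupled) / sum(sel) else NA_real_)
  }))
  early_frac <- c(
    electrical = if (any(coupled))
      mean(early[coupled] == "early") else NA_real_,
    chemical = if (any(!coupled))
      mean(early[!coupled] == "early") else NA_real_
  )
  structure(list(counts = counts, by_class = by_class,
                 early_fraction_by_coupling = early_frac),
            class = "synapse_breakdown")
}

#' @export
print.synapse_breakdown <- function(x, ...) {
  cat("Synapse breakdown (kind x length class x early/late)\n")
  print(x$by_class, row.names = FALSE)
  invisible(x)
}

#' Within-region connection fractions
#'
#' For each body region (head / body / tail), the endpoint-weighted
#' fraction of connections made by that region's neurons that stay within
#' the region (same weighting as [phase_fractions()]); a `"link"` method
#' counts each connection once instead.
#'
#' @param con A `connectome` with `region` populated.
#' @param method `"endpoint"` (default) or `"link"`.
#' @return Named numeric vector of within-region fractions; regions with no
#'   neurons are omitted.
#' @export
region_connectivity <- function(con, method = c("endpoint", "link")) {
  stopifnot(inherits(con, "connectome"))
  method <- match.arg(method)
  reg <- setNames(con$neurons$region, con$neurons$id)
  e <- con$connections
  present <- intersect(c("head", "body", "tail"), unique(reg[!is.na(reg)]))
  out <- vapply(present, function(R) {
    p <- !is.na(reg[e$pre]) & reg[e$pre] == R
    q <- !is.na(reg[e$post]) & reg[e$post] == R
    if (method == "endpoint") {
      contrib <- sum(p) + sum(q); within <- 2 * sum(p & q)
    } else {
      contrib <- sum(p | q); within <- sum(p & q)
    }
    if (contrib == 0) NA_real_ else within / contrib
  }, numeric(1))
  out
}

#' Per-circuit connection-pair appearance curves
#'
#' A connection pair belongs to every functional circuit either endpoint
#' belongs to (a pair spanning two circuits counts in both). For each
#' circuit, the percentage of its adult pair count present at each stage.
#'
#' @param con A `connectome` with `circuits` populated
#'   (semicolon-separated).
#' @param stage_times Stage cutoffs in minutes.
#' @return Data frame with `stage_time` and one percentage column per
#'   circuit.
#' @export
circuit_curves <- function(con, stage_times = con$config$stage_times) {
  stopifnot(inherits(con, "connectome"))
  circ <- split_set(con$neurons$circuits)
  names(circ) <- con$neurons$id
  if (any(lengths(circ) == 0)) {
    warning(sum(lengths(circ) == 0),
            " neuron(s) with empty circuit set contribute to no circuit")
  }
  e <- con$connections
  bt <- setNames(con$neurons$birth_time, con$neurons$id)
  pair_circ <- mapply(function(a, b) unique(c(circ[[a]], circ[[b]])),
                      e$pre, e$post, SIMPLIFY = FALSE)
  all_circuits <- sort(unique(unlist(pair_circ)))
  born <- outer(pmax(bt[e$pre], bt[e$post]), stage_times, `<=`)
  out <- data.frame(stage_time = stage_times)
  for (cc in all_circuits) {
    sel <- vapply(pair_circ, function(v) cc %in% v, logical(1))
    out[[cc]] <- 100 * colSums(born[sel, , drop = FALSE]) / sum(sel)
  }
  out
}

#' Correlation of degree with short/long connection proportions
#'
#' Per neuron, the proportion of its connections in the short (resp. long)
#' length class; returns the Pearson correlation of degree against each
#' proportion over neurons with at least one connection. Near-zero values
#' mean hubs are not preferentially wired at any particular length scale.
#'
#' @param con A `connectome` (>= 3 connected neurons).
#' @param classifier A [length_classifier()].
#' @return Named numeric vector `c(r_short, r_long)`.
#' @export
degree_length_correlations <- function(con,
                                       classifier = length_classifier()) {
  stopifnot(inherits(con, "connectome"))
  len <- connection_lengths(con)
  cls <- classify_length(len, classifier)
  e <- con$connections
  deg <- neuron_degree(con)
  ids <- names(deg)[deg > 0]
  if (length(ids) < 3) stop("need at least 3 connected neurons")
  prop <- function(cl) {
    vapply(ids, function(id) {
      inc <- e$pre == id | e$post == id
      mean(cls[inc] == cl)
    }, numeric(1))
  }
  d <- as.numeric(deg[ids])
  if (sd(d) == 0) stop("degree has zero variance")
  ps <- prop("short"); pl <- prop("long")
  if (sd(ps) == 0) stop("short-connection proportion has zero variance")
  if (sd(pl) == 0) stop("long-connection proportion has zero variance")
  c(r_short = cor(d, ps), r_long = cor(d, pl))
}
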