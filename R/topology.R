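#' Clustering coefficient (Watts–Strogatz)
#'
#' Mean over all nodes of the local clustering coefficient — the fraction
#' of a node's neighbour pairs that are themselves connected — computed on
#' the symmetrized simple undirected graph (a link exists if any arc
#' exists). Nodes of degree < 2 contribute 0 to the average (they are not
#' excluded); this is one of the two common conventions and is fixed here
#' because it changes C.
#'
#' @param con A `connectome` (or an `igraph` graph, taken as-is).
#' @return C in `[0, 1]`.
#' @export
clustering_coefficient <- function(con) {
  g <- if (inherits(con, "igraph")) con else as_igraph(con, "undirected")
  if (igraph::vcount(g) == 0) stop("empty graph")
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Characteristic path length
#'
#' Mean shortest-path length over all connected ordered node pairs within
#' the largest connected component of the symmetrized undirected graph.
#' Early-stage networks can be disconnected; restricting to the largest
#' component keeps L finite, and the component coverage is available via
#' [small_world_series()] so the approximation stays visible.
#'
#' @param con A `connectome` (or an `igraph` graph) with at least one edge.
#' @return L >= 1.
#' @export
characteristic_path_length <- function(con) {
  g <- if (inherits(con, "igraph")) con else as_igraph(con, "undirected")
  if (igraph::ecount(g) == 0) stop("edgeless graph")
  comp <- igraph::components(g)
  giant <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == giant))
  igraph::mean_distance(sub, directed = FALSE)
}

#' Per-stage small-world report against Erdős–Rényi baselines
#'
#' For each developmental stage, computes the clustering coefficient C and
#' characteristic path length L of the staged network and compares them
#' with ensemble means over `n_random` Erdős–Rényi G(n, m) graphs matched
#' on node and link counts. A network is conventionally called small-world
#' when C/C_rand exceeds ~2 while L/L_rand stays near 1.
#'
#' @param con The adult `connectome`.
#' @param stage_times Stage cutoffs in minutes.
#' @param n_random Number of random baseline graphs per stage (default 20).
#' @param seed Master integer seed for the baseline ensembles.
#' @return Data frame with one row per stage: `stage_time`, `n_nodes`,
#'   `n_links`, `giant_fraction` (share of present nodes in the largest
#'   component), `C`, `L`, `C_rand`, `L_rand`, `ratio_C`, `ratio_L`. Stages
#'   with no edges are flagged with NA metrics.
#' @export
small_world_series <- function(con, stage_times = con$config$stage_times,
                               n_random = 20, seed = 1L) {
  stopifnot(inherits(con, "connectome"), n_random >= 1)
  stage_seeds <- with_rng_seed(seed,
    matrix(sample.int(.Machine$integer.max, length(stage_times) * n_random),
           nrow = length(stage_times)))
  rows <- lapply(seq_along(stage_times), function(si) {
    t <- stage_times[si]
    st <- stage_network(con, t)
    g <- as_igraph(st, "undirected")
    n <- igraph::vcount(g)
    m <- igraph::ecount(g)
    base <- data.frame(stage_time = t, n_nodes = n, n_links = m,
                       giant_fraction = NA_real_, C = NA_real_, L = NA_real_,
                       C_rand = NA_real_, L_rand = NA_real_,
                       ratio_C = NA_real_, ratio_L = NA_real_)
    if (m == 0) return(base)
    comp <- igraph::components(g)
    base$giant_fraction <- max(comp$csize) / n
    base$C <- clustering_coefficient(g)
    base$L <- characteristic_path_length(g)
    rand <- vapply(seq_len(n_random), function(k) {
      rg <- erdos_renyi(n, m, stage_seeds[si, k])
      c(clustering_coefficient(rg), characteristic_path_length(rg))
    }, numeric(2))
    base$C_rand <- mean(rand[1, ])
    base$L_rand <- mean(rand[2, ])
    base$ratio_C <- if (base$C_rand > 0) base$C / base$C_rand else NA_real_
    base$ratio_L <- if (base$L_rand > 0) base$L / base$L_rand else NA_real_
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
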