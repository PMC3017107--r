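# In-code fixtures and independent brute-force oracles.

# Small hand-built connectome: 5 neurons (2 bilateral pairs + 1 midline),
# mixed synapse kinds, births straddling hatching.
toy_connectome <- function(config = spatial_config()) {
  neurons <- data.frame(
    id = c("AL", "AR", "BL", "BR", "M"),
    neuron_class = c("A", "A", "B", "B", "M"),
    ap_mm = c(0.10, 0.10, 0.50, 0.50, 1.00),
    dv_mm = c(0.00, 0.00, 0.03, 0.03, 0.00),
    side = c("left", "right", "left", "right", "midline"),
    birth_time = c(400, 406, 500, 505, 900),
    neuron_type = c("sensory", "sensory", "inter", "inter", "motor"),
    region = c("head", "head", "body", "body", "tail"),
    circuits = c("X", "X", "X;Y", "Y", "Y"),
    bilateral_partner = c("AR", "AL", "BR", "BL", NA),
    stringsAsFactors = FALSE
  )
  pos <- lift_to_3d(neurons$ap_mm, neurons$dv_mm, neurons$side, config)
  neurons$x <- pos$x; neurons$y <- pos$y; neurons$z <- pos$z
  edges <- data.frame(
    pre = c("AL", "AL", "BL", "AR"),
    post = c("AR", "BL", "M", "M"),
    synapse_kind = c("gap", "chemical", "chemical", "combination"),
    directedness = c("bi", "uni", "uni", "bi"),
    stringsAsFactors = FALSE
  )
  connectome(neurons, edges, config)
}

# Bare connectome from an edge list and birth times; positions optional.
mini_connectome <- function(edges_df, birth, pos = NULL,
                            config = spatial_config()) {
  ids <- names(birth)
  neurons <- data.frame(id = ids, birth_time = as.numeric(birth),
                        stringsAsFactors = FALSE)
  if (!is.null(pos)) {
    neurons$x <- pos[ids, 1]; neurons$y <- pos[ids, 2]; neurons$z <- pos[ids, 3]
  }
  if (!("synapse_kind" %in% names(edges_df))) {
    edges_df$synapse_kind <- "chemical"
  }
  if (!("directedness" %in% names(edges_df))) edges_df$directedness <- "uni"
  connectome(neurons, edges_df, config)
}

pair_ids <- function(con) paste(con$connections$pre, con$connections$post)

# symmetric 0/1 adjacency matrix of a connectome's undirected graph
adjacency_of <- function(con) {
  ids <- con$neurons$id
  n <- length(ids)
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  e <- con$connections
  for (k in seq_len(nrow(e))) {
    A[e$pre[k], e$post[k]] <- 1L
    A[e$post[k], e$pre[k]] <- 1L
  }
  A
}

# O(n^3) clustering coefficient: triangles through each node over k(k-1)/2,
# nodes with k < 2 contribute 0
bf_clustering <- function(A) {
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(v) {
    nbr <- which(A[v, ] == 1L)
    k <- length(nbr)
    if (k < 2) return(0)
    tri <- 0L
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) tri <- tri + A[nbr[i], nbr[j]]
    }
    tri / (k * (k - 1) / 2)
  }, numeric(1))
  mean(vals)
}

# Floyd-Warshall characteristic path length over the largest component
bf_path_length <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1L] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  comp_of <- integer(n)
  cc <- 0L
  for (v in seq_len(n)) {
    if (comp_of[v] == 0L) {
      cc <- cc + 1L
      comp_of[is.finite(D[v, ])] <- cc
    }
  }
  sizes <- tabulate(comp_of)
  members <- which(comp_of == which.max(sizes))
  if (length(members) < 2) stop("largest component has no pairs")
  sub <- D[members, members]
  mean(sub[row(sub) != col(sub)])
}
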