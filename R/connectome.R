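#' @importFrom stats cor pt sd setNames quantile median runif
#' @importFrom utils read.csv write.csv
NULL

SIDE_LEVELS <- c("left", "right", "midline")
KIND_LEVELS <- c("gap", "chemical", "combination")
NEURON_COLS <- c("id", "neuron_class", "ap_mm", "dv_mm", "side", "birth_time",
                 "x", "y", "z", "neuron_type", "region", "circuits",
                 "bilateral_partner")

#' Lift 2D soma positions onto the cylindrical body model
#'
#' The worm body is modelled as a cylinder of radius `r` around the
#' anterior-posterior axis. A soma with anterior-posterior coordinate `ap`
#' and dorsoventral coordinate `dv` (both mm) lies on the circular cross
#' section at `ap`, so its third coordinate satisfies `z^2 = r^2 - dv^2`.
#' Left-side neurons take the positive root, right-side neurons the negative
#' root, and neurons on the dorsal or ventral midline have `z = 0` by
#' construction (forced for `side = "midline"`).
#'
#' `|dv|` values exceeding the radius by at most 1e-6 mm (digitization
#' noise) are clamped silently; larger excesses are clamped to the radius
#' with a warning. In both cases the clamped neuron sits on the dorsal or
#' ventral line, so `z = 0`.
#'
#' @param ap,dv Numeric vectors of anterior-posterior and dorsoventral
#'   coordinates (mm).
#' @param side Character vector in `c("left", "right", "midline")`, recycled
#'   if length 1.
#' @param config A [spatial_config()].
#' @return A data frame with columns `x`, `y`, `z` (mm): `x = ap`, `y = dv`.
#' @examples
#' lift_to_3d(0.1, 0.03, "right")  # z = -sqrt(0.05^2 - 0.03^2) = -0.04
#' @export
lift_to_3d <- function(ap, dv, side, config = spatial_config()) {
  stopifnot(inherits(config, "spatial_config"))
  n <- length(ap)
  if (length(dv) != n) stop("`ap` and `dv` must have equal length")
  if (length(side) == 1L) side <- rep(side, n)
  if (length(side) != n) stop("`side` must have length 1 or length(ap)")
  if (!all(side %in% SIDE_LEVELS)) {
    stop("`side` values must be one of: ", paste(SIDE_LEVELS, collapse = ", "))
  }
  if (anyNA(ap) || anyNA(dv) || any(!is.finite(ap)) || any(!is.finite(dv))) {
    stop("non-finite coordinate passed to lift_to_3d()")
  }
  r <- config$body_radius
  excess <- abs(dv) - r
  if (any(excess > 1e-6)) {
    warning(sum(excess > 1e-6),
            " dorsoventral coordinate(s) exceed the body radius by more ",
            "than 1e-6 mm; clamped to the radius (z = 0)")
  }
  dv_cl <- pmin(pmax(dv, -r), r)
  zmag <- sqrt(pmax(r^2 - dv_cl^2, 0))
  z <- ifelse(side == "left", zmag, ifelse(side == "right", -zmag, 0))
  data.frame(x = ap, y = dv_cl, z = z)
}

normalize_neurons <- function(neurons) {
  n <- nrow(neurons)
  for (col in setdiff(NEURON_COLS, names(neurons))) {
    neurons[[col]] <- if (col %in% c("ap_mm", "dv_mm", "birth_time",
                                     "x", "y", "z")) rep(NA_real_, n)
                      else rep(NA_character_, n)
  }
  chr <- c("id", "neuron_class", "side", "neuron_type", "region", "circuits",
           "bilateral_partner")
  for (col in chr) neurons[[col]] <- as.character(neurons[[col]])
  # canonical empties: annotation sets are "", partner links are NA
  for (col in c("neuron_class", "neuron_type", "region", "circuits")) {
    neurons[[col]][is.na(neurons[[col]])] <- ""
  }
  bp <- neurons$bilateral_partner
  neurons$bilateral_partner[!is.na(bp) & !nzchar(bp)] <- NA_character_
  neurons[, NEURON_COLS, drop = FALSE]
}

#' Construct a validated connectome
#'
#' The container every analysis consumes: an annotated neuron table, a link
#' table, and the spatial configuration. Validation enforces that every
#' link endpoint is a known neuron, that there are no self-loops, that no
#' unordered neuron pair appears twice, and that gap and combination
#' junctions are bidirectional. Links are stored once per neuron pair;
#' bidirectional links are expanded to two arcs only inside degree and
#' topology computations.
#'
#' @param neurons Data frame with at least columns `id`, `birth_time`; the
#'   full column set is `id`, `neuron_class`, `ap_mm`, `dv_mm`, `side`,
#'   `birth_time`, `x`, `y`, `z`, `neuron_type`, `region`, `circuits`,
#'   `bilateral_partner`. `neuron_type` and `circuits` are
#'   semicolon-separated sets.
#' @param connections Data frame with columns `pre`, `post`, `synapse_kind`
#'   (`"gap"`, `"chemical"` or `"combination"`) and `directedness` (`"uni"`
#'   or `"bi"`).
#' @param config A [spatial_config()].
#' @param provenance Free-text metadata string.
#' @return An object of class `connectome`.
#' @export
connectome <- function(neurons, connections, config = spatial_config(),
                       provenance = "") {
  stopifnot(is.data.frame(neurons), is.data.frame(connections),
            inherits(config, "spatial_config"))
  neurons <- normalize_neurons(as.data.frame(neurons))
  if (anyDuplicated(neurons$id)) {
    dup <- unique(neurons$id[duplicated(neurons$id)])
    stop("duplicate neuron id(s): ", paste(dup, collapse = ", "))
  }
  if (nrow(connections) == 0L) {
    connections <- data.frame(pre = character(), post = character(),
                              synapse_kind = character(),
                              directedness = character())
  }
  req <- c("pre", "post", "synapse_kind", "directedness")
  if (!all(req %in% names(connections))) {
    stop("connection table must have columns: ", paste(req, collapse = ", "))
  }
  connections <- as.data.frame(connections)[, req, drop = FALSE]
  for (col in req) connections[[col]] <- as.character(connections[[col]])
  unknown <- setdiff(c(connections$pre, connections$post), neurons$id)
  if (length(unknown) > 0L) {
    stop("connection endpoint(s) not in neuron table: ",
         paste(unique(unknown), collapse = ", "))
  }
  if (any(connections$pre == connections$post)) {
    stop("self-loop connection(s) present; remove them with apply_exclusions()")
  }
  if (!all(connections$synapse_kind %in% KIND_LEVELS)) {
    stop("synapse_kind must be one of: ", paste(KIND_LEVELS, collapse = ", "))
  }
  if (!all(connections$directedness %in% c("uni", "bi"))) {
    stop("directedness must be 'uni' or 'bi'")
  }
  bad_dir <- connections$synapse_kind %in% c("gap", "combination") &
    connections$directedness != "bi"
  if (any(bad_dir)) {
    stop("gap and combination junctions must be bidirectional (",
         sum(bad_dir), " violating link(s))")
  }
  key <- pair_key(connections$pre, connections$post)
  if (anyDuplicated(key)) {
    stop("duplicate connection(s) between the same neuron pair: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  rownames(neurons) <- NULL
  rownames(connections) <- NULL
  structure(
    list(neurons = neurons, connections = connections, config = config,
         provenance = provenance),
    class = "connectome"
  )
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' @export
print.connectome <- function(x, ...) {
  n_bi <- sum(x$connections$directedness == "bi")
  cat("Connectome: ", nrow(x$neurons), " neurons, ",
      nrow(x$connections), " connections (",
      nrow(x$connections) - n_bi, " uni, ", n_bi, " bi)\n", sep = "")
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Load a neuron table from CSV
#'
#' Reads a comma-separated neuron table (UTF-8, header required, `.` decimal
#' separator) and lifts the 2D soma coordinates onto the cylinder via
#' [lift_to_3d()]. Required columns: `id`, `ap_mm`, `dv_mm`, `side`,
#' `birth_time_min`. Optional columns: `neuron_class`, `neuron_type`,
#' `region`, `circuits` (semicolon-separated), `bilateral_partner`; missing
#' optional columns default to empty.
#'
#' @param path Path to the CSV file.
#' @param config A [spatial_config()].
#' @return A neuron data frame ready for [connectome()].
#' @export
load_neuron_table <- function(path, config = spatial_config()) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  encoding = "UTF-8")
  req <- c("id", "ap_mm", "dv_mm", "side", "birth_time_min")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0L) {
    stop("neuron table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(raw$id)) {
    dup <- unique(raw$id[duplicated(raw$id)])
    stop("duplicate neuron id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("", "NA")))
    if (length(bad) > 0L) {
      stop("non-numeric value in column '", col, "' of ", path,
           " at data line(s) ", paste(bad, collapse = ", "))
    }
    v
  }
  ap <- num("ap_mm"); dv <- num("dv_mm"); bt <- num("birth_time_min")
  if (anyNA(ap) || anyNA(dv) || anyNA(bt)) {
    stop("missing coordinate or birth time in ", path)
  }
  if (any(bt < 0)) stop("negative birth_time_min in ", path)
  if (!all(raw$side %in% SIDE_LEVELS)) {
    stop("invalid side value(s) in ", path, "; expected ",
         paste(SIDE_LEVELS, collapse = "/"))
  }
  pos <- lift_to_3d(ap, dv, raw$side, config)
  opt <- function(col) if (col %in% names(raw)) raw[[col]] else ""
  normalize_neurons(data.frame(
    id = raw$id,
    neuron_class = opt("neuron_class"),
    ap_mm = ap, dv_mm = pos$y, side = raw$side, birth_time = bt,
    x = pos$x, y = pos$y, z = pos$z,
    neuron_type = opt("neuron_type"),
    region = opt("region"),
    circuits = opt("circuits"),
    bilateral_partner = opt("bilateral_partner"),
    stringsAsFactors = FALSE
  ))
}

#' Load an edge table from CSV
#'
#' Reads a comma-separated edge table with columns `pre`, `post`,
#' `synapse_kind` and optionally `directedness`. Duplicate rows for the same
#' unordered neuron pair are collapsed: if both a gap junction and a
#' chemical synapse are recorded the link becomes a `combination`; a
#' chemical synapse recorded in both directions becomes bidirectional. Gap
#' and combination junctions are always bidirectional.
#'
#' @param path Path to the CSV file.
#' @return A connection data frame ready for [connectome()].
#' @export
load_edge_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  encoding = "UTF-8")
  req <- c("pre", "post", "synapse_kind")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0L) {
    stop("edge table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(raw$synapse_kind %in% KIND_LEVELS)) {
    stop("invalid synapse_kind in ", path, "; expected ",
         paste(KIND_LEVELS, collapse = "/"))
  }
  if (!("directedness" %in% names(raw))) {
    raw$directedness <- ifelse(raw$synapse_kind == "chemical", "uni", "bi")
  }
  if (nrow(raw) == 0L) {
    return(data.frame(pre = character(), post = character(),
                      synapse_kind = character(), directedness = character()))
  }
  key <- pair_key(raw$pre, raw$post)
  collapse <- function(idx) {
    rows <- raw[idx, , drop = FALSE]
    kinds <- unique(rows$synapse_kind)
    has_gap <- any(kinds %in% c("gap", "combination"))
    has_chem <- any(kinds %in% c("chemical", "combination"))
    kind <- if (has_gap && has_chem) "combination"
            else if (has_gap) "gap" else "chemical"
    both_dirs <- length(unique(paste(rows$pre, rows$post))) > 1L
    dir <- if (kind != "chemical" || any(rows$directedness == "bi") ||
               both_dirs) "bi" else "uni"
    data.frame(pre = rows$pre[1L], post = rows$post[1L],
               synapse_kind = kind, directedness = dir,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(raw)), key), collapse))
  rownames(out) <- NULL
  out
}

#' Read a connectome from a neuron CSV and an edge CSV
#'
#' Convenience wrapper around [load_neuron_table()], [load_edge_table()] and
#' [connectome()]. Self-loop edges in the raw table are dropped before
#' validation (they carry no spatial or topological information).
#'
#' @param neuron_path,edge_path CSV file paths.
#' @param config A [spatial_config()].
#' @param provenance Free-text metadata string.
#' @return A `connectome`.
#' @export
read_connectome <- function(neuron_path, edge_path,
                            config = spatial_config(), provenance = "") {
  neurons <- load_neuron_table(neuron_path, config)
  edges <- load_edge_table(edge_path)
  loops <- edges$pre == edges$post
  if (any(loops)) {
    message("dropping ", sum(loops), " self-loop connection(s)")
    edges <- edges[!loops, , drop = FALSE]
  }
  connectome(neurons, edges, config, provenance)
}

#' Write a connectome as a neuron CSV and an edge CSV
#'
#' Emits `neurons.csv` and `edges.csv` in the dialect read by
#' [load_neuron_table()] and [load_edge_table()]; a written connectome
#' reloads field-for-field identical (up to floating-point formatting,
#' avoided by writing full precision).
#'
#' @param con A `connectome`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths written.
#' @export
write_connectome <- function(con, dir) {
  stopifnot(inherits(con, "connectome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nfile <- file.path(dir, "neurons.csv")
  efile <- file.path(dir, "edges.csv")
  nn <- con$neurons
  out <- data.frame(
    id = nn$id, neuron_class = nn$neuron_class,
    ap_mm = format(nn$ap_mm, digits = 17, trim = TRUE, scientific = FALSE),
    dv_mm = format(nn$dv_mm, digits = 17, trim = TRUE, scientific = FALSE),
    side = nn$side,
    birth_time_min = format(nn$birth_time, digits = 17, trim = TRUE,
                            scientific = FALSE),
    neuron_type = nn$neuron_type, region = nn$region, circuits = nn$circuits,
    bilateral_partner = nn$bilateral_partner,
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) {
    out$ap_mm <- character(); out$dv_mm <- character()
    out$birth_time_min <- character()
  }
  write.csv(out, nfile, row.names = FALSE, na = "", quote = FALSE)
  write.csv(con$connections, efile, row.names = FALSE, na = "", quote = FALSE)
  invisible(c(neurons = nfile, edges = efile))
}

#' Remove excluded neurons and self-loops
#'
#' Drops the named neurons with all their incident connections, and removes
#' any self-loop connections (a neuron connected to itself carries no
#' spatial or topological information). Idempotent. The real dataset this
#' mirrors excludes the ventral cord neuron VC6, which connects only through
#' neuro-muscular junctions.
#'
#' @param con A `connectome` or a list with raw `neurons`/`connections`
#'   tables (so exclusions can be applied before validation).
#' @param excluded_ids Character vector of neuron ids to remove; ids not
#'   present trigger a warning, not an error.
#' @return A new validated `connectome`.
#' @export
apply_exclusions <- function(con, excluded_ids = character()) {
  neurons <- con$neurons
  edges <- con$connections
  config <- if (!is.null(con$config)) con$config else spatial_config()
  absent <- setdiff(excluded_ids, neurons$id)
  if (length(absent) > 0L) {
    warning("excluded id(s) not present: ", paste(absent, collapse = ", "))
  }
  keep_n <- !(neurons$id %in% excluded_ids)
  loops <- edges$pre == edges$post
  keep_e <- !loops & !(edges$pre %in% excluded_ids) &
    !(edges$post %in% excluded_ids)
  n_dropped_e <- sum(!keep_e)
  if (length(absent) < length(excluded_ids) || any(loops)) {
    message("apply_exclusions: removed ", sum(!keep_n), " neuron(s), ",
            n_dropped_e, " connection(s) (", sum(loops), " self-loops)")
  }
  connectome(neurons[keep_n, , drop = FALSE], edges[keep_e, , drop = FALSE],
             config,
             provenance = if (!is.null(con$provenance)) con$provenance else "")
}

#' Network present at a developmental time
#'
#' Induces the sub-connectome on neurons born at or before `t` minutes.
#' A connection is present iff both of its adult endpoints have been born
#' ("connection-pair" semantics): presence says nothing about when the
#' synapse itself forms.
#'
#' @param con A `connectome`.
#' @param t Time in minutes post-fertilization (cutoff inclusive).
#' @return A `connectome` restricted to neurons with `birth_time <= t`.
#' @export
stage_network <- function(con, t) {
  stopifnot(inherits(con, "connectome"), is.numeric(t), length(t) == 1L,
            t >= 0)
  keep <- con$neurons$birth_time <= t
  ids <- con$neurons$id[keep]
  e <- con$connections
  keep_e <- e$pre %in% ids & e$post %in% ids
  connectome(con$neurons[keep, , drop = FALSE], e[keep_e, , drop = FALSE],
             con$config, con$provenance)
}

#' Neuron degree (in + out)
#'
#' Degree counts incoming plus outgoing arcs after expanding each
#' bidirectional link into two arcs: a unidirectional link contributes 1 to
#' each endpoint, a bidirectional link contributes 2 to each endpoint.
#'
#' @param con A `connectome`.
#' @param id Optional neuron id; if omitted, a named vector over all neurons.
#' @return Integer degree(s).
#' @export
neuron_degree <- function(con, id = NULL) {
  stopifnot(inherits(con, "connectome"))
  e <- con$connections
  w <- ifelse(e$directedness == "bi", 2L, 1L)
  deg <- setNames(integer(nrow(con$neurons)), con$neurons$id)
  if (nrow(e) > 0L) {
    tab <- tapply(c(w, w), c(e$pre, e$post), sum)
    deg[names(tab)] <- as.integer(tab)
  }
  if (is.null(id)) return(deg)
  if (!id %in% names(deg)) stop("unknown neuron id: ", id)
  deg[[id]]
}

#' Convert a connectome to an igraph graph
#'
#' Directed mode expands bidirectional links to two arcs; undirected mode
#' symmetrizes (a link exists if any arc exists), which is the graph the
#' small-world metrics are computed on.
#'
#' @param con A `connectome`.
#' @param mode `"directed"` or `"undirected"`.
#' @return An `igraph` graph with all neuron annotations as vertex
#'   attributes and `synapse_kind`/`directedness` as edge attributes.
#' @export
as_igraph <- function(con, mode = c("directed", "undirected")) {
  stopifnot(inherits(con, "connectome"))
  mode <- match.arg(mode)
  e <- con$connections
  if (mode == "directed") {
    bi <- e$directedness == "bi"
    el <- rbind(
      data.frame(from = e$pre, to = e$post, synapse_kind = e$synapse_kind,
                 directedness = e$directedness),
      data.frame(from = e$post[bi], to = e$pre[bi],
                 synapse_kind = e$synapse_kind[bi],
                 directedness = e$directedness[bi])
    )
  } else {
    el <- data.frame(from = e$pre, to = e$post,
                     synapse_kind = e$synapse_kind,
                     directedness = e$directedness)
  }
  g <- igraph::graph_from_data_frame(el, directed = (mode == "directed"),
                                     vertices = con$neurons)
  if (mode == "undirected") g <- igraph::simplify(g, edge.attr.comb = "first")
  g
}

#' Export a connectome to GraphML
#'
#' @param con A `connectome`.
#' @param path Output file path.
#' @param mode Graph mode passed to [as_igraph()].
#' @return Invisibly, `path`.
#' @export
export_graphml <- function(con, path, mode = "directed") {
  g <- as_igraph(con, mode)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# split a semicolon-separated set column into a list of character vectors
split_set <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
}
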