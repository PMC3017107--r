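#' Pipeline run configuration
#'
#' Describes one end-to-end analysis run: where the connectome comes from
#' (exactly one of CSV paths or a synthetic-generator configuration), the
#' spatial and length-class settings, the null-ensemble size, the master
#' seed, and which analysis blocks to run.
#'
#' @param neuron_csv,edge_csv Input CSV paths (both or neither).
#' @param synth A [generator_config()] to generate the input instead.
#' @param spatial A [spatial_config()].
#' @param classifier A [length_classifier()].
#' @param exclude_ids Neuron ids to remove before analysis.
#' @param n_trials Identity-shuffle trials per ensemble comparison
#'   (default 20); 0 disables ensembles but still reports every observed
#'   statistic.
#' @param seed Master integer seed.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param analyses Subset of
#'   `c("temporal", "spatial", "circuits", "topology")`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(neuron_csv = NULL, edge_csv = NULL, synth = NULL,
                       spatial = spatial_config(),
                       classifier = length_classifier(),
                       exclude_ids = character(),
                       n_trials = 20, seed = 1L, out_dir = NULL,
                       analyses = c("temporal", "spatial", "circuits",
                                    "topology")) {
  from_files <- !is.null(neuron_csv) || !is.null(edge_csv)
  if (from_files && (is.null(neuron_csv) || is.null(edge_csv))) {
    stop("both `neuron_csv` and `edge_csv` must be given")
  }
  if (from_files == !is.null(synth)) {
    stop("exactly one of (neuron_csv + edge_csv) or `synth` must be set")
  }
  analyses <- match.arg(analyses, several.ok = TRUE)
  stopifnot(inherits(spatial, "spatial_config"),
            inherits(classifier, "length_classifier"),
            n_trials >= 0)
  structure(
    list(neuron_csv = neuron_csv, edge_csv = edge_csv, synth = synth,
         spatial = spatial, classifier = classifier,
         exclude_ids = exclude_ids, n_trials = as.integer(n_trials),
         seed = as.integer(seed), out_dir = out_dir, analyses = analyses),
    class = "run_config"
  )
}

#' Validate pipeline inputs without running analyses
#'
#' Checks the CSV schemas, identity completeness, bilateral-annotation
#' symmetry and coordinate ranges, returning findings rather than throwing.
#'
#' @param config A [run_config()] (file-based).
#' @return Data frame of findings with columns `level` (`"error"` or
#'   `"warning"`) and `message`; zero rows means the inputs are clean.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  findings <- data.frame(level = character(), message = character(),
                         stringsAsFactors = FALSE)
  add <- function(level, msg) {
    rbind(findings, data.frame(level = level, message = msg,
                               stringsAsFactors = FALSE))
  }
  if (is.null(config$neuron_csv)) {
    return(add("warning", "synthetic input: nothing to validate"))
  }
  neurons <- tryCatch(
    withCallingHandlers(
      load_neuron_table(config$neuron_csv, config$spatial),
      warning = function(w) {
        findings <<- add("warning", conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
    error = function(e) {
      findings <<- add("error", conditionMessage(e))
      NULL
    })
  edges <- tryCatch(load_edge_table(config$edge_csv), error = function(e) {
    findings <<- add("error", conditionMessage(e))
    NULL
  })
  if (is.null(neurons) || is.null(edges)) return(findings)
  unknown <- setdiff(c(edges$pre, edges$post), neurons$id)
  for (u in unknown) {
    rows <- which(edges$pre == u | edges$post == u)
    findings <- add("error",
                    paste0("edge(s) ", paste(rows, collapse = ","),
                           " reference unknown neuron '", u, "'"))
  }
  loops <- which(edges$pre == edges$post)
  if (length(loops) > 0L) {
    findings <- add("warning",
                    paste0(length(loops), " self-loop edge(s); they will be ",
                           "removed by apply_exclusions()"))
  }
  partner <- setNames(neurons$bilateral_partner, neurons$id)
  has <- !is.na(partner) & nzchar(partner)
  for (id in neurons$id[has]) {
    p <- partner[[id]]
    ok <- p %in% neurons$id && !is.na(partner[p]) && nzchar(partner[p]) &&
      partner[[p]] == id
    if (!ok) {
      findings <- add("error",
                      paste0("asymmetric bilateral annotation between '",
                             id, "' and '", p, "'"))
    }
  }
  findings
}

compare_to_ensemble <- function(observed, metric, con, n_trials, seed, name) {
  out <- list(observed = observed, ensemble_mean = NA_real_,
              ensemble_sd = NA_real_, t = NA_real_, p = NA_real_,
              n_trials = n_trials, available = FALSE)
  if (n_trials >= 2 && is.finite(observed)) {
    ens <- ensemble(metric, con, n_trials = n_trials, seed = seed,
                    metric_name = name)
    out$ensemble_mean <- ens$mean
    out$ensemble_sd <- ens$sd
    if (is.finite(ens$sd) && ens$sd > 0) {
      tt <- one_sample_ttest(observed, ens)
      out$t <- unname(tt["t"]); out$p <- unname(tt["p"])
    }
    out$available <- TRUE
  }
  out
}

# percentage of adult class-`cl` connection pairs with both endpoints born
# by hatching; the headline pre-hatch wiring statistic
prehatch_class_pct <- function(con, cl, classifier, hatch_time) {
  len <- connection_lengths(con)
  cls <- classify_length(len, classifier)
  bt <- setNames(con$neurons$birth_time, con$neurons$id)
  e <- con$connections
  sel <- cls == cl
  if (!any(sel)) return(NA_real_)
  100 * sum(sel & bt[e$pre] <= hatch_time & bt[e$post] <= hatch_time) /
    sum(sel)
}

#' Run the full developmental-connectome analysis
#'
#' Loads or generates the connectome, applies exclusions, and runs the
#' enabled analysis blocks — temporal (birth-time differences, phase
#' fractions, degree/birth-time correlation, hub reports, bilateral timing,
#' type growth curves), spatial (length classes, appearance curves, synapse
#' breakdown, region connectivity, degree/length correlations), circuits,
#' and topology (per-stage small-world indices). Every scalar with a
#' meaningful identity-shuffle null is reported together with its ensemble
#' mean, sd, t statistic and p value. Fully deterministic given the master
#' seed; percentages are on the 0-100 scale.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report` with one element per analysis block
#'   plus `provenance` (config echo, seeds, package version). If
#'   `config$out_dir` is set, CSV tables and a JSON report are written
#'   there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(stage, ...) {
    message(sprintf("[%6.1fs] %s %s", proc.time()[["elapsed"]] - t0, stage,
                    paste0(...)))
  }

  if (!is.null(config$synth)) {
    sim <- generate_connectome(config$synth, spatial = config$spatial,
                               classifier = config$classifier)
    con <- sim$connectome
  } else {
    con <- read_connectome(config$neuron_csv, config$edge_csv,
                           config$spatial)
  }
  con <- apply_exclusions(con, config$exclude_ids)
  log_stage("input", sprintf("%d neurons, %d connections",
                             nrow(con$neurons), nrow(con$connections)))

  hatch <- config$spatial$hatch_time
  stages <- config$spatial$stage_times
  classifier <- config$classifier
  nt <- config$n_trials
  seed <- config$seed
  report <- list()

  if ("temporal" %in% config$analyses) {
    diffs <- birth_time_differences(con)
    pf <- phase_fractions(con, hatch)
    hub30 <- hub_report(con, 30, hatch, ">")
    comparisons <- list(
      median_birth_time_difference = compare_to_ensemble(
        median(diffs), function(cc) median(birth_time_differences(cc)),
        con, nt, seed + 11L, "median_birth_time_difference"),
      embryonic_within_fraction = compare_to_ensemble(
        unname(pf["embryonic_within"]),
        function(cc) unname(phase_fractions(cc, hatch)["embryonic_within"]),
        con, nt, seed + 12L, "embryonic_within_fraction"),
      postembryonic_within_fraction = compare_to_ensemble(
        unname(pf["postembryonic_within"]),
        function(cc)
          unname(phase_fractions(cc, hatch)["postembryonic_within"]),
        con, nt, seed + 13L, "postembryonic_within_fraction"),
      hub30_fraction_born_before = compare_to_ensemble(
        hub30$fraction_born_before,
        function(cc) hub_report(cc, 30, hatch, ">")$fraction_born_before,
        con, nt, seed + 14L, "hub30_fraction_born_before"),
      degree_birth_correlation = compare_to_ensemble(
        degree_birth_correlation(con),
        degree_birth_correlation, con, nt, seed + 15L,
        "degree_birth_correlation")
    )
    report$temporal <- list(
      birth_time_histogram = binned_histogram(diffs, 10),
      phase_fractions = pf,
      hub_reports = list(`20` = hub_report(con, 20, hatch, ">="),
                         `30` = hub30,
                         `60` = hub_report(con, 60, hatch, ">")),
      bilateral_timing = bilateral_timing(con),
      type_growth_curves = tryCatch(type_growth_curves(con, stages),
                                    warning = function(w)
                                      suppressWarnings(
                                        type_growth_curves(con, stages))),
      comparisons = comparisons
    )
    log_stage("temporal", "done")
  }

  if ("spatial" %in% config$analyses) {
    curves <- suppressWarnings(appearance_curves(con, stages, classifier))
    comparisons <- list()
    for (cl in c("short", "medium", "long")) {
      comparisons[[paste0("prehatch_", cl, "_pct")]] <- compare_to_ensemble(
        prehatch_class_pct(con, cl, classifier, hatch),
        function(cc) prehatch_class_pct(cc, cl, classifier, hatch),
        con, nt, seed + 20L + match(cl, c("short", "medium", "long")),
        paste0("prehatch_", cl, "_pct"))
    }
    report$spatial <- list(
      length_class_counts = table(classify_length(connection_lengths(con),
                                                  classifier)),
      appearance_curves = curves,
      synapse_breakdown = synapse_breakdown(con, classifier, hatch),
      region_connectivity = region_connectivity(con),
      degree_length_correlations =
        tryCatch(degree_length_correlations(con, classifier),
                 error = function(e) c(r_short = NA_real_,
                                       r_long = NA_real_)),
      comparisons = comparisons
    )
    log_stage("spatial", "done")
  }

  if ("circuits" %in% config$analyses) {
    report$circuits <- list(
      circuit_curves = suppressWarnings(circuit_curves(con, stages)))
    log_stage("circuits", "done")
  }

  if ("topology" %in% config$analyses) {
    report$topology <- list(
      small_world = small_world_series(con, stages,
                                       n_random = max(nt, 1),
                                       seed = seed + 31L))
    log_stage("topology", "done")
  }

  report$provenance <- list(
    seed = seed, n_trials = nt,
    exclude_ids = config$exclude_ids,
    input = if (is.null(config$synth)) {
      list(kind = "files", neuron_csv = config$neuron_csv,
           edge_csv = config$edge_csv)
    } else {
      list(kind = "synthetic", generator_seed = config$synth$seed,
           n_neurons = config$synth$n_neurons,
           n_connections = config$synth$n_connections)
    },
    stage_times = stages, hatch_time = hatch,
    package_version = as.character(utils::packageVersion("wormdev"))
  )
  class(report) <- "run_report"

  if (!is.null(config$out_dir)) {
    write_run_report(report, config$out_dir)
    log_stage("output", paste("written to", config$out_dir))
  }
  report
}

#' Write a run report to disk
#'
#' Emits per-analysis CSV tables plus a `report.json` with every scalar and
#' its ensemble comparison.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(report$temporal)) {
    h <- report$temporal$birth_time_histogram
    emit(data.frame(lo = h$bin_edges[-length(h$bin_edges)],
                    hi = h$bin_edges[-1], count = h$counts,
                    bin_mean = h$bin_means),
         "birth_time_histogram.csv")
    emit(report$temporal$hub_reports[["30"]]$neurons, "hub_table.csv")
    emit(report$temporal$type_growth_curves, "type_growth_curves.csv")
  }
  if (!is.null(report$spatial)) {
    emit(report$spatial$appearance_curves, "appearance_curves.csv")
    emit(report$spatial$synapse_breakdown$counts, "synapse_breakdown.csv")
  }
  if (!is.null(report$circuits)) {
    emit(report$circuits$circuit_curves, "circuit_curves.csv")
  }
  if (!is.null(report$topology)) {
    emit(report$topology$small_world, "small_world.csv")
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(unclass_deep(report), jp, auto_unbox = TRUE,
                       digits = NA, force = TRUE, na = "null")
  invisible(c(paths, jp))
}

unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lapply(unclass(x), unclass_deep)
  } else if (inherits(x, "table")) {
    as.list(x)
  } else {
    x
  }
}

#' Check a run report against the shipped schema
#'
#' Structurally validates a `run_report` (or its JSON form reloaded as a
#' list) against the required-property sets of the schema document shipped
#' at `inst/schema/run-report.schema.json`: the enabled blocks carry their
#' required tables, and every ensemble comparison has the full
#' observed/mean/sd/t/p/n_trials/available field set.
#'
#' @param report A `run_report` or a list parsed from `report.json`.
#' @return Character vector of violations; `character(0)` when valid.
#' @export
validate_run_report <- function(report) {
  schema <- jsonlite::read_json(system.file("schema",
                                            "run-report.schema.json",
                                            package = "wormdev"))
  problems <- character()
  need <- function(obj, keys, where) {
    missing <- setdiff(unlist(keys), names(obj))
    if (length(missing) > 0L) {
      problems <<- c(problems,
                     paste0(where, " missing: ",
                            paste(missing, collapse = ", ")))
    }
  }
  need(report, schema$required, "report")
  for (block in names(schema$properties)) {
    if (is.null(report[[block]])) next
    spec <- schema$properties[[block]]
    need(report[[block]], spec$required, block)
    if (!is.null(report[[block]]$comparisons)) {
      cmp_req <- schema$definitions$comparison$required
      for (nm in names(report[[block]]$comparisons)) {
        need(report[[block]]$comparisons[[nm]], cmp_req,
             paste0(block, "$comparisons$", nm))
      }
    }
  }
  problems
}

#' @export
print.run_report <- function(x, ...) {
  cat("Developmental connectome run report\n")
  for (block in intersect(c("temporal", "spatial", "circuits", "topology"),
                          names(x))) {
    cat("  -", block, "\n")
  }
  invisible(x)
}
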