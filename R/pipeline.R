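# Orchestration: a single configured run from peak lists (real or
# simulated) to the QC report, diagnostic evaluation, biomarker table and
# pathway table. No computation happens here; every number comes from one
# upstream module function.

.default_params <- list(
  ppm_tol = 5.0, rt_window = 0.2,
  ls_cutoff = 10.0, lbc_cutoff = 50,
  pls_components = 2,
  p_max = 0.05, vip_min = 1.1, fc_min = 2.0,
  log_base = "e"
)

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a list. Recognized top-level keys:
#' \code{paths} (\code{library}, \code{peaklists}, \code{qc_peaklists},
#' \code{metadata}, \code{pathways}), \code{simulate} (logical: generate
#' the library, cohort and QC replicates instead of reading files),
#' \code{params} (any of ppm_tol, rt_window, ls_cutoff, lbc_cutoff,
#' pls_components, p_max, vip_min, fc_min, log_base), \code{seed},
#' \code{output_dir}. Missing params are filled with the documented
#' defaults; unknown keys produce a warning, not an error.
#'
#' @param config Path to a YAML config or a list.
#' @return A validated \code{run_config} list with defaults injected.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("paths", "simulate", "params", "seed", "output_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  params <- utils::modifyList(.default_params,
                              if (is.null(config$params)) list()
                              else config$params)
  for (k in c("ppm_tol", "rt_window", "ls_cutoff", "lbc_cutoff",
              "pls_components", "p_max", "vip_min", "fc_min")) {
    if (!is.numeric(params[[k]]) || params[[k]] <= 0)
      stop("config parameter ", k, " must be a positive number")
  }
  if (!params$log_base %in% c("e", "10"))
    stop("config parameter log_base must be 'e' or '10'")
  paths <- if (is.null(config$paths)) list() else config$paths
  for (k in names(paths)) {
    if (!is.null(paths[[k]]) && !file.exists(paths[[k]]))
      stop("config path ", sQuote(k), " does not exist: ", paths[[k]])
  }
  simulate <- isTRUE(config$simulate)
  if (!simulate && is.null(paths$metadata) && is.null(paths$peaklists))
    stop("config needs either simulate: true or paths to input data")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  structure(list(paths = paths, simulate = simulate, params = params,
                 seed = seed, output_dir = config$output_dir),
            class = "run_config")
}

.skipped <- function(reason) list(skipped = TRUE, reason = reason)

#' Run the full pipeline under a validated configuration
#'
#' Stages run in order: extract -> normalize -> QC -> diagnostics ->
#' differential -> pathways. Stages whose inputs are absent are skipped
#' with a recorded reason rather than failing. The same configuration and
#' seed always produce an identical report.
#'
#' @param config A \code{run_config} (see \code{\link{validate_config}}),
#'   or anything that function accepts.
#' @return A \code{run_report} list with sections \code{qc},
#'   \code{diagnostics}, \code{biomarkers}, \code{pathways} and
#'   \code{provenance}.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  p <- config$params
  set.seed(config$seed)

  library_obj <- if (!is.null(config$paths$library))
    load_library(config$paths$library)
  else if (config$simulate) generate_library(config$seed)
  else NULL

  peaklists <- NULL; records <- NULL; qc_lists <- NULL
  if (config$simulate) {
    cohort <- generate_cohort(
      cohort_spec(seed = config$seed), library_obj)
    peaklists <- cohort$peaklists
    records <- cohort$records
    qc_lists <- generate_qc(library_obj, seed = config$seed + 1L)
  } else {
    if (!is.null(config$paths$peaklists))
      peaklists <- read_peaklists(config$paths$peaklists)
    if (!is.null(config$paths$qc_peaklists))
      qc_lists <- read_peaklists(config$paths$qc_peaklists)
    if (!is.null(config$paths$metadata))
      records <- read_cohort(config$paths$metadata)
  }

  # extract + normalize
  norm <- NULL
  if (!is.null(peaklists) && !is.null(library_obj)) {
    raw <- build_matrix(peaklists, library_obj,
                        ppm_tol = p$ppm_tol, rt_window = p$rt_window)
    norm <- tic_normalize(raw)
    if (!is.null(records)) {
      records <- records[match(rownames(norm), records$sample_id), ,
                         drop = FALSE]
      records$ls_ratio <- unname(ls_ratios(norm, library_obj))
    }
  }

  # QC
  qc_section <- if (!is.null(qc_lists) && !is.null(library_obj)) {
    qc_mat <- tic_normalize(build_matrix(qc_lists, library_obj,
                                         ppm_tol = p$ppm_tol,
                                         rt_window = p$rt_window))
    rep_report <- qc_cv(qc_mat, library_obj)
    list(
      class_average_cv = as.list(rep_report$class_average_cv),
      lecithin_average_cv = rep_report$lecithin_average_cv,
      sphingomyelin_average_cv = rep_report$sphingomyelin_average_cv,
      n_replicates = rep_report$n_replicates
    )
  } else .skipped("no QC peak lists provided")

  # diagnostics
  diagnostics <- if (!is.null(records) &&
                     "flm_outcome" %in% names(records) &&
                     any(records$flm_outcome != "unknown")) {
    out <- list()
    if ("ls_ratio" %in% names(records))
      out$ls <- unclass(evaluate_classifier(records, "ls",
                                            cutoff = p$ls_cutoff))
    if ("lbc" %in% names(records))
      out$lbc <- unclass(evaluate_classifier(records, "lbc",
                                             cutoff = p$lbc_cutoff))
    if (length(out)) out else .skipped("no classifier inputs in metadata")
  } else .skipped("no outcome metadata provided")

  # differential
  biomarkers <- if (!is.null(norm) && !is.null(records) &&
                    all(c("premature", "mature") %in% records$flm_outcome)) {
    two <- records$flm_outcome %in% c("premature", "mature")
    stats_tab <- biomarker_stats(norm[records$sample_id[two], , drop = FALSE],
                                 records$flm_outcome[two],
                                 n_components = p$pls_components,
                                 p_max = p$p_max, vip_min = p$vip_min,
                                 fc_min = p$fc_min)
    list(table = stats_tab,
         selected = select_biomarkers(stats_tab, p_max = p$p_max,
                                      vip_min = p$vip_min, fc_min = p$fc_min))
  } else .skipped("need an intensity matrix and both outcome groups")

  # pathways
  pathways <- if (!is.null(config$paths$pathways) &&
                  !isTRUE(biomarkers$skipped) && !is.null(library_obj)) {
    pws <- read_pathways(config$paths$pathways)
    hits <- intersect(biomarkers$selected$species_name, library_obj$name)
    if (length(hits) == 0L) .skipped("no selected biomarkers to enrich")
    else enrich(pws, hits, library_obj$name, log_base = p$log_base)
  } else .skipped("no pathway definitions provided or no biomarker stage")

  report <- structure(list(
    qc = qc_section,
    diagnostics = diagnostics,
    biomarkers = biomarkers,
    pathways = pathways,
    provenance = list(
      package = "amniolipids",
      version = as.character(utils::packageVersion("amniolipids")),
      seed = config$seed,
      params = p,
      paths = config$paths,
      simulate = config$simulate
    )
  ), class = "run_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(config$output_dir, "run_report.json"))
    if (!is.null(norm))
      write_matrix(norm, file.path(config$output_dir,
                                   "intensity_matrix_normalized.tsv"))
  }
  report
}

#' Serialize a run report to JSON
#'
#' @param report A \code{run_report}.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       dataframe = "rows")
  invisible(path)
}

#' Re-load a serialized run report
#'
#' @param path JSON path written by \code{\link{write_report}}.
#' @export
read_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_report")
}
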