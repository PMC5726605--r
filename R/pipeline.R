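#' Pipeline configuration
#'
#' Validated bundle of all pipeline settings: the cohort design, the
#' individual-threshold level, the bidirectional combination rule, the
#' group participant threshold and the module-detection settings. Unknown
#' fields are rejected by name.
#'
#' @param design A [cohort_design()].
#' @param alpha Individual Poisson-tail level; default 0.05.
#' @param combine `"mean"` or `"max"` bidirectional combination.
#' @param participant_threshold Group threshold in percent (50 or 75 by
#'   convention; other values allowed).
#' @param method,n_restarts Module detection settings, see
#'   [detect_modules()].
#' @param rng_seed Master seed for all stochastic stages.
#' @param ... Rejected; present so misspelled fields fail loudly.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(design, alpha = 0.05,
                            combine = c("mean", "max"),
                            participant_threshold = 50,
                            method = c("spectral", "louvain"),
                            n_restarts = 20, rng_seed = 1, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration field(s): ",
         paste(names(extra), collapse = ", "))
  stopifnot(inherits(design, "cohort_design"))
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  structure(list(design = design, alpha = alpha,
                 combine = match.arg(combine),
                 participant_threshold = participant_threshold,
                 method = match.arg(method), n_restarts = n_restarts,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Run the full connectome pipeline
#'
#' Simulates (or takes) a cohort of subject pair matrices, applies the
#' Poisson individual threshold per subject, forms the group consensus,
#' detects modules and computes the centrality report, and writes every
#' stage to `out_dir` as delimited text plus a JSON provenance record
#' (seed, configuration, file checksums). Reruns with the same
#' configuration are byte-identical. On error, partial outputs are
#' removed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param cohort Optional list of subject matrices; when missing, a cohort
#'   is simulated from `config$design`.
#' @return Invisibly, a list with the in-memory stage results and the
#'   written file paths.
#' @export
run_pipeline <- function(config, out_dir, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  created <- !dir.exists(out_dir)
  if (created) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    if (created) unlink(out_dir, recursive = TRUE)
    stop(e)
  }
  tryCatch({
    emit <- function(obj, name) {
      f <- file.path(out_dir, name)
      if (is.matrix(obj)) {
        utils::write.table(obj, f, sep = "\t", quote = FALSE, col.names = NA)
      } else {
        utils::write.table(obj, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
      written <<- c(written, f)
      f
    }
    if (is.null(cohort))
      cohort <- simulate_cohort(config$design, rng_seed = config$rng_seed)
    for (s in seq_along(cohort))
      emit(cohort[[s]], sprintf("subject_%02d_counts.tsv", s))

    thr <- lapply(cohort, threshold_subject, alpha = config$alpha,
                  combine = config$combine)
    thr_tab <- data.frame(
      subject = seq_along(thr),
      lambda_hat = vapply(thr, function(x) x$threshold$lambda_hat, 0),
      k_star = vapply(thr, function(x) x$threshold$k_star, 0L),
      percent_equiv = vapply(thr, function(x) x$threshold$percent_equiv, 0)
    )
    emit(thr_tab, "individual_thresholds.tsv")

    grp <- group_consensus(lapply(thr, `[[`, "binary"),
                           participant_threshold = config$participant_threshold)
    emit(percent_table(grp), "group_percent.tsv")
    emit(grp$graph$adjacency, "group_adjacency.tsv")
    emit(as_edge_list(grp$graph), "group_edges.tsv")

    if (sum(grp$graph$adjacency) > 0) {
      part <- detect_modules(grp$graph, method = config$method,
                             n_restarts = config$n_restarts,
                             rng_seed = config$rng_seed)
      emit(data.frame(node = names(part$membership),
                      module = unname(part$membership)),
           "module_partition.tsv")
      report <- centrality_report(grp$graph, partition = part)
    } else {
      part <- NULL
      report <- centrality_report(grp$graph)
    }
    emit(format_report(report), "centrality_report.tsv")

    prov <- list(
      package = "tractnet",
      version = as.character(utils::packageVersion("tractnet")),
      rng_seed = config$rng_seed,
      alpha = config$alpha,
      combine = config$combine,
      participant_threshold = config$participant_threshold,
      method = config$method,
      n_restarts = config$n_restarts,
      design = unclass(config$design)[c("n_rois", "n_subjects",
                                        "signal_rate", "noise_lambda",
                                        "subject_dropout", "n_streamlines")],
      q = if (!is.null(part)) part$q else NA,
      n_modules = if (!is.null(part)) part$n_modules else 0L,
      file_md5 = as.list(tools::md5sum(sort(written)))
    )
    pf <- file.path(out_dir, "provenance.json")
    jsonlite::write_json(prov, pf, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, pf)
    invisible(list(cohort = cohort, thresholds = thr, group = grp,
                   partition = part, report = report, files = written))
  }, error = on_fail)
}

# fixed-format numeric columns so identical runs are byte-identical
format_report <- function(report) {
  num <- vapply(report, is.numeric, TRUE)
  report[num] <- lapply(report[num], function(x) format(x, digits = 10))
  report
}
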