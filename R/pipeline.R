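#' Run the full analysis pipeline from a single configuration
#'
#' Orchestrates simulate (or load) -> outlier QC -> per-sector fits ->
#' posterior summaries -> paired-proportion comparison -> report, writing
#' every stage's output as CSV under `out_dir` together with a JSON run
#' manifest (config snapshot, seed, per-stage timings, convergence flags,
#' and an MD5 hash of every output file). Identical config and seed give
#' identical data hashes.
#'
#' The configuration is a nested list (or path to a YAML file) with
#' sections:
#' \describe{
#'   \item{seed}{integer, required; drives every stochastic stage.}
#'   \item{out_dir}{output directory, created if needed.}
#'   \item{data}{either `input_csv` (a cohort file to read) or `design`
#'     (fields of [cohort_design()]; `visit_count_draw` is not
#'     configurable from file).}
#'   \item{qc}{`enabled` (default TRUE), `k`, `min_n`.}
#'   \item{priors}{fields of [prior_spec()].}
#'   \item{sampler}{fields of [sampler_config()] except `seed`.}
#'   \item{sectors}{sectors to fit (default: sectors present in the data).}
#'   \item{summaries}{`level` (default 0.95).}
#'   \item{report}{`enabled` (default TRUE) to emit figures.}
#' }
#'
#' @param config A nested list or a YAML file path.
#' @return The run manifest, invisibly (a list, also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  if (is.null(config$out_dir)) stop("config$out_dir is required",
                                    call. = FALSE)
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(tool = paste0("rnfltrend ",
                                 as.character(utils::packageVersion("rnfltrend"))),
                   seed = seed, config = config,
                   stages = list(), files = list(), log = character())
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    manifest$log <<- c(manifest$log, msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    manifest$stages[[name]] <<- list(seconds = round(
      proc.time()[["elapsed"]] - t0, 3))
    res
  }
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    readr::write_csv(tibble::as_tibble(df), path, progress = FALSE)
    path
  }

  ## stage 1: obtain data --------------------------------------------------
  cohort <- stage("data", {
    if (!is.null(config$data$input_csv)) {
      note("reading cohort from ", config$data$input_csv)
      read_cohort(config$data$input_csv, min_visits = 0L)
    } else {
      design <- do.call(cohort_design, config$data$design %||% list())
      note("simulating cohort: ", design$n_eyes, " eyes, sectors ",
           paste(design$sectors, collapse = " "))
      gen <- generate_cohort(design, seed = seed)
      emit(gen$truth$effects, "truth_effects.csv")
      if (nrow(gen$truth$outliers) > 0) {
        emit(gen$truth$outliers, "truth_outliers.csv")
      }
      gen$cohort
    }
  })
  emit(cohort, "cohort.csv")

  ## stage 2: outlier QC ---------------------------------------------------
  qc_cfg <- config$qc %||% list()
  if (isTRUE(qc_cfg$enabled %||% TRUE)) {
    qc <- stage("qc", qc_cohort(cohort, k = qc_cfg$k %||% 4,
                                min_n = qc_cfg$min_n %||% 4L))
    note("qc: ", nrow(qc$report$flags), " flags, ",
         nrow(qc$report$removed_pairs), " cells removed from both devices (",
         "Spectralis-only ", qc$report$counts[["spectralis_only"]],
         ", Cirrus-only ", qc$report$counts[["cirrus_only"]],
         ", both ", qc$report$counts[["both"]], ")")
    emit(qc$report$flags, "qc_flags.csv")
    cohort <- qc$cohort
    emit(cohort, "cohort_clean.csv")
    manifest$qc_counts <- as.list(qc$report$counts)
  }

  ## stage 3: fits ---------------------------------------------------------
  priors <- do.call(prior_spec, config$priors %||% list())
  sampler_args <- config$sampler %||% list()
  sampler_args$seed <- seed
  cfg <- do.call(sampler_config, sampler_args)
  sectors <- config$sectors %||% sort(unique(cohort$sector))
  level <- config$summaries$level %||% 0.95

  fits <- stage("fit", lapply(sectors, function(sec) {
    note("fitting sector ", sec)
    fit <- suppressWarnings(
      fit_sector(cohort, sector = sec, priors = priors, config = cfg))
    if (length(fit$dropped_eyes) > 0) {
      note("sector ", sec, ": dropped eyes ",
           paste(fit$dropped_eyes, collapse = ", "),
           " (fewer than 2 visits)")
    }
    pd <- pop_draws(fit) |>
      tidyr::pivot_longer(-c("chain", "draw"), names_to = "parameter",
                          values_to = "value")
    emit(pd, paste0("draws_", sec, ".csv"))
    fit
  }))
  names(fits) <- sectors
  manifest$diagnostics <- lapply(fits, function(f) {
    list(converged = attr(f$diagnostics, "pass"),
         max_rhat = suppressWarnings(max(f$diagnostics$rhat, na.rm = TRUE)),
         min_ess = min(f$diagnostics$ess, na.rm = TRUE))
  })

  ## stage 4-5: summaries and comparisons ----------------------------------
  products <- stage("summarize", {
    summaries <- purrr::map_dfr(fits, function(f) {
      suppressWarnings(summarize_sector(f, level = level))
    })
    classification <- purrr::map_dfr(fits, function(f) {
      classify_slopes(f, level = level) |>
        dplyr::mutate(sector = f$sector, .before = 1)
    })
    proportions <- purrr::map_dfr(sectors, function(sec) {
      cls <- classification[classification$sector == sec, ]
      attr(cls, "sector") <- sec
      slope_proportions(cls) |> dplyr::mutate(sector = sec, .before = 1)
    })
    mcnemar <- purrr::map_dfr(sectors, function(sec) {
      cls <- classification[classification$sector == sec, ]
      attr(cls, "sector") <- sec
      dplyr::bind_rows(
        bayesian_mcnemar(cls, "negative", level = level),
        bayesian_mcnemar(cls, "positive", level = level)
      )
    })
    emit(summaries, "summary.csv")
    emit(classification, "classification.csv")
    emit(proportions, "proportions.csv")
    emit(mcnemar, "mcnemar.csv")
    list(summaries = summaries, classification = classification,
         proportions = proportions, mcnemar = mcnemar)
  })

  ## stage 6: report -------------------------------------------------------
  if (isTRUE(config$report$enabled %||% TRUE)) {
    stage("report", {
      plots <- render_report(products$summaries, products$proportions)
      for (nm in names(plots)) {
        ggplot2::ggsave(file.path(out_dir, paste0(nm, ".png")), plots[[nm]],
                        width = 7, height = 4, dpi = 150)
      }
      NULL
    })
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$files <- as.list(tools::md5sum(files))
  names(manifest$files) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

#' Assemble the reporting figures
#'
#' Produces the figures whose backing numbers are exactly the summary and
#' proportion tables passed in (which the pipeline also writes as CSV): rate
#' of change and residual-SD bar charts with significance markers, and
#' significant-slope percentage charts with counts annotated.
#'
#' @param summaries Row-bound [summarize_sector()] tables.
#' @param proportions Row-bound [slope_proportions()] tables with a `sector`
#'   column.
#' @return A named list of ggplot objects.
#' @export
render_report <- function(summaries, proportions) {
  stopifnot(nrow(summaries) > 0)
  list(
    roc = plot_roc(summaries),
    residual_sd = plot_residual_sd(summaries),
    prop_negative = plot_proportions(proportions, "negative"),
    prop_positive = plot_proportions(proportions, "positive")
  )
}
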