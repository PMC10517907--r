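#' Configuration for an end-to-end synthetic run
#'
#' Bundles everything a run needs: the cohort group specs, a small
#' signal-level phantom for the map-fitting stage, statistical options and a
#' seed. A config can be written to / read from JSON; the manifest emitted by
#' [run_pipeline()] records it together with the package version so a run can
#' be reproduced from the manifest alone.
#'
#' @param seed Integer seed driving every random stage.
#' @param out_dir Output directory.
#' @param adverse,non_adverse [group_spec()]s for the cohort stage.
#' @param phantom A [phantom_spec()] for the map-fitting demo stage, or
#'   `NULL` to skip it.
#' @param fit_model Model fitted on the phantom.
#' @param icc_reader_sd Reader noise SD (kPa) for the reader-agreement stage.
#' @param roc_parameters Parameters given individual ROC analyses.
#' @param correlation_method Method for the gestational-age correlation.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("placentadwi_run"),
                       adverse = group_spec("adverse"),
                       non_adverse = group_spec("non_adverse"),
                       phantom = phantom_spec(seed = seed),
                       fit_model = "ivim_segmented",
                       icc_reader_sd = 0.3,
                       roc_parameters = c("mu_diff", "f"),
                       correlation_method = "spearman") {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 adverse = adverse, non_adverse = non_adverse,
                 phantom = phantom, fit_model = fit_model,
                 icc_reader_sd = icc_reader_sd,
                 roc_parameters = roc_parameters,
                 correlation_method = correlation_method),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full synthetic pipeline
#'
#' Stages, mirroring the analysis workflow: simulate a cohort; fit the
#' phantom and summarize its ROIs; simulate repeated reads and compute
#' reader-agreement ICC; group-compare every quantitative parameter; select
#' and fit the multivariable logistic risk model; ROC per parameter plus the
#' combined logistic score; gestational-age correlation. All tabular outputs
#' are written as CSV/JSON under `config$out_dir` along with a manifest
#' (package version, seed, config). Deterministic: rerunning with the same
#' config reproduces all outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- stage("simulate_cohort",
                  simulate_cohort(config$adverse, config$non_adverse,
                                  seed = config$seed))
  stage("write_cohort",
        write_cohort(cohort, file.path(config$out_dir, "cohort.csv")))

  roi <- NULL
  if (!is.null(config$phantom)) {
    roi <- stage("phantom_fit", {
      ph <- simulate_phantom(config$phantom)
      maps <- fit_volume(ph$series, ph$mask, model = config$fit_model)
      for (p in names(maps))
        write_parameter_map(maps[[p]],
                            file.path(config$out_dir,
                                      sprintf("map_%s.nii.gz", p)))
      summaries <- do.call(rbind, lapply(names(maps), function(p)
        roi_summary(maps[[p]], ph$mask, subject_id = "phantom")))
      utils::write.csv(summaries,
                       file.path(config$out_dir, "roi_summaries.csv"),
                       row.names = FALSE)
      summaries
    })
  }

  icc_res <- stage("reader_agreement", {
    ratings <- simulate_reader_pair(cohort$mu_diff,
                                    reader_sd = config$icc_reader_sd,
                                    seed = config$seed + 1L)
    icc(ratings, model = "two_way_random_absolute")
  })

  params <- intersect(c("mu_diff", "f", "D", "Dstar", "DDC", "Alpha", "ADC"),
                      names(cohort))
  comparisons <- stage("group_comparison", {
    res <- lapply(params, function(p) compare_groups(cohort, p))
    names(res) <- params
    tab <- data.frame(parameter = params,
                      test = vapply(res, `[[`, "", "test"),
                      statistic = vapply(res, `[[`, 1.0, "statistic"),
                      p = vapply(res, `[[`, 1.0, "p"))
    utils::write.csv(tab, file.path(config$out_dir, "group_comparisons.csv"),
                     row.names = FALSE)
    res
  })

  risk <- stage("logistic_model", select_risk_model(cohort, params))
  if (!is.null(risk$model))
    utils::write.csv(risk$model$terms,
                     file.path(config$out_dir, "logistic_terms.csv"),
                     row.names = FALSE)

  rocs <- stage("roc_analysis", {
    res <- lapply(config$roc_parameters, function(p)
      roc_analysis(cohort[[p]], cohort$group))
    names(res) <- config$roc_parameters
    if (!is.null(risk$model) && length(risk$selected) > 1L) {
      combined <- stats::predict(risk$model$fit, type = "link")
      res$combined <- roc_analysis(combined, cohort$group)
    }
    tab <- data.frame(score = names(res),
                      auc = vapply(res, `[[`, 1.0, "auc"),
                      ci_low = vapply(res, `[[`, 1.0, "ci_low"),
                      ci_high = vapply(res, `[[`, 1.0, "ci_high"),
                      cutoff = vapply(res, `[[`, 1.0, "cutoff"),
                      sensitivity = vapply(res, `[[`, 1.0, "sensitivity"),
                      specificity = vapply(res, `[[`, 1.0, "specificity"))
    utils::write.csv(tab, file.path(config$out_dir, "roc_results.csv"),
                     row.names = FALSE)
    res
  })

  ga_cor <- stage("ga_correlation",
                  ga_correlation(cohort, "mu_diff",
                                 method = config$correlation_method))

  manifest <- list(
    package = "placentadwi",
    version = as.character(utils::packageVersion("placentadwi")),
    seed = config$seed,
    config = serialize_config(config),
    outputs = list.files(config$out_dir))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, roi = roi, icc = icc_res,
                 comparisons = comparisons, risk = risk, roc = rocs,
                 ga_correlation = ga_cor, out_dir = config$out_dir))
}

serialize_config <- function(config) {
  gs <- function(s) list(name = s$name, n = s$n,
                         parameter_means = as.list(s$parameter_means),
                         parameter_sds = as.list(s$parameter_sds),
                         correlation = s$correlation,
                         covariates = s$covariates)
  list(seed = config$seed,
       adverse = gs(config$adverse),
       non_adverse = gs(config$non_adverse),
       phantom = if (is.null(config$phantom)) NULL else
         unclass(config$phantom),
       fit_model = config$fit_model,
       icc_reader_sd = config$icc_reader_sd,
       roc_parameters = config$roc_parameters,
       correlation_method = config$correlation_method)
}
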