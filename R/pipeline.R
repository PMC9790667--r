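#' Pipeline run configuration
#'
#' @param manifest path to a manifest CSV (`subject_id, edf_path,
#'   lesion_side, outcome`, optional sidecar columns), or `NULL` when an
#'   in-memory cohort is supplied to [run_pipeline()].
#' @param n2_sidecar,bad_sidecar optional sidecar CSV paths (N2 segments /
#'   bad derivations per subject).
#' @param params a [detector_params()].
#' @param regions region map, see [region_map()].
#' @param cutoff SPA cut-off for diagnostics.
#' @param p_enter,p_remove stepwise logistic thresholds.
#' @param alpha significance level for group comparisons.
#' @param hp_hz,lp_hz acquisition band.
#' @param min_n2_s minimum N2 duration per subject.
#' @param output_dir where [run_pipeline()] writes reports (`NULL` = no
#'   files).
#' @param seed seed recorded in run metadata (the analysis itself is
#'   deterministic).
#' @return object of class `run_config`.
#' @export
run_config <- function(manifest = NULL, n2_sidecar = NULL, bad_sidecar = NULL,
                       params = detector_params(), regions = region_map(),
                       cutoff = 0.65, p_enter = 0.05, p_remove = 0.1,
                       alpha = 0.05, hp_hz = 0.3, lp_hz = 70,
                       min_n2_s = 300, output_dir = NULL, seed = 1) {
  structure(list(manifest = manifest, n2_sidecar = n2_sidecar,
                 bad_sidecar = bad_sidecar, params = params,
                 regions = regions, cutoff = cutoff, p_enter = p_enter,
                 p_remove = p_remove, alpha = alpha, hp_hz = hp_hz,
                 lp_hz = lp_hz, min_n2_s = min_n2_s,
                 output_dir = output_dir, seed = seed),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Round-trips losslessly through file serialization (the region map and
#' detector parameters included).
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$params <- unclass(x$params)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$params <- do.call(detector_params, x$params)
  x$regions <- lapply(x$regions, unlist)
  do.call(run_config, x)
}

#' Process one subject: filtered EEG to SPA indexes
#'
#' @param rec a [raw_recording()].
#' @param lesion_side `"left"` or `"right"`.
#' @param config a [run_config()].
#' @param segments N2 segments (`NULL` = from annotations).
#' @param excluded bad derivations.
#' @return list with `indexes` (a [spa_indexes()] result) and `events`.
#' @export
process_subject <- function(rec, lesion_side, config = run_config(),
                            segments = NULL, excluded = character(0)) {
  ## The acquisition band-pass and the detector's sigma filter are both
  ## zero-phase frequency-domain transfers, so applying both equals applying
  ## the sigma filter alone whenever the acquisition passband is flat across
  ## the sigma band; the redundant pass is skipped in that case (the
  ## detector and all downstream quantities are unchanged).
  absorbed <- config$hp_hz <= config$params$sigma_band[1] - 1 &&
    config$lp_hz >= config$params$sigma_band[2] + 1
  if (!absorbed || rec$fs != 256) {
    rec <- apply_filters(rec, config$hp_hz, config$lp_hz)
  }
  derivs <- unique(unlist(config$regions))
  bip <- make_bipolar(rec, derivations = derivs, excluded = excluded)
  bip <- extract_n2(bip, segments, min_total_s = config$min_n2_s)
  events <- detect_spindles(bip, config$params, min_total_s = config$min_n2_s)
  list(indexes = spa_indexes(events, lesion_side,
                             subject_id = rec$subject_id,
                             regions = config$regions, excluded = excluded),
       events = events)
}

#' Run the full pipeline over a cohort
#'
#' Stages mirror the analysis order: spindle detection per subject, SPA
#' index computation, then the statistical stage ([analyze_cohort()]).
#' Subjects failing eligibility (insufficient N2 sleep, unreadable files,
#' missing electrodes) are excluded and logged, not fatal.
#'
#' @param config a [run_config()]; `config$manifest` names the input files,
#'   unless `cohort` is given.
#' @param cohort optionally, a `synthetic_cohort` from [synth_cohort()]
#'   processed in memory (no EDF round-trip).
#' @return object of class `pipeline_result`: `spa_table`, `report` (a
#'   `diagnostic_report`, or `NULL` if only one outcome class), `exclusions`,
#'   `config`. With `config$output_dir`, the SPA table (CSV), report (JSON +
#'   Markdown) and run metadata are written there.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  exclusions <- list()
  index_sets <- list()
  outcomes <- character(0)

  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "synthetic_cohort"))
    meta <- cohort$metadata
    for (i in seq_len(nrow(meta))) {
      id <- meta$subject_id[i]
      res <- tryCatch({
        sub <- synth_subject(cohort$subject_specs[[i]])
        process_subject(sub$recording, meta$lesion_side[i], config,
                        segments = sub$segments)
      }, spindlespa_error = function(e) e)
      if (inherits(res, "error")) {
        exclusions[[id]] <- conditionMessage(res)
      } else {
        index_sets[[id]] <- res$indexes
        outcomes[id] <- meta$group[i]
      }
    }
  } else {
    assert_that(!is.null(config$manifest), "parameter",
                "config$manifest or a cohort is required")
    manifest <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
    assert_that(nrow(manifest) >= 1, "parameter", "empty manifest")
    for (i in seq_len(nrow(manifest))) {
      id <- manifest$subject_id[i]
      res <- tryCatch({
        rec <- read_edf(manifest$edf_path[i])
        rec$subject_id <- id
        segments <- NULL
        if (!is.null(config$n2_sidecar)) {
          sc <- read_sidecar(config$n2_sidecar, id)
          if (nrow(sc)) segments <- n2_segments(sc$start_s, sc$end_s)
        }
        excluded <- character(0)
        if (!is.null(config$bad_sidecar)) {
          bc <- read_sidecar(config$bad_sidecar, id)
          excluded <- bc$derivation
        }
        process_subject(rec, manifest$lesion_side[i], config,
                        segments = segments, excluded = excluded)
      }, spindlespa_error = function(e) e)
      if (inherits(res, "error")) {
        exclusions[[id]] <- conditionMessage(res)
      } else {
        index_sets[[id]] <- res$indexes
        outcomes[id] <- manifest$outcome[i]
      }
    }
  }

  assert_that(length(index_sets) > 0, "eligibility",
              "no eligible subjects remain")
  tab <- spa_table(index_sets, outcomes)
  report <- NULL
  if (length(unique(stats::na.omit(tab$outcome))) == 2) {
    report <- analyze_cohort(tab, config)
  } else {
    message("only one outcome class present; statistical stage skipped")
  }
  out <- structure(list(spa_table = tab, report = report,
                        exclusions = exclusions, config = config),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_outputs(out)
  out
}

#' Statistical stage over a cohort SPA table
#'
#' Reproduces the biomarker evaluation: Shapiro-Wilk normality gate (logged),
#' Mann-Whitney comparison of each of the 15 SPA indexes between outcome
#' groups (raw p-values, with Holm-adjusted values in a separate column for
#' transparency), forward-conditional logistic selection over the indexes
#' significant at `alpha`, ROC/AUC of the best predictor, diagnostics at the
#' SPA cut-off, and Grubbs outlier screening overall and per group.
#'
#' @param tab a [spa_table()] with a binary `outcome` column
#'   (`"UCP"` / `"typical"`).
#' @param config a [run_config()] (thresholds are taken from it).
#' @return object of class `diagnostic_report`.
#' @export
analyze_cohort <- function(tab, config = run_config()) {
  idx <- intersect(spa_index_names(), names(tab))
  is_ucp <- tab$outcome == "UCP"
  assert_that(any(is_ucp) && any(!is_ucp), "parameter",
              "both outcome classes are required")

  comparisons <- do.call(rbind, lapply(idx, function(v) {
    u <- tab[[v]][is_ucp]; t <- tab[[v]][!is_ucp]
    sw_u <- tryCatch(shapiro_wilk(u)$p, spindlespa_error = function(e) NA_real_)
    sw_t <- tryCatch(shapiro_wilk(t)$p, spindlespa_error = function(e) NA_real_)
    mw <- mann_whitney_u(u, t)
    data.frame(index = v,
               median_ucp = mw$median["a"], iqr_ucp = mw$iqr["a"],
               median_typical = mw$median["b"], iqr_typical = mw$iqr["b"],
               U = mw$U, p = mw$p, method = mw$method,
               shapiro_p_ucp = sw_u, shapiro_p_typical = sw_t,
               n_ucp = sum(!is.na(u)), n_typical = sum(!is.na(t)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  comparisons$p_holm <- stats::p.adjust(comparisons$p, method = "holm")

  significant <- comparisons$index[!is.na(comparisons$p) &
                                     comparisons$p < config$alpha]
  selection <- NULL
  best_index <- NULL
  roc <- NULL
  diagnostics <- NULL
  if (length(significant) >= 1) {
    df <- tab[, c("outcome", significant), drop = FALSE]
    df$.ucp <- as.integer(is_ucp)
    selection <- tryCatch(
      suppressWarnings(
        forward_conditional_logistic(df, significant, ".ucp",
                                     p_enter = config$p_enter,
                                     p_remove = config$p_remove)),
      spindlespa_error = function(e) NULL)
    best_index <- if (!is.null(selection) && length(selection$selected)) {
      selection$selected[1]
    } else {
      significant[which.min(comparisons$p[match(significant,
                                                comparisons$index)])]
    }
    roc <- roc_auc(tab[[best_index]], is_ucp)
    diagnostics <- diagnostic_metrics(tab[[best_index]], is_ucp,
                                      cutoff = config$cutoff)
  }

  grubbs <- do.call(rbind, lapply(idx, function(v) {
    vals <- stats::setNames(tab[[v]], tab$subject_id)
    groups <- list(all = vals, UCP = vals[is_ucp], typical = vals[!is_ucp])
    do.call(rbind, lapply(names(groups), function(g) {
      r <- tryCatch(grubbs_test(groups[[g]]),
                    spindlespa_error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(index = v, group = g, G = r$G, critical = r$critical,
                 outlier_id = r$outlier, stringsAsFactors = FALSE)
    }))
  }))

  structure(list(comparisons = comparisons, significant = significant,
                 selection = selection, best_index = best_index,
                 roc = roc, diagnostics = diagnostics, grubbs = grubbs,
                 alpha = config$alpha, cutoff = config$cutoff,
                 n = c(UCP = sum(is_ucp), typical = sum(!is_ucp))),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("Diagnostic report: %d UCP vs %d typical\n",
              x$n["UCP"], x$n["typical"]))
  sig <- x$comparisons[!is.na(x$comparisons$p) & x$comparisons$p < x$alpha, ]
  cat(sprintf("  %d of %d SPA indexes significant at alpha = %.2f\n",
              nrow(sig), nrow(x$comparisons), x$alpha))
  if (!is.null(x$best_index)) {
    cat(sprintf("  best predictor: %s (AUC %.3f)\n", x$best_index, x$roc$auc))
    d <- x$diagnostics
    cat(sprintf("  at SPA < %.2f: sens %.1f%%, spec %.1f%%, PPV %.1f%%, NPV %.1f%%\n",
                d$cutoff, 100 * d$sensitivity, 100 * d$specificity,
                100 * d$ppv, 100 * d$npv))
  }
  invisible(x)
}

#' Flatten a diagnostic report into plain lists
#'
#' Machine-readable form of a `diagnostic_report`, as written to
#' `report.json`; useful for programmatic comparison of runs.
#' @param report a `diagnostic_report` from [analyze_cohort()].
#' @return nested list of plain vectors and data frames.
#' @export
report_as_list <- function(report) {
  list(n = as.list(report$n),
       alpha = report$alpha, cutoff = report$cutoff,
       comparisons = report$comparisons,
       significant = report$significant,
       selection = if (!is.null(report$selection))
         list(selected = report$selection$selected,
              coefficients = report$selection$coefficients,
              nagelkerke_r2 = report$selection$nagelkerke_r2,
              classification_accuracy = report$selection$classification_accuracy,
              separation = report$selection$separation),
       best_index = report$best_index,
       roc = if (!is.null(report$roc))
         list(auc = report$roc$auc, se = report$roc$se,
              ci95 = report$roc$ci95, orientation = report$roc$orientation),
       diagnostics = if (!is.null(report$diagnostics))
         unclass(report$diagnostics),
       grubbs = report$grubbs)
}

#' Write pipeline outputs
#'
#' SPA table as CSV, the report as JSON (machine) and Markdown (human), the
#' ROC curve as CSV, and run metadata (config, package version, exclusions).
#' Every number in the Markdown table is taken verbatim from the JSON
#' content.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (defaults to `config$output_dir`).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir = NULL) {
  dir <- dir %||% result$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$spa_table, file.path(dir, "spa_table.csv"),
                   row.names = FALSE, na = "")
  meta <- list(package_version = as.character(utils::packageVersion("spindlespa")),
               config = list(cutoff = result$config$cutoff,
                             p_enter = result$config$p_enter,
                             p_remove = result$config$p_remove,
                             alpha = result$config$alpha,
                             hp_hz = result$config$hp_hz,
                             lp_hz = result$config$lp_hz,
                             min_n2_s = result$config$min_n2_s,
                             seed = result$config$seed,
                             params = unclass(result$config$params)),
               exclusions = result$exclusions)
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(result$report)) {
    jsonlite::write_json(report_as_list(result$report),
                         file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    writeLines(report_markdown(result$report), file.path(dir, "report.md"))
    if (!is.null(result$report$roc)) {
      utils::write.csv(result$report$roc$curve,
                       file.path(dir, "roc_curve.csv"), row.names = FALSE)
    }
  }
  invisible(dir)
}

report_markdown <- function(report) {
  cmp <- report$comparisons
  lines <- c("# Spindle power asymmetry report", "",
             sprintf("Cohort: %d UCP vs %d typical outcome.",
                     report$n["UCP"], report$n["typical"]), "",
             "## Group comparisons (Mann-Whitney U)", "",
             "| Index | Median UCP | IQR UCP | Median typical | IQR typical | U | p | p (Holm) |",
             "|---|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(cmp))) {
    lines <- c(lines, sprintf("| %s | %.2f | %.2f | %.2f | %.2f | %.2f | %s | %s |",
                              cmp$index[i], cmp$median_ucp[i], cmp$iqr_ucp[i],
                              cmp$median_typical[i], cmp$iqr_typical[i],
                              cmp$U[i], format_p(cmp$p[i]),
                              format_p(cmp$p_holm[i])))
  }
  if (!is.null(report$best_index)) {
    d <- report$diagnostics
    lines <- c(lines, "", "## Outcome prediction", "",
               sprintf("Best predictor: **%s**.", report$best_index),
               sprintf("AUC = %.3f (SE %.3f, 95%% CI %.3f-%.3f).",
                       report$roc$auc, report$roc$se,
                       report$roc$ci95[1], report$roc$ci95[2]),
               sprintf("At SPA < %.2f: sensitivity %.1f%%, specificity %.1f%%, PPV %.1f%%, NPV %.1f%% (tp %d, fp %d, tn %d, fn %d).",
                       d$cutoff, 100 * d$sensitivity, 100 * d$specificity,
                       100 * d$ppv, 100 * d$npv, d$tp, d$fp, d$tn, d$fn))
    if (!is.null(report$selection)) {
      lines <- c(lines,
                 sprintf("Stepwise logistic model: %s; Nagelkerke R2 = %.3f; %.1f%% correctly classified.%s",
                         if (length(report$selection$selected))
                           paste(report$selection$selected, collapse = " + ")
                         else "(empty)",
                         report$selection$nagelkerke_r2,
                         100 * report$selection$classification_accuracy,
                         if (report$selection$separation)
                           " Separation detected; penalized coefficients." else ""))
    }
  }
  lines
}

format_p <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 0.001) "<0.001" else sprintf("%.3f", p)
}
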