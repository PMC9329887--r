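#' Run configuration
#'
#' Bundles the quantification settings, response criteria and survival options
#' for a full pipeline run; serialized (as JSON) with every report so results
#' are traceable to their settings.
#'
#' @param qeasl a \code{qeasl_config}.
#' @param criteria a \code{response_criteria}.
#' @param censoring_mode \code{"censor"} (default) or \code{"drop_censored"}
#'   (replication of analyses that excluded alive/lost patients).
#' @param reference_mode volume reference per session: \code{"previous"}
#'   (default; session k is judged against the most recent pre-session
#'   imaging) or \code{"baseline"} (always against session-1 reference).
#' @param entry_p univariate p threshold for multivariate Cox entry.
#' @param seed integer seed recorded with the run.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(qeasl = qeasl_config(), criteria = response_criteria(),
                       censoring_mode = c("censor", "drop_censored"),
                       reference_mode = c("previous", "baseline"),
                       entry_p = 0.10, seed = 1L) {
  structure(list(qeasl = qeasl, criteria = criteria,
                 censoring_mode = match.arg(censoring_mode),
                 reference_mode = match.arg(reference_mode),
                 entry_p = entry_p, seed = as.integer(seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run_config: k=%g, PR<=-%g%%, PD>=+%g%%, censoring=%s, reference=%s, seed=%d\n",
              x$qeasl$enhancement_k, 100 * x$criteria$pr_decrease,
              100 * x$criteria$pd_increase, x$censoring_mode, x$reference_mode, x$seed))
  invisible(x)
}

#' Measure every lesion in an image manifest
#'
#' Runs the per-lesion quantification over a manifest of NIfTI files, one row
#' per lesion-session-reader, then averages readers per lesion-session.
#' Row-level failures (missing files, ROI placement errors) are collected and
#' reported; the remaining rows are still processed.
#'
#' @param config a \code{run_config}.
#' @param manifest data.frame with columns \code{session_id},
#'   \code{lesion_id}, \code{reader_id}, \code{arterial}, \code{unenhanced},
#'   \code{mask} (file paths) and \code{roi_x}, \code{roi_y}, \code{roi_z}
#'   (reference-ROI center, mm).
#' @return list with \code{measurements} (per reader),
#'   \code{averaged} (per lesion-session, reader_id \code{"mean"}) and
#'   \code{errors} (data.frame row, message). Empty manifest gives empty
#'   tables with a warning.
#' @export
run_measure <- function(config, manifest) {
  stopifnot(inherits(config, "run_config"))
  cols <- c("session_id", "lesion_id", "reader_id", "arterial", "unenhanced",
            "mask", "roi_x", "roi_y", "roi_z")
  if (!is.data.frame(manifest) || nrow(manifest) == 0) {
    warning("empty manifest: nothing to measure", call. = FALSE)
    return(list(measurements = data.frame(), averaged = data.frame(),
                errors = data.frame(row = integer(), message = character())))
  }
  if (!all(cols %in% names(manifest)))
    stop("manifest needs columns: ", paste(cols, collapse = ", "), call. = FALSE)
  meas <- list(); errs <- list()
  for (r in seq_len(nrow(manifest))) {
    row <- manifest[r, ]
    res <- tryCatch({
      for (f in c(row$arterial, row$unenhanced, row$mask))
        if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
      art <- read_volume(row$arterial, "arterial_T1")
      une <- read_volume(row$unenhanced, "unenhanced_T1")
      tum <- read_mask(row$mask, row$lesion_id)
      m <- measure_lesion(art, une, tum,
                          roi_spec(c(row$roi_x, row$roi_y, row$roi_z)),
                          cfg = config$qeasl,
                          session_id = row$session_id, reader_id = row$reader_id)
      m
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(row = r, message = conditionMessage(res),
                                              stringsAsFactors = FALSE)
    } else meas[[length(meas) + 1L]] <- res
  }
  measurements <- if (length(meas)) do.call(rbind, meas) else data.frame()
  averaged <- if (nrow(measurements)) {
    key <- interaction(measurements$lesion_id, measurements$session_id, drop = TRUE)
    do.call(rbind, lapply(split(measurements, key), average_readers))
  } else data.frame()
  rownames(averaged) <- NULL
  list(measurements = measurements, averaged = averaged,
       errors = if (length(errs)) do.call(rbind, errs)
                else data.frame(row = integer(), message = character()))
}

## Re-derive per-session assessments from a patient's stored volume sums,
## honoring the configured reference mode.
assess_patient <- function(patient, config) {
  s <- patient$sessions
  base_ref <- s$sum_enh_ref_cm3[1]
  rows <- lapply(seq_len(nrow(s)), function(k) {
    ref <- if (config$reference_mode == "baseline") base_ref else s$sum_enh_ref_cm3[k]
    classify_response(ref, s$sum_enh_post_cm3[k], config$criteria,
                      cr_epsilon_cm3 = config$qeasl$cr_epsilon_cm3,
                      patient_id = patient$patient_id, session_index = k)
  })
  do.call(rbind, rows)
}

#' Full cohort analysis
#'
#' End-to-end run over a cohort of patient records carrying per-session
#' enhancing-volume sums: re-derives each session's CR/PR/SD/PD category,
#' labels each patient's course (initial/secondary responder, non-responder,
#' window exclusion, lost to follow-up), tabulates the treatment flow, and
#' compares overall survival of responders (initial or secondary) versus
#' non-responders with Kaplan-Meier, log-rank and Cox models. Deterministic:
#' no randomness beyond what the input records already contain.
#'
#' @param config a \code{run_config}.
#' @param patients list of \code{patient_record}s with sessions carrying
#'   \code{sum_enh_ref_cm3}/\code{sum_enh_post_cm3} and survival fields.
#' @return A list of class \code{run_report}: \code{assessments},
#'   \code{labels}, \code{flow}, \code{survival} (NULL when either group is
#'   empty or lacks events; otherwise km_responder, km_nonresponder, logrank,
#'   cox), \code{notes}, \code{config}.
#' @export
run_full <- function(config, patients) {
  stopifnot(inherits(config, "run_config"))
  if (length(patients) == 0) stop("empty cohort", call. = FALSE)
  assessments <- do.call(rbind, lapply(patients, assess_patient, config = config))
  relabeled <- lapply(patients, function(p) {
    a <- assessments[assessments$patient_id == p$patient_id, ]
    p$sessions$category <- a$category[match(p$sessions$session_index, a$session_index)]
    p
  })
  labels <- do.call(rbind, lapply(relabeled, label_sessions, criteria = config$criteria))
  flow <- cohort_flow(relabeled, config$criteria)
  grp <- ifelse(labels$label %in% c("initial_responder", "secondary_responder"),
                "responder", as.character(labels$label))
  analyzable <- grp %in% c("responder", "non_responder") &
    vapply(relabeled, function(p) is.finite(p$time_months) && !is.na(p$event), logical(1))
  notes <- character(0)
  surv <- NULL
  if (any(analyzable)) {
    rec <- survival_records(
      patient_id = labels$patient_id[analyzable],
      time_months = vapply(relabeled[analyzable], `[[`, numeric(1), "time_months"),
      event = vapply(relabeled[analyzable], `[[`, logical(1), "event"),
      group = grp[analyzable], censoring_mode = config$censoring_mode)
    ga <- rec[rec$group == "responder", ]
    gb <- rec[rec$group == "non_responder", ]
    if (nrow(ga) == 0 || nrow(gb) == 0 || sum(rec$event) == 0) {
      notes <- c(notes, "survival comparison skipped: a response group is empty or no events")
    } else {
      rec$non_response <- rec$group == "non_responder"
      surv <- list(records = rec,
                   km_responder = km_fit(ga),
                   km_nonresponder = km_fit(gb),
                   logrank = logrank_test(ga, gb),
                   cox = cox_fit(rec, "non_response", mode = "univariate"))
    }
  } else notes <- c(notes, "survival comparison skipped: no analyzable patients")
  out <- list(assessments = assessments, labels = labels, flow = flow,
              survival = surv, notes = notes, config = config)
  class(out) <- "run_report"
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("qEASL cohort run\n")
  print(x$config)
  cat(sprintf("patients: %d; sessions assessed: %d\n",
              nrow(x$labels), nrow(x$assessments)))
  print(table(x$labels$label))
  if (!is.null(x$survival)) {
    cat("\nresponders:      "); print(x$survival$km_responder)
    cat("non-responders:  "); print(x$survival$km_nonresponder)
    cat(sprintf("log-rank: chisq=%.3f, p=%.4f\n",
                x$survival$logrank$chisq, x$survival$logrank$p))
    cat(sprintf("Cox non-response HR=%.3f (95%% CI %.3f-%.3f), p=%.4f\n",
                x$survival$cox$hr, x$survival$cox$ci_lower,
                x$survival$cox$ci_upper, x$survival$cox$p))
  }
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' Serialize a run configuration to JSON
#'
#' @param config a \code{run_config}.
#' @param file optional path to write to.
#' @return JSON string (invisibly when written to file).
#' @export
config_json <- function(config, file = NULL) {
  stopifnot(inherits(config, "run_config"))
  x <- list(qeasl = unclass(config$qeasl), criteria = unclass(config$criteria),
            censoring_mode = config$censoring_mode,
            reference_mode = config$reference_mode,
            entry_p = config$entry_p, seed = config$seed)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(file)) { writeLines(js, file); return(invisible(js)) }
  js
}
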