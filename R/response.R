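#' qEASL response criteria
#'
#' Thresholds and target-lesion rules for volumetric response categorization:
#' partial response (PR) is a >= 65\% decrease and progressive disease (PD) a
#' >= 73\% increase of the summed enhancing-tumor volume of the target
#' lesions; complete response (CR) is disappearance of all enhancing tissue;
#' anything else is stable disease (SD). Both bounds are closed (-65.0\% is
#' PR, +73.0\% is PD). Up to two target lesions are analyzed per patient,
#' each therapy-naive, artifact-free, and over 1 cm in diameter. A repeat
#' treatment counts toward secondary response only when delivered within
#' 3 months (months of 30.4375 days) of the initial non-response.
#'
#' @param pr_decrease fraction decrease for PR (default 0.65).
#' @param pd_increase fraction increase for PD (default 0.73).
#' @param max_target_lesions maximum target lesions per patient (default 2).
#' @param min_lesion_diameter_cm minimum eligible diameter (default 1).
#' @param retreat_window_months window for a counted repeat session (default 3).
#' @return An object of class \code{response_criteria}.
#' @export
response_criteria <- function(pr_decrease = 0.65, pd_increase = 0.73,
                              max_target_lesions = 2L,
                              min_lesion_diameter_cm = 1.0,
                              retreat_window_months = 3.0) {
  if (!(pr_decrease > 0 && pr_decrease < 1)) stop("`pr_decrease` must be in (0,1)", call. = FALSE)
  if (!(pd_increase > 0)) stop("`pd_increase` must be > 0", call. = FALSE)
  structure(list(pr_decrease = pr_decrease, pd_increase = pd_increase,
                 max_target_lesions = as.integer(max_target_lesions),
                 min_lesion_diameter_cm = min_lesion_diameter_cm,
                 retreat_window_months = retreat_window_months),
            class = "response_criteria")
}

#' Days per month used when converting dates to months
#' @export
DAYS_PER_MONTH <- 30.4375

response_levels <- c("CR", "PR", "SD", "PD")

#' Select target lesions
#'
#' Filters lesions to those that are therapy-naive, artifact-free on MR, and
#' over the minimum diameter, ranks the remainder by descending diameter
#' (ties broken by lesion id, ascending), and keeps at most
#' \code{criteria$max_target_lesions}.
#'
#' @param lesions data.frame with columns \code{lesion_id},
#'   \code{diameter_cm}, \code{therapy_naive}, \code{artifact_free}.
#' @param criteria a \code{response_criteria}.
#' @return Character vector of selected lesion ids.
#' @export
select_target_lesions <- function(lesions, criteria = response_criteria()) {
  req <- c("lesion_id", "diameter_cm", "therapy_naive", "artifact_free")
  if (!is.data.frame(lesions) || nrow(lesions) == 0)
    stop("`lesions` must be a non-empty data.frame", call. = FALSE)
  if (!all(req %in% names(lesions)))
    stop("`lesions` needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  ok <- lesions$therapy_naive & lesions$artifact_free &
    lesions$diameter_cm > criteria$min_lesion_diameter_cm
  el <- lesions[ok, , drop = FALSE]
  if (nrow(el) == 0)
    stop("no eligible target lesion (therapy-naive, artifact-free, diameter > ",
         criteria$min_lesion_diameter_cm, " cm); patient excluded", call. = FALSE)
  el <- el[order(-el$diameter_cm, as.character(el$lesion_id)), , drop = FALSE]
  as.character(utils::head(el$lesion_id, criteria$max_target_lesions))
}

#' Percent change of summed enhancing volume
#'
#' \code{100 * (post - ref) / ref}. When both sums are zero the change is 0
#' (sustained complete response). When the reference is zero but enhancement
#' reappears the percent change is undefined (\code{NA}) and classification
#' treats the case as progression directly.
#'
#' @param sum_ref,sum_post non-negative summed enhancing volumes (cm^3).
#' @return Signed percent change, or \code{NA} when undefined.
#' @export
percent_change <- function(sum_ref, sum_post) {
  if (!is.finite(sum_ref) || !is.finite(sum_post) || sum_ref < 0 || sum_post < 0)
    stop("volumes must be finite and non-negative", call. = FALSE)
  if (sum_ref == 0) {
    if (sum_post == 0) return(0)
    return(NA_real_)
  }
  100 * (sum_post - sum_ref) / sum_ref
}

#' Classify a qEASL response
#'
#' Categorizes one patient-session from the summed enhancing volumes of the
#' target lesions at the reference timepoint and after treatment. CR when the
#' post volume is at or below \code{cr_epsilon_cm3}; else PR when the change
#' is <= -100*pr_decrease \%; PD when >= +100*pd_increase \% (or when
#' enhancement reappears from zero); otherwise SD. Responder means CR or PR.
#'
#' @param sum_ref,sum_post summed enhancing volumes (cm^3) over target lesions.
#' @param criteria a \code{response_criteria}.
#' @param cr_epsilon_cm3 CR tolerance (default 0).
#' @param patient_id,session_index identifiers carried into the output.
#' @return A one-row data.frame of class \code{response_assessment}:
#'   patient_id, session_index, sum_enh_ref_cm3, sum_enh_post_cm3,
#'   percent_change, category (factor CR/PR/SD/PD), responder.
#' @export
classify_response <- function(sum_ref, sum_post, criteria = response_criteria(),
                              cr_epsilon_cm3 = 0, patient_id = NA_character_,
                              session_index = 1L) {
  if (!is.finite(sum_ref) || !is.finite(sum_post) || sum_ref < 0 || sum_post < 0)
    stop("volumes must be finite and non-negative", call. = FALSE)
  pc <- percent_change(sum_ref, sum_post)
  category <- if (sum_post <= cr_epsilon_cm3) {
    "CR"
  } else if (is.na(pc)) {
    "PD"  # enhancement reappeared from a zero reference
  } else if (pc <= -100 * criteria$pr_decrease) {
    "PR"
  } else if (pc >= 100 * criteria$pd_increase) {
    "PD"
  } else {
    "SD"
  }
  out <- data.frame(patient_id = as.character(patient_id),
                    session_index = as.integer(session_index),
                    sum_enh_ref_cm3 = sum_ref, sum_enh_post_cm3 = sum_post,
                    percent_change = pc,
                    category = factor(category, levels = response_levels),
                    responder = category %in% c("CR", "PR"),
                    stringsAsFactors = FALSE)
  class(out) <- c("response_assessment", "data.frame")
  out
}

#' Per-patient session record
#'
#' A light container for one patient's treatment course: an ordered sessions
#' table plus optional survival fields used downstream.
#'
#' @param patient_id identifier.
#' @param sessions data.frame with one row per treatment session, ordered by
#'   time, with columns \code{session_index}, \code{months_since_prev}
#'   (months from the previous session's response imaging to this treatment;
#'   0 or NA for the first session), \code{category} (CR/PR/SD/PD or NA when
#'   imaging is missing) and optionally \code{has_imaging} (default TRUE).
#' @param time_months,event optional overall-survival time from first
#'   treatment (months) and death indicator.
#' @param covariates optional named list of baseline covariates.
#' @return An object of class \code{patient_record}.
#' @export
patient_record <- function(patient_id, sessions, time_months = NA_real_,
                           event = NA, covariates = list()) {
  stopifnot(is.data.frame(sessions), nrow(sessions) >= 1)
  if (!all(c("session_index", "category") %in% names(sessions)))
    stop("`sessions` needs columns session_index and category", call. = FALSE)
  if (is.unsorted(sessions$session_index, strictly = TRUE))
    stop("sessions must be strictly ordered by session_index", call. = FALSE)
  if (!"months_since_prev" %in% names(sessions))
    sessions$months_since_prev <- c(NA_real_, rep(NA_real_, nrow(sessions) - 1L))
  if (!"has_imaging" %in% names(sessions))
    sessions$has_imaging <- !is.na(sessions$category)
  sessions$category <- factor(as.character(sessions$category), levels = response_levels)
  structure(list(patient_id = as.character(patient_id), sessions = sessions,
                 time_months = time_months, event = event, covariates = covariates),
            class = "patient_record")
}

#' Convert ISO-8601 dates to months between consecutive sessions
#'
#' @param dates character or Date vector of session dates, ordered.
#' @return numeric vector: NA for the first session, then months elapsed since
#'   the previous session using 30.4375 days per month.
#' @export
months_between_sessions <- function(dates) {
  d <- as.Date(dates)
  if (anyNA(d)) stop("dates must parse as ISO-8601 (YYYY-MM-DD)", call. = FALSE)
  if (is.unsorted(d)) stop("session dates must be non-decreasing", call. = FALSE)
  c(NA_real_, as.numeric(diff(d)) / DAYS_PER_MONTH)
}

#' Label a patient's treatment course
#'
#' Implements the repeat-treatment flow: a patient responding (CR/PR) to the
#' first session is an \code{initial_responder}; an initial non-responder who
#' responds to a second session delivered within the retreatment window is a
#' \code{secondary_responder}; a second session outside the window is
#' \code{excluded_window}; missing response imaging at the decisive session is
#' \code{lost_followup}; everything else is \code{non_responder}.
#'
#' @param patient a \code{patient_record}.
#' @param criteria a \code{response_criteria}.
#' @return A one-row data.frame: patient_id, label, n_sessions.
#' @export
label_sessions <- function(patient, criteria = response_criteria()) {
  stopifnot(inherits(patient, "patient_record"))
  s <- patient$sessions
  lab <- local({
    if (!s$has_imaging[1] || is.na(s$category[1])) return("lost_followup")
    if (s$category[1] %in% c("CR", "PR")) return("initial_responder")
    if (nrow(s) < 2L) return("non_responder")
    gap <- s$months_since_prev[2]
    if (is.na(gap))
      stop("second session needs months_since_prev to apply the retreatment window", call. = FALSE)
    if (gap > criteria$retreat_window_months) return("excluded_window")
    if (!s$has_imaging[2] || is.na(s$category[2])) return("lost_followup")
    if (s$category[2] %in% c("CR", "PR")) return("secondary_responder")
    "non_responder"
  })
  data.frame(patient_id = patient$patient_id,
             label = factor(lab, levels = c("initial_responder", "secondary_responder",
                                            "non_responder", "excluded_window",
                                            "lost_followup")),
             n_sessions = nrow(s), stringsAsFactors = FALSE)
}

#' Cohort flow table
#'
#' Tabulates the treatment flow over sessions: patients treated at each
#' session, CR/PR/SD/PD counts, responders and non-responders, window
#' exclusions and losses to follow-up. Counts are conserved: at every session
#' the categorized, unimaged and (for session >= 2) window-excluded patients
#' sum to the treated count, and treated at session k+1 never exceeds
#' within-window non-responders at session k.
#'
#' @param cohort list of \code{patient_record}s.
#' @param criteria a \code{response_criteria}.
#' @return data.frame with one row per session: session, n_treated, n_CR,
#'   n_PR, n_SD, n_PD, n_responder, n_nonresponder, n_no_imaging,
#'   n_excluded_window (sessions >= 2 arriving outside the window).
#' @export
cohort_flow <- function(cohort, criteria = response_criteria()) {
  empty <- data.frame(session = integer(), n_treated = integer(), n_CR = integer(),
                      n_PR = integer(), n_SD = integer(), n_PD = integer(),
                      n_responder = integer(), n_nonresponder = integer(),
                      n_no_imaging = integer(), n_excluded_window = integer())
  if (length(cohort) == 0) return(empty)
  kmax <- max(vapply(cohort, function(p) nrow(p$sessions), integer(1)))
  rows <- lapply(seq_len(kmax), function(k) {
    has_k <- vapply(cohort, function(p) nrow(p$sessions) >= k, logical(1))
    ps <- cohort[has_k]
    in_window <- vapply(ps, function(p) {
      if (k == 1L) return(TRUE)
      gap <- p$sessions$months_since_prev[k]
      !is.na(gap) && gap <= criteria$retreat_window_months
    }, logical(1))
    cats <- vapply(ps, function(p) as.character(p$sessions$category[k]), character(1))
    imaged <- vapply(ps, function(p) isTRUE(p$sessions$has_imaging[k]), logical(1)) & !is.na(cats)
    counted <- in_window & imaged
    tab <- table(factor(cats[counted], levels = response_levels))
    data.frame(session = k, n_treated = length(ps),
               n_CR = as.integer(tab["CR"]), n_PR = as.integer(tab["PR"]),
               n_SD = as.integer(tab["SD"]), n_PD = as.integer(tab["PD"]),
               n_responder = as.integer(tab["CR"] + tab["PR"]),
               n_nonresponder = as.integer(tab["SD"] + tab["PD"]),
               n_no_imaging = sum(in_window & !imaged),
               n_excluded_window = sum(!in_window))
  })
  do.call(rbind, rows)
}
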