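#' Assemble survival records
#'
#' Overall survival is the time from the first treatment until death from any
#' cause. The default analysis right-censors patients who are alive or lost
#' to follow-up at their last known time. An alternative
#' \code{censoring_mode = "drop_censored"} removes those patients entirely —
#' a replication mode for analyses that excluded rather than censored them —
#' and is not recommended for new work because it biases the estimate.
#'
#' @param patient_id identifiers.
#' @param time_months positive times from first treatment (months).
#' @param event logical or 0/1, TRUE for death from any cause.
#' @param group optional categorical label (e.g. responder / non_responder).
#' @param censoring_mode \code{"censor"} (default) or \code{"drop_censored"}.
#' @return data.frame of class \code{survival_records}.
#' @export
survival_records <- function(patient_id, time_months, event, group = NULL,
                             censoring_mode = c("censor", "drop_censored")) {
  censoring_mode <- match.arg(censoring_mode)
  if (any(!is.finite(time_months) | time_months <= 0))
    stop("`time_months` must be positive and finite", call. = FALSE)
  event <- as.logical(event)
  if (anyNA(event)) stop("`event` must be TRUE/FALSE", call. = FALSE)
  d <- data.frame(patient_id = as.character(patient_id),
                  time_months = as.numeric(time_months), event = event,
                  stringsAsFactors = FALSE)
  d$group <- if (is.null(group)) NA_character_ else as.character(group)
  if (censoring_mode == "drop_censored") d <- d[d$event, , drop = FALSE]
  attr(d, "censoring_mode") <- censoring_mode
  class(d) <- c("survival_records", "data.frame")
  d
}

#' Kaplan-Meier fit with median and 95\% CI
#'
#' Product-limit estimate of the survival function. The median is the
#' earliest time at which the estimate drops to 0.5 or below (undefined when
#' the curve never reaches 0.5). The 95\% CI for the median is obtained by
#' inverting pointwise log(-log) confidence bands for S(t)
#' (Brookmeyer-Crowley-style), as computed by \code{survival::survfit} with
#' \code{conf.type = "log-log"}.
#'
#' @param records a \code{survival_records} data.frame (or any data.frame with
#'   \code{time_months} and \code{event}).
#' @return A list of class \code{km_fit}: \code{time}, \code{surv} (step
#'   function points), \code{n}, \code{n_events}, \code{median_months} (NA if
#'   undefined), \code{median_ci95} (length-2, may contain NA), and the
#'   underlying \code{survfit} object in \code{fit}.
#' @export
km_fit <- function(records) {
  if (nrow(records) == 0) stop("no survival records", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = records,
                           conf.type = "log-log")
  tab <- summary(fit)$table
  med <- unname(tab["median"])
  out <- list(time = fit$time, surv = fit$surv,
              n = unname(tab["records"]), n_events = unname(tab["events"]),
              median_months = if (is.na(med)) NA_real_ else med,
              median_ci95 = unname(c(tab["0.95LCL"], tab["0.95UCL"])),
              fit = fit)
  class(out) <- "km_fit"
  out
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier: n=%d, events=%d, median OS %s months (95%% CI %s-%s)\n",
              x$n, x$n_events,
              ifelse(is.na(x$median_months), "not reached", format(x$median_months)),
              format(x$median_ci95[1]), format(x$median_ci95[2])))
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param group_a,group_b \code{survival_records} for the two arms.
#' @return list with \code{chisq} (1 df statistic) and \code{p} (upper-tail
#'   chi-square p-value).
#' @export
logrank_test <- function(group_a, group_b) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  d <- rbind(data.frame(time_months = group_a$time_months, event = group_a$event,
                        arm = "A", stringsAsFactors = FALSE),
             data.frame(time_months = group_b$time_months, event = group_b$event,
                        arm = "B", stringsAsFactors = FALSE))
  sd <- survival::survdiff(survival::Surv(time_months, event) ~ arm, data = d)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Breslow handling of tied event times.
#' Univariate mode fits one model per covariate; multivariate mode enters the
#' covariates jointly. Hazard ratios with Wald 95\% CIs and p-values are
#' reported per covariate.
#'
#' @param records data.frame with \code{time_months}, \code{event} and the
#'   covariate columns.
#' @param covariates character vector of covariate column names.
#' @param mode \code{"univariate"} or \code{"multivariate"}.
#' @return data.frame of class \code{cox_result}: covariate, term, hr,
#'   ci_lower, ci_upper, p, mode.
#' @export
cox_fit <- function(records, covariates, mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  if (sum(records$event) < 1) stop("at least one event is required", call. = FALSE)
  for (cv in covariates) {
    if (!cv %in% names(records)) stop("missing covariate column: ", cv, call. = FALSE)
    if (length(unique(records[[cv]])) < 2L)
      stop("constant covariate: ", cv, call. = FALSE)
  }
  fit_one <- function(cvs) {
    fml <- stats::as.formula(paste("survival::Surv(time_months, event) ~",
                                   paste(cvs, collapse = " + ")))
    fit <- tryCatch(survival::coxph(fml, data = records, ties = "breslow"),
                    warning = function(w) {
                      if (grepl("did not converge|infinite", conditionMessage(w)))
                        stop("cox_fit did not converge for: ",
                             paste(cvs, collapse = ", "), " (", conditionMessage(w), ")",
                             call. = FALSE)
                      suppressWarnings(survival::coxph(fml, data = records, ties = "breslow"))
                    })
    s <- summary(fit)
    data.frame(covariate = rep(cvs[1], nrow(s$coefficients))[seq_len(nrow(s$coefficients))],
               term = rownames(s$coefficients),
               hr = unname(s$coefficients[, "exp(coef)"]),
               ci_lower = unname(s$conf.int[, "lower .95"]),
               ci_upper = unname(s$conf.int[, "upper .95"]),
               p = unname(s$coefficients[, "Pr(>|z|)"]),
               stringsAsFactors = FALSE)
  }
  out <- if (mode == "univariate") {
    do.call(rbind, lapply(covariates, function(cv) {
      r <- fit_one(cv); r$covariate <- cv; r
    }))
  } else {
    r <- fit_one(covariates)
    r$covariate <- sub("(TRUE|FALSE|[0-9.]+)?$", "", r$term)
    r
  }
  out$mode <- mode
  rownames(out) <- NULL
  class(out) <- c("cox_result", "data.frame")
  out
}

#' Univariate screen then multivariate Cox model
#'
#' Fits each candidate covariate alone, then enters those with univariate
#' p below \code{entry_p} (default 0.10) jointly into a multivariate model.
#'
#' @inheritParams cox_fit
#' @param entry_p univariate p-value threshold for multivariate entry.
#' @return list with \code{univariate} and \code{multivariate} (\code{NULL}
#'   when fewer than one covariate passes the screen) \code{cox_result}s,
#'   plus \code{entered}, the covariates entering the joint model.
#' @export
cox_screen <- function(records, covariates, entry_p = 0.10) {
  uni <- cox_fit(records, covariates, mode = "univariate")
  best_p <- vapply(split(uni$p, uni$covariate), min, numeric(1))
  entered <- covariates[covariates %in% names(best_p)[best_p < entry_p]]
  multi <- if (length(entered) >= 1L)
    cox_fit(records, entered, mode = "multivariate") else NULL
  list(univariate = uni, multivariate = multi, entered = entered)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-tailed p-value by hypergeometric enumeration: with margins
#' fixed, all tables whose point probability does not exceed that of the
#' observed table (within a relative tolerance of 1e-7 for floating-point
#' ties) contribute to p. A table with a zero margin has p = 1 by convention.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return two-tailed p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(6, 1, 22, 14), nrow = 2))
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != round(tab)))
    stop("`tab` must be a 2x2 matrix of non-negative integers", call. = FALSE)
  m <- sum(tab[1, ])           # row-1 margin
  n <- sum(tab[2, ])           # row-2 margin
  k <- sum(tab[, 1])           # column-1 margin
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x, m, n, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Welch's two-sample t test
#'
#' @param xs,ys numeric samples, each of length >= 2.
#' @return list with \code{t}, \code{df}, \code{p} (two-tailed).
#' @export
welch_t_test <- function(xs, ys) {
  if (length(xs) < 2 || length(ys) < 2)
    stop("each sample needs n >= 2", call. = FALSE)
  if (stats::var(xs) == 0 && stats::var(ys) == 0)
    stop("both samples have zero variance", call. = FALSE)
  ht <- stats::t.test(xs, ys, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Pearson chi-square test of independence
#'
#' Without continuity correction, so the statistic is the plain
#' sum((O-E)^2/E).
#'
#' @param tab contingency table of counts.
#' @return list with \code{chisq}, \code{df}, \code{p}.
#' @export
chi_square_test <- function(tab) {
  ht <- stats::chisq.test(as.matrix(tab), correct = FALSE)
  if (any(ht$expected <= 0))
    stop("expected counts must be positive", call. = FALSE)
  list(chisq = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
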