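#' Multiphasic phantom specification
#'
#' Defines a synthetic liver-like scene with spherical lesions whose enhancing
#' and necrotic compartments have voxel-exact known volumes, used to validate
#' the quantification pipeline end to end.
#'
#' Intensity model (arbitrary T1 units): the unenhanced image is
#' \code{parenchyma_base} everywhere except lesions at \code{tumor_base};
#' in the arterial phase parenchyma gains \code{parenchyma_gain}, enhancing
#' (viable) tumor voxels gain \code{parenchyma_gain * enhancing_gain_multiple},
#' and necrotic voxels gain nothing. Independent additive Gaussian noise of
#' standard deviation \code{noise_sd} is applied to each phase. The default
#' noise level is half the parenchyma contrast gain, a moderately noisy
#' arterial-phase acquisition.
#'
#' @param shape,spacing,origin grid geometry (see \code{\link{image_grid}}).
#' @param lesions data.frame with columns \code{lesion_id}, \code{cx},
#'   \code{cy}, \code{cz} (center, mm), \code{radius_mm},
#'   \code{enhancing_fraction} (in [0, 1]).
#' @param parenchyma_base,tumor_base unenhanced intensities.
#' @param parenchyma_gain arterial contrast uptake of normal parenchyma.
#' @param enhancing_gain_multiple viable-tumor gain as a multiple of
#'   \code{parenchyma_gain} (default 4: strongly hyperenhancing).
#' @param noise_sd per-phase additive Gaussian noise SD (default
#'   \code{0.5 * parenchyma_gain}).
#' @param seed integer RNG seed.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 48L), spacing = c(1, 1, 1),
                         origin = c(0, 0, 0),
                         lesions = data.frame(lesion_id = "L1", cx = 32, cy = 32,
                                              cz = 24, radius_mm = 15,
                                              enhancing_fraction = 0.4),
                         parenchyma_base = 200, tumor_base = 160,
                         parenchyma_gain = 100, enhancing_gain_multiple = 4,
                         noise_sd = 0.5 * parenchyma_gain, seed = 1L) {
  grid <- image_grid(shape, spacing, origin)
  req <- c("lesion_id", "cx", "cy", "cz", "radius_mm", "enhancing_fraction")
  if (!is.data.frame(lesions) || !all(req %in% names(lesions)))
    stop("`lesions` needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (any(lesions$radius_mm <= 0)) stop("lesion radii must be > 0", call. = FALSE)
  if (any(lesions$enhancing_fraction < 0 | lesions$enhancing_fraction > 1))
    stop("enhancing_fraction must be in [0, 1]", call. = FALSE)
  lo <- grid$origin; hi <- grid$origin + (grid$shape - 1) * grid$spacing
  for (i in seq_len(nrow(lesions))) {
    ctr <- c(lesions$cx[i], lesions$cy[i], lesions$cz[i])
    if (any(ctr - lesions$radius_mm[i] < lo) || any(ctr + lesions$radius_mm[i] > hi))
      stop("lesion '", lesions$lesion_id[i], "' extends beyond the grid", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(grid = grid, lesions = lesions,
                 parenchyma_base = parenchyma_base, tumor_base = tumor_base,
                 parenchyma_gain = parenchyma_gain,
                 enhancing_gain_multiple = enhancing_gain_multiple,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

## Voxel-exact concentric core/shell split: the outermost round(f*n) voxels
## (by center distance, descending; ties by linear index) become the
## enhancing shell, emulating the rim enhancement seen after embolization.
split_shell <- function(d2_inside, f) {
  n <- length(d2_inside)
  k <- round(f * n)
  if (abs(k / n - f) > 0.02)
    stop(sprintf("enhancing_fraction %.3f infeasible on a %d-voxel lesion (granularity 1/%d = %.3f)",
                 f, n, n, 1 / n), call. = FALSE)
  if (k == 0L) return(integer(0))
  ord <- order(d2_inside, seq_len(n), decreasing = TRUE)
  ord[seq_len(k)]
}

#' Generate a multiphasic phantom
#'
#' Builds the unenhanced and arterial phases, one segmentation mask per
#' lesion, a voxel-exact truth table of whole and enhancing volumes, and a
#' safe parenchyma reference-ROI center. The enhancing compartment is a
#' concentric outer shell hitting the requested fraction exactly by voxel
#' count (within a 2\% feasibility guard on tiny lesions). Deterministic
#' under the spec seed.
#'
#' @param spec a \code{phantom_spec}.
#' @return list with \code{unenhanced}, \code{arterial}
#'   (\code{volume_image}s), \code{masks} (named list of
#'   \code{segmentation_mask}s), \code{truth} (data.frame: lesion_id,
#'   n_voxels, whole_volume_cm3, n_enhancing, enhancing_volume_cm3,
#'   enhancing_fraction), \code{enhancing_masks} (truth masks), and
#'   \code{roi_center} (mm).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  g <- spec$grid
  vv <- voxel_volume_cm3(g)
  unenh <- array(spec$parenchyma_base, dim = g$shape)
  gain <- array(spec$parenchyma_gain, dim = g$shape)
  masks <- list(); enh_masks <- list(); truth <- list()
  for (i in seq_len(nrow(spec$lesions))) {
    L <- spec$lesions[i, ]
    d2 <- distance2_field(g, c(L$cx, L$cy, L$cz))
    inside <- which(d2 <= L$radius_mm^2)
    if (length(inside) == 0)
      stop("lesion '", L$lesion_id, "' contains no voxel centers", call. = FALSE)
    enh_idx <- inside[split_shell(d2[inside], L$enhancing_fraction)]
    vox <- array(FALSE, dim = g$shape); vox[inside] <- TRUE
    evox <- array(FALSE, dim = g$shape); evox[enh_idx] <- TRUE
    unenh[inside] <- spec$tumor_base
    gain[inside] <- 0                                  # necrotic: no uptake
    gain[enh_idx] <- spec$parenchyma_gain * spec$enhancing_gain_multiple
    masks[[L$lesion_id]] <- segmentation_mask(vox, g, L$lesion_id)
    enh_masks[[L$lesion_id]] <- segmentation_mask(evox, g, L$lesion_id)
    truth[[i]] <- data.frame(lesion_id = L$lesion_id,
                             n_voxels = length(inside),
                             whole_volume_cm3 = length(inside) * vv,
                             n_enhancing = length(enh_idx),
                             enhancing_volume_cm3 = length(enh_idx) * vv,
                             enhancing_fraction = length(enh_idx) / length(inside),
                             stringsAsFactors = FALSE)
  }
  arterial <- unenh + gain
  if (spec$noise_sd > 0) {
    unenh <- unenh + array(stats::rnorm(length(unenh), 0, spec$noise_sd), dim = g$shape)
    arterial <- arterial + array(stats::rnorm(length(arterial), 0, spec$noise_sd), dim = g$shape)
  }
  list(unenhanced = volume_image(unenh, g, "unenhanced_T1"),
       arterial = volume_image(arterial, g, "arterial_T1"),
       masks = masks, enhancing_masks = enh_masks,
       truth = do.call(rbind, truth),
       roi_center = find_roi_center(g, masks))
}

## A reference-ROI center: the voxel center maximizing distance to all lesion
## centers while keeping a 1 cm^3 ball inside the grid (coarse search).
find_roi_center <- function(grid, masks, target_volume_cm3 = 1) {
  r <- (3 * target_volume_cm3 * 1000 / (4 * pi))^(1 / 3) + max(grid$spacing)
  lo <- grid$origin + r; hi <- grid$origin + (grid$shape - 1) * grid$spacing - r
  if (any(lo > hi)) stop("grid too small to host the reference ROI", call. = FALSE)
  cand <- as.matrix(expand.grid(x = seq(lo[1], hi[1], length.out = 7),
                                y = seq(lo[2], hi[2], length.out = 7),
                                z = seq(lo[3], hi[3], length.out = 5)))
  score <- rep(Inf, nrow(cand))
  for (m in masks) {
    idx <- which(m$voxels, arr.ind = TRUE)
    ctr <- grid$origin + (colMeans(idx) - 1) * grid$spacing
    rad <- sqrt(max(rowSums((sweep(idx, 2, 1) %*% diag(grid$spacing) -
                               matrix(ctr - grid$origin, nrow(idx), 3, byrow = TRUE))^2)))
    d <- sqrt(rowSums(sweep(cand, 2, ctr)^2)) - rad
    score <- pmin(score, d)
  }
  best <- cand[which.max(score), ]
  if (length(masks) > 0 && max(score) < r)
    stop("no room for the reference ROI outside all lesions", call. = FALSE)
  as.numeric(best)
}

#' Enhancing-volume trajectory realizing a category sequence
#'
#' Emits per-session (reference, post) summed enhancing volumes whose
#' classification reproduces a requested CR/PR/SD/PD sequence; each session's
#' reference is the previous session's post volume. Random draws stay well
#' inside the category bands (PR between -95\% and -67\%, PD between +75\%
#' and +200\%, SD between -63\% and +71\%) so classification is unambiguous.
#' A PR or SD request immediately after a CR is contradictory (no enhancing
#' tissue is left to shrink by a fraction) and raises an error; CR after CR
#' sustains the zero volume and PD after CR models regrowth.
#'
#' @param categories character vector of requested categories per session.
#' @param criteria a \code{response_criteria}.
#' @param start_enh_cm3 baseline summed enhancing volume (default 100).
#' @param cr_epsilon_cm3 CR tolerance passed to the classifier (default 0).
#' @param seed optional RNG seed.
#' @return data.frame: session, sum_enh_ref_cm3, sum_enh_post_cm3, category.
#' @export
generate_trajectory <- function(categories, criteria = response_criteria(),
                                start_enh_cm3 = 100, cr_epsilon_cm3 = 0,
                                seed = NULL) {
  if (length(categories) == 0) stop("request at least one session", call. = FALSE)
  if (!all(categories %in% response_levels))
    stop("categories must be CR, PR, SD or PD", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ref <- start_enh_cm3
  rows <- vector("list", length(categories))
  for (s in seq_along(categories)) {
    cat_s <- categories[s]
    if (ref <= cr_epsilon_cm3 && cat_s %in% c("PR", "SD"))
      stop(sprintf("session %d: %s after CR is contradictory (no enhancing tissue left)", s, cat_s),
           call. = FALSE)
    post <- switch(cat_s,
      CR = 0,
      PR = ref * stats::runif(1, 0.05, 1 - criteria$pr_decrease - 0.02),
      PD = if (ref <= cr_epsilon_cm3) stats::runif(1, 5, 50)
           else ref * stats::runif(1, 1 + criteria$pd_increase + 0.02, 3),
      SD = ref * stats::runif(1, 1 - criteria$pr_decrease + 0.02,
                              1 + criteria$pd_increase - 0.02))
    got <- classify_response(ref, post, criteria, cr_epsilon_cm3)$category
    stopifnot(as.character(got) == cat_s)  # construction guarantees this
    rows[[s]] <- data.frame(session = s, sum_enh_ref_cm3 = ref,
                            sum_enh_post_cm3 = post, category = cat_s,
                            stringsAsFactors = FALSE)
    ref <- post
  }
  do.call(rbind, rows)
}

#' Worked two-session trajectory preset
#'
#' A fixed enhancing/whole volume course for one patient: baseline enhancing
#' 653.8 cm^3 falling to 401.9 cm^3 after the first session (stable disease,
#' -38.5\%) and to 131.4 cm^3 after the second (partial response, -67.3\%),
#' with whole-tumor volumes 793.9, 899.6 and 549.8 cm^3.
#'
#' @return data.frame: session, sum_enh_ref_cm3, sum_enh_post_cm3,
#'   whole_ref_cm3, whole_post_cm3.
#' @export
trajectory_preset_case <- function() {
  data.frame(session = 1:2,
             sum_enh_ref_cm3 = c(653.8, 401.9),
             sum_enh_post_cm3 = c(401.9, 131.4),
             whole_ref_cm3 = c(793.9, 899.6),
             whole_post_cm3 = c(899.6, 549.8))
}

#' Cohort simulation specification
#'
#' Session-1 category probabilities default to the observed mix in a 94-patient
#' TACE series (CR 3.2\%, PR 26.6\%, SD 60.6\%, PD 9.6\%); 34.9\% of retreated
#' non-responders respond at session 2; retreatment intervals are log-normal
#' with median 0.8 months truncated to [0.1, 3]; survival is exponential with
#' responder median 47.8 months and a proportional-hazards multiplier of 2.8
#' on final non-responders; independent exponential censoring targets the
#' requested censoring fraction.
#'
#' @param n_patients cohort size (default 94).
#' @param p_session1 named probabilities for CR/PR/SD/PD at session 1.
#' @param p_response_session2 probability a retreated non-responder responds.
#' @param hr_nonresponse hazard ratio of final non-responders vs responders.
#' @param responder_median_os_months baseline (responder) median OS.
#' @param censoring_rate target fraction censored (alive/lost), in [0, 1).
#' @param retreat_range months, admissible second-session interval.
#' @param retreat_median_months median of the interval distribution.
#' @param seed integer RNG seed.
#' @return An object of class \code{cohort_sim_spec}.
#' @export
cohort_sim_spec <- function(n_patients = 94L,
                            p_session1 = c(CR = 0.032, PR = 0.266, SD = 0.606, PD = 0.096),
                            p_response_session2 = 15 / 43,
                            hr_nonresponse = 2.8,
                            responder_median_os_months = 47.8,
                            censoring_rate = 0.36,
                            retreat_range = c(0.1, 3),
                            retreat_median_months = 0.8,
                            seed = 1L) {
  p_session1 <- p_session1[response_levels]
  if (anyNA(p_session1) || abs(sum(p_session1) - 1) > 1e-8)
    stop("`p_session1` must give CR/PR/SD/PD probabilities summing to 1", call. = FALSE)
  if (hr_nonresponse <= 0) stop("`hr_nonresponse` must be > 0", call. = FALSE)
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("`censoring_rate` must be in [0, 1)", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients), p_session1 = p_session1,
                 p_response_session2 = p_response_session2,
                 hr_nonresponse = hr_nonresponse,
                 responder_median_os_months = responder_median_os_months,
                 censoring_rate = censoring_rate,
                 retreat_range = retreat_range,
                 retreat_median_months = retreat_median_months,
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

rtruncated_lnorm <- function(n, median, sdlog, range) {
  out <- numeric(n); need <- seq_len(n)
  while (length(need)) {
    x <- stats::rlnorm(length(need), meanlog = log(median), sdlog = sdlog)
    ok <- x >= range[1] & x <= range[2]
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Simulate a longitudinal treatment cohort with linked survival
#'
#' Per patient: a session-1 category is drawn from the spec probabilities;
#' non-responders are retreated after an interval drawn from the truncated
#' log-normal; the session-2 category is a response (PR, or CR with small
#' probability) with probability \code{p_response_session2}, otherwise SD/PD.
#' Enhancing-volume sums realizing each category come from
#' \code{\link{generate_trajectory}}. Survival is exponential: responders
#' (initial or secondary) at the baseline hazard
#' \code{log(2) / responder_median_os_months}, final non-responders at that
#' hazard times \code{hr_nonresponse}; right-censoring is independent
#' exponential calibrated to the target censoring fraction. Bit-reproducible
#' under the spec seed.
#'
#' @param spec a \code{cohort_sim_spec}.
#' @return list with \code{patients} (list of \code{patient_record}) and
#'   \code{truth} (data.frame: patient_id, category1, category2, true_group,
#'   label, true_time_months, time_months, event).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  lam_r <- log(2) / spec$responder_median_os_months
  lam_n <- lam_r * spec$hr_nonresponse
  cat1 <- sample(response_levels, n, replace = TRUE, prob = spec$p_session1)
  patients <- vector("list", n); truth <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    resp1 <- cat1[i] %in% c("CR", "PR")
    cat2 <- NA_character_; gap2 <- NA_real_
    if (!resp1) {
      gap2 <- rtruncated_lnorm(1, spec$retreat_median_months, 0.6, spec$retreat_range)
      cat2 <- if (stats::runif(1) < spec$p_response_session2) {
        if (stats::runif(1) < 0.1) "CR" else "PR"
      } else {
        if (stats::runif(1) < 0.25) "PD" else "SD"
      }
    }
    cats <- if (resp1) cat1[i] else c(cat1[i], cat2)
    traj <- generate_trajectory(cats, start_enh_cm3 = stats::rlnorm(1, log(80), 0.8))
    responder <- resp1 || cat2 %in% c("CR", "PR")
    lam <- if (responder) lam_r else lam_n
    t_true <- stats::rexp(1, lam)
    # P(C < T) = rate_c / (lam + rate_c) = censoring_rate  =>  rate_c below
    rate_c <- if (spec$censoring_rate > 0)
      lam * spec$censoring_rate / (1 - spec$censoring_rate) else 0
    c_time <- if (rate_c > 0) stats::rexp(1, rate_c) else Inf
    obs <- min(t_true, c_time)
    sessions <- data.frame(session_index = seq_along(cats),
                           months_since_prev = c(NA_real_, gap2)[seq_along(cats)],
                           category = cats,
                           sum_enh_ref_cm3 = traj$sum_enh_ref_cm3,
                           sum_enh_post_cm3 = traj$sum_enh_post_cm3,
                           stringsAsFactors = FALSE)
    patients[[i]] <- patient_record(pid, sessions, time_months = obs,
                                    event = t_true <= c_time,
                                    covariates = list(responder = responder))
    truth[[i]] <- data.frame(patient_id = pid, category1 = cat1[i],
                             category2 = cat2,
                             true_group = if (responder) "responder" else "non_responder",
                             true_time_months = t_true, time_months = obs,
                             event = t_true <= c_time, stringsAsFactors = FALSE)
  }
  list(patients = patients, truth = do.call(rbind, truth))
}
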