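#' qEASL quantification settings
#'
#' A tumor voxel is classified enhancing when its subtracted intensity exceeds
#' the parenchyma reference-ROI mean by more than \code{enhancement_k}
#' standard deviations. \code{k = 2} is the conventional cutoff in the
#' quantitative-EASL literature; it is configurable because the cutoff is a
#' normalization convention, not a physical constant, and it is recorded in
#' every output table.
#'
#' @param enhancement_k non-negative multiplier for the ROI SD (default 2).
#' @param roi_min_voxels minimum number of voxels a realized reference ROI may
#'   contain (default 10).
#' @param cr_epsilon_cm3 enhancing-volume at or below which a lesion counts as
#'   completely devascularized (default 0: literal disappearance of all
#'   enhancing tissue; raise to absorb single-voxel noise).
#' @return An object of class \code{qeasl_config}.
#' @export
qeasl_config <- function(enhancement_k = 2, roi_min_voxels = 10L, cr_epsilon_cm3 = 0) {
  if (!is.finite(enhancement_k) || enhancement_k < 0)
    stop("`enhancement_k` must be >= 0", call. = FALSE)
  if (roi_min_voxels < 1L) stop("`roi_min_voxels` must be >= 1", call. = FALSE)
  if (!is.finite(cr_epsilon_cm3) || cr_epsilon_cm3 < 0)
    stop("`cr_epsilon_cm3` must be >= 0", call. = FALSE)
  structure(list(enhancement_k = enhancement_k,
                 roi_min_voxels = as.integer(roi_min_voxels),
                 cr_epsilon_cm3 = cr_epsilon_cm3),
            class = "qeasl_config")
}

#' Parenchyma reference-ROI specification
#'
#' A spherical region of interest of target volume (default 1 cm^3) placed in
#' non-tumor liver parenchyma on the subtracted image; its mean and SD anchor
#' the enhancing-voxel cutoff.
#'
#' @param center physical coordinates (mm) of the ROI center.
#' @param target_volume_cm3 positive target volume; the ball radius is solved
#'   from \code{(3V / 4 pi)^(1/3)}.
#' @return An object of class \code{roi_spec}.
#' @export
roi_spec <- function(center, target_volume_cm3 = 1) {
  center <- as.numeric(center)
  if (length(center) != 3L || anyNA(center))
    stop("`center` must be 3 finite reals (mm)", call. = FALSE)
  if (!is.finite(target_volume_cm3) || target_volume_cm3 <= 0)
    stop("`target_volume_cm3` must be > 0", call. = FALSE)
  structure(list(center = center, target_volume_cm3 = target_volume_cm3),
            class = "roi_spec")
}

#' Subtract the unenhanced phase from the arterial phase
#'
#' Voxelwise \code{arterial - unenhanced}, removing background T1 signal so
#' that remaining intensity reflects contrast uptake. Negative values are
#' retained (clipping would bias the reference-ROI statistics).
#'
#' @param arterial a \code{volume_image} with phase \code{arterial_T1}.
#' @param unenhanced a \code{volume_image} with phase \code{unenhanced_T1}.
#' @return A \code{volume_image} with phase \code{subtracted} on the same grid.
#' @export
subtract_phases <- function(arterial, unenhanced) {
  stopifnot(inherits(arterial, "volume_image"), inherits(unenhanced, "volume_image"))
  if (arterial$phase != "arterial_T1" || unenhanced$phase != "unenhanced_T1")
    stop("phase labels must be arterial_T1 and unenhanced_T1", call. = FALSE)
  check_same_grid(arterial$grid, unenhanced$grid, "phases of one session")
  volume_image(arterial$values - unenhanced$values, arterial$grid, "subtracted")
}

#' Realize a reference ROI as a voxel mask
#'
#' Converts a spherical ROI specification into the set of voxels whose centers
#' lie within the analytic ball. The realized ROI must lie fully inside the
#' image and must not touch any exclusion (lesion) mask.
#'
#' @param spec an \code{roi_spec}.
#' @param grid the target \code{image_grid}.
#' @param exclusion_masks list of \code{segmentation_mask}s the ROI must avoid.
#' @return A \code{segmentation_mask} labelled \code{"roi"}.
#' @export
realize_roi <- function(spec, grid, exclusion_masks = list()) {
  stopifnot(inherits(spec, "roi_spec"), inherits(grid, "image_grid"))
  r_mm <- (3 * spec$target_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  lo <- grid$origin
  hi <- grid$origin + (grid$shape - 1) * grid$spacing
  if (any(spec$center < lo) || any(spec$center > hi))
    stop("roi placement: center lies outside the image grid", call. = FALSE)
  if (any(spec$center - r_mm < lo - grid$spacing / 2) ||
      any(spec$center + r_mm > hi + grid$spacing / 2))
    stop(sprintf("roi placement: ball of radius %.2f mm crosses the image boundary", r_mm),
         call. = FALSE)
  vox <- distance2_field(grid, spec$center) <= r_mm^2
  for (m in exclusion_masks) {
    stopifnot(inherits(m, "segmentation_mask"))
    check_same_grid(grid, m$grid, "ROI grid and exclusion mask")
    if (any(vox & m$voxels))
      stop(sprintf("roi placement: ROI overlaps lesion mask '%s'; move the reference ROI", m$lesion_id),
           call. = FALSE)
  }
  segmentation_mask(vox, grid, "roi")
}

#' Reference-ROI statistics
#'
#' Mean and population standard deviation of the subtracted intensities over
#' the ROI voxels. The population (n) rather than sample (n-1) SD is used; for
#' the >= 100-voxel ROIs of a 1 cm^3 sphere at typical spacing the difference
#' is negligible.
#'
#' @param subtracted a \code{volume_image} with phase \code{subtracted}.
#' @param roi a non-empty \code{segmentation_mask}.
#' @param min_voxels minimum voxel count (default 10).
#' @return A list of class \code{roi_stats} with \code{mean}, \code{sd},
#'   \code{n_voxels}.
#' @export
roi_stats <- function(subtracted, roi, min_voxels = 10L) {
  stopifnot(inherits(subtracted, "volume_image"), inherits(roi, "segmentation_mask"))
  if (subtracted$phase != "subtracted")
    stop("roi_stats expects the subtracted image", call. = FALSE)
  check_same_grid(subtracted$grid, roi$grid, "subtracted image and ROI")
  x <- subtracted$values[roi$voxels]
  if (length(x) < min_voxels)
    stop(sprintf("reference ROI has %d voxels; at least %d required", length(x), min_voxels),
         call. = FALSE)
  mu <- mean(x)
  structure(list(mean = mu, sd = sqrt(mean((x - mu)^2)), n_voxels = length(x)),
            class = "roi_stats")
}

#' Classify enhancing voxels within a tumor mask
#'
#' A tumor voxel is enhancing (viable) when its subtracted intensity exceeds
#' \code{ref$mean + k * ref$sd}; the remainder is non-enhancing (necrotic).
#' An all-FALSE result is legal and indicates complete devascularization.
#'
#' @param subtracted \code{volume_image}, phase \code{subtracted}.
#' @param tumor non-empty \code{segmentation_mask}.
#' @param ref \code{roi_stats} from the parenchyma reference ROI.
#' @param cfg \code{qeasl_config}.
#' @return A \code{segmentation_mask}, subset of \code{tumor}.
#' @export
classify_enhancing <- function(subtracted, tumor, ref, cfg = qeasl_config()) {
  stopifnot(inherits(subtracted, "volume_image"), inherits(tumor, "segmentation_mask"),
            inherits(ref, "roi_stats"), inherits(cfg, "qeasl_config"))
  if (subtracted$phase != "subtracted")
    stop("classify_enhancing expects the subtracted image", call. = FALSE)
  check_same_grid(subtracted$grid, tumor$grid, "subtracted image and tumor mask")
  if (!any(tumor$voxels)) stop("tumor mask is empty", call. = FALSE)
  cutoff <- ref$mean + cfg$enhancement_k * ref$sd
  segmentation_mask(tumor$voxels & (subtracted$values > cutoff),
                    tumor$grid, tumor$lesion_id)
}

#' Measure one lesion at one timepoint
#'
#' Runs the full per-lesion quantification: phase subtraction, reference-ROI
#' realization and statistics, enhancing-voxel classification, and volumetry.
#' By construction the enhancing volume never exceeds the whole-tumor volume.
#'
#' @param arterial,unenhanced the two phases (\code{volume_image}).
#' @param tumor lesion \code{segmentation_mask}.
#' @param roi the parenchyma reference: an \code{roi_spec} (realized against
#'   the grid with the tumor as exclusion) or an already-realized
#'   \code{segmentation_mask}.
#' @param cfg \code{qeasl_config}.
#' @param session_id,reader_id identifiers carried into the output row.
#' @return A one-row data.frame of class \code{lesion_measurement}: lesion_id,
#'   session_id, reader_id, whole_volume_cm3, enhancing_volume_cm3,
#'   roi_mean, roi_sd, roi_n, enhancement_k.
#' @export
measure_lesion <- function(arterial, unenhanced, tumor, roi,
                           cfg = qeasl_config(), session_id = 1L, reader_id = "reader1") {
  sub <- subtract_phases(arterial, unenhanced)
  roi_mask <- if (inherits(roi, "roi_spec")) {
    realize_roi(roi, sub$grid, exclusion_masks = list(tumor))
  } else if (inherits(roi, "segmentation_mask")) {
    if (any(roi$voxels & tumor$voxels))
      stop("roi placement: reference ROI overlaps the tumor mask", call. = FALSE)
    roi
  } else stop("`roi` must be an roi_spec or a segmentation_mask", call. = FALSE)
  ref <- roi_stats(sub, roi_mask, min_voxels = cfg$roi_min_voxels)
  enh <- classify_enhancing(sub, tumor, ref, cfg)
  out <- data.frame(lesion_id = tumor$lesion_id,
                    session_id = session_id,
                    reader_id = reader_id,
                    whole_volume_cm3 = mask_volume_cm3(tumor),
                    enhancing_volume_cm3 = mask_volume_cm3(enh),
                    roi_mean = ref$mean, roi_sd = ref$sd, roi_n = ref$n_voxels,
                    enhancement_k = cfg$enhancement_k,
                    stringsAsFactors = FALSE)
  class(out) <- c("lesion_measurement", "data.frame")
  out
}

#' Average independent readers' measurements
#'
#' Two readers segment and measure each lesion independently; their whole- and
#' enhancing-volume readings are averaged arithmetically before response
#' classification (volumes are averaged, never categories).
#'
#' @param measurements a \code{lesion_measurement} data.frame (rows from one or
#'   more readers) or a list of such rows; all rows must share
#'   \code{lesion_id} and \code{session_id}.
#' @return A one-row \code{lesion_measurement} with \code{reader_id = "mean"}.
#' @export
average_readers <- function(measurements) {
  if (is.list(measurements) && !is.data.frame(measurements))
    measurements <- do.call(rbind, measurements)
  if (!is.data.frame(measurements) || nrow(measurements) == 0)
    stop("no measurements to average", call. = FALSE)
  if (length(unique(measurements$lesion_id)) != 1L ||
      length(unique(measurements$session_id)) != 1L)
    stop("measurements mix lesion or session ids; average per lesion-session", call. = FALSE)
  out <- measurements[1, , drop = FALSE]
  out$reader_id <- "mean"
  out$whole_volume_cm3 <- mean(measurements$whole_volume_cm3)
  out$enhancing_volume_cm3 <- mean(measurements$enhancing_volume_cm3)
  if (all(c("roi_mean", "roi_sd") %in% names(measurements))) {
    out$roi_mean <- mean(measurements$roi_mean)
    out$roi_sd <- mean(measurements$roi_sd)
  }
  class(out) <- c("lesion_measurement", "data.frame")
  out
}

#' Viability color map
#'
#' Labels every voxel of the tumor as enhancing/viable (displayed red, label
#' 1) or non-enhancing/necrotic (blue, label 2); voxels outside the tumor are
#' background (0). The red set equals \code{classify_enhancing}'s output and
#' red plus blue partition the tumor.
#'
#' @inheritParams classify_enhancing
#' @param file optional path; when given the label field is written as a
#'   NIfTI overlay.
#' @return An integer 3D array of labels with attribute \code{legend}.
#' @export
color_map <- function(subtracted, tumor, ref, cfg = qeasl_config(), file = NULL) {
  enh <- classify_enhancing(subtracted, tumor, ref, cfg)
  lab <- array(0L, dim = tumor$grid$shape)
  lab[tumor$voxels] <- 2L
  lab[enh$voxels] <- 1L
  attr(lab, "legend") <- c(background = 0L, red_enhancing = 1L, blue_nonenhancing = 2L)
  if (!is.null(file)) {
    img <- as_nifti_with_grid(lab, tumor$grid)
    img <- RNifti::asNifti(img, datatype = "uint8")
    RNifti::writeNifti(img, file)
  }
  lab
}
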