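# Per-subject muscle quantification from a PDFF map and compartment masks.
#
# Total muscle mass is the complete segmented cross-sectional area including
# fatty septa; fat-free mass keeps only voxels at or below the intensity
# threshold (default 200 = 20% fat), excluding extramyocellular adipose
# tissue; myosteatosis is the mean fat fraction over the whole mask.

#' Total muscle cross-sectional area
#'
#' Sums voxels across all eight compartment masks and converts to mm^2 via
#' the squared pixel spacing. All mask voxels count regardless of intensity:
#' intermyocellular-intrafascial fatty septa are part of the total
#' cross-section by definition.
#'
#' @param masks a [compartment_masks()] object.
#' @param map a [pdff_map()] on the same grid.
#' @return total cross-sectional area in mm^2.
#' @export
compute_csa_total <- function(masks, map) {
  check_congruent(masks, map)
  n <- sum(masks$labels > 0L)
  if (n == 0) warning("empty mask set: total CSA is 0", call. = FALSE)
  n * map$pixel_spacing^2
}

#' Fat-free muscle cross-sectional area by intensity threshold
#'
#' Implements the threshold rule
#' \deqn{CSA_{fat-free} = CSA_{total} \times N_{\le threshold} / N_{\le 1000}}
#' where \eqn{N_{\le t}} counts mask voxels with intensity at or below `t`.
#' With intensities clamped to \[0, 1000\] on ingest the denominator is the
#' full mask count, so the result equals the fat-free voxel count times the
#' pixel area. The default threshold 200 corresponds to 20% fat fraction, the
#' upper bound of purely intramyocellular lipid content; voxels above it
#' contain extramyocellular adipose tissue and are excluded.
#'
#' @inheritParams compute_csa_total
#' @param threshold fat-free intensity threshold in (0, 1000\]; default 200.
#' @return fat-free cross-sectional area in mm^2.
#' @export
compute_csa_fatfree <- function(masks, map, threshold = 200) {
  check_congruent(masks, map)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !is.finite(threshold) || threshold <= 0 || threshold > 1000) {
    mm_abort("`threshold` must be a single number in (0, 1000]")
  }
  in_mask <- masks$labels > 0L
  n_all <- sum(in_mask)
  if (n_all == 0) {
    warning("empty mask set: fat-free CSA is 0", call. = FALSE)
    return(0)
  }
  vals <- map$intensities[in_mask]
  csa_total <- n_all * map$pixel_spacing^2
  csa_total * sum(vals <= threshold) / sum(vals <= 1000)
}

#' Height-normalized muscle mass index
#'
#' @param csa cross-sectional area in mm^2.
#' @param height body height in metres (positive).
#' @return abdominal muscle mass index in mm^2/m^2.
#' @export
compute_ammi <- function(csa, height) {
  if (any(!is.finite(height) | height <= 0)) {
    mm_abort("`height` must be positive (metres)")
  }
  csa / height^2
}

#' Fat-free to total index ratio in percent
#'
#' The share of the muscle cross-section made of functionally contractable
#' (fat-free) tissue.
#'
#' @param ammi_fatfree,ammi_total indices in mm^2/m^2 with
#'   `0 <= ammi_fatfree <= ammi_total`, `ammi_total > 0`.
#' @return ratio in percent, in \[0, 100\].
#' @export
compute_ratio <- function(ammi_fatfree, ammi_total) {
  if (any(!is.finite(ammi_total) | ammi_total <= 0)) {
    mm_abort("`ammi_total` must be positive; ratio undefined for empty muscle",
             class = "musclemap_undefined")
  }
  if (any(ammi_fatfree < 0 | ammi_fatfree > ammi_total)) {
    mm_abort("`ammi_fatfree` must lie in [0, ammi_total]")
  }
  100 * ammi_fatfree / ammi_total
}

#' Mean muscle fat fraction (myosteatosis)
#'
#' Mean PDFF in percent over all voxels of the union mask, fatty septa
#' included: the same segmented compartments used for the area measures.
#'
#' @inheritParams compute_csa_total
#' @return mean fat fraction in percent.
#' @export
compute_pdff_muscle <- function(masks, map) {
  check_congruent(masks, map)
  in_mask <- masks$labels > 0L
  if (!any(in_mask)) {
    mm_abort("empty union mask: mean PDFF undefined",
             class = "musclemap_undefined")
  }
  mean(map$intensities[in_mask]) / 10
}

#' Quantify one subject's slice
#'
#' Composes the area, index, ratio and myosteatosis measures for a single
#' axial L3-level slice. Per-compartment voxel sub-totals are retained in a
#' nested list-column for reporting.
#'
#' @inheritParams compute_csa_fatfree
#' @param height subject body height in metres.
#' @param id optional subject identifier carried into the output.
#' @return a one-row tibble with columns `subject_id`, `csa_total`,
#'   `csa_fatfree`, `ammi_total`, `ammi_fatfree`, `ratio`, `pdff_muscle` and a
#'   list-column `compartments` of per-compartment voxel counts.
#' @export
quantify_subject <- function(map, masks, height, threshold = 200, id = NA_character_) {
  check_congruent(masks, map)
  if (sum(masks$labels > 0L) == 0) {
    mm_abort(paste0("empty masks for subject ", id), class = "musclemap_undefined")
  }
  csa_total <- compute_csa_total(masks, map)
  csa_fatfree <- compute_csa_fatfree(masks, map, threshold)
  ammi_total <- compute_ammi(csa_total, height)
  ammi_fatfree <- compute_ammi(csa_fatfree, height)
  tibble(
    subject_id = id,
    csa_total = csa_total,
    csa_fatfree = csa_fatfree,
    ammi_total = ammi_total,
    ammi_fatfree = ammi_fatfree,
    ratio = compute_ratio(ammi_fatfree, ammi_total),
    pdff_muscle = compute_pdff_muscle(masks, map),
    compartments = list(compartment_counts(masks))
  )
}

#' Quantify a whole cohort of generated slices
#'
#' Maps [quantify_subject()] over a list of `(map, masks)` pairs as produced
#' by [generate_pdff_slice()], or over NIfTI pairs on disk.
#'
#' @param cohort subject table with `subject_id` and `height` columns.
#' @param slices named list of slices (names = subject ids), each a list with
#'   elements `map` and `masks`; if `NULL`, images are read from `image_dir`.
#' @param image_dir directory of `<id>_pdff.nii.gz` / `<id>_mask.nii.gz`
#'   pairs, used when `slices` is `NULL`.
#' @param threshold fat-free intensity threshold, default 200.
#' @return tibble of per-subject measures (one row per subject).
#' @export
quantify_cohort <- function(cohort, slices = NULL, image_dir = NULL,
                            threshold = 200) {
  need <- c("subject_id", "height")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0) {
    mm_abort(paste0("missing required columns: ",
                    paste(missing_cols, collapse = ", ")),
             class = "musclemap_schema_error")
  }
  if (is.null(slices) && is.null(image_dir)) {
    mm_abort("provide either `slices` or `image_dir`")
  }
  purrr::map2_dfr(cohort$subject_id, cohort$height, function(id, h) {
    sl <- if (!is.null(slices)) slices[[id]] else read_subject_nifti(image_dir, id)
    if (is.null(sl)) mm_abort(paste0("no slice found for subject ", id))
    quantify_subject(sl$map, sl$masks, height = h, threshold = threshold,
                     id = id)
  })
}

check_congruent <- function(masks, map) {
  stopifnot(inherits(masks, "compartment_masks"), inherits(map, "pdff_map"))
  if (!identical(dim(masks$labels), dim(map$intensities))) {
    mm_abort("mask grid and PDFF map grid differ",
             class = "musclemap_contract")
  }
  invisible(TRUE)
}
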