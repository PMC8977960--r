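# Containers for the imaging substrate: a 2-D proton-density fat-fraction
# (PDFF) map on the 0-1000 intensity scale (0-100% fat fraction) and the set
# of eight binary abdominal muscle compartment masks on the same grid.

#' The eight abdominal muscle compartments
#'
#' Left/right psoas major, quadratus lumborum, rectus abdominis and
#' autochthonous back muscles, in the label order used by mask images
#' (values 1-8; 0 is background).
#' @export
COMPARTMENTS <- c(
  "psoas_L", "psoas_R",
  "quadratus_L", "quadratus_R",
  "rectus_L", "rectus_R",
  "autochthonous_L", "autochthonous_R"
)

#' Construct a PDFF map
#'
#' Wraps a 2-D intensity matrix on the 0-1000 scale (1 intensity unit =
#' 0.1 percentage point fat fraction) with pixel-spacing metadata.
#' Intensities outside \[0, 1000\] are clamped on ingest and the number of
#' clamped voxels recorded in the `clamped` attribute (quality event).
#'
#' @param intensities numeric matrix, intensity scale 0-1000.
#' @param pixel_spacing in-plane voxel edge length in mm (isotropic, > 0).
#' @param slice_label vertebral-level token, default `"L3"`.
#' @return an object of class `pdff_map`.
#' @export
pdff_map <- function(intensities, pixel_spacing = 1.5, slice_label = "L3") {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    mm_abort("`intensities` must be a numeric matrix")
  }
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1 ||
      !is.finite(pixel_spacing) || pixel_spacing <= 0) {
    mm_abort("`pixel_spacing` must be a single positive number")
  }
  if (anyNA(intensities)) mm_abort("`intensities` must not contain NA")
  n_clamped <- sum(intensities < 0 | intensities > 1000)
  if (n_clamped > 0) {
    warning(n_clamped, " voxel(s) outside [0, 1000] clamped on ingest",
            call. = FALSE)
    intensities[intensities < 0] <- 0
    intensities[intensities > 1000] <- 1000
  }
  structure(
    list(intensities = intensities, pixel_spacing = pixel_spacing,
         slice_label = slice_label, clamped = n_clamped),
    class = "pdff_map"
  )
}

#' @export
print.pdff_map <- function(x, ...) {
  cat("<pdff_map> ", nrow(x$intensities), "x", ncol(x$intensities),
      " @ ", x$pixel_spacing, " mm, slice ", x$slice_label,
      ", mean fat fraction ", sprintf("%.1f%%",
                                      mean(x$intensities) / 10), "\n", sep = "")
  invisible(x)
}

#' Construct a compartment mask set
#'
#' Takes an integer label matrix (0 = background, 1-8 = [COMPARTMENTS]) and
#' validates the mask-set contract: labels in 0-8, compartments pairwise
#' disjoint (guaranteed by the label encoding) and each non-empty compartment
#' 4-connected.
#'
#' @param labels integer matrix of compartment labels.
#' @param check_connected validate 4-connectivity (default `TRUE`).
#' @return an object of class `compartment_masks`.
#' @export
compartment_masks <- function(labels, check_connected = TRUE) {
  if (!is.matrix(labels)) mm_abort("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L | labels > 8L)) {
    mm_abort("mask labels must be integers in 0..8")
  }
  if (check_connected) {
    for (k in seq_along(COMPARTMENTS)) {
      if (any(labels == k) && !is_four_connected(labels == k)) {
        mm_abort(paste0("compartment ", COMPARTMENTS[k],
                        " is not 4-connected"))
      }
    }
  }
  structure(list(labels = labels), class = "compartment_masks")
}

#' @export
print.compartment_masks <- function(x, ...) {
  counts <- tabulate(x$labels[x$labels > 0L], nbins = 8L)
  cat("<compartment_masks> ", nrow(x$labels), "x", ncol(x$labels),
      ", ", sum(counts), " mask voxels\n", sep = "")
  print(setNames(counts, COMPARTMENTS))
  invisible(x)
}

#' Per-compartment voxel counts as a tibble
#' @param masks a [compartment_masks()] object.
#' @return tibble with columns `compartment`, `n_voxels`.
#' @export
compartment_counts <- function(masks) {
  stopifnot(inherits(masks, "compartment_masks"))
  counts <- tabulate(masks$labels[masks$labels > 0L], nbins = 8L)
  tibble(compartment = COMPARTMENTS, n_voxels = as.integer(counts))
}

# flood-fill 4-connectivity check on a logical matrix
is_four_connected <- function(mask) {
  idx <- which(mask)
  if (length(idx) <= 1) return(TRUE)
  nr <- nrow(mask)
  visited <- logical(length(mask))
  queue <- idx[1]
  visited[queue] <- TRUE
  while (length(queue) > 0) {
    cur <- queue
    queue <- integer(0)
    for (d in list(-1L, 1L, -nr, nr)) {
      nb <- cur + d
      # row wrap guard for +-1 moves
      if (d == -1L) nb <- nb[(cur - 1L) %% nr != 0L]
      if (d == 1L) nb <- nb[cur %% nr != 0L]
      nb <- nb[nb >= 1L & nb <= length(mask)]
      nb <- nb[mask[nb] & !visited[nb]]
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  all(visited[idx])
}

#' Convert map intensity to percent fat fraction (and back)
#'
#' The 0-1000 intensity scale maps linearly onto 0-100% fat fraction, so the
#' fat-free threshold intensity of 200 corresponds to 20% fat.
#'
#' @param intensity intensity on the 0-1000 scale.
#' @param fat_fraction fat fraction in percent.
#' @return the converted value.
#' @examples
#' intensity_to_fat_fraction(200) # 20
#' @export
intensity_to_fat_fraction <- function(intensity) intensity / 10

#' @rdname intensity_to_fat_fraction
#' @export
fat_fraction_to_intensity <- function(fat_fraction) fat_fraction * 10

#' Write / read a subject's PDFF map and mask as NIfTI
#'
#' Images are written as a `<id>_pdff.nii.gz` / `<id>_mask.nii.gz` pair; mask
#' voxel values 1-8 encode the compartments in [COMPARTMENTS] order, 0 is
#' background. Pixel spacing is carried in the NIfTI `pixdim`.
#'
#' @param map a [pdff_map()].
#' @param masks a [compartment_masks()].
#' @param dir output directory.
#' @param id subject identifier used as file prefix.
#' @return `write_subject_nifti()` the two file paths (invisibly);
#'   `read_subject_nifti()` a list with elements `map` and `masks`.
#' @export
write_subject_nifti <- function(map, masks, dir, id) {
  stopifnot(inherits(map, "pdff_map"), inherits(masks, "compartment_masks"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- map$pixel_spacing
  pdff_path <- file.path(dir, paste0(id, "_pdff.nii.gz"))
  mask_path <- file.path(dir, paste0(id, "_mask.nii.gz"))
  img <- RNifti::asNifti(structure(map$intensities, pixdim = c(sp, sp)))
  RNifti::writeNifti(img, pdff_path)
  lab <- RNifti::asNifti(structure(masks$labels, pixdim = c(sp, sp)),
                         datatype = "uint8")
  RNifti::writeNifti(lab, mask_path)
  invisible(c(pdff = pdff_path, mask = mask_path))
}

#' @rdname write_subject_nifti
#' @export
read_subject_nifti <- function(dir, id) {
  pdff_path <- file.path(dir, paste0(id, "_pdff.nii.gz"))
  mask_path <- file.path(dir, paste0(id, "_mask.nii.gz"))
  if (!file.exists(pdff_path) || !file.exists(mask_path)) {
    mm_abort(paste0("missing NIfTI pair for subject ", id, " in ", dir),
             class = "musclemap_io_error")
  }
  img <- RNifti::readNifti(pdff_path)
  lab <- RNifti::readNifti(mask_path)
  sp <- RNifti::pixdim(img)[1]
  map <- pdff_map(matrix(as.numeric(img), nrow = dim(img)[1]),
                  pixel_spacing = sp)
  masks <- compartment_masks(matrix(as.integer(lab), nrow = dim(lab)[1]),
                             check_connected = FALSE)
  if (!identical(dim(map$intensities), dim(masks$labels))) {
    mm_abort(paste0("map/mask grids differ for subject ", id))
  }
  list(map = map, masks = masks)
}
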