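#' Per-pixel patch features
#'
#' Describes each requested pixel by its 9x9 in-plane region of interest
#' (ROI): intensity mean and sample standard deviation, four Haralick
#' statistics of the gray level co-occurrence matrix (GLCM), and seven Haar
#' wavelet subband statistics. ROIs reaching outside the slice are completed
#' by whole-sample reflection, so boundary pixels get full-size ROIs.
#'
#' The GLCM is computed after quantizing the ROI to 8 gray levels between
#' its own min and max (per-ROI ranging makes the texture statistics
#' insensitive to the per-slice gain inhomogeneity of sparse MRI); counts are
#' accumulated symmetrically over the four distance-1 offsets (0, 45, 90,
#' 135 degrees) and the contrast, correlation, energy (angular second
#' moment) and homogeneity are averaged over offsets. A constant ROI
#' quantizes to a single level: energy 1, contrast 0, homogeneity 1,
#' correlation 1 by convention.
#'
#' The Haar features come from a 2-level orthonormal 2D Haar transform of
#' the leading 8x8 block of the ROI: the mean absolute coefficient of each
#' detail subband (LH, HL, HH at both levels) plus the mean level-2
#' approximation coefficient (equal to 4c for a constant ROI of value c).
#'
#' The `"lowlevel"` feature set is the two intensity statistics alone.
#'
#' @param slice_image numeric matrix (one slice).
#' @param pixels integer matrix with columns `(row, col)`, 1-based.
#' @param low_level if `TRUE`, return only the intensity statistics.
#' @return A list with `values` (`n_pixels x n_features` matrix),
#'   `feature_names`, and `pixels` (the input coordinates).
#' @export
extract_features <- function(slice_image, pixels, low_level = FALSE) {
  if (any(!is.finite(slice_image))) stop("slice contains non-finite values")
  pixels <- as_pixel_matrix(pixels)
  vals <- extract_features_cpp(slice_image, pixels, low_level)
  colnames(vals) <- feature_names(low_level)
  list(values = vals, feature_names = colnames(vals), pixels = pixels)
}

#' @param low_level logical.
#' @rdname extract_features
#' @export
feature_names <- function(low_level = FALSE) {
  nm <- c("int_mean", "int_sd")
  if (!low_level)
    nm <- c(nm, paste0("glcm_", c("contrast", "correlation", "energy",
                                  "homogeneity")),
            paste0("haar_", c("lh1", "hl1", "hh1", "lh2", "hl2", "hh2",
                              "ll2")))
  nm
}

#' @param roi square numeric matrix (typically 9x9).
#' @rdname extract_features
#' @export
glcm_stats <- function(roi) {
  v <- glcm_stats_cpp(roi)
  names(v) <- c("contrast", "correlation", "energy", "homogeneity")
  v
}

#' @rdname extract_features
#' @export
haar_stats <- function(roi) {
  v <- haar_stats_cpp(roi)
  names(v) <- c("lh1", "hl1", "hh1", "lh2", "hl2", "hh2", "ll2")
  v
}
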