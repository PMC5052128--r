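#' Dice overlap coefficient
#'
#' `Dice = 2 |A intersect B| / (|A| + |B|)` between a segmentation and a
#' reference on the same grid. Two empty masks are an error (the ratio is
#' undefined).
#'
#' @param seg,truth [new_label_volume()] objects (or plain binary arrays)
#'   on the same grid.
#' @return Dice in `[0, 1]`.
#' @export
dice <- function(seg, truth) {
  a <- label_array(seg); b <- label_array(truth)
  if (!all(dim(a) == dim(b))) stop("masks must share one grid")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) stop("both masks are empty; Dice undefined")
  2 * sum(a & b) / (sa + sb)
}

label_array <- function(x) {
  if (inherits(x, "scribseg_volume")) x <- x$data
  if (!all(x %in% c(0, 1))) stop("mask must be binary")
  if (is.null(dim(x))) dim(x) <- length(x)
  array(as.integer(x), dim(x))
}

#' Per-slice Dice profile
#'
#' @param axis slice axis (3 = the sparse axis).
#' @return Numeric vector, one Dice per slice; `NA` where both slices are
#'   empty.
#' @rdname dice
#' @export
per_slice_dice <- function(seg, truth, axis = 3L) {
  a <- label_array(seg); b <- label_array(truth)
  vapply(seq_len(dim(a)[axis]), function(k) {
    sa <- slice_along(a, k, axis); sb <- slice_along(b, k, axis)
    if (sum(sa) + sum(sb) == 0) return(NA_real_)
    2 * sum(sa & sb) / (sum(sa) + sum(sb))
  }, numeric(1))
}

slice_along <- function(a, k, axis) {
  switch(axis, a[k, , ], a[, k, ], a[, , k])
}

#' Average symmetric surface distance (mm)
#'
#' Surface voxels are mask voxels with at least one background
#' face-neighbor (voxels beyond the grid count as background). The metric
#' averages, over both surfaces, each surface voxel's shortest Euclidean
#' distance in mm to the other surface:
#' `ASSD = (sum_{i in Ss} d(i, Sg) + sum_{i in Sg} d(i, Ss)) / (|Ss| + |Sg|)`.
#'
#' @param seg,truth nonempty binary masks on one grid.
#' @param spacing mm voxel spacing triple (taken from `seg` if it is a
#'   volume).
#' @return ASSD in mm.
#' @export
assd <- function(seg, truth, spacing = NULL) {
  if (is.null(spacing) && inherits(seg, "scribseg_volume"))
    spacing <- seg$spacing
  if (is.null(spacing)) stop("spacing required")
  a <- label_array(seg); b <- label_array(truth)
  if (!all(dim(a) == dim(b))) stop("masks must share one grid")
  if (sum(a) == 0 || sum(b) == 0) stop("ASSD undefined for an empty mask")
  sa <- surface_mm(a, spacing); sb <- surface_mm(b, spacing)
  (sum(min_cross_dist(sa, sb)) + sum(min_cross_dist(sb, sa))) /
    (nrow(sa) + nrow(sb))
}

# mm coordinates of face-connected surface voxels
surface_mm <- function(mask, spacing) {
  d <- dim(mask)
  padded <- array(0L, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  nb <- array(0L, d)
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))) {
    nb <- nb + padded[2:(d[1] + 1) + sh[1], 2:(d[2] + 1) + sh[2],
                      2:(d[3] + 1) + sh[3]]
  }
  surf <- mask == 1L & nb < 6L
  idx <- which(surf, arr.ind = TRUE)
  sweep(idx - 1, 2, spacing, "*")
}

# for each row of a: min Euclidean distance to rows of b (chunked)
min_cross_dist <- function(a, b, chunk = 512L) {
  out <- numeric(nrow(a))
  bt <- t(b)
  b2 <- colSums(bt^2)
  for (s in seq(1L, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(a))
    aa <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(aa^2), b2, "+") - 2 * aa %*% bt
    m <- apply(d2, 1, min)
    m[m < 1e-9] <- 0  # cancellation residue on coincident points
    out[s:e] <- sqrt(m)
  }
  out
}

#' Fleiss' kappa multi-rater agreement
#'
#' Treats every voxel as a subject rated into 2 categories by `n` raters:
#' the observed agreement `Pa` is the mean over voxels of the fraction of
#' agreeing rater pairs, the chance agreement `Pe` the sum of squared
#' overall category proportions, and `kappa = (Pa - Pe) / (1 - Pe)`.
#'
#' @param segmentations list of >= 2 binary masks on one grid.
#' @return kappa (<= 1); perfect agreement with both classes present gives
#'   1, independent random raters about 0. All raters constant and
#'   identical (`Pe = 1`) is an error (kappa undefined).
#' @export
fleiss_kappa <- function(segmentations) {
  if (length(segmentations) < 2L) stop("need at least 2 raters")
  mats <- lapply(segmentations, label_array)
  d <- dim(mats[[1]])
  for (m in mats) if (!all(dim(m) == d)) stop("raters must share one grid")
  n <- length(mats)
  npos <- Reduce(`+`, mats)
  # agreeing pairs per voxel: C(npos,2) + C(n-npos,2) out of C(n,2)
  pa <- (npos * (npos - 1) + (n - npos) * (n - npos - 1)) / (n * (n - 1))
  p1 <- mean(npos) / n
  pe <- p1^2 + (1 - p1)^2
  if (1 - pe < 1e-12)
    stop("all raters constant and identical; kappa undefined")
  (mean(pa) - pe) / (1 - pe)
}

#' Evaluate a segmentation against a reference
#'
#' @param raters optional list of label volumes for the kappa entry.
#' @return List with `dice`, `assd_mm`, `per_slice_dice` and (if raters
#'   given) `kappa`.
#' @rdname dice
#' @export
eval_report <- function(seg, truth, spacing = NULL, raters = NULL) {
  rep <- list(dice = dice(seg, truth),
              assd_mm = assd(seg, truth, spacing),
              per_slice_dice = per_slice_dice(seg, truth))
  if (!is.null(raters)) rep$kappa <- fleiss_kappa(raters)
  rep
}
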