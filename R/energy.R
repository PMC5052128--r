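#' Energy terms of the segmentation CRF
#'
#' The labeling energy is a sum of unary data terms and contrast-sensitive
#' Potts pairwise terms. The unary cost of assigning label `c` to a pixel
#' with foreground posterior `p` is `-log(p)` for `c = 1` and `-log(1 - p)`
#' for `c = 0`, with `p` clamped to `[1e-6, 1 - 1e-6]` so certainty stays
#' finite.
#'
#' @param prob foreground posterior(s) in `[0, 1]`.
#' @param label 0 or 1 (recycled).
#' @return Nonnegative cost(s).
#' @export
unary_cost <- function(prob, label) {
  if (any(prob < 0 | prob > 1, na.rm = TRUE) || any(!is.finite(prob)))
    stop("probabilities must lie in [0, 1]")
  eps <- 1e-6
  k <- max(length(prob), length(label))
  p <- rep_len(pmin(pmax(prob, eps), 1 - eps), k)
  lab <- rep_len(label, k)
  out <- -log(1 - p)
  out[lab == 1] <- -log(p[lab == 1])
  out
}

#' @description
#' `intensity_pairwise` is the in-plane contrast term
#' `B = 1/dist * exp(-(Ii - Ij)^2 / (2 sigma1^2))`: maximal (`1/dist`) for
#' equal intensities, decaying with contrast, so cuts are cheap across
#' strong edges.
#'
#' @param Ii,Ij neighboring pixel intensities.
#' @param dist center distance in mm (> 0).
#' @param sigma1 intensity contrast scale (default 2.5).
#' @rdname unary_cost
#' @export
intensity_pairwise <- function(Ii, Ij, dist, sigma1 = 2.5) {
  if (any(dist <= 0)) stop("dist must be > 0")
  exp(-(Ii - Ij)^2 / (2 * sigma1^2)) / dist
}

#' @description
#' `prob_pairwise_slice` is the inter-slice term of the 4D refinement,
#' identical in form but driven by the phase-1 foreground posteriors, whose
#' scale is homogeneous across slices even when intensities are not
#' (`sigma2`, default 0.005).
#'
#' @param Pi,Pj foreground posteriors of the pair.
#' @param sigma2 probability contrast scale of the inter-slice term.
#' @rdname unary_cost
#' @export
prob_pairwise_slice <- function(Pi, Pj, dist, sigma2 = 0.005) {
  if (any(dist <= 0)) stop("dist must be > 0")
  exp(-(Pi - Pj)^2 / (2 * sigma2^2)) / dist
}

#' @description
#' `prob_pairwise_interimage` couples corresponding voxels of different
#' views: `exp(-(Pi - Pj)^2 / (2 sigma3^2))`, with **no** distance factor —
#' the constant inter-image weight is carried by its coefficient `lambda3`.
#'
#' @param sigma3 probability contrast scale of the inter-volume term.
#' @rdname unary_cost
#' @export
prob_pairwise_interimage <- function(Pi, Pj, sigma3 = 0.08) {
  exp(-(Pi - Pj)^2 / (2 * sigma3^2))
}

#' CRF parameter sets
#'
#' `crf_params` holds the per-slice CRF weights (`lambda1 = 40`,
#' `sigma1 = 2.5` by default); `coseg_params` extends them with the
#' inter-slice and inter-volume weights of the 4D refinement
#' (`lambda2 = 10`, `lambda3 = 3`, `sigma2 = 0.005`, `sigma3 = 0.08`).
#'
#' @param lambda1 in-plane pairwise weight (>= 0).
#' @param sigma1 intensity contrast scale (> 0).
#' @export
crf_params <- function(lambda1 = 40, sigma1 = 2.5) {
  if (lambda1 < 0 || sigma1 <= 0) stop("need lambda1 >= 0 and sigma1 > 0")
  structure(list(lambda1 = lambda1, sigma1 = sigma1),
            class = "scribseg_crf_params")
}

#' @param lambda2,lambda3 inter-slice / inter-volume pairwise weights.
#' @param sigma2,sigma3 probability contrast scales.
#' @rdname crf_params
#' @export
coseg_params <- function(lambda1 = 40, lambda2 = 10, lambda3 = 3,
                         sigma1 = 2.5, sigma2 = 0.005, sigma3 = 0.08) {
  if (any(c(lambda1, lambda2, lambda3) < 0))
    stop("lambda weights must be >= 0")
  if (any(c(sigma1, sigma2, sigma3) <= 0))
    stop("sigma scales must be > 0")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 sigma1 = sigma1, sigma2 = sigma2, sigma3 = sigma3),
            class = "scribseg_coseg_params")
}
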