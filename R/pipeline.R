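#' Segmentation configuration
#'
#' Bundles every tunable of the two-phase pipeline: the online forest, the
#' per-slice CRF, the 4D refinement weights, the self-training harvest
#' radius (10 px), the propagation stop rule and the ablation variant.
#'
#' Variants: `"full"` (online forest + high-level features + CRF),
#' `"offline"` (forest frozen after the start slice), `"lowlevel"`
#' (intensity mean/sd features only), `"nocrf"` (threshold at
#' `nocrf_threshold`, keep the largest connected component, then
#' morphological opening and closing, disc radius 2).
#'
#' @param forest a [forest_config()].
#' @param crf a [crf_params()].
#' @param coseg a [coseg_params()].
#' @param erosion_radius_px background-erosion radius (pixels) for
#'   harvesting negative seeds.
#' @param variant one of `"full"`, `"offline"`, `"lowlevel"`, `"nocrf"`.
#' @param nocrf_threshold probability threshold of the `"nocrf"` variant.
#' @param stop_min_fg_px propagation along a direction stops when the
#'   foreground area drops below this many pixels.
#' @return An object of class `scribseg_config`.
#' @export
seg_config <- function(forest = forest_config(), crf = crf_params(),
                       coseg = coseg_params(), erosion_radius_px = 10L,
                       variant = c("full", "offline", "lowlevel", "nocrf"),
                       nocrf_threshold = 0.5, stop_min_fg_px = 20L) {
  variant <- match.arg(variant)
  if (erosion_radius_px < 0L) stop("erosion_radius_px must be >= 0")
  if (nocrf_threshold <= 0 || nocrf_threshold >= 1)
    stop("nocrf_threshold must lie in (0, 1)")
  structure(list(forest = forest, crf = crf, coseg = coseg,
                 erosion_radius_px = as.integer(erosion_radius_px),
                 variant = variant, nocrf_threshold = nocrf_threshold,
                 stop_min_fg_px = as.integer(stop_min_fg_px)),
            class = "scribseg_config")
}

#' Harvest self-training seeds from a segmented slice
#'
#' After a slice is labeled, new positive seeds are the morphological
#' skeleton of its foreground (Zhang-Suen thinning to the medial axis) and
#' new negative seeds are the background eroded by a disc of
#' `erosion_radius_px` (10 px by default), with pixels beyond the image
#' treated as background. Seeds sit well inside their regions, so a
#' moderately wrong boundary does not poison the forest.
#'
#' @param mask binary matrix (one slice's labels).
#' @param erosion_radius_px background erosion radius in pixels.
#' @return List with `fg` and `bg` pixel matrices (either may be empty).
#' @export
harvest_training <- function(mask, erosion_radius_px = 10L) {
  mask <- matrix(as.integer(mask != 0), nrow(mask))
  fg <- which(morph_skeleton(mask) == 1L, arr.ind = TRUE)
  bgmask <- 1L - mask
  if (erosion_radius_px > 0L && any(bgmask == 1L))
    bgmask <- mask_morph(bgmask, EBImage::erode,
      EBImage::makeBrush(2L * erosion_radius_px + 1L, "disc"))
  bg <- which(bgmask == 1L, arr.ind = TRUE)
  list(fg = as_pixel_matrix(fg), bg = as_pixel_matrix(bg))
}

# morphological skeleton by Zhang-Suen thinning: iteratively peels boundary
# pixels that do not disconnect or shorten the shape, leaving the medial
# axis (a 1-px line is its own skeleton; a disk thins to its center)
morph_skeleton <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask))
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(p, dr, dc)
    p[2L + dr + seq_len(nr) - 1L, 2L + dc + seq_len(nc) - 1L]
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- matrix(0L, nr + 2L, nc + 2L)
      p[1L + seq_len(nr), 1L + seq_len(nc)] <- m
      # clockwise neighbors starting north
      n2 <- shift(p, -1L, 0L); n3 <- shift(p, -1L, 1L)
      n4 <- shift(p, 0L, 1L);  n5 <- shift(p, 1L, 1L)
      n6 <- shift(p, 1L, 0L);  n7 <- shift(p, 1L, -1L)
      n8 <- shift(p, 0L, -1L); n9 <- shift(p, -1L, -1L)
      B <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
      A <- (n2 == 0L & n3 == 1L) + (n3 == 0L & n4 == 1L) +
        (n4 == 0L & n5 == 1L) + (n5 == 0L & n6 == 1L) +
        (n6 == 0L & n7 == 1L) + (n7 == 0L & n8 == 1L) +
        (n8 == 0L & n9 == 1L) + (n9 == 0L & n2 == 1L)
      if (sub == 1L) {
        del <- m == 1L & B >= 2L & B <= 6L & A == 1L &
          n2 * n4 * n6 == 0L & n4 * n6 * n8 == 0L
      } else {
        del <- m == 1L & B >= 2L & B <= 6L & A == 1L &
          n2 * n4 * n8 == 0L & n2 * n6 * n8 == 0L
      }
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# binary morphology with the pixels beyond the image treated as background:
# EBImage replicates the border (an all-foreground mask would never erode),
# so pad with zeros by the brush radius and crop back
mask_morph <- function(mask, op, brush) {
  r <- (nrow(brush) - 1L) %/% 2L
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2L * r, nc + 2L * r)
  p[r + seq_len(nr), r + seq_len(nc)] <- mask
  res <- matrix(as.integer(round(as.numeric(op(p, brush)))), nr + 2L * r)
  res[r + seq_len(nr), r + seq_len(nc)]
}

#' Segment the annotated start slice
#'
#' Extracts features for the whole slice, trains a fresh online forest on
#' the scribbled pixels (one feature row per scribbled pixel), predicts the
#' foreground posterior everywhere, and turns it into labels with the
#' per-slice CRF — the scribbles act as hard constraints there. The
#' `"nocrf"` variant thresholds the posterior, keeps the largest connected
#' component and smooths it by opening/closing instead.
#'
#' @param volume a [new_volume()].
#' @param scribbles a [new_scribbles()] with nonempty fg and bg.
#' @param config a [seg_config()].
#' @return List with `prob` (matrix), `labels` (0/1 matrix) and `forest`.
#' @export
segment_start_slice <- function(volume, scribbles, config = seg_config()) {
  stopifnot(inherits(volume, "scribseg_volume"),
            inherits(scribbles, "scribseg_scribbles"))
  if (nrow(scribbles$fg) == 0L || nrow(scribbles$bg) == 0L)
    stop("start slice needs scribbles of both classes")
  k <- scribbles$slice_index
  if (k < 1L || k > dim(volume$data)[3]) stop("start slice out of range")
  low <- config$variant == "lowlevel"
  img <- volume$data[, , k]
  feats <- extract_features(img, all_pixels(img), low_level = low)
  forest <- forest_init(config$forest, feats$feature_names)
  ridx <- function(px) px[, 1] + (px[, 2] - 1L) * nrow(img)
  train_rows <- c(ridx(scribbles$fg), ridx(scribbles$bg))
  labels <- c(rep(1, nrow(scribbles$fg)), rep(0, nrow(scribbles$bg)))
  forest <- forest_update(forest,
                          feats$values[train_rows, , drop = FALSE], labels)
  prob <- matrix(forest_predict(forest, feats$values), nrow(img))
  lab <- apply_labeling_rule(prob, img, volume$spacing[1:2], config,
                             hard_fg = scribbles$fg, hard_bg = scribbles$bg)
  list(prob = prob, labels = lab, forest = forest)
}

all_pixels <- function(img) {
  cbind(rep(seq_len(nrow(img)), ncol(img)),
        rep(seq_len(ncol(img)), each = nrow(img)))
}

# CRF labeling, or the nocrf replacement rule
apply_labeling_rule <- function(prob, img, spacing_inplane, config,
                                hard_fg = NULL, hard_bg = NULL) {
  if (config$variant == "nocrf") {
    bin <- matrix(as.integer(prob >= config$nocrf_threshold), nrow(prob))
    if (any(bin == 1L)) {
      cc <- EBImage::bwlabel(bin)
      bin <- matrix(as.integer(cc == which.max(tabulate(cc[cc > 0]))),
                    nrow(prob))
      br <- EBImage::makeBrush(5, "disc")   # disc radius 2
      bin <- mask_morph(mask_morph(bin, EBImage::opening, br),
                        EBImage::closing, br)
    }
    bin
  } else {
    crf_segment_slice(prob, img, spacing_inplane, config$crf,
                      hard_fg = hard_fg, hard_bg = hard_bg)
  }
}

#' Propagate the segmentation through the whole volume
#'
#' Starting from the user-annotated slice, the segmentation advances
#' slice-by-slice toward both ends of the volume independently, each
#' direction carrying its own copy of the start-slice forest (so neither
#' direction depends on the other's updates). For every new slice the
#' previous slice's labels are harvested ([harvest_training()]) and their
#' feature rows stream into the forest (skipped by the `"offline"`
#' variant), the updated forest predicts the slice posterior, and the CRF
#' (or variant rule) labels it. A direction stops when the predicted
#' foreground area falls below `stop_min_fg_px` or slices run out.
#'
#' @inheritParams segment_start_slice
#' @return A `scribseg_seg_result`: `prob_volume`, `label_volume` and
#'   `per_slice_log` (data frame: slice, n_train_fg, n_train_bg, fg_px,
#'   energy).
#' @export
propagate <- function(volume, scribbles, config = seg_config()) {
  g <- dim(volume$data)
  start <- segment_start_slice(volume, scribbles, config)
  low <- config$variant == "lowlevel"
  prob <- array(0, g); lab <- array(0L, g)
  prob[, , scribbles$slice_index] <- start$prob
  lab[, , scribbles$slice_index] <- start$labels
  log <- data.frame(slice = scribbles$slice_index,
                    n_train_fg = nrow(scribbles$fg),
                    n_train_bg = nrow(scribbles$bg),
                    fg_px = sum(start$labels),
                    energy = energy_or_na(start$labels))

  for (step in c(1L, -1L)) {
    forest <- start$forest
    prev_lab <- start$labels
    prev_img <- volume$data[, , scribbles$slice_index]
    k <- scribbles$slice_index + step
    while (k >= 1L && k <= g[3]) {
      seeds <- harvest_training(prev_lab, config$erosion_radius_px)
      if (config$variant != "offline" &&
          nrow(seeds$fg) > 0L && nrow(seeds$bg) > 0L) {
        tf <- extract_features(prev_img, rbind(seeds$fg, seeds$bg),
                               low_level = low)
        forest <- forest_update(forest, tf$values,
                                c(rep(1, nrow(seeds$fg)),
                                  rep(0, nrow(seeds$bg))))
      }
      img <- volume$data[, , k]
      feats <- extract_features(img, all_pixels(img), low_level = low)
      pk <- matrix(forest_predict(forest, feats$values), g[1])
      lk <- apply_labeling_rule(pk, img, volume$spacing[1:2], config)
      prob[, , k] <- pk; lab[, , k] <- lk
      log <- rbind(log, data.frame(slice = k, n_train_fg = nrow(seeds$fg),
                                   n_train_bg = nrow(seeds$bg),
                                   fg_px = sum(lk),
                                   energy = energy_or_na(lk)))
      if (sum(lk) < config$stop_min_fg_px) break
      prev_lab <- lk; prev_img <- img
      k <- k + step
    }
  }
  structure(list(
    prob_volume = new_volume(prob, volume$spacing, volume$origin),
    label_volume = new_label_volume(lab, volume$spacing, volume$origin),
    per_slice_log = log[order(log$slice), ]),
    class = "scribseg_seg_result")
}

energy_or_na <- function(lab) {
  e <- attr(lab, "energy")
  if (is.null(e)) NA_real_ else e
}

#' Run the full two-phase study
#'
#' Phase 1 runs [propagate()] on each view independently from its own
#' scribbles. Phase 2 builds inter-volume correspondences from the study's
#' view transforms and refines all views jointly with [coseg_refine()].
#' With a single view the refinement degenerates to a pure 3D probability
#' refinement (the inter-volume term is empty).
#'
#' @param study a [generate_study()] result, or any list with `volumes` and
#'   `view_transforms`.
#' @param scribbles_per_view list of one [new_scribbles()] per view.
#' @param config a [seg_config()].
#' @return List with `initial` (per-view `scribseg_seg_result`) and
#'   `refined` (per-view [new_label_volume()]).
#' @export
run_study <- function(study, scribbles_per_view, config = seg_config()) {
  K <- length(study$volumes)
  if (length(scribbles_per_view) != K)
    stop("need one scribble set per view")
  initial <- vector("list", K)
  for (k in seq_len(K))
    initial[[k]] <- propagate(study$volumes[[k]], scribbles_per_view[[k]],
                              config)
  corr <- if (K >= 2L)
    build_correspondences(study$volumes, study$view_transforms) else NULL
  refined <- coseg_refine(study$volumes,
                          lapply(initial, `[[`, "prob_volume"),
                          init_labels = lapply(initial, `[[`, "label_volume"),
                          correspondences = corr, params = config$coseg)
  list(initial = initial, refined = refined)
}
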