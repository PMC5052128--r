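#' Phantom specification for sparse multi-view studies
#'
#' Describes a synthetic acquisition of one smooth object (an ellipsoid or a
#' placenta-like crescent) sampled on one or more sparsely-sliced grids, each
#' slice independently corrupted by a multiplicative gain, additive Gaussian
#' noise and a small random in-plane translation (inter-slice motion). The
#' background carries a smooth sinusoidal texture defined in world
#' coordinates, so it is consistent across views.
#'
#' Intensities are in arbitrary units chosen so that the shipped contrast
#' scale `sigma1 = 2.5` of the slice CRF is meaningful: background mean 10,
#' foreground mean 16 by default.
#'
#' The per-slice log-gain follows a centered random walk with step standard
#' deviation `slice_gain_sd`, emulating the appearance drift between
#' interleaved slices that online learning is meant to track.
#'
#' @param grid_shape_per_view list of integer triples `(rows, cols, slices)`,
#'   one per view; all dims must be at least 8.
#' @param spacing_per_view list of mm triples `(row, col, slice)`; the slice
#'   spacing must strictly exceed the in-plane spacings.
#' @param object_kind `"crescent"` or `"ellipsoid"`.
#' @param fg_intensity_mean,bg_intensity_mean mean intensities (arbitrary
#'   units) of object and background.
#' @param noise_sd additive Gaussian noise sd.
#' @param slice_gain_sd step sd of the per-slice multiplicative log-gain walk.
#' @param motion_shift_sd sd (mm) of the random per-slice in-plane
#'   translation.
#' @param texture_amplitude peak amplitude of the background texture.
#' @param seed integer RNG seed; identical seeds give bit-identical studies.
#' @return An object of class `scribseg_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape_per_view = list(c(96L, 96L, 24L),
                                                    c(96L, 96L, 24L)),
                         spacing_per_view = list(c(0.7422, 0.7422, 3.0),
                                                 c(1.484, 1.484, 4.0)),
                         object_kind = c("crescent", "ellipsoid"),
                         fg_intensity_mean = 19,
                         bg_intensity_mean = 10,
                         noise_sd = 2.25,
                         slice_gain_sd = 0.05,
                         motion_shift_sd = 1.0,
                         texture_amplitude = 3.75,
                         seed = 1L) {
  object_kind <- match.arg(object_kind)
  stopifnot(length(grid_shape_per_view) == length(spacing_per_view))
  for (g in grid_shape_per_view)
    if (length(g) != 3L || any(g < 8L)) stop("grid dims must all be >= 8")
  for (s in spacing_per_view) {
    if (length(s) != 3L || any(s <= 0)) stop("spacings must be positive")
    if (s[3] <= max(s[1:2]))
      stop("slice spacing must strictly exceed in-plane spacing")
  }
  if (noise_sd < 0 || slice_gain_sd < 0 || motion_shift_sd < 0 ||
      texture_amplitude < 0)
    stop("noise, gain, motion and texture parameters must be >= 0")
  structure(list(
    grid_shape_per_view = lapply(grid_shape_per_view, as.integer),
    spacing_per_view = lapply(spacing_per_view, as.numeric),
    object_kind = object_kind,
    fg_intensity_mean = fg_intensity_mean,
    bg_intensity_mean = bg_intensity_mean,
    noise_sd = noise_sd, slice_gain_sd = slice_gain_sd,
    motion_shift_sd = motion_shift_sd,
    texture_amplitude = texture_amplitude,
    seed = as.integer(seed)), class = "scribseg_phantom_spec")
}

# implicit object indicator in world mm coordinates (object centered at 0).
# crescent = ellipsoid with an overlapping ellipsoidal bite taken out; the
# bite shrinks to nothing near the poles so every slice stays connected.
object_indicator <- function(kind, p) {
  inside_ell <- function(p, ctr, semi) {
    ((p[, 1] - ctr[1]) / semi[1])^2 + ((p[, 2] - ctr[2]) / semi[2])^2 +
      ((p[, 3] - ctr[3]) / semi[3])^2 <= 1
  }
  main <- inside_ell(p, c(0, 0, 0), c(28, 22, 20))
  if (kind == "ellipsoid") return(main)
  # the bite is deeper than the main ellipsoid along z, so every planar
  # cross-section of the crescent is a single connected lobe
  bite <- inside_ell(p, c(0, 14, 0), c(20, 14, 24))
  main & !bite
}

# smooth background texture in world coordinates, deterministic per study
make_texture_fun <- function(amplitude) {
  # 3 plane waves, wavelengths 8-15 mm, directions/phases drawn from the
  # caller's RNG stream
  nwave <- 3L
  dirs <- matrix(stats::rnorm(3 * nwave), nwave, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  wl <- stats::runif(nwave, 8, 15)
  ph <- stats::runif(nwave, 0, 2 * pi)
  function(p) {
    s <- 0
    for (w in seq_len(nwave))
      s <- s + sin(2 * pi * (p %*% dirs[w, ]) / wl[w] + ph[w])
    amplitude * as.numeric(s) / nwave
  }
}

# rigid rotation for view v: view 1 identity; view 2 slices along world x;
# further views alternate
view_rotation <- function(v) {
  if (v %% 2L == 1L) diag(3)
  else matrix(c(0, 0, 1,   0, 1, 0,   -1, 0, 0), 3, 3)  # slice axis -> world x
}

#' Generate a synthetic multi-view study
#'
#' Samples the continuous phantom object on each view's grid. Every slice is
#' perturbed independently: an in-plane translation (drawn with sd
#' `motion_shift_sd`), a multiplicative gain from the log-gain walk, and
#' voxelwise Gaussian noise. Ground-truth labels are sampled with the *same*
#' per-slice shifts, so each truth matches its corrupted image; the recorded
#' `view_transforms` ignore the motion, as an external registration would.
#'
#' @param spec a [phantom_spec()].
#' @param n_views number of views to generate (recycled geometry if `spec`
#'   lists fewer).
#' @return A `scribseg_study`: `volumes`, `truths` (per-view
#'   [new_label_volume()]), `view_transforms` (list of
#'   `list(rotation, translation)` mapping volume frame to world mm), and
#'   `applied_slice_shifts` (per-view `n_slices x 2` matrix, mm).
#' @export
generate_study <- function(spec, n_views = length(spec$grid_shape_per_view)) {
  stopifnot(inherits(spec, "scribseg_phantom_spec"))
  if (n_views < 1L) stop("n_views must be >= 1")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(spec$seed)
  texture <- make_texture_fun(spec$texture_amplitude)

  volumes <- truths <- transforms <- shifts_out <- vector("list", n_views)
  for (v in seq_len(n_views)) {
    g <- spec$grid_shape_per_view[[(v - 1L) %% length(spec$grid_shape_per_view) + 1L]]
    sp <- spec$spacing_per_view[[(v - 1L) %% length(spec$spacing_per_view) + 1L]]
    rot <- view_rotation(v)
    # volume frame centered on the object: origin places the grid center at 0
    origin <- -(g - 1) / 2 * sp
    shifts <- matrix(stats::rnorm(2L * g[3], 0, spec$motion_shift_sd), g[3], 2)
    gains <- exp(cumsum(stats::rnorm(g[3], 0, spec$slice_gain_sd)))
    gains <- gains / mean(gains)

    dat <- array(0, g); tru <- array(0L, g)
    rr <- (seq_len(g[1]) - 1) * sp[1] + origin[1]
    cc <- (seq_len(g[2]) - 1) * sp[2] + origin[2]
    base_rc <- cbind(rep(rr, times = g[2]), rep(cc, each = g[1]))
    for (k in seq_len(g[3])) {
      pv <- cbind(base_rc[, 1] + shifts[k, 1], base_rc[, 2] + shifts[k, 2],
                  (k - 1) * sp[3] + origin[3])
      pw <- pv %*% t(rot)
      ind <- object_indicator(spec$object_kind, pw)
      # sampling a cusp (crescent tip) can shed sub-voxel satellite
      # fragments; keep the largest in-plane component so slices are
      # connected, and color the image from the same cleaned mask
      im <- matrix(as.integer(ind), g[1], g[2])
      if (any(im == 1L)) {
        cc <- EBImage::bwlabel(im)
        main_comp <- which.max(tabulate(cc[cc > 0]))
        ind <- as.numeric(cc == main_comp) == 1
      }
      inten <- ifelse(ind, spec$fg_intensity_mean,
                      spec$bg_intensity_mean + texture(pw))
      inten <- gains[k] * inten
      if (spec$noise_sd > 0)
        inten <- inten + stats::rnorm(length(inten), 0, spec$noise_sd)
      dat[, , k] <- matrix(inten, g[1], g[2])
      tru[, , k] <- matrix(as.integer(ind), g[1], g[2])
    }
    volumes[[v]] <- new_volume(dat, sp, origin)
    truths[[v]] <- new_label_volume(tru, sp, origin)
    transforms[[v]] <- list(rotation = rot, translation = c(0, 0, 0))
    shifts_out[[v]] <- shifts
  }
  structure(list(volumes = volumes, truths = truths,
                 view_transforms = transforms,
                 applied_slice_shifts = shifts_out, spec = spec),
            class = "scribseg_study")
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Auto-generate scribbles from a ground-truth slice
#'
#' Emulates a careful user: the foreground stroke follows the ordered outer
#' contour of the truth foreground eroded by `erosion_px` in-plane pixels,
#' and the background stroke the contour of the similarly eroded background,
#' so every scribbled pixel carries the correct label with a safety margin
#' from the boundary. Points are recorded in contour order; prefixes of a
#' stated physical length can be cut with [scribble_prefix()].
#'
#' @param truth a [new_label_volume()].
#' @param slice_index slice to annotate.
#' @param fg_len_mm,bg_len_mm requested cumulative polyline lengths (mm);
#'   0 gives an empty stroke.
#' @param seed integer; rotates the contour starting point.
#' @param erosion_px erosion radius in pixels (default 3).
#' @return A [new_scribbles()] object.
#' @export
auto_scribbles <- function(truth, slice_index, fg_len_mm, bg_len_mm,
                           seed = 1L, erosion_px = 3L) {
  stopifnot(inherits(truth, "scribseg_label_volume"))
  sl <- truth$data[, , slice_index]
  if (!any(sl == 1L) || !any(sl == 0L))
    stop("slice ", slice_index, " lacks one of the classes")
  sp <- truth$spacing[1:2]
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  fg <- contour_stroke(sl == 1L, fg_len_mm, sp, erosion_px, "foreground")
  bg <- contour_stroke(sl == 0L, bg_len_mm, sp, erosion_px, "background")
  new_scribbles(slice_index, fg, bg)
}

# ordered stroke of target mm length along the contour of the eroded mask;
# when one contour lap is too short the stroke continues on the contour of
# a deeper erosion (spiraling inward, always strictly inside the class)
contour_stroke <- function(mask, len_mm, spacing, erosion_px, what) {
  if (len_mm <= 0) return(NULL)
  mask <- matrix(as.integer(mask), nrow(mask))
  pts <- NULL
  r <- erosion_px
  repeat {
    er <- mask_morph(mask, EBImage::erode,
                     EBImage::makeBrush(2L * r + 1L, "disc"))
    if (!any(er == 1L)) break
    lab <- EBImage::bwlabel(er)
    comp <- which.max(tabulate(lab[lab > 0]))
    cont <- EBImage::ocontour(EBImage::Image(lab == comp))[[1]] + 1L
    # ocontour returns (x, y) = (row-index, col-index) for matrix input
    m <- cbind(cont[, 1], cont[, 2])
    # rotate the starting point of the first lap for seed variety
    if (is.null(pts) && nrow(m) > 1L) {
      start <- sample.int(nrow(m), 1L)
      m <- rbind(m[start:nrow(m), , drop = FALSE],
                 m[seq_len(start - 1L), , drop = FALSE])
    }
    pts <- rbind(pts, m)
    cl <- cumsum(c(0, polyline_lengths(pts, spacing)))
    if (max(cl) + 1e-9 >= len_mm)
      return(pts[cl <= len_mm + 1e-9, , drop = FALSE])
    r <- r + 2L
  }
  if (is.null(pts)) stop("eroded ", what, " support is empty")
  stop(sprintf("requested %s scribble of %.0f mm but only %.0f mm achievable",
               what, len_mm,
               max(cumsum(c(0, polyline_lengths(pts, spacing))))))
}
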