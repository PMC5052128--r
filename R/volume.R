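#' Volume containers
#'
#' A `scribseg_volume` wraps a 3D intensity array together with its voxel
#' geometry. Arrays are stored in `(row, col, slice)` order with 1-based
#' indices; the third axis is always the sparse (thick-slice) axis. Physical
#' positions are `origin + (index - 1) * spacing` along each axis of the
#' volume's own frame; a rigid `view_transform` (rotation + translation) maps
#' that frame into a common world space when several views of the same
#' subject are combined.
#'
#' @param data 3D numeric array, `(row, col, slice)`.
#' @param spacing positive length-3 numeric, voxel spacing in mm for the
#'   row, column and slice axes. The slice spacing is expected to exceed the
#'   in-plane spacings (sparse acquisition).
#' @param origin length-3 numeric, mm position of voxel `(1, 1, 1)` in the
#'   volume frame.
#' @return An object of class `scribseg_volume`.
#' @export
new_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), " dims")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers (mm)")
  if (any(!is.finite(data))) stop("volume data contains non-finite values")
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "scribseg_volume")
}

#' @param label_data 3D array with values in \{0, 1\}.
#' @rdname new_volume
#' @export
new_label_volume <- function(label_data, spacing, origin = c(0, 0, 0)) {
  if (!all(label_data %in% c(0, 1)))
    stop("label volume must be binary (0/1)")
  v <- new_volume(array(as.integer(label_data), dim(label_data)),
                  spacing, origin)
  class(v) <- c("scribseg_label_volume", class(v))
  v
}

#' @export
print.scribseg_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 5), collapse = " x ")))
  invisible(x)
}

#' @export
dim.scribseg_volume <- function(x) dim(x$data)

#' Read / write NIfTI volumes
#'
#' Volumes are exchanged as NIfTI-1 files whose `pixdim` carries the voxel
#' spacing; data and spacing round-trip bit-exactly within dtype. Only 3D
#' images are accepted.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a [new_volume()]; `write_volume` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  im <- RNifti::readNifti(path)
  if (length(dim(im)) != 3L)
    stop("expected a 3D NIfTI image, got ", length(dim(im)),
         "D in ", path)
  sp <- RNifti::pixdim(im)
  new_volume(array(as.numeric(im), dim(im)), spacing = sp[1:3])
}

#' @param vol a [new_volume()] or [new_label_volume()].
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "scribseg_volume"))
  dat <- vol$data
  if (inherits(vol, "scribseg_label_volume")) storage.mode(dat) <- "integer"
  im <- RNifti::asNifti(dat)
  RNifti::pixdim(im) <- vol$spacing
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Scribble sets
#'
#' A scribble set records the ordered foreground and background polyline
#' pixels a user (or [auto_scribbles()]) drew in one start slice. Point
#' order is preserved so prefixes of a stated physical length can be taken.
#'
#' @param slice_index 1-based index of the annotated slice.
#' @param fg,bg integer matrices with columns `(row, col)`, ordered along
#'   the stroke; 1-based pixel indices.
#' @return An object of class `scribseg_scribbles`.
#' @export
new_scribbles <- function(slice_index, fg, bg) {
  fg <- as_pixel_matrix(fg); bg <- as_pixel_matrix(bg)
  if (nrow(fg) && nrow(bg)) {
    key <- function(m) paste(m[, 1], m[, 2])
    if (any(key(fg) %in% key(bg)))
      stop("foreground and background scribbles overlap")
  }
  structure(list(slice_index = as.integer(slice_index), fg = fg, bg = bg),
            class = "scribseg_scribbles")
}

as_pixel_matrix <- function(m) {
  if (is.null(m) || length(m) == 0L)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  m <- matrix(as.integer(round(m)), ncol = 2,
              dimnames = list(NULL, c("row", "col")))
  m
}

#' Read / write scribbles
#'
#' Two equivalent on-disk dialects: a JSON file
#' `{"slice_index": k, "index_base": 1, "fg": [[r,c],...], "bg": [[r,c],...]}`
#' preserving point order, and a NIfTI label map (0 = unlabeled, 1 =
#' foreground, 2 = background) which loses order. Both produce the same
#' pixel sets for equivalent content.
#'
#' @param path `.json` file, or a NIfTI file for the label-map dialect.
#' @return A [new_scribbles()] object.
#' @export
read_scribbles <- function(path) {
  if (grepl("\\.json$", path)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    base <- if (!is.null(x$index_base)) x$index_base else 1L
    shift <- 1L - as.integer(base)
    fix <- function(m) if (length(m)) matrix(as.integer(m), ncol = 2) + shift else NULL
    new_scribbles(x$slice_index + shift, fix(x$fg), fix(x$bg))
  } else {
    im <- RNifti::readNifti(path)
    if (length(dim(im)) != 3L) stop("scribble label map must be 3D")
    lab <- array(as.integer(im), dim(im))
    ks <- which(apply(lab != 0, 3, any))
    if (length(ks) != 1L)
      stop("scribble label map must mark exactly one slice, found ",
           length(ks))
    sl <- lab[, , ks]
    new_scribbles(ks, which(sl == 1L, arr.ind = TRUE),
                  which(sl == 2L, arr.ind = TRUE))
  }
}

#' @param scr a [new_scribbles()] object.
#' @param dims for the label-map dialect, the 3D grid dims to paint into.
#' @param spacing voxel spacing for the label-map dialect.
#' @rdname read_scribbles
#' @export
write_scribbles <- function(scr, path, dims = NULL, spacing = c(1, 1, 1)) {
  stopifnot(inherits(scr, "scribseg_scribbles"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(slice_index = scr$slice_index, index_base = 1L,
           fg = unname(scr$fg), bg = unname(scr$bg)),
      path, auto_unbox = TRUE)
  } else {
    if (is.null(dims)) stop("dims required for the label-map dialect")
    lab <- array(0L, dims)
    k <- scr$slice_index
    lab[cbind(scr$fg, k)] <- 1L
    lab[cbind(scr$bg, k)] <- 2L
    write_volume(new_volume(lab, spacing), path)
  }
  invisible(path)
}

#' Take a prefix of a scribble set by physical length
#'
#' Walks each stroke in recorded point order, accumulating the Euclidean
#' in-plane length in mm, and keeps points until the cumulative length
#' reaches the request (mirrors incremental scribble-length experiments).
#'
#' @param scr a [new_scribbles()] object.
#' @param fg_len_mm,bg_len_mm target cumulative polyline lengths in mm.
#' @param spacing_inplane length-2 mm spacing `(row, col)`.
#' @return A truncated [new_scribbles()] object.
#' @export
scribble_prefix <- function(scr, fg_len_mm, bg_len_mm, spacing_inplane) {
  cut_poly <- function(m, target) {
    if (nrow(m) == 0L || target <= 0) return(m[0, , drop = FALSE])
    d <- polyline_lengths(m, spacing_inplane)
    cl <- cumsum(c(0, d))
    m[cl <= target + 1e-9, , drop = FALSE]
  }
  new_scribbles(scr$slice_index, cut_poly(scr$fg, fg_len_mm),
                cut_poly(scr$bg, bg_len_mm))
}

# segment lengths (mm) between successive polyline points
polyline_lengths <- function(m, spacing_inplane) {
  if (nrow(m) < 2L) return(numeric(0))
  dr <- diff(m[, 1]) * spacing_inplane[1]
  dc <- diff(m[, 2]) * spacing_inplane[2]
  sqrt(dr^2 + dc^2)
}
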