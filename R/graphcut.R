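#' Exact per-slice CRF segmentation by max-flow
#'
#' Minimizes the slice labeling energy
#' `E(C) = sum_i U(c_i) + lambda1 * sum_{N1} B_ij * [c_i != c_j]`
#' over binary labelings, where the unaries come from [unary_cost()] on the
#' forest posteriors and the pairwise contrast term from
#' [intensity_pairwise()]. `N1` is the 8-connected in-plane neighborhood
#' (under 4-connectivity the `1/dist` factor would be vacuous on an
#' isotropic slice); distances are in mm from the in-plane spacing. The
#' energy is submodular, so the max-flow/min-cut solution is the exact
#' global minimum. Hard constraints are enforced by adding a cost of `1e9`
#' to the forbidden label.
#'
#' @param prob_map numeric matrix of foreground posteriors.
#' @param intensity numeric matrix of slice intensities (same shape).
#' @param spacing length-2 in-plane spacing `(row, col)` in mm.
#' @param params a [crf_params()].
#' @param hard_fg,hard_bg optional `(row, col)` matrices of pixels clamped
#'   to foreground / background; must be disjoint.
#' @return Integer 0/1 matrix of labels, with attribute `"energy"`.
#' @export
crf_segment_slice <- function(prob_map, intensity, spacing,
                              params = crf_params(),
                              hard_fg = NULL, hard_bg = NULL) {
  if (!all(dim(prob_map) == dim(intensity)))
    stop("prob_map and intensity shapes differ")
  if (any(!is.finite(prob_map)) || any(!is.finite(intensity)))
    stop("non-finite inputs")
  nr <- nrow(prob_map); nc <- ncol(prob_map); n <- nr * nc
  hard_fg <- as_pixel_matrix(hard_fg); hard_bg <- as_pixel_matrix(hard_bg)
  ifg <- hard_fg[, 1] + (hard_fg[, 2] - 1L) * nr
  ibg <- hard_bg[, 1] + (hard_bg[, 2] - 1L) * nr
  if (length(intersect(ifg, ibg)))
    stop("hard foreground and background sets overlap")

  u0 <- unary_cost(as.numeric(prob_map), 0L)
  u1 <- unary_cost(as.numeric(prob_map), 1L)
  u0[ifg] <- u0[ifg] + 1e9
  u1[ibg] <- u1[ibg] + 1e9

  ed <- slice_pair_edges(nr, nc, spacing)
  w <- params$lambda1 *
    intensity_pairwise(intensity[ed$i], intensity[ed$j], ed$dist,
                       params$sigma1)
  lab <- solve_binary_cut(n, u0, u1, ed$i, ed$j, w)
  out <- matrix(lab, nr, nc)
  attr(out, "energy") <- labeling_energy(lab, u0, u1, ed$i, ed$j, w) -
    1e9 * (sum(lab[ifg] == 0) + sum(lab[ibg] == 1))
  out
}

# 8-connected in-plane pair list with mm distances, linear indices r+(c-1)*nr
slice_pair_edges <- function(nr, nc, spacing) {
  idx <- matrix(seq_len(nr * nc), nr, nc)
  pair <- function(a, b, d) list(i = as.integer(a), j = as.integer(b),
                                 dist = rep(d, length(a)))
  dr <- spacing[1]; dc <- spacing[2]; dd <- sqrt(dr^2 + dc^2)
  p1 <- pair(idx[-nr, ], idx[-1, ], dr)                  # vertical
  p2 <- pair(idx[, -nc], idx[, -1], dc)                  # horizontal
  p3 <- pair(idx[-nr, -nc], idx[-1, -1], dd)             # diagonal \
  p4 <- pair(idx[-1, -nc], idx[-nr, -1], dd)             # diagonal /
  list(i = c(p1$i, p2$i, p3$i, p4$i), j = c(p1$j, p2$j, p3$j, p4$j),
       dist = c(p1$dist, p2$dist, p3$dist, p4$dist))
}

# exact binary submodular cut: nodes 1..n, t-link capacities u0 (label-0
# cost) and u1, undirected pairwise capacities w on (ei, ej).
# returns 0/1 labels; source side = foreground.
solve_binary_cut <- function(n, u0, u1, ei, ej, w) {
  stopifnot(length(u0) == n, length(u1) == n,
            length(ei) == length(w), length(ej) == length(w))
  keep <- w > 0
  maxflow_labels_cpp(n, as.integer(ei[keep]), as.integer(ej[keep]),
                     as.numeric(w[keep]), as.numeric(u0), as.numeric(u1))
}

labeling_energy <- function(lab, u0, u1, ei, ej, w) {
  sum(ifelse(lab == 1L, u1, u0)) + sum(w[lab[ei] != lab[ej]])
}

#' Inter-volume voxel correspondences
#'
#' For every voxel of every volume, finds the physically nearest voxel among
#' all *other* volumes: the voxel center is mapped through its view's rigid
#' transform into world space, back into each other volume's frame, and
#' rounded to the nearest grid index (for axis-aligned grids rounding per
#' axis gives the Euclidean nearest center). Voxels landing outside the
#' other grids contribute no pair; unordered pairs are recorded once.
#'
#' @param volumes list of >= 2 [new_volume()] objects.
#' @param transforms list of `list(rotation, translation)` rigid transforms
#'   mapping each volume's frame to world mm coordinates.
#' @return A `scribseg_correspondences`: integer matrix with columns
#'   `k1, i1, k2, i2` (volume index, linear voxel index).
#' @export
build_correspondences <- function(volumes, transforms) {
  K <- length(volumes)
  if (K < 2L) stop("need at least 2 volumes")
  stopifnot(length(transforms) == K)
  centers_world <- function(k) {
    v <- volumes[[k]]; g <- dim(v$data)
    idx <- arrayInd(seq_len(prod(g)), g)
    fr <- sweep(sweep(idx - 1, 2, v$spacing, "*"), 2, v$origin, "+")
    sweep(fr %*% t(transforms[[k]]$rotation), 2,
          transforms[[k]]$translation, "+")
  }
  worlds <- lapply(seq_len(K), centers_world)
  out <- vector("list", K)
  for (k1 in seq_len(K)) {
    p <- worlds[[k1]]
    best_d <- rep(Inf, nrow(p)); best_k <- best_i <- rep(NA_integer_, nrow(p))
    for (k2 in setdiff(seq_len(K), k1)) {
      v2 <- volumes[[k2]]; g2 <- dim(v2$data)
      fr2 <- sweep(p, 2, transforms[[k2]]$translation, "-") %*%
        transforms[[k2]]$rotation   # R^T = inverse rotation
      ci <- sweep(sweep(fr2, 2, v2$origin, "-"), 2, v2$spacing, "/") + 1
      ri <- round(ci)
      ok <- ri[, 1] >= 1 & ri[, 1] <= g2[1] & ri[, 2] >= 1 &
        ri[, 2] <= g2[2] & ri[, 3] >= 1 & ri[, 3] <= g2[3]
      d2 <- rowSums(((ri - ci) * rep(v2$spacing, each = nrow(ri)))^2)
      upd <- ok & d2 < best_d
      lin <- as.integer(ri[, 1] + (ri[, 2] - 1) * g2[1] +
                          (ri[, 3] - 1) * g2[1] * g2[2])
      best_d[upd] <- d2[upd]; best_k[upd] <- k2; best_i[upd] <- lin[upd]
    }
    has <- !is.na(best_k)
    out[[k1]] <- cbind(k1 = k1, i1 = which(has), k2 = best_k[has],
                       i2 = best_i[has])
  }
  m <- do.call(rbind, out)
  # canonical unordered order, then dedupe
  flip <- m[, "k1"] > m[, "k2"] |
    (m[, "k1"] == m[, "k2"] & m[, "i1"] > m[, "i2"])
  m[flip, ] <- m[flip, c(3, 4, 1, 2)]
  m <- m[!duplicated(m), , drop = FALSE]
  structure(m, class = "scribseg_correspondences")
}

#' 4D probability-based co-segmentation refinement
#'
#' Jointly relabels `K` volumes by one exact max-flow over the union of all
#' voxels, minimizing
#' `E = sum_k sum_i U(c_i) + lambda1 sum_{N1} B + lambda2 sum_{N2} B' +
#'  lambda3 sum_{N3} B''` (all pairwise terms Potts). `N1` are 8-connected
#' in-plane pairs weighted by intensity contrast; `N2` face-adjacent
#' inter-slice pairs within a volume, weighted by the phase-1 probability
#' contrast at distance = slice spacing; `N3` the inter-volume
#' correspondences, probability-weighted with no distance factor. Unaries
#' come from the phase-1 probability volumes, so the refinement needs no new
#' appearance model.
#'
#' @param volumes list of [new_volume()] (intensities).
#' @param prob_volumes list of matching [new_volume()] holding the phase-1
#'   foreground posteriors.
#' @param init_labels optional list of [new_label_volume()]; only used to
#'   report the energy decrease in the `"energy_initial"` attribute.
#' @param correspondences a [build_correspondences()] result, or `NULL` for
#'   `K = 1` (pure 3D refinement, the `lambda3` term is empty).
#' @param params a [coseg_params()].
#' @return List of `K` [new_label_volume()]; attributes `"energy"` and (if
#'   `init_labels` given) `"energy_initial"`.
#' @export
coseg_refine <- function(volumes, prob_volumes, init_labels = NULL,
                         correspondences = NULL, params = coseg_params()) {
  K <- length(volumes)
  stopifnot(length(prob_volumes) == K)
  if (K >= 2L && is.null(correspondences))
    stop("correspondences required for K >= 2")
  dims <- lapply(volumes, function(v) dim(v$data))
  for (k in seq_len(K)) {
    if (!all(dims[[k]] == dim(prob_volumes[[k]]$data)))
      stop("probability volume ", k, " shape mismatch")
    if (length(prob_volumes[[k]]$data) == 0L)
      stop("empty probability volume")
  }
  sizes <- vapply(dims, prod, 1)
  offset <- c(0, cumsum(sizes))[seq_len(K)]
  n <- sum(sizes)

  u0 <- u1 <- numeric(n)
  ei <- ej <- list(); w <- list()
  for (k in seq_len(K)) {
    v <- volumes[[k]]; P <- prob_volumes[[k]]$data
    g <- dims[[k]]; nr <- g[1]; nc <- g[2]; ns <- g[3]
    rng <- offset[k] + seq_len(sizes[k])
    u0[rng] <- unary_cost(as.numeric(P), 0L)
    u1[rng] <- unary_cost(as.numeric(P), 1L)
    # N1: replicate one slice's in-plane pairs across slices
    ed <- slice_pair_edges(nr, nc, v$spacing[1:2])
    koff <- rep((seq_len(ns) - 1L) * nr * nc, each = length(ed$i))
    i1 <- rep(ed$i, ns) + koff; j1 <- rep(ed$j, ns) + koff
    d1 <- rep(ed$dist, ns)
    w1 <- params$lambda1 *
      intensity_pairwise(v$data[i1], v$data[j1], d1, params$sigma1)
    ei <- c(ei, list(offset[k] + i1)); ej <- c(ej, list(offset[k] + j1))
    w <- c(w, list(w1))
    # N2: face pairs across adjacent slices
    if (ns > 1L && params$lambda2 > 0) {
      base <- seq_len(nr * nc * (ns - 1L))
      i2 <- base; j2 <- base + nr * nc
      w2 <- params$lambda2 *
        prob_pairwise_slice(P[i2], P[j2], v$spacing[3], params$sigma2)
      ei <- c(ei, list(offset[k] + i2)); ej <- c(ej, list(offset[k] + j2))
      w <- c(w, list(w2))
    }
  }
  if (!is.null(correspondences) && nrow(correspondences) > 0L &&
      params$lambda3 > 0) {
    m <- unclass(correspondences)
    Pi <- numeric(nrow(m)); Pj <- numeric(nrow(m))
    gi <- offset[m[, "k1"]] + m[, "i1"]
    gj <- offset[m[, "k2"]] + m[, "i2"]
    for (k in seq_len(K)) {
      s1 <- m[, "k1"] == k; s2 <- m[, "k2"] == k
      Pi[s1] <- prob_volumes[[k]]$data[m[s1, "i1"]]
      Pj[s2] <- prob_volumes[[k]]$data[m[s2, "i2"]]
    }
    w3 <- params$lambda3 * prob_pairwise_interimage(Pi, Pj, params$sigma3)
    ei <- c(ei, list(gi)); ej <- c(ej, list(gj)); w <- c(w, list(w3))
  }
  ei <- unlist(ei, use.names = FALSE); ej <- unlist(ej, use.names = FALSE)
  w <- unlist(w, use.names = FALSE)

  lab <- solve_binary_cut(n, u0, u1, ei, ej, w)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    lk <- lab[offset[k] + seq_len(sizes[k])]
    out[[k]] <- new_label_volume(array(lk, dims[[k]]), volumes[[k]]$spacing,
                                 volumes[[k]]$origin)
  }
  attr(out, "energy") <- labeling_energy(lab, u0, u1, ei, ej, w)
  if (!is.null(init_labels)) {
    l0 <- unlist(lapply(init_labels, function(x) as.integer(x$data)),
                 use.names = FALSE)
    attr(out, "energy_initial") <- labeling_energy(l0, u0, u1, ei, ej, w)
  }
  out
}
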