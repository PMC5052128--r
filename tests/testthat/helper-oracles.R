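# Independent oracles used across tests. These are deliberately written as
# plain double loops / enumerations, separate from the package's vectorized
# and compiled implementations.

# all 8-connected in-plane pixel pairs of an nr x nc slice, with mm distances
oracle_slice_pairs <- function(nr, nc, spacing) {
  out <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (d in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        out[[length(out) + 1L]] <- c(r, c, r2, c2,
                                     sqrt(sum((d * spacing)^2)))
      }
    }
  }
  do.call(rbind, out)
}

# slice CRF energy (unary -log with 1e-6 clamp + contrast Potts)
oracle_crf_energy <- function(lab, prob, img, spacing, lambda1, sigma1) {
  eps <- 1e-6
  p <- pmin(pmax(prob, eps), 1 - eps)
  e <- sum(ifelse(lab == 1, -log(p), -log(1 - p)))
  pr <- oracle_slice_pairs(nrow(prob), ncol(prob), spacing)
  for (k in seq_len(nrow(pr))) {
    a <- pr[k, 1:2]; b <- pr[k, 3:4]; dist <- pr[k, 5]
    if (lab[a[1], a[2]] != lab[b[1], b[2]]) {
      B <- exp(-(img[a[1], a[2]] - img[b[1], b[2]])^2 / (2 * sigma1^2)) / dist
      e <- e + lambda1 * B
    }
  }
  e
}

# enumerate all binary labelings of n pixels as an (2^n x n) matrix
all_labelings <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))
}

# joint co-segmentation energy for K volumes stacked into one label vector;
# corr is a plain matrix with columns k1, i1, k2, i2
oracle_coseg_energy <- function(labs, probs, vols, corr, par) {
  eps <- 1e-6
  e <- 0
  K <- length(vols)
  for (k in seq_len(K)) {
    P <- pmin(pmax(probs[[k]]$data, eps), 1 - eps)
    L <- labs[[k]]
    e <- e + sum(ifelse(L == 1, -log(P), -log(1 - P)))
    g <- dim(P); sp <- vols[[k]]$spacing
    for (s in seq_len(g[3])) {
      pr <- oracle_slice_pairs(g[1], g[2], sp[1:2])
      for (q in seq_len(nrow(pr))) {
        if (L[pr[q, 1], pr[q, 2], s] != L[pr[q, 3], pr[q, 4], s]) {
          B <- exp(-(vols[[k]]$data[pr[q, 1], pr[q, 2], s] -
                       vols[[k]]$data[pr[q, 3], pr[q, 4], s])^2 /
                     (2 * par$sigma1^2)) / pr[q, 5]
          e <- e + par$lambda1 * B
        }
      }
    }
    if (g[3] > 1) {
      for (s in seq_len(g[3] - 1)) for (r in seq_len(g[1]))
        for (cc in seq_len(g[2])) {
          if (L[r, cc, s] != L[r, cc, s + 1]) {
            B <- exp(-(probs[[k]]$data[r, cc, s] -
                         probs[[k]]$data[r, cc, s + 1])^2 /
                       (2 * par$sigma2^2)) / sp[3]
            e <- e + par$lambda2 * B
          }
        }
    }
  }
  if (!is.null(corr)) {
    for (q in seq_len(nrow(corr))) {
      k1 <- corr[q, 1]; i1 <- corr[q, 2]; k2 <- corr[q, 3]; i2 <- corr[q, 4]
      if (labs[[k1]][i1] != labs[[k2]][i2]) {
        B <- exp(-(probs[[k1]]$data[i1] - probs[[k2]]$data[i2])^2 /
                   (2 * par$sigma3^2))
        e <- e + par$lambda3 * B
      }
    }
  }
  e
}

# textbook 2-level orthonormal 2D Haar transform of an 8x8 block by explicit
# averaging/differencing; returns the subband summaries in package order
oracle_haar_features <- function(blk) {
  one_level <- function(x) {
    h <- nrow(x) / 2
    ll <- lh <- hl <- hh <- matrix(0, h, h)
    for (r in seq_len(h)) for (c in seq_len(h)) {
      a <- x[2 * r - 1, 2 * c - 1]; b <- x[2 * r - 1, 2 * c]
      cc <- x[2 * r, 2 * c - 1]; d <- x[2 * r, 2 * c]
      ll[r, c] <- (a + b + cc + d) / 2
      hl[r, c] <- (a - b + cc - d) / 2
      lh[r, c] <- (a + b - cc - d) / 2
      hh[r, c] <- (a - b - cc + d) / 2
    }
    list(ll = ll, lh = lh, hl = hl, hh = hh)
  }
  l1 <- one_level(blk)
  l2 <- one_level(l1$ll)
  c(mean(abs(l1$lh)), mean(abs(l1$hl)), mean(abs(l1$hh)),
    mean(abs(l2$lh)), mean(abs(l2$hl)), mean(abs(l2$hh)), mean(l2$ll))
}

# GLCM statistics by hand: quantize to 8 levels over min..max, count pairs
# symmetrically for the four distance-1 offsets, average the four stats
oracle_glcm_features <- function(roi) {
  lo <- min(roi); hi <- max(roi)
  q <- if (hi > lo) pmin(floor((roi - lo) / (hi - lo) * 8), 7) else
    matrix(0, nrow(roi), ncol(roi))
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  stats <- matrix(0, 4, 4)
  for (o in seq_along(offs)) {
    P <- matrix(0, 8, 8)
    for (r in seq_len(nrow(q))) for (c in seq_len(ncol(q))) {
      r2 <- r + offs[[o]][1]; c2 <- c + offs[[o]][2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        a <- q[r, c] + 1; b <- q[r2, c2] + 1
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
    }
    P <- P / sum(P)
    lv <- 0:7
    con <- sum(outer(lv, lv, function(a, b) (a - b)^2) * P)
    en <- sum(P^2)
    hom <- sum(P / (1 + outer(lv, lv, function(a, b) (a - b)^2)))
    mu_r <- sum(rowSums(P) * lv); mu_c <- sum(colSums(P) * lv)
    v_r <- sum(rowSums(P) * (lv - mu_r)^2)
    v_c <- sum(colSums(P) * (lv - mu_c)^2)
    cr <- if (v_r > 1e-14 && v_c > 1e-14)
      sum(outer(lv - mu_r, lv - mu_c) * P) / sqrt(v_r * v_c) else 1
    stats[o, ] <- c(con, cr, en, hom)
  }
  colMeans(stats)
}

# small single-view phantom spec for fast pipeline tests
small_spec <- function(..., seed = 1L) {
  phantom_spec(grid_shape_per_view = list(c(48L, 48L, 10L)),
               spacing_per_view = list(c(1.2, 1.2, 3.0)),
               seed = seed, ...)
}

# a quick forest config for unit tests
quick_forest <- function(...) forest_config(n_trees = 5L, max_depth = 6L, ...)
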