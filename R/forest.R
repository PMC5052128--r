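#' Online random forest configuration
#'
#' Depth-limited binary decision trees with information-gain splits and leaf
#' posteriors equal to the averaged labels of the samples reaching the leaf.
#' Streaming updates use online bagging: each incoming sample is replicated
#' `k ~ Pois(lambda)` times independently per tree, so each tree sees each
#' sample `lambda` times in expectation. Defaults `n_trees = 20`,
#' `max_depth = 10`, `poisson_lambda = 1`.
#'
#' A leaf splits once it has accumulated at least `min_samples_split`
#' replicates of both classes and its depth is below `max_depth` (the root
#' has depth 0, so `max_depth = 1` admits a single split). Candidate splits
#' are `n_candidate_features` randomly drawn features (default
#' `ceiling(sqrt(F))`) times `n_candidate_thresholds` thresholds drawn
#' uniformly within the leaf's observed feature range; the pair maximizing
#' the information gain wins. The split trigger is an implementation choice:
#' classic random forests grow offline and leave the online trigger open.
#'
#' @param n_trees number of trees `N`.
#' @param max_depth maximum tree depth `D` (number of split levels).
#' @param poisson_lambda replication rate `lambda` of online bagging.
#' @param n_candidate_features features sampled per split; `NULL` means
#'   `ceiling(sqrt(F))`.
#' @param n_candidate_thresholds thresholds sampled per candidate feature.
#' @param min_samples_split replicates a leaf must buffer before splitting.
#' @param buffer_cap maximum replicates buffered per leaf for split search
#'   (bounds memory under streaming; counts keep accumulating beyond it).
#' @param seed master seed; per-tree RNG streams are derived from it, so
#'   results do not depend on the caller's RNG.
#' @return An object of class `scribseg_forest_config`.
#' @export
forest_config <- function(n_trees = 20L, max_depth = 10L, poisson_lambda = 1,
                          n_candidate_features = NULL,
                          n_candidate_thresholds = 10L,
                          min_samples_split = 20L, buffer_cap = 10000L,
                          seed = 1L) {
  if (n_trees < 1L) stop("n_trees must be >= 1")
  if (max_depth < 1L) stop("max_depth must be >= 1")
  if (poisson_lambda < 0) stop("poisson_lambda must be >= 0")
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 poisson_lambda = poisson_lambda,
                 n_candidate_features = n_candidate_features,
                 n_candidate_thresholds = as.integer(n_candidate_thresholds),
                 min_samples_split = as.integer(min_samples_split),
                 buffer_cap = as.integer(buffer_cap),
                 seed = as.integer(seed)),
            class = "scribseg_forest_config")
}

#' Initialize, update and query an online random forest
#'
#' `forest_init` creates `n_trees` single-leaf trees with empty counts;
#' `forest_update` streams a labeled batch through every tree with Poisson
#' replication; `forest_predict` averages the leaf posteriors across trees.
#' An untrained leaf (no sample seen) predicts 0.5.
#'
#' @param config a [forest_config()].
#' @param feature_names character vector fixing the feature arity and order
#'   for the forest's lifetime.
#' @return `forest_init` returns a `scribseg_forest`.
#' @export
forest_init <- function(config, feature_names) {
  stopifnot(inherits(config, "scribseg_forest_config"))
  if (length(feature_names) < 1L) stop("at least one feature required")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(config$seed)
  tree_seeds <- sample.int(.Machine$integer.max, config$n_trees)
  trees <- lapply(tree_seeds, function(s) {
    set.seed(s)
    new_tree(rng = get(".Random.seed", envir = globalenv()))
  })
  structure(list(config = config, feature_names = feature_names,
                 trees = trees),
            class = "scribseg_forest")
}

new_tree <- function(rng) {
  list(feature = NA_integer_, threshold = NA_real_,
       left = NA_integer_, right = NA_integer_, depth = 0L,
       pos = 0, tot = 0, buf_x = list(NULL), buf_y = list(NULL),
       rng = rng)
}

#' @export
print.scribseg_forest <- function(x, ...) {
  nn <- vapply(x$trees, function(t) length(t$feature), 1L)
  cat(sprintf("<scribseg_forest> %d trees, %d features, %d-%d nodes/tree, %.0f samples seen\n",
              length(x$trees), length(x$feature_names), min(nn), max(nn),
              x$trees[[1]]$tot[1]))
  invisible(x)
}

# route rows of x to leaf indices of a tree (vectorized, level by level)
route_to_leaves <- function(tree, x) {
  node <- rep(1L, nrow(x))
  repeat {
    f <- tree$feature[node]
    active <- !is.na(f)
    if (!any(active)) break
    ia <- which(active)
    goes_left <- x[cbind(ia, f[ia])] < tree$threshold[node[ia]]
    node[ia] <- ifelse(goes_left, tree$left[node[ia]], tree$right[node[ia]])
  }
  node
}

entropy2 <- function(npos, ntot) {
  p <- npos / ntot
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -(p[ok] * log(p[ok]) + (1 - p[ok]) * log(1 - p[ok]))
  h
}

# try to split leaf `node`; recurses into children. Mutates and returns tree.
try_split <- function(tree, node, cfg, nfeat) {
  x <- tree$buf_x[[node]]; y <- tree$buf_y[[node]]
  if (is.null(x) || nrow(x) < cfg$min_samples_split) return(tree)
  if (tree$depth[node] >= cfg$max_depth) return(tree)
  np <- sum(y); nt <- length(y)
  if (np == 0 || np == nt) return(tree)

  m <- cfg$n_candidate_features
  if (is.null(m)) m <- ceiling(sqrt(nfeat))
  feats <- sample.int(nfeat, min(m, nfeat))
  best <- list(gain = 0)
  h0 <- entropy2(np, nt)
  for (f in feats) {
    v <- x[, f]
    lo <- min(v); hi <- max(v)
    if (hi <= lo) next
    thr <- stats::runif(cfg$n_candidate_thresholds, lo, hi)
    for (t in thr) {
      lmask <- v < t
      nl <- sum(lmask)
      if (nl == 0L || nl == nt) next
      npl <- sum(y[lmask])
      gain <- h0 - (nl * entropy2(npl, nl) +
                      (nt - nl) * entropy2(np - npl, nt - nl)) / nt
      if (gain > best$gain)
        best <- list(gain = gain, f = f, t = t, lmask = lmask)
    }
  }
  if (best$gain <= 0) return(tree)

  n_old <- length(tree$feature)
  li <- n_old + 1L; ri <- n_old + 2L
  grow <- function(v, fill) c(v, fill, fill)
  tree$feature <- grow(tree$feature, NA_integer_)
  tree$threshold <- grow(tree$threshold, NA_real_)
  tree$left <- grow(tree$left, NA_integer_)
  tree$right <- grow(tree$right, NA_integer_)
  tree$depth <- grow(tree$depth, tree$depth[node] + 1L)
  tree$pos <- grow(tree$pos, 0); tree$tot <- grow(tree$tot, 0)
  tree$buf_x <- c(tree$buf_x, list(NULL), list(NULL))
  tree$buf_y <- c(tree$buf_y, list(NULL), list(NULL))

  tree$feature[node] <- best$f
  tree$threshold[node] <- best$t
  tree$left[node] <- li; tree$right[node] <- ri
  for (side in c("l", "r")) {
    idx <- if (side == "l") li else ri
    mask <- if (side == "l") best$lmask else !best$lmask
    tree$pos[idx] <- sum(y[mask]); tree$tot[idx] <- sum(mask)
    if (tree$depth[idx] < cfg$max_depth) {
      tree$buf_x[[idx]] <- x[mask, , drop = FALSE]
      tree$buf_y[[idx]] <- y[mask]
    }
  }
  tree$buf_x[node] <- list(NULL); tree$buf_y[node] <- list(NULL)
  tree <- try_split(tree, li, cfg, nfeat)
  try_split(tree, ri, cfg, nfeat)
}

#' @param forest a `scribseg_forest`.
#' @param x numeric matrix (`n x n_features`) or a list from
#'   [extract_features()].
#' @param y binary 0/1 label vector.
#' @return `forest_update` returns the updated forest.
#' @rdname forest_init
#' @export
forest_update <- function(forest, x, y) {
  x <- as_feature_matrix(x, forest)
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("labels must match rows of x")
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
  if (nrow(x) == 0L) return(forest)
  cfg <- forest$config
  nfeat <- length(forest$feature_names)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)

  forest$trees <- lapply(forest$trees, function(tree) {
    assign(".Random.seed", tree$rng, envir = globalenv())
    k <- stats::rpois(nrow(x), cfg$poisson_lambda)
    if (sum(k) > 0L) {
      rows <- rep.int(seq_len(nrow(x)), k)
      xr <- x[rows, , drop = FALSE]
      yr <- y[rows]
      leaf <- route_to_leaves(tree, xr)
      tp <- tapply(yr, leaf, sum)
      tn <- tapply(rep(1, length(leaf)), leaf, sum)
      ids <- as.integer(names(tn))
      tree$pos[ids] <- tree$pos[ids] + as.numeric(tp)
      tree$tot[ids] <- tree$tot[ids] + as.numeric(tn)
      for (id in ids) {
        if (tree$depth[id] >= cfg$max_depth) next
        have <- if (is.null(tree$buf_y[[id]])) 0L else length(tree$buf_y[[id]])
        if (have >= cfg$buffer_cap) next
        sel <- which(leaf == id)
        if (length(sel) + have > cfg$buffer_cap)
          sel <- sel[seq_len(cfg$buffer_cap - have)]
        tree$buf_x[[id]] <- rbind(tree$buf_x[[id]], xr[sel, , drop = FALSE])
        tree$buf_y[[id]] <- c(tree$buf_y[[id]], yr[sel])
      }
      for (id in ids) tree <- try_split(tree, id, cfg, nfeat)
    }
    tree$rng <- get(".Random.seed", envir = globalenv())
    tree
  })
  forest
}

#' @return `forest_predict` returns a vector of foreground posteriors in
#'   `[0, 1]`.
#' @rdname forest_init
#' @export
forest_predict <- function(forest, x) {
  x <- as_feature_matrix(x, forest)
  if (nrow(x) == 0L) return(numeric(0))
  p <- numeric(nrow(x))
  for (tree in forest$trees) {
    leaf <- route_to_leaves(tree, x)
    tot <- tree$tot[leaf]
    pt <- ifelse(tot > 0, tree$pos[leaf] / tot, 0.5)
    p <- p + pt
  }
  p / length(forest$trees)
}

as_feature_matrix <- function(x, forest) {
  if (is.list(x) && !is.null(x$values)) x <- x$values
  x <- as.matrix(x)
  if (ncol(x) != length(forest$feature_names))
    stop("feature arity mismatch: forest expects ",
         length(forest$feature_names), " features, got ", ncol(x))
  x
}

#' Save / load a forest as JSON
#'
#' Serializes tree topology, thresholds, counts and feature names (split
#' buffers and RNG streams are dropped: a reloaded forest predicts
#' identically but no longer learns).
#'
#' @param forest a `scribseg_forest`.
#' @param path output `.json` path.
#' @export
forest_save <- function(forest, path) {
  trees <- lapply(forest$trees, function(t)
    list(feature = t$feature, threshold = t$threshold, left = t$left,
         right = t$right, depth = t$depth, pos = t$pos, tot = t$tot))
  jsonlite::write_json(list(config = unclass(forest$config)[
    c("n_trees", "max_depth", "poisson_lambda")],
    feature_names = forest$feature_names, trees = trees),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname forest_save
#' @export
forest_load <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- forest_config(n_trees = x$config$n_trees,
                       max_depth = x$config$max_depth,
                       poisson_lambda = x$config$poisson_lambda)
  trees <- lapply(seq_len(nrow(x$trees)), function(i) {
    t <- lapply(x$trees[i, ], function(col) col[[1]])
    n <- length(t$feature)
    list(feature = as.integer(t$feature), threshold = as.numeric(t$threshold),
         left = as.integer(t$left), right = as.integer(t$right),
         depth = as.integer(t$depth), pos = as.numeric(t$pos),
         tot = as.numeric(t$tot),
         buf_x = rep(list(NULL), n), buf_y = rep(list(NULL), n),
         rng = NULL)
  })
  structure(list(config = cfg, feature_names = x$feature_names,
                 trees = trees), class = "scribseg_forest")
}
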