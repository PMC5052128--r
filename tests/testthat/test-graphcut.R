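# a plain correspondence matrix (volume, linear-index pairs)
corr_matrix <- function(k1, i1, k2, i2) {
  structure(cbind(k1 = k1, i1 = i1, k2 = k2, i2 = i2),
            class = "scribseg_correspondences")
}

test_that("with lambda1 = 0 the CRF thresholds the posterior", {
  set.seed(1)
  pm <- matrix(runif(64, 0.05, 0.95), 8, 8)
  img <- matrix(rnorm(64), 8, 8)
  lab <- crf_segment_slice(pm, img, c(1, 1), crf_params(lambda1 = 0))
  expect_equal(unclass(lab), matrix(as.integer(pm > 0.5), 8, 8),
               ignore_attr = TRUE)
})

test_that("a dominant posterior floods the slice", {
  lab <- crf_segment_slice(matrix(0.9, 6, 6), matrix(5, 6, 6), c(1, 1))
  expect_true(all(lab == 1L))
})

test_that("slice CRF reaches the exhaustive-enumeration optimum", {
  set.seed(2)
  L <- all_labelings(9)
  for (rep in 1:20) {
    pm <- matrix(runif(9, 0.02, 0.98), 3, 3)
    img <- matrix(rnorm(9, 10, 3), 3, 3)
    par <- crf_params(lambda1 = runif(1, 0, 20), sigma1 = 2.5)
    lab <- crf_segment_slice(pm, img, c(0.8, 1.1), par)
    e_got <- oracle_crf_energy(lab, pm, img, c(0.8, 1.1),
                               par$lambda1, par$sigma1)
    e_all <- apply(L, 1, function(l)
      oracle_crf_energy(matrix(l, 3, 3), pm, img, c(0.8, 1.1),
                        par$lambda1, par$sigma1))
    expect_equal(e_got, min(e_all), tolerance = 1e-10)
  }
})

test_that("the compiled cut agrees with an independent max-flow library", {
  skip_if_not_installed("igraph")
  set.seed(3)
  for (rep in 1:5) {
    nr <- 8; nc <- 8
    pm <- matrix(runif(nr * nc, 0.02, 0.98), nr, nc)
    img <- matrix(rnorm(nr * nc, 10, 2), nr, nc)
    par <- crf_params()
    lab <- crf_segment_slice(pm, img, c(1, 1), par)
    # rebuild the identical flow network with igraph and cut it there
    n <- nr * nc
    eps <- 1e-6
    p <- pmin(pmax(as.numeric(pm), eps), 1 - eps)
    u0 <- -log(1 - p); u1 <- -log(p)
    pr <- oracle_slice_pairs(nr, nc, c(1, 1))
    ei <- pr[, 1] + (pr[, 2] - 1) * nr; ej <- pr[, 3] + (pr[, 4] - 1) * nr
    w <- par$lambda1 *
      exp(-(img[ei] - img[ej])^2 / (2 * par$sigma1^2)) / pr[, 5]
    edges <- c(rbind(n + 1L, 1:n), rbind(1:n, n + 2L), rbind(ei, ej))
    g <- igraph::make_graph(edges, n = n + 2L, directed = FALSE)
    mf <- igraph::max_flow(g, n + 1L, n + 2L, capacity = c(u0, u1, w))
    lab2 <- integer(n)
    side <- as.integer(mf$partition1)
    lab2[side[side <= n]] <- 1L
    en <- function(l) sum(ifelse(l == 1, u1, u0)) + sum(w[l[ei] != l[ej]])
    expect_equal(en(as.integer(lab)), en(lab2), tolerance = 1e-9)
    expect_equal(en(as.integer(lab)), mf$value, tolerance = 1e-9)
  }
})

test_that("hard constraints always carry their mandated label", {
  set.seed(4)
  pm <- matrix(runif(100, 0.3, 0.7), 10, 10)
  img <- matrix(rnorm(100), 10, 10)
  fg <- cbind(c(2L, 3L), c(2L, 8L)); bg <- cbind(c(8L, 9L), c(2L, 8L))
  lab <- crf_segment_slice(pm, img, c(1, 1), crf_params(), fg, bg)
  expect_true(all(lab[fg] == 1L))
  expect_true(all(lab[bg] == 0L))
  expect_error(crf_segment_slice(pm, img, c(1, 1), crf_params(), fg, fg),
               "overlap")
})

test_that("swapping probabilities and hard sets complements the labeling", {
  set.seed(5)
  pm <- matrix(runif(64, 0.1, 0.9), 8, 8)
  img <- matrix(rnorm(64, 0, 2), 8, 8)
  fg <- cbind(2L, 2L); bg <- cbind(7L, 7L)
  a <- crf_segment_slice(pm, img, c(1, 1), crf_params(lambda1 = 5), fg, bg)
  b <- crf_segment_slice(1 - pm, img, c(1, 1), crf_params(lambda1 = 5),
                         hard_fg = bg, hard_bg = fg)
  expect_equal(unclass(a), 1L - unclass(b), ignore_attr = TRUE)
})

test_that("coincident grids pair voxel-for-voxel", {
  mk <- function() new_volume(array(0, c(3, 3, 2)), c(1, 1, 2))
  idt <- list(rotation = diag(3), translation = c(0, 0, 0))
  corr <- build_correspondences(list(mk(), mk()), list(idt, idt))
  expect_equal(nrow(corr), 18L)
  expect_true(all(corr[, "i1"] == corr[, "i2"]))
  expect_true(all(corr[, "k1"] == 1L & corr[, "k2"] == 2L))
})

test_that("sub-pitch shifts round to the same-index neighbor", {
  mk <- function() new_volume(array(0, c(4, 4, 2)), c(1, 1, 2))
  idt <- list(rotation = diag(3), translation = c(0, 0, 0))
  shifted <- list(rotation = diag(3), translation = c(0.4, 0, 0))
  corr <- build_correspondences(list(mk(), mk()), list(idt, shifted))
  expect_true(all(corr[, "i1"] == corr[, "i2"]))
  # counting bound: each voxel contributes at most one new pair
  expect_lte(nrow(corr), 2L * 32L)
  expect_error(build_correspondences(list(mk()), list(idt)), "2 volumes")
})

test_that("with lambda2 = lambda3 = 0 refinement decouples into slice CRFs", {
  set.seed(6)
  g <- c(6, 6, 3)
  vol <- new_volume(array(rnorm(prod(g), 10, 2), g), c(1, 1, 3))
  pv <- new_volume(array(runif(prod(g), 0.05, 0.95), g), c(1, 1, 3))
  par <- coseg_params(lambda2 = 1e-12, lambda3 = 1e-12)
  # exactly zero couplings are dropped from the graph; use the same params
  par$lambda2 <- 0; par$lambda3 <- 0
  ref <- coseg_refine(list(vol), list(pv), params = par)
  for (k in seq_len(g[3])) {
    sl <- crf_segment_slice(pv$data[, , k], vol$data[, , k], c(1, 1),
                            crf_params(par$lambda1, par$sigma1))
    expect_equal(ref[[1]]$data[, , k], unclass(sl), ignore_attr = TRUE)
  }
})

test_that("joint 4D refinement reaches the exhaustive optimum", {
  set.seed(7)
  g <- c(2, 2, 2)  # 8 voxels per volume, 16 joint
  L <- all_labelings(16)
  for (rep in 1:8) {
    vols <- lapply(1:2, function(k)
      new_volume(array(rnorm(8, 10, 2), g), c(1, 1, 2)))
    probs <- lapply(1:2, function(k)
      new_volume(array(runif(8, 0.05, 0.95), g), c(1, 1, 2)))
    corr <- corr_matrix(rep(1L, 8), 1:8, rep(2L, 8), 1:8)
    par <- coseg_params(lambda1 = runif(1, 0, 10), lambda2 = runif(1, 0, 5),
                        lambda3 = runif(1, 0, 3),
                        sigma2 = 0.1, sigma3 = 0.2)
    ref <- coseg_refine(vols, probs, correspondences = corr, params = par)
    labs <- list(ref[[1]]$data, ref[[2]]$data)
    e_got <- oracle_coseg_energy(labs, probs, vols, corr, par)
    e_all <- apply(L, 1, function(l)
      oracle_coseg_energy(list(array(l[1:8], g), array(l[9:16], g)),
                          probs, vols, corr, par))
    expect_equal(e_got, min(e_all), tolerance = 1e-9)
  }
})

test_that("refinement energy never exceeds trivial labelings", {
  set.seed(8)
  g <- c(5, 5, 3)
  vol <- new_volume(array(rnorm(prod(g), 10, 2), g), c(1, 1, 3))
  pv <- new_volume(array(runif(prod(g)), g), c(1, 1, 3))
  init <- new_label_volume(array(rbinom(prod(g), 1, 0.5), g), c(1, 1, 3))
  ref <- coseg_refine(list(vol), list(pv), init_labels = list(init))
  e <- attr(ref, "energy")
  expect_lte(e, attr(ref, "energy_initial"))
  for (const in c(0L, 1L)) {
    cl <- list(new_label_volume(array(const, g), c(1, 1, 3)))
    e_const <- attr(coseg_refine(list(vol), list(pv), init_labels = cl),
                    "energy_initial")
    expect_lte(e, e_const)
  }
})
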