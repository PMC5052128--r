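test_that("identical seeds give bit-identical studies", {
  s1 <- generate_study(small_spec(seed = 11L), 1)
  s2 <- generate_study(small_spec(seed = 11L), 1)
  expect_identical(s1$volumes[[1]]$data, s2$volumes[[1]]$data)
  expect_identical(s1$truths[[1]]$data, s2$truths[[1]]$data)
  expect_identical(s1$applied_slice_shifts, s2$applied_slice_shifts)
  s3 <- generate_study(small_spec(seed = 12L), 1)
  expect_false(identical(s1$volumes[[1]]$data, s3$volumes[[1]]$data))
})

test_that("noiseless phantom is exactly separable at the midpoint threshold", {
  spec <- small_spec(noise_sd = 0, slice_gain_sd = 0, motion_shift_sd = 0,
                     texture_amplitude = 0, object_kind = "ellipsoid")
  st <- generate_study(spec, 1)
  mid <- (spec$fg_intensity_mean + spec$bg_intensity_mean) / 2
  expect_identical(array(as.integer(st$volumes[[1]]$data > mid),
                         dim(st$volumes[[1]]$data)),
                   st$truths[[1]]$data)
})

test_that("applied slice shifts match the requested motion scale", {
  # pool >= 200 slices over views and compare the sample sd of the recorded
  # shifts with the nominal 2 mm
  spec <- phantom_spec(grid_shape_per_view = list(c(16L, 16L, 50L)),
                       spacing_per_view = list(c(1, 1, 3)),
                       motion_shift_sd = 2, seed = 5L)
  st <- generate_study(spec, 4)   # 200 slices
  shifts <- unlist(st$applied_slice_shifts)
  expect_gt(length(shifts), 200)
  expect_lt(abs(sd(shifts) - 2) / 2, 0.15)
})

test_that("per-slice gain is constant within a slice", {
  spec <- small_spec(noise_sd = 0, texture_amplitude = 0,
                     slice_gain_sd = 0.1, motion_shift_sd = 0)
  st <- generate_study(spec, 1)
  v <- st$volumes[[1]]$data; tr <- st$truths[[1]]$data
  for (k in seq_len(dim(v)[3])) {
    bgvals <- unique(v[, , k][tr[, , k] == 0])
    expect_lte(length(bgvals), 1L)
  }
})

test_that("ground-truth masks are connected per slice", {
  for (kind in c("crescent", "ellipsoid")) {
    st <- generate_study(phantom_spec(object_kind = kind, seed = 2L), 2)
    for (v in 1:2) {
      tr <- st$truths[[v]]$data
      for (k in seq_len(dim(tr)[3])) {
        if (!any(tr[, , k] == 1L)) next
        ncomp <- max(EBImage::bwlabel(tr[, , k]))
        expect_equal(ncomp, 1L)
      }
    }
  }
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec(grid_shape_per_view = list(c(48L, 48L, 10L)),
                            spacing_per_view = list(c(1, 1, 0.9))),
               "slice spacing")
  expect_error(phantom_spec(grid_shape_per_view = list(c(4L, 48L, 10L)),
                            spacing_per_view = list(c(1, 1, 3))),
               ">= 8")
  expect_error(phantom_spec(noise_sd = -1), ">= 0")
  expect_error(generate_study(small_spec(), 0), "n_views")
})

test_that("auto scribbles stay inside the correct class and measure up", {
  spec <- phantom_spec(seed = 3L)   # 0.7422 mm in-plane pitch on view 1
  st <- generate_study(spec, 1)
  tru <- st$truths[[1]]
  k <- middle_object_slice(tru)

  scr <- auto_scribbles(tru, k, fg_len_mm = 100, bg_len_mm = 80, seed = 9L)
  expect_true(all(tru$data[cbind(scr$fg, k)] == 1L))
  expect_true(all(tru$data[cbind(scr$bg, k)] == 0L))

  # cumulative polyline length computed independently
  seglen <- function(m, sp) {
    tot <- 0
    for (i in seq_len(nrow(m) - 1))
      tot <- tot + sqrt(sum(((m[i + 1, ] - m[i, ]) * sp)^2))
    tot
  }
  len <- seglen(scr$fg, tru$spacing[1:2])
  expect_lt(abs(len - 100), sqrt(2) * 0.7422)  # one (diagonal) step

  empty <- auto_scribbles(tru, k, 0, 0)
  expect_equal(nrow(empty$fg), 0L)
  expect_equal(nrow(empty$bg), 0L)

  # the first slice lies beyond the object: no foreground class there
  expect_true(all(tru$data[, , 1] == 0L))
  expect_error(auto_scribbles(tru, 1L, 10, 10), "lacks")
})

test_that("scribble prefixes follow recorded point order", {
  st <- generate_study(phantom_spec(seed = 4L), 1)
  tru <- st$truths[[1]]
  k <- middle_object_slice(tru)
  scr <- auto_scribbles(tru, k, 120, 120, seed = 2L)
  pre <- scribble_prefix(scr, 60, 30, tru$spacing[1:2])
  expect_true(nrow(pre$fg) < nrow(scr$fg))
  expect_identical(pre$fg, scr$fg[seq_len(nrow(pre$fg)), ])
  expect_identical(pre$bg, scr$bg[seq_len(nrow(pre$bg)), ])
})
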