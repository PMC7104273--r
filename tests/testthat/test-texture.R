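test_that("feature inventory is 41 names split 12/5/11/4/9", {
  nm <- dect_feature_names()
  expect_length(nm, 41)
  expect_equal(unname(attr(nm, "families")), c(12, 5, 11, 4, 9))
  expect_false(anyDuplicated(nm) > 0)
  expect_true(all(grepl("^(histogram|glcm|glrl|glgm|laws)\\.", nm)))
})

test_that("quantization is monotone, order-preserving and identity on a matched ramp", {
  expect_equal(unique(as.vector(quantize(matrix(7.3, 3, 3), 64))), 0L)
  two <- quantize(c(10, 50), n_levels = 2)
  expect_equal(two, c(0L, 1L))
  ramp <- 0:63
  expect_equal(quantize(ramp, n_levels = 64), as.integer(ramp))
  x <- runif(50, -100, 100)
  q <- quantize(x, n_levels = 16)
  expect_true(all(diff(q[order(x)]) >= 0))
  expect_true(all(q >= 0 & q <= 15))
  expect_error(quantize(numeric(0)), "ROI error")
})

test_that("histogram features match hand arithmetic and symmetry", {
  f <- histogram_features(rep(1071.9, 20))
  expect_equal(unname(f["mean"]), 1071.9)
  expect_equal(unname(f["median"]), 1071.9)
  expect_equal(unname(f["sd"]), 0)
  expect_equal(unname(f["energy"]), 1)
  expect_equal(unname(f["entropy"]), 0)
  g <- histogram_features(c(1, 2, 3, 4))
  expect_equal(unname(g["mean"]), 2.5)
  expect_equal(unname(g["median"]), 2.5)
  expect_equal(unname(g["range"]), 3)
  expect_equal(unname(g["min"]), 1)
  expect_equal(unname(g["max"]), 4)
  expect_equal(unname(histogram_features(c(-1, 0, 1))["skewness"]), 0)
  expect_error(histogram_features(numeric(0)), "ROI error")
})

test_that("GLCM matches closed forms on constant and checkerboard images", {
  f <- glcm_features(matrix(5L, 6, 6), n_levels = 8)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["energy"]), 1)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["homogeneity"]), 1)
  expect_equal(unname(f["correlation"]), 0)

  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2L)
  h <- glcm_features(cb, n_levels = 2, angles = 0)
  expect_equal(unname(h["contrast"]), 1)   # every horizontal pair differs by 1
  expect_equal(unname(h["energy"]), 0.5)   # p(0,1) = p(1,0) = 1/2
  expect_error(glcm_features(matrix(NA_integer_, 3, 3)), "ROI error")
})

test_that("GLRL matches closed forms on constant images and strips", {
  n <- 5
  f <- glrl_features(matrix(2L, n, n), n_levels = 4, directions = 0)
  expect_equal(unname(f["SRE"]), 1 / n^2)
  expect_equal(unname(f["LRE"]), n^2)
  expect_equal(unname(f["RP"]), 1 / n)
  strip <- matrix(c(0L, 0L, 1L, 1L), 1, 4)
  g <- glrl_features(strip, n_levels = 2, directions = 0)
  expect_equal(unname(g["RP"]), 0.5)
  expect_equal(unname(g["SRE"]), 0.25)
})

test_that("GLGM matches linear-field closed forms", {
  m <- matrix(TRUE, 5, 5)
  cst <- glgm_features(matrix(4, 5, 5), m)
  expect_equal(unname(cst["MGR"]), 0)
  expect_equal(unname(cst["VGR"]), 0)
  plane <- matrix(rep(3 * (1:5), each = 5), 5, 5)  # I = 3 * column index
  f <- glgm_features(plane, m)
  expect_equal(unname(f["MGR"]), 3)
  expect_equal(unname(f["VGR"]), 0)
  # spacing scales the gradient
  f2 <- glgm_features(plane, m, spacing = c(1, 2))
  expect_equal(unname(f2["MGR"]), 1.5)
  expect_error(glgm_features(matrix(1, 2, 2), matrix(TRUE, 2, 2)), "ROI error")
})

test_that("Laws responses vanish on constant ROIs and orient with step edges", {
  m <- matrix(TRUE, 5, 5)
  f <- laws_features(matrix(9, 5, 5), m)
  expect_equal(unname(f), rep(0, 9))
  # step along the column (x) axis: edge-along-x kernels must dominate
  step <- matrix(rep(c(0, 0, 0, 100, 100), each = 3), 3, 5)
  g <- laws_features(step, matrix(TRUE, 3, 5))
  expect_gt(g[["E3L3"]], g[["L3E3"]])
  expect_error(laws_features(matrix(1, 2, 2), matrix(TRUE, 2, 2)), "ROI error")
})

test_that("all four spatial families agree with brute-force oracles", {
  set.seed(41)
  for (rep in 1:25) {
    nr <- sample(3:6, 1); nc <- sample(3:6, 1)
    n_levels <- sample(2:4, 1)
    im <- random_level_image(nr, nc, n_levels, p_mask = 0.9)
    ref_glcm <- oracle_glcm(im$levels, n_levels)
    if (!is.null(ref_glcm))
      expect_equal(glcm_features(im$levels, n_levels = n_levels), ref_glcm,
                   tolerance = 1e-12)
    expect_equal(glrl_features(im$levels, n_levels = n_levels),
                 oracle_glrl(im$levels, n_levels), tolerance = 1e-12)
    x <- matrix(rnorm(nr * nc, 1000, 50), nr, nc)
    ref_glgm <- oracle_glgm(x, im$mask)
    if (!is.null(ref_glgm))
      expect_equal(glgm_features(x, im$mask), ref_glgm, tolerance = 1e-12)
    ref_laws <- oracle_laws(x, im$mask)
    if (!is.null(ref_laws))
      expect_equal(laws_features(x, im$mask), ref_laws, tolerance = 1e-12)
  }
})

toy_stack <- function(vol, mask3, spacing = c(1, 1, 3)) {
  list(stack = vmi_stack(list(`40` = vol), spacing = spacing),
       mask = roi_mask(mask3, "toy"))
}

test_that("nodule features aggregate slices by the unweighted mean", {
  set.seed(13)
  sl1 <- matrix(rnorm(64, 1000, 30), 8, 8)
  sl2 <- matrix(rnorm(64, 1050, 10), 8, 8)
  m <- matrix(TRUE, 8, 8)

  one <- toy_stack(array(sl1, c(8, 8, 1)), array(m, c(8, 8, 1)))
  fv1 <- nodule_features(one$stack, one$mask, 40)
  expect_length(fv1, 41)
  expect_equal(attr(fv1, "n_slices"), 1)

  dup <- toy_stack(array(c(sl1, sl1), c(8, 8, 2)), array(m, c(8, 8, 2)))
  fvd <- nodule_features(dup$stack, dup$mask, 40)
  expect_equal(as.numeric(fvd), as.numeric(fv1))
  expect_equal(attr(fvd, "n_slices"), 2)

  two <- toy_stack(array(c(sl1, sl2), c(8, 8, 2)), array(m, c(8, 8, 2)))
  fv2 <- nodule_features(two$stack, two$mask, 40)
  onlytwo <- toy_stack(array(sl2, c(8, 8, 1)), array(m, c(8, 8, 1)))
  fv2b <- nodule_features(onlytwo$stack, onlytwo$mask, 40)
  expect_equal(as.numeric(fv2), (as.numeric(fv1) + as.numeric(fv2b)) / 2)

  expect_error(nodule_features(one$stack, one$mask, 60), "not present")
  tiny <- array(FALSE, c(8, 8, 1)); tiny[1:2, 1, 1] <- TRUE
  expect_error(nodule_features(one$stack, roi_mask(tiny), 40), "usable slice")
})

test_that("features are invariant to joint translation and respond to gray shift", {
  set.seed(99)
  base <- matrix(rnorm(36, 1000, 40), 6, 6)
  mask <- matrix(FALSE, 6, 6); mask[2:5, 2:5] <- TRUE
  pad <- function(m, fill) {
    out <- matrix(fill, 10, 10)
    out[3:8, 3:8] <- m
    out
  }
  v1 <- array(pad(base, 0), c(10, 10, 1))
  m1 <- array(pad(mask, FALSE), c(10, 10, 1))
  v2 <- array(0, c(10, 10, 1)); m2 <- array(FALSE, c(10, 10, 1))
  v2[2:7, 4:9, 1] <- base; m2[2:7, 4:9, 1] <- mask  # shifted by (-1, +1)
  f1 <- nodule_features(vmi_stack(list(`40` = v1)), roi_mask(m1), 40, min_voxels = 4)
  f2 <- nodule_features(vmi_stack(list(`40` = v2)), roi_mask(m2), 40, min_voxels = 4)
  expect_equal(as.numeric(f1), as.numeric(f2))

  # +c HU shifts histogram mean/median by c and leaves the rest unchanged
  v3 <- v1 + 100
  f3 <- nodule_features(vmi_stack(list(`40` = v3)), roi_mask(m1), 40, min_voxels = 4)
  expect_equal(f3[["histogram.mean"]], f1[["histogram.mean"]] + 100)
  expect_equal(f3[["histogram.median"]], f1[["histogram.median"]] + 100)
  expect_equal(f3[["histogram.min"]], f1[["histogram.min"]] + 100)
  expect_equal(f3[["histogram.max"]], f1[["histogram.max"]] + 100)
  unchanged <- setdiff(names(f1), paste0("histogram.",
                                         c("mean", "median", "min", "max")))
  expect_equal(as.numeric(f3[unchanged]), as.numeric(f1[unchanged]))
})

test_that("larger texture amplitude raises GLCM contrast and GLGM mean gradient", {
  # contrast is judged on a fixed intensity window: per-ROI min-max
  # quantization deliberately removes the amplitude scale (see the
  # gray-shift invariance test), so the heterogeneity response is only
  # visible against a fixed window
  wins_contrast <- 0; wins_mgr <- 0
  for (s in 1:20) {
    lo <- gaussian_random_field(c(32, 32), 2, 10, seed = s)
    hi <- gaussian_random_field(c(32, 32), 2, 30, seed = s)
    m <- matrix(TRUE, 32, 32)
    q <- function(f) quantize(f, 16, range = c(-120, 120))
    wins_contrast <- wins_contrast +
      (glcm_features(q(hi), n_levels = 16)[["contrast"]] >
       glcm_features(q(lo), n_levels = 16)[["contrast"]])
    wins_mgr <- wins_mgr +
      (glgm_features(hi, m)[["MGR"]] > glgm_features(lo, m)[["MGR"]])
  }
  expect_gte(wins_contrast, 19)
  expect_equal(wins_mgr, 20)  # MGR is linear in amplitude: always larger
})

test_that("extract_features yields one row per nodule and energy with 41 columns", {
  cohort <- generate_cohort(tiny_phantom_config(n_benign = 2, n_malignant = 2,
                                                rng_seed = 21))
  wide <- extract_features(cohort, energies = c(40, 80))
  expect_equal(nrow(wide), 8)
  expect_true(all(dect_feature_names() %in% names(wide)))
  expect_true(all(is.finite(as.matrix(wide[, dect_feature_names()]))))
  long <- features_long(wide)
  expect_equal(nrow(long), 8 * 41)
  expect_setequal(unique(long$feature), dect_feature_names())
})
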