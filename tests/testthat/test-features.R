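test_that("resampling is the identity on an already-isotropic grid and preserves constants", {
  cfg <- extraction_config(target_spacing_mm = 2)
  vol <- array(runif(4^3), dim = c(4, 4, 4))
  msk <- array(1L, dim = c(4, 4, 4))
  rs <- resample_voi(vol, msk, c(2, 2, 2), cfg)
  expect_identical(rs$volume, vol)
  cvol <- array(7, dim = c(4, 4, 4))
  rs2 <- resample_voi(cvol, msk, c(1, 1, 1), cfg)
  expect_true(all(abs(rs2$volume - 7) < 1e-12))
})

test_that("trilinear downsampling matches the direct interpolation formula", {
  # 4x4x4 ramp along x at 1 mm, downsampled to 2 mm
  vol <- array(rep(1:4, 16), dim = c(4, 4, 4))  # value = x index
  msk <- array(1L, dim = c(4, 4, 4))
  rs <- resample_voi(vol, msk, 1, extraction_config(target_spacing_mm = 2))
  # target centres at 1 mm, 3 mm -> continuous input indices 1.5, 3.5;
  # linear ramp f(x) = x  =>  expected values 1.5 and 3.5 everywhere
  expect_equal(dim(rs$volume), c(2, 2, 2))
  expect_equal(as.numeric(rs$volume[1, , ]), rep(1.5, 4), tolerance = 1e-12)
  expect_equal(as.numeric(rs$volume[2, , ]), rep(3.5, 4), tolerance = 1e-12)
})

test_that("discretization follows the binning formula and its edge cases", {
  cfg4 <- extraction_config(n_bins = 4)
  vol <- array(c(0, 1, 2, 3), dim = c(4, 1, 1))
  msk <- array(1L, dim = c(4, 1, 1))
  voi <- discretize_voi(vol, msk, 1, cfg4)
  expect_equal(as.integer(voi$levels), 1:4)
  # constant VOI -> all level 1
  voiC <- discretize_voi(array(5, dim = c(3, 1, 1)),
                         array(1L, dim = c(3, 1, 1)), 1, cfg4)
  expect_true(all(voiC$levels == 1L))
  # absolute bounds (0, 20), values {0, 5, 10} -> levels {1, 2, 3}
  cfgA <- extraction_config(n_bins = 4,
                            discretization_mode = "ABSOLUTE_BOUNDS",
                            absolute_bounds = c(0, 20))
  voiA <- discretize_voi(array(c(0, 5, 10), dim = c(3, 1, 1)),
                         array(1L, dim = c(3, 1, 1)), 1, cfgA)
  expect_equal(as.integer(voiA$levels), c(1L, 2L, 3L))
})

test_that("discretization is monotone in voxel intensity", {
  set.seed(42)
  for (rep in 1:20) {
    x <- runif(30, 0, 10)
    vol <- array(x, dim = c(30, 1, 1))
    msk <- array(1L, dim = c(30, 1, 1))
    voi <- discretize_voi(vol, msk, 1, extraction_config(n_bins = 8))
    lev <- as.integer(voi$levels)
    expect_true(all(diff(lev[order(x)]) >= 0))
  }
})

test_that("first-order features match direct summation", {
  x <- c(1, 2, 3, 4, 10)
  voi <- toy_voi(array(x, dim = c(5, 1, 1)), n_bins = 10)
  fo <- first_order_features(voi)
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  expect_equal(unname(fo["SUV_mean"]), m)
  expect_equal(unname(fo["SUV_std"]), s)
  expect_equal(unname(fo["Skewness"]), mean((x - m)^3) / s^3)
  expect_equal(unname(fo["Kurtosis"]), mean((x - m)^4) / s^4)
})

test_that("first-order entropy and uniformity on two equal bins", {
  voi <- toy_voi(array(c(1, 1, 2, 2), dim = c(4, 1, 1)), n_bins = 2)
  fo <- first_order_features(voi)
  expect_equal(unname(fo["Entropy"]), 1)
  expect_equal(unname(fo["Uniformity"]), 0.5)
})

test_that("constant VOI first-order conventions", {
  voi <- toy_voi(array(4, dim = c(2, 2, 2)), n_bins = 16)
  fo <- first_order_features(voi)
  expect_equal(unname(fo[c("SUV_min", "SUV_mean", "SUV_max")]), rep(4, 3))
  expect_equal(unname(fo[c("SUV_std", "Skewness", "Kurtosis", "Entropy")]),
               rep(0, 4))
  expect_equal(unname(fo[c("Energy", "Uniformity")]), c(1, 1))
  expect_true(attr(fo, "degenerate"))
})

test_that("shape features: cube closed form and digitized ball", {
  m <- array(0L, c(14, 14, 14)); m[3:12, 3:12, 3:12] <- 1L
  sf <- shape_features(m, 1)
  expect_equal(unname(sf["Volume_mL"]), 1.0)
  # closed-form sphericity with the exact cube surface (600 mm^2)
  expect_equal(unname(sf["Sphericity"]),
               pi^(1 / 3) * (6 * 1000)^(2 / 3) / 600, tolerance = 0.05)
  b <- ball_mask(10)
  expect_gte(unname(shape_features(b, 1)["Sphericity"]), 0.95)
  s1 <- array(0L, c(5, 5, 5)); s1[3, 3, 3] <- 1L
  sf1 <- shape_features(s1, 1)  # single voxel: area from its 6 faces
  expect_equal(unname(sf1["Sphericity"]),
               pi^(1 / 3) * 6^(2 / 3) / 6, tolerance = 1e-12)
})

test_that("GLCM matches exhaustive pair enumeration on a toy grid", {
  lv <- array(c(1L, 1L, 2L, 2L), dim = c(2, 2, 1))  # [[1,2],[1,2]]
  voi <- toy_voi(lv, n_bins = 2)
  p <- glcm_matrix(voi)
  expect_equal(unclass(p), oracle_glcm(lv, 2), ignore_attr = TRUE)
  f <- glcm_features(p)
  # independent arithmetic on the enumerated matrix
  po <- oracle_glcm(lv, 2)
  i <- row(po); j <- col(po)
  expect_equal(unname(f["GLCM_Contrast"]), sum((i - j)^2 * po))
  expect_equal(unname(f["GLCM_Energy"]), sum(po^2))
  expect_equal(unname(f["GLCM_Dissimilarity"]), sum(abs(i - j) * po))
})

test_that("constant VOI GLCM conventions", {
  voi <- toy_voi(array(1L, dim = c(3, 3, 3)), n_bins = 8)
  f <- glcm_features(glcm_matrix(voi))
  expect_equal(unname(f[c("GLCM_Contrast", "GLCM_Dissimilarity",
                          "GLCM_Entropy", "GLCM_Correlation")]),
               rep(0, 4))
  expect_equal(unname(f[c("GLCM_Homogeneity", "GLCM_Energy")]), c(1, 1))
})

test_that("checkerboard maximizes GLCM contrast among 2-level grids", {
  d <- c(4, 4, 1)
  g <- expand.grid(x = 1:4, y = 1:4, z = 1)
  chk <- array(1L + (g$x + g$y) %% 2L, dim = d)
  voiC <- toy_voi(chk, n_bins = 2)
  fC <- glcm_features(glcm_matrix(voiC, directions = rbind(c(1, 0, 0),
                                                           c(0, 1, 0))))
  set.seed(1)
  for (k in 1:20) {
    rnd <- array(sample(1:2, 16, TRUE), dim = d)
    fR <- glcm_features(glcm_matrix(toy_voi(rnd, n_bins = 2),
                                    directions = rbind(c(1, 0, 0),
                                                       c(0, 1, 0))))
    expect_lte(fR[["GLCM_Contrast"]], fC[["GLCM_Contrast"]] + 1e-12)
  }
})

test_that("GLCM matrix is symmetric, nonnegative, and sums to one", {
  for (seed in 1:10) {
    v <- random_voi(seed)
    voi <- discretize_voi(v$volume, v$mask, 1, extraction_config(n_bins = 6))
    p <- glcm_matrix(voi)
    expect_true(all(p >= 0))
    expect_lt(abs(sum(p) - 1), 1e-9)
    expect_lt(max(abs(p - t(p))), 1e-12)
  }
})

test_that("direction-aggregated GLCM/GLRLM features are invariant to axis rotations", {
  v <- random_voi(99)
  voi <- discretize_voi(v$volume, v$mask, 1, extraction_config(n_bins = 5))
  rot <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  vol_r <- rot(v$volume); msk_r <- rot(v$mask)
  voi_r <- discretize_voi(vol_r, msk_r, 1, extraction_config(n_bins = 5))
  expect_equal(glcm_features(glcm_matrix(voi)),
               glcm_features(glcm_matrix(voi_r)), tolerance = 1e-12)
  expect_equal(glrlm_features(voi), glrlm_features(voi_r),
               tolerance = 1e-12)
})

test_that("GLRLM closed forms on 1-D runs", {
  # constant segment of 5, single direction: one run of length 5
  voi <- toy_voi(array(1L, dim = c(5, 1, 1)), n_bins = 2)
  f <- glrlm_features(voi, directions = rbind(c(1, 0, 0)))
  expect_equal(unname(f["GLRLM_SRE"]), 1 / 25)
  expect_equal(unname(f["GLRLM_LRE"]), 25)
  expect_equal(unname(f["GLRLM_RP"]), 1 / 5)
  # alternating 1,2,1,2: all runs length 1
  voiA <- toy_voi(array(c(1L, 2L, 1L, 2L), dim = c(4, 1, 1)), n_bins = 2)
  fA <- glrlm_features(voiA, directions = rbind(c(1, 0, 0)))
  expect_equal(unname(fA[c("GLRLM_SRE", "GLRLM_LRE", "GLRLM_RP")]),
               c(1, 1, 1))
})

test_that("runs partition the voxel set in every direction", {
  for (seed in 11:16) {
    v <- random_voi(seed)
    voi <- discretize_voi(v$volume, v$mask, 1, extraction_config(n_bins = 4))
    for (k in sample(13, 4)) {
      rl <- radiohet:::glrlm_matrix(voi,
                                    radiohet:::DIRECTIONS_13[k, , drop = FALSE])
      expect_equal(sum(rl * col(rl)), sum(voi$mask))
    }
  }
})

test_that("NGLDM features match hand enumeration on a 2-voxel mask", {
  voi <- toy_voi(array(c(1L, 2L), dim = c(2, 1, 1)), n_bins = 2)
  f <- ngldm_features(voi)
  # each voxel's sole neighbour differs by 1: s = (1, 1), p = (.5, .5)
  expect_equal(unname(f["NGLDM_Coarseness"]), 1)
  expect_equal(unname(f["NGLDM_Contrast"]), 0.25)
  expect_equal(unname(f["NGLDM_Busyness"]), 1)
})

test_that("NGLDM conventions on constant VOIs are bin-count invariant", {
  voi <- toy_voi(array(1L, dim = c(3, 3, 1)), n_bins = 4)
  f4 <- ngldm_features(voi)
  voi$n_bins <- 8L
  f8 <- ngldm_features(voi)
  expect_equal(unname(f4["NGLDM_Contrast"]), 0)
  expect_equal(unname(f4["NGLDM_Busyness"]), 0)
  expect_true(is.finite(f4[["NGLDM_Coarseness"]]))
  expect_equal(f4, f8)
})

test_that("GLZLM closed forms for single and disjoint zones", {
  voi <- toy_voi(array(1L, dim = c(2, 3, 1)), n_bins = 2)  # one zone of 6
  f <- glzlm_features(voi)
  expect_equal(unname(f["GLZLM_SZE"]), 1 / 36)
  expect_equal(unname(f["GLZLM_LZE"]), 36)
  expect_equal(unname(f["GLZLM_ZP"]), 1 / 6)
  # two single-voxel zones of the same level, separated by another level
  lv <- array(c(1L, 2L, 2L, 2L, 1L), dim = c(5, 1, 1))
  # zones: {1},{2,2,2},{1} -> but the two 1-voxels are not adjacent
  f2 <- glzlm_features(toy_voi(lv, n_bins = 2))
  zm <- radiohet:::glzlm_matrix(toy_voi(lv, n_bins = 2))$matrix
  expect_equal(zm[1, 1], 2)  # two size-1 zones of level 1
  expect_equal(zm[2, 3], 1)  # one size-3 zone of level 2
})

test_that("zones partition the voxel set", {
  for (seed in 21:26) {
    v <- random_voi(seed)
    voi <- discretize_voi(v$volume, v$mask, 1, extraction_config(n_bins = 4))
    z <- radiohet:::glzlm_matrix(voi)
    expect_equal(sum(z$matrix * col(z$matrix)), sum(voi$mask))
  }
})

test_that("the default extractor emits exactly the 42-feature roster in order", {
  v <- generate_lesion_volume(list(mean_suv = 5, sd_suv = 1,
                                   corr_length_mm = 3),
                              radius_mm = 8, spacing_mm = 2, seed = 4)
  fv <- extract_features(v$volume, v$mask, v$spacing_mm)
  expect_length(fv, 42)
  expect_identical(names(fv), default_feature_roster())
})

test_that("roster permutation permutes the output identically", {
  v <- generate_lesion_volume(list(mean_suv = 5, sd_suv = 1,
                                   corr_length_mm = 3),
                              radius_mm = 7, spacing_mm = 2, seed = 8)
  fv <- extract_features(v$volume, v$mask, v$spacing_mm)
  perm <- rev(default_feature_roster())
  fvp <- extract_features(v$volume, v$mask, v$spacing_mm,
                          extraction_config(feature_roster = perm))
  expect_identical(unclass(fvp), unclass(fv)[perm], ignore_attr = TRUE)
})

test_that("a constant ball yields the degenerate texture conventions", {
  v <- generate_lesion_volume(list(mean_suv = 4, sd_suv = 0,
                                   corr_length_mm = 2),
                              radius_mm = 8, spacing_mm = 2, seed = 2)
  fv <- extract_features(v$volume, v$mask, v$spacing_mm)
  expect_equal(unname(fv["Entropy"]), 0)
  expect_equal(unname(fv["GLCM_Entropy"]), 0)
  expect_equal(unname(fv["GLCM_Contrast"]), 0)
  expect_equal(unname(fv["Energy"]), 1)
  expect_equal(unname(fv["GLCM_Energy"]), 1)
  expect_equal(unname(fv["Uniformity"]), 1)
})

test_that("all 42 features are finite on seeded random lesion volumes", {
  for (seed in 1:8) {
    set.seed(seed)
    tex <- list(mean_suv = runif(1, 3, 8), sd_suv = runif(1, 0.2, 2),
                corr_length_mm = runif(1, 1.5, 5))
    v <- generate_lesion_volume(tex, radius_mm = runif(3, 5, 10),
                                spacing_mm = 2, seed = seed + 100)
    fv <- extract_features(v$volume, v$mask, v$spacing_mm)
    expect_true(all(is.finite(fv)), info = paste("seed", seed))
  }
})

test_that("extraction errors carry the lesion id", {
  vol <- array(1, dim = c(4, 4, 4))
  msk <- array(0L, dim = c(4, 4, 4))
  expect_error(extract_features(vol, msk, 2, lesion_id = "P001_L01"),
               "P001_L01", class = "radiohet_degenerate_voi")
})
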