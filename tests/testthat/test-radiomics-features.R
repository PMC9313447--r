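test_that("first-order features match hand values and degenerate limits", {
  f <- first_order(c(1, 2, 3, 4))
  expect_equal(unname(f["Mean"]), 2.5)
  expect_equal(unname(f["Range"]), 3)
  expect_equal(unname(f["Skewness"]), 0)
  expect_equal(unname(f["Energy"]), 30)
  expect_equal(unname(f["Variance"]), 1.25)
  expect_equal(unname(f["RootMeanSquared"]), sqrt(30 / 4))

  g <- first_order(c(5, 5, 5))
  expect_equal(unname(g["Entropy"]), 0)
  expect_equal(unname(g["Uniformity"]), 1)
  expect_equal(unname(g["Variance"]), 0)

  expect_error(first_order(numeric(0)), "empty")
})

test_that("GLCM reproduces the hand-enumerated strip and degenerate limits", {
  strip <- array(c(1, 2, 1, 2), c(4L, 1L, 1L))
  mask <- array(TRUE, c(4L, 1L, 1L))
  per_dir <- glcm_features(strip, mask, disc_spec("fixed-bin-count", 2),
                           aggregate = FALSE)
  # only direction (1,0,0) has pairs on a 1D strip
  expect_equal(unname(per_dir["Contrast", 1]), 1)
  expect_equal(unname(per_dir["Correlation", 1]), -1)
  expect_equal(unname(per_dir["JointEntropy", 1]), 1)
  expect_equal(unname(per_dir["MaximumProbability", 1]), 0.5)
  expect_true(all(is.na(per_dir[, 2])))

  const <- glcm_features(array(7, c(3L, 3L, 3L)), array(TRUE, c(3L, 3L, 3L)))
  expect_equal(unname(const["Contrast"]), 0)
  expect_equal(unname(const["JointEnergy"]), 1)
  expect_equal(unname(const["MaximumProbability"]), 1)
  expect_equal(unname(const["JointEntropy"]), 0)
})

test_that("checkerboard texture has higher contrast than smooth noise", {
  d <- c(6L, 6L, 6L)
  idx <- array(seq_len(prod(d)), d)
  parity <- (slice.index(idx, 1) + slice.index(idx, 2) + slice.index(idx, 3)) %% 2
  checker <- array(ifelse(parity == 1, 10, 20), d)
  set.seed(31)
  noise <- array(runif(prod(d), 10, 20), d)
  mask <- array(TRUE, d)
  spec2 <- disc_spec("fixed-bin-count", 2)  # equal gray-level count
  expect_gt(glcm_features(checker, mask, spec2)["Contrast"],
            glcm_features(noise, mask, spec2)["Contrast"])
})

test_that("shape features match analytic limits", {
  sv <- array(FALSE, c(6L, 6L, 6L)); sv[3, 3, 3] <- TRUE
  s1 <- shape_features(sv, c(1, 1, 1))
  expect_equal(unname(s1["VoxelVolume"]), 1)
  expect_equal(unname(s1["MeshVolume"]), 1)       # single-voxel cube
  expect_equal(unname(s1["SurfaceArea"]), 6)
  expect_equal(unname(s1["MajorAxisLength"]), 0)  # axis features are 0
  expect_equal(unname(s1["Elongation"]), 0)

  # digital ball, radius 8: near-unit sphericity
  n <- 22L; ctr <- 11
  ball <- array(FALSE, c(n, n, n))
  for (x in 1:n) for (y in 1:n) for (z in 1:n) {
    ball[x, y, z] <- (x - ctr)^2 + (y - ctr)^2 + (z - ctr)^2 <= 64
  }
  sb <- shape_features(ball, c(1, 1, 1))
  expect_gte(unname(sb["Sphericity"]), 0.95)
  expect_lte(unname(sb["Sphericity"]), 1.0)
  expect_lt(abs(sb["MeshVolume"] - sum(ball)) / sum(ball), 0.06)

  # 4 x 2 x 2 axis-aligned box: lambda1 > lambda2 = lambda3
  box <- array(FALSE, c(10L, 8L, 8L)); box[3:6, 3:4, 3:4] <- TRUE
  sx <- shape_features(box, c(1, 1, 1))
  expect_equal(unname(sx["Elongation"]), unname(sx["Flatness"]))
  expect_equal(unname(sx["MajorAxisLength"]), 4 * sqrt(1.25))
  expect_equal(unname(sx["MinorAxisLength"]), unname(sx["LeastAxisLength"]))

  expect_error(shape_features(array(FALSE, c(4L, 4L, 4L))), "empty")
})

test_that("implementation matches the naive oracles on random ROIs", {
  for (s in 1:4) {
    roi <- random_roi(s)
    x <- roi$volume[roi$mask]
    expect_rel_equal(first_order(x), oracle_first_order(x))
    expect_rel_equal(shape_features(roi$mask, c(1.8, 1.8, 4.0)),
                     oracle_shape(roi$mask, c(1.8, 1.8, 4.0)))
    expect_rel_equal(glcm_features(roi$volume, roi$mask),
                     oracle_glcm(roi$volume, roi$mask))
  }
})

test_that("features are invariant to whole-voxel translation", {
  roi <- random_roi(17, dim = c(6L, 6L, 6L))
  big <- array(0, c(12L, 12L, 12L)); bigm <- array(FALSE, c(12L, 12L, 12L))
  big[1:6, 1:6, 1:6] <- roi$volume; bigm[1:6, 1:6, 1:6] <- roi$mask
  big2 <- array(0, c(12L, 12L, 12L)); bigm2 <- array(FALSE, c(12L, 12L, 12L))
  big2[4:9, 5:10, 3:8] <- roi$volume; bigm2[4:9, 5:10, 3:8] <- roi$mask
  expect_equal(first_order(big[bigm]), first_order(big2[bigm2]))
  expect_equal(shape_features(bigm, c(1, 2, 3)), shape_features(bigm2, c(1, 2, 3)))
  expect_equal(glcm_features(big, bigm), glcm_features(big2, bigm2))
})

test_that("intensity shifts move location features and leave the rest", {
  roi <- random_roi(23)
  x <- roi$volume[roi$mask]
  f0 <- first_order(x)
  f1 <- first_order(x + 50)
  loc <- c("Mean", "Median", "Minimum", "Maximum", "10Percentile", "90Percentile")
  expect_equal(unname(f1[loc]), unname(f0[loc] + 50))
  keep <- c("Variance", "Entropy", "Uniformity", "Skewness", "Kurtosis",
            "InterquartileRange", "Range", "MeanAbsoluteDeviation")
  expect_equal(f1[keep], f0[keep])
  # fixed-bin-count discretization makes the GLCM shift-invariant
  expect_equal(glcm_features(roi$volume + 50, roi$mask),
               glcm_features(roi$volume, roi$mask))
})

test_that("direction-averaged GLCM features are invariant to 90-degree rotations", {
  roi <- random_roi(29)
  rot <- function(a) aperm(a[, dim(a)[2]:1, , drop = FALSE], c(2, 1, 3))
  expect_equal(glcm_features(rot(roi$volume), rot(roi$mask)),
               glcm_features(roi$volume, roi$mask))
})

test_that("patient extraction has the fixed counts, order and determinism", {
  co <- test_cohort()
  p <- co$patients[[2]]
  rois <- build_roi_set(co$atlas, p$infarct, p$hypoperfusion, p$abnormal_side)
  fv <- extract_patient(p$maps, rois, spacing = co$config$spacing_mm)
  expect_length(fv, 5400L)
  expect_false(anyNA(fv))
  expect_identical(anyDuplicated(names(fv)), 0L)

  fv1 <- extract_patient(p$maps["CBF"], rois, spacing = co$config$spacing_mm,
                         sequences = "CBF")
  expect_length(fv1, 1080L)
  expect_equal(fv[names(fv1)], fv1)

  # per ROI x sequence: 18 first-order + 14 shape + 22 texture
  cats <- table(sub("^[A-Z]+_[a-z0-9]+_(abnormal|normal)_([a-z]+)_.*$", "\\2", names(fv)))
  expect_equal(as.vector(cats[c("firstorder", "shape", "glcm")]) / 100,
               c(18, 14, 22))

  # insertion order of the ROI list does not change the output
  scrambled <- rois[sample(seq_along(rois))]
  class(scrambled) <- "roi_set"
  expect_identical(extract_patient(p$maps, scrambled, spacing = co$config$spacing_mm), fv)

  expect_error(extract_patient(p$maps[c("ADC", "CBF")], rois,
                               sequences = c("ADC", "TTP")), "missing sequences")
})

test_that("batched extraction agrees with the single-ROI operations", {
  co <- test_cohort()
  p <- co$patients[[1]]
  rois <- build_roi_set(co$atlas, p$infarct, p$hypoperfusion, p$abnormal_side)
  fv <- extract_patient(p$maps, rois, spacing = co$config$spacing_mm)
  sp <- co$config$spacing_mm
  for (roi_name in c("m2_abnormal", "i_normal")) {
    m <- rois[[roi_name]]
    for (s in c("ADC", "TTP")) {
      manual <- c(first_order(p$maps[[s]][m], spacing = sp),
                  shape_features(m, sp),
                  glcm_features(p$maps[[s]], m))
      got <- fv[paste(s, roi_name, c(paste0("firstorder_", names(first_order(1:2))),
                                     paste0("shape_", names(shape_features(array(TRUE, c(2,2,2))))),
                                     paste0("glcm_", names(glcm_features(array(1:8, c(2,2,2)), array(TRUE, c(2,2,2)))))),
                      sep = "_")]
      expect_equal(unname(got), unname(manual))
    }
  }
})

test_that("cohort extraction stacks patients with planted effect signs", {
  co <- test_cohort_m2()  # lesion always in m2, strong lesion effect
  ft <- extract_cohort(co)
  expect_identical(dim(ft$features), c(14L, 5400L))
  expect_false(anyNA(ft$features))
  ft2 <- extract_cohort(simulate_cohort(co$config))
  expect_identical(ft$features, ft2$features)
  # CBF decreases in the lesion: abnormal m2 mean below its mirror
  expect_lt(mean(ft$features[, "CBF_m2_abnormal_firstorder_Mean"]),
            mean(ft$features[, "CBF_m2_normal_firstorder_Mean"]))
  expect_gt(mean(ft$features[, "TTP_m2_abnormal_firstorder_Mean"]),
            mean(ft$features[, "TTP_m2_normal_firstorder_Mean"]))
})

test_that("feature tables round-trip through CSV", {
  co <- test_cohort_m2()
  ft <- extract_cohort(co)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_identical(colnames(back$features), colnames(ft$features))
  expect_equal(back$features, ft$features, ignore_attr = TRUE)
  expect_identical(back$labels, ft$labels)
})
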