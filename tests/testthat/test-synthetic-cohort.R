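test_that("atlas has 10 mirror-symmetric territories per hemisphere", {
  atlas <- generate_atlas(c(32L, 32L, 16L), seed = 3L)
  labs <- sort(unique(as.vector(atlas$labels[atlas$labels > 0])))
  expect_identical(labs, 1:20)
  expect_identical(atlas$code_map$territory,
                   c("a", "m1", "m2", "m3", "m4", "m5", "p", "l", "c", "i"))
  # every left territory mask is the flip of its right counterpart
  for (k in seq_len(10)) {
    left <- atlas$labels == atlas$code_map$left[k]
    right <- atlas$labels == atlas$code_map$right[k]
    expect_identical(left, mirror_mask(right, 1L))
    expect_identical(sum(left), sum(right))
  }
  # determinism
  atlas2 <- generate_atlas(c(32L, 32L, 16L), seed = 3L)
  expect_identical(atlas$labels, atlas2$labels)
  atlas3 <- generate_atlas(c(32L, 32L, 16L), seed = 4L)
  expect_false(identical(atlas$labels, atlas3$labels))
  # no unique symmetry plane on odd grids
  expect_error(generate_atlas(c(31L, 32L, 16L)), "even")
})

test_that("lesions are unilateral, nested and hit the requested territory", {
  atlas <- test_atlas()
  set.seed(11)
  for (i in 1:10) {
    side <- sample(c("left", "right"), 1)
    les <- simulate_lesion(atlas, side, "m2")
    expect_gt(sum(les$infarct), 0)
    expect_gt(sum(les$hypoperfusion), 0)
    expect_true(all(les$infarct[!les$hypoperfusion] == FALSE))  # core inside envelope
    other <- setdiff(c("left", "right"), side)
    other_hemi <- array(atlas$labels %in% atlas$code_map[[other]], dim(atlas$labels))
    expect_identical(sum(les$hypoperfusion & other_hemi), 0L)
    expect_gt(sum(les$hypoperfusion & territory_mask(atlas, "m2", side)), 0)
  }
  expect_error(simulate_lesion(atlas, "left", "zz"), "absent.*zz")
})

test_that("infarct core volume fraction tracks the configured fraction", {
  atlas <- test_atlas()
  set.seed(21)
  frac <- replicate(100, {
    les <- simulate_lesion(atlas, "left", c("m1", "m2", "m3"), core_fraction = 0.4)
    sum(les$infarct) / sum(les$hypoperfusion)
  })
  expect_lt(abs(mean(frac) - 0.4), 0.1)
})

test_that("lesion effects carry the physiological signs", {
  atlas <- test_atlas()
  cfg2 <- cohort_config(grid_shape = c(24L, 24L, 12L), effect_size_abnormal = 2,
                        effect_size_ht_abnormal = 0, effect_size_ht_normal = 0)
  set.seed(31)
  signs <- t(replicate(100, {
    les <- simulate_lesion(atlas, "left", cfg2$lesion_territories)
    maps <- simulate_parametric_maps(atlas, les, ht_label = 0, cfg2)
    lesion <- les$infarct | les$hypoperfusion
    mirror <- mirror_mask(lesion, 1L)
    vapply(maps, function(m) mean(m[lesion]) - mean(m[mirror]), 0)
  }))
  expect_gte(sum(signs[, "CBF"] < 0), 95)  # flow decreases in the lesion
  expect_gte(sum(signs[, "MTT"] > 0), 95)  # transit time increases
  expect_gte(sum(signs[, "TTP"] > 0), 95)
  expect_gte(sum(signs[, "ADC"] < 0), 95)
  expect_gte(sum(signs[, "CBV"] < 0), 95)
})

test_that("zero effect sizes leave no lesion-vs-mirror intensity gap", {
  atlas <- test_atlas()
  cfg0 <- cohort_config(grid_shape = c(24L, 24L, 12L), effect_size_abnormal = 0,
                        effect_size_ht_abnormal = 0, effect_size_ht_normal = 0)
  set.seed(41)
  gaps <- replicate(50, {
    les <- simulate_lesion(atlas, "right", cfg0$lesion_territories)
    maps <- simulate_parametric_maps(atlas, les, ht_label = 1, cfg0)
    lesion <- les$infarct | les$hypoperfusion
    mirror <- mirror_mask(lesion, 1L)
    n <- sum(lesion)
    (mean(maps$CBF[lesion]) - mean(maps$CBF[mirror])) / sqrt(2 / n)
  })
  z <- mean(gaps) / (sd(gaps) / sqrt(length(gaps)))
  expect_lt(abs(z), 4)
})

test_that("lesion-vs-mirror gap grows monotonically with the effect size", {
  atlas <- test_atlas()
  set.seed(51)
  gap_at <- vapply(c(0.5, 1.5, 3), function(es) {
    cfg <- cohort_config(grid_shape = c(24L, 24L, 12L), effect_size_abnormal = es,
                         effect_size_ht_abnormal = 0, effect_size_ht_normal = 0)
    mean(replicate(30, {
      les <- simulate_lesion(atlas, "left", cfg$lesion_territories)
      maps <- simulate_parametric_maps(atlas, les, 0, cfg)
      lesion <- les$infarct | les$hypoperfusion
      mean(maps$MTT[lesion]) - mean(maps$MTT[mirror_mask(lesion, 1L)])
    }))
  }, 0)
  expect_true(all(diff(gap_at) > 0))
})

test_that("clinical factors follow the per-group prevalences", {
  tab <- reference_prevalences()
  expect_identical(nrow(tab), 15L)  # 15 binaries + age = 16 factors
  expect_identical(tab$ht[tab$factor == "SVS_1"], 1.0)

  set.seed(61)
  n <- 10000
  cl <- simulate_clinical(n, rep(0L, n))
  expect_identical(ncol(cl), 16L)
  expect_lt(abs(mean(cl$SVS_1) - 0.617), 0.015)
  expect_true(all(cl$age >= 18 & cl$age <= 85))
  expect_lt(abs(median(cl$age) - 64), 2)

  # HT-group probabilities are never touched when no HT labels are present
  tweaked <- tab
  tweaked$ht[] <- 0
  cl0 <- simulate_clinical(2000, rep(0L, 2000), tweaked)
  expect_gt(mean(cl0$SVS_1), 0.5)  # still the no-HT prevalence, not 0
  cl1 <- simulate_clinical(2000, rep(1L, 2000), tweaked)
  expect_identical(sum(cl1$SVS_1), 0L)

  bad <- tab
  bad$ht[1] <- 1.5
  expect_error(simulate_clinical(10, rep(0L, 10), bad), "\\[0, 1\\]")
})

test_that("cohort simulation is deterministic and labels match the HT fraction", {
  co <- test_cohort()
  co2 <- simulate_cohort(co$config)
  expect_identical(co$labels, co2$labels)
  expect_identical(co$patients[[3]]$maps$TTP, co2$patients[[3]]$maps$TTP)
  expect_identical(co$clinical, co2$clinical)
  expect_equal(sum(co$labels), max(1, round(8 * 11 / 71)))
  for (p in co$patients) {
    expect_true(all(dim(p$maps$ADC) == co$config$grid_shape))
    side_labels <- co$atlas$code_map[[p$abnormal_side]]
    hemi <- array(co$atlas$labels %in% side_labels, dim(co$atlas$labels))
    expect_identical(sum((p$infarct | p$hypoperfusion) & !hemi), 0L)
  }
})

test_that("cohort round-trips through NIfTI + CSV bit-exactly", {
  co <- test_cohort()
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  expect_error(write_cohort(co, dir), "exists")
  expect_identical(manifest$n_patients, 8L)

  back <- read_cohort(dir)
  expect_identical(dim(back$atlas_labels), dim(co$atlas$labels))
  expect_true(all(back$atlas_labels == co$atlas$labels))
  p1 <- co$patients[[1]]
  b1 <- back$patients[[p1$patient_id]]
  expect_identical(as.numeric(b1$maps$CBF), as.numeric(p1$maps$CBF))
  expect_identical(which(b1$infarct), which(p1$infarct))
  expect_identical(b1$abnormal_side, p1$abnormal_side)
  # clinical CSV: id + 16 factors + HT label
  expect_identical(ncol(back$clinical), 18L)
  expect_identical(back$labels, co$labels)
})
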