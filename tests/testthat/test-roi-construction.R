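test_that("mirror_mask is the index reflection about the mid-plane", {
  m <- array(FALSE, c(8L, 6L, 4L))
  m[3, 2, 4] <- TRUE
  r <- mirror_mask(m, 1L)
  expect_identical(which(r), which(array(seq_len(8 * 6 * 4), c(8, 6, 4)) ==
                                     (8 - 3 + 1) + 8 * (2 - 1) + 48 * (4 - 1)))
  expect_true(r[6, 2, 4])

  set.seed(5)
  rnd <- array(runif(8 * 6 * 4) < 0.3, c(8L, 6L, 4L))
  expect_identical(mirror_mask(mirror_mask(rnd, 1L), 1L), rnd)  # involution
  expect_identical(sum(mirror_mask(rnd, 1L)), sum(rnd))
  # centroid reflects about (W + 1) / 2 (1-based voxel centres)
  cx <- mean(which(rnd, arr.ind = TRUE)[, 1])
  cx_m <- mean(which(mirror_mask(rnd, 1L), arr.ind = TRUE)[, 1])
  expect_equal(cx_m, 8 + 1 - cx)

  expect_error(mirror_mask(array(FALSE, c(7L, 4L, 4L)), 1L), "odd")
  expect_identical(sum(mirror_mask(rnd, 3L)), sum(rnd))
})

test_that("merge_labels merges fine parcels into territories", {
  set.seed(8)
  fine <- array(sample(0:3, 4 * 4 * 4, replace = TRUE), c(4L, 4L, 4L))
  merged <- merge_labels(fine, c("1" = "a", "2" = "a", "3" = "m1"))
  a_label <- merged$code_map$label[merged$code_map$territory == "a"]
  # brute-force voxel-wise check
  for (z in 1:4) for (y in 1:4) for (x in 1:4) {
    expect_identical(merged$labels[x, y, z] == a_label, fine[x, y, z] %in% c(1L, 2L))
  }
  expect_identical(sum(merged$labels == a_label), sum(fine %in% c(1L, 2L)))

  # identity map leaves the synthetic atlas unchanged (up to relabeling)
  atlas <- test_atlas()
  idmap <- setNames(rep(territory_codes(), 2), as.character(1:20))
  ident <- merge_labels(atlas$labels, idmap)
  for (k in 1:10) {
    expect_identical(as.vector(ident$labels == k),
                     as.vector(atlas$labels) %in% c(k, k + 10L))
  }

  expect_error(merge_labels(fine, c("1" = "a", "2" = "a")), "absent.*3")
})

test_that("build_roi_set yields 20 masks with lesion intersection and fallback", {
  co <- test_cohort()
  p <- co$patients[[1]]
  rois <- build_roi_set(co$atlas, p$infarct, p$hypoperfusion, p$abnormal_side)
  expect_length(rois, 20L)
  expect_identical(names(rois),
                   c(paste0(territory_codes(), "_abnormal"),
                     paste0(territory_codes(), "_normal")))
  expect_true(all(vapply(rois, sum, 0L) > 0))

  lesion <- p$infarct | p$hypoperfusion
  normal_side <- setdiff(c("left", "right"), p$abnormal_side)
  normal_hemi <- array(co$atlas$labels %in% co$atlas$code_map[[normal_side]],
                       dim(co$atlas$labels))
  for (t in territory_codes()) {
    abn <- rois[[paste0(t, "_abnormal")]]
    nrm <- rois[[paste0(t, "_normal")]]
    terr <- territory_mask(co$atlas, t, p$abnormal_side)
    overlap <- terr & lesion
    if (sum(overlap) >= 8) {
      expect_identical(abn, overlap)           # lesion intersection
    } else if (sum(overlap) == 0) {
      expect_identical(abn, terr)              # fallback to the full territory
    }
    expect_identical(sum(abn & normal_hemi), 0L)       # stays in its hemisphere
    expect_identical(nrm, mirror_mask(abn, 1L))        # exact mirror
    expect_identical(sum(nrm & lesion), 0L)            # normal ROIs miss the lesion
    expect_identical(sum(nrm), sum(abn))               # count preserved
  }
})

test_that("tiny intersections are padded by one dilation inside the territory", {
  atlas <- test_atlas()
  # craft a lesion covering a single interior voxel of territory m3
  terr <- territory_mask(atlas, "m3", "left")
  inner <- which(terr & htradiomics:::.dilate_within(terr, terr))
  seed_vox <- which(terr)[which.max(vapply(which(terr), function(v) {
    one <- array(FALSE, dim(terr)); one[v] <- TRUE
    sum(htradiomics:::.dilate_within(one, terr))
  }, 0))]
  lesion <- array(FALSE, dim(terr))
  lesion[seed_vox] <- TRUE
  rois <- build_roi_set(atlas, lesion, array(FALSE, dim(terr)), "left")
  m3 <- rois[["m3_abnormal"]]
  expect_gt(sum(m3), 1L)                  # dilated beyond the single voxel
  expect_true(m3[seed_vox])
  expect_identical(sum(m3 & !terr), 0L)   # never leaves the territory
})

test_that("side inconsistencies are rejected", {
  co <- test_cohort()
  p <- co$patients[[1]]
  wrong <- setdiff(c("left", "right"), p$abnormal_side)
  expect_error(build_roi_set(co$atlas, p$infarct, p$hypoperfusion, wrong),
               "normal hemisphere")
})
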