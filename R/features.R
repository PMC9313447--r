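#' Gray-level discretization specification
#'
#' Controls the histogram used by Entropy/Uniformity and by the GLCM.
#' `fixed-bin-count` (the default, 32 bins) computes bin edges from the
#' per-ROI minimum/maximum, making the discretization invariant to
#' intensity shifts and positive scalings; `fixed-bin-width` anchors bin
#' edges at 0 with the given width in intensity units.
#'
#' @param mode `"fixed-bin-count"` or `"fixed-bin-width"`.
#' @param value bin count (default 32) or bin width.
#' @return object of class `disc_spec`.
#' @export
disc_spec <- function(mode = c("fixed-bin-count", "fixed-bin-width"), value = 32) {
  mode <- match.arg(mode)
  if (value <= 0) stopf("discretization value must be > 0")
  if (mode == "fixed-bin-count" && value != round(value)) {
    stopf("bin count must be an integer")
  }
  structure(list(mode = mode, value = value), class = "disc_spec")
}

#' Gray-level co-occurrence matrix specification
#'
#' Defaults follow common radiomics practice: voxel distance 1, the 13
#' unique (non-antiparallel) 3D neighbour directions, symmetric
#' accumulation, and feature-then-average aggregation over directions.
#'
#' @param distance voxel offset magnitude (default 1).
#' @param symmetric accumulate both (i, j) and (j, i)? Default `TRUE`.
#' @param aggregation only `"mean"` (feature computed per direction, then
#'   averaged over directions that have voxel pairs).
#' @return object of class `glcm_spec`.
#' @export
glcm_spec <- function(distance = 1L, symmetric = TRUE, aggregation = "mean") {
  if (distance < 1) stopf("distance must be >= 1")
  aggregation <- match.arg(aggregation, "mean")
  structure(list(distance = as.integer(distance), symmetric = symmetric,
                 aggregation = aggregation),
            class = "glcm_spec")
}

#' The 13 unique 3D neighbour directions
#'
#' One of each antiparallel pair of the 26 neighbours, scaled by
#' `distance`.
#'
#' @param distance voxel offset magnitude.
#' @return 13 x 3 integer matrix.
#' @export
glcm_directions <- function(distance = 1L) {
  base <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
  storage.mode(base) <- "integer"
  base * as.integer(distance)
}

.first_order_names <- function() {
  c("10Percentile", "90Percentile", "Energy", "Entropy", "InterquartileRange",
    "Kurtosis", "Maximum", "MeanAbsoluteDeviation", "Mean", "Median",
    "Minimum", "Range", "RobustMeanAbsoluteDeviation", "RootMeanSquared",
    "Skewness", "TotalEnergy", "Uniformity", "Variance")
}

.shape_names <- function() {
  c("Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
    "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "Maximum2DDiameterSlice",
    "Maximum3DDiameter", "MeshVolume", "MinorAxisLength", "Sphericity",
    "SurfaceArea", "SurfaceVolumeRatio", "VoxelVolume")
}

.glcm_names <- function() {
  c("Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
    "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
    "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
    "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn", "InverseVariance",
    "MaximumProbability", "SumEntropy", "SumSquares")
}

#' Discretize ROI intensities to integer gray levels
#'
#' @param x numeric intensities.
#' @param spec a [disc_spec()].
#' @return integer vector of gray levels (1..nlevels) with attribute
#'   `nlevels`.
#' @export
discretize_intensities <- function(x, spec = disc_spec()) {
  if (length(x) == 0) stopf("empty intensity vector")
  .cpp_discretize(as.numeric(x), if (spec$mode == "fixed-bin-count") 0L else 1L,
                  spec$value)
}

#' The 18 first-order intensity features
#'
#' Energy is the raw sum of squares, TotalEnergy scales it by the voxel
#' volume, Entropy (bits) and Uniformity are computed on the discretized
#' histogram, Variance is the population variance, Kurtosis is the
#' non-excess (Pearson) kurtosis, and percentiles use linear
#' interpolation.
#'
#' @param x numeric vector of ROI intensities (>= 1 value).
#' @param disc a [disc_spec()].
#' @param spacing voxel size triple (for TotalEnergy).
#' @return named numeric vector of length 18.
#' @export
first_order <- function(x, disc = disc_spec(), spacing = c(1, 1, 1)) {
  if (length(x) == 0) stopf("empty intensity vector")
  bins <- discretize_intensities(x, disc)
  out <- .cpp_first_order(as.numeric(x), bins, attr(bins, "nlevels"),
                          prod(spacing))
  setNames(out, .first_order_names())
}

#' The 14 geometry (shape) features of a binary mask
#'
#' VoxelVolume is count x voxel volume. MeshVolume and SurfaceArea come
#' from a closed triangulated isosurface: the mask is anti-aliased with a
#' Gaussian (sigma 0.8 voxel) and triangulated by marching tetrahedra with
#' linear interpolation at level 0.5; masks too small or thin for the
#' smoothed field to reach the level (e.g. a single voxel) use the exact
#' voxel-boundary surface instead. Sphericity is
#' `(36 pi V^2)^(1/3) / A`. Axis lengths are `4 sqrt(lambda)` from the
#' eigenvalues of the physical voxel-coordinate covariance;
#' Elongation/Flatness are `sqrt(lambda2/lambda1)` / `sqrt(lambda3/lambda1)`.
#' Maximum diameters are the largest pairwise surface-vertex distances:
#' Maximum3DDiameter in full 3D, Maximum2DDiameterSlice ignoring axis 3,
#' Maximum2DDiameterRow ignoring axis 2, Maximum2DDiameterColumn ignoring
#' axis 1.
#'
#' @param mask logical (or 0/1) 3D array, non-empty.
#' @param spacing voxel size triple in physical units.
#' @return named numeric vector of length 14.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  if (is.null(d) || length(d) != 3) stopf("mask must be a 3D array")
  idx <- which(mask != 0)
  if (length(idx) == 0) stopf("empty mask")
  out <- .cpp_shape_features(idx, as.integer(d), as.numeric(spacing))
  setNames(out, .shape_names())
}

#' The 22 gray-level co-occurrence matrix texture features
#'
#' Intensities inside the mask are discretized, co-occurrence counts are
#' accumulated per direction over in-mask voxel pairs, symmetrized and
#' normalized, each feature is computed per direction and the features are
#' averaged over directions that have at least one pair. Logarithms are
#' base 2 with `0 log 0 = 0`; a constant ROI yields the single-cell limit
#' (Contrast 0, JointEnergy 1, MaximumProbability 1, Correlation defined
#' as 1); IMC2 is clamped to \[0, 1\].
#'
#' @param volume numeric 3D array of intensities.
#' @param mask logical 3D array on the same grid.
#' @param disc a [disc_spec()].
#' @param spec a [glcm_spec()].
#' @param aggregate return the direction average (default) or the per
#'   direction 22 x 13 matrix.
#' @return named numeric vector of length 22, or a matrix when
#'   `aggregate = FALSE`.
#' @export
glcm_features <- function(volume, mask, disc = disc_spec(), spec = glcm_spec(),
                          aggregate = TRUE) {
  d <- dim(volume)
  stopifnot(identical(d, dim(mask)))
  idx <- which(mask != 0)
  if (length(idx) == 0) stopf("empty mask")
  bins_roi <- discretize_intensities(volume[idx], disc)
  nlevels <- attr(bins_roi, "nlevels")
  binvol <- array(0L, d)
  binvol[idx] <- bins_roi
  dirs <- glcm_directions(spec$distance)
  per_dir <- .cpp_glcm_features(as.integer(binvol), as.integer(d), nlevels,
                                dirs, spec$symmetric)
  rownames(per_dir) <- .glcm_names()
  if (all(is.na(per_dir))) {
    stopf("mask too thin: no voxel pairs in any direction")
  }
  if (!aggregate) return(per_dir)
  rowMeans(per_dir, na.rm = TRUE)
}

#' Canonical radiomics feature names
#'
#' `Sequence_Territory_SideClass_Category_Feature`, e.g.
#' `CBF_a_abnormal_shape_MajorAxisLength`. Order: sequences outermost,
#' then the 20 ROIs (abnormal block before normal block, territories in
#' canonical order), then 18 first-order + 14 shape + 22 GLCM features.
#'
#' @param sequences sequence names (default the five parametric maps).
#' @param roi_names ROI names (default the 20 canonical ones).
#' @return character vector of length
#'   `length(sequences) * length(roi_names) * 54`.
#' @export
radiomics_feature_names <- function(sequences = .sequences(),
                                    roi_names = NULL) {
  if (is.null(roi_names)) {
    roi_names <- c(paste0(territory_codes(), "_abnormal"),
                   paste0(territory_codes(), "_normal"))
  }
  per_roi <- c(paste0("firstorder_", .first_order_names()),
               paste0("shape_", .shape_names()),
               paste0("glcm_", .glcm_names()))
  unlist(lapply(sequences, function(s) {
    unlist(lapply(roi_names, function(r) paste(s, r, per_roi, sep = "_")))
  }), use.names = FALSE)
}

#' Extract the full radiomics feature vector of one patient
#'
#' 54 features per ROI per sequence: 5400 values for the five-sequence
#' run, 1080 for a single sequence. Shape features are computed once per
#' ROI (the mask does not depend on the sequence) and replicated across
#' sequences, preserving the fixed per-sequence feature count. Ordering
#' and naming are deterministic regardless of the insertion order of the
#' input lists.
#'
#' @param maps named list of numeric 3D arrays (subset of ADC, CBF, CBV,
#'   MTT, TTP).
#' @param roi_set an `roi_set` (or named list of logical masks).
#' @param disc a [disc_spec()].
#' @param glcm a [glcm_spec()].
#' @param spacing voxel size triple.
#' @param sequences sequences to extract, in canonical order by default.
#' @return named numeric vector of length
#'   `length(sequences) * length(roi_set) * 54`.
#' @export
extract_patient <- function(maps, roi_set, disc = disc_spec(),
                            glcm = glcm_spec(), spacing = c(1, 1, 1),
                            sequences = NULL) {
  if (is.null(sequences)) sequences <- intersect(.sequences(), names(maps))
  missing_seq <- setdiff(sequences, names(maps))
  if (length(missing_seq) > 0) {
    stopf("missing sequences: %s", paste(missing_seq, collapse = ", "))
  }
  canonical_rois <- c(paste0(territory_codes(), "_abnormal"),
                      paste0(territory_codes(), "_normal"))
  roi_names <- if (all(canonical_rois %in% names(roi_set))) {
    canonical_rois
  } else {
    names(roi_set)
  }
  d <- dim(roi_set[[1]])
  roi_idx <- lapply(roi_set[roi_names], function(m) which(m != 0))
  if (any(vapply(roi_idx, length, 0L) == 0)) stopf("empty ROI mask")
  vals <- .cpp_extract_patient(
    lapply(maps[sequences], as.numeric), roi_idx, as.integer(d),
    as.numeric(spacing), if (disc$mode == "fixed-bin-count") 0L else 1L,
    disc$value, glcm_directions(glcm$distance), glcm$symmetric
  )
  setNames(vals, radiomics_feature_names(sequences, roi_names))
}

#' Extract the feature table of a whole cohort
#'
#' Runs ROI construction and feature extraction for every patient and
#' stacks the per-patient vectors into a patients x features matrix with
#' the HT labels attached.
#'
#' @param cohort a `synthetic_cohort`.
#' @param disc,glcm feature specs.
#' @param sequences sequences to extract (default all five).
#' @param min_voxels minimum ROI size passed to [build_roi_set()].
#' @return object of class `feature_table`: list with `features` (numeric
#'   matrix), `labels`, `patient_ids`, `sequences`.
#' @export
extract_cohort <- function(cohort, disc = disc_spec(), glcm = glcm_spec(),
                           sequences = .sequences(), min_voxels = 8L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  spacing <- cohort$config$spacing_mm
  rows <- lapply(cohort$patients, function(p) {
    rois <- build_roi_set(cohort$atlas, p$infarct, p$hypoperfusion,
                          p$abnormal_side, min_voxels = min_voxels)
    extract_patient(p$maps, rois, disc = disc, glcm = glcm,
                    spacing = spacing, sequences = sequences)
  })
  lens <- vapply(rows, length, 0L)
  if (length(unique(lens)) != 1) {
    stopf("inconsistent feature vector lengths across patients")
  }
  features <- do.call(rbind, rows)
  rownames(features) <- vapply(cohort$patients, `[[`, "", "patient_id")
  structure(
    list(features = features, labels = cohort$labels,
         patient_ids = rownames(features), sequences = sequences),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$features), "patients x", ncol(x$features),
      "features (", sum(x$labels), "HT )\n")
  invisible(x)
}

#' Write / read a feature table as CSV
#'
#' One row per patient: `patient_id`, `HT`, then the named features.
#' @param ft a `feature_table`.
#' @param path CSV path.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(patient_id = ft$patient_ids, HT = ft$labels,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(ft$features, check.names = FALSE))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @param path CSV path written by [write_feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, check.names = FALSE))
  features <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(features) <- df$patient_id
  structure(
    list(features = features, labels = df$HT, patient_ids = df$patient_id,
         sequences = unique(sub("_.*$", "", colnames(features)))),
    class = "feature_table"
  )
}
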