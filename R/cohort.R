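#' Clinical factor prevalences of the HT and No-HT groups
#'
#' Per-group prevalences of the 15 binary clinical factors used by the
#' cohort generator, plus the age model (truncated normal, median 64,
#' support 18-85). Defaults reproduce the published group frequencies of
#' the source cohort (11 HT / 60 No-HT patients); gender is coded 1 = male.
#'
#' @return data.frame with columns `factor`, `ht`, `no_ht` (probabilities).
#' @export
reference_prevalences <- function() {
  data.frame(
    factor = c("gender", "hypertension", "hyperlipidemia", "diabetes",
               "atrial_fibrillation", "leukoaraiosis", "coronary",
               "A", "M1", "M2", "P", "SVS_1", "SVS_2", "mTICI_2",
               "recanalization"),
    ht    = c(0.636, 0.636, 0.182, 0.364, 0.182, 0.636, 0.182,
              0.091, 0.545, 0.364, 0.091, 1.000, 0.273, 0.455, 0.455),
    no_ht = c(0.733, 0.783, 0.150, 0.217, 0.050, 0.667, 0.133,
              0.100, 0.533, 0.583, 0.100, 0.617, 0.367, 0.467, 0.433),
    stringsAsFactors = FALSE
  )
}

#' Prevalence table with no group differences
#'
#' Pools the two groups (weighted 11:60) so clinical factors carry no HT
#' signal; used for null-calibration cohorts.
#' @return data.frame like [reference_prevalences()].
#' @export
pooled_prevalences <- function() {
  tab <- reference_prevalences()
  pooled <- (11 * tab$ht + 60 * tab$no_ht) / 71
  tab$ht <- pooled
  tab$no_ht <- pooled
  tab
}

#' Synthetic cohort configuration
#'
#' Bundles every knob of the cohort generator. Effect sizes are
#' standardized mean shifts in units of `noise_sd`. The lesion effect
#' (`effect_size_abnormal`) separates lesioned from healthy tissue in every
#' patient, with the physiological signs: ADC, CBF and CBV decrease inside
#' the lesion while MTT and TTP increase. The HT effect is an additional
#' shift applied only in HT-positive patients, split between the lesion
#' region (`effect_size_ht_abnormal`) and its mirrored contralateral region
#' (`effect_size_ht_normal`); the default 2/3 vs 1/3 split of a total HT
#' effect of 2 encodes the assumption that part of the HT-predictive signal
#' is comparative information between diseased and normal hemispheres.
#'
#' @param n_patients cohort size (>= 2). Default 71, the source cohort.
#' @param ht_fraction fraction of HT-positive patients in (0, 1). Default
#'   11/71.
#' @param grid_shape voxels per axis (left-right axis first, even).
#' @param spacing_mm voxel size triple in mm (default 1.8 x 1.8 x 4.0, the
#'   perfusion-map resolution).
#' @param lesion_territories territory codes eligible to host the lesion
#'   centre.
#' @param effect_size_abnormal standardized lesion-vs-background shift.
#' @param effect_size_ht_abnormal additional standardized shift applied to
#'   the whole abnormal-hemisphere tissue when HT = 1 (a diffuse
#'   perfusion derangement of the affected side).
#' @param effect_size_ht_normal additional standardized shift applied to
#'   the whole normal-hemisphere tissue when HT = 1 (the milder diffuse
#'   contralateral component of the same derangement).
#' @param core_fraction infarct-core volume fraction within the
#'   hypoperfusion envelope.
#' @param noise_sd voxel intensity noise scale (> = 0).
#' @param severity_sd patient-level ischemic severity scale (units of
#'   `noise_sd`). Each patient draws one severity value that shifts all
#'   abnormal-hemisphere tissue with the same per-sequence signs as
#'   hypoperfusion itself (ADC/CBF/CBV down, MTT/TTP up), independently
#'   of the HT outcome. Because severity mimics the HT effect's signature
#'   exactly on the abnormal side, absolute abnormal-side intensities
#'   cannot distinguish a severe-but-stable patient from an HT-prone one;
#'   the unaffected contralateral hemisphere is what disambiguates them.
#' @param global_offset_sd patient-level global intensity offset scale
#'   (units of `noise_sd`), one draw per patient shared by all five maps
#'   and both hemispheres (acquisition scale variation).
#' @param territory_offset_sd per-territory, per-sequence baseline offset
#'   scale (units of `noise_sd`), applied mirror-symmetrically to both
#'   hemispheres (regional baseline variation).
#' @param clinical_prevalences per-group factor prevalence table
#'   ([reference_prevalences()] by default).
#' @param seed master seed; all randomness derives from it.
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_patients = 71L,
                          ht_fraction = 11 / 71,
                          grid_shape = c(32L, 32L, 16L),
                          spacing_mm = c(1.8, 1.8, 4.0),
                          lesion_territories = c("m1", "m2", "m3"),
                          effect_size_abnormal = 2.0,
                          effect_size_ht_abnormal = 4 / 3,
                          effect_size_ht_normal = 2 / 3,
                          core_fraction = 0.4,
                          noise_sd = 1.0,
                          severity_sd = 1.0,
                          global_offset_sd = 0.25,
                          territory_offset_sd = 0.3,
                          clinical_prevalences = reference_prevalences(),
                          seed = 1L) {
  if (n_patients < 2) stopf("n_patients must be >= 2")
  if (ht_fraction <= 0 || ht_fraction >= 1) stopf("ht_fraction must be in (0, 1)")
  if (any(spacing_mm <= 0)) stopf("all spacings must be > 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (core_fraction <= 0 || core_fraction > 1) stopf("core_fraction must be in (0, 1]")
  if (length(lesion_territories) == 0) stopf("lesion_territories must be non-empty")
  bad <- setdiff(lesion_territories, territory_codes())
  if (length(bad) > 0) stopf("unknown lesion territories: %s", paste(bad, collapse = ", "))
  if (any(clinical_prevalences$ht < 0 | clinical_prevalences$ht > 1) ||
      any(clinical_prevalences$no_ht < 0 | clinical_prevalences$no_ht > 1)) {
    stopf("clinical prevalences must lie in [0, 1]")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), ht_fraction = ht_fraction,
      grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
      lesion_territories = lesion_territories,
      effect_size_abnormal = effect_size_abnormal,
      effect_size_ht_abnormal = effect_size_ht_abnormal,
      effect_size_ht_normal = effect_size_ht_normal,
      core_fraction = core_fraction, noise_sd = noise_sd,
      severity_sd = severity_sd,
      global_offset_sd = global_offset_sd,
      territory_offset_sd = territory_offset_sd,
      clinical_prevalences = clinical_prevalences, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Zero-effect configuration for null calibration
#'
#' All image effect sizes zero and pooled clinical prevalences, so no
#' feature (radiomics or clinical) carries HT signal; any downstream
#' validation AUC should then be statistically indistinguishable from 0.5.
#'
#' @param ... overrides passed to [cohort_config()].
#' @return `cohort_config`.
#' @export
null_cohort_config <- function(...) {
  cohort_config(effect_size_abnormal = 0, effect_size_ht_abnormal = 0,
                effect_size_ht_normal = 0,
                clinical_prevalences = pooled_prevalences(), ...)
}

# sequence order, lesion effect signs and baseline map values (map units:
# ADC 1e-6 mm^2/s, CBF mL/100g/min, CBV mL/100g, MTT s, TTP s)
.sequences <- function() c("ADC", "CBF", "CBV", "MTT", "TTP")
.sequence_signs <- function() c(ADC = -1, CBF = -1, CBV = -1, MTT = 1, TTP = 1)
.sequence_baselines <- function() c(ADC = 800, CBF = 50, CBV = 4, MTT = 6, TTP = 20)

#' Simulate an infarct core and hypoperfusion envelope
#'
#' Draws a spherical-ish hypoperfusion envelope centred in one of the
#' requested territories of the abnormal hemisphere (clipped to that
#' hemisphere's brain mask), then takes the `core_fraction` of its voxels
#' closest to the centre as the infarct core, so the core volume fraction
#' matches the configuration by construction (up to rounding).
#'
#' Consumes the current RNG stream (seed it with the caller).
#'
#' @param atlas a `territory_atlas`.
#' @param abnormal_side `"left"` or `"right"`.
#' @param lesion_territories candidate territory codes for the lesion
#'   centre.
#' @param core_fraction infarct volume fraction within the envelope.
#' @param radius_range hypoperfusion radius range in voxels.
#' @return list with logical arrays `infarct` and `hypoperfusion`.
#' @export
simulate_lesion <- function(atlas, abnormal_side, lesion_territories,
                            core_fraction = 0.4, radius_range = c(2.8, 5.5)) {
  if (length(lesion_territories) == 0) stopf("lesion_territories must be non-empty")
  bad <- setdiff(lesion_territories, atlas$code_map$territory)
  if (length(bad) > 0) stopf("territory absent from atlas: %s", paste(bad, collapse = ", "))

  d <- dim(atlas$labels)
  terr <- lesion_territories[sample.int(length(lesion_territories), 1)]
  tmask <- territory_mask(atlas, terr, abnormal_side)
  tvox <- which(tmask)
  centre_idx <- tvox[sample.int(length(tvox), 1)]
  ctr <- arrayInd(centre_idx, d)[1, ]

  side_labels <- atlas$code_map[[abnormal_side]]
  hemi <- array(atlas$labels %in% side_labels, d)

  ax <- slice.index(array(0, d), 1) - ctr[1]
  ay <- slice.index(array(0, d), 2) - ctr[2]
  az <- slice.index(array(0, d), 3) - ctr[3]
  dist2 <- ax^2 + ay^2 + az^2
  r <- runif(1, radius_range[1], radius_range[2])
  hypo <- (dist2 <= r^2) & hemi

  n_core <- max(1L, round(core_fraction * sum(hypo)))
  hv <- which(hypo)
  core_vox <- hv[order(dist2[hv])[seq_len(n_core)]]
  infarct <- array(FALSE, d)
  infarct[core_vox] <- TRUE

  list(infarct = infarct, hypoperfusion = hypo)
}

#' Simulate the five parametric maps of one patient
#'
#' Intensity model per sequence: baseline + one per-patient global
#' intensity offset (acquisition scale, shared by the whole brain and all
#' five sequences) + mirror-symmetric per-territory offsets + the
#' patient's ischemic severity shift on the whole abnormal hemisphere
#' (hypoperfusion sign pattern, HT-independent) + lesion effect with the
#' physiological sign (ADC/CBF/CBV down, MTT/TTP up inside the lesion;
#' the infarct core gets 1.5x the envelope shift) + hemisphere-wide
#' HT-dependent tissue shifts (the abnormal hemisphere gets
#' `effect_size_ht_abnormal`, the normal hemisphere
#' `effect_size_ht_normal`, with the same per-sequence signs) + i.i.d.
#' Gaussian noise. All shifts are `effect * noise_sd`, making effect
#' sizes standardized. On the abnormal side the severity confounder and
#' the HT effect share one signature, so absolute abnormal-side
#' intensities cannot separate them; the normal hemisphere carries the
#' HT component but not the severity shift, which is what makes
#' contralateral ROIs informative.
#'
#' Consumes the current RNG stream.
#'
#' @param atlas a `territory_atlas`.
#' @param lesion list with `infarct` and `hypoperfusion` masks.
#' @param ht_label 0/1 HT outcome of the patient.
#' @param config a `cohort_config`.
#' @return named list of five numeric 3D arrays (ADC, CBF, CBV, MTT, TTP).
#' @export
simulate_parametric_maps <- function(atlas, lesion, ht_label, config) {
  d <- dim(atlas$labels)
  signs <- .sequence_signs()
  base <- .sequence_baselines()
  sdn <- config$noise_sd
  lesion_all <- lesion$infarct | lesion$hypoperfusion

  # abnormal hemisphere = the one holding the lesion
  left_hemi <- array(atlas$labels %in% atlas$code_map$left, d)
  right_hemi <- array(atlas$labels %in% atlas$code_map$right, d)
  lesion_left <- any(lesion_all & left_hemi)
  abn_hemi <- if (lesion_left) left_hemi else right_hemi
  nrm_hemi <- if (lesion_left) right_hemi else left_hemi

  # territory index 1..10 regardless of hemisphere (0 = background)
  tidx <- atlas$labels
  tidx[tidx > 10] <- tidx[tidx > 10] - 10L

  maps <- vector("list", 5)
  names(maps) <- .sequences()
  global <- rnorm(1, 0, config$global_offset_sd * sdn)
  severity <- rnorm(1, 0, config$severity_sd * sdn)
  for (s in .sequences()) {
    offsets <- c(0, rnorm(10, 0, config$territory_offset_sd * sdn))  # symmetric across hemispheres
    vol <- array(0, d)
    inb <- tidx > 0
    vol[inb] <- base[[s]] + global + offsets[tidx[inb] + 1]
    vol[abn_hemi] <- vol[abn_hemi] + signs[[s]] * severity
    shift <- signs[[s]] * config$effect_size_abnormal * sdn
    vol[lesion$hypoperfusion] <- vol[lesion$hypoperfusion] + shift
    vol[lesion$infarct] <- vol[lesion$infarct] + 1.5 * shift
    if (ht_label == 1) {
      vol[abn_hemi] <- vol[abn_hemi] +
        signs[[s]] * config$effect_size_ht_abnormal * sdn
      vol[nrm_hemi] <- vol[nrm_hemi] +
        signs[[s]] * config$effect_size_ht_normal * sdn
    }
    maps[[s]] <- vol + array(rnorm(prod(d), 0, sdn), d)
  }
  maps
}

#' Simulate the 16-factor clinical table
#'
#' Binary factors are drawn independently per HT group from the prevalence
#' table; age is a truncated normal on \[18, 85\] with median 64.
#'
#' Consumes the current RNG stream.
#'
#' @param n number of patients.
#' @param ht_labels integer 0/1 vector of length `n`.
#' @param prevalence_table per-group probabilities
#'   ([reference_prevalences()] format).
#' @param age_median,age_sd,age_range age distribution parameters (years).
#' @return data.frame with 16 factor columns (age first).
#' @export
simulate_clinical <- function(n, ht_labels,
                              prevalence_table = reference_prevalences(),
                              age_median = 64, age_sd = 11,
                              age_range = c(18, 85)) {
  if (length(ht_labels) != n) stopf("ht_labels must have length n")
  if (any(prevalence_table$ht < 0 | prevalence_table$ht > 1) ||
      any(prevalence_table$no_ht < 0 | prevalence_table$no_ht > 1)) {
    stopf("prevalences must lie in [0, 1]")
  }
  age <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    age[todo] <- rnorm(length(todo), age_median, age_sd)
    todo <- todo[age[todo] < age_range[1] | age[todo] > age_range[2]]
  }
  out <- data.frame(age = round(age, 1))
  for (k in seq_len(nrow(prevalence_table))) {
    p <- ifelse(ht_labels == 1, prevalence_table$ht[k], prevalence_table$no_ht[k])
    out[[prevalence_table$factor[k]]] <- rbinom(n, 1, p)
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Generates the shared atlas, then per patient: abnormal side (randomized
#' left/right), lesion masks, five parametric maps, HT label and clinical
#' record. Fully deterministic given the configuration (including its
#' seed).
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: list with `atlas`,
#'   `patients` (list of per-patient lists), `clinical` (data.frame),
#'   `labels` (integer vector), `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  atlas <- generate_atlas(config$grid_shape, config$spacing_mm,
                          seed = derive_seed(config$seed, 1L))
  n <- config$n_patients
  n_ht <- max(1L, min(n - 1L, round(n * config$ht_fraction)))
  labels <- with_seed(derive_seed(config$seed, 2L), {
    lab <- integer(n)
    lab[sample(n, n_ht)] <- 1L
    lab
  })
  clinical <- with_seed(derive_seed(config$seed, 3L),
    simulate_clinical(n, labels, config$clinical_prevalences))

  patients <- vector("list", n)
  for (i in seq_len(n)) {
    patients[[i]] <- with_seed(derive_seed(config$seed, 10L + i), {
      side <- sample(c("left", "right"), 1)
      lesion <- simulate_lesion(atlas, side, config$lesion_territories,
                                config$core_fraction)
      maps <- simulate_parametric_maps(atlas, lesion, labels[i], config)
      list(patient_id = sprintf("P%03d", i), abnormal_side = side,
           infarct = lesion$infarct, hypoperfusion = lesion$hypoperfusion,
           maps = maps, ht_label = labels[i])
    })
  }
  structure(
    list(atlas = atlas, patients = patients, clinical = clinical,
         labels = labels, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", length(x$patients), "patients (",
      sum(x$labels), "HT ),", paste(dim(x$atlas$labels), collapse = "x"),
      "grid\n")
  invisible(x)
}

#' Write a cohort to disk (NIfTI volumes + CSV tables + JSON manifest)
#'
#' One NIfTI file per map and mask per patient, a shared atlas volume, a
#' clinical CSV (id + 16 factors + HT label), a labels CSV and a JSON
#' manifest recording paths, seed and configuration hash. Re-reading with
#' [read_cohort()] reproduces the voxel arrays bit-exactly.
#'
#' @param cohort a `synthetic_cohort`.
#' @param out_dir output directory (created if needed).
#' @param overwrite overwrite an existing manifest? Default `FALSE`.
#' @return the manifest (invisibly), also written as `manifest.json`.
#' @export
write_cohort <- function(cohort, out_dir, overwrite = FALSE) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stopf("manifest already exists at %s (use overwrite = TRUE)", manifest_path)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sp <- cohort$config$spacing_mm
  write_vol <- function(arr, path) {
    img <- RNifti::asNifti(arr * 1)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path)
    path
  }
  files <- list(atlas = write_vol(cohort$atlas$labels, file.path(out_dir, "atlas.nii.gz")))
  pat_files <- lapply(cohort$patients, function(p) {
    base <- file.path(out_dir, p$patient_id)
    f <- list(
      infarct = write_vol(p$infarct, paste0(base, "_infarct.nii.gz")),
      hypoperfusion = write_vol(p$hypoperfusion, paste0(base, "_hypoperfusion.nii.gz"))
    )
    for (s in names(p$maps)) f[[s]] <- write_vol(p$maps[[s]], paste0(base, "_", s, ".nii.gz"))
    c(f, list(abnormal_side = p$abnormal_side))
  })
  names(pat_files) <- vapply(cohort$patients, `[[`, "", "patient_id")

  clinical <- cbind(
    data.frame(patient_id = names(pat_files), stringsAsFactors = FALSE),
    cohort$clinical, HT = cohort$labels
  )
  data.table::fwrite(clinical, file.path(out_dir, "clinical.csv"))
  data.table::fwrite(
    data.frame(patient_id = names(pat_files), HT = cohort$labels),
    file.path(out_dir, "labels.csv")
  )

  manifest <- list(
    n_patients = length(cohort$patients),
    seed = cohort$config$seed,
    config_hash = config_hash(cohort$config[setdiff(names(cohort$config), "clinical_prevalences")]),
    grid_shape = dim(cohort$atlas$labels),
    spacing_mm = sp,
    files = c(files, list(clinical = file.path(out_dir, "clinical.csv"),
                          labels = file.path(out_dir, "labels.csv"))),
    patients = pat_files
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `manifest.json`.
#' @return list with `atlas_labels` (integer array), `patients` (list of
#'   maps/masks/side), `clinical`, `labels`, `manifest`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  read_vol <- function(path) {
    v <- RNifti::readNifti(path)
    array(as.numeric(v), dim = dim(v))
  }
  atlas_labels <- array(as.integer(read_vol(manifest$files$atlas)),
                        dim = manifest$grid_shape)
  clinical <- as.data.frame(data.table::fread(manifest$files$clinical))
  patients <- lapply(manifest$patients, function(pf) {
    maps <- lapply(pf[.sequences()], read_vol)
    list(
      maps = maps,
      infarct = read_vol(pf$infarct) > 0.5,
      hypoperfusion = read_vol(pf$hypoperfusion) > 0.5,
      abnormal_side = pf$abnormal_side
    )
  })
  list(atlas_labels = atlas_labels, patients = patients, clinical = clinical,
       labels = clinical$HT, manifest = manifest)
}
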