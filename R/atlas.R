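#' Vascular supply territory codes
#'
#' The ten cerebral blood-supply areas used as ROI units: anterior cerebral
#' (a), middle cerebral artery subdivisions (m1-m5), posterior cerebral
#' artery (p), lenticular nucleus (l), caudate nucleus (c) and insula (i).
#'
#' @return character vector of length 10, in canonical order.
#' @export
territory_codes <- function() {
  c("a", "m1", "m2", "m3", "m4", "m5", "p", "l", "c", "i")
}

# canonical seed positions of the ten territories in normalized
# left-hemisphere coordinates (x: left-right in (0, 0.5), y: posterior ->
# anterior, z: inferior -> superior); rough anatomical layout, jittered per
# atlas seed
.territory_seed_positions <- function() {
  rbind(
    a  = c(0.30, 0.85, 0.55),
    m1 = c(0.15, 0.72, 0.45),
    m2 = c(0.12, 0.60, 0.60),
    m3 = c(0.12, 0.45, 0.65),
    m4 = c(0.15, 0.32, 0.55),
    m5 = c(0.18, 0.25, 0.40),
    p  = c(0.30, 0.12, 0.45),
    l  = c(0.35, 0.55, 0.45),
    c  = c(0.38, 0.62, 0.58),
    i  = c(0.28, 0.55, 0.50)
  )
}

#' Generate a bilaterally symmetric vascular-territory atlas
#'
#' Builds a label volume with 10 blood-supply territories per hemisphere
#' inside an ellipsoidal brain mask. The left hemisphere is a jittered
#' Voronoi partition around canonical territory seed points; the right
#' hemisphere is its exact mirror image about the midsagittal grid plane
#' (axis 1), so left and right territory masks are voxel-wise reflections
#' of each other by construction.
#'
#' Labels: left-hemisphere territories are coded 1..10 (canonical
#' [territory_codes()] order), right-hemisphere territories 11..20,
#' background 0.
#'
#' @param grid_shape integer triple of voxels per axis; the first
#'   (left-right) dimension must be even so the symmetry plane is unique.
#' @param spacing_mm voxel size triple in millimetres.
#' @param seed integer seed controlling the territory-seed jitter.
#' @return object of class `territory_atlas`: list with `labels` (integer
#'   3D array), `code_map` (data.frame territory/left/right), `spacing`,
#'   `seed`.
#' @export
generate_atlas <- function(grid_shape = c(32L, 32L, 16L),
                           spacing_mm = c(1.8, 1.8, 4.0),
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 8)) {
    stopf("grid_shape must be three dimensions of at least 8 voxels")
  }
  if (grid_shape[1] %% 2 != 0) {
    stopf("left-right dimension (%d) must be even: no unique symmetry plane", grid_shape[1])
  }
  if (any(spacing_mm <= 0)) stopf("all spacings must be > 0")

  codes <- territory_codes()
  pos <- with_seed(seed, {
    base <- .territory_seed_positions()
    base + matrix(runif(30, -0.03, 0.03), 10, 3)
  })

  d <- grid_shape
  # normalized voxel-center coordinates in [0, 1]
  cx <- (seq_len(d[1]) - 0.5) / d[1]
  cy <- (seq_len(d[2]) - 0.5) / d[2]
  cz <- (seq_len(d[3]) - 0.5) / d[3]
  gx <- array(cx, d)
  gy <- array(rep(cy, each = d[1]), d)
  gz <- array(rep(cz, each = d[1] * d[2]), d)

  brain <- ((gx - 0.5) / 0.45)^2 + ((gy - 0.5) / 0.45)^2 + ((gz - 0.5) / 0.45)^2 <= 1
  left <- gx < 0.5

  labels <- array(0L, d)
  sel <- which(brain & left)
  if (length(sel) == 0) stopf("degenerate grid: empty brain mask")
  dist2 <- sapply(seq_len(10), function(k) {
    (gx[sel] - pos[k, 1])^2 + (gy[sel] - pos[k, 2])^2 + (gz[sel] - pos[k, 3])^2
  })
  labels[sel] <- max.col(-dist2, ties.method = "first")

  # mirror to the right hemisphere with the +10 label offset
  flipped <- labels[d[1]:1, , , drop = FALSE]
  labels[flipped > 0 & labels == 0] <- flipped[flipped > 0 & labels == 0] + 10L

  if (length(setdiff(1:20, unique(as.vector(labels)))) > 0) {
    stopf("atlas generation produced an empty territory; use a larger grid")
  }

  structure(
    list(
      labels = labels,
      code_map = data.frame(territory = codes, left = 1:10, right = 11:20,
                            stringsAsFactors = FALSE),
      spacing = as.numeric(spacing_mm),
      seed = as.integer(seed)
    ),
    class = "territory_atlas"
  )
}

#' @export
print.territory_atlas <- function(x, ...) {
  cat("territory_atlas:", paste(dim(x$labels), collapse = "x"),
      "grid,", sum(x$labels > 0), "brain voxels,",
      length(unique(x$labels[x$labels > 0])), "territory labels\n")
  invisible(x)
}

#' Look up the label volume mask of one territory
#'
#' @param atlas a `territory_atlas`.
#' @param territory territory code (see [territory_codes()]).
#' @param side `"left"` or `"right"`.
#' @return logical 3D array.
#' @export
territory_mask <- function(atlas, territory, side = c("left", "right")) {
  side <- match.arg(side)
  row <- match(territory, atlas$code_map$territory)
  if (is.na(row)) stopf("unknown territory code '%s'", territory)
  atlas$labels == atlas$code_map[[side]][row]
}

#' Merge a fine parcellation into vascular territories
#'
#' Relabels a fine-grained integer parcellation (e.g. an automatic cortical
#' segmentation) into merged territory labels. Every fine label present in
#' the volume must be assigned by `merge_map` to a territory code or to
#' background (`NA`).
#'
#' @param fine_labels integer 3D array of fine parcel labels (0 =
#'   background).
#' @param merge_map named character vector: names are fine labels (as
#'   characters), values are territory codes or `NA` for background.
#' @return list with `labels` (merged integer array) and `code_map`
#'   (data.frame territory/label, labels 1..K in canonical order).
#' @export
merge_labels <- function(fine_labels, merge_map) {
  present <- setdiff(unique(as.vector(fine_labels)), 0L)
  orphans <- setdiff(as.character(present), names(merge_map))
  if (length(orphans) > 0) {
    stopf("fine labels absent from merge_map: %s", paste(orphans, collapse = ", "))
  }
  codes <- unique(merge_map[!is.na(merge_map)])
  canonical <- c(intersect(territory_codes(), codes), setdiff(sort(codes), territory_codes()))
  out <- array(0L, dim(fine_labels))
  for (fl in names(merge_map)) {
    code <- merge_map[[fl]]
    if (is.na(code)) next
    out[fine_labels == as.integer(fl)] <- match(code, canonical)
  }
  if (length(canonical) > 20) stopf("merge_map yields %d territories (> 20)", length(canonical))
  list(
    labels = out,
    code_map = data.frame(territory = canonical, label = seq_along(canonical),
                          stringsAsFactors = FALSE)
  )
}
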