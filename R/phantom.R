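# Synthetic brain phantoms: head-like 3D intensity volumes with bilateral
# hippocampus-like bright ellipsoids whose radius shrinks along the
# NC -> sMCI -> pMCI -> AD axis and a central ventricle-like dark region
# that enlarges along the same axis. Cohorts carry multiple images per
# subject with subject-level morphology jitter.

.CLASS_LABELS <- c("AD", "NC", "sMCI", "pMCI")

#' Phantom generator parameters
#'
#' Controls the morphology and noise of the synthetic volumes. The atrophy
#' factors multiply the hippocampal radius per class (nonincreasing along
#' NC, sMCI, pMCI, AD, so hippocampal volume shrinks as disease
#' progresses); ventricle scales multiply the central ventricle radius
#' (nondecreasing along the same order).
#'
#' @param base_side Native cubic grid side in voxels.
#' @param hippo_radius_mean Hippocampal radius for the NC baseline, in
#'   voxels.
#' @param atrophy_factor Named vector in (0, 1] over the four classes.
#' @param ventricle_scale Named vector (>= 1) over the four classes.
#' @param noise_sd Additive Gaussian intensity noise (intensities live in
#'   `[0, 1]`).
#' @param subject_jitter_sd Standard deviation of the per-subject relative
#'   jitter applied to structure radii.
#' @param seed Integer seed.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(base_side = 96L,
                           hippo_radius_mean = base_side / 12,
                           atrophy_factor = c(NC = 1.0, sMCI = 0.9,
                                              pMCI = 0.8, AD = 0.7),
                           ventricle_scale = c(NC = 1.0, sMCI = 1.1,
                                               pMCI = 1.25, AD = 1.4),
                           noise_sd = 0.05, subject_jitter_sd = 0.02,
                           seed = 1L) {
  stopifnot(base_side >= 16, hippo_radius_mean > 0, noise_sd >= 0,
            subject_jitter_sd >= 0)
  atrophy_factor <- atrophy_factor[.CLASS_LABELS[c(2, 3, 4, 1)]]
  ventricle_scale <- ventricle_scale[.CLASS_LABELS[c(2, 3, 4, 1)]]
  if (any(is.na(atrophy_factor)) || any(is.na(ventricle_scale))) {
    stop("atrophy_factor and ventricle_scale need all four class labels",
         call. = FALSE)
  }
  if (any(diff(atrophy_factor) > 0)) {
    stop("atrophy factors must be nonincreasing along NC, sMCI, pMCI, AD",
         call. = FALSE)
  }
  if (any(diff(ventricle_scale) < 0)) {
    stop("ventricle scales must be nondecreasing along NC, sMCI, pMCI, AD",
         call. = FALSE)
  }
  stopifnot(all(atrophy_factor > 0), all(atrophy_factor <= 1),
            all(ventricle_scale >= 1))
  structure(list(base_side = as.integer(base_side),
                 hippo_radius_mean = hippo_radius_mean,
                 atrophy_factor = atrophy_factor,
                 ventricle_scale = ventricle_scale,
                 noise_sd = noise_sd,
                 subject_jitter_sd = subject_jitter_sd,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

#' A labeled volumetric sample
#'
#' @param voxels 3D numeric array of intensities.
#' @param label One of `"AD"`, `"NC"`, `"sMCI"`, `"pMCI"`.
#' @param subject_id Subject identifier string.
#' @param voxel_spacing Numeric triple of voxel spacings in mm.
#' @return An object of class `volume_sample`.
#' @export
volume_sample <- function(voxels, label, subject_id,
                          voxel_spacing = c(1, 1, 1)) {
  if (!label %in% .CLASS_LABELS) {
    stop("unknown class label: ", label, call. = FALSE)
  }
  stopifnot(is.array(voxels), length(dim(voxels)) == 3,
            all(is.finite(voxels)), length(voxel_spacing) == 3,
            all(voxel_spacing > 0))
  structure(list(voxels = voxels, label = label,
                 subject_id = as.character(subject_id),
                 voxel_spacing = as.numeric(voxel_spacing)),
            class = "volume_sample")
}

#' @export
print.volume_sample <- function(x, ...) {
  cat(sprintf("<volume_sample> %s subject=%s dims=%s spacing=%s mm\n",
              x$label, x$subject_id, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$voxel_spacing, 3), collapse = "x")))
  invisible(x)
}

# squared normalized ellipsoid coordinate field; centers/radii in voxels
.ellipsoid_field <- function(side, center, radii) {
  ax <- seq_len(side)
  dx <- (ax - center[1]) / radii[1]
  dy <- (ax - center[2]) / radii[2]
  dz <- (ax - center[3]) / radii[3]
  outer(outer(dx^2, dy^2, "+"), dz^2, "+")
}

# structure geometry at unit jitter; all coordinates relative to side
.phantom_geometry <- function(side, hippo_radius) {
  c0 <- (side + 1) / 2
  list(
    head = list(center = c(c0, c0, c0),
                radii = side * c(0.42, 0.46, 0.40)),
    hippo_left = list(center = c(c0 - 0.18 * side, c0 - 0.05 * side,
                                 c0 - 0.08 * side),
                      radii = rep(hippo_radius, 3)),
    hippo_right = list(center = c(c0 + 0.18 * side, c0 - 0.05 * side,
                                  c0 - 0.08 * side),
                       radii = rep(hippo_radius, 3)),
    ventricle = list(center = c(c0, c0 + 0.04 * side, c0 + 0.06 * side),
                     radii = side * c(0.10, 0.14, 0.10))
  )
}

#' Generate one brain phantom
#'
#' Draws a head-like ellipsoidal background (intensity 0.5) with two
#' lateral hippocampus-like bright ellipsoids (intensity 0.9) of radius
#' `hippo_radius_mean * atrophy_factor[label] * (1 + jitter)` and a
#' central ventricle-like dark ellipsoid (intensity 0.08) scaled by
#' `ventricle_scale[label]`, adds Gaussian noise of sd `noise_sd` from the
#' current RNG stream, and clips intensities to `[0, 1]`. Identical
#' parameters, label and RNG state give identical volumes.
#'
#' @param params A [phantom_params()].
#' @param label Diagnostic class, one of `"AD"`, `"NC"`, `"sMCI"`,
#'   `"pMCI"`.
#' @param subject_id Identifier stored in the sample.
#' @param subject_jitter Relative radius perturbation for this subject
#'   (drawn once per subject by [generate_cohort()]).
#' @param voxel_spacing Voxel spacing triple (mm).
#' @return A [volume_sample()].
#' @export
generate_brain_phantom <- function(params, label, subject_id = "s1",
                                   subject_jitter = 0,
                                   voxel_spacing = c(1, 1, 1)) {
  stopifnot(inherits(params, "phantom_params"))
  if (!label %in% .CLASS_LABELS) {
    stop("unknown class label: ", label, call. = FALSE)
  }
  side <- params$base_side
  hr <- params$hippo_radius_mean * params$atrophy_factor[[label]] *
    (1 + subject_jitter)
  geo <- .phantom_geometry(side, hr)
  vsc <- params$ventricle_scale[[label]] * (1 + subject_jitter / 2)

  v <- array(0, c(side, side, side))
  head <- .ellipsoid_field(side, geo$head$center, geo$head$radii) <= 1
  v[head] <- 0.5
  hip <- (.ellipsoid_field(side, geo$hippo_left$center,
                           geo$hippo_left$radii) <= 1) |
    (.ellipsoid_field(side, geo$hippo_right$center,
                      geo$hippo_right$radii) <= 1)
  v[hip] <- 0.9
  ven <- .ellipsoid_field(side, geo$ventricle$center,
                          geo$ventricle$radii * vsc) <= 1
  v[ven] <- 0.08

  if (params$noise_sd > 0) {
    v <- v + array(stats::rnorm(side^3, sd = params$noise_sd),
                   c(side, side, side))
  }
  v[v < 0] <- 0
  v[v > 1] <- 1
  volume_sample(v, label, subject_id, voxel_spacing)
}

#' Count bright hippocampus-like voxels
#'
#' Suprathreshold voxel count within the lateral hippocampal regions (a
#' generous bounding mask around the two structure sites). On noiseless
#' phantoms this is the discretized hippocampal volume; the AD/NC ratio
#' approaches the cubed atrophy factor.
#'
#' @param v A [volume_sample()].
#' @param threshold Intensity threshold separating the bright structures
#'   from the 0.5 background.
#' @return Integer voxel count.
#' @export
hippocampal_voxel_count <- function(v, threshold = 0.75) {
  stopifnot(inherits(v, "volume_sample"))
  sum(v$voxels > threshold)
}

#' Resample a volume onto a cubic grid
#'
#' Trilinear interpolation of the input volume onto a `side^3` grid
#' spanning the same physical extent (corner-aligned), with voxel spacing
#' rescaled accordingly. Constant volumes map to constant volumes and the
#' output range never exceeds the input range; resampling at the input's
#' own side is the identity.
#'
#' @param v A [volume_sample()].
#' @param side Target side length (at least 2).
#' @return A resampled [volume_sample()].
#' @export
resample_to_cube <- function(v, side) {
  stopifnot(inherits(v, "volume_sample"), side >= 2)
  d <- dim(v$voxels)
  if (any(d < 2)) stop("degenerate axis: all dims must be >= 2",
                       call. = FALSE)
  side <- as.integer(side)

  coords <- lapply(1:3, function(ax) {
    (seq_len(side) - 1) * (d[ax] - 1) / (side - 1) + 1
  })
  lo <- lapply(seq_along(coords), function(ax) {
    pmin(as.integer(floor(coords[[ax]])), d[ax] - 1L)
  })
  fr <- lapply(seq_along(coords), function(ax) coords[[ax]] - lo[[ax]])

  x0 <- lo[[1]]; y0 <- lo[[2]]; z0 <- lo[[3]]
  fx <- fr[[1]]; fy <- fr[[2]]; fz <- fr[[3]]
  vv <- v$voxels

  out <- array(0, c(side, side, side))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- outer(outer(if (cx) fx else 1 - fx,
                     if (cy) fy else 1 - fy, "*"),
               if (cz) fz else 1 - fz, "*")
    out <- out + w * vv[x0 + cx, y0 + cy, z0 + cz]
  }

  spacing <- v$voxel_spacing * (d - 1) / (side - 1)
  volume_sample(out, v$label, v$subject_id, spacing)
}

#' NIfTI input and output
#'
#' Volumes round-trip through the NIfTI-1 format preserving voxel data,
#' spacing and orientation. Class label and subject id are carried in a
#' sidecar delimited-text manifest (see [write_cohort()]); `read_volume()`
#' looks them up when a manifest is supplied.
#'
#' @param v A [volume_sample()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns a [volume_sample()].
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume_sample"))
  vox <- v$voxels
  attr(vox, "pixdim") <- v$voxel_spacing
  RNifti::writeNifti(RNifti::asNifti(vox, datatype = "double"), path)
  invisible(path)
}

#' @rdname write_volume
#' @param manifest Optional manifest: a data frame with columns
#'   `subject_id`, `label`, `path`, or the path of such a tab-separated
#'   file. When given, label and subject id are restored from it (error if
#'   the volume is absent from the manifest).
#' @export
read_volume <- function(path, manifest = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim(img))
  spacing <- RNifti::pixdim(img)[1:3]
  label <- "NC"; subject_id <- basename(path)
  if (!is.null(manifest)) {
    if (is.character(manifest)) {
      manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
    }
    hit <- which(basename(manifest$path) == basename(path))
    if (length(hit) != 1) {
      stop("volume not listed (or listed twice) in the manifest: ", path,
           call. = FALSE)
    }
    label <- manifest$label[hit]
    subject_id <- manifest$subject_id[hit]
  }
  volume_sample(vox, label, subject_id, spacing)
}

#' Generate a labeled cohort of phantoms
#'
#' For each subject, a subject-level morphology jitter is drawn once; each
#' of the subject's images then adds small per-image jitter and fresh
#' intensity noise, so images of the same subject correlate more strongly
#' than images of different subjects. Default class counts follow the
#' 78/100/117/53 AD/NC/sMCI/pMCI cohort proportions scaled to desk size.
#'
#' @param params A [phantom_params()].
#' @param subjects_per_class Named integer vector of subject counts (any
#'   subset of the four classes).
#' @param images_per_subject Images per subject.
#' @param seed Integer seed (defaults to `params$seed`).
#' @return An object of class `cohort`: a list with `samples` (list of
#'   [volume_sample()]), `manifest` (tibble with `subject_id`, `label`,
#'   `image`), and `counts`.
#' @export
generate_cohort <- function(params,
                            subjects_per_class = c(AD = 8, NC = 10,
                                                   sMCI = 12, pMCI = 5),
                            images_per_subject = 3L, seed = params$seed) {
  stopifnot(inherits(params, "phantom_params"),
            all(names(subjects_per_class) %in% .CLASS_LABELS),
            all(subjects_per_class >= 1), images_per_subject >= 1)
  set.seed(seed)
  samples <- list()
  rows <- list()
  k <- 0L
  for (cls in names(subjects_per_class)) {
    for (s in seq_len(subjects_per_class[[cls]])) {
      sid <- sprintf("%s_s%02d", cls, s)
      sj <- stats::rnorm(1, sd = params$subject_jitter_sd)
      for (im in seq_len(images_per_subject)) {
        ij <- stats::rnorm(1, sd = params$subject_jitter_sd / 5)
        v <- generate_brain_phantom(params, cls, sid,
                                    subject_jitter = sj + ij)
        k <- k + 1L
        samples[[k]] <- v
        rows[[k]] <- tibble::tibble(subject_id = sid, label = cls,
                                    image = sprintf("%s_i%02d", sid, im))
      }
    }
  }
  manifest <- do.call(rbind, rows)
  structure(list(samples = samples, manifest = manifest,
                 counts = table(manifest$label)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d images, %d subjects\n", length(x$samples),
              length(unique(x$manifest$subject_id))))
  print(x$counts)
  invisible(x)
}

#' Resample every volume of a cohort
#'
#' The preprocessing step that makes the dataset image-based: every volume
#' is reshaped onto a `side^3` cube by trilinear interpolation.
#'
#' @param cohort A [generate_cohort()] cohort.
#' @param side Target cube side.
#' @return The cohort with all volumes resampled.
#' @export
preprocess_cohort <- function(cohort, side) {
  stopifnot(inherits(cohort, "cohort"))
  cohort$samples <- lapply(cohort$samples, resample_to_cube, side = side)
  cohort
}

#' Write a cohort to disk (NIfTI volumes plus manifest)
#'
#' @param cohort A cohort.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(cohort$samples))
  for (i in seq_along(cohort$samples)) {
    paths[i] <- file.path(dir, paste0(cohort$manifest$image[i], ".nii.gz"))
    write_volume(cohort$samples[[i]], paths[i])
  }
  mf <- cohort$manifest
  mf$path <- paths
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(mf, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest_path Path to the manifest file.
#' @return A cohort.
#' @export
read_cohort <- function(manifest_path) {
  mf <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(mf)), function(i) {
    v <- read_volume(mf$path[i])
    v$label <- mf$label[i]
    v$subject_id <- mf$subject_id[i]
    v
  })
  structure(list(samples = samples,
                 manifest = tibble::as_tibble(mf[c("subject_id", "label",
                                                   "image")]),
                 counts = table(mf$label)),
            class = "cohort")
}
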