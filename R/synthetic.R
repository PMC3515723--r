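#' Synthetic PET rCBF study generator
#'
#' Generates a complete synthetic study -- ROI masks, per-scan volumes,
#' a scan manifest and a clinical score table -- with recorded ground truth,
#' emulating a three-session (off-drug baseline, week one, week six),
#' three-condition (rest, sensorimotor control, auditory decision) H215O PET
#' design with two replicate scans per condition. Each scan's regional latent
#' signals are drawn from a session-specific inter-region correlation matrix,
#' a shared global signal is added over a brain ellipsoid, and iid voxel noise
#' (optionally Gaussian-smoothed) completes the image. One designated edge's
#' per-participant connectivity drives a planted linear clinical response.
#'
#' @name synthetic-cohort
NULL

#' Region specification
#'
#' @param name region label, e.g. `"MFC"`.
#' @param center_mm MNI mm coordinates of the region centre.
#' @param radius_or_halfwidth_mm sphere radius or box half-width, in mm.
#' @param shape `"sphere"` or `"box"`.
#' @return A `region_spec` list.
#' @export
region_spec <- function(name, center_mm, radius_or_halfwidth_mm,
                        shape = c("sphere", "box")) {
  shape <- match.arg(shape)
  stopifnot(length(center_mm) == 3L, radius_or_halfwidth_mm >= 0)
  structure(list(name = name, shape = shape,
                 center_mm = as.numeric(center_mm),
                 radius_or_halfwidth_mm = as.numeric(radius_or_halfwidth_mm)),
            class = "region_spec")
}

.default_regions <- function() {
  list(
    region_spec("MFC",   c(-1, 47, -4),    10),  # 10-mm medial frontal sphere
    region_spec("LNAcc", c(-10, 10, -8),    6),
    region_spec("RNAcc", c(10, 10, -8),     6),
    region_spec("LHIP",  c(-28, -20, -12), 10),
    region_spec("RHIP",  c(28, -20, -12),  10)
  )
}

# Published combined-task inter-region correlation patterns, one matrix per
# session, used as the default planted connectivity (order MFC, LNAcc, RNAcc,
# LHIP, RHIP). All three are positive definite.
.default_session_corr <- function() {
  nm <- c("MFC", "LNAcc", "RNAcc", "LHIP", "RHIP")
  mk <- function(v) {
    m <- diag(5)
    m[lower.tri(m)] <- v
    m <- m + t(m) - diag(5)
    dimnames(m) <- list(nm, nm)
    m
  }
  list(
    SZ0 = mk(c(0.339, -0.018, 0.344, 0.477, 0.262, 0.304, 0.092,
               -0.115, -0.277, 0.740)),
    SZ1 = mk(c(0.573, 0.023, 0.329, 0.056, 0.249, 0.383, 0.122,
               -0.163, -0.400, 0.716)),
    SZ6 = mk(c(0.222, 0.104, 0.068, -0.126, 0.391, 0.443, 0.096,
               -0.057, -0.553, 0.666))
  )
}

.default_affine <- function(grid_shape, voxel_size_mm, origin_vox = NULL) {
  # origin_vox: 0-based voxel index mapping to mm (0,0,0)
  if (is.null(origin_vox)) origin_vox <- floor(grid_shape / 2)
  aff <- diag(4)
  diag(aff)[1:3] <- voxel_size_mm
  aff[1:3, 4] <- -origin_vox * voxel_size_mm
  aff
}

#' Synthetic study configuration
#'
#' Defaults mirror the emulated study: a 48 x 56 x 48 grid at 2 mm isotropic
#' spacing centred on MNI (0,0,0); five regions (MFC, bilateral NAcc,
#' bilateral hippocampus); three sessions (SZ0, SZ1, SZ6) whose inter-region
#' correlation matrices follow the published combined-task connectivity
#' pattern; three conditions with two replicates each; 29 participants.
#'
#' @param grid_shape length-3 voxel counts.
#' @param voxel_size_mm isotropic voxel spacing in mm.
#' @param regions list of [region_spec()] objects.
#' @param session_edge_corr named list (one per session) of symmetric positive
#'   definite correlation matrices over the regions.
#' @param global_sd sd of the additive whole-brain signal.
#' @param noise_sd sd of iid voxel noise.
#' @param smooth_fwhm_mm generation-time Gaussian smoothing FWHM (0 = none).
#' @param n_participants participant count.
#' @param sessions ordered session labels.
#' @param conditions ordered condition labels.
#' @param replicates_per_condition scans per condition per session.
#' @param response_edge length-2 region names carrying the planted
#'   clinical-response association.
#' @param response_session session whose edge signal drives response.
#' @param response_effect slope linking the participant mean edge signal
#'   product to the baseline-to-week-six clinical score change.
#' @param response_intercept mean clinical improvement.
#' @param response_noise_sd sd of the clinical score change noise.
#' @param origin_vox 0-based voxel index mapped to MNI (0,0,0); the default
#'   for the standard grid places the field of view so all default regions
#'   (including the frontal sphere reaching y = 57 mm) fit; `NULL` centres
#'   the grid.
#' @param brain_center_mm centre of the whole-brain ellipsoid.
#' @param brain_semiaxes_mm semi-axes of the whole-brain ellipsoid.
#' @param seed integer RNG seed; fixed seed implies byte-identical outputs.
#' @return A `synth_config` list.
#' @export
synth_config <- function(grid_shape = c(48L, 56L, 48L),
                         voxel_size_mm = 2,
                         regions = .default_regions(),
                         session_edge_corr = NULL,
                         global_sd = 0.5,
                         noise_sd = 1,
                         smooth_fwhm_mm = 0,
                         n_participants = 29L,
                         sessions = c("SZ0", "SZ1", "SZ6"),
                         conditions = c("rest", "SMC", "DEC"),
                         replicates_per_condition = 2L,
                         response_edge = c("MFC", "LHIP"),
                         response_session = "SZ1",
                         response_effect = 5,
                         response_intercept = 6,
                         response_noise_sd = 4,
                         origin_vox = c(24L, 25L, 24L),
                         brain_center_mm = c(0, 5, -4),
                         brain_semiaxes_mm = c(46, 55, 42),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L), voxel_size_mm > 0)
  region_names <- vapply(regions, `[[`, "", "name")
  if (anyDuplicated(region_names)) stop("duplicate region names")
  if (is.null(session_edge_corr)) {
    base <- .default_session_corr()
    if (length(regions) == 5L && identical(region_names, colnames(base[[1]]))) {
      session_edge_corr <- base[seq_along(sessions)]
      names(session_edge_corr) <- sessions
    } else {
      session_edge_corr <- stats::setNames(
        rep(list(diag(length(regions))), length(sessions)), sessions)
    }
  }
  if (!setequal(names(session_edge_corr), sessions))
    stop("session_edge_corr must be named by session")
  for (s in sessions) {
    m <- session_edge_corr[[s]]
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
      stop("session_edge_corr[['", s, "']] is not symmetric")
    if (any(abs(diag(m) - 1) > 1e-8))
      stop("session_edge_corr[['", s, "']] must have unit diagonal")
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("session_edge_corr[['", s, "']] is not positive definite")
  }
  if (!all(response_edge %in% region_names))
    stop("response_edge names unknown regions")
  if (!response_session %in% sessions) stop("unknown response_session")
  structure(list(
    grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
    affine = .default_affine(grid_shape, voxel_size_mm, origin_vox),
    regions = regions, region_names = region_names,
    session_edge_corr = session_edge_corr,
    global_sd = global_sd, noise_sd = noise_sd,
    smooth_fwhm_mm = smooth_fwhm_mm,
    n_participants = as.integer(n_participants),
    sessions = sessions, conditions = conditions,
    replicates_per_condition = as.integer(replicates_per_condition),
    response_edge = response_edge, response_session = response_session,
    response_effect = response_effect,
    response_intercept = response_intercept,
    response_noise_sd = response_noise_sd,
    brain_center_mm = brain_center_mm,
    brain_semiaxes_mm = brain_semiaxes_mm,
    seed = as.integer(seed)), class = "synth_config")
}

#' ROI mask constructor
#' @param name label.
#' @param mask logical 3D array.
#' @param affine 4x4 voxel-to-mm matrix.
#' @param provenance free-form description of how the mask was built.
#' @return An `roi_mask`.
#' @export
roi_mask <- function(name, mask, affine, provenance = NULL) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("mask '", name, "' is empty")
  structure(list(name = name, mask = mask, affine = as.matrix(affine),
                 provenance = provenance), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s: %d voxels\n", x$name, sum(x$mask)))
  invisible(x)
}

#' Generate ROI masks plus a whole-brain mask
#'
#' Builds one mask per region (sphere: voxel centres within the radius of the
#' centre; box: within the half-width on every axis) and a whole-brain
#' ellipsoid mask, all sharing the configured grid and affine. Regions must
#' lie inside the grid and be pairwise disjoint.
#'
#' @param config a [synth_config()].
#' @return Named list of `roi_mask` objects; the whole-brain mask is named
#'   `"brain"`.
#' @export
generate_masks <- function(config) {
  d <- config$grid_shape
  coords <- voxel_coords_mm(d, config$affine)
  lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)

  masks <- list()
  for (rg in config$regions) {
    r <- rg$radius_or_halfwidth_mm
    if (any(rg$center_mm - r < lo - config$voxel_size_mm / 2) ||
        any(rg$center_mm + r > hi + config$voxel_size_mm / 2))
      stop("region '", rg$name, "' extends outside the grid")
    delta <- sweep(coords, 2, rg$center_mm)
    inside <- if (rg$shape == "sphere") {
      sqrt(rowSums(delta^2)) <= r
    } else {
      apply(abs(delta) <= r, 1, all)
    }
    if (!any(inside)) stop("region '", rg$name, "' contains no voxels")
    masks[[rg$name]] <- roi_mask(
      rg$name, array(inside, dim = d), config$affine,
      provenance = sprintf("%s r=%gmm at (%s)", rg$shape, r,
                           paste(rg$center_mm, collapse = ", ")))
  }

  counts <- Reduce(`+`, lapply(masks, function(m) as.integer(m$mask)))
  if (any(counts > 1L)) {
    offender <- which(counts > 1L)[1]
    inv <- vapply(masks, function(m) m$mask[offender], logical(1))
    stop("regions overlap: ", paste(names(which(inv)), collapse = " and "))
  }

  br <- sweep(coords, 2, config$brain_center_mm)
  br <- sweep(br, 2, config$brain_semiaxes_mm, `/`)
  masks[["brain"]] <- roi_mask("brain", array(rowSums(br^2) <= 1, dim = d),
                               config$affine, provenance = "brain ellipsoid")
  for (nm in config$region_names)
    if (any(masks[[nm]]$mask & !masks[["brain"]]$mask))
      stop("region '", nm, "' leaves the brain ellipsoid")
  masks
}

.edge_index <- function(region_names, edge) {
  match(edge, region_names)
}

#' Generate a full synthetic cohort
#'
#' For each participant x session x condition x replicate, one volume is
#' built as the sum of the scan's regional latent signals over the region
#' masks, a global signal over the brain ellipsoid, and iid voxel noise,
#' optionally Gaussian-smoothed. Latents are zero-mean unit-variance
#' multivariate normal with the session's inter-region correlation matrix.
#' The clinical table plants `change = intercept + effect * mean edge signal
#' product + noise` on the configured edge and session.
#'
#' @param config a [synth_config()].
#' @param out_dir directory for NIfTI files; `NULL` keeps volumes in memory
#'   (list of `rcbf_volume`), which is much faster for simulations.
#' @param masks optional precomputed [generate_masks()] result.
#' @return List with `manifest` (data.frame: participant, session, condition,
#'   replicate, path), `clinical` (participant, bprs_psychosis_baseline,
#'   bprs_psychosis_week6), `ground_truth` (latent matrix, the correlation
#'   matrices used, planted slope, per-participant mean edge products),
#'   `masks`, and `volumes` (named by scan id when `out_dir` is `NULL`).
#' @export
generate_cohort <- function(config, out_dir = NULL, masks = NULL) {
  if (is.null(masks)) masks <- generate_masks(config)
  set.seed(config$seed)

  rn <- config$region_names
  chol_by_session <- lapply(config$session_edge_corr, chol)
  scans <- expand.grid(replicate = seq_len(config$replicates_per_condition),
                       condition = config$conditions,
                       session = config$sessions,
                       participant = sprintf("P%02d", seq_len(config$n_participants)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  scans <- scans[, c("participant", "session", "condition", "replicate")]
  n_scan <- nrow(scans)

  latents <- matrix(NA_real_, n_scan, length(rn), dimnames = list(NULL, rn))
  d <- config$grid_shape
  nvox <- prod(d)
  region_idx <- lapply(masks[rn], function(m) which(m$mask))
  brain_idx <- which(masks$brain$mask)

  volumes <- if (is.null(out_dir)) vector("list", n_scan) else NULL
  paths <- rep(NA_character_, n_scan)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  globals <- numeric(n_scan)
  for (i in seq_len(n_scan)) {
    ses <- scans$session[i]
    lat <- drop(rnorm(length(rn)) %*% chol_by_session[[ses]])
    g <- if (config$global_sd > 0) rnorm(1, sd = config$global_sd) else 0
    latents[i, ] <- lat
    globals[i] <- g
    vol <- if (config$noise_sd > 0)
      array(rnorm(nvox, sd = config$noise_sd), dim = d) else array(0, dim = d)
    for (r in seq_along(rn))
      vol[region_idx[[r]]] <- vol[region_idx[[r]]] + lat[r]
    vol[brain_idx] <- vol[brain_idx] + g
    if (config$smooth_fwhm_mm > 0)
      vol <- smooth_array(vol, config$smooth_fwhm_mm,
                          voxel_sizes(config$affine))
    key <- scans[i, ]
    if (is.null(out_dir)) {
      volumes[[i]] <- rcbf_volume(vol, config$affine, scan_key = as.list(key))
    } else {
      fn <- sprintf("%s_%s_%s_%d.nii.gz", key$participant, key$session,
                    key$condition, key$replicate)
      paths[i] <- file.path(out_dir, fn)
      write_nifti(rcbf_volume(vol, config$affine, scan_key = as.list(key)),
                  paths[i])
    }
  }
  scans$path <- paths
  scan_id <- sprintf("%s_%s_%s_%d", scans$participant, scans$session,
                     scans$condition, scans$replicate)
  if (is.null(out_dir)) names(volumes) <- scan_id

  # clinical response: planted on the designated edge at the designated session
  ei <- .edge_index(rn, config$response_edge)
  sel <- scans$session == config$response_session
  prod_scan <- latents[sel, ei[1]] * latents[sel, ei[2]]
  mean_prod <- tapply(prod_scan, scans$participant[sel], mean)
  pid <- sprintf("P%02d", seq_len(config$n_participants))
  mean_prod <- as.numeric(mean_prod[pid])
  change <- config$response_intercept +
    config$response_effect * mean_prod +
    rnorm(config$n_participants, sd = config$response_noise_sd)
  baseline <- round(rnorm(config$n_participants, mean = 14, sd = 3), 1)
  clinical <- data.frame(participant = pid,
                         bprs_psychosis_baseline = baseline,
                         bprs_psychosis_week6 = baseline - change,
                         stringsAsFactors = FALSE)

  list(manifest = scans,
       clinical = clinical,
       ground_truth = list(latent_signals = latents,
                           global_signals = globals,
                           true_edge_corr = config$session_edge_corr,
                           true_response_slope = config$response_effect,
                           mean_edge_product = stats::setNames(mean_prod, pid),
                           per_participant_scores = clinical),
       masks = masks,
       volumes = volumes)
}

#' Write manifest and clinical tables as tab-delimited text
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory.
#' @return Paths of the two files, invisibly.
#' @export
write_cohort_tables <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mp <- file.path(dir, "manifest.tsv")
  cp <- file.path(dir, "clinical.tsv")
  utils::write.table(cohort$manifest, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$clinical, cp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(manifest = mp, clinical = cp))
}
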