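#' ROI signal extraction
#'
#' Functions taking preprocessed volumes and masks to the analysis-unit x
#' region eigenvariate table plus the whole-brain ("total intracranial
#' activation") covariate.
#'
#' @name roi-signals
NULL

.fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

.gauss_kernel_matrix <- function(n, sigma_vox) {
  # n x n zero-padded convolution operator with a truncated (4 sigma),
  # unit-sum Gaussian kernel
  if (sigma_vox == 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1L & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + w[off + r + 1L]
  }
  K
}

#' Gaussian smoothing of a 3D array
#'
#' Separable per-axis convolution with a Gaussian of the stated full width at
#' half maximum; `sigma_voxels = fwhm_mm / (voxel_size * 2 sqrt(2 ln 2))` per
#' axis (anisotropic spacings handled per axis). The kernel is truncated at
#' 4 sigma and zero-padded at the grid boundary. `fwhm_mm = 0` is the
#' identity.
#'
#' @param x 3D numeric array.
#' @param fwhm_mm smoothing FWHM in mm (scalar, >= 0).
#' @param voxel_size_mm per-axis voxel spacings (recycled to length 3).
#' @return Smoothed array of the same shape.
#' @export
smooth_array <- function(x, fwhm_mm, voxel_size_mm) {
  stopifnot(length(dim(x)) == 3L)
  if (length(fwhm_mm) != 1L || !is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("fwhm_mm must be a single non-negative number")
  if (fwhm_mm == 0) return(x)
  vs <- rep_len(voxel_size_mm, 3L)
  d <- dim(x)
  out <- x
  for (ax in 1:3) {
    sigma <- .fwhm_to_sigma(fwhm_mm) / vs[ax]
    K <- .gauss_kernel_matrix(d[ax], sigma)
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(out, perm), nrow = d[ax])
    m <- K %*% m
    out <- aperm(array(m, dim = d[perm]), order(perm))
  }
  out
}

#' Gaussian smoothing of a volume
#'
#' @param volume an [rcbf_volume()].
#' @param fwhm_mm smoothing FWHM in mm.
#' @return A smoothed `rcbf_volume` on the same grid.
#' @export
smooth_volume <- function(volume, fwhm_mm) {
  stopifnot(inherits(volume, "rcbf_volume"))
  rcbf_volume(smooth_array(volume$data, fwhm_mm, voxel_sizes(volume$affine)),
              volume$affine, scan_key = volume$scan_key)
}

.load_volume <- function(manifest_row, volumes) {
  id <- sprintf("%s_%s_%s_%d", manifest_row$participant, manifest_row$session,
                manifest_row$condition, manifest_row$replicate)
  if (!is.null(volumes) && id %in% names(volumes)) return(volumes[[id]])
  if (is.na(manifest_row$path))
    stop("scan ", id, " has no in-memory volume and no path")
  read_nifti(manifest_row$path, scan_key = as.list(manifest_row))
}

#' Stack scans into per-group 4D matrices
#'
#' Groups the manifest by session (optionally per condition), combines
#' replicate scans within each participant x session x condition cell
#' (voxelwise average by default), and flattens each group's volumes into a
#' units x voxels matrix with row bookkeeping. The `"session_combined"`
#' grouping concatenates the per-condition analysis units of one session, the
#' "all tasks" pooling used for combined connectivity tables.
#'
#' @param manifest data.frame with participant, session, condition, replicate
#'   and path columns.
#' @param volumes optional named list of in-memory `rcbf_volume`s (names
#'   `participant_session_condition_replicate`); scans not found here are
#'   read from `path`.
#' @param group_by `"session_condition"` or `"session_combined"`.
#' @param use_replicates `"average"` (default) or `"first"`.
#' @return Named list of stacks; each stack has `data` (units x voxels),
#'   `units` (data.frame), `dim`, `affine`.
#' @export
stack_scans <- function(manifest, volumes = NULL,
                        group_by = c("session_condition", "session_combined"),
                        use_replicates = c("average", "first")) {
  group_by <- match.arg(group_by)
  use_replicates <- match.arg(use_replicates)
  req <- c("participant", "session", "condition", "replicate")
  if (!all(req %in% names(manifest))) stop("manifest lacks required columns")
  if (!"path" %in% names(manifest)) manifest$path <- NA_character_

  cells <- unique(manifest[, c("participant", "session", "condition")])
  ref_dim <- NULL; ref_aff <- NULL
  unit_rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- manifest$participant == cells$participant[i] &
      manifest$session == cells$session[i] &
      manifest$condition == cells$condition[i]
    rows <- manifest[sel, , drop = FALSE]
    rows <- rows[order(rows$replicate), , drop = FALSE]
    if (use_replicates == "first") rows <- rows[1, , drop = FALSE]
    vols <- lapply(seq_len(nrow(rows)),
                   function(j) .load_volume(rows[j, ], volumes))
    for (v in vols) {
      if (is.null(ref_dim)) { ref_dim <- dim(v$data); ref_aff <- v$affine }
      if (!identical(dim(v$data), ref_dim) ||
          !isTRUE(all.equal(v$affine, ref_aff)))
        stop("grid/affine mismatch at scan ",
             paste(unlist(v$scan_key), collapse = "/"))
    }
    acc <- Reduce(`+`, lapply(vols, function(v) as.vector(v$data)))
    unit_rows[[i]] <- acc / length(vols)
  }

  keys <- if (group_by == "session_condition")
    paste(cells$session, cells$condition, sep = ".") else cells$session
  stacks <- list()
  for (k in unique(keys)) {
    idx <- which(keys == k)
    stacks[[k]] <- list(
      data = do.call(rbind, unit_rows[idx]),
      units = cells[idx, , drop = FALSE],
      dim = ref_dim, affine = ref_aff)
  }
  stacks
}

#' Recover one unit's volume from a stack
#' @param stack a [stack_scans()] element.
#' @param i unit (row) index.
#' @return 3D array.
#' @export
unstack_scan <- function(stack, i) {
  array(stack$data[i, ], dim = stack$dim)
}

#' First eigenvariate of a masked stack
#'
#' Column-mean-centres the units x masked-voxels matrix across units, takes
#' the projection on the first right singular vector (computed through the
#' units x units Gram matrix), rescales to unit population variance, and
#' fixes the sign so the result correlates non-negatively with the mask mean
#' signal. Deterministic for fixed input.
#'
#' @param stack a [stack_scans()] element (or any list with a `data` units x
#'   voxels matrix).
#' @param mask an [roi_mask()] (or logical array / integer index vector).
#' @return Numeric vector, one standardized signal value per unit.
#' @export
extract_eigenvariate <- function(stack, mask) {
  idx <- if (inherits(mask, "roi_mask")) which(mask$mask)
         else if (is.logical(mask)) which(mask)
         else as.integer(mask)
  if (length(idx) == 0L) stop("mask is empty")
  Y <- stack$data[, idx, drop = FALSE]
  n <- nrow(Y)
  if (n < 2L) stop("need at least 2 units to extract an eigenvariate")
  Yc <- sweep(Y, 2, colMeans(Y))
  K <- tcrossprod(Yc)
  e <- eigen(K, symmetric = TRUE)
  if (e$values[1] <= max(1e-12, 1e-12 * sum(abs(diag(K)))))
    stop("masked data are constant across units; eigenvariate undefined")
  u <- e$vectors[, 1]
  s <- u / sqrt(mean(u^2))           # population-sd standardization
  msig <- rowMeans(Y)
  align <- sum(s * (msig - mean(msig)))
  if (align < 0) s <- -s
  else if (align == 0 && s[which(s != 0)[1]] < 0) s <- -s
  s
}

#' Whole-brain covariate (total intracranial activation)
#'
#' Same eigenvariate operator applied to the whole-brain mask.
#'
#' @inheritParams extract_eigenvariate
#' @return Numeric vector of standardized global signal values per unit.
#' @export
extract_global <- function(stack, mask) {
  extract_eigenvariate(stack, mask)
}

#' Build the analysis-unit x region eigenvariate table
#'
#' @param stacks [stack_scans()] result (any grouping; rows concatenate over
#'   stacks).
#' @param masks named mask list including a `"brain"` entry.
#' @param regions region names to extract; defaults to all non-brain masks.
#' @return data.frame: participant, session, condition, one column per
#'   region, and `global`.
#' @export
eigenvariate_table <- function(stacks, masks, regions = NULL) {
  if (is.null(regions)) regions <- setdiff(names(masks), "brain")
  if (!"brain" %in% names(masks)) stop("masks must include 'brain'")
  out <- lapply(stacks, function(st) {
    tab <- st$units
    for (r in regions) tab[[r]] <- extract_eigenvariate(st, masks[[r]])
    tab$global <- extract_global(st, masks$brain)
    tab
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write an eigenvariate table as tab-delimited text
#' @param table [eigenvariate_table()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eigenvariate_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
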