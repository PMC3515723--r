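#' Voxelwise paired contrasts with permutation cluster inference
#'
#' Paired-t maps between sessions and cluster-level inference with a
#' sign-flip permutation null on maximum cluster extent, an assumption-light
#' emulation of random-field cluster FDR.
#'
#' @name voxelwise-maps
NULL

.match_pairs <- function(stack_A, stack_B) {
  ka <- paste(stack_A$units$participant, stack_A$units$condition, sep = ".")
  kb <- paste(stack_B$units$participant, stack_B$units$condition, sep = ".")
  common <- intersect(ka, kb)
  orphans <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(orphans) > 0)
    stop("unmatched units between sessions: ",
         paste(orphans, collapse = ", "))
  list(ia = match(common, ka), ib = match(common, kb))
}

#' Paired-difference matrix between two stacks
#'
#' @param stack_A,stack_B [stack_scans()] elements; units matched by
#'   participant (and condition).
#' @return pairs x voxels matrix of B - A differences.
#' @export
paired_differences <- function(stack_A, stack_B) {
  if (!identical(stack_A$dim, stack_B$dim)) stop("grid mismatch between stacks")
  m <- .match_pairs(stack_A, stack_B)
  if (length(m$ia) < 3L) stop("need at least 3 matched pairs")
  stack_B$data[m$ib, , drop = FALSE] - stack_A$data[m$ia, , drop = FALSE]
}

.t_from_diff <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  ss <- colSums(D^2) - n * m^2
  s2 <- pmax(ss, 0) / (n - 1)
  se <- sqrt(s2 / n)
  t <- m / se
  zero <- se == 0
  if (any(zero)) {
    t[zero & m == 0] <- 0
    t[zero & m > 0] <- Inf
    t[zero & m < 0] <- -Inf
  }
  t
}

#' Voxelwise paired-t map between two sessions
#'
#' Per-voxel one-sample t of the paired B - A differences. Voxels where the
#' difference is exactly constant zero get t = 0 (with a warning); voxels
#' outside `mask` (if given) are NA.
#'
#' @param stack_A,stack_B [stack_scans()] elements (e.g. baseline and week
#'   one); units matched by participant and condition.
#' @param mask optional [roi_mask()] restricting the map (e.g. whole brain).
#' @return 3D array of t values.
#' @export
paired_t_map <- function(stack_A, stack_B, mask = NULL) {
  D <- paired_differences(stack_A, stack_B)
  t <- .t_from_diff(D)
  if (any(colSums(D^2) == 0))
    warning("constant-zero difference at some voxels; t set to 0 there")
  tm <- array(t, dim = stack_A$dim)
  if (!is.null(mask)) tm[!mask$mask] <- NA_real_
  tm
}

#' Face-connected suprathreshold clusters
#'
#' Maximal 6-connected (face-adjacent) components of `{t > thr}` (positive
#' sign) or `{t < -thr}` (negative sign), ordered by extent (descending) then
#' by peak voxel coordinates. Diagonal contact does not join clusters.
#'
#' @param t_map 3D array (NAs treated as subthreshold).
#' @param forming_threshold positive primary threshold on |t|.
#' @param sign `"pos"` or `"neg"`.
#' @param affine optional 4x4 matrix to report peak mm coordinates.
#' @return data.frame: cluster, k_E, peak_i/j/k (1-based voxel), peak_t, and
#'   peak_x/y/z_mm when an affine is supplied. Zero rows when nothing
#'   survives.
#' @export
find_clusters <- function(t_map, forming_threshold, sign = c("pos", "neg"),
                          affine = NULL) {
  sign <- match.arg(sign)
  if (forming_threshold <= 0) stop("forming_threshold must be positive")
  d <- dim(t_map)
  supra <- if (sign == "pos") which(!is.na(t_map) & t_map > forming_threshold)
           else which(!is.na(t_map) & t_map < -forming_threshold)
  empty <- data.frame(cluster = integer(0), k_E = integer(0),
                      peak_i = integer(0), peak_j = integer(0),
                      peak_k = integer(0), peak_t = numeric(0))
  if (length(supra) == 0L) {
    if (!is.null(affine))
      empty$peak_x_mm <- empty$peak_y_mm <- empty$peak_z_mm <- numeric(0)
    return(empty)
  }

  lab <- integer(length(supra))
  names(lab) <- supra
  pos <- match(supra, supra)          # identity; lookup by voxel index below
  in_supra <- integer(prod(d))
  in_supra[supra] <- seq_along(supra)
  strides <- c(1L, d[1], d[1] * d[2])

  cur <- 0L
  comp <- integer(length(supra))
  for (s in seq_along(supra)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- supra[queue[1]]
      queue <- queue[-1]
      vi <- arrayInd(v, d)
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        ni <- vi[ax] + dd
        if (ni < 1L || ni > d[ax]) next
        nb <- v + dd * strides[ax]
        sidx <- in_supra[nb]
        if (sidx != 0L && comp[sidx] == 0L) {
          comp[sidx] <- cur
          queue <- c(queue, sidx)
        }
      }
    }
  }

  rows <- lapply(seq_len(cur), function(cid) {
    vox <- supra[comp == cid]
    tv <- t_map[vox]
    peak <- vox[which.max(abs(tv))]
    pi <- arrayInd(peak, d)
    data.frame(cluster = cid, k_E = length(vox),
               peak_i = pi[1], peak_j = pi[2], peak_k = pi[3],
               peak_t = t_map[peak])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$k_E, out$peak_i, out$peak_j, out$peak_k), , drop = FALSE]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (!is.null(affine)) {
    mm <- t(affine[1:3, 1:3] %*%
              t(cbind(out$peak_i, out$peak_j, out$peak_k) - 1) + affine[1:3, 4])
    out$peak_x_mm <- mm[, 1]; out$peak_y_mm <- mm[, 2]; out$peak_z_mm <- mm[, 3]
  }
  out
}

.max_extent <- function(t, thr, d, sign) {
  cl <- find_clusters(array(t, dim = d), thr, sign = sign)
  if (nrow(cl) == 0L) 0L else max(cl$k_E)
}

#' Cluster-level inference by sign-flip permutation
#'
#' Builds the null distribution of the maximum cluster extent by randomly
#' sign-flipping the per-pair difference images, assigns each observed
#' cluster `p = (1 + #(null max extent >= k_E)) / (1 + n_permutations)`, and
#' applies the Benjamini-Hochberg step-up across the observed clusters of
#' each sign separately. When `2^pairs < n_permutations` the sign patterns
#' are enumerated exhaustively instead (and a message is emitted).
#'
#' @param stack_A,stack_B [stack_scans()] elements; pairs matched by
#'   participant and condition.
#' @param forming_threshold primary t threshold; default corresponds to a
#'   two-sided voxelwise p < 0.001 at the paired df.
#' @param n_permutations number of random sign flips (>= 100).
#' @param seed RNG seed for the permutation stream.
#' @param mask optional brain mask.
#' @param signs which cluster signs to test.
#' @return A `cluster_map`: list with `t_map`, `clusters` (per-sign
#'   data.frame with k_E, peak coordinates, p and p_adjusted),
#'   `forming_threshold`, `n_permutations`, `n_pairs`, `exhaustive`, `seed`.
#' @export
cluster_fdr <- function(stack_A, stack_B, forming_threshold = NULL,
                        n_permutations = 1000L, seed = 1L, mask = NULL,
                        signs = c("pos", "neg")) {
  if (n_permutations < 100L) stop("need at least 100 permutations")
  D <- paired_differences(stack_A, stack_B)
  n <- nrow(D)
  d <- stack_A$dim
  if (is.null(forming_threshold))
    forming_threshold <- stats::qt(1 - 0.001 / 2, df = n - 1)
  keep <- if (!is.null(mask)) which(mask$mask) else seq_len(ncol(D))

  t_obs_full <- rep(NA_real_, ncol(D))
  t_obs_full[keep] <- .t_from_diff(D[, keep, drop = FALSE])
  t_map <- array(t_obs_full, dim = d)

  exhaustive <- 2^n < n_permutations
  if (exhaustive) {
    message("2^", n, " < ", n_permutations,
            ": enumerating all sign patterns exhaustively")
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    set.seed(seed)
    flips <- matrix(sample(c(-1, 1), n * n_permutations, replace = TRUE),
                    nrow = n_permutations, byrow = TRUE)
  }

  Dk <- D[, keep, drop = FALSE]
  null_max <- matrix(0L, nrow(flips), 2,
                     dimnames = list(NULL, c("pos", "neg")))
  tperm_full <- rep(NA_real_, ncol(D))
  for (b in seq_len(nrow(flips))) {
    tb <- .t_from_diff(Dk * flips[b, ])
    tperm_full[keep] <- tb
    for (sg in c("pos", "neg"))
      null_max[b, sg] <- .max_extent(tperm_full, forming_threshold, d, sg)
  }

  clusters <- list()
  for (sg in signs) {
    cl <- find_clusters(t_map, forming_threshold, sign = sg,
                        affine = stack_A$affine)
    if (nrow(cl) > 0L) {
      cl$sign <- sg
      cl$p <- vapply(cl$k_E, function(k)
        (1 + sum(null_max[, sg] >= k)) / (1 + nrow(flips)), 0)
      cl$p_adjusted <- adjust_pvalues(cl$p)
    } else {
      cl$sign <- character(0); cl$p <- numeric(0); cl$p_adjusted <- numeric(0)
    }
    clusters[[sg]] <- cl
  }
  clusters <- do.call(rbind, clusters)
  rownames(clusters) <- NULL
  structure(list(t_map = t_map, clusters = clusters,
                 forming_threshold = forming_threshold,
                 n_permutations = nrow(flips), n_pairs = n,
                 exhaustive = exhaustive, seed = seed,
                 affine = stack_A$affine),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> %d pairs, threshold t > %.3f, %d permutations%s\n",
              x$n_pairs, x$forming_threshold, x$n_permutations,
              if (x$exhaustive) " (exhaustive)" else ""))
  if (nrow(x$clusters) == 0L) cat("  no suprathreshold clusters\n")
  else print(x$clusters, digits = 3)
  invisible(x)
}

#' Write a cluster table as tab-delimited text
#' @param cluster_map a [cluster_fdr()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(cluster_map, path) {
  cl <- cluster_map$clusters
  cols <- intersect(c("sign", "peak_x_mm", "peak_y_mm", "peak_z_mm",
                      "peak_t", "p", "p_adjusted", "k_E"), names(cl))
  utils::write.table(cl[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
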