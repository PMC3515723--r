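# Small synthetic worlds used across tests. All fixtures are built in code.

# two-region world on a compact grid; planted edge correlation rho
two_region_config <- function(rho = 0.6, n = 200, grid = 28L, semiax = 26,
                              radius = 5, noise_sd = 0.1, global_sd = 0.5,
                              seed = 1L, sessions = "S", conditions = "c1",
                              replicates = 1L, ...) {
  cx <- min(12, semiax - radius - 3)   # keep regions inside the ellipsoid
  regs <- list(region_spec("A", c(-cx, 0, 0), radius),
               region_spec("B", c(cx, 0, 0), radius))
  R <- matrix(c(1, rho, rho, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  synth_config(grid_shape = rep(grid, 3L), voxel_size_mm = 2, regions = regs,
               session_edge_corr = stats::setNames(
                 rep(list(R), length(sessions)), sessions),
               sessions = sessions, conditions = conditions,
               replicates_per_condition = replicates,
               n_participants = n, noise_sd = noise_sd, global_sd = global_sd,
               origin_vox = NULL, brain_center_mm = c(0, 0, 0),
               brain_semiaxes_mm = rep(semiax, 3L),
               response_edge = c("A", "B"), response_session = sessions[1],
               seed = seed, ...)
}

# three small regions in a 12^3 grid, for pipeline-level tests
three_region_config <- function(corrs, n = 8, sessions = c("S1", "S2"),
                                conditions = c("c1", "c2"), replicates = 2L,
                                noise_sd = 0.3, global_sd = 0.5, seed = 1L,
                                ...) {
  regs <- list(region_spec("MFC", c(-6, 0, 0), 4),
               region_spec("LNAcc", c(6, 0, 0), 4),
               region_spec("LHIP", c(0, 0, 6), 4))
  nm <- c("MFC", "LNAcc", "LHIP")
  mk <- function(v) {
    m <- diag(3); m[lower.tri(m)] <- v; m <- m + t(m) - diag(3)
    dimnames(m) <- list(nm, nm); m
  }
  synth_config(grid_shape = c(12L, 12L, 12L), voxel_size_mm = 2,
               regions = regs,
               session_edge_corr = stats::setNames(lapply(corrs, mk), sessions),
               sessions = sessions, conditions = conditions,
               replicates_per_condition = replicates, n_participants = n,
               noise_sd = noise_sd, global_sd = global_sd,
               origin_vox = NULL, brain_center_mm = c(0, 0, 0),
               brain_semiaxes_mm = c(11, 11, 11),
               response_edge = c("MFC", "LHIP"), response_session = sessions[1],
               seed = seed, ...)
}

# bare stack from a units x voxels matrix (for voxelwise tests)
raw_stack <- function(data, dim3, session = "A",
                      participants = sprintf("P%02d", seq_len(nrow(data))),
                      condition = "c1") {
  list(data = data,
       units = data.frame(participant = participants, session = session,
                          condition = condition, stringsAsFactors = FALSE),
       dim = as.integer(dim3), affine = diag(c(2, 2, 2, 1)))
}

# independent flood-fill labelling via igraph, used as the clustering oracle
oracle_cluster_extents <- function(t_map, thr, sign) {
  d <- dim(t_map)
  supra <- if (sign == "pos") which(!is.na(t_map) & t_map > thr)
           else which(!is.na(t_map) & t_map < -thr)
  if (length(supra) == 0L) return(integer(0))
  idx <- arrayInd(supra, d)
  edges <- NULL
  strides <- c(1L, d[1], d[1] * d[2])
  pos <- integer(prod(d)); pos[supra] <- seq_along(supra)
  for (ax in 1:3) {
    ok <- idx[, ax] < d[ax]
    nb <- supra[ok] + strides[ax]
    keep <- pos[nb] != 0L
    if (any(keep))
      edges <- rbind(edges, cbind(pos[supra[ok]][keep], pos[nb][keep]))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(supra) - igraph::vcount(g)))
  sort(as.integer(table(igraph::components(g)$membership)), decreasing = TRUE)
}
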