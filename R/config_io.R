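#' Read a synthetic-study configuration from JSON
#'
#' The file is a single key-value object mirroring the [synth_config()]
#' arguments. Regions are a list of objects with `name`, `shape`,
#' `center_mm`, `radius_or_halfwidth_mm`; `session_edge_corr` is an object
#' mapping session label to a full correlation matrix (list of rows).
#' Omitted keys fall back to the package defaults.
#'
#' @param path JSON file path.
#' @return A `synth_config`.
#' @export
read_synth_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  scalar_keys <- c("voxel_size_mm", "global_sd", "noise_sd", "smooth_fwhm_mm",
                   "n_participants", "replicates_per_condition",
                   "response_effect", "response_intercept",
                   "response_noise_sd", "response_session", "seed")
  vector_keys <- c("grid_shape", "sessions", "conditions", "response_edge",
                   "origin_vox", "brain_center_mm", "brain_semiaxes_mm")
  for (k in intersect(scalar_keys, names(raw))) args[[k]] <- raw[[k]]
  for (k in intersect(vector_keys, names(raw))) args[[k]] <- unlist(raw[[k]])
  if (!is.null(raw$regions)) {
    rg <- raw$regions
    if (is.data.frame(rg)) rg <- split(rg, seq_len(nrow(rg)))
    args$regions <- unname(lapply(rg, function(r)
      region_spec(r$name, unlist(r$center_mm), r$radius_or_halfwidth_mm,
                  shape = if (is.null(r$shape)) "sphere" else r$shape)))
  }
  if (!is.null(raw$session_edge_corr)) {
    args$session_edge_corr <- lapply(raw$session_edge_corr, function(m) {
      m <- if (is.matrix(m)) m
           else if (is.data.frame(m)) as.matrix(m)
           else do.call(rbind, lapply(m, unlist))
      nm <- unname(vapply(args$regions %||% .default_regions(), `[[`, "", "name"))
      dimnames(m) <- list(nm, nm)
      m
    })
  }
  do.call(synth_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a configuration as JSON
#' @param config a [synth_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_synth_config <- function(config, path) {
  out <- config[c("grid_shape", "voxel_size_mm", "global_sd", "noise_sd",
                  "smooth_fwhm_mm", "n_participants", "sessions",
                  "conditions", "replicates_per_condition", "response_edge",
                  "response_session", "response_effect", "response_intercept",
                  "response_noise_sd", "brain_center_mm", "brain_semiaxes_mm",
                  "seed")]
  out$origin_vox <- as.integer(round(-config$affine[1:3, 4] /
                                       config$voxel_size_mm))
  out$regions <- lapply(config$regions, unclass)
  out$session_edge_corr <- lapply(config$session_edge_corr, function(m)
    lapply(seq_len(nrow(m)), function(i) as.list(unname(m[i, ]))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
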