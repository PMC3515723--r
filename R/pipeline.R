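#' End-to-end pipeline orchestration
#'
#' Runs simulate -> smooth -> extract -> connect -> compare -> map ->
#' associate with one seed, writing tab-delimited tables, NIfTI t-maps and a
#' machine-readable JSON summary with output checksums.
#'
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param out_dir output directory.
#' @param synth a [synth_config()] (the pipeline simulates its input cohort;
#'   alternatively set `manifest_path`/`clinical_path` to load one).
#' @param manifest_path,clinical_path optional paths to an existing cohort's
#'   manifest and clinical tables (tab-delimited).
#' @param analysis_fwhm_mm analysis-time smoothing FWHM (0 = none; synthetic
#'   volumes may already carry generation-time smoothness).
#' @param use_replicates replicate handling, `"average"` or `"first"`.
#' @param comparisons list of session comparisons, each
#'   `list(pair = c(A, B), direction = "increase"|"decrease")`.
#' @param forming_p two-sided voxelwise p for the cluster-forming threshold.
#' @param n_permutations sign-flip permutation count for cluster inference.
#' @param response_edge edge tested for clinical association.
#' @param response_session session of the association.
#' @param run_maps logical; voxelwise mapping is the expensive stage.
#' @param seed master seed; stage-local substreams are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       synth = synth_config(),
                       manifest_path = NULL, clinical_path = NULL,
                       analysis_fwhm_mm = 0,
                       use_replicates = c("average", "first"),
                       comparisons = list(
                         list(pair = c("SZ0", "SZ1"), direction = "increase"),
                         list(pair = c("SZ0", "SZ6"), direction = "increase"),
                         list(pair = c("SZ1", "SZ6"), direction = "decrease")),
                       forming_p = 0.001,
                       n_permutations = 500L,
                       response_edge = c("MFC", "LHIP"),
                       response_session = "SZ1",
                       run_maps = TRUE,
                       seed = 1L) {
  use_replicates <- match.arg(use_replicates)
  if (!is.null(manifest_path) && !file.exists(manifest_path))
    stop("manifest_path does not exist: ", manifest_path)
  if (!is.null(clinical_path) && !file.exists(clinical_path))
    stop("clinical_path does not exist: ", clinical_path)
  structure(list(out_dir = out_dir, synth = synth,
                 manifest_path = manifest_path, clinical_path = clinical_path,
                 analysis_fwhm_mm = analysis_fwhm_mm,
                 use_replicates = use_replicates,
                 comparisons = comparisons, forming_p = forming_p,
                 n_permutations = as.integer(n_permutations),
                 response_edge = response_edge,
                 response_session = response_session,
                 run_maps = isTRUE(run_maps),
                 seed = as.integer(seed)), class = "run_config")
}

.stage_seed <- function(seed, stage) {
  (seed * 97L + stage * 1009L) %% 2000000011L
}

#' Run the full analysis pipeline
#'
#' @param config a [run_config()].
#' @return Invisibly, a result bundle: cohort, eigenvariate table, graphs,
#'   comparison table, cluster maps, association results, and the path of the
#'   JSON summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message("[petfc] ", msg)
  }

  # -- simulate / load --------------------------------------------------
  if (is.null(config$manifest_path)) {
    sc <- config$synth
    sc$seed <- .stage_seed(config$seed, 1L) %% 2147483647L
    note("simulate: %d participants, seed %d", sc$n_participants, sc$seed)
    cohort <- generate_cohort(sc)
    manifest <- cohort$manifest
    clinical <- cohort$clinical
    masks <- cohort$masks
    volumes <- cohort$volumes
  } else {
    note("load: %s", config$manifest_path)
    manifest <- utils::read.delim(config$manifest_path,
                                  stringsAsFactors = FALSE)
    clinical <- utils::read.delim(config$clinical_path,
                                  stringsAsFactors = FALSE)
    masks <- generate_masks(config$synth)
    volumes <- NULL
    cohort <- NULL
  }
  write_cohort_tables(list(manifest = manifest, clinical = clinical),
                      config$out_dir)

  # -- smooth -----------------------------------------------------------
  if (config$analysis_fwhm_mm > 0) {
    note("smooth: fwhm %.1f mm", config$analysis_fwhm_mm)
    volumes <- lapply(volumes, smooth_volume,
                      fwhm_mm = config$analysis_fwhm_mm)
  }

  # -- extract ----------------------------------------------------------
  note("extract: replicates=%s", config$use_replicates)
  stacks_cond <- stack_scans(manifest, volumes,
                             group_by = "session_condition",
                             use_replicates = config$use_replicates)
  stacks_comb <- stack_scans(manifest, volumes,
                             group_by = "session_combined",
                             use_replicates = config$use_replicates)
  etab_cond <- eigenvariate_table(stacks_cond, masks)
  # combined-condition signals are extracted over the pooled session stack
  # (the "all tasks" 4D vector), not by concatenating per-condition signals
  etab <- eigenvariate_table(stacks_comb, masks)
  write_eigenvariate_table(etab_cond, file.path(config$out_dir,
                                                "eigenvariates_task.tsv"))
  write_eigenvariate_table(etab, file.path(config$out_dir,
                                           "eigenvariates_combined.tsv"))

  # -- connect ----------------------------------------------------------
  sessions <- unique(manifest$session)
  conditions <- unique(manifest$condition)
  graphs <- list()
  for (s in sessions) {
    graphs[[paste0(s, ".combined")]] <- build_graph(etab, session = s)
    for (cond in conditions)
      graphs[[paste0(s, ".", cond)]] <-
        build_graph(etab_cond, session = s, condition = cond)
  }
  write_edge_tables(graphs, file.path(config$out_dir, "edges"))
  for (s in sessions) {
    e <- graphs[[paste0(s, ".combined")]]$edges
    note("connect: session %s, %d edges, n per edge %s", s, nrow(e),
         paste(unique(e$n), collapse = "/"))
  }

  # -- compare ----------------------------------------------------------
  comp <- do.call(rbind, lapply(config$comparisons, function(cc) {
    compare_graphs(graphs[[paste0(cc$pair[1], ".combined")]],
                   graphs[[paste0(cc$pair[2], ".combined")]],
                   direction = cc$direction)
  }))
  rownames(comp) <- NULL
  utils::write.table(comp, file.path(config$out_dir, "comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # -- map --------------------------------------------------------------
  maps <- list()
  if (config$run_maps) {
    sc_stacks <- stacks_comb
    for (ci in seq_along(config$comparisons)) {
      cc <- config$comparisons[[ci]]
      key <- paste(cc$pair, collapse = "_vs_")
      note("map: %s, %d permutations", key, config$n_permutations)
      n_pairs <- length(intersect(
        paste(sc_stacks[[cc$pair[1]]]$units$participant,
              sc_stacks[[cc$pair[1]]]$units$condition),
        paste(sc_stacks[[cc$pair[2]]]$units$participant,
              sc_stacks[[cc$pair[2]]]$units$condition)))
      thr <- stats::qt(1 - config$forming_p / 2, df = n_pairs - 1)
      cm <- cluster_fdr(sc_stacks[[cc$pair[1]]], sc_stacks[[cc$pair[2]]],
                        forming_threshold = thr,
                        n_permutations = config$n_permutations,
                        seed = .stage_seed(config$seed, 5L + ci),
                        mask = masks$brain)
      maps[[key]] <- cm
      write_nifti(rcbf_volume(ifelse(is.na(cm$t_map), 0, cm$t_map),
                              masks$brain$affine),
                  file.path(config$out_dir, paste0("tmap_", key, ".nii.gz")))
      write_cluster_table(cm, file.path(config$out_dir,
                                        paste0("clusters_", key, ".tsv")))
    }
  }

  # -- associate --------------------------------------------------------
  clin <- clinical_table(clinical)
  assoc <- lapply(sessions, function(s) {
    ev <- participant_edge_connectivity(etab, config$response_edge[1],
                                        config$response_edge[2], s)
    response_association(clin, ev, edge = config$response_edge, session = s)
  })
  assoc_df <- data.frame(
    session = sessions,
    edge = paste(config$response_edge, collapse = "-"),
    r_assoc = vapply(assoc, `[[`, 0, "r_assoc"),
    r_squared = vapply(assoc, `[[`, 0, "r_squared"),
    p = vapply(assoc, `[[`, 0, "p"),
    n = vapply(assoc, `[[`, 0L, "n"))
  utils::write.table(assoc_df, file.path(config$out_dir, "association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # -- summary ----------------------------------------------------------
  outputs <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(config$out_dir, "summary.json"))
  checksums <- tools::md5sum(outputs)
  summary <- list(
    seed = config$seed,
    use_replicates = config$use_replicates,
    analysis_fwhm_mm = config$analysis_fwhm_mm,
    forming_p = config$forming_p,
    n_permutations = config$n_permutations,
    sessions = sessions, conditions = conditions,
    edges_n = stats::setNames(
      lapply(sessions,
             function(s) graphs[[paste0(s, ".combined")]]$edges$n[1]),
      sessions),
    comparisons = comp,
    association = assoc_df,
    log = log_lines,
    outputs = data.frame(path = basename(names(checksums)),
                         md5 = unname(checksums)))
  sp <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")

  invisible(list(cohort = cohort, eigenvariates = etab, graphs = graphs,
                 comparisons = comp, maps = maps, association = assoc_df,
                 summary_path = sp, log = log_lines))
}

#' Task-performance session comparison (utility)
#'
#' One-way repeated-measures ANOVA of a performance measure (accuracy or
#' reaction time) across sessions with participant as the blocking factor,
#' plus Bonferroni-adjusted pairwise paired-t contrasts. Participants missing
#' any session are dropped listwise (count reported).
#'
#' @param perf data.frame with participant, session, value columns.
#' @return List with `F`, `df`, `p`, `pairwise` (data.frame of contrasts with
#'   Bonferroni-adjusted p), `n_dropped`.
#' @export
task_performance_check <- function(perf) {
  req <- c("participant", "session", "value")
  if (!all(req %in% names(perf))) stop("need columns participant, session, value")
  sessions <- unique(perf$session)
  if (length(sessions) < 2L) stop("need at least 2 sessions")
  counts <- table(perf$participant)
  complete <- names(counts)[counts == length(sessions)]
  n_dropped <- length(counts) - length(complete)
  perf <- perf[perf$participant %in% complete, , drop = FALSE]
  if (length(complete) < 2L) stop("need at least 2 complete participants")

  perf$session <- factor(perf$session)
  perf$participant <- factor(perf$participant)
  fit <- stats::aov(value ~ session + participant, data = perf)
  an <- summary(fit)[[1]]
  i <- trimws(rownames(an)) == "session"

  pairs <- utils::combn(levels(perf$session), 2)
  k <- ncol(pairs)
  pw <- data.frame(session_A = pairs[1, ], session_B = pairs[2, ],
                   t = NA_real_, p_raw = NA_real_, p_bonferroni = NA_real_)
  wide <- stats::reshape(perf, idvar = "participant", timevar = "session",
                         direction = "wide")
  for (j in seq_len(k)) {
    a <- wide[[paste0("value.", pairs[1, j])]]
    b <- wide[[paste0("value.", pairs[2, j])]]
    tt <- stats::t.test(a, b, paired = TRUE)
    pw$t[j] <- unname(tt$statistic)
    pw$p_raw[j] <- tt$p.value
  }
  pw$p_bonferroni <- pmin(pw$p_raw * k, 1)
  list(F = an$`F value`[i], df = c(an$Df[i], an$Df[nrow(an)]),
       p = an$`Pr(>F)`[i], pairwise = pw, n_dropped = n_dropped)
}
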