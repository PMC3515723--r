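#' Between-session comparison of connectivity
#'
#' Fisher z-difference tests of edge connectivity between treatment time
#' points, Benjamini-Hochberg step-up adjustment across the edge family, and
#' association of connectivity with clinical treatment response.
#'
#' @name session-comparison
NULL

#' Compare one edge's connectivity between two sessions
#'
#' Standardized difference of Fisher z values,
#' `z_stat = (z_B - z_A) / sqrt(1/(n_A - 3) + 1/(n_B - 3))`, with a one-sided
#' standard-normal tail probability in the tested direction (`"increase"`
#' tests B > A, `"decrease"` tests B < A).
#'
#' @param z_A,z_B Fisher z connectivity at sessions A and B.
#' @param n_A,n_B effective analysis-unit counts.
#' @param direction `"increase"` or `"decrease"` (direction of B relative to
#'   A being tested; never inferred from the data).
#' @return List with `z_stat`, `p_one_sided`, `direction`, `n_A`, `n_B`.
#' @export
compare_connections <- function(z_A, n_A, z_B, n_B,
                                direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (n_A <= 3L || n_B <= 3L) stop("need n > 3 in both sessions")
  se <- sqrt(1 / (n_A - 3) + 1 / (n_B - 3))
  z_stat <- (z_B - z_A) / se
  list(z_stat = z_stat,
       p_one_sided = normal_tail_p(z_stat, direction),
       direction = direction, n_A = n_A, n_B = n_B)
}

#' One-sided standard-normal tail probability
#'
#' @param z_stat finite z statistic.
#' @param direction `"increase"` (upper tail) or `"decrease"` (lower tail).
#' @return Tail probability.
#' @export
normal_tail_p <- function(z_stat, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (!all(is.finite(z_stat))) stop("z_stat must be finite")
  stats::pnorm(z_stat, lower.tail = (direction == "decrease"))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `adjusted_(i) = min_{j >= i} (m * p_(j) / j)` over the ascending order
#' statistics, clipped at 1, returned in the input order.
#'
#' @param p_list numeric p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p_list) {
  m <- length(p_list)
  if (m == 0L) return(numeric(0))
  if (any(!is.finite(p_list)) || any(p_list <= 0) || any(p_list > 1))
    stop("p-values must lie in (0, 1]")
  o <- order(p_list)
  ranked <- p_list[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  # guard the adjusted >= raw invariant against 1-ulp cummin round-off
  pmax(out, p_list)
}

#' Session-pair comparison table for all edges
#'
#' Runs [compare_connections()] for every edge of two graphs sharing the same
#' node set and adjusts the one-sided p-values across the edge family.
#'
#' @param graph_A,graph_B [build_graph()] results for sessions A and B.
#' @param direction tested direction of B relative to A (scalar, or one per
#'   edge in the graph's edge order).
#' @return data.frame: region_a, region_b, session_A, session_B, direction,
#'   z_A, z_B, z_stat, p_one_sided, p_adjusted, n_A, n_B.
#' @export
compare_graphs <- function(graph_A, graph_B, direction = "increase") {
  ea <- graph_A$edges; eb <- graph_B$edges
  key <- function(e) paste(e$region_a, e$region_b, sep = "-")
  if (!identical(key(ea), key(eb))) stop("graphs have different edge sets")
  direction <- rep_len(direction, nrow(ea))
  res <- lapply(seq_len(nrow(ea)), function(i)
    compare_connections(ea$z[i], ea$n[i], eb$z[i], eb$n[i], direction[i]))
  out <- data.frame(region_a = ea$region_a, region_b = ea$region_b,
                    session_A = graph_A$session, session_B = graph_B$session,
                    direction = direction,
                    z_A = ea$z, z_B = eb$z,
                    z_stat = vapply(res, `[[`, 0, "z_stat"),
                    p_one_sided = vapply(res, `[[`, 0, "p_one_sided"),
                    n_A = ea$n, n_B = eb$n, stringsAsFactors = FALSE)
  out$p_adjusted <- adjust_pvalues(out$p_one_sided)
  out[, c("region_a", "region_b", "session_A", "session_B", "direction",
          "z_A", "z_B", "z_stat", "p_one_sided", "p_adjusted", "n_A", "n_B")]
}

#' Clinical score table with treatment response
#'
#' @param clinical data.frame with participant, bprs_psychosis_baseline,
#'   bprs_psychosis_week6 columns (as read from the tab-delimited clinical
#'   file).
#' @return Same data.frame with a `response` column,
#'   `baseline - week6` (positive = improvement), computed once.
#' @export
clinical_table <- function(clinical) {
  req <- c("participant", "bprs_psychosis_baseline", "bprs_psychosis_week6")
  if (!all(req %in% names(clinical))) stop("clinical table lacks ",
    paste(setdiff(req, names(clinical)), collapse = ", "))
  clinical$response <- clinical$bprs_psychosis_baseline -
    clinical$bprs_psychosis_week6
  clinical
}

#' Per-participant edge connectivity surrogate
#'
#' A group-level partial correlation has no per-participant value; two
#' surrogates are offered. `"product"` (default): residualize both region
#' signals on the global covariate across the session's analysis units,
#' standardize by the population sd, and average the per-unit product within
#' each participant (the participant's contribution to the group
#' correlation). `"loo"`: jackknife pseudo-values of the group Fisher z,
#' `n*z - (n-1)*z_without_participant`.
#'
#' @param table [eigenvariate_table()] data.frame.
#' @param region_a,region_b edge region names.
#' @param session session label.
#' @param method `"product"` or `"loo"`.
#' @return Named numeric vector, one value per participant.
#' @export
participant_edge_connectivity <- function(table, region_a, region_b, session,
                                          method = c("product", "loo")) {
  method <- match.arg(method)
  sub <- table[table$session == session, , drop = FALSE]
  if (nrow(sub) < 4L) stop("fewer than 4 units in session ", session)
  a <- sub[[region_a]]; b <- sub[[region_b]]; g <- sub$global
  if (method == "product") {
    ra <- .residualize(a, g); rb <- .residualize(b, g)
    std <- function(v) {
      s <- sqrt(mean(v^2))
      if (s == 0) stop("zero residual variance in edge signal")
      v / s
    }
    prod_unit <- std(ra) * std(rb)
    out <- tapply(prod_unit, sub$participant, mean)
  } else {
    parts <- unique(sub$participant)
    n <- length(parts)
    z_full <- fisher_z(partial_corr(a, b, g))
    out <- vapply(parts, function(p) {
      keep <- sub$participant != p
      n * z_full - (n - 1) * fisher_z(partial_corr(a[keep], b[keep], g[keep]))
    }, 0)
    names(out) <- parts
  }
  out[sort(names(out))]
}

#' Association between treatment response and edge connectivity
#'
#' Pearson correlation across participants of the clinical response with
#' per-participant edge connectivity values; reports r, r-squared and the
#' two-sided p.
#'
#' @param clinical a [clinical_table()] data.frame (must carry `response`).
#' @param edge_values named per-participant connectivity values (as from
#'   [participant_edge_connectivity()]).
#' @param edge optional length-2 edge label for bookkeeping.
#' @param session optional session label for bookkeeping.
#' @return List with `r_assoc`, `r_squared`, `p`, `n`, `edge`, `session`.
#' @export
response_association <- function(clinical, edge_values, edge = NULL,
                                 session = NULL) {
  if (!"response" %in% names(clinical)) clinical <- clinical_table(clinical)
  common <- intersect(clinical$participant, names(edge_values))
  if (length(common) < 4L)
    stop("need at least 4 participants with both scores and connectivity")
  resp <- clinical$response[match(common, clinical$participant)]
  conn <- as.numeric(edge_values[common])
  if (stats::sd(resp) == 0) stop("zero variance in clinical response")
  if (stats::sd(conn) == 0) stop("zero variance in edge connectivity")
  ct <- stats::cor.test(resp, conn)
  list(r_assoc = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = length(common), edge = edge, session = session)
}
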