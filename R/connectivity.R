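#' Edge-level functional connectivity
#'
#' Partial correlations between ROI eigenvariates controlling for the global
#' covariate, Fisher r-to-z transformation, and per-edge significance with
#' df = n - 3 (one controlled covariate).
#'
#' @name connectivity
NULL

.residualize <- function(v, covariate) {
  fit <- stats::lm.fit(cbind(1, covariate), v)
  fit$residuals
}

#' Partial correlation controlling for one covariate
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' regression on an intercept and `covariate`.
#'
#' @param x,y numeric signal vectors.
#' @param covariate numeric covariate vector of the same length.
#' @return Partial correlation in `[-1, 1]`.
#' @export
partial_corr <- function(x, y, covariate) {
  n <- length(x)
  if (length(y) != n || length(covariate) != n)
    stop("x, y and covariate must have equal length")
  if (n < 4L) stop("need at least 4 observations for a partial correlation")
  if (!all(is.finite(x), is.finite(y), is.finite(covariate)))
    stop("non-finite values in input")
  rx <- .residualize(x, covariate)
  ry <- .residualize(y, covariate)
  sx <- sqrt(sum(rx^2)); sy <- sqrt(sum(ry^2))
  tol <- 1e-12 * n
  if (sx <= tol * max(1, stats::sd(x)))
    stop("x has zero residual variance after removing the covariate")
  if (sy <= tol * max(1, stats::sd(y)))
    stop("y has zero residual variance after removing the covariate")
  sum(rx * ry) / (sx * sy)
}

#' Fisher r-to-z transformation
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`.
#'
#' @param r correlation(s), `|r| < 1`.
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisher_z requires |r| < 1")
  atanh(r)
}

#' Two-sided p-value for a partial correlation
#'
#' Student-t test of r != 0 with `df = n - 3` (one controlled covariate):
#' `t = r * sqrt(df / (1 - r^2))`.
#'
#' @param r partial correlation.
#' @param n number of analysis units.
#' @return Two-sided p-value.
#' @export
connection_pvalue <- function(r, n) {
  if (n < 4L) stop("need n >= 4")
  if (abs(r) > 1) stop("|r| must be <= 1")
  if (abs(r) == 1) {
    warning("|r| = 1: p-value degenerate at 0")
    return(0)
  }
  df <- n - 3
  t <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t), df)
}

#' Connectivity graph over all region pairs
#'
#' For one session (and one condition, or the pooled `"combined"` condition)
#' computes, for every unordered region pair, the partial correlation
#' controlling for the global covariate, its Fisher z, the effective n from
#' non-missing units, df = n - 3 and the two-sided p.
#'
#' @param table an [eigenvariate_table()] data.frame.
#' @param regions region column names; default: all columns that are not
#'   bookkeeping or `global`.
#' @param session session label to select.
#' @param condition condition label, or `"combined"` to pool all conditions
#'   of the session (analysis units are stacked, not averaged).
#' @return A `connectivity_graph`: list with `edges` data.frame (region_a,
#'   region_b, session, condition, r, z, n, df, p) and `nodes`.
#' @export
build_graph <- function(table, regions = NULL, session, condition = "combined") {
  if (is.null(regions))
    regions <- setdiff(names(table),
                       c("participant", "session", "condition", "global"))
  sel <- table$session == session
  if (!identical(condition, "combined")) sel <- sel & table$condition == condition
  sub <- table[sel, , drop = FALSE]
  if (nrow(sub) < 4L)
    stop("fewer than 4 analysis units for session ", session,
         " condition ", condition)
  pairs <- utils::combn(regions, 2)
  edges <- data.frame(region_a = pairs[1, ], region_b = pairs[2, ],
                      session = session, condition = condition,
                      r = NA_real_, z = NA_real_, n = NA_integer_,
                      df = NA_integer_, p = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(edges))) {
    a <- sub[[edges$region_a[i]]]; b <- sub[[edges$region_b[i]]]
    g <- sub$global
    ok <- is.finite(a) & is.finite(b) & is.finite(g)
    n <- sum(ok)
    if (n < 4L) stop("fewer than 4 complete units for edge ",
                     edges$region_a[i], "-", edges$region_b[i])
    r <- partial_corr(a[ok], b[ok], g[ok])
    edges$r[i] <- r
    edges$z[i] <- fisher_z(min(max(r, -1 + 1e-15), 1 - 1e-15))
    edges$n[i] <- n
    edges$df[i] <- n - 3L
    edges$p[i] <- connection_pvalue(r, n)
  }
  structure(list(nodes = regions, edges = edges,
                 session = session, condition = condition),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("<connectivity_graph> session %s, condition %s: %d nodes, %d edges\n",
              x$session, x$condition, length(x$nodes), nrow(x$edges)))
  print(x$edges, digits = 3)
  invisible(x)
}

#' Lower-triangle connectivity matrix table
#'
#' Formats a graph as the familiar lower-triangular r / p table (one row and
#' column per region, `r p=...` in each cell).
#'
#' @param graph a [build_graph()] result.
#' @return Character matrix with region dimnames.
#' @export
graph_triangle <- function(graph) {
  rg <- graph$nodes
  m <- matrix("", length(rg), length(rg), dimnames = list(rg, rg))
  diag(m) <- "1.000"
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    m[e$region_b, e$region_a] <-
      sprintf("%.3f p=%.3f", e$r, e$p)
  }
  m
}

#' Write per-session edge tables
#'
#' Writes the lower-triangle table and appends the long-format edge rows
#' (edge, session, condition, r, z, n, df, p) to a combined file.
#'
#' @param graphs list of `connectivity_graph`s.
#' @param dir output directory.
#' @return Path of the long-format file, invisibly.
#' @export
write_edge_tables <- function(graphs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  long <- do.call(rbind, lapply(graphs, `[[`, "edges"))
  rownames(long) <- NULL
  for (g in graphs) {
    fn <- file.path(dir, sprintf("edges_%s_%s.tsv", g$session, g$condition))
    utils::write.table(graph_triangle(g), fn, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  lp <- file.path(dir, "edges_long.tsv")
  utils::write.table(long, lp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(lp)
}
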