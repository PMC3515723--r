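test_that("partial correlation matches the closed-form three-correlation oracle", {
  set.seed(40)
  for (i in 1:20) {
    x <- rnorm(20); y <- rnorm(20); cv <- rnorm(20)
    r_xy <- cor(x, y); r_xc <- cor(x, cv); r_yc <- cor(y, cv)
    oracle <- (r_xy - r_xc * r_yc) / sqrt((1 - r_xc^2) * (1 - r_yc^2))
    expect_equal(partial_corr(x, y, cv), oracle, tolerance = 1e-12)
  }
})

test_that("partial correlation: orthogonal covariate, degeneracy, invariances", {
  set.seed(41)
  x <- rnorm(24); y <- rnorm(24)
  # covariate orthogonal to x and y by construction
  cv <- rnorm(24)
  cv <- stats::residuals(stats::lm(cv ~ x + y))
  expect_equal(partial_corr(x, y, cv), cor(x, y), tolerance = 1e-12)

  expect_error(partial_corr(cv, y, cv), "zero residual variance")
  expect_error(partial_corr(x, y, cv[1:10]), "equal length")
  expect_error(partial_corr(x[1:3], y[1:3], cv[1:3]), "at least 4")

  cv2 <- rnorm(24)
  r <- partial_corr(x, y, cv2)
  expect_equal(partial_corr(y, x, cv2), r, tolerance = 1e-12)  # symmetry
  # affine rescaling of any input leaves r unchanged
  expect_equal(partial_corr(3 * x - 7, y, cv2), r, tolerance = 1e-12)
  expect_equal(partial_corr(x, -2 * y + 1, cv2), -r, tolerance = 1e-12)
  expect_equal(partial_corr(x, y, 0.1 * cv2 + 5), r, tolerance = 1e-12)
})

test_that("fisher_z is the area hyperbolic tangent with domain checks", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-15)
  rs <- seq(-0.95, 0.95, by = 0.1)
  expect_equal(fisher_z(-rs), -fisher_z(rs), tolerance = 1e-15)
  expect_error(fisher_z(1), "< 1")
  expect_error(fisher_z(-1.2), "< 1")
})

test_that("connection p-values use df = n - 3 and are null-uniform", {
  expect_equal(connection_pvalue(0, 17), 1)
  expect_error(connection_pvalue(0.5, 3), "n >= 4")
  expect_warning(p1 <- connection_pvalue(1, 10), "degenerate")
  expect_identical(p1, 0)

  # agreement with a direct t-distribution oracle at arbitrary (r, n)
  r <- 0.37; n <- 23
  t <- r * sqrt((n - 3) / (1 - r^2))
  expect_equal(connection_pvalue(r, n), 2 * pt(-t, n - 3), tolerance = 1e-14)

  # null p-values are Uniform(0,1): KS at 2000 simulated draws
  set.seed(42)
  n <- 20
  ps <- replicate(2000, {
    x <- rnorm(n); y <- rnorm(n); cv <- rnorm(n)
    connection_pvalue(partial_corr(x, y, cv), n)
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("estimator bias on generated cohorts is below 0.02", {
  # estimator-level form of the bias invariant: the volume-level form with
  # global_sd = 0 is unattainable (see methods vignette); the partial-corr
  # estimator applied to the generator's recorded latents with an
  # uninformative covariate must recover rho almost unbiasedly
  rho <- 0.6; n <- 200
  rs <- vapply(1:200, function(s) {
    cfg <- two_region_config(rho = rho, n = n, grid = 16L, semiax = 14,
                             radius = 2, noise_sd = 0, global_sd = 0, seed = s)
    co <- generate_cohort(cfg)
    lat <- co$ground_truth$latent_signals
    set.seed(s + 1000L)
    partial_corr(lat[, "A"], lat[, "B"], rnorm(n))
  }, 0)
  expect_lt(abs(mean(rs) - rho), 0.02)
})

test_that("build_graph enumerates pairs, records n, recovers planted signs", {
  cfg <- three_region_config(corrs = list(c(0.6, -0.4, 0.4), c(0.6, -0.4, 0.4)),
                             n = 15, noise_sd = 0.05, global_sd = 0.8, seed = 17)
  co <- generate_cohort(cfg)
  stc <- stack_scans(co$manifest, co$volumes, group_by = "session_condition")
  stm <- stack_scans(co$manifest, co$volumes, group_by = "session_combined")
  et_cond <- eigenvariate_table(stc, co$masks)
  et_comb <- eigenvariate_table(stm, co$masks)

  g <- build_graph(et_comb, session = "S1")
  expect_identical(nrow(g$edges), 3L)
  # 5 regions -> 10 edges (pair-count contract on a wider node set)
  fake <- et_comb
  fake$R4 <- rnorm(nrow(fake)); fake$R5 <- rnorm(nrow(fake))
  expect_identical(nrow(build_graph(fake, session = "S1")$edges), 10L)

  # combined n equals the sum of per-condition n for complete data
  g1 <- build_graph(et_cond, session = "S1", condition = "c1")
  g2 <- build_graph(et_cond, session = "S1", condition = "c2")
  expect_identical(g$edges$n, g1$edges$n + g2$edges$n)

  # planted correlation signs recovered on a low-noise cohort
  planted <- cfg$session_edge_corr$S1
  for (i in seq_len(nrow(g$edges)))
    expect_identical(sign(g$edges$r[i]),
                     sign(planted[g$edges$region_a[i], g$edges$region_b[i]]),
                     info = paste(g$edges$region_a[i], g$edges$region_b[i]))
  expect_equal(g$edges$df, g$edges$n - 3L)
  expect_error(build_graph(et_comb[1:3, ], session = "S1"), "fewer than 4")
})

test_that("edge tables are written and re-readable", {
  cfg <- three_region_config(corrs = list(c(0.3, 0.2, 0.1), c(0.3, 0.2, 0.1)),
                             n = 6, seed = 23)
  co <- generate_cohort(cfg)
  st <- stack_scans(co$manifest, co$volumes, group_by = "session_combined")
  et <- eigenvariate_table(st, co$masks)
  g <- build_graph(et, session = "S1")
  d <- file.path(tempdir(), "edges_out")
  long <- write_edge_tables(list(g), d)
  back <- utils::read.delim(long)
  expect_identical(nrow(back), nrow(g$edges))
  expect_equal(back$r, g$edges$r)
  tri <- graph_triangle(g)
  expect_identical(tri["LNAcc", "MFC"],
                   sprintf("%.3f p=%.3f", g$edges$r[1], g$edges$p[1]))
  unlink(d, recursive = TRUE)
})
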