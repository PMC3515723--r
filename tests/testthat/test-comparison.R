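test_that("compare_connections: no-change null, antisymmetry, error guards", {
  res <- compare_connections(0.42, 30, 0.42, 25, "increase")
  expect_identical(res$z_stat, 0)
  expect_identical(res$p_one_sided, 0.5)

  a <- compare_connections(0.2, 40, 0.6, 25, "increase")
  b <- compare_connections(0.6, 25, 0.2, 40, "decrease")
  expect_equal(a$z_stat, -b$z_stat, tolerance = 1e-14)   # antisymmetric
  expect_equal(a$p_one_sided, b$p_one_sided, tolerance = 1e-14)
  expect_equal(a$z_stat, (0.6 - 0.2) / sqrt(1 / 37 + 1 / 22),
               tolerance = 1e-14)

  expect_error(compare_connections(0.2, 3, 0.6, 25, "increase"), "n > 3")
})

test_that("normal_tail_p is the exact standard-normal tail", {
  expect_identical(normal_tail_p(0, "increase"), 0.5)
  expect_equal(normal_tail_p(1.96, "increase"), pnorm(-1.96), tolerance = 1e-15)
  expect_equal(normal_tail_p(-1.3, "decrease"), pnorm(-1.3), tolerance = 1e-15)
  expect_error(normal_tail_p(Inf, "increase"), "finite")
})

test_that("Benjamini-Hochberg step-up: definition, oracle, properties", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_identical(adjust_pvalues(numeric(0)), numeric(0))
  expect_equal(adjust_pvalues(0.2), 0.2)                  # m = 1 unchanged
  expect_equal(adjust_pvalues(rep(0.03, 5)), rep(0.03, 5))  # tie symmetry

  set.seed(50)
  for (i in 1:10) {
    p <- runif(sample(2:12, 1))
    expect_equal(adjust_pvalues(p), stats::p.adjust(p, "BH"),
                 tolerance = 1e-14)  # independent implementation oracle
  }

  # monotone: raising one input never lowers any output
  p <- c(0.01, 0.2, 0.05, 0.6)
  base <- adjust_pvalues(p)
  p2 <- p; p2[2] <- 0.4
  expect_true(all(adjust_pvalues(p2) >= base - 1e-14))
  # idempotent on already-adjusted ties
  expect_equal(adjust_pvalues(adjust_pvalues(rep(0.02, 4))),
               adjust_pvalues(rep(0.02, 4)))

  expect_error(adjust_pvalues(c(0.1, 0)), "0, 1")
})

test_that("compare_graphs pairs edges and adjusts across the family", {
  cfg <- three_region_config(corrs = list(c(0.2, 0.2, 0.2), c(0.8, 0.2, 0.2)),
                             n = 15, noise_sd = 0.1, seed = 33)
  co <- generate_cohort(cfg)
  st <- stack_scans(co$manifest, co$volumes, group_by = "session_combined")
  et <- eigenvariate_table(st, co$masks)
  cmp <- compare_graphs(build_graph(et, session = "S1"),
                        build_graph(et, session = "S2"),
                        direction = "increase")
  expect_identical(nrow(cmp), 3L)
  expect_true(all(cmp$p_adjusted >= cmp$p_one_sided))
  expect_equal(cmp$p_adjusted, adjust_pvalues(cmp$p_one_sided))
})

test_that("response association: perfect linearity, planted slope, null", {
  cl <- data.frame(participant = sprintf("P%02d", 1:10),
                   bprs_psychosis_baseline = 20,
                   bprs_psychosis_week6 = 20 - (3 + 2 * (1:10)))
  cl <- clinical_table(cl)
  expect_equal(cl$response, 3 + 2 * (1:10))
  ev <- stats::setNames(as.numeric(1:10), cl$participant)
  res <- response_association(cl, ev)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)

  flat <- data.frame(participant = cl$participant,
                     bprs_psychosis_baseline = 20,
                     bprs_psychosis_week6 = 20)
  expect_error(response_association(flat, ev), "zero variance")
  expect_error(response_association(cl[1:3, ], ev[1:3]), "at least 4")

  # planted slope 0: observed r^2 sits inside its permutation null
  # (5 replicate cohorts; at least 4 below the 95th percentile)
  below <- 0
  for (s in 1:5) {
    cfg <- two_region_config(rho = 0.5, n = 100, grid = 16L, semiax = 14,
                             radius = 3, noise_sd = 0.2, global_sd = 0.5,
                             seed = 60 + s)
    cfg$response_effect <- 0
    co <- generate_cohort(cfg)
    st <- stack_scans(co$manifest, co$volumes)
    et <- eigenvariate_table(st, co$masks)
    ev <- participant_edge_connectivity(et, "A", "B", "S")
    cl <- clinical_table(co$clinical)
    obs <- response_association(cl, ev)$r_squared
    set.seed(60 + s)
    null <- replicate(400, {
      cl2 <- cl; cl2$response <- sample(cl2$response)
      response_association(cl2, ev)$r_squared
    })
    below <- below + (obs < stats::quantile(null, 0.95))
  }
  expect_gte(below, 4)
})

test_that("per-participant connectivity surrogates average to the group signal", {
  cfg <- two_region_config(rho = 0.6, n = 30, grid = 16L, semiax = 14,
                           radius = 3, noise_sd = 0.1, seed = 71)
  co <- generate_cohort(cfg)
  st <- stack_scans(co$manifest, co$volumes)
  et <- eigenvariate_table(st, co$masks)
  prod <- participant_edge_connectivity(et, "A", "B", "S", method = "product")
  expect_identical(length(prod), 30L)
  # mean of per-unit standardized residual products equals the group partial r
  r_group <- partial_corr(et$A, et$B, et$global)
  expect_equal(mean(prod), r_group, tolerance = 1e-10)
  # jackknife pseudo-values average to about the group z
  loo <- participant_edge_connectivity(et, "A", "B", "S", method = "loo")
  expect_equal(mean(loo), fisher_z(r_group), tolerance = 0.1)
})
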