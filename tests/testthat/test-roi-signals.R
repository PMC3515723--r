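test_that("smoothing: identity at fwhm 0, Gaussian profile on a delta spike", {
  set.seed(20)
  x <- array(rnorm(15^3), dim = c(15, 15, 15))
  expect_identical(smooth_array(x, 0, 2), x)
  expect_error(smooth_array(x, -1, 2), "non-negative")

  # delta spike -> sampled 3D Gaussian (direct kernel evaluation oracle)
  spike <- array(0, dim = c(21, 21, 21)); spike[11, 11, 11] <- 1
  vs <- c(2, 2, 3)                      # anisotropic spacings, per-axis sigma
  fwhm <- 9
  sm <- smooth_array(spike, fwhm, vs)
  sig <- fwhm / (2 * sqrt(2 * log(2))) / vs
  g1 <- function(i, s) {
    r <- max(1L, ceiling(4 * s))
    w <- exp(-((-r:r)^2) / (2 * s^2)); w <- w / sum(w)
    out <- numeric(21); out[11 + (-r:r)] <- w; out[i]
  }
  idx <- as.matrix(expand.grid(1:21, 1:21, 1:21))
  expected <- g1(idx[, 1], sig[1]) * g1(idx[, 2], sig[2]) * g1(idx[, 3], sig[3])
  expect_lt(max(abs(as.vector(sm) - expected)) / max(expected), 1e-6)
  expect_equal(sum(sm), 1, tolerance = 1e-10)   # mass conservation (interior)
})

test_that("stacking conserves counts, drops incomplete cells, round-trips", {
  cfg <- three_region_config(corrs = list(c(0.3, 0.2, 0.1), c(0.3, 0.2, 0.1)),
                             n = 5, replicates = 2L, seed = 9)
  co <- generate_cohort(cfg)

  comb <- stack_scans(co$manifest, co$volumes, group_by = "session_combined")
  expect_identical(nrow(comb$S1$data), 5L * 2L)     # 2 conditions x 5 units
  cond <- stack_scans(co$manifest, co$volumes, group_by = "session_condition")
  expect_identical(nrow(comb$S1$data),
                   nrow(cond$S1.c1$data) + nrow(cond$S1.c2$data))

  # dropout: removing one participant's condition drops only that unit
  man2 <- co$manifest[!(co$manifest$participant == "P03" &
                          co$manifest$condition == "c2"), ]
  comb2 <- stack_scans(man2, co$volumes, group_by = "session_combined")
  expect_identical(nrow(comb2$S1$data), 9L)
  expect_false(any(comb2$S1$units$participant == "P03" &
                     comb2$S1$units$condition == "c2"))

  # round-trip: with use_replicates = "first", rows reproduce volumes bitwise
  first <- stack_scans(co$manifest, co$volumes, use_replicates = "first")
  st <- first$S1.c1
  for (i in seq_len(nrow(st$data))) {
    key <- sprintf("%s_%s_%s_1", st$units$participant[i], st$units$session[i],
                   st$units$condition[i])
    expect_identical(unstack_scan(st, i), co$volumes[[key]]$data)
  }

  # grid mismatch is caught and names the scan
  volumes_bad <- co$volumes
  volumes_bad[["P01_S1_c1_1"]] <-
    rcbf_volume(array(0, dim = c(3, 3, 3)), diag(4),
                scan_key = list("P01", "S1", "c1", 1))
  expect_error(stack_scans(co$manifest, volumes_bad), "mismatch")
})

test_that("eigenvariate matches rank-1 structure and a dense SVD oracle", {
  set.seed(30)
  # rank-1: outer(u, v), v >= 0 -> standardized u (population sd)
  u <- rnorm(9); v <- runif(12, 0.5, 2)
  st <- raw_stack(outer(u, v), c(12, 1, 1))
  got <- extract_eigenvariate(st, seq_len(12))
  uc <- u - mean(u)
  expect_equal(got, uc / sqrt(mean(uc^2)), tolerance = 1e-10)

  # arbitrary small stack vs dense SVD of the centred matrix (oracle)
  Y <- matrix(rnorm(6 * 10), 6, 10)
  got <- extract_eigenvariate(raw_stack(Y, c(10, 1, 1)), seq_len(10))
  Yc <- sweep(Y, 2, colMeans(Y))
  oracle <- svd(Yc, nu = 1, nv = 0)$u[, 1]
  cosang <- abs(sum(got * oracle)) / sqrt(sum(got^2) * sum(oracle^2))
  expect_gt(cosang, 1 - 1e-10)

  # voxel duplication leaves the leading direction unchanged
  got2 <- extract_eigenvariate(raw_stack(cbind(Y, Y), c(20, 1, 1)), seq_len(20))
  expect_equal(got2, got, tolerance = 1e-9)

  # constant masked data is an error, not NaN
  expect_error(extract_eigenvariate(raw_stack(matrix(3, 5, 4), c(4, 1, 1)),
                                    seq_len(4)), "constant")

  # two-unit stacks standardize to +/- 1
  got3 <- extract_eigenvariate(raw_stack(matrix(c(1, 2, 5, 3), 2, 2),
                                         c(2, 1, 1)), 1:2)
  expect_equal(sort(got3), c(-1, 1), tolerance = 1e-12)
})

test_that("eigenvariate standardization, sign rule and ordering invariance", {
  set.seed(31)
  Y <- matrix(rnorm(8 * 30), 8, 30) + outer(rnorm(8, sd = 2), rep(1, 30))
  st <- raw_stack(Y, c(30, 1, 1))
  s <- extract_eigenvariate(st, seq_len(30))
  expect_lt(abs(mean(s)), 1e-9)
  expect_equal(mean(s^2), 1, tolerance = 1e-9)
  expect_gte(stats::cor(s, rowMeans(Y)), 0)
  # deterministic sign across repeated runs
  expect_identical(s, extract_eigenvariate(st, seq_len(30)))
  # invariant to voxel ordering
  perm <- sample(30)
  expect_equal(extract_eigenvariate(raw_stack(Y[, perm], c(30, 1, 1)),
                                    seq_len(30)), s, tolerance = 1e-9)
})

test_that("global covariate recovers a planted uniform shift", {
  cfg <- two_region_config(rho = 0.3, n = 120, grid = 16L, semiax = 14,
                           radius = 3, noise_sd = 0.05, global_sd = 1, seed = 13)
  co <- generate_cohort(cfg)
  st <- stack_scans(co$manifest, co$volumes)
  g <- extract_global(st$S, co$masks$brain)
  m <- match(st$S$units$participant, co$manifest$participant)
  expect_gt(abs(stats::cor(g, co$ground_truth$global_signals[m])), 0.999)
  # whole-brain mask equal to an ROI mask gives that ROI's eigenvariate
  expect_identical(extract_global(st$S, co$masks$A),
                   extract_eigenvariate(st$S, co$masks$A))
})
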