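test_that("closed-form adjustment matches the leave-one-out oracle exactly", {
  # three equal-precision cohorts; removing the third must reproduce the
  # two-cohort meta computed independently
  m <- ivw_pool(c(0.1, 0.2, 0.3), c(0.1, 0.1, 0.1))
  expect_equal(m$B, 0.2)
  expect_equal(m$SE^2, 1 / 300)
  a <- adjust_marker(m$B, m$SE, 0.3, 0.1)
  expect_equal(a$status, "adjusted")
  expect_equal(a$w_n, 100)
  expect_equal(a$denom, 2 / 3)
  expect_equal(a$B_adj, 0.15)
  expect_equal(a$SE_adj^2, 0.005)
  ora <- oracle_pool(c(0.1, 0.2), c(0.1, 0.1))
  expect_equal(a$B_adj, ora$B, tolerance = 1e-14)
  expect_equal(a$SE_adj, ora$SE, tolerance = 1e-14)
})

test_that("two-cohort removal recovers the remaining cohort's estimate", {
  set.seed(12)
  M <- 1000
  b1 <- rnorm(M); s1 <- runif(M, 0.01, 0.5)
  b2 <- rnorm(M); s2 <- runif(M, 0.01, 0.5)
  W <- 1 / s1^2 + 1 / s2^2
  B <- (b1 / s1^2 + b2 / s2^2) / W
  SE <- sqrt(1 / W)
  a <- adjust_marker(B, SE, b2, s2)
  expect_true(all(a$status == "adjusted"))
  expect_equal(a$B_adj, b1, tolerance = 1e-12)
  expect_equal(a$SE_adj, s1, tolerance = 1e-12)
})

test_that("fixed point, SE monotonicity, and re-pooling round-trip hold over random draws", {
  set.seed(77)
  N <- 10000
  k <- sample(2:6, N, replace = TRUE)
  B <- SE <- bn <- sn <- numeric(N)
  for (i in seq_len(N)) {
    beta <- rnorm(k[i], 0, 0.3); se <- runif(k[i], 0.02, 0.5)
    m <- ivw_pool(beta, se)
    B[i] <- m$B; SE[i] <- m$SE; bn[i] <- beta[k[i]]; sn[i] <- se[k[i]]
  }
  a <- adjust_marker(B, SE, bn, sn)
  expect_true(all(a$status == "adjusted"))
  # removing a cohort can only lose information
  expect_true(all(a$SE_adj >= SE))
  # re-pooling the adjusted estimate with the removed cohort restores the
  # meta; B compared at its own scale max(|B|, SE) since pooled effects can
  # sit arbitrarily close to 0
  W_back <- 1 / a$SE_adj^2 + 1 / sn^2
  B_back <- (a$B_adj / a$SE_adj^2 + bn / sn^2) / W_back
  expect_lt(max(abs(B_back - B) / pmax(abs(B), SE)), 1e-12)
  expect_equal(sqrt(1 / W_back), SE, tolerance = 1e-12)

  # fixed point: a cohort sitting exactly at the pooled effect moves nothing
  fp <- adjust_marker(B, SE, B, sn)
  expect_equal(fp$B_adj, B, tolerance = 1e-14)
  expect_true(all(fp$SE_adj > SE))
})

test_that("degenerate inputs are flagged, not computed", {
  # removed cohort carries the whole weight: d = 0 exactly
  d0 <- adjust_marker(0.2, 0.1, 0.3, 0.1)
  expect_equal(d0$status, "dominant_cohort")
  expect_true(is.na(d0$B_adj) && is.na(d0$SE_adj))
  # cohort claims more weight than the meta: impossible for consistent input
  expect_warning(bad <- adjust_marker(0.2, 0.1, 0.3, 0.05),
                 "inconsistent_inputs")
  expect_equal(bad$status, "inconsistent_inputs")
  expect_true(is.na(bad$B_adj))
  # hard errors
  expect_error(adjust_marker(NA, 0.1, 0.1, 0.1), "non-finite")
  expect_error(adjust_marker(0.1, -0.1, 0.1, 0.1), "> 0")
  expect_error(adjust_marker(0.1, 0.1, 0.1, 0.1, eps = -1), "eps")
})

test_that("recompute_significance gives two-sided normal p in (0,1]", {
  s <- recompute_significance(0, 0.3)
  expect_equal(s$z, 0)
  expect_equal(s$p, 1)
  s2 <- recompute_significance(1.959964 * 0.25, 0.25)
  expect_equal(s2$p, 0.05, tolerance = 1e-4)
  expect_equal(recompute_significance(0.4, 0.1)$p,
               recompute_significance(-0.4, 0.1)$p)
})

test_that("adjust_table splits markers into adjusted and passthrough and keeps meta order", {
  tabs <- lapply(1:3, function(i) random_table(10, seed = 40 + i))
  meta <- meta_analyze(tabs)
  cohort <- tabs[[3]][1:6, ]  # cohort lacks markers 7..10
  cohort <- sumstats_table(as.data.frame(cohort))
  adj <- adjust_table(meta, cohort)
  expect_equal(nrow(adj$table), 10L)
  expect_equal(adj$table$marker_id, meta$marker_id)
  expect_equal(adj$status_counts[["adjusted"]], 6L)
  expect_equal(adj$status_counts[["passthrough_not_in_cohort"]], 4L)
  pass <- adj$table[adj$table$status == "passthrough_not_in_cohort", ]
  i <- match(pass$marker_id, meta$marker_id)
  expect_identical(pass$beta, meta$beta[i])  # meta values verbatim
  expect_identical(pass$se, meta$se[i])
})

test_that("full-overlap adjust_table equals leave_one_out_meta for every cohort", {
  cfg <- sim_config(K = 4, M = 2000, seed = 3)
  sim <- simulate_cohorts(cfg)
  meta <- meta_analyze(sim$tables)
  for (k in 1:4) {
    adj <- adjust_table(meta, sim$tables[[k]])
    loo <- leave_one_out_meta(sim$tables, k)
    i <- match(adj$table$marker_id, loo$marker_id)
    expect_true(all(adj$table$status == "adjusted"))
    expect_equal(adj$table$beta, loo$beta[i], tolerance = 1e-10)
    expect_equal(adj$table$se, loo$se[i], tolerance = 1e-10)
  }
})

test_that("oracle equivalence holds across K = 2..6 cohorts", {
  for (K in 2:6) {
    cfg <- sim_config(K = K, M = 1000, n_per_cohort = rep(15000, K),
                      seed = 50 + K)
    sim <- simulate_cohorts(cfg)
    meta <- meta_analyze(sim$tables)
    adj <- adjust_table(meta, sim$tables[[K]])
    loo <- leave_one_out_meta(sim$tables, K)
    i <- match(adj$table$marker_id, loo$marker_id)
    rel_b <- abs(adj$table$beta - loo$beta[i]) / pmax(abs(loo$beta[i]), 1e-30)
    expect_lt(max(rel_b), 1e-10)
    expect_gt(cor(adj$table$beta, loo$beta[i]), 1 - 1e-12)
    expect_gt(cor(adj$table$se^2, loo$se[i]^2), 1 - 1e-12)
  }
})

test_that("a swapped-allele cohort still matches the aligned-input oracle", {
  cfg <- sim_config(K = 3, M = 500, n_per_cohort = rep(20000, 3), seed = 8)
  sim <- simulate_cohorts(cfg)
  meta <- meta_analyze(sim$tables)
  pert <- perturb_alleles(sim$tables[[2]], fraction_swapped = 0.5, seed = 4)
  adj <- adjust_table(meta, pert)
  loo <- leave_one_out_meta(sim$tables, 2)  # oracle on pre-aligned tables
  adj_ok <- adj$table[adj$table$status == "adjusted", ]
  i <- match(adj_ok$marker_id, loo$marker_id)
  expect_equal(adj_ok$beta, loo$beta[i], tolerance = 1e-10)
  expect_equal(adj_ok$se, loo$se[i], tolerance = 1e-10)
})

test_that("iterated adjustment removes two cohorts one at a time", {
  cfg <- sim_config(K = 4, M = 300, seed = 15)
  sim <- simulate_cohorts(cfg)
  meta <- meta_analyze(sim$tables)
  a1 <- adjust_table(meta, sim$tables[[4]])
  t1 <- sumstats_table(a1$table[c("marker_id", "effect_allele",
                                  "other_allele", "beta", "se")])
  a2 <- adjust_table(t1, sim$tables[[3]])
  direct <- meta_analyze(sim$tables[1:2])
  i <- match(a2$table$marker_id, direct$marker_id)
  expect_equal(a2$table$beta, direct$beta[i], tolerance = 1e-9)
  expect_equal(a2$table$se, direct$se[i], tolerance = 1e-9)
})

test_that("write_adjustment emits a re-readable table of adjusted statistics", {
  cfg <- sim_config(K = 3, M = 50, n_per_cohort = rep(10000, 3), seed = 21)
  sim <- simulate_cohorts(cfg)
  meta <- meta_analyze(sim$tables)
  adj <- adjust_table(meta, sim$tables[[1]])
  path <- tempfile(fileext = ".tsv")
  write_adjustment(adj, path)
  back <- read_sumstats(path, dialect = dialect(
    marker_id = "marker_id", beta = "beta", se = "se",
    effect_allele = "effect_allele", other_allele = "other_allele",
    pvalue = "pvalue"))
  expect_identical(back$beta, adj$table$beta)
  expect_identical(back$se, adj$table$se)
})
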