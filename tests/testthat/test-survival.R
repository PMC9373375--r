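test_that("product-limit estimate matches hand computation", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  # all censored: no event steps, curve stays flat at 1
  flat <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(flat), 0L)
  # censoring decrements the risk set without a step:
  # times 1,2,2,3 / events 1,1,0,1 -> S(1)=3/4, S(2)=1/2, S(3)=0
  km2 <- km_estimate(c(1, 2, 2, 3), c(1, 1, 0, 1))
  expect_equal(km2$surv, c(3 / 4, 1 / 2, 0))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(2)
  tt <- rexp(40)
  km <- km_estimate(tt, rep(1, 40))
  emp <- vapply(km$time, function(s) mean(tt > s), numeric(1))
  expect_equal(km$surv, emp)
})

test_that("log-rank statistic equals the direct O-E/V oracle", {
  expect_error(logrank_test(1:3, c(1, 1, 1), c("a", "a", "a")), "groups")
  grp <- rep(c("a", "b"), each = 5)
  same <- logrank_test(rep(1:5, 2), rep(1, 10), grp)
  expect_lt(same$statistic, 1e-12)
  expect_equal(same$p_value, 1)
  set.seed(14)
  for (i in 1:100) {
    n <- sample(8:30, 1)
    tt <- round(rexp(n), 2) + 0.01
    ee <- rbinom(n, 1, 0.8)
    gg <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(gg)) < 2 || sum(ee) == 0) next
    lr <- logrank_test(tt, ee, gg)
    expect_equal(lr$statistic, logrank_oracle(tt, ee, gg), tolerance = 1e-9)
  }
})

test_that("cox_fit agrees with an exhaustive partial-likelihood grid search", {
  set.seed(5)
  n <- 25
  x <- rbinom(n, 1, 0.5)
  tt <- round(rexp(n, exp(0.8 * x) / 10), 3)
  fit <- cox_fit(data.frame(x = x), tt, rep(1, n))
  beta_hat <- log(fit$hr)
  beta_grid <- cox_grid_oracle(x, tt, rep(1, n))
  expect_lt(abs(beta_hat - beta_grid), 1.5e-3)
})

test_that("cox_fit recovers simulated hazard ratios at n = 2000", {
  set.seed(6)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  # true HR = 1
  tt <- rexp(n, 0.02)
  cens <- rexp(n, 0.01)
  fit0 <- cox_fit(data.frame(x = x), pmin(tt, cens),
                  as.integer(tt <= cens))
  expect_gt(fit0$hr, 0.85); expect_lt(fit0$hr, 1.18)
  # true HR = 3
  tt3 <- rexp(n, 0.02 * exp(log(3) * x))
  fit3 <- cox_fit(data.frame(x = x), pmin(tt3, cens),
                  as.integer(tt3 <= cens))
  expect_gt(fit3$hr, 2.2); expect_lt(fit3$hr, 4.1)
})

test_that("monotone-likelihood levels are flagged with infinite CIs", {
  # all events in the x=0 level, none in x=1: coefficient diverges
  x <- rep(c(0, 1), each = 10)
  tt <- c(1:10, rep(20, 10))
  ee <- c(rep(1, 10), rep(0, 10))
  fit <- suppressWarnings(cox_fit(data.frame(x = x), tt, ee))
  expect_true(fit$infinite_ci[1])
})

test_that("backward stepwise removes noise and keeps real effects", {
  set.seed(7)
  n <- 600
  x_real <- rbinom(n, 1, 0.4)
  noise <- data.frame(z1 = rnorm(n), z2 = rbinom(n, 1, 0.5), z3 = rnorm(n))
  tt <- rexp(n, 0.02 * exp(log(3) * x_real))
  cens <- rexp(n, 0.015)
  covs <- cbind(data.frame(x_real = x_real), noise)
  res <- stepwise_backward(covs, pmin(tt, cens), as.integer(tt <= cens))
  expect_true("x_real" %in% attr(res, "retained"))
  expect_true(all(res$p_value <= 0.05 + 1e-12))
  # a model whose covariates are all strong stays unchanged
  res2 <- stepwise_backward(data.frame(x_real = x_real),
                            pmin(tt, cens), as.integer(tt <= cens))
  expect_identical(attr(res2, "eliminated"), character(0))
  # gene dummy pairs leave jointly
  units <- clonarch:::.default_units(c("G1_subclonal_vs_WT",
                                       "G1_clonal_vs_WT", "age_high"))
  expect_equal(units$G1, c("G1_subclonal_vs_WT", "G1_clonal_vs_WT"))
})

test_that("pure-noise models can eliminate everything, flagged", {
  set.seed(8)
  n <- 300
  covs <- data.frame(z = rnorm(n))
  tt <- rexp(n, 0.05)
  res <- stepwise_backward(covs, tt, rep(1, n))
  if (length(attr(res, "retained")) == 0) {
    expect_true(attr(res, "empty_model"))
    expect_equal(nrow(res), 0L)
  } else {
    expect_lte(min(res$p_value), 0.05)
  }
})

test_that("bootstrap inclusion frequencies separate strong from null effects", {
  set.seed(9)
  n <- 600
  x <- rbinom(n, 1, 0.5)
  z <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.02 * exp(log(10) * x))
  cens <- rexp(n, 0.01)
  covs <- data.frame(x = x, z = z)
  bs <- bootstrap_stability(covs, pmin(tt, cens), as.integer(tt <= cens),
                            B = 100, seed = 31)
  expect_gte(bs$inclusion_frequency["x"], 0.99)
  expect_lt(bs$inclusion_frequency["z"], 0.5)
  bs2 <- bootstrap_stability(covs, pmin(tt, cens), as.integer(tt <= cens),
                             B = 100, seed = 31)
  expect_identical(bs$inclusion_frequency, bs2$inclusion_frequency)
})

test_that("gene survival scan enforces eligibility and subgroup evaluability", {
  sim <- simulate_cohort(sim_config(n_patients = 300), seed = 41)
  calls <- call_clonality(sim$bundle)
  categories <- patient_gene_category(calls,
                                      samples = sim$bundle$clinical$sample_id)
  km <- gene_survival_scan(categories, sim$bundle$clinical, min_patients = 5)
  for (g in km$gene) {
    cat_g <- categories[[g]]
    should <- sum(cat_g == "clonal") >= 5 && sum(cat_g == "subclonal") >= 5
    expect_identical(km$eligible[km$gene == g], should)
  }
  expect_true(all(is.na(km$p_overall[!km$eligible])))
  # subgroup restriction returns NA where a category empties
  sub <- gene_survival_scan(categories, sim$bundle$clinical,
                            min_patients = 5, subgroup = "msi")
  expect_true(is.data.frame(sub))
  expect_true(all(is.na(sub$p_overall) | sub$p_overall >= 0))
})
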