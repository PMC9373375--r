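test_that("simulated read fractions converge to the analytic expected VAF", {
  set.seed(42)
  r <- simulate_reads(1, purity = 1, local_cn = 2, depth = 1e6)
  expect_equal(r$t_alt / r$t_depth, 0.5, tolerance = 0.002 / 0.5)
  r <- simulate_reads(0.4, purity = 0.5, local_cn = 2, depth = 1e6)
  expect_equal(r$t_alt / r$t_depth, 0.10, tolerance = 0.002 / 0.10)
  expect_error(simulate_reads(0.5, 0.5, 0, 100), "local_cn")
})

test_that("simulate_reads is deterministic under a fixed seed", {
  set.seed(7); a <- simulate_reads(0.6, 0.7, 2, 120)
  set.seed(7); b <- simulate_reads(0.6, 0.7, 2, 120)
  expect_identical(a, b)
})

test_that("observation model consistency: replicate alt fractions match the model", {
  set.seed(3)
  cases <- data.frame(ccf = c(1, 0.5, 0.25), purity = c(0.9, 0.6, 0.4),
                      cn = c(2, 3, 2))
  for (i in seq_len(nrow(cases))) {
    ev <- expected_vaf(cases$purity[i], cases$ccf[i], cases$cn[i])
    reps <- simulate_reads(rep(cases$ccf[i], 3000), cases$purity[i],
                           cases$cn[i], depth = 100)
    se <- sqrt(ev * (1 - ev) / (3000 * 100))
    expect_lt(abs(mean(reps$t_alt / reps$t_depth) - ev), 3 * se)
  }
})

test_that("gene clonal bias and mutation rate govern the generated truth", {
  genes <- data.frame(gene = c("G1", "G2"), rate = c(0.5, 0.3),
                      clonal_bias = c(1.0, 0.5))
  cfg <- sim_config(n_patients = 200, genes = genes, msi_rate_mult = 1,
                    msi_link = NULL,
                    loghr_effects = data.frame(gene = character(),
                                               label = character(),
                                               loghr = numeric()))
  sim <- simulate_cohort(cfg, seed = 2)
  tg1 <- sim$truth[sim$truth$gene == "G1", ]
  expect_true(all(tg1$true_label == "clonal"))
  expect_true(all(tg1$true_ccf == 1))
  n_g2 <- sum(sim$truth$gene == "G2")
  expect_lt(abs(n_g2 - 60), 3 * sqrt(200 * 0.3 * 0.7))
  # truth labels and CCFs agree by construction
  expect_true(all((sim$truth$true_label == "clonal") ==
                    (sim$truth$true_ccf == 1)))
  expect_true(all(sim$truth$true_ccf[sim$truth$true_label == "subclonal"] < 0.9))
})

test_that("same seed yields byte-identical cohort files", {
  cfg <- sim_config(n_patients = 40)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_cohort(cfg, seed = 9); write_cohort(s1$bundle, s1$truth, d1)
  s2 <- simulate_cohort(cfg, seed = 9); write_cohort(s2$bundle, s2$truth, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(genes = data.frame()), "genes")
  expect_error(sim_config(subclonal_ccf_range = c(0.2, 0.95)), "0.9")
  expect_error(sim_config(censor_rate = 1), "censor_rate")
})

test_that("a configured subclonal log-HR of log(3) is recovered by Cox on truth", {
  cfg <- sim_config(n_patients = 2000,
                    genes = data.frame(gene = "GX", rate = 0.3,
                                       clonal_bias = 0.5),
                    msi_link = NULL, msi_rate_mult = 1,
                    loghr_effects = data.frame(gene = "GX",
                                               label = "subclonal",
                                               loghr = log(3)),
                    clinical_loghr = NULL)
  sim <- simulate_cohort(cfg, seed = 4)
  clin <- sim$bundle$clinical
  sub_ids <- sim$truth$sample_id[sim$truth$true_label == "subclonal"]
  x <- as.integer(clin$sample_id %in% sub_ids)
  fit <- cox_fit(data.frame(gx_subclonal = x), clin$os_time, clin$os_event)
  expect_gt(fit$hr, 2.2)
  expect_lt(fit$hr, 4.1)
})
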