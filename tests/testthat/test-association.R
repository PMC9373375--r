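test_that("both-carrier patients collapse according to the stated rule", {
  sim <- simulate_cohort(sim_config(n_patients = 80, both_rate = 0.5),
                         seed = 17)
  calls <- call_clonality(sim$bundle)
  arch <- calls$patient_architecture
  both_idx <- which(arch == "both", arr.ind = TRUE)
  expect_gt(nrow(both_idx), 0)
  cd <- patient_gene_category(calls, rule = "clonal-dominant")
  sd <- patient_gene_category(calls, rule = "subclonal-dominant")
  i <- both_idx[1, ]
  expect_equal(cd[i[1], i[2]], "clonal")
  expect_equal(sd[i[1], i[2]], "subclonal")
  # unmutated patients are WT under both rules
  wt_idx <- which(arch == "WT", arr.ind = TRUE)[1, ]
  expect_equal(cd[wt_idx[1], wt_idx[2]], "WT")
})

test_that("exact 2x2 p-values match the hypergeometric-sum oracle", {
  expect_equal(fisher_exact_2xk(rbind(c(2, 0), c(0, 2)))$p_value, 1 / 3,
               tolerance = 1e-10)
  expect_equal(fisher_exact_2xk(rbind(c(5, 5), c(5, 5)))$p_value, 1,
               tolerance = 1e-10)
  set.seed(8)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(2:15, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2xk(tab)$p_value, fisher_2x2_oracle(tab),
                 tolerance = 1e-10)
  }
})

test_that("2x3 exact p-values agree with the classical implementation", {
  set.seed(12)
  for (i in 1:40) {
    tab <- matrix(rpois(6, sample(3:25, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    mine <- fisher_exact_2xk(tab)
    expect_equal(mine$method, "fisher-exact")
    expect_equal(mine$p_value, stats::fisher.test(tab)$p.value,
                 tolerance = 1e-6)
  }
})

test_that("Monte-Carlo fallback agrees with enumeration within sampling error", {
  tab <- rbind(c(30, 8, 40), c(25, 15, 35))
  exact <- fisher_exact_2xk(tab)
  mc <- fisher_exact_2xk(tab, max_tables = 1, mc_draws = 1e5, seed = 3)
  expect_equal(mc$method, "fisher-montecarlo")
  p <- exact$p_value
  expect_lt(abs(mc$p_value - p), 3 * sqrt(p * (1 - p) / 1e5) + 1e-5)
})

test_that("degenerate tables are flagged not evaluable", {
  expect_false(fisher_exact_2xk(rbind(c(0, 0), c(1, 2)))$evaluable)
  expect_false(fisher_exact_2xk(rbind(c(3, 0), c(2, 0)))$evaluable)
})

test_that("association scan applies the >=5 carrier filter and median age split", {
  sim <- simulate_cohort(sim_config(n_patients = 250), seed = 23)
  calls <- call_clonality(sim$bundle)
  categories <- patient_gene_category(calls,
                                      samples = sim$bundle$clinical$sample_id)
  scan <- association_scan(categories, sim$bundle$clinical, min_patients = 5)
  res <- scan$results
  gs <- calls$gene_summary
  for (g in gs$gene) {
    cat_g <- categories[[g]]
    should <- sum(cat_g == "clonal") >= 5 && sum(cat_g == "subclonal") >= 5
    expect_identical(unique(res$eligible[res$gene == g]), should)
  }
  expect_true(all(is.na(res$p_value[!res$eligible])))
  expect_true(all(res$p_value[res$eligible] >= 0 &
                    res$p_value[res$eligible] <= 1))
})

test_that("a configured MSI-subclonality link is detected by the scan", {
  cfg <- sim_config(n_patients = 600,
                    genes = data.frame(gene = "GL", rate = 0.3,
                                       clonal_bias = 0.5),
                    depth_mean = 250,
                    msi_prevalence = 0.3, msi_rate_mult = 1,
                    msi_link = list(gene = "GL", odds = 8),
                    loghr_effects = NULL, clinical_loghr = NULL)
  sim <- simulate_cohort(cfg, seed = 29)
  calls <- call_clonality(sim$bundle)
  categories <- patient_gene_category(calls,
                                      samples = sim$bundle$clinical$sample_id)
  scan <- association_scan(categories, sim$bundle$clinical)
  p <- scan$results$p_value[scan$results$gene == "GL" &
                              scan$results$variable == "msi_status"]
  expect_lt(p, 0.05)
})

test_that("burden comparisons separate well-separated groups and flag tiny ones", {
  same <- burden_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3),
                         method = "t-test")
  expect_equal(same$p_value, 1)
  far <- burden_compare(c(1, 2, 3, 101, 102, 103),
                        rep(c("a", "b"), each = 3), method = "t-test")
  expect_lt(far$p_value, 1e-3)
  wil <- burden_compare(c(1:10, 101:110), rep(c("a", "b"), each = 10),
                        method = "wilcoxon")
  expect_lt(wil$p_value, 1e-3)
  tiny <- burden_compare(c(1, 2, 3), c("a", "a", "b"))
  expect_false(tiny$evaluable)
})

test_that("mutation-type tests reproduce the enumerated indel example", {
  calls <- structure(list(calls = data.frame(
    gene = "G",
    sample_id = sprintf("S%d", 1:10),
    variant_class = rep(c("Frame_Shift_Del", "Missense_Mutation"), each = 5),
    label = rep(c("subclonal", "clonal"), each = 5),
    stringsAsFactors = FALSE)), class = "clonality_calls")
  res <- mutation_type_vs_clonality(calls)
  indel <- res[res$comparison == "indel", ]
  expect_equal(indel$p_value, 2 / 252, tolerance = 1e-10)
  # label swap leaves the two-sided p unchanged
  calls$calls$label <- ifelse(calls$calls$label == "clonal",
                              "subclonal", "clonal")
  res2 <- mutation_type_vs_clonality(calls)
  expect_equal(res2$p_value[res2$comparison == "indel"], indel$p_value)
  # single-mutation gene is not evaluable
  calls$calls <- calls$calls[1, ]
  expect_false(any(mutation_type_vs_clonality(calls)$evaluable))
})
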