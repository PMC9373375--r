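test_that("the CCF grid spans 0.01 to 1.00 in 100 even steps", {
  g <- ccf_grid()
  expect_length(g, 100L)
  expect_equal(g[1], 0.01)
  expect_equal(g[100], 1.00)
  expect_true(all(abs(diff(g) - 0.01) < 1e-12))
})

test_that("expected_vaf matches hand-evaluated cases and guards degeneracy", {
  expect_equal(expected_vaf(1.0, 1.0, 2), 0.5)
  expect_equal(expected_vaf(0.5, 1.0, 2), 0.25)
  expect_equal(expected_vaf(0.6, 0.5, 3), 0.3 / 2.6)
  expect_error(expected_vaf(1.0, 0.5, 0), "degenerate")
  expect_error(expected_vaf(0, 0.5, 2), "purity")
})

test_that("posterior MAP and tails behave at the anchoring read counts", {
  p0 <- ccf_posterior(0, 1000, purity = 0.8, local_cn = 2)
  expect_equal(p0$map_ccf, 0.01)
  expect_gt(p0$p_subclonal, 0.99)

  p1 <- ccf_posterior(25, 100, purity = 0.5, local_cn = 2)
  expect_equal(p1$map_ccf, 1.00)
  expect_equal(classify_clonality(p1), "clonal")

  p2 <- ccf_posterior(10, 100, purity = 0.5, local_cn = 2)
  expect_lte(abs(p2$map_ccf - 0.40), 0.01)
  expect_equal(classify_clonality(p2), "subclonal")
})

test_that("posteriors normalize to 1 and match the direct-probability oracle", {
  set.seed(11)
  for (i in 1:60) {
    N <- sample(30:800, 1)
    t <- rbinom(1, N, runif(1, 0.02, 0.6))
    purity <- runif(1, 0.2, 1)
    cn <- sample(1:5, 1)
    post <- ccf_posterior(t, N, purity, cn)
    expect_lt(abs(sum(post$probs) - 1), 1e-9)
    naive <- naive_ccf_posterior(t, N, purity, cn)
    if (!is.null(naive)) {
      tv <- 0.5 * sum(abs(post$probs - naive))
      expect_lt(tv, 1e-9)
    }
  }
})

test_that("MAP CCF is non-decreasing in the alt read count", {
  for (purity in c(0.4, 0.8)) {
    maps <- vapply(0:80, function(t)
      ccf_posterior(t, 80, purity, 2)$map_ccf, numeric(1))
    expect_true(all(diff(maps) >= 0))
  }
})

test_that("stored posterior summaries always satisfy the call invariant", {
  set.seed(21)
  for (i in 1:40) {
    N <- sample(30:400, 1)
    post <- ccf_posterior(rbinom(1, N, runif(1, 0.05, 0.5)), N,
                          runif(1, 0.3, 1), sample(1:4, 1))
    lab <- classify_clonality(post)
    expect_identical(lab == "subclonal",
                     !post$ci_high_at_top && post$p_subclonal > 0.5)
    expect_lte(post$ci_low, post$map_ccf)
    expect_gte(post$ci_high, post$map_ccf)
  }
})

test_that("MAP CCF tracks truth closely at depth 500", {
  set.seed(31)
  truth <- runif(400, 0.2, 0.8)
  reads <- simulate_reads(truth, purity = 0.7, local_cn = 2, depth = 500)
  maps <- vapply(seq_along(truth), function(i)
    ccf_posterior(reads$t_alt[i], 500, 0.7, 2)$map_ccf, numeric(1))
  expect_lt(mean(abs(maps - truth)), 0.07)  # analytic SE is ~0.05 per site
})

test_that("KS uniformity test flags short input and detects point masses", {
  flat <- ks_uniformity(c(0.25, 0.5, 0.75))
  expect_true(flat$evaluable)
  expect_lte(flat$statistic, 0.25)
  peak <- ks_uniformity(rep(0.99, 100))
  expect_gte(peak$statistic, 0.98)
  expect_lt(peak$p_value, 1e-3)
  expect_false(ks_uniformity(c(0.2, 0.4))$evaluable)
})

test_that("annotation joins purity and copy number and itemizes exclusions", {
  ann <- annotate_mutations(toy_bundle())
  m <- ann$mutations
  # S1 position 50 sits in the 1-100 segment with CN 2
  expect_equal(m$local_cn[m$sample_id == "S1" & m$pos == 50], 2L)
  expect_equal(m$purity[m$sample_id == "S1"][1], 0.6)
  sk <- ann$skip_report
  expect_equal(sk$n[sk$reason == "non-autosome"], 1L)       # chrX mutation
  expect_equal(sk$n[sk$reason == "homozygous-deletion"], 1L) # CN 0 segment
  expect_equal(sk$n[sk$reason == "no-purity"], 1L)           # sample S3
  expect_false(any(m$chrom == "X"))
})

test_that("cohort calls conserve counts and count absent genes as WT", {
  sim <- simulate_cohort(sim_config(n_patients = 60), seed = 13)
  calls <- call_clonality(sim$bundle)
  gs <- calls$gene_summary
  for (g in gs$gene) {
    cg <- calls$calls[calls$calls$gene == g, ]
    expect_equal(gs$c1[gs$gene == g] + gs$s1[gs$gene == g], nrow(cg))
  }
  # patient categories partition the cohort
  n_cohort <- length(unique(c(sim$bundle$purities$sample_id,
                              sim$bundle$clinical$sample_id)))
  expect_true(all(gs$patients_clonal_only + gs$patients_subclonal_only +
                    gs$patients_both + gs$patients_wt == n_cohort))
  # a sample with no mutation in a gene is WT in the architecture table
  arch <- calls$patient_architecture
  g1 <- gs$gene[1]
  unmut <- setdiff(arch$sample_id,
                   calls$calls$sample_id[calls$calls$gene == g1])
  expect_true(all(arch[[g1]][arch$sample_id %in% unmut] == "WT"))
  # silent mutations are excluded and accounted for
  expect_equal(nrow(calls$calls) +
                 sum(calls$skip_report$n),
               nrow(sim$bundle$mutations))
})
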