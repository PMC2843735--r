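test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_snps = 100, n_cases = 0),
               class = "psagwas_config_error")
  expect_error(sim_config(n_snps = 100, n_controls = 0),
               class = "psagwas_config_error")
  expect_error(sim_config(n_snps = 10, causal_ids = 11, causal_or = 2),
               class = "psagwas_config_error")
  expect_error(sim_config(n_snps = 10, causal_ids = 1, causal_or = 0),
               class = "psagwas_config_error")
  expect_error(sim_config(n_snps = 10, causal_ids = 1, causal_or = -2),
               class = "psagwas_config_error")
  expect_error(sim_config(n_snps = 10, prioritized_subset_size = 11),
               class = "psagwas_config_error")
  expect_error(sim_config(n_snps = 10, maf_range = c(0, 0.5)),
               class = "psagwas_config_error")
  expect_error(sim_config(n_snps = 10, missing_rate = 1),
               class = "psagwas_config_error")
})

test_that("same seed gives a bit-identical panel, different seed does not", {
  cfg <- sim_config(n_snps = 50, causal_ids = 1:2, causal_or = 2,
                    missing_rate = 0.05, seed = 7)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1, p2)
  cfg2 <- sim_config(n_snps = 50, causal_ids = 1:2, causal_or = 2,
                     missing_rate = 0.05, seed = 8)
  expect_false(identical(simulate_panel(cfg2)$dosages, p1$dosages))
})

test_that("panel has consistent dimensions, labels and dosage values", {
  cfg <- sim_config(n_snps = 30, n_cases = 9, n_controls = 4,
                    missing_rate = 0.1, seed = 3)
  panel <- simulate_panel(cfg)
  expect_equal(n_snps(panel), 30)
  expect_equal(n_samples(panel), 13)
  expect_equal(sum(panel$samples$status == "case"), 9)
  expect_true(all(panel$dosages[!is.na(panel$dosages)] %in% 0:2))
  expect_true(all(diff(panel$map$pos) == 1000))
  expect_false(anyDuplicated(panel$map$snp_id) > 0)
})

test_that("control MAF is recovered within sampling error at large n", {
  # one SNP, control MAF 0.3, OR 1, 10,000 controls: binomial oracle
  cfg <- sim_config(n_snps = 1, n_cases = 2, n_controls = 10000,
                    maf_range = c(0.3, 0.3), seed = 99)
  panel <- simulate_panel(cfg)
  ctrl <- panel$dosages[1, panel$samples$status == "control"]
  f <- sum(ctrl) / (2 * length(ctrl))
  se <- sqrt(0.3 * 0.7 / (2 * 10000))
  expect_lt(abs(f - 0.3), 3 * se)
})

test_that("control genotypes follow Hardy-Weinberg proportions at large n", {
  cfg <- sim_config(n_snps = 1, n_cases = 2, n_controls = 20000,
                    maf_range = c(0.25, 0.25), seed = 123)
  ctrl <- simulate_panel(cfg)$dosages[1, -(1:2)]
  expected <- 20000 * c(0.75^2, 2 * 0.25 * 0.75, 0.25^2)
  observed <- tabulate(ctrl + 1, nbins = 3)
  expect_gt(chisq.test(observed, p = expected / sum(expected))$p.value, 1e-4)
})

test_that("null panels give the allelic test its nominal type-I error", {
  cfg <- sim_config(n_snps = 2000, seed = 2718)
  sc <- association_scan(simulate_panel(cfg))
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(mean(sc$p_value <= 0.05) - 0.05), 3 * se)
})

test_that("the odds-ratio model shifts the case allele frequency as specified", {
  # OR 3 at control MAF 0.25: case freq = 3*(1/3)/(1 + 3*(1/3)) = 0.5
  cfg <- sim_config(n_snps = 1, n_cases = 20000, n_controls = 100,
                    maf_range = c(0.25, 0.25), causal_ids = 1L,
                    causal_or = 3, seed = 5)
  case <- simulate_panel(cfg)$dosages[1, 1:20000]
  f1 <- mean(case) / 2
  se <- sqrt(0.5 * 0.5 / (2 * 20000))
  expect_lt(abs(f1 - 0.5), 3 * se)
})

test_that("simulated regions cover the configured subset and causal fraction", {
  cfg <- sim_config(n_snps = 200, causal_ids = c(5L, 50L, 120L),
                    causal_or = 3, prioritized_subset_size = 40,
                    prioritized_fraction_of_causal = 1, seed = 10)
  panel <- simulate_panel(cfg)
  regions <- simulate_regions(cfg, panel)
  asn <- assign_subsets(panel, regions)
  expect_equal(sum(asn$prioritized), 40)
  expect_true(all(asn$prioritized[cfg$causal_ids]))

  # fraction 0: no causal SNP inside
  cfg0 <- sim_config(n_snps = 200, causal_ids = c(5L, 50L, 120L),
                     causal_or = 3, prioritized_subset_size = 40,
                     prioritized_fraction_of_causal = 0, seed = 10)
  asn0 <- assign_subsets(panel, simulate_regions(cfg0, panel))
  expect_equal(sum(asn0$prioritized), 40)
  expect_false(any(asn0$prioritized[cfg0$causal_ids]))
})

test_that("region simulation is deterministic and honors edge cases", {
  cfg <- sim_config(n_snps = 100, causal_ids = 1:4, causal_or = 2,
                    prioritized_subset_size = 20, seed = 77)
  panel <- simulate_panel(cfg)
  expect_identical(simulate_regions(cfg, panel), simulate_regions(cfg, panel))

  cfg0 <- sim_config(n_snps = 100, prioritized_subset_size = 0, seed = 77)
  expect_equal(nrow(simulate_regions(cfg0, simulate_panel(cfg0))), 0)

  # byte-identical file output under the same seed
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_regions(simulate_regions(cfg, panel), f1)
  write_regions(simulate_regions(cfg, panel), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("case and control genotypes are exchangeable when OR = 1", {
  # pooled genotype distribution must match between groups at large n
  cfg <- sim_config(n_snps = 1, n_cases = 20000, n_controls = 20000,
                    maf_range = c(0.2, 0.2), seed = 31)
  panel <- simulate_panel(cfg)
  case <- panel$dosages[1, panel$samples$status == "case"]
  ctrl <- panel$dosages[1, panel$samples$status == "control"]
  tab <- rbind(tabulate(case + 1, 3), tabulate(ctrl + 1, 3))
  expect_gt(chisq.test(tab)$p.value, 1e-4)
})
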