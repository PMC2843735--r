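test_that("Bonferroni threshold is alpha/m with validated inputs", {
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(20, 0.05), 0.0025)
  expect_error(bonferroni_threshold(0, 0.05))
  expect_error(bonferroni_threshold(10, 1.5))
})

test_that("pi0 estimation recovers known null proportions", {
  set.seed(71)
  est <- estimate_pi0(runif(10000))
  expect_gte(est$pi0, 0.90)
  expect_lte(est$pi0, 1.0)
  expect_equal(est$method, "spline")
  expect_true(all(est$raw_pi0 >= 0))

  # pathological: everything in the far right tail clamps at 1
  expect_equal(estimate_pi0(rep(0.97, 500))$pi0, 1)

  # 50/50 uniform + Beta(0.05, 1) mixture: known pi0 = 0.5
  set.seed(72)
  p <- c(runif(10000), rbeta(10000, 0.05, 1))
  expect_lt(abs(estimate_pi0(p)$pi0 - 0.5), 0.1)
})

test_that("small inputs fall back to the conservative pi0 = 1", {
  expect_warning(est <- estimate_pi0(runif(10)), "falling back")
  expect_equal(est$pi0, 1)
  expect_equal(est$method, "fixed")
  expect_silent(estimate_pi0(runif(10), warn = FALSE))
})

test_that("q-values match brute-force step-up enumeration", {
  expect_equal(qvalues(0.37), 0.37)  # m = 1, pi0 = 1 identity
  p <- c(0.01, 0.02, 0.03, 0.9)
  expect_equal(qvalues(p), qvalues_bruteforce(p))

  set.seed(81)
  for (i in 1:25) {
    n <- sample(2:10, 1)
    p <- round(runif(n), 2)  # rounding forces ties regularly
    for (pi0 in c(1, 0.6)) {
      expect_equal(qvalues(p, pi0), qvalues_bruteforce(p, pi0),
                   info = paste(pi0, paste(p, collapse = ",")))
    }
  }
})

test_that("q-values are monotone in p, bounded by pi0, and permutation-invariant", {
  set.seed(82)
  p <- runif(500)
  q <- qvalues(p, pi0 = 0.8)
  expect_true(all(q <= 0.8 + 1e-12))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  sh <- sample(500)
  expect_equal(qvalues(p[sh], 0.8), q[sh])
  expect_error(qvalues(c(0.5, 1.2)))
})

test_that("traditional FDR discoveries behave at the extremes", {
  expect_length(fdr_discoveries(rep(1, 200), warn = FALSE)$discoveries, 0)
  # 20 overwhelming signals among 5000 are all discovered
  set.seed(83)
  p <- c(rep(1e-8, 20), runif(4980))
  res <- fdr_discoveries(p, alpha = 0.05)
  expect_true(all(1:20 %in% res$discoveries))
  expect_true(all(res$qvalues[res$discoveries] <= 0.05))
})

test_that("null FDR discoveries are rare and empirical FDR is controlled", {
  # all-null: FDP is 1{any discovery}; expect rate near alpha
  set.seed(84)
  fdp <- vapply(1:200, function(i) {
    res <- fdr_discoveries(runif(5000), alpha = 0.05, warn = FALSE)
    as.numeric(length(res$discoveries) > 0)
  }, numeric(1))
  se <- sd(fdp) / sqrt(200)
  expect_lte(mean(fdp), 0.05 + 3 * se)
})

test_that("PSA with a trivial partition reduces exactly to traditional FDR", {
  set.seed(85)
  p <- c(rep(1e-7, 5), runif(995))
  res1 <- psa(p, rep(TRUE, 1000), alpha = 0.05)
  res2 <- psa(p, rep(FALSE, 1000), alpha = 0.05)
  trad <- fdr_discoveries(p, alpha = 0.05, warn = FALSE)
  expect_identical(res1$discoveries, trad$discoveries)
  expect_identical(res2$discoveries, trad$discoveries)
  expect_equal(res1$snps$q_value, trad$qvalues)
})

test_that("PSA harvests the union of per-stratum discoveries with no sharing", {
  set.seed(86)
  p <- c(rep(1e-6, 3), runif(497), rep(1e-6, 2), runif(498))
  prio <- rep(c(TRUE, FALSE), each = 500)
  res <- psa(p, prio, alpha = 0.05)
  in_p <- intersect(res$discoveries, which(prio))
  in_n <- intersect(res$discoveries, which(!prio))
  expect_setequal(res$discoveries, union(in_p, in_n))
  # per-stratum q-values equal standalone runs on each stratum alone
  fit_p <- fdr_discoveries(p[prio], alpha = 0.05, warn = FALSE)
  expect_equal(res$snps$q_value[prio], fit_p$qvalues)
  # q-value monotonicity within each stratum
  for (s in list(which(prio), which(!prio))) {
    ord <- s[order(p[s])]
    expect_true(all(diff(res$snps$q_value[ord]) >= -1e-12))
  }
  # all-1 input: nothing anywhere
  expect_length(psa(rep(1, 1000), prio)$discoveries, 0)
})

test_that("PSA handles empty strata and assignment tibbles", {
  p <- c(0.001, 0.5, 0.9)
  res <- psa(p, rep(FALSE, 3))
  expect_equal(res$strata$prioritized$n, 0L)
  asn <- tibble::tibble(snp_id = c("a", "b", "c"),
                        prioritized = c(TRUE, FALSE, FALSE),
                        matched_regions = c("r1", "", ""))
  res2 <- psa(p, asn)
  expect_equal(res2$snps$snp_id, c("a", "b", "c"))
  expect_equal(res2$snps$stratum,
               c("prioritized", "non_prioritized", "non_prioritized"))
  g <- glance(res2)
  expect_equal(g$stratum, c("prioritized", "non_prioritized"))
  expect_equal(g$n, c(1L, 2L))
})

test_that("informative prioritization beats pooled FDR on true positives", {
  set.seed(87)
  reps <- 30
  wins <- vapply(seq_len(reps), function(i) {
    p <- c(rbeta(20, 0.05, 1), runif(480), runif(4500))
    prio <- rep(c(TRUE, FALSE), c(500, 4500))
    tp_psa <- sum(psa(p, prio)$discoveries <= 20)
    tp_trad <- sum(fdr_discoveries(p, warn = FALSE)$discoveries <= 20)
    tp_psa >= tp_trad
  }, logical(1))
  expect_true(all(wins))
})
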