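# Shared fixtures, built in code.

# The seven published p-values of the worked example (the prioritized-stratum
# discoveries of a classic small case-control scan), used as inputs throughout.
seven_pvalues <- c(5.12e-4, 3.01e-4, 5.40e-8, 3.09e-6, 1.59e-4, 7.20e-5,
                   3.69e-4)

tiny_panel <- function(n_snps = 10, n_cases = 6, n_controls = 6, seed = 42,
                       ...) {
  simulate_panel(sim_config(
    n_snps = n_snps, n_cases = n_cases, n_controls = n_controls,
    seed = seed, ...
  ))
}

# independent enumeration oracle for the exact HWE test: direct combinatorial
# probabilities from choose(), inclusion rule matching the test's definition
hwe_enumeration_oracle <- function(n_hom_minor, n_het, n_hom_major) {
  n <- n_hom_minor + n_het + n_hom_major
  na <- 2 * min(n_hom_minor, n_hom_major) + n_het
  if (na == 0) return(1)
  hs <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  pr <- vapply(hs, function(h) {
    nrr <- (na - h) / 2
    choose(n, nrr) * choose(n - nrr, h) * 2^h / choose(2 * n, na)
  }, numeric(1))
  p_obs <- pr[hs == n_het]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

# brute-force step-up q-values: literal min over j >= i of pi0 * m * p_(j) / j
qvalues_bruteforce <- function(p, pi0 = 1) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(vapply(i:m, function(j) min(1, pi0 * m * ps[j] / j), numeric(1)))
  }, numeric(1))
  q <- numeric(m)
  q[ord] <- q_sorted
  # ties share the q-value of their common p
  for (pp in unique(p)) q[p == pp] <- min(q[p == pp])
  q
}
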