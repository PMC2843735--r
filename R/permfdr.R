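#' Threshold for permutation-based FDR estimation
#'
#' The threshold `d` is the largest p-value among the declared discoveries;
#' the permutation FDR estimate then counts null p-values at or below `d`.
#'
#' @param discovery_pvalues Non-empty vector of the discoveries' p-values.
#' @return `max(discovery_pvalues)`.
#' @export
#' @examples
#' pick_threshold_d(c(5.12e-4, 3.01e-4, 5.40e-8))
pick_threshold_d <- function(discovery_pvalues) {
  if (!length(discovery_pvalues)) {
    abort("Empty discovery set: R = 0, permutation FDR is undefined.",
          class = "psagwas_no_discoveries")
  }
  check_pvalues(discovery_pvalues)
  max(discovery_pvalues)
}

#' Expected false positives from label permutations
#'
#' For each of `B` permutations the case/control labels are shuffled
#' uniformly at random (group sizes preserved, genotypes fixed -- so any
#' linkage disequilibrium across SNPs is retained), the allelic chi-square
#' test is recomputed for every SNP of the stratum, and the p-values at or
#' below `d` (inclusive) are counted. The estimate is the mean count over
#' permutations, computed in chunks of matrix products for speed.
#'
#' @param panel A (QC-passed) [genotype_panel()].
#' @param stratum_snps SNP row indices or ids defining the stratum; defaults
#'   to all SNPs of the panel.
#' @param d P-value threshold in \[0, 1\].
#' @param B Number of permutations (at least 1).
#' @param seed Integer seed; identical seeds give identical estimates.
#' @return `fp_hat`, the expected false-positive count (a single number).
#' @export
#' @examples
#' panel <- simulate_panel(sim_config(n_snps = 50, seed = 5))
#' permutation_fp(panel, d = 0.01, B = 200, seed = 9)
permutation_fp <- function(panel, stratum_snps = NULL, d, B = 10000,
                           seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (length(d) != 1 || is.na(d) || d < 0 || d > 1) {
    abort("`d` must be a single value in [0, 1].")
  }
  B <- as.integer(B)
  if (B < 1) abort("`B` must be at least 1.")
  idx <- if (is.null(stratum_snps)) seq_len(n_snps(panel)) else {
    resolve_snp_index(panel, stratum_snps)
  }
  if (!length(idx)) abort("Stratum is empty.")

  dos <- panel$dosages[idx, , drop = FALSE]
  is_case <- is_case_vector(panel)
  n_case <- sum(is_case)
  n_sample <- length(is_case)
  A0 <- dos; A0[is.na(A0)] <- 0L
  storage.mode(A0) <- "double"
  M <- !is.na(dos)
  storage.mode(M) <- "double"
  tot_allele <- rowSums(A0)
  tot_called <- rowSums(M)

  withr::with_seed(seed, {
    total <- 0
    done <- 0L
    chunk <- max(1L, min(2000L, B))
    while (done < B) {
      nb <- min(chunk, B - done)
      # columns: indicator of case membership under each permutation
      Z <- vapply(
        seq_len(nb),
        function(b) {
          z <- numeric(n_sample)
          z[sample.int(n_sample, n_case)] <- 1
          z
        },
        numeric(n_sample)
      )
      a <- A0 %*% Z
      nc_case <- M %*% Z
      c_ <- tot_allele - a
      nc_ctrl <- tot_called - nc_case
      b2 <- 2 * nc_case - a
      d2 <- 2 * nc_ctrl - c_
      n <- a + b2 + c_ + d2
      denom <- (a + c_) * (b2 + d2) * (a + b2) * (c_ + d2)
      chi2 <- ifelse(denom > 0, n * (a * d2 - b2 * c_)^2 / denom, 0)
      p <- ifelse(chi2 > 0, pchisq(chi2, df = 1, lower.tail = FALSE), 1)
      total <- total + sum(p <= d)
      done <- done + nb
    }
    total / B
  })
}

#' Expected false positives from a precomputed null p-value matrix
#'
#' Secondary entry point used when null p-values are available directly
#' (e.g. analytic or externally permuted), bypassing the genotype machinery:
#' the mean, over rows, of the count of entries at or below `d`.
#'
#' @param pmat Numeric matrix of null p-values, one row per permutation and
#'   one column per test.
#' @param d P-value threshold in \[0, 1\].
#' @return `fp_hat`.
#' @export
permutation_fp_matrix <- function(pmat, d) {
  if (!is.matrix(pmat)) abort("`pmat` must be a matrix.")
  check_pvalues(as.vector(pmat))
  if (length(d) != 1 || is.na(d) || d < 0 || d > 1) {
    abort("`d` must be a single value in [0, 1].")
  }
  mean(rowSums(pmat <= d))
}

#' Permutation-based FDR from expected false positives
#'
#' @param fp_hat Expected false positives (non-negative).
#' @param R Number of declared discoveries; must be at least 1, otherwise
#'   the estimate is undefined.
#' @return `fp_hat / R`.
#' @export
#' @examples
#' permutation_fdr(0.225, 7)
permutation_fdr <- function(fp_hat, R) {
  if (length(fp_hat) != 1 || is.na(fp_hat) || fp_hat < 0) {
    abort("`fp_hat` must be a single non-negative value.")
  }
  if (length(R) != 1 || is.na(R) || R != round(R) || R < 1) {
    abort("`R` must be a positive integer: with R = 0 the FDR estimate is undefined.",
          class = "psagwas_no_discoveries")
  }
  fp_hat / R
}

#' Full permutation-FDR estimate for a discovery set within a stratum
#'
#' Convenience wrapper: picks `d` as the largest discovery p-value, runs
#' [permutation_fp()] over the stratum, and forms `fdr_hat = fp_hat / R`.
#'
#' @inheritParams permutation_fp
#' @param discovery_pvalues P-values of the declared discoveries within the
#'   stratum (non-empty).
#' @return An object of class `perm_fdr`: list with `d`, `B`, `seed`,
#'   `fp_hat`, `R`, `fdr_hat`, `m_stratum`.
#' @export
permutation_fdr_estimate <- function(panel, stratum_snps = NULL,
                                     discovery_pvalues, B = 10000, seed = 1) {
  d <- pick_threshold_d(discovery_pvalues)
  idx <- if (is.null(stratum_snps)) seq_len(n_snps(panel)) else {
    resolve_snp_index(panel, stratum_snps)
  }
  fp_hat <- permutation_fp(panel, idx, d = d, B = B, seed = seed)
  R <- length(discovery_pvalues)
  structure(
    list(d = d, B = as.integer(B), seed = as.integer(seed), fp_hat = fp_hat,
         R = R, fdr_hat = permutation_fdr(fp_hat, R),
         m_stratum = length(idx)),
    class = "perm_fdr"
  )
}

#' @export
print.perm_fdr <- function(x, ...) {
  cat(sprintf(
    "<perm_fdr> d = %.3g, B = %d: FP-hat = %.4g over %d SNPs; R = %d; FDR-hat = %.4g\n",
    x$d, x$B, x$fp_hat, x$m_stratum, x$R, x$fdr_hat
  ))
  invisible(x)
}
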