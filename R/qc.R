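#' Minor allele frequency of one SNP
#'
#' Missing genotypes are excluded from both numerator and denominator. The
#' returned frequency is folded to the minor allele, so it never exceeds 0.5.
#'
#' @param dosages Vector of minor-allele dosages in `{0, 1, 2}`, `NA` for
#'   missing.
#' @return `min(f, 1 - f)` where `f = sum(dosages) / (2 * n_called)`;
#'   `NA_real_` when every entry is missing.
#' @export
#' @examples
#' minor_allele_frequency(c(rep(1, 25), rep(0, 25)))  # 0.25
minor_allele_frequency <- function(dosages) {
  x <- dosages[!is.na(dosages)]
  if (!length(x)) return(NA_real_)
  if (!all(x %in% 0:2)) abort("Dosages must be 0, 1, 2 or NA.")
  f <- sum(x) / (2 * length(x))
  min(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test: with the total genotype count and the
#' minor-allele count fixed, the p-value sums the Hardy-Weinberg
#' probabilities of every heterozygote count whose probability does not
#' exceed that of the observed count. Probabilities are built by the standard
#' relative-probability recurrence over heterozygote counts, so the test is
#' exact for any sample size. Monomorphic SNPs return 1. No mid-p
#' correction is applied.
#'
#' @param n_hom_minor,n_het,n_hom_major Non-negative genotype counts
#'   (minor-allele homozygotes, heterozygotes, major-allele homozygotes);
#'   their sum must be at least 1. The test is symmetric in the two
#'   homozygote counts.
#' @return The exact p-value in \[0, 1\].
#' @export
#' @examples
#' hwe_exact_test(0, 0, 50)   # monomorphic: 1
#' hwe_exact_test(5, 20, 25)
hwe_exact_test <- function(n_hom_minor, n_het, n_hom_major) {
  counts <- c(n_hom_minor, n_het, n_hom_major)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort("Genotype counts must be non-negative integers.")
  }
  n <- sum(counts)
  if (n < 1) abort("At least one genotype is required.")
  rare <- 2 * min(n_hom_minor, n_hom_major) + n_het
  if (rare == 0) return(1)

  probs <- hwe_het_probabilities(n, rare)
  hs <- as.integer(names(probs))
  p_obs <- probs[hs == n_het]
  # tolerance absorbs floating-point ties between equal-probability tails
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# HWE probabilities of each heterozygote count given n genotypes and
# `rare` copies of the rarer allele; relative-probability recurrence,
# normalized. Returns a named vector (names = heterozygote counts).
hwe_het_probabilities <- function(n, rare) {
  hs <- seq.int(rare %% 2L, min(rare, 2L * n - rare), by = 2L)
  k <- length(hs)
  probs <- numeric(k)
  mid <- which.min(abs(hs - rare * (2 * n - rare) / (2 * n)))
  probs[mid] <- 1
  if (mid < k) {
    for (i in mid:(k - 1L)) {
      h <- hs[i]
      n_rr <- (rare - h) / 2
      n_cc <- n - (rare + h) / 2
      probs[i + 1L] <- probs[i] * 4 * n_rr * n_cc / ((h + 1) * (h + 2))
    }
  }
  if (mid > 1L) {
    for (i in mid:2L) {
      h <- hs[i]
      n_rr <- (rare - h) / 2
      n_cc <- n - (rare + h) / 2
      probs[i - 1L] <- probs[i] * h * (h - 1) / (4 * (n_rr + 1) * (n_cc + 1))
    }
  }
  probs <- probs / sum(probs)
  names(probs) <- hs
  probs
}

# vectorized HWE over many SNPs, memoized over distinct count triples
hwe_exact_vec <- function(n_hom_minor, n_het, n_hom_major) {
  key <- paste(n_hom_minor, n_het, n_hom_major)
  first <- !duplicated(key)
  p_first <- vapply(
    which(first),
    function(i) hwe_exact_test(n_hom_minor[i], n_het[i], n_hom_major[i]),
    numeric(1)
  )
  unname(p_first[match(key, key[first])])
}

#' Apply SNP quality control to a genotype panel
#'
#' Keeps SNPs that are informative (MAF at or above `maf_min`, computed over
#' all samples) and conform to Hardy-Weinberg equilibrium (exact HWE p-value
#' at or above `hwe_min`, computed in the controls only). Both thresholds are
#' inclusive. SNPs with no called genotype are dropped as `all_missing`.
#' Original SNP order is preserved in the filtered panel.
#'
#' @param panel A [genotype_panel()].
#' @param maf_min Minimum minor-allele frequency (default 0.01).
#' @param hwe_min Minimum exact HWE p-value in controls (default 0.05).
#' @return An object of class `qc_result`: a list with
#'   \describe{
#'     \item{report}{tibble with `snp_id`, `maf`, `hwe_p`, `n_called`,
#'       `pass`, `fail_reason` (`NA` for passing SNPs; otherwise one of
#'       `low_maf`, `hwe_violation`, `all_missing`).}
#'     \item{panel}{the filtered `genotype_panel` of passing SNPs.}
#'     \item{params}{thresholds used, and whether the HWE stage was skipped
#'       for lack of controls.}
#'   }
#' @export
#' @examples
#' panel <- simulate_panel(sim_config(n_snps = 200, seed = 3))
#' qc <- apply_qc(panel)
#' glance(qc)
apply_qc <- function(panel, maf_min = 0.01, hwe_min = 0.05) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (maf_min < 0 || maf_min > 0.5) abort("`maf_min` must be in [0, 0.5].")
  if (hwe_min < 0 || hwe_min > 1) abort("`hwe_min` must be in [0, 1].")

  dos <- panel$dosages
  n_called <- unname(rowSums(!is.na(dos)))
  maf_raw <- unname(rowSums(dos, na.rm = TRUE)) / (2 * n_called)
  maf <- pmin(maf_raw, 1 - maf_raw)
  maf[n_called == 0] <- NA_real_

  is_ctrl <- !is_case_vector(panel)
  hwe_skipped <- !any(is_ctrl)
  if (hwe_skipped) {
    warn("Panel has no controls; Hardy-Weinberg filter skipped.")
    hwe_p <- rep(NA_real_, n_snps(panel))
    hwe_ok <- rep(TRUE, n_snps(panel))
  } else {
    ctrl <- dos[, is_ctrl, drop = FALSE]
    n2 <- unname(rowSums(ctrl == 2L, na.rm = TRUE))
    n1 <- unname(rowSums(ctrl == 1L, na.rm = TRUE))
    n0 <- unname(rowSums(ctrl == 0L, na.rm = TRUE))
    hwe_p <- rep(NA_real_, n_snps(panel))
    has_ctrl_calls <- (n0 + n1 + n2) > 0
    hwe_p[has_ctrl_calls] <- hwe_exact_vec(
      n2[has_ctrl_calls], n1[has_ctrl_calls], n0[has_ctrl_calls]
    )
    # SNPs with zero called controls cannot be HWE-tested; not penalized
    hwe_ok <- is.na(hwe_p) | hwe_p >= hwe_min
  }

  pass <- n_called > 0 & !is.na(maf) & maf >= maf_min & hwe_ok
  fail_reason <- rep(NA_character_, n_snps(panel))
  fail_reason[!hwe_ok] <- "hwe_violation"
  fail_reason[n_called > 0 & maf < maf_min] <- "low_maf"
  fail_reason[n_called == 0] <- "all_missing"

  report <- tibble::tibble(
    snp_id = panel$map$snp_id,
    maf = maf,
    hwe_p = hwe_p,
    n_called = as.integer(n_called),
    pass = pass,
    fail_reason = fail_reason
  )
  structure(
    list(
      report = report,
      panel = panel_subset(panel, which(pass)),
      params = list(maf_min = maf_min, hwe_min = hwe_min,
                    hwe_skipped = hwe_skipped)
    ),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf(
    "<qc_result> %d of %d SNPs pass (maf_min = %g, hwe_min = %g%s)\n",
    sum(x$report$pass), nrow(x$report),
    x$params$maf_min, x$params$hwe_min,
    if (x$params$hwe_skipped) "; HWE skipped: no controls" else ""
  ))
  fails <- table(x$report$fail_reason)
  if (length(fails)) {
    cat("  failures:", paste(names(fails), fails, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}
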