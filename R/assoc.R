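#' Allele-count table for one SNP
#'
#' Collapses diploid dosages to allele counts (two alleles per called
#' sample) and tabulates them by case/control status.
#'
#' @param dosages Minor-allele dosage vector in `{0, 1, 2}`, `NA` missing.
#' @param phenotype Character vector of `"case"`/`"control"`, or a logical
#'   case indicator, aligned with `dosages`.
#' @return A 2x2 integer matrix with rows `minor`, `major` and columns
#'   `case`, `control`.
#' @export
#' @examples
#' allele_table(c(2, 1, 0, 0), c("case", "case", "control", "control"))
allele_table <- function(dosages, phenotype) {
  if (is.logical(phenotype)) {
    phenotype <- ifelse(phenotype, "case", "control")
  }
  if (length(dosages) != length(phenotype)) {
    abort("`dosages` and `phenotype` must have the same length.")
  }
  if (!all(phenotype %in% c("case", "control"))) {
    abort("Phenotype labels must be \"case\" or \"control\".")
  }
  is_case <- phenotype == "case"
  called_case <- is_case & !is.na(dosages)
  called_ctrl <- !is_case & !is.na(dosages)
  if (!any(called_case) || !any(called_ctrl)) {
    abort("Need at least one called case and one called control.",
          class = "psagwas_untestable")
  }
  a <- sum(dosages[called_case])
  c_ <- sum(dosages[called_ctrl])
  tab <- matrix(
    as.integer(c(a, 2 * sum(called_case) - a, c_, 2 * sum(called_ctrl) - c_)),
    nrow = 2,
    dimnames = list(c("minor", "major"), c("case", "control"))
  )
  tab
}

#' Pearson chi-square test on a 2x2 allele table
#'
#' One degree of freedom, no continuity correction, two-sided p-value from
#' the upper tail of the chi-square distribution. When an allele is entirely
#' absent (a zero row margin) or a group is empty, the statistic is 0 and
#' the p-value 1.
#'
#' @param table 2x2 matrix of non-negative allele counts
#'   (allele x case/control).
#' @return A list with `chi2` and `p_value`.
#' @export
#' @examples
#' allelic_chi2(matrix(c(30, 162, 10, 90), nrow = 2))
allelic_chi2 <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == 2)) {
    abort("`table` must be a 2x2 matrix.")
  }
  if (any(is.na(table)) || any(table < 0)) {
    abort("Allele counts must be non-negative.")
  }
  a <- table[1, 1]; c_ <- table[1, 2]
  b <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c_ + d
  if (n == 0) abort("Empty table.")
  r1 <- a + c_; r2 <- b + d; c1 <- a + b; c2 <- c_ + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(list(chi2 = 0, p_value = 1))
  }
  chi2 <- n * (a * d - b * c_)^2 / (r1 * r2 * c1 * c2)
  list(chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Allelic association scan over a panel
#'
#' Runs the allelic chi-square test of disease status on every SNP. SNPs
#' with a phenotype group entirely missing are flagged untestable and get
#' `p_value = 1`. The odds ratio is `ad/bc` and is `NA` whenever a cell is
#' zero (no continuity correction is applied).
#'
#' @param panel A [genotype_panel()], normally QC-passed.
#' @return A tibble with one row per SNP, in panel order: `snp_id`, `chrom`,
#'   `pos`, the allele-table cells `a` (case minor), `b` (case major),
#'   `c` (control minor), `d` (control major), `chi2`, `p_value`,
#'   `odds_ratio`, `testable`.
#' @export
#' @examples
#' panel <- simulate_panel(sim_config(n_snps = 20, seed = 11))
#' association_scan(panel)
association_scan <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (n_snps(panel) == 0) {
    warn("Empty panel: no SNPs to test.")
  }
  res <- allelic_scan_counts(panel$dosages, is_case_vector(panel))
  dplyr::bind_cols(panel$map, res)
}

# vectorized allelic test given a dosage matrix and case indicator;
# returns one row per SNP
allelic_scan_counts <- function(dos, is_case) {
  case <- dos[, is_case, drop = FALSE]
  ctrl <- dos[, !is_case, drop = FALSE]
  nc_case <- unname(rowSums(!is.na(case)))
  nc_ctrl <- unname(rowSums(!is.na(ctrl)))
  a <- unname(rowSums(case, na.rm = TRUE))
  c_ <- unname(rowSums(ctrl, na.rm = TRUE))
  b <- 2 * nc_case - a
  d <- 2 * nc_ctrl - c_
  testable <- nc_case > 0 & nc_ctrl > 0

  n <- a + b + c_ + d
  r1 <- a + c_; r2 <- b + d; c1 <- a + b; c2 <- c_ + d
  denom <- r1 * r2 * c1 * c2
  chi2 <- ifelse(denom > 0, n * (a * d - b * c_)^2 / denom, 0)
  p <- ifelse(chi2 > 0, pchisq(chi2, df = 1, lower.tail = FALSE), 1)
  or <- ifelse(a > 0 & b > 0 & c_ > 0 & d > 0, (a * d) / (b * c_), NA_real_)

  chi2[!testable] <- NA_real_
  p[!testable] <- 1
  or[!testable] <- NA_real_
  tibble::tibble(
    a = as.integer(a), b = as.integer(b),
    c = as.integer(c_), d = as.integer(d),
    chi2 = chi2, p_value = p, odds_ratio = or, testable = testable
  )
}
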