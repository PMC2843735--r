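#' Simulation configuration for synthetic case-control panels
#'
#' Describes a synthetic case-control genotype study: biallelic SNPs with
#' control minor-allele frequencies drawn uniformly from `maf_range`, control
#' genotypes in Hardy-Weinberg proportions, and case genotypes in
#' Hardy-Weinberg proportions at the case allele frequency implied by a
#' per-SNP allelic odds ratio (case minor-allele odds = OR x control odds).
#' Non-causal SNPs have OR = 1. The defaults mirror a small classic
#' case-control scan design of 96 cases and 50 controls.
#'
#' @param n_snps Number of SNPs to simulate.
#' @param n_cases,n_controls Group sizes; both must be at least 1.
#' @param maf_range Length-2 numeric in (0, 0.5]: bounds of the uniform
#'   distribution of control minor-allele frequencies.
#' @param causal_ids Integer vector of 1-based SNP indices carrying a
#'   non-null effect.
#' @param causal_or Allelic odds ratio(s) for the causal SNPs, strictly
#'   positive; a scalar is recycled.
#' @param prioritized_fraction_of_causal Proportion in \[0, 1\] of causal SNPs
#'   that [simulate_regions()] places inside prioritized regions.
#' @param prioritized_subset_size Number of SNPs the emitted regions cover;
#'   must not exceed `n_snps`.
#' @param missing_rate Per-genotype independent missingness probability in
#'   \[0, 1).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#'
#' @return An object of class `sim_config` (a named list of the above).
#' @export
#' @examples
#' sim_config(n_snps = 100, causal_ids = 1:5, causal_or = 3, seed = 42)
sim_config <- function(n_snps,
                       n_cases = 96,
                       n_controls = 50,
                       maf_range = c(0.05, 0.5),
                       causal_ids = integer(),
                       causal_or = numeric(),
                       prioritized_fraction_of_causal = 1,
                       prioritized_subset_size = 0,
                       missing_rate = 0,
                       seed = 1) {
  n_snps <- as.integer(n_snps)
  n_cases <- as.integer(n_cases)
  n_controls <- as.integer(n_controls)
  causal_ids <- as.integer(causal_ids)
  if (n_snps < 1) abort("`n_snps` must be at least 1.", class = "psagwas_config_error")
  if (n_cases < 1 || n_controls < 1) {
    abort("A case-control panel needs at least 1 case and 1 control.",
          class = "psagwas_config_error")
  }
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair in (0, 0.5].",
          class = "psagwas_config_error")
  }
  if (length(causal_ids)) {
    if (anyDuplicated(causal_ids) || min(causal_ids) < 1L ||
        max(causal_ids) > n_snps) {
      abort("`causal_ids` must be distinct indices in 1..n_snps.",
            class = "psagwas_config_error")
    }
    if (length(causal_or) == 1L) causal_or <- rep(causal_or, length(causal_ids))
    if (length(causal_or) != length(causal_ids)) {
      abort("`causal_or` must match `causal_ids` in length (or be scalar).",
            class = "psagwas_config_error")
    }
    if (any(!is.finite(causal_or)) || any(causal_or <= 0)) {
      abort("Causal odds ratios must be finite and > 0.",
            class = "psagwas_config_error")
    }
  } else {
    causal_or <- numeric()
  }
  if (prioritized_fraction_of_causal < 0 || prioritized_fraction_of_causal > 1) {
    abort("`prioritized_fraction_of_causal` must be in [0, 1].",
          class = "psagwas_config_error")
  }
  prioritized_subset_size <- as.integer(prioritized_subset_size)
  if (prioritized_subset_size < 0 || prioritized_subset_size > n_snps) {
    abort("`prioritized_subset_size` must be in 0..n_snps.",
          class = "psagwas_config_error")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must be in [0, 1).", class = "psagwas_config_error")
  }
  structure(
    list(
      n_snps = n_snps, n_cases = n_cases, n_controls = n_controls,
      maf_range = as.numeric(maf_range), causal_ids = causal_ids,
      causal_or = as.numeric(causal_or),
      prioritized_fraction_of_causal = prioritized_fraction_of_causal,
      prioritized_subset_size = prioritized_subset_size,
      missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a synthetic case-control genotype panel
#'
#' Control genotypes are drawn under Hardy-Weinberg equilibrium at a control
#' minor-allele frequency drawn uniformly from `maf_range`; case genotypes
#' under HWE at the frequency implied by the SNP's allelic odds ratio.
#' Missing genotypes are inserted independently at `missing_rate`. SNPs are
#' independent (no linkage disequilibrium) and placed on a single synthetic
#' chromosome at 1 kb spacing, which keeps interval arithmetic checkable by
#' hand. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [genotype_panel()]. Cases occupy the first columns.
#' @export
#' @examples
#' panel <- simulate_panel(sim_config(n_snps = 50, seed = 7))
#' table(panel$samples$status)
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_snps
    p0 <- runif(n, config$maf_range[1], config$maf_range[2])
    or <- rep(1, n)
    or[config$causal_ids] <- config$causal_or
    odds1 <- or * p0 / (1 - p0)
    p1 <- odds1 / (1 + odds1)

    case_dos <- matrix(
      rbinom(n * config$n_cases, 2L, p1),
      nrow = n, ncol = config$n_cases
    )
    ctrl_dos <- matrix(
      rbinom(n * config$n_controls, 2L, p0),
      nrow = n, ncol = config$n_controls
    )
    dos <- cbind(case_dos, ctrl_dos)
    if (config$missing_rate > 0) {
      dos[runif(length(dos)) < config$missing_rate] <- NA_integer_
    }

    map <- tibble::tibble(
      snp_id = sprintf("snp%06d", seq_len(n)),
      chrom = "1",
      pos = (seq_len(n) - 1L) * 1000L + 1L
    )
    samples <- tibble::tibble(
      sample_id = c(
        sprintf("case%03d", seq_len(config$n_cases)),
        sprintf("ctrl%03d", seq_len(config$n_controls))
      ),
      status = rep(c("case", "control"), c(config$n_cases, config$n_controls))
    )
    genotype_panel(map, dos, samples)
  })
}

#' Simulate prioritized candidate regions for a synthetic panel
#'
#' Emits intervals (1-based, inclusive, `window_bp = 0`) covering exactly
#' `prioritized_subset_size` SNPs of the panel, of which a
#' `prioritized_fraction_of_causal` share of the causal SNPs are inside.
#' Filler SNPs are drawn from the non-causal pool, so causal SNPs left out of
#' the subset are guaranteed to be non-prioritized. Runs of consecutive
#' selected SNPs are merged into single intervals. Deterministic given
#' `config$seed`.
#'
#' @param config The [sim_config()] used to build `panel`.
#' @param panel The matching [genotype_panel()].
#' @return A tibble of regions with columns `chrom`, `start`, `end`, `name`,
#'   `window_bp`, as consumed by [assign_subsets()].
#' @export
simulate_regions <- function(config, panel) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "genotype_panel"))
  if (config$prioritized_subset_size > n_snps(panel)) {
    abort("`prioritized_subset_size` exceeds the panel's SNP count.",
          class = "psagwas_config_error")
  }
  k <- config$prioritized_subset_size
  empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    name = character(), window_bp = integer()
  )
  if (k == 0L) return(empty)
  k_in <- round(config$prioritized_fraction_of_causal * length(config$causal_ids))
  if (k_in > k) {
    abort("`prioritized_subset_size` too small to hold the requested fraction of causal SNPs.",
          class = "psagwas_config_error")
  }
  withr::with_seed(config$seed + 1L, {
    causal_in <- sort(sample_safe(config$causal_ids, k_in))
    pool <- setdiff(seq_len(n_snps(panel)), config$causal_ids)
    if (k - k_in > length(pool)) {
      abort("Not enough non-causal SNPs to fill the prioritized subset.",
            class = "psagwas_config_error")
    }
    filler <- sample_safe(pool, k - k_in)
    sel <- sort(unique(c(causal_in, filler)))
  })
  # merge runs of consecutive SNP indices into single intervals
  run <- cumsum(c(1L, diff(sel) != 1L))
  purrr::map_dfr(split(sel, run), function(idx) {
    tibble::tibble(
      chrom = panel$map$chrom[idx[1]],
      start = panel$map$pos[idx[1]],
      end = panel$map$pos[idx[length(idx)]],
      name = NA_character_,
      window_bp = 0L
    )
  }) |>
    dplyr::mutate(name = sprintf("region%03d", dplyr::row_number()))
}

# sample() without the length-1 surprise
sample_safe <- function(x, size) {
  if (size == 0L) return(x[0])
  x[sample.int(length(x), size)]
}
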