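#' Genotype panel objects
#'
#' A `genotype_panel` bundles the three pieces every analysis stage consumes:
#' a SNP map, a SNP-by-sample minor-allele dosage matrix, and per-sample
#' case/control labels.
#'
#' @param map A tibble with columns `snp_id` (unique identifiers), `chrom`
#'   (chromosome label) and `pos` (1-based base-pair position, strictly
#'   positive). `(chrom, pos)` pairs need not be unique; `snp_id` must be.
#' @param dosages Integer matrix, one row per SNP and one column per sample,
#'   with entries in `{0, 1, 2}` (minor-allele dosage) or `NA` for missing
#'   genotypes.
#' @param samples A tibble with columns `sample_id` and `status`
#'   (`"case"` or `"control"`), aligned with the columns of `dosages`.
#'
#' @return An object of class `genotype_panel`: a list with elements `map`,
#'   `dosages` and `samples`.
#' @export
#' @examples
#' cfg <- sim_config(n_snps = 10, n_cases = 5, n_controls = 5, seed = 1)
#' panel <- simulate_panel(cfg)
#' panel
genotype_panel <- function(map, dosages, samples) {
  map <- tibble::as_tibble(map)
  samples <- tibble::as_tibble(samples)
  if (!all(c("snp_id", "chrom", "pos") %in% names(map))) {
    abort("`map` must have columns snp_id, chrom, pos.")
  }
  if (!all(c("sample_id", "status") %in% names(samples))) {
    abort("`samples` must have columns sample_id, status.")
  }
  if (!is.matrix(dosages)) abort("`dosages` must be a matrix.")
  if (nrow(dosages) != nrow(map)) {
    abort("`dosages` must have one row per SNP in `map`.")
  }
  if (ncol(dosages) != nrow(samples)) {
    abort("`dosages` must have one column per sample.")
  }
  if (anyDuplicated(map$snp_id)) abort("SNP ids must be unique.")
  if (any(map$pos < 1)) abort("Positions must be strictly positive.")
  if (!all(samples$status %in% c("case", "control"))) {
    abort("Sample status must be \"case\" or \"control\".")
  }
  ok <- dosages[!is.na(dosages)]
  if (length(ok) && !all(ok %in% 0:2)) {
    abort("Dosages must be 0, 1, 2 or NA.")
  }
  rownames(dosages) <- map$snp_id
  colnames(dosages) <- samples$sample_id
  structure(
    list(map = map, dosages = dosages, samples = samples),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  n_case <- sum(x$samples$status == "case")
  n_ctrl <- sum(x$samples$status == "control")
  cat(sprintf(
    "<genotype_panel> %d SNPs x %d samples (%d cases / %d controls)\n",
    nrow(x$map), nrow(x$samples), n_case, n_ctrl
  ))
  n_miss <- sum(is.na(x$dosages))
  cat(sprintf(
    "  chromosomes: %s; missing dosages: %d (%.2f%%)\n",
    paste(unique(x$map$chrom), collapse = ", "),
    n_miss, 100 * n_miss / length(x$dosages)
  ))
  invisible(x)
}

#' Number of SNPs / samples in a panel
#' @param panel A [genotype_panel()].
#' @return An integer count.
#' @export
n_snps <- function(panel) nrow(panel$map)

#' @rdname n_snps
#' @export
n_samples <- function(panel) nrow(panel$samples)

#' Subset a panel to selected SNPs
#'
#' @param panel A [genotype_panel()].
#' @param snps Integer row indices or `snp_id` strings; original order of the
#'   panel is preserved regardless of the order given.
#' @return A `genotype_panel` restricted to those SNPs.
#' @export
panel_subset <- function(panel, snps) {
  idx <- resolve_snp_index(panel, snps)
  idx <- sort(unique(idx))
  genotype_panel(
    map = panel$map[idx, , drop = FALSE],
    dosages = panel$dosages[idx, , drop = FALSE],
    samples = panel$samples
  )
}

# map snp ids or indices to validated integer row indices
resolve_snp_index <- function(panel, snps) {
  if (is.character(snps)) {
    idx <- match(snps, panel$map$snp_id)
    if (anyNA(idx)) {
      abort(paste0("Unknown snp_id: ", paste(snps[is.na(idx)], collapse = ", ")))
    }
    return(idx)
  }
  idx <- as.integer(snps)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_snps(panel))) {
    abort("SNP indices out of range.")
  }
  idx
}

is_case_vector <- function(panel) panel$samples$status == "case"
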