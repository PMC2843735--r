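#' Read a genotype panel from TSV files
#'
#' The genotype file has columns `snp_id`, `chrom`, `pos`, then one column
#' per sample holding minor-allele dosages `0/1/2` (`NA` for missing). The
#' phenotype file has columns `sample_id` and `status` in
#' `{"case", "control"}`. Sample ids must match between the two files
#' (order taken from the genotype file's columns).
#'
#' @param path_geno,path_pheno Paths to the two TSV files.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path_geno, path_pheno) {
  geno <- readr::read_tsv(
    path_geno,
    col_types = readr::cols(
      snp_id = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_double(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  if (!all(c("snp_id", "chrom", "pos") %in% names(geno))) {
    abort("Genotype file must start with columns snp_id, chrom, pos.")
  }
  sample_cols <- setdiff(names(geno), c("snp_id", "chrom", "pos"))
  if (!length(sample_cols)) abort("Genotype file has no sample columns.")

  dos <- matrix(NA_integer_, nrow = nrow(geno), ncol = length(sample_cols))
  for (j in seq_along(sample_cols)) {
    v <- geno[[sample_cols[j]]]
    bad <- !is.na(v) & !v %in% c("0", "1", "2")
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf(
        "Genotype file: invalid value \"%s\" at row %d (SNP %s), column %s; expected 0, 1, 2 or NA.",
        v[i], i, geno$snp_id[i], sample_cols[j]
      ))
    }
    dos[, j] <- as.integer(v)
  }

  pheno <- readr::read_tsv(
    path_pheno,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      status = readr::col_character()
    ),
    progress = FALSE
  )
  if (!all(c("sample_id", "status") %in% names(pheno))) {
    abort("Phenotype file must have columns sample_id, status.")
  }
  bad <- !pheno$status %in% c("case", "control")
  if (any(bad)) {
    abort(sprintf(
      "Phenotype file: unknown status \"%s\" for sample %s.",
      pheno$status[which(bad)[1]], pheno$sample_id[which(bad)[1]]
    ))
  }
  if (!setequal(pheno$sample_id, sample_cols) ||
      nrow(pheno) != length(sample_cols)) {
    abort("Sample ids differ between genotype and phenotype files.")
  }
  pheno <- pheno[match(sample_cols, pheno$sample_id), ]

  genotype_panel(
    map = geno[, c("snp_id", "chrom", "pos")],
    dosages = dos,
    samples = pheno
  )
}

#' Write a genotype panel to TSV files
#'
#' Inverse of [read_genotypes()]: a round-trip reproduces the panel exactly.
#'
#' @param panel A [genotype_panel()].
#' @param path_geno,path_pheno Output paths.
#' @return `path_geno`, invisibly.
#' @export
write_genotypes <- function(panel, path_geno, path_pheno) {
  stopifnot(inherits(panel, "genotype_panel"))
  geno <- dplyr::bind_cols(
    panel$map,
    tibble::as_tibble(panel$dosages, .name_repair = "minimal")
  )
  readr::write_tsv(geno, path_geno, progress = FALSE)
  readr::write_tsv(panel$samples, path_pheno, progress = FALSE)
  invisible(path_geno)
}
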