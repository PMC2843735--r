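#' Configuration of a full analysis run
#'
#' Exactly one input source must be given: either the three file paths
#' (`geno`, `pheno`, `regions`) of an existing study, or a [sim_config()]
#' in `sim` (in which case regions are simulated too, unless a `regions`
#' path or tibble is supplied).
#'
#' @param geno,pheno Paths to genotype/phenotype TSVs (see
#'   [read_genotypes()]).
#' @param regions Path to a candidate-region TSV, or a region tibble;
#'   optional when simulating.
#' @param sim A [sim_config()] for a synthetic run.
#' @param alpha FDR / FWER level shared by every method (default 0.05).
#' @param maf_min,hwe_min QC thresholds (see [apply_qc()]).
#' @param permutations Permutation count for the permutation-FDR check of
#'   the prioritized stratum; 0 (default) skips it.
#' @param seed Seed for the permutation stage.
#' @param output_dir Optional directory; when given, per-stage TSV/JSON
#'   artifacts are written there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(geno = NULL, pheno = NULL, regions = NULL, sim = NULL,
                       alpha = 0.05, maf_min = 0.01, hwe_min = 0.05,
                       permutations = 0, seed = 1, output_dir = NULL) {
  has_files <- !is.null(geno) || !is.null(pheno)
  if (has_files && !is.null(sim)) {
    abort("Give either input file paths or a simulation block, not both.",
          class = "psagwas_config_error")
  }
  if (!has_files && is.null(sim)) {
    abort("One of file paths (geno + pheno) or `sim` is required.",
          class = "psagwas_config_error")
  }
  if (has_files && (is.null(geno) || is.null(pheno))) {
    abort("Both `geno` and `pheno` paths are required.",
          class = "psagwas_config_error")
  }
  if (has_files && is.null(regions)) {
    abort("`regions` is required when reading genotypes from files.",
          class = "psagwas_config_error")
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  structure(
    list(geno = geno, pheno = pheno, regions = regions, sim = sim,
         alpha = alpha, maf_min = maf_min, hwe_min = hwe_min,
         permutations = as.integer(permutations), seed = as.integer(seed),
         output_dir = output_dir),
    class = "run_config"
  )
}

#' Run the full prioritized-subset-analysis pipeline
#'
#' Executes, in order: input (read or simulate) -> QC -> allelic association
#' scan -> subset assignment -> three multiple-testing procedures at the
#' same level (Bonferroni, traditional single-stratum FDR, PSA) -> optional
#' permutation-FDR check of the prioritized stratum. Counts at each stage
#' are narrated via [rlang::inform()] messages.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage messages (default `FALSE`).
#' @return An object of class `comparison_report`: list with `methods`
#'   (tibble: `method`, `n_discoveries`, `discoveries` list-column of SNP
#'   ids), `qc`, `assoc`, `assignment`, `psa`, `perm` (a `perm_fdr` or
#'   `NULL`), `counts`, `alpha`, `config_hash`.
#' @export
#' @examples
#' cfg <- run_config(
#'   sim = sim_config(n_snps = 500, causal_ids = 1:3, causal_or = 4,
#'                    prioritized_subset_size = 50, seed = 8),
#'   alpha = 0.05
#' )
#' report <- run_pipeline(cfg, quiet = TRUE)
#' report
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))

  if (!is.null(config$sim)) {
    panel <- simulate_panel(config$sim)
    regions <- if (is.null(config$regions)) {
      simulate_regions(config$sim, panel)
    } else {
      resolve_regions(config$regions)
    }
  } else {
    panel <- read_genotypes(config$geno, config$pheno)
    regions <- resolve_regions(config$regions)
  }
  say("input: %d SNPs, %d cases / %d controls",
      n_snps(panel), sum(is_case_vector(panel)), sum(!is_case_vector(panel)))

  qc <- apply_qc(panel, maf_min = config$maf_min, hwe_min = config$hwe_min)
  say("qc: %d SNPs pass (of %d)", n_snps(qc$panel), n_snps(panel))

  assoc <- association_scan(qc$panel)
  assignment <- assign_subsets(qc$panel, regions)
  say("prioritized subset: %d SNPs; non-prioritized: %d",
      sum(assignment$prioritized), sum(!assignment$prioritized))

  m <- nrow(assoc)
  p <- assoc$p_value
  bonf_thr <- bonferroni_threshold(m, config$alpha)
  disc_bonf <- which(p <= bonf_thr)
  trad <- fdr_discoveries(p, alpha = config$alpha, warn = FALSE)
  psa_res <- psa(p, assignment, alpha = config$alpha,
                 snp_id = assoc$snp_id)

  perm <- NULL
  prio_disc <- psa_res$snps$discovered & psa_res$snps$stratum == "prioritized"
  if (config$permutations > 0 && any(prio_disc)) {
    perm <- permutation_fdr_estimate(
      qc$panel,
      stratum_snps = which(assignment$prioritized),
      discovery_pvalues = p[prio_disc],
      B = config$permutations,
      seed = config$seed
    )
    say("permutation FDR (prioritized stratum): FP-hat = %.4g, FDR-hat = %.4g",
        perm$fp_hat, perm$fdr_hat)
  }

  methods <- tibble::tibble(
    method = c("bonferroni", "fdr_traditional", "psa"),
    n_discoveries = c(length(disc_bonf), length(trad$discoveries),
                      length(psa_res$discoveries)),
    discoveries = list(
      assoc$snp_id[disc_bonf],
      assoc$snp_id[trad$discoveries],
      assoc$snp_id[psa_res$discoveries]
    )
  )
  report <- structure(
    list(
      methods = methods, qc = qc, assoc = assoc, assignment = assignment,
      psa = psa_res, fdr_traditional = trad, perm = perm,
      counts = list(
        n_input = n_snps(panel), n_pass = m,
        n_prioritized = sum(assignment$prioritized),
        n_non_prioritized = sum(!assignment$prioritized)
      ),
      alpha = config$alpha,
      seed = config$seed,
      config_hash = rlang::hash(config[setdiff(names(config), "output_dir")])
    ),
    class = "comparison_report"
  )
  if (!is.null(config$output_dir)) {
    write_report_artifacts(report, config$output_dir)
  }
  report
}

resolve_regions <- function(regions) {
  if (is.character(regions)) read_regions(regions) else {
    validate_regions(tibble::as_tibble(regions))
  }
}

write_report_artifacts <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$qc$report, file.path(dir, "qc_report.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$assoc, file.path(dir, "assoc.tsv"), progress = FALSE)
  subsets <- dplyr::mutate(
    report$assignment,
    prioritized = as.integer(.data$prioritized)
  )
  readr::write_tsv(subsets, file.path(dir, "subsets.tsv"), progress = FALSE)
  readr::write_tsv(tidy(report$psa), file.path(dir, "discoveries.tsv"),
                   progress = FALSE)
  if (!is.null(report$perm)) {
    jsonlite::write_json(
      unclass(report$perm), file.path(dir, "permfdr.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  jsonlite::write_json(
    list(
      alpha = report$alpha,
      seed = report$seed,
      config_hash = report$config_hash,
      counts = report$counts,
      methods = dplyr::mutate(
        report$methods,
        discoveries = purrr::map(.data$discoveries, identity)
      )
    ),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "<comparison_report> %d SNPs in, %d after QC; %d prioritized / %d non-prioritized; alpha = %g\n",
    x$counts$n_input, x$counts$n_pass, x$counts$n_prioritized,
    x$counts$n_non_prioritized, x$alpha
  ))
  for (i in seq_len(nrow(x$methods))) {
    ids <- x$methods$discoveries[[i]]
    cat(sprintf(
      "  %-16s %3d discoveries%s\n",
      x$methods$method[i], x$methods$n_discoveries[i],
      if (length(ids)) paste0(": ", paste(head(ids, 8), collapse = ", "),
                              if (length(ids) > 8) ", ..." else "")
      else ""
    ))
  }
  if (!is.null(x$perm)) print(x$perm)
  invisible(x)
}
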