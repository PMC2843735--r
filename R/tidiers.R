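#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects: `tidy()` returns
#' the per-SNP (or per-quantity) tibble, `glance()` a one-row-per-group
#' summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name psagwas-tidiers
NULL

#' @rdname psagwas-tidiers
#' @export
tidy.qc_result <- function(x, ...) x$report

#' @rdname psagwas-tidiers
#' @export
glance.qc_result <- function(x, ...) {
  fr <- x$report$fail_reason
  tibble::tibble(
    n_snps = nrow(x$report),
    n_pass = sum(x$report$pass),
    n_low_maf = sum(fr == "low_maf", na.rm = TRUE),
    n_hwe_violation = sum(fr == "hwe_violation", na.rm = TRUE),
    n_all_missing = sum(fr == "all_missing", na.rm = TRUE),
    maf_min = x$params$maf_min,
    hwe_min = x$params$hwe_min,
    hwe_skipped = x$params$hwe_skipped
  )
}

#' @rdname psagwas-tidiers
#' @export
tidy.fdr_result <- function(x, ...) {
  tibble::tibble(
    p_value = x$pvalues,
    q_value = x$qvalues,
    discovered = seq_along(x$pvalues) %in% x$discoveries
  )
}

#' @rdname psagwas-tidiers
#' @export
glance.fdr_result <- function(x, ...) {
  tibble::tibble(
    n_tests = length(x$pvalues),
    pi0 = x$pi0$pi0,
    pi0_method = x$pi0$method,
    alpha = x$alpha,
    n_discoveries = length(x$discoveries)
  )
}

#' @rdname psagwas-tidiers
#' @export
tidy.psa_result <- function(x, ...) x$snps

#' @rdname psagwas-tidiers
#' @export
glance.psa_result <- function(x, ...) {
  purrr::map_dfr(names(x$strata), function(s) {
    st <- x$strata[[s]]
    tibble::tibble(
      stratum = s,
      n = st$n,
      pi0 = if (is.null(st$pi0)) NA_real_ else st$pi0$pi0,
      pi0_method = if (is.null(st$pi0)) NA_character_ else st$pi0$method,
      n_discoveries = st$n_discoveries,
      alpha = x$alpha
    )
  })
}

#' @rdname psagwas-tidiers
#' @export
tidy.perm_fdr <- function(x, ...) {
  tibble::tibble(
    d = x$d, B = x$B, seed = x$seed, m_stratum = x$m_stratum,
    fp_hat = x$fp_hat, R = x$R, fdr_hat = x$fdr_hat
  )
}

#' @rdname psagwas-tidiers
#' @export
glance.perm_fdr <- tidy.perm_fdr

#' @rdname psagwas-tidiers
#' @export
tidy.comparison_report <- function(x, ...) {
  dplyr::mutate(
    x$methods,
    discoveries = purrr::map_chr(.data$discoveries, paste, collapse = ";")
  )
}

#' @rdname psagwas-tidiers
#' @export
glance.comparison_report <- function(x, ...) {
  tibble::tibble(
    n_input = x$counts$n_input,
    n_pass = x$counts$n_pass,
    n_prioritized = x$counts$n_prioritized,
    n_non_prioritized = x$counts$n_non_prioritized,
    alpha = x$alpha,
    n_bonferroni = x$methods$n_discoveries[x$methods$method == "bonferroni"],
    n_fdr_traditional =
      x$methods$n_discoveries[x$methods$method == "fdr_traditional"],
    n_psa = x$methods$n_discoveries[x$methods$method == "psa"],
    perm_fdr_hat = if (is.null(x$perm)) NA_real_ else x$perm$fdr_hat
  )
}
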