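#' Bonferroni per-test significance threshold
#'
#' @param m Number of tests (at least 1).
#' @param alpha Family-wise error level in (0, 1).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(99317, 0.05)
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (length(m) != 1 || is.na(m) || m < 1 || m != round(m)) {
    abort("`m` must be a positive integer count.")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  alpha / m
}

#' Estimate the proportion of true nulls (pi0)
#'
#' Storey-Tibshirani smoothing-spline estimator: the raw estimates
#' `#\{p > lambda\} / (m (1 - lambda))` are computed on a grid of lambda
#' values, a cubic smoothing spline with 3 effective degrees of freedom is
#' fit to them, and the estimate is the spline value at the largest lambda,
#' clamped into (0, 1]. With fewer than `min_n` p-values the spline is
#' unstable, so the estimator falls back to the conservative `pi0 = 1`
#' (plain Benjamini-Hochberg behavior).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param lambda Grid of evaluation thresholds in \[0, 1); default
#'   `seq(0, 0.90, by = 0.05)`.
#' @param min_n Minimum number of p-values for spline estimation
#'   (default 100).
#' @param warn Emit a warning when the fallback is used (default `TRUE`).
#' @return An object of class `pi0_estimate`: list with `pi0`,
#'   `lambda`, `raw_pi0` (per-lambda raw estimates), `method`
#'   (`"spline"` or `"fixed"`), `n`.
#' @export
#' @examples
#' set.seed(1)
#' estimate_pi0(runif(5000))
estimate_pi0 <- function(pvalues, lambda = seq(0, 0.90, by = 0.05),
                         min_n = 100, warn = TRUE) {
  check_pvalues(pvalues)
  if (any(lambda < 0) || any(lambda >= 1)) {
    abort("`lambda` values must lie in [0, 1).")
  }
  m <- length(pvalues)
  if (m < min_n) {
    if (warn) {
      rlang::warn(sprintf(
        "Only %d p-values (< %d); falling back to pi0 = 1.", m, min_n
      ))
    }
    return(structure(
      list(pi0 = 1, lambda = lambda, raw_pi0 = NULL, method = "fixed", n = m),
      class = "pi0_estimate"
    ))
  }
  lambda <- sort(lambda)
  raw <- vapply(lambda, function(l) mean(pvalues > l) / (1 - l), numeric(1))
  fit <- smooth.spline(lambda, raw, df = 3)
  pi0 <- predict(fit, x = max(lambda))$y
  pi0 <- min(max(pi0, .Machine$double.eps), 1)
  structure(
    list(pi0 = pi0, lambda = lambda, raw_pi0 = raw, method = "spline", n = m),
    class = "pi0_estimate"
  )
}

#' @export
print.pi0_estimate <- function(x, ...) {
  cat(sprintf("<pi0_estimate> pi0 = %.4f (%s, n = %d)\n",
              x$pi0, x$method, x$n))
  invisible(x)
}

check_pvalues <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1)) {
    abort("p-values must lie in [0, 1] with no NA.")
  }
  invisible(pvalues)
}

#' Storey q-values
#'
#' `q(p_(i)) = min over j >= i of pi0 * m * p_(j) / j` on the sorted
#' p-values, mapped back to the input order; computed as `pi0` times the
#' Benjamini-Hochberg step-up adjustment. Ties share a q-value and every
#' q-value is at most `pi0`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param pi0 Proportion of true nulls in (0, 1] (default 1).
#' @return Numeric vector of q-values aligned with `pvalues`.
#' @export
#' @examples
#' qvalues(c(0.01, 0.02, 0.03, 0.9))
qvalues <- function(pvalues, pi0 = 1) {
  check_pvalues(pvalues)
  if (length(pi0) != 1 || is.na(pi0) || pi0 <= 0 || pi0 > 1) {
    abort("`pi0` must be a single value in (0, 1].")
  }
  pi0 * p.adjust(pvalues, method = "BH")
}

#' Traditional single-stratum FDR discoveries
#'
#' Estimates pi0 from the p-values themselves (see [estimate_pi0()]),
#' converts to q-values, and declares every test with `q <= alpha`
#' significant (inclusive threshold).
#'
#' @inheritParams estimate_pi0
#' @param alpha FDR control level in (0, 1) (default 0.05).
#' @param pi0 Optional fixed pi0; when `NULL` (default) it is estimated.
#' @return An object of class `fdr_result`: list with `pvalues`, `qvalues`,
#'   `pi0` (a `pi0_estimate`), `alpha`, `discoveries` (integer indices into
#'   `pvalues`).
#' @export
#' @examples
#' set.seed(1)
#' p <- c(1e-8, 1e-7, runif(998))
#' fdr_discoveries(p)$discoveries
fdr_discoveries <- function(pvalues, alpha = 0.05, pi0 = NULL,
                            min_n = 100, warn = TRUE) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  est <- if (is.null(pi0)) {
    estimate_pi0(pvalues, min_n = min_n, warn = warn)
  } else {
    structure(
      list(pi0 = pi0, lambda = NULL, raw_pi0 = NULL, method = "fixed",
           n = length(pvalues)),
      class = "pi0_estimate"
    )
  }
  q <- qvalues(pvalues, est$pi0)
  structure(
    list(
      pvalues = pvalues, qvalues = q, pi0 = est, alpha = alpha,
      discoveries = which(q <= alpha)
    ),
    class = "fdr_result"
  )
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf(
    "<fdr_result> %d discoveries of %d tests at FDR <= %g (pi0 = %.3f, %s)\n",
    length(x$discoveries), length(x$pvalues), x$alpha,
    x$pi0$pi0, x$pi0$method
  ))
  invisible(x)
}

#' Prioritized subset analysis (stratified FDR control)
#'
#' Partitions the tests into a prioritized and a non-prioritized stratum,
#' applies FDR control (pi0 estimation, q-values, `q <= alpha`) within each
#' stratum independently at the same level, and harvests the union of the
#' per-stratum discoveries. No information -- neither pi0 nor p-values --
#' is shared across strata. Strata smaller than `min_n` use the
#' conservative `pi0 = 1` fallback silently (by design for tiny strata).
#'
#' @param pvalues Numeric vector of per-SNP p-values.
#' @param prioritized Logical vector aligned with `pvalues`, or a subset
#'   assignment tibble from [assign_subsets()] (its `prioritized` column is
#'   used, and its `snp_id` column labels the output).
#' @param alpha FDR level applied within each stratum (default 0.05).
#' @param snp_id Optional identifiers for labeling the output.
#' @inheritParams estimate_pi0
#' @return An object of class `psa_result`: list with
#'   \describe{
#'     \item{snps}{tibble (`snp_id`, `stratum`, `p_value`, `q_value`,
#'       `discovered`), in input order.}
#'     \item{strata}{named list (`prioritized`, `non_prioritized`) of
#'       per-stratum summaries: `n`, `pi0` (a `pi0_estimate`),
#'       `n_discoveries`.}
#'     \item{discoveries}{integer indices into `pvalues` of the combined
#'       (union) discovery set.}
#'     \item{alpha}{the control level.}
#'   }
#' @export
#' @examples
#' set.seed(1)
#' p <- c(1e-6, 5e-5, runif(998))
#' prio <- c(TRUE, TRUE, rep(FALSE, 498), rep(TRUE, 48), rep(FALSE, 452))
#' res <- psa(p, prio)
#' glance(res)
psa <- function(pvalues, prioritized, alpha = 0.05, snp_id = NULL,
                min_n = 100) {
  check_pvalues(pvalues)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (is.data.frame(prioritized)) {
    if (is.null(snp_id) && "snp_id" %in% names(prioritized)) {
      snp_id <- prioritized$snp_id
    }
    prioritized <- prioritized$prioritized
  }
  if (!is.logical(prioritized) || length(prioritized) != length(pvalues) ||
      anyNA(prioritized)) {
    abort("`prioritized` must be a complete logical vector aligned with `pvalues`.")
  }
  if (is.null(snp_id)) snp_id <- sprintf("snp%06d", seq_along(pvalues))

  q <- rep(NA_real_, length(pvalues))
  discovered <- rep(FALSE, length(pvalues))
  strata <- list()
  for (s in c("prioritized", "non_prioritized")) {
    idx <- if (s == "prioritized") which(prioritized) else which(!prioritized)
    if (!length(idx)) {
      strata[[s]] <- list(n = 0L, pi0 = NULL, n_discoveries = 0L)
      next
    }
    fit <- fdr_discoveries(pvalues[idx], alpha = alpha, min_n = min_n,
                           warn = FALSE)
    q[idx] <- fit$qvalues
    discovered[idx[fit$discoveries]] <- TRUE
    strata[[s]] <- list(
      n = length(idx), pi0 = fit$pi0,
      n_discoveries = length(fit$discoveries)
    )
  }
  structure(
    list(
      snps = tibble::tibble(
        snp_id = snp_id,
        stratum = ifelse(prioritized, "prioritized", "non_prioritized"),
        p_value = pvalues,
        q_value = q,
        discovered = discovered
      ),
      strata = strata,
      discoveries = which(discovered),
      alpha = alpha
    ),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "<psa_result> %d discoveries at within-stratum FDR <= %g\n",
    length(x$discoveries), x$alpha
  ))
  for (s in names(x$strata)) {
    st <- x$strata[[s]]
    pi0 <- if (is.null(st$pi0)) NA_real_ else st$pi0$pi0
    cat(sprintf("  %-16s n = %6d, pi0 = %s, discoveries = %d\n",
                s, st$n,
                ifelse(is.na(pi0), "-", sprintf("%.3f", pi0)),
                st$n_discoveries))
  }
  invisible(x)
}
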