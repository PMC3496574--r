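#' Hardy-Weinberg equilibrium test for a bi-allelic probeset
#'
#' Pearson's chi-square goodness-of-fit test of observed genotype counts
#' against the Hardy-Weinberg proportions p^2 : 2pq : q^2, with the allele
#' frequency estimated from the data: p = (2 * hom_ref + het) / (2n).
#' Degrees of freedom are 1 (three genotype classes, one estimated
#' frequency). A monomorphic input (p = 0 or 1) cannot deviate from
#' equilibrium: chi-square is 0 and the result is flagged.
#'
#' @param n_hom_ref,n_het,n_hom_var Observed genotype counts (homozygote
#'   reference, heterozygote, homozygote variant).
#' @param alpha Significance level in (0, 1) for the equilibrium decision.
#' @param continuity Apply Yates' continuity correction
#'   (|O - E| reduced by 0.5, floored at 0). Off by default.
#' @return An object of class `hwe_result`; see [tidy.hwe_result()] for the
#'   tabular view. Fields: observed and expected counts, `p_allele`,
#'   `q_allele`, `chi2`, `df`, `p_value`, `alpha`, `reject_equilibrium`,
#'   `monomorphic`.
#' @examples
#' hwe_test(50, 20, 30)   # strong deviation, chi2 ~ 34.03
#' hwe_test(25, 50, 25)   # exact equilibrium proportions, chi2 = 0
#' @export
hwe_test <- function(n_hom_ref, n_het, n_hom_var, alpha = 0.05,
                     continuity = FALSE) {
  obs <- c(hom_ref = n_hom_ref, het = n_het, hom_var = n_hom_var)
  if (any(is.na(obs)) || any(obs < 0) || any(obs != round(obs))) {
    abort("Genotype counts must be non-negative integers.",
          class = "dmetr_domain_error")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).", class = "dmetr_domain_error")
  }
  n <- sum(obs)
  if (n < 1) {
    abort("Total genotype count must be >= 1.", class = "dmetr_domain_error")
  }
  p <- (2 * obs[["hom_ref"]] + obs[["het"]]) / (2 * n)
  q <- 1 - p
  expected <- n * c(hom_ref = p^2, het = 2 * p * q, hom_var = q^2)
  monomorphic <- p == 0 || p == 1
  if (monomorphic) {
    chi2 <- 0
  } else {
    dev <- abs(obs - expected)
    if (continuity) dev <- pmax(dev - 0.5, 0)
    nz <- expected > 0
    chi2 <- sum(dev[nz]^2 / expected[nz])
  }
  p_value <- if (monomorphic) 1 else pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(
    list(
      n_hom_ref = obs[["hom_ref"]], n_het = obs[["het"]],
      n_hom_var = obs[["hom_var"]],
      p_allele = p, q_allele = q,
      expected = expected,
      chi2 = chi2, df = 1L, p_value = p_value,
      alpha = alpha, reject_equilibrium = p_value < alpha,
      monomorphic = monomorphic, continuity = continuity
    ),
    class = "hwe_result"
  )
}

#' @export
print.hwe_result <- function(x, ...) {
  cat("Hardy-Weinberg equilibrium chi-square test\n")
  obs <- c(x$n_hom_ref, x$n_het, x$n_hom_var)
  tab <- rbind(observed = obs, expected = round(x$expected, 3))
  colnames(tab) <- c("hom_ref", "het", "hom_var")
  print(tab)
  cat(sprintf("allele frequencies: p = %.4f, q = %.4f\n",
              x$p_allele, x$q_allele))
  if (x$monomorphic) cat("monomorphic probe: no deviation possible\n")
  cat(sprintf("chi2 = %.4f (df = %d), p = %.4g\n", x$chi2, x$df, x$p_value))
  cat(sprintf("deviation from equilibrium at alpha = %g: %s\n", x$alpha,
              if (x$reject_equilibrium) "REJECT equilibrium" else "not rejected"))
  invisible(x)
}

#' Tidy a Hardy-Weinberg test result
#'
#' @param x An `hwe_result`.
#' @param ... Unused.
#' @return `tidy()`: one row per genotype class with observed and expected
#'   counts. `glance()`: a one-row tibble with the statistic, p-value and
#'   decision.
#' @export
tidy.hwe_result <- function(x, ...) {
  tibble::tibble(
    genotype = c("hom_ref", "het", "hom_var"),
    observed = c(x$n_hom_ref, x$n_het, x$n_hom_var),
    expected = unname(x$expected)
  )
}

#' @rdname tidy.hwe_result
#' @export
glance.hwe_result <- function(x, ...) {
  tibble::tibble(
    n = x$n_hom_ref + x$n_het + x$n_hom_var,
    p_allele = x$p_allele, q_allele = x$q_allele,
    chi2 = x$chi2, df = x$df, p_value = x$p_value,
    alpha = x$alpha, reject_equilibrium = x$reject_equilibrium,
    monomorphic = x$monomorphic
  )
}
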