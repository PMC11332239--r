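#' Residual diagnostics for a beta GLMM
#'
#' Computes randomized quantile residuals: the probability-integral
#' transform `u = F(y; mu_hat, phi)` of each observation under the fitted
#' conditional beta distribution (BLUPs included), mapped to the normal
#' scale. Under a correctly specified model the `u` are uniform on (0,1);
#' departures (e.g. heavy tails, wrong precision) show up in a
#' Kolmogorov-Smirnov test against uniformity and in residual-vs-fitted
#' summaries. Optionally summarises residuals by a grouping column (e.g.
#' taxonomic order).
#'
#' @param fit A [beta_glmm()] fit.
#' @param group Optional vector (length n) to summarise residuals by, e.g.
#'   `data$order`.
#' @return A list of class `beta_glmm_diag`: `residuals` (normal-scale),
#'   `pit` (uniform-scale), `ks` (the `htest`), `fitted`, `by_group`
#'   (tibble of per-group mean/SD/n, or `NULL`), `fitted_bins` (mean
#'   residual in fitted-value quintiles).
#' @export
validate <- function(fit, group = NULL) {
  stopifnot(inherits(fit, "beta_glmm"))
  mu <- fit$fitted
  u <- stats::pbeta(fit$y, mu * fit$phi, (1 - mu) * fit$phi)
  u <- clamp(u, 1e-12, 1 - 1e-12)
  r <- stats::qnorm(u)
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  qs <- stats::quantile(mu, probs = seq(0, 1, 0.2))
  fbin <- cut(mu, breaks = unique(qs), include.lowest = TRUE)
  fitted_bins <- tibble::tibble(
    bin = levels(fbin),
    mean_resid = as.numeric(tapply(r, fbin, mean)),
    n = as.integer(table(fbin))
  )
  by_group <- NULL
  if (!is.null(group)) {
    abort_if(length(group) != fit$n, "group must have one value per observation")
    by_group <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(group = group, r = r), .data$group),
      mean_resid = mean(.data$r), sd_resid = stats::sd(.data$r),
      n = dplyr::n(), .groups = "drop")
  }
  structure(list(residuals = r, pit = u, ks = ks, fitted = mu,
                 by_group = by_group, fitted_bins = fitted_bins),
            class = "beta_glmm_diag")
}

#' @export
print.beta_glmm_diag <- function(x, ...) {
  cat(sprintf("quantile residuals: n = %d, KS uniformity D = %.4f (p = %.3g)\n",
              length(x$residuals), unname(x$ks$statistic), x$ks$p.value))
  cat("mean residual by fitted-value quintile:\n")
  print(as.data.frame(x$fitted_bins), digits = 3, row.names = FALSE)
  if (!is.null(x$by_group)) {
    cat("residual summaries by group:\n")
    print(as.data.frame(x$by_group), digits = 3, row.names = FALSE)
  }
  invisible(x)
}
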