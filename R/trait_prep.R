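# Phenotype preparation: normality transform, covariate adjustment, and
# narrow-sense heritability estimation for the null simulations.

#' Rank-based inverse normal transformation
#'
#' Maps trait values to normal scores via the Blom offset:
#' `qnorm((rank - 3/8) / (n + 1/4))`, with ties receiving their average rank
#' and missing values preserved. Because only ranks enter, any strictly
#' increasing transform of the input yields identical output.
#'
#' @param values numeric vector, may contain `NA`.
#' @return Transformed vector of the same length and names.
#' @export
inverse_normal_transform <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(unique(x)) < 2)
    .rvkt_error("rvkt_constant_trait_error",
                "trait is constant (or has < 2 distinct values); cannot transform")
  n <- length(x)
  r <- rank(x, ties.method = "average")
  out <- values
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Residualize a trait on covariates
#'
#' Ordinary least-squares fit of the trait on an intercept plus the given
#' covariates (categorical columns expanded to indicator contrasts);
#' residuals are re-standardized to unit variance. Rows with a missing trait
#' or covariate value come back `NA`.
#'
#' @param values numeric trait vector.
#' @param covariates data frame, one row per element of `values`.
#' @return Named numeric vector of standardized residuals.
#' @export
adjust_covariates <- function(values, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(values))
    stop("covariate rows must align with trait values")
  dat <- cbind(.y = values, covariates)
  fit <- stats::lm(.y ~ ., data = dat, na.action = stats::na.exclude)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    .rvkt_error("rvkt_collinear_covariates_error",
                "rank-deficient covariate design; collinear terms: %s",
                paste(names(cf)[is.na(cf)], collapse = ", "))
  res <- stats::residuals(fit)
  s <- stats::sd(res, na.rm = TRUE)
  if (!is.finite(s) || s < 1e-10 * max(stats::sd(values, na.rm = TRUE), 1e-10))
    .rvkt_error("rvkt_degenerate_residuals_error",
                "trait is (numerically) an exact function of the covariates; nothing left to test")
  out <- res / s
  names(out) <- names(values)
  out
}

#' Should a trait be inverse-normal transformed?
#'
#' Operationalizes "transform when necessary": a Shapiro-Wilk normality
#' check at level `alpha` (default 0.01) on the non-missing values (a
#' deterministic stride subsample is used above the test's 5,000-value
#' limit).
#'
#' @param values numeric vector.
#' @param alpha significance level of the normality check.
#' @return Logical.
#' @export
needs_transform <- function(values, alpha = 0.01) {
  x <- values[!is.na(values)]
  if (length(unique(x)) < 3) return(FALSE)
  if (length(x) > 5000) x <- x[seq(1L, length(x), length.out = 5000)]
  stats::shapiro.test(x)$p.value < alpha
}

#' Estimate narrow-sense heritability from pedigree data
#'
#' Maximum likelihood under the standard polygenic variance-component model:
#' the trait vector is multivariate normal with mean mu and covariance
#' `sigma2 * (2 * Phi * h2 + I * (1 - h2))`, where `Phi` is the kinship
#' matrix. A single eigendecomposition of `2 * Phi` makes the profile
#' log-likelihood over `h2` cheap: for each `h2` the mean and `sigma2` are
#' profiled in closed form. The profile is evaluated on a grid over
#' `[0, 0.99]` and refined locally; the confidence interval is the
#' profile-likelihood interval at the 0.95 chi-square cutoff.
#'
#' @param values named numeric trait vector (names are ids in `K`), missing
#'   values dropped.
#' @param K kinship matrix covering the named ids.
#' @param grid_step spacing of the initial `h2` grid.
#' @return An object of class `h2_estimate`: list with `h2_hat`, `ci`,
#'   `sigma2`, `mu`, `loglik_profile` (data frame of `h2`, `loglik`), and
#'   `lrt_vs_zero` (likelihood-ratio statistic against `h2 = 0`, a
#'   diagnostic only).
#' @export
estimate_h2 <- function(values, K, grid_step = 0.01) {
  ok <- !is.na(values)
  y <- values[ok]
  ids <- names(y)
  if (is.null(ids)) stop("values must be named by individual id")
  idx <- match(ids, rownames(K))
  if (anyNA(idx)) stop("ids not present in kinship matrix: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  if (stats::sd(y) < 1e-12)
    .rvkt_error("rvkt_constant_trait_error", "trait is constant; h2 unidentifiable")
  A <- 2 * unclass(K)[idx, idx]
  if (max(A[upper.tri(A)]) <= 0)
    .rvkt_error("rvkt_unrelated_sample_error",
                "no related phenotyped pairs; h2 unidentifiable")
  n <- length(y)
  eg <- eigen(A, symmetric = TRUE)
  lam <- eg$values
  yt <- drop(crossprod(eg$vectors, y))
  xt <- drop(crossprod(eg$vectors, rep(1, n)))

  prof <- function(h2) {
    d <- h2 * lam + (1 - h2)
    mu <- sum(xt * yt / d) / sum(xt^2 / d)
    r <- yt - mu * xt
    s2 <- sum(r^2 / d) / n
    list(loglik = -0.5 * (n * log(s2) + sum(log(d)) + n), mu = mu, sigma2 = s2)
  }
  grid <- seq(0, 0.99, by = grid_step)
  ll <- vapply(grid, function(h) prof(h)$loglik, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(h) prof(h)$loglik, c(lo, hi), maximum = TRUE,
                         tol = 1e-6)
  h2_hat <- if (opt$objective > ll[i]) opt$maximum else grid[i]
  at_hat <- prof(h2_hat)
  llmax <- at_hat$loglik
  cut <- llmax - stats::qchisq(0.95, 1) / 2
  inside <- grid[ll >= cut]
  ci <- if (length(inside)) range(inside) else c(h2_hat, h2_hat)
  structure(list(h2_hat = h2_hat, ci = ci, sigma2 = at_hat$sigma2,
                 mu = at_hat$mu,
                 loglik_profile = data.frame(h2 = grid, loglik = ll),
                 lrt_vs_zero = 2 * (llmax - prof(0)$loglik), n = n),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("h2_estimate: h2 = %.3f (95%% profile CI %.3f-%.3f), n = %d, LRT vs h2=0: %.2f\n",
              x$h2_hat, x$ci[1], x$ci[2], x$n, x$lrt_vs_zero))
  invisible(x)
}

#' Read a phenotype table
#'
#' Tab-delimited, header row, an `id` column (matching the pedigree's
#' `"fid:iid"` keys, or bare individual ids when those are unique), and one
#' column per trait or covariate.
#'
#' @param path file path.
#' @param na_strings strings read as missing.
#' @return A data frame.
#' @export
read_phenotypes <- function(path, na_strings = c("NA", "", ".")) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, na.strings = na_strings,
                           check.names = FALSE, comment.char = "#")
  if (!nrow(tab) || !ncol(tab))
    .rvkt_error("rvkt_empty_phenotypes_error", "phenotype file is empty: %s", path)
  if (!"id" %in% names(tab))
    stop("phenotype table needs an 'id' column")
  tab
}
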