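# Effective number of tests among correlated traits and the Bonferroni
# correction applied to per-trait minimum p-values.

#' Effective number of independent tests (eigenvalue method)
#'
#' From the trait-trait correlation matrix (pairwise-complete observations)
#' with eigenvalues `lambda_i`, the effective number of tests is
#' `sum_i [ I(|lambda_i| >= 1) + (|lambda_i| - floor(|lambda_i|)) ]`:
#' M mutually independent traits give M, M perfectly correlated traits give
#' 1. Constant or all-missing traits are excluded with a warning before the
#' eigen-analysis. Both the raw value and its ceiling are returned; the
#' ceiling is the integer used for correction.
#'
#' @param traits numeric matrix or data frame, one column per trait.
#' @param min_overlap smallest acceptable number of pairwise-complete
#'   observations for any trait pair (default 30).
#' @return An object of class `m_eff`: list with `m` (traits used),
#'   `m_eff_raw`, `m_eff` (ceiling), `excluded`, and `eigenvalues`.
#' @export
effective_tests <- function(traits, min_overlap = 30) {
  X <- as.matrix(as.data.frame(traits))
  storage.mode(X) <- "double"
  usable <- apply(X, 2, function(x) sum(!is.na(x)) >= 2 &&
                                    stats::sd(x, na.rm = TRUE) > 0)
  if (any(!usable))
    warning("excluding constant or all-missing traits: ",
            paste(colnames(X)[!usable], collapse = ", "), call. = FALSE)
  X <- X[, usable, drop = FALSE]
  M <- ncol(X)
  if (M < 2) stop("need at least 2 usable traits")
  overlap <- crossprod(!is.na(X))
  off <- overlap[upper.tri(overlap)]
  if (any(off < min_overlap)) {
    bad <- which(overlap < min_overlap & upper.tri(overlap), arr.ind = TRUE)
    stop("trait pairs with fewer than ", min_overlap,
         " overlapping observations: ",
         paste(colnames(X)[bad[, 1]], colnames(X)[bad[, 2]],
               sep = "~", collapse = ", "))
  }
  C <- stats::cor(X, use = "pairwise.complete.obs")
  lam <- abs(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  lam_r <- round(lam, 10)   # guard floor() against eigenvalues like 4 - 1e-15
  m_eff_raw <- sum((lam_r >= 1) + (lam_r - floor(lam_r)))
  structure(list(m = M, m_eff_raw = m_eff_raw,
                 m_eff = as.integer(ceiling(m_eff_raw - 1e-9)),
                 excluded = colnames(as.data.frame(traits))[!usable],
                 eigenvalues = lam),
            class = "m_eff")
}

#' @export
print.m_eff <- function(x, ...) {
  cat(sprintf("effective tests: %.3f raw (ceiling %d) among %d traits\n",
              x$m_eff_raw, x$m_eff, x$m))
  invisible(x)
}

#' Bonferroni-correct per-trait minimum p-values
#'
#' Multiplies each trait's minimum empirical p-value by the effective number
#' of tests and caps at 1. Note the correction addresses testing many
#' traits; it deliberately does not account for the tail sizes and sides
#' searched within a trait, which the screen leaves uncorrected.
#'
#' @param p_min named numeric vector of per-trait minimum p-values in
#'   `[0, 1]`.
#' @param m_eff effective number of tests (an `m_eff` object or a number).
#' @param alpha significance level for the flags.
#' @return An object of class `multiplicity_report`: list with `m_eff`,
#'   `alpha`, and `table` (trait, p_min, p_min_corrected, significant).
#' @export
correct_pmin <- function(p_min, m_eff, alpha = 0.05) {
  if (inherits(m_eff, "m_eff")) m_eff <- m_eff$m_eff
  if (any(p_min < 0 | p_min > 1, na.rm = TRUE))
    stop("p_min values must be in [0, 1]")
  if (m_eff < 1) stop("m_eff must be >= 1")
  corrected <- pmin(1, p_min * m_eff)
  tab <- data.frame(trait = if (is.null(names(p_min)))
                              sprintf("trait%d", seq_along(p_min))
                            else names(p_min),
                    p_min = as.numeric(p_min),
                    p_min_corrected = as.numeric(corrected),
                    significant = corrected <= alpha,
                    row.names = NULL)
  structure(list(m_eff = m_eff, alpha = alpha, table = tab),
            class = "multiplicity_report")
}

#' @export
print.multiplicity_report <- function(x, ...) {
  cat(sprintf("multiplicity_report: m_eff = %d, alpha = %g\n", x$m_eff, x$alpha))
  cat("(correction covers the number of traits only, not the tail sizes and sides searched within each trait)\n")
  print(x$table[order(x$table$p_min_corrected), ], row.names = FALSE)
  invisible(x)
}
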