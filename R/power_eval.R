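# Power of the tail-kinship screen under a rare-variant alternative,
# estimated by simulation against a polygenic empirical null.

#' Tail size maximizing power for a given allele frequency
#'
#' Power is generally greatest when the tail size matches the expected
#' carrier frequency of the rare allele under Hardy-Weinberg proportions:
#' `2 q (1 - q) + q^2`.
#'
#' @param q allele frequency in (0, 1).
#' @return The carrier frequency.
#' @export
optimal_tail_fraction <- function(q) {
  if (!(q > 0 && q < 1)) stop("q must be in (0, 1)")
  2 * (1 - q) * q + q^2
}

#' Estimate power of the tail-kinship test by simulation
#'
#' Builds (or reuses) one empirical null of `N_null` purely polygenic
#' replicates, sets a per-tail rejection threshold with size as close as
#' possible to `alpha` without exceeding it, then simulates `N_alt`
#' replicates under the rare-variant alternative and reports, per tail size,
#' the proportion whose statistic reaches the threshold. Power is evaluated
#' on the tail matching the variant's direction of effect only (an applied
#' screen would test both sides).
#'
#' @param ped a [pedigree()].
#' @param h2 narrow-sense heritability (total, including the variant).
#' @param q rare allele founder frequency.
#' @param v fraction of total trait variance explained by the variant.
#' @param direction `"raise"` or `"lower"`.
#' @param tail_fractions tail-size grid, default 1, 2, 4, 6, 8%.
#' @param alpha nominal test size.
#' @param N_null,N_alt replicate counts for the null and the alternative.
#' @param seed integer seed covering both phases.
#' @param K optional precomputed kinship matrix.
#' @param null optional precomputed `rvkt_null` (matching pedigree/h2) to
#'   reuse across parameter settings.
#' @param chunk replicates per simulation block.
#' @return An object of class `rvkt_power`: list with `per_tail` (data frame
#'   with power, Monte-Carlo standard error, achieved size, threshold,
#'   feasibility, and mean carrier enrichment among tail members), `best`
#'   (the feasible tail with maximal power), and the parameters.
#' @export
estimate_power <- function(ped, h2, q, v, direction = c("raise", "lower"),
                           tail_fractions = c(.01, .02, .04, .06, .08),
                           alpha = 0.05, N_null = 10000, N_alt = 1000,
                           seed = NULL, K = NULL, null = NULL, chunk = 2000) {
  direction <- match.arg(direction)
  stopifnot(inherits(ped, "pedigree"), N_alt >= 100)
  if (is.null(K)) K <- compute_kinship(ped)
  side <- if (direction == "raise") "upper" else "lower"
  if (!is.null(seed)) set.seed(seed)
  if (is.null(null))
    null <- build_null(ped, K, h2, tail_fractions, sides = side,
                       N_null = N_null, seed = NULL, chunk = chunk)

  subj <- ped$id[ped$study]
  Ks <- unclass(K)[subj, subj]
  tails <- .resolve_tails(tail_fractions, side, length(subj))
  thr <- lapply(tails$fraction, function(f)
    rejection_threshold(null, alpha, side = side, fraction = f))

  model <- trait_model(h2, rare_variant_spec(q, v = v, direction = direction))
  n_tails <- nrow(tails)
  hits <- integer(n_tails)
  enrich <- numeric(n_tails)
  selfk <- .self_kinship(ped, K)
  sgn <- if (direction == "raise") 1 else -1
  a <- sqrt(v / (2 * q * (1 - q)))
  done <- 0L
  while (done < N_alt) {
    m <- min(chunk, N_alt - done)
    copies <- drop_rare_variant(ped, q, m, seed = NULL)
    A <- .sim_additive_matrix(ped, h2 - v, m, selfk)
    E <- matrix(stats::rnorm(nrow(ped) * m, 0, sqrt(1 - h2)), nrow(ped), m)
    V <- (sgn * a * (copies - 2 * q) + A + E)[ped$study, , drop = FALSE]
    carr <- copies[ped$study, , drop = FALSE] >= 1L
    st <- .tail_stats_matrix(V, Ks, tails)
    for (j in seq_len(n_tails)) {
      if (thr[[j]]$feasible)
        hits[j] <- hits[j] + sum(st[, j] >= thr[[j]]$threshold - 1e-12)
    }
    # carrier enrichment: mean fraction of tail members carrying the allele
    n <- nrow(V)
    for (r in seq_len(m)) {
      o <- order(V[, r])
      for (j in seq_len(n_tails)) {
        k <- tails$n_tail[j]
        sel <- if (side == "lower") o[seq_len(k)] else o[n - seq_len(k) + 1L]
        enrich[j] <- enrich[j] + mean(carr[sel, r])
      }
    }
    done <- done + m
  }
  feasible <- vapply(thr, `[[`, logical(1), "feasible")
  power <- ifelse(feasible, hits / N_alt, NA_real_)
  per_tail <- data.frame(
    fraction = tails$fraction, n_tail = tails$n_tail,
    threshold = vapply(thr, `[[`, numeric(1), "threshold"),
    achieved_size = vapply(thr, `[[`, numeric(1), "size"),
    min_size = vapply(thr, `[[`, numeric(1), "min_size"),
    feasible = feasible,
    power = power,
    mc_se = sqrt(power * (1 - power) / N_alt),
    carrier_enrichment = enrich / N_alt)
  best <- if (any(feasible)) {
    i <- which(per_tail$power == max(per_tail$power, na.rm = TRUE))[1L]
    per_tail[i, , drop = FALSE]
  } else NULL
  structure(list(per_tail = per_tail, best = best, side = side,
                 h2 = h2, q = q, v = v, alpha = alpha,
                 N_null = N_null, N_alt = N_alt, seed = seed,
                 carrier_frequency = optimal_tail_fraction(q)),
            class = "rvkt_power")
}

#' @export
print.rvkt_power <- function(x, ...) {
  cat(sprintf("rvkt_power: q = %g, v = %g, h2 = %g, alpha = %g (%d null / %d alt replicates)\n",
              x$q, x$v, x$h2, x$alpha, x$N_null, x$N_alt))
  print(x$per_tail, row.names = FALSE)
  if (!is.null(x$best))
    cat(sprintf("best tail: %g%% (power %.3f)\n",
                100 * x$best$fraction, x$best$power))
  invisible(x)
}

#' Run a grid of power evaluations
#'
#' Batches [estimate_power()] over a parameter grid of allele frequencies,
#' variance fractions, and heritabilities on one cohort, reusing a single
#' null distribution per heritability value (the null does not depend on
#' the alternative's q and v).
#'
#' @param ped a [pedigree()].
#' @param qs,vs,h2s parameter vectors crossed into a grid.
#' @inheritParams estimate_power
#' @return A data frame with one row per (q, v, h2, tail fraction).
#' @export
power_grid <- function(ped, qs, vs, h2s, direction = "raise",
                       tail_fractions = c(.01, .02, .04, .06, .08),
                       alpha = 0.05, N_null = 10000, N_alt = 1000,
                       seed = NULL, K = NULL, chunk = 2000) {
  if (is.null(K)) K <- compute_kinship(ped)
  side <- if (direction == "raise") "upper" else "lower"
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (h2 in h2s) {
    null <- build_null(ped, K, h2, tail_fractions, sides = side,
                       N_null = N_null, seed = NULL, chunk = chunk)
    for (q in qs) for (v in vs) {
      pw <- estimate_power(ped, h2, q, v, direction, tail_fractions,
                           alpha, N_null, N_alt, seed = NULL,
                           K = K, null = null, chunk = chunk)
      tab <- pw$per_tail
      tab <- cbind(q = q, v = v, h2 = h2, tab)
      out[[length(out) + 1L]] <- tab
    }
  }
  do.call(rbind, out)
}
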