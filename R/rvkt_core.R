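# The tail-kinship statistic, its simulated null distribution, empirical
# p-values, and discreteness-aware rejection thresholds.

#' Resolve a tail fraction to a subject count
#'
#' Round-half-up of `n_subjects * fraction`. For a cohort of 1,481 subjects
#' and the default tail grid of 1, 2, 4, 6, 8% this gives 15, 30, 59, 89,
#' and 118 subjects. Counts are always resolved on the non-missing sample
#' for each trait.
#'
#' @param n_subjects number of subjects with non-missing trait values.
#' @param fraction tail size in (0, 0.5).
#' @return Integer tail count, at least 2.
#' @export
tail_count <- function(n_subjects, fraction) {
  if (!(fraction > 0 && fraction < 0.5))
    stop("tail fraction must be in (0, 0.5)")
  if (n_subjects < 4) stop("need at least 4 subjects")
  k <- floor(n_subjects * fraction + 0.5)
  if (k < 2)
    .rvkt_error("rvkt_tail_too_small_error",
                "tail of %g%% of %d subjects resolves to %d (< 2); statistic undefined",
                100 * fraction, n_subjects, k)
  as.integer(k)
}

#' Select the members of a trait tail
#'
#' Returns the ids of the `tail_count(n_nonmissing, fraction)` subjects with
#' the smallest (`side = "lower"`) or largest (`"upper"`) trait values.
#' Missing values are excluded before the count is resolved. Ties at the
#' tail boundary are broken deterministically by id order and flagged with a
#' warning; a fully degenerate (constant) trait is likewise flagged.
#'
#' @param values named numeric vector of trait values (names are ids), or an
#'   unnamed vector with `ids` supplied.
#' @param side `"lower"` or `"upper"`.
#' @param fraction tail size in (0, 0.5).
#' @param ids optional ids, defaults to `names(values)`.
#' @return Character vector of tail-member ids, ordered from most to least
#'   extreme.
#' @export
select_tail <- function(values, side = c("lower", "upper"), fraction,
                        ids = names(values)) {
  side <- match.arg(side)
  if (is.null(ids)) stop("values must be named or ids supplied")
  ok <- !is.na(values)
  x <- values[ok]; ids_ok <- ids[ok]
  k <- tail_count(length(x), fraction)
  if (length(x) < k) stop("too few non-missing values for the requested tail")
  key <- if (side == "lower") x else -x
  ord <- order(key, ids_ok)
  sel <- ord[seq_len(k)]
  if (length(unique(x)) == 1L)
    warning("degenerate trait: all values identical; tail chosen by id order",
            call. = FALSE)
  else if (k < length(x) && key[ord[k]] == key[ord[k + 1L]])
    warning("tie at the tail boundary broken by id order", call. = FALSE)
  ids_ok[sel]
}

#' The tail-kinship statistic
#'
#' Mean pairwise kinship coefficient among the members of one tail of the
#' trait distribution. Only trait ranks enter the tail selection, so the
#' statistic is invariant under any strictly increasing transform of the
#' trait.
#'
#' @inheritParams select_tail
#' @param K kinship matrix covering all ids.
#' @return The statistic value.
#' @export
rvkt_statistic <- function(values, side, fraction, K, ids = names(values)) {
  sel <- select_tail(values, side, fraction, ids)
  mean_pairwise_kinship(K, sel)
}

# Resolve tail specs to a data.frame(side, fraction, n_tail).
.resolve_tails <- function(tail_fractions, sides, n_subjects) {
  tails <- expand.grid(fraction = tail_fractions, side = sides,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tails$n_tail <- vapply(tails$fraction, tail_count,
                         integer(1), n_subjects = n_subjects)
  tails[, c("side", "fraction", "n_tail")]
}

# Statistic for every (replicate, tail spec). V: subjects x replicates value
# matrix; Ks: kinship among the same subjects (same row order). Tails on the
# same side are prefixes of one ordering, so pair sums accumulate:
# with tail members m_1..m_k ordered by extremeness, the pair sum after
# adding m_j grows by sum_i<j phi(m_i, m_j).
.tail_stats_matrix <- function(V, Ks, tails) {
  n <- nrow(V); R <- ncol(V)
  out <- matrix(NA_real_, R, nrow(tails))
  colnames(out) <- paste(tails$side, tails$fraction, sep = "_")
  for (side in unique(tails$side)) {
    rows <- which(tails$side == side)
    ks <- tails$n_tail[rows]
    kmax <- max(ks)
    ltri <- lower.tri(matrix(0, kmax, kmax))
    denom <- ks * (ks - 1) / 2
    for (r in seq_len(R)) {
      o <- order(V[, r])
      sel <- if (side == "lower") o[seq_len(kmax)] else o[n - seq_len(kmax) + 1L]
      M <- Ks[sel, sel]
      cs <- cumsum(rowSums(M * ltri))
      out[r, rows] <- cs[ks] / denom
    }
  }
  out
}

#' Build the empirical null distribution of the tail-kinship statistic
#'
#' Simulates `N_null` replicates of a purely polygenic trait with
#' heritability `h2` conditional on the pedigree, and computes the tail
#' statistic of every replicate for every requested tail size and side. One
#' shared set of trait replicates serves all tails, mirroring how the
#' observed data are tested.
#'
#' @param ped a [pedigree()].
#' @param K kinship matrix of `ped` (computed if missing).
#' @param h2 narrow-sense heritability of the trait being screened.
#' @param tail_fractions numeric vector of tail sizes, default
#'   `c(.01, .02, .04, .06, .08)`.
#' @param sides character, subset of `c("lower", "upper")`.
#' @param N_null number of replicates, at least 100 (default 10,000).
#' @param seed integer seed.
#' @param chunk replicates simulated per block (memory control only; results
#'   are identical for any chunk size given the same seed order, and the
#'   default is fixed).
#' @param subjects optional ids restricting the statistic to a subset of the
#'   study subjects (e.g. those with non-missing values for a trait); the
#'   polygenic trait is still simulated on the full pedigree.
#' @return An object of class `rvkt_null`: list with `stats` (replicates x
#'   tail specs matrix), `tails`, `h2`, `N_null`, `seed`, `n_subjects`.
#' @export
build_null <- function(ped, K = NULL, h2, tail_fractions = c(.01, .02, .04, .06, .08),
                       sides = c("lower", "upper"), N_null = 10000,
                       seed = NULL, chunk = 2000, subjects = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (N_null < 100) stop("N_null must be at least 100")
  if (is.null(K)) K <- compute_kinship(ped)
  sides <- match.arg(sides, c("lower", "upper"), several.ok = TRUE)
  subj <- if (is.null(subjects)) ped$id[ped$study] else subjects
  if (!all(subj %in% ped$id[ped$study]))
    stop("subjects must be study-subject ids of the pedigree")
  Ks <- unclass(K)[subj, subj]
  tails <- .resolve_tails(tail_fractions, sides, length(subj))
  if (!is.null(seed)) set.seed(seed)
  stats <- matrix(NA_real_, N_null, nrow(tails))
  selfk <- .self_kinship(ped, K)
  done <- 0L
  rows <- match(subj, ped$id)
  while (done < N_null) {
    m <- min(chunk, N_null - done)
    A <- .sim_additive_matrix(ped, h2, m, selfk)
    E <- matrix(stats::rnorm(nrow(ped) * m, 0, sqrt(1 - h2)), nrow(ped), m)
    V <- (A + E)[rows, , drop = FALSE]
    stats[done + seq_len(m), ] <- .tail_stats_matrix(V, Ks, tails)
    done <- done + m
  }
  colnames(stats) <- paste(tails$side, tails$fraction, sep = "_")
  structure(list(stats = stats, tails = tails, h2 = h2, N_null = N_null,
                 seed = seed, n_subjects = length(subj)),
            class = "rvkt_null")
}

#' @export
print.rvkt_null <- function(x, ...) {
  cat(sprintf("rvkt_null: %d polygenic replicates (h2 = %g) on %d subjects; tails:\n",
              x$N_null, x$h2, x$n_subjects))
  print(x$tails)
  invisible(x)
}

# Pull the null statistic vector for one tail spec.
.null_values <- function(null, side, fraction) {
  col <- paste(side, fraction, sep = "_")
  if (!col %in% colnames(null$stats))
    stop("null distribution has no tail ", col)
  null$stats[, col]
}

#' Empirical one-sided p-value
#'
#' The raw exceedance proportion: the fraction of null replicates whose
#' statistic is at least the observed value. A value exceeded by no
#' replicate yields p = 0, which reports should display as
#' `< 1/N_null` (see [format_pvalue()]) rather than zero.
#'
#' @param obs observed statistic value.
#' @param null an `rvkt_null`, or a numeric vector of null statistic values.
#' @param side,fraction tail spec to read from an `rvkt_null` object.
#' @return The empirical p-value in `[0, 1]`.
#' @export
empirical_pvalue <- function(obs, null, side = NULL, fraction = NULL) {
  vals <- if (inherits(null, "rvkt_null")) .null_values(null, side, fraction)
          else null
  if (!length(vals)) stop("empty null distribution")
  mean(vals >= obs - 1e-12)
}

#' @rdname empirical_pvalue
#' @param p an empirical p-value.
#' @param N_null the replicate count behind it.
#' @export
format_pvalue <- function(p, N_null) {
  ifelse(p == 0, sprintf("<%.*f", max(1, ceiling(log10(N_null))), 1 / N_null),
         format(p, digits = 4))
}

#' Select the minimum-p result over tail sizes
#'
#' Given per-tail results for one side of a trait distribution, returns the
#' row with the smallest p-value; ties go to the smaller tail fraction (the
#' more extreme subset).
#'
#' @param results data frame with at least columns `p_value` and `fraction`
#'   (typically the per-trait rows of a screen result).
#' @param side optional filter on a `side` column.
#' @return A single row of `results`.
#' @export
min_p_over_tails <- function(results, side = NULL) {
  if (!is.null(side)) results <- results[results$side == side, , drop = FALSE]
  if (!nrow(results)) stop("no results for the requested side")
  results[order(results$p_value, results$fraction)[1L], , drop = FALSE]
}

#' Discreteness-aware rejection threshold
#'
#' The null distribution of the tail-kinship statistic is discrete, so a
#' test of size exactly `alpha` usually does not exist. This returns the
#' smallest distinct null value `c` whose exceedance probability
#' `P(null >= c)` does not exceed `alpha` — the rejection region with size
#' as close as possible to `alpha` without exceeding it. When even the
#' largest realized value occurs too often, no valid test of level `alpha`
#' exists and an infeasibility report carrying the minimum achievable size
#' is returned instead of an error.
#'
#' @param null an `rvkt_null` or numeric vector of null statistic values.
#' @param alpha nominal size in (0, 1).
#' @inheritParams empirical_pvalue
#' @return A list with `feasible`, `threshold`, `size` (achieved size), and
#'   `min_size` (smallest achievable size; equals `size` when feasible).
#' @export
rejection_threshold <- function(null, alpha, side = NULL, fraction = NULL) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  vals <- if (inherits(null, "rvkt_null")) .null_values(null, side, fraction)
          else null
  N <- length(vals)
  v <- signif(vals, 12)                 # collapse float noise on the lattice
  tab <- table(v)
  distinct <- as.numeric(names(tab))    # ascending
  counts <- as.integer(tab)
  exceed <- rev(cumsum(rev(counts)))    # exceed[i] = #{null >= distinct[i]}
  min_size <- exceed[length(exceed)] / N
  ok <- which(exceed / N <= alpha)
  if (!length(ok))
    return(list(feasible = FALSE, threshold = NA_real_, size = NA_real_,
                min_size = min_size, alpha = alpha))
  i <- ok[1L]
  list(feasible = TRUE, threshold = distinct[i], size = exceed[i] / N,
       min_size = min_size, alpha = alpha)
}

#' Count distinct null statistic values in the upper band
#'
#' Diagnostic of the discreteness of the null cumulative distribution:
#' the number of distinct statistic values among the top
#' `quantile_band` fraction of replicates (e.g. `0.2` for the top quintile).
#'
#' @param null an `rvkt_null` or numeric vector of null values.
#' @param quantile_band fraction of replicates in the band, in (0, 1].
#' @inheritParams empirical_pvalue
#' @return Integer count of distinct values.
#' @export
null_support_summary <- function(null, quantile_band, side = NULL, fraction = NULL) {
  if (!(quantile_band > 0 && quantile_band <= 1))
    stop("quantile_band must be in (0, 1]")
  vals <- if (inherits(null, "rvkt_null")) .null_values(null, side, fraction)
          else null
  m <- max(1L, as.integer(round(length(vals) * quantile_band)))
  top <- sort(vals, decreasing = TRUE)[seq_len(m)]
  length(unique(signif(top, 12)))
}
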