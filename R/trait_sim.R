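# Simulation of quantitative traits on pedigrees: purely polygenic traits
# (the screen's null model) and traits carrying a single rare biallelic
# variant on a polygenic background (the alternative).

#' Rare variant specification
#'
#' Describes a single additive biallelic locus. The per-allele effect is
#' sized from the variance it must explain: with founder allele frequency q
#' under Hardy-Weinberg proportions the copy count has variance 2q(1-q), so
#' an allele effect a = sqrt(v / (2 q (1 - q))) makes the locus explain a
#' fraction v of total trait variance in a random-mating population.
#'
#' @param q founder frequency of the trait-influencing allele, in (0, 1).
#' @param v fraction of TOTAL trait variance explained, in (0, 1). Exactly
#'   one of `v` and `v_genetic` must be given.
#' @param v_genetic fraction of the GENETIC variance explained; converted to
#'   `v = v_genetic * h2` when the spec is attached to a [trait_model()].
#' @param direction `"raise"` (allele increases the trait) or `"lower"`.
#' @return An object of class `rare_variant_spec`.
#' @export
rare_variant_spec <- function(q, v = NULL, v_genetic = NULL,
                              direction = c("raise", "lower")) {
  direction <- match.arg(direction)
  if (!(q > 0 && q < 1)) stop("allele frequency q must be in (0, 1)")
  if (is.null(v) == is.null(v_genetic))
    stop("give exactly one of v (total-variance fraction) or v_genetic")
  if (!is.null(v) && !(v > 0 && v < 1))
    stop("variance fraction v must be in (0, 1)")
  if (!is.null(v_genetic) && !(v_genetic > 0 && v_genetic <= 1))
    stop("v_genetic must be in (0, 1]")
  structure(list(q = q, v = v, v_genetic = v_genetic, direction = direction),
            class = "rare_variant_spec")
}

#' Trait model: heritability plus optional rare variant
#'
#' @param h2 narrow-sense heritability, in `[0, 1)`: the fraction of trait
#'   variance attributable to additive genetic effects.
#' @param rare_variant optional [rare_variant_spec()]; its variance fraction
#'   must not exceed `h2` (the variant is one of the additive genetic
#'   factors).
#' @param seed integer seed used when the model is simulated.
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(h2, rare_variant = NULL, seed = NULL) {
  if (!(h2 >= 0 && h2 < 1)) stop("h2 must be in [0, 1)")
  if (!is.null(rare_variant)) {
    stopifnot(inherits(rare_variant, "rare_variant_spec"))
    if (is.null(rare_variant$v))
      rare_variant$v <- rare_variant$v_genetic * h2
    if (rare_variant$v > h2)
      stop("rare variant cannot exceed genetic variance (v > h2)")
  }
  structure(list(h2 = h2, rare_variant = rare_variant, seed = seed),
            class = "trait_model")
}

# Self-kinship vector (phi_ii) used for Mendelian-sampling variances.
.self_kinship <- function(ped, K = NULL) {
  if (!is.null(K)) return(diag(K)[ped$id])
  selfk <- numeric(nrow(ped))
  # only parental kinships are needed; for outbred pedigrees all are 1/2,
  # otherwise fall back to the full matrix
  if (all(ped$level <= 1L)) return(rep(0.5, nrow(ped)))
  diag(compute_kinship(ped))
}

# Additive genetic values for all pedigree members, variance sig2_g,
# sampled recursively level by level (vectorized across replicates):
# founders ~ N(0, sig2_g); non-founders get the mid-parent mean plus a
# Mendelian deviation ~ N(0, (sig2_g/2) (1 - (F_f + F_m)/2)) where
# F_x = 2 phi_xx - 1 is the inbreeding coefficient.
.sim_additive_matrix <- function(ped, sig2_g, R, selfk) {
  n <- nrow(ped)
  A <- matrix(0, n, R)
  if (sig2_g <= 0) return(A)
  founders <- which(is.na(ped$father))
  A[founders, ] <- stats::rnorm(length(founders) * R, 0, sqrt(sig2_g))
  Fcoef <- 2 * selfk - 1
  for (lev in seq_len(max(ped$level))) {
    idx <- which(ped$level == lev)
    if (!length(idx)) next
    f <- ped$father[idx]; m <- ped$mother[idx]
    sd_mend <- sqrt((sig2_g / 2) * (1 - (Fcoef[f] + Fcoef[m]) / 2))
    A[idx, ] <- (A[f, , drop = FALSE] + A[m, , drop = FALSE]) / 2 +
      matrix(stats::rnorm(length(idx) * R), length(idx), R) * sd_mend
  }
  A
}

#' Simulate purely polygenic traits on a pedigree
#'
#' The null model of the rare-variant kinship screen: a quantitative trait
#' determined by many additive, independent small-effect loci plus
#' independent environment, with total variance 1. Additive values are drawn
#' by recursive, inbreeding-aware Mendelian sampling in pedigree order (see
#' the package vignette), which is exact for arbitrary (including inbred)
#' pedigrees and gives trait covariance `2 * phi_ij * h2` between relatives.
#'
#' @param ped a [pedigree()].
#' @param h2 narrow-sense heritability in `[0, 1)`.
#' @param n_rep number of independent replicate traits.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param K optional precomputed kinship matrix (only its diagonal is used,
#'   to obtain inbreeding coefficients).
#' @return An object of class `simulated_trait`: a list with `values`, a
#'   numeric matrix (study subjects x replicates, rownames the `"fid:iid"`
#'   keys), `carriers = NULL`, and the model parameters.
#' @export
simulate_polygenic <- function(ped, h2, n_rep = 1, seed = NULL, K = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (!(h2 >= 0 && h2 < 1)) stop("h2 must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  selfk <- .self_kinship(ped, K)
  A <- .sim_additive_matrix(ped, h2, n_rep, selfk)
  E <- matrix(stats::rnorm(nrow(ped) * n_rep, 0, sqrt(1 - h2)),
              nrow(ped), n_rep)
  vals <- (A + E)[ped$study, , drop = FALSE]
  rownames(vals) <- ped$id[ped$study]
  structure(list(values = vals, carriers = NULL, h2 = h2, seed = seed),
            class = "simulated_trait")
}

#' Gene-drop a biallelic variant through a pedigree
#'
#' Founders receive two alleles drawn independently Bernoulli(q); each
#' non-founder inherits one uniformly chosen allele from each parent.
#' Replicates with zero carriers are legitimate draws (no conditioning on
#' the variant segregating).
#'
#' @param ped a [pedigree()].
#' @param q founder allele frequency in `[0, 1]`.
#' @param n_rep number of independent drops.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return Integer matrix of copy counts in `{0, 1, 2}`, all pedigree
#'   members x replicates, rownames the `"fid:iid"` keys.
#' @export
drop_rare_variant <- function(ped, q, n_rep = 1, seed = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (!(q >= 0 && q <= 1)) stop("allele frequency q must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  a1 <- matrix(0L, n, n_rep); a2 <- matrix(0L, n, n_rep)
  founders <- which(is.na(ped$father))
  a1[founders, ] <- stats::rbinom(length(founders) * n_rep, 1L, q)
  a2[founders, ] <- stats::rbinom(length(founders) * n_rep, 1L, q)
  for (lev in seq_len(max(ped$level))) {
    idx <- which(ped$level == lev)
    if (!length(idx)) next
    f <- ped$father[idx]; m <- ped$mother[idx]
    pickf <- matrix(stats::runif(length(idx) * n_rep) < 0.5, length(idx), n_rep)
    pickm <- matrix(stats::runif(length(idx) * n_rep) < 0.5, length(idx), n_rep)
    a1[idx, ] <- ifelse(pickf, a1[f, , drop = FALSE], a2[f, , drop = FALSE])
    a2[idx, ] <- ifelse(pickm, a1[m, , drop = FALSE], a2[m, , drop = FALSE])
  }
  copies <- a1 + a2
  rownames(copies) <- ped$id
  copies
}

#' Simulate traits under a rare-variant-plus-polygenic model
#'
#' The trait is the sum of a mean-centered variant term
#' `a * (copies - 2q)` (sign flipped for a lowering allele), a residual
#' polygenic value with variance `h2 - v`, and environment with variance
#' `1 - h2`, so total variance is 1 in expectation. With no rare variant the
#' model reduces exactly to [simulate_polygenic()].
#'
#' @param ped a [pedigree()].
#' @param model a [trait_model()].
#' @param n_rep number of replicates.
#' @param seed integer seed; overrides `model$seed` when given.
#' @param K optional precomputed kinship matrix.
#' @return A `simulated_trait`; `carriers` holds the copy-count matrix for
#'   study subjects when the model has a rare variant.
#' @export
simulate_trait <- function(ped, model, n_rep = 1, seed = NULL, K = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(model, "trait_model"))
  if (is.null(seed)) seed <- model$seed
  if (!is.null(seed)) set.seed(seed)
  rv <- model$rare_variant
  if (is.null(rv))
    return(simulate_polygenic(ped, model$h2, n_rep, seed = NULL, K = K))
  q <- rv$q; v <- rv$v
  a <- sqrt(v / (2 * q * (1 - q)))
  sgn <- if (rv$direction == "raise") 1 else -1
  copies <- drop_rare_variant(ped, q, n_rep, seed = NULL)
  selfk <- .self_kinship(ped, K)
  A <- .sim_additive_matrix(ped, model$h2 - v, n_rep, selfk)
  E <- matrix(stats::rnorm(nrow(ped) * n_rep, 0, sqrt(1 - model$h2)),
              nrow(ped), n_rep)
  vals <- sgn * a * (copies - 2 * q) + A + E
  keep <- ped$study
  vals <- vals[keep, , drop = FALSE]
  rownames(vals) <- ped$id[keep]
  structure(list(values = vals,
                 carriers = copies[keep, , drop = FALSE],
                 h2 = model$h2, rare_variant = rv, seed = seed),
            class = "simulated_trait")
}

#' @export
print.simulated_trait <- function(x, ...) {
  cat(sprintf("simulated_trait: %d subjects x %d replicates, h2 = %g%s\n",
              nrow(x$values), ncol(x$values), x$h2,
              if (is.null(x$carriers)) " (purely polygenic)"
              else sprintf(", rare variant q = %g, v = %g",
                           x$rare_variant$q, x$rare_variant$v)))
  invisible(x)
}

#' Generate four-person nuclear families
#'
#' `n_families` disjoint families of two founder parents and two full-sib
#' offspring, all flagged as study subjects, with deterministic identifiers
#' (`famNNNN`, members `1`-`4`).
#'
#' @param n_families number of families, at least 1.
#' @return A [pedigree()] with `4 * n_families` members.
#' @export
make_nuclear_families <- function(n_families) {
  stopifnot(n_families >= 1)
  fid <- rep(sprintf("fam%04d", seq_len(n_families)), each = 4)
  iid <- rep(c("1", "2", "3", "4"), n_families)
  pedigree(fid = fid, iid = iid,
           father_id = rep(c("0", "0", "1", "1"), n_families),
           mother_id = rep(c("0", "0", "2", "2"), n_families),
           sex = rep(c("male", "female", "male", "female"), n_families))
}

#' Generate sibling-pair families
#'
#' `n_families` disjoint families each contributing one full-sib pair of
#' study subjects; the two parents are present as connecting relatives
#' (needed for the kinship and simulation recursions) but are not study
#' subjects.
#'
#' @param n_families number of families, at least 1.
#' @return A [pedigree()] with `2 * n_families` study subjects.
#' @export
make_sibpair_families <- function(n_families) {
  stopifnot(n_families >= 1)
  fid <- rep(sprintf("fam%04d", seq_len(n_families)), each = 4)
  iid <- rep(c("1", "2", "3", "4"), n_families)
  pedigree(fid = fid, iid = iid,
           father_id = rep(c("0", "0", "1", "1"), n_families),
           mother_id = rep(c("0", "0", "2", "2"), n_families),
           sex = rep(c("male", "female", "male", "female"), n_families),
           study = rep(c(FALSE, FALSE, TRUE, TRUE), n_families))
}

#' Write simulated phenotypes / carrier status to TSV
#'
#' `write_phenotypes` writes one row per study subject with an `id` column
#' and one column per replicate (`trait1`, `trait2`, ...); `write_carriers`
#' writes two columns, `id` and `copies` (first replicate).
#'
#' @param sim a `simulated_trait`.
#' @param path output path.
#' @param trait_names optional column names for the replicates.
#' @export
write_phenotypes <- function(sim, path, trait_names = NULL) {
  stopifnot(inherits(sim, "simulated_trait"))
  vals <- sim$values
  if (is.null(trait_names))
    trait_names <- sprintf("trait%d", seq_len(ncol(vals)))
  out <- data.frame(id = rownames(vals), vals, check.names = FALSE)
  names(out) <- c("id", trait_names)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
write_carriers <- function(sim, path) {
  stopifnot(inherits(sim, "simulated_trait"))
  if (is.null(sim$carriers)) stop("simulation has no rare variant, no carriers")
  out <- data.frame(id = rownames(sim$carriers),
                    copies = sim$carriers[, 1])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
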