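# End-to-end screen: phenotype preparation, per-trait empirical nulls,
# tail-kinship tests over sides and tail sizes, minimum-p selection, and the
# effective-tests correction. This is the workflow the command-line wrapper
# in inst/cli drives.

#' Screen quantitative traits for rare-variant signatures
#'
#' For each trait: (optionally) inverse-normal transform, residualize on
#' covariates, then compare the mean pairwise kinship among the most extreme
#' individuals — for both sides of the distribution and a grid of tail
#' sizes — against an empirical null of purely polygenic traits simulated on
#' the pedigree at the trait's narrow-sense heritability. The smallest
#' empirical p-value per trait (p_min) is Bonferroni-corrected by the
#' effective number of tests among the (correlated) traits.
#'
#' Within a trait, no correction is applied across the tail sizes and sides
#' searched; the final report states this caveat.
#'
#' @param ped a [pedigree()].
#' @param phenotypes data frame with an `id` column (matching `"fid:iid"`
#'   keys, or bare individual ids when unique) plus trait and covariate
#'   columns, as read by [read_phenotypes()].
#' @param traits character vector of trait column names; default all columns
#'   other than `id`, covariates, and strata.
#' @param covariates character vector of covariate column names (residualized
#'   out per trait), or `NULL`.
#' @param strata optional name of a column defining strata; the screen is
#'   then run independently within each stratum (sharing the pedigree) and a
#'   named list of screens is returned.
#' @param tail_fractions tail-size grid, default 1, 2, 4, 6, 8%.
#' @param N_null polygenic replicates per null distribution (default
#'   10,000).
#' @param alpha significance level (default 0.05).
#' @param seed master seed for the null simulations.
#' @param h2 per-trait heritability overrides: a single number, or a named
#'   vector keyed by trait; traits without an override get a maximum
#'   likelihood estimate from the data ([estimate_h2()]).
#' @param transform `"auto"` (transform when a Shapiro-Wilk check at 0.01
#'   rejects normality), `"always"`, or `"never"`.
#' @param min_overlap floor on pairwise-complete observations for the
#'   effective-tests correlation matrix.
#' @param chunk simulation block size.
#' @return An object of class `rvkt_screen`: list with `results` (one row
#'   per trait x side x tail), `summary` (per trait: p_min side/tail,
#'   p_min, p_min_corrected, significance flag, h2 used), `m_eff`,
#'   `tail_members` (per trait, the ids at the minimum-p tail — the
#'   sequencing candidate list), `prep` (per-trait preparation log), and
#'   `config`. With `strata`, a named list of such objects.
#' @export
rvkt_screen <- function(ped, phenotypes, traits = NULL, covariates = NULL,
                        strata = NULL,
                        tail_fractions = c(.01, .02, .04, .06, .08),
                        N_null = 10000, alpha = 0.05, seed = NULL,
                        h2 = NULL, transform = c("auto", "always", "never"),
                        min_overlap = 30, chunk = 2000) {
  transform <- match.arg(transform)
  stopifnot(inherits(ped, "pedigree"))
  phenotypes <- as.data.frame(phenotypes)
  if (!nrow(phenotypes))
    .rvkt_error("rvkt_empty_phenotypes_error", "phenotype table has no rows")
  if (!"id" %in% names(phenotypes))
    stop("phenotype table needs an 'id' column")
  if (!is.null(strata)) {
    if (!strata %in% names(phenotypes)) stop("no such strata column: ", strata)
    levels <- unique(stats::na.omit(phenotypes[[strata]]))
    if (is.null(traits))
      traits <- setdiff(names(phenotypes), c("id", covariates, strata))
    out <- lapply(levels, function(s) {
      rvkt_screen(ped, phenotypes[phenotypes[[strata]] %in% s, , drop = FALSE],
                  traits = traits, covariates = covariates, strata = NULL,
                  tail_fractions = tail_fractions, N_null = N_null,
                  alpha = alpha, seed = seed, h2 = h2, transform = transform,
                  min_overlap = min_overlap, chunk = chunk)
    })
    names(out) <- as.character(levels)
    return(out)
  }

  if (is.null(traits))
    traits <- setdiff(names(phenotypes), c("id", covariates, strata))
  if (!length(traits)) stop("no trait columns to test")

  K <- compute_kinship(ped)
  subj <- ped$id[ped$study]
  pid <- as.character(phenotypes$id)
  if (!all(pid %in% subj)) {
    if (!anyDuplicated(ped$iid) && all(pid %in% ped$iid)) {
      pid <- ped$id[match(pid, ped$iid)]
    } else {
      stop("phenotype ids not resolvable against study subjects: ",
           paste(utils::head(setdiff(pid, subj), 5), collapse = ", "))
    }
  }
  rows <- match(subj, pid)              # phenotype row per study subject

  # prepare each trait: transform (when called for), then adjust
  prep <- data.frame(trait = traits, transformed = NA, n_used = NA_integer_,
                     h2 = NA_real_, h2_source = NA_character_,
                     stringsAsFactors = FALSE)
  P <- matrix(NA_real_, length(subj), length(traits),
              dimnames = list(subj, traits))
  for (j in seq_along(traits)) {
    x <- stats::setNames(as.numeric(phenotypes[[traits[j]]])[rows], subj)
    do_tr <- switch(transform, always = TRUE, never = FALSE,
                    auto = needs_transform(x))
    if (do_tr) x <- inverse_normal_transform(x)
    if (!is.null(covariates)) {
      cov <- phenotypes[rows, covariates, drop = FALSE]
      x <- stats::setNames(adjust_covariates(x, cov), subj)
    }
    P[, j] <- x
    prep$transformed[j] <- do_tr
    prep$n_used[j] <- sum(!is.na(x))
  }

  # heritability per trait: override or ML estimate
  h2_of <- function(trait) {
    if (!is.null(h2)) {
      if (length(h2) == 1 && is.null(names(h2))) return(c(h2, "override"))
      if (trait %in% names(h2)) return(c(h2[[trait]], "override"))
    }
    est <- estimate_h2(stats::setNames(P[, trait], subj)[!is.na(P[, trait])], K)
    c(est$h2_hat, "estimated")
  }

  if (!is.null(seed)) set.seed(seed)
  null_cache <- new.env(parent = emptyenv())
  results <- list()
  tail_members <- list()
  for (j in seq_along(traits)) {
    tr <- traits[j]
    x <- stats::setNames(P[, j], subj)
    hh <- h2_of(tr)
    h2j <- round(as.numeric(hh[1]), 3)
    prep$h2[j] <- h2j; prep$h2_source[j] <- hh[2]
    use <- names(x)[!is.na(x)]
    key <- paste(sprintf("%.3f", h2j), paste(sort(use), collapse = ","), sep = "|")
    if (is.null(null_cache[[key]]))
      null_cache[[key]] <- build_null(ped, K, h2j, tail_fractions,
                                      sides = c("lower", "upper"),
                                      N_null = N_null, seed = NULL,
                                      chunk = chunk, subjects = use)
    null <- null_cache[[key]]
    for (side in c("lower", "upper")) {
      for (f in tail_fractions) {
        sel <- select_tail(x, side, f)
        obs <- mean_pairwise_kinship(K, sel)
        nv <- .null_values(null, side, f)
        results[[length(results) + 1L]] <- data.frame(
          trait = tr, side = side, fraction = f, n_tail = length(sel),
          observed_stat = obs, expected_stat = mean(nv),
          null_ci_low = unname(stats::quantile(nv, 0.025)),
          null_ci_high = unname(stats::quantile(nv, 0.975)),
          p_value = empirical_pvalue(obs, nv),
          stringsAsFactors = FALSE)
        tail_members[[paste(tr, side, f, sep = "_")]] <- sel
      }
    }
  }
  results <- do.call(rbind, results)
  results$p_label <- format_pvalue(results$p_value, N_null)

  # per-trait minimum p over sides and tails
  summary <- do.call(rbind, lapply(traits, function(tr) {
    sub <- results[results$trait == tr, , drop = FALSE]
    best <- min_p_over_tails(sub[order(match(sub$side, c("lower", "upper"))), ])
    best[, c("trait", "side", "fraction", "n_tail", "observed_stat",
             "expected_stat", "null_ci_low", "null_ci_high", "p_value")]
  }))
  names(summary)[names(summary) == "p_value"] <- "p_min"

  m_eff <- if (length(traits) >= 2)
    effective_tests(P, min_overlap = min_overlap)
  else structure(list(m = 1L, m_eff_raw = 1, m_eff = 1L,
                      excluded = character(0), eigenvalues = 1),
                 class = "m_eff")
  corr <- correct_pmin(stats::setNames(summary$p_min, summary$trait),
                       m_eff, alpha)
  summary$p_min_corrected <- corr$table$p_min_corrected
  summary$significant <- corr$table$significant
  summary$h2 <- prep$h2
  rownames(summary) <- NULL

  best_members <- stats::setNames(lapply(seq_along(traits), function(j) {
    s <- summary[j, ]
    tail_members[[paste(s$trait, s$side, s$fraction, sep = "_")]]
  }), traits)

  structure(list(results = results, summary = summary, m_eff = m_eff,
                 tail_members = best_members, prep = prep,
                 config = list(tail_fractions = tail_fractions,
                               N_null = N_null, alpha = alpha, seed = seed,
                               covariates = covariates,
                               transform = transform, h2 = h2)),
            class = "rvkt_screen")
}

#' @export
print.rvkt_screen <- function(x, ...) {
  cat(sprintf("rvkt_screen: %d traits, %d null replicates per trait, alpha = %g\n",
              nrow(x$summary), x$config$N_null, x$config$alpha))
  cat(sprintf("effective tests: %d (of %d traits)\n", x$m_eff$m_eff, x$m_eff$m))
  cat("note: p_min is not corrected for the tail sizes and sides searched within a trait\n")
  print(x$summary[order(x$summary$p_min_corrected),
                  c("trait", "side", "fraction", "n_tail", "observed_stat",
                    "expected_stat", "p_min", "p_min_corrected", "significant")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

# djb2-style rolling hash (mod 2^31 - 1, exact in doubles), for config
# fingerprints in output headers.
.confhash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

.header_lines <- function(config) {
  ver <- tryCatch(as.character(utils::packageVersion("rvkt")), error = function(e) "dev")
  cfg <- jsonlite::toJSON(config, auto_unbox = TRUE, null = "null")
  c(sprintf("# rvkt %s", ver),
    sprintf("# config_hash %s", .confhash(as.character(cfg))),
    sprintf("# seed %s", if (is.null(config$seed)) "none" else config$seed))
}

#' Write a screen report to disk
#'
#' Writes `results.tsv` (full trait x side x tail grid), `summary.tsv`
#' (per-trait minimum-p rows with corrected p-values), `tail_members.json`
#' (the per-trait sequencing candidate lists), and `config.json`. Every file
#' carries the package version, a hash of the resolved configuration, and
#' the master seed in header comments.
#'
#' @param screen an `rvkt_screen`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_screen_report <- function(screen, dir) {
  stopifnot(inherits(screen, "rvkt_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .header_lines(screen$config)
  for (piece in c("results", "summary")) {
    path <- file.path(dir, paste0(piece, ".tsv"))
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(screen[[piece]], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, append = TRUE))
  }
  jsonlite::write_json(
    list(header = hdr, tail_members = screen$tail_members),
    file.path(dir, "tail_members.json"), auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(
    list(header = hdr, config = screen$config, m_eff = screen$m_eff$m_eff,
         m_eff_raw = screen$m_eff$m_eff_raw),
    file.path(dir, "config.json"), auto_unbox = TRUE, pretty = TRUE,
    null = "null")
  invisible(dir)
}

#' Generate a demonstration cohort
#'
#' A sibling-pair cohort with several independent polygenic traits and one
#' trait carrying an embedded rare variant, useful for exercising the whole
#' screen end to end on synthetic data.
#'
#' @param n_families number of sibling-pair families.
#' @param n_traits total traits; the last one carries the variant.
#' @param q,v,h2 variant frequency, variance fraction, and heritability.
#' @param seed integer seed.
#' @return List with `ped` (a [pedigree()]), `phenotypes` (data frame with
#'   `id` and trait columns), `variant_trait` (its column name), and
#'   `carriers`.
#' @export
simulate_demo_cohort <- function(n_families = 400, n_traits = 5,
                                 q = 0.03, v = 0.35, h2 = 0.4, seed = 1) {
  ped <- make_sibpair_families(n_families)
  set.seed(seed)
  base <- simulate_polygenic(ped, h2, n_rep = n_traits - 1, seed = NULL)
  rv <- simulate_trait(ped, trait_model(h2, rare_variant_spec(q, v = v)),
                       n_rep = 1, seed = NULL)
  vals <- cbind(base$values, rv$values)
  nm <- c(sprintf("trait%d", seq_len(n_traits - 1)), "trait_rv")
  colnames(vals) <- nm
  list(ped = ped,
       phenotypes = data.frame(id = rownames(vals), vals,
                               check.names = FALSE, row.names = NULL),
       variant_trait = "trait_rv",
       carriers = rv$carriers)
}
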