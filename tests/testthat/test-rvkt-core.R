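# Tail resolution, the statistic, empirical nulls, p-values, thresholds.

test_that("tail counts follow round-half-up on the non-missing sample", {
  expect_equal(sapply(c(.01, .02, .04, .06, .08), tail_count,
                      n_subjects = 1481),
               c(15L, 30L, 59L, 89L, 118L))
  expect_equal(tail_count(100, 0.04), 4L)
  expect_equal(tail_count(1482, 0.01), 15L)
  expect_error(tail_count(100, 0.6), "fraction")
  expect_error(tail_count(20, 0.05), class = "rvkt_tail_too_small_error")
})

test_that("select_tail picks extremes, resolves counts on non-missing values", {
  x <- stats::setNames(as.numeric(1:100), sprintf("id%03d", 1:100))
  expect_equal(select_tail(x, "lower", 0.04), c("id001", "id002", "id003", "id004"))
  expect_equal(select_tail(x, "upper", 0.04), c("id100", "id099", "id098", "id097"))
  x[1:5] <- NA                           # 95 non-missing, 8% -> 8
  expect_length(select_tail(x, "upper", 0.08), 8)
  y <- stats::setNames(rep(1, 50), sprintf("id%02d", 1:50))
  expect_warning(sel <- select_tail(y, "lower", 0.1), "degenerate")
  expect_equal(sel, sprintf("id%02d", 1:5))  # deterministic id order
  z <- stats::setNames(c(0, 1, 1, 2, 3), letters[1:5])
  expect_warning(select_tail(z, "lower", 0.4), "tie at the tail boundary")
})

test_that("the statistic is the tail's mean pairwise kinship, rank-invariant", {
  ped <- make_nuclear_families(30)
  K <- compute_kinship(ped)
  # trait putting one whole family in the upper 4-member tail of 120
  x <- stats::setNames(stats::rnorm(120), ped$id)
  fam <- ped$id[ped$fid == "fam0007"]
  x[fam] <- max(x) + 1:4
  s <- rvkt_statistic(x, "upper", 4 / 120, K)
  expect_equal(s, 1.25 / 6)
  # mutually unrelated tail
  x2 <- stats::setNames(stats::rnorm(120), ped$id)
  founders <- ped$id[is.na(ped$father)]
  x2[] <- seq(-2, -1, length.out = 120); x2[founders[1:4]] <- 1:4
  expect_equal(rvkt_statistic(x2, "upper", 4 / 120, K), 0)
  # invariance under strictly increasing transform
  x3 <- stats::setNames(stats::rnorm(120), ped$id)
  expect_equal(rvkt_statistic(x3, "lower", 0.05, K),
               rvkt_statistic(exp(x3), "lower", 0.05, K))
})

test_that("empirical p-values are raw exceedance proportions", {
  null <- c(rep(0, 9996), rep(0.3, 4))
  expect_equal(empirical_pvalue(0.3, null), 4e-4)
  expect_equal(empirical_pvalue(0.4, null), 0)
  expect_equal(format_pvalue(0, 10000), "<0.0001")
  expect_equal(empirical_pvalue(0, null), 1)
  expect_equal(empirical_pvalue(0.1, null), 4e-4)
})

test_that("rejection thresholds have size at most alpha, else report infeasibility", {
  null1 <- c(rep(0, 950), rep(0.1, 30), rep(0.2, 20))
  r1 <- rejection_threshold(null1, 0.05)
  expect_true(r1$feasible)
  expect_equal(r1$threshold, 0.1)
  expect_equal(r1$size, 0.05)
  null2 <- c(rep(0, 983), rep(0.2, 17))
  r2 <- rejection_threshold(null2, 0.01)
  expect_false(r2$feasible)
  expect_equal(r2$min_size, 0.017)
  # near-1 alpha: the minimum value always has exceedance 1, so the
  # smallest admissible region starts at the next distinct value
  r3 <- rejection_threshold(null1, 0.9999)
  expect_equal(r3$threshold, 0.1)
  expect_equal(r3$size, 0.05)
})

test_that("null support diagnostics count distinct values in the top band", {
  cont <- stats::rnorm(1000)
  expect_equal(null_support_summary(cont, 0.2), 200L)
  expect_equal(null_support_summary(rep(0.5, 400), 0.25), 1L)
  latt <- c(rep(0, 800), rep(1 / 105, 150), rep(2 / 105, 45), rep(5 / 105, 5))
  expect_equal(null_support_summary(latt, 0.2), 3L)
})

test_that("minimum-p selection breaks ties toward the smaller tail", {
  res <- data.frame(side = "lower", fraction = c(.01, .02, .04),
                    p_value = c(0.2, 0.05, 0.3))
  expect_equal(min_p_over_tails(res)$fraction, 0.02)
  res$p_value <- 0.1
  expect_equal(min_p_over_tails(res)$fraction, 0.01)
  expect_equal(min_p_over_tails(res[2, ])$fraction, 0.02)
})

test_that("sib-pair nulls live on the kinship lattice and are reproducible", {
  ped <- make_sibpair_families(200)     # 400 subjects, 1% tail = 4
  K <- compute_kinship(ped)
  n1 <- build_null(ped, K, h2 = 0.4, tail_fractions = c(0.01, 0.05),
                   sides = "upper", N_null = 500, seed = 31)
  k4 <- choose(4, 2)
  lattice <- 0.25 * (0:k4) / k4
  expect_true(all(n1$stats[, "upper_0.01"] %in% lattice))
  n2 <- build_null(ped, K, h2 = 0.4, tail_fractions = c(0.01, 0.05),
                   sides = "upper", N_null = 500, seed = 31)
  expect_identical(n1$stats, n2$stats)
  # enlarging the observed statistic never increases its p-value
  obs <- sort(stats::runif(20, 0, 0.3))
  ps <- sapply(obs, empirical_pvalue, null = n1, side = "upper",
               fraction = 0.01)
  expect_true(all(diff(ps) <= 0))
})

test_that("batched null statistics equal the direct per-replicate statistic", {
  ped <- make_nuclear_families(40)
  K <- compute_kinship(ped)
  null <- build_null(ped, K, h2 = 0.4, tail_fractions = c(0.02, 0.08),
                     sides = c("lower", "upper"), N_null = 100, seed = 8)
  # recompute one replicate's trait by rerunning the stream
  set.seed(8)
  selfk <- rvkt:::.self_kinship(ped, K)
  A <- rvkt:::.sim_additive_matrix(ped, 0.4, 100, selfk)
  E <- matrix(stats::rnorm(nrow(ped) * 100, 0, sqrt(0.6)), nrow(ped), 100)
  V <- A + E
  for (r in c(1, 57)) {
    x <- stats::setNames(V[, r], ped$id)
    expect_equal(unname(null$stats[r, "upper_0.08"]),
                 rvkt_statistic(x, "upper", 0.08, K))
    expect_equal(unname(null$stats[r, "lower_0.02"]),
                 rvkt_statistic(x, "lower", 0.02, K))
  }
})

test_that("the test holds its size and p-values are conservative on fresh nulls", {
  ped <- make_nuclear_families(100)
  K <- compute_kinship(ped)
  null <- build_null(ped, K, h2 = 0.4, tail_fractions = 0.04,
                     sides = "upper", N_null = 2000, seed = 71)
  thr <- rejection_threshold(null, 0.05, "upper", 0.04)
  fresh <- build_null(ped, K, h2 = 0.4, tail_fractions = 0.04,
                      sides = "upper", N_null = 1000, seed = 72)
  rate <- mean(fresh$stats[, 1] >= thr$threshold - 1e-12)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
  # p-values on fresh null replicates are stochastically >= uniform
  ps <- sapply(fresh$stats[, 1], empirical_pvalue, null = null,
               side = "upper", fraction = 0.04)
  for (a in c(0.01, 0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / 1000))
  }
})
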