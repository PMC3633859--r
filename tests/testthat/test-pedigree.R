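# Pedigree parsing, validation, and exact kinship.

test_that("read_ped parses a simple family and ignores the phenotype column", {
  path <- write_tmp_ped(c(
    "f1 dad 0 0 1 -9",
    "f1 mom 0 0 2 2.7",
    "f1 kid1 dad mom 1 0",
    "f1 kid2 dad mom 2 0"))
  ped <- read_ped(path)
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 4)
  expect_equal(sum(is.na(ped$father)), 2)   # two founders
  expect_equal(sum(!is.na(ped$father)), 2)  # two non-founders
  expect_setequal(ped$sex[ped$iid %in% c("dad", "mom")], c("male", "female"))
})

test_that("read_ped handles the tab dialect", {
  path <- write_tmp_ped(c(
    "f1\tdad\t0\t0\t1\t0",
    "f1\tmom\t0\t0\t2\t0",
    "f1\tkid\tdad\tmom\t1\t0"))
  ped <- read_ped(path, dialect = "tab")
  expect_equal(nrow(ped), 3)
})

test_that("validation rejects malformed pedigrees with named errors", {
  # single parent
  expect_error(
    read_ped(write_tmp_ped(c("f1 a 0 0 1 0", "f1 k a 0 1 0"))),
    class = "rvkt_single_parent_error")
  # absent parent
  expect_error(
    read_ped(write_tmp_ped(c("f1 a 0 0 1 0", "f1 k a ghost 1 0"))),
    class = "rvkt_missing_parent_error")
  # duplicate id within family
  expect_error(
    read_ped(write_tmp_ped(c("f1 a 0 0 1 0", "f1 a 0 0 2 0"))),
    class = "rvkt_duplicate_id_error")
  # child listed as its own grandparent
  expect_error(
    read_ped(write_tmp_ped(c(
      "f1 gran kid spouse2 2 0",
      "f1 spouse2 0 0 1 0",
      "f1 par gran spouse 1 0",
      "f1 spouse 0 0 2 0",
      "f1 spouse3 0 0 2 0",
      "f1 kid par spouse3 1 0"))),
    class = "rvkt_cycle_error")
  # cross-family parent reference is not resolvable
  expect_error(
    read_ped(write_tmp_ped(c("f1 a 0 0 1 0", "f2 b 0 0 2 0",
                             "f2 k a b 1 0"))),
    class = "rvkt_missing_parent_error")
  # too few columns
  expect_error(read_ped(write_tmp_ped("f1 a 0 0 1")), "6 columns")
})

test_that("kinship recursion reproduces textbook coefficients", {
  ped <- ped_three_gen()
  K <- compute_kinship(ped)
  expect_equal(K["f1:p1", "f1:c1"], 0.25)      # parent-offspring
  expect_equal(K["f1:c1", "f1:c2"], 0.25)      # full sibs
  expect_equal(K["f1:gp1", "f1:c1"], 0.125)    # grandparent-grandchild
  expect_equal(K["f1:p3", "f1:c1"], 0.125)     # avuncular
  expect_equal(K["f1:gp1", "f1:gp2"], 0)       # founders unrelated
  expect_equal(unname(diag(K)), rep(0.5, 7))   # all outbred

  Kc <- compute_kinship(ped_cousins())
  expect_equal(Kc["f1:k1", "f1:k2"], 0.0625)   # first cousins

  Kh <- compute_kinship(ped_halfsib_child())
  expect_equal(Kh["f1:h1", "f1:h2"], 0.125)    # half sibs
  expect_equal(Kh["f1:x", "f1:x"], 0.5625)     # inbred self-kinship (1+F)/2
})

test_that("members of disconnected families have zero kinship", {
  ped <- make_nuclear_families(2)
  K <- compute_kinship(ped)
  ids1 <- ped$id[ped$fid == "fam0001"]
  ids2 <- ped$id[ped$fid == "fam0002"]
  expect_true(all(K[ids1, ids2] == 0))
})

test_that("kinship agrees with the gene-drop IBD oracle on small pedigrees", {
  for (ped in list(ped_three_gen(), ped_cousins(), ped_halfsib_child())) {
    K <- compute_kinship(ped)
    n_drops <- 1e5
    Khat <- gene_drop_kinship(ped, n_drops = n_drops, seed = 7)
    # binomial MC standard error per entry, floored for phi = 0 entries
    se <- pmax(sqrt(pmax(K * (1 - K), 0) / n_drops), 1 / n_drops)
    expect_true(all(abs(K - Khat) <= 3 * se + 1e-12))
  }
})

test_that("kinship is invariant to input row order and to added families", {
  rows <- c(
    "f1 gp1 0 0 1 0", "f1 gp2 0 0 2 0", "f1 p1 gp1 gp2 1 0",
    "f1 p2 0 0 2 0", "f1 c1 p1 p2 1 0", "f1 c2 p1 p2 2 0")
  K1 <- compute_kinship(read_ped(write_tmp_ped(rows)))
  set.seed(42)
  for (r in 1:5) {
    K2 <- compute_kinship(read_ped(write_tmp_ped(sample(rows))))
    expect_equal(K2[rownames(K1), colnames(K1)], unclass(K1)[, ])
  }
  # appending an unrelated family changes no existing entry
  K3 <- compute_kinship(read_ped(write_tmp_ped(c(
    rows, "f2 a 0 0 1 0", "f2 b 0 0 2 0", "f2 k a b 1 0"))))
  expect_equal(K3[rownames(K1), colnames(K1)], unclass(K1)[, ])
})

test_that("compute_kinship refuses non-pedigree input", {
  expect_error(compute_kinship(data.frame(iid = "a")), "validated pedigree")
})

test_that("mean pairwise kinship averages over unordered pairs only", {
  ped <- make_nuclear_families(8)
  K <- compute_kinship(ped)
  # one full nuclear family: 5 pairs at 0.25, the spouse pair at 0
  fam <- ped$id[ped$fid == "fam0001"]
  expect_equal(mean_pairwise_kinship(K, fam), 1.25 / 6)
  # 15 pairwise-unrelated individuals: founders from distinct marriages
  founders <- ped$id[is.na(ped$father)][1:15]
  expect_equal(mean_pairwise_kinship(K, founders), 0)
  expect_error(mean_pairwise_kinship(K, fam[1]), "fewer than 2")
  expect_error(mean_pairwise_kinship(K, c(fam[1], "nope")), "not present")
})

test_that("a lone sib pair among unrelated subjects gives 0.25 / C(15,2)", {
  ped <- make_sibpair_families(14)
  K <- compute_kinship(ped)
  sibs <- ped$id[ped$study]
  # both sibs of family 1 plus one sib from each of the other 13 families
  subset <- c(sibs[1:2], sibs[seq(3, 27, by = 2)])
  expect_equal(length(subset), 15)
  expect_equal(mean_pairwise_kinship(K, subset), 0.25 / choose(15, 2))
})

test_that("classify_pairs counts nuclear-family relationships exactly", {
  ped <- make_nuclear_families(371)
  K <- compute_kinship(ped)
  tab <- classify_pairs(ped, K)
  counts <- stats::setNames(tab$n_pairs, tab$relationship)
  expect_equal(unname(counts["parent-offspring"]), 4 * 371)
  expect_equal(unname(counts["siblings"]), 371)
  expect_equal(sum(counts), 5 * 371)  # nothing else
})

test_that("classify_pairs distinguishes lineal and collateral categories", {
  ped <- ped_three_gen()
  K <- compute_kinship(ped)
  tab <- classify_pairs(ped, K)
  counts <- stats::setNames(tab$n_pairs, tab$relationship)
  # by hand: PO = gp1/gp2-p1, gp1/gp2-p3, p1-c1, p1-c2, p2-c1, p2-c2 -> 8
  expect_equal(unname(counts["parent-offspring"]), 8)
  expect_equal(unname(counts["siblings"]), 2)            # p1-p3, c1-c2
  expect_equal(unname(counts["grandparent-grandchild"]), 4)
  expect_equal(unname(counts["avuncular"]), 2)           # p3-c1, p3-c2
  expect_equal(unname(counts["other"]), 0)

  sibped <- make_sibpair_families(5)
  tab2 <- classify_pairs(sibped, compute_kinship(sibped))
  expect_equal(tab2$n_pairs[tab2$relationship == "siblings"], 5)
  expect_equal(sum(tab2$n_pairs), 5)  # parents are not study subjects
})

test_that("PED round trip preserves structure and kinship", {
  ped <- make_nuclear_families(3)
  path <- withr::local_tempfile(fileext = ".ped")
  write_ped(ped, path)
  ped2 <- read_ped(path)
  expect_equal(compute_kinship(ped2)[ped$id, ped$id],
               unclass(compute_kinship(ped))[, ])
})

test_that("kinship matrix writers emit readable tables", {
  ped <- make_nuclear_families(2)
  K <- compute_kinship(ped)
  long <- withr::local_tempfile(fileext = ".tsv")
  write_kinship(K, long, "long")
  tab <- read.delim(long)
  expect_named(tab, c("id1", "id2", "phi"))
  expect_true(all(tab$phi > 0))
  sq <- withr::local_tempfile(fileext = ".tsv")
  write_kinship(K, sq, "matrix")
  m <- read.delim(sq, check.names = FALSE)
  expect_equal(unname(as.matrix(m[, -1])), unname(unclass(K)[, ]))
})
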