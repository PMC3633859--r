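# Shared fixtures and independent oracles used across the suite.

# Monte-Carlo gene-drop oracle for kinship: founders get uniquely labelled
# alleles, labels are dropped through the pedigree, and the kinship between
# i and j is estimated as the probability that a random allele of i matches
# a random allele of j (averaged over the four allele pairings). Independent
# of the recursive tabular method under test.
gene_drop_kinship <- function(ped, n_drops = 1e5, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  a1 <- matrix(0L, n, n_drops); a2 <- matrix(0L, n, n_drops)
  founders <- which(is.na(ped$father))
  for (i in seq_along(founders)) {
    a1[founders[i], ] <- 2L * i - 1L
    a2[founders[i], ] <- 2L * i
  }
  for (lev in seq_len(max(ped$level))) {
    for (i in which(ped$level == lev)) {
      f <- ped$father[i]; m <- ped$mother[i]
      pf <- stats::runif(n_drops) < 0.5
      pm <- stats::runif(n_drops) < 0.5
      a1[i, ] <- ifelse(pf, a1[f, ], a2[f, ])
      a2[i, ] <- ifelse(pm, a1[m, ], a2[m, ])
    }
  }
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    p <- (mean(a1[i, ] == a1[j, ]) + mean(a1[i, ] == a2[j, ]) +
          mean(a2[i, ] == a1[j, ]) + mean(a2[i, ] == a2[j, ])) / 4
    phi[i, j] <- p; phi[j, i] <- p
  }
  phi
}

# Three-generation family: grandparents gp1 x gp2 -> p1; p1 x p2 -> c1, c2;
# plus p2's parents absent (founder). Also an avuncular via p3 (sib of p1).
ped_three_gen <- function() {
  pedigree(
    fid = rep("f1", 7),
    iid = c("gp1", "gp2", "p1", "p3", "p2", "c1", "c2"),
    father_id = c("0", "0", "gp1", "gp1", "0", "p1", "p1"),
    mother_id = c("0", "0", "gp2", "gp2", "0", "p2", "p2"))
}

# First cousins: two sibs (s1, s2) marry unrelated spouses; one child each.
ped_cousins <- function() {
  pedigree(
    fid = rep("f1", 8),
    iid = c("g1", "g2", "s1", "s2", "m1", "m2", "k1", "k2"),
    father_id = c("0", "0", "g1", "g1", "0", "0", "s1", "s2"),
    mother_id = c("0", "0", "g2", "g2", "0", "0", "m1", "m2"))
}

# Half-sib mating: f mates m1 and m2 producing half sibs h1, h2, whose
# child x has inbreeding F = 0.125 and self-kinship (1 + 0.125)/2.
ped_halfsib_child <- function() {
  pedigree(
    fid = rep("f1", 6),
    iid = c("f", "m1", "m2", "h1", "h2", "x"),
    father_id = c("0", "0", "0", "f", "f", "h1"),
    mother_id = c("0", "0", "0", "m1", "m2", "h2"),
    sex = c("male", "female", "female", "male", "female", "unknown"))
}

write_tmp_ped <- function(lines) {
  path <- withr::local_tempfile(fileext = ".ped",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
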