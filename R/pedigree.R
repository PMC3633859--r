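# Pedigree representation, PED parsing, and exact kinship coefficients.

.rvkt_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "rvkt_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Construct a validated pedigree
#'
#' Builds a `pedigree` object from per-individual records. Individuals are
#' keyed by `(family_id, individual_id)`; parent references are resolved
#' within the same family only, so each input family must be self-contained.
#' Validation enforces the structural invariants the kinship recursion relies
#' on: an individual has either both parents present or none (founder),
#' every referenced parent exists, identifiers are unique within a family,
#' and the parent graph is acyclic.
#'
#' @param fid,iid character vectors of family and individual identifiers.
#' @param father_id,mother_id character vectors of parent identifiers;
#'   `"0"`, `NA` or `""` marks a missing parent (founder).
#' @param sex sex codes: `1`/`"male"` male, `2`/`"female"` female, anything
#'   else unknown. Stored but unused by any computation (kinship is
#'   autosomal).
#' @param study logical; `TRUE` marks phenotyped study subjects, `FALSE`
#'   marks connecting relatives carried only for their pedigree links.
#' @return A `pedigree`: a data frame with one row per individual in
#'   topological order (parents precede offspring), columns `fid`, `iid`,
#'   `id` (the `"fid:iid"` key), `father`, `mother` (integer row indices,
#'   `NA` for founders), `sex`, `study`, and `level` (generation depth used
#'   by the simulators).
#' @export
pedigree <- function(fid, iid, father_id, mother_id,
                     sex = rep("unknown", length(iid)),
                     study = rep(TRUE, length(iid))) {
  fid <- as.character(fid); iid <- as.character(iid)
  father_id <- as.character(father_id); mother_id <- as.character(mother_id)
  n <- length(iid)
  stopifnot(length(fid) == n, length(father_id) == n, length(mother_id) == n)
  miss <- function(x) is.na(x) | x == "0" | x == ""
  id <- paste(fid, iid, sep = ":")
  dup <- duplicated(id)
  if (any(dup))
    .rvkt_error("rvkt_duplicate_id_error",
                "duplicate individual id within family: %s",
                paste(unique(id[dup]), collapse = ", "))

  f_miss <- miss(father_id); m_miss <- miss(mother_id)
  half <- xor(f_miss, m_miss)
  if (any(half))
    .rvkt_error("rvkt_single_parent_error",
                "single-parent record (one parent missing) for: %s",
                paste(id[half], collapse = ", "))

  fkey <- ifelse(f_miss, NA, paste(fid, father_id, sep = ":"))
  mkey <- ifelse(m_miss, NA, paste(fid, mother_id, sep = ":"))
  father <- match(fkey, id); mother <- match(mkey, id)
  bad <- (!is.na(fkey) & is.na(father)) | (!is.na(mkey) & is.na(mother))
  if (any(bad))
    .rvkt_error("rvkt_missing_parent_error",
                "referenced parent not present in family for: %s",
                paste(id[bad], collapse = ", "))

  sex <- as.character(sex)
  sex <- ifelse(sex %in% c("1", "male", "M", "m"), "male",
         ifelse(sex %in% c("2", "female", "F", "f"), "female", "unknown"))

  ord <- .topological_order(father, mother, id)
  ped <- data.frame(fid = fid, iid = iid, id = id,
                    father = father, mother = mother,
                    sex = sex, study = as.logical(study),
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(ped) <- NULL
  remap <- match(seq_len(n), ord)
  ped$father <- remap[ped$father]
  ped$mother <- remap[ped$mother]

  lev <- integer(n)
  for (i in seq_len(n)) {
    lev[i] <- if (is.na(ped$father[i])) 0L
              else max(lev[ped$father[i]], lev[ped$mother[i]]) + 1L
  }
  ped$level <- lev
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn's algorithm; raises a cycle error if no topological order exists.
.topological_order <- function(father, mother, id) {
  n <- length(id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(father[i], mother[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n)
    .rvkt_error("rvkt_cycle_error",
                "pedigree contains a cycle involving: %s",
                paste(id[setdiff(seq_len(n), ord)], collapse = ", "))
  ord
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals (%d founders, %d study subjects) in %d families\n",
              nrow(x), sum(is.na(x$father)), sum(x$study),
              length(unique(x$fid))))
  invisible(x)
}

#' Read a PLINK-style PED/FAM file
#'
#' Expects at least six columns per row: family id, individual id, father id,
#' mother id, sex, phenotype. `"0"` denotes a missing parent. The phenotype
#' column is ignored; phenotypes are supplied separately through a phenotype
#' table. All individuals are initially flagged as study subjects.
#'
#' @param path path to the file.
#' @param dialect `"whitespace"` (any run of blanks) or `"tab"`.
#' @return A validated [pedigree()].
#' @export
read_ped <- function(path, dialect = c("whitespace", "tab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tab") "\t" else ""
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character",
                           comment.char = "#", strip.white = TRUE)
  if (ncol(tab) < 6)
    stop("PED file must have at least 6 columns (FID IID PAT MAT SEX PHENO), got ",
         ncol(tab))
  pedigree(fid = tab[[1]], iid = tab[[2]],
           father_id = tab[[3]], mother_id = tab[[4]], sex = tab[[5]])
}

#' Write a pedigree as a PED file
#'
#' Six whitespace-delimited columns (FID IID PAT MAT SEX PHENO); missing
#' parents and phenotypes are written as `"0"`, sex as 1/2/0.
#'
#' @param ped a [pedigree()].
#' @param path output path.
#' @export
write_ped <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  sexcode <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  pat <- ifelse(is.na(ped$father), "0", ped$iid[ped$father])
  mat <- ifelse(is.na(ped$mother), "0", ped$iid[ped$mother])
  utils::write.table(
    data.frame(ped$fid, ped$iid, pat, mat, sexcode, "0"),
    path, sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Compute the kinship coefficient matrix of a pedigree
#'
#' The kinship coefficient phi_ij is the probability that an allele drawn at
#' random from individual i and one drawn from individual j at an autosomal
#' locus are identical by descent through the pedigree. Computed exactly by
#' the recursive tabular method in topological order: founders get
#' phi_ii = 1/2 and zero kinship with everyone already placed; a non-founder
#' i with parents f and m gets phi_ij = (phi_fj + phi_mj)/2 for every earlier
#' j, and self-kinship phi_ii = (1 + phi_fm)/2, which exceeds 1/2 exactly
#' when i is inbred.
#'
#' @param ped a validated [pedigree()].
#' @return A symmetric numeric matrix with the `"fid:iid"` keys as dimnames,
#'   of class `kinship_matrix`.
#' @export
compute_kinship <- function(ped) {
  if (!inherits(ped, "pedigree"))
    stop("compute_kinship() requires a validated pedigree object; see pedigree()")
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    f <- ped$father[i]
    if (is.na(f)) {
      phi[i, i] <- 0.5
    } else {
      m <- ped$mother[i]
      if (i > 1L) {
        j <- seq_len(i - 1L)
        phi[i, j] <- (phi[f, j] + phi[m, j]) / 2
        phi[j, i] <- phi[i, j]
      }
      phi[i, i] <- (1 + phi[f, m]) / 2
    }
  }
  class(phi) <- c("kinship_matrix", class(phi))
  phi
}

#' Mean pairwise kinship of a subset of individuals
#'
#' The mean of phi_ij over all unordered pairs i < j in `ids` (self-kinship
#' excluded). This is the tail statistic of the rare-variant kinship screen.
#'
#' @param K a kinship matrix from [compute_kinship()].
#' @param ids character ids (rows of `K`) of the subset, at least 2.
#' @return The mean pairwise kinship, a value in `[0, 0.5]` and above only
#'   for inbred pairs.
#' @export
mean_pairwise_kinship <- function(K, ids) {
  idx <- match(ids, rownames(K))
  if (anyNA(idx)) stop("ids not present in kinship matrix: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  k <- length(idx)
  if (k < 2) stop("mean pairwise kinship undefined for fewer than 2 individuals")
  M <- K[idx, idx]
  (sum(M) - sum(diag(M))) / (k * (k - 1))
}

#' Classify related study-subject pairs by pedigree path
#'
#' Every pair of study subjects with nonzero kinship is assigned exactly one
#' relationship category by structural path tests (not kinship-value
#' thresholds, so inbreeding cannot shift a pair between categories). The
#' category is read off the generation distances to the closest common
#' ancestors: lineal pairs give parent-offspring or grandparent-grandchild;
#' pairs whose closest common ancestors are a shared parental couple give
#' siblings, avuncular, first cousins, first cousins once removed, or second
#' cousins; everything else (including half relationships and more remote
#' paths) is "other". Unrelated pairs (phi = 0) are excluded.
#'
#' @param ped a [pedigree()].
#' @param K the kinship matrix of `ped`.
#' @return A data frame of category counts, one row per category with a
#'   nonzero count plus all canonical categories, columns `relationship` and
#'   `n_pairs`.
#' @export
classify_pairs <- function(ped, K) {
  stopifnot(inherits(ped, "pedigree"))
  subj <- which(ped$study)
  cats <- c("parent-offspring", "siblings", "grandparent-grandchild",
            "avuncular", "1st cousins", "1st cousins once removed",
            "2nd cousins", "other")
  counts <- stats::setNames(integer(length(cats)), cats)

  anc <- .ancestor_depths(ped)
  Ks <- K[ped$id[subj], ped$id[subj], drop = FALSE]
  rel <- which(Ks > 0 & upper.tri(Ks), arr.ind = TRUE)
  for (r in seq_len(nrow(rel))) {
    a <- subj[rel[r, 1]]; b <- subj[rel[r, 2]]
    counts[.classify_one(a, b, anc, ped)] <-
      counts[.classify_one(a, b, anc, ped)] + 1L
  }
  data.frame(relationship = cats, n_pairs = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Per-individual map of ancestor row index -> minimal generation distance
# (the individual itself at distance 0).
.ancestor_depths <- function(ped) {
  n <- nrow(ped)
  anc <- vector("list", n)
  for (i in seq_len(n)) {
    d <- c(stats::setNames(0L, i))
    f <- ped$father[i]
    if (!is.na(f)) {
      for (p in c(f, ped$mother[i])) {
        dp <- anc[[p]] + 1L
        for (k in names(dp)) {
          if (is.na(d[k]) || is.null(d[k]) || !(k %in% names(d)) || dp[k] < d[k])
            d[k] <- dp[k]
        }
      }
    }
    anc[[i]] <- d
  }
  anc
}

.classify_one <- function(a, b, anc, ped) {
  da <- anc[[a]]; db <- anc[[b]]
  common <- intersect(names(da), names(db))
  if (!length(common)) return("other")
  tot <- da[common] + db[common]
  closest <- common[tot == min(tot)]
  d1 <- min(da[closest]); d2 <- min(db[closest])
  lo <- min(d1, d2); hi <- max(d1, d2)
  if (lo == 0L) {                       # lineal: one is the other's ancestor
    if (hi == 1L) return("parent-offspring")
    if (hi == 2L) return("grandparent-grandchild")
    return("other")
  }
  # collateral: require the closest common ancestors to be a parental couple
  if (length(closest) < 2L) return("other")
  idx <- as.integer(closest)
  couple <- any(outer(idx, idx, function(x, y) {
    mapply(function(u, v) any(ped$father == u & ped$mother == v, na.rm = TRUE) ||
                          any(ped$father == v & ped$mother == u, na.rm = TRUE),
           x, y)
  }))
  if (!couple) return("other")
  if (lo == 1L && hi == 1L) return("siblings")
  if (lo == 1L && hi == 2L) return("avuncular")
  if (lo == 2L && hi == 2L) return("1st cousins")
  if (lo == 2L && hi == 3L) return("1st cousins once removed")
  if (lo == 3L && hi == 3L) return("2nd cousins")
  "other"
}

#' Write a kinship matrix to disk
#'
#' Either long format (one row per ordered pair `i <= j` with nonzero
#' kinship, columns `id1`, `id2`, `phi`) or a full square matrix with ids as
#' the first column and header.
#'
#' @param K a kinship matrix.
#' @param path output path.
#' @param format `"long"` or `"matrix"`.
#' @export
write_kinship <- function(K, path, format = c("long", "matrix")) {
  format <- match.arg(format)
  if (format == "long") {
    keep <- which(K > 0 & upper.tri(K, diag = TRUE), arr.ind = TRUE)
    out <- data.frame(id1 = rownames(K)[keep[, 1]],
                      id2 = colnames(K)[keep[, 2]],
                      phi = K[keep])
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    out <- data.frame(id = rownames(K), as.data.frame(unclass(K)),
                      check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
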