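test_that("FASTA and Clustal readers give the same block; bad input rejected", {
  rows <- c(SP = "MK-LVDE", ES = "MKALVDE", CF = "MKALVEE",
            PP = "MKALVDE", CO = "MK-LVDQ", PC = "LKALVDQ")
  ff <- withr::local_tempfile(fileext = ".fasta")
  fc <- withr::local_tempfile(fileext = ".aln")
  write_alignment_fasta(alignment_block(rows), ff)
  write_clustal(rows, fc)
  a1 <- read_alignment(ff, "fasta")
  a2 <- read_alignment(fc, "clustal")
  expect_s3_class(a1, "alignment_block")
  expect_identical(unclass(a1), unclass(a2))
  expect_identical(names(a1), names(rows))

  writeLines(c(">s1", "MKAL", ">s2", "MKA"), ff)
  expect_error(read_alignment(ff, "fasta"), "ragged.*s2")
  expect_error(alignment_block(c(a = "MK1L", b = "MKAL")), "unknown.*1")
})

test_that("consensus calling follows the at-least-4-of-6 majority rule", {
  a <- alignment_block(c(s1 = "AKK-", s2 = "AKR-", s3 = "AKR-",
                         s4 = "AKK-", s5 = "ARK-", s6 = "AKKA"))
  cons <- build_consensus(a, threshold_count = 4)
  # col1: 6/6 A; col2: 5 K 1 R; col3: 4 K 2 R; col4: 5 '-' (gap counts)
  expect_equal(as.character(cons), "AKK-")
  expect_equal(attr(cons, "threshold_count"), 4)

  # 3/3 split never reaches a count of 4
  a33 <- alignment_block(c(s1 = "K", s2 = "K", s3 = "K",
                           s4 = "R", s5 = "R", s6 = "R"))
  expect_equal(as.character(build_consensus(a33, 4)), "X")
  # default threshold is a strict majority: floor(6/2) + 1 = 4
  expect_equal(attr(build_consensus(a), "threshold_count"), 4)
  expect_error(build_consensus(a, 7), "threshold_count")
})

test_that("similarity scoring separates identical / similar / dissimilar", {
  cons2 <- function(s) build_consensus(alignment_block(c(a = s, b = s)), 2)
  # all BLOSUM62 pairs K-R, I-L, E-Q score 2 (similar); D-D identical
  sc <- similarity_to_consensus("KIDE", cons2("RLDQ"))
  expect_equal(sc$percent, 100)
  expect_equal(sc$identical, 1)
  expect_equal(sc$similar, 3)
  # P-W = -4 and G-W = -2: all dissimilar
  expect_equal(similarity_to_consensus("PGPG", cons2("WWWW"))$percent, 0)
  # identity scores 100 with all-identical counts
  sc2 <- similarity_to_consensus("RLDQ", cons2("RLDQ"))
  expect_equal(sc2$percent, 100)
  expect_equal(sc2$identical, 4)
  expect_error(similarity_to_consensus("RLD", cons2("RLDQ")), "length")
})

test_that("gap and ambiguity columns follow the exclusion rules", {
  cons <- build_consensus(alignment_block(
    c(s1 = "A-KR", s2 = "A-KR", s3 = "A-KK", s4 = "A-RK")), 3)
  expect_equal(as.character(cons), "A-KX")
  sc <- similarity_to_consensus("AAK-", cons)
  # col1 identical; col2 residue-vs-gap dissimilar; col3 identical;
  # col4 ambiguous consensus excluded
  expect_equal(sc$identical, 2)
  expect_equal(sc$dissimilar, 1)
  expect_equal(sc$excluded, 1)
  expect_equal(sc$percent, 100 * 2 / 3)
  # gap-vs-gap excluded, so a row equal to a gapped consensus still scores 100
  sc2 <- similarity_to_consensus("A-KR", cons)
  expect_equal(sc2$percent, 100)
  expect_equal(sc2$excluded, 2)   # the gap column and the ambiguous column
  # count conservation
  expect_equal(sc$identical + sc$similar + sc$dissimilar + sc$excluded, 4)
})

test_that("similarity percent matches a per-column BLOSUM62 table lookup", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(19)
  for (rep in 1:50) {
    len <- sample(5:15, 1)
    rows <- vapply(1:4, function(i) {
      paste(sample(aa, len, replace = TRUE), collapse = "")
    }, "")
    names(rows) <- paste0("s", 1:4)
    a <- alignment_block(rows)
    cons <- build_consensus(a, threshold_count = 3)
    cs <- strsplit(unclass(cons), "")[[1]]
    for (row in rows) {
      rs <- strsplit(row, "")[[1]]
      # independent oracle: published BLOSUM62 table, explicit column walk
      cls <- mapply(function(r, c) {
        if (c == "X") "exc"
        else if (r == c) "id"
        else if (BLOSUM62[r, c] >= 1) "sim"
        else "dis"
      }, rs, cs)
      expected <- 100 * sum(cls %in% c("id", "sim")) / sum(cls != "exc")
      got <- similarity_to_consensus(row, cons)$percent
      if (all(cls == "exc")) expect_true(is.na(got))
      else expect_equal(got, expected)
    }
  }
})

test_that("raising the similar-cutoff never raises a similarity percent", {
  set.seed(23)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rows <- vapply(1:6, function(i) {
    paste(sample(aa, 40, replace = TRUE), collapse = "")
  }, "")
  names(rows) <- paste0("s", 1:6)
  a <- alignment_block(rows)
  cons <- build_consensus(a, 2)
  for (row in rows) {
    p <- vapply(0:4, function(k) {
      similarity_to_consensus(row, cons, similar_cutoff = k)$percent
    }, 0)
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("consensus construction ignores row order", {
  a <- gen_protein_family(seed = 31, length = 80)
  perm <- alignment_block(unclass(a)[sample(length(a))])
  expect_identical(as.character(build_consensus(a)),
                   as.character(build_consensus(perm)))
})

test_that("epitope coordinates map through reference gaps", {
  a <- alignment_block(c(REF = "M-KL", S2 = "MAKL", S3 = "M-RL"))
  e <- epitope_region("TM", "TM_E1", "REF", 2, 3, "KL")
  sub <- map_epitope(a, e)
  expect_equal(attr(sub, "columns"), c(3, 4))
  expect_equal(unclass(sub), c(REF = "KL", S2 = "KL", S3 = "RL"),
               ignore_attr = TRUE)

  # gapless: positions are columns
  g <- alignment_block(c(REF = "MKALV", S2 = "MKALV"))
  sub2 <- map_epitope(g, epitope_region("TM", "E", "REF", 1, 5, "MKALV"))
  expect_equal(attr(sub2, "columns"), c(1, 5))

  expect_error(map_epitope(a, epitope_region("TM", "E", "REF", 2, 3, "KK")),
               "expected 'KK' but found 'KL'")
  expect_error(map_epitope(a, epitope_region("TM", "E", "REF", 2, 4, "KLX")),
               "beyond ungapped")
  expect_error(map_epitope(a, epitope_region("TM", "E", "NOPE", 1, 2, "MK")),
               "not in alignment")
})

test_that("epitope similarity table scores each epitope sub-alignment", {
  # identical sequences: every epitope scores 100 everywhere
  rows <- setNames(rep("MKALVDEQRS", 6), paste0("s", 1:6))
  a <- alignment_block(rows)
  eps <- list(epitope_region("TM", "E1", "s1", 2, 5, "KALV"),
              epitope_region("TM", "E2", "s1", 7, 9, "EQR"))
  tab <- epitope_similarity_table(a, eps)
  expect_equal(dim(tab), c(2L, 6L))
  expect_true(all(tab == 100))

  # single-column epitope with a 3/3 split: all NA and flagged
  a33 <- alignment_block(c(s1 = "MK", s2 = "MK", s3 = "MK",
                           s4 = "MR", s5 = "MR", s6 = "MR"))
  e33 <- list(epitope_region("AK", "AK_E1", "s1", 2, 2, "K"))
  tab33 <- epitope_similarity_table(a33, e33)
  expect_true(all(is.na(tab33)))
  expect_equal(attr(tab33, "all_excluded"), "AK_E1")
})

test_that("conserved epitope blocks score above the whole protein", {
  regs <- list(c(50, 80), c(150, 200))
  wins <- 0
  for (s in 1:20) {
    a <- gen_protein_family(seed = s, epitope_regions = regs)
    eps <- lapply(seq_along(regs), function(i) {
      r <- regs[[i]]
      epitope_region("TM", paste0("E", i), "SP", r[1], r[2],
                     substr(a[["SP"]], r[1], r[2]))
    })
    etab <- epitope_similarity_table(a, eps)
    prot <- protein_similarity_scores(a)$percent
    if (mean(etab) > mean(prot)) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("whole-protein score is the count-weighted average of column blocks", {
  a <- gen_protein_family(seed = 13, length = 120)
  cons <- build_consensus(a)
  split_at <- 50
  subcons <- function(from, to) {
    structure(substr(unclass(cons), from, to),
              threshold_count = attr(cons, "threshold_count"),
              ambiguity = attr(cons, "ambiguity"),
              class = "consensus_sequence")
  }
  c1 <- subcons(1, split_at); c2 <- subcons(split_at + 1, 120)
  for (row in unclass(a)) {
    full <- similarity_to_consensus(row, cons)
    s1 <- similarity_to_consensus(substr(row, 1, split_at), c1)
    s2 <- similarity_to_consensus(substr(row, split_at + 1, 120), c2)
    expect_equal(full$identical, s1$identical + s2$identical)
    expect_equal(full$similar, s1$similar + s2$similar)
    expect_equal(full$excluded, s1$excluded + s2$excluded)
    n1 <- split_at - s1$excluded; n2 <- 120 - split_at - s2$excluded
    expect_equal(full$percent, (s1$percent * n1 + s2$percent * n2) / (n1 + n2))
  }
})

test_that("bundled BLOSUM62 matches the published reference table", {
  m <- blosum62()
  data(BLOSUM62, package = "Biostrings", envir = environment())
  common <- intersect(rownames(m), rownames(BLOSUM62))
  expect_true(all(c("A", "R", "X", "*") %in% common))
  expect_equal(unclass(m)[common, common], BLOSUM62[common, common],
               ignore_attr = TRUE)
  expect_true(isSymmetric(unname(unclass(m))))
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (r in aa20) expect_true(all(m[r, r] >= m[r, setdiff(aa20, r)]))
})
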