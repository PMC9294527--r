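test_that("percent similarity counts matches over compared sites", {
  s <- paste(rep("A", 397), collapse = "")
  r <- similarity_percent(s, s)
  expect_equal(r$percent, 100)
  expect_equal(r$compared_sites, 397)

  # 10 sites, 1 mismatch, 1 column gapped in one record: 8/9
  a <- "AAAAAAAAAA"
  b <- "AAAAC-AAAA"
  r <- similarity_percent(a, b)
  expect_equal(r$compared_sites, 9)
  expect_equal(r$percent, 100 * 8 / 9)

  # hybrid Y overlaps parental C: match under intersect, not under mismatch
  expect_equal(similarity_percent("ACYA", "ACCA")$percent, 100)
  expect_equal(similarity_percent("ACYA", "ACCA",
    site_policy(ambiguity_match = "mismatch"))$percent, 75)

  expect_error(similarity_percent("--", "AA"), "no comparable sites")
  expect_error(similarity_percent("AC", "ACG"), "equal")
})

test_that("p-distance separates transitions from transversions", {
  r <- p_distance("AAAAAAAAAA", "AAAAAAAAAA")
  expect_equal(c(r$p, r$P, r$Q), c(0, 0, 0))
  r <- p_distance("AAAAAAAAAA", "AAAAGAAAAA")
  expect_equal(c(r$P, r$Q), c(0.1, 0))
  r <- p_distance("AAAAAAAAAA", "AAAACAAAAA")
  expect_equal(c(r$P, r$Q), c(0, 0.1))
  # p = P + Q on random pairs, and similarity complements p under the
  # same (mismatch) ambiguity policy
  pol <- site_policy(ambiguity_match = "mismatch")
  for (seed in 1:10) {
    aln <- random_alignment(2L, 120L, seed)
    r <- p_distance(aln$seqs[1L], aln$seqs[2L], pol)
    expect_equal(r$p, r$P + r$Q)
    expect_equal(similarity_percent(aln$seqs[1L], aln$seqs[2L], pol)$percent,
                 100 * (1 - r$p))
  }
})

test_that("K2P and JC69 corrections evaluate their closed forms", {
  expect_equal(k2p_distance(0, 0)$d, 0)
  expect_equal(k2p_distance(0.1, 0)$d, -0.5 * log(0.8), tolerance = 1e-12)
  expect_equal(round(k2p_distance(0.1, 0)$d, 4), 0.1116)
  sat <- k2p_distance(0.3, 0.4)
  expect_true(sat$saturated)
  expect_true(is.na(sat$d))
  expect_equal(jc69_distance(0)$d, 0)
  expect_true(jc69_distance(0.76)$saturated)
})

test_that("K2P pairwise distances agree with an independent oracle", {
  aln <- random_alignment(6L, 300L, 42L)
  dm <- distance_matrix(aln, "K2P")
  bin <- ape::as.DNAbin(lapply(strsplit(tolower(aln$seqs), ""), identity))
  names(bin) <- aln$ids
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(dm$values, ref[aln$ids, aln$ids], tolerance = 1e-10)
})

test_that("TN93 reduces to K2P at equal frequencies and matches ape", {
  # balanced composition: every base equally frequent in both sequences
  a <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  b <- a
  substr(b, 1, 1) <- "G"   # A->G purine transition
  substr(b, 2, 2) <- "T"   # C->T pyrimidine transition
  tn <- tn93_distance(a, b, freqs = rep(0.25, 4))
  pq <- p_distance(a, b)
  k2 <- k2p_distance(pq$P, pq$Q)
  expect_equal(tn$d, k2$d, tolerance = 1e-9)

  for (seed in 1:6) {
    aln <- random_alignment(2L, 400L, seed + 100L)
    bin <- ape::as.DNAbin(lapply(strsplit(tolower(aln$seqs), ""), identity))
    names(bin) <- aln$ids
    ref <- as.matrix(ape::dist.dna(bin, model = "TN93",
                                   pairwise.deletion = TRUE))[1L, 2L]
    got <- tn93_distance(aln$seqs[1L], aln$seqs[2L])
    expect_equal(got$d, ref, tolerance = 1e-9)
    # the model correction never shrinks the observed distance
    expect_gte(got$d, p_distance(aln$seqs[1L], aln$seqs[2L])$p)
  }

  expect_equal(tn93_distance("ACGT", "ACGT")$d, 0)
})

test_that("distance_matrix equals per-pair brute force and is symmetric", {
  aln <- random_alignment(5L, 150L, 3L)
  pol <- site_policy(ambiguity_match = "mismatch")
  dm <- distance_matrix(aln, "K2P", pol)
  for (i in 1:4) for (j in (i + 1):5) {
    pq <- p_distance(aln$seqs[i], aln$seqs[j], pol)
    expect_equal(dm$values[i, j], k2p_distance(pq$P, pq$Q)$d)
  }
  expect_equal(dm$values, t(dm$values))
  expect_equal(diag(dm$values), stats::setNames(rep(0, 5), aln$ids))

  # permutation equivariance
  perm <- c(4L, 2L, 5L, 1L, 3L)
  dmp <- distance_matrix(aln[perm], "K2P", pol)
  expect_equal(dmp$values, dm$values[aln$ids[perm], aln$ids[perm]])

  # identical records: off-diagonal zero / 100% similarity
  two <- aligned_set(c("u", "v"), rep("ACGTACGT", 2))
  expect_equal(distance_matrix(two, "K2P")$values["u", "v"], 0)
  expect_equal(distance_matrix(two, "similarity")$values["u", "v"], 100)
})

test_that("saturated pairs are flagged, not fatal", {
  # maximally divergent pair saturates K2P
  a <- paste(rep("A", 50), collapse = "")
  g <- paste(rep("G", 50), collapse = "")
  c50 <- paste(rep("C", 50), collapse = "")
  aln <- aligned_set(c("x", "y", "z"), c(a, g, c50))
  dm <- distance_matrix(aln, "K2P")
  expect_true(is.na(dm$values["x", "y"]))
  expect_true(dm$saturated["x", "y"])
})

test_that("matrix exports are written and readable", {
  aln <- random_alignment(4L, 60L, 9L)
  dm <- distance_matrix(aln, "p")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_tsv(dm, f)
  back <- utils::read.delim(f)
  expect_equal(back$id, aln$ids)
  expect_equal(as.matrix(back[, -1L]),
               matrix(dm$values, 4, dimnames = list(NULL, aln$ids)),
               tolerance = 1e-12)
  fp <- withr::local_tempfile(fileext = ".phy")
  write_distance_phylip(dm, fp)
  lines <- readLines(fp)
  expect_equal(length(lines), 5L)
  expect_equal(as.integer(trimws(lines[1L])), 4L)
})
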