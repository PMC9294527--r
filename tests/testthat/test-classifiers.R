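# ---- DSC ----------------------------------------------------------------

test_that("DSC assigns by similarity threshold and flags pass through", {
  aln <- toy_two_species(n_a = 3L, n_b = 3L, n_hybrids = 1L)
  # query identical to species A references
  q <- aligned_set(c(aln$ids, "q"), c(aln$seqs, aln$seqs[1L]),
                   c(aln$labels, NA))
  r <- dsc_classify(q, "q", threshold_pct = 98)
  expect_equal(r$call, "A")
  # pre-flagged hybrid passes through untested
  r <- dsc_classify(q, "h1", flagged_hybrids = "h1")
  expect_equal(r$call, "putative_hybrid")
})

test_that("DSC exclusive rule reports overlap as ambiguous, best rule decides", {
  # two species >= 99% similar to the query, threshold 99
  base <- paste(rep("ACGT", 50), collapse = "")      # 200 sites
  refA <- mutate_sites(base, 1L, seed = 5L)
  refB <- mutate_sites(base, 1L, seed = 9L)
  aln <- aligned_set(c("rA1", "rA2", "rB1", "rB2", "q"),
                     c(refA, refA, refB, refB, base),
                     c("A", "A", "B", "B", NA))
  ex <- dsc_classify(aln, "q", threshold_pct = 99, rule = "exclusive")
  expect_equal(ex$call, "ambiguous")
  # both qualify at identical similarity: best rule also cannot decide
  expect_equal(dsc_classify(aln, "q", threshold_pct = 99)$call, "ambiguous")
  # below threshold for everyone: no_match
  expect_equal(dsc_classify(aln, "q", threshold_pct = 99.9)$call, "no_match")
})

test_that("DSC at a 99% threshold is exact on a hybrid-free dataset", {
  sim <- simulate_paperlike()
  pure <- sim$aln[sim$truth$id[sim$truth$truth != "F1_hybrid"]]
  ev <- evaluate_method(pure, "DSC", params = list(threshold_pct = 99))
  expect_equal(ev$summary$percent[ev$summary$outcome == "correct"], 100)
})

# ---- BCM / AB ------------------------------------------------------------

test_that("the BCM threshold is the 95th percentile of intraspecific distances", {
  # all conspecific pairs identical
  aln <- aligned_set(c("a1", "a2", "b1"), c("AAAA", "AAAA", "TTTT"),
                     c("A", "A", "B"))
  dm <- distance_matrix(aln, "p")
  expect_equal(bcm_threshold(dm, aln$labels)$value_pct, 0)

  # two species cliques of 5 realise exactly the pooled intraspecific
  # distance list 0.1%, 0.2%, ..., 2.0% (10 + 10 pairs); the 95th
  # percentile with linear interpolation is 1.905%
  d <- seq(0.001, 0.020, by = 0.001)
  ids <- sprintf("s%02d", 1:10)
  m <- matrix(0.5, 10L, 10L)               # interspecific: large, unused
  m[1:5, 1:5][upper.tri(matrix(0, 5, 5))] <- d[1:10]
  m[6:10, 6:10][upper.tri(matrix(0, 5, 5))] <- d[11:20]
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  labs <- rep(c("A", "B"), each = 5L)
  thr <- bcm_threshold(as_dm(m, ids), labs)
  oracle <- function(x, q) {
    x <- sort(x); h <- (length(x) - 1) * q + 1
    x[floor(h)] + (h - floor(h)) * (x[min(ceiling(h), length(x))] - x[floor(h)])
  }
  expect_equal(thr$n_intraspecific_pairs, 20L)
  expect_equal(thr$value, oracle(d, 0.95))
  expect_equal(thr$value_pct, 1.905)

  expect_error(bcm_threshold(as_dm(m, ids), rep(NA_character_, 10L)),
               "intraspecific")
})

test_that("BCM assigns the closest species within the threshold", {
  ids <- c("q", "a1", "a2", "b1", "b2")
  m <- matrix(0.02, 5L, 5L, dimnames = list(ids, ids)); diag(m) <- 0
  m["q", c("a1", "a2")] <- m[c("a1", "a2"), "q"] <- 0.001
  m["q", c("b1", "b2")] <- m[c("b1", "b2"), "q"] <- 0.02
  dm <- as_dm(m, ids)
  labs <- c(NA, "A", "A", "B", "B")
  expect_equal(bcm_classify(dm, labs, "q", 0.0128)$call, "A")
  # exact tie between an A and a B reference within threshold
  m2 <- m; m2["q", "b1"] <- m2["b1", "q"] <- 0.001
  expect_equal(bcm_classify(as_dm(m2, ids), labs, "q", 0.0128)$call,
               "ambiguous")
  # minimum beyond threshold
  expect_equal(bcm_classify(dm, labs, "q", 0.0005)$call, "no_match")
})

test_that("AB requires all conspecific barcodes to top the ranking", {
  ids <- c("q", "a1", "a2", "b1", "b2")
  labs <- c(NA, "A", "A", "B", "B")
  m <- matrix(0, 5L, 5L, dimnames = list(ids, ids))
  m["q", ] <- m[, "q"] <- c(0, 0.001, 0.002, 0.01, 0.012)
  m[2:5, 2:5] <- 0.01; diag(m) <- 0
  dm <- as_dm(m, ids)
  expect_equal(ab_classify(dm, labs, "q", 0.0128)$call, "A")
  # heterospecific interleaved between the conspecific references
  m2 <- m; m2["q", "b1"] <- m2["b1", "q"] <- 0.0015
  expect_equal(ab_classify(as_dm(m2, ids), labs, "q", 0.0128)$call,
               "ambiguous")
  # best match beyond the threshold
  expect_equal(ab_classify(dm, labs, "q", 0.0005)$call, "no_match")
  # fewer than two conspecific references
  labs1 <- c(NA, "A", "C", "B", "B")
  expect_equal(ab_classify(dm, labs1, "q", 0.0128)$call, "no_match")
})

test_that("AB success implies BCM success at the same threshold", {
  sim <- simulate_dataset(sim_config(n_A = 6L, n_B = 10L, n_hybrids = 0L,
                                     intraspecific_theta = 0.002, seed = 31L))
  dm <- distance_matrix(sim$aln, "K2P",
                        site_policy(ambiguity_match = "mismatch"))
  thr <- bcm_threshold(dm, sim$aln$labels)
  n_ab_success <- 0L
  for (q in sim$aln$ids) {
    ab <- ab_classify(dm, sim$aln$labels, q, thr)
    if (!ab$call %in% c("ambiguous", "no_match")) {
      n_ab_success <- n_ab_success + 1L
      bcm <- bcm_classify(dm, sim$aln$labels, q, thr)
      expect_equal(bcm$call, ab$call)
    }
  }
  expect_gt(n_ab_success, 0L)
})

# ---- ABGD ----------------------------------------------------------------

test_that("ABGD partitions at a clear barcode gap and recurses no further", {
  sim <- simulate_dataset(sim_config(n_A = 6L, n_B = 9L, n_hybrids = 0L,
                                     intraspecific_theta = 0.001,
                                     interspecific_divergence = 0.02,
                                     seed = 5L))
  dm <- distance_matrix(sim$aln, "JC69",
                        site_policy(ambiguity_match = "exclude"))
  part <- abgd_partition(dm, 0.01)
  expect_equal(part$n_groups, 2L)
  split_labels <- split(sim$aln$labels, part$groups)
  expect_true(all(vapply(split_labels, function(x)
    length(unique(x)) == 1L, logical(1L))))
  expect_false(is.null(part$gap))

  # no distances above the prior: trivial partition
  expect_equal(abgd_partition(dm, 0.5)$n_groups, 1L)

  # a single pair cannot be partitioned
  two <- as_dm(matrix(c(0, 0.05, 0.05, 0), 2L), c("x", "y"))
  expect_equal(abgd_partition(two, 0.01)$n_groups, 1L)
})

test_that("hybrids chain the species into a single ABGD group", {
  sim <- simulate_paperlike()
  dm1 <- distance_matrix(sim$aln, "JC69",
                         site_policy(ambiguity_match = "exclude"))
  p1 <- abgd_partition(dm1, 0.01)
  expect_equal(p1$n_groups, 1L)
  expect_true(is.null(p1$gap))
  calls <- abgd_calls(p1, sim$aln$labels)
  expect_true(all(calls$call == "ambiguous"))
})

# ---- NJ ------------------------------------------------------------------

test_that("three taxa solve the closed-form branch lengths", {
  m <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3L, byrow = TRUE)
  tr <- nj_tree(as_dm(m, c("a", "b", "c")))
  cp <- ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(cp, m, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("NJ recovers every random additive tree at 4-6 taxa", {
  for (n in 4:6) for (seed in 1:8) {
    ad <- random_additive(n, seed * 100 + n)
    tr <- nj_tree(as_dm(ad$D, rownames(ad$D)))
    # exact topology...
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ad$tree), tr)), 0)
    # ...and exact path lengths
    expect_equal(ape::cophenetic.phylo(tr)[rownames(ad$D), rownames(ad$D)],
                 ad$D, tolerance = 1e-8)
    # and it agrees with the reference NJ implementation
    ref <- ape::nj(as.dist(ad$D))
    expect_equal(as.numeric(ape::dist.topo(ref, tr)), 0)
  }
})

test_that("NJ output is invariant to record order", {
  ad <- random_additive(6L, 77L)
  ids <- rownames(ad$D)
  t1 <- nj_tree(as_dm(ad$D, ids))
  perm <- c(3L, 6L, 1L, 5L, 2L, 4L)
  t2 <- nj_tree(as_dm(ad$D[perm, perm], ids[perm]))
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
  expect_equal(ape::cophenetic.phylo(t2)[ids, ids],
               ape::cophenetic.phylo(t1)[ids, ids], tolerance = 1e-10)
})

test_that("NJ clamps negative branch lengths without changing path sums", {
  # a non-additive matrix known to induce a negative NJ branch
  m <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0), 4L, byrow = TRUE) / 10
  m[1, 2] <- m[2, 1] <- 0.58  # stress the 3-point estimates
  tr <- nj_tree(as_dm(m, letters[1:4]))
  expect_true(all(tr$edge.length >= 0))
  expect_error(nj_tree(as_dm(matrix(c(0, NA, NA, 0), 2L), c("x", "y"))),
               "non-finite|at least 3")
})

# ---- bootstrap + FINS ----------------------------------------------------

test_that("bootstrap supports are deterministic and find clear clades", {
  sim <- simulate_dataset(sim_config(n_A = 4L, n_B = 4L, n_hybrids = 0L,
                                     intraspecific_theta = 0.002,
                                     interspecific_divergence = 0.05,
                                     length = 300L, seed = 13L))
  b1 <- bootstrap_support(sim$aln, model = "K2P", replicates = 60L,
                          seed = 99L)
  b2 <- bootstrap_support(sim$aln, model = "K2P", replicates = 60L,
                          seed = 99L)
  expect_identical(b1$support, b2$support)
  expect_identical(write_newick(b1$tree), write_newick(b2$tree))
  # the bipartition separating the two species should be near-certain
  expect_gte(max(b1$support), 95)
})

test_that("FINS assigns inside supported conspecific clades only", {
  txt <- "(((q:1,a1:1)95:2,a2:1)90:2,(b1:1,b2:1)99:4,c:9);"
  tr <- read_newick(txt)
  labs <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  r <- fins_classify(tr, "q", labs, min_support = 70)
  expect_equal(r$call, "A")
  expect_equal(r$evidence$clade_support, 95)
  # insufficient support
  expect_equal(fins_classify(tr, "q", labs, min_support = 99)$call,
               "ambiguous")
  # mixed clade
  mixed <- read_newick("((q:1,(a1:1,b1:1)80:1)85:2,(a2:1,b2:1)90:2,c:5);")
  expect_equal(fins_classify(mixed, "q", labs)$call, "ambiguous")
  # rooting on the outgroup must not change the call
  r2 <- fins_classify(tr, "q", labs, min_support = 70, outgroup_id = "c")
  expect_equal(r2$call, "A")
  expect_error(fins_classify(tr, "zz", labs), "not in tree")
})

# ---- evaluation ----------------------------------------------------------

test_that("leave-one-out summaries bucket outcomes and sum to 100", {
  sim <- simulate_dataset(sim_config(n_A = 6L, n_B = 10L, n_hybrids = 0L,
                                     intraspecific_theta = 0.001,
                                     interspecific_divergence = 0.02,
                                     seed = 17L))
  for (m in c("DSC", "BCM", "AB")) {
    ev <- evaluate_method(sim$aln, m)
    expect_equal(sum(ev$summary$count), length(sim$aln$ids))
    expect_equal(sum(ev$summary$percent), 100)
    expect_equal(ev$summary$percent[ev$summary$outcome == "correct"], 100,
                 info = m)
  }
  ev <- evaluate_method(sim$aln, "ABGD")
  expect_equal(ev$summary$percent[ev$summary$outcome == "correct"], 100)
  expect_false(is.null(ev$extras$partition$gap))
})
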