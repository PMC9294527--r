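# Shared fixture builders; everything is generated in code.

# aligned set of two species separated at fixed columns, plus optional
# hybrids carrying the combined IUPAC code there
toy_two_species <- function(n_a = 3L, n_b = 3L, len = 40L,
                            diag_cols = c(5L, 12L, 20L, 28L, 33L),
                            allele_a = c("T", "A", "C", "G", "A"),
                            allele_b = c("C", "G", "T", "A", "C"),
                            n_hybrids = 0L, seed = 7L) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  cons_a <- cons_b <- base
  cons_a[diag_cols] <- allele_a
  cons_b[diag_cols] <- allele_b
  het <- vapply(seq_along(diag_cols), function(k)
    iupac_code(c(allele_a[k], allele_b[k])), character(1L))
  hyb <- base
  hyb[diag_cols] <- het
  ids <- c(sprintf("a%d", seq_len(n_a)), sprintf("b%d", seq_len(n_b)),
           if (n_hybrids > 0L) sprintf("h%d", seq_len(n_hybrids)))
  seqs <- c(rep(paste(cons_a, collapse = ""), n_a),
            rep(paste(cons_b, collapse = ""), n_b),
            rep(paste(hyb, collapse = ""), n_hybrids))
  labels <- c(rep("A", n_a), rep("B", n_b), rep(NA_character_, n_hybrids))
  aligned_set(ids, seqs, labels)
}

# random unambiguous alignment of related sequences (each a mutated copy
# of a common ancestor, ~divergence substitutions/site) for distance oracles
random_alignment <- function(n = 4L, len = 200L, seed = 1L,
                             divergence = 0.08) {
  set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    ch <- anc
    pos <- sample(len, max(1L, stats::rpois(1L, len * divergence)))
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    paste(ch, collapse = "")
  }, character(1L))
  aligned_set(sprintf("s%02d", seq_len(n)), seqs)
}

# mutate `k` random sites of a sequence string
mutate_sites <- function(seq, k, seed = 1L) {
  set.seed(seed)
  ch <- strsplit(seq, "")[[1L]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# wrap a plain symmetric matrix as a distance_matrix object
as_dm <- function(values, ids = rownames(values), model = "K2P") {
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, model = model,
                 policy = site_policy(ambiguity_match = "mismatch"),
                 saturated = matrix(FALSE, nrow(values), ncol(values))),
            class = "distance_matrix")
}

# additive distance matrix from a random unrooted binary tree
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.05, 1))
  tr$tip.label <- sort(tr$tip.label)  # labels t1..tn in fixed order
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# the reconstructed study contingency tables (printed marginal counts)
study_table_dsc <- function() {
  m <- matrix(c(7, 0, 2,
                0, 42, 10,
                0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("Mg", "Mch", "hybrid"),
                              c("Mg", "Mch", "hybrid")))
  m
}

study_table_ab <- function() {
  matrix(c(5, 0, 2,
           0, 41, 1,
           0, 0, 0), nrow = 3, byrow = TRUE,
         dimnames = list(c("Mg", "Mch", "no_match"),
                         c("Mg", "Mch", "no_match")))
}
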