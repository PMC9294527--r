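# The five barcode species-identification methods: DSC (direct sequence
# comparison), BCM (best close match), AB (all barcodes), simplified ABGD
# (automatic barcode-gap discovery) and FINS (tree-based placement), plus
# leave-one-out evaluation summaries.

.result <- function(query_id, method, call, evidence = list()) {
  list(query_id = query_id, method = method, call = call,
       evidence = evidence)
}

# references for a query: all other records with a non-NA label,
# optionally minus an exclusion set
.ref_ids <- function(ids, labels, query_id, exclude = character()) {
  keep <- ids != query_id & !is.na(labels) & !(ids %in% exclude)
  ids[keep]
}

# ---- DSC -----------------------------------------------------------------

#' Direct sequence comparison (DSC) classification
#'
#' A species qualifies when its reference similarities to the query exceed
#' `threshold_pct` under the chosen aggregation (`"all"`: every conspecific
#' reference must exceed the threshold; `"mean"`/`"max"`: the mean/best
#' reference similarity must).  Exactly one qualifying species is the call;
#' two or more give `ambiguous`; none gives `no_match`.  Queries listed in
#' `flagged_hybrids` (e.g. from [call_hybrids()]) are returned as
#' `putative_hybrid` without comparison, and flagged records never serve as
#' references.
#'
#' @param aln A labelled [aligned_set()].
#' @param query_id Id of the query record (excluded from the references).
#' @param threshold_pct Similarity threshold in percent (default 98).
#' @param aggregate `"all"`, `"mean"` or `"max"`.
#' @param rule `"best"` (default): among qualifying species the one with
#'   the highest aggregated similarity is called, `ambiguous` only on a
#'   tie.  `"exclusive"`: any second qualifying species makes the call
#'   `ambiguous`.  With markers this conserved, heterospecific similarities
#'   routinely exceed a 98% threshold, so the exclusive rule can never
#'   decide; the best rule reflects how similarity-threshold assignment is
#'   applied in practice.
#' @param policy [site_policy()] for the similarity computation; the
#'   default scores overlapping IUPAC base sets as matches.
#' @param flagged_hybrids Character vector of ids pre-flagged as putative
#'   hybrids.
#' @param sim Optional precomputed similarity `distance_matrix` over `aln`
#'   (model `"similarity"`), to avoid recomputation in loops.
#' @return An identification result: list with `query_id`, `method`,
#'   `call`, `evidence`.
#' @export
dsc_classify <- function(aln, query_id, threshold_pct = 98,
                         aggregate = c("all", "mean", "max"),
                         rule = c("best", "exclusive"),
                         policy = site_policy(),
                         flagged_hybrids = character(), sim = NULL) {
  aggregate <- match.arg(aggregate)
  rule <- match.arg(rule)
  if (!query_id %in% aln$ids) stop("unknown query id: ", query_id)
  if (query_id %in% flagged_hybrids)
    return(.result(query_id, "DSC", "putative_hybrid",
                   list(reason = "pre-flagged by diagnostic-site analysis")))
  refs <- .ref_ids(aln$ids, aln$labels, query_id, flagged_hybrids)
  if (length(refs) == 0L) stop("no labelled references for DSC")
  if (is.null(sim)) sim <- distance_matrix(aln, "similarity", policy)
  s <- sim$values[query_id, refs]
  spp <- aln$labels[match(refs, aln$ids)]
  agg <- vapply(split(s, spp), switch(aggregate, all = min, mean = mean,
                                      max = max), numeric(1L))
  qual <- names(agg)[agg > threshold_pct]
  call <- if (length(qual) == 0L) "no_match"
  else if (length(qual) == 1L) qual
  else if (rule == "exclusive") "ambiguous"
  else {
    top <- agg[qual]
    best <- names(top)[top >= max(top) - 1e-9]
    if (length(best) == 1L) best else "ambiguous"
  }
  .result(query_id, "DSC", call,
          list(aggregated_similarity = agg, threshold_pct = threshold_pct,
               aggregate = aggregate, rule = rule))
}

# ---- BCM / AB ------------------------------------------------------------

#' Best-close-match threshold: 95th percentile of intraspecific distances
#'
#' Pools every pairwise distance between two references sharing a label and
#' takes the 95th percentile with linear interpolation.
#'
#' @param dm A `distance_matrix` (conventionally K2P with
#'   ambiguity-as-mismatch, the classical barcoding choice).
#' @param labels Character vector of species labels aligned with `dm$ids`
#'   (`NA` = unlabelled, not used).
#' @param percentile Percentile of the intraspecific distance distribution,
#'   default 95.
#' @return Object of class `bcm_threshold`: list with `value`
#'   (substitutions/site), `value_pct`, `percentile`,
#'   `n_intraspecific_pairs`.
#' @export
bcm_threshold <- function(dm, labels, percentile = 95) {
  stopifnot(length(labels) == length(dm$ids))
  pairs <- .pair_list(dm)
  l1 <- labels[match(pairs$id1, dm$ids)]
  l2 <- labels[match(pairs$id2, dm$ids)]
  intra <- pairs$value[!is.na(l1) & !is.na(l2) & l1 == l2]
  intra <- intra[!is.na(intra)]
  if (length(intra) == 0L)
    stop("no intraspecific reference pair: need a species with >= 2 references")
  v <- as.numeric(stats::quantile(intra, percentile / 100, type = 7))
  structure(list(value = v, value_pct = 100 * v, percentile = percentile,
                 n_intraspecific_pairs = length(intra)),
            class = "bcm_threshold")
}

#' @export
print.bcm_threshold <- function(x, ...) {
  cat(sprintf("bcm_threshold: %.4f%% (%dth percentile of %d intraspecific pairs)\n",
              x$value_pct, x$percentile, x$n_intraspecific_pairs))
  invisible(x)
}

.as_threshold_value <- function(threshold) {
  if (inherits(threshold, "bcm_threshold")) threshold$value
  else as.numeric(threshold)
}

#' Best close match (BCM) classification
#'
#' The query is assigned the species of its closest reference(s), provided
#' the closest distance lies within the threshold.  A tie between species
#' at the minimum distance gives `ambiguous`; a minimum beyond the
#' threshold gives `no_match`.
#'
#' @param dm A `distance_matrix` over the labelled set (query included).
#' @param labels Species labels aligned with `dm$ids`.
#' @param query_id Query record id (its own distances are ignored:
#'   leave-one-out).
#' @param threshold A [bcm_threshold()] or a numeric distance in
#'   substitutions/site.
#' @param exclude Ids never used as references.
#' @return An identification result list.
#' @export
bcm_classify <- function(dm, labels, query_id, threshold,
                         exclude = character()) {
  thr <- .as_threshold_value(threshold)
  refs <- .ref_ids(dm$ids, labels, query_id, exclude)
  if (length(refs) == 0L) stop("no labelled references for BCM")
  d <- dm$values[query_id, refs]
  if (all(is.na(d))) stop("all reference distances undefined for ", query_id)
  dmin <- min(d, na.rm = TRUE)
  nearest <- refs[!is.na(d) & d <= dmin + 1e-12]
  spp <- unique(labels[match(nearest, dm$ids)])
  call <- if (dmin > thr) "no_match" else
    if (length(spp) > 1L) "ambiguous" else spp
  .result(query_id, "BCM", call,
          list(min_distance = dmin, nearest = nearest, threshold = thr))
}

#' All barcodes (AB) classification
#'
#' References are ranked by distance to the query.  Let S be the species of
#' the best match: the call is S only when S has at least two references
#' and every S reference strictly outranks every heterospecific reference
#' (no interleaving, ties count as interleaved) and the best match lies
#' within the threshold.  A best match beyond the threshold is `no_match`;
#' interleaving or a tie at the top is `ambiguous`.
#'
#' @inheritParams bcm_classify
#' @return An identification result list.
#' @export
ab_classify <- function(dm, labels, query_id, threshold,
                        exclude = character()) {
  thr <- .as_threshold_value(threshold)
  refs <- .ref_ids(dm$ids, labels, query_id, exclude)
  if (length(refs) == 0L) stop("no labelled references for AB")
  d <- dm$values[query_id, refs]
  ok <- !is.na(d)
  refs <- refs[ok]; d <- d[ok]
  spp <- labels[match(refs, dm$ids)]
  dmin <- min(d)
  top <- unique(spp[d <= dmin + 1e-12])
  ev <- list(min_distance = dmin, threshold = thr)
  if (dmin > thr) return(.result(query_id, "AB", "no_match", ev))
  if (length(top) > 1L) return(.result(query_id, "AB", "ambiguous", ev))
  S <- top
  con <- d[spp == S]
  het <- d[spp != S]
  if (length(con) < 2L) return(.result(query_id, "AB", "no_match",
                                       c(ev, list(reason = "<2 conspecific references"))))
  call <- if (length(het) == 0L || min(het) > max(con) + 1e-12) S else "ambiguous"
  .result(query_id, "AB", call, c(ev, list(max_conspecific = max(con),
                                           min_heterospecific =
                                             if (length(het)) min(het) else NA_real_)))
}

# ---- simplified ABGD -----------------------------------------------------

# First significant gap in a sorted distance vector: the first step
# d[i] -> d[i+1] with d[i+1] > prior_P whose width exceeds X times the mean
# successive gap among the distances up to d[i].
.find_gap <- function(d, prior_P, X) {
  m <- length(d)
  if (m < 2L) return(NULL)
  for (i in seq_len(m - 1L)) {
    if (d[i + 1L] <= prior_P) next
    g <- d[i + 1L] - d[i]
    if (g <= 0) next
    mean_prev <- if (i > 1L) (d[i] - d[1L]) / (i - 1L) else 0
    if (g > X * mean_prev) return(list(index = i, low = d[i],
                                       high = d[i + 1L], width = g))
  }
  NULL
}

#' Simplified automatic barcode-gap discovery (ABGD) partition
#'
#' Sorts all pairwise distances, finds the first significant gap above the
#' prior maximum intraspecific divergence (a step wider than
#' `rel_gap_X` times the mean step among the smaller distances), clusters
#' by single linkage below the gap, and recurses into each group until no
#' further gap is found.  Absence of any gap returns a single group.
#'
#' This is the recursive-gap core of ABGD, not the original
#' coalescent-calibrated program; it reproduces the qualitative gap /
#' no-gap behaviour that matters for identification.
#'
#' @param dm A `distance_matrix` (ambiguity-excluded p or JC69 distances
#'   are the classical choice).
#' @param prior_P Prior maximum intraspecific divergence (substitutions per
#'   site), e.g. swept over 0.001-0.1.
#' @param rel_gap_X Relative gap width multiplier, default 1.5.
#' @return Object of class `abgd_partition`: list with `groups` (named
#'   integer vector), `n_groups`, `gap` (first-gap record or `NULL`),
#'   `prior_P`.
#' @export
abgd_partition <- function(dm, prior_P = 0.01, rel_gap_X = 1.5) {
  vals <- dm$values
  if (any(is.na(vals[upper.tri(vals)])))
    stop("distance matrix contains undefined cells")
  ids <- dm$ids
  first_gap <- NULL
  recurse <- function(sub_ids) {
    n <- length(sub_ids)
    if (n <= 2L) return(list(sub_ids))
    v <- vals[sub_ids, sub_ids, drop = FALSE]
    d <- sort(v[upper.tri(v)])
    gap <- .find_gap(d, prior_P, rel_gap_X)
    if (is.null(gap)) return(list(sub_ids))
    cutoff <- (gap$low + gap$high) / 2
    hc <- stats::hclust(stats::as.dist(v), method = "single")
    grp <- stats::cutree(hc, h = cutoff)
    # single linkage can chain across a numeric gap (intermediate
    # genotypes); an ineffective gap does not partition
    if (length(unique(grp)) == 1L) return(list(sub_ids))
    if (is.null(first_gap)) first_gap <<- gap
    unlist(lapply(split(sub_ids, grp), recurse), recursive = FALSE)
  }
  parts <- recurse(ids)
  groups <- integer(length(ids)); names(groups) <- ids
  for (k in seq_along(parts)) groups[parts[[k]]] <- k
  structure(list(groups = groups, n_groups = length(parts),
                 gap = first_gap, prior_P = prior_P),
            class = "abgd_partition")
}

#' Sweep ABGD over a grid of prior intraspecific divergences
#'
#' @inheritParams abgd_partition
#' @param priors Numeric vector of priors; default a log-spaced grid over
#'   0.001-0.1 (the span conventionally explored).
#' @return List with `partitions` (one [abgd_partition()] per prior),
#'   `priors`, and `modal` -- the partition whose group assignment occurs
#'   most often across the sweep (ties resolved towards the smaller prior).
#' @export
abgd_sweep <- function(dm, priors = 10^seq(log10(0.001), log10(0.1),
                                           length.out = 10),
                       rel_gap_X = 1.5) {
  parts <- lapply(priors, function(p) abgd_partition(dm, p, rel_gap_X))
  sig <- vapply(parts, function(p)
    paste(match(p$groups, unique(p$groups)), collapse = ","), character(1L))
  modal_sig <- names(sort(table(sig), decreasing = TRUE))[1L]
  modal <- parts[[which(sig == modal_sig)[1L]]]
  list(partitions = parts, priors = priors, modal = modal)
}

#' Species calls from an ABGD partition
#'
#' Groups are mapped to species by the majority label of their members; a
#' single-group partition (no barcode gap) makes every call `ambiguous`, as
#' does membership in a group without a label majority.
#'
#' @param partition An [abgd_partition()].
#' @param labels Species labels aligned with `names(partition$groups)`.
#' @return data.frame with `query_id`, `method`, `call`.
#' @export
abgd_calls <- function(partition, labels) {
  ids <- names(partition$groups)
  stopifnot(length(labels) == length(ids))
  call <- rep("ambiguous", length(ids))
  if (partition$n_groups > 1L) {
    for (g in unique(partition$groups)) {
      member <- partition$groups == g
      lab <- labels[member]
      lab <- lab[!is.na(lab)]
      if (length(lab) == 0L) next
      tab <- sort(table(lab), decreasing = TRUE)
      if (length(tab) == 1L || tab[1L] > tab[2L])
        call[member] <- names(tab)[1L]
    }
  }
  data.frame(query_id = ids, method = "ABGD", call = call,
             stringsAsFactors = FALSE)
}

# ---- neighbour joining ---------------------------------------------------

#' Neighbour-joining tree with deterministic tie-breaking
#'
#' Saitou-Nei agglomeration on `Q(i,j) = (n-2) d(i,j) - r_i - r_j`.  Ties
#' in Q are broken towards the lexicographically smallest id pair, so the
#' topology is invariant to record order.  Negative branch lengths are
#' clamped to zero with the deficit moved to the sibling branch, preserving
#' the distance between the joined pair.
#'
#' @param dm A `distance_matrix` with finite values (>= 3 records).
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  D <- dm$values
  if (any(!is.finite(D))) stop("non-finite distance in matrix")
  ids <- dm$ids
  n <- length(ids)
  if (n < 3L) stop("need at least 3 records for NJ")
  nwk <- ids                       # subtree newick fragment per active node
  key <- ids                       # lexicographic key per active node
  active <- seq_len(n)
  rownames(D) <- colnames(D) <- NULL
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  while (length(active) > 3L) {
    m <- length(active)
    Dm <- D[active, active]
    r <- rowSums(Dm)
    Qm <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Qm) <- Inf
    qmin <- min(Qm)
    cand <- which(Qm <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pair_key <- apply(cand, 1L, function(ij) {
      ks <- sort(c(key[active[ij[1L]]], key[active[ij[2L]]]))
      paste(ks, collapse = "\r")
    })
    best <- cand[order(pair_key)[1L], ]
    i <- active[best[1L]]; j <- active[best[2L]]
    dij <- D[i, j]
    bi <- dij / 2 + (r[best[1L]] - r[best[2L]]) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- dij; bi <- 0 }
    if (bj < 0) { bi <- dij; bj <- 0 }
    # distances from the new node to the remaining actives
    rest <- setdiff(active, c(i, j))
    dnew <- (D[i, rest] + D[j, rest] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    D[u, rest] <- D[rest, u] <- dnew
    nwk <- c(nwk, paste0("(", nwk[i], ":", fmt(bi), ",",
                         nwk[j], ":", fmt(bj), ")"))
    key <- c(key, min(key[i], key[j]))
    active <- c(rest, u)
  }
  a <- active[order(key[active])]
  d12 <- D[a[1L], a[2L]]; d13 <- D[a[1L], a[3L]]; d23 <- D[a[2L], a[3L]]
  b1 <- (d12 + d13 - d23) / 2
  b2 <- (d12 + d23 - d13) / 2
  b3 <- (d13 + d23 - d12) / 2
  txt <- paste0("(", nwk[a[1L]], ":", fmt(b1), ",",
                nwk[a[2L]], ":", fmt(b2), ",",
                nwk[a[3L]], ":", fmt(b3), ");")
  ape::read.tree(text = txt)
}

# ---- bootstrap -----------------------------------------------------------

#' Bootstrap support for the internal edges of the NJ tree
#'
#' Alignment columns are resampled with replacement `replicates` times; the
#' NJ tree is rebuilt on each pseudo-alignment and the support of every
#' bipartition of the full-data tree is the percentage of replicate trees
#' containing it.  The same seed and input always give identical supports.
#'
#' @param aln An [aligned_set()] (>= 4 records for internal edges).
#' @param model Distance model passed to [distance_matrix()], default
#'   `"TN93"` (the conventional choice for tree-based identification).
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed fixing the column-resampling stream.
#' @param policy [site_policy()] for the distances.
#' @return List with `tree` (the full-data NJ tree, supports as
#'   `node.label`), `support` (numeric per internal node, percent),
#'   `replicates`, `seed`.
#' @export
bootstrap_support <- function(aln, model = "TN93", replicates = 100L,
                              seed = 1L, policy = NULL) {
  stopifnot(replicates >= 1L)
  full <- nj_tree(distance_matrix(aln, model, policy))
  m <- .aln_matrix(aln)
  set.seed(as.integer(seed))
  reps <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    sub <- aligned_set(aln$ids,
                       apply(m[, cols, drop = FALSE], 1L, paste,
                             collapse = ""),
                       aln$labels)
    reps[[b]] <- nj_tree(distance_matrix(sub, model, policy))
  }
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / replicates
  full$node.label <- formatC(support, format = "fg")
  list(tree = full, support = support, replicates = replicates,
       seed = as.integer(seed))
}

# ---- FINS ----------------------------------------------------------------

# tip ids (integers) below each node of a phylo tree
.clade_tips <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  kids <- vector("list", nt + nn)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1L]]] <- c(kids[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  below <- vector("list", nt + nn)
  fill <- function(v) {
    if (v <= nt) { below[[v]] <<- v; return(v) }
    tips <- unlist(lapply(kids[[v]], fill))
    below[[v]] <<- tips
    tips
  }
  fill(nt + 1L)
  below
}

#' Tree-based (FINS-style) classification of one query
#'
#' The tree is rooted on the outgroup and the smallest clade containing the
#' query and at least one labelled reference is located.  The query is
#' assigned that clade's species only when every reference in the clade is
#' conspecific and the clade's bootstrap support reaches `min_support`;
#' otherwise the call is `ambiguous`.
#'
#' @param tree A [ape::phylo] tree whose `node.label` holds percent
#'   bootstrap supports (as produced by [bootstrap_support()]).
#' @param query_id Tip label of the query.
#' @param labels Named character vector: species labels for reference tips
#'   (`NA` or absent = unlabelled).
#' @param min_support Minimum clade support in percent, default 70.
#' @param outgroup_id Optional tip label to root on.
#' @return An identification result list.
#' @export
fins_classify <- function(tree, query_id, labels, min_support = 70,
                          outgroup_id = NULL) {
  if (!query_id %in% tree$tip.label)
    stop("query '", query_id, "' not in tree")
  if (!is.null(outgroup_id)) {
    if (!outgroup_id %in% tree$tip.label)
      stop("outgroup '", outgroup_id, "' not in tree")
    tree <- ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE,
                      edgelabel = TRUE)
  }
  nt <- length(tree$tip.label)
  below <- .clade_tips(tree)
  lab_of <- function(tips) {
    l <- labels[tree$tip.label[tips]]
    l[!is.na(l)]
  }
  q <- match(query_id, tree$tip.label)
  parent <- integer(nt + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  node <- q
  repeat {
    node <- parent[node]
    if (node == 0L) return(.result(query_id, "FINS", "ambiguous",
                                   list(reason = "no labelled reference clade")))
    refs <- lab_of(setdiff(below[[node]], q))
    if (length(refs) > 0L) break
  }
  supp <- NA_real_
  if (!is.null(tree$node.label)) {
    s <- suppressWarnings(as.numeric(tree$node.label[node - nt]))
    if (length(s) == 1L && !is.na(s)) supp <- s
  }
  species <- unique(refs)
  call <- if (length(species) == 1L && !is.na(supp) && supp >= min_support)
    species else "ambiguous"
  .result(query_id, "FINS", call,
          list(clade_support = supp, clade_species = species,
               min_support = min_support))
}

# ---- evaluation ----------------------------------------------------------

#' Leave-one-out evaluation of an identification method
#'
#' Each labelled record is queried in turn against all the others, and
#' calls are scored against the truth labels.  `no_match` and
#' `putative_hybrid` outcomes are counted in the `ambiguous` column by
#' default, so the three summary percentages always total 100.
#'
#' @param aln A labelled [aligned_set()].
#' @param method One of `"DSC"`, `"BCM"`, `"AB"`, `"ABGD"`, `"FINS"`.
#' @param truth Truth labels for scoring; defaults to `aln$labels`.
#' @param params List of method parameters: `threshold_pct`, `aggregate`,
#'   `rule`, `flagged_hybrids` (DSC); `model`, `percentile` (BCM/AB);
#'   `prior_P` (default 0.01), `priors` (optional sweep grid),
#'   `rel_gap_X`, `model` (ABGD); `replicates`, `seed`, `min_support`,
#'   `outgroup_id`, `model` (FINS).
#' @return List of class `method_evaluation`: `results` (data.frame of
#'   per-query calls), `summary` (counts and percentages of
#'   correct/ambiguous/incorrect), `method`, `extras` (method-specific:
#'   threshold, partition, tree).
#' @export
evaluate_method <- function(aln, method = c("DSC", "BCM", "AB", "ABGD", "FINS"),
                            truth = NULL, params = list()) {
  method <- match.arg(method)
  if (is.null(truth)) truth <- aln$labels
  stopifnot(length(truth) == length(aln$ids))
  queries <- aln$ids[!is.na(truth)]
  extras <- list()
  p <- params

  if (method == "DSC") {
    thr <- p$threshold_pct %||% 98
    agg <- p$aggregate %||% "all"
    rule <- p$rule %||% "best"
    flagged <- p$flagged_hybrids %||% character()
    sim <- distance_matrix(aln, "similarity")
    res <- lapply(queries, function(q)
      dsc_classify(aln, q, thr, agg, rule, flagged_hybrids = flagged,
                   sim = sim))
  } else if (method %in% c("BCM", "AB")) {
    model <- p$model %||% "K2P"
    dm <- distance_matrix(aln, model,
                          site_policy(ambiguity_match = "mismatch"))
    thr <- bcm_threshold(dm, aln$labels, p$percentile %||% 95)
    extras$threshold <- thr
    fun <- if (method == "BCM") bcm_classify else ab_classify
    res <- lapply(queries, function(q) fun(dm, aln$labels, q, thr))
  } else if (method == "ABGD") {
    model <- p$model %||% "JC69"
    dm <- distance_matrix(aln, model,
                          site_policy(ambiguity_match = "exclude"))
    part <- abgd_partition(dm, p$prior_P %||% 0.01, p$rel_gap_X %||% 1.5)
    extras$partition <- part
    if (!is.null(p$priors))
      extras$sweep <- abgd_sweep(dm, p$priors, p$rel_gap_X %||% 1.5)
    calls <- abgd_calls(part, aln$labels)
    res <- lapply(queries, function(q)
      .result(q, "ABGD", calls$call[calls$query_id == q]))
  } else { # FINS
    bs <- bootstrap_support(aln, model = p$model %||% "TN93",
                            replicates = p$replicates %||% 100L,
                            seed = p$seed %||% 1L)
    extras$tree <- bs$tree
    labs <- stats::setNames(aln$labels, aln$ids)
    res <- lapply(queries, function(q) {
      ref_labs <- labs
      ref_labs[q] <- NA  # the query never references itself
      fins_classify(bs$tree, q, ref_labs,
                    min_support = p$min_support %||% 70,
                    outgroup_id = p$outgroup_id)
    })
  }

  calls <- vapply(res, `[[`, character(1L), "call")
  tr <- truth[match(queries, aln$ids)]
  special <- c("ambiguous", "no_match", "putative_hybrid")
  bucket <- ifelse(calls %in% special, "ambiguous",
                   ifelse(calls == tr, "correct", "incorrect"))
  n <- length(queries)
  counts <- vapply(c("correct", "ambiguous", "incorrect"),
                   function(b) sum(bucket == b), integer(1L))
  summary <- data.frame(outcome = names(counts), count = as.integer(counts),
                        percent = 100 * as.numeric(counts) / n,
                        stringsAsFactors = FALSE)
  structure(list(method = method,
                 results = data.frame(query_id = queries, method = method,
                                      call = calls, truth = tr,
                                      outcome = bucket,
                                      stringsAsFactors = FALSE),
                 summary = summary, n = n, extras = extras),
            class = "method_evaluation")
}

#' @export
print.method_evaluation <- function(x, ...) {
  cat(sprintf("%s: n = %d | correct %.1f%% | ambiguous %.1f%% | incorrect %.1f%%\n",
              x$method, x$n, x$summary$percent[1L], x$summary$percent[2L],
              x$summary$percent[3L]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
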