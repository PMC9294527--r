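# Pairwise similarity and model-corrected genetic distances.
#
# All pairwise comparisons run through per-site weight tables built once per
# ambiguity policy: for each ordered pair of alignment characters we
# precompute whether the site is compared at all, its mismatch weight, and
# how that weight splits into purine transitions (A<->G), pyrimidine
# transitions (C<->T) and transversions.  Ambiguity codes are resolved by
# enumerating their base sets, so e.g. Y-vs-C is half C-C (match) and half
# T-C (pyrimidine transition).

#' Site-handling policy for pairwise comparisons
#'
#' @param gap_handling `"pairwise"` (drop a column only for pairs in which
#'   either record is gapped; the default) or `"complete"` (drop any column
#'   gapped in any record of the alignment before computing a matrix).
#' @param ambiguity_match How IUPAC ambiguity codes are scored:
#'   `"intersect"` (a site matches when the two base sets overlap — a
#'   hybrid's Y matches both parental C and T), `"mismatch"` (strict
#'   character comparison: any two different codes mismatch), `"fractional"`
#'   (mismatch weight is the probability that independent random
#'   resolutions of the two codes differ), or `"exclude"` (sites with an
#'   ambiguity code in either record are removed from the comparison, as in
#'   classical barcode-gap tools that treat ambiguity as missing data).
#' @return Object of class `site_policy`.
#' @export
site_policy <- function(gap_handling = c("pairwise", "complete"),
                        ambiguity_match = c("intersect", "mismatch",
                                            "fractional", "exclude")) {
  structure(list(gap_handling = match.arg(gap_handling),
                 ambiguity_match = match.arg(ambiguity_match)),
            class = "site_policy")
}

# ---- per-policy weight tables -------------------------------------------

.policy_cache <- new.env(parent = emptyenv())

.is_ts1 <- function(x, y) (x == "A" & y == "G") | (x == "G" & y == "A")
.is_ts2 <- function(x, y) (x == "C" & y == "T") | (x == "T" & y == "C")

.build_tables <- function(ambiguity) {
  n <- length(.ALPHABET)
  comp <- mis <- ts1 <- ts2 <- matrix(0, n, n,
                                      dimnames = list(.ALPHABET, .ALPHABET))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- .ALPHABET[i]; b <- .ALPHABET[j]
    if (a == "-" || b == "-") next
    A <- .IUPAC[[a]]; B <- .IUPAC[[b]]
    if (ambiguity == "exclude" && (length(A) > 1L || length(B) > 1L)) next
    grid <- expand.grid(x = A, y = B, stringsAsFactors = FALSE)
    w <- 1 / nrow(grid)
    d <- grid$x != grid$y
    f_diff <- sum(d) * w
    f_ts1 <- sum(d & .is_ts1(grid$x, grid$y)) * w
    f_ts2 <- sum(d & .is_ts2(grid$x, grid$y)) * w
    m <- switch(ambiguity,
                fractional = f_diff,
                intersect  = if (length(intersect(A, B)) > 0L) 0 else 1,
                mismatch   = if (a == b) 0 else 1,
                exclude    = f_diff)  # both unambiguous here: f_diff is 0/1
    comp[i, j] <- 1
    mis[i, j] <- m
    if (m > 0 && f_diff > 0) {
      ts1[i, j] <- m * f_ts1 / f_diff
      ts2[i, j] <- m * f_ts2 / f_diff
    }
  }
  list(comp = comp, mis = mis, ts1 = ts1, ts2 = ts2)
}

.tables <- function(policy) {
  key <- policy$ambiguity_match
  if (is.null(.policy_cache[[key]]))
    .policy_cache[[key]] <- .build_tables(key)
  .policy_cache[[key]]
}

# Raw per-pair site statistics for two character vectors.
.pair_stats <- function(ca, cb, policy) {
  tb <- .tables(policy)
  idx <- cbind(match(ca, .ALPHABET), match(cb, .ALPHABET))
  compared <- sum(tb$comp[idx])
  mism <- sum(tb$mis[idx])
  s1 <- sum(tb$ts1[idx])
  s2 <- sum(tb$ts2[idx])
  list(compared = compared, mismatches = mism,
       P1 = if (compared > 0) s1 / compared else NA_real_,
       P2 = if (compared > 0) s2 / compared else NA_real_,
       Q = if (compared > 0) (mism - s1 - s2) / compared else NA_real_)
}

.seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.check_pair <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("sequences must have equal aligned length")
}

# ---- pairwise operations -------------------------------------------------

#' Percent similarity between two aligned sequences
#'
#' `100 * matches / compared_sites`, where columns removed by the site
#' policy (gaps, and ambiguity codes under the `"exclude"` policy) do not
#' count as compared.
#'
#' @param a,b Aligned sequences (character strings of equal length).
#' @param policy A [site_policy()]; the default scores overlapping IUPAC
#'   base sets as matches.
#' @return List with `percent` and `compared_sites`.
#' @export
similarity_percent <- function(a, b, policy = site_policy()) {
  .check_pair(a, b)
  st <- .pair_stats(.seq_chars(a), .seq_chars(b), policy)
  if (st$compared == 0)
    stop("undefined similarity: no comparable sites under this policy")
  list(percent = 100 * (st$compared - st$mismatches) / st$compared,
       compared_sites = st$compared)
}

#' Uncorrected p-distance with transition/transversion split
#'
#' @inheritParams similarity_percent
#' @return List with `p` (substitutions/site), `P` (transition proportion),
#'   `Q` (transversion proportion) and `compared_sites`; `p = P + Q`.
#' @export
p_distance <- function(a, b, policy = site_policy(ambiguity_match = "mismatch")) {
  .check_pair(a, b)
  st <- .pair_stats(.seq_chars(a), .seq_chars(b), policy)
  if (st$compared == 0)
    stop("undefined distance: no comparable sites under this policy")
  list(p = st$mismatches / st$compared, P = st$P1 + st$P2, Q = st$Q,
       compared_sites = st$compared)
}

#' Kimura two-parameter distance from transition/transversion proportions
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.  When a log argument is
#' non-positive the distance is saturated: `NA` with `saturated = TRUE`
#' rather than an error.
#'
#' @param P Transition proportion.
#' @param Q Transversion proportion.
#' @return List with `d` and `saturated`.
#' @export
k2p_distance <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(list(d = NA_real_, saturated = TRUE))
  list(d = -0.5 * log(w1) - 0.25 * log(w2), saturated = FALSE)
}

#' Jukes-Cantor distance from a p-distance
#'
#' @param p Proportion of differing sites.
#' @return List with `d` and `saturated`.
#' @export
jc69_distance <- function(p) {
  w <- 1 - 4 * p / 3
  if (w <= 0) return(list(d = NA_real_, saturated = TRUE))
  list(d = -0.75 * log(w), saturated = FALSE)
}

# base frequencies from the unambiguous characters of one or more sequences
.base_freqs <- function(seqs) {
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  chars <- chars[chars %in% c("A", "C", "G", "T")]
  if (length(chars) == 0L) return(rep(0.25, 4))
  tab <- table(factor(chars, levels = c("A", "C", "G", "T")))
  as.numeric(tab) / sum(tab)
}

#' Tamura-Nei (TN93) distance between two aligned sequences
#'
#' Closed-form TN93 with separate purine-transition (`P1`),
#' pyrimidine-transition (`P2`) and transversion (`Q`) proportions.  Base
#' frequencies are estimated from the two sequences themselves unless
#' supplied (e.g. from the whole alignment).  Reduces to K2P when base
#' frequencies are equal.
#'
#' @inheritParams similarity_percent
#' @param freqs Optional numeric vector of base frequencies
#'   `(A, C, G, T)`; defaults to the empirical frequencies of the pair.
#' @return List with `d`, `P1`, `P2`, `Q`, `compared_sites`, `saturated`.
#' @export
tn93_distance <- function(a, b,
                          policy = site_policy(ambiguity_match = "mismatch"),
                          freqs = NULL) {
  .check_pair(a, b)
  st <- .pair_stats(.seq_chars(a), .seq_chars(b), policy)
  if (st$compared == 0)
    stop("undefined distance: no comparable sites under this policy")
  if (is.null(freqs)) freqs <- .base_freqs(c(a, b))
  stopifnot(length(freqs) == 4L, all(freqs >= 0))
  freqs <- freqs / sum(freqs)
  pA <- freqs[1L]; pC <- freqs[2L]; pG <- freqs[3L]; pT <- freqs[4L]
  pR <- pA + pG; pY <- pC + pT
  P1 <- st$P1; P2 <- st$P2; Q <- st$Q
  out <- list(d = NA_real_, P1 = P1, P2 = P2, Q = Q,
              compared_sites = st$compared, saturated = FALSE)
  if (pR <= 0 || pY <= 0 || pA * pG <= 0 && P1 > 0 || pC * pT <= 0 && P2 > 0) {
    out$saturated <- TRUE
    return(out)
  }
  k1 <- 2 * pA * pG / pR
  k2 <- 2 * pT * pC / pY
  k3 <- 2 * (pR * pY - pA * pG * pY / pR - pT * pC * pR / pY)
  w1 <- if (k1 > 0) 1 - P1 / k1 - Q / (2 * pR) else 1
  w2 <- if (k2 > 0) 1 - P2 / k2 - Q / (2 * pY) else 1
  w3 <- 1 - Q / (2 * pR * pY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) {
    out$saturated <- TRUE
    return(out)
  }
  out$d <- -(if (k1 > 0) k1 * log(w1) else 0) -
    (if (k2 > 0) k2 * log(w2) else 0) - k3 * log(w3)
  out
}

# ---- distance matrices ---------------------------------------------------

#' Pairwise distance (or similarity) matrix over an aligned set
#'
#' @param aln An [aligned_set()] with at least two records.
#' @param model One of `"p"`, `"similarity"`, `"JC69"`, `"K2P"`, `"TN93"`.
#'   `"similarity"` gives percent similarity (diagonal 100); all others give
#'   substitutions/site (diagonal 0).
#' @param policy A [site_policy()].  The default ambiguity handling is
#'   `"intersect"` for the similarity model and `"mismatch"` otherwise.
#' @param tn93_freqs For `model = "TN93"`: `"pair"` (default) estimates
#'   base frequencies per pair; `"alignment"` uses the whole alignment.
#' @return Object of class `distance_matrix`: fields `ids`, `values`
#'   (symmetric matrix), `model`, `policy`, `saturated` (logical matrix;
#'   saturated cells hold `NA` in `values`).
#' @export
distance_matrix <- function(aln,
                            model = c("K2P", "p", "similarity", "JC69", "TN93"),
                            policy = NULL, tn93_freqs = c("pair", "alignment")) {
  model <- match.arg(model)
  tn93_freqs <- match.arg(tn93_freqs)
  if (length(aln$ids) < 2L) stop("need at least 2 records")
  if (is.null(policy))
    policy <- if (model == "similarity") site_policy() else
      site_policy(ambiguity_match = "mismatch")
  m <- .aln_matrix(aln)
  if (policy$gap_handling == "complete") {
    keep <- colSums(m == "-") == 0L
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  vals <- matrix(if (model == "similarity") 100 else 0, n, n,
                 dimnames = list(aln$ids, aln$ids))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(vals))
  aln_freqs <- if (model == "TN93" && tn93_freqs == "alignment")
    .base_freqs(aln$seqs) else NULL
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    st <- .pair_stats(m[i, ], m[j, ], policy)
    if (st$compared == 0) {
      vals[i, j] <- vals[j, i] <- NA_real_
      sat[i, j] <- sat[j, i] <- TRUE
      next
    }
    p <- st$mismatches / st$compared
    v <- switch(model,
      similarity = 100 * (1 - p),
      p = p,
      JC69 = jc69_distance(p)$d,
      K2P = k2p_distance(st$P1 + st$P2, st$Q)$d,
      TN93 = {
        fr <- if (is.null(aln_freqs))
          .base_freqs(aln$seqs[c(i, j)]) else aln_freqs
        tn93_distance(aln$seqs[i], aln$seqs[j], policy, freqs = fr)$d
      })
    vals[i, j] <- vals[j, i] <- v
    if (is.na(v)) sat[i, j] <- sat[j, i] <- TRUE
  }
  structure(list(ids = aln$ids, values = vals, model = model,
                 policy = policy, saturated = sat),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix:", length(x$ids), "records, model", x$model,
      "(gap:", x$policy$gap_handling, "/ ambiguity:",
      paste0(x$policy$ambiguity_match, ")"), "\n")
  off <- x$values[upper.tri(x$values)]
  if (length(off) > 0L)
    cat("off-diagonal range:", format(min(off, na.rm = TRUE), digits = 4),
        "-", format(max(off, na.rm = TRUE), digits = 4), "\n")
  invisible(x)
}

# off-diagonal pair values with id pairs, ascending
.pair_list <- function(dm) {
  ut <- which(upper.tri(dm$values), arr.ind = TRUE)
  data.frame(id1 = dm$ids[ut[, 1L]], id2 = dm$ids[ut[, 2L]],
             value = dm$values[ut], stringsAsFactors = FALSE)
}

#' Export a distance matrix as square TSV
#'
#' @param dm A `distance_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  out <- cbind(data.frame(id = dm$ids, stringsAsFactors = FALSE),
               as.data.frame(dm$values))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a distance matrix in PHYLIP square format
#'
#' Ids are truncated/padded to ten characters as the format requires.
#'
#' @param dm A `distance_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distance_phylip <- function(dm, path) {
  n <- length(dm$ids)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste0(formatC(substr(dm$ids[i], 1L, 10L), width = -10L),
                      paste(sprintf("%.6f", dm$values[i, ]), collapse = "  "))
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}
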