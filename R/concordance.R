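# Inter-method agreement statistics: confusion tables, Cohen's kappa with
# large-sample CI and one-sided test, Gorodkin's multiclass Matthews
# correlation, Benjamini-Hochberg correction, Landis-Koch bands.

#' Cross-tabulate two categorical call sets over the same individuals
#'
#' The category set is the union of the categories observed in either
#' method, so a category emitted by only one method (a hybrid or no-match
#' class, say) appears with a zero marginal for the other.
#'
#' @param calls1,calls2 Named character vectors (names = individual ids) or
#'   unnamed vectors of equal length over the same individuals.
#' @param categories Optional explicit category ordering.
#' @return Object of class `confusion_table`: `counts` (square matrix,
#'   rows = method 1), `categories`, `n`.
#' @export
confusion_table <- function(calls1, calls2, categories = NULL) {
  if (!is.null(names(calls1)) && !is.null(names(calls2))) {
    if (!setequal(names(calls1), names(calls2)))
      stop("the two call sets cover different individuals")
    calls2 <- calls2[names(calls1)]
  } else if (length(calls1) != length(calls2))
    stop("call vectors must have equal length")
  if (length(calls1) == 0L) stop("empty call set")
  if (is.null(categories))
    categories <- sort(unique(c(calls1, calls2)))
  f1 <- factor(calls1, levels = categories)
  f2 <- factor(calls2, levels = categories)
  if (anyNA(f1) || anyNA(f2)) stop("calls outside the category set")
  counts <- table(f1, f2)
  counts <- matrix(as.integer(counts), nrow = length(categories),
                   dimnames = list(categories, categories))
  structure(list(counts = counts, categories = categories,
                 n = sum(counts)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("confusion_table: n =", x$n, "\n")
  print(x$counts)
  invisible(x)
}

.as_counts <- function(t) {
  if (inherits(t, "confusion_table")) t$counts
  else as.matrix(t)
}

#' Cohen's kappa with large-sample confidence interval and one-sided test
#'
#' `po` is the observed agreement, `pe` the chance agreement from the
#' marginal products, `kappa = (po - pe) / (1 - pe)`.  The 95% interval
#' uses the large-sample standard error
#' `sqrt(po (1 - po) / (n (1 - pe)^2))`; the p-value is the one-sided
#' normal test of kappa > 0 using the null-hypothesis (Fleiss) standard
#' error.
#'
#' @param t A [confusion_table()] or square count matrix (n >= 2).
#' @return List with `kappa`, `po`, `pe`, `se`, `ci95` (length-2 vector),
#'   `z`, `p` (one-sided), `n`.  Both raters constant (`pe = 1`) gives
#'   `kappa = NA` with `degenerate = TRUE`.
#' @export
cohen_kappa <- function(t) {
  counts <- .as_counts(t)
  n <- sum(counts)
  if (n < 2) stop("need at least 2 individuals")
  po <- sum(diag(counts)) / n
  p_row <- rowSums(counts) / n
  p_col <- colSums(counts) / n
  pe <- sum(p_row * p_col)
  if (1 - pe < .Machine$double.eps ^ 0.5)
    return(list(kappa = NA_real_, po = po, pe = pe, se = NA_real_,
                ci95 = c(NA_real_, NA_real_), z = NA_real_, p = NA_real_,
                n = n, degenerate = TRUE))
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  ci95 <- kappa + c(-1, 1) * stats::qnorm(0.975) * se
  # Fleiss null SE for the test of kappa = 0
  se0 <- sqrt(max(0, pe + pe^2 - sum(p_row * p_col * (p_row + p_col)))) /
    ((1 - pe) * sqrt(n))
  z <- if (se0 > 0) kappa / se0 else sign(kappa) * Inf
  if (se0 == 0 && kappa == 0) z <- 0
  list(kappa = kappa, po = po, pe = pe, se = se, ci95 = ci95, z = z,
       p = stats::pnorm(z, lower.tail = FALSE), n = n, degenerate = FALSE)
}

#' Multiclass Matthews correlation coefficient (Gorodkin's RK)
#'
#' `RK = (c s - sum_k p_k t_k) / sqrt((s^2 - sum p_k^2)(s^2 - sum t_k^2))`
#' with `c` the diagonal total, `s` the grand total, `p_k`/`t_k` the
#' row/column sums.  Reduces to the classical binary MCC on 2x2 tables.
#'
#' @param t A [confusion_table()] or square count matrix.
#' @return List with `mcc` and `degenerate` (`TRUE` when a zero
#'   denominator forces `mcc = 0`).
#' @export
mcc_multiclass <- function(t) {
  counts <- .as_counts(t)
  s <- sum(counts)
  cc <- sum(diag(counts))
  p <- rowSums(counts)
  tt <- colSums(counts)
  den2 <- (s^2 - sum(p^2)) * (s^2 - sum(tt^2))
  if (den2 <= 0) return(list(mcc = 0, degenerate = TRUE))
  list(mcc = (cc * s - sum(p * tt)) / sqrt(den2), degenerate = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment of a vector of p-values; adjusted values are
#' monotone after sorting and never smaller than the raw ones.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Landis-Koch verbal band for a kappa value
#'
#' `< 0` poor; `0-0.20` slight; `0.21-0.40` fair; `0.41-0.60` moderate;
#' `0.61-0.80` substantial; `0.81-1` almost perfect, with exactly 1
#' reported as perfect.
#'
#' @param kappa Kappa value (may be vectorised).
#' @return Character vector of band labels.
#' @export
agreement_band <- function(kappa) {
  vapply(kappa, function(k) {
    if (is.na(k)) return(NA_character_)
    if (k < 0) "poor"
    else if (k <= 0.20) "slight"
    else if (k <= 0.40) "fair"
    else if (k <= 0.60) "moderate"
    else if (k <= 0.80) "substantial"
    else if (k < 1) "almost perfect"
    else "perfect"
  }, character(1L))
}

#' Full agreement analysis of one method pair
#'
#' @param calls1,calls2 Call vectors as in [confusion_table()].
#' @param categories Optional category ordering.
#' @return Object of class `agreement_result`: the confusion table plus
#'   `kappa`, `se`, `ci95`, `p_raw` (`p_fdr` is filled by
#'   [agreement_matrix()]), `mcc`, `band`.
#' @export
agreement <- function(calls1, calls2, categories = NULL) {
  ct <- confusion_table(calls1, calls2, categories)
  kp <- cohen_kappa(ct)
  mc <- mcc_multiclass(ct)
  structure(list(table = ct, kappa = kp$kappa, se = kp$se,
                 ci95 = kp$ci95, p_raw = kp$p, p_fdr = NA_real_,
                 mcc = mc$mcc, band = agreement_band(kp$kappa),
                 n = ct$n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("kappa = %.4f (95%% CI %.4f-%.4f), MCC = %.4f, %s agreement, n = %d\n",
              x$kappa, x$ci95[1L], x$ci95[2L], x$mcc, x$band, x$n))
  invisible(x)
}

#' Pairwise agreement matrix over several call sets
#'
#' Computes [agreement()] for every unordered pair of call sets and applies
#' the Benjamini-Hochberg correction across the pairs' kappa p-values.
#'
#' @param calls Named list of call vectors over the same individuals.
#' @return data.frame with one row per pair: `method1`, `method2`, `n`,
#'   `kappa`, `ci_lower`, `ci_upper`, `p_raw`, `p_fdr`, `band`, `mcc`.
#' @export
agreement_matrix <- function(calls) {
  stopifnot(is.list(calls), length(calls) >= 2L, !is.null(names(calls)))
  nm <- names(calls)
  pairs <- utils::combn(nm, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- agreement(calls[[pr[1L]]], calls[[pr[2L]]])
    data.frame(method1 = pr[1L], method2 = pr[2L], n = a$n,
               kappa = a$kappa, ci_lower = a$ci95[1L],
               ci_upper = a$ci95[2L], p_raw = a$p_raw,
               p_fdr = NA_real_, band = a$band, mcc = a$mcc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p_raw)
  out
}
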