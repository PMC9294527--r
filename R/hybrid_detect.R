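# Diagnostic-site discovery between two reference species and
# IUPAC-heterozygote hybrid calling.
#
# A diagnostic site is an alignment column where every reference of species
# A carries one fixed unambiguous base and every reference of species B a
# different fixed unambiguous base.  An individual whose IUPAC base set at
# such a site contains BOTH parental alleles (Y at a C/T site, say) shows
# the double chromatogram peak expected of a heterozygote, and enough such
# sites flag it as a putative hybrid.

#' Discover fixed diagnostic sites between two reference sets
#'
#' @param aln An [aligned_set()].
#' @param refs_A,refs_B Character vectors of record ids serving as
#'   references for species A and B.  Both must be non-empty.
#' @param species_A,species_B Names for the two species (used in reports).
#' @return Object of class `diagnostic_panel`: data.frame `sites` with
#'   columns `column` (1-based alignment column), `allele_A`, `allele_B`,
#'   plus attributes `species_A`, `species_B`.
#' @export
find_diagnostic_sites <- function(aln, refs_A, refs_B,
                                  species_A = "A", species_B = "B") {
  if (length(refs_A) == 0L || length(refs_B) == 0L)
    stop("both reference sets must be non-empty")
  m <- .aln_matrix(aln)
  missing <- setdiff(c(refs_A, refs_B), rownames(m))
  if (length(missing) > 0L)
    stop("reference ids not in alignment: ", paste(missing, collapse = ", "))
  ma <- m[refs_A, , drop = FALSE]
  mb <- m[refs_B, , drop = FALSE]
  fixed_base <- function(col) {
    u <- unique(col)
    if (length(u) == 1L && u %in% c("A", "C", "G", "T")) u else NA_character_
  }
  a_fix <- apply(ma, 2L, fixed_base)
  b_fix <- apply(mb, 2L, fixed_base)
  keep <- !is.na(a_fix) & !is.na(b_fix) & a_fix != b_fix
  sites <- data.frame(column = which(keep),
                      allele_A = a_fix[keep], allele_B = b_fix[keep],
                      stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  structure(list(sites = sites, species_A = species_A,
                 species_B = species_B),
            class = "diagnostic_panel")
}

#' @export
print.diagnostic_panel <- function(x, ...) {
  cat("diagnostic_panel:", nrow(x$sites), "fixed sites between",
      x$species_A, "and", x$species_B, "\n")
  if (nrow(x$sites) > 0L) print(x$sites)
  invisible(x)
}

#' Call putative hybrids from heterozygous diagnostic-site genotypes
#'
#' A panel site counts as heterozygous for a record when the record's IUPAC
#' base set there contains both parental alleles (gaps count towards
#' neither).  A record is a `putative_hybrid` when at least `min_het_sites`
#' panel sites are heterozygous; `pure_A`/`pure_B` when every panel site
#' matches one parent exactly; otherwise `undetermined`.
#'
#' The default `min_het_sites = 1` is deliberately permissive: field data
#' show individuals heterozygous at only a subset of the panel (later
#' generation hybrids or backcrosses), and these are still reported as
#' putative hybrids; raise the threshold for strict F1-only calling.
#'
#' @param aln An [aligned_set()].
#' @param panel A [find_diagnostic_sites()] panel with at least one site.
#' @param min_het_sites Minimum heterozygous panel sites, integer >= 1.
#' @return data.frame with columns `id`, `status` (`pure_A`, `pure_B`,
#'   `putative_hybrid`, `undetermined`), `het_sites`, `genotype` (the
#'   observed characters at panel sites, in panel order).
#' @export
call_hybrids <- function(aln, panel, min_het_sites = 1L) {
  if (!inherits(panel, "diagnostic_panel")) stop("panel must be a diagnostic_panel")
  if (nrow(panel$sites) == 0L) stop("diagnostic panel is empty")
  stopifnot(min_het_sites >= 1L)
  m <- .aln_matrix(aln)
  cols <- panel$sites$column
  if (max(cols) > ncol(m)) stop("panel columns exceed alignment length")
  geno <- m[, cols, drop = FALSE]
  n_sites <- length(cols)
  het <- matrix(FALSE, nrow(geno), n_sites)
  is_a <- is_b <- matrix(FALSE, nrow(geno), n_sites)
  for (k in seq_len(n_sites)) {
    aA <- panel$sites$allele_A[k]
    aB <- panel$sites$allele_B[k]
    ch <- geno[, k]
    hasA <- .iupac_contains(ch, aA)
    hasB <- .iupac_contains(ch, aB)
    het[, k] <- hasA & hasB
    is_a[, k] <- ch == aA
    is_b[, k] <- ch == aB
  }
  het_sites <- rowSums(het)
  status <- ifelse(het_sites >= min_het_sites, "putative_hybrid",
                   ifelse(rowSums(is_a) == n_sites, "pure_A",
                          ifelse(rowSums(is_b) == n_sites, "pure_B",
                                 "undetermined")))
  data.frame(id = aln$ids, status = status,
             het_sites = as.integer(het_sites),
             genotype = apply(geno, 1L, paste, collapse = ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Export a diagnostic panel as TSV
#'
#' @param panel A `diagnostic_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  utils::write.table(panel$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
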