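# Aligned barcode containers and file IO (FASTA, label tables, newick).

#' Construct an aligned barcode set
#'
#' The central container of the package: an ordered set of equal-length
#' aligned sequences over the IUPAC+gap alphabet, with optional nominal
#' species labels and optional auxiliary labelling schemes (e.g. calls made
#' by an independent wet-lab method).
#'
#' @param ids Character vector of unique record identifiers.
#' @param seqs Character vector of aligned sequences (same length as `ids`).
#'   Lower case and `U` are normalised; any character outside the IUPAC+gap
#'   alphabet is an error.
#' @param labels Optional character vector of nominal species labels
#'   (`NA` where unknown).
#' @param aux_labels Optional data.frame of additional labelling schemes,
#'   one row per record, one column per scheme.
#' @return Object of class `aligned_set` with fields `ids`, `seqs`,
#'   `labels`, `aux_labels`, `length`.
#' @export
aligned_set <- function(ids, seqs, labels = NULL, aux_labels = NULL) {
  ids <- as.character(ids)
  seqs <- as.character(seqs)
  if (length(ids) != length(seqs))
    stop("ids and seqs must have equal length")
  if (anyDuplicated(ids))
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(seqs) > 0L && any(nchar(seqs) == 0L))
    stop("empty sequence for record '", ids[which(nchar(seqs) == 0L)[1L]], "'")
  seqs <- mapply(.normalize_seq, seqs, ids, USE.NAMES = FALSE)
  len <- unique(nchar(seqs))
  if (length(len) > 1L)
    stop("alignment error: sequences have unequal lengths (",
         paste(sort(len), collapse = ", "), ")")
  if (length(len) == 0L) len <- 0L
  if (is.null(labels)) labels <- rep(NA_character_, length(ids))
  labels <- as.character(labels)
  if (length(labels) != length(ids))
    stop("labels must match the number of records")
  if (!is.null(aux_labels)) {
    aux_labels <- as.data.frame(aux_labels, stringsAsFactors = FALSE)
    if (nrow(aux_labels) != length(ids))
      stop("aux_labels must have one row per record")
    rownames(aux_labels) <- ids
  }
  structure(list(ids = ids, seqs = seqs, labels = labels,
                 aux_labels = aux_labels, length = as.integer(len)),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat("aligned_set:", length(x$ids), "records,", x$length,
      "alignment columns\n")
  lab <- x$labels[!is.na(x$labels)]
  if (length(lab) > 0L) {
    tab <- table(lab)
    cat("labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.aligned_set <- function(x) length(x$ids)

#' Subset an aligned set by record id or position
#'
#' @param x An `aligned_set`.
#' @param i Character ids or integer/logical index.
#' @param ... Unused.
#' @return An `aligned_set` with the selected records, in the given order.
#' @export
`[.aligned_set` <- function(x, i, ...) {
  if (is.character(i)) {
    idx <- match(i, x$ids)
    if (anyNA(idx)) stop("unknown record id(s): ",
                         paste(i[is.na(idx)], collapse = ", "))
  } else idx <- seq_along(x$ids)[i]
  aligned_set(x$ids[idx], x$seqs[idx], x$labels[idx],
              if (is.null(x$aux_labels)) NULL else
                x$aux_labels[idx, , drop = FALSE])
}

# alignment as a character matrix (records x columns)
.aln_matrix <- function(aln) {
  if (length(aln$ids) == 0L)
    return(matrix(character(0L), nrow = 0L, ncol = aln$length))
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

#' Read an aligned FASTA file
#'
#' Headers of the form `>id|species` populate the nominal label; a bare
#' `>id` leaves the label unset.  Sequences are validated against the
#' IUPAC+gap alphabet and must all have the same length.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return An [aligned_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(seqinr::read.fasta(path, as.string = TRUE,
                                   forceDNAtolower = FALSE),
                error = function(e) list())
  if (length(x) == 0L) return(aligned_set(character(0L), character(0L)))
  headers <- names(x)
  seqs <- vapply(x, function(s) as.character(s)[1L], character(1L),
                 USE.NAMES = FALSE)
  parts <- strsplit(headers, "|", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1L), 1L)
  labels <- vapply(parts, function(p)
    if (length(p) >= 2L) p[[2L]] else NA_character_, character(1L))
  aligned_set(trimws(ids), seqs, trimws(labels))
}

#' Write an aligned set to FASTA
#'
#' Records with a nominal label are written with `>id|species` headers so
#' that [read_fasta()] round-trips labels.
#'
#' @param aln An `aligned_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  headers <- ifelse(is.na(aln$labels), aln$ids,
                    paste(aln$ids, aln$labels, sep = "|"))
  lines <- character(2L * length(aln$ids))
  lines[c(TRUE, FALSE)] <- paste0(">", headers)
  lines[c(FALSE, TRUE)] <- aln$seqs
  writeLines(lines, path)
  invisible(path)
}

#' Read a tab-separated label table
#'
#' The table must have a header row; the first column holds record ids and
#' every other column is a labelling scheme (e.g. `nominal_species`, an
#' HRM-style call, a SNP-panel call).  Empty cells become `NA`
#' ("unlabelled").
#'
#' @param path Path to a TSV file.
#' @return data.frame with one row per id (rownames = ids) and one column
#'   per scheme; zero rows for an empty table.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE, na.strings = c("", "NA"))
  if (nrow(raw) == 0L) {
    out <- raw[, -1L, drop = FALSE]
    return(out)
  }
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate id in label table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- raw[, -1L, drop = FALSE]
  rownames(out) <- ids
  out
}

#' Write a label table as TSV
#'
#' @param labels data.frame with ids as rownames (as returned by
#'   [read_labels()]).
#' @param path Output file path.
#' @param id_column Name for the id column, default `"id"`.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, id_column = "id") {
  out <- cbind(stats::setNames(data.frame(rownames(labels),
                                          stringsAsFactors = FALSE),
                               id_column),
               labels)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialise a phylogenetic tree as newick text
#'
#' Bootstrap supports stored in `tree$node.label` are written as
#' internal-node labels (the support-as-node-label newick dialect).
#'
#' @param tree An [ape::phylo] tree with labelled tips.
#' @param path Optional file path; when `NULL` the newick string is
#'   returned.
#' @return Newick string (or `path` invisibly when writing to file).
#' @export
write_newick <- function(tree, path = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(tree$tip.label == ""))
    stop("every tip must be labelled")
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#'
#' @param text Newick string, or `NULL` when reading from `path`.
#' @param path Optional file path.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text) && is.null(path)) stop("supply text or path")
  if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
}
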