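# IUPAC nucleotide ambiguity semantics.  The gap character "-" is carried in
# alignments but is never a member of any ambiguity set.

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.ALPHABET <- c(names(.IUPAC), "-")

#' Expand an IUPAC nucleotide code to its base set
#'
#' @param code A single IUPAC character (case-insensitive; `U` is treated as
#'   `T`).  The gap character is not a valid code.
#' @return Character vector of unambiguous bases, a subset of `A,C,G,T`.
#' @examples
#' iupac_bases("Y")  # C T
#' iupac_bases("N")  # A C G T
#' @export
iupac_bases <- function(code) {
  stopifnot(length(code) == 1L, nchar(code) == 1L)
  code <- toupper(code)
  if (code == "U") code <- "T"
  b <- .IUPAC[[code]]
  if (is.null(b)) stop("not an IUPAC nucleotide code: '", code, "'")
  b
}

#' Encode a set of bases as the IUPAC code denoting exactly that set
#'
#' Inverse of [iupac_bases()]: `iupac_code(iupac_bases(x)) == x` for every
#' code `x`.
#'
#' @param bases Character vector, a non-empty subset of `A,C,G,T`.
#' @return Single IUPAC character.
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (length(bases) == 0L || !all(bases %in% c("A", "C", "G", "T")))
    stop("bases must be a non-empty subset of A,C,G,T")
  key <- paste(bases, collapse = "")
  hit <- names(.IUPAC)[vapply(.IUPAC, function(b)
    identical(sort(b), bases), logical(1L))]
  if (length(hit) != 1L) stop("no IUPAC code for base set ", key)
  hit
}

# TRUE where an observed alignment character's base set contains `base`.
# Vectorised over `chars`; gaps are FALSE.
.iupac_contains <- function(chars, base) {
  vapply(chars, function(ch) {
    if (ch == "-") return(FALSE)
    base %in% .IUPAC[[ch]]
  }, logical(1L), USE.NAMES = FALSE)
}

# Normalise raw sequence text: upper case, U -> T; error on anything outside
# the IUPAC+gap alphabet, naming the record and first offending column.
.normalize_seq <- function(seq, id = "?") {
  s <- chartr("u", "T", toupper(seq))
  s <- chartr("U", "T", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% .ALPHABET))
  if (length(bad) > 0L)
    stop("record '", id, "': illegal character '", chars[bad[1L]],
         "' at alignment column ", bad[1L])
  paste(chars, collapse = "")
}
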