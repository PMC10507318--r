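#' The RNA alphabet
#'
#' The four ribonucleotide symbols used throughout the package, in the fixed
#' order that also defines the integer/token codes (`A = 1`, `C = 2`, `G = 3`,
#' `U = 4`; the padding token is 0).
#'
#' @return A character vector `c("A", "C", "G", "U")`.
#' @export
rna_bases <- function() c("A", "C", "G", "U")

#' Maximum strand length supported by the fixed-size input layout
#' @return The integer 10.
#' @export
max_strand_length <- function() 10L

.wc_map <- c(A = "U", C = "G", G = "C", U = "A")

#' Watson-Crick complement of single bases
#'
#' Maps A to U, C to G, G to C and U to A. The map is an involution.
#'
#' @param b Character vector of single-base symbols in `{A, C, G, U}`.
#' @return Character vector of complementary bases.
#' @examples
#' complement_base(c("A", "C"))
#' @export
complement_base <- function(b) {
  out <- unname(.wc_map[b])
  if (anyNA(out) || any(nchar(b) != 1L)) {
    bad <- unique(b[is.na(out) | nchar(b) != 1L])
    stop("invalid alphabet symbol(s): ", paste(bad, collapse = ", "),
         " (expected one of A, C, G, U)", call. = FALSE)
  }
  out
}

#' Exact complement of a strand
#'
#' Returns the unique strand `s*` fully complementary to `s`: both strands read
#' 5'-to-3', position `i` of `s` pairs with position `L + 1 - i` of `s*`, so
#' `s*` is the reverse of the base-wise Watson-Crick complement.
#'
#' @param s Character vector of strands over `{A, C, G, U}`.
#' @return Character vector of exact complements, same lengths as the inputs.
#' @examples
#' exact_complement("AGUCAG") # "CUGACU"
#' @export
exact_complement <- function(s) {
  validate_strands(s)
  comp <- chartr("ACGU", "UGCA", s)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Validate strand strings
#'
#' Checks that every string is non-empty, no longer than `max_len`, and drawn
#' from the RNA alphabet.
#'
#' @param s Character vector of strands.
#' @param max_len Maximum admissible length (default [max_strand_length()]).
#' @return Invisibly, `s`.
#' @export
validate_strands <- function(s, max_len = max_strand_length()) {
  if (!is.character(s) || length(s) == 0L) {
    stop("strands must be a non-empty character vector", call. = FALSE)
  }
  n <- nchar(s)
  if (any(n < 1L) || any(n > max_len)) {
    stop("strand length must be in [1, ", max_len, "]", call. = FALSE)
  }
  if (any(grepl("[^ACGU]", s))) {
    stop("strands may only contain A, C, G, U", call. = FALSE)
  }
  invisible(s)
}

## ---- internal integer representation ------------------------------------
## Strands are manipulated internally as integer matrices (one row per strand,
## values 1..4 in the rna_bases() order); the complement is then 5 - x and the
## exact complement reverses the columns. Sequence-space enumeration uses the
## base-4 expansion of a strand id in [0, 4^L).

strands_to_int <- function(s) {
  L <- nchar(s[1])
  m <- matrix(match(unlist(strsplit(s, "", fixed = TRUE)), rna_bases()),
              ncol = L, byrow = TRUE)
  if (anyNA(m)) stop("strands may only contain A, C, G, U", call. = FALSE)
  m
}

int_to_strands <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  letters <- matrix(rna_bases()[m], nrow = nrow(m))
  do.call(paste0, as.data.frame(letters, stringsAsFactors = FALSE))
}

int_complement <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  (5L - m)[, rev(seq_len(ncol(m))), drop = FALSE]
}

## ids are in [0, 4^L); most-significant digit first
ids_to_int <- function(ids, L) {
  m <- matrix(0L, nrow = length(ids), ncol = L)
  for (pos in seq_len(L)) {
    m[, pos] <- as.integer((ids %/% 4^(L - pos)) %% 4) + 1L
  }
  m
}

int_to_ids <- function(m) {
  L <- ncol(m)
  ids <- numeric(nrow(m))
  for (pos in seq_len(L)) {
    ids <- ids + (m[, pos] - 1) * 4^(L - pos)
  }
  ids
}

#' Enumerate all strands of a given length
#'
#' @param L Strand length, `1 <= L <= 10`. Lengths above 8 enumerate more than
#'   a million strands; the experiments here use `L <= 8`.
#' @return Character vector of all `4^L` strands, in lexicographic order of the
#'   alphabet `A < C < G < U`.
#' @export
all_strands <- function(L) {
  stopifnot(L >= 1, L <= max_strand_length())
  int_to_strands(ids_to_int(0:(4^L - 1), L))
}
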