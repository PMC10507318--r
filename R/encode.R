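#' Token codes for the fixed-size input layout
#'
#' Inputs are tokenised as `PAD = 0`, `A = 1`, `C = 2`, `G = 3`, `U = 4`.
#' A hairpin example with stem length `L` and loop length `k` is laid out as
#' `PAD^(m-L) s a s_bar PAD^(m-L)` where `m` is the maximum stem length (10),
#' for a fixed total length of `2 * m + k` tokens (24 with the default
#' tetraloop). The padding token always embeds to the zero vector inside the
#' networks.
#'
#' @param ds A `hairpin_dataset`, or a data frame with `s`, `loop`, `s_bar`
#'   character columns.
#' @param max_len Maximum stem length `m` (default [max_strand_length()]).
#' @return An integer matrix with one row per example and `2 * max_len +
#'   loop_length` columns, with attribute `"labels"` carrying the observed
#'   labels when present in `ds`.
#' @examples
#' ds <- make_example("ACGUA", positive = TRUE, seed = 1)
#' dim(encode_dataset(ds)) # 1 x 24
#' @export
encode_dataset <- function(ds, max_len = max_strand_length()) {
  L <- nchar(ds$s[1])
  k <- nchar(ds$loop[1])
  if (L > max_len) stop("strand length exceeds max_len", call. = FALSE)
  if (any(nchar(ds$s) != L) || any(nchar(ds$s_bar) != L) || any(nchar(ds$loop) != k)) {
    stop("all examples must share one stem length and one loop length", call. = FALSE)
  }
  n <- nrow(ds)
  pad <- matrix(0L, nrow = n, ncol = max_len - L)
  tok <- cbind(pad, strands_to_int(ds$s), strands_to_int(ds$loop),
               strands_to_int(ds$s_bar), pad)
  dimnames(tok) <- NULL
  if ("observed_label" %in% names(ds)) attr(tok, "labels") <- ds$observed_label
  tok
}

#' Encode one example
#'
#' @param s,loop,s_bar Strings giving the stem, apical loop, and second strand.
#' @param max_len Maximum stem length (default 10).
#' @return Integer token vector of length `2 * max_len + nchar(loop)`.
#' @export
encode_example <- function(s, loop, s_bar, max_len = max_strand_length()) {
  tok <- encode_dataset(tibble::tibble(s = s, loop = loop, s_bar = s_bar),
                        max_len = max_len)
  as.integer(tok[1, ])
}
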