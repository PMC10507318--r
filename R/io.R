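#' Export a hairpin dataset to FASTA
#'
#' Writes one record per example; the sequence is the concatenation
#' `s + loop + s_bar` without padding symbols, and the header carries the
#' example index, labels and layout as `id|true=.|obs=.|L=.|loop=.`.
#'
#' @param ds A `hairpin_dataset`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_fasta <- function(ds, path) {
  L <- attr(ds, "L") %||% nchar(ds$s[1])
  k <- attr(ds, "loop_length") %||% nchar(ds$loop[1])
  seqs <- Biostrings::RNAStringSet(paste0(ds$s, ds$loop, ds$s_bar))
  names(seqs) <- sprintf("%d|true=%d|obs=%d|L=%d|loop=%d",
                         ds$id, ds$true_label, ds$observed_label, L, k)
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Import a FASTA file written by [export_fasta()]
#'
#' @param path FASTA file path.
#' @return A `hairpin_dataset` tibble reconstructed from the records.
#' @export
import_fasta <- function(path) {
  seqs <- Biostrings::readRNAStringSet(path)
  hdr <- strsplit(names(seqs), "|", fixed = TRUE)
  field <- function(i, pat) as.integer(sub(pat, "", vapply(hdr, `[[`, "", i)))
  id <- field(1, "^")
  true_label <- field(2, "true=")
  observed_label <- field(3, "obs=")
  L <- field(4, "L=")
  k <- field(5, "loop=")
  if (length(unique(L)) != 1L || length(unique(k)) != 1L) {
    stop("mixed stem or loop lengths in FASTA", call. = FALSE)
  }
  chars <- unname(as.character(seqs))
  tbl <- tibble::tibble(
    id = id,
    s = substr(chars, 1, L[1]),
    loop = substr(chars, L[1] + 1, L[1] + k[1]),
    s_bar = substr(chars, L[1] + k[1] + 1, 2 * L[1] + k[1]),
    true_label = true_label,
    observed_label = observed_label,
    is_mislabelled = true_label != observed_label
  )
  new_hairpin_dataset(tbl, L[1], mean(tbl$true_label),
                      mean(tbl$is_mislabelled) > 0, "train", k[1], NA_integer_)
}

#' Write a hairpin dataset as CSV
#'
#' Columns: `id, s, loop, s_bar, true_label, observed_label`.
#'
#' @param ds A `hairpin_dataset`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_dataset_csv <- function(ds, path) {
  readr::write_csv(
    tibble::as_tibble(ds)[, c("id", "s", "loop", "s_bar",
                              "true_label", "observed_label")],
    path)
  invisible(path)
}

#' Read a hairpin dataset CSV written by [write_dataset_csv()]
#'
#' @param path CSV file path.
#' @param role Dataset role to record on the result (default `"train"`).
#' @return A `hairpin_dataset` tibble.
#' @export
read_dataset_csv <- function(path, role = "train") {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           id = "i", s = "c", loop = "c", s_bar = "c",
                           true_label = "i", observed_label = "i"))
  tbl$is_mislabelled <- tbl$true_label != tbl$observed_label
  new_hairpin_dataset(tbl, nchar(tbl$s[1]), mean(tbl$true_label),
                      mean(tbl$is_mislabelled), role, nchar(tbl$loop[1]),
                      NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
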