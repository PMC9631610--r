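#' GC content and Chargaff parity of nucleotide sequences
#'
#' Computes the GC fraction \eqn{(G + C) / (A + C + G + T)} of one or
#' more sequences together with the within-strand Chargaff parity
#' deviations \eqn{|\%A - \%T|} and \eqn{|\%G - \%C|}. Double-stranded
#' genomes (and many single-stranded viral genomes) have these
#' deviations near zero, which is what licenses summarising base
#' composition by GC content alone (GC% = 100% - AT%).
#'
#' `U` is counted as `T` (RNA input); IUPAC ambiguity codes and `N` are
#' excluded from the denominator; case is ignored.
#'
#' @param sequences Character vector of nucleotide sequences, or a named
#'   vector (names become `seq_id`).
#' @return A tibble with one row per sequence: `seq_id`, `length_used`
#'   (unambiguous bases), `gc` (fraction in `[0, 1]`), `at_parity_dev`
#'   and `gc_parity_dev` (absolute percentage-point deviations).
#' @examples
#' gc_content(c(s1 = "ATGC", s2 = "GGCC"))
#' @export
gc_content <- function(sequences) {
  if (!is.character(sequences) || length(sequences) == 0L) {
    stop("`sequences` must be a non-empty character vector.", call. = FALSE)
  }
  ids <- names(sequences) %||% paste0("seq", seq_along(sequences))
  ids[ids == ""] <- paste0("seq", which(ids == ""))
  rows <- purrr::map2(sequences, ids, function(s, id) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
    n_a <- sum(chars == "A")
    n_t <- sum(chars == "T" | chars == "U")
    n_g <- sum(chars == "G")
    n_c <- sum(chars == "C")
    denom <- n_a + n_t + n_g + n_c
    if (denom == 0L) {
      stop(sprintf("sequence '%s' has no unambiguous A/C/G/T(/U) bases.",
                   id), call. = FALSE)
    }
    tibble::tibble(
      seq_id = id,
      length_used = denom,
      gc = (n_g + n_c) / denom,
      at_parity_dev = abs(n_a - n_t) / denom * 100,
      gc_parity_dev = abs(n_g - n_c) / denom * 100)
  })
  dplyr::bind_rows(rows)
}

#' GC content of a FASTA file
#'
#' Reads a (possibly multi-record) FASTA file and applies [gc_content()]
#' to every record.
#'
#' @param path Path to a FASTA file.
#' @return As [gc_content()], one row per record.
#' @export
gc_content_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  }
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  if (length(recs) == 0L) {
    stop("FASTA file contains no records.", call. = FALSE)
  }
  seqs <- vapply(recs, function(r) as.character(r)[1L], character(1))
  names(seqs) <- names(recs)
  gc_content(seqs)
}
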