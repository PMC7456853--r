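#' Read a FASTA file of miRNA or UTR sequences
#'
#' Sequences are canonicalized to uppercase RNA on ingest (`T` becomes `U`),
#' multi-line records are concatenated, and any description text after the
#' first whitespace in a header is kept separately.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id`, `description`, `seq`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id)) {
    abort(sprintf("duplicate sequence id '%s' in %s (record %d)",
                  id[duplicated(id)][1], path, which(duplicated(id))[1]))
  }
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    abort(sprintf("empty sequence for id '%s' in %s (record %d)",
                  id[!nzchar(seqs)][1], path, which(!nzchar(seqs))[1]))
  }
  tibble(id = unname(id), description = unname(description),
         seq = unname(canonicalize_rna(seqs)))
}

#' Write sequences to a FASTA file
#'
#' Sequences are emitted in the RNA alphabet (U, not T).
#'
#' @param records a data frame with columns `id` and `seq`, and optionally
#'   `description`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  seqs <- canonicalize_rna(records$seq)
  set <- Biostrings::BStringSet(seqs)
  desc <- if ("description" %in% names(records)) records$description
          else rep("", nrow(records))
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
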