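#' Quantify mature miRNAs by exact matching
#'
#' A cleaned small-RNA read increments a mature miRNA's count if and only if
#' the read equals the mature sequence exactly (after canonicalization to
#' uppercase RNA) -- the "no mismatch" rule used for known-miRNA
#' identification.  A read identical to several mature sequences (identical
#' family members) increments every match, so deduplicate mature inputs if
#' that is not wanted.  Reads matching nothing are tallied as unassigned;
#' the library total is the number of input reads (assigned + unassigned),
#' which is the TPM denominator.
#'
#' @param reads_esi,reads_esa data frames of cleaned reads per condition with
#'   a `seq` column (e.g. from [read_fasta()]).
#' @param mature data frame of mature miRNA sequences with `id` and `seq`.
#' @return a [count_table()] with attributes `unassigned_esi`,
#'   `unassigned_esa`.
#' @export
quantify_exact <- function(reads_esi, reads_esa, mature) {
  if (nrow(mature) == 0) abort("empty mature miRNA set")
  mseq <- canonicalize_rna(mature$seq)
  tally <- function(reads) {
    rs <- canonicalize_rna(reads$seq)
    tab <- table(rs)
    counts <- as.integer(tab[mseq])
    counts[is.na(counts)] <- 0L
    assigned <- sum(!is.na(match(rs, mseq)))
    list(counts = counts, total = length(rs),
         unassigned = length(rs) - assigned)
  }
  esi <- tally(reads_esi)
  esa <- tally(reads_esa)
  out <- count_table(
    tibble(mirna_id = mature$id,
           count_esi = esi$counts, count_esa = esa$counts),
    total_esi = max(esi$total, sum(esi$counts)),
    total_esa = max(esa$total, sum(esa$counts)))
  attr(out, "unassigned_esi") <- esi$unassigned
  attr(out, "unassigned_esa") <- esa$unassigned
  out
}

#' Normalize miRNA counts to transcripts per million
#'
#' Adds `tpm_esi` and `tpm_esa` columns using
#' `tpm = count / library_total * 1e6` (mapped reads over total reads, times
#' ten to the sixth).  Counts are unchanged.
#'
#' @param table a [count_table()].
#' @return the table with TPM columns filled.
#' @export
normalize_tpm <- function(table) {
  tot <- library_totals(table)
  if (any(tot <= 0)) abort("zero library total: TPM is undefined")
  table$tpm_esi <- table$count_esi / tot[["esi"]] * 1e6
  table$tpm_esa <- table$count_esa / tot[["esa"]] * 1e6
  table
}

#' Remove low-abundance miRNAs
#'
#' Drops miRNAs whose read count is at or below `min_reads`.  By default the
#' counts of the two libraries are summed before comparison (`pooled`); the
#' `per_library` mode instead requires the count in each library to exceed
#' `min_reads`.
#'
#' @param table a [count_table()].
#' @param min_reads threshold; miRNAs with reads `<= min_reads` are removed
#'   (default 20).
#' @param mode `"pooled"` (default) or `"per_library"`.
#' @return the filtered table, with the removed ids in attribute
#'   `removed_ids`.
#' @export
filter_low_abundance <- function(table, min_reads = 20,
                                 mode = c("pooled", "per_library")) {
  mode <- match.arg(mode)
  keep <- if (mode == "pooled") {
    table$count_esi + table$count_esa > min_reads
  } else {
    table$count_esi > min_reads & table$count_esa > min_reads
  }
  removed <- table$mirna_id[!keep]
  out <- table[keep, , drop = FALSE]
  attr(out, "total_esi") <- attr(table, "total_esi")
  attr(out, "total_esa") <- attr(table, "total_esa")
  attr(out, "removed_ids") <- removed
  class(out) <- class(table)
  out
}
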