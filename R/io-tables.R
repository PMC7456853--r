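#' Construct a two-condition miRNA count table
#'
#' The container behind quantification and miRNA differential expression: one
#' row per miRNA with the mapped-read count in each pooled library
#' (eyestalk-intact `esi`, eyestalk-ablated `esa`).  Library totals -- the
#' "total reads" denominator of the TPM formula -- are carried as attributes
#' so that unassigned reads can be included in the denominator.
#'
#' @param counts data frame with columns `mirna_id`, `count_esi`, `count_esa`.
#' @param total_esi,total_esa positive integer library totals; default to the
#'   column sums.
#' @return a `count_table` tibble.
#' @export
count_table <- function(counts, total_esi = NULL, total_esa = NULL) {
  need <- c("mirna_id", "count_esi", "count_esa")
  miss <- setdiff(need, names(counts))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  for (col in c("count_esi", "count_esa")) {
    v <- counts[[col]]
    if (any(v < 0) || any(v != round(v))) {
      abort(sprintf("field '%s': negative or non-integer count at line %d",
                    col, which(v < 0 | v != round(v))[1]))
    }
  }
  total_esi <- total_esi %||% sum(counts$count_esi)
  total_esa <- total_esa %||% sum(counts$count_esa)
  if (total_esi < sum(counts$count_esi) || total_esa < sum(counts$count_esa)) {
    abort("library totals are smaller than the column sums")
  }
  out <- as_tibble(counts[, intersect(c(need, "tpm_esi", "tpm_esa"), names(counts))])
  attr(out, "total_esi") <- as.numeric(total_esi)
  attr(out, "total_esa") <- as.numeric(total_esa)
  class(out) <- c("count_table", class(out))
  out
}

#' Library totals of a count table
#' @param table a `count_table`.
#' @return named numeric vector with elements `esi` and `esa`.
#' @export
library_totals <- function(table) {
  c(esi = attr(table, "total_esi") %||% sum(table$count_esi),
    esa = attr(table, "total_esa") %||% sum(table$count_esa))
}

#' Read a miRNA count table from a tab-separated file
#'
#' Expected columns: `mirna_id`, `count_esi`, `count_esa`.  An optional
#' leading comment line of the form `# total_esi=<int> total_esa=<int>`
#' supplies library totals; otherwise totals default to the column sums.
#'
#' @param path input path.
#' @return a [count_table()].
#' @export
read_count_table <- function(path) {
  first <- readLines(path, n = 1L)
  totals <- c(NA_real_, NA_real_)
  if (startsWith(first, "#")) {
    m1 <- regmatches(first, regexec("total_esi=([0-9]+)", first))[[1]]
    m2 <- regmatches(first, regexec("total_esa=([0-9]+)", first))[[1]]
    if (length(m1) < 2 || length(m2) < 2) {
      abort("line 1: malformed totals comment (expect total_esi=<int> total_esa=<int>)")
    }
    totals <- as.numeric(c(m1[2], m2[2]))
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  count_table(df,
              total_esi = if (is.na(totals[1])) NULL else totals[1],
              total_esa = if (is.na(totals[2])) NULL else totals[2])
}

#' Write a miRNA count table to a tab-separated file
#'
#' @param table a [count_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  tot <- library_totals(table)
  writeLines(sprintf("# total_esi=%.0f total_esa=%.0f", tot[["esi"]], tot[["esa"]]),
             path)
  readr::write_tsv(as_tibble(table), path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Load the published differential-expression tables
#'
#' Returns the two machine-readable tables packaged with mirpronet: the
#' annotated differentially expressed proteins (accession, name, ESA/ESI fold
#' change) and the miRNA-protein pairs of the published inverse-correlation
#' network (miRNA, miRNA fold change, target protein, protein fold change).
#' Continuation rows of the printed pair table are already expanded so every
#' row is self-contained; a protein accession is joined onto the pair table
#' where the protein name matches the protein table uniquely.
#'
#' @return a list with tibbles `table1` and `table2`.
#' @export
load_paper_tables <- function() {
  t1 <- readr::read_tsv(
    system.file("extdata", "table1_de_proteins.tsv", package = "mirpronet"),
    show_col_types = FALSE, progress = FALSE)
  t2 <- readr::read_tsv(
    system.file("extdata", "table2_network_pairs.tsv", package = "mirpronet"),
    show_col_types = FALSE, progress = FALSE)
  stopifnot(all(t1$fold_change > 0), all(t2$mirna_fc > 0), all(t2$protein_fc > 0))
  bad <- sign(log(t2$mirna_fc)) * sign(log(t2$protein_fc)) >= 0
  if (any(bad)) {
    abort(sprintf("pair table row %d violates the inverse-direction invariant",
                  which(bad)[1]))
  }
  name_counts <- table(t1$name)
  unique_names <- names(name_counts)[name_counts == 1]
  acc <- setNames(t1$accession, t1$name)
  t2$accession <- ifelse(t2$protein %in% unique_names, acc[t2$protein], NA_character_)
  list(table1 = t1, table2 = t2)
}
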