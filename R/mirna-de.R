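#' Conditional exact binomial test for two pooled libraries
#'
#' Tests whether a miRNA's reads are split between two libraries in
#' proportion to the library sizes.  Conditional on the miRNA's total
#' `n = k1 + k2`, `k1` is Binomial(n, p0) with `p0 = n1 / (n1 + n2)` under
#' the null of equal concentration; the two-sided p-value sums the
#' probability of every outcome no more likely than the observed one (the
#' minimum-likelihood rule, the small-count exact behaviour of two-library
#' count DE tests).  Vectorized over `k1`, `k2`.
#'
#' @param k1,k2 per-library read counts for the miRNA.
#' @param n1,n2 library totals.
#' @return numeric vector of two-sided p-values.  Entries with
#'   `k1 + k2 == 0` are undefined and returned as 1, flagged in the logical
#'   attribute `undefined`.
#' @export
binomial_test <- function(k1, k2, n1, n2) {
  stopifnot(all(n1 >= 1), all(n2 >= 1))
  k1 <- as.numeric(k1); k2 <- as.numeric(k2)
  df <- tibble(k1 = k1, k2 = k2, n1 = n1, n2 = n2)
  p <- purrr::pmap_dbl(df, function(k1, k2, n1, n2) {
    if (k1 + k2 == 0) return(1)
    stats::binom.test(k1, k1 + k2, p = n1 / (n1 + n2))$p.value
  })
  attr(p, "undefined") <- (k1 + k2) == 0
  p
}

#' TPM fold change between conditions
#'
#' `fc = (tpm_esa + pseudocount) / (tpm_esi + pseudocount)`, reported as
#' ablated over intact.  The pseudocount (in TPM units) guards against
#' division by zero; it must be positive whenever a zero TPM occurs.
#'
#' @param tpm_esa,tpm_esi normalized expression per condition.
#' @param pseudocount_tpm pseudocount added to both terms (default 0).
#' @return positive fold changes.
#' @export
fold_change <- function(tpm_esa, tpm_esi, pseudocount_tpm = 0) {
  if (any(tpm_esa + pseudocount_tpm == 0 & tpm_esi + pseudocount_tpm == 0)) {
    abort("both TPM values are zero and the pseudocount is zero")
  }
  if (any(tpm_esi + pseudocount_tpm == 0)) {
    abort("zero denominator TPM; supply a positive pseudocount")
  }
  (tpm_esa + pseudocount_tpm) / (tpm_esi + pseudocount_tpm)
}

# Storey-style q-values with pi0 estimated at a single lambda
storey_qvalue <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  o <- order(p, decreasing = TRUE)
  q <- pi0 * p * m / rank(p, ties.method = "max")
  q[o] <- cummin(q[o])
  pmin(q, 1)
}

#' Call differentially expressed miRNAs between two pooled libraries
#'
#' Computes TPM fold changes (ablated over intact), per-miRNA conditional
#' exact binomial p-values, multiplicity-adjusted q-values, and a
#' significance call.  Two published threshold profiles are offered:
#' `"methods"` (default) requires `q < q_max` and `|log2 fold change| >
#' min_abs_log2fc`; `"results"` requires `p < 0.05` and fold change at least
#' 2 (or at most 1/2).
#'
#' @param table a normalized, filtered [count_table()].
#' @param profile `"methods"` or `"results"` threshold profile.
#' @param q_max,min_abs_log2fc thresholds for the methods profile
#'   (defaults 0.01 and 1).
#' @param pseudocount_reads reads added to both raw counts (before the TPM
#'   ratio) for miRNAs where either count is zero (default 0.5).
#' @param q_method `"BH"` (Benjamini-Hochberg, default) or `"storey"`.
#' @return a tibble with columns `mirna_id`, `count_esi`, `count_esa`,
#'   `tpm_esi`, `tpm_esa`, `fc`, `log2fc`, `p`, `q`, `direction`,
#'   `significant`.
#' @export
call_de_mirnas <- function(table, profile = c("methods", "results"),
                           q_max = 0.01, min_abs_log2fc = 1,
                           pseudocount_reads = 0.5,
                           q_method = c("BH", "storey")) {
  profile <- match.arg(profile)
  q_method <- match.arg(q_method)
  if (nrow(table) == 0) {
    return(tibble(mirna_id = character(), count_esi = numeric(),
                  count_esa = numeric(), tpm_esi = numeric(),
                  tpm_esa = numeric(), fc = numeric(), log2fc = numeric(),
                  p = numeric(), q = numeric(), direction = character(),
                  significant = logical()))
  }
  if (!"tpm_esi" %in% names(table)) table <- normalize_tpm(table)
  tot <- library_totals(table)

  zero <- table$count_esi == 0 | table$count_esa == 0
  adj_esi <- table$count_esi + ifelse(zero, pseudocount_reads, 0)
  adj_esa <- table$count_esa + ifelse(zero, pseudocount_reads, 0)
  if (any(adj_esi == 0 & adj_esa == 0)) {
    abort("miRNA with zero counts in both libraries and zero pseudocount")
  }
  fc <- (adj_esa / tot[["esa"]]) / (adj_esi / tot[["esi"]])
  log2fc <- log2(fc)

  p <- as.numeric(binomial_test(table$count_esa, table$count_esi,
                                tot[["esa"]], tot[["esi"]]))
  q <- if (q_method == "BH") stats::p.adjust(p, "BH") else storey_qvalue(p)

  significant <- if (profile == "methods") {
    q < q_max & abs(log2fc) > min_abs_log2fc
  } else {
    p < 0.05 & (fc >= 2 | fc <= 0.5)
  }
  direction <- dplyr::case_when(
    log2fc > 0 ~ "up",
    log2fc < 0 ~ "down",
    .default = "none")

  tibble(mirna_id = table$mirna_id,
         count_esi = table$count_esi, count_esa = table$count_esa,
         tpm_esi = table$tpm_esi, tpm_esa = table$tpm_esa,
         fc = fc, log2fc = log2fc, p = p, q = q,
         direction = direction, significant = significant)
}
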