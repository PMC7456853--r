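#' Classify a protein fold change into a regulation direction
#'
#' A protein counts as upregulated when `fc >= fc_threshold` and as
#' downregulated when `fc <= 1 / fc_threshold`; the criterion is symmetric so
#' that, at the default 1.2, down-regulation means `fc <= 0.8333`.
#'
#' @param fc positive fold changes (ablated over intact).
#' @param fc_threshold threshold, default 1.2.
#' @return character vector: `"up"`, `"down"`, or `"none"`.
#' @export
classify_by_fc <- function(fc, fc_threshold = 1.2) {
  if (any(fc <= 0)) abort("fold change must be positive")
  dplyr::case_when(fc >= fc_threshold ~ "up",
                   fc <= 1 / fc_threshold ~ "down",
                   .default = "none")
}

# Welch two-sample t on log2 abundances; zero-variance groups are handled
# explicitly (identical means -> p = 1, distinct means -> p = 0)
welch_p <- function(x, y) {
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Call differentially expressed proteins
#'
#' Two input modes. In `"fc"` mode the table already carries one fold change
#' per protein (a published-style ratio table); significance is inherited
#' from the upstream quantification (such tables list only proteins that
#' passed it), so every row with a non-`"none"` direction is flagged
#' significant and the result carries attribute `passthrough_significance`.
#' In `"replicates"` mode the table holds per-replicate log2 abundances for
#' the two groups; each protein gets a Welch two-sample t-test, fold change
#' `2^(mean difference)`, and Benjamini-Hochberg q-values across proteins.
#'
#' @param table for `"fc"` mode, a data frame with `protein_id` and `fc`
#'   (optional `name`); for `"replicates"` mode, a long data frame with
#'   `protein_id`, `condition` (`"esi"`/`"esa"`), `replicate`, and
#'   `log2_abundance`.
#' @param mode `"fc"` or `"replicates"`.
#' @param fc_threshold fold-change threshold (default 1.2).
#' @param q_max adjusted-significance threshold for the methods profile
#'   (default 0.05).
#' @param profile `"methods"` (q-based, default) or `"results"` (raw
#'   `p < 0.05`), mirroring the two published phrasings of the criterion.
#' @return a tibble with `protein_id`, `fc`, `log2fc`, `p`, `q`,
#'   `direction`, `significant` (plus `name` when supplied).
#' @export
call_de_proteins <- function(table, mode = c("fc", "replicates"),
                             fc_threshold = 1.2, q_max = 0.05,
                             profile = c("methods", "results")) {
  mode <- match.arg(mode)
  profile <- match.arg(profile)

  if (mode == "fc") {
    direction <- classify_by_fc(table$fc, fc_threshold)
    out <- tibble(protein_id = table$protein_id, fc = table$fc,
                  log2fc = log2(table$fc), p = NA_real_, q = NA_real_,
                  direction = direction, significant = direction != "none")
    if ("name" %in% names(table)) out$name <- table$name
    attr(out, "passthrough_significance") <- TRUE
    return(out)
  }

  need <- c("protein_id", "condition", "log2_abundance")
  miss <- setdiff(need, names(table))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  nrep <- dplyr::count(table, .data$protein_id, .data$condition)
  if (any(nrep$n < 2)) {
    abort("replicates mode needs at least 2 replicates per group per protein")
  }
  out <- table |>
    dplyr::summarise(
      fc = 2^(mean(.data$log2_abundance[.data$condition == "esa"]) -
                mean(.data$log2_abundance[.data$condition == "esi"])),
      p = welch_p(.data$log2_abundance[.data$condition == "esa"],
                  .data$log2_abundance[.data$condition == "esi"]),
      .by = "protein_id")
  out$log2fc <- log2(out$fc)
  out$q <- stats::p.adjust(out$p, "BH")
  out$direction <- classify_by_fc(out$fc, fc_threshold)
  out$significant <- if (profile == "methods") {
    out$q <= q_max & out$direction != "none"
  } else {
    out$p < 0.05 & out$direction != "none"
  }
  out[, c("protein_id", "fc", "log2fc", "p", "q", "direction", "significant")]
}

#' Share of differentially expressed features in one direction
#'
#' The percentage summary used to report results such as "132 of 163 DE
#' proteins (80.98%) were upregulated".
#'
#' @param n_direction number of DE features in the direction of interest.
#' @param n_total total number of DE features.
#' @param digits decimal places (default 2).
#' @return percentage, rounded.
#' @export
de_direction_share <- function(n_direction, n_total, digits = 2) {
  stopifnot(n_total > 0, n_direction >= 0, n_direction <= n_total)
  round(100 * n_direction / n_total, digits)
}
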