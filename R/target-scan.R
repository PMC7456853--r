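#' Scanner parameters for miRNA target prediction
#'
#' Parameterizes the seed-weighted, G:U-aware local alignment used to find
#' candidate miRNA binding sites in 3'UTRs (a miRanda-style scanner without
#' the thermodynamic filter).  Pair scores are per alignment column:
#' Watson-Crick `wc_score`, G:U wobble `gu_score`, other pairs
#' `mismatch_score`; gaps are affine (`gap_open` for the first gap column of
#' a run, `gap_extend` for each further column).  Columns whose miRNA base
#' lies in the seed region (positions `seed_start`..`seed_end`, 1-based from
#' the miRNA 5' end) have their pair score multiplied by `seed_weight`; gap
#' columns are never weighted.  Only sites scoring at least
#' `score_threshold` are reported.
#'
#' @param wc_score,gu_score,mismatch_score per-column pair scores
#'   (defaults +5, +1, -3).
#' @param gap_open,gap_extend affine gap penalties (defaults -9, -4).
#' @param seed_start,seed_end seed region bounds (defaults 2 and 8).
#' @param seed_weight multiplier on seed-column pair scores (default 2).
#' @param score_threshold minimum reported site score (default 140).
#' @param require_strict_seed if `TRUE`, additionally demand six contiguous
#'   Watson-Crick pairs at miRNA positions 2-7 (default `FALSE`).
#' @return a `scan_params` list.
#' @export
scan_params <- function(wc_score = 5L, gu_score = 1L, mismatch_score = -3L,
                        gap_open = -9L, gap_extend = -4L,
                        seed_start = 2L, seed_end = 8L, seed_weight = 2L,
                        score_threshold = 140L,
                        require_strict_seed = FALSE) {
  stopifnot(wc_score > gu_score, gu_score > 0, mismatch_score < 0,
            gap_open <= gap_extend, gap_extend < 0, score_threshold > 0,
            seed_start >= 1, seed_end >= seed_start, seed_weight >= 1)
  structure(list(wc_score = as.integer(wc_score),
                 gu_score = as.integer(gu_score),
                 mismatch_score = as.integer(mismatch_score),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 seed_start = as.integer(seed_start),
                 seed_end = as.integer(seed_end),
                 seed_weight = as.integer(seed_weight),
                 score_threshold = as.integer(score_threshold),
                 require_strict_seed = isTRUE(require_strict_seed)),
            class = "scan_params")
}

#' One-line fingerprint of scanner parameters
#' @param params a [scan_params()] object.
#' @return a single string recording every parameter.
#' @export
params_fingerprint <- function(params) {
  paste(vapply(names(params),
               function(nm) paste0(nm, "=", params[[nm]]), character(1)),
        collapse = " ")
}

pair_score_r <- function(m, u, params) {
  code <- function(b) match(b, c("A", "C", "G", "U")) - 1L
  s <- code(m) + code(u)
  if (s == 3) params$wc_score
  else if (s == 5) params$gu_score
  else params$mismatch_score
}

#' Score a gapped miRNA/UTR alignment
#'
#' Recomputes the scanner score of an explicit alignment.  The two strings
#' must have equal length and no column may hold two gaps.  `mirna_aln` is
#' read 5'->3' and `utr_aln` 3'->5', so paired columns are antiparallel as
#' in a duplex.  Seed positions are counted over non-gap miRNA bases from
#' the miRNA 5' end.
#'
#' @param mirna_aln,utr_aln gapped aligned strings over `A`,`C`,`G`,`U`,`-`.
#' @param params a [scan_params()] object.
#' @param mirna_start 1-based miRNA position (from the 5' end of the full
#'   miRNA) of the first aligned miRNA base.  Local alignments need not
#'   cover the whole miRNA, and seed weighting follows absolute positions;
#'   the default 1 scores a full-length alignment.
#' @return integer alignment score.
#' @export
score_alignment <- function(mirna_aln, utr_aln, params = scan_params(),
                            mirna_start = 1L) {
  m <- strsplit(canonicalize_rna(gsub("-", "N", mirna_aln)), "", fixed = TRUE)[[1]]
  u <- strsplit(canonicalize_rna(gsub("-", "N", utr_aln)), "", fixed = TRUE)[[1]]
  m[m == "N"] <- "-"; u[u == "N"] <- "-"
  if (length(m) != length(u)) abort("aligned strings differ in length")
  if (any(m == "-" & u == "-")) abort("column with two gaps")
  score <- 0L
  pos <- as.integer(mirna_start) - 1L  # miRNA position, 1-based from the 5' end
  prev_gap <- ""            # which side the previous column's gap was on
  for (k in seq_along(m)) {
    if (m[k] == "-") {
      score <- score + if (prev_gap == "m") params$gap_extend else params$gap_open
      prev_gap <- "m"
    } else if (u[k] == "-") {
      pos <- pos + 1L
      score <- score + if (prev_gap == "u") params$gap_extend else params$gap_open
      prev_gap <- "u"
    } else {
      pos <- pos + 1L
      w <- if (pos >= params$seed_start && pos <= params$seed_end)
        params$seed_weight else 1L
      score <- score + w * pair_score_r(m[k], u[k], params)
      prev_gap <- ""
    }
  }
  as.integer(score)
}

# TRUE when miRNA positions 2..7 are six contiguous Watson-Crick columns
strict_seed_ok <- function(mirna_aln, utr_aln, mirna_start = 1L) {
  m <- strsplit(mirna_aln, "", fixed = TRUE)[[1]]
  u <- strsplit(utr_aln, "", fixed = TRUE)[[1]]
  pos <- mirna_start - 1L + cumsum(m != "-")
  idx <- which(pos >= 2 & pos <= 6 + 1 & m != "-")
  idx <- idx[pos[idx] <= 7]
  if (length(idx) < 6) return(FALSE)
  if (any(diff(idx) != 1)) return(FALSE)
  code <- function(b) match(b, c("A", "C", "G", "U")) - 1L
  all(u[idx] != "-") && all(code(m[idx]) + code(u[idx]) == 3)
}

greedy_select <- function(cand) {
  if (nrow(cand) == 0) return(cand)
  cand <- cand[order(-cand$score, cand$utr_start, cand$utr_end), , drop = FALSE]
  taken_start <- integer(0); taken_end <- integer(0)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    s <- cand$utr_start[r]; e <- cand$utr_end[r]
    if (!any(s <= taken_end & e >= taken_start)) {
      keep[r] <- TRUE
      taken_start <- c(taken_start, s); taken_end <- c(taken_end, e)
    }
  }
  cand[keep, , drop = FALSE]
}

#' Scan one miRNA against one 3'UTR
#'
#' Local dynamic-programming alignment of the miRNA (antiparallel) against
#' the UTR under the column rules of [score_alignment()].  All
#' non-overlapping locally maximal sites with score at or above the
#' threshold are returned, best first (ties broken towards the leftmost UTR
#' start); overlap resolution is greedy by descending score.
#'
#' @param mirna_seq,utr_seq RNA sequences (canonicalized on entry).
#' @param params a [scan_params()] object.
#' @param mirna_id,utr_id identifiers carried into the result.
#' @return a tibble of target hits with columns `mirna_id`, `utr_id`,
#'   `score`, `utr_start`, `utr_end` (1-based inclusive, UTR 5'->3'),
#'   `mirna_start`, `mirna_end` (1-based from the miRNA 5' end), `n_wc`,
#'   `n_gu`, `n_gaps`, `mirna_aln` (5'->3'), `utr_aln` (3'->5').
#' @export
scan_pair <- function(mirna_seq, utr_seq, params = scan_params(),
                      mirna_id = "mirna", utr_id = "utr") {
  mirna_seq <- canonicalize_rna(mirna_seq)
  utr_seq <- canonicalize_rna(utr_seq)
  if (nchar(mirna_seq) < 8) abort("miRNA shorter than 8 nt")
  mir <- encode_rna(mirna_seq)
  m <- length(mir)
  mir_rev <- rev(mir)
  pos_of_row <- m - seq_len(m) + 1L
  weights <- ifelse(pos_of_row >= params$seed_start &
                      pos_of_row <= params$seed_end,
                    params$seed_weight, 1L)
  raw <- cpp_scan_pair(mir_rev, encode_rna(utr_seq), as.integer(weights),
                       params$wc_score, params$gu_score,
                       params$mismatch_score, params$gap_open,
                       params$gap_extend, params$score_threshold)
  cand <- as_tibble(raw)
  if (nrow(cand) > 0 && params$require_strict_seed) {
    ok <- mapply(strict_seed_ok, cand$mirna_aln, cand$utr_aln,
                 cand$mirna_start)
    cand <- cand[ok, , drop = FALSE]
  }
  hits <- greedy_select(cand)
  out <- tibble(mirna_id = rep(mirna_id, nrow(hits)),
                utr_id = rep(utr_id, nrow(hits)))
  dplyr::bind_cols(out, hits[, c("score", "utr_start", "utr_end",
                                 "mirna_start", "mirna_end", "n_wc",
                                 "n_gu", "n_gaps", "mirna_aln", "utr_aln")])
}

#' Scan many miRNAs against many 3'UTRs
#'
#' Applies [scan_pair()] to every miRNA/UTR combination.  With
#' `best_per_pair = TRUE` (the target-map form used for network
#' construction) only the best-scoring hit of each pair is kept.
#'
#' @param mirnas,utrs data frames with `id` and `seq` columns.
#' @param params a [scan_params()] object.
#' @param best_per_pair keep only the top hit per (miRNA, UTR) pair.
#' @return a tibble of hits as in [scan_pair()], with attribute
#'   `params_fingerprint`.
#' @export
scan_targets <- function(mirnas, utrs, params = scan_params(),
                         best_per_pair = TRUE) {
  res <- purrr::map(seq_len(nrow(mirnas)), function(i) {
    purrr::map(seq_len(nrow(utrs)), function(j) {
      scan_pair(mirnas$seq[i], utrs$seq[j], params,
                mirna_id = mirnas$id[i], utr_id = utrs$id[j])
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  if (is.null(res) || nrow(res) == 0) {
    res <- tibble(mirna_id = character(), utr_id = character(),
                  score = integer(), utr_start = integer(),
                  utr_end = integer(), mirna_start = integer(),
                  mirna_end = integer(), n_wc = integer(),
                  n_gu = integer(), n_gaps = integer(),
                  mirna_aln = character(), utr_aln = character())
  }
  if (best_per_pair && nrow(res) > 0) {
    res <- res |>
      dplyr::arrange(dplyr::desc(.data$score), .data$utr_start) |>
      dplyr::distinct(.data$mirna_id, .data$utr_id, .keep_all = TRUE) |>
      dplyr::arrange(.data$mirna_id, .data$utr_id)
  }
  attr(res, "params_fingerprint") <- params_fingerprint(params)
  res
}

#' Write target hits to a tab-separated file
#'
#' The scanner parameter fingerprint is recorded as a leading comment line.
#'
#' @param hits a hit tibble from [scan_targets()] or [scan_pair()].
#' @param path output path.
#' @param params the [scan_params()] the hits were produced with; defaults
#'   to the fingerprint stored on `hits`.
#' @return `path`, invisibly.
#' @export
write_target_hits <- function(hits, path, params = NULL) {
  fp <- if (!is.null(params)) params_fingerprint(params)
        else attr(hits, "params_fingerprint") %||% ""
  writeLines(paste("# scan_params:", fp), path)
  readr::write_tsv(hits, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}
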