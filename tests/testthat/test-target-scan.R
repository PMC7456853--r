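rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                              collapse = "")
# partner that is neither Watson-Crick nor G:U for each base
mismatch_of <- c(A = "C", C = "A", G = "A", U = "C")

test_that("scan_params enforces its invariants", {
  expect_error(scan_params(gu_score = 6))         # wobble must score below WC
  expect_error(scan_params(gap_extend = 1))       # gap penalties negative
  expect_error(scan_params(gap_open = -2, gap_extend = -4))  # open <= extend
  expect_error(scan_params(score_threshold = 0))
  fp <- params_fingerprint(scan_params())
  expect_match(fp, "wc_score=5")
  expect_match(fp, "score_threshold=140")
})

test_that("a perfect full-length site scores 5L + 35", {
  set.seed(41)
  low <- scan_params(score_threshold = 1)
  for (L in 8:24) {
    m <- rand_rna(L)
    hits <- scan_pair(m, reverse_complement(m), low)
    expect_equal(max(hits$score), 5L * L + 35L)
    best <- hits[which.max(hits$score), ]
    expect_equal(best$n_wc, L)
    expect_equal(best$n_gu, 0L)
    expect_equal(best$n_gaps, 0L)
  }
})

test_that("the default threshold admits 21-nt but not 20-nt perfect sites", {
  set.seed(42)
  m20 <- rand_rna(20); m21 <- rand_rna(21)
  pad <- function(core) paste0(rand_rna(30), core, rand_rna(30))
  expect_equal(nrow(scan_pair(m20, pad(reverse_complement(m20)))), 0)
  h21 <- scan_pair(m21, pad(reverse_complement(m21)))
  expect_gte(nrow(h21), 1)
  expect_equal(max(h21$score), 140L)
})

test_that("score_alignment applies seed weights, wobbles and affine gaps", {
  p <- scan_params()
  # 4 Watson-Crick columns; position 1 unweighted, 2-4 doubled
  expect_equal(score_alignment("ACGU", "UGCA", p), 5L + 3L * 10L)
  # single-column gap costs gap_open
  expect_equal(score_alignment("AC-GU", "UGACA", p), 35L - 9L)
  # a two-column gap run costs open + extend
  expect_equal(score_alignment("AC--GU", "UGAACA", p), 35L - 9L - 4L)
  # G:U wobble at an unweighted position (miRNA position 11, outside 2-8)
  expect_equal(score_alignment("ACGUACGUACGUA", "UGCAUGCAUGUAU", p),
               score_alignment("ACGUACGUACGUA", "UGCAUGCAUGCAU", p) - 4L)
  # the same wobble inside the seed costs twice as much
  expect_equal(score_alignment("ACGUACGUACGUA", "UGUAUGCAUGCAU", p),
               score_alignment("ACGUACGUACGUA", "UGCAUGCAUGCAU", p) - 8L)
  expect_error(score_alignment("AC", "UGA", p), "length")
  expect_error(score_alignment("A-C", "U-G", p), "two gaps")
})

test_that("every reported hit's score is reproduced by score_alignment", {
  set.seed(43)
  low <- scan_params(score_threshold = 40)
  for (i in 1:20) {
    m <- rand_rna(sample(19:23, 1))
    u <- rand_rna(300)
    hits <- scan_pair(m, u, low)
    for (r in seq_len(nrow(hits))) {
      expect_equal(score_alignment(hits$mirna_aln[r], hits$utr_aln[r], low,
                                   mirna_start = hits$mirna_start[r]),
                   hits$score[r])
      # reported site substring matches the UTR-side alignment
      site <- substr(u, hits$utr_start[r], hits$utr_end[r])
      aln_u <- gsub("-", "", hits$utr_aln[r])
      expect_equal(paste(rev(strsplit(aln_u, "")[[1]]), collapse = ""), site)
    }
  }
})

test_that("reported sites within a pair never overlap", {
  set.seed(44)
  low <- scan_params(score_threshold = 40)
  m <- rand_rna(21)
  u <- paste0(rand_rna(50), reverse_complement(m), rand_rna(50),
              reverse_complement(m), rand_rna(50))
  hits <- scan_pair(m, u, low)
  expect_gte(nrow(hits), 2)
  hits <- hits[order(hits$utr_start), ]
  expect_true(all(hits$utr_start[-1] > hits$utr_end[-nrow(hits)]))
  # the two planted copies are both recovered at full score
  expect_equal(sum(hits$score == 5L * 21L + 35L), 2)
})

test_that("a wobble in the site lowers the score by the pair-score gap", {
  m <- "ACGUACGUAGGUACGUACGUA"     # position 10 is G
  u <- reverse_complement(m)
  substr(u, 12, 12) <- "U"          # pairs miRNA position 10 as G:U
  hits <- scan_pair(m, u, scan_params(score_threshold = 50))
  expect_equal(max(hits$score), (5L * 21L + 35L) - 4L)
  expect_equal(hits$n_gu[which.max(hits$score)], 1L)
})

test_that("strict seed filtering rejects a seed mismatch", {
  set.seed(45)
  m <- rand_rna(21)
  u <- reverse_complement(m)
  substr(u, 19, 19) <- mismatch_of[[substr(m, 3, 3)]]  # breaks seed pos 3
  p_off <- scan_params(score_threshold = 50)
  p_on <- scan_params(score_threshold = 50, require_strict_seed = TRUE)
  h_off <- scan_pair(m, u, p_off)
  # the in-register site loses one weighted seed pair: 2*(5 + 3) = 16
  expect_equal(max(h_off$score), (5L * 21L + 35L) - 16L)
  h_on <- scan_pair(m, u, p_on)
  # any surviving hit must satisfy the strict rule and cannot be the
  # in-register mismatch alignment
  if (nrow(h_on) > 0) {
    expect_true(all(mapply(mirpronet:::strict_seed_ok, h_on$mirna_aln,
                           h_on$utr_aln, h_on$mirna_start)))
    expect_lt(max(h_on$score), max(h_off$score))
  }
  # an intact site passes the strict filter at full score
  h_ok <- scan_pair(m, reverse_complement(m), p_on)
  expect_equal(max(h_ok$score), 5L * 21L + 35L)
})

test_that("scan_pair validates the miRNA length", {
  expect_error(scan_pair("ACGUACG", rand_rna(50)), "shorter than 8")
})

test_that("scan_targets keeps the best hit per pair and fingerprints", {
  set.seed(46)
  m1 <- rand_rna(21); m2 <- rand_rna(22)
  mirnas <- tibble::tibble(id = c("m1", "m2"), seq = c(m1, m2))
  utrs <- tibble::tibble(
    id = c("u1", "u2"),
    seq = c(paste0(rand_rna(40), reverse_complement(m1), rand_rna(40)),
            rand_rna(120)))
  hits <- scan_targets(mirnas, utrs)
  expect_lte(nrow(dplyr::distinct(hits, mirna_id, utr_id)), nrow(hits) + 0)
  expect_equal(nrow(hits), nrow(dplyr::distinct(hits, mirna_id, utr_id)))
  expect_true(any(hits$mirna_id == "m1" & hits$utr_id == "u1"))
  expect_match(attr(hits, "params_fingerprint"), "score_threshold=140")
  all_hits <- scan_targets(mirnas, utrs, scan_params(score_threshold = 40),
                           best_per_pair = FALSE)
  expect_gte(nrow(all_hits), nrow(hits))
})

test_that("target hits serialize with a parameter fingerprint header", {
  set.seed(47)
  m <- rand_rna(21)
  hits <- scan_targets(tibble::tibble(id = "m", seq = m),
                       tibble::tibble(id = "u",
                                      seq = paste0(rand_rna(20),
                                                   reverse_complement(m),
                                                   rand_rna(20))))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_target_hits(hits, f)
  expect_match(readLines(f, n = 1), "^# scan_params: wc_score=5")
  back <- readr::read_tsv(f, comment = "#", show_col_types = FALSE)
  expect_equal(back$score, hits$score)
  expect_equal(back$utr_start, hits$utr_start)
})

test_that("the DP scanner agrees with the brute-force enumerator", {
  # unit-scale version (50 pairs); the full 200-pair run is in the
  # acceptance suite
  set.seed(48)
  for (k in 1:50) {
    ml <- sample(8:15, 1); ul <- sample(8:15, 1)
    ms <- rand_rna(ml); us <- rand_rna(ul)
    mir_rev <- rev(mirpronet:::encode_rna(ms))
    w <- ifelse((ml - seq_len(ml) + 1L) %in% 2:8, 2L, 1L)
    u <- mirpronet:::encode_rna(us)
    raw <- mirpronet:::cpp_scan_pair(mir_rev, u, w, 5L, 1L, -3L, -9L, -4L, 1L)
    if (length(raw$score) == 0) next
    gaps <- raw$n_gaps[which.max(raw$score)]
    e <- mirpronet:::cpp_enum_best(mir_rev, u, w, 5L, 1L, -3L, -9L, -4L,
                                   max(2L, gaps))
    expect_equal(max(raw$score), max(e, na.rm = TRUE))
  }
})
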