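test_that("identical configurations generate identical studies", {
  a <- simulate_study(synth_config(seed = 5, n_mirnas = 20, n_proteins = 30,
                                   n_de_mirnas = 3, n_de_proteins = 4))
  b <- simulate_study(synth_config(seed = 5, n_mirnas = 20, n_proteins = 30,
                                   n_de_mirnas = 3, n_de_proteins = 4))
  expect_identical(a, b)
  c <- simulate_study(synth_config(seed = 6, n_mirnas = 20, n_proteins = 30,
                                   n_de_mirnas = 3, n_de_proteins = 4))
  expect_false(identical(a$counts, c$counts))
})

test_that("planted sites are the reverse complement at recorded coordinates", {
  st <- simulate_study(synth_config(seed = 9, n_mirnas = 20, n_proteins = 30,
                                    n_de_mirnas = 3, n_de_proteins = 5))
  ed <- st$truth$edges
  expect_equal(nrow(ed), 5)
  for (r in seq_len(nrow(ed))) {
    mseq <- st$mirnas$seq[st$mirnas$id == ed$mirna_id[r]]
    useq <- st$utrs$seq[st$utrs$id == ed$utr_id[r]]
    expect_equal(substr(useq, ed$site_start[r], ed$site_end[r]),
                 reverse_complement(mseq))
  }
})

test_that("the scanner detects every planted site at default thresholds", {
  st <- simulate_study(synth_config(seed = 9, n_mirnas = 20, n_proteins = 30,
                                    n_de_mirnas = 3, n_de_proteins = 5))
  ed <- st$truth$edges
  for (r in seq_len(nrow(ed))) {
    mseq <- st$mirnas$seq[st$mirnas$id == ed$mirna_id[r]]
    useq <- st$utrs$seq[st$utrs$id == ed$utr_id[r]]
    hits <- scan_pair(mseq, useq)
    expect_gte(nrow(hits), 1)
    best <- hits[1, ]
    expect_equal(best$score, 5L * nchar(mseq) + 35L)
    expect_lte(best$utr_start, ed$site_start[r])
    expect_gte(best$utr_end, ed$site_end[r])
  }
})

test_that("noiseless counts equal their means exactly", {
  cfg <- synth_config(seed = 4, n_mirnas = 15, n_proteins = 20,
                      n_de_mirnas = 2, n_de_proteins = 2, noiseless = TRUE)
  st <- simulate_study(cfg)
  lfc <- setNames(rep(0, 15), st$counts$mirna_id)
  lfc[st$truth$de_mirnas$mirna_id] <- st$truth$de_mirnas$log2fc
  expect_equal(st$counts$count_esi, rep(150, 15))
  expect_equal(st$counts$count_esa, round(150 * 2^unname(lfc)))
})

test_that("noiseless protein group-mean ratio equals the planted fold change", {
  cfg <- synth_config(seed = 4, n_mirnas = 15, n_proteins = 20,
                      n_de_mirnas = 2, n_de_proteins = 3, noiseless = TRUE)
  st <- simulate_study(cfg)
  means <- st$proteins |>
    dplyr::summarise(m = mean(log2_abundance),
                     .by = c(protein_id, condition)) |>
    tidyr::pivot_wider(names_from = condition, values_from = m)
  means$ratio <- 2^(means$esa - means$esi)
  tr <- st$truth$de_proteins
  for (r in seq_len(nrow(tr))) {
    expect_equal(means$ratio[means$protein_id == tr$protein_id[r]],
                 2^tr$log2fc[r])
  }
  expect_equal(means$ratio[!means$protein_id %in% tr$protein_id],
               rep(1, 20 - 3))
})

test_that("the default configuration supports >= 80% protein recall at seed 42", {
  st <- simulate_study(synth_config(seed = 42))
  de <- call_de_proteins(st$proteins, mode = "replicates")
  planted <- st$truth$de_proteins$protein_id
  recall <- mean(de$significant[match(planted, de$protein_id)])
  expect_gte(recall, 0.8)
})

test_that("planted miRNA directions follow the down fraction", {
  st <- generate_sequences(synth_config(seed = 3))
  expect_equal(sum(st$truth$de_mirnas$log2fc < 0), 8)  # round(0.75 * 10)
  expect_equal(sum(st$truth$de_mirnas$log2fc > 0), 2)
  expect_true(all(abs(st$truth$de_mirnas$log2fc) >= 1.5))
  expect_true(all(abs(st$truth$de_mirnas$log2fc) <= 3))
})

test_that("coupled proteins respond inversely with the coupling strength", {
  st <- generate_sequences(synth_config(seed = 3))
  ed <- st$truth$edges
  m_lfc <- setNames(st$truth$de_mirnas$log2fc, st$truth$de_mirnas$mirna_id)
  p_lfc <- setNames(st$truth$de_proteins$log2fc, st$truth$de_proteins$protein_id)
  expect_equal(unname(p_lfc[ed$protein_id]), -0.3 * unname(m_lfc[ed$mirna_id]))
})

test_that("timecourse latents are anti-monotone and error cases are caught", {
  cfg <- synth_config(seed = 2, noiseless = TRUE)
  tc <- generate_timecourse(cfg, c("m", "p"))
  mir_ct <- tapply(tc$mirna$ct_target, tc$mirna$time_h, mean)
  tgt_ct <- tapply(tc$target$ct_target, tc$target$time_h, mean)
  expect_true(all(diff(mir_ct) > 0))   # miRNA falls, CT rises
  expect_true(all(diff(tgt_ct) < 0))   # target rises, CT falls
  expect_error(generate_timecourse(synth_config(timepoints_h = 5), c("m", "p")),
               "two time points")
  expect_error(generate_timecourse(synth_config(timepoints_h = c(5, 3)),
                                   c("m", "p")),
               "strictly increasing")
})

test_that("noiseless luciferase plate represses only wild-type + mimic", {
  plate <- relative_activity(
    generate_luciferase_plate(synth_config(seed = 2, noiseless = TRUE)))
  wt <- plate$construct == "wild-type" & plate$treatment == "mimic"
  expect_equal(plate$ratio[wt], rep(0.5, 3))
  expect_equal(plate$ratio[!wt], rep(1, 9))
})

test_that("synth_config validates its parameters", {
  expect_error(synth_config(luciferase_repression = 1), "must lie in")
  expect_error(synth_config(n_de_mirnas = 200, n_mirnas = 100))
  cfg <- synth_config(n_de_mirnas = 4, targets_per_de_mirna = 3)
  expect_equal(cfg$n_de_proteins, 12L)
})
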