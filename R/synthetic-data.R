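#' Configuration for the synthetic study generator
#'
#' Defines a seeded, fully deterministic synthetic analogue of the study
#' design: two pooled small-RNA libraries (ablated vs intact), three
#' replicate protein abundance profiles per condition, a planted set of
#' differentially expressed miRNAs whose 3'UTR targets respond inversely,
#' six-point post-treatment time courses, and four-group dual-luciferase
#' plates.
#'
#' @param seed integer seed; identical configurations generate byte-identical
#'   outputs.
#' @param n_mirnas,n_proteins numbers of miRNAs and proteins (each protein
#'   carries one 3'UTR with the same identifier).
#' @param mirna_length_range,utr_length_range length ranges in nt.  The
#'   miRNA default (21-23) keeps a perfect full-length site above the
#'   default scanner threshold (a site for an L-nt miRNA scores `5L + 35`).
#' @param n_de_mirnas number of planted DE miRNAs.
#' @param n_de_proteins number of planted DE proteins; each is coupled to
#'   one DE miRNA (round-robin) and responds with the opposite sign.
#' @param targets_per_de_mirna optional override: when given,
#'   `n_de_proteins` is set to `n_de_mirnas * targets_per_de_mirna`.
#' @param de_log2fc_range magnitude range of planted miRNA log2 fold changes.
#' @param de_down_fraction fraction of planted DE miRNAs that are
#'   downregulated after ablation (default 0.75, as in ablation studies
#'   where most responsive miRNAs drop).
#' @param coupling_strength protein log2 fold change induced per unit of
#'   (negated) miRNA log2 fold change (default 0.3).
#' @param protein_fc_noise_sd replicate noise sd on log2 abundances.  The
#'   default (0.05, i.e. about 3.5% CV) reflects the technical precision of
#'   isobaric-label quantification and is the level at which the smallest
#'   planted effect (coupling 0.3 x log2FC 1.5 = 0.45) is detectable with
#'   n = 3 Welch tests after multiplicity adjustment over 200 proteins.
#' @param nb_dispersion extra-Poisson dispersion of counts (per-miRNA gamma
#'   factor shared between the two libraries; marginally each count is
#'   negative binomial, while the between-library comparison stays Poisson,
#'   matching a single pooled library per condition).
#' @param base_mean median baseline expected count per miRNA.
#' @param base_mean_log_sd log-sd of the baseline count means.
#' @param n_replicates biological replicates per condition (default 3).
#' @param timepoints_h time-course sampling times in hours.
#' @param ct_noise_sd Gaussian noise sd on CT values.
#' @param luciferase_repression fractional repression of the wild-type +
#'   mimic group in (0, 1).
#' @param luciferase_noise_sd multiplicative (log-normal) noise sd on
#'   luciferase signals.
#' @param noiseless when `TRUE`, every stochastic layer is replaced by its
#'   mean (counts rounded); sequences and planted assignments stay random
#'   but seeded.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 42L, n_mirnas = 100L, n_proteins = 200L,
                         mirna_length_range = c(21L, 23L),
                         utr_length_range = c(200L, 1500L),
                         n_de_mirnas = 10L, n_de_proteins = 15L,
                         targets_per_de_mirna = NULL,
                         de_log2fc_range = c(1.5, 3.0),
                         de_down_fraction = 0.75,
                         coupling_strength = 0.3,
                         protein_fc_noise_sd = 0.05,
                         nb_dispersion = 0.05,
                         base_mean = 150, base_mean_log_sd = 1,
                         n_replicates = 3L,
                         timepoints_h = c(0, 24, 48, 72, 96, 168),
                         ct_noise_sd = 0.15,
                         luciferase_repression = 0.5,
                         luciferase_noise_sd = 0.05,
                         noiseless = FALSE) {
  if (!is.null(targets_per_de_mirna)) {
    n_de_proteins <- n_de_mirnas * targets_per_de_mirna
  }
  cfg <- list(seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
              n_proteins = as.integer(n_proteins),
              mirna_length_range = as.integer(mirna_length_range),
              utr_length_range = as.integer(utr_length_range),
              n_de_mirnas = as.integer(n_de_mirnas),
              n_de_proteins = as.integer(n_de_proteins),
              de_log2fc_range = de_log2fc_range,
              de_down_fraction = de_down_fraction,
              coupling_strength = coupling_strength,
              protein_fc_noise_sd = protein_fc_noise_sd,
              nb_dispersion = nb_dispersion,
              base_mean = base_mean, base_mean_log_sd = base_mean_log_sd,
              n_replicates = as.integer(n_replicates),
              timepoints_h = timepoints_h, ct_noise_sd = ct_noise_sd,
              luciferase_repression = luciferase_repression,
              luciferase_noise_sd = luciferase_noise_sd,
              noiseless = isTRUE(noiseless))
  stopifnot(cfg$n_de_mirnas <= cfg$n_mirnas,
            cfg$n_de_proteins <= cfg$n_proteins,
            cfg$protein_fc_noise_sd >= 0, cfg$nb_dispersion >= 0,
            cfg$coupling_strength > 0,
            diff(cfg$mirna_length_range) >= 0,
            diff(cfg$utr_length_range) >= 0,
            cfg$de_down_fraction >= 0, cfg$de_down_fraction <= 1)
  if (cfg$luciferase_repression < 0 || cfg$luciferase_repression >= 1) {
    abort("luciferase_repression must lie in [0, 1)")
  }
  structure(cfg, class = "synth_config")
}

rand_seq <- function(n, len) {
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "U"), l, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate miRNA and 3'UTR sequences with planted target sites
#'
#' Draws random miRNA and UTR sequences, picks the planted DE miRNAs and
#' their coupled target proteins, and embeds, at a recorded position of each
#' target's UTR, the full reverse complement of the targeting miRNA (which
#' in particular contains the reverse complement of positions 1-8, the seed
#' region and its anchor).  All other sequence content is uniform over
#' A/C/G/U.
#'
#' @param cfg a [synth_config()].
#' @return a list with tibbles `mirnas` (`id`, `seq`), `utrs` (`id`, `seq`)
#'   and a `truth` list: `de_mirnas` (`mirna_id`, `log2fc`), `de_proteins`
#'   (`protein_id`, `log2fc`), `edges` (`mirna_id`, `protein_id`, `utr_id`,
#'   `site_start`, `site_end`).
#' @export
generate_sequences <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 1L), {
    mirna_ids <- sprintf("mir-%03d", seq_len(cfg$n_mirnas))
    prot_ids <- sprintf("prot-%03d", seq_len(cfg$n_proteins))
    mlen <- sample(seq(cfg$mirna_length_range[1], cfg$mirna_length_range[2]),
                   cfg$n_mirnas, replace = TRUE)
    ulen <- sample(seq(cfg$utr_length_range[1], cfg$utr_length_range[2]),
                   cfg$n_proteins, replace = TRUE)
    mirnas <- tibble(id = mirna_ids, seq = rand_seq(cfg$n_mirnas, mlen))
    utrs <- tibble(id = prot_ids, seq = rand_seq(cfg$n_proteins, ulen))

    de_idx <- sample(cfg$n_mirnas, cfg$n_de_mirnas)
    n_down <- round(cfg$de_down_fraction * cfg$n_de_mirnas)
    signs <- c(rep(-1, n_down), rep(1, cfg$n_de_mirnas - n_down))
    lfc <- signs * runif(cfg$n_de_mirnas, cfg$de_log2fc_range[1],
                         cfg$de_log2fc_range[2])
    de_mirnas <- tibble(mirna_id = mirna_ids[de_idx], log2fc = lfc)

    if (cfg$n_de_proteins > 0 && cfg$n_de_mirnas > 0) {
      de_prot_idx <- sample(cfg$n_proteins, cfg$n_de_proteins)
      owner <- ((seq_len(cfg$n_de_proteins) - 1L) %% cfg$n_de_mirnas) + 1L
      prot_lfc <- -cfg$coupling_strength * lfc[owner]
      de_proteins <- tibble(protein_id = prot_ids[de_prot_idx],
                            log2fc = prot_lfc)
      edges <- tibble(mirna_id = mirna_ids[de_idx][owner],
                      protein_id = prot_ids[de_prot_idx],
                      utr_id = prot_ids[de_prot_idx],
                      site_start = NA_integer_, site_end = NA_integer_)
      for (r in seq_len(nrow(edges))) {
        mseq <- mirnas$seq[mirnas$id == edges$mirna_id[r]]
        site <- reverse_complement(mseq)
        ui <- which(utrs$id == edges$utr_id[r])
        L <- nchar(utrs$seq[ui]); sl <- nchar(site)
        if (sl > L) {
          abort(sprintf("planted site for (%s, %s) does not fit in the UTR",
                        edges$mirna_id[r], edges$utr_id[r]))
        }
        pos <- sample(L - sl + 1L, 1L)
        substr(utrs$seq[ui], pos, pos + sl - 1L) <- site
        edges$site_start[r] <- pos
        edges$site_end[r] <- pos + sl - 1L
      }
    } else {
      de_proteins <- tibble(protein_id = character(), log2fc = numeric())
      edges <- tibble(mirna_id = character(), protein_id = character(),
                      utr_id = character(), site_start = integer(),
                      site_end = integer())
    }
    list(mirnas = mirnas, utrs = utrs,
         truth = list(de_mirnas = de_mirnas, de_proteins = de_proteins,
                      edges = edges))
  })
}

#' Generate pooled two-library miRNA counts
#'
#' Baseline expected counts are log-normal across miRNAs; planted DE miRNAs
#' have their ablated-library mean multiplied by `2^log2fc`.  Extra-Poisson
#' dispersion enters as a per-miRNA gamma factor shared by the two
#' conditions (each library then adds independent Poisson sampling), so
#' marginal counts are negative binomial while library-to-library
#' differences under the null remain Poisson -- the noise structure of one
#' pooled sequencing library per condition.
#'
#' @param cfg a [synth_config()].
#' @param truth the `truth` element from [generate_sequences()].
#' @return a [count_table()] with totals set to the column sums.
#' @export
generate_counts <- function(cfg, truth) {
  with_seed(derive_seed(cfg$seed, 2L), {
    n <- cfg$n_mirnas
    ids <- sprintf("mir-%03d", seq_len(n))
    base <- cfg$base_mean * exp(if (cfg$noiseless) rep(0, n)
                                else rnorm(n, 0, cfg$base_mean_log_sd))
    lfc <- setNames(rep(0, n), ids)
    lfc[truth$de_mirnas$mirna_id] <- truth$de_mirnas$log2fc
    g <- if (cfg$nb_dispersion > 0 && !cfg$noiseless) {
      rgamma(n, shape = 1 / cfg$nb_dispersion, rate = 1 / cfg$nb_dispersion)
    } else rep(1, n)
    mu_esi <- base * g
    mu_esa <- base * g * 2^unname(lfc)
    counts <- if (cfg$noiseless) {
      tibble(mirna_id = ids, count_esi = round(mu_esi),
             count_esa = round(mu_esa))
    } else {
      tibble(mirna_id = ids, count_esi = rpois(n, mu_esi),
             count_esa = rpois(n, mu_esa))
    }
    count_table(counts)
  })
}

#' Generate replicate protein log2 abundances
#'
#' Each protein has a baseline log2 abundance; ablated-condition replicates
#' are shifted by the planted log2 fold change (zero for unplanted
#' proteins), so a protein targeted by a downregulated miRNA rises by
#' `coupling_strength * |miRNA log2fc|`.  Replicate noise is Gaussian on the
#' log2 scale (log-normal abundances).
#'
#' @param cfg a [synth_config()].
#' @param truth the `truth` element from [generate_sequences()].
#' @return a long tibble: `protein_id`, `condition`, `replicate`,
#'   `log2_abundance`.
#' @export
generate_protein_table <- function(cfg, truth) {
  with_seed(derive_seed(cfg$seed, 3L), {
    ids <- sprintf("prot-%03d", seq_len(cfg$n_proteins))
    lfc <- setNames(rep(0, cfg$n_proteins), ids)
    lfc[truth$de_proteins$protein_id] <- truth$de_proteins$log2fc
    baseline <- rnorm(cfg$n_proteins, 12, 2)
    grid <- tidyr::expand_grid(protein_id = ids,
                               condition = c("esi", "esa"),
                               replicate = seq_len(cfg$n_replicates))
    noise <- if (cfg$noiseless) 0 else rnorm(nrow(grid), 0,
                                             cfg$protein_fc_noise_sd)
    grid$log2_abundance <- baseline[match(grid$protein_id, ids)] +
      ifelse(grid$condition == "esa", lfc[grid$protein_id], 0) + noise
    grid
  })
}

#' Generate a post-treatment time course for a coupled miRNA/target pair
#'
#' The miRNA's latent log2 level declines linearly with time while the
#' target's rises, so the two latent series are perfectly anti-monotone.
#' CT values are `offset - log2(level)` plus Gaussian noise; the reference
#' gene's CT is constant plus noise.  Three biological by three technical
#' replicates per time point.
#'
#' @param cfg a [synth_config()].
#' @param pair character vector `c(mirna_id, protein_id)` naming the pair
#'   (used only to seed and label the draw).
#' @return a list of two tibbles, `mirna` and `target`, each with columns
#'   `time_h`, `bio_rep`, `tech_rep`, `ct_target`, `ct_reference`.
#' @export
generate_timecourse <- function(cfg, pair = c("mirna", "target")) {
  tp <- cfg$timepoints_h
  if (length(tp) < 2) abort("need at least two time points (correlation undefined)")
  if (is.unsorted(tp, strictly = TRUE)) abort("timepoints must be strictly increasing")
  tag <- sum(utf8ToInt(paste(pair, collapse = "/")))
  with_seed(derive_seed(cfg$seed, 4L + tag), {
    frac <- (tp - tp[1]) / (tp[length(tp)] - tp[1])
    one <- function(latent_log2, offset) {
      grid <- tidyr::expand_grid(time_h = tp,
                                 bio_rep = seq_len(cfg$n_replicates),
                                 tech_rep = 1:3)
      lat <- latent_log2[match(grid$time_h, tp)]
      noise <- function() if (cfg$noiseless) 0 else
        rnorm(nrow(grid), 0, cfg$ct_noise_sd)
      grid$ct_target <- offset - lat + noise()
      grid$ct_reference <- 20 + noise()
      grid
    }
    list(mirna = one(-2 * frac, 25), target = one(1.5 * frac, 25))
  })
}

#' Generate a four-group dual-luciferase plate
#'
#' Wild-type and mutant reporter constructs crossed with miRNA mimic and
#' scrambled negative control, `n_replicates` wells per group.  The expected
#' firefly/Renilla ratio of the wild-type + mimic group is
#' `(1 - luciferase_repression)` times the common mean of the other three
#' groups; noise is multiplicative log-normal on both signals.
#'
#' @param cfg a [synth_config()].
#' @return a tibble with columns `group`, `construct`, `treatment`, `well`,
#'   `firefly`, `renilla`.
#' @export
generate_luciferase_plate <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 5L), {
    grid <- tidyr::expand_grid(construct = c("wild-type", "mutant"),
                               treatment = c("mimic", "negative-control"),
                               well = seq_len(cfg$n_replicates))
    grid$group <- paste(grid$construct, grid$treatment, sep = "+")
    ratio_mean <- ifelse(grid$construct == "wild-type" &
                           grid$treatment == "mimic",
                         1 - cfg$luciferase_repression, 1)
    noise <- function() if (cfg$noiseless) 0 else
      rnorm(nrow(grid), 0, cfg$luciferase_noise_sd)
    grid$renilla <- 1000 * exp(noise())
    grid$firefly <- grid$renilla * ratio_mean * exp(noise())
    grid[, c("group", "construct", "treatment", "well", "firefly", "renilla")]
  })
}

#' Generate the full synthetic study
#'
#' Convenience wrapper bundling sequences, counts and the protein table.
#'
#' @param cfg a [synth_config()].
#' @return list with `mirnas`, `utrs`, `truth`, `counts`, `proteins`.
#' @export
simulate_study <- function(cfg = synth_config()) {
  seqs <- generate_sequences(cfg)
  list(mirnas = seqs$mirnas, utrs = seqs$utrs, truth = seqs$truth,
       counts = generate_counts(cfg, seqs$truth),
       proteins = generate_protein_table(cfg, seqs$truth))
}
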