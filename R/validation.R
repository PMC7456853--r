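#' Per-well relative luciferase activity
#'
#' Normalizes the firefly signal to the Renilla signal in each well:
#' `ratio = firefly / renilla`, with no further scaling.
#'
#' @param plate tibble with columns `group`, `firefly`, `renilla` (and
#'   typically `construct`, `treatment`).
#' @return the plate with a `ratio` column added.
#' @export
relative_activity <- function(plate) {
  stopifnot(all(c("group", "firefly", "renilla") %in% names(plate)))
  if (any(plate$renilla == 0)) {
    abort(sprintf("zero Renilla signal in well %d (group %s)",
                  which(plate$renilla == 0)[1],
                  plate$group[which(plate$renilla == 0)[1]]))
  }
  plate$ratio <- plate$firefly / plate$renilla
  plate
}

# insert-absorb compact letter display: groups sharing a letter do not
# differ at alpha; ties in the mean ordering are broken by group label
compact_letters <- function(group_names, sig_pairs) {
  sets <- list(group_names)
  for (r in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$g1[r]; b <- sig_pairs$g2[r]
    hit <- which(vapply(sets, function(s) a %in% s && b %in% s, logical(1)))
    for (h in hit) {
      s <- sets[[h]]
      sets[[h]] <- setdiff(s, a)
      sets[[length(sets) + 1]] <- setdiff(s, b)
    }
    # absorb: drop sets contained in another surviving set (and duplicates)
    keep <- rep(TRUE, length(sets))
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (i == j || !keep[i] || !keep[j]) next
        if (all(sets[[i]] %in% sets[[j]]) &&
            (length(sets[[i]]) < length(sets[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    sets <- sets[keep]
  }
  sets <- sets[order(vapply(sets, function(s) min(match(s, group_names)),
                            numeric(1)))]
  letters_out <- setNames(rep("", length(group_names)), group_names)
  for (k in seq_along(sets)) {
    for (g in sets[[k]]) {
      letters_out[g] <- paste0(letters_out[g], letters[k])
    }
  }
  letters_out
}

#' One-way ANOVA with Tukey's HSD and a compact letter display
#'
#' Fits a one-way ANOVA of `ratio ~ group`, computes Tukey-Kramer pairwise
#' adjusted p-values from the studentized range distribution, and derives a
#' compact letter display in which two groups share a letter exactly when
#' their adjusted p-value is at least `alpha`.
#'
#' @param data tibble with columns `group` and `ratio` (e.g. from
#'   [relative_activity()]).
#' @param alpha familywise significance level (default 0.05).
#' @return a `tukey_result`: list with `anova_f`, `anova_p`, `means`
#'   (tibble), `pairwise` (tibble with `g1`, `g2`, `diff`, `p_adj`),
#'   `letters` (named character), `alpha`.
#' @export
anova_tukey <- function(data, alpha = 0.05) {
  stopifnot(all(c("group", "ratio") %in% names(data)))
  data$group <- factor(data$group)
  if (nlevels(data$group) < 2) abort("need at least 2 groups")
  if (any(table(data$group) < 2)) abort("need at least 2 observations per group")
  if (all(tapply(data$ratio, data$group, stats::var) == 0)) {
    abort("zero within-group variance in every group: ANOVA is degenerate")
  }
  fit <- stats::aov(ratio ~ group, data = data)
  av <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  # TukeyHSD labels rows "levelB-levelA" over combn(levels, 2); rebuild the
  # pair from the level set rather than splitting on "-", which breaks when
  # group names themselves contain hyphens
  cmb <- utils::combn(levels(data$group), 2)
  stopifnot(identical(rownames(tk), paste(cmb[2, ], cmb[1, ], sep = "-")))
  pairwise <- tibble(
    g1 = cmb[2, ],
    g2 = cmb[1, ],
    diff = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"]))
  means <- data |>
    dplyr::summarise(mean = mean(.data$ratio), sd = sd(.data$ratio),
                     n = dplyr::n(), .by = "group") |>
    dplyr::arrange(dplyr::desc(.data$mean))
  sig <- pairwise[pairwise$p_adj < alpha, , drop = FALSE]
  lett <- compact_letters(as.character(means$group), sig)
  structure(list(anova_f = av[["F value"]][1], anova_p = av[["Pr(>F)"]][1],
                 means = means, pairwise = pairwise, letters = lett,
                 alpha = alpha),
            class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F = %.3f, p = %.3g; Tukey HSD at alpha = %g\n",
              x$anova_f, x$anova_p, x$alpha))
  m <- x$means
  m$letters <- x$letters[as.character(m$group)]
  print(m)
  invisible(x)
}

#' @rdname anova_tukey
#' @param x a `tukey_result`.
#' @param ... unused.
#' @export
tidy.tukey_result <- function(x, ...) x$pairwise

#' @rdname anova_tukey
#' @export
glance.tukey_result <- function(x, ...) {
  tibble(statistic = x$anova_f, p.value = x$anova_p,
         n_groups = nrow(x$means), alpha = x$alpha)
}

#' Comparative-CT relative expression over a time course
#'
#' Implements the 2^(-ddCT) method.  Technical replicates (a `tech_rep`
#' column), when present, are first averaged into one CT per biological
#' replicate.  Per biological replicate `dCT = CT_target - CT_reference`;
#' `ddCT` subtracts the mean dCT at the calibrator time; `RQ = 2^(-ddCT)`.
#' Each later time point is compared with the calibrator by a Welch t-test
#' on the ddCT values.
#'
#' @param tc tibble with columns `time_h`, `bio_rep`, `ct_target`,
#'   `ct_reference` and optionally `tech_rep`.
#' @param calibrator_time calibrator time point (default 0).
#' @param alpha significance level for the per-time flag (default 0.05).
#' @return a tibble with one row per time point: `time_h`, `rq_mean`,
#'   `rq_sd`, `p_vs_calibrator`, `significant`.
#' @export
relative_expression <- function(tc, calibrator_time = 0, alpha = 0.05) {
  need <- c("time_h", "bio_rep", "ct_target", "ct_reference")
  miss <- setdiff(need, names(tc))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyNA(tc$ct_reference)) abort("missing reference CT")
  if (!calibrator_time %in% tc$time_h) abort("calibrator time not present")
  bio <- tc |>
    dplyr::summarise(ct_target = mean(.data$ct_target),
                     ct_reference = mean(.data$ct_reference),
                     .by = c("time_h", "bio_rep")) |>
    dplyr::mutate(dct = .data$ct_target - .data$ct_reference)
  cal_mean <- mean(bio$dct[bio$time_h == calibrator_time])
  bio$ddct <- bio$dct - cal_mean
  bio$rq <- 2^(-bio$ddct)
  cal_ddct <- bio$ddct[bio$time_h == calibrator_time]
  bio |>
    dplyr::summarise(
      rq_mean = mean(.data$rq), rq_sd = sd(.data$rq),
      p_vs_calibrator = if (.data$time_h[1] == calibrator_time ||
                            dplyr::n() < 2 || length(cal_ddct) < 2) NA_real_
        else welch_p(.data$ddct, cal_ddct),
      .by = "time_h") |>
    dplyr::mutate(significant = !is.na(.data$p_vs_calibrator) &
                    .data$p_vs_calibrator < alpha) |>
    dplyr::arrange(.data$time_h)
}

perms_int <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_int(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Spearman rank correlation with an exact small-sample permutation test
#'
#' Computes rho on average ranks (ties averaged).  For `n <= 8` the
#' two-sided p-value is exact, by enumeration of all `n!` permutations of
#' one series; for larger `n` the usual t approximation is used.
#'
#' @param x,y numeric series of equal length `>= 3`.
#' @return a one-row tibble: `rho`, `p`, `n`, `method`.  Constant input
#'   yields `rho = NA` with a warning (correlation undefined).
#' @export
spearman_pair <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) abort("need two equal-length series of length >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant series: Spearman rho is undefined", call. = FALSE)
    return(tibble(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    pm <- perms_int(n)
    rhos <- apply(pm, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    method <- "t approximation"
  }
  tibble(rho = rho, p = p, n = n, method = method)
}
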