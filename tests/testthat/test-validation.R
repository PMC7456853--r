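test_that("relative_activity normalizes firefly by Renilla", {
  plate <- tibble::tibble(group = c("g1", "g1"), firefly = c(500, 800),
                          renilla = c(1000, 1000))
  expect_equal(relative_activity(plate)$ratio, c(0.5, 0.8))
  bad <- plate; bad$renilla[2] <- 0
  expect_error(relative_activity(bad), "well 2")
})

test_that("compact letters separate exactly the significant pairs", {
  cl <- mirpronet:::compact_letters
  none <- cl(c("A", "B", "C"), tibble::tibble(g1 = character(),
                                              g2 = character()))
  expect_equal(unname(none), c("a", "a", "a"))
  one <- cl(c("A", "B", "C"), tibble::tibble(g1 = "A", g2 = "C"))
  expect_equal(one, c(A = "a", B = "ab", C = "b"))
  all_pairs <- cl(c("A", "B", "C"),
                  tibble::tibble(g1 = c("A", "A", "B"), g2 = c("B", "C", "C")))
  expect_equal(unname(all_pairs), c("a", "b", "c"))
})

test_that("anova_tukey matches aov and a reference studentized-range p", {
  set.seed(51)
  for (i in 1:50) {
    k <- sample(3:4, 1)
    n_per <- sample(3:6, k, replace = TRUE)
    g <- factor(rep(sprintf("grp%d", seq_len(k)), n_per))
    y <- rnorm(length(g)) + rep(runif(k, 0, 2), n_per)
    res <- anova_tukey(tibble::tibble(group = g, ratio = y))
    # reference computation from first principles
    N <- length(y)
    mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / (N - k)
    means <- tapply(y, g, mean); ns <- tapply(y, g, length)
    cmb <- utils::combn(levels(g), 2)
    dif <- means[cmb[2, ]] - means[cmb[1, ]]
    se <- sqrt(mse / 2 * (1 / ns[cmb[1, ]] + 1 / ns[cmb[2, ]]))
    p_ref <- stats::ptukey(abs(dif) / se, k, N - k, lower.tail = FALSE)
    expect_equal(res$pairwise$p_adj, as.vector(p_ref), tolerance = 1e-8)
    expect_equal(res$pairwise$diff, as.vector(dif))
    fit <- summary(stats::aov(y ~ g))[[1]]
    expect_equal(res$anova_f, fit[["F value"]][1])
  }
})

test_that("anova_tukey handles hyphenated group names", {
  set.seed(52)
  g <- rep(c("wild-type+mimic", "wild-type+negative-control",
             "mutant+mimic", "mutant+negative-control"), each = 3)
  y <- rnorm(12, 0, 0.03) + ifelse(g == "wild-type+mimic", 0.5, 1)
  res <- anova_tukey(tibble::tibble(group = g, ratio = y))
  expect_setequal(c(res$pairwise$g1, res$pairwise$g2), unique(g))
  # the repressed group carries its own letter; the other three share one
  lt <- res$letters
  expect_equal(length(unique(lt)), 2)
  expect_false(lt[["wild-type+mimic"]] %in%
                 lt[setdiff(names(lt), "wild-type+mimic")])
})

test_that("anova_tukey rejects degenerate designs", {
  expect_error(anova_tukey(tibble::tibble(group = c("a", "a"),
                                          ratio = c(1, 2))), "2 groups")
  expect_error(anova_tukey(tibble::tibble(group = c("a", "a", "b"),
                                          ratio = c(1, 2, 3))),
               "2 observations")
  expect_error(anova_tukey(tibble::tibble(group = rep(c("a", "b"), each = 2),
                                          ratio = c(1, 1, 2, 2))),
               "degenerate")
})

test_that("tukey_result methods expose the fit", {
  set.seed(53)
  d <- tibble::tibble(group = rep(c("a", "b", "c"), each = 4),
                      ratio = rnorm(12) + rep(c(0, 0, 3), each = 4))
  res <- anova_tukey(d)
  expect_equal(nrow(tidy(res)), 3)
  gl <- glance(res)
  expect_equal(gl$n_groups, 3)
  expect_output(print(res), "one-way ANOVA")
})

test_that("relative expression implements the comparative-CT method", {
  # a one-cycle CT drop at 24 h doubles relative expression exactly
  tc <- tidyr::expand_grid(time_h = c(0, 24), bio_rep = 1:3)
  tc$ct_target <- ifelse(tc$time_h == 0, 25, 24)
  tc$ct_reference <- 20
  rq <- relative_expression(tc)
  expect_equal(rq$rq_mean[rq$time_h == 0], 1)
  expect_equal(rq$rq_mean[rq$time_h == 24], 2)
  expect_true(is.na(rq$p_vs_calibrator[rq$time_h == 0]))
  expect_equal(rq$p_vs_calibrator[rq$time_h == 24], 0)  # zero variance, shifted
  expect_true(rq$significant[rq$time_h == 24])
})

test_that("technical replicates are averaged before the delta-CT", {
  tc <- tidyr::expand_grid(time_h = c(0, 48), bio_rep = 1:2, tech_rep = 1:2)
  tc$ct_target <- ifelse(tc$time_h == 0, 25, 23) +
    ifelse(tc$tech_rep == 1, -0.3, 0.3)   # tech noise cancels in the mean
  tc$ct_reference <- 20
  rq <- relative_expression(tc)
  expect_equal(rq$rq_mean[rq$time_h == 48], 4)
})

test_that("the geometric mean RQ at the calibrator is one by construction", {
  set.seed(54)
  tc <- tidyr::expand_grid(time_h = c(0, 24, 48), bio_rep = 1:4)
  tc$ct_target <- 25 + rnorm(nrow(tc), 0, 0.4)
  tc$ct_reference <- 20 + rnorm(nrow(tc), 0, 0.2)
  bio <- tc
  bio$dct <- bio$ct_target - bio$ct_reference
  cal <- bio$dct[bio$time_h == 0] - mean(bio$dct[bio$time_h == 0])
  expect_equal(exp(mean(log(2^(-cal)))), 1)
  rq <- relative_expression(tc)
  expect_equal(nrow(rq), 3)
})

test_that("relative_expression validates its input", {
  tc <- tidyr::expand_grid(time_h = c(0, 24), bio_rep = 1:3)
  tc$ct_target <- 25; tc$ct_reference <- 20
  expect_error(relative_expression(tc[, -4]), "missing columns")
  expect_error(relative_expression(tc, calibrator_time = 5), "not present")
  tc$ct_reference[1] <- NA
  expect_error(relative_expression(tc), "missing reference CT")
})

test_that("spearman_pair is exact for small n", {
  sp <- spearman_pair(1:6, 6:1)
  expect_equal(sp$rho, -1)
  expect_equal(sp$p, 2 / factorial(6))
  expect_equal(sp$method, "exact permutation")
  expect_equal(spearman_pair(1:6, 1:6)$p, 2 / factorial(6))
})

test_that("exact permutation p matches an independent enumeration at n = 5", {
  # independent oracle: permutations from a filtered cartesian grid
  grid <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- grid[apply(grid, 1, function(r) length(unique(r)) == 5), ,
                drop = FALSE]
  set.seed(55)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(5)
    rho <- cor(rank(x), rank(y))
    rhos <- apply(perms, 1, function(idx) cor(rank(x), rank(y)[idx]))
    p_ref <- mean(abs(rhos) >= abs(rho) - 1e-12)
    expect_equal(spearman_pair(x, y)$p, p_ref)
  }
})

test_that("spearman_pair falls back to the t approximation for larger n", {
  set.seed(56)
  x <- rnorm(12); y <- x + rnorm(12)
  sp <- spearman_pair(x, y)
  expect_equal(sp$method, "t approximation")
  rho <- cor(x, y, method = "spearman")
  expect_equal(sp$rho, rho)
  tval <- rho * sqrt(10 / (1 - rho^2))
  expect_equal(sp$p, 2 * pt(-abs(tval), 10))
})

test_that("spearman_pair flags degenerate input", {
  expect_warning(sp <- spearman_pair(rep(1, 5), 1:5), "constant")
  expect_true(is.na(sp$rho))
  expect_error(spearman_pair(1:2, 2:1), "length >= 3")
})
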