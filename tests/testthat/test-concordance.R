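# Independent textbook evaluation of tie-corrected W.
oracle_w <- function(R) {
  m <- nrow(R); n <- ncol(R)
  ranks <- t(apply(R, 1, rank))
  S <- sum((colSums(ranks) - m * (n + 1) / 2)^2)
  Tj <- sum(apply(R, 1, function(r) {
    t <- as.numeric(table(r)); sum(t^3 - t)
  }))
  12 * S / (m^2 * (n^3 - n) - m * Tj)
}

test_that("Kendall's W spans perfect agreement to perfect reversal", {
  expect_equal(kendalls_w(rbind(1:6, 1:6)), 1)
  expect_equal(kendalls_w(rbind(1:6, 6:1)), 0)
  expect_error(kendalls_w(rbind(rep(2, 5), 1:5)), "constant",
               class = "ihcquant_degenerate")
})

test_that("tie-corrected W matches the defining formula and an established implementation", {
  for (seed in 1:8) {
    R <- withr::with_seed(seed, matrix(sample(0:3, 24, replace = TRUE), 3, 8))
    w <- tryCatch(kendalls_w(R), ihcquant_degenerate = function(e) NULL)
    if (is.null(w)) next
    expect_equal(w, oracle_w(R), tolerance = 1e-12)
    veg <- suppressWarnings(vegan::kendall.global(t(R)))$Concordance_analysis["W", 1]
    expect_equal(w, veg, tolerance = 1e-10)
  }
})

test_that("W is invariant to monotone relabelling of the ordinal codes", {
  R <- withr::with_seed(3, matrix(sample(0:3, 30, replace = TRUE), 3, 10))
  relab <- c(`0` = 10, `1` = 20, `2` = 25, `3` = 99)
  R2 <- matrix(relab[as.character(R)], nrow(R), ncol(R))
  expect_equal(kendalls_w(R), kendalls_w(R2), tolerance = 1e-12)
})

test_that("the chi-square statistic is m(n-1)W with an upper-tail p", {
  res <- kcc_chisq(0.5, 3, 11)
  expect_equal(res$chi2, 3 * 10 * 0.5)
  expect_equal(res$df, 10L)
  expect_equal(res$p, pchisq(15, 10, lower.tail = FALSE))
  z <- kcc_chisq(0, 2, 50)
  expect_equal(z$chi2, 0)
  expect_equal(z$p, 1)
})

test_that("Cohen's kappa reproduces hand-worked tables and the oracle implementation", {
  diag4 <- diag(c(10, 5, 3, 2))
  expect_equal(cohens_kappa(diag4)$kappa, 1)
  expect_equal(cohens_kappa(matrix(1, 2, 2))$kappa, 0)
  # hand evaluation: p_o = 0.7, p_e = 0.5 -> kappa = 0.4
  tab <- matrix(c(20, 10, 5, 15), 2, 2)
  expect_equal(cohens_kappa(tab)$kappa, 0.4, tolerance = 1e-12)
  for (seed in 1:6) {
    t4 <- withr::with_seed(seed, matrix(rpois(16, 6), 4, 4))
    expect_equal(cohens_kappa(t4)$kappa, e1071::classAgreement(t4)$kappa,
                 tolerance = 1e-10)
  }
  expect_error(cohens_kappa(matrix(c(5, 0, 0, 0), 2, 2)), "undefined",
               class = "ihcquant_degenerate")
})

test_that("kappa is invariant to simultaneous category relabelling", {
  t4 <- withr::with_seed(9, matrix(rpois(16, 5), 4, 4))
  perm <- c(3, 1, 4, 2)
  expect_equal(cohens_kappa(t4)$kappa, cohens_kappa(t4[perm, perm])$kappa,
               tolerance = 1e-12)
})

test_that("Fleiss' kappa matches the defining formulas and the two-rater special case", {
  allagree <- cbind(c(0, 1, 2, 3, 1), c(0, 1, 2, 3, 1), c(0, 1, 2, 3, 1))
  expect_equal(fleiss_kappa(allagree), 1)

  oracle_fleiss <- function(R) {
    n <- nrow(R); k <- ncol(R)
    cats <- sort(unique(as.vector(R)))
    nij <- sapply(cats, function(cc) rowSums(R == cc))
    pj <- colSums(nij) / (n * k)
    Pbar <- mean((rowSums(nij^2) - k) / (k * (k - 1)))
    (Pbar - sum(pj^2)) / (1 - sum(pj^2))
  }
  for (seed in 1:6) {
    R <- withr::with_seed(seed + 20, matrix(sample(0:3, 40, replace = TRUE), 10, 4))
    expect_equal(fleiss_kappa(R), oracle_fleiss(R), tolerance = 1e-12)
  }

  # independent two-rater computation (pooled-marginal chance agreement)
  R2 <- withr::with_seed(8, matrix(sample(0:3, 60, replace = TRUE), 30, 2))
  po <- mean(R2[, 1] == R2[, 2])
  pj <- as.numeric(table(factor(as.vector(R2), levels = 0:3))) / 60
  expect_equal(fleiss_kappa(R2), (po - sum(pj^2)) / (1 - sum(pj^2)),
               tolerance = 1e-12)
})

test_that("exact binomial concordance intervals behave at the boundaries", {
  res <- percent_concordance_ci(103, 105)
  expect_equal(round(res$concordance_pct, 1), 98.1)
  expect_true(res$ci_lo <= res$concordance_pct && res$concordance_pct <= res$ci_hi)

  full <- percent_concordance_ci(10, 10)
  expect_equal(full$concordance_pct, 100)
  expect_equal(full$ci_hi, 100)
  none <- percent_concordance_ci(0, 10)
  expect_equal(none$concordance_pct, 0)
  expect_equal(none$ci_lo, 0)

  # Clopper-Pearson closed form via beta quantiles
  x <- 17; n <- 60
  lo <- qbeta(0.025, x, n - x + 1)
  hi <- qbeta(0.975, x + 1, n - x)
  cp <- percent_concordance_ci(x, n)
  expect_equal(cp$ci_lo, 100 * lo, tolerance = 1e-9)
  expect_equal(cp$ci_hi, 100 * hi, tolerance = 1e-9)
})

test_that("Pearson correlation matches its covariance formula", {
  x <- withr::with_seed(4, rnorm(25))
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  y <- withr::with_seed(5, rnorm(25))
  byhand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(x, y), byhand, tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 25), y), "variance")
})

test_that("Levene's test equals an ANOVA on absolute deviations from group means", {
  g1 <- withr::with_seed(6, rnorm(20, 0, 1))
  g2 <- withr::with_seed(7, rnorm(25, 0, 3))
  res <- levene_test(list(g1, g2))
  z <- c(abs(g1 - mean(g1)), abs(g2 - mean(g2)))
  g <- factor(rep(1:2, c(20, 25)))
  a <- anova(stats::aov(z ~ g))
  expect_equal(res$statistic, a$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p, a$`Pr(>F)`[1], tolerance = 1e-10)

  same <- levene_test(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("Levene's test detects a 100-fold variance difference", {
  hits <- vapply(1:200, function(s) {
    g1 <- withr::with_seed(2000 + s, rnorm(50, sd = 1))
    g2 <- withr::with_seed(7000 + s, rnorm(50, sd = 10))
    levene_test(list(g1, g2))$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("the pooled t test matches its formula and detects a 3-sigma shift", {
  x <- withr::with_seed(8, rnorm(12)); y <- withr::with_seed(9, rnorm(15))
  res <- two_sample_t(x, y)
  sp2 <- ((11 * var(x) + 14 * var(y)) / 25)
  tman <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 12 + 1 / 15))
  expect_equal(res$t, tman, tolerance = 1e-12)
  expect_equal(res$df, 25)

  eq <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  hits <- vapply(1:200, function(s) {
    a <- withr::with_seed(3000 + s, rnorm(30))
    b <- withr::with_seed(8000 + s, rnorm(30, mean = 3))
    two_sample_t(a, b)$p < 0.001
  }, TRUE)
  expect_gte(mean(hits), 0.99)
})

test_that("Latin designs satisfy the defining property; the published square is fixed", {
  d4 <- latin_design(4, "published4")
  expect_true(is_latin_square(d4))
  expect_equal(unclass(d4)[3, ], c(3L, 4L, 1L, 2L)) # PR, Ki-67, ER, HER2
  cyc <- latin_design(4, "cyclic")
  expect_true(is_latin_square(cyc))
  expect_equal(unclass(cyc)[2, ], c(2L, 3L, 4L, 1L))
  for (k in c(3, 5, 7)) expect_true(is_latin_square(latin_design(k, "cyclic")))
  expect_error(latin_design(5, "published4"), "k = 4")
})

test_that("reproducibility W is 1 for identical slides and drops under one disagreement", {
  base <- c(0, 1, 2, 3, 1, 2)
  four <- matrix(rep(base, 4), nrow = 4, byrow = TRUE)
  rep_w <- reproducibility_kcc(list(er = four))
  expect_equal(rep_w$W, 1)
  expect_equal(rep_w$chi2, 4 * 5 * 1)

  off <- four; off[2, 3] <- 3
  expect_lt(reproducibility_kcc(off)$W, 1)
})

test_that("generated repeated slides recover high concordance", {
  ws <- c()
  for (s in 1:100) {
    # four slides of the same six cases; each repeat keeps a case's score
    # with probability 0.9, otherwise redraws from the marginals
    slides <- withr::with_seed(s, {
      marg <- c(0.4, 0.3, 0.2, 0.1)
      base <- sample(0:3, 6, replace = TRUE, prob = marg)
      t(vapply(1:4, function(k) {
        keep <- runif(6) < 0.9
        ifelse(keep, base, sample(0:3, 6, replace = TRUE, prob = marg))
      }, numeric(6)))
    })
    w <- tryCatch(kendalls_w(slides), ihcquant_degenerate = function(e) NULL)
    if (is.null(w)) next
    expect_equal(w, oracle_w(slides), tolerance = 1e-12)
    ws <- c(ws, w)
  }
  expect_gt(mean(ws), 0.8)
})

test_that("the full agreement report keeps its internal identities", {
  r <- generate_paired_ratings(rating_gen_config(n_cases = 105, agreement = 0.95,
                                                 seed = 10))
  rep <- agreement_report(r$method_a, r$method_b)
  expect_equal(rep$chi2, rep$m_raters * (rep$n - 1) * rep$W, tolerance = 1e-9)
  expect_true(rep$ci_lo <= rep$concordance_pct && rep$concordance_pct <= rep$ci_hi)
  expect_true(rep$kappa <= 1)

  perfect <- agreement_report(c(0, 1, 2, 3, 2), c(0, 1, 2, 3, 2))
  expect_equal(perfect$W, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$concordance_pct, 100)
})

test_that("p-values format to four decimals with a floor marker", {
  expect_equal(format_p(c(0.5, 0.04321, 5e-5)), c("0.5000", "0.0432", "<0.0001"))
})
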