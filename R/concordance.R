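#' Kendall's coefficient of concordance (W) with tie correction
#'
#' Agreement among `m` raters ranking `n` items, computed on within-rater
#' mid-ranks with the standard tie-correction term:
#' `W = 12 S / (m^2 (n^3 - n) - m * sum_j T_j)` where `S` is the sum of
#' squared deviations of the item rank sums from their mean and
#' `T_j = sum (t^3 - t)` over the tie groups of rater `j`. Applied to
#' two scoring methods over cases, this is the attribute-agreement "KCC".
#'
#' @param ratings `m x n` numeric matrix: rows are raters (or slides, or
#'   scoring methods), columns are items; values are ordinal scores.
#' @return `W` in `[0, 1]`.
#' @export
kendalls_w <- function(ratings) {
  R <- as.matrix(ratings)
  m <- nrow(R); n <- ncol(R)
  if (m < 2 || n < 2) abort("need at least 2 raters and 2 items")
  ranks <- t(apply(R, 1, rank)) # mid-ranks within each rater
  if (any(apply(R, 1, function(r) length(unique(r)) == 1))) {
    abort("a rater assigned a single constant score to all items; W is degenerate",
          class = "ihcquant_degenerate")
  }
  Tj <- apply(R, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  })
  colsums <- colSums(ranks)
  S <- sum((colsums - mean(colsums))^2)
  denom <- m^2 * (n^3 - n) - m * sum(Tj)
  if (denom <= 0) {
    abort("tie structure leaves no rank variance; W is degenerate",
          class = "ihcquant_degenerate")
  }
  12 * S / denom
}

#' Chi-square test for Kendall's W
#'
#' Large-sample test of `W` against no concordance:
#' `chi2 = m (n - 1) W` on `n - 1` degrees of freedom, with the p-value
#' from the upper chi-square tail.
#'
#' @param W Kendall's W in `[0, 1]`.
#' @param m Number of raters.
#' @param n Number of items.
#' @return One-row tibble with `chi2`, `df`, `p`.
#' @export
kcc_chisq <- function(W, m, n) {
  if (m < 2 || n < 2) abort("need m >= 2 and n >= 2")
  if (W < 0 || W > 1) abort("W must lie in [0, 1]")
  chi2 <- m * (n - 1) * W
  df <- n - 1
  tibble::tibble(chi2 = chi2, df = as.integer(df),
                 p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Cohen's kappa for a two-rater contingency table
#'
#' Unweighted chance-corrected agreement
#' `kappa = (p_o - p_e) / (1 - p_e)` with the expected agreement `p_e`
#' from the products of the marginals. The p-value tests `kappa = 0` via
#' the large-sample normal approximation with the null standard error.
#'
#' @param table Square `r x r` matrix of joint counts (rows = rater A,
#'   columns = rater B, same category order).
#' @return One-row tibble with `kappa`, `z`, `p`, `n`.
#' @export
cohens_kappa <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) != ncol(tab)) abort("contingency table must be square")
  n <- sum(tab)
  if (n < 1) abort("contingency table is empty")
  p <- tab / n
  po <- sum(diag(p))
  ra <- rowSums(p); cb <- colSums(p)
  pe <- sum(ra * cb)
  if (1 - pe < .Machine$double.eps) {
    abort("both raters are constant in the same category; kappa undefined",
          class = "ihcquant_degenerate")
  }
  kap <- (po - pe) / (1 - pe)
  # null-hypothesis SE (Fleiss, Cohen & Everitt)
  se0 <- sqrt((pe + pe^2 - sum(ra * cb * (ra + cb))) / (n * (1 - pe)^2))
  z <- if (se0 > 0) kap / se0 else NA_real_
  tibble::tibble(
    kappa = kap,
    z = z,
    p = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
    n = n
  )
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for `k >= 2` raters assigning categorical
#' scores to `n` items: `kappa = (Pbar - Pbar_e) / (1 - Pbar_e)` where
#' `Pbar` averages the per-item pairwise agreement and `Pbar_e` is the sum
#' of squared overall category proportions.
#'
#' @param ratings `n x k` matrix: rows are items, columns raters, values
#'   categorical codes.
#' @return Fleiss' kappa (a single number, at most 1).
#' @export
fleiss_kappa <- function(ratings) {
  R <- as.matrix(ratings)
  n <- nrow(R); k <- ncol(R)
  if (k < 2) abort("need at least 2 raters")
  cats <- sort(unique(as.vector(R)))
  counts <- vapply(cats, function(cc) rowSums(R == cc), numeric(n))
  counts <- matrix(counts, nrow = n)
  pj <- colSums(counts) / (n * k)
  Pi <- (rowSums(counts^2) - k) / (k * (k - 1))
  Pbar <- mean(Pi)
  Pe <- sum(pj^2)
  if (1 - Pe < .Machine$double.eps) {
    abort("all raters used a single category; kappa undefined",
          class = "ihcquant_degenerate")
  }
  (Pbar - Pe) / (1 - Pe)
}

#' Percent concordance with an exact binomial confidence interval
#'
#' Point estimate `100 * matches / n` with a Clopper-Pearson (exact
#' binomial) 95% interval by default.
#'
#' @param matches Number of concordant cases.
#' @param n Total cases.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble with `concordance_pct`, `ci_lo`, `ci_hi` (all on
#'   the percent scale) and `method = "clopper-pearson"`.
#' @export
percent_concordance_ci <- function(matches, n, conf_level = 0.95) {
  if (n < 1) abort("n must be positive")
  if (matches < 0 || matches > n) abort("matches must lie in 0..n")
  ci <- stats::binom.test(matches, n, conf.level = conf_level)$conf.int
  tibble::tibble(
    concordance_pct = 100 * matches / n,
    ci_lo = 100 * ci[1],
    ci_hi = 100 * ci[2],
    method = "clopper-pearson"
  )
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors with nonzero variance.
#' @return Correlation coefficient `r` in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("x and y must have equal length >= 2")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("zero variance: correlation undefined")
  }
  stats::cor(x, y, method = "pearson")
}

#' Levene's test for equality of variances
#'
#' Classic Levene test (absolute deviations from the group means, not
#' medians), delegated to [car::leveneTest()].
#'
#' @param groups List of numeric vectors, one per group (each of length
#'   at least 2).
#' @return One-row tibble with `statistic`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    abort("need at least 2 groups with at least 2 values each")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  res <- car::leveneTest(y, g, center = mean)
  tibble::tibble(
    statistic = res[1, "F value"],
    df1 = res[1, "Df"],
    df2 = res[2, "Df"],
    p = res[1, "Pr(>F)"]
  )
}

#' Two-sample t test
#'
#' Two-sided comparison of two group means; pooled-variance by default,
#' Welch optional.
#'
#' @param x,y Numeric vectors of length at least 2.
#' @param var_equal Pool the variances (classic two-sample t)?
#' @return One-row tibble with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) abort("each sample needs >= 2 values")
  if (var_equal && stats::var(c(x - mean(x), y - mean(y))) == 0) {
    abort("zero pooled variance: t undefined")
  }
  res <- stats::t.test(x, y, var.equal = var_equal)
  tibble::tibble(t = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value)
}

#' Latin-square designs for biomarker ordering
#'
#' An order-`k` Latin square assigns each biomarker to each slide position
#' exactly once, decoupling biomarker identity from channel position in
#' reproducibility studies. Two styles are provided: `"cyclic"` builds row
#' `i` as the left-rotation of `1..k` by `i - 1`; `"published4"` (only for
#' `k = 4`, biomarkers ordered ER, HER2, PR, Ki-67) returns the specific
#' published 4x4 arrangement ER,HER2,PR,Ki67 / HER2,ER,Ki67,PR /
#' PR,Ki67,ER,HER2 / Ki67,PR,HER2,ER, which is a Latin square of pairwise
#' swaps rather than a strict rotation.
#'
#' @param k Order of the square (`k >= 2`).
#' @param style `"published4"` or `"cyclic"`.
#' @return `k x k` integer matrix of class `"latin_design"`; rows are
#'   slides, columns channel positions, entries biomarker indices.
#' @export
latin_design <- function(k = 4L, style = c("published4", "cyclic")) {
  style <- match.arg(style)
  k <- as.integer(k)
  if (k < 2) abort("k must be at least 2")
  if (style == "published4") {
    if (k != 4) abort("style 'published4' is defined only for k = 4")
    M <- rbind(
      c(1L, 2L, 3L, 4L), # ER, HER2, PR,  Ki67
      c(2L, 1L, 4L, 3L), # HER2, ER, Ki67, PR
      c(3L, 4L, 1L, 2L), # PR, Ki67, ER,  HER2
      c(4L, 3L, 2L, 1L)  # Ki67, PR, HER2, ER
    )
  } else {
    M <- t(vapply(seq_len(k), function(i) {
      ((seq_len(k) + i - 2L) %% k) + 1L
    }, integer(k)))
  }
  structure(M, class = c("latin_design", "matrix"))
}

#' @export
print.latin_design <- function(x, ...) {
  cat(sprintf("<latin_design: order %d>\n", nrow(x)))
  print(unclass(x))
  invisible(x)
}

#' Check the Latin-square property
#'
#' @param design A square integer matrix.
#' @return `TRUE` if each symbol occurs exactly once per row and column.
#' @export
is_latin_square <- function(design) {
  M <- unclass(as.matrix(design))
  k <- nrow(M)
  if (ncol(M) != k) return(FALSE)
  syms <- sort(unique(as.vector(M)))
  if (length(syms) != k) return(FALSE)
  all(apply(M, 1, function(r) setequal(r, syms))) &&
    all(apply(M, 2, function(cc) setequal(cc, syms)))
}

#' Reproducibility concordance across repeated slides
#'
#' Treats repeated slides of the same cases as raters and computes
#' Kendall's W per biomarker.
#'
#' @param ratings Either a single slides-by-cases matrix, or a named list
#'   of such matrices (one per biomarker).
#' @return Tibble with columns `biomarker`, `W`, `chi2`, `df`, `p`.
#' @export
reproducibility_kcc <- function(ratings) {
  if (!is.list(ratings)) ratings <- list(biomarker = ratings)
  nms <- names(ratings) %||% paste0("biomarker", seq_along(ratings))
  purrr::map2_dfr(ratings, nms, function(R, nm) {
    W <- kendalls_w(R)
    dplyr::bind_cols(tibble::tibble(biomarker = nm, W = W),
                     kcc_chisq(W, nrow(R), ncol(R)))
  })
}

#' Full two-method agreement report for ordinal scores
#'
#' Combines the Table-style agreement statistics for two scoring methods
#' over the same cases: Kendall's W (methods as raters) with its
#' chi-square test, unweighted Cohen's kappa with its normal-approximation
#' test, and percent concordance with an exact binomial 95% CI. The
#' invariant `chi2 = m (n - 1) W` holds by construction.
#'
#' @param method_a,method_b Equal-length vectors of ordinal codes 0-3 (or
#'   glyphs `-`, `+`, `++`, `+++`).
#' @return One-row tibble of class `"agreement_report"` with columns `n`,
#'   `m_raters`, `W`, `chi2`, `df`, `p_w`, `kappa`, `p_kappa`,
#'   `concordance_pct`, `ci_lo`, `ci_hi`.
#' @export
agreement_report <- function(method_a, method_b) {
  a <- category_code(method_a)
  b <- category_code(method_b)
  if (length(a) != length(b)) abort("methods rated different numbers of cases")
  n <- length(a)
  if (n < 2) abort("need at least 2 cases")
  W <- kendalls_w(rbind(a, b))
  chs <- kcc_chisq(W, 2, n)
  tab <- table(factor(a, levels = 0:3), factor(b, levels = 0:3))
  kap <- cohens_kappa(tab)
  conc <- percent_concordance_ci(sum(a == b), n)
  out <- tibble::tibble(
    n = n, m_raters = 2L,
    W = W, chi2 = chs$chi2, df = chs$df, p_w = chs$p,
    kappa = kap$kappa, p_kappa = kap$p,
    concordance_pct = conc$concordance_pct,
    ci_lo = conc$ci_lo, ci_hi = conc$ci_hi
  )
  class(out) <- c("agreement_report", class(out))
  out
}

#' Format a p-value the way agreement tables print them
#'
#' Four decimals, with values below 1e-4 printed as `<0.0001`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p))
}
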