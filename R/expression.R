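#' Stained-area ratio of a segmented field
#'
#' The staining ratio is the area of the stained cell part (SP) divided by
#' the total cell area (SP plus NSP); background pixels are excluded. A
#' field with no cell pixels at all has no defined ratio and is rejected.
#'
#' @param mask Integer label matrix (1 = SP, 2 = NSP, 3 = BG) as produced by
#'   [classify_pixels()] or [generate_ihc_field()].
#' @return The ratio `|SP| / (|SP| + |NSP|)` in `[0, 1]`.
#' @export
staining_ratio <- function(mask) {
  n_sp <- sum(mask == 1L)
  n_nsp <- sum(mask == 2L)
  if (n_sp + n_nsp == 0) {
    abort("field has no cell pixels: staining ratio undefined",
          class = "ihcquant_empty_field")
  }
  n_sp / (n_sp + n_nsp)
}

# Scalar staining signal in [0, 1] per pixel.
#  - "darkness": 1 - luminance / 255 with luminance = mean(R, G, B);
#    parameter-free and monotone in stain darkness.
#  - "dab_od": optical density projected onto the unit DAB stain vector
#    (Ruifrok-Johnston 0.268, 0.570, 0.776), mapped back to [0, 1) via
#    1 - 10^(-OD_dab).
staining_signal <- function(rgb, signal = c("darkness", "dab_od")) {
  signal <- match.arg(signal)
  if (signal == "darkness") {
    lum <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
    1 - lum / 255
  } else {
    dab <- c(0.268, 0.570, 0.776)
    dab <- dab / sqrt(sum(dab^2))
    od <- -log10(pmax(rgb, 1) / 255)
    proj <- od[, , 1] * dab[1] + od[, , 2] * dab[2] + od[, , 3] * dab[3]
    1 - 10^(-pmax(proj, 0))
  }
}

#' Mean staining intensity within the stained part
#'
#' Averages a scalar staining signal over the SP pixels. The default
#' "darkness" signal is `1 - luminance/255`; the alternative "dab_od"
#' signal projects per-pixel optical density onto the DAB stain vector.
#' A field without SP pixels returns intensity 0 (flagged via attribute
#' `no_sp`), so its expression level is 0.
#'
#' @param image `H x W x 3` RGB array (0-255).
#' @param mask Label matrix aligned with `image`.
#' @param signal `"darkness"` (default) or `"dab_od"`.
#' @return Mean signal over SP pixels, in `[0, 1]`.
#' @export
staining_intensity <- function(image, mask, signal = c("darkness", "dab_od")) {
  signal <- match.arg(signal)
  if (!all(dim(image)[1:2] == dim(mask))) abort("image and mask sizes differ")
  if (sum(mask == 1L) == 0) {
    return(structure(0, no_sp = TRUE))
  }
  sig <- staining_signal(image, signal)
  mean(sig[mask == 1L])
}

#' Expression level of one field
#'
#' The expression level is the staining ratio multiplied by the mean
#' staining intensity in the stained part, so it lies in `[0, 1]`.
#'
#' @inheritParams staining_intensity
#' @return One-row tibble of class `"ihc_expression"` with columns
#'   `n_sp`, `n_nsp`, `n_bg`, `staining_ratio`, `staining_intensity`,
#'   `expression_level`, `signal`.
#' @export
expression_level <- function(image, mask, signal = c("darkness", "dab_od")) {
  signal <- match.arg(signal)
  ratio <- staining_ratio(mask)
  intensity <- as.numeric(staining_intensity(image, mask, signal))
  out <- tibble::tibble(
    n_sp = sum(mask == 1L),
    n_nsp = sum(mask == 2L),
    n_bg = sum(mask == 3L),
    staining_ratio = ratio,
    staining_intensity = intensity,
    expression_level = ratio * intensity,
    signal = signal
  )
  class(out) <- c("ihc_expression", class(out))
  out
}

#' Aggregate per-field expression into a channel summary
#'
#' A biomarker channel is summarised by the unweighted arithmetic mean of
#' its per-field expression levels. At least `min_fields` fields (default
#' five, matching the acquisition convention of at least five random
#' 400x fields per reaction channel) are required.
#'
#' @param results Tibble of per-field rows as from [expression_level()]
#'   (rows may be bound together with [dplyr::bind_rows()]).
#' @param min_fields Minimum acceptable number of fields.
#' @param magnification Magnification tag recorded with the summary.
#' @return One-row tibble of class `"ihc_field_set"` with `n_fields`,
#'   `mean_ratio`, `mean_intensity`, `mean_expression`, `magnification`;
#'   the per-field table is kept in attribute `"fields"`.
#' @export
aggregate_fields <- function(results, min_fields = 5L, magnification = "400x") {
  results <- tibble::as_tibble(results)
  if (nrow(results) < min_fields) {
    abort(sprintf(
      "only %d field(s) supplied; at least %d are required per channel",
      nrow(results), min_fields
    ), class = "ihcquant_too_few_fields")
  }
  out <- tibble::tibble(
    n_fields = nrow(results),
    mean_ratio = mean(results$staining_ratio),
    mean_intensity = mean(results$staining_intensity),
    mean_expression = mean(results$expression_level),
    magnification = magnification
  )
  attr(out, "fields") <- results
  class(out) <- c("ihc_field_set", class(out))
  out
}

#' Normalize an expression matrix by per-biomarker means
#'
#' Divides every value by the mean of its biomarker column, so each
#' biomarker's column mean becomes exactly 1. Used to put staining methods
#' on a common scale before comparing their variability.
#'
#' @param x A methods-by-biomarkers data frame or matrix of expression
#'   values; non-numeric columns (e.g. a method label) are passed through
#'   untouched.
#' @return Same-shape tibble with each numeric column divided by its mean.
#' @export
normalize_by_biomarker_mean <- function(x) {
  tbl <- tibble::as_tibble(as.data.frame(x))
  num <- vapply(tbl, is.numeric, TRUE)
  for (nm in names(tbl)[num]) {
    m <- mean(tbl[[nm]])
    if (!is.finite(m) || m == 0) {
      abort(sprintf("biomarker '%s' has zero (or undefined) mean; cannot normalize", nm))
    }
    tbl[[nm]] <- tbl[[nm]] / m
  }
  tbl
}
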