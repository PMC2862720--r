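ORDINAL_GLYPHS <- c("-", "+", "++", "+++")

ordinal_factor <- function(codes) {
  factor(ORDINAL_GLYPHS[codes + 1L], levels = ORDINAL_GLYPHS, ordered = TRUE)
}

#' Ordinal category helpers
#'
#' The four-level ordinal scale used throughout: negative `-` (code 0),
#' weak `+` (1), intermediate `++` (2), strong `+++` (3).
#'
#' @param x An ordered factor from one of the `*_to_category()` translators,
#'   a glyph character vector, or integer codes.
#' @return `category_code()` returns integer codes 0-3; `category_glyph()`
#'   the glyph labels.
#' @export
category_code <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(x < 0 | x > 3, na.rm = TRUE)) abort("codes must lie in 0..3")
    return(x)
  }
  m <- match(as.character(x), ORDINAL_GLYPHS)
  if (anyNA(m) && !anyNA(x)) abort("unrecognised ordinal category glyph")
  m - 1L
}

#' @rdname category_code
#' @export
category_glyph <- function(x) ORDINAL_GLYPHS[category_code(x) + 1L]

#' Translate Allred scores to the four-level ordinal scale
#'
#' Allred scores (the 0-8 composite of proportion and intensity subscores
#' used for ER and PR) map to: 0 -> negative, 2-3 -> weak, 4-6 ->
#' intermediate, 7-8 -> strong. A composite score of 1 cannot occur (the
#' smallest positive composite is 2 = 1 + 1) and is rejected rather than
#' guessed at.
#'
#' @param score Integer vector of Allred scores in `{0, 2, 3, ..., 8}`.
#' @return Ordered factor over `-`, `+`, `++`, `+++`.
#' @export
allred_to_category <- function(score) {
  score <- as.numeric(score)
  if (any(score != floor(score) | score < 0 | score > 8 | score == 1)) {
    abort("Allred scores must be integers in {0, 2, 3, ..., 8}")
  }
  codes <- ifelse(score == 0, 0L,
           ifelse(score <= 3, 1L,
           ifelse(score <= 6, 2L, 3L)))
  ordinal_factor(codes)
}

#' Translate HER2 scores to the four-level ordinal scale
#'
#' The FDA HER2 membrane-staining scores 0 / 1+ / 2+ / 3+ map directly to
#' negative / weak / intermediate / strong.
#'
#' @param score Integer vector in `{0, 1, 2, 3}`.
#' @return Ordered factor over `-`, `+`, `++`, `+++`.
#' @export
her2_to_category <- function(score) {
  score <- as.numeric(score)
  if (any(score != floor(score) | score < 0 | score > 3)) {
    abort("HER2 scores must be integers in {0, 1, 2, 3}")
  }
  ordinal_factor(as.integer(score))
}

#' Translate a Ki-67 labelling index to the four-level ordinal scale
#'
#' Boundaries are right-closed exactly as conventionally stated:
#' `<= 5%` negative, `5% < x <= 20%` weak, `20% < x <= 40%` intermediate,
#' `> 40%` strong.
#'
#' @param percent Numeric vector of percentages in `[0, 100]`.
#' @return Ordered factor over `-`, `+`, `++`, `+++`.
#' @export
ki67_to_category <- function(percent) {
  percent <- as.numeric(percent)
  if (any(percent < 0 | percent > 100)) {
    abort("Ki-67 percentages must lie in [0, 100]")
  }
  codes <- ifelse(percent <= 5, 0L,
           ifelse(percent <= 20, 1L,
           ifelse(percent <= 40, 2L, 3L)))
  ordinal_factor(codes)
}

# Two-pass connected-component labelling with union-find; supports 4- and
# 8-connectivity (EBImage::bwlabel is 4-only, hence in-package).
label_components <- function(binary, connectivity = 8L) {
  h <- nrow(binary); w <- ncol(binary)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nxt <- 0L
  for (x in seq_len(w)) {
    for (y in seq_len(h)) {
      if (!binary[y, x]) next
      nb <- integer(0)
      if (y > 1 && binary[y - 1, x]) nb <- c(nb, lab[y - 1, x])
      if (x > 1 && binary[y, x - 1]) nb <- c(nb, lab[y, x - 1])
      if (connectivity == 8L) {
        if (y > 1 && x > 1 && binary[y - 1, x - 1]) nb <- c(nb, lab[y - 1, x - 1])
        if (y < h && x > 1 && binary[y + 1, x - 1]) nb <- c(nb, lab[y + 1, x - 1])
      }
      if (!length(nb)) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[y, x] <- nxt
      } else {
        roots <- vapply(nb, find, 1L)
        r <- min(roots)
        lab[y, x] <- r
        for (rr in roots) parent[rr] <- r
      }
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, 1L)
  remap <- match(roots, sort(unique(roots)))
  nz <- lab > 0L
  lab[nz] <- remap[lab[nz]]
  lab
}

#' Count stained and unstained cells in a label mask
#'
#' Cells are taken to be connected components of SP (stained) and NSP
#' (unstained) pixels, filtered by a minimum size. Components touching the
#' field border are counted. The positive-cell percentage is
#' `100 * positive / total`.
#'
#' @param labels Integer label matrix (1 = SP, 2 = NSP, 3 = BG).
#' @param connectivity Pixel connectivity, 4 or 8 (default 8).
#' @param min_size_px Minimum component area in pixels (default 30).
#' @return One-row tibble with `positive_cells`, `total_cells`,
#'   `percent_positive`.
#' @export
count_positive_cells <- function(labels, connectivity = 8L, min_size_px = 30L) {
  if (!connectivity %in% c(4L, 8L)) abort("connectivity must be 4 or 8")
  count_class <- function(k) {
    comp <- label_components(labels == k, connectivity)
    if (max(comp) == 0L) return(0L)
    sizes <- tabulate(comp[comp > 0L])
    sum(sizes >= min_size_px)
  }
  pos <- count_class(1L)
  neg <- count_class(2L)
  total <- pos + neg
  if (total == 0L) {
    abort("no cells detected: percent positive undefined",
          class = "ihcquant_empty_field")
  }
  tibble::tibble(
    positive_cells = pos,
    total_cells = total,
    percent_positive = 100 * pos / total
  )
}
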