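#' Train per-class colour models from labeled fields
#'
#' Pools pixels of each class (SP / NSP / BG) across a set of labeled
#' fields, subsamples them, and fits one Gaussian mixture per class by EM.
#' The conventional component counts are 5 (SP), 10 (NSP) and 2 (BG).
#'
#' @param fields List of `ihc_field` objects (e.g. from
#'   [generate_ihc_field()]), or any list of lists with elements `rgb` and
#'   `labels`.
#' @param C Named integer vector of component counts for `sp`, `nsp`, `bg`.
#' @param priors Class priors passed to [class_model_set()].
#' @param max_pixels_per_class Subsample cap per class (keeps EM fast).
#' @param seed Integer seed (subsampling + EM initialization).
#' @param ... Passed on to [fit_gmm_em()] (`tol`, `max_iter`, `reg`).
#' @return A [class_model_set()] with attribute `"fit_reports"` holding the
#'   three `gmm_fit` objects.
#' @export
train_class_models <- function(fields, C = c(sp = 5L, nsp = 10L, bg = 2L),
                               priors = c(1, 1, 1) / 3,
                               max_pixels_per_class = 20000L, seed = 1L, ...) {
  if (!length(fields)) abort("no training fields supplied")
  pix <- list(SP = NULL, NSP = NULL, BG = NULL)
  for (f in fields) {
    X <- cbind(as.numeric(f$rgb[, , 1]), as.numeric(f$rgb[, , 2]),
               as.numeric(f$rgb[, , 3]))
    for (k in 1:3) {
      idx <- which(as.vector(f$labels) == k)
      if (length(idx)) pix[[k]] <- rbind(pix[[k]], X[idx, , drop = FALSE])
    }
  }
  keys <- c("sp", "nsp", "bg")
  fits <- withr::with_seed(seed, {
    lapply(1:3, function(k) {
      X <- pix[[k]]
      ck <- C[[keys[k]]]
      if (is.null(X) || nrow(X) < ck) {
        abort(sprintf("too few %s pixels (%d) to fit %d components",
                      names(pix)[k], if (is.null(X)) 0L else nrow(X), ck))
      }
      if (nrow(X) > max_pixels_per_class) {
        X <- X[sample.int(nrow(X), max_pixels_per_class), , drop = FALSE]
      }
      fit_gmm_em(X, C = ck, seed = sample.int(.Machine$integer.max, 1), ...)
    })
  })
  set <- class_model_set(fits[[1]]$model, fits[[2]]$model, fits[[3]]$model,
                         priors = priors)
  attr(set, "fit_reports") <- setNames(fits, keys)
  set
}

#' Quantify expression across a set of fields
#'
#' Segments each field with the class models, computes the per-field
#' staining ratio, intensity and expression level, rejects fields without
#' cell pixels, and aggregates the survivors into a channel summary.
#'
#' @param images List of `H x W x 3` RGB arrays, `ihc_field` objects, or
#'   file paths to PNG images.
#' @param models A [class_model_set()].
#' @param signal Staining-signal definition, `"darkness"` or `"dab_od"`.
#' @param min_fields Minimum number of usable fields (default 5).
#' @return The [aggregate_fields()] summary; the per-field tibble (with a
#'   `field_id` column) is in attribute `"fields"`, any rejected field ids
#'   in attribute `"rejected"`.
#' @export
quantify_fields <- function(images, models, signal = c("darkness", "dab_od"),
                            min_fields = 5L) {
  signal <- match.arg(signal)
  if (!length(images)) abort("no images supplied")
  rows <- list()
  rejected <- character(0)
  for (i in seq_along(images)) {
    img <- images[[i]]
    id <- names(images)[i] %||% sprintf("field_%03d", i)
    if (is.character(img)) {
      id <- basename(img)
      img <- read_ihc_image(img)
    } else if (inherits(img, "ihc_field")) {
      img <- img$rgb
    }
    mask <- classify_pixels(img, models)
    row <- tryCatch(expression_level(img, mask, signal),
                    ihcquant_empty_field = function(e) NULL)
    if (is.null(row)) {
      rejected <- c(rejected, id)
    } else {
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(field_id = id), row
      )
    }
  }
  fields <- dplyr::bind_rows(rows)
  out <- aggregate_fields(fields, min_fields = min_fields)
  attr(out, "fields") <- fields
  attr(out, "rejected") <- rejected
  out
}

#' Table-style concordance report per biomarker
#'
#' Takes a long table of paired ordinal scores (one row per case and
#' biomarker) and produces one agreement row per biomarker: Kendall's W,
#' its chi-square test, Cohen's kappa with p-value, and percent
#' concordance with an exact 95% CI.
#'
#' @param ratings Data frame with columns `biomarker`, `method_a`,
#'   `method_b` (ordinal codes 0-3 or glyphs); a `paired_ratings` tibble
#'   from [generate_paired_ratings()] is accepted (a single unnamed
#'   biomarker).
#' @return Tibble with one row per biomarker, the columns of
#'   [agreement_report()] plus formatted p-value columns.
#' @export
concordance_report <- function(ratings) {
  tbl <- tibble::as_tibble(ratings)
  if (!"biomarker" %in% names(tbl)) tbl$biomarker <- "all"
  missing_cols <- setdiff(c("method_a", "method_b"), names(tbl))
  if (length(missing_cols)) {
    abort(paste("ratings lack column(s):", paste(missing_cols, collapse = ", ")))
  }
  tbl |>
    dplyr::group_by(.data$biomarker) |>
    dplyr::group_modify(function(d, key) {
      agreement_report(d$method_a, d$method_b)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      p_w_fmt = format_p(.data$p_w),
      p_kappa_fmt = format_p(.data$p_kappa)
    )
}

#' Read / write paired ratings CSV
#'
#' The interchange format is a CSV with columns `case_id`, `biomarker`
#' (optional), `method_a`, `method_b`, scores as codes 0-3 or glyphs.
#'
#' @param ratings A data frame of paired ratings.
#' @param path CSV file path.
#' @return `write_ratings_csv()` the path, invisibly; `read_ratings_csv()`
#'   a tibble with integer code columns.
#' @export
write_ratings_csv <- function(ratings, path) {
  readr::write_csv(tibble::as_tibble(ratings), path)
  invisible(path)
}

#' @rdname write_ratings_csv
#' @export
read_ratings_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  for (col in intersect(c("method_a", "method_b"), names(tbl))) {
    vals <- tbl[[col]]
    codes <- tryCatch(category_code(vals), error = function(e) {
      bad <- if (is.numeric(vals)) {
        which(!(as.integer(vals) %in% 0:3))
      } else {
        which(is.na(match(as.character(vals), ORDINAL_GLYPHS)))
      }
      abort(sprintf(
        "invalid ordinal category in column '%s' at data line(s) %s",
        col, paste(utils::head(bad, 5), collapse = ", ")
      ))
    })
    tbl[[col]] <- codes
  }
  tbl
}

#' @importFrom utils head
NULL
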