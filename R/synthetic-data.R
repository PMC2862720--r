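#' Default colour models for synthetic IHC fields
#'
#' Fixture mixtures mimicking the three colour populations of a DAB-stained,
#' hematoxylin-counterstained field: SP (stained cells) is a multi-modal
#' brown centred near RGB (140, 90, 60), NSP (counterstained cells) a
#' multi-modal hematoxylin blue near (120, 120, 180), and BG a near-white
#' background near (235, 230, 235). The multi-component structure imitates
#' the multi-modal class distributions of real chromogen / counterstain
#' colour clouds; the numbers are generator fixtures, not measurements.
#'
#' @return Named list with [mixture_model()] elements `sp`, `nsp`, `bg`.
#' @export
default_color_models <- function() {
  iso <- function(s) diag(s^2, 3)
  sp <- mixture_model(
    weights = c(0.5, 0.3, 0.2),
    means = rbind(c(140, 90, 60), c(110, 70, 45), c(165, 115, 80)),
    covs = list(iso(9), iso(8), iso(10))
  )
  nsp <- mixture_model(
    weights = c(0.4, 0.35, 0.25),
    means = rbind(c(120, 120, 180), c(95, 100, 160), c(145, 145, 200)),
    covs = list(iso(9), iso(9), iso(10))
  )
  bg <- mixture_model(
    weights = c(0.6, 0.4),
    means = rbind(c(235, 230, 235), c(245, 242, 244)),
    covs = list(iso(5), iso(4))
  )
  list(sp = sp, nsp = nsp, bg = bg)
}

#' Configuration for the synthetic IHC field generator
#'
#' Describes a synthetic micrograph: field size, number of cells (rendered
#' as disks), nucleus radius range, the fraction of cells that are stained,
#' and the per-class colour mixtures plus additive pixel noise.
#'
#' @param width_px,height_px Field size in pixels.
#' @param n_cells Number of cell disks to place.
#' @param nucleus_radius_px Length-2 positive range (min, max) of disk radii.
#' @param fraction_stained Fraction of cells drawn as stained (SP), in
#'   `[0, 1]`.
#' @param sp_color_model,nsp_color_model,bg_color_model [mixture_model()]s
#'   over RGB with means inside `[0, 255]^3`.
#' @param pixel_noise_sd Standard deviation of additive i.i.d. Gaussian
#'   noise applied per channel before clipping to `[0, 255]`.
#' @param allow_overlap Allow cell disks to overlap (overlaps are resolved
#'   by draw order, with stained cells drawn last)? When `FALSE`, disk
#'   centres are rejection-sampled so disks are disjoint, which makes the
#'   true cell count equal the component count of the label mask.
#' @param seed Integer seed; generation with the same config and seed is
#'   bit-identical.
#' @return A list of class `"image_gen_config"`.
#' @export
image_gen_config <- function(width_px = 128L, height_px = 128L,
                             n_cells = 60L,
                             nucleus_radius_px = c(4, 9),
                             fraction_stained = 0.3,
                             sp_color_model = default_color_models()$sp,
                             nsp_color_model = default_color_models()$nsp,
                             bg_color_model = default_color_models()$bg,
                             pixel_noise_sd = 4,
                             allow_overlap = TRUE,
                             seed = 1L) {
  if (width_px < 1 || height_px < 1) abort("field dimensions must be positive")
  if (n_cells < 0) abort("n_cells must be non-negative")
  if (length(nucleus_radius_px) != 2 || any(nucleus_radius_px <= 0) ||
      nucleus_radius_px[1] > nucleus_radius_px[2]) {
    abort("nucleus_radius_px must be a positive (min, max) range")
  }
  if (fraction_stained < 0 || fraction_stained > 1) {
    abort("fraction_stained must lie in [0, 1]")
  }
  if (pixel_noise_sd < 0) abort("pixel_noise_sd must be non-negative")
  for (m in list(sp_color_model, nsp_color_model, bg_color_model)) {
    stopifnot(inherits(m, "mixture_model"))
    if (any(m$means < 0) || any(m$means > 255)) {
      abort("colour-model means must lie within [0, 255]^3")
    }
  }
  structure(
    list(
      width_px = as.integer(width_px), height_px = as.integer(height_px),
      n_cells = as.integer(n_cells),
      nucleus_radius_px = as.numeric(nucleus_radius_px),
      fraction_stained = fraction_stained,
      sp_color_model = sp_color_model,
      nsp_color_model = nsp_color_model,
      bg_color_model = bg_color_model,
      pixel_noise_sd = pixel_noise_sd,
      allow_overlap = isTRUE(allow_overlap),
      seed = as.integer(seed)
    ),
    class = "image_gen_config"
  )
}

#' Draw i.i.d. samples from a Gaussian mixture
#'
#' @param model A [mixture_model()].
#' @param n Number of draws (`n >= 1`).
#' @param seed Integer seed; the same seed reproduces the sample exactly.
#' @return `n x d` numeric matrix of draws.
#' @export
generate_gmm_sample <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "mixture_model"))
  if (n < 1) abort("n must be at least 1")
  withr::with_seed(as.integer(seed), {
    comp <- sample.int(model$C, n, replace = TRUE, prob = model$weights)
    Z <- matrix(stats::rnorm(n * model$d), n, model$d)
    X <- matrix(0, n, model$d)
    for (j in seq_len(model$C)) {
      idx <- which(comp == j)
      if (!length(idx)) next
      R <- chol(model$covs[[j]])
      X[idx, ] <- Z[idx, , drop = FALSE] %*% R +
        matrix(model$means[j, ], length(idx), model$d, byrow = TRUE)
    }
    X
  })
}

# Paint a disk into an integer label matrix (1 = SP, 2 = NSP, 3 = BG).
paint_disk <- function(labels, cx, cy, r, value) {
  h <- nrow(labels); w <- ncol(labels)
  x0 <- max(1L, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(labels)
  xs <- x0:x1; ys <- y0:y1
  dx2 <- (xs - cx)^2
  dy2 <- (ys - cy)^2
  inside <- outer(dy2, dx2, "+") <= r^2
  block <- labels[ys, xs, drop = FALSE]
  block[inside] <- value
  labels[ys, xs] <- block
  labels
}

#' Generate a synthetic IHC field with exact ground truth
#'
#' Renders cells as disks on a background, labels every pixel as SP
#' (stained cell), NSP (counterstained cell) or BG, then colours each
#' region with draws from the corresponding mixture model plus additive
#' Gaussian noise, clipped and rounded to 8-bit. Overlapping disks are
#' resolved by draw order with all stained cells drawn last, so the label
#' mask - and therefore the recorded ground truth - stays exact.
#'
#' The recorded truth contains the staining ratio `|SP| / (|SP| + |NSP|)`
#' recomputed from the final label mask, and the mean darkness staining
#' intensity of the rendered SP pixels.
#'
#' @param config An [image_gen_config()].
#' @return An object of class `"ihc_field"`: list with `rgb`
#'   (`H x W x 3` array, 0-255), `labels` (integer `H x W`, 1 = SP,
#'   2 = NSP, 3 = BG), `truth` (list: `staining_ratio`,
#'   `staining_intensity`, `expression_level`, `n_cells_placed`,
#'   `n_sp_cells`) and the generating `config`.
#' @export
generate_ihc_field <- function(config) {
  stopifnot(inherits(config, "image_gen_config"))
  h <- config$height_px; w <- config$width_px
  withr::with_seed(config$seed, {
    labels <- matrix(3L, h, w) # BG
    n <- config$n_cells
    n_sp <- round(config$fraction_stained * n)
    centers <- NULL
    if (n > 0) {
      radii <- stats::runif(n, config$nucleus_radius_px[1], config$nucleus_radius_px[2])
      if (config$allow_overlap) {
        cx <- stats::runif(n, 1, w)
        cy <- stats::runif(n, 1, h)
      } else {
        cx <- cy <- numeric(n)
        placed <- 0L
        tries <- 0L
        while (placed < n && tries < 200L * n) {
          tries <- tries + 1L
          px <- stats::runif(1, 1 + radii[placed + 1L], w - radii[placed + 1L])
          py <- stats::runif(1, 1 + radii[placed + 1L], h - radii[placed + 1L])
          ok <- placed == 0L ||
            all((cx[seq_len(placed)] - px)^2 + (cy[seq_len(placed)] - py)^2 >
                  (radii[seq_len(placed)] + radii[placed + 1L] + 2)^2)
          if (ok) {
            placed <- placed + 1L
            cx[placed] <- px; cy[placed] <- py
          }
        }
        if (placed < n) abort("could not place non-overlapping cells; reduce n_cells")
      }
      # NSP cells first, SP last so staining wins overlaps deterministically.
      is_sp <- c(rep(FALSE, n - n_sp), rep(TRUE, n_sp))
      ord <- order(is_sp)
      for (i in ord) {
        labels <- paint_disk(labels, cx[i], cy[i], radii[i],
                             if (is_sp[i]) 1L else 2L)
      }
      centers <- tibble::tibble(x = cx, y = cy, r = radii, stained = is_sp)
    }

    rgb <- array(0, c(h, w, 3))
    models <- list(config$sp_color_model, config$nsp_color_model,
                   config$bg_color_model)
    for (k in 1:3) {
      idx <- which(labels == k)
      if (!length(idx)) next
      draws <- local({
        comp <- sample.int(models[[k]]$C, length(idx), replace = TRUE,
                           prob = models[[k]]$weights)
        Z <- matrix(stats::rnorm(length(idx) * 3), length(idx), 3)
        out <- matrix(0, length(idx), 3)
        for (j in seq_len(models[[k]]$C)) {
          sel <- which(comp == j)
          if (!length(sel)) next
          R <- chol(models[[k]]$covs[[j]])
          out[sel, ] <- Z[sel, , drop = FALSE] %*% R +
            matrix(models[[k]]$means[j, ], length(sel), 3, byrow = TRUE)
        }
        out
      })
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[idx] <- draws[, ch]
        rgb[, , ch] <- plane
      }
    }
    if (config$pixel_noise_sd > 0) {
      rgb <- rgb + array(stats::rnorm(length(rgb), 0, config$pixel_noise_sd), dim(rgb))
    }
    rgb <- round(pmin(pmax(rgb, 0), 255))

    n_sp_px <- sum(labels == 1L)
    n_nsp_px <- sum(labels == 2L)
    ratio <- if (n_sp_px + n_nsp_px > 0) n_sp_px / (n_sp_px + n_nsp_px) else NA_real_
    intensity <- if (n_sp_px > 0) {
      lum <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
      mean(1 - lum[labels == 1L] / 255)
    } else 0
    structure(
      list(
        rgb = rgb,
        labels = structure(labels, levels = CLASS_LEVELS),
        truth = list(
          staining_ratio = ratio,
          staining_intensity = intensity,
          expression_level = if (is.na(ratio)) NA_real_ else ratio * intensity,
          n_cells_placed = n,
          n_sp_cells = if (n > 0) sum(centers$stained) else 0L
        ),
        centers = centers,
        config = config
      ),
      class = "ihc_field"
    )
  })
}

#' @export
print.ihc_field <- function(x, ...) {
  cat(sprintf(
    "<ihc_field: %d x %d px, %d cells, truth ratio %.3f>\n",
    ncol(x$labels), nrow(x$labels), x$truth$n_cells_placed,
    x$truth$staining_ratio
  ))
  invisible(x)
}

#' Configuration for the paired ordinal ratings generator
#'
#' Generates paired 4-level ordinal scores over cases, as produced by two
#' scoring methods rating the same specimens. The first method draws from
#' `marginals`; the second copies the first with probability `agreement`
#' and otherwise draws from the corresponding row of `confusion_kernel`.
#'
#' @param n_cases Number of cases (positive).
#' @param marginals Length-4 probability vector over the ordinal categories
#'   (codes 0-3), summing to 1.
#' @param agreement Probability in `[0, 1]` that method B copies method A.
#' @param confusion_kernel Row-stochastic 4x4 matrix; row `i` is method B's
#'   distribution given method A chose category `i`, used on non-copy
#'   draws. Defaults to drawing from `marginals` independently.
#' @param seed Integer seed.
#' @return A list of class `"rating_gen_config"`.
#' @export
rating_gen_config <- function(n_cases = 105L,
                              marginals = c(0.4, 0.3, 0.2, 0.1),
                              agreement = 0.9,
                              confusion_kernel = NULL,
                              seed = 1L) {
  if (n_cases < 1) abort("n_cases must be positive")
  marginals <- as.numeric(marginals)
  if (length(marginals) != 4 || any(marginals < 0) ||
      abs(sum(marginals) - 1) > 1e-9) {
    abort("marginals must be 4 non-negative probabilities summing to 1")
  }
  if (agreement < 0 || agreement > 1) abort("agreement must lie in [0, 1]")
  if (is.null(confusion_kernel)) {
    confusion_kernel <- matrix(marginals, 4, 4, byrow = TRUE)
  }
  confusion_kernel <- as.matrix(confusion_kernel)
  if (!all(dim(confusion_kernel) == c(4, 4)) || any(confusion_kernel < 0) ||
      any(abs(rowSums(confusion_kernel) - 1) > 1e-9)) {
    abort("confusion_kernel must be a 4x4 row-stochastic matrix")
  }
  structure(
    list(
      n_cases = as.integer(n_cases), marginals = marginals,
      agreement = agreement, confusion_kernel = confusion_kernel,
      seed = as.integer(seed)
    ),
    class = "rating_gen_config"
  )
}

#' Generate paired 4-level ordinal ratings
#'
#' @param config A [rating_gen_config()].
#' @return A tibble with columns `case_id`, `method_a`, `method_b`
#'   (integer codes 0-3), of class `"paired_ratings"`.
#' @export
generate_paired_ratings <- function(config) {
  stopifnot(inherits(config, "rating_gen_config"))
  withr::with_seed(config$seed, {
    n <- config$n_cases
    a <- sample.int(4, n, replace = TRUE, prob = config$marginals) - 1L
    copy <- stats::runif(n) < config$agreement
    b <- a
    for (i in which(!copy)) {
      b[i] <- sample.int(4, 1, prob = config$confusion_kernel[a[i] + 1L, ]) - 1L
    }
    out <- tibble::tibble(case_id = seq_len(n), method_a = a, method_b = b)
    class(out) <- c("paired_ratings", class(out))
    out
  })
}

#' Write / read a synthetic field as portable plain files
#'
#' The RGB field is written as an 8-bit PNG, the label mask as a
#' single-channel PNG with grey codes 0 = BG, 1 = NSP, 2 = SP, and the
#' ground-truth quantities as a sidecar JSON pointing at the mask file.
#'
#' @param field An `ihc_field` from [generate_ihc_field()].
#' @param path Path of the image PNG; the mask and JSON take derived names
#'   (`*_mask.png`, `*.json`).
#' @return `write_ihc_field()` returns the three paths invisibly;
#'   `read_ihc_image()` returns an `H x W x 3` 0-255 array;
#'   `read_label_mask()` an integer label matrix (1 = SP, 2 = NSP, 3 = BG).
#' @export
write_ihc_field <- function(field, path) {
  stopifnot(inherits(field, "ihc_field"))
  png::writePNG(field$rgb / 255, path)
  mask_path <- sub("\\.png$", "_mask.png", path)
  json_path <- sub("\\.png$", ".json", path)
  # grey codes: 0 = BG, 1 = NSP, 2 = SP
  grey <- matrix(0L, nrow(field$labels), ncol(field$labels))
  grey[field$labels == 2L] <- 1L
  grey[field$labels == 1L] <- 2L
  png::writePNG(grey / 255, mask_path)
  jsonlite::write_json(
    list(mask = basename(mask_path), truth = field$truth,
         seed = field$config$seed),
    json_path, digits = NA, auto_unbox = TRUE
  )
  invisible(c(image = path, mask = mask_path, truth = json_path))
}

#' @rdname write_ihc_field
#' @export
read_ihc_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) abort("expected an RGB image, got single-channel")
  round(a[, , 1:3] * 255)
}

#' @rdname write_ihc_field
#' @export
read_label_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  grey <- round(a * 255)
  labels <- matrix(3L, nrow(grey), ncol(grey))
  labels[grey == 1L] <- 2L
  labels[grey == 2L] <- 1L
  attr(labels, "levels") <- CLASS_LEVELS
  labels
}
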