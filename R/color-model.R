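#' @importFrom rlang abort warn %||%
#' @importFrom stats kmeans cov pchisq pf pnorm qbeta setNames
NULL

CLASS_LEVELS <- c("SP", "NSP", "BG")

#' Construct a Gaussian mixture colour model
#'
#' A mixture model is a convex combination of multivariate Gaussian
#' densities, here over RGB colour space. Each component has a weight, a
#' mean colour and a full covariance matrix; the weights must sum to one.
#'
#' @param weights Numeric vector of positive component weights summing to 1.
#' @param means Numeric matrix, one row per component, `d` columns
#'   (typically `d = 3` for RGB means on the 0-255 scale).
#' @param covs List of `d x d` symmetric positive-definite covariance
#'   matrices, one per component.
#' @return An object of class `"mixture_model"` with elements `weights`,
#'   `means`, `covs`, and counts `C` (components) and `d` (dimension).
#' @examples
#' m <- mixture_model(1, matrix(c(0, 0, 0), 1), list(diag(3)))
#' mixture_density(c(0, 0, 0), m)
#' @export
mixture_model <- function(weights, means, covs) {
  weights <- as.numeric(weights)
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  means <- as.matrix(means)
  if (!is.list(covs)) covs <- list(covs)
  C <- length(weights)
  if (nrow(means) != C || length(covs) != C) {
    abort("weights, means and covs must describe the same number of components")
  }
  if (any(weights <= 0)) abort("component weights must be positive")
  if (abs(sum(weights) - 1) > 1e-9) {
    abort("component weights must sum to 1 (within 1e-9)")
  }
  d <- ncol(means)
  for (j in seq_len(C)) {
    S <- as.matrix(covs[[j]])
    if (!all(dim(S) == c(d, d))) abort(sprintf("covariance %d has wrong dimension", j))
    if (max(abs(S - t(S))) > 1e-8) abort(sprintf("covariance %d is not symmetric", j))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) abort(sprintf("covariance of component %d is not positive definite", j))
    covs[[j]] <- S
  }
  structure(
    list(weights = weights, means = means, covs = covs, C = C, d = d),
    class = "mixture_model"
  )
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("<mixture_model: %d component(s) in %d dimensions>\n", x$C, x$d))
  invisible(x)
}

# Per-component log Gaussian density for an N x d data matrix.
# Cholesky-based: numerically safe for byte-scale colour data.
log_gauss_density <- function(X, mean, cov, component = NA_integer_) {
  d <- length(mean)
  R <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(R)) {
    abort(sprintf(
      "covariance of component %s is singular or not positive definite",
      as.character(component)
    ))
  }
  logdet <- 2 * sum(log(diag(R)))
  Z <- backsolve(R, t(X) - mean, transpose = TRUE) # d x N
  quad <- colSums(Z^2)
  -0.5 * (d * log(2 * pi) + logdet + quad)
}

# N x C matrix of log(p_j) + log N(x; mu_j, Sigma_j)
component_log_densities <- function(X, model) {
  X <- matrix(as.numeric(X), ncol = model$d)
  vapply(seq_len(model$C), function(j) {
    log(model$weights[j]) +
      log_gauss_density(X, model$means[j, ], model$covs[[j]], j)
  }, numeric(nrow(X)))
}

log_sum_exp_rows <- function(M) {
  M <- matrix(M, ncol = ncol(as.matrix(M)))
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Evaluate the mixture density
#'
#' Computes `sum_j p_j N(x; mu_j, Sigma_j)`, the convex combination of the
#' component Gaussian densities, at one or more points.
#'
#' @param x Numeric vector of length `d`, or an `N x d` matrix of points.
#' @param model A [mixture_model()].
#' @param log Return the log density?
#' @return Numeric vector of (log) densities, one per row of `x`.
#' @export
mixture_density <- function(x, model, log = FALSE) {
  stopifnot(inherits(model, "mixture_model"))
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != model$d) abort("x has the wrong dimension for this model")
  ll <- log_sum_exp_rows(matrix(component_log_densities(X, model), nrow = nrow(X)))
  if (log) ll else exp(ll)
}

#' Fit a Gaussian mixture by expectation-maximization
#'
#' Maximum-likelihood estimation of a `C`-component Gaussian mixture with
#' full covariances. Responsibilities are computed in log space; each
#' M-step covariance receives a small ridge (`reg * I`, on the 0-255 colour
#' scale) so quantized colour samples cannot produce singular fits.
#' Initialization is k-means seeding under the supplied seed, so fits are
#' reproducible. Iteration stops when the relative log-likelihood
#' improvement falls below `tol` or `max_iter` is reached.
#'
#' @param samples `N x d` numeric matrix of observations (rows are points).
#' @param C Number of mixture components (`N >= C >= 1`).
#' @param seed Integer seed controlling initialization.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum number of EM iterations.
#' @param reg Ridge added to each covariance diagonal every M-step.
#' @return An object of class `"gmm_fit"`: a list with `model`
#'   (a [mixture_model()]), `loglik_trace`, `n_iter`, `converged`, `n`, and
#'   the settings used. `tidy()` and `glance()` methods are provided.
#' @export
fit_gmm_em <- function(samples, C, seed = 1L, tol = 1e-6, max_iter = 500L,
                       reg = 1e-3) {
  X <- as.matrix(samples)
  storage.mode(X) <- "double"
  N <- nrow(X)
  d <- ncol(X)
  if (C < 1) abort("C must be at least 1")
  if (N < C) abort(sprintf("need at least C = %d samples, got %d", C, N))

  # k-means seeding (reproducible under `seed`); collapse to distinct rows
  # if the sample has fewer unique points than clusters.
  init <- withr::with_seed(seed, {
    if (C == 1) {
      list(centers = matrix(colMeans(X), 1), cluster = rep(1L, N))
    } else {
      ux <- unique(X)
      if (nrow(ux) < C) abort("too few distinct samples for the requested C")
      suppressWarnings(stats::kmeans(X, centers = C, nstart = 3, iter.max = 50))
    }
  })

  weights <- tabulate(init$cluster, nbins = C) / N
  weights[weights == 0] <- 1 / N
  weights <- weights / sum(weights)
  means <- init$centers
  base_cov <- cov(X) * (N - 1) / N + diag(reg, d)
  covs <- lapply(seq_len(C), function(j) {
    idx <- which(init$cluster == j)
    if (length(idx) > d) {
      cov(X[idx, , drop = FALSE]) * (length(idx) - 1) / length(idx) + diag(reg, d)
    } else {
      base_cov
    }
  })

  loglik_trace <- numeric(0)
  converged <- FALSE
  ll_old <- -Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    model <- mixture_model(weights, means, covs)
    logd <- matrix(component_log_densities(X, model), nrow = N) # N x C
    lse <- log_sum_exp_rows(logd)
    ll <- sum(lse)
    loglik_trace <- c(loglik_trace, ll)
    resp <- exp(logd - lse) # responsibilities, rows sum to 1

    nk <- colSums(resp)
    if (any(nk < .Machine$double.eps * N)) {
      abort("a mixture component collapsed to zero responsibility; reduce C")
    }
    weights <- nk / N
    means <- t(resp) %*% X / nk
    covs <- lapply(seq_len(C), function(j) {
      Xc <- sweep(X, 2, means[j, ])
      S <- crossprod(Xc * resp[, j], Xc) / nk[j]
      S <- (S + t(S)) / 2 + diag(reg, d)
      S
    })

    if (is.finite(ll_old) &&
        (ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }

  structure(
    list(
      model = mixture_model(weights, means, covs),
      loglik_trace = loglik_trace,
      n_iter = iter,
      converged = converged,
      n = N,
      C = C,
      seed = seed,
      tol = tol,
      reg = reg
    ),
    class = "gmm_fit"
  )
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(
    "<gmm_fit: C = %d, n = %d, loglik = %.3f, %d iteration(s), %s>\n",
    x$C, x$n, x$loglik_trace[length(x$loglik_trace)], x$n_iter,
    if (x$converged) "converged" else "not converged"
  ))
  invisible(x)
}

#' @rdname fit_gmm_em
#' @param x A `gmm_fit` object.
#' @param ... Unused.
#' @export
tidy.gmm_fit <- function(x, ...) {
  m <- x$model
  tibble::tibble(
    component = seq_len(m$C),
    weight = m$weights,
    mean = lapply(seq_len(m$C), function(j) m$means[j, ]),
    cov = m$covs
  )
}

#' @rdname fit_gmm_em
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble::tibble(
    C = x$C,
    n = x$n,
    loglik = x$loglik_trace[length(x$loglik_trace)],
    n_iter = x$n_iter,
    converged = x$converged
  )
}

#' Bundle per-class colour models for Bayesian segmentation
#'
#' Holds one mixture model per pixel class - stained cell part (SP),
#' non-stained counterstained cell part (NSP) and background (BG) - together
#' with the class prior probabilities. The conventional component counts are
#' 5 for SP, 10 for NSP and 2 for BG; priors default to uniform.
#'
#' @param sp,nsp,bg [mixture_model()] objects for the three classes.
#' @param priors Length-3 probability vector (SP, NSP, BG), summing to 1.
#' @return An object of class `"class_model_set"`.
#' @export
class_model_set <- function(sp, nsp, bg, priors = c(1, 1, 1) / 3) {
  for (m in list(sp, nsp, bg)) stopifnot(inherits(m, "mixture_model"))
  priors <- as.numeric(priors)
  if (length(priors) != 3 || any(priors < 0) || abs(sum(priors) - 1) > 1e-9) {
    abort("priors must be 3 non-negative values summing to 1")
  }
  structure(
    list(sp = sp, nsp = nsp, bg = bg, priors = setNames(priors, CLASS_LEVELS)),
    class = "class_model_set"
  )
}

#' @export
print.class_model_set <- function(x, ...) {
  cat(sprintf(
    "<class_model_set: C = (SP %d, NSP %d, BG %d), priors = (%.3f, %.3f, %.3f)>\n",
    x$sp$C, x$nsp$C, x$bg$C, x$priors[1], x$priors[2], x$priors[3]
  ))
  invisible(x)
}

# N x 3 matrix of per-class log posterior numerators
class_log_scores <- function(X, set) {
  cbind(
    SP  = log(set$priors[1]) + mixture_density(X, set$sp, log = TRUE),
    NSP = log(set$priors[2]) + mixture_density(X, set$nsp, log = TRUE),
    BG  = log(set$priors[3]) + mixture_density(X, set$bg, log = TRUE)
  )
}

#' Posterior class probabilities for pixel colours
#'
#' Bayes' rule over the three class models: the posterior for class `c` is
#' proportional to `prior_c * f_c(x)` where `f_c` is that class's mixture
#' density. All work is done in log space, so extreme colours far from every
#' model underflow gracefully; only a colour assigned a hard zero prior by
#' every class (impossible with positive priors) errors.
#'
#' @param x RGB vector (length 3) or `N x 3` matrix of colours.
#' @param set A [class_model_set()].
#' @return Numeric vector (or `N x 3` matrix) of posterior probabilities in
#'   class order SP, NSP, BG, each row summing to 1.
#' @export
class_posteriors <- function(x, set) {
  stopifnot(inherits(set, "class_model_set"))
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1) else as.matrix(x)
  if (any(set$priors == 0)) {
    keep <- set$priors > 0
    if (!any(keep)) abort("all class priors are zero")
  }
  ls <- class_log_scores(X, set)
  bad <- !is.finite(apply(ls, 1, max))
  if (any(bad)) abort("posterior undefined: all class densities are zero for some input")
  post <- exp(ls - log_sum_exp_rows(ls))
  colnames(post) <- CLASS_LEVELS
  if (single) post[1, ] else post
}

#' Segment an RGB image into SP / NSP / BG
#'
#' Assigns every pixel the maximum-posterior class under the supplied class
#' model set. Ties are broken deterministically in the fixed order
#' SP > NSP > BG, which biases ties toward detecting staining.
#'
#' @param image `H x W x 3` numeric array of 8-bit RGB values (0-255).
#' @param set A [class_model_set()].
#' @return Integer `H x W` matrix with values 1 = SP, 2 = NSP, 3 = BG and
#'   attribute `levels = c("SP", "NSP", "BG")`.
#' @export
classify_pixels <- function(image, set) {
  stopifnot(inherits(set, "class_model_set"))
  dm <- dim(image)
  if (is.null(dm) || length(dm) != 3 || dm[3] != 3 || dm[1] * dm[2] == 0) {
    abort("image must be a non-empty H x W x 3 RGB array")
  }
  X <- cbind(as.numeric(image[, , 1]), as.numeric(image[, , 2]),
             as.numeric(image[, , 3]))
  ls <- class_log_scores(X, set)
  # max.col with ties.method = "first" realises the SP > NSP > BG tie-break
  # because the columns are already in that order.
  lab <- max.col(ls, ties.method = "first")
  out <- matrix(as.integer(lab), dm[1], dm[2])
  attr(out, "levels") <- CLASS_LEVELS
  out
}

#' Persist and restore class model sets as JSON
#'
#' Models round-trip through JSON with full double precision, so reloading
#' a model reproduces classifications bit-identically.
#'
#' @param set A [class_model_set()].
#' @param path File path for the JSON model.
#' @return `write_class_models()` returns `path` invisibly;
#'   `read_class_models()` returns the restored [class_model_set()].
#' @export
write_class_models <- function(set, path) {
  stopifnot(inherits(set, "class_model_set"))
  ser <- function(m) {
    list(components = lapply(seq_len(m$C), function(j) {
      list(weight = m$weights[j], mean = m$means[j, ], cov = m$covs[[j]])
    }))
  }
  obj <- list(
    priors = as.numeric(set$priors),
    classes = list(sp = ser(set$sp), nsp = ser(set$nsp), bg = ser(set$bg))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_class_models
#' @export
read_class_models <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  deser <- function(cl) {
    comps <- cl$components
    mixture_model(
      weights = vapply(comps, function(k) as.numeric(k$weight), 1),
      means = do.call(rbind, lapply(comps, function(k) as.numeric(unlist(k$mean)))),
      covs = lapply(comps, function(k) {
        # JSON stores the matrix as a list of rows; covariances are symmetric
        # so row- vs column-major is immaterial, but rebuild by rows anyway.
        do.call(rbind, lapply(k$cov, function(r) as.numeric(unlist(r))))
      })
    )
  }
  class_model_set(
    sp = deser(obj$classes$sp),
    nsp = deser(obj$classes$nsp),
    bg = deser(obj$classes$bg),
    priors = as.numeric(obj$priors)
  )
}
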