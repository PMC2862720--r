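# Shared fixtures, all generated in code.

# Random valid mixture over RGB: SPD covariances via A A' + ridge.
rand_mixture <- function(C, seed, d = 3) {
  withr::with_seed(seed, {
    w <- runif(C) + 0.2
    w <- w / sum(w)
    means <- matrix(runif(C * d, 30, 220), C, d)
    covs <- lapply(seq_len(C), function(j) {
      A <- matrix(rnorm(d * d, sd = 4), d, d)
      A %*% t(A) + diag(5, d)
    })
    mixture_model(w, means, covs)
  })
}

rand_class_set <- function(seed) {
  withr::with_seed(seed, {
    pri <- runif(3) + 0.1
    pri <- pri / sum(pri)
    class_model_set(
      rand_mixture(2, seed + 1), rand_mixture(3, seed + 2),
      rand_mixture(2, seed + 3), priors = pri
    )
  })
}

default_class_set <- function(priors = c(1, 1, 1) / 3) {
  cm <- default_color_models()
  class_model_set(cm$sp, cm$nsp, cm$bg, priors = priors)
}

# Independent hand evaluation of the mixture density: explicit per-component
# Gaussian formula with solve() and det(), summed term by term.
oracle_mixture_density <- function(x, model) {
  d <- model$d
  sum(vapply(seq_len(model$C), function(j) {
    S <- model$covs[[j]]
    diff <- x - model$means[j, ]
    model$weights[j] * (2 * pi)^(-d / 2) * det(S)^(-1 / 2) *
      exp(-0.5 * as.numeric(t(diff) %*% solve(S) %*% diff))
  }, 1))
}

# Brute-force Bayes rule with explicit normalization.
oracle_posterior <- function(x, set) {
  num <- set$priors * c(
    oracle_mixture_density(x, set$sp),
    oracle_mixture_density(x, set$nsp),
    oracle_mixture_density(x, set$bg)
  )
  num / sum(num)
}

# Class models trained once on synthetic fields and cached for the session.
cached_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fields <- lapply(1:3, function(s) {
        generate_ihc_field(image_gen_config(seed = 1000 + s))
      })
      cache <<- train_class_models(fields, max_pixels_per_class = 6000, seed = 99)
    }
    cache
  }
})
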