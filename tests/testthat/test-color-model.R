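test_that("mixture density matches the closed-form Gaussian peak and a hand summation", {
  m <- mixture_model(1, matrix(0, 1, 3), list(diag(3)))
  expect_equal(mixture_density(c(0, 0, 0), m), (2 * pi)^(-3 / 2), tolerance = 1e-12)

  for (seed in 1:5) {
    model <- rand_mixture(3, seed)
    x <- withr::with_seed(seed + 100, runif(3, 0, 255))
    expect_equal(mixture_density(x, model), oracle_mixture_density(x, model),
                 tolerance = 1e-12)
  }
})

test_that("mixture density is non-negative over random colours", {
  model <- rand_mixture(4, 7)
  X <- withr::with_seed(8, matrix(runif(3000, 0, 255), ncol = 3))
  expect_true(all(mixture_density(X, model) >= 0))
})

test_that("invalid mixtures are rejected", {
  expect_error(mixture_model(c(0.5, 0.6), matrix(0, 2, 3), list(diag(3), diag(3))),
               "sum to 1")
  expect_error(mixture_model(1, matrix(0, 1, 3), list(matrix(0, 3, 3))),
               "positive definite")
  bad <- diag(3); bad[1, 1] <- 0
  expect_error(mixture_model(1, matrix(0, 1, 3), list(bad)), "component 1")
})

test_that("one-component EM reproduces the closed-form MLE", {
  X <- withr::with_seed(3, matrix(rnorm(300, 100, 12), ncol = 3))
  fit <- fit_gmm_em(X, C = 1, seed = 1)
  expect_equal(fit$model$means[1, ], colMeans(X), tolerance = 1e-8,
               ignore_attr = TRUE)
  n <- nrow(X)
  expect_equal(fit$model$covs[[1]],
               cov(X) * (n - 1) / n + diag(fit$reg, 3), tolerance = 1e-8)
})

test_that("EM recovers two well-separated clusters and keeps weights on the simplex", {
  truth <- mixture_model(
    c(0.5, 0.5),
    rbind(c(40, 40, 40), c(200, 200, 200)),
    list(diag(25, 3), diag(25, 3))
  )
  X <- generate_gmm_sample(truth, 5000, seed = 11)
  fit <- fit_gmm_em(X, C = 2, seed = 5)
  expect_true(fit$converged)
  expect_equal(sum(fit$model$weights), 1, tolerance = 1e-9)
  # label-permutation-invariant matching of recovered means
  perm <- if (fit$model$means[1, 1] < fit$model$means[2, 1]) 1:2 else 2:1
  for (j in 1:2) {
    expect_lt(
      max(abs(fit$model$means[perm[j], ] - truth$means[j, ]) / truth$means[j, ]),
      0.05
    )
  }
})

test_that("EM log-likelihood is non-decreasing and errors on tiny samples", {
  X <- generate_gmm_sample(rand_mixture(3, 21), 400, seed = 22)
  fit <- fit_gmm_em(X, C = 3, seed = 4)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_error(fit_gmm_em(X[1:2, ], C = 3), "at least C")
})

test_that("tidy and glance summarise a fit", {
  fit <- fit_gmm_em(generate_gmm_sample(rand_mixture(2, 1), 300, seed = 2),
                    C = 2, seed = 3)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$weight), 1, tolerance = 1e-9)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$C, 2)
})

test_that("class posteriors follow Bayes' rule and normalize", {
  for (seed in 1:10) {
    set <- rand_class_set(seed)
    # points drawn from one of the class mixtures, so the (non-log) oracle
    # evaluates without underflow
    x <- generate_gmm_sample(set$nsp, 1, seed = seed + 50)[1, ]
    post <- class_posteriors(x, set)
    expect_equal(sum(post), 1, tolerance = 1e-12)
    expect_equal(unname(post), unname(oracle_posterior(x, set)), tolerance = 1e-10)
    # far from every class, the log-space path must still normalize
    far <- withr::with_seed(seed, runif(3, 0, 255))
    expect_equal(sum(class_posteriors(far, set)), 1, tolerance = 1e-12)
  }
})

test_that("posteriors collapse to the dominant class and cancel identical likelihoods", {
  near <- mixture_model(1, matrix(c(50, 50, 50), 1), list(diag(1, 3)))
  far1 <- mixture_model(1, matrix(c(200, 200, 200), 1), list(diag(1, 3)))
  far2 <- mixture_model(1, matrix(c(0, 200, 0), 1), list(diag(1, 3)))
  set <- class_model_set(near, far1, far2)
  post <- class_posteriors(c(50, 50, 50), set)
  expect_equal(unname(post), c(1, 0, 0), tolerance = 1e-6)

  same <- class_model_set(near, near, near, priors = c(0.2, 0.3, 0.5))
  expect_equal(unname(class_posteriors(c(120, 10, 240), same)),
               c(0.2, 0.3, 0.5), tolerance = 1e-9)
})

test_that("classification equals the per-pixel posterior argmax with SP-first ties", {
  set <- default_class_set()
  field <- generate_ihc_field(image_gen_config(width_px = 24, height_px = 20, seed = 5))
  mask <- classify_pixels(field$rgb, set)
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      post <- class_posteriors(field$rgb[i, j, ], set)
      expect_equal(unname(mask[i, j]), unname(which.max(post)))
    }
  }
})

test_that("classification is invariant to rescaling the priors", {
  field <- generate_ihc_field(image_gen_config(width_px = 32, height_px = 32, seed = 9))
  m1 <- default_class_set(priors = c(0.2, 0.5, 0.3))
  # same ratios, different absolute scale before the constructor renormalizes
  m2 <- default_class_set(priors = c(0.2, 0.5, 0.3) * 4 / sum(c(0.2, 0.5, 0.3) * 4))
  expect_identical(classify_pixels(field$rgb, m1), classify_pixels(field$rgb, m2))
})

test_that("a uniform image at the background mean is all background", {
  set <- default_class_set()
  img <- array(0, c(8, 8, 3))
  img[, , 1] <- 235; img[, , 2] <- 230; img[, , 3] <- 235
  expect_true(all(classify_pixels(img, set) == 3L))
  expect_error(classify_pixels(array(0, c(0, 4, 3)), set), "non-empty")
})

test_that("segmentation of well-separated synthetic fields is at least 98% correct", {
  models <- cached_models()
  accs <- vapply(1:10, function(s) {
    f <- generate_ihc_field(image_gen_config(seed = 300 + s))
    mean(classify_pixels(f$rgb, models) == f$labels)
  }, 1)
  expect_true(all(accs >= 0.98))
})

test_that("model JSON round-trips to full precision", {
  models <- cached_models()
  path <- withr::local_tempfile(fileext = ".json")
  write_class_models(models, path)
  back <- read_class_models(path)
  expect_equal(back$priors, models$priors, tolerance = 1e-12)
  for (cl in c("sp", "nsp", "bg")) {
    expect_equal(back[[cl]]$weights, models[[cl]]$weights, tolerance = 1e-12)
    expect_equal(back[[cl]]$means, models[[cl]]$means, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  f <- generate_ihc_field(image_gen_config(width_px = 48, height_px = 48, seed = 77))
  expect_identical(classify_pixels(f$rgb, models), classify_pixels(f$rgb, back))
})

test_that("EM agrees with an established mixture fitter on a separable sample", {
  truth <- mixture_model(
    c(0.5, 0.5), rbind(c(60, 60, 60), c(180, 180, 180)),
    list(diag(16, 3), diag(16, 3))
  )
  X <- generate_gmm_sample(truth, 2000, seed = 31)
  fit <- fit_gmm_em(X, C = 2, seed = 6)
  withr::local_package("mclust")
  mc <- mclust::Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  mu_mine <- fit$model$means[order(fit$model$means[, 1]), ]
  mu_mc <- t(mc$parameters$mean)[order(t(mc$parameters$mean)[, 1]), ]
  expect_equal(mu_mine, mu_mc, tolerance = 0.01, ignore_attr = TRUE)
})
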