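test_that("a one-component fit equals the closed-form mean and covariance", {
  set.seed(31)
  x <- matrix(rnorm(400 * 4), ncol = 4)
  fit <- fit_gmm(x, n_components = 1, seed = 1)
  mle_cov <- stats::cov(x) * (nrow(x) - 1) / nrow(x) + 1e-6 * diag(4)
  expect_equal(drop(fit$means), colMeans(x), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fit$covariances[[1]], mle_cov, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fit$weights, 1)
  expect_true(all(diff(fit$training_log) >= -1e-9))
})

test_that("EM recovers a well-separated two-component mixture", {
  skip_if_not_installed("MASS")
  true_w <- c(0.3, 0.7)
  mu <- rbind(c(0, 0), c(1, 0))          # unit-distance means
  sd0 <- 0.2
  for (s in 1:10) {
    set.seed(200 + s)
    n1 <- rbinom(1, 5000, true_w[1])
    x <- rbind(MASS::mvrnorm(n1, mu[1, ], sd0^2 * diag(2)),
               MASS::mvrnorm(5000 - n1, mu[2, ], sd0^2 * diag(2)))
    fit <- fit_gmm(x, n_components = 2, seed = s)
    ord <- order(fit$means[, 1])
    expect_lt(max(abs(fit$weights[ord] - true_w)), 0.02)
    expect_lt(max(abs(fit$means[ord, ] - mu)), 0.05)
    expect_true(all(diff(fit$training_log) >= -1e-9))
    expect_lt(abs(sum(fit$weights) - 1), 1e-12)
  }
})

test_that("EM is deterministic given the seed and guards identifiability", {
  set.seed(33)
  x <- matrix(rnorm(600 * 3), ncol = 3)
  a <- fit_gmm(x, 3, seed = 7)
  b <- fit_gmm(x, 3, seed = 7)
  expect_identical(a$weights, b$weights)
  expect_identical(a$means, b$means)
  expect_identical(a$covariances, b$covariances)
  expect_error(fit_gmm(x[1:20, ], 8), "fewer components")
})

test_that("diagonal covariance mode fits and scores", {
  set.seed(34)
  x <- matrix(rnorm(500 * 3), ncol = 3)
  fit <- fit_gmm(x, 2, covariance_mode = "diagonal", seed = 2)
  expect_equal(dim(fit$covariances), c(2, 3))
  expect_true(all(fit$covariances >= 1e-6))
  expect_true(all(is.finite(predict(fit, x))))
  expect_true(all(diff(fit$training_log) >= -1e-9))
})

test_that("average NLL matches closed form and a brute-force density oracle", {
  m <- fit_gmm(matrix(rnorm(300 * 13), ncol = 13), 1, seed = 1)
  m$means[1, ] <- 0
  m$covariances[[1]] <- diag(13)
  at_mean <- matrix(0, 1, 13)
  expect_equal(average_nll(at_mean, m), 13 / 2 * log(2 * pi),
               tolerance = 1e-12)

  set.seed(35)
  x <- matrix(rnorm(40 * 3), ncol = 3)
  fit <- fit_gmm(matrix(rnorm(200 * 3), ncol = 3), 2, seed = 4)
  want <- -mean(log(oracle_mixture_density(x, fit$weights, fit$means,
                                           fit$covariances)))
  expect_equal(average_nll(x, fit), want, tolerance = 1e-8)

  # duplicating frames leaves the average unchanged
  expect_equal(average_nll(rbind(x, x), fit), average_nll(x, fit),
               tolerance = 1e-12)
})

test_that("mixture log density agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(38)
  x <- matrix(rnorm(300 * 3), ncol = 3)
  fit <- fit_gmm(x, 3, seed = 6)
  sigma <- array(unlist(fit$covariances), dim = c(3, 3, 3))
  cholsigma <- array(unlist(lapply(fit$covariances, chol)),
                     dim = c(3, 3, 3))
  params <- list(pro = fit$weights, mean = t(fit$means),
                 variance = list(modelName = "VVV", d = 3, G = 3,
                                 sigma = sigma, cholsigma = cholsigma))
  ref <- mclust::dens(modelName = "VVV", data = x, parameters = params,
                      logarithm = TRUE)
  expect_equal(average_nll(x, fit), -mean(ref), tolerance = 1e-8)
})

test_that("mixture density integrates to one (K = 1, D = 1)", {
  fit <- fit_gmm(matrix(rnorm(100), ncol = 1), 1, seed = 1)
  mu <- drop(fit$means); sd_ <- sqrt(fit$covariances[[1]][1, 1])
  dens <- function(z) predict(fit, matrix(z, ncol = 1), type = "density")
  got <- stats::integrate(dens, mu - 8 * sd_, mu + 8 * sd_,
                          rel.tol = 1e-9)$value
  expect_equal(got, 1, tolerance = 1e-6)
})

test_that("classification picks the lowest average NLL and swaps antisymmetrically", {
  set.seed(36)
  x <- matrix(rnorm(100 * 3), ncol = 3)
  near <- fit_gmm(x, 1, seed = 1)
  far <- near
  far$means <- far$means + 20 * sqrt(mean(diag(far$covariances[[1]])))
  sc <- classify_subject(x, model_ph = near, model_nonph = far, "s")
  expect_identical(sc$predicted, "PH")
  expect_lt(sc$nll_ratio, 1)

  swapped <- classify_subject(x, model_ph = far, model_nonph = near, "s")
  expect_identical(swapped$predicted, "non-PH")
  expect_equal(swapped$nll_ph, sc$nll_nonph)
  expect_equal(swapped$nll_nonph, sc$nll_ph)

  expect_message(tie <- classify_subject(x, near, near, "s"), "tie")
  expect_equal(tie$nll_ratio, 1.0)
  expect_identical(tie$predicted, "non-PH")
})

test_that("simulate() round-trips through fitting", {
  set.seed(37)
  base <- fit_gmm(matrix(rnorm(300 * 2), ncol = 2), 1, seed = 1)
  base$means[1, ] <- c(3, -2)
  draws <- simulate(base, nsim = 4000, seed = 9)
  expect_equal(colMeans(draws), c(3, -2), tolerance = 0.1)
})

test_that("model JSON serialization round-trips and enforces fingerprints", {
  rec <- clean_subject(mpap = 40, seed = 41)
  f <- subject_features(extract_s2_segments(rec))
  fit <- fit_gmm(f, n_components = 2, seed = 3)
  expect_identical(fit$fingerprint, f$fingerprint)
  path <- withr::local_tempfile(fileext = ".json")
  write_gmm(fit, path)
  back <- read_gmm(path)
  expect_equal(back$weights, fit$weights, tolerance = 1e-12)
  expect_equal(back$means, fit$means, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$covariances[[2]], fit$covariances[[2]],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(average_nll(f, back), average_nll(f, fit), tolerance = 1e-10)

  other <- subject_features(extract_s2_segments(rec),
                            mfcc_config(n_mel_filters = 22))
  expect_error(average_nll(other, back), "fingerprint")
})
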