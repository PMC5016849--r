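# Independent brute-force oracles. These deliberately avoid the package's
# computational paths (no FFT, no log-sum-exp, no threshold sweep) so they
# can certify them.

# Power spectrum by direct DFT summation and cepstrum by the explicit
# orthonormal cosine sum, mirroring only the *definitions* of the steps.
oracle_mfcc <- function(frame, filterbank, config) {
  nfft <- attr(filterbank, "fft_length")
  nbins <- nfft %/% 2 + 1
  x <- c(frame, rep(0, nfft - length(frame)))
  n <- seq_along(x) - 1
  power <- vapply(seq_len(nbins) - 1, function(k) {
    re <- sum(x * cos(2 * pi * k * n / nfft))
    im <- -sum(x * sin(2 * pi * k * n / nfft))
    re^2 + im^2
  }, 0)
  energies <- as.numeric(filterbank %*% power)
  floor_ <- max(1e-12 * max(energies), 1e-30)
  logE <- log(pmax(energies, floor_))
  M <- length(logE)
  D <- config$n_coefficients
  vapply(seq_len(D) - 1, function(k) {
    ck <- sum(logE * cos(pi * k * (2 * (seq_len(M) - 1) + 1) / (2 * M)))
    ck * sqrt(2 / M) * (if (k == 0) 1 / sqrt(2) else 1)
  }, 0)
}

# Mixture density per row by plain summation of multivariate normal
# densities (explicit quadratic forms, no Cholesky reuse, no log tricks).
oracle_mixture_density <- function(x, weights, means, covs) {
  apply(x, 1, function(row) {
    sum(vapply(seq_along(weights), function(k) {
      S <- covs[[k]]
      d <- row - means[k, ]
      weights[k] * exp(-0.5 * drop(t(d) %*% solve(S) %*% d)) /
        sqrt((2 * pi)^length(d) * det(S))
    }, 0))
  })
}

# AUC as the normalized Mann-Whitney U by exhaustive pair counting.
# Orientation matches the pipeline statistic: lower score = more PH-like.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == "PH"]
  neg <- scores[labels == "non-PH"]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p < q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Two-proportion test p-value by exact enumeration: the distribution of the
# chi-squared statistic under independent binomials at the pooled rate.
oracle_two_prop_p <- function(x1, n1, x2, n2) {
  stat <- function(a, b) {
    p1 <- a / n1; p2 <- b / n2; pp <- (a + b) / (n1 + n2)
    if (pp == 0 || pp == 1) return(0)
    (p1 - p2)^2 / (pp * (1 - pp) * (1 / n1 + 1 / n2))
  }
  obs <- stat(x1, x2)
  pp <- (x1 + x2) / (n1 + n2)
  p <- 0
  for (a in 0:n1) for (b in 0:n2) {
    if (stat(a, b) >= obs - 1e-12)
      p <- p + stats::dbinom(a, n1, pp) * stats::dbinom(b, n2, pp)
  }
  p
}
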