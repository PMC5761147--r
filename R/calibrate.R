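#' Gumbel (extreme-value) parameter container
#'
#' @param mu Location parameter.
#' @param lambda Scale parameter (> 0).
#' @param n_samples,sample_len,seed Provenance of the calibration sample.
#' @return A `gumbel_params` object.
#' @export
gumbel_params <- function(mu, lambda, n_samples = NA_integer_,
                          sample_len = NA_integer_, seed = NA_integer_) {
  stopifnot(is.finite(mu), is.finite(lambda), lambda > 0)
  structure(list(mu = mu, lambda = lambda, n_samples = n_samples,
                 sample_len = sample_len, seed = seed),
            class = "gumbel_params")
}

#' Maximum-likelihood fit of a Gumbel distribution
#'
#' Fits location `mu` and scale `lambda` of the Gumbel law
#' `F(x) = exp(-exp(-lambda * (x - mu)))` to a score sample. `lambda` is
#' obtained by solving the profile-likelihood score equation with
#' [stats::uniroot] (bracketed around the method-of-moments start
#' `pi / (sd * sqrt(6))`), then `mu = -log(mean(exp(-lambda x))) / lambda`.
#'
#' @param x Numeric sample (length >= 2, not all equal).
#' @return A [gumbel_params].
#' @export
fit_gumbel <- function(x) {
  stopifnot(length(x) >= 2)
  if (diff(range(x)) < 1e-9) stop("degenerate (all-equal) score sample")
  xm <- mean(x)
  # centre for numerical stability of exp(-lambda * x)
  xc <- x - xm
  g <- function(lam) {
    w <- exp(-lam * xc)
    1 / lam - mean(xc) + sum(xc * w) / sum(w)
  }
  lam0 <- pi / (stats::sd(x) * sqrt(6))
  lo <- lam0 / 100; hi <- lam0 * 100
  lam <- stats::uniroot(g, c(lo, hi), tol = 1e-12, extendInt = "yes")$root
  mu <- xm - log(mean(exp(-lam * xc))) / lam
  gumbel_params(mu, lam)
}

#' Calibrate a profile against random background sequences
#'
#' Scores `n_samples` i.i.d. sequences drawn from the profile's background
#' residue distribution and fits a Gumbel law to the resulting bit scores
#' by maximum likelihood. The fitted parameters feed [evalue]. The run is
#' deterministic given `seed`.
#'
#' @param p A `profile_hmm`.
#' @param n_samples Number of random sequences (>= 50; default 200).
#' @param sample_len Length of each random sequence (default 350).
#' @param seed RNG seed (default 42); recorded in the result.
#' @return A [gumbel_params].
#' @export
calibrate <- function(p, n_samples = 200L, sample_len = 350L, seed = 42L) {
  if (n_samples < 50L) stop("calibration requires n_samples >= 50")
  stopifnot(sample_len >= 10L)
  scores <- with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      s <- paste(sample(AA20, sample_len, replace = TRUE,
                        prob = p$background), collapse = "")
      viterbi_score(p, s)$bit_score
    }, 0)
  })
  if (diff(range(scores)) < 1e-9) stop("degenerate calibration sample")
  g <- fit_gumbel(scores)
  g$n_samples <- as.integer(n_samples)
  g$sample_len <- as.integer(sample_len)
  g$seed <- as.integer(seed)
  g
}

#' Calibrate a profile in place
#' @inheritParams calibrate
#' @return The profile with its `calibration` field set.
#' @export
calibrate_profile <- function(p, n_samples = 200L, sample_len = 350L,
                              seed = 42L) {
  p$calibration <- calibrate(p, n_samples, sample_len, seed)
  p
}

#' E-value of a bit score under a Gumbel calibration
#'
#' Expected number of random sequences, out of `n_targets`, scoring at
#' least `bit_score`:
#' `E = n_targets * (1 - exp(-exp(-lambda * (s - mu))))`. Strictly
#' decreasing in the score and exactly linear in `n_targets`.
#'
#' @param g A [gumbel_params] (or a calibrated `profile_hmm`).
#' @param bit_score Numeric score(s).
#' @param n_targets Number of sequences in the scanned set (> 0).
#' @return Numeric E-value(s).
#' @export
evalue <- function(g, bit_score, n_targets = 1) {
  if (inherits(g, "profile_hmm")) g <- g$calibration
  if (is.null(g)) stop("profile is not calibrated")
  if (n_targets <= 0) stop("n_targets must be positive")
  n_targets * (-expm1(-exp(-g$lambda * (bit_score - g$mu))))
}
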