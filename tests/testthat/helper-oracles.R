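# Independent oracles and shared fixtures for the test suite.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# ---- brute-force Viterbi oracle -------------------------------------------
# Exhaustive enumeration of every legal local path (entry at any match
# state, exit at any match state), computed recursively and entirely
# independently of the package's dynamic program. Tractable for profile
# length <= 3 and sequence length <= 4.
oracle_viterbi <- function(p, s) {
  codes <- match(strsplit(toupper(s), "")[[1]], AA20)
  n <- length(codes)
  L <- p$L
  lodds <- log2(p$match / rep(p$background, each = L))
  ltM <- log2(p$tM); ltI <- log2(p$tI); ltD <- log2(p$tD)
  emit <- function(j, i) if (is.na(codes[i])) 0 else lodds[j, codes[i]]

  fM <- function(j, i) {          # arrive at M_j, emit residue i
    if (i > n) return(-Inf)
    e <- emit(j, i)
    best <- e                      # exit here
    if (j < L) {
      best <- max(best,
                  e + ltM[j, "MM"] + fM(j + 1L, i + 1L),
                  e + ltM[j, "MI"] + fI(j, i + 1L),
                  e + ltM[j, "MD"] + fD(j + 1L, i + 1L))
    }
    best
  }
  fI <- function(j, i) {          # arrive at I_j, emit residue i (bg, 0)
    if (i > n) return(-Inf)
    max(ltI[j, "IM"] + fM(j + 1L, i + 1L),
        ltI[j, "II"] + fI(j, i + 1L))
  }
  fD <- function(j, i) {          # arrive at D_j, consume nothing
    if (j >= L) return(-Inf)      # dead end: exit only from match states
    max(ltD[j, "DM"] + fM(j + 1L, i),
        ltD[j, "DD"] + fD(j + 1L, i))
  }
  entry <- -log2(L)
  best <- -Inf
  for (j0 in seq_len(L))
    for (i0 in seq_len(n))
      best <- max(best, entry + fM(j0, i0))
  best
}

# random, fully-parameterised small profile (valid distributions, all
# probabilities positive) for oracle-equivalence checks
random_small_profile <- function(L, seed) {
  set.seed(seed)
  rdist <- function(k) { x <- stats::rexp(k) + 0.05; x / sum(x) }
  p <- list(family = "rnd", L = L,
            alphabet = paste(AA20, collapse = ""),
            match = t(vapply(seq_len(L), function(j) rdist(20L),
                             numeric(20L))),
            background = stats::setNames(rdist(20L), AA20),
            tM = matrix(NA_real_, max(L - 1L, 0L), 3L,
                        dimnames = list(NULL, c("MM", "MI", "MD"))),
            tI = matrix(NA_real_, max(L - 1L, 0L), 2L,
                        dimnames = list(NULL, c("IM", "II"))),
            tD = matrix(NA_real_, max(L - 1L, 0L), 2L,
                        dimnames = list(NULL, c("DM", "DD"))),
            pseudocount = 1, calibration = NULL)
  colnames(p$match) <- AA20
  if (L > 1L) for (j in seq_len(L - 1L)) {
    p$tM[j, ] <- rdist(3L); p$tI[j, ] <- rdist(2L); p$tD[j, ] <- rdist(2L)
  }
  structure(p, class = "profile_hmm")
}

# ---- regular-expression motif oracle --------------------------------------
# Overlapping matches via lookahead; independent of scan_motif's
# position-constraint implementation. X fails the explicit classes and
# matches the "." wildcards, like the implementation's rule.
oracle_motif_regex <- function(s, name) {
  pat <- switch(name,
                classI_aspRich = "(?=DD..[DE])",
                classI_NSE_DTE = "(?=[ND]D[LIV].[ST]...E)",
                classII_DxDD = "(?=D.DD)")
  m <- gregexpr(pat, toupper(s), perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# inverse-CDF Gumbel sampler for the calibration recovery check
rgumbel <- function(n, mu, lambda) mu - log(-log(stats::runif(n))) / lambda

# random protein string from background frequencies
random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE, prob = terpscan::aa_background()),
        collapse = "")
}

# ---- shared heavy fixture --------------------------------------------------
# The default 12+1-family synthetic benchmark and its trained, calibrated
# banks, built once per test run and reused across test files.
.fixture_env <- new.env(parent = emptyenv())

benchmark_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    bm <- generate_benchmark(seed = 42L)
    banks <- train_banks(bm$train)
    profiles12 <- c(banks$FB$profiles, banks$GB$profiles)
    .fixture_env$fx <- list(bm = bm, banks = banks, profiles12 = profiles12)
  }
  .fixture_env$fx
}
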