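#' Family rosters of the three classification schemes
#'
#' The default configuration carries 13 profiles: six function-based (FB)
#' families — mono-, di- and sesquiterpene synthases, each trained
#' separately for dicots (`D`) and monocots (`M`) —, six gene-family (GB)
#' clades TPSa..TPSg (TPSe and TPSf merged as `TPSe_f`), and one prenyl
#' transferase (PT) profile.
#'
#' @return Named list of character vectors `FB`, `GB`, `PT`.
#' @export
scheme_families <- function() {
  list(FB = c("DiD", "DiM", "MonoD", "MonoM", "SesD", "SesM"),
       GB = c("TPSa", "TPSb", "TPSc", "TPSd", "TPSe_f", "TPSg"),
       PT = "PT")
}

#' Bundle profiles into a scheme bank
#'
#' @param profiles Named list of `profile_hmm` objects (names = families).
#' @param scheme `"FB"`, `"GB"` or `"PT"`. The profile set must be exactly
#'   the scheme's family roster (see [scheme_families]).
#' @return A `profile_bank`.
#' @export
profile_bank <- function(profiles, scheme = c("FB", "GB", "PT")) {
  scheme <- match.arg(scheme)
  if (!length(profiles)) stop("empty profile bank")
  want <- scheme_families()[[scheme]]
  have <- sort(names(profiles))
  if (!identical(sort(want), have))
    stop(scheme, " bank must contain exactly: ", paste(want, collapse = ", "),
         " (got: ", paste(have, collapse = ", "), ")")
  structure(list(scheme = scheme, profiles = profiles[sort(names(profiles))]),
            class = "profile_bank")
}

#' @export
print.profile_bank <- function(x, ...) {
  cat("profile bank [", x$scheme, "]: ",
      paste(names(x$profiles), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Train a profile for each family of labelled training sequences
#'
#' Sequences sharing a `label` are treated as one family; each family's
#' (un-gapped or aligned) rows are turned into an [alignment], weighted
#' with [henikoff_weights], compiled with [build_profile] and calibrated
#' with [calibrate].
#'
#' @param train A labelled protein [tps_seqs] (rows with label
#'   `"negative"` or `NA` are ignored).
#' @param families Which families to train (default: all labels present).
#' @param pseudocount Additive pseudocount for [build_profile].
#' @param gap_threshold Match-column gap threshold.
#' @param calibrate_n,calibrate_len Calibration sample size and length.
#' @param seed Base seed for per-profile calibration.
#' @return Named list of calibrated `profile_hmm` objects.
#' @export
train_profiles <- function(train, families = NULL, pseudocount = 1,
                           gap_threshold = 0.5, calibrate_n = 200L,
                           calibrate_len = 350L, seed = 42L) {
  labs <- unique(train$label)
  labs <- labs[!is.na(labs) & labs != "negative"]
  if (!is.null(families)) {
    missing <- setdiff(families, labs)
    if (length(missing))
      stop("no training sequences for: ", paste(missing, collapse = ", "))
    labs <- families
  }
  profiles <- lapply(seq_along(labs), function(k) {
    fam <- labs[k]
    aln <- alignment(train[train$label == fam, , drop = FALSE], family = fam)
    mask <- select_match_columns(aln, gap_threshold)
    w <- henikoff_weights(aln, mask)
    p <- build_profile(aln, w, mask, pseudocount = pseudocount, family = fam)
    calibrate_profile(p, calibrate_n, calibrate_len,
                      seed = child_seed(seed, k))
  })
  stats::setNames(profiles, labs)
}

#' Train the full three-scheme bank configuration
#'
#' @param train Labelled training sequences covering all 13 families.
#' @param schemes Which schemes to train (default all three).
#' @param ... Passed to [train_profiles].
#' @return Named list of `profile_bank`s keyed by scheme.
#' @export
train_banks <- function(train, schemes = c("FB", "GB", "PT"), ...) {
  rosters <- scheme_families()[schemes]
  stats::setNames(lapply(schemes, function(sc)
    profile_bank(train_profiles(train, families = rosters[[sc]], ...),
                 scheme = sc)), schemes)
}

#' Write a bank's profiles to a directory
#' @param banks A `profile_bank` or named list of banks.
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_banks <- function(banks, dir) {
  if (inherits(banks, "profile_bank")) banks <- list(banks)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- unlist(lapply(banks, function(b)
    vapply(b$profiles, function(p) {
      path <- file.path(dir, paste0(b$scheme, "_", p$family, ".hmm"))
      write_profile(p, path)
      path
    }, "")))
  invisible(paths)
}

#' Read banks written by [write_banks]
#' @param dir Directory of `<scheme>_<family>.hmm` files.
#' @param schemes Schemes to load.
#' @return Named list of `profile_bank`s.
#' @export
read_banks <- function(dir, schemes = c("FB", "GB", "PT")) {
  files <- list.files(dir, pattern = "\\.hmm$", full.names = TRUE)
  if (!length(files)) stop("no profile files in ", dir)
  sc <- sub("_.*$", "", basename(files))
  stats::setNames(lapply(schemes, function(s) {
    ps <- lapply(files[sc == s], read_profile)
    profile_bank(stats::setNames(ps, vapply(ps, function(p) p$family, "")),
                 scheme = s)
  }), schemes)
}
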