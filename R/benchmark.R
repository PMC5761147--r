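#' Stratified train/test split of labelled families
#'
#' Per family, `ceiling(test_fraction * n)` sequences are held out for
#' testing; the split is disjoint and deterministic given `seed`.
#'
#' @param seqs A labelled [tps_seqs] (every row must carry a `label`).
#' @param test_fraction Fraction held out per family, in `(0, 1)`.
#' @param seed RNG seed.
#' @return List with `train` and `test` [tps_seqs].
#' @export
split_train_test <- function(seqs, test_fraction = 0.1, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  if (any(is.na(seqs$label))) stop("all sequences must be labelled")
  test_idx <- with_seed(seed, {
    unlist(lapply(sort(unique(seqs$label)), function(fam) {
      idx <- which(seqs$label == fam)
      if (length(idx) < 2L)
        stop("family '", fam, "' has < 2 members; cannot split")
      sample(idx, ceiling(test_fraction * length(idx)))
    }))
  })
  list(train = seqs[-test_idx, , drop = FALSE],
       test = seqs[sort(test_idx), , drop = FALSE])
}

#' Bit-score and E-value matrices of a bank over a test set
#'
#' @param profiles Named list of `profile_hmm`s, or a `profile_bank`.
#' @param seqs A protein [tps_seqs].
#' @param n_targets E-value database size; defaults to `nrow(seqs)`.
#' @return List of two `length(profiles) x nrow(seqs)` matrices `bits`
#'   and `evalues` (dimnames: family x sequence id).
#' @export
score_matrix <- function(profiles, seqs, n_targets = nrow(seqs)) {
  if (inherits(profiles, "profile_bank")) profiles <- profiles$profiles
  profiles <- profiles[sort(names(profiles))]
  bits <- matrix(NA_real_, length(profiles), nrow(seqs),
                 dimnames = list(names(profiles), seqs$id))
  ev <- bits
  for (f in seq_along(profiles)) {
    p <- profiles[[f]]
    for (i in seq_len(nrow(seqs))) {
      b <- viterbi_score(p, seqs$residues[i])$bit_score
      bits[f, i] <- b
      if (!is.null(p$calibration))
        ev[f, i] <- evalue(p$calibration, b, n_targets)
    }
  }
  list(bits = bits, evalues = ev)
}

#' Per-family sensitivity and accuracy of a profile bank
#'
#' Reproduces the two evaluation modes of the classifier benchmark:
#' * `single`: each profile independently predicts positive for any test
#'   sequence whose E-value passes `evalue_max`. Cross-family homology
#'   makes this mode sensitive but imprecise.
#' * `combined`: all profiles scan each sequence in parallel and the
#'   sequence is assigned to the argmax-bit-score family (provided its
#'   E-value passes); false cross-family positives are thereby eliminated
#'   whenever the true family's own profile ranks first.
#'
#' Sensitivity is `TP / (TP + FN)`; accuracy is the positive predictive
#' value `TP / (TP + FP)`.
#'
#' @param profiles Named list of `profile_hmm`s (or a `profile_bank`) —
#'   for the classical 12-profile evaluation, the union of the FB and GB
#'   profiles.
#' @param test A labelled [tps_seqs]; labels must be profile families or
#'   `"negative"`.
#' @param mode `"combined"` (default) or `"single"`.
#' @param evalue_max Positive-call threshold (default 0.01).
#' @param scores Optional precomputed [score_matrix] (avoids rescanning
#'   when evaluating both modes on the same data).
#' @return A `benchmark_result` data frame: one row per family with
#'   `TP`, `FP`, `FN`, `sensitivity`, `accuracy`, `mode`. Families with no
#'   positives in the test set report `sensitivity = NA`.
#' @export
evaluate_bank <- function(profiles, test, mode = c("combined", "single"),
                          evalue_max = 0.01, scores = NULL) {
  mode <- match.arg(mode)
  if (inherits(profiles, "profile_bank")) profiles <- profiles$profiles
  if (nrow(test) == 0L) stop("empty test set")
  fams <- sort(names(profiles))
  extra <- setdiff(unique(test$label), c(fams, "negative"))
  if (length(extra))
    stop("test labels outside bank families: ", paste(extra, collapse = ", "))
  if (is.null(scores)) scores <- score_matrix(profiles, test)
  bits <- scores$bits[fams, , drop = FALSE]
  ev <- scores$evalues[fams, , drop = FALSE]
  pass <- !is.na(ev) & ev <= evalue_max

  if (mode == "single") {
    predicted <- pass   # family x sequence logical matrix
  } else {
    predicted <- matrix(FALSE, nrow(bits), ncol(bits), dimnames = dimnames(bits))
    for (i in seq_len(ncol(bits))) {
      ord <- order(-bits[, i], fams)
      top <- ord[1L]
      if (pass[top, i]) predicted[top, i] <- TRUE
    }
  }
  truth <- outer(fams, test$label, "==")
  res <- data.frame(
    family = fams,
    TP = rowSums(predicted & truth),
    FP = rowSums(predicted & !truth),
    FN = rowSums(!predicted & truth),
    stringsAsFactors = FALSE)
  res$sensitivity <- ifelse(res$TP + res$FN > 0,
                            res$TP / (res$TP + res$FN), NA_real_)
  res$accuracy <- ifelse(res$TP + res$FP > 0,
                         res$TP / (res$TP + res$FP), NA_real_)
  res$mode <- mode
  class(res) <- c("benchmark_result", "data.frame")
  res
}
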