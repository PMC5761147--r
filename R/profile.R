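#' Build a profile HMM from a weighted alignment
#'
#' Match-state emission probabilities are weighted residue counts with an
#' additive (Laplace) pseudocount:
#' `(sum of weights of rows carrying residue a + pc) / (column weight total
#' + 20 * pc)`. Insert states emit the background distribution. Node
#' transitions (M->M/I/D, I->M/I, D->M/D) are estimated from the weighted
#' observed state events of each row with the same additive pseudocount.
#' The background is the weighted pooled residue frequency of the whole
#' alignment, smoothed additively. Gap and ambiguous (`X`/`B`/`Z`)
#' characters contribute nothing to emission counts.
#'
#' @param aln A [alignment].
#' @param weights Row weights, e.g. from [henikoff_weights] (default).
#' @param mask Match-column mask, e.g. from [select_match_columns] (default).
#' @param pseudocount Additive pseudocount, must be > 0 (default 1).
#' @param family Family label stored on the model.
#' @return A `profile_hmm`: list with `family`, `L`, `match` (L x 20
#'   probability matrix), `background`, `tM`/`tI`/`tD` transition matrices
#'   (rows are source nodes 1..L-1), `pseudocount`, `calibration`.
#' @export
build_profile <- function(aln,
                          weights = henikoff_weights(aln, mask),
                          mask = select_match_columns(aln),
                          pseudocount = 1,
                          family = aln$family) {
  if (length(aln$ids) < 2L) stop("profile requires an alignment with >= 2 rows")
  stopifnot(pseudocount > 0, length(weights) == nrow(aln$mat),
            length(mask) == aln$width)
  match_cols <- which(mask)
  L <- length(match_cols)
  if (L < 1L) stop("mask selects zero match columns")
  nr <- nrow(aln$mat)
  pc <- pseudocount

  emit <- matrix(0, nrow = L, ncol = 20L, dimnames = list(NULL, AA20))
  for (j in seq_len(L)) {
    col <- aln$mat[, match_cols[j]]
    ok <- col %in% AA20
    cnt <- vapply(AA20, function(a) sum(weights[ok & col == a]), 0)
    emit[j, ] <- (cnt + pc) / (sum(weights[ok]) + 20 * pc)
  }

  # background: weighted pooled residue frequencies over all columns
  bg_cnt <- stats::setNames(numeric(20L), AA20)
  for (c0 in seq_len(aln$width)) {
    col <- aln$mat[, c0]
    ok <- col %in% AA20
    if (any(ok))
      bg_cnt[col[ok]] <- bg_cnt[col[ok]] + weights[ok]
  }
  background <- (bg_cnt + pc) / (sum(bg_cnt) + 20 * pc)

  # transition counts between consecutive nodes, per row, weighted.
  # state at node j is M (residue) or D (gap); residues in insert columns
  # between nodes j and j+1 are I events. D->I and I->D are not part of
  # the state graph and are skipped.
  tM <- matrix(pc, nrow = max(L - 1L, 0L), ncol = 3L,
               dimnames = list(NULL, c("MM", "MI", "MD")))
  tI <- matrix(pc, nrow = max(L - 1L, 0L), ncol = 2L,
               dimnames = list(NULL, c("IM", "II")))
  tD <- matrix(pc, nrow = max(L - 1L, 0L), ncol = 2L,
               dimnames = list(NULL, c("DM", "DD")))
  if (L > 1L) {
    ins_between <- function(j) {
      lo <- match_cols[j]; hi <- match_cols[j + 1L]
      if (hi - lo < 2L) return(rep(0, nr))
      cols <- aln$mat[, (lo + 1L):(hi - 1L), drop = FALSE]
      rowSums(cols != "-")
    }
    for (j in seq_len(L - 1L)) {
      s_from <- ifelse(aln$mat[, match_cols[j]] == "-", "D", "M")
      s_to <- ifelse(aln$mat[, match_cols[j + 1L]] == "-", "D", "M")
      n_ins <- ins_between(j)
      for (i in seq_len(nr)) {
        w <- weights[i]
        if (n_ins[i] > 0) {
          if (s_from[i] == "M") tM[j, "MI"] <- tM[j, "MI"] + w
          if (n_ins[i] > 1) tI[j, "II"] <- tI[j, "II"] + w * (n_ins[i] - 1)
          if (s_to[i] == "M") tI[j, "IM"] <- tI[j, "IM"] + w
        } else {
          key <- paste0(s_from[i], s_to[i])
          if (key == "MM") tM[j, "MM"] <- tM[j, "MM"] + w
          else if (key == "MD") tM[j, "MD"] <- tM[j, "MD"] + w
          else if (key == "DM") tD[j, "DM"] <- tD[j, "DM"] + w
          else tD[j, "DD"] <- tD[j, "DD"] + w
        }
      }
    }
    tM <- tM / rowSums(tM)
    tI <- tI / rowSums(tI)
    tD <- tD / rowSums(tD)
  }

  structure(list(family = if (is.null(family)) NA_character_ else family,
                 L = L, alphabet = paste(AA20, collapse = ""),
                 match = emit, background = background,
                 tM = tM, tI = tI, tD = tD,
                 pseudocount = pc, calibration = NULL),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile HMM '", x$family, "': ", x$L, " match states",
      if (!is.null(x$calibration))
        sprintf("; Gumbel(mu=%.2f, lambda=%.3f)", x$calibration$mu,
                x$calibration$lambda) else "; uncalibrated",
      "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a profile (argmax emission per match state)
#' @param p A `profile_hmm`.
#' @return A protein string of length `p$L`.
#' @export
profile_consensus <- function(p) {
  paste(AA20[max.col(p$match, ties.method = "first")], collapse = "")
}

#' Score a protein sequence against a profile HMM (local Viterbi, bits)
#'
#' Computes the best local alignment score in bits,
#' `log2 P(path, s | profile) / P(s | background)`, by dynamic programming
#' over match/insert/delete states. Entry is uniform over match states
#' (cost `log2(1/L)`), exit is free from any match state, and unmatched
#' flanking residues are scored by the null model (net contribution 0).
#' Ambiguity codes `X`/`B`/`Z` emit the background distribution, i.e.
#' log-odds 0.
#'
#' @param p A `profile_hmm`.
#' @param s A protein string or single-row [tps_seqs].
#' @return A `tps_score`: list with `bit_score`, `path` (string over
#'   `M`/`I`/`D`), `query_span` and `model_span` (1-based inclusive).
#' @export
viterbi_score <- function(p, s) {
  if (!is.character(s)) {
    stopifnot(nrow(s) == 1L)
    s <- s$residues
  }
  s <- toupper(s)
  if (!nzchar(s)) stop("empty sequence")
  codes <- match(strsplit(s, "")[[1]], AA20) - 1L
  codes[is.na(codes)] <- -1L   # ambiguous: background emission
  lodds <- log2(p$match / rep(p$background, each = p$L))
  res <- viterbi_dp(codes, lodds,
                    log2(p$tM), log2(p$tI), log2(p$tD))
  structure(list(bit_score = res$score,
                 path = res$path,
                 query_span = c(res$qstart, res$qend),
                 model_span = c(res$mstart, res$mend),
                 family = p$family),
            class = "tps_score")
}

#' Render a simple profile-query alignment
#'
#' Shows the profile consensus against the aligned query span of a
#' [viterbi_score] result, with `|` marking identities to the consensus.
#'
#' @param score A `tps_score`.
#' @param p The profile it was computed with.
#' @param s The query sequence (string or single-row [tps_seqs]).
#' @return Character vector of three display lines.
#' @export
format_alignment <- function(score, p, s) {
  if (!is.character(s)) s <- s$residues
  cons <- strsplit(profile_consensus(p), "")[[1]]
  q <- strsplit(toupper(s), "")[[1]]
  states <- strsplit(score$path, "")[[1]]
  i <- score$query_span[1]; j <- score$model_span[1]
  top <- qrow <- mid <- character(length(states))
  for (k in seq_along(states)) {
    st <- states[k]
    if (st == "M") {
      top[k] <- cons[j]; qrow[k] <- q[i]
      mid[k] <- if (cons[j] == q[i]) "|" else " "
      i <- i + 1L; j <- j + 1L
    } else if (st == "I") {
      top[k] <- "."; qrow[k] <- tolower(q[i]); mid[k] <- " "
      i <- i + 1L
    } else {
      top[k] <- cons[j]; qrow[k] <- "-"; mid[k] <- " "
      j <- j + 1L
    }
  }
  c(sprintf("%-10s %s", p$family, paste(top, collapse = "")),
    sprintf("%-10s %s", "", paste(mid, collapse = "")),
    sprintf("%-10s %s", "query", paste(qrow, collapse = "")))
}

# ---- serialization ---------------------------------------------------------

#' Write a profile HMM to a plain-text file
#'
#' The format is line-oriented: a header (`family`, `length`, `alphabet`,
#' `pseudocount`, optional `calibration`), a `background` line, one
#' `match` line of 20 emission probabilities per node and one `trans` line
#' (MM MI MD IM II DM DD) per source node 1..L-1. Values are written with
#' 12 significant digits so a read/write round trip is stable.
#'
#' @param p A `profile_hmm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path) {
  num <- function(x) paste(sprintf("%.12g", x), collapse = " ")
  con <- file(path, "w"); on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# terpscan profile HMM v1")
  wl("family ", p$family)
  wl("length ", p$L)
  wl("alphabet ", p$alphabet)
  wl("pseudocount ", sprintf("%.12g", p$pseudocount))
  if (!is.null(p$calibration))
    wl("calibration ", num(c(p$calibration$mu, p$calibration$lambda,
                             p$calibration$n_samples,
                             p$calibration$sample_len, p$calibration$seed)))
  wl("background ", num(p$background))
  for (j in seq_len(p$L)) wl("match ", j, " ", num(p$match[j, ]))
  for (j in seq_len(p$L - 1L))
    wl("trans ", j, " ", num(c(p$tM[j, ], p$tI[j, ], p$tD[j, ])))
  invisible(path)
}

#' Read a profile HMM written by [write_profile]
#' @param path Path to a profile file.
#' @return A `profile_hmm`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, " +")
  key <- vapply(fields, `[`, "", 1L)
  getv <- function(k) fields[[match(k, key)]][-1L]
  L <- as.integer(getv("length"))
  p <- list(family = getv("family"), L = L,
            alphabet = getv("alphabet"),
            pseudocount = as.numeric(getv("pseudocount")),
            calibration = NULL)
  if ("calibration" %in% key) {
    v <- as.numeric(getv("calibration"))
    p$calibration <- gumbel_params(v[1], v[2], n_samples = v[3],
                                   sample_len = v[4], seed = v[5])
  }
  p$background <- stats::setNames(as.numeric(getv("background")), AA20)
  p$match <- matrix(0, L, 20L, dimnames = list(NULL, AA20))
  p$tM <- matrix(NA_real_, max(L - 1L, 0L), 3L,
                 dimnames = list(NULL, c("MM", "MI", "MD")))
  p$tI <- matrix(NA_real_, max(L - 1L, 0L), 2L,
                 dimnames = list(NULL, c("IM", "II")))
  p$tD <- matrix(NA_real_, max(L - 1L, 0L), 2L,
                 dimnames = list(NULL, c("DM", "DD")))
  for (f in fields[key == "match"])
    p$match[as.integer(f[2L]), ] <- as.numeric(f[-(1:2)])
  for (f in fields[key == "trans"]) {
    j <- as.integer(f[2L]); v <- as.numeric(f[-(1:2)])
    p$tM[j, ] <- v[1:3]; p$tI[j, ] <- v[4:5]; p$tD[j, ] <- v[6:7]
  }
  structure(p, class = "profile_hmm")
}
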