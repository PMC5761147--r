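fb_class_map <- function(family) {
  cls <- c(Mono = "monoterpene synthase", Di = "diterpene synthase",
           Ses = "sesquiterpene synthase")
  stem <- sub("[DM]$", "", family)
  list(functional_class = unname(cls[stem]),
       taxon = if (grepl("M$", family)) "monocot" else "dicot")
}

#' Scan one sequence against every profile of a bank
#'
#' All profiles of the bank score the sequence in parallel (conceptually:
#' results are identical, bit for bit, to sequential scanning) and the
#' hits are ranked by bit score, descending, with ties broken by
#' lexicographic family name. The ranking is independent of the order in
#' which profiles were inserted into the bank.
#'
#' @param bank A `profile_bank`.
#' @param s A protein string or single-row [tps_seqs].
#' @param n_targets Database-size multiplier for E-values (default 1).
#' @return Data frame of hits: `family`, `bit_score`, `e_value`,
#'   `qstart`, `qend`, `mstart`, `mend`, sorted best first.
#' @export
scan_bank <- function(bank, s, n_targets = 1) {
  if (!length(bank$profiles)) stop("empty profile bank")
  hits <- lapply(bank$profiles, function(p) {
    sc <- viterbi_score(p, s)
    data.frame(family = p$family, bit_score = sc$bit_score,
               e_value = if (is.null(p$calibration)) NA_real_ else
                 evalue(p$calibration, sc$bit_score, n_targets),
               qstart = sc$query_span[1], qend = sc$query_span[2],
               mstart = sc$model_span[1], mend = sc$model_span[2],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  hits <- hits[order(-hits$bit_score, hits$family), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Classify a protein sequence under each scheme
#'
#' For every scheme independently, the sequence is assigned the family of
#' its highest-scoring profile, provided the top hit passes the reporting
#' E-value threshold; otherwise it is `"unclassified"`. Schemes are
#' independent: a sequence legitimately receives both an FB and a GB call.
#' FB assignments additionally report the implied functional class
#' (mono-/di-/sesquiterpene synthase) and taxon profile (dicot/monocot).
#'
#' @param banks Named list of `profile_bank`s (from [train_banks]).
#' @param s Protein string or single-row [tps_seqs].
#' @param evalue_max Reporting E-value threshold (default 10, the protein
#'   path default; EST peptides use [classify_est] and 0.01).
#' @param n_targets Database-size multiplier for E-values.
#' @return A `tps_classification`: list with `query_id`, `input_type`,
#'   `calls` (one data-frame row per scheme) and `hits` (ranked hit table
#'   per scheme).
#' @export
assign_family <- function(banks, s, evalue_max = 10, n_targets = 1) {
  if (inherits(banks, "profile_bank")) banks <- list(banks)
  query_id <- if (is.character(s)) "query" else s$id
  hits <- lapply(banks, scan_bank, s = s, n_targets = n_targets)
  calls <- do.call(rbind, lapply(names(hits), function(sc) {
    top <- hits[[sc]][1L, ]
    pass <- is.na(top$e_value) || top$e_value <= evalue_max
    fam <- if (pass) top$family else "unclassified"
    extra <- if (banks[[sc]]$scheme == "FB" && pass) fb_class_map(fam) else
      list(functional_class = NA_character_, taxon = NA_character_)
    data.frame(query_id = query_id, scheme = banks[[sc]]$scheme,
               family = fam, bit_score = top$bit_score,
               e_value = top$e_value,
               qstart = top$qstart, qend = top$qend,
               functional_class = extra$functional_class,
               taxon = extra$taxon,
               frame = NA_integer_, offset_aa = NA_integer_,
               stringsAsFactors = FALSE)
  }))
  structure(list(query_id = query_id, input_type = "protein",
                 calls = calls, hits = hits, reason = NULL),
            class = "tps_classification")
}

#' Classify an EST (nucleotide) sequence
#'
#' The nucleotide query is six-frame translated, each frame is split at
#' stop codons into candidate peptides of at least `min_len` residues, and
#' every peptide is scanned against every bank. Per scheme, the best
#' (peptide, profile) pair by bit score wins; assignment requires its
#' E-value (Bonferroni-scaled by the number of candidate peptides) to pass
#' the EST filter of 0.01. The provenance (frame, amino-acid offset) of
#' the winning peptide is recorded.
#'
#' @param banks Named list of `profile_bank`s.
#' @param nuc Nucleotide string or single-row DNA [tps_seqs].
#' @param min_len Minimum peptide length (default 50).
#' @param evalue_max EST E-value filter (default 0.01).
#' @param genetic_code NCBI genetic-code table number.
#' @return A `tps_classification` (input_type `"est"`); when no peptide
#'   reaches `min_len`, every scheme is `"unclassified"` and `reason` is
#'   set.
#' @export
classify_est <- function(banks, nuc, min_len = 50L, evalue_max = 0.01,
                         genetic_code = 1L) {
  if (inherits(banks, "profile_bank")) banks <- list(banks)
  if (is.character(nuc)) nuc <- tps_seqs("query", nuc, alphabet = "DNA")
  frames <- six_frame_translate(nuc, genetic_code)
  peps <- split_orfs(frames, min_len)
  empty_call <- function(sc) data.frame(
    query_id = nuc$id, scheme = sc, family = "unclassified",
    bit_score = NA_real_, e_value = NA_real_, qstart = NA_integer_,
    qend = NA_integer_, functional_class = NA_character_,
    taxon = NA_character_, frame = NA_integer_, offset_aa = NA_integer_,
    stringsAsFactors = FALSE)
  if (nrow(peps) == 0L) {
    calls <- do.call(rbind, lapply(names(banks), empty_call))
    return(structure(list(query_id = nuc$id, input_type = "est",
                          calls = calls, hits = list(),
                          reason = sprintf("no ORF >= %d aa", min_len)),
                     class = "tps_classification"))
  }
  n_pep <- nrow(peps)
  calls <- list(); hits_out <- list()
  for (sc in names(banks)) {
    per_pep <- lapply(seq_len(n_pep), function(i)
      cbind(scan_bank(banks[[sc]], peps[i, , drop = FALSE],
                      n_targets = n_pep),
            frame = peps$frame[i], offset_aa = peps$offset_aa[i],
            peptide_id = peps$id[i]))
    all_hits <- do.call(rbind, per_pep)
    all_hits <- all_hits[order(-all_hits$bit_score, all_hits$family), ,
                         drop = FALSE]
    top <- all_hits[1L, ]
    pass <- !is.na(top$e_value) && top$e_value <= evalue_max
    hits_out[[sc]] <- all_hits
    if (!pass) {
      cl <- empty_call(sc)
      cl$bit_score <- top$bit_score; cl$e_value <- top$e_value
      calls[[sc]] <- cl
    } else {
      extra <- if (sc == "FB") fb_class_map(top$family) else
        list(functional_class = NA_character_, taxon = NA_character_)
      calls[[sc]] <- data.frame(
        query_id = nuc$id, scheme = sc, family = top$family,
        bit_score = top$bit_score, e_value = top$e_value,
        qstart = top$qstart, qend = top$qend,
        functional_class = extra$functional_class, taxon = extra$taxon,
        frame = top$frame, offset_aa = top$offset_aa,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(query_id = nuc$id, input_type = "est",
                 calls = do.call(rbind, calls), hits = hits_out,
                 reason = NULL),
            class = "tps_classification")
}

#' Classify every sequence of a FASTA file
#'
#' @param banks Named list of `profile_bank`s.
#' @param path Path to a protein or nucleotide FASTA file.
#' @param input_type `"protein"` or `"est"`.
#' @param evalue_max Reporting threshold (default 10 for protein, 0.01
#'   for EST).
#' @param ... Passed to [assign_family] / [classify_est].
#' @return Data frame with one row per (input sequence, scheme), in input
#'   order: `query_id`, `scheme`, `family`, `bit_score`, `e_value`,
#'   `qstart`, `qend`, `functional_class`, `taxon`, `frame`, `offset_aa`.
#' @export
classify_fasta <- function(banks, path, input_type = c("protein", "est"),
                           evalue_max = NULL, ...) {
  input_type <- match.arg(input_type)
  if (is.null(evalue_max))
    evalue_max <- if (input_type == "protein") 10 else 0.01
  seqs <- read_fasta(path,
                     alphabet = if (input_type == "protein") "AA" else "DNA")
  rows <- lapply(seq_len(nrow(seqs)), function(i) {
    res <- tryCatch({
      if (input_type == "protein")
        assign_family(banks, seqs[i, , drop = FALSE],
                      evalue_max = evalue_max, ...)
      else
        classify_est(banks, seqs[i, , drop = FALSE],
                     evalue_max = evalue_max, ...)
    }, error = function(e)
      stop("record ", i, " (", seqs$id[i], "): ", conditionMessage(e)))
    res$calls
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
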