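#' Diterpene-synthase signature motif patterns
#'
#' The three catalytic signature motifs used to sub-classify diterpene
#' synthases:
#' * `classI_aspRich` — aspartate-rich `DDxxD/E` (length 5), the class I
#'   divalent-metal binding motif of ionization-initiated synthases;
#' * `classI_NSE_DTE` — the non-aspartate-rich "NSE/DTE" consensus
#'   `(N,D) D (L,I,V) x (S,T) x x x E` (length 9), the alternative class I
#'   metal-binding motif;
#' * `classII_DxDD` — `DxDD` (length 4), the class II motif of
#'   protonation-initiated cyclases.
#'
#' Each pattern is an ordered list of position constraints: a character
#' vector of allowed residues, or `NULL` for a wildcard position.
#'
#' @return Named list of `motif_pattern` objects.
#' @export
motif_patterns <- function() {
  mk <- function(name, positions)
    structure(list(name = name, positions = positions,
                   length = length(positions)), class = "motif_pattern")
  list(
    classI_aspRich = mk("classI_aspRich",
                        list("D", "D", NULL, NULL, c("D", "E"))),
    classI_NSE_DTE = mk("classI_NSE_DTE",
                        list(c("N", "D"), "D", c("L", "I", "V"), NULL,
                             c("S", "T"), NULL, NULL, NULL, "E")),
    classII_DxDD = mk("classII_DxDD", list("D", NULL, "D", "D"))
  )
}

#' Scan a protein sequence for a signature motif
#'
#' Reports every (possibly overlapping) 0-based start position at which all
#' constrained positions of the pattern match exactly. Wildcard positions
#' match any residue, including `X`; `X` never satisfies a constrained
#' position (unknown residues are treated conservatively so low-quality
#' translations do not produce spurious class I calls).
#'
#' @param s A protein string or single-row [tps_seqs].
#' @param pattern A `motif_pattern` from [motif_patterns] (or its name).
#' @return Integer vector of 0-based start positions (possibly empty).
#' @export
#' @examples
#' scan_motif("DDIYD", "classI_aspRich")
scan_motif <- function(s, pattern) {
  if (is.character(pattern)) pattern <- motif_patterns()[[pattern]]
  stopifnot(inherits(pattern, "motif_pattern"))
  if (!is.character(s)) s <- s$residues
  chars <- strsplit(toupper(s), "")[[1]]
  n <- length(chars); m <- pattern$length
  if (n < m) return(integer(0))
  starts <- seq_len(n - m + 1L)
  ok <- rep(TRUE, length(starts))
  for (k in seq_len(m)) {
    allowed <- pattern$positions[[k]]
    if (is.null(allowed)) next
    ok <- ok & chars[starts + k - 1L] %in% allowed
  }
  starts[ok] - 1L
}

#' Four-way class assignment of a diterpene synthase
#'
#' Scans a sequence for the class I motifs (aspartate-rich DDxxD/E and
#' NSE/DTE) and the class II motif (DxDD) and classifies it as:
#' `Bifunctional` if both class I and class II evidence is present,
#' `ClassI` if only class I, `ClassII` if only class II, and
#' `Noncanonical` if neither. Bifunctional takes precedence so the four
#' classes form a partition.
#'
#' @param s A protein string or single-row [tps_seqs].
#' @param query_id Identifier recorded on the call (defaults to the
#'   sequence id, if any).
#' @return A `ditps_call`: list with `query_id`, the three site lists
#'   (0-based starts) and `four_way`.
#' @export
#' @examples
#' classify_diterpene("MKDDIYDAAGDIDDG")$four_way
classify_diterpene <- function(s, query_id = NULL) {
  if (!is.character(s)) {
    if (is.null(query_id)) query_id <- s$id
    s <- s$residues
  }
  if (is.null(query_id)) query_id <- "query"
  pats <- motif_patterns()
  asp <- scan_motif(s, pats$classI_aspRich)
  nse <- scan_motif(s, pats$classI_NSE_DTE)
  dxdd <- scan_motif(s, pats$classII_DxDD)
  class1 <- length(asp) > 0L || length(nse) > 0L
  class2 <- length(dxdd) > 0L
  four_way <- if (class1 && class2) "Bifunctional" else
    if (class1) "ClassI" else if (class2) "ClassII" else "Noncanonical"
  structure(list(query_id = query_id,
                 classI_aspRich_sites = asp,
                 classI_NSE_sites = nse,
                 classII_sites = dxdd,
                 four_way = four_way),
            class = "ditps_call")
}

#' Motif-classify every sequence of a collection
#'
#' @param seqs A protein [tps_seqs].
#' @return Data frame with columns `id`, `aspRich_sites`, `NSE_sites`,
#'   `DxDD_sites` (comma-separated 0-based starts) and `class`.
#' @export
classify_diterpene_set <- function(seqs) {
  calls <- lapply(seq_len(nrow(seqs)), function(i)
    classify_diterpene(seqs[i, , drop = FALSE]))
  fmt <- function(x) if (length(x)) paste(x, collapse = ",") else ""
  data.frame(
    id = seqs$id,
    aspRich_sites = vapply(calls, function(cl) fmt(cl$classI_aspRich_sites), ""),
    NSE_sites = vapply(calls, function(cl) fmt(cl$classI_NSE_sites), ""),
    DxDD_sites = vapply(calls, function(cl) fmt(cl$classII_sites), ""),
    class = vapply(calls, function(cl) cl$four_way, ""),
    stringsAsFactors = FALSE)
}
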