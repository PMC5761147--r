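#' Construct a family multiple alignment
#'
#' @param seqs A [tps_seqs] collection whose residue strings all have the
#'   same aligned length; the gap character is `-` (`.` is accepted and
#'   normalised to `-`).
#' @param family Optional family label (defaults to the common `label` of
#'   the rows, if any).
#' @param taxon Optional taxon tag.
#' @return A `tps_alignment`: list with `ids`, `rows` (character vector),
#'   `mat` (residue matrix), `width`, `family`, `taxon`.
#' @export
alignment <- function(seqs, family = NULL, taxon = NULL) {
  if (is.character(seqs)) {
    ids <- if (!is.null(names(seqs))) names(seqs) else
      paste0("row", seq_along(seqs))
    seqs <- data.frame(id = ids, residues = seqs, label = NA_character_,
                       stringsAsFactors = FALSE)
  }
  rows <- toupper(seqs$residues)
  rows <- gsub(".", "-", rows, fixed = TRUE)
  if (length(rows) < 2L) stop("alignment requires >= 2 rows")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows differ in length")
  mat <- matrix(unlist(strsplit(rows, "")), nrow = length(rows),
                ncol = w, byrow = TRUE)
  if (all(mat == "-")) stop("alignment has no non-gap column")
  if (is.null(family)) {
    fam <- unique(seqs$label)
    family <- if (length(fam) == 1L && !is.na(fam)) fam else NA_character_
  }
  structure(list(ids = seqs$id, rows = rows, mat = mat, width = w,
                 family = family, taxon = taxon),
            class = "tps_alignment")
}

#' Read a multiple alignment (aligned FASTA or Stockholm)
#'
#' @param path Path to the alignment file.
#' @param format `"auto"` (Stockholm is recognised by its `# STOCKHOLM`
#'   header), `"fasta"` or `"stockholm"`.
#' @param family Optional family label.
#' @return A [alignment] object.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm"),
                           family = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty alignment file: ", path)
    return(alignment(stats::setNames(toupper(as.character(set)),
                                     sub("\\s.*$", "", names(set))),
                     family = family))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|//)", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty Stockholm alignment: ", path)
  parts <- strsplit(trimws(lines), "\\s+")
  ids <- vapply(parts, `[`, "", 1L)
  segs <- vapply(parts, `[`, "", 2L)
  # interleaved blocks: concatenate segments per id in first-seen order
  ord <- unique(ids)
  rows <- vapply(ord, function(i)
    paste(segs[ids == i], collapse = ""), "")
  alignment(stats::setNames(toupper(rows), ord), family = family)
}

# fraction of gap characters per column
column_gap_fraction <- function(aln) colMeans(aln$mat == "-")

#' Select match columns of an alignment
#'
#' A column becomes a match state of the profile iff its gap fraction is
#' strictly below `gap_threshold`; all other columns are insert columns.
#'
#' @param aln A [alignment].
#' @param gap_threshold Gap-fraction cut-off in `(0, 1]` (default 0.5).
#' @return Logical vector (`TRUE` = match) of length `aln$width`.
#' @export
#' @examples
#' a <- alignment(tps_seqs(c("r1", "r2", "r3"), c("AC-A", "A--A", "ACCA")))
#' select_match_columns(a)
select_match_columns <- function(aln, gap_threshold = 0.5) {
  stopifnot(gap_threshold > 0, gap_threshold <= 1)
  mask <- column_gap_fraction(aln) < gap_threshold
  if (!any(mask)) stop("no match column survives gap threshold ",
                       gap_threshold)
  mask
}

#' Henikoff position-based sequence weights
#'
#' In every match column with `r` distinct residue types, a row holding a
#' residue shared by `s` rows receives `1/(r*s)`; gap (and all-gap columns)
#' contribute nothing. Per-row sums are normalised so the weights sum to
#' the number of rows, i.e. the effective sequence count is conserved.
#' Redundant (near-duplicate) rows are thereby down-weighted relative to
#' divergent ones.
#'
#' @param aln A [alignment].
#' @param mask Match-column mask from [select_match_columns].
#' @return Numeric weight vector, one per row, summing to `nrow`.
#' @export
#' @examples
#' a <- alignment(tps_seqs(c("r1", "r2", "r3"), c("A", "A", "C")))
#' henikoff_weights(a, select_match_columns(a))
henikoff_weights <- function(aln, mask = select_match_columns(aln)) {
  stopifnot(length(mask) == aln$width)
  if (!any(mask)) stop("mask selects zero match columns")
  n <- nrow(aln$mat)
  raw <- numeric(n)
  for (c0 in which(mask)) {
    col <- aln$mat[, c0]
    res <- col[col != "-"]
    if (!length(res)) next          # all-gap column: skip, avoids 0/0
    tab <- table(res)
    r <- length(tab)
    contrib <- 1 / (r * as.numeric(tab[col]))
    contrib[is.na(contrib)] <- 0    # gapped rows
    raw <- raw + contrib
  }
  if (any(raw <= 0))
    stop("row(s) entirely gapped in match columns: ",
         paste(aln$ids[raw <= 0], collapse = ", "))
  raw * n / sum(raw)
}
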