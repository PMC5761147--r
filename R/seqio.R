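#' Construct a sequence collection
#'
#' The basic container used throughout the package: a data frame with one
#' row per sequence and columns `id`, `residues`, `desc`, `label`, `taxon`.
#' Residues are stored upper-case and validated against the declared
#' alphabet (protein: the 20 standard residues plus `X`/`B`/`Z`/`*`;
#' nucleotide: `ACGTN`). Ids must be unique within a collection.
#'
#' @param id Character vector of sequence identifiers.
#' @param residues Character vector of residue strings (same length as `id`).
#' @param alphabet `"AA"` (protein) or `"DNA"` (nucleotide).
#' @param desc Optional description strings.
#' @param label Optional family labels.
#' @param taxon Optional taxon tags (e.g. `"monocot"`, `"dicot"`).
#' @return A `tps_seqs` data frame.
#' @export
#' @examples
#' tps_seqs(c("a", "b"), c("MKV", "MLV"))
tps_seqs <- function(id, residues, alphabet = c("AA", "DNA"),
                     desc = NA_character_, label = NA_character_,
                     taxon = NA_character_) {
  alphabet <- match.arg(alphabet)
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  stopifnot(length(id) == length(residues))
  if (any(!nzchar(residues)))
    stop("empty residue string for id(s): ",
         paste(id[!nzchar(residues)], collapse = ", "))
  dup <- id[duplicated(id)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  allowed <- if (alphabet == "AA") c(AA20, AA_AMBIG, "*") else
    c("A", "C", "G", "T", "N")
  bad <- !grepl(sprintf("^[%s]+$", paste(gsub("\\*", "\\\\*", allowed),
                                         collapse = "")), residues)
  if (any(bad))
    stop("invalid ", if (alphabet == "AA") "protein" else "nucleotide",
         " characters in sequence(s): ", paste(id[bad], collapse = ", "))
  out <- data.frame(id = id, residues = residues,
                    desc = rep_len(as.character(desc), length(id)),
                    label = rep_len(as.character(label), length(id)),
                    taxon = rep_len(as.character(taxon), length(id)),
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  class(out) <- c("tps_seqs", "data.frame")
  out
}

seq_alphabet <- function(seqs) {
  a <- attr(seqs, "alphabet")
  if (is.null(a)) "AA" else a
}

#' Read sequences from a FASTA file
#'
#' @param path Path to an existing FASTA file.
#' @param alphabet `"AA"` or `"DNA"`.
#' @return A [tps_seqs] collection; the part of each header after the first
#'   whitespace is kept in the `desc` column.
#' @export
read_fasta <- function(path, alphabet = c("AA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), NA_character_)
  tps_seqs(id, as.character(set), alphabet = alphabet, desc = desc)
}

#' Write sequences to a FASTA file
#'
#' @param seqs A [tps_seqs] collection.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  hdr <- ifelse(is.na(seqs$desc), seqs$id, paste(seqs$id, seqs$desc))
  set <- Biostrings::BStringSet(stats::setNames(seqs$residues, hdr))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Six-frame translation of a nucleotide sequence
#'
#' Translates a nucleotide sequence in all six reading frames (+1..+3 on
#' the forward strand, -1..-3 on the reverse complement) with a standard
#' genetic-code table. Stop codons are rendered `*`; codons containing `N`
#' translate to `X`; the trailing 1-2 nucleotides that do not complete a
#' codon are dropped.
#'
#' @param nuc A single-row DNA [tps_seqs] (or a plain nucleotide string).
#' @param genetic_code NCBI genetic-code table number (default 1, standard).
#' @return A protein [tps_seqs] with six rows and a `frame` column in
#'   `c(1, 2, 3, -1, -2, -3)`.
#' @export
#' @examples
#' six_frame_translate(tps_seqs("x", "ATGGCCTAA", alphabet = "DNA"))
six_frame_translate <- function(nuc, genetic_code = 1L) {
  if (is.character(nuc)) nuc <- tps_seqs("query", nuc, alphabet = "DNA")
  stopifnot(nrow(nuc) == 1L)
  if (seq_alphabet(nuc) != "DNA" ||
      grepl("[^ACGTN]", nuc$residues))
    stop("six_frame_translate requires a nucleotide (ACGTN) sequence")
  if (nchar(nuc$residues) < 3L)
    stop("sequence shorter than one codon")
  gc_tab <- Biostrings::getGeneticCode(as.character(genetic_code))
  fwd <- Biostrings::DNAString(nuc$residues)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(s, off) {
    n <- length(s)
    keep <- 3L * ((n - off + 1L) %/% 3L)
    if (keep < 3L) return("")
    aa <- Biostrings::translate(Biostrings::subseq(s, off, off + keep - 1L),
                                genetic.code = gc_tab,
                                if.fuzzy.codon = "X")
    as.character(aa)
  }
  prot <- c(vapply(1:3, function(f) one(fwd, f), ""),
            vapply(1:3, function(f) one(rev, f), ""))
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  keep <- nzchar(prot)
  out <- tps_seqs(paste0(nuc$id, "_frame", ifelse(frames > 0, "+", ""),
                         frames)[keep],
                  prot[keep], alphabet = "AA")
  out$frame <- frames[keep]
  out$parent <- nuc$id
  out
}

#' Split translated frames at stop codons into candidate ORFs
#'
#' Each protein sequence is split at every `*`; segments of at least
#' `min_len` residues are kept. Segment ids record the parent frame and the
#' 0-based amino-acid offset of the segment within its frame.
#'
#' @param frames A protein [tps_seqs], typically from [six_frame_translate];
#'   may contain `*`.
#' @param min_len Minimum segment length in residues (default 50, far below
#'   the shortest genuine terpene-synthase at ~550 aa).
#' @return A protein [tps_seqs] of segments (possibly zero rows) with
#'   `frame` and `offset_aa` columns.
#' @export
split_orfs <- function(frames, min_len = 50L) {
  rows <- lapply(seq_len(nrow(frames)), function(i) {
    segs <- strsplit(frames$residues[i], "*", fixed = TRUE)[[1]]
    if (!length(segs)) return(NULL)
    lens <- nchar(segs)
    # aa offset of each segment: cumulative lengths + one per stop passed
    off <- cumsum(c(0L, head(lens, -1L) + 1L))
    keep <- lens >= min_len
    if (!any(keep)) return(NULL)
    data.frame(id = paste0(frames$id[i], "_orf", off[keep]),
               residues = segs[keep],
               frame = if (is.null(frames$frame)) NA_integer_ else
                 frames$frame[i],
               offset_aa = off[keep],
               parent = if (is.null(frames$parent)) frames$id[i] else
                 frames$parent[i],
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(id = character(), residues = character(),
                       frame = integer(), offset_aa = integer(),
                       parent = character(), stringsAsFactors = FALSE)
  out <- tps_seqs(rows$id, rows$residues, alphabet = "AA")
  out$frame <- rows$frame
  out$offset_aa <- rows$offset_aa
  out$parent <- rows$parent
  out
}

# validate raw BED/GFF3 lines so coordinate errors are reported with their
# line number before handing the file to rtracklayer
check_loci_lines <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || grepl("^(#|track|browser)", ln)) next
    f <- strsplit(ln, "\t")[[1]]
    if (format == "bed") {
      if (length(f) < 3L) stop("line ", i, ": BED record with < 3 fields")
      s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
      if (is.na(s) || is.na(e)) stop("line ", i, ": non-numeric coordinates")
      if (s >= e) stop("line ", i, ": start >= end")
      if (s < 0) stop("line ", i, ": negative start")
    } else {
      if (length(f) != 9L) stop("line ", i, ": GFF3 record with != 9 fields")
      s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
      if (is.na(s) || is.na(e)) stop("line ", i, ": non-numeric coordinates")
      if (s > e) stop("line ", i, ": start > end")
      if (s < 1) stop("line ", i, ": GFF3 start < 1")
    }
  }
  invisible(TRUE)
}

#' Read gene loci from BED or GFF3
#'
#' Loci are converted on read to the package-wide coordinate convention:
#' 0-based, half-open, sorted by `(chrom, start)`. BED input is already
#' 0-based half-open; GFF3 (1-based inclusive) is shifted at the boundary.
#'
#' @param path Path to a BED or GFF3 file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @param chrom_lengths Optional named vector of chromosome lengths used to
#'   validate that loci fall inside their chromosome.
#' @return A `gene_loci` data frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `family`.
#' @export
read_loci <- function(path, format = c("auto", "bed", "gff3"),
                      chrom_lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE))
      "gff3" else "bed"
  check_loci_lines(path, format)
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  ids <- NULL
  mc <- GenomicRanges::mcols(gr)
  if (format == "bed" && !is.null(mc$name)) ids <- as.character(mc$name)
  if (format == "gff3") {
    ids <- as.character(if (!is.null(mc$ID)) mc$ID else mc$Name)
  }
  if (is.null(ids) || all(is.na(ids)))
    ids <- paste0("locus", seq_along(gr))
  ids[is.na(ids)] <- paste0("locus", which(is.na(ids)))
  fam <- if (!is.null(mc$family)) as.character(mc$family) else NA_character_
  loci <- gene_loci(gene_id = ids,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    family = fam)
  if (!is.null(chrom_lengths)) {
    over <- loci$end > chrom_lengths[loci$chrom]
    if (any(is.na(over)) || any(over))
      stop("loci outside declared chromosome lengths: ",
           paste(loci$gene_id[is.na(over) | over], collapse = ", "))
  }
  loci
}

#' Construct a gene-locus table (0-based, half-open)
#'
#' @param gene_id,chrom,start,end,strand,family Locus fields; `strand`
#'   one of `+`, `-`, `.`/`*`.
#' @return A `gene_loci` data frame sorted by `(chrom, start)`.
#' @export
gene_loci <- function(gene_id, chrom, start, end, strand = ".",
                      family = NA_character_) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("negative start coordinate")
  if (any(start >= end)) stop("start >= end for locus: ",
                              paste(gene_id[start >= end], collapse = ", "))
  strand <- as.character(strand)
  strand[strand == "*"] <- "."
  out <- data.frame(gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    start = start, end = end,
                    strand = rep_len(strand, length(gene_id)),
                    family = rep_len(as.character(family), length(gene_id)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_loci", "data.frame")
  out
}
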