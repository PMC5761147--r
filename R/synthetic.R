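#' Specification of a synthetic protein family
#'
#' A family is generated from a consensus built on a shared
#' terpene-fold-like backbone: positions outside conserved blocks follow
#' the backbone (shared across families, the source of cross-family
#' homology), family-specific conserved blocks overwrite their positions,
#' and class signature motifs may be embedded with a stated fidelity.
#' Family members are drawn by mutating this consensus at `divergence`
#' per position (blocks at their own, lower rates).
#'
#' @param family Family name.
#' @param len_range Integer length range (min, max) in residues; one
#'   length is drawn per generated family so members form an un-gapped
#'   alignment.
#' @param blocks List of conserved blocks, each
#'   `list(consensus = peptide, start = 1-based position, rate = per-position
#'   substitution rate)`.
#' @param motifs List of `list(name = motif name from [motif_patterns],
#'   instance = concrete peptide, start = 1-based position, fidelity =
#'   probability a member carries the motif intact)`.
#' @param background Residue distribution (default [aa_background]).
#' @param divergence Per-position substitution probability outside blocks
#'   (default 0.25).
#' @param backbone Optional shared backbone string (>= max length); when
#'   `NULL` the consensus outside blocks is drawn from `background`.
#' @param taxon Optional taxon tag.
#' @return A `family_spec`.
#' @export
family_spec <- function(family, len_range, blocks = list(), motifs = list(),
                        background = aa_background(), divergence = 0.25,
                        backbone = NULL, taxon = NA_character_) {
  len_range <- as.integer(len_range)
  stopifnot(length(len_range) == 2L, all(len_range > 0),
            len_range[1] <= len_range[2],
            divergence >= 0, divergence <= 1)
  for (b in blocks) {
    stopifnot(b$rate >= 0, b$rate <= 1, b$start >= 1)
    if (b$start + nchar(b$consensus) - 1L > len_range[1])
      stop("block at ", b$start, " does not fit within minimum length ",
           len_range[1], " of family ", family)
  }
  for (m in motifs) {
    stopifnot(m$fidelity >= 0, m$fidelity <= 1)
    if (m$start + nchar(m$instance) - 1L > len_range[1])
      stop("motif at ", m$start, " does not fit within minimum length ",
           len_range[1], " of family ", family)
  }
  if (!is.null(backbone) && nchar(backbone) < len_range[2])
    stop("backbone shorter than maximum family length")
  structure(list(family = family, len_range = len_range, blocks = blocks,
                 motifs = motifs, background = background,
                 divergence = divergence, backbone = backbone,
                 taxon = taxon),
            class = "family_spec")
}

# deterministic shared backbone: the "terpene fold" all TPS families of the
# default configuration descend from; fixed seed so every session builds
# the identical fold
default_backbone <- function(len = 900L, background = aa_background()) {
  with_seed(191919L,
            paste(sample(AA20, len, replace = TRUE, prob = background),
                  collapse = ""))
}

# deterministic family-specific conserved-block peptides
random_peptide <- function(len, seed, background = aa_background()) {
  with_seed(seed,
            paste(sample(AA20, len, replace = TRUE, prob = background),
                  collapse = ""))
}

#' Default 13-family synthetic configuration
#'
#' Emulates the default bank: six function-based TPS families (MonoD,
#' MonoM, SesD, SesM at mono-/sesquiterpene-synthase lengths; DiD, DiM at
#' diterpene-synthase length), six gene-family clades (TPSa..TPSg with
#' TPSe_f merged) and one shorter prenyl-transferase family. Length
#' ranges follow the family biology: diterpene synthases are the longest
#' (>= 850 aa), monoterpene synthases 600-650 aa, sesquiterpene synthases
#' 550-580 aa, prenyl transferases 300-400 aa. The twelve TPS families
#' share one fold backbone (so cross-family homology, and hence
#' single-profile false positives, occur as they do in real data) and are
#' distinguished by three 24-residue conserved blocks each; diterpene
#' families carry their class signature motifs (class I DDxxD/E or
#' NSE/DTE, class II DxDD) at fidelity 1, the remaining TPS families an
#' aspartate-rich class I motif at fidelity 0.9. The PT family has its own
#' backbone.
#'
#' @param divergence Per-position substitution rate outside blocks
#'   (default 0.25).
#' @param block_rate Substitution rate inside conserved blocks
#'   (default 0.02).
#' @return Named list of 13 [family_spec]s.
#' @export
default_family_specs <- function(divergence = 0.25, block_rate = 0.02) {
  fold <- default_backbone(900L)
  pt_backbone <- random_peptide(400L, 282828L)
  lens <- list(MonoD = c(600L, 650L), MonoM = c(600L, 650L),
               DiD = c(850L, 900L), DiM = c(850L, 900L),
               SesD = c(550L, 580L), SesM = c(550L, 580L),
               TPSa = c(550L, 580L), TPSb = c(600L, 650L),
               TPSc = c(850L, 900L), TPSd = c(600L, 650L),
               TPSe_f = c(850L, 900L), TPSg = c(600L, 650L),
               PT = c(300L, 400L))
  # class signature motifs per family: instance peptide + fidelity
  motif_for <- function(fam, min_len) {
    inst <- list(classI_aspRich = "DDIYD",
                 classI_NSE_DTE = "NDLASTAAE",
                 classII_DxDD = "DIDD")
    pick <- switch(fam,
                   DiD = list(c("classI_aspRich", "classII_DxDD"), 1),
                   DiM = list(c("classI_NSE_DTE", "classII_DxDD"), 1),
                   TPSc = list("classII_DxDD", 1),          # CPS-like, class II
                   TPSe_f = list("classI_aspRich", 1),      # KSL-like, class I
                   PT = NULL,
                   list("classI_aspRich", 0.9))
    if (is.null(pick)) return(list())
    starts <- min_len - c(40L, 80L)  # near the C-terminal end, clear of blocks
    lapply(seq_along(pick[[1]]), function(k)
      list(name = pick[[1]][k], instance = inst[[pick[[1]][k]]],
           start = starts[k], fidelity = pick[[2]]))
  }
  specs <- lapply(seq_along(lens), function(i) {
    fam <- names(lens)[i]
    lr <- lens[[fam]]
    bstarts <- if (fam == "PT") c(40L, 130L, 220L) else
      c(60L, 230L, 400L) + 4L * (i - 1L)
    blocks <- lapply(seq_along(bstarts), function(k)
      list(consensus = random_peptide(24L, 1000L * i + k),
           start = bstarts[k], rate = block_rate))
    family_spec(fam, lr, blocks = blocks,
                motifs = motif_for(fam, lr[1]),
                divergence = divergence,
                backbone = if (fam == "PT") pt_backbone else fold,
                taxon = if (grepl("M$", fam) && fam != "PT") "monocot"
                        else if (grepl("D$", fam)) "dicot" else NA_character_)
  })
  stats::setNames(specs, names(lens))
}

# substitute residues at `idx` with background-drawn residues different
# from the current one (so the realised substitution rate is exact)
mutate_positions <- function(chars, idx, background) {
  for (i in idx) {
    probs <- background
    probs[chars[i]] <- 0
    chars[i] <- sample(AA20, 1L, prob = probs)
  }
  chars
}

#' Generate labelled members of a synthetic family
#'
#' One family length is drawn uniformly from the spec's range; the family
#' consensus is the shared backbone truncated to that length with
#' conserved blocks and signature motifs written in. Each member mutates
#' the consensus: positions outside blocks at `divergence`, block
#' positions at the block rate, motif positions kept intact with the
#' motif's fidelity (else mutated like ordinary positions). Substituted
#' residues are drawn from the background excluding the consensus residue.
#' Deterministic given `seed`.
#'
#' @param spec A [family_spec].
#' @param n Number of sequences (>= 2).
#' @param seed RNG seed.
#' @return A labelled protein [tps_seqs] of `n` rows, all the same length
#'   (so the collection is simultaneously a valid un-gapped [alignment]).
#' @export
generate_family <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "family_spec"), n >= 2)
  with_seed(seed, {
    lens <- seq.int(spec$len_range[1], spec$len_range[2])
    L <- lens[sample.int(length(lens), 1L)]   # safe when min == max
    cons <- if (!is.null(spec$backbone))
      strsplit(substr(spec$backbone, 1L, L), "")[[1]]
    else sample(AA20, L, replace = TRUE, prob = spec$background)
    rate <- rep(spec$divergence, L)
    for (b in spec$blocks) {
      pos <- b$start:(b$start + nchar(b$consensus) - 1L)
      cons[pos] <- strsplit(b$consensus, "")[[1]]
      rate[pos] <- b$rate
    }
    motif_pos <- lapply(spec$motifs, function(m)
      m$start:(m$start + nchar(m$instance) - 1L))
    for (k in seq_along(spec$motifs))
      cons[motif_pos[[k]]] <- strsplit(spec$motifs[[k]]$instance, "")[[1]]
    bg <- stats::setNames(spec$background[AA20], AA20)
    residues <- vapply(seq_len(n), function(i) {
      r <- rate
      for (k in seq_along(spec$motifs)) {
        keep <- runif(1) < spec$motifs[[k]]$fidelity
        r[motif_pos[[k]]] <- if (keep) 0 else spec$divergence
      }
      idx <- which(runif(L) < r)
      paste(mutate_positions(cons, idx, bg), collapse = "")
    }, "")
    tps_seqs(sprintf("%s_%03d", spec$family, seq_len(n)), residues,
             label = spec$family, taxon = spec$taxon)
  })
}

#' Generate a full labelled benchmark with train/test split
#'
#' Generates every family of `specs`, splits the positives with
#' [split_train_test] (stratified, 10% held out by default) and adds
#' `n_negatives` pure-background sequences (no fold backbone, no blocks,
#' no motifs — label `"negative"`) to the test set.
#'
#' @param specs Named list of [family_spec]s (default
#'   [default_family_specs]).
#' @param n_per_family Sequences per family (default 30).
#' @param test_fraction Held-out fraction (default 0.1).
#' @param n_negatives Background sequences added to the test set
#'   (default 30).
#' @param seed RNG seed; per-family seeds are derived from it.
#' @return A `synthetic_benchmark`: list with `train`, `test`
#'   (labelled [tps_seqs]), `specs`, `seed`.
#' @export
generate_benchmark <- function(specs = default_family_specs(),
                               n_per_family = 30L, test_fraction = 0.1,
                               n_negatives = 30L, seed = 42L) {
  stopifnot(length(specs) >= 2L)
  fams <- lapply(seq_along(specs), function(k)
    generate_family(specs[[k]], n_per_family, seed = child_seed(seed, k)))
  all_pos <- do.call(rbind, fams)
  attr(all_pos, "alphabet") <- "AA"
  class(all_pos) <- c("tps_seqs", "data.frame")
  split <- split_train_test(all_pos, test_fraction,
                            seed = child_seed(seed, 9999L))
  test <- split$test
  if (n_negatives > 0L) {
    bg <- aa_background()
    lens <- range(unlist(lapply(specs, `[[`, "len_range")))
    neg <- with_seed(child_seed(seed, 8888L), {
      lseq <- seq.int(lens[1], lens[2])
      tps_seqs(sprintf("negative_%03d", seq_len(n_negatives)),
               vapply(seq_len(n_negatives), function(i)
                 paste(sample(AA20, lseq[sample.int(length(lseq), 1L)],
                              replace = TRUE, prob = bg), collapse = ""), ""),
               label = "negative")
    })
    test <- rbind(test, neg)
    attr(test, "alphabet") <- "AA"
    class(test) <- c("tps_seqs", "data.frame")
  }
  structure(list(train = split$train, test = test, specs = specs,
                 seed = seed),
            class = "synthetic_benchmark")
}

#' Generate a synthetic genome of family gene loci
#'
#' Places `n_family_genes` loci on `n_chrom` chromosomes of equal length.
#' A fraction `cluster_fraction` of the genes is placed in tandem runs of
#' 2-15 genes confined to windows of `cluster_span_bp`; the remainder (and
#' the run anchors) are uniform along chromosomes. Deterministic given
#' `seed`.
#'
#' @param n_chrom Number of chromosomes (default 5).
#' @param n_family_genes Number of family loci (default 60).
#' @param cluster_fraction Fraction of genes placed in enforced clusters,
#'   in `[0, 1]`.
#' @param cluster_span_bp Window width of an enforced cluster (default
#'   5e4).
#' @param chrom_length Chromosome length in bp (default 3e7).
#' @param gene_length Locus length in bp (default 3000).
#' @param seed RNG seed.
#' @return A [gene_loci] table.
#' @export
generate_genome <- function(n_chrom = 5L, n_family_genes = 60L,
                            cluster_fraction = 0, cluster_span_bp = 5e4,
                            chrom_length = 3e7, seed = 1L,
                            gene_length = 3000L) {
  stopifnot(cluster_fraction >= 0, cluster_fraction <= 1)
  if (chrom_length < cluster_span_bp + gene_length ||
      n_family_genes * gene_length > n_chrom * chrom_length)
    stop("genes do not fit on the declared chromosomes")
  with_seed(seed, {
    n_clustered <- round(cluster_fraction * n_family_genes)
    chrom <- character(0); start <- numeric(0)
    placed <- 0L
    while (placed < n_clustered) {
      run <- sample(2:15, 1L)
      run <- min(run, n_clustered - placed)
      if (run < 2L) run <- 2L
      ch <- sample(n_chrom, 1L)
      w0 <- floor(runif(1, 0, chrom_length - cluster_span_bp - gene_length))
      s <- sort(floor(runif(run, w0, w0 + cluster_span_bp)))
      chrom <- c(chrom, rep(paste0("chr", ch), run))
      start <- c(start, s)
      placed <- placed + run
    }
    n_uniform <- n_family_genes - placed
    if (n_uniform > 0L) {
      ch <- sample(n_chrom, n_uniform, replace = TRUE)
      chrom <- c(chrom, paste0("chr", ch))
      start <- c(start, floor(runif(n_uniform, 0, chrom_length - gene_length)))
    }
    gene_loci(gene_id = sprintf("tps%03d", seq_along(start)),
              chrom = chrom, start = start, end = start + gene_length,
              strand = sample(c("+", "-"), length(start), replace = TRUE),
              family = "TPS")
  })
}

#' Reverse-translate a protein into a synthetic EST
#'
#' Encodes the protein with uniformly chosen synonymous codons and pads
#' the 5' end so the coding region sits in the requested reading frame;
#' for negative frames the construct is reverse-complemented. Translating
#' the result in the same frame with [six_frame_translate] recovers the
#' protein exactly.
#'
#' @param s Protein string or single-row [tps_seqs] (no `*`).
#' @param frame Reading frame in `c(1, 2, 3, -1, -2, -3)`.
#' @param seed RNG seed for codon choice.
#' @param genetic_code NCBI genetic-code table number.
#' @return A single-row DNA [tps_seqs].
#' @export
encode_as_est <- function(s, frame = 1L, seed = 1L, genetic_code = 1L) {
  id <- "est"
  if (!is.character(s)) { id <- paste0(s$id, "_est"); s <- s$residues }
  stopifnot(frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
  if (grepl("\\*", s)) stop("protein contains stop characters")
  gc_tab <- Biostrings::getGeneticCode(as.character(genetic_code))
  by_aa <- split(names(gc_tab), gc_tab)
  aa <- strsplit(toupper(s), "")[[1]]
  if (any(!aa %in% names(by_aa)))
    stop("residue(s) without codon: ",
         paste(unique(aa[!aa %in% names(by_aa)]), collapse = ", "))
  with_seed(seed, {
    codons <- vapply(aa, function(a) {
      opts <- by_aa[[a]]
      if (length(opts) == 1L) opts else sample(opts, 1L)
    }, "")
    pad <- abs(frame) - 1L
    nt <- paste0(paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
                       collapse = ""),
                 paste(codons, collapse = ""))
    if (frame < 0L)
      nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    tps_seqs(id, nt, alphabet = "DNA")
  })
}
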