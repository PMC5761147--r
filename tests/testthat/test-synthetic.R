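test_that("degenerate generation reproduces the consensus exactly", {
  spec <- family_spec("toy", c(60, 60),
                      blocks = list(list(consensus = "WWWWW", start = 10,
                                         rate = 0)),
                      divergence = 0)
  fam <- generate_family(spec, 4, seed = 1)
  expect_equal(length(unique(fam$residues)), 1L)
  expect_equal(substr(fam$residues[1], 10, 14), "WWWWW")
  expect_equal(unique(nchar(fam$residues)), 60L)
})

test_that("motif fidelity 1 guarantees a detectable site in every member", {
  spec <- default_family_specs()[["DiD"]]
  fam <- generate_family(spec, 10, seed = 5)
  for (i in seq_len(nrow(fam))) {
    expect_gte(length(scan_motif(fam$residues[i], "classI_aspRich")), 1L)
    expect_gte(length(scan_motif(fam$residues[i], "classII_DxDD")), 1L)
    expect_equal(classify_diterpene(fam[i, ])$four_way, "Bifunctional")
  }
  # class II-only family (copalyl-diphosphate-synthase-like)
  tpsc <- generate_family(default_family_specs()[["TPSc"]], 5, seed = 5)
  for (i in 1:5)
    expect_gte(length(scan_motif(tpsc$residues[i], "classII_DxDD")), 1L)
})

test_that("generation is deterministic and divergence controls identity", {
  spec <- default_family_specs()[["MonoD"]]
  a <- generate_family(spec, 5, seed = 11)
  b <- generate_family(spec, 5, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a$residues,
                         generate_family(spec, 5, seed = 12)$residues))
  pid <- function(x, y) {
    cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
    mean(cx == cy)
  }
  mean_id <- function(div) {
    sp <- family_spec("t", c(200, 200), divergence = div)
    fam <- generate_family(sp, 6, seed = 3)
    prs <- utils::combn(6, 2)
    mean(apply(prs, 2, function(ij)
      pid(fam$residues[ij[1]], fam$residues[ij[2]])))
  }
  ids <- vapply(c(0.05, 0.25, 0.5), mean_id, 0)
  expect_true(all(diff(ids) < 0))   # identity falls as divergence rises
})

test_that("family lengths respect the family-biology ranges", {
  specs <- default_family_specs()
  expect_length(specs, 13L)
  check <- function(fam, lo, hi) {
    f <- generate_family(specs[[fam]], 3, seed = 2)
    expect_true(all(nchar(f$residues) >= lo & nchar(f$residues) <= hi))
  }
  check("DiD", 850, 900)     # diterpene synthases are the longest
  check("MonoM", 600, 650)
  check("SesD", 550, 580)
  check("PT", 300, 400)
  expect_error(family_spec("bad", c(30, 40),
                           blocks = list(list(consensus = strrep("A", 35),
                                              start = 1, rate = 0))),
               "does not fit")
})

test_that("benchmark generation honours counts, split and labels", {
  specs <- default_family_specs()[c("TPSa", "TPSb", "TPSc")]
  bm <- generate_benchmark(specs, n_per_family = 10, test_fraction = 0.1,
                           n_negatives = 5, seed = 9)
  expect_equal(nrow(bm$train), 27L)
  expect_equal(sum(bm$test$label != "negative"), 3L)
  expect_equal(sum(bm$test$label == "negative"), 5L)
  expect_length(intersect(bm$train$id, bm$test$id), 0L)
  expect_identical(bm, generate_benchmark(specs, n_per_family = 10,
                                          test_fraction = 0.1,
                                          n_negatives = 5, seed = 9))
  # each family's members share one length: valid un-gapped alignment
  for (f in c("TPSa", "TPSb", "TPSc")) {
    lens <- nchar(bm$train$residues[bm$train$label == f])
    expect_equal(length(unique(lens)), 1L)
  }
})

test_that("synthetic genomes respect cluster fraction and determinism", {
  g <- generate_genome(cluster_fraction = 0.8, cluster_span_bp = 5e4,
                       seed = 21)
  expect_gte(detect_clusters(g, max_gap_bp = 1e5)$percent_clustered, 70)
  g0 <- generate_genome(cluster_fraction = 0, seed = 21)
  expect_lte(detect_clusters(g0, max_gap_bp = 1e4)$percent_clustered, 20)
  expect_identical(g, generate_genome(cluster_fraction = 0.8,
                                      cluster_span_bp = 5e4, seed = 21))
  expect_error(generate_genome(n_chrom = 1, chrom_length = 1e4,
                               cluster_fraction = 0), "fit")
})

test_that("EST encoding round-trips through translation in every frame", {
  set.seed(8)
  prot <- tps_seqs("p", random_protein(80))
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    est <- encode_as_est(prot, frame = fr, seed = 4)
    tr <- six_frame_translate(est)
    expect_equal(tr$residues[tr$frame == fr], prot$residues)
  }
  expect_identical(encode_as_est(prot, frame = -2, seed = 4),
                   encode_as_est(prot, frame = -2, seed = 4))
  # a reverse-frame encoding leaves only stop-broken junk on the forward
  # frames (no forward ORF of the full protein length)
  est <- encode_as_est(prot, frame = -2, seed = 4)
  tr <- six_frame_translate(est)
  fwd <- tr[tr$frame > 0, ]
  expect_false(any(vapply(fwd$residues, function(r)
    grepl(prot$residues, r, fixed = TRUE), TRUE)))
})
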