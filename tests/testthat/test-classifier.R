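# These tests use the shared trained fixture (12 TPS + 1 PT profiles on the
# default synthetic benchmark, seed 42) built once in helper-oracles.R.

test_that("scan_bank ranks hits by bit score with deterministic ties", {
  fx <- benchmark_fixture()
  s <- fx$bm$test[fx$bm$test$label == "MonoD", ][1, ]
  hits <- scan_bank(fx$banks$FB, s)
  expect_equal(nrow(hits), 6L)
  expect_equal(hits$family[1], "MonoD")
  expect_true(all(diff(hits$bit_score) <= 0))
  # insertion order must not matter
  rev_bank <- fx$banks$FB
  rev_bank$profiles <- rev(rev_bank$profiles)
  expect_equal(scan_bank(rev_bank, s), hits)
  # identical profiles tie -> lexicographic family order wins
  tie_bank <- fx$banks$FB
  for (f in names(tie_bank$profiles)) {
    tie_bank$profiles[[f]] <- tie_bank$profiles[["MonoD"]]
    tie_bank$profiles[[f]]$family <- f
  }
  tie_hits <- scan_bank(tie_bank, s)
  expect_equal(tie_hits$family, sort(tie_hits$family))
})

test_that("a one-profile bank assigns regardless of score when unthresholded", {
  fx <- benchmark_fixture()
  hits <- scan_bank(fx$banks$PT, random_protein(80))
  expect_equal(nrow(hits), 1L)
  cl <- assign_family(fx$banks["PT"], random_protein(80),
                      evalue_max = Inf)
  expect_equal(cl$calls$family, "PT")
})

test_that("schemes classify independently and FB maps to class and taxon", {
  fx <- benchmark_fixture()
  s <- fx$bm$test[fx$bm$test$label == "TPSd", ][1, ]
  cl <- assign_family(fx$banks, s)
  calls <- cl$calls
  expect_setequal(calls$scheme, c("FB", "GB", "PT"))
  gb <- calls[calls$scheme == "GB", ]
  expect_equal(gb$family, "TPSd")
  fb <- calls[calls$scheme == "FB", ]
  expect_true(fb$family %in% scheme_families()$FB)
  expect_match(fb$functional_class, "terpene synthase")
  expect_true(fb$taxon %in% c("monocot", "dicot"))
  # assigned family always equals the top-ranked hit
  for (sc in names(cl$hits))
    if (calls$family[calls$scheme == sc] != "unclassified")
      expect_equal(calls$family[calls$scheme == sc],
                   cl$hits[[sc]]$family[1])
  s2 <- fx$bm$test[fx$bm$test$label == "MonoD", ][1, ]
  fb2 <- assign_family(fx$banks, s2)$calls
  expect_equal(fb2$family[fb2$scheme == "FB"], "MonoD")
  expect_equal(fb2$functional_class[fb2$scheme == "FB"],
               "monoterpene synthase")
  expect_equal(fb2$taxon[fb2$scheme == "FB"], "dicot")
})

test_that("argmax assignment ignores profiles that never rank first", {
  fx <- benchmark_fixture()
  pos <- fx$bm$test[fx$bm$test$label %in% scheme_families()$GB, ]
  sm <- score_matrix(fx$banks$GB, pos)
  full <- evaluate_bank(fx$banks$GB, pos, mode = "combined", scores = sm)
  # drop a profile that is nobody's argmax: assignments of other families
  # are unchanged
  argmax <- rownames(sm$bits)[apply(sm$bits, 2, which.max)]
  never_top <- setdiff(rownames(sm$bits), argmax)
  if (length(never_top)) {
    keep <- setdiff(names(fx$banks$GB$profiles), never_top[1])
    sub <- evaluate_bank(fx$banks$GB$profiles[keep],
                         pos[pos$label %in% keep, ], mode = "combined")
    for (f in keep)
      expect_equal(sub$TP[sub$family == f], full$TP[full$family == f])
  }
  # every training sequence ranks its own family first (the mechanism that
  # lets combining rescue precision)
  tr <- fx$bm$train[fx$bm$train$label %in% scheme_families()$GB, ]
  tr_sub <- tr[seq(1, nrow(tr), by = 12), ]
  smt <- score_matrix(fx$banks$GB, tr_sub)
  top <- rownames(smt$bits)[apply(smt$bits, 2, which.max)]
  expect_equal(top, tr_sub$label)
})

test_that("EST classification equals protein classification up to the filter", {
  fx <- benchmark_fixture()
  prot <- fx$bm$test[fx$bm$test$label == "SesM", ][1, ]
  est <- encode_as_est(prot, frame = 1, seed = 3)
  cl_est <- classify_est(fx$banks, est)
  cl_prot <- assign_family(fx$banks, prot)
  for (sc in c("FB", "GB")) {
    ce <- cl_est$calls[cl_est$calls$scheme == sc, ]
    cp <- cl_prot$calls[cl_prot$calls$scheme == sc, ]
    expect_equal(ce$family, cp$family)
    expect_equal(ce$bit_score, cp$bit_score, tolerance = 1e-9)
    expect_equal(ce$frame, 1L)
  }
  # too-short input is unclassified with a reason
  short <- tps_seqs("s", paste(rep("ACG", 40), collapse = ""),
                    alphabet = "DNA")
  cl0 <- classify_est(fx$banks, short)
  expect_true(all(cl0$calls$family == "unclassified"))
  expect_match(cl0$reason, "no ORF")
})

test_that("classify_fasta preserves input order and normalises case", {
  fx <- benchmark_fixture()
  take <- c(which(fx$bm$test$label == "TPSb")[1],
            which(fx$bm$test$label == "DiD")[1],
            which(fx$bm$test$label == "PT")[1])
  seqs <- fx$bm$test[take, ]
  f <- tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  tab <- classify_fasta(fx$banks, f)
  expect_equal(nrow(tab), 3L * 3L)   # three sequences x three schemes
  expect_equal(unique(tab$query_id), seqs$id)
  expect_equal(tab$family[tab$scheme == "GB" & tab$query_id == seqs$id[1]],
               "TPSb")
  expect_equal(tab$family[tab$scheme == "PT" & tab$query_id == seqs$id[3]],
               "PT")
  # lower-case input gives the identical table
  f2 <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", seqs$id, "\n", tolower(seqs$residues)), f2)
  expect_equal(classify_fasta(fx$banks, f2), tab)
  f3 <- tempfile(fileext = ".fasta")
  writeLines(character(), f3)
  expect_error(classify_fasta(fx$banks, f3), "empty")
})

test_that("profile alignment rendering is consistent with the traceback", {
  fx <- benchmark_fixture()
  p <- fx$banks$GB$profiles$TPSa
  s <- fx$bm$test[fx$bm$test$label == "TPSa", ][1, ]
  sc <- viterbi_score(p, s)
  lines <- format_alignment(sc, p, s)
  expect_length(lines, 3L)
  expect_equal(nchar(lines[1]), nchar(lines[3]))
})
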