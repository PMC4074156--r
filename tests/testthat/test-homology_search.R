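test_that("six-frame translation follows the codon table and strand symmetry", {
  fr <- six_frame_translate("ATGGCC")
  expect_equal(fr[[1]]$peptide, "MA")
  s <- withr::with_seed(2, rscout:::random_nt(300))
  rc <- rscout:::revcomp(s)
  f_s <- six_frame_translate(s)
  f_rc <- six_frame_translate(rc)
  for (f in 0:2) {
    minus <- Filter(function(x) x$strand == "-" && x$frame == f, f_s)[[1]]
    plus_rc <- Filter(function(x) x$strand == "+" && x$frame == f, f_rc)[[1]]
    expect_equal(minus$peptide, plus_rc$peptide)
  }
  expect_error(six_frame_translate("ACGU"), "nucleotide")
})

test_that("every framed peptide position maps back to its own codon", {
  s <- withr::with_seed(3, rscout:::random_nt(3000))
  L <- nchar(s)
  rc <- rscout:::revcomp(s)
  for (fr in six_frame_translate(s)) {
    pep <- strsplit(fr$peptide, "", fixed = TRUE)[[1]]
    idx <- withr::with_seed(4, sample(seq_along(pep), 50))
    ci <- codon_interval(L, fr$strand, fr$frame, idx)
    for (k in seq_along(idx)) {
      codon <- substr(s, ci[k, 1] + 1L, ci[k, 2])
      if (fr$strand == "-") codon <- rscout:::revcomp(codon)
      expect_equal(rscout:::translate_cds(codon), pep[idx[k]])
    }
  }
})

test_that("an exact intron-free match yields one full-coverage hit with the
           diagonal score", {
  query <- rand_protein(100, seed = 5)
  cds <- withr::with_seed(6, rscout:::reverse_translate(query))
  # in-frame stop codons fence the planted CDS so extension cannot drift
  scaf <- withr::with_seed(7,
    paste0(rscout:::random_nt(1200), "TAA", cds, "TAA",
           rscout:::random_nt(1200)))
  h <- find_exon_hits(query, scaf)
  top <- h[which.max(h$score), ]
  expect_equal(top$q_start, 1L)
  expect_equal(top$q_end, 100L)
  expect_equal(top$n_ident, 100L)
  M <- rscout:::blosum62()
  expect_equal(top$score, sum(diag(M)[rscout:::aa_codes(query)]))
  expect_equal(top$g_start, 1203L)
  expect_equal(top$g_end, 1503L)
})

test_that("queries sharing no seed word return an empty hit table", {
  scaf <- strrep("ACGT", 500)
  h <- find_exon_hits(strrep("W", 50), scaf)
  expect_equal(nrow(h), 0L)
})

test_that("hit scores re-derive from their aligned residue pairs", {
  ds <- demo_dataset()
  hits <- find_exon_hits(as.character(ds$references[[1]]),
                         as.character(ds$genome[[1]]),
                         query_id = "RefOR1", scaffold_id = "scaf_001")
  expect_gt(nrow(hits), 0L)
  for (i in seq_len(nrow(hits))) {
    expect_equal(hits$score[i],
                 rscout:::ungapped_score(hits$qseq[i], hits$sseq[i]))
    expect_equal(nchar(hits$qseq[i]), hits$q_end[i] - hits$q_start[i] + 1L)
    if (hits$strand[i] == "+")
      expect_equal(hits$g_end[i] - hits$g_start[i],
                   3L * (hits$q_end[i] - hits$q_start[i] + 1L))
  }
})

test_that("a multi-intron implant produces hits tiling the query", {
  prot <- rand_protein(400, seed = 21)
  sp <- implant_spec("ref", data.frame(aa_pos = c(110, 240), phase = c(2, 1)),
                     substitution_rate = 0)
  set.seed(22)
  r <- implant_gene(rscout:::random_nt(20000), prot, sp, strand = "+")
  h <- find_exon_hits(prot, r$scaffold)
  expect_gte(nrow(h), 3L)
  covered <- sort(unique(unlist(mapply(seq, h$q_start, h$q_end))))
  expect_gte(length(covered) / 400, 0.95)
})

test_that("intron-free zero-substitution hits match local Smith-Waterman", {
  prot <- rand_protein(300, seed = 23)
  cds <- withr::with_seed(24, rscout:::reverse_translate(prot))
  scaf <- withr::with_seed(25,
    paste0(rscout:::random_nt(1500), "TAA", cds, "TAA",
           rscout:::random_nt(1500)))
  h <- find_exon_hits(prot, scaf)
  top <- h[which.max(h$score), ]
  expect_equal(top$n_ident / (top$q_end - top$q_start + 1L), 1.0)
  expect_equal(c(top$q_start, top$q_end), c(1L, 300L))
  # independent oracle: optimal local alignment in the planted frame
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(prot),
    Biostrings::AAString(gsub("*", "X", rscout:::translate_cds(
      substr(scaf, 1504, 1503 + 900)), fixed = TRUE)),
    substitutionMatrix = rscout:::blosum62(),
    gapOpening = 11, gapExtension = 1, type = "local")
  expect_equal(top$score, Biostrings::score(pa))
})
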