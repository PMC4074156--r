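mk_exon_model <- function(lens, cds = NULL) {
  # exon lengths in nt, laid head-to-tail with 100-nt introns
  starts <- cumsum(c(0L, head(lens, -1) + 100L))
  structure(list(id = "g", scaffold_id = "s", strand = "+",
                 exons = cbind(start = starts, end = starts + lens),
                 cds = cds), class = "GeneModel")
}

test_that("splice positions follow the floor(c/3)+1 / c mod 3 convention", {
  m <- mk_exon_model(c(300L, 300L))
  expect_equal(splice_to_aa(m), data.frame(aa_pos = 101L, phase = 0L))
  m2 <- mk_exon_model(c(298L, 302L))
  expect_equal(splice_to_aa(m2), data.frame(aa_pos = 100L, phase = 1L))
  expect_equal(nrow(splice_to_aa(mk_exon_model(600L))), 0L)
  expect_error(splice_to_aa(mk_exon_model(c(0L, 300L))), "intron outside")
})

test_that("splice_to_aa inverts the implant convention on synthetic genes", {
  ds <- demo_dataset()
  for (tr in ds$truth) {
    m <- structure(list(exons = tr$exons, cds = NULL), class = "GeneModel")
    got <- splice_to_aa(m)
    if (tr$lesion %in% c("none", "premature_stop")) {
      expect_equal(got$aa_pos, tr$introns$aa_pos)
      expect_equal(got$phase, tr$introns$phase)
    }
  }
})

test_that("marks project through gapped alignments and invert correctly", {
  marks <- data.frame(gene_id = "g1", aa_pos = 2L, phase = 0L)
  msa <- c(g1 = "A-CD")
  out <- map_to_alignment(marks, msa)
  expect_equal(out$msa_column, 3L)
  # gap-free alignment: column equals the aa position
  out2 <- map_to_alignment(data.frame(gene_id = "g1", aa_pos = 3L, phase = 1L),
                           c(g1 = "AWCDE"))
  expect_equal(out2$msa_column, 3L)
  expect_error(map_to_alignment(marks, c(g2 = "ACD-")), "missing")
  expect_error(map_to_alignment(marks, c(g1 = "A-CD"),
                                proteins = c(g1 = "AQD")), "does not match")
  # random gapped rows: un-gapping the prefix up to the column recovers aa_pos
  for (seed in 1:8) {
    row <- withr::with_seed(seed, {
      chars <- sample(c(rscout:::AA20, "-"), 120, replace = TRUE,
                      prob = c(rep(1, 20), 6))
      paste(chars, collapse = "")
    })
    n_aa <- nchar(gsub("-", "", row))
    if (n_aa < 5) next
    aa_pos <- withr::with_seed(seed + 50, sample(n_aa - 1, 1))
    mk <- map_to_alignment(data.frame(gene_id = "g", aa_pos = aa_pos,
                                      phase = 0L), c(g = row))
    prefix <- substr(row, 1, mk$msa_column)
    expect_equal(nchar(gsub("-", "", prefix)), aa_pos)
    expect_equal(mk$scaled_pos,
                 min(400L, max(1L, floor(mk$msa_column / nchar(row) * 400 + 0.5))))
  }
})

test_that("histogram merging keeps mass and follows the count-maximizing rule", {
  m1 <- data.frame(gene_id = sprintf("g%d", 1:10), scaled_pos = 200L)
  r <- conservation_histogram(list(sp = m1), min_genes = 8, merge_radius = 1)
  expect_equal(r$conserved, 200L)
  expect_equal(r$merged$total, 10)

  # 7 genes at 200 + 2 at 201 merge onto 200 with count 9
  m2 <- data.frame(gene_id = sprintf("g%d", 1:9),
                   scaled_pos = c(rep(200L, 7), 201L, 201L))
  r2 <- conservation_histogram(list(sp = m2), min_genes = 8, merge_radius = 1)
  expect_equal(r2$merged$scaled_pos, 200L)
  expect_equal(r2$merged$total, 9)
  expect_equal(r2$conserved, 200L)

  # mass conservation under merging, including multi-species input
  m3 <- data.frame(gene_id = sprintf("h%d", 1:6),
                   scaled_pos = c(100L, 101L, 102L, 250L, 251L, 399L))
  r3 <- conservation_histogram(list(a = m2, b = m3), min_genes = 8,
                               merge_radius = 1)
  expect_equal(sum(r3$merged$a) + sum(r3$merged$b), 9 + 6)
  expect_equal(length(r3$conserved), 0L)
})

test_that("a shared implanted intron is the only conserved position called", {
  # 15 genes: 12 share an intron site, each has one private site
  prot_len <- 400L
  shared_aa <- 180L
  marks <- do.call(rbind, lapply(1:15, function(i) {
    pos <- withr::with_seed(300 + i, sample(setdiff(seq(20, 380), 170:190), 1))
    rows <- data.frame(gene_id = sprintf("g%02d", i), aa_pos = pos, phase = 0L)
    if (i <= 12)
      rows <- rbind(rows, data.frame(gene_id = sprintf("g%02d", i),
                                     aa_pos = shared_aa, phase = 1L))
    rows
  }))
  msa <- stats::setNames(rep(strrep("A", prot_len), 15),
                         sprintf("g%02d", 1:15))
  mapped <- map_to_alignment(marks, msa)
  rep <- conservation_histogram(list(target = mapped), min_genes = 8,
                                merge_radius = 1)
  expect_equal(rep$conserved, 180L)
})
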