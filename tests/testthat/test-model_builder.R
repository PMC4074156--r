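test_that("chaining handles single and colinear hit pairs", {
  h <- random_hits(1, seed = 1)
  h$q_end <- h$q_start + 50L
  ch <- chain_exons(h)
  expect_equal(length(ch), 1L)
  expect_equal(nrow(ch[[1]]$hits), 1L)

  h2 <- data.frame(scaffold_id = "s", strand = "+", frame = 0L,
                   g_start = c(1000L, 2000L), g_end = c(1500L, 2400L),
                   query_id = "q", q_start = c(1L, 170L),
                   q_end = c(167L, 300L), s_start = 1L, s_end = 1L,
                   score = c(300, 250), n_ident = 1L, qseq = "", sseq = "",
                   stringsAsFactors = FALSE)
  ch2 <- chain_exons(h2)
  expect_equal(nrow(ch2[[1]]$hits), 2L)
  expect_equal(ch2[[1]]$score, 550)
})

test_that("chain scores equal the exhaustive-subset maximum", {
  for (seed in 1:12) {
    h <- random_hits(6, seed = seed)
    h$q_end <- pmin(300L, h$q_start + as.integer((h$g_end - h$g_start) / 3) - 1L)
    ch <- chain_exons(h, chain_params(min_chain_score = 0))
    got <- if (length(ch)) max(vapply(ch, `[[`, numeric(1), "score")) else 0
    expect_equal(got, brute_force_chain(h))
  }
})

test_that("single-exon chains pass through refinement unchanged", {
  prot <- rand_protein(250, seed = 31)
  cds <- withr::with_seed(32, rscout:::reverse_translate(prot))
  scaf <- withr::with_seed(33,
    paste0(rscout:::random_nt(999), "TAA", cds, "TAA",
           rscout:::random_nt(999)))
  h <- find_exon_hits(prot, scaf)
  ch <- chain_exons(h)
  m <- refine_splice_sites(ch[[1]], scaf, prot, id = "x")
  expect_equal(nrow(m$exons), 1L)
  expect_false(m$flags$frame_break)
  expect_equal(m$protein, prot)
})

test_that("intact multi-exon implants are recovered to the exact base", {
  prot <- rand_protein(420, seed = 41)
  sp <- implant_spec("ref", data.frame(aa_pos = c(140, 300), phase = c(2, 1)),
                     substitution_rate = 0.02)
  for (strand in c("+", "-")) {
    set.seed(42)
    r <- implant_gene(rscout:::random_nt(25000), prot, sp, strand = strand)
    h <- find_exon_hits(prot, r$scaffold)
    ch <- chain_exons(h)
    m <- refine_splice_sites(ch[[1]], r$scaffold, prot, id = "x")
    expect_equal(m$exons[order(m$exons[, 1]), ],
                 r$truth$exons[order(r$truth$exons[, 1]), ],
                 ignore_attr = TRUE)
    sp_aa <- splice_to_aa(m)
    expect_equal(sp_aa$aa_pos, r$truth$introns$aa_pos)
    expect_equal(sp_aa$phase, r$truth$introns$phase)
  }
})

test_that("frameshift implants raise a lesion flag through the full build", {
  prot <- rand_protein(420, seed = 51)
  sp <- implant_spec("ref", data.frame(aa_pos = c(140, 300), phase = c(0, 0)),
                     substitution_rate = 0, lesion = "frameshift")
  set.seed(52)
  r <- implant_gene(rscout:::random_nt(25000), prot, sp, strand = "+")
  h <- find_exon_hits(prot, r$scaffold)
  ch <- chain_exons(h)
  m <- refine_splice_sites(ch[[1]], r$scaffold, prot, id = "x")
  m <- translate_model(m, prot)
  expect_true(m$flags$frame_break || m$flags$internal_stop)
})

test_that("translate_model flags stops and frame-disrupting indels", {
  ref <- rand_protein(300, seed = 61)
  cds <- withr::with_seed(62, rscout:::reverse_translate(ref))
  mk <- function(cds) structure(
    list(id = "t", scaffold_id = "s", strand = "+",
         exons = cbind(start = 0L, end = nchar(cds)), cds = cds,
         protein = "", protein_full = rscout:::translate_cds(cds),
         flags = list(internal_stop = FALSE, frame_break = FALSE,
                      has_internal_N = FALSE, start_codon_present = TRUE,
                      stop_codon_present = TRUE),
         junctions = list(), source_query = "r"), class = "GeneModel")
  # internal stop at codon 100 of 300
  stopped <- paste0(substr(cds, 1, 297), "TAA", substr(cds, 301, 900))
  m1 <- mk(stopped)
  expect_true(grepl("*", substr(m1$protein_full, 1, 299), fixed = TRUE))
  m1 <- translate_model(m1, ref)
  expect_false(m1$flags$frame_break)
  # a 1-nt deletion versus the reference breaks the frame
  shifted <- paste0(substr(cds, 1, 450), substr(cds, 452, 900))
  m2 <- translate_model(mk(shifted), ref)
  expect_true(m2$flags$frame_break)
  # the clean CDS raises nothing
  m3 <- translate_model(mk(cds), ref)
  expect_false(m3$flags$frame_break)
})
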