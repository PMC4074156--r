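test_that("reference families are deterministic and share conserved blocks", {
  a <- make_reference_family(n_genes = 4, length_aa = 200, seed = 5)
  b <- make_reference_family(n_genes = 4, length_aa = 200, seed = 5)
  expect_identical(as.character(a), as.character(b))

  z <- make_reference_family(n_genes = 3, length_aa = 200, divergence = 0,
                             seed = 1)
  expect_equal(length(unique(as.character(z))), 1L)
  expect_error(make_reference_family(divergence = 1.5), "divergence")
})

test_that("family divergence lands in the expected identity band", {
  fam <- make_reference_family(n_genes = 10, length_aa = 400,
                               divergence = 0.4, seed = 1)
  s <- as.character(fam)
  pairs <- utils::combn(length(s), 2)
  ids <- apply(pairs[, seq(1, ncol(pairs), by = 3)], 2, function(p)
    pairwise_identity(s[p[1]], s[p[2]]))
  expect_gt(mean(ids), 0.45)
  expect_lt(mean(ids), 0.75)
})

test_that("a clean implant translates back to its source protein", {
  prot <- rand_protein(200, seed = 2)
  sp <- implant_spec("ref", substitution_rate = 0)
  r <- implant_gene(strrep("A", 10000), prot, sp, seed = 3, pos = 3000)
  tr <- r$truth
  expect_equal(nrow(tr$exons), 1L)
  cds <- substr(r$scaffold, tr$exons[1, 1] + 1L, tr$exons[1, 2])
  expect_equal(rscout:::translate_cds(cds), paste0(prot, "*"))
})

test_that("intron splitting obeys the aa/phase convention and GT..AG ends", {
  prot <- rand_protein(400, seed = 4)
  sp <- implant_spec("ref", data.frame(aa_pos = c(100, 250), phase = c(1, 0)),
                     substitution_rate = 0)
  set.seed(9)
  r <- implant_gene(rscout:::random_nt(12000), prot, sp, strand = "+")
  tr <- r$truth
  expect_equal(nrow(tr$exons), 3L)
  spliced <- paste(substring(r$scaffold, tr$exons[, 1] + 1L, tr$exons[, 2]),
                   collapse = "")
  expect_equal(rscout:::translate_cds(spliced), paste0(prot, "*"))
  unspliced <- substr(r$scaffold, tr$exons[1, 1] + 1L, tr$exons[3, 2])
  expect_false(rscout:::translate_cds(unspliced) == paste0(prot, "*"))
  # GT / AG at every intron boundary
  for (i in 1:2) {
    don <- substr(r$scaffold, tr$exons[i, 2] + 1L, tr$exons[i, 2] + 2L)
    acc <- substr(r$scaffold, tr$exons[i + 1, 1] - 1L, tr$exons[i + 1, 1])
    expect_equal(don, "GT")
    expect_equal(acc, "AG")
  }
})

test_that("implant lesions are consistent with their expected status", {
  prot <- rand_protein(400, seed = 11)
  introns <- data.frame(aa_pos = c(120, 260), phase = c(0, 2))
  mk <- function(lesion) {
    sp <- implant_spec("ref", introns, substitution_rate = 0, lesion = lesion)
    set.seed(13)
    implant_gene(rscout:::random_nt(12000), prot, sp)$truth
  }
  expect_equal(mk("frameshift")$expected_status, "pseudogene")
  expect_equal(mk("truncate_5p")$expected_status, "partial_N")
  # a frameshifted CDS no longer translates to the source protein downstream
  sp <- implant_spec("ref", introns, substitution_rate = 0,
                     lesion = "frameshift")
  set.seed(13)
  r <- implant_gene(rscout:::random_nt(12000), prot, sp)
  spliced <- paste(substring(r$scaffold, r$truth$exons[, 1] + 1L,
                             r$truth$exons[, 2]), collapse = "")
  expect_false(grepl(substr(prot, 350, 380), rscout:::translate_cds(spliced),
                     fixed = TRUE))
  expect_error(implant_gene(strrep("A", 10000), prot,
                            implant_spec("ref",
                                         data.frame(aa_pos = 500, phase = 0))),
               "incompatible")
})

test_that("generated datasets match their config and are reproducible", {
  cfg <- default_config(n_intact = 2L, n_frameshift = 1L,
                        n_premature_stop = 0L, n_truncate_5p = 0L,
                        n_truncate_3p = 0L, n_internal_gap = 0L,
                        n_allele_pairs = 1L, n_tandem_arrays = 1L,
                        n_decoys = 1L, scaffold_nt = 15000L)
  ds1 <- generate_dataset(cfg, seed = 7)
  ds2 <- generate_dataset(cfg, seed = 7)
  expect_identical(as.character(ds1$genome), as.character(ds2$genome))
  expect_identical(lapply(ds1$truth, `[[`, "exons"),
                   lapply(ds2$truth, `[[`, "exons"))
  # bookkeeping: 2 intact + 1 frameshift + allele pair (2) + tandem (2)
  expect_equal(length(ds1$truth), 7L)
  expect_equal(sum(vapply(ds1$truth, `[[`, character(1), "lesion") ==
                     "frameshift"), 1L)
  expect_equal(sum(!vapply(ds1$truth, `[[`, logical(1), "expected_kept")), 1L)
  # allele copy sits on a contig below the small-contig bound
  allele <- Filter(function(t) t$placement == "short_contig_allele", ds1$truth)
  w <- Biostrings::width(ds1$genome)[fasta_ids(ds1$genome) ==
                                       allele[[1]]$scaffold_id]
  expect_lt(w, 10000)
})

test_that("truth coordinates round-trip through GFF3", {
  ds <- demo_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  feats <- read_gff3(file.path(dir, "truth.gff3"))
  for (tr in ds$truth[1:3]) {
    ex <- feats[feats$feature_type == "exon" &
                  grepl(paste0(tr$gene_id, "\\."), feats$id), ]
    got <- as.matrix(ex[order(ex$start), c("start", "end")])
    want <- tr$exons[order(tr$exons[, 1]), , drop = FALSE]
    expect_equal(unname(got[, 1]), unname(want[, 1] + 1L))
    expect_equal(unname(got[, 2]), unname(want[, 2]))
  }
})
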