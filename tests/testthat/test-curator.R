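mk_model <- function(protein_full, id = "m1", scaffold_id = "s1",
                     flags = list()) {
  fl <- utils::modifyList(list(internal_stop = FALSE, frame_break = FALSE,
                               has_internal_N = FALSE,
                               start_codon_present = TRUE,
                               stop_codon_present = TRUE), flags)
  cds <- withr::with_seed(99, rscout:::reverse_translate(
    gsub("[X*]", "A", protein_full)))
  structure(list(id = id, scaffold_id = scaffold_id, strand = "+",
                 exons = cbind(start = 0L, end = nchar(cds)),
                 cds = cds, protein = protein_full,
                 protein_full = protein_full, flags = fl,
                 junctions = list(), source_query = "r", chain_score = 100),
            class = "GeneModel")
}

test_that("the fragment filter cuts exactly below 150 aa", {
  short <- mk_model(rand_protein(149, seed = 1), id = "a")
  exact <- mk_model(rand_protein(150, seed = 2), id = "b")
  fr <- filter_fragments(list(short, exact))
  expect_equal(vapply(fr$dropped, `[[`, character(1), "id"), "a")
  expect_equal(vapply(fr$kept, `[[`, character(1), "id"), "b")
  expect_equal(filter_fragments(list()),
               list(kept = list(), dropped = list()))
})

test_that("status classification follows the lesion and terminus rules", {
  ref <- rand_protein(400, seed = 3)
  full <- mk_model(ref)
  expect_equal(classify_status(full, ref), "complete")
  # lesion flags take precedence
  expect_equal(classify_status(mk_model(ref, flags = list(internal_stop = TRUE)),
                               ref), "pseudogene")
  expect_equal(classify_status(mk_model(ref, flags = list(frame_break = TRUE)),
                               ref), "pseudogene")
  # missing termini
  n_trunc <- mk_model(substr(ref, 41, 400),
                      flags = list(start_codon_present = FALSE))
  expect_equal(classify_status(n_trunc, ref), "partial_N")
  c_trunc <- mk_model(substr(ref, 1, 360),
                      flags = list(stop_codon_present = FALSE))
  expect_equal(classify_status(c_trunc, ref), "partial_C")
  nc <- mk_model(substr(ref, 41, 360),
                 flags = list(start_codon_present = FALSE,
                              stop_codon_present = FALSE))
  expect_equal(classify_status(nc, ref), "partial_NC")
  # internal N run marks a missing internal exon
  gap <- mk_model(paste0(substr(ref, 1, 150), strrep("X", 60),
                         substr(ref, 211, 400)),
                  flags = list(has_internal_N = TRUE))
  expect_equal(classify_status(gap, ref), "partial_M")
})

test_that("allele resolution drops only frame-preserving small-contig copies", {
  prot <- rand_protein(400, seed = 4)
  cds <- withr::with_seed(5, rscout:::reverse_translate(prot))
  mut <- function(cds, k, seed, drop_codon = NULL) {
    nt <- strsplit(cds, "", fixed = TRUE)[[1]]
    withr::with_seed(seed, {
      pos <- sample(seq_along(nt), k)
      for (p in pos) nt[p] <- sample(setdiff(c("A", "C", "G", "T"), nt[p]), 1)
    })
    if (!is.null(drop_codon)) nt <- nt[-((drop_codon * 3 + 1):(drop_codon * 3 + 3))]
    paste(nt, collapse = "")
  }
  base <- structure(list(id = "big", scaffold_id = "scafA", strand = "+",
                         exons = cbind(start = 0L, end = nchar(cds)),
                         cds = cds, protein = prot, protein_full = prot,
                         flags = list(), junctions = list(),
                         source_query = "r", chain_score = 10),
                    class = "GeneModel")
  allele <- base
  allele$id <- "small"; allele$scaffold_id <- "contigB"
  allele$cds <- mut(cds, 20, seed = 6, drop_codon = 100)
  lens <- c(scafA = 40000, contigB = 8000)
  d <- resolve_alleles_paralogs(list(base, allele), lens)
  expect_false(d$kept[d$model_id == "small"])
  expect_equal(d$drop_reason[d$model_id == "small"], "allelic_variant")
  expect_true(d$kept[d$model_id == "big"])

  # same scaffold: tandem paralogs, both kept
  par2 <- allele; par2$scaffold_id <- "scafA"; par2$id <- "tandem"
  d2 <- resolve_alleles_paralogs(list(base, par2), lens)
  expect_true(all(d2$kept))
  expect_true(all(grepl("tandem_paralog", d2$pair_note)))

  # unrelated models are untouched
  other <- base; other$id <- "other"; other$scaffold_id <- "contigB"
  other$cds <- withr::with_seed(8, rscout:::reverse_translate(
    rand_protein(400, seed = 7)))
  d3 <- resolve_alleles_paralogs(list(base, other), lens)
  expect_true(all(d3$kept))
  expect_true(all(d3$drop_reason == "none"))
})

test_that("naming inherits reciprocal-best reference numbers", {
  d <- data.frame(model_id = c("m1", "m2", "m3"),
                  best_ref = c("RefOR23", "RefOR43", "RefOR43"),
                  identity = c(0.9, 0.8, 0.6),
                  status = c("complete", "complete", "pseudogene"),
                  kept = TRUE,
                  scaffold_id = c("s1", "s2", "s3"),
                  g_start = c(10, 10, 10), stringsAsFactors = FALSE)
  out <- assign_names(d, paste0("RefOR", 1:50), prefix = "AgoOR")
  expect_equal(out$assigned_name[1], "AgoOR23")
  expect_equal(out$assigned_name[2], "AgoOR43")
  # the non-reciprocal rival gets the smallest unused number, suffixed P
  expect_equal(out$assigned_name[3], "AgoOR1P")
  expect_equal(anyDuplicated(out$assigned_name), 0L)
  empty <- assign_names(d[0, ], paste0("RefOR", 1:50))
  expect_equal(nrow(empty), 0L)
})
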