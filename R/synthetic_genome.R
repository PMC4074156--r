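# Synthetic genome generator: receptor-like multi-exon genes implanted into
# random scaffolds with a machine-readable truth set. Emulates every situation
# the curation rules must handle: intact multi-exon genes, frameshift and
# premature-stop pseudogenes, edge-truncated and N-gapped partial models,
# near-identical allelic copies on short contigs, and tandem paralog arrays.

LESIONS <- c("none", "frameshift", "premature_stop", "truncate_5p",
             "truncate_3p", "internal_gap")
PLACEMENTS <- c("normal", "short_contig_allele", "tandem_array")

#' Implant specification for one synthetic gene
#'
#' @param protein_source id of the reference protein the implant derives from.
#' @param intron_positions matrix/data.frame with columns `aa_pos` (1-based)
#'   and `phase` (0/1/2): an intron at (p, f) interrupts the CDS after
#'   `3*(p-1)+f` coding nucleotides.
#' @param intron_lengths intron lengths in nt (recycled); `NULL` draws
#'   uniformly from 60-1200 nt. Minimum 40 nt.
#' @param substitution_rate fraction of internal residues substituted
#'   (amino-acid level, never the first/last residue, never to a stop).
#' @param lesion one of `r paste(LESIONS, collapse=", ")`.
#' @param placement one of `r paste(PLACEMENTS, collapse=", ")`.
#' @export
implant_spec <- function(protein_source, intron_positions = NULL,
                         intron_lengths = NULL, substitution_rate = 0,
                         lesion = "none", placement = "normal") {
  lesion <- match.arg(lesion, LESIONS)
  placement <- match.arg(placement, PLACEMENTS)
  if (substitution_rate < 0 || substitution_rate > 0.5)
    stop("substitution_rate must lie in [0, 0.5]")
  if (!is.null(intron_positions)) {
    intron_positions <- as.data.frame(intron_positions)
    names(intron_positions) <- c("aa_pos", "phase")
    if (any(diff(intron_positions$aa_pos) <= 0))
      stop("intron aa positions must be strictly increasing")
    if (any(!intron_positions$phase %in% 0:2)) stop("phase must be 0, 1 or 2")
  } else {
    intron_positions <- data.frame(aa_pos = integer(), phase = integer())
  }
  if (!is.null(intron_lengths) && any(intron_lengths < 40))
    stop("introns must be at least 40 nt")
  structure(list(protein_source = protein_source,
                 intron_positions = intron_positions,
                 intron_lengths = intron_lengths,
                 substitution_rate = substitution_rate,
                 lesion = lesion, placement = placement),
            class = "ImplantSpec")
}

#' Generate a synthetic reference receptor family
#'
#' Proteins share `n_conserved_blocks` identical blocks (so alignment seeds
#' exist across the family) and diverge elsewhere from a common ancestor at
#' the given per-site substitution probability.
#'
#' @param n_genes number of family members (>= 2).
#' @param length_aa protein length (>= 150).
#' @param n_conserved_blocks number of conserved 12-aa blocks.
#' @param divergence per-site substitution probability outside blocks, in \[0,1\].
#' @param seed RNG seed (deterministic output).
#' @param prefix id prefix; members are named `<prefix>1 .. <prefix>n`.
#' @return [Biostrings::AAStringSet] of family members.
#' @export
make_reference_family <- function(n_genes = 10, length_aa = 420,
                                  n_conserved_blocks = 6, divergence = 0.35,
                                  seed = 1, prefix = "RefOR") {
  if (n_genes < 2) stop("n_genes must be >= 2")
  if (length_aa < 150) stop("length_aa must be >= 150")
  if (divergence < 0 || divergence > 1) stop("divergence must lie in [0, 1]")
  with_seed(seed, {
    anc <- c("M", sample(AA20, length_aa - 1L, replace = TRUE))
    block_w <- 12L
    starts <- round(seq(30, length_aa - block_w - 10, length.out = n_conserved_blocks))
    conserved <- unique(unlist(lapply(starts, function(s) s:(s + block_w - 1L))))
    mutable <- setdiff(2:length_aa, conserved)
    out <- vapply(seq_len(n_genes), function(i) {
      p <- anc
      hit <- mutable[stats::runif(length(mutable)) < divergence]
      p[hit] <- vapply(p[hit], function(a) sample(setdiff(AA20, a), 1L), character(1))
      paste(p, collapse = "")
    }, character(1))
    names(out) <- paste0(prefix, seq_len(n_genes))
    Biostrings::AAStringSet(out)
  })
}

#' @noRd
substitute_protein <- function(protein, rate) {
  if (rate <= 0) return(protein)
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  L <- length(aa)
  k <- round(rate * (L - 2L))
  if (k > 0) {
    pos <- sample(2:(L - 1L), k)
    aa[pos] <- vapply(aa[pos], function(a) sample(setdiff(AA20, a), 1L),
                      character(1))
  }
  paste(aa, collapse = "")
}

#' Implant one receptor gene into a scaffold
#'
#' The (optionally substituted) protein is reverse-translated with uniform
#' synonymous codon choice, split at the specified amino-acid/phase
#' boundaries, interleaved with GT..AG introns, lesioned, and inserted into
#' the scaffold. Exon coordinates in the returned truth record are 0-based
#' half-open on the forward strand, in coding order, with the stop codon
#' included in the terminal exon.
#'
#' @param scaffold nucleotide string.
#' @param protein amino-acid string (no stop).
#' @param spec an [implant_spec()].
#' @param seed optional RNG seed; `NULL` uses the current RNG stream.
#' @param pos 0-based insertion offset; `NULL` picks a position leaving
#'   2-kb flanks (edge-truncation lesions override this).
#' @param strand `"+"` or `"-"`.
#' @param gene_id,scaffold_id ids recorded in the truth record.
#' @return list with elements `scaffold` (modified string) and `truth`
#'   (a `TruthRecord` list).
#' @export
implant_gene <- function(scaffold, protein, spec, seed = NULL, pos = NULL,
                         strand = "+", gene_id = "gene", scaffold_id = "scaffold") {
  run <- function() {
    L_aa <- nchar(protein)
    ip <- spec$intron_positions
    if (nrow(ip) && any(ip$aa_pos >= L_aa | ip$aa_pos < 1))
      stop("intron aa position incompatible with protein length")
    prot <- substitute_protein(protein, spec$substitution_rate)
    cds <- paste0(reverse_translate(prot), "TAA")
    cuts <- if (nrow(ip)) 3L * (ip$aa_pos - 1L) + ip$phase else integer()
    if (any(cuts <= 0 | cuts >= nchar(cds))) stop("intron outside CDS")
    bounds <- c(0L, cuts, nchar(cds))
    exon_nt <- vapply(seq_len(length(bounds) - 1L), function(i)
      substr(cds, bounds[i] + 1L, bounds[i + 1L]), character(1))
    n_introns <- length(cuts)
    ilen <- if (n_introns == 0L) integer() else {
      if (!is.null(spec$intron_lengths)) rep_len(spec$intron_lengths, n_introns)
      else 2L * sample(30:600, n_introns, replace = TRUE)
    }
    intron_nt <- vapply(ilen, function(l) paste0("GT", random_nt(l - 4L), "AG"),
                        character(1))

    lesion <- spec$lesion
    clip5 <- 0L; clip3 <- 0L
    if (lesion == "frameshift") {
      i <- if (length(exon_nt) >= 3L) 2L else 1L
      at <- nchar(exon_nt[i]) %/% 2L
      exon_nt[i] <- paste0(substr(exon_nt[i], 1L, at - 1L),
                           substr(exon_nt[i], at + 1L, nchar(exon_nt[i])))
    } else if (lesion == "premature_stop") {
      # replace a codon that lies fully inside one exon near the middle
      target <- (L_aa %/% 2L)
      repeat {
        c0 <- 3L * (target - 1L)
        i <- findInterval(c0, bounds, rightmost.closed = FALSE)
        if (c0 >= bounds[i] && c0 + 3L <= bounds[i + 1L]) break
        target <- target + 1L
        if (target >= L_aa) stop("no internal codon available for premature stop")
      }
      off <- c0 - bounds[i]
      exon_nt[i] <- paste0(substr(exon_nt[i], 1L, off),
                           "TAA",
                           substr(exon_nt[i], off + 4L, nchar(exon_nt[i])))
    } else if (lesion == "truncate_5p") {
      clip5 <- 120L
      if (nchar(exon_nt[1]) <= clip5 + 60L) stop("first exon too short to clip")
      exon_nt[1] <- substr(exon_nt[1], clip5 + 1L, nchar(exon_nt[1]))
    } else if (lesion == "truncate_3p") {
      clip3 <- 120L
      k <- length(exon_nt)
      if (nchar(exon_nt[k]) <= clip3 + 60L) stop("last exon too short to clip")
      exon_nt[k] <- substr(exon_nt[k], 1L, nchar(exon_nt[k]) - clip3)
    } else if (lesion == "internal_gap") {
      if (length(exon_nt) < 3L) stop("internal_gap needs >= 3 exons")
      exon_nt[2] <- strrep("N", nchar(exon_nt[2]))
    }

    # interleave exons and introns on the coding strand
    pieces <- character(0)
    is_exon <- logical(0)
    for (i in seq_along(exon_nt)) {
      pieces <- c(pieces, exon_nt[i]); is_exon <- c(is_exon, TRUE)
      if (i <= n_introns) { pieces <- c(pieces, intron_nt[i]); is_exon <- c(is_exon, FALSE) }
    }
    gene_nt <- paste(pieces, collapse = "")
    G <- nchar(gene_nt)
    off <- cumsum(c(0L, nchar(pieces)))[seq_along(pieces)]
    ex_off <- off[is_exon]
    ex_len <- nchar(pieces)[is_exon]

    Ls <- nchar(scaffold)
    if (lesion == "truncate_5p") pos <- 0L
    else if (lesion == "truncate_3p") pos <- Ls
    else if (is.null(pos)) {
      if (Ls < 4000L) stop("scaffold too short for 2 kb flanks")
      pos <- sample(2000:(Ls - 2000L), 1L)
    }
    ins <- if (strand == "+") gene_nt else revcomp(gene_nt)
    scaffold2 <- paste0(substr(scaffold, 1L, pos), ins,
                        substr(scaffold, pos + 1L, Ls))
    exons <- if (strand == "+")
      cbind(start = pos + ex_off, end = pos + ex_off + ex_len)
    else
      cbind(start = pos + G - (ex_off + ex_len), end = pos + G - ex_off)

    expected_status <- switch(lesion,
      none = "complete", frameshift = "pseudogene",
      premature_stop = "pseudogene", truncate_5p = "partial_N",
      truncate_3p = "partial_C", internal_gap = "partial_M")
    truth <- structure(list(
      gene_id = gene_id, scaffold_id = scaffold_id, strand = strand,
      exons = exons,
      introns = data.frame(aa_pos = ip$aa_pos, phase = ip$phase),
      lesion = lesion, placement = spec$placement,
      expected_status = expected_status,
      expected_kept = spec$placement != "short_contig_allele",
      source_protein = spec$protein_source,
      protein = prot, cds_len = sum(nchar(exon_nt)),
      span = c(pos, pos + G)), class = "TruthRecord")
    list(scaffold = scaffold2, truth = truth)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @noRd
sample_intron_spec <- function(length_aa, n_introns) {
  # positions spaced so every coding segment spans >= ~60 aa
  lo <- 70L; hi <- length_aa - 70L
  repeat {
    p <- sort(sample(lo:hi, n_introns))
    if (n_introns == 1L || all(diff(p) >= 60L)) break
  }
  data.frame(aa_pos = p, phase = sample(0:2, n_introns, replace = TRUE))
}

#' Default synthetic-dataset configuration
#'
#' Counts per lesion/placement class plus generator parameters. The defaults
#' define the standard validation conditions used throughout the test-suite:
#' ~18 implanted receptor loci (including one allelic pair and one tandem
#' array) in scaffolds totalling well under 2 Mb.
#' @param ... overrides of the listed defaults.
#' @export
default_config <- function(...) {
  cfg <- list(
    n_intact = 8L, n_frameshift = 2L, n_premature_stop = 1L,
    n_truncate_5p = 1L, n_truncate_3p = 1L, n_internal_gap = 1L,
    n_allele_pairs = 1L, n_tandem_arrays = 1L, tandem_size = 2L,
    n_decoys = 2L,
    scaffold_nt = 30000L, decoy_nt = 20000L, small_contig_nt = 8000L,
    substitution_rate = 0.02, allele_sub_nt = 0.02, tandem_sub_nt = 0.03,
    ref_n_genes = 10L, ref_length_aa = 420L, ref_blocks = 6L,
    ref_divergence = 0.35, ref_prefix = "RefOR")
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' Substitute nucleotides in a gene copy, sparing structural signals
#'
#' Used to derive allelic/paralogous copies: substitutions never touch the
#' start/stop codons or splice-site dinucleotides and never create an
#' in-frame stop. Draws from the active RNG.
#' @noRd
mutate_gene_copy <- function(gene_nt, ex_off, ex_len, rate, delete_codon = FALSE) {
  nt <- strsplit(gene_nt, "", fixed = TRUE)[[1]]
  G <- length(nt)
  # map CDS position -> gene position
  cds_map <- unlist(lapply(seq_along(ex_off), function(i)
    (ex_off[i] + 1L):(ex_off[i] + ex_len[i])))
  in_exon <- logical(G); in_exon[cds_map] <- TRUE
  cds_index <- integer(G); cds_index[cds_map] <- seq_along(cds_map)
  protected <- logical(G)
  protected[cds_map[1:3]] <- TRUE                                  # start codon
  protected[cds_map[(length(cds_map) - 2L):length(cds_map)]] <- TRUE  # stop
  for (i in seq_along(ex_off)) {                                   # GT / AG
    if (i > 1L) protected[(ex_off[i] - 1L):ex_off[i]] <- TRUE
    if (i < length(ex_off)) protected[(ex_off[i] + ex_len[i] + 1L):(ex_off[i] + ex_len[i] + 2L)] <- TRUE
  }
  eligible <- which(!protected)
  k <- round(rate * length(eligible))
  if (k > 0) {
    pos <- sample(eligible, k)
    for (p in pos) {
      alts <- setdiff(NT4, nt[p])
      if (in_exon[p]) {
        ci <- cds_index[p]
        cod0 <- (ci - 1L) %/% 3L
        cpos <- cds_map[(cod0 * 3L + 1L):(cod0 * 3L + 3L)]
        ok <- alts[vapply(alts, function(b) {
          cod <- nt[cpos]; cod[cpos == p] <- b
          !(paste(cod, collapse = "") %in% STOP_CODONS)
        }, logical(1))]
        if (length(ok)) nt[p] <- if (length(ok) == 1L) ok else sample(ok, 1L)
      } else {
        nt[p] <- if (length(alts) == 1L) alts else sample(alts, 1L)
      }
    }
  }
  del_at <- NA_integer_
  if (delete_codon) {
    # drop one full codon from the interior of the largest exon
    i <- which.max(ex_len)
    cds_before <- sum(ex_len[seq_len(i - 1L)])
    first_cod <- ceiling(cds_before / 3) + 4L
    last_cod <- (cds_before + ex_len[i]) %/% 3L - 4L
    cod <- sample(first_cod:last_cod, 1L)
    gpos <- cds_map[((cod - 1L) * 3L + 1L):((cod - 1L) * 3L + 3L)]
    nt <- nt[-gpos]
    del_at <- gpos[1]
  }
  list(gene_nt = paste(nt, collapse = ""), deleted_at = del_at)
}

#' Generate a synthetic genome with implanted receptor genes and truth
#'
#' @param config list from [default_config()].
#' @param seed RNG seed; the whole dataset is deterministic given the seed.
#' @param out_dir optional directory; when given, writes `genome.fasta`,
#'   `references.fasta`, `truth.gff3` and `truth.json`.
#' @return list with `genome` (DNAStringSet), `references` (AAStringSet),
#'   `truth` (list of TruthRecords) and `config`.
#' @export
generate_dataset <- function(config = default_config(), seed = 42, out_dir = NULL) {
  refs <- make_reference_family(config$ref_n_genes, config$ref_length_aa,
                                config$ref_blocks, config$ref_divergence,
                                seed = seed + 1L, prefix = config$ref_prefix)
  res <- with_seed(seed, {
    genome <- list(); truth <- list()
    gi <- 0L; si <- 0L
    ref_idx <- 0L
    next_ref <- function() {
      ref_idx <<- ref_idx %% length(refs) + 1L
      ref_idx
    }
    add_simple <- function(lesion) {
      gi <<- gi + 1L; si <<- si + 1L
      rid <- next_ref()
      n_introns <- sample(2:3, 1L)
      sp <- implant_spec(names(refs)[rid],
                         sample_intron_spec(config$ref_length_aa, n_introns),
                         substitution_rate = config$substitution_rate,
                         lesion = lesion)
      strand <- if (lesion %in% c("truncate_5p", "truncate_3p")) "+"
                else sample(c("+", "-"), 1L)
      scid <- sprintf("scaf_%03d", si)
      r <- implant_gene(random_nt(config$scaffold_nt),
                        as.character(refs[[rid]]), sp,
                        strand = strand,
                        gene_id = sprintf("g%03d", gi), scaffold_id = scid)
      genome[[scid]] <<- r$scaffold
      truth[[r$truth$gene_id]] <<- r$truth
    }
    total_simple <- c(rep("none", config$n_intact),
                      rep("frameshift", config$n_frameshift),
                      rep("premature_stop", config$n_premature_stop),
                      rep("truncate_5p", config$n_truncate_5p),
                      rep("truncate_3p", config$n_truncate_3p),
                      rep("internal_gap", config$n_internal_gap))
    for (les in total_simple) add_simple(les)

    # allelic pair: intact host gene + a substituted copy on a short contig
    for (a in seq_len(config$n_allele_pairs)) {
      gi <- gi + 1L; si <- si + 1L
      rid <- next_ref()
      sp <- implant_spec(names(refs)[rid],
                         sample_intron_spec(config$ref_length_aa, 2L),
                         substitution_rate = config$substitution_rate,
                         lesion = "none")
      scid <- sprintf("scaf_%03d", si)
      r <- implant_gene(random_nt(config$scaffold_nt),
                        as.character(refs[[rid]]), sp, strand = "+",
                        gene_id = sprintf("g%03d", gi), scaffold_id = scid)
      genome[[scid]] <- r$scaffold
      truth[[r$truth$gene_id]] <- r$truth
      host <- r$truth
      gene_nt <- substr(r$scaffold, host$span[1] + 1L, host$span[2])
      ex_off <- host$exons[, 1] - host$span[1]
      ex_len <- host$exons[, 2] - host$exons[, 1]
      mut <- mutate_gene_copy(gene_nt, ex_off, ex_len, config$allele_sub_nt,
                              delete_codon = TRUE)
      gi <- gi + 1L; si <- si + 1L
      scid2 <- sprintf("contig_%03d", si)
      G2 <- nchar(mut$gene_nt)
      flank <- (config$small_contig_nt - G2) %/% 2L
      pos <- flank
      contig <- paste0(random_nt(flank), mut$gene_nt,
                       random_nt(config$small_contig_nt - flank - G2))
      # exon offsets after the codon deletion
      ex_off2 <- ex_off; ex_len2 <- ex_len
      hit <- which(mut$deleted_at > ex_off & mut$deleted_at <= ex_off + ex_len)[1]
      ex_len2[hit] <- ex_len2[hit] - 3L
      if (hit < length(ex_off2)) ex_off2[(hit + 1L):length(ex_off2)] <-
        ex_off2[(hit + 1L):length(ex_off2)] - 3L
      genome[[scid2]] <- contig
      truth[[sprintf("g%03d", gi)]] <- structure(list(
        gene_id = sprintf("g%03d", gi), scaffold_id = scid2, strand = "+",
        exons = cbind(start = pos + ex_off2, end = pos + ex_off2 + ex_len2),
        introns = host$introns, lesion = "none",
        placement = "short_contig_allele",
        expected_status = "complete", expected_kept = FALSE,
        source_protein = host$source_protein,
        protein = NA_character_, cds_len = sum(ex_len2),
        span = c(pos, pos + G2)), class = "TruthRecord")
    }

    # tandem array: paralogous copies side by side on one scaffold
    for (a in seq_len(config$n_tandem_arrays)) {
      si <- si + 1L
      rid <- next_ref()
      scid <- sprintf("scaf_%03d", si)
      sp <- implant_spec(names(refs)[rid],
                         sample_intron_spec(config$ref_length_aa, 2L),
                         substitution_rate = config$substitution_rate,
                         lesion = "none", placement = "tandem_array")
      gi <- gi + 1L
      base_len <- config$scaffold_nt + 20000L
      r <- implant_gene(random_nt(base_len), as.character(refs[[rid]]), sp,
                        pos = 4000L, strand = "+",
                        gene_id = sprintf("g%03d", gi), scaffold_id = scid)
      scaf <- r$scaffold
      truth[[r$truth$gene_id]] <- r$truth
      first <- r$truth
      gene_nt <- substr(scaf, first$span[1] + 1L, first$span[2])
      ex_off <- first$exons[, 1] - first$span[1]
      ex_len <- first$exons[, 2] - first$exons[, 1]
      for (k in seq_len(config$tandem_size - 1L)) {
        mut <- mutate_gene_copy(gene_nt, ex_off, ex_len, config$tandem_sub_nt,
                                delete_codon = FALSE)
        gi <- gi + 1L
        pos2 <- nchar(scaf) - 14000L + (k - 1L) * (nchar(gene_nt) + 2000L)
        scaf <- paste0(substr(scaf, 1L, pos2), mut$gene_nt,
                       substr(scaf, pos2 + 1L, nchar(scaf)))
        truth[[sprintf("g%03d", gi)]] <- structure(list(
          gene_id = sprintf("g%03d", gi), scaffold_id = scid, strand = "+",
          exons = cbind(start = pos2 + ex_off, end = pos2 + ex_off + ex_len),
          introns = first$introns, lesion = "none",
          placement = "tandem_array",
          expected_status = "complete", expected_kept = TRUE,
          source_protein = first$source_protein,
          protein = NA_character_, cds_len = sum(ex_len),
          span = c(pos2, pos2 + nchar(gene_nt))), class = "TruthRecord")
      }
      genome[[scid]] <- scaf
    }

    for (d in seq_len(config$n_decoys)) {
      si <- si + 1L
      genome[[sprintf("decoy_%03d", si)]] <- random_nt(config$decoy_nt)
    }
    list(genome = Biostrings::DNAStringSet(unlist(genome)), truth = truth)
  })
  out <- list(genome = res$genome, references = refs, truth = res$truth,
              config = config, seed = seed)
  if (!is.null(out_dir)) write_dataset(out, out_dir)
  out
}

#' @noRd
truth_to_model <- function(tr) {
  structure(list(id = tr$gene_id, scaffold_id = tr$scaffold_id,
                 strand = tr$strand, exons = tr$exons,
                 cds = NA_character_, protein = tr$protein,
                 flags = list(), source_query = tr$source_protein),
            class = "GeneModel")
}

#' Write a generated dataset to disk
#' @param ds list from [generate_dataset()].
#' @param out_dir output directory (created if missing).
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ds$genome, file.path(out_dir, "genome.fasta"))
  write_fasta(ds$references, file.path(out_dir, "references.fasta"))
  write_gff3(lapply(ds$truth, truth_to_model), file.path(out_dir, "truth.gff3"))
  tr <- lapply(ds$truth, function(t) {
    t$exons <- apply(unname(t$exons), 1, as.list)
    unclass(t)
  })
  jsonlite::write_json(tr, file.path(out_dir, "truth.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
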