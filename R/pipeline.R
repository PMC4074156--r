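# End-to-end orchestration: search -> chain/build -> curate -> stats ->
# introns -> phylogeny, with per-decision logging and a catalog report, plus
# evaluation of a run against a synthetic truth set.

#' Pipeline configuration
#'
#' Bundles the per-module parameter blocks with run-level options. Every
#' default matches the value pinned in the corresponding module.
#'
#' @param search [search_params()].
#' @param chain [chain_params()].
#' @param build [build_params()].
#' @param curation [curation_params()].
#' @param prefix catalog name prefix.
#' @param min_genes,merge_radius intron-conservation calling parameters.
#' @param run_introns,run_phylogeny stage switches (both need an external
#'   `mafft` binary for the protein MSA).
#' @param bootstrap_reps bootstrap replicates for the phylogeny stage.
#' @param min_support subgroup support threshold.
#' @param seed run seed (bootstrap resampling).
#' @export
pipeline_config <- function(search = search_params(), chain = chain_params(),
                            build = build_params(),
                            curation = curation_params(),
                            prefix = "AgoOR",
                            min_genes = 8L, merge_radius = 1L,
                            run_introns = FALSE, run_phylogeny = FALSE,
                            bootstrap_reps = 100L, min_support = 70,
                            seed = 1L) {
  list(search = search, chain = chain, build = build, curation = curation,
       prefix = prefix, min_genes = min_genes, merge_radius = merge_radius,
       run_introns = run_introns, run_phylogeny = run_phylogeny,
       bootstrap_reps = bootstrap_reps, min_support = min_support,
       seed = seed)
}

#' Build gene models from a hit table
#'
#' Chains hits per scaffold/query pair, refines splice sites, and removes
#' redundant models (overlapping models of one locus from different queries;
#' the top-scoring chain wins).
#'
#' @param hits combined hit table from [search_genome()].
#' @param genome [Biostrings::DNAStringSet].
#' @param references [Biostrings::AAStringSet].
#' @param chain_par [chain_params()]; `build_par` [build_params()].
#' @param build_par see above.
#' @return list with `models` (kept) and `redundant` (model ids dropped at
#'   locus deduplication).
#' @export
build_models <- function(hits, genome, references,
                         chain_par = chain_params(),
                         build_par = build_params()) {
  gid <- fasta_ids(genome)
  rid <- fasta_ids(references)
  models <- list()
  mi <- 0L
  if (nrow(hits)) {
    for (key in unique(paste(hits$scaffold_id, hits$query_id, sep = "\r"))) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      h <- hits[hits$scaffold_id == parts[1] & hits$query_id == parts[2], ,
                drop = FALSE]
      scaf <- as.character(genome[[match(parts[1], gid)]])
      query <- as.character(references[[match(parts[2], rid)]])
      for (ch in chain_exons(h, chain_par)) {
        mi <- mi + 1L
        m <- refine_splice_sites(ch, scaf, query, build_par,
                                 id = sprintf("m%03d", mi))
        models[[m$id]] <- m
      }
    }
  }
  # locus deduplication: overlapping models on one scaffold collapse to the
  # top-scoring chain
  if (length(models) > 1L) {
    score <- vapply(models, `[[`, numeric(1), "chain_score")
    ord <- order(-score)
    spans <- lapply(models, function(m) c(min(m$exons[, 1]), max(m$exons[, 2])))
    keep <- character(0); redundant <- character(0)
    occupied <- list()
    for (i in ord) {
      m <- models[[i]]
      sp <- spans[[i]]
      clash <- FALSE
      for (o in occupied[[m$scaffold_id]] %||% list())
        if (sp[1] < o[2] && sp[2] > o[1]) { clash <- TRUE; break }
      if (clash) redundant <- c(redundant, m$id)
      else {
        keep <- c(keep, m$id)
        occupied[[m$scaffold_id]] <- c(occupied[[m$scaffold_id]] %||% list(),
                                       list(sp))
      }
    }
    list(models = models[keep], redundant = redundant,
         redundant_models = models[redundant])
  } else list(models = models, redundant = character(0),
              redundant_models = list())
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Curate gene models into a catalog
#'
#' Applies the full curation sequence: lesion-flag finalization against each
#' model's best reference, fragment filtering, status classification,
#' allelic-variant/paralog resolution, and reference-based naming.
#'
#' @param models list of `GeneModel`s.
#' @param references [Biostrings::AAStringSet] of reference proteins.
#' @param scaffold_lengths named vector of scaffold lengths (nt).
#' @param params [curation_params()].
#' @param prefix naming prefix.
#' @return data.frame catalog: one row per model with curation decision,
#'   naming, identity and TM count.
#' @export
curate_models <- function(models, references, scaffold_lengths,
                          params = curation_params(), prefix = "AgoOR") {
  if (!length(models)) return(empty_catalog())
  refs <- stats::setNames(as.character(references), fasta_ids(references))
  prots <- stats::setNames(
    vapply(models, function(m) gsub("*", "X", m$protein_full, fixed = TRUE),
           character(1)),
    vapply(models, `[[`, character(1), "id"))
  idm <- identity_matrix(prots, refs)
  best_idx <- apply(idm, 1, function(r) order(-r, colnames(idm))[1])
  best_ref <- colnames(idm)[best_idx]
  best_id <- idm[cbind(seq_along(models), best_idx)]
  models <- lapply(seq_along(models), function(i)
    translate_model(models[[i]], refs[[best_ref[i]]]))
  fr <- filter_fragments(models, params$min_aa)
  frag_ids <- vapply(fr$dropped, `[[`, character(1), "id")
  kept_models <- fr$kept
  status <- vapply(kept_models, function(m)
    classify_status(m, refs[[best_ref[match(m$id, names(prots))]]], params),
    character(1))
  ap <- resolve_alleles_paralogs(kept_models, scaffold_lengths, params)
  ids <- vapply(models, `[[`, character(1), "id")
  d <- data.frame(
    model_id = ids,
    scaffold_id = vapply(models, `[[`, character(1), "scaffold_id"),
    strand = vapply(models, `[[`, character(1), "strand"),
    g_start = vapply(models, function(m) min(m$exons[, 1]), numeric(1)),
    g_end = vapply(models, function(m) max(m$exons[, 2]), numeric(1)),
    length_nt = vapply(models, function(m) nchar(m$cds), integer(1)),
    n_exons = vapply(models, function(m) nrow(m$exons), integer(1)),
    best_ref = best_ref, identity = best_id,
    stringsAsFactors = FALSE)
  d$status <- NA_character_
  d$kept <- FALSE
  d$drop_reason <- "fragment_lt_150aa"
  d$pair_note <- ""
  mk <- match(ap$model_id, d$model_id)
  d$status[match(vapply(kept_models, `[[`, character(1), "id"), d$model_id)] <- status
  d$kept[mk] <- ap$kept
  d$drop_reason[mk] <- ap$drop_reason
  d$pair_note[mk] <- ap$pair_note
  d$tm_count <- vapply(models, function(m)
    suppressWarnings(count_tm_segments(m$protein, protein_id = m$id)$tm_count),
    integer(1))
  d <- assign_names(d, names(refs), prefix = prefix, identity_matrix = idm)
  d
}

#' @noRd
empty_catalog <- function() {
  data.frame(model_id = character(), scaffold_id = character(),
             strand = character(), g_start = numeric(), g_end = numeric(),
             length_nt = integer(), n_exons = integer(),
             best_ref = character(), identity = numeric(),
             status = character(), kept = logical(),
             drop_reason = character(), pair_note = character(),
             tm_count = integer(), assigned_name = character(),
             stringsAsFactors = FALSE)
}

#' Align proteins with the external mafft binary
#'
#' @param seqs [Biostrings::AAStringSet] or named character vector.
#' @return [Biostrings::AAStringSet] of aligned rows.
#' @export
align_proteins <- function(seqs) {
  if (Sys.which("mafft") == "")
    stop("protein alignment needs the 'mafft' binary on the PATH")
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)))
  nm <- names(seqs)
  x <- Biostrings::AAStringSet(as.character(seqs))
  names(x) <- nm
  write_fasta(x, fin)
  status <- system2("mafft", c("--auto", "--quiet", "--thread", "1", fin),
                    stdout = fout)
  if (status != 0L) stop("mafft failed with status ", status)
  read_fasta(fout, "aa")
}

#' Run the full annotation pipeline
#'
#' search -> build -> curate -> stats (-> introns -> phylogeny), with every
#' candidate accounted for as kept or dropped-with-reason. Deterministic for
#' a given config and inputs.
#'
#' @param genome [Biostrings::DNAStringSet] or path to a nucleotide FASTA.
#' @param references [Biostrings::AAStringSet] or path to a protein FASTA.
#' @param config [pipeline_config()].
#' @param out_dir optional output directory (catalog CSV, models GFF3,
#'   summary JSON, decision log).
#' @return list of class `RunReport`: `hits`, `models`, `redundant`,
#'   `catalog`, `summary`, optional `introns` and `phylogeny`.
#' @export
run_all <- function(genome, references, config = pipeline_config(),
                    out_dir = NULL) {
  if (is.character(genome)) genome <- read_fasta(genome, "nt")
  if (is.character(references)) references <- read_fasta(references, "aa")
  scaffold_lengths <- stats::setNames(Biostrings::width(genome),
                                      fasta_ids(genome))
  hits <- search_genome(references, genome, config$search)
  bm <- build_models(hits, genome, references, config$chain, config$build)
  catalog <- curate_models(bm$models, references, scaffold_lengths,
                           config$curation, config$prefix)
  if (length(bm$redundant)) {
    # redundant locus duplicates stay in the accounting as dropped rows
    red <- do.call(rbind, lapply(bm$redundant_models, function(m) data.frame(
      model_id = m$id, scaffold_id = m$scaffold_id, strand = m$strand,
      g_start = min(m$exons[, 1]), g_end = max(m$exons[, 2]),
      length_nt = nchar(m$cds), n_exons = nrow(m$exons),
      best_ref = m$source_query, identity = NA_real_,
      status = NA_character_, kept = FALSE, drop_reason = "redundant",
      pair_note = "", tm_count = NA_integer_,
      assigned_name = NA_character_, stringsAsFactors = FALSE)))
    catalog <- rbind(catalog, red)
  }
  kept <- catalog[catalog$kept, , drop = FALSE]
  summary <- if (nrow(kept))
    summarize_catalog(data.frame(gene = kept$assigned_name,
                                 status = kept$status,
                                 identity = kept$identity,
                                 best_ref = kept$best_ref,
                                 stringsAsFactors = FALSE))
  else NULL
  report <- list(hits = hits, models = bm$models, redundant = bm$redundant,
                 catalog = catalog, summary = summary, config = config)
  kept_models <- bm$models[kept$model_id]
  if ((isTRUE(config$run_introns) || isTRUE(config$run_phylogeny)) &&
      length(kept_models) >= 3L) {
    # full reading-frame translation (stops as X) so splice coordinates of
    # pseudogene models still fall inside their MSA rows
    prots <- stats::setNames(
      vapply(kept_models, function(m)
        gsub("*", "X", m$protein_full, fixed = TRUE), character(1)),
      vapply(kept_models, `[[`, character(1), "id"))
    prots <- prots[nchar(prots) >= 30L]
    msa <- align_proteins(prots)
    if (isTRUE(config$run_introns)) {
      marks <- do.call(rbind, lapply(kept_models[names(prots)], function(m) {
        sp <- splice_to_aa(m)
        if (nrow(sp)) cbind(gene_id = m$id, sp) else NULL
      }))
      if (!is.null(marks) && nrow(marks)) {
        marks <- map_to_alignment(marks, msa)
        report$introns <- conservation_histogram(
          list(target = marks), min_genes = config$min_genes,
          merge_radius = config$merge_radius)
        report$intron_marks <- marks
      }
    }
    if (isTRUE(config$run_phylogeny)) {
      report$phylogeny <- bootstrap_support(msa, reps = config$bootstrap_reps,
                                            seed = config$seed)
    }
  }
  class(report) <- "RunReport"
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("rscout run:", nrow(x$hits), "hits,", length(x$models), "models,",
      sum(x$catalog$kept), "kept /", sum(!x$catalog$kept), "dropped\n")
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Write a run report to disk
#' @param report a `RunReport`.
#' @param out_dir output directory.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$catalog, file.path(out_dir, "catalog.csv"),
                   row.names = FALSE)
  write_hits_tsv(report$hits, file.path(out_dir, "hits.tsv"))
  kept_ids <- report$catalog$model_id[report$catalog$kept]
  write_gff3(report$models[kept_ids], file.path(out_dir, "models.gff3"))
  if (!is.null(report$summary))
    jsonlite::write_json(unclass(report$summary),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  log <- report$catalog[, c("model_id", "assigned_name", "kept",
                            "drop_reason", "pair_note")]
  utils::write.csv(log, file.path(out_dir, "decisions.csv"), row.names = FALSE)
  if (!is.null(report$phylogeny))
    ape::write.tree(report$phylogeny, file.path(out_dir, "tree.nwk"))
  invisible(out_dir)
}

#' Score a pipeline run against a synthetic truth set
#'
#' Matches every truth record to candidate models by scaffold and span
#' overlap and checks structure recovery (exact exon coordinates and intron
#' amino-acid positions/phases), status classification, and keep/drop
#' decisions.
#'
#' @param report a `RunReport` from [run_all()].
#' @param truth truth list from [generate_dataset()].
#' @return list with a per-gene `table` and summary `rates`.
#' @export
evaluate_against_truth <- function(report, truth) {
  cat_df <- report$catalog
  rows <- lapply(truth, function(tr) {
    cand <- cat_df[cat_df$scaffold_id == tr$scaffold_id &
                     cat_df$g_start < tr$span[2] &
                     cat_df$g_end > tr$span[1], , drop = FALSE]
    found <- nrow(cand) > 0L
    kept_any <- found && any(cand$kept)
    pick <- if (kept_any) cand[cand$kept, ][1, ] else if (found) cand[1, ] else NULL
    status <- if (!is.null(pick)) pick$status else NA_character_
    exact <- FALSE
    if (!is.null(pick) && pick$model_id %in% names(report$models)) {
      m <- report$models[[pick$model_id]]
      ex_m <- m$exons[order(m$exons[, 1]), , drop = FALSE]
      ex_t <- tr$exons[order(tr$exons[, 1]), , drop = FALSE]
      same_exons <- nrow(ex_m) == nrow(ex_t) &&
        all(ex_m == ex_t) && m$strand == tr$strand
      same_introns <- tryCatch({
        sp <- splice_to_aa(m)
        nrow(sp) == nrow(tr$introns) &&
          all(sp$aa_pos == tr$introns$aa_pos) &&
          all(sp$phase == tr$introns$phase)
      }, error = function(e) FALSE)
      exact <- same_exons && same_introns
    }
    data.frame(
      gene_id = tr$gene_id, lesion = tr$lesion, placement = tr$placement,
      expected_status = tr$expected_status, expected_kept = tr$expected_kept,
      found = found, kept = kept_any, status = status,
      drop_reason = if (!is.null(pick)) pick$drop_reason else NA_character_,
      status_match = identical(status, tr$expected_status),
      kept_match = kept_any == tr$expected_kept,
      exact_structure = exact, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  intact <- tab$lesion == "none" & tab$expected_kept
  pseudo <- tab$lesion %in% c("frameshift", "premature_stop")
  fshift <- tab$lesion == "frameshift"
  allele <- tab$placement == "short_contig_allele"
  tandem <- tab$placement == "tandem_array"
  rate <- function(x) if (any(x)) mean(x, na.rm = TRUE) else NA_real_
  rates <- list(
    intact_exact = rate(tab$exact_structure[intact]),
    frameshift_flagged = rate(tab$status[fshift] == "pseudogene"),
    pseudogene_flagged = rate(tab$status[pseudo] == "pseudogene"),
    allele_dropped = rate(!tab$kept[allele] &
                            tab$drop_reason[allele] == "allelic_variant"),
    tandem_retained = rate(tab$kept[tandem]),
    status_accuracy = rate(tab$status_match[tab$expected_kept]),
    kept_accuracy = rate(tab$kept_match))
  list(table = tab, rates = rates)
}
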