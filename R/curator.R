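# Curation rules: fragment filter, status classification (complete /
# N / C / NC / M partials / pseudogene), allelic-variant exclusion versus
# tandem-paralog retention, and reference-based naming.

DROP_REASONS <- c("none", "fragment_lt_150aa", "allelic_variant", "redundant")

#' Curation parameters
#' @param min_aa fragment threshold: deduced proteins shorter than this are
#'   discarded as probable gene fragments.
#' @param min_ref_coverage reference coverage required to call a model
#'   complete.
#' @param terminal_gap_min_aa unmatched reference residues at a terminus
#'   that mark a missing 5'/3' end.
#' @param internal_gap_min_aa unmatched internal reference block that marks
#'   a missing internal exon.
#' @param min_nt_identity global CDS nucleotide identity above which a model
#'   pair becomes an allele/paralog candidate.
#' @param small_contig_nt contigs shorter than this count as "small" for the
#'   allelic-variant rule.
#' @export
curation_params <- function(min_aa = 150L, min_ref_coverage = 0.8,
                            terminal_gap_min_aa = 20L,
                            internal_gap_min_aa = 30L,
                            min_nt_identity = 0.95,
                            small_contig_nt = 10000L) {
  list(min_aa = min_aa, min_ref_coverage = min_ref_coverage,
       terminal_gap_min_aa = terminal_gap_min_aa,
       internal_gap_min_aa = internal_gap_min_aa,
       min_nt_identity = min_nt_identity, small_contig_nt = small_contig_nt)
}

#' Discard probable gene fragments
#'
#' Models whose deduced amino-acid sequence (full translation, so pseudogene
#' models are judged on their whole reading frame, not the pre-stop prefix)
#' is shorter than `min_aa` are dropped.
#'
#' @param models list of `GeneModel`s.
#' @param min_aa length threshold in amino acids.
#' @return list with elements `kept` and `dropped`.
#' @export
filter_fragments <- function(models, min_aa = 150L) {
  n <- vapply(models, function(m) nchar(m$protein_full), integer(1))
  list(kept = models[n >= min_aa], dropped = models[n < min_aa])
}

#' @noRd
global_aln <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(), gapOpening = gap_open,
    gapExtension = gap_ext, type = "global")
}

#' @noRd
gap_runs_in_subject <- function(pa) {
  # runs of reference (subject) residues aligned to gaps in the pattern,
  # classified as leading / internal / trailing
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  gap <- p == "-" & s != "-"
  if (!any(gap)) return(data.frame(len = integer(), where = character()))
  r <- rle(gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gi <- which(r$values)
  where <- vapply(gi, function(i) {
    if (starts[i] == 1L) "leading"
    else if (ends[i] == length(gap)) "trailing"
    else "internal"
  }, character(1))
  data.frame(len = r$lengths[gi], where = where)
}

#' Classify a model's completeness status
#'
#' Pseudogene (internal stop or frame break) takes precedence; then missing
#' 5' (no start codon, or >= `terminal_gap_min_aa` unmatched reference
#' N-terminal residues), missing 3' (analogously), both (`partial_NC`),
#' missing internal material (N runs inside exons or an unmatched internal
#' reference block), else complete when reference coverage is sufficient.
#' Models failing the coverage bar without a localized missing block fall
#' back to `partial_M`.
#'
#' @param model a flagged `GeneModel` (after [translate_model()]).
#' @param reference its reference protein (aa string).
#' @param params [curation_params()].
#' @return one of `r paste(CATALOG_STATUSES, collapse=", ")`.
#' @export
classify_status <- function(model, reference, params = curation_params()) {
  f <- model$flags
  if (isTRUE(f$internal_stop) || isTRUE(f$frame_break)) return("pseudogene")
  prot <- gsub("*", "X", model$protein_full, fixed = TRUE)
  pa <- global_aln(prot, reference)
  runs <- gap_runs_in_subject(pa)
  n_missing <- !isTRUE(f$start_codon_present) ||
    any(runs$where == "leading" & runs$len >= params$terminal_gap_min_aa)
  c_missing <- !isTRUE(f$stop_codon_present) ||
    any(runs$where == "trailing" & runs$len >= params$terminal_gap_min_aa)
  if (n_missing && c_missing) return("partial_NC")
  if (n_missing) return("partial_N")
  if (c_missing) return("partial_C")
  m_missing <- isTRUE(f$has_internal_N) ||
    any(runs$where == "internal" & runs$len >= params$internal_gap_min_aa)
  if (m_missing) return("partial_M")
  coverage <- 1 - sum(runs$len) / nchar(reference)
  if (coverage >= params$min_ref_coverage) "complete" else "partial_M"
}

#' @noRd
nt_global_aln <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2,
                                                  baseOnly = FALSE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = mat, gapOpening = 8, gapExtension = 2,
    type = "global")
}

#' @noRd
indel_lengths <- function(pa) {
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  gp <- rle(p == "-"); gs <- rle(s == "-")
  c(gp$lengths[gp$values], gs$lengths[gs$values])
}

#' Resolve allelic variants versus tandem paralogs
#'
#' For every model pair with global CDS nucleotide identity at or above
#' `min_nt_identity`: if the pair differs only by substitutions and
#' frame-preserving gaps (all indel lengths divisible by 3) and exactly one
#' member lies on a small contig, the small-contig member is excluded as a
#' likely allelic variant; pairs on one scaffold are retained as tandem
#' paralogs; anything else is retained and logged.
#'
#' @param models list of `GeneModel`s.
#' @param scaffold_lengths named vector of scaffold lengths (nt).
#' @param params [curation_params()].
#' @return data.frame with columns `model_id`, `kept`, `drop_reason`,
#'   `pair_note`.
#' @export
resolve_alleles_paralogs <- function(models, scaffold_lengths,
                                     params = curation_params()) {
  n <- length(models)
  ids <- vapply(models, `[[`, character(1), "id")
  kept <- rep(TRUE, n)
  reason <- rep("none", n)
  note <- rep("", n)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (!kept[i] && !kept[j]) next
    a <- models[[i]]; b <- models[[j]]
    # cheap length prefilter: wildly different CDS cannot reach 95% identity
    if (min(nchar(a$cds), nchar(b$cds)) / max(nchar(a$cds), nchar(b$cds)) < 0.9)
      next
    pa <- nt_global_aln(a$cds, b$cds)
    ident <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
    if (ident < params$min_nt_identity) next
    il <- indel_lengths(pa)
    frame_preserving <- length(il) == 0L || all(il %% 3L == 0L)
    small_a <- scaffold_lengths[[a$scaffold_id]] < params$small_contig_nt
    small_b <- scaffold_lengths[[b$scaffold_id]] < params$small_contig_nt
    if (a$scaffold_id == b$scaffold_id) {
      note[c(i, j)] <- sprintf("tandem_paralog_of:%s", ids[c(j, i)])
    } else if (frame_preserving && xor(small_a, small_b)) {
      drop <- if (small_a) i else j
      kept[drop] <- FALSE
      reason[drop] <- "allelic_variant"
      note[drop] <- sprintf("allele_of:%s", ids[if (small_a) j else i])
    } else {
      note[c(i, j)] <- sprintf("high_identity_pair:%s", ids[c(j, i)])
    }
  }
  data.frame(model_id = ids, kept = kept, drop_reason = reason,
             pair_note = note, stringsAsFactors = FALSE)
}

#' Assign catalog names from reference numbering
#'
#' A model inherits its best reference's number when the two are reciprocal
#' best matches; remaining kept models receive the smallest unused positive
#' integers in genomic order. The completeness suffix (N/C/NC/M/P) is
#' appended for reporting.
#'
#' @param decisions data.frame with columns `model_id`, `best_ref`,
#'   `identity`, `status`, `kept`, `scaffold_id`, `g_start`.
#' @param reference_names character vector of all reference ids.
#' @param prefix name prefix (e.g. `"AgoOR"`).
#' @param identity_matrix optional models-by-references identity matrix
#'   (dimnames = model ids / reference ids); when given, reciprocity is
#'   checked against each reference's best model over all kept models rather
#'   than only models sharing that best reference.
#' @return `decisions` with an `assigned_name` column.
#' @export
assign_names <- function(decisions, reference_names, prefix = "AgoOR",
                         identity_matrix = NULL) {
  d <- decisions
  if (nrow(d) == 0L) {
    d$assigned_name <- character(0)
    return(d)
  }
  d$assigned_name <- NA_character_
  suffix <- c(complete = "", partial_N = "N", partial_C = "C",
              partial_NC = "NC", partial_M = "M", pseudogene = "P")
  kept_idx <- which(d$kept)
  # reciprocal best: per reference, its top-identity kept model
  used <- integer(0)
  ref_num <- function(r) {
    x <- suppressWarnings(as.integer(sub("^.*?(\\d+)$", "\\1", r)))
    x
  }
  for (r in unique(d$best_ref[kept_idx])) {
    if (!is.null(identity_matrix) && r %in% colnames(identity_matrix)) {
      col <- identity_matrix[d$model_id[kept_idx], r]
      top <- kept_idx[which.max(col)]
      if (d$best_ref[top] != r) next  # not reciprocal
    } else {
      cand <- kept_idx[d$best_ref[kept_idx] == r]
      top <- cand[which.max(d$identity[cand])]
    }
    num <- ref_num(r)
    if (!is.na(num) && !num %in% used) {
      d$assigned_name[top] <- paste0(prefix, num)
      used <- c(used, num)
    }
  }
  todo <- kept_idx[is.na(d$assigned_name[kept_idx])]
  todo <- todo[order(d$scaffold_id[todo], d$g_start[todo])]
  nxt <- 1L
  for (i in todo) {
    while (nxt %in% used) nxt <- nxt + 1L
    d$assigned_name[i] <- paste0(prefix, nxt)
    used <- c(used, nxt)
  }
  d$assigned_name <- ifelse(is.na(d$assigned_name), d$assigned_name,
                            paste0(d$assigned_name,
                                   unname(suffix[d$status])))
  d
}
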