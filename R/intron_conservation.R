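# Intron-position conservation: splice sites as amino-acid coordinates with
# phase, projected through a protein MSA and scaled to a common 400-aa axis,
# then merged and called conserved per species.

#' Splice sites of a model in amino-acid coordinates
#'
#' An intron falling after `c` coding nucleotides sits at
#' `aa_pos = floor(c/3) + 1` with `phase = c mod 3` (the exact inverse of
#' the implant convention used by [implant_gene()]). Single-exon models
#' return an empty table. N-placeholder exons bridging assembly gaps count
#' as coding sequence but contribute no junction of their own (the flanking
#' junctions are not genuine splice sites either, and are skipped).
#'
#' @param model a `GeneModel` or any list with an `exons` matrix (and
#'   optionally `junctions` from [refine_splice_sites()]).
#' @return data.frame with columns `aa_pos`, `phase`.
#' @export
splice_to_aa <- function(model) {
  ex <- model$exons
  if (is.null(ex) || nrow(ex) == 0L) stop("model has no exons")
  lens <- ex[, 2] - ex[, 1]
  total <- sum(lens)
  if (nrow(ex) == 1L) return(data.frame(aa_pos = integer(), phase = integer()))
  cuts <- cumsum(lens)[-nrow(ex)]
  if (any(cuts == 0L | cuts == total)) stop("intron outside CDS")
  # drop junctions flanking N-placeholder exons: not genuine splice sites
  genuine <- rep(TRUE, length(cuts))
  if (!is.null(model$cds)) {
    pieces <- diff(c(0L, cumsum(lens)))
    is_n <- vapply(seq_len(nrow(ex)), function(i) {
      piece <- substr(model$cds, cumsum(lens)[i] - lens[i] + 1L, cumsum(lens)[i])
      nchar(piece) > 0L && longest_n_run(piece) == nchar(piece)
    }, logical(1))
    for (i in which(is_n)) {
      if (i > 1L) genuine[i - 1L] <- FALSE
      if (i <= length(genuine)) genuine[i] <- FALSE
    }
  }
  cuts <- cuts[genuine]
  data.frame(aa_pos = as.integer(cuts %/% 3L + 1L),
             phase = as.integer(cuts %% 3L))
}

#' Project intron marks onto MSA columns and the 400-aa scale
#'
#' @param marks data.frame with columns `gene_id`, `aa_pos`, `phase`.
#' @param msa named character vector (or AAStringSet) of aligned rows; each
#'   gene's ungapped row must equal its protein.
#' @param proteins optional named proteins to validate rows against.
#' @return `marks` with `msa_column` and `scaled_pos` (half-up rounding of
#'   `msa_column / alignment_length * 400`, clamped to \[1, 400\]).
#' @export
map_to_alignment <- function(marks, msa, proteins = NULL) {
  nm <- names(msa)
  rows <- as.character(msa)
  names(rows) <- sub("\\s.*$", "", nm)
  alen <- unique(nchar(rows))
  if (length(alen) != 1L) stop("MSA rows differ in length")
  if (!is.null(proteins)) {
    pn <- names(proteins)
    pr <- as.character(proteins)
    names(pr) <- sub("\\s.*$", "", pn)
    for (g in intersect(names(rows), names(pr))) {
      if (gsub("-", "", rows[[g]], fixed = TRUE) != pr[[g]])
        stop("MSA row does not match protein for gene: ", g)
    }
  }
  marks$msa_column <- NA_integer_
  marks$scaled_pos <- NA_integer_
  for (i in seq_len(nrow(marks))) {
    g <- marks$gene_id[i]
    if (!g %in% names(rows)) stop("gene missing from MSA: ", g)
    rc <- strsplit(rows[[g]], "", fixed = TRUE)[[1]]
    notgap <- cumsum(rc != "-")
    col <- which(notgap == marks$aa_pos[i] & rc != "-")[1]
    if (is.na(col)) stop("aa position ", marks$aa_pos[i],
                         " beyond ungapped length of gene ", g)
    marks$msa_column[i] <- col
    marks$scaled_pos[i] <- min(400L, max(1L, round_half_up(col / alen * 400)))
  }
  marks
}

#' Merge scaled intron positions and call conserved sites
#'
#' Positions within `merge_radius` of each other are merged onto the
#' position carrying the largest pooled gene count (the parsimony reading:
#' nearby marks are treated as one ancestral intron). A merged position is
#' conserved within a species when at least `min_genes` of its genes have an
#' intron there, and conserved across species when conserved in every
#' species set.
#'
#' @param marks_by_species named list of mark tables (with `gene_id`,
#'   `scaled_pos`), one per species.
#' @param min_genes per-species gene count needed to call conservation.
#' @param merge_radius positions at most this far apart are merged (set 0 to
#'   disable merging).
#' @return list of class `ConservationReport`: `histograms` (per species,
#'   unmerged), `merged` (position/species count table), `conserved`
#'   (positions conserved in every species), `params`.
#' @export
conservation_histogram <- function(marks_by_species, min_genes = 8L,
                                   merge_radius = 1L) {
  if (!length(marks_by_species)) stop("at least one species set required")
  species <- names(marks_by_species)
  if (is.null(species)) species <- paste0("sp", seq_along(marks_by_species))
  # one count per (gene, position)
  counts <- lapply(marks_by_species, function(m) {
    u <- unique(m[, c("gene_id", "scaled_pos")])
    table(factor(u$scaled_pos, levels = 1:400))
  })
  pooled <- Reduce(`+`, counts)
  pos <- which(pooled > 0)
  merged_to <- stats::setNames(pos, pos)
  if (merge_radius > 0L && length(pos) > 1L) {
    remaining <- pos
    while (length(remaining)) {
      centre <- remaining[which.max(pooled[remaining])]
      close <- remaining[abs(remaining - centre) <= merge_radius]
      merged_to[as.character(close)] <- centre
      remaining <- setdiff(remaining, close)
    }
  }
  merged_tab <- do.call(rbind, lapply(sort(unique(merged_to)), function(ctr) {
    members <- as.integer(names(merged_to)[merged_to == ctr])
    row <- vapply(species, function(sp) sum(counts[[sp]][members]), numeric(1))
    data.frame(scaled_pos = ctr, t(row),
               total = sum(row), check.names = FALSE)
  }))
  conserved_each <- lapply(species, function(sp)
    merged_tab$scaled_pos[merged_tab[[sp]] >= min_genes])
  names(conserved_each) <- species
  conserved <- Reduce(intersect, conserved_each)
  structure(list(histograms = counts, merged = merged_tab,
                 conserved_by_species = conserved_each,
                 conserved = conserved,
                 params = list(min_genes = min_genes,
                               merge_radius = merge_radius)),
            class = "ConservationReport")
}

#' @export
print.ConservationReport <- function(x, ...) {
  cat("Intron conservation across", length(x$histograms), "species set(s)\n")
  cat("  marks:", sum(vapply(x$histograms, sum, numeric(1))),
      " merged positions:", nrow(x$merged), "\n")
  cat("  conserved positions:",
      if (length(x$conserved)) paste(x$conserved, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Plot intron-position histograms on the common 400-aa axis
#'
#' Base-graphics bar plot, one panel per species, mirroring the standard
#' intron-conservation figure (x: scaled position 1-400, y: gene count).
#' @param x a `ConservationReport`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ConservationReport <- function(x, ...) {
  sp <- names(x$histograms)
  op <- graphics::par(mfrow = c(length(sp), 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in sp) {
    graphics::barplot(as.numeric(x$histograms[[s]]), names.arg = NULL,
                      main = s, xlab = "scaled aa position (1-400)",
                      ylab = "genes with intron", border = NA, ...)
  }
  invisible(x)
}
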