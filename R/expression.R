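# Relative expression from qPCR Ct tables by the 2^-ddCt method with
# reference-gene normalization.

#' Read a long-format Ct table
#'
#' Expects CSV columns `gene`, `sample`, `rep`, `ct`.
#' @param path CSV path.
#' @export
read_ct_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ct_table(x)
  x
}

#' @noRd
validate_ct_table <- function(x) {
  need <- c("gene", "sample", "rep", "ct")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(x$ct)) || any(x$ct <= 0)) stop("Ct values must be positive")
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged on the Ct scale; then
#' `dCt(g,s) = mean Ct(g,s) - mean Ct(ref,s)`,
#' `ddCt(g,s) = dCt(g,s) - dCt(g, calibrator)` and `fold = 2^-ddCt`.
#' No efficiency correction is applied. Genes without a calibrator
#' measurement are flagged and left uncomputed.
#'
#' @param table long-format Ct data.frame (`gene`, `sample`, `rep`, `ct`).
#' @param reference_gene normalizer gene (must be measured in every sample).
#' @param calibrator_sample sample whose fold is 1 by construction.
#' @return data.frame of class `ExpressionProfile`: per (gene, sample) rows
#'   with `mean_ct`, `sd_ct`, `delta_ct`, `delta_delta_ct`, `fold`,
#'   `flagged`.
#' @export
delta_delta_ct <- function(table, reference_gene, calibrator_sample) {
  validate_ct_table(table)
  samples <- unique(table$sample)
  if (!calibrator_sample %in% samples)
    stop("calibrator sample not present: ", calibrator_sample)
  agg <- stats::aggregate(ct ~ gene + sample, table, mean)
  names(agg)[3] <- "mean_ct"
  sdv <- stats::aggregate(ct ~ gene + sample, table, stats::sd)
  agg$sd_ct <- sdv$ct[match(paste(agg$gene, agg$sample),
                            paste(sdv$gene, sdv$sample))]
  ref <- agg[agg$gene == reference_gene, ]
  missing_ref <- setdiff(samples, ref$sample)
  if (length(missing_ref))
    stop("reference gene '", reference_gene, "' missing in sample: ",
         missing_ref[1])
  agg$delta_ct <- agg$mean_ct - ref$mean_ct[match(agg$sample, ref$sample)]
  cal <- agg[agg$sample == calibrator_sample, ]
  cal_dct <- cal$delta_ct[match(agg$gene, cal$gene)]
  agg$flagged <- is.na(cal_dct)
  agg$delta_delta_ct <- agg$delta_ct - cal_dct
  agg$fold <- 2^(-agg$delta_delta_ct)
  attr(agg, "reference_gene") <- reference_gene
  attr(agg, "calibrator_sample") <- calibrator_sample
  class(agg) <- c("ExpressionProfile", "data.frame")
  agg
}

#' Flag genes enriched in a target sample
#'
#' A gene is enriched iff its fold change in the target sample is at least
#' `min_fold` times its fold in every other sample (ties fail).
#'
#' @param profile an `ExpressionProfile`.
#' @param target_sample sample to test for enrichment (e.g. `"head"`).
#' @param min_fold dominance factor.
#' @return named logical vector (per gene; NA when the target or another
#'   sample is uncomputed).
#' @export
enrichment_flag <- function(profile, target_sample, min_fold = 2) {
  genes <- setdiff(unique(profile$gene), attr(profile, "reference_gene"))
  out <- stats::setNames(rep(NA, length(genes)), genes)
  for (g in genes) {
    rows <- profile[profile$gene == g & !profile$flagged, ]
    tf <- rows$fold[rows$sample == target_sample]
    of <- rows$fold[rows$sample != target_sample]
    if (!length(tf) || any(is.na(c(tf, of)))) next
    out[g] <- all(tf >= min_fold * of)
  }
  out
}

#' Simulate a long-format Ct table
#'
#' Generates technical-replicate Ct measurements for a gene panel across
#' samples, with a subset of genes shifted to lower Ct (higher expression)
#' in one target sample. The reference gene is constant across samples.
#'
#' @param n_genes number of target genes.
#' @param samples sample names (first is the enriched target by default).
#' @param enriched_genes indices (or names) of genes enriched in
#'   `target_sample`.
#' @param target_sample the enriched sample.
#' @param shift Ct decrease in the target sample for enriched genes (cycles).
#' @param n_rep technical replicates.
#' @param noise_sd replicate noise (cycles).
#' @param reference_gene reference gene name.
#' @param seed RNG seed.
#' @export
simulate_ct_table <- function(n_genes = 38, samples = c("head", "leg", "body"),
                              enriched_genes = seq_len(30),
                              target_sample = "head", shift = 4,
                              n_rep = 3, noise_sd = 0.05,
                              reference_gene = "GAPDH", seed = 1) {
  with_seed(seed, {
    genes <- sprintf("gene%02d", seq_len(n_genes))
    enr <- if (is.character(enriched_genes)) enriched_genes
           else genes[enriched_genes]
    base <- stats::setNames(stats::runif(n_genes, 24, 30), genes)
    rows <- list()
    for (g in genes) for (s in samples) {
      mu <- base[[g]] - if (g %in% enr && s == target_sample) shift else 0
      for (r in seq_len(n_rep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, sample = s, rep = r,
          ct = stats::rnorm(1, mu, noise_sd))
      }
    }
    for (s in samples) for (r in seq_len(n_rep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = reference_gene, sample = s, rep = r,
        ct = stats::rnorm(1, 20, noise_sd))
    }
    out <- do.call(rbind, rows)
    attr(out, "enriched") <- enr
    out
  })
}

#' Bar plot of an expression profile
#'
#' One bar group per gene (folds per sample), mirroring the standard
#' tissue-profile figure.
#' @param x an `ExpressionProfile`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ExpressionProfile <- function(x, ...) {
  ref <- attr(x, "reference_gene")
  d <- x[x$gene != ref & !x$flagged, ]
  m <- tapply(d$fold, list(d$sample, d$gene), mean)
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = "relative expression (2^-ddCt)",
                    las = 2, ...)
  invisible(x)
}
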