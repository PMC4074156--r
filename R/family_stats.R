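# Pairwise identity, best-reference assignment, and the catalog summary
# statistics reported for a curated receptor family.

#' Global pairwise amino-acid identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 10 / extend 0.5);
#' identity is the fraction of alignment columns (gaps included) holding
#' identical residues. The denominator is configurable: `"all"` counts every
#' alignment column, `"aligned"` only gap-free columns, `"shorter"` divides
#' by the shorter sequence length.
#'
#' @param a,b amino-acid strings.
#' @param denom identity denominator convention.
#' @return fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, denom = c("all", "aligned", "shorter")) {
  denom <- match.arg(denom)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  pa <- global_aln(a, b)
  nid <- Biostrings::nmatch(pa)
  den <- switch(denom,
    all = Biostrings::nchar(pa),
    aligned = {
      p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
      s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
      sum(p != "-" & s != "-")
    },
    shorter = min(nchar(a), nchar(b)))
  nid / den
}

#' Best reference of a protein
#'
#' @param protein amino-acid string.
#' @param references [Biostrings::AAStringSet] (or named character vector).
#' @return list with `ref_id` and `identity`; ties break to the
#'   lexicographically first reference id.
#' @export
best_reference <- function(protein, references) {
  nm <- names(references)  # before coercion: as.character() drops names
  refs <- as.character(references)
  if (!length(refs)) stop("empty reference set")
  ids <- if (!is.null(nm)) sub("\\s.*$", "", nm)
         else paste0("ref", seq_along(refs))
  idv <- vapply(refs, function(r) pairwise_identity(protein, r), numeric(1))
  o <- order(-idv, ids)
  list(ref_id = ids[o[1]], identity = unname(idv[o[1]]))
}

#' Identity matrix of proteins against references
#' @param proteins,references AAStringSets or named character vectors.
#' @return numeric matrix, rows = proteins, columns = references.
#' @export
identity_matrix <- function(proteins, references) {
  pn <- names(proteins); rn <- names(references)
  p <- as.character(proteins); r <- as.character(references)
  out <- matrix(NA_real_, length(p), length(r),
                dimnames = list(if (!is.null(pn)) sub("\\s.*$", "", pn),
                                if (!is.null(rn)) sub("\\s.*$", "", rn)))
  for (i in seq_along(p)) for (j in seq_along(r))
    out[i, j] <- pairwise_identity(p[i], r[j])
  out
}

#' Summarize a receptor catalog
#'
#' Computes the family-level statistics reported for a curated catalog:
#' total count, counts per status, mean identity over all rows and over
#' complete rows, counts above identity thresholds (strict inequality), and
#' the top-identity row.
#'
#' @param records data.frame with columns `gene`, `status`, `identity`,
#'   `best_ref` (a loaded table fixture or a pipeline catalog).
#' @param thresholds identity thresholds for strict `>` counting.
#' @return list of class `CatalogSummary`.
#' @export
summarize_catalog <- function(records, thresholds = 0.5) {
  if (!nrow(records)) stop("empty catalog")
  validate_catalog_like(records)
  n_by_status <- vapply(CATALOG_STATUSES,
                        function(s) sum(records$status == s), integer(1))
  top <- which.max(records$identity)
  out <- list(
    n_total = nrow(records),
    n_by_status = n_by_status,
    mean_identity_all = mean(records$identity),
    mean_identity_complete = if (any(records$status == "complete"))
      mean(records$identity[records$status == "complete"]) else NA_real_,
    n_identity_gt = vapply(thresholds,
                           function(t) sum(records$identity > t), integer(1)),
    max_identity = list(gene = records$gene[top],
                        ref = records$best_ref[top],
                        identity = records$identity[top]))
  names(out$n_identity_gt) <- as.character(thresholds)
  structure(out, class = "CatalogSummary")
}

#' @noRd
validate_catalog_like <- function(records) {
  need <- c("gene", "status", "identity", "best_ref")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("catalog lacks column(s): ", paste(miss, collapse = ", "))
  if (any(records$identity < 0 | records$identity > 1))
    stop("identity outside [0,1]")
  invisible(records)
}

#' @export
print.CatalogSummary <- function(x, ...) {
  cat("Catalog of", x$n_total, "genes\n")
  cat("  by status:",
      paste(sprintf("%s=%d", names(x$n_by_status), x$n_by_status),
            collapse = " "), "\n")
  cat(sprintf("  mean identity: %.4f (complete rows: %.4f)\n",
              x$mean_identity_all, x$mean_identity_complete))
  for (t in names(x$n_identity_gt))
    cat(sprintf("  identity > %s: %d genes\n", t, x$n_identity_gt[[t]]))
  cat(sprintf("  top: %s vs %s at %.3f\n", x$max_identity$gene,
              x$max_identity$ref, x$max_identity$identity))
  invisible(x)
}
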