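# Readers and writers for the standard formats the pipeline touches, plus
# the bundled receptor-catalog table fixtures.

LEGAL_NT <- c("A", "C", "G", "T", "N", "-")  # N is the nucleotide wildcard
LEGAL_AA <- c(AA20, "N", "X", "-", "*")

CATALOG_STATUSES <- c("complete", "partial_N", "partial_C", "partial_NC",
                      "partial_M", "pseudogene")

#' Read a FASTA file with alphabet validation
#'
#' Wraps [Biostrings::readBStringSet()] and validates that record ids are
#' unique and every residue belongs to the declared alphabet (plus the
#' ambiguity letters `N`, `X` and the gap `-`; `*` is additionally legal for
#' amino acids so translated pseudogene proteins round-trip).
#'
#' @param path path to a FASTA file.
#' @param alphabet `"nt"` or `"aa"`.
#' @return A [Biostrings::DNAStringSet] (`nt`) or [Biostrings::AAStringSet]
#'   (`aa`). Names hold the full header line; use [fasta_ids()] for the
#'   id token alone.
#' @export
read_fasta <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id: ", dup[1])
  w <- Biostrings::width(x)
  if (any(w == 0L)) stop("empty sequence: ", ids[w == 0L][1])
  legal <- if (alphabet == "nt") LEGAL_NT else LEGAL_AA
  up <- toupper(as.character(x))
  used <- Biostrings::uniqueLetters(Biostrings::BStringSet(up))
  bad <- setdiff(used, legal)
  if (length(bad)) {
    pos <- regexpr(bad[1], up, fixed = TRUE)
    i <- which(pos > 0)[1]
    stop("illegal ", alphabet, " residue '", bad[1], "' in record '", ids[i],
         "' at position ", pos[i])
  }
  x <- Biostrings::BStringSet(stats::setNames(up, names(x)))
  out <- if (alphabet == "nt") Biostrings::DNAStringSet(x)
         else Biostrings::AAStringSet(x)
  out
}

#' @rdname read_fasta
#' @param x a string set (or named character vector) to write.
#' @param width line-wrap width.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Id tokens (first whitespace-delimited word) of a FASTA set
#' @param x a string set returned by [read_fasta()].
#' @export
fasta_ids <- function(x) sub("\\s.*$", "", names(x))

# ---- GFF3 -------------------------------------------------------------------

#' Write gene models as GFF3
#'
#' Emits a `gene -> mRNA -> exon/CDS` hierarchy, 1-based inclusive
#' coordinates (models store 0-based half-open internally), with CDS phase
#' computed from cumulative coding length along the coding strand.
#'
#' @param models list of [GeneModel] objects (see [refine_splice_sites()]).
#' @param path output path.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    if (!inherits(m, "GeneModel")) stop("write_gff3 expects GeneModel objects")
    ex <- m$exons
    if (is.null(ex) || nrow(ex) == 0L || any(!is.finite(ex)))
      stop("model '", m$id, "' has unresolved coordinates")
    g1 <- min(ex[, 1]) + 1L
    g2 <- max(ex[, 2])
    gid <- m$id
    attr_g <- sprintf("ID=gene:%s;Name=%s", gid, gid)
    attr_m <- sprintf("ID=mRNA:%s;Parent=gene:%s", gid, gid)
    lines <- c(lines,
      paste(m$scaffold_id, "rscout", "gene", g1, g2, ".", m$strand, ".", attr_g,
            sep = "\t"),
      paste(m$scaffold_id, "rscout", "mRNA", g1, g2, ".", m$strand, ".", attr_m,
            sep = "\t"))
    # exon rows in coding order carry cumulative phase for the matching CDS
    cum <- c(0L, cumsum(ex[, 2] - ex[, 1]))
    phase <- (3L - cum[seq_len(nrow(ex))] %% 3L) %% 3L
    ord <- order(ex[, 1])
    for (k in seq_len(nrow(ex))) {
      i <- ord[k]
      lines <- c(lines,
        paste(m$scaffold_id, "rscout", "exon", ex[i, 1] + 1L, ex[i, 2], ".",
              m$strand, ".", sprintf("ID=exon:%s.%d;Parent=mRNA:%s", gid, i, gid),
              sep = "\t"),
        paste(m$scaffold_id, "rscout", "CDS", ex[i, 1] + 1L, ex[i, 2], ".",
              m$strand, phase[i], sprintf("ID=cds:%s;Parent=mRNA:%s", gid, gid),
              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file into a feature table
#'
#' Thin wrapper over [rtracklayer::import()]; returns a data.frame with
#' 1-based inclusive coordinates and resolved `ID`/`Parent` attributes.
#'
#' @param path path to a GFF3 file.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  parent <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(df))
  out <- data.frame(
    seq_id = as.character(df$seqnames),
    source = if ("source" %in% names(df)) as.character(df$source) else "rscout",
    feature_type = as.character(df$type),
    start = df$start,
    end = df$end,
    strand = as.character(df$strand),
    phase = if ("phase" %in% names(df)) as.integer(df$phase) else NA_integer_,
    id = if ("ID" %in% names(df)) as.character(df$ID) else NA_character_,
    parent = parent,
    stringsAsFactors = FALSE
  )
  out
}

# ---- paper-table fixtures ---------------------------------------------------

#' Load a bundled receptor-catalog table fixture
#'
#' The package bundles the published cotton-aphid OR (45 rows) and IR
#' (13 rows) catalog summaries as transcribed CSVs. Columns: `gene`,
#' `length_nt`, `status`, `best_ref`, `identity` (fraction), `tm_count`.
#'
#' @param name `"OR"` or `"IR"`.
#' @return data.frame with one row per curated gene.
#' @export
load_table_fixture <- function(name = c("OR", "IR")) {
  name <- match.arg(name)
  f <- system.file("extdata",
                   if (name == "OR") "table1_or.csv" else "table2_ir.csv",
                   package = "rscout", mustWork = TRUE)
  x <- utils::read.csv(f, stringsAsFactors = FALSE)
  validate_catalog_table(x, expected_rows = if (name == "OR") 45L else 13L)
  x
}

#' @noRd
validate_catalog_table <- function(x, expected_rows = NULL) {
  need <- c("gene", "length_nt", "status", "best_ref", "identity", "tm_count")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("catalog table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(expected_rows) && nrow(x) != expected_rows)
    stop("fixture has ", nrow(x), " rows, expected ", expected_rows)
  if (any(!x$status %in% CATALOG_STATUSES))
    stop("unknown status value: ",
         paste(setdiff(x$status, CATALOG_STATUSES), collapse = ", "))
  if (any(x$identity < 0 | x$identity > 1)) stop("identity outside [0,1]")
  if (any(x$tm_count < 0)) stop("negative tm_count")
  invisible(x)
}
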