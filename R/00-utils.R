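# Internal helpers shared across modules.

.rscout_cache <- new.env(parent = emptyenv())

#' @noRd
blosum62 <- function() {
  if (is.null(.rscout_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .rscout_cache$blosum62 <- e$BLOSUM62
  }
  .rscout_cache$blosum62
}

# 20 canonical amino acids, in the classical PAM/JTT ordering used by jtt_q().
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

NT4 <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Evaluate code with a temporary RNG seed, restoring global RNG state after.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a CDS string to amino acids.
#'
#' Trailing nucleotides beyond a codon multiple are dropped; codons
#' containing N (or any non-ACGT letter) translate to X; stops render '*'.
#' Vectorized codon-table lookup (much faster than repeated fuzzy-codon
#' dispatch for scaffold-scale input).
#' @noRd
translate_cds <- function(cds) {
  n <- nchar(cds)
  n3 <- n - n %% 3L
  if (n3 == 0L) return("")
  gc <- .rscout_cache$genetic_code
  if (is.null(gc)) {
    gc <- Biostrings::GENETIC_CODE
    .rscout_cache$genetic_code <- gc
  }
  codons <- substring(cds, seq.int(1L, n3 - 2L, 3L), seq.int(3L, n3, 3L))
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Integer codes of an amino-acid string against the BLOSUM62 row order.
#' Unknown letters are mapped to 'X'.
#' @noRd
aa_codes <- function(s) {
  m <- blosum62()
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], rownames(m))
  idx[is.na(idx)] <- match("X", rownames(m))
  idx
}

#' Ungapped BLOSUM62 score of two equal-length amino-acid strings.
#' @noRd
ungapped_score <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0)
  m <- blosum62()
  sum(m[cbind(aa_codes(a), aa_codes(b))])
}

#' Codon table helpers (standard genetic code).
#' @noRd
codons_by_aa <- function() {
  if (is.null(.rscout_cache$codons_by_aa)) {
    gc <- Biostrings::GENETIC_CODE
    .rscout_cache$codons_by_aa <- split(names(gc), unname(gc))
  }
  .rscout_cache$codons_by_aa
}

#' Reverse-translate a protein with uniform synonymous codon choice.
#' Draws from the active RNG; callers wrap in with_seed().
#' @noRd
reverse_translate <- function(protein) {
  tab <- codons_by_aa()
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(aa), names(tab))
  if (length(bad)) stop("cannot reverse-translate residue(s): ",
                        paste(bad, collapse = ", "))
  paste(vapply(aa, function(a) {
    cs <- tab[[a]]
    if (length(cs) == 1L) cs else sample(cs, 1L)
  }, character(1)), collapse = "")
}

#' Random nucleotide string (uses active RNG).
#' @noRd
random_nt <- function(n) paste(sample(NT4, n, replace = TRUE), collapse = "")

#' Random amino-acid string over the 20-letter alphabet (uses active RNG).
#' @noRd
random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

#' Half-up rounding (R's round() is round-half-even).
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' Longest run of the letter N in a string; 0 when absent.
#' @noRd
longest_n_run <- function(s) {
  r <- gregexpr("N+", s)[[1]]
  if (r[1] == -1L) return(0L)
  max(attr(r, "match.length"))
}
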