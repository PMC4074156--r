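# Protein-level feature checks: hydropathy-based transmembrane-segment
# counting (desk-scale stand-in for an HMM topology predictor) and
# alignment transfer of the IR ligand-binding-domain layout (S1/S2 lobes,
# pore) with key-residue checks.

# Kyte-Doolittle hydropathy scale
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Count transmembrane segments by sliding-window hydropathy
#'
#' Kyte-Doolittle mean hydropathy over a sliding window; positions whose
#' centered window mean reaches `threshold` form candidate segments, and
#' segments separated by at most `merge_gap` residues are merged. Unknown
#' residues (X, N, gaps) score 0.
#'
#' @param protein amino-acid string.
#' @param window window length (aa, odd).
#' @param threshold mean-hydropathy cutoff for a transmembrane window.
#' @param merge_gap segments at most this far apart are merged.
#' @return list of class `TopologyResult`: `protein_id`, `tm_count`,
#'   `segments` (matrix of 1-based inclusive aa intervals), `too_short`.
#' @param protein_id id recorded in the result.
#' @export
count_tm_segments <- function(protein, window = 19L, threshold = 1.6,
                              merge_gap = 5L, protein_id = "protein") {
  L <- nchar(protein)
  if (L < window) {
    warning("protein shorter than hydropathy window; no segments called")
    return(structure(list(protein_id = protein_id, tm_count = 0L,
                          segments = cbind(start = integer(), end = integer()),
                          too_short = TRUE), class = "TopologyResult"))
  }
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  h <- unname(KYTE_DOOLITTLE[aa])
  h[is.na(h)] <- 0
  cs <- cumsum(c(0, h))
  means <- (cs[(window + 1L):(L + 1L)] - cs[1:(L - window + 1L)]) / window
  half <- (window - 1L) %/% 2L
  centers <- (1:(L - window + 1L)) + half
  hot <- centers[means >= threshold]
  segs <- cbind(start = integer(), end = integer())
  if (length(hot)) {
    brk <- c(0L, which(diff(hot) > 1L), length(hot))
    segs <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i)
      cbind(start = hot[brk[i] + 1L], end = hot[brk[i + 1L]])))
    # merge segments separated by short dips
    if (nrow(segs) > 1L) {
      keep <- list(segs[1, ])
      for (i in 2:nrow(segs)) {
        last <- keep[[length(keep)]]
        if (segs[i, 1] - last[2] - 1L <= merge_gap)
          keep[[length(keep)]] <- c(last[1], segs[i, 2])
        else keep[[length(keep) + 1L]] <- segs[i, ]
      }
      segs <- do.call(rbind, keep)
      colnames(segs) <- c("start", "end")
    }
  }
  structure(list(protein_id = protein_id, tm_count = nrow(segs),
                 segments = segs, too_short = FALSE),
            class = "TopologyResult")
}

#' Bundled synthetic annotated IR reference
#'
#' A deterministic synthetic stand-in for an annotated ionotropic-receptor
#' (iGluR-like) reference: a 500-aa protein with S1/S2 ligand-binding lobe
#' and pore (P) intervals and the three key ligand-binding residue
#' positions (S1 arginine, S2 threonine, S2-end aspartate). Synthetic
#' coordinates, not measured ones: they exercise the annotation-transfer
#' machinery.
#'
#' @return list with `seq`, `domains` (list S1/S2/P of c(start, end)),
#'   `key_residues` (list R_s1/T_s2/DE_s2 of aa positions).
#' @export
make_ir_reference <- function() {
  seq <- with_seed(20140627, {
    aa <- sample(AA20, 500, replace = TRUE)
    aa[1] <- "M"
    aa[100] <- "R"   # S1 arginine contacting the glutamate alpha-carboxyl
    aa[290] <- "T"   # S2 threonine contacting the gamma-carboxyl
    aa[395] <- "D"   # S2-end aspartate contacting the alpha-amino group
    paste(aa, collapse = "")
  })
  list(seq = seq,
       domains = list(S1 = c(60L, 180L), S2 = c(260L, 400L), P = c(420L, 470L)),
       key_residues = list(R_s1 = 100L, T_s2 = 290L, DE_s2 = 395L))
}

#' Transfer IR domain annotations onto a candidate protein
#'
#' Globally aligns the candidate to an annotated reference and transfers
#' each domain as the candidate interval spanning the reference domain's
#' aligned columns; a domain is absent when more than half its reference
#' columns align to gaps in the candidate.
#'
#' @param protein candidate amino-acid string.
#' @param reference annotated reference, as from [make_ir_reference()].
#' @param protein_id id recorded in the result.
#' @return list of class `IRDomainAnnotation`: `protein_id`, `domains`
#'   (list of c(start, end) or NULL when absent), `key_residues` (logical
#'   flags with a `gap` attribute), `alignment`.
#' @export
annotate_ir_domains <- function(protein, reference, protein_id = "protein") {
  if (is.null(reference$domains) || is.null(reference$key_residues))
    stop("reference lacks domain/key-residue annotations")
  pa <- global_aln(protein, reference$seq)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ref2col <- which(s != "-")          # reference position -> column
  cand_at <- cumsum(p != "-")         # column -> candidate position (last)
  domains <- lapply(reference$domains, function(iv) {
    cols <- ref2col[iv[1]:iv[2]]
    gap_frac <- mean(p[cols] == "-")
    if (gap_frac > 0.5) return(NULL)
    nz <- cols[p[cols] != "-"]
    c(start = cand_at[nz[1]], end = cand_at[nz[length(nz)]])
  })
  keys <- check_key_residues_at(p, s, ref2col, cand_at, reference$key_residues)
  structure(list(protein_id = protein_id, domains = domains,
                 key_residues = keys, alignment = pa),
            class = "IRDomainAnnotation")
}

#' @noRd
check_key_residues_at <- function(p, s, ref2col, cand_at, key_positions) {
  res <- list()
  want <- list(R_s1 = "R", T_s2 = "T", DE_s2 = c("D", "E"))
  for (k in names(want)) {
    col <- ref2col[key_positions[[k]]]
    ch <- p[col]
    val <- ch %in% want[[k]]
    attr(val, "gap") <- ch == "-"
    res[[k]] <- val
  }
  res
}

#' Key ligand-binding residue flags of an annotated candidate
#'
#' Reads the columns aligned to the reference's S1 arginine, S2 threonine
#' and S2-end aspartate/glutamate: each flag is TRUE iff the candidate
#' holds the expected residue there (FALSE with a `gap` attribute when the
#' column is deleted).
#'
#' @param annotation an `IRDomainAnnotation`.
#' @return named list of logical flags `R_s1`, `T_s2`, `DE_s2`.
#' @export
check_key_residues <- function(annotation) {
  annotation$key_residues
}

#' @export
print.TopologyResult <- function(x, ...) {
  cat("Topology of", x$protein_id, ":", x$tm_count, "TM segment(s)\n")
  invisible(x)
}

#' @export
print.IRDomainAnnotation <- function(x, ...) {
  present <- names(Filter(Negate(is.null), x$domains))
  keys <- vapply(x$key_residues, isTRUE, logical(1))
  cat("IR domains of", x$protein_id, ":",
      if (length(present)) paste(present, collapse = " ") else "none", "\n")
  cat("  key residues:",
      paste(sprintf("%s=%s", names(keys), keys), collapse = " "), "\n")
  invisible(x)
}
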