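# Six-frame translated homology search: the in-repo stand-in for a
# tblastn-style scan. Exact-word seeding on 3-mers (two-hit rule per
# diagonal) followed by ungapped X-drop extension under BLOSUM62. Each hit is
# a candidate exon: extensions never cross a stop codon in the translated
# frame, and intron spanning is left to the exon chainer.

#' Translated-search parameters
#'
#' Conventional translated-search defaults, pinned for reproducibility:
#' BLOSUM62, 3-residue words, X-drop 20. `score_min` is a raw-score
#' reporting threshold (no E-value statistics at desk scale).
#'
#' @param word_size seed word length (fixed at 3).
#' @param seed_score_min minimum BLOSUM62 self-score of a seed word.
#' @param x_drop ungapped extension termination threshold.
#' @param score_min minimum reported hit score.
#' @param two_hit_window maximum same-diagonal distance between two seed
#'   words required to trigger an extension.
#' @export
search_params <- function(word_size = 3L, seed_score_min = 11, x_drop = 20,
                          score_min = 50, two_hit_window = 40L) {
  if (word_size != 3L) stop("word_size is fixed at 3")
  list(word_size = word_size, seed_score_min = seed_score_min,
       x_drop = x_drop, score_min = score_min,
       two_hit_window = two_hit_window)
}

#' Six-frame translation with coordinate maps
#'
#' @param scaffold nucleotide string (N allowed; translates to X).
#' @return list of 6 frames, each `list(strand, frame, peptide)` with
#'   `frame` in 0..2. Peptide position `i` of a frame maps to the
#'   forward-strand codon interval given by [codon_interval()].
#' @export
six_frame_translate <- function(scaffold) {
  if (grepl("[^ACGTNX]", scaffold)) stop("scaffold must be nucleotide (ACGTN)")
  L <- nchar(scaffold)
  rc <- revcomp(scaffold)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") scaffold else rc
    for (f in 0:2) {
      pep <- if (L - f >= 3L) translate_cds(substr(s, f + 1L, L)) else ""
      out[[length(out) + 1L]] <- list(strand = strand, frame = f, peptide = pep)
    }
  }
  out
}

#' Forward-strand codon interval of a framed peptide position
#'
#' @param L scaffold length.
#' @param strand `"+"` or `"-"`.
#' @param frame 0..2 (offset within the strand read).
#' @param i peptide position (1-based); vectorized.
#' @return matrix with 0-based half-open columns `start`, `end`.
#' @export
codon_interval <- function(L, strand, frame, i) {
  if (strand == "+") cbind(start = frame + 3L * (i - 1L), end = frame + 3L * i)
  else cbind(start = L - frame - 3L * i, end = L - frame - 3L * (i - 1L))
}

#' Precomputed per-scaffold frame data (peptides, residue codes, seed words,
#' stop positions) reused across queries.
#' @noRd
scaffold_frames <- function(scaffold) {
  frames <- six_frame_translate(scaffold)
  lapply(frames, function(fr) {
    fr$codes <- aa_codes(fr$peptide)
    fr$words <- word_codes(fr$codes)
    fr$stars <- which(strsplit(fr$peptide, "", fixed = TRUE)[[1]] == "*")
    fr
  })
}

#' @noRd
word_codes <- function(codes, k = 3L) {
  n <- length(codes)
  if (n < k) return(integer(0))
  codes[codes > 20L] <- NA_integer_  # only canonical residues seed
  w <- codes[1:(n - 2L)] * 625L + codes[2:(n - 1L)] * 25L + codes[3:n]
  w
}

#' Find candidate-exon hits of a protein query in one scaffold
#'
#' Seeds are exact shared 3-mers whose BLOSUM62 self-score reaches
#' `seed_score_min`; a diagonal is extended when two seeds co-occur within
#' `two_hit_window` (single-seed diagonals are extended for short queries
#' < 2x the window, so that tiny exact queries still report). Extension is
#' ungapped with X-drop termination and never crosses a translated stop.
#'
#' @param query amino-acid string.
#' @param scaffold nucleotide string.
#' @param params [search_params()].
#' @param query_id,scaffold_id ids copied into the hit table.
#' @param frames optional precomputed frame data for the scaffold (internal
#'   reuse across queries).
#' @return data.frame of hits: `scaffold_id, strand, frame, g_start, g_end`
#'   (0-based half-open, forward strand), `query_id, q_start, q_end` (1-based
#'   aa), `s_start, s_end` (framed-peptide aa), `score`, `n_ident`, `qseq`,
#'   `sseq` (aligned ungapped residue strings).
#' @export
find_exon_hits <- function(query, scaffold, params = search_params(),
                           query_id = "query", scaffold_id = "scaffold",
                           frames = NULL) {
  if (nchar(query) < params$word_size) stop("query shorter than word_size")
  L <- nchar(scaffold)
  if (is.null(frames)) frames <- scaffold_frames(scaffold)
  M <- blosum62()
  qc <- aa_codes(query)
  nq <- length(qc)
  qw <- word_codes(qc)
  self <- diag(M)[qc]
  wself <- self[seq_len(max(nq - 2L, 0L))] +
    self[seq_len(max(nq - 2L, 0L)) + 1L] + self[seq_len(max(nq - 2L, 0L)) + 2L]
  ok_q <- which(!is.na(qw) & wself >= params$seed_score_min)
  hits <- list()
  if (length(ok_q)) {
    qpos_by_word <- split(ok_q, qw[ok_q])
    for (fr in frames) {
      pep <- fr$peptide
      if (nchar(pep) < params$word_size) next
      sc <- fr$codes
      sw <- fr$words
      m <- match(sw, as.integer(names(qpos_by_word)))
      spos <- which(!is.na(m))
      if (!length(spos)) next
      seeds_q <- qpos_by_word[m[spos]]
      nrep <- lengths(seeds_q)
      seed_s <- rep.int(spos, nrep)
      seed_q <- unlist(seeds_q, use.names = FALSE)
      diag_id <- seed_s - seed_q
      o <- order(diag_id, seed_s)
      seed_s <- seed_s[o]; seed_q <- seed_q[o]; diag_id <- diag_id[o]
      same <- c(FALSE, diff(diag_id) == 0 &
                  diff(seed_s) <= params$two_hit_window)
      grp <- cumsum(!same)
      trigger <- nq < 2L * params$two_hit_window
      star_pos <- fr$stars
      done <- list()
      if (!trigger) {
        cnt <- tabulate(grp)
        keep <- cnt[grp] >= 2L
        if (!any(keep)) next
        seed_s <- seed_s[keep]; seed_q <- seed_q[keep]
        diag_id <- diag_id[keep]; grp <- grp[keep]
      }
      for (idx in split(seq_along(grp), grp)) {
        d <- diag_id[idx[1]]
        key <- as.character(d)
        # extension domain: whole diagonal, truncated at stops around the seed
        q1 <- max(1L, 1L - min(d, 0L))
        q2 <- min(nq, nchar(pep) - d)
        if (q2 < q1) next
        qs_rng <- q1:q2
        ss_rng <- qs_rng + d
        v <- M[cbind(qc[qs_rng], sc[ss_rng])]
        sstar <- ss_rng %in% star_pos
        seedq <- seed_q[idx[1]]
        k0 <- seedq - q1 + 1L
        # clip at stops: nearest '*' at or after/before the seed word
        lo <- 1L; hi <- length(v)
        if (any(sstar)) {
          before <- which(sstar & seq_along(v) < k0)
          after <- which(sstar & seq_along(v) >= k0)
          if (length(before)) lo <- max(before) + 1L
          if (length(after)) hi <- min(after) - 1L
        }
        if (hi < lo || k0 < lo || k0 > hi) next
        seg <- lo:hi
        # skip if this diagonal segment was already emitted
        if (!is.null(done[[key]]) && any(done[[key]] == k0)) next
        vv <- v[seg]
        kk <- k0 - lo + 1L
        # right X-drop from seed word end
        kend <- min(kk + 2L, length(vv))
        re <- kend
        if (kend < length(vv)) {
          cum <- cumsum(vv[(kend + 1L):length(vv)])
          cm <- cummax(cum)
          stop_at <- which(cm - cum > params$x_drop)
          lim <- if (length(stop_at)) stop_at[1] - 1L else length(cum)
          if (lim > 0L) {
            best <- which.max(cum[1:lim])
            if (cum[best] > 0) re <- kend + best
          }
        }
        ls <- kk
        if (kk > 1L) {
          cum <- cumsum(rev(vv[1:(kk - 1L)]))
          cm <- cummax(cum)
          stop_at <- which(cm - cum > params$x_drop)
          lim <- if (length(stop_at)) stop_at[1] - 1L else length(cum)
          if (lim > 0L) {
            best <- which.max(cum[1:lim])
            if (cum[best] > 0) ls <- kk - best
          }
        }
        # trim low-identity drift at the ends: X-drop extensions can wander a
        # few lucky codons past a true exon boundary; require the terminal
        # 8-residue window to hold at least 50% identities
        eqv <- qc[qs_rng[seg]] == sc[ss_rng[seg]]
        tw <- 8L
        while (re - ls + 1L > tw && mean(eqv[ls:(ls + tw - 1L)]) < 0.5) ls <- ls + 1L
        while (re - ls + 1L > tw && mean(eqv[(re - tw + 1L):re]) < 0.5) re <- re - 1L
        score <- sum(vv[ls:re])
        if (score < params$score_min) { done[[key]] <- c(done[[key]], k0); next }
        qs <- qs_rng[seg[ls]]; qe <- qs_rng[seg[re]]
        ss <- qs + d; se <- qe + d
        ci1 <- codon_interval(L, fr$strand, fr$frame, ss)
        ci2 <- codon_interval(L, fr$strand, fr$frame, se)
        g_start <- min(ci1[, 1], ci2[, 1])
        g_end <- max(ci1[, 2], ci2[, 2])
        qseq <- substr(query, qs, qe)
        sseq <- substr(pep, ss, se)
        hits[[length(hits) + 1L]] <- data.frame(
          scaffold_id = scaffold_id, strand = fr$strand, frame = fr$frame,
          g_start = g_start, g_end = g_end, query_id = query_id,
          q_start = qs, q_end = qe, s_start = ss, s_end = se,
          score = score,
          n_ident = sum(substring(qseq, 1:nchar(qseq), 1:nchar(qseq)) ==
                          substring(sseq, 1:nchar(sseq), 1:nchar(sseq))),
          qseq = qseq, sseq = sseq, stringsAsFactors = FALSE)
        done[[key]] <- c(done[[key]], k0)
      }
    }
  }
  if (!length(hits)) return(empty_hits())
  out <- do.call(rbind, hits)
  out <- unique(out)
  # collapse duplicate extensions of one diagonal segment
  key <- paste(out$strand, out$frame, out$g_start, out$g_end, out$q_start)
  out <- out[!duplicated(key), , drop = FALSE]
  out[order(out$g_start, out$q_start), , drop = FALSE]
}

#' @noRd
empty_hits <- function() {
  data.frame(scaffold_id = character(), strand = character(),
             frame = integer(), g_start = integer(), g_end = integer(),
             query_id = character(), q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(), score = numeric(),
             n_ident = integer(), qseq = character(), sseq = character(),
             stringsAsFactors = FALSE)
}

#' Search a whole reference panel against a genome
#'
#' @param references [Biostrings::AAStringSet] of query proteins.
#' @param genome [Biostrings::DNAStringSet] of scaffolds.
#' @param params [search_params()].
#' @return combined hit data.frame (see [find_exon_hits()]).
#' @export
search_genome <- function(references, genome, params = search_params()) {
  rid <- fasta_ids(references)
  gid <- fasta_ids(genome)
  res <- list()
  for (i in seq_along(genome)) {
    scaf <- as.character(genome[[i]])
    frames <- scaffold_frames(scaf)
    for (j in seq_along(references)) {
      h <- find_exon_hits(as.character(references[[j]]), scaf, params,
                          query_id = rid[j], scaffold_id = gid[i],
                          frames = frames)
      if (nrow(h)) res[[length(res) + 1L]] <- h
    }
  }
  if (!length(res)) return(empty_hits())
  do.call(rbind, res)
}

#' Write hits as a BLAST-like 12-column TSV
#' @param hits hit table from [search_genome()].
#' @param path output path.
#' @export
write_hits_tsv <- function(hits, path) {
  alen <- nchar(hits$qseq)
  tab <- data.frame(
    qseqid = hits$query_id, sseqid = hits$scaffold_id,
    pident = round(100 * hits$n_ident / pmax(alen, 1L), 2),
    length = alen, mismatch = alen - hits$n_ident, gapopen = 0L,
    qstart = hits$q_start, qend = hits$q_end,
    sstart = ifelse(hits$strand == "+", hits$g_start + 1L, hits$g_end),
    send = ifelse(hits$strand == "+", hits$g_end, hits$g_start + 1L),
    evalue = NA_real_, bitscore = hits$score)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
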