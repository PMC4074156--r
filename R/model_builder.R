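# Gene-model construction: chain compatible exon hits into colinear
# structures, refine splice boundaries to canonical GT..AG donors/acceptors,
# and translate into flagged GeneModels.

#' Exon-chaining parameters
#' @param max_intron maximum genomic gap (nt) bridged between chained hits.
#' @param max_query_overlap maximum query-coordinate overlap (aa) between
#'   adjacent chained hits.
#' @param min_chain_score minimum total score of a reported chain.
#' @export
chain_params <- function(max_intron = 10000L, max_query_overlap = 15L,
                         min_chain_score = 50) {
  list(max_intron = max_intron, max_query_overlap = max_query_overlap,
       min_chain_score = min_chain_score)
}

#' Model-building parameters
#' @param window splice-site search window (nt) around raw hit boundaries.
#' @param min_intron minimum believable intron length (nt); junctions whose
#'   implied intron would be shorter cannot be spliced and are flagged.
#' @param min_hit_identity when a junction cannot be refined, a flanking hit
#'   below this identity is treated as spurious and dropped from the chain.
#' @param context_codons codons of context translated on each side when
#'   scoring candidate splice junctions.
#' @export
build_params <- function(window = 15L, min_intron = 40L,
                         min_hit_identity = 0.75, context_codons = 10L) {
  list(window = window, min_intron = min_intron,
       min_hit_identity = min_hit_identity, context_codons = context_codons)
}

#' Chain compatible exon hits into candidate gene structures
#'
#' Weighted colinear chaining (interval-scheduling DP) of hits from one
#' scaffold/query pair: chained hits share a strand, advance in both genomic
#' and query coordinates, bridge at most `max_intron` nt, and overlap by at
#' most `max_query_overlap` aa on the query. Chains are extracted greedily
#' by score; ties break to the leftmost genomic start.
#'
#' @param hits hit table from [find_exon_hits()] (one scaffold, one query).
#' @param params [chain_params()].
#' @return list of chains; each chain is a list with `hits` (rows in coding
#'   order), `score`, `strand`, `scaffold_id`, `query_id`.
#' @export
chain_exons <- function(hits, params = chain_params()) {
  if (nrow(hits) == 0L) return(list())
  if (length(unique(hits$scaffold_id)) > 1L || length(unique(hits$query_id)) > 1L)
    stop("chain_exons expects hits from a single scaffold/query pair")
  out <- list()
  for (strand in unique(hits$strand)) {
    h <- hits[hits$strand == strand, , drop = FALSE]
    if (strand == "+") { cs <- h$g_start; ce <- h$g_end }
    else { cs <- -h$g_end; ce <- -h$g_start }
    o <- order(cs, h$q_start)
    h <- h[o, , drop = FALSE]; cs <- cs[o]; ce <- ce[o]
    active <- rep(TRUE, nrow(h))
    repeat {
      idx <- which(active)
      if (!length(idx)) break
      n <- length(idx)
      total <- h$score[idx]
      pred <- rep(NA_integer_, n)
      for (j in seq_len(n)) {
        J <- idx[j]
        for (i in seq_len(max(j - 1L, 0L))) {
          I <- idx[i]
          gap <- cs[J] - ce[I]
          q_over <- h$q_end[I] - h$q_start[J] + 1L
          if (cs[J] > cs[I] && gap <= params$max_intron &&
              gap >= -3L * params$max_query_overlap &&
              h$q_start[J] > h$q_start[I] && h$q_end[J] > h$q_end[I] &&
              q_over <= params$max_query_overlap) {
            cand <- total[i] + h$score[J]
            if (cand > total[j]) { total[j] <- cand; pred[j] <- i }
          }
        }
      }
      best <- which(total == max(total))
      best <- best[which.min(cs[idx[best]])]
      if (total[best] < params$min_chain_score) break
      path <- integer()
      k <- best
      while (!is.na(k)) { path <- c(k, path); k <- pred[k] }
      rows <- idx[path]
      chain_hits <- h[rows, , drop = FALSE]
      out[[length(out) + 1L]] <- list(
        hits = chain_hits, score = total[best], strand = strand,
        scaffold_id = h$scaffold_id[1], query_id = h$query_id[1])
      # retire chain members and anything genomically inside the chain span
      span <- range(c(h$g_start[rows], h$g_end[rows]))
      inside <- h$g_start < span[2] & h$g_end > span[1]
      active[rows] <- FALSE
      active[inside] <- FALSE
    }
  }
  out[order(vapply(out, function(x) -x$score, numeric(1)))]
}

#' @noRd
to_coding <- function(g_start, g_end, strand, L) {
  if (strand == "+") cbind(start = g_start, end = g_end)
  else cbind(start = L - g_end, end = L - g_start)
}

#' @noRd
from_coding <- function(cs, ce, strand, L) {
  if (strand == "+") cbind(start = cs, end = ce)
  else cbind(start = L - ce, end = L - cs)
}

#' Refine splice boundaries of a chain and assemble a gene model
#'
#' For each adjacent exon pair the donor GT and acceptor AG are sought within
#' `window` nt of the raw hit boundaries (widened across query overlaps or
#' gaps), subject to reading-frame continuity (split-codon phases summing to
#' a codon) and a minimum intron length; among candidates the pair maximizing
#' the translated junction's alignment score against the query wins, with
#' ties broken by distance to the raw boundaries, then leftmost. Junctions
#' spanning a long N run become gap junctions bridged by an N placeholder
#' exon; junctions with no admissible GT..AG pair keep their raw boundaries
#' and set the `frame_break` flag. Terminal exons are extended to cover the
#' query ends, and a downstream stop codon is absorbed into the last exon.
#'
#' @param chain a chain from [chain_exons()].
#' @param scaffold nucleotide string of the chain's scaffold.
#' @param query amino-acid string of the chain's query protein.
#' @param params [build_params()].
#' @param id model identifier.
#' @return a `GeneModel`: list with `id`, `scaffold_id`, `strand`, `exons`
#'   (0-based half-open forward-strand coordinates, coding order), `cds`,
#'   `protein` (translation up to the first stop), `protein_full`, `flags`,
#'   `junctions`, `source_query`.
#' @export
refine_splice_sites <- function(chain, scaffold, query, params = build_params(),
                                id = "model") {
  h <- chain$hits
  if (nrow(h) == 0L) stop("empty chain")
  strand <- chain$strand
  L <- nchar(scaffold)
  cs_seq <- if (strand == "+") scaffold else revcomp(scaffold)
  qlen <- nchar(query)
  M <- blosum62()

  repeat {
    k <- nrow(h)
    cc <- to_coding(h$g_start, h$g_end, strand, L)
    if (any(diff(cc[, 1]) <= 0)) stop("chain exons out of order")
    cs <- cc[, 1]; ce <- cc[, 2]
    qs <- h$q_start; qe <- h$q_end
    # trim genomic overlaps in codon steps, keeping each hit's frame
    if (k > 1L) for (i in 2:k) {
      while (cs[i] < ce[i - 1L]) { cs[i] <- cs[i] + 3L; qs[i] <- qs[i] + 1L }
    }
    # codon-grid anchors: refined acceptors gain partial codons, so all
    # phase arithmetic stays relative to the raw (codon-aligned) hit starts
    cs0 <- cs; qs0 <- qs
    junctions <- list()
    failed_at <- 0L
    if (k > 1L) for (i in seq_len(k - 1L)) {
      raw_d <- ce[i]; raw_a <- cs[i + 1L]
      gap_seq <- substr(cs_seq, raw_d + 1L, raw_a)
      if (longest_n_run(gap_seq) >= 20L) {
        junctions[[i]] <- list(type = "gap")
        next
      }
      q_over <- max(0L, qe[i] - qs[i + 1L] + 1L)
      q_gap <- max(0L, qs[i + 1L] - qe[i] - 1L)
      w <- params$window
      rng <- function(lo, hi) if (hi < lo) integer(0) else lo:hi
      d_rng <- rng(max(cs[i] + 3L, raw_d - w - 3L * q_over),
                   min(raw_a, raw_d + w + 3L * q_gap))
      a_rng <- rng(max(raw_d, raw_a - w - 3L * q_gap),
                   min(ce[i + 1L] - 3L, raw_a + w + 3L * q_over))
      dd <- d_rng[substring(cs_seq, d_rng + 1L, d_rng + 2L) == "GT"]
      aa <- a_rng[substring(cs_seq, a_rng - 1L, a_rng) == "AG"]
      best <- NULL
      for (d in dd) {
        p1 <- (d - cs0[i]) %% 3L
        p2 <- (3L - p1) %% 3L
        for (a in aa) {
          if (a - d < params$min_intron) next
          if ((cs0[i + 1L] - a) %% 3L != p2) next
          nl <- max(0L, min(params$context_codons, (d - p1 - cs[i]) %/% 3L))
          nr <- max(0L, min(params$context_codons, (ce[i + 1L] - (a + p2)) %/% 3L))
          left_start <- d - p1 - 3L * nl
          chunk <- paste0(substr(cs_seq, left_start + 1L, d),
                          substr(cs_seq, a + 1L, a + p2 + 3L * nr))
          pep <- translate_cds(chunk)
          qa <- qs0[i] + (left_start - cs0[i]) %/% 3L
          qseg <- substr(query, qa, qa + nchar(pep) - 1L)
          if (nchar(qseg) < nchar(pep)) pep <- substr(pep, 1L, nchar(qseg))
          sc <- ungapped_score(pep, qseg)
          dist <- abs(d - raw_d) + abs(a - raw_a)
          cand <- list(d = d, a = a, score = sc, dist = dist)
          if (is.null(best) || sc > best$score ||
              (sc == best$score && (dist < best$dist ||
                (dist == best$dist && (d < best$d || (d == best$d && a < best$a))))))
            best <- cand
        }
      }
      if (is.null(best)) {
        junctions[[i]] <- list(type = "break")
        id_i <- h$n_ident[i] / (h$q_end[i] - h$q_start[i] + 1L)
        id_j <- h$n_ident[i + 1L] / (h$q_end[i + 1L] - h$q_start[i + 1L] + 1L)
        if (min(id_i, id_j) < params$min_hit_identity && k > 1L) {
          failed_at <- if (id_i < id_j) i else i + 1L
          break
        }
      } else {
        junctions[[i]] <- list(type = "splice", d = best$d, a = best$a)
        ce[i] <- best$d
        cs[i + 1L] <- best$a
      }
    }
    if (failed_at > 0L) {
      h <- h[-failed_at, , drop = FALSE]
      if (nrow(h) == 0L) stop("no credible hits left in chain")
      next
    }

    # terminal fill to query ends (codon-aligned, clamped at scaffold edges);
    # only credible terminal hits are filled, so spurious low-identity chains
    # are not inflated to full-length models
    hit_ident <- h$n_ident / (h$q_end - h$q_start + 1L)
    if (hit_ident[1] >= params$min_hit_identity) {
      fill <- 3L * (qs[1] - 1L)
      new_start <- max(0L, cs[1] - fill)
      new_start <- new_start + (cs[1] - new_start) %% 3L
      cs[1] <- new_start
    }
    if (hit_ident[k] >= params$min_hit_identity) {
      add <- 3L * (qlen - qe[k])
      new_end <- min(L, ce[k] + add)
      new_end <- new_end - (new_end - ce[k]) %% 3L
      ce[k] <- new_end
    }
    stop_present <- FALSE
    if (ce[k] + 3L <= L &&
        substr(cs_seq, ce[k] + 1L, ce[k] + 3L) %in% STOP_CODONS) {
      ce[k] <- ce[k] + 3L
      stop_present <- TRUE
    }

    # assemble exons, inserting N placeholders across gap junctions
    ex_cs <- integer(); ex_ce <- integer()
    for (i in seq_len(k)) {
      ex_cs <- c(ex_cs, cs[i]); ex_ce <- c(ex_ce, ce[i])
      if (i <= length(junctions) && identical(junctions[[i]]$type, "gap")) {
        n_missing <- max(0L, qs[i + 1L] - qe[i] - 1L)
        if (n_missing > 0L) {
          gap_seq <- substr(cs_seq, ce[i] + 1L, cs[i + 1L])
          r <- regexpr("N{20,}", gap_seq)
          if (r[1] > 0L) {
            run_len <- attr(r, "match.length")
            len <- min(3L * n_missing, (run_len %/% 3L) * 3L)
            p0 <- ce[i] + as.integer(r[1]) - 1L
            ex_cs <- c(ex_cs, p0); ex_ce <- c(ex_ce, p0 + len)
          }
        }
      }
    }
    cds <- paste(substring(cs_seq, ex_cs + 1L, ex_ce), collapse = "")
    protein_full <- translate_cds(cds)
    pf <- protein_full
    if (stop_present && endsWith(pf, "*")) pf <- substr(pf, 1L, nchar(pf) - 1L)
    star <- regexpr("*", pf, fixed = TRUE)
    protein <- if (star[1] > 0L) substr(pf, 1L, star[1] - 1L) else pf
    flags <- list(
      internal_stop = star[1] > 0L,
      frame_break = any(vapply(junctions, function(j)
        identical(j$type, "break"), logical(1))),
      has_internal_N = grepl("N", cds, fixed = TRUE),
      start_codon_present = substr(cds, 1L, 3L) == "ATG",
      stop_codon_present = stop_present)
    exons <- from_coding(ex_cs, ex_ce, strand, L)
    return(structure(list(
      id = id, scaffold_id = chain$scaffold_id, strand = strand,
      exons = exons, cds = cds, protein = protein,
      protein_full = pf, flags = flags, junctions = junctions,
      source_query = chain$query_id, chain_score = chain$score),
      class = "GeneModel"))
  }
}

#' @export
print.GeneModel <- function(x, ...) {
  cat("GeneModel", x$id, "on", x$scaffold_id, x$strand, "\n")
  cat("  exons:", nrow(x$exons), " cds:", nchar(x$cds), "nt  protein:",
      nchar(x$protein), "aa\n")
  on <- names(Filter(isTRUE, x$flags))
  cat("  flags:", if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Detect a frame-disrupting indel by multi-frame alignment
#'
#' A CDS whose best reconciliation with the reference needs an indel of
#' length not divisible by three aligns different portions of the reference
#' in different translation frames. Flags when two frames align
#' near-disjoint reference regions with credible scores.
#' @noRd
frame_break_by_alignment <- function(cds, reference, min_score = 55,
                                     min_span = 20L, min_new_cov = 25L) {
  M <- blosum62()
  res <- lapply(0:2, function(f) {
    pep <- translate_cds(substr(cds, f + 1L, nchar(cds)))
    if (nchar(pep) < 10L) return(NULL)
    pep <- gsub("*", "X", pep, fixed = TRUE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(pep), Biostrings::AAString(reference),
      substitutionMatrix = M, gapOpening = 11, gapExtension = 1,
      type = "local")
    list(score = Biostrings::score(pa),
         r1 = Biostrings::start(Biostrings::subject(pa)),
         r2 = Biostrings::end(Biostrings::subject(pa)))
  })
  res <- Filter(Negate(is.null), res)
  if (length(res) < 2L) return(FALSE)
  sc <- vapply(res, `[[`, numeric(1), "score")
  b <- which.max(sc)
  for (f in seq_along(res)) {
    if (f == b) next
    if (sc[f] < min_score) next
    span <- res[[f]]$r2 - res[[f]]$r1 + 1L
    overlap <- max(0L, min(res[[f]]$r2, res[[b]]$r2) -
                     max(res[[f]]$r1, res[[b]]$r1) + 1L)
    # the second frame must explain reference residues the best frame does not
    if (span >= min_span && span - overlap >= min_new_cov) return(TRUE)
  }
  FALSE
}

#' Finalize a model's lesion flags against its reference protein
#'
#' Recomputes `internal_stop` and `has_internal_N` from the CDS, sets the
#' terminal-codon flags, and raises `frame_break` when the best alignment to
#' the reference requires a frame-disrupting (non 3n) exonic indel.
#'
#' @param model a `GeneModel`.
#' @param reference amino-acid string of the model's reference protein.
#' @return the model with updated flags.
#' @export
translate_model <- function(model, reference) {
  if (!nzchar(model$cds)) stop("model has empty cds")
  model$flags$frame_break <- isTRUE(model$flags$frame_break) ||
    frame_break_by_alignment(model$cds, reference)
  model
}
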