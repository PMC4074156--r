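# Phylogeny: pairwise maximum-likelihood distances under the JTT model,
# neighbor-joining trees, column-bootstrap supports, and ortholog-subgroup
# extraction from species-labeled trees.

#' Pairwise site-pattern counts over shared non-gap columns
#' @noRd
pair_counts <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(av) != length(bv)) stop("aligned rows differ in length")
  keep <- av %in% AA20 & bv %in% AA20
  if (!any(keep)) stop("no shared non-gap columns")
  table(factor(av[keep], AA20), factor(bv[keep], AA20))
}

#' Maximum-likelihood JTT distance between two aligned proteins
#'
#' Estimates the evolutionary time separating two aligned rows by maximizing
#' the likelihood `prod pi_i P_ij(t)` over shared non-gap columns, using the
#' eigendecomposed JTT rate matrix and scalar optimization. Identical rows
#' return exactly 0; saturated pairs are capped.
#'
#' @param a,b aligned amino-acid strings (equal length, `-` for gaps).
#' @param cap distance ceiling for saturated pairs.
#' @param tol optimization tolerance on t.
#' @return distance in expected substitutions per site.
#' @export
jtt_distance <- function(a, b, cap = 10, tol = 1e-8) {
  n <- pair_counts(a, b)
  if (sum(n) == sum(diag(n))) return(0)
  nll <- function(t) {
    P <- jtt_probability(t)
    -sum(n * log(pmax(P, 1e-300)))
  }
  opt <- stats::optimize(nll, c(tol, cap), tol = tol)
  if (opt$minimum > cap - 0.01 && nll(cap) <= opt$objective) return(cap)
  opt$minimum
}

#' JTT ML distance matrix of an MSA
#'
#' @param msa named character vector or [Biostrings::AAStringSet] of aligned
#'   rows.
#' @param cap saturation ceiling passed to [jtt_distance()].
#' @return symmetric matrix (class `dist`-compatible plain matrix) with zero
#'   diagonal.
#' @export
jtt_distance_matrix <- function(msa, cap = 10) {
  nm <- names(msa)
  rows <- as.character(msa)
  ids <- sub("\\s.*$", "", nm)
  n <- length(rows)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- jtt_distance(rows[i], rows[j], cap = cap)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()]); additive matrices
#' are recovered exactly.
#'
#' @param mat symmetric distance matrix with labels.
#' @return unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(mat) {
  if (nrow(mat) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(abs(mat - t(mat)) > 1e-9)) stop("matrix must be symmetric")
  ape::nj(stats::as.dist(mat))
}

#' Column-bootstrap supports on the NJ/JTT tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the original tree the
#' percentage of replicates containing the same bipartition.
#'
#' @param msa named aligned rows.
#' @param reps number of replicates (0 returns the tree without supports).
#' @param seed RNG seed (deterministic supports).
#' @param cap saturation ceiling for distances.
#' @return the NJ tree with `node.label` set to support percentages
#'   (`NA` on the root node).
#' @export
bootstrap_support <- function(msa, reps = 1000, seed = 1, cap = 10) {
  nm <- names(msa)
  rows <- stats::setNames(as.character(msa), nm)
  ids <- sub("\\s.*$", "", nm)
  tree <- neighbor_joining(jtt_distance_matrix(rows))
  if (reps <= 0) return(tree)
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(m) <- ids
  L <- ncol(m)
  btrees <- with_seed(seed, lapply(seq_len(reps), function(r) {
    cols <- sample.int(L, L, replace = TRUE)
    mm <- m[, cols, drop = FALSE]
    rs <- apply(mm, 1, paste, collapse = "")
    names(rs) <- ids
    neighbor_joining(jtt_distance_matrix(rs))
  }))
  cnt <- ape::prop.clades(tree, btrees, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  supports <- 100 * cnt / reps
  supports[1] <- NA  # root of the unrooted representation
  tree$node.label <- supports
  tree
}

#' @noRd
node_leaves <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, node_leaves, tree = tree))
}

#' Extract ortholog subgroups from a species-labeled tree
#'
#' A subgroup is a clade containing members of at least two species with
#' support at or above `min_support` and no qualifying clade nested inside
#' it (the smallest supported mixed clades). Also reports species-specific
#' clades: maximal supported clades of >= 2 leaves from a single species.
#' Internal nodes without a support value (including the root) are treated
#' as supported.
#'
#' @param tree [ape::phylo] with `node.label` supports (0-100 or `NA`).
#' @param species_map named character vector: leaf label -> species tag.
#' @param min_support minimum bootstrap percentage for a clade to count.
#' @return list with `subgroups` and `species_clades`; each entry carries
#'   `leaves`, `species`, `support`.
#' @export
ortholog_subgroups <- function(tree, species_map, min_support = 70) {
  tips <- tree$tip.label
  unmapped <- setdiff(tips, names(species_map))
  if (length(unmapped)) stop("leaf not in species map: ", unmapped[1])
  n_tip <- length(tips)
  n_node <- tree$Nnode
  supports <- if (!is.null(tree$node.label)) {
    suppressWarnings(as.numeric(tree$node.label))
  } else rep(NA_real_, n_node)
  ok_support <- function(node) {
    s <- supports[node - n_tip]
    is.na(s) || s >= min_support
  }
  internal <- (n_tip + 1L):(n_tip + n_node)
  leaves_of <- lapply(internal, function(nd) tips[node_leaves(tree, nd)])
  species_of <- lapply(leaves_of, function(lv) unique(unname(species_map[lv])))
  mixed_ok <- vapply(internal, function(nd) {
    i <- nd - n_tip
    length(species_of[[i]]) >= 2L && ok_support(nd)
  }, logical(1))
  single_ok <- vapply(internal, function(nd) {
    i <- nd - n_tip
    length(species_of[[i]]) == 1L && length(leaves_of[[i]]) >= 2L &&
      ok_support(nd)
  }, logical(1))
  has_desc <- function(nd, ok) {
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    for (k in kids) {
      if (k > n_tip && (ok[k - n_tip] || has_desc(k, ok))) return(TRUE)
    }
    FALSE
  }
  mk <- function(nd) list(leaves = leaves_of[[nd - n_tip]],
                          species = species_of[[nd - n_tip]],
                          support = supports[nd - n_tip])
  minimal_mixed <- internal[mixed_ok & !vapply(internal, has_desc,
                                               logical(1), ok = mixed_ok)]
  subgroups <- lapply(minimal_mixed, mk)
  # species-specific: qualifying single-species clades with no qualifying
  # single-species ancestor
  anc <- function(nd) {
    p <- tree$edge[tree$edge[, 2] == nd, 1]
    if (length(p)) p else NA_integer_
  }
  maximal_single <- Filter(function(nd) {
    p <- anc(nd)
    while (!is.na(p)) {
      if (p > n_tip && single_ok[p - n_tip]) return(FALSE)
      p <- anc(p)
    }
    TRUE
  }, internal[single_ok])
  # an expansion nested inside a called ortholog subgroup is part of that
  # subgroup, not a species-specific clade
  sub_leafsets <- lapply(minimal_mixed, function(nd) leaves_of[[nd - n_tip]])
  maximal_single <- Filter(function(nd) {
    lv <- leaves_of[[nd - n_tip]]
    !any(vapply(sub_leafsets, function(s) all(lv %in% s), logical(1)))
  }, maximal_single)
  list(subgroups = subgroups,
       species_clades = lapply(maximal_single, mk))
}
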