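test_that("JTT distances: zero case, symmetry, and oracle agreement", {
  a <- rand_protein(300, seed = 71)
  expect_equal(jtt_distance(a, a), 0)
  b <- withr::with_seed(72, {
    bv <- strsplit(a, "", fixed = TRUE)[[1]]
    idx <- sample(300, 150)
    for (i in idx) bv[i] <- sample(setdiff(rscout:::AA20, bv[i]), 1)
    paste(bv, collapse = "")
  })
  d <- jtt_distance(a, b)
  expect_equal(jtt_distance(b, a), d)
  # brute-force likelihood scan on a 1e-4 grid
  n <- rscout:::pair_counts(a, b)
  grid <- seq(1e-4, 3, by = 1e-4)
  nll <- vapply(grid, function(t)
    -sum(n * log(pmax(jtt_probability(t), 1e-300))), numeric(1))
  expect_lt(abs(d - grid[which.min(nll)]), 1e-3)
  expect_error(jtt_distance("A-", "-A"), "no shared")
})

test_that("JTT distances agree with an independent implementation", {
  a <- rand_protein(400, seed = 73)
  b <- withr::with_seed(74, {
    bv <- strsplit(a, "", fixed = TRUE)[[1]]
    idx <- sample(400, 120)
    for (i in idx) bv[i] <- sample(setdiff(rscout:::AA20, bv[i]), 1)
    paste(bv, collapse = "")
  })
  m <- matrix(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]]), nrow = 2,
              byrow = TRUE, dimnames = list(c("a", "b"), NULL))
  pd <- phangorn::as.phyDat(m, type = "AA")
  ref <- as.matrix(phangorn::dist.ml(pd, model = "JTT"))["a", "b"]
  expect_lt(abs(jtt_distance(a, b) - ref), 1e-3)
})

test_that("neighbor joining recovers additive trees exactly", {
  expect_error(neighbor_joining(matrix(0, 2, 2)), "3 taxa")
  # 3 taxa: closed-form three-point branch lengths
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  t3 <- neighbor_joining(D)
  expect_equal(sort(ape::cophenetic.phylo(t3)[letters[1:3], letters[1:3]]),
               sort(D))
  # 5-taxon additive matrices from random trees
  for (seed in 1:5) {
    tr <- withr::with_seed(seed, ape::rtree(5))
    DD <- ape::cophenetic.phylo(tr)
    rec <- neighbor_joining(DD)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), rec)), 0)
    expect_equal(sort(round(ape::cophenetic.phylo(rec)[rownames(DD),
                                                       colnames(DD)], 9)),
                 sort(round(DD, 9)))
    # label permutation gives an isomorphic tree
    perm <- withr::with_seed(seed + 10, sample(5))
    rec2 <- neighbor_joining(DD[perm, perm])
    expect_equal(as.numeric(ape::dist.topo(rec, rec2)), 0)
  }
})

test_that("bootstrap supports are deterministic and strong on clean signal", {
  base <- withr::with_seed(81, {
    tr <- ape::rtree(6)
    tr$edge.length <- tr$edge.length * 0.3
    tr
  })
  sim <- withr::with_seed(82,
    phangorn::simSeq(base, l = 800, type = "AA", model = "JTT"))
  msa <- toupper(apply(as.character(sim), 1, paste, collapse = ""))
  bt1 <- bootstrap_support(msa, reps = 100, seed = 5)
  bt2 <- bootstrap_support(msa, reps = 100, seed = 5)
  expect_identical(bt1$node.label, bt2$node.label)
  sup <- suppressWarnings(as.numeric(bt1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 95))
  bt0 <- bootstrap_support(msa, reps = 0, seed = 5)
  expect_null(bt0$node.label)
})

test_that("ortholog subgroups are the smallest supported mixed clades", {
  t2 <- ape::read.tree(
    text = "((A1:1,P1:1)100:1,((A2:1,A3:1)100:1,P2:1)100:1)100;")
  sm <- c(A1 = "Ago", A2 = "Ago", A3 = "Ago", P1 = "Ap", P2 = "Ap")
  og <- ortholog_subgroups(t2, sm)
  leaves <- lapply(og$subgroups, function(x) sort(x$leaves))
  expect_equal(length(og$subgroups), 2L)
  expect_true(list(c("A1", "P1")) %in% leaves || any(
    vapply(leaves, identical, logical(1), c("A1", "P1"))))
  expect_true(any(vapply(leaves, identical, logical(1), c("A2", "A3", "P2"))))
  expect_equal(length(og$species_clades), 0L)
  expect_error(ortholog_subgroups(t2, sm[-1]), "not in species map")

  # single-species tree: no subgroups, one species-specific clade
  t3 <- ape::read.tree(text = "((A1:1,A2:1)95:1,(A3:1,A4:1)90:1);")
  og3 <- ortholog_subgroups(t3, c(A1 = "Ago", A2 = "Ago", A3 = "Ago",
                                  A4 = "Ago"))
  expect_equal(length(og3$subgroups), 0L)
  expect_equal(length(og3$species_clades), 1L)
  expect_equal(sort(og3$species_clades[[1]]$leaves), paste0("A", 1:4))
})

test_that("low-divergence ortholog pairs come back as 2-leaf subgroups", {
  # 4 ortholog pairs: deep splits between families, shallow within pairs,
  # plus a distant outgroup to fix the root of the NJ representation
  nwk <- paste0("((((a1:0.05,b1:0.05):0.6,(a2:0.05,b2:0.05):0.6):0.3,",
                "((a3:0.05,b3:0.05):0.6,(a4:0.05,b4:0.05):0.7):0.3):0.5,",
                "out:1.5);")
  tr <- ape::read.tree(text = nwk)
  sim <- withr::with_seed(83,
    phangorn::simSeq(tr, l = 700, type = "AA", model = "JTT"))
  msa <- toupper(apply(as.character(sim), 1, paste, collapse = ""))
  bt <- bootstrap_support(msa, reps = 100, seed = 7)
  bt <- ape::root(bt, "out", resolve.root = TRUE, edgelabel = TRUE)
  sm <- c(a1 = "A", a2 = "A", a3 = "A", a4 = "A",
          b1 = "B", b2 = "B", b3 = "B", b4 = "B", out = "Out")
  og <- ortholog_subgroups(bt, sm, min_support = 70)
  pair_sets <- lapply(og$subgroups, function(x) sort(x$leaves))
  for (i in 1:4)
    expect_true(any(vapply(pair_sets, identical, logical(1),
                           sort(c(paste0("a", i), paste0("b", i))))))
})
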