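test_that("p-distance is the complement of identity excluding indels", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  set.seed(3)
  for (i in 1:10) {
    a <- random_seq(30); b <- random_seq(30)
    expect_equal(p_distance(a, b), 1 - identity_excluding_indels(a, b))
  }
})

test_that("TN93 distance matches an independent closed-form evaluation", {
  expect_equal(tn93_distance("ACGTACGTACGT", "ACGTACGTACGT"), 0)

  ## 100 sites, 5 A<->G transitions only, balanced base composition
  base <- strrep("ACGT", 25)
  ca <- strsplit(base, "")[[1]]
  cb <- ca
  ag <- which(ca == "A")[1:5]
  cb[ag] <- "G"
  a <- paste(ca, collapse = ""); b <- paste(cb, collapse = "")
  expect_equal(tn93_distance(a, b), oracle_tn93(ca, cb), tolerance = 1e-12)
  expect_equal(tn93_distance(a, b), tn93_distance(b, a))

  ## random diverged pairs agree with the oracle and with ape::dist.dna
  set.seed(19)
  for (i in 1:8) {
    x <- random_seq(400)
    y <- mutate_oracle(x, 60)
    cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
    expect_equal(tn93_distance(x, y), oracle_tn93(cx, cy), tolerance = 1e-10)
    db <- ape::dist.dna(ape::as.DNAbin(rbind(a = tolower(cx), b = tolower(cy))),
                        model = "TN93")
    expect_equal(tn93_distance(x, y), as.numeric(db), tolerance = 1e-10)
  }
})

test_that("TN93 errors on saturation and always dominates the p-distance", {
  expect_error(tn93_distance(strrep("A", 50), strrep("G", 50)), "saturated")
  set.seed(29)
  for (i in 1:10) {
    x <- random_seq(300)
    y <- mutate_oracle(x, 45)
    expect_gte(tn93_distance(x, y), p_distance(x, y))
  }
})

test_that("neighbor joining recovers hand-built additive matrices exactly", {
  ## 4-taxon tree ((a:2,b:3):1,(c:4,d:5)) as an additive matrix
  D <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 9, 0), 4, 4,
              dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  tr <- neighbor_joining(D)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D)
  expect_equal(robinson_foulds(tr, ape::read.tree(text = "((a,b),(c,d));")), 0)

  ## 3-taxon closed form
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(D3)
  el <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(el[["a"]], (3 + 4 - 5) / 2, tolerance = 1e-12)
  expect_equal(el[["b"]], (3 + 5 - 4) / 2, tolerance = 1e-12)
  expect_equal(el[["c"]], (4 + 5 - 3) / 2, tolerance = 1e-12)

  expect_error(neighbor_joining(D3[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining recovers random additive and ultrametric trees", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(D)
    expect_equal(robinson_foulds(nj, ape::unroot(tr)), 0)
    expect_equal(max(abs(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)] - D)),
                 0, tolerance = 1e-8)
    ## independent route: ape's own NJ agrees on the topology
    expect_equal(robinson_foulds(nj, ape::nj(D)), 0)
  }
  ## ultrametric 6-taxon balanced tree
  tr <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,(e:2,f:2):1);")
  D <- ape::cophenetic.phylo(tr)
  expect_equal(robinson_foulds(neighbor_joining(D), ape::unroot(tr)), 0)
})

test_that("bootstrap gives full support on perfectly congruent data", {
  tree10 <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)),(i,j));")
  rows <- congruent_alignment(tree10, per_edge = 25)
  msa <- lepscan:::new_msa(names(rows), rows)
  bt <- bootstrap_support(msa, n_reps = 100, seed = 5)
  sup <- attr(bt, "bootstrap")
  expect_length(sup, 7)            # 10 taxa -> 7 internal edges
  expect_true(all(sup == 100))
  ## identical seed, identical supports; different seed may differ
  bt2 <- bootstrap_support(msa, n_reps = 100, seed = 5)
  expect_identical(attr(bt2, "bootstrap"), sup)
})

test_that("single-replicate bootstrap yields supports of 0 or 100", {
  set.seed(55)
  base <- random_seq(80)
  seqs <- stats::setNames(vapply(1:5, function(i) mutate_oracle(base, 10), ""),
                          paste0("s", 1:5))
  msa <- progressive_msa(seqs)
  bt <- bootstrap_support(msa, n_reps = 1, seed = 2)
  expect_true(all(attr(bt, "bootstrap") %in% c(0, 100)))
})

test_that("newick output applies the support display threshold", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,(e:1,f:1):1);")
  tr$node.label <- c("", "49", "73", "100")
  nwk <- to_newick(tr, support_threshold = 50)
  expect_false(grepl("49", nwk))
  expect_true(grepl("73", nwk))
  expect_true(grepl("100", nwk))
  ## round-trip preserves topology and branch lengths
  back <- ape::read.tree(text = nwk)
  expect_equal(robinson_foulds(back, tr), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length))
  ## 3-taxon star shape
  star <- neighbor_joining(matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3, 3,
                                  dimnames = list(c("A", "B", "C"),
                                                  c("A", "B", "C"))))
  expect_match(to_newick(star), "^\\(A:1,B:1,C:1\\);$")
})

test_that("Robinson-Foulds distance counts discordant bipartitions", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(robinson_foulds(t1, t1), 0)
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(robinson_foulds(t1, t2), 2)
  expect_equal(robinson_foulds(t2, t1), 2)
  expect_error(robinson_foulds(t1, ape::read.tree(text = "((a,b),(c,e));")),
               "leaf sets")
  ## agreement with an independent implementation on random trees
  skip_if_not_installed("phangorn")
  set.seed(61)
  for (i in 1:10) {
    x <- ape::rtree(7); y <- ape::rtree(7)
    expect_equal(robinson_foulds(x, y),
                 as.integer(phangorn::RF.dist(ape::unroot(x), ape::unroot(y))))
  }
})

test_that("distance matrices from alignments use pairwise deletion", {
  msa <- lepscan:::new_msa(c("a", "b", "c"),
                           c("ACGTACGT--", "ACGAACGTGG", "ACGTAC-TGG"))
  D <- msa_distance_matrix(msa, "p")
  expect_equal(D["a", "b"], 1 / 8)   # 8 shared columns, 1 difference
  expect_equal(D["a", "c"], 0 / 7)
  expect_equal(D, t(D))
})
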