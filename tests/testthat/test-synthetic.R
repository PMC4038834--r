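test_that("random genomes honour GC content, length and the seed", {
  g <- random_genome(1e4, gc_fraction = 0.5, seed = 1)
  expect_equal(nchar(g$residues), 1e4)
  gc <- mean(strsplit(g$residues, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.02)

  expect_identical(random_genome(5000, seed = 3)$residues,
                   random_genome(5000, seed = 3)$residues)
  expect_false(random_genome(5000, seed = 3)$residues ==
                 random_genome(5000, seed = 4)$residues)

  g1 <- random_genome(2000, gc_fraction = 1, seed = 2)
  expect_true(all(strsplit(g1$residues, "")[[1]] %in% c("G", "C")))
  expect_error(random_genome(0), "positive")
  expect_error(random_genome(100, gc_fraction = 1.5), "\\[0,1\\]")
})

test_that("constructed elements carry every hallmark at the stated coordinates", {
  cons <- default_core_consensus()
  el <- make_element(cons, 65, seed = 2)
  expect_equal(nchar(el$residues), 134 + 65)
  hm <- attr(el, "hallmarks")

  expect_equal(substr(el$residues, 1, 2), "TC")
  expect_true(iupac_match(extract_region(el, hm$ctry), "CTRY"))
  expect_true(iupac_match(extract_region(el, hm$ctrr), "CTRR"))
  expect_true(hm$ctrr$start >= nchar(el$residues) - 15)
  ## written hairpin arms are perfect reverse complements, >= 6 bp from end
  expect_equal(extract_region(el, hm$hairpin_right),
               reverse_complement(extract_region(el, hm$hairpin_left)))
  expect_gte(nchar(el$residues) - hm$hairpin_right$end, 6)
  ## detector finds a hairpin containing the written arms
  hp <- find_hairpin(el$residues)
  expect_false(is.null(hp))
  expect_lte(hp$left_arm$start, hm$hairpin_left$start)
  expect_gte(hp$right_arm$end, hm$hairpin_right$end - 1L)

  ## two seeds: identical core, different tails
  el2 <- make_element(cons, 65, seed = 3)
  expect_equal(substr(el$residues, 1, 134), substr(el2$residues, 1, 134))
  expect_false(substr(el$residues, 135, 199) == substr(el2$residues, 135, 199))

  expect_error(make_element(cons, 30), ">= 35")
})

test_that("freshly constructed elements pass the full-length criteria", {
  cons <- default_core_consensus()
  for (seed in 1:15) {
    el <- make_element(cons, 65, seed = seed)
    g <- random_genome(3000, seed = seed + 100)
    pl <- plant_insertions(g, el, 1, seed = seed + 200)
    hit <- data.frame(subject_id = pl$genome$id, start = pl$truth$start,
                      end = pl$truth$end, strand = pl$truth$strand)
    ann <- annotate_element(hit, pl$genome, cons)
    expect_true(ann$full_length, info = paste("seed", seed))
  }
})

test_that("mutation respects rates, protection and bookkeeping", {
  cons <- default_core_consensus()
  el <- make_element(cons, 65, seed = 5)

  same <- mutate_sequence(el, 0, 0, seed = 1)
  expect_equal(same$residues, el$residues)
  expect_equal(attr(same, "n_substitutions"), 0L)

  m <- mutate_sequence(el, 0.05, 0, seed = 3)
  nd <- sum(strsplit(m$residues, "")[[1]] != strsplit(el$residues, "")[[1]])
  expect_equal(nd, attr(m, "n_substitutions"))

  ## protected hallmarks survive heavy mutation
  hm <- attr(el, "hallmarks")
  prot <- list(hm$tc, hm$hairpin_left, hm$hairpin_right, hm$ctrr, hm$ctry)
  mh <- mutate_sequence(el, 0.5, 0, seed = 7, protect = prot)
  expect_equal(substr(mh$residues, 1, 2), "TC")
  expect_true(iupac_match(extract_region(mh, hm$ctry), "CTRY"))
  expect_equal(extract_region(mh, hm$hairpin_right),
               reverse_complement(extract_region(mh, hm$hairpin_left)))

  expect_error(mutate_sequence(el, 1.2), "\\[0,1\\]")
})

test_that("identity after light mutation stays near its expectation", {
  set.seed(6)
  base <- dna_record("b", random_seq(134))
  ids <- vapply(1:40, function(i) {
    m <- mutate_sequence(base, 0.02, 0, seed = 1000 + i)
    identity_excluding_indels(global_align(base, m))
  }, numeric(1))
  expect_gte(mean(ids >= 0.95), 0.9)
  expect_lt(abs(mean(ids) - 0.98), 0.02)
})

test_that("planting conserves genome length and the A^T junction", {
  g <- random_genome(50000, seed = 8)
  el <- make_element(default_core_consensus(), 65, seed = 9)
  pl <- plant_insertions(g, el, 5, seed = 10)
  expect_equal(nchar(pl$genome$residues),
               nchar(g$residues) + 5 * nchar(el$residues))
  expect_equal(nrow(pl$truth), 5)
  s <- pl$genome$residues
  for (i in 1:5) {
    tr <- pl$truth[i, ]
    ## host base before the element is A and after is T (plus orientation)
    expect_equal(substr(s, tr$start, tr$start), "A")
    expect_equal(substr(s, tr$end + 1, tr$end + 1), "T")
    planted <- substr(s, tr$start + 1, tr$end)
    if (tr$strand == "-") planted <- reverse_complement(planted)
    expect_equal(planted, el$residues)
  }

  ## n = 0 leaves the genome untouched
  pl0 <- plant_insertions(g, el, 0, seed = 1)
  expect_equal(pl0$genome$residues, g$residues)
  expect_equal(nrow(pl0$truth), 0)

  expect_error(plant_insertions(random_genome(1000, seed = 2), el, 20,
                                seed = 3), "insufficient AT")
})

test_that("the full pipeline recovers planted copies from simulated genomes", {
  sim <- simulate_genome(genome_length = 1e5, n_insertions = 20,
                         sub_rate = 0.10, seed = 31)
  expect_equal(nrow(sim$truth), 20)
  hits <- find_candidates(sim$element, sim$genome)
  found <- vapply(seq_len(nrow(sim$truth)), function(i)
    any(hits$start < sim$truth$end[i] & hits$end > sim$truth$start[i]),
    logical(1))
  expect_gte(mean(found), 0.95)
  ## annotations of detected copies are full length (hallmarks protected)
  anns <- annotate_genome(sim$genome, sim$element, default_core_consensus())
  expect_gte(mean(vapply(anns, `[[`, TRUE, "full_length")), 0.9)
})

test_that("clade simulation tracks the host tree without HT", {
  tr <- ape::read.tree(
    text = "(((A:0.05,B:0.05):0.04,C:0.08):0.04,(D:0.08,(E:0.05,F:0.05):0.04):0.04);")
  el <- make_element(default_core_consensus(), 311, seed = 21)
  res <- simulate_clade(tr, el, seed = 17)
  expect_setequal(names(res$elements), tr$tip.label)
  D <- ape::cophenetic.phylo(tr)
  L <- nchar(el$residues)
  for (pair in list(c("A", "B"), c("A", "F"), c("C", "D"))) {
    p <- global_align(res$elements[[pair[1]]], res$elements[[pair[2]]])
    obs <- p_distance(p)
    expected <- 0.75 * (1 - exp(-4 * D[pair[1], pair[2]] / 3))
    se <- sqrt(expected * (1 - expected) / L)
    expect_lt(abs(obs - expected), 3 * se + 1e-9,
              label = paste(pair, collapse = "-"))
  }
  ## reproducibility
  res2 <- simulate_clade(tr, el, seed = 17)
  expect_identical(vapply(res2$elements, `[[`, "", "residues"),
                   vapply(res$elements, `[[`, "", "residues"))
})

test_that("an HT event makes the pair more similar than the host path predicts", {
  tr <- ape::read.tree(
    text = "(((A:0.5,B:0.05):0.05,C:0.05):0.05,(D:0.05,(E:0.05,F:0.5):0.05):0.05);")
  el <- make_element(default_core_consensus(), 311, seed = 22)
  ht <- list(list(donor = "A", recipient = "F",
                  donor_frac = 0.96, recipient_frac = 0))
  res <- simulate_clade(tr, el, ht_events = ht, seed = 23)
  D <- ape::cophenetic.phylo(tr)
  pAF <- p_distance(global_align(res$elements$A, res$elements$F))
  host_pAF <- 0.75 * (1 - exp(-4 * D["A", "F"] / 3))
  expect_lt(pAF, host_pAF - 0.1)
  expect_true(res$truth$received_ht[res$truth$taxon == "F"])
  expect_error(simulate_clade(tr, el,
                              ht_events = list(list(donor = "Z", recipient = "F",
                                                    donor_frac = 0.5,
                                                    recipient_frac = 0))),
               "tip labels")
})
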