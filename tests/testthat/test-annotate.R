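## A hallmark-complete plant with known truth, used across boundary tests.
make_plant <- function(seed = 4, acquired = 65, genome_len = 6000,
                       minus = FALSE) {
  g <- random_genome(genome_len, seed = seed)
  el <- make_element(default_core_consensus(), acquired, seed = seed + 1)
  pl <- plant_insertions(g, el, 1, seed = seed + 2,
                         minus_strand_prob = as.numeric(minus))
  list(genome = pl$genome, element = el, truth = pl$truth)
}

test_that("boundaries trimmed short of a hallmarked plant refine to truth", {
  for (minus in c(FALSE, TRUE)) {
    pl <- make_plant(minus = minus)
    hit <- data.frame(subject_id = pl$genome$id,
                      start = pl$truth$start + 7L, end = pl$truth$end - 7L,
                      strand = pl$truth$strand)
    iv <- suppressWarnings(refine_boundaries(hit, pl$genome))
    expect_equal(iv$start, pl$truth$start)
    expect_equal(iv$end, pl$truth$end)
    expect_true(attr(iv, "refined_5p"))
    expect_true(attr(iv, "refined_3p"))
  }
})

test_that("hits without junction context keep their raw boundaries", {
  set.seed(42)
  ## a window guaranteed free of A+TC / CTRY+T context: all-C subject
  genome <- dna_record("g", strrep("C", 2000))
  hit <- data.frame(subject_id = "g", start = 900L, end = 1100L, strand = "+")
  iv <- suppressWarnings(refine_boundaries(hit, genome))
  expect_equal(c(iv$start, iv$end), c(900L, 1100L))
  expect_false(attr(iv, "refined_5p"))
  expect_false(attr(iv, "refined_3p"))
})

test_that("a plant at the contig edge warns of truncated flank", {
  pl <- make_plant(genome_len = 900)   # everything is within 500 bp of an edge
  hit <- data.frame(subject_id = pl$genome$id, start = pl$truth$start,
                    end = pl$truth$end, strand = pl$truth$strand)
  expect_warning(refine_boundaries(hit, pl$genome, flank = 500), "truncated")
  ## explicit edge case: hit at position 0, no upstream flank at all
  el <- make_element(default_core_consensus(), 65, seed = 30)
  g2 <- dna_record("g2", paste0(el$residues, "T", random_seq(1000)))
  hit2 <- data.frame(subject_id = "g2", start = 0L,
                     end = nchar(el$residues), strand = "+")
  expect_warning(refine_boundaries(hit2, g2), "truncated")
})

test_that("terminal motif detection matches the motif definitions", {
  expect_equal(unname(detect_termini("TCAAAAACTGC")), c(TRUE, TRUE))
  expect_equal(unname(detect_termini("TCAAAAACTTA")), c(TRUE, FALSE))
  expect_equal(unname(detect_termini("GCAAAAACTAT")), c(FALSE, TRUE))
  expect_error(detect_termini("TCAppp"), "invalid")
  expect_error(detect_termini("TCA"), "too short")
})

test_that("hairpin search finds the constructed inverted repeat", {
  ## last 40 bp contain GCATGCAT + AAAA + revcomp(GCATGCAT)
  left <- "GCATGCAT"; loop <- "AAAA"; right <- reverse_complement(left)
  el <- paste0(strrep("T", 60), "GG", left, loop, right, strrep("G", 6),
               "CTAC")
  hp <- find_hairpin(el)
  expect_false(is.null(hp))
  ## the written 8-bp-arm palindrome is found (possibly extended by one
  ## tolerated-mismatch position under the arm-length-first ranking)
  written_left <- c(62L, 70L)       # 0-based [start, end) of the written arm
  expect_gte(lepscan:::interval_length(hp$left_arm), 8L)
  expect_lte(hp$mismatches, 1L)
  expect_true(hp$left_arm$start <= written_left[1] &&
                hp$left_arm$end >= written_left[2] - 1L)
  ora <- oracle_hairpin(el)
  expect_equal(lepscan:::interval_length(hp$left_arm), ora$arm)
  expect_equal(hp$mismatches, ora$mismatches)

  expect_null(find_hairpin(paste0(strrep("G", 60), strrep("A", 50))))
})

test_that("the longer of two candidate hairpins wins", {
  arm6 <- "ACGTAC"; arm9 <- "GACTGACTG"
  el <- paste0(strrep("T", 60),
               arm6, "AA", reverse_complement(arm6), "CC",
               arm9, "AAA", reverse_complement(arm9), "GCTAC")
  hp <- find_hairpin(el)
  expect_gte(lepscan:::interval_length(hp$left_arm), 9L)
  ora <- oracle_hairpin(el)
  expect_equal(lepscan:::interval_length(hp$left_arm), ora$arm)
  expect_equal(hp$left_arm$start, ora$left_start)
  ## the arm-9 repeat region, not the arm-6 one, holds the winner
  expect_gte(hp$left_arm$start, 70L)
})

test_that("hairpin search agrees with brute-force enumeration on random 100-mers", {
  set.seed(1234)
  for (i in 1:60) {
    s <- random_seq(100)
    hp <- find_hairpin(s)
    ora <- oracle_hairpin(s)
    if (is.null(ora)) {
      expect_null(hp)
    } else {
      expect_false(is.null(hp))
      expect_equal(lepscan:::interval_length(hp$left_arm), ora$arm)
      expect_equal(hp$mismatches, ora$mismatches)
      expect_equal(hp$left_arm$start, ora$left_start)
      expect_equal(hp$right_arm$start, ora$right_start)
    }
  }
})

test_that("A^T junction test reads the terminal flank bases", {
  expect_true(check_at_junction("GGGA", "TCCC"))
  expect_false(check_at_junction("GGGC", "TCCC"))
  expect_false(check_at_junction("GGGA", "ACCC"))
  expect_error(check_at_junction("", "TCC"), "empty flank")
})

test_that("TSD detection respects the k range", {
  up <- paste0(random_seq(14), "TTAACG")
  dn <- paste0("TTAACG", random_seq(14))
  set.seed(7)
  expect_true(detect_tsd(up, dn))
  expect_equal(attr(detect_tsd(up, dn), "kmer"), "TTAACG")
  expect_false(detect_tsd(random_seq(20), random_seq(20)))
  ## duplication of length 3 only is below k_min
  up3 <- paste0(random_seq(17), "ACG")
  dn3 <- paste0("ACG", random_seq(17))
  if (substr(dn3, 4, 4) == substr(up3, 17, 17)) dn3 <- paste0("ACGT", random_seq(16))
  expect_false(detect_tsd(up3, dn3))
  expect_warning(detect_tsd("AAAA", "AAAA"), "up to k = 4")
})

test_that("core/acquired delineation matches construction", {
  cons <- default_core_consensus()
  el <- make_element(cons, 65, seed = 3)
  d <- delineate_acquired(el, cons)
  expect_equal(c(d$core_iv$start, d$core_iv$end), c(0L, 134L))
  expect_equal(c(d$acquired_iv$start, d$acquired_iv$end), c(134L, 199L))
  expect_true(d$ctrr_in_acquired)
  expect_equal(d$identity_to_consensus, 1.0)

  ## acquired tail lacking CTRR
  el2 <- paste0(cons$residues, strrep("T", 60), "CTGC")
  d2 <- delineate_acquired(el2, cons)
  expect_false(d2$ctrr_in_acquired)

  ## 14 substitutions in the core, no indels
  set.seed(8)
  core_mut <- mutate_oracle(cons$residues, 14)
  d3 <- delineate_acquired(paste0(core_mut, strrep("A", 40), "CTGACTAC"), cons)
  expect_equal(d3$identity_to_consensus, 120 / 134, tolerance = 0.02)

  expect_error(delineate_acquired(random_seq(200), cons), "not a Lep1")
})

test_that("annotation composes all hallmark tests into a full-length call", {
  pl <- make_plant(seed = 15)
  hits <- find_candidates(pl$element, pl$genome)
  expect_equal(nrow(hits), 1)
  ann <- annotate_element(hits[1, ], pl$genome, default_core_consensus())
  expect_true(ann$full_length)
  expect_true(ann$five_prime_tc && ann$three_prime_ctry)
  expect_true(ann$ctrr_in_acquired)
  expect_true(ann$at_junction)
  expect_false(ann$tsd_detected)
  expect_false(is.null(ann$hairpin))
  expect_equal(lepscan:::interval_length(ann$element_iv),
               lepscan:::interval_length(ann$core_iv) +
                 lepscan:::interval_length(ann$acquired_iv))

  ## mutate the 3' terminus to CTTA: not full length
  s <- pl$genome$residues
  e <- pl$truth$end
  mut <- paste0(substr(s, 1, e - 2), "TA", substr(s, e + 1, nchar(s)))
  g2 <- dna_record(pl$genome$id, mut)
  hit2 <- data.frame(subject_id = pl$genome$id, start = pl$truth$start,
                     end = pl$truth$end, strand = "+")
  ann2 <- annotate_element(hit2, g2, default_core_consensus(), window = 0L)
  expect_false(ann2$three_prime_ctry)
  expect_false(ann2$full_length)
})

test_that("a contig-edge element gets an undetermined junction and is not full length", {
  el <- make_element(default_core_consensus(), 65, seed = 6)
  g <- dna_record("edge", paste0(el$residues, "T", random_seq(2000)))
  hit <- data.frame(subject_id = "edge", start = 0L,
                    end = nchar(el$residues), strand = "+")
  ann <- annotate_element(hit, g, default_core_consensus())
  expect_true(is.na(ann$at_junction))
  expect_false(ann$full_length)
})

test_that("refined boundaries stay within 2 bp of truth for most divergent copies", {
  sim <- simulate_genome(genome_length = 1.3e5, n_insertions = 30,
                         sub_rate = 0.10, seed = 27)
  hits <- find_candidates(sim$element, sim$genome)
  ok <- 0L; detected <- 0L
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    m <- which(hits$start < tr$end & hits$end > tr$start)
    if (!length(m)) next
    detected <- detected + 1L
    iv <- refine_boundaries(hits[m[1], ], sim$genome)
    if (abs(iv$start - tr$start) <= 2 && abs(iv$end - tr$end) <= 2)
      ok <- ok + 1L
  }
  expect_gte(detected / nrow(sim$truth), 0.95)
  expect_gte(ok / detected, 0.9)
})
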