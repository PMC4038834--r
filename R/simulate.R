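## Synthetic genomes with planted, hallmark-complete elements and exact
## ground truth; vertical-descent and horizontal-transfer scenarios.
##
## Generator regime (the conditions the rest of the package is tested
## against): insect-like AT-rich background (GC 0.35), a 134-bp core
## consensus plus a 65-bp acquired tail by default, per-copy divergence
## defaulting to 2% substitutions (the within-family identity regime of
## recently active copies), insertion precisely between a host A and T with
## no target-site duplication. Hallmark motif positions are by default
## protected from mutation: real copies of this family almost always retain
## their termini, so a generator of hallmark-complete copies holds the
## motifs fixed while the rest of the copy diverges.

#' Random host background sequence
#'
#' i.i.d. bases with the requested GC fraction; reproducible per seed.
#'
#' @param length Sequence length (bp).
#' @param gc_fraction P(G) + P(C), default 0.35 (insect-like).
#' @param seed Integer seed.
#' @param id Record id.
#' @return A `dna_record`.
#' @export
random_genome <- function(length, gc_fraction = 0.35, seed = 1L,
                          id = "synthetic_genome") {
  if (length <= 0) stop("length must be positive")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0,1]")
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  dna_record(id, paste(sample(names(p), length, replace = TRUE, prob = p),
                       collapse = ""),
             description = sprintf("synthetic background gc=%.2f seed=%d",
                                   gc_fraction, seed))
}

#' Construct a hallmark-complete synthetic element
#'
#' The element is the core consensus (forced to start `TC`) followed by a
#' random acquired tail carrying, from 5' to 3': a perfect 8-bp-arm /
#' 4-bp-loop hairpin ending at least 6 bp before the terminus, a `CTRR`
#' 4-mer within the last 15 bp, and a `CTRY` terminal 4-mer.
#'
#' @param consensus Core consensus `dna_record` or string.
#' @param acquired_length Acquired-tail length (>= 35 for the default
#'   hairpin geometry; default 65).
#' @param seed Integer seed.
#' @param id Record id.
#' @return A `dna_record` with attribute `hallmarks`: element-local 0-based
#'   intervals/positions of every written motif (`tc`, `ctry`, `ctrr`,
#'   `hairpin_left`, `hairpin_right`, `core_end`).
#' @export
make_element <- function(consensus, acquired_length = 65L, seed = 1L,
                         id = "synthetic_element") {
  core <- seq_chars(consensus)
  if (acquired_length < 35L)
    stop("acquired_length must be >= 35 to fit hairpin + CTRR + CTRY")
  if (substr(core, 1, 2) != "TC")
    core <- paste0("TC", substr(core, 3, nchar(core)))
  set.seed(seed)
  L <- acquired_length
  tail_ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  ## terminal CTRY (1-based tail positions L-3..L)
  tail_ch[(L - 3):L] <- c("C", "T", sample(c("A", "G"), 1), sample(c("C", "T"), 1))
  ## CTRR inside the last 15 bp, clear of the terminal tetramer
  ctrr_start <- L - 11L                    # occupies L-11..L-8
  tail_ch[ctrr_start:(ctrr_start + 3)] <- c("C", "T", sample(c("A", "G"), 1),
                                            sample(c("A", "G"), 1))
  ## perfect hairpin: 8 bp arm + 4 bp loop + 8 bp arm, ending >= 6 bp
  ## before the terminus and clear of the CTRR
  hp_end <- ctrr_start - 3L                # 1-based tail pos of right-arm end
  hp_start <- hp_end - 19L
  if (hp_start < 1L) stop("acquired tail too short for hairpin geometry")
  left <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
  loop <- sample(c("A", "C", "G", "T"), 4, replace = TRUE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  right <- rev(unname(comp[left]))
  tail_ch[hp_start:hp_end] <- c(left, loop, right)
  tail_str <- paste(tail_ch, collapse = "")
  seqs <- paste0(core, tail_str)
  nc <- nchar(core)
  off <- nc                                 # 0-based offset of the tail
  hallmarks <- list(
    tc = interval(id, 0L, 2L),
    core_end = nc,
    hairpin_left = interval(id, off + hp_start - 1L, off + hp_start + 7L),
    hairpin_right = interval(id, off + hp_end - 8L, off + hp_end),
    ctrr = interval(id, off + ctrr_start - 1L, off + ctrr_start + 3L),
    ctry = interval(id, off + L - 4L, off + L))
  rec <- dna_record(id, seqs,
                    description = sprintf("synthetic element core=%d acquired=%d seed=%d",
                                          nc, L, seed))
  attr(rec, "hallmarks") <- hallmarks
  rec
}

#' Mutate a sequence with substitutions and indels
#'
#' Per-site substitution with probability `sub_rate` (uniform over the three
#' alternative bases) and per-site indel initiation with probability
#' `indel_rate` (insertion or deletion equally likely; lengths geometric
#' with mean 2). Positions inside `protect` intervals are immune to
#' substitution and indel initiation, and deletions never extend into them.
#'
#' @param seq `dna_record` or string.
#' @param sub_rate,indel_rate Per-site rates in \[0, 1\].
#' @param seed Integer seed.
#' @param protect Optional list of element-local 0-based [interval()]s (or
#'   integer positions) never altered.
#' @return A `dna_record`; attributes `n_substitutions` and `n_indels`
#'   record the realised event counts.
#' @export
mutate_sequence <- function(seq, sub_rate, indel_rate = 0, seed = 1L,
                            protect = NULL) {
  s <- seq_chars(seq)
  if (sub_rate < 0 || sub_rate > 1 || indel_rate < 0 || indel_rate > 1)
    stop("rates must be fractions in [0,1]")
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  prot <- rep(FALSE, n)
  if (!is.null(protect)) {
    for (pv in protect) {
      if (inherits(pv, "interval")) prot[(pv$start + 1L):pv$end] <- TRUE
      else prot[pv + 1L] <- TRUE        # 0-based positions
    }
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  sub_at <- which(stats::runif(n) < sub_rate & !prot & ch %in% bases)
  for (i in sub_at) ch[i] <- sample(setdiff(bases, ch[i]), 1)
  n_indel <- 0L
  if (indel_rate > 0) {
    ind_at <- which(stats::runif(n) < indel_rate & !prot)
    for (i in rev(ind_at)) {           # apply 3'->5' to keep positions valid
      len <- stats::rgeom(1, 0.5) + 1L
      if (stats::runif(1) < 0.5) {     # insertion after position i
        ins <- sample(bases, len, replace = TRUE)
        ch <- append(ch, ins, after = i)
      } else {                         # deletion of up to len sites from i
        last <- min(i + len - 1L, length(ch))
        span <- i:last
        span <- span[!prot[pmin(span, n)]]
        if (!length(span)) next
        ch <- ch[-span]
      }
      n_indel <- n_indel + 1L
    }
  }
  out <- dna_record(id_of(seq, "mutated"), paste(ch, collapse = ""),
                    description = sprintf("mutated sub=%g indel=%g seed=%d",
                                          sub_rate, indel_rate, seed))
  attr(out, "n_substitutions") <- length(sub_at)
  attr(out, "n_indels") <- n_indel
  out
}

#' Plant element copies between host A and T nucleotides
#'
#' Each copy is inserted precisely between the A and T of a chosen `AT`
#' dinucleotide (so the upstream flank ends `...A` and the downstream flank
#' begins `T...`), creating no target-site duplication. Copies are
#' non-overlapping with at least `flank_min` clearance.
#'
#' @param genome Host `dna_record`.
#' @param elements A single `dna_record` (planted `n` times) or a list of
#'   length `n` of per-copy records.
#' @param n Number of insertions.
#' @param flank_min Minimum clearance between insertion sites and from
#'   contig ends (default 150).
#' @param seed Integer seed.
#' @param minus_strand_prob Probability a copy is planted in reverse
#'   orientation (default 0.5).
#' @return List with `genome` (the new `dna_record`) and `truth`, a
#'   data.frame of [TruthRecord]-style rows: `element_id`, `start`, `end`
#'   (0-based half-open, final coordinates), `strand`,
#'   `divergence_applied`, `junction_up`, `junction_down`.
#' @export
plant_insertions <- function(genome, elements, n, flank_min = 150L, seed = 1L,
                             minus_strand_prob = 0.5) {
  g <- seq_chars(genome)
  L <- nchar(g)
  if (inherits(elements, "dna_record")) elements <- rep(list(elements), n)
  stopifnot(length(elements) == n)
  if (n == 0L)
    return(list(genome = genome,
                truth = data.frame(element_id = character(), start = integer(),
                                   end = integer(), strand = character(),
                                   divergence_applied = numeric(),
                                   junction_up = character(),
                                   junction_down = character(),
                                   stringsAsFactors = FALSE)))
  at <- gregexpr("AT", g, fixed = TRUE)[[1]]
  at <- at[at > flank_min & at < L - flank_min]
  if (length(at) < n) stop("insufficient AT dinucleotide sites with clearance")
  set.seed(seed)
  chosen <- integer(0)
  for (p in sample(at)) {
    if (all(abs(p - chosen) >= flank_min)) chosen <- c(chosen, p)
    if (length(chosen) == n) break
  }
  if (length(chosen) < n)
    stop("insufficient AT sites after enforcing spacing; lengthen the genome")
  chosen <- sort(chosen)
  strands <- ifelse(stats::runif(n) < minus_strand_prob, "-", "+")
  ## insertion point: after the A at 1-based position p
  segs <- character(0); truth <- list(); prev <- 1L; offset <- 0L
  for (i in seq_len(n)) {
    p <- chosen[i]
    el <- seq_chars(elements[[i]])
    ins <- if (strands[i] == "+") el else reverse_complement(el)
    segs <- c(segs, substr(g, prev, p), ins)
    start0 <- p + offset                   # 0-based start of the copy
    nsub <- attr(elements[[i]], "n_substitutions")
    truth[[i]] <- data.frame(
      element_id = sprintf("%s_copy%03d", id_of(elements[[i]], "element"), i),
      start = start0, end = start0 + nchar(ins), strand = strands[i],
      divergence_applied = if (is.null(nsub)) 0
                           else nsub / nchar(el),
      junction_up = "A", junction_down = "T", stringsAsFactors = FALSE)
    offset <- offset + nchar(ins)
    prev <- p + 1L
  }
  segs <- c(segs, substr(g, prev, L))
  out <- dna_record(id_of(genome, "genome"), paste(segs, collapse = ""),
                    description = sprintf("%s +%d planted copies",
                                          if (inherits(genome, "dna_record"))
                                            genome$description else "",
                                          n))
  list(genome = out, truth = do.call(rbind, truth))
}

#' Default synthetic core consensus
#'
#' A fixed 134-bp synthetic stand-in for the family core consensus (the real
#' consensus is not redistributed here); deterministic, starts `TC`.
#'
#' @return A `dna_record` of length 134.
#' @export
default_core_consensus <- function() {
  path <- system.file("extdata", "core_consensus_synthetic.fasta",
                      package = "lepscan")
  read_fasta(path)[[1]]
}

#' Simulate a host genome with planted divergent element copies
#'
#' End-to-end generator: background genome, a hallmark-complete founder
#' element, `n_insertions` independently mutated copies, planted at A^T
#' sites. With `protect_hallmarks = TRUE` (default) the hallmark motif
#' positions of each copy are held fixed while the rest diverges, yielding
#' hallmark-complete copies at the requested divergence.
#'
#' @param genome_length,gc_fraction Background parameters.
#' @param n_insertions Number of planted copies.
#' @param consensus Core consensus (default [default_core_consensus()]).
#' @param acquired_length Acquired-tail length (default 65).
#' @param sub_rate Per-copy substitution rate (default 0.02, the
#'   recently-active within-family regime).
#' @param indel_rate Per-copy indel initiation rate (default 0).
#' @param flank_min Insertion-site clearance (default 150).
#' @param protect_hallmarks Hold hallmark motifs fixed under mutation.
#' @param seed Integer seed governing every random choice.
#' @return List: `genome` (`dna_record`), `element` (founder, with
#'   `hallmarks` attribute), `copies` (list of mutated copies), `truth`
#'   (data.frame as in [plant_insertions()]).
#' @export
simulate_genome <- function(genome_length = 1e5, gc_fraction = 0.35,
                            n_insertions = 20L,
                            consensus = default_core_consensus(),
                            acquired_length = 65L, sub_rate = 0.02,
                            indel_rate = 0, flank_min = 150L,
                            protect_hallmarks = TRUE, seed = 1L) {
  need <- n_insertions *
    (nchar(seq_chars(consensus)) + acquired_length + 2 * flank_min)
  if (genome_length < need)
    stop(sprintf("genome_length %g too small for %d insertions (need >= %g)",
                 genome_length, n_insertions, need))
  genome <- random_genome(genome_length, gc_fraction, seed = seed)
  founder <- make_element(consensus, acquired_length, seed = seed + 1L)
  hm <- attr(founder, "hallmarks")
  protect <- if (protect_hallmarks)
    list(hm$tc, hm$hairpin_left, hm$hairpin_right, hm$ctrr, hm$ctry) else NULL
  copies <- lapply(seq_len(n_insertions), function(i)
    mutate_sequence(founder, sub_rate, indel_rate, seed = seed + 1L + i,
                    protect = protect))
  planted <- plant_insertions(genome, copies, n_insertions,
                              flank_min = flank_min, seed = seed)
  list(genome = planted$genome, element = founder, copies = copies,
       truth = planted$truth)
}

#' Simulate element evolution over a host clade, with horizontal transfer
#'
#' The element evolves down the (rooted) host tree; each branch applies
#' substitutions at a rate equal to its length (substitutions per site). An
#' HT event copies the donor lineage's element state at a point along the
#' donor's terminal branch into the recipient's terminal branch, replacing
#' the recipient's element, which then evolves for the remainder of its
#' branch. Each taxon's final element is planted in a small host genome.
#'
#' @param host_tree Rooted `phylo` with branch lengths in substitutions/site.
#' @param element Founder `dna_record` at the root.
#' @param ht_events List of lists with fields `donor`, `recipient` (tip
#'   labels), `donor_frac`, `recipient_frac` (fractions of the respective
#'   terminal branches completed at the moment of transfer).
#' @param seed Integer seed.
#' @param genome_length Per-taxon host genome length (default 5000).
#' @return List: `elements` (named list of per-taxon `dna_record`s),
#'   `genomes` (named list, each with the element planted), `truth`
#'   (data.frame: taxon, element interval, strand, ht flag).
#' @export
simulate_clade <- function(host_tree, element, ht_events = list(), seed = 1L,
                           genome_length = 5000L) {
  tree <- host_tree
  nt <- length(tree$tip.label)
  for (ev in ht_events) {
    if (!ev$donor %in% tree$tip.label || !ev$recipient %in% tree$tip.label)
      stop("HT donor/recipient must reference tip labels")
    if (ev$donor == ev$recipient) stop("HT recipient must differ from donor")
  }
  donors <- vapply(ht_events, `[[`, "", "donor")
  recipients <- vapply(ht_events, `[[`, "", "recipient")
  if (any(donors %in% recipients))
    stop("chained HT (a donor that is also a recipient) is not supported")
  root <- nt + 1L
  states <- vector("list", nt + tree$Nnode)
  states[[root]] <- element
  edges <- tree$edge
  ## preorder: sort edges by depth of child node
  depth <- rep(NA_real_, nt + tree$Nnode); depth[root] <- 0
  while (anyNA(depth[edges[, 2]]))
    for (e in seq_len(nrow(edges)))
      if (!is.na(depth[edges[e, 1]])) depth[edges[e, 2]] <- depth[edges[e, 1]] + 1
  ord <- order(depth[edges[, 2]])
  counter <- 0L
  next_seed <- function() { counter <<- counter + 1L; seed * 1000L + counter }
  donor_mid <- list()  # element state at the transfer point, per event
  ## pass 1: everything except recipient terminal branches; donor branches
  ## are simulated in two segments so the transferred state is the donor's
  ## actual state at the transfer point
  for (e in ord) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    bl <- tree$edge.length[e]
    tip_lab <- if (ch <= nt) tree$tip.label[ch] else ""
    if (nzchar(tip_lab) && tip_lab %in% recipients) next
    if (nzchar(tip_lab) && tip_lab %in% donors) {
      k <- which(donors == tip_lab)[1]
      frac <- ht_events[[k]]$donor_frac
      mid <- mutate_sequence(states[[p]], pexp_rate(bl * frac),
                             seed = next_seed())
      donor_mid[[tip_lab]] <- mid
      states[[ch]] <- mutate_sequence(mid, pexp_rate(bl * (1 - frac)),
                                      seed = next_seed())
    } else {
      states[[ch]] <- mutate_sequence(states[[p]], pexp_rate(bl),
                                      seed = next_seed())
    }
  }
  ## pass 2: recipient terminal branches restart from the transferred state
  for (ev in ht_events) {
    ch <- match(ev$recipient, tree$tip.label)
    e <- which(edges[, 2] == ch)
    bl <- tree$edge.length[e]
    states[[ch]] <- mutate_sequence(donor_mid[[ev$donor]],
                                    pexp_rate(bl * (1 - ev$recipient_frac)),
                                    seed = next_seed())
  }
  elements <- stats::setNames(lapply(seq_len(nt), function(i) {
    r <- states[[i]]; r$id <- tree$tip.label[i]; r
  }), tree$tip.label)
  genomes <- list(); truth <- list()
  ht_recipients <- vapply(ht_events, `[[`, "", "recipient")
  for (i in seq_len(nt)) {
    g <- random_genome(genome_length, seed = next_seed(),
                       id = paste0(tree$tip.label[i], "_genome"))
    planted <- plant_insertions(g, elements[[i]], 1L, flank_min = 150L,
                                seed = next_seed(), minus_strand_prob = 0)
    genomes[[tree$tip.label[i]]] <- planted$genome
    truth[[i]] <- data.frame(taxon = tree$tip.label[i],
                             start = planted$truth$start,
                             end = planted$truth$end,
                             strand = planted$truth$strand,
                             received_ht = tree$tip.label[i] %in% ht_recipients,
                             stringsAsFactors = FALSE)
  }
  list(elements = elements, genomes = genomes, truth = do.call(rbind, truth))
}

## expected substitutions/site -> per-site substitution probability under
## uniform (Jukes-Cantor) multiple-hit dynamics
pexp_rate <- function(d) {
  if (d <= 0) return(0)
  0.75 * (1 - exp(-4 * d / 3))
}
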