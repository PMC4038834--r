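## In-silico insertion-polymorphism assessment (chimeric empty-site queries)
## and horizontal-transfer evidence scoring.

#' Build a chimeric empty-site query
#'
#' Concatenates about `flank` bp of host sequence immediately upstream and
#' downstream of an element insertion (in the element's orientation),
#' producing the roughly 200-bp junction query used to detect orthologous or
#' paralogous empty sites. Truncated at contig ends with a warning.
#'
#' @param genome Host `dna_record`.
#' @param element_iv [interval()] of the element on the genome.
#' @param flank Flank length each side (default 100).
#' @return A `dna_record`; its id records the junction coordinate and the
#'   attribute `junction` gives the 0-based position of the junction within
#'   the query.
#' @export
build_chimeric_query <- function(genome, element_iv, flank = 100L) {
  s <- seq_chars(genome)
  L <- nchar(s)
  iv <- element_iv
  if (iv$start < 0L || iv$end > L)
    stop(sprintf("element interval [%d,%d) out of bounds (length %d)",
                 iv$start, iv$end, L))
  if (iv$strand == "+") {
    u0 <- max(0L, iv$start - flank)
    up <- if (iv$start > 0L)
      extract_region(genome, interval(iv$seq_id, u0, iv$start, "+")) else ""
    d1 <- min(L, iv$end + flank)
    dn <- if (iv$end < L)
      extract_region(genome, interval(iv$seq_id, iv$end, d1, "+")) else ""
  } else {
    up <- if (iv$end < L)
      extract_region(genome, interval(iv$seq_id, iv$end,
                                      min(L, iv$end + flank), "-")) else ""
    dn <- if (iv$start > 0L)
      extract_region(genome, interval(iv$seq_id, max(0L, iv$start - flank),
                                      iv$start, "-")) else ""
  }
  if (nchar(up) < flank || nchar(dn) < flank)
    warning("chimeric query truncated at contig end", call. = FALSE)
  if (!nzchar(up) && !nzchar(dn)) stop("no flanking sequence available")
  id <- sprintf("%s_junction_%d%s", iv$seq_id,
                if (iv$strand == "+") iv$start else iv$end, iv$strand)
  q <- dna_record(id, paste0(up, dn),
                  description = sprintf("chimeric empty-site query (%d+%d bp)",
                                        nchar(up), nchar(dn)))
  attr(q, "junction") <- nchar(up)
  q
}

#' Classify a site as occupied, empty or absent
#'
#' The two halves of a chimeric junction query are aligned locally to the
#' target. The site is `empty` when both halves land contiguously (no
#' intervening target sequence beyond alignment slop), `occupied` when both
#' halves hit with an intervening gap of at least `min_insert` bp (reported
#' as the insert length estimate), and `absent` otherwise.
#'
#' @param query Chimeric `dna_record` from [build_chimeric_query()].
#' @param target Target `dna_record` to search.
#' @param min_identity Minimum identity for a flank hit (default 0.70).
#' @param min_flank_hit Minimum aligned bases required of each flank half
#'   (default 50).
#' @param min_insert Minimum intervening gap called as an insertion
#'   (default 50).
#' @param slop Alignment-end fuzz tolerated when calling contiguity
#'   (default 10).
#' @return List of class `occupancy_call`: `site_id`, `status`, `evidence`
#'   (data.frame of the half-query hits), `insert_length_estimate`.
#' @export
classify_site <- function(query, target, min_identity = 0.70,
                          min_flank_hit = 50L, min_insert = 50L, slop = 10L) {
  j <- attr(query, "junction")
  if (is.null(j)) j <- nchar(seq_chars(query)) %/% 2L
  qs <- seq_chars(query)
  up <- substr(qs, 1L, j)
  dn <- substr(qs, j + 1L, nchar(qs))
  halves <- list(up = up, dn = dn)
  hits <- lapply(halves, function(h) {
    if (!nzchar(h)) return(NULL)
    best <- NULL
    for (strand in c("+", "-")) {
      hq <- if (strand == "+") h else reverse_complement(h)
      a <- local_align(hq, target)
      if (a$score <= 0) next
      ident <- identity_excluding_indels(a)
      naln <- a$a_end - a$a_start
      if (ident < min_identity || naln < min_flank_hit) next
      cand <- list(strand = strand, b_start = a$b_start, b_end = a$b_end,
                   a_start = a$a_start, a_end = a$a_end,
                   identity = ident, score = a$score)
      if (is.null(best) || cand$score > best$score) best <- cand
    }
    best
  })
  ev <- do.call(rbind, lapply(names(hits), function(nm) {
    h <- hits[[nm]]
    if (is.null(h)) return(NULL)
    data.frame(half = nm, strand = h$strand, start = h$b_start, end = h$b_end,
               identity = h$identity, score = h$score,
               stringsAsFactors = FALSE)
  }))
  status <- "absent"; est <- NA_integer_
  hu <- hits$up; hd <- hits$dn
  if (!is.null(hu) && !is.null(hd) && hu$strand == hd$strand) {
    if (hu$strand == "+") {
      gap <- hd$b_start - hu$b_end
      ## bases of the query junction left unaligned contribute fuzz
      fuzz <- (j - hu$a_end) + hd$a_start
    } else {
      gap <- hu$b_start - hd$b_end
      fuzz <- (j - hu$a_end) + hd$a_start
    }
    if (gap >= min_insert) {
      status <- "occupied"
      est <- as.integer(gap - fuzz)
    } else if (gap >= -slop && gap - fuzz <= slop) {
      status <- "empty"
    }
  }
  structure(list(site_id = id_of(query, "site"), status = status,
                 evidence = ev, insert_length_estimate = est),
            class = "occupancy_call")
}

#' @export
print.occupancy_call <- function(x, ...) {
  cat(sprintf("<occupancy_call> %s: %s%s\n", x$site_id, x$status,
              if (!is.na(x$insert_length_estimate))
                sprintf(" (insert ~%d bp)", x$insert_length_estimate) else ""))
  invisible(x)
}

#' Expected identity under vertical inheritance (Jukes-Cantor)
#'
#' Two lineages separated for `T` years accumulate `2 * rate * T` expected
#' substitutions per site; the expected observable identity is
#' `1 - (3/4)(1 - exp(-8 * rate * T / 3))`, saturating at 25%.
#'
#' @param T_years Divergence time of the two hosts (years).
#' @param rate Neutral substitution rate per site per year per lineage
#'   (default 2e-9).
#' @return Expected identity fraction in (0.25, 1\].
#' @export
expected_vertical_identity <- function(T_years, rate = 2e-9) {
  if (any(T_years < 0)) stop("divergence time must be >= 0")
  if (any(rate <= 0)) stop("substitution rate must be > 0")
  1 - 0.75 * (1 - exp(-8 * rate * T_years / 3))
}

#' Score a taxon pair for horizontal-transfer evidence
#'
#' Flags the pair when the observed element identity exceeds the identity
#' expected under vertical inheritance at the hosts' divergence time by more
#' than `margin`. The qualitative argument of the source analysis is made
#' explicit: conclusions must be reported together with the rate and margin
#' used.
#'
#' @param observed_identity Identity fraction between the elements of the
#'   two taxa (excluding indels).
#' @param T_years Host divergence time in years.
#' @param rate Substitution rate per site per year per lineage.
#' @param margin Excess identity required to flag (default 0.10).
#' @param taxon_pair Optional length-2 character vector of taxon names.
#' @return List of class `ht_evidence` with fields `taxon_pair`,
#'   `observed_identity`, `divergence_time`, `assumed_rate`,
#'   `expected_identity`, `margin`, `flagged`.
#' @export
flag_ht <- function(observed_identity, T_years, rate = 2e-9, margin = 0.10,
                    taxon_pair = c("taxon1", "taxon2")) {
  if (observed_identity < 0 || observed_identity > 1)
    stop("observed_identity must be a fraction")
  exp_id <- expected_vertical_identity(T_years, rate)
  structure(list(taxon_pair = taxon_pair,
                 observed_identity = observed_identity,
                 divergence_time = T_years,
                 assumed_rate = rate,
                 expected_identity = exp_id,
                 margin = margin,
                 flagged = observed_identity > exp_id + margin),
            class = "ht_evidence")
}

#' @export
print.ht_evidence <- function(x, ...) {
  cat(sprintf(
    "<ht_evidence> %s vs %s: observed %.3f, expected %.3f (T = %.3g y, rate = %.2g), margin %.2f -> %s\n",
    x$taxon_pair[1], x$taxon_pair[2], x$observed_identity,
    x$expected_identity, x$divergence_time, x$assumed_rate, x$margin,
    if (x$flagged) "FLAGGED" else "not flagged"))
  invisible(x)
}

#' Minimum losses under a single-gain (Dollo) model
#'
#' The gain is placed at the most recent common ancestor of the taxa carrying
#' the element; the returned count is the minimum number of loss events on
#' the host tree explaining the presence/absence pattern.
#'
#' @param pam Presence/absence: either a logical matrix (rows = taxa, columns
#'   = elements, with dimnames) or a named logical vector for a single
#'   element.
#' @param host_tree Rooted `phylo` whose tips include the pam taxa.
#' @param element Column name when `pam` is a matrix.
#' @return Non-negative integer count of losses.
#' @export
dollo_loss_count <- function(pam, host_tree, element = NULL) {
  pres <- if (is.matrix(pam) || is.data.frame(pam)) {
    if (is.null(element)) stop("element column must be named")
    stats::setNames(as.logical(pam[, element]), rownames(pam))
  } else {
    stats::setNames(as.logical(pam), names(pam))
  }
  if (!all(names(pres) %in% host_tree$tip.label))
    stop("pam taxa must be a subset of the host tree leaves")
  if (!any(pres)) stop("element absent from every taxon: no gain to place")
  tree <- ape::keep.tip(host_tree, names(pres))
  present <- names(pres)[pres]
  if (length(present) == length(pres)) return(0L)
  if (length(present) == 1L) return(0L)   # gain on the terminal branch
  mrca <- ape::getMRCA(tree, present)
  nt <- length(tree$tip.label)
  ## tip sets below each node (postorder accumulation)
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  edges <- tree$edge
  for (e in ape::postorder(tree)) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  ## a loss = an edge inside the MRCA subtree whose child clade is entirely
  ## absent while its parent's clade is not (maximal all-absent clades)
  losses <- 0L
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    if (!(p == mrca || is_under(tree, p, mrca))) next
    if (!any(pres[desc[[ch]]]) && any(pres[desc[[p]]])) losses <- losses + 1L
  }
  losses
}

## is node `x` strictly below `anc`?
is_under <- function(tree, x, anc) {
  p <- x
  repeat {
    row <- which(tree$edge[, 2] == p)
    if (!length(row)) return(FALSE)
    p <- tree$edge[row[1], 1]
    if (p == anc) return(TRUE)
  }
}

#' Occupancy calls and HT evidence as TSV / presence matrix as CSV
#'
#' @param calls List of `occupancy_call` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occupancy_tsv <- function(calls, path) {
  df <- do.call(rbind, lapply(calls, function(x)
    data.frame(site_id = x$site_id, status = x$status,
               insert_length_estimate = x$insert_length_estimate,
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occupancy_tsv
#' @param evidence List of `ht_evidence` objects.
#' @export
write_ht_tsv <- function(evidence, path) {
  df <- do.call(rbind, lapply(evidence, function(x)
    data.frame(taxon_a = x$taxon_pair[1], taxon_b = x$taxon_pair[2],
               observed_identity = x$observed_identity,
               divergence_time = x$divergence_time,
               assumed_rate = x$assumed_rate,
               expected_identity = x$expected_identity,
               margin = x$margin, flagged = x$flagged,
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occupancy_tsv
#' @param pam Logical presence/absence matrix.
#' @export
write_presence_csv <- function(pam, path) {
  utils::write.csv(data.frame(taxon = rownames(pam), pam,
                              check.names = FALSE, stringsAsFactors = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
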