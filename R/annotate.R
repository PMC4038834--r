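## Structural annotation of candidate hits: boundary refinement against the
## A^TC ... CTRY^T junction context, terminal motifs, the subterminal
## palindromic hairpin, target-site-duplication screening, and delineation of
## the conserved core vs the 3' acquired sequence.

#' Refine element boundaries around a candidate hit
#'
#' The element start is the position nearest the hit 5' end (within
#' `window`) where the element begins `TC` with the preceding host base `A`;
#' the element end is the position nearest the hit 3' end where the element
#' ends on a `CTRY` followed by host `T` (the rolling-circle junction
#' context). Ends lacking such context keep the raw hit boundary. All
#' searches are performed in the element's own orientation for minus-strand
#' hits.
#'
#' @param hit One row of a `lep_hits` data.frame (or an equivalent list with
#'   `start`, `end`, `strand`).
#' @param subject The subject `dna_record`.
#' @param flank Flanking context intended for downstream junction tests;
#'   a warning is issued when the contig truncates it.
#' @param window Maximum distance (bp) the refined boundary may move.
#' @return An [interval()] on the subject, with attributes `refined_5p`,
#'   `refined_3p` (logical) and `truncated_5p`, `truncated_3p`.
#' @export
refine_boundaries <- function(hit, subject, flank = 500L, window = 30L) {
  s <- seq_chars(subject)
  L <- nchar(s)
  st <- as.integer(hit$start); en <- as.integer(hit$end)
  strand <- as.character(hit$strand)
  if (st < 0L || en > L || en <= st)
    stop(sprintf("hit interval [%d,%d) outside subject of length %d", st, en, L))

  if (strand == "-") {
    rc <- reverse_complement(s)
    riv <- refine_plus(rc, L - en, L - st, window)
    out <- interval(subject_id_of(subject, hit), L - riv$end, L - riv$start, "-")
    attr(out, "refined_5p") <- attr(riv, "refined_5p")
    attr(out, "refined_3p") <- attr(riv, "refined_3p")
    attr(out, "truncated_5p") <- attr(riv, "truncated_5p")
    attr(out, "truncated_3p") <- attr(riv, "truncated_3p")
  } else {
    out <- refine_plus(s, st, en, window)
    out$seq_id <- subject_id_of(subject, hit)
  }
  tr5 <- (if (out$strand == "+") out$start else L - out$end) < flank
  tr3 <- (if (out$strand == "+") L - out$end else out$start) < flank
  if (tr5 || tr3)
    warning("flanking context truncated at contig edge", call. = FALSE)
  out
}

subject_id_of <- function(subject, hit) {
  if (inherits(subject, "dna_record")) subject$id
  else if (!is.null(hit$subject_id)) as.character(hit$subject_id)
  else "subject"
}

## Boundary search on the plus/element orientation. st/en 0-based half-open.
refine_plus <- function(s, st, en, window) {
  L <- nchar(s)
  ## 5': 0-based start p needs s[p-1] == A, s[p..p+1] == TC
  cand5 <- integer(0)
  for (p in seq(max(1L, st - window), min(L - 2L, st + window))) {
    if (substr(s, p, p) == "A" && substr(s, p + 1L, p + 2L) == "TC")
      cand5 <- c(cand5, p)
  }
  new_st <- st; refined5 <- FALSE
  if (length(cand5)) {
    new_st <- cand5[order(abs(cand5 - st), cand5)][1]
    refined5 <- TRUE
  }
  ## 3': 0-based exclusive end e needs s[e-4..e-1] matching CTRY, s[e] == T
  cand3 <- integer(0)
  for (e in seq(max(4L, en - window), min(L - 1L, en + window))) {
    tail4 <- substr(s, e - 3L, e)
    if (substr(s, e + 1L, e + 1L) == "T" && iupac_match_quiet(tail4, "CTRY"))
      cand3 <- c(cand3, e)
  }
  new_en <- en; refined3 <- FALSE
  if (length(cand3)) {
    new_en <- cand3[order(abs(cand3 - en), cand3)][1]
    refined3 <- TRUE
  }
  if (new_en <= new_st) { new_st <- st; new_en <- en; refined5 <- refined3 <- FALSE }
  out <- interval("subject", new_st, new_en, "+")
  attr(out, "refined_5p") <- refined5
  attr(out, "refined_3p") <- refined3
  attr(out, "truncated_5p") <- new_st == 0L
  attr(out, "truncated_3p") <- new_en == L
  out
}

iupac_match_quiet <- function(s, pattern) {
  if (nchar(s) != nchar(pattern)) return(FALSE)
  if (length(invalid_residue_pos(s))) return(FALSE)
  iupac_match(s, pattern)
}

#' Test the element's terminal motifs
#'
#' @param element Element nucleotide string (element orientation).
#' @return Named logical vector: `five_prime_tc` (prefix `TC`) and
#'   `three_prime_ctry` (4-residue suffix matching `CTRY`).
#' @export
detect_termini <- function(element) {
  s <- seq_chars(element)
  n <- nchar(s)
  if (n < 6L) stop("element too short (", n, " bp) for terminus tests")
  bad <- invalid_residue_pos(s)
  if (length(bad))
    stop(sprintf("invalid residue '%s' at position %d",
                 substr(s, bad[1], bad[1]), bad[1]))
  c(five_prime_tc = substr(s, 1L, 2L) == "TC",
    three_prime_ctry = iupac_match_quiet(substr(s, n - 3L, n), "CTRY"))
}

#' Find the best subterminal inverted repeat (hairpin)
#'
#' Exhaustive scan of the last `search_window` bases for an inverted repeat
#' with arm length in `[arm_min, arm_max]`, loop length in
#' `[loop_min, loop_max]` and at most `max_mismatch` arm mismatches. The best
#' hairpin maximises arm length, then minimises mismatches, then lies closest
#' to the 3' terminus. A perfect 16-20 bp palindrome (8-10 bp arms around a
#' small loop), the hallmark of this element family, passes the defaults.
#'
#' @param element Element nucleotide string.
#' @param search_window,arm_min,arm_max,loop_min,loop_max,max_mismatch
#'   Search parameters.
#' @return A list of class `hairpin` (`left_arm`, `right_arm` element-local
#'   0-based intervals, `loop_len`, `mismatches`, `span`) or `NULL`.
#' @export
find_hairpin <- function(element, search_window = 50L, arm_min = 6L,
                         arm_max = 12L, loop_min = 2L, loop_max = 8L,
                         max_mismatch = 1L) {
  s <- seq_chars(element)
  n <- nchar(s)
  w <- min(search_window, n)
  off <- n - w                      # 0-based offset of the window
  win <- strsplit(substr(s, off + 1L, n), "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- NULL
  for (arm in seq(arm_min, min(arm_max, floor((w - loop_min) / 2)))) {
    for (i in seq_len(w - 2L * arm - loop_min + 1L)) {
      for (loop in seq(loop_min, min(loop_max, w - i + 1L - 2L * arm))) {
        rstart <- i + arm + loop
        left <- win[i:(i + arm - 1L)]
        right <- win[rstart:(rstart + arm - 1L)]
        mm <- sum(left != comp[rev(right)], na.rm = FALSE)
        if (is.na(mm)) mm <- arm   # non-ACGT residues never pair
        if (mm > max_mismatch) next
        rend <- rstart + arm - 1L  # window-local 1-based right arm end
        if (is.null(best) || arm > best$arm ||
            (arm == best$arm && (mm < best$mismatches ||
             (mm == best$mismatches && rend > best$rend)))) {
          best <- list(arm = arm, i = i, loop = loop, mismatches = mm,
                       rend = rend, rstart = rstart)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  l0 <- off + best$i - 1L
  r0 <- off + best$rstart - 1L
  structure(list(
    left_arm = interval("element", l0, l0 + best$arm),
    right_arm = interval("element", r0, r0 + best$arm),
    loop_len = best$loop,
    mismatches = best$mismatches,
    span = (r0 + best$arm) - l0), class = "hairpin")
}

#' @export
print.hairpin <- function(x, ...) {
  cat(sprintf("<hairpin> arms %d bp, loop %d bp, %d mismatch(es), span %d bp at [%d,%d)\n",
              interval_length(x$left_arm), x$loop_len, x$mismatches, x$span,
              x$left_arm$start, x$right_arm$end))
  invisible(x)
}

#' Test the A^T insertion junction
#'
#' Rolling-circle integration places the element precisely between a host A
#' and T.
#'
#' @param upstream_flank,downstream_flank Host flanks in element orientation.
#' @return `TRUE` iff the upstream flank ends in `A` and the downstream flank
#'   begins with `T`.
#' @export
check_at_junction <- function(upstream_flank, downstream_flank) {
  up <- seq_chars(upstream_flank); dn <- seq_chars(downstream_flank)
  if (!nzchar(up) || !nzchar(dn)) stop("empty flank: junction undetermined")
  substr(up, nchar(up), nchar(up)) == "A" && substr(dn, 1L, 1L) == "T"
}

#' Screen for a target-site duplication
#'
#' Helitron insertions create no TSD; a detected duplication argues against a
#' genuine element of this family.
#'
#' @param upstream_flank,downstream_flank Host flanks in element orientation.
#' @param k_min,k_max Duplication lengths tested.
#' @return Logical; attribute `kmer` holds the longest duplicated word found.
#' @export
detect_tsd <- function(upstream_flank, downstream_flank, k_min = 4L, k_max = 10L) {
  up <- seq_chars(upstream_flank); dn <- seq_chars(downstream_flank)
  avail <- min(nchar(up), nchar(dn), k_max)
  if (avail < k_max)
    warning(sprintf("flanks support TSD scan only up to k = %d", avail),
            call. = FALSE)
  found <- NA_character_
  if (avail >= k_min) for (k in seq(k_min, avail)) {
    suf <- substr(up, nchar(up) - k + 1L, nchar(up))
    pre <- substr(dn, 1L, k)
    if (suf == pre) found <- suf
  }
  out <- !is.na(found)
  attr(out, "kmer") <- found
  out
}

#' Delineate the conserved core and the 3' acquired sequence
#'
#' The core is the element span covered by a fit alignment of the consensus
#' (consensus fully aligned, element end gaps free); the acquired sequence is
#' the remainder 3' of the core. Identity to the consensus is computed over
#' aligned columns excluding indels.
#'
#' @param element Element nucleotide string (element orientation).
#' @param consensus Core consensus `dna_record` or string.
#' @param ctrr_window The CTRR motif must lie within this many bases of the
#'   acquired 3' end (default 15).
#' @param min_identity Below this core identity the element is rejected as
#'   not a family member.
#' @return List: `core_iv`, `acquired_iv` (element-local 0-based; `NULL` when
#'   the acquired region is empty), `ctrr_in_acquired`, `ctrr_pos`
#'   (element-local 0-based start or `NA`), `identity_to_consensus`.
#' @export
delineate_acquired <- function(element, consensus, ctrr_window = 15L,
                               min_identity = 0.5) {
  s <- seq_chars(element)
  n <- nchar(s)
  p <- global_align(consensus, s, free_b_ends = TRUE)
  ident <- identity_excluding_indels(p)
  if (p$score <= 0 || ident < min_identity)
    stop(sprintf("not a Lep1 candidate: core identity %.2f below %.2f",
                 ident, min_identity))
  core <- interval("element", p$b_start, p$b_end)
  acquired <- if (p$b_end < n) interval("element", p$b_end, n) else NULL
  ctrr <- FALSE; ctrr_pos <- NA_integer_
  if (!is.null(acquired)) {
    zone_start <- max(acquired$start, n - ctrr_window)   # 0-based
    zone <- substr(s, zone_start + 1L, n)
    m <- gregexpr("CT[AG][AG]", zone)[[1]]
    if (m[1] != -1L) {
      ctrr <- TRUE
      ctrr_pos <- zone_start + m[length(m)] - 1L        # last occurrence
    }
  }
  list(core_iv = core, acquired_iv = acquired, ctrr_in_acquired = ctrr,
       ctrr_pos = ctrr_pos, identity_to_consensus = ident)
}

#' Annotate a candidate hit as a Lep1-family element
#'
#' Composition of [refine_boundaries()], [detect_termini()],
#' [find_hairpin()], [check_at_junction()], [detect_tsd()] and
#' [delineate_acquired()]. An element is called full length iff it has the
#' 5'-TC terminus, a 3'-CTRY terminus, a determinable A^T junction that holds,
#' and no target-site duplication.
#'
#' @param hit One row of a `lep_hits` data.frame.
#' @param subject The subject `dna_record`.
#' @param consensus Core consensus used to delineate the acquired region.
#' @param flank Host flank used for junction and TSD tests (default 500).
#' @param window Boundary-refinement window (default 30).
#' @param ... Passed to [find_hairpin()].
#' @return An object of class `lep1_annotation`.
#' @export
annotate_element <- function(hit, subject, consensus, flank = 500L,
                             window = 30L, ...) {
  iv <- withCallingHandlers(
    refine_boundaries(hit, subject, flank, window),
    warning = function(w) invokeRestart("muffleWarning"))
  s <- seq_chars(subject)
  L <- nchar(s)
  element <- extract_region(subject, iv)

  term <- detect_termini(element)
  hp <- find_hairpin(element, ...)

  ## host flanks in element orientation
  if (iv$strand == "+") {
    up <- if (iv$start > 0L)
      extract_region(subject, interval(iv$seq_id, max(0L, iv$start - flank),
                                       iv$start, "+")) else ""
    dn <- if (iv$end < L)
      extract_region(subject, interval(iv$seq_id, iv$end,
                                       min(L, iv$end + flank), "+")) else ""
  } else {
    up <- if (iv$end < L)
      extract_region(subject, interval(iv$seq_id, iv$end,
                                       min(L, iv$end + flank), "-")) else ""
    dn <- if (iv$start > 0L)
      extract_region(subject, interval(iv$seq_id, max(0L, iv$start - flank),
                                       iv$start, "-")) else ""
  }

  at_junction <- if (nzchar(up) && nzchar(dn)) check_at_junction(up, dn) else NA
  tsd <- if (nzchar(up) && nzchar(dn))
    suppressWarnings(detect_tsd(up, dn)) else NA

  deli <- delineate_acquired(element, consensus)

  full_length <- isTRUE(unname(term["five_prime_tc"])) &&
    isTRUE(unname(term["three_prime_ctry"])) &&
    isTRUE(at_junction) && !isTRUE(as.logical(tsd))

  structure(list(
    element_iv = iv,
    element_seq = element,
    core_iv = local_to_subject(deli$core_iv, iv),
    acquired_iv = if (is.null(deli$acquired_iv)) NULL
                  else local_to_subject(deli$acquired_iv, iv),
    five_prime_tc = unname(term["five_prime_tc"]),
    three_prime_ctry = unname(term["three_prime_ctry"]),
    ctrr_in_acquired = deli$ctrr_in_acquired,
    ctrr_pos = deli$ctrr_pos,
    hairpin = hp,
    at_junction = at_junction,
    tsd_detected = if (is.na(at_junction)) NA else as.logical(tsd),
    identity_to_consensus = deli$identity_to_consensus,
    full_length = full_length), class = "lep1_annotation")
}

## element-local 0-based interval -> subject coordinates, strand-aware
local_to_subject <- function(liv, element_iv) {
  if (element_iv$strand == "+")
    interval(element_iv$seq_id, element_iv$start + liv$start,
             element_iv$start + liv$end, "+")
  else
    interval(element_iv$seq_id, element_iv$end - liv$end,
             element_iv$end - liv$start, "-")
}

#' @export
print.lep1_annotation <- function(x, ...) {
  iv <- x$element_iv
  cat(sprintf("<lep1_annotation> %s:[%d,%d)%s (%d bp)%s\n",
              iv$seq_id, iv$start, iv$end, iv$strand, interval_length(iv),
              if (x$full_length) " FULL LENGTH" else ""))
  cat(sprintf("  5'-TC %s | 3'-CTRY %s | CTRR(acq) %s | A^T junction %s | TSD %s\n",
              x$five_prime_tc, x$three_prime_ctry, x$ctrr_in_acquired,
              x$at_junction, x$tsd_detected))
  cat(sprintf("  core %d bp + acquired %d bp; identity to consensus %.3f; hairpin %s\n",
              interval_length(x$core_iv),
              if (is.null(x$acquired_iv)) 0L else interval_length(x$acquired_iv),
              x$identity_to_consensus,
              if (is.null(x$hairpin)) "none"
              else sprintf("arm %d/loop %d", interval_length(x$hairpin$left_arm),
                           x$hairpin$loop_len)))
  invisible(x)
}

#' Scan sequences and annotate every candidate
#'
#' Runs [find_candidates()] with `query` then [annotate_element()] on every
#' hit. Hits whose core identity falls below the delineation threshold are
#' dropped with a warning.
#'
#' @param subjects List of `dna_record`s (or a single one).
#' @param query Search query (typically a full-length element consensus).
#' @param consensus Core consensus for acquired-region delineation
#'   (defaults to `query`).
#' @param ... Passed to [find_candidates()].
#' @param flank,window Passed to [annotate_element()].
#' @return List of `lep1_annotation` objects.
#' @export
annotate_genome <- function(subjects, query, consensus = query,
                            flank = 500L, window = 30L, ...) {
  hits <- find_candidates(query, subjects, ...)
  if (inherits(subjects, "dna_record")) subjects <- list(subjects)
  subjects <- as_record_list(subjects)
  names(subjects) <- vapply(subjects, `[[`, "", "id")
  anns <- list()
  for (i in seq_len(nrow(hits))) {
    hit <- hits[i, ]
    ann <- tryCatch(
      annotate_element(hit, subjects[[hit$subject_id]], consensus,
                       flank = flank, window = window),
      error = function(e) { warning(conditionMessage(e), call. = FALSE); NULL })
    if (!is.null(ann)) anns[[length(anns) + 1L]] <- ann
  }
  anns
}

#' Tabulate annotations
#'
#' @param anns List of `lep1_annotation` objects.
#' @return A data.frame, one row per element (Table-1-style report).
#' @export
annotation_table <- function(anns) {
  if (!length(anns))
    return(data.frame(element_id = character(), seq_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      size_bp = integer(), core_bp = integer(),
                      acquired_bp = integer(), five_prime_tc = logical(),
                      three_prime_ctry = logical(),
                      ctrr_in_acquired = logical(), hairpin = logical(),
                      at_junction = logical(), tsd_detected = logical(),
                      identity_to_consensus = numeric(),
                      full_length = logical(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_along(anns), function(i) {
    a <- anns[[i]]
    data.frame(
      element_id = sprintf("element_%03d", i),
      seq_id = a$element_iv$seq_id,
      start = a$element_iv$start, end = a$element_iv$end,
      strand = a$element_iv$strand,
      size_bp = interval_length(a$element_iv),
      core_bp = interval_length(a$core_iv),
      acquired_bp = if (is.null(a$acquired_iv)) 0L
                    else interval_length(a$acquired_iv),
      five_prime_tc = a$five_prime_tc,
      three_prime_ctry = a$three_prime_ctry,
      ctrr_in_acquired = a$ctrr_in_acquired,
      hairpin = !is.null(a$hairpin),
      at_junction = a$at_junction,
      tsd_detected = a$tsd_detected,
      identity_to_consensus = round(a$identity_to_consensus, 4),
      full_length = a$full_length,
      stringsAsFactors = FALSE)
  }))
}
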