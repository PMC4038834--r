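## Candidate discovery: exact k-mer seeding on both strands, extension by
## optimal local alignment, and the published hit filter (identity >= 70%
## over more than 100 aligned columns, gapped columns counted).

#' Find candidate element loci by seeded local alignment
#'
#' Exact `k`-mer seeds from the query (both strands) are located in each
#' subject, clustered into loci, and each locus is verified by optimal local
#' alignment ([local_align()]). Alignments bridging unrelated loci through
#' long gap runs are split at gap runs of `split_gap` or more columns.
#' Hits passing both thresholds are returned sorted by subject position;
#' overlapping hits on the same subject are merged, keeping the best-scoring
#' representative.
#'
#' @param query `dna_record` (or string) used as the search query.
#' @param subjects List of `dna_record`s (a single record is accepted).
#' @param min_identity Minimum identity over gap-free aligned columns
#'   (default 0.70).
#' @param min_length Hits must span strictly more than this many aligned
#'   columns, gaps included (default 100).
#' @param k Seed length (default 11).
#' @param split_gap Split alignments at gap runs of at least this length.
#' @param match,mismatch,gap_open,gap_extend Alignment scoring.
#' @return A data.frame of class `lep_hits` with columns `query_id`,
#'   `subject_id`, `start`, `end` (0-based half-open, subject + strand),
#'   `strand`, `identity`, `aln_length`, `score`.
#' @export
find_candidates <- function(query, subjects, min_identity = 0.70,
                            min_length = 100L, k = 11L, split_gap = 40L,
                            match = 1, mismatch = -1,
                            gap_open = -2, gap_extend = -1) {
  qs <- seq_chars(query)
  if (nchar(qs) < k) stop("query shorter than seed size k = ", k)
  if (inherits(subjects, "dna_record")) subjects <- list(subjects)
  subjects <- as_record_list(subjects)
  qid <- id_of(query, "query")
  qlen <- nchar(qs)
  queries <- list(`+` = qs, `-` = reverse_complement(qs))

  rows <- list()
  for (subj in subjects) {
    ss <- subj$residues
    slen <- nchar(ss)
    if (slen < k) next
    skmers <- substring(ss, 1:(slen - k + 1L), k:slen)
    for (strand in c("+", "-")) {
      qstr <- queries[[strand]]
      qk <- unique(substring(qstr, 1:(qlen - k + 1L), k:qlen))
      seed_pos <- which(skmers %in% qk)  # 1-based subject positions
      if (!length(seed_pos)) next
      gaps <- diff(seed_pos)
      grp <- cumsum(c(1L, as.integer(gaps > qlen)))
      for (g in unique(grp)) {
        pos <- seed_pos[grp == g]
        w0 <- max(1L, min(pos) - qlen - 20L)
        w1 <- min(slen, max(pos) + k - 1L + qlen + 20L)
        win <- substr(ss, w0, w1)
        aln <- local_align(qstr, win, match, mismatch, gap_open, gap_extend)
        if (aln$score <= 0) next
        for (piece in split_alignment(aln, split_gap, match, mismatch,
                                      gap_open, gap_extend)) {
          st <- w0 - 1L + piece$b_start    # 0-based on subject
          en <- w0 - 1L + piece$b_end
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = qid, subject_id = subj$id,
            start = st, end = en, strand = strand,
            identity = piece$identity, aln_length = piece$aln_length,
            score = piece$score, stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty_hits()
  hits <- hits[hits$identity >= min_identity & hits$aln_length > min_length, ,
               drop = FALSE]
  hits <- merge_hits(hits)
  class(hits) <- c("lep_hits", "data.frame")
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             start = integer(), end = integer(), strand = character(),
             identity = numeric(), aln_length = integer(), score = numeric(),
             stringsAsFactors = FALSE)
}

## Split an aligned_pair at gap runs of >= split_gap columns; returns a list
## of pieces with fields b_start, b_end (0-based within the aligned subject),
## identity, aln_length, score.
split_alignment <- function(aln, split_gap, match, mismatch,
                            gap_open, gap_extend) {
  ca <- strsplit(aln$a_row, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$b_row, "", fixed = TRUE)[[1]]
  L <- length(ca)
  isgap <- ca == "-" | cb == "-"
  runs <- rle(isgap)
  cut <- rep(FALSE, L)
  idx <- cumsum(runs$lengths)
  for (r in seq_along(runs$lengths))
    if (runs$values[r] && runs$lengths[r] >= split_gap)
      cut[(idx[r] - runs$lengths[r] + 1L):idx[r]] <- TRUE
  grp <- cumsum(c(TRUE, diff(cut) != 0))
  grp[cut] <- NA
  pieces <- list()
  bpos <- cumsum(cb != "-")            # subject offset at each column
  for (g in unique(grp[!is.na(grp)])) {
    cols <- which(!is.na(grp) & grp == g)
    pa <- ca[cols]; pb <- cb[cols]
    aligned <- pa != "-" & pb != "-"
    if (!any(aligned)) next
    matches <- sum(mapply(iupac_compatible, pa[aligned], pb[aligned]))
    score <- matches * match + (sum(aligned) - matches) * mismatch +
      gap_cost(pa, gap_open, gap_extend) + gap_cost(pb, gap_open, gap_extend)
    b_cols <- cols[cb[cols] != "-"]
    pieces[[length(pieces) + 1L]] <- list(
      b_start = aln$b_start + bpos[min(b_cols)] - 1L,
      b_end = aln$b_start + bpos[max(b_cols)],
      identity = matches / sum(aligned),
      aln_length = length(cols),
      score = score)
  }
  pieces
}

gap_cost <- function(chars, gap_open, gap_extend) {
  runs <- rle(chars == "-")
  glens <- runs$lengths[runs$values]
  if (!length(glens)) return(0)
  sum(gap_open + glens * gap_extend)
}

## Merge overlapping hits on the same subject, keeping the best score
## (ties: longer, then leftmost).
merge_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  out <- list()
  for (sid in unique(hits$subject_id)) {
    h <- hits[hits$subject_id == sid, , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    grp <- integer(nrow(h)); g <- 1L; grp[1] <- 1L
    hi <- h$end[1]
    if (nrow(h) > 1) for (i in 2:nrow(h)) {
      if (h$start[i] < hi) grp[i] <- g
      else { g <- g + 1L; grp[i] <- g }
      hi <- max(hi, h$end[i])
    }
    for (gg in unique(grp)) {
      sub <- h[grp == gg, , drop = FALSE]
      best <- order(-sub$score, -(sub$end - sub$start), sub$start)[1]
      out[[length(out) + 1L]] <- sub[best, , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$subject_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a 12-column BLAST tabular hit file
#'
#' Standard `outfmt 6` columns (qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore). Identity percentages are
#' converted to fractions; subject coordinates to 0-based half-open, with
#' strand inferred from coordinate order (`sstart > send` means minus).
#'
#' @param path Path to the tabular file.
#' @return A `lep_hits` data.frame (see [find_candidates()]).
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    h <- empty_hits(); class(h) <- c("lep_hits", "data.frame"); return(h)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop(sprintf("expected 12 tab-separated columns, found %d at line %d",
                 nf[nf != 12L][1], which(nf != 12L)[1]))
  m <- do.call(rbind, fields)
  sstart <- as.integer(m[, 9]); send <- as.integer(m[, 10])
  minus <- sstart > send
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    start = ifelse(minus, send, sstart) - 1L,
    end = ifelse(minus, sstart, send),
    strand = ifelse(minus, "-", "+"),
    identity = as.numeric(m[, 3]) / 100,
    aln_length = as.integer(m[, 4]),
    score = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
  class(hits) <- c("lep_hits", "data.frame")
  hits
}

#' Export hits as TSV or BED
#'
#' @param hits A `lep_hits` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
write_hits_bed <- function(hits, path) {
  if (!nrow(hits)) { writeLines(character(), path); return(invisible(path)) }
  gr <- GenomicRanges::GRanges(
    seqnames = hits$subject_id,
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = hits$strand,
    score = round(hits$score, 3))
  names(gr) <- paste0(hits$query_id, "_hit", seq_len(nrow(hits)))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
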