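## Pairwise and multiple alignment, identity excluding indels, consensus.
##
## Scoring convention used throughout the package: match/mismatch are scored
## per aligned column; a gap run of length L costs gap_open + L * gap_extend
## and runs in opposite rows may abut. Two symbols "match" when their IUPAC
## degeneracy sets intersect.

default_scoring <- function() list(match = 1, mismatch = -1,
                                   gap_open = -2, gap_extend = -1)

new_aligned_pair <- function(a_id, b_id, a_row, b_row, score) {
  stopifnot(nchar(a_row) == nchar(b_row))
  structure(list(a_id = a_id, b_id = b_id, a_row = a_row, b_row = b_row,
                 score = score), class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("<aligned_pair> %s / %s, %d columns, score %g\n",
              x$a_id, x$b_id, nchar(x$a_row), x$score))
  invisible(x)
}

#' Optimal global pairwise alignment (affine gaps)
#'
#' Needleman-Wunsch-Gotoh alignment with deterministic traceback (diagonal
#' preferred, then gap-in-second, then gap-in-first).
#'
#' @param a,b Nucleotide strings or `dna_record`s.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters; a gap run of
#'   length L costs `gap_open + L * gap_extend`.
#' @param free_b_ends If `TRUE`, leading/trailing gaps in `b` are free ("fit"
#'   alignment: all of `a` aligned to the best-matching stretch of `b`).
#' @return An `aligned_pair` with fields `a_row`, `b_row`, `score`, and (for
#'   fit alignments) `b_start`/`b_end`, the 0-based half-open span of `b`
#'   covered by the aligned core.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1,
                         gap_open = -2, gap_extend = -1, free_b_ends = FALSE) {
  sa <- seq_chars(a); sb <- seq_chars(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence passed to global_align")
  res <- .align_pair_cpp(sa, sb, match, mismatch, gap_open, gap_extend,
                         if (free_b_ends) 2L else 0L)
  p <- new_aligned_pair(id_of(a, "a"), id_of(b, "b"), res$a_row, res$b_row,
                        res$score)
  p$b_start <- res$b_start - 1L
  p$b_end <- res$b_end
  p
}

#' Optimal local pairwise alignment (affine gaps)
#'
#' Smith-Waterman-Gotoh. Among tied optima the alignment with the lowest
#' subject end coordinate, then lowest query end, is returned (deterministic).
#'
#' @param a Query nucleotide string or `dna_record`.
#' @param b Subject nucleotide string or `dna_record`.
#' @inheritParams global_align
#' @return An `aligned_pair` with additional 0-based half-open fields
#'   `a_start`, `a_end`, `b_start`, `b_end`. A best score of 0 yields an empty
#'   alignment (all coordinates 0).
#' @export
local_align <- function(a, b, match = 1, mismatch = -1,
                        gap_open = -2, gap_extend = -1) {
  sa <- seq_chars(a); sb <- seq_chars(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence passed to local_align")
  res <- .align_pair_cpp(sa, sb, match, mismatch, gap_open, gap_extend, 1L)
  p <- new_aligned_pair(id_of(a, "a"), id_of(b, "b"), res$a_row, res$b_row,
                        res$score)
  p$a_start <- max(res$a_start - 1L, 0L); p$a_end <- res$a_end
  p$b_start <- max(res$b_start - 1L, 0L); p$b_end <- res$b_end
  p
}

id_of <- function(x, fallback) if (inherits(x, "dna_record")) x$id else fallback

#' Identity excluding indels
#'
#' Fraction of matching residues over the columns that carry a residue in
#' both rows; gap columns are excluded from numerator and denominator
#' (the Table-1-style similarity convention).
#'
#' @param pair An `aligned_pair`, or a gapped row (with `b_row` supplied).
#' @param b_row Second gapped row when `pair` is given as a string.
#' @return Fraction in \[0, 1\].
#' @export
identity_excluding_indels <- function(pair, b_row = NULL) {
  if (inherits(pair, "aligned_pair")) {
    ra <- pair$a_row; rb <- pair$b_row
  } else {
    ra <- toupper(pair); rb <- toupper(b_row)
  }
  if (nchar(ra) != nchar(rb)) stop("rows differ in length")
  ca <- strsplit(ra, "", fixed = TRUE)[[1]]
  cb <- strsplit(rb, "", fixed = TRUE)[[1]]
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) stop("no gap-free columns; identity undefined")
  ca <- ca[keep]; cb <- cb[keep]
  matches <- sum(vapply(seq_along(ca), function(k)
    iupac_compatible(ca[k], cb[k]), logical(1)))
  matches / length(ca)
}

## Fast path for concrete A/C/G/T rows (used in distance loops).
identity_concrete <- function(ca, cb) {
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) stop("no gap-free columns; identity undefined")
  mean(ca[keep] == cb[keep])
}

degap <- function(row) gsub("-", "", row, fixed = TRUE)

#' Progressive multiple sequence alignment
#'
#' Guide tree from 6-mer count distances by UPGMA (average-linkage
#' [stats::hclust()]), profiles merged by global affine profile-profile
#' alignment.
#'
#' @param seqs List of `dna_record`s (or named character vector), length >= 2.
#' @param k k-mer size for the guide-tree distance (default 6).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return An object of class `msa`: list with `ids` and `rows` (equal-length
#'   gapped strings in input order).
#' @export
progressive_msa <- function(seqs, k = 6L, match = 1, mismatch = -1,
                            gap_open = -2, gap_extend = -1) {
  seqs <- as_record_list(seqs)
  n <- length(seqs)
  if (n < 2L) stop("progressive_msa needs at least 2 sequences")
  ids <- vapply(seqs, function(r) r$id, character(1))
  strs <- vapply(seqs, function(r) r$residues, character(1))
  if (n == 2L) {
    p <- global_align(seqs[[1]], seqs[[2]], match, mismatch, gap_open, gap_extend)
    return(new_msa(ids, c(p$a_row, p$b_row)))
  }

  D <- kmer_distance_matrix(strs, k)
  hc <- stats::hclust(stats::as.dist(D), method = "average")

  clusters <- lapply(seq_len(n), function(i) list(members = i, rows = strs[i]))
  merged <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    pick <- function(idx) if (idx < 0) clusters[[-idx]] else merged[[idx]]
    ca <- pick(hc$merge[s, 1]); cb <- pick(hc$merge[s, 2])
    pa <- profile_of(ca$rows); pb <- profile_of(cb$rows)
    path <- .align_profiles_cpp(pa, pb, match, mismatch, gap_open, gap_extend)
    rows_a <- apply_path(ca$rows, path$a_path)
    rows_b <- apply_path(cb$rows, path$b_path)
    merged[[s]] <- list(members = c(ca$members, cb$members),
                        rows = c(rows_a, rows_b))
  }
  final <- merged[[n - 1L]]
  ord <- order(final$members)
  new_msa(ids, final$rows[ord])
}

new_msa <- function(ids, rows) {
  stopifnot(length(ids) == length(rows),
            length(unique(nchar(rows))) == 1L)
  structure(list(ids = unname(ids), rows = stats::setNames(rows, ids),
                 ncol = unname(nchar(rows[1]))), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x$ids), x$ncol))
  invisible(x)
}

kmer_distance_matrix <- function(strs, k) {
  counts <- lapply(strs, function(s) {
    L <- nchar(s)
    if (L < k) return(table(character()))
    table(substring(s, 1:(L - k + 1L), k:L))
  })
  n <- length(strs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ci <- counts[[i]]; cj <- counts[[j]]
    shared <- intersect(names(ci), names(cj))
    common <- sum(pmin(ci[shared], cj[shared]))
    denom <- min(sum(ci), sum(cj))
    D[i, j] <- D[j, i] <- if (denom > 0) 1 - common / denom else 1
  }
  D
}

## Column frequency profile (rows A,C,G,T) over non-gap residues; degenerate
## codes distribute their weight uniformly over their degeneracy set.
profile_of <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(mat)
  prof <- matrix(0, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(L)) {
    col <- mat[, j]
    for (ch in col) {
      if (ch == "-") next
      set <- strsplit(IUPAC_CODES[[ch]], "")[[1]]
      prof[set, j] <- prof[set, j] + 1 / length(set)
    }
  }
  prof / length(rows)
}

apply_path <- function(rows, path) {
  vapply(rows, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    paste(ifelse(path == 0L, "-", ch[pmax(path, 1L)]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Majority-rule consensus of a multiple alignment
#'
#' Per column the most frequent non-gap residue is taken when it is a unique
#' maximum with frequency (over non-gap residues) at least `min_fraction`;
#' otherwise the IUPAC code of the minimal top set of residues reaching
#' `min_fraction` cumulatively (ties included) is emitted. Columns gapped in
#' more than half the rows are dropped.
#'
#' @param msa An `msa` object.
#' @param min_fraction Majority threshold (default 0.5).
#' @return List of class `consensus_result` with `residues` and per-column
#'   `support` (frequency of the majority residue among non-gap residues).
#' @export
build_consensus <- function(msa, min_fraction = 0.5) {
  stopifnot(inherits(msa, "msa"), length(msa$rows) >= 2L)
  mat <- do.call(rbind, strsplit(unname(msa$rows), "", fixed = TRUE))
  nrow_ <- nrow(mat)
  residues <- character(0); support <- numeric(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    gaps <- sum(col == "-")
    if (gaps > nrow_ / 2) next
    bases <- col[col != "-"]
    tab <- sort(table(bases), decreasing = TRUE)
    freqs <- as.numeric(tab) / length(bases)
    top <- freqs[1]
    tied <- names(tab)[freqs == top]
    if (length(tied) == 1L && top >= min_fraction) {
      residues <- c(residues, tied)
      support <- c(support, top)
    } else {
      cum <- cumsum(freqs)
      need <- which(cum >= min_fraction)[1]
      if (is.na(need)) need <- length(freqs)
      need <- max(need, sum(freqs == top))  # keep all tied-at-top residues
      set <- sort(unique(unlist(strsplit(IUPAC_CODES[names(tab)[1:need]], ""))))
      residues <- c(residues, iupac_code_for(set))
      support <- c(support, top)
    }
  }
  structure(list(residues = paste(residues, collapse = ""), support = support),
            class = "consensus_result")
}

iupac_code_for <- function(bases) {
  bases <- sort(unique(bases))
  key <- paste(bases, collapse = "")
  hit <- names(IUPAC_CODES)[vapply(IUPAC_CODES, function(s)
    paste(sort(strsplit(s, "")[[1]]), collapse = "") == key, logical(1))]
  if (!length(hit)) stop("no IUPAC code for base set: ", key)
  hit[1]
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus> %d bp, mean support %.3f\n",
              nchar(x$residues), mean(x$support)))
  invisible(x)
}

#' Pairwise identity matrix (excluding indels)
#'
#' Global (or fit) alignment of every pair, identity computed over gap-free
#' columns. Symmetric with unit diagonal.
#'
#' @param seqs List of `dna_record`s or named character vector.
#' @param ... Scoring parameters passed to [global_align()].
#' @return Symmetric numeric matrix with sequence ids as dimnames.
#' @export
pairwise_identity_matrix <- function(seqs, ...) {
  seqs <- as_record_list(seqs)
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  ids <- vapply(seqs, function(r) r$id, character(1))
  M <- diag(1, n); dimnames(M) <- list(ids, ids)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- global_align(seqs[[i]], seqs[[j]], ...)
    M[i, j] <- M[j, i] <- identity_excluding_indels(p)
  }
  M
}

#' Write / read a multiple alignment as aligned FASTA
#' @param msa An `msa` object.
#' @param path Output path.
#' @return `path` invisibly (write); an `msa` (read).
#' @export
write_msa <- function(msa, path) {
  write_fasta(msa$rows, path)
}

#' @rdname write_msa
#' @export
read_msa <- function(path) {
  recs <- read_fasta(path, allow_gaps = TRUE)
  new_msa(vapply(recs, `[[`, "", "id"),
          vapply(recs, `[[`, "", "residues"))
}
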