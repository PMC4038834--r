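## Sequence and interval primitives.
## All coordinates are 0-based half-open [start, end); GenBank-style 1-based
## inclusive "a-b" locations are converted on ingest, with reversed pairs
## (a > b) read as minus-strand features.

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Construct a nucleotide sequence record
#'
#' A light container for an identified IUPAC nucleotide string. Residues are
#' upper-cased and `U` is normalised to `T` on construction.
#'
#' @param id Record identifier.
#' @param residues Nucleotide string (IUPAC codes; `-` permitted only when
#'   `allow_gaps = TRUE`).
#' @param description Free-text description (may be empty).
#' @param allow_gaps Permit `-` characters (aligned sequences).
#' @return An object of class `dna_record` with fields `id`, `residues`,
#'   `description`.
#' @export
dna_record <- function(id, residues, description = "", allow_gaps = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(residues), length(residues) == 1L)
  residues <- chartr("u", "t", toupper(residues))
  residues <- chartr("U", "T", residues)
  bad <- invalid_residue_pos(residues, allow_gaps)
  if (length(bad))
    stop(sprintf("invalid residue '%s' at position %d in sequence '%s'",
                 substr(residues, bad[1], bad[1]), bad[1], id), call. = FALSE)
  structure(list(id = id, residues = residues, description = description),
            class = "dna_record")
}

invalid_residue_pos <- function(residues, allow_gaps = FALSE) {
  alphabet <- names(IUPAC_CODES)
  if (allow_gaps) alphabet <- c(alphabet, "-")
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  which(!(ch %in% alphabet))
}

#' @export
print.dna_record <- function(x, ...) {
  n <- nchar(x$residues)
  shown <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<dna_record> %s (%d bp)%s\n  %s\n", x$id, n,
              if (nzchar(x$description)) paste0(" ", x$description) else "",
              shown))
  invisible(x)
}

#' @export
as.character.dna_record <- function(x, ...) x$residues

## Accept either a dna_record or a plain string wherever a nucleotide string
## is expected.
seq_chars <- function(x) {
  if (inherits(x, "dna_record")) x$residues
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a dna_record or a single nucleotide string")
}

#' Construct a genomic interval
#'
#' 0-based half-open interval on a named sequence.
#'
#' @param seq_id Identifier of the sequence the interval refers to.
#' @param start 0-based inclusive start.
#' @param end Exclusive end, `end > start`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `interval`.
#' @export
interval <- function(seq_id, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L, !is.na(start), !is.na(end))
  if (start < 0L) stop("interval start must be >= 0, got ", start)
  if (end <= start) stop(sprintf("interval end (%d) must exceed start (%d)", end, start))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(seq_id = as.character(seq_id), start = start, end = end,
                 strand = strand), class = "interval")
}

#' @export
print.interval <- function(x, ...) {
  cat(sprintf("<interval> %s:[%d,%d)%s (%d bp)\n", x$seq_id, x$start, x$end,
              x$strand, x$end - x$start))
  invisible(x)
}

interval_length <- function(iv) iv$end - iv$start

#' Convert a GenBank-style location to an interval
#'
#' Locations are 1-based inclusive `from`/`to` pairs; a reversed pair
#' (`from > to`, e.g. "371-171") denotes the minus strand.
#'
#' @param seq_id Sequence identifier.
#' @param from,to 1-based inclusive endpoints as printed.
#' @return An [interval()].
#' @export
genbank_interval <- function(seq_id, from, to) {
  from <- as.integer(from); to <- as.integer(to)
  if (from <= to) interval(seq_id, from - 1L, to, "+")
  else interval(seq_id, to - 1L, from, "-")
}

#' Read a FASTA file
#'
#' Line-based parser: one record per `>` header, residues concatenated across
#' wrapped lines and upper-cased, order preserved. Malformed headers and
#' non-IUPAC characters raise errors naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @param allow_gaps Accept `-` characters (aligned FASTA).
#' @return A list of [dna_record()] objects.
#' @export
read_fasta <- function(path, allow_gaps = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  records <- list()
  cur_id <- NULL; cur_desc <- ""; cur_seq <- character(); cur_line <- NA_integer_
  flush <- function() {
    if (is.null(cur_id)) return()
    res <- paste(cur_seq, collapse = "")
    if (!nzchar(res))
      stop(sprintf("empty sequence for record '%s' (line %d)", cur_id, cur_line),
           call. = FALSE)
    records[[length(records) + 1L]] <<- dna_record(cur_id, res, cur_desc,
                                                   allow_gaps = allow_gaps)
  }
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    line <- lines[i]
    if (startsWith(line, ">")) {
      flush()
      header <- sub("^>\\s*", "", line)
      if (!nzchar(header))
        stop(sprintf("malformed FASTA header at line %d", i), call. = FALSE)
      parts <- strsplit(header, "\\s+")[[1]]
      cur_id <- parts[1]
      cur_desc <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else ""
      cur_seq <- character(); cur_line <- i
    } else {
      if (is.null(cur_id))
        stop(sprintf("sequence data before any FASTA header at line %d", i),
             call. = FALSE)
      line <- gsub("\\s", "", line)
      up <- chartr("u", "t", toupper(line)); up <- chartr("U", "T", up)
      bad <- invalid_residue_pos(up, allow_gaps)
      if (length(bad))
        stop(sprintf("invalid residue '%s' at line %d, column %d",
                     substr(up, bad[1], bad[1]), i, bad[1]), call. = FALSE)
      cur_seq <- c(cur_seq, up)
    }
  }
  flush()
  records
}

#' Write sequences as FASTA
#'
#' @param records A `dna_record`, or a list of them, or a named character
#'   vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  records <- as_record_list(records)
  con <- file(path, "w"); on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", header), con)
    n <- nchar(r$residues)
    starts <- seq(1L, n, by = width)
    writeLines(substring(r$residues, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

as_record_list <- function(x) {
  if (inherits(x, "dna_record")) return(list(x))
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(mapply(function(id, s) dna_record(id, s, allow_gaps = TRUE),
                  ids, x, SIMPLIFY = FALSE, USE.NAMES = FALSE))
  }
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "dna_record")))
  x
}

#' Reverse complement
#'
#' Complements all IUPAC degeneracy codes (R with Y, K with M, ...) and
#' reverses; an involution. Gap characters are preserved.
#'
#' @param s Nucleotide string or `dna_record`.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(s) {
  s <- seq_chars(s)
  bad <- invalid_residue_pos(s, allow_gaps = TRUE)
  if (length(bad))
    stop(sprintf("invalid residue '%s' at position %d",
                 substr(s, bad[1], bad[1]), bad[1]))
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Match a string against an IUPAC pattern
#'
#' @param s Concrete (or degenerate) nucleotide string.
#' @param pattern IUPAC pattern of the same length.
#' @return `TRUE` iff every residue of `s` lies in the degeneracy class of the
#'   corresponding pattern symbol.
#' @export
iupac_match <- function(s, pattern) {
  s <- seq_chars(s); pattern <- toupper(pattern)
  if (nchar(s) != nchar(pattern))
    stop(sprintf("length mismatch: sequence %d vs pattern %d",
                 nchar(s), nchar(pattern)))
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  for (k in seq_along(sc)) {
    cls <- IUPAC_CODES[[pc[k]]]
    if (is.null(cls)) stop("invalid IUPAC pattern symbol: ", pc[k])
    sset <- IUPAC_CODES[[sc[k]]]
    if (is.null(sset)) stop("invalid residue: ", sc[k])
    ## every base the residue could be must be admitted by the pattern symbol
    if (!all(strsplit(sset, "")[[1]] %in% strsplit(cls, "")[[1]])) return(FALSE)
  }
  TRUE
}

## TRUE iff the degeneracy sets of two symbols intersect (the aligner's
## match rule; N matches everything).
iupac_compatible <- function(a, b) {
  sa <- IUPAC_CODES[[a]]; sb <- IUPAC_CODES[[b]]
  if (is.null(sa) || is.null(sb)) return(FALSE)
  any(strsplit(sa, "")[[1]] %in% strsplit(sb, "")[[1]])
}

#' Extract a region from a sequence
#'
#' Substring for the 0-based half-open interval; reverse-complemented when the
#' interval is on the minus strand.
#'
#' @param seq A `dna_record` (or plain string).
#' @param iv An [interval()].
#' @return Nucleotide string.
#' @export
extract_region <- function(seq, iv) {
  s <- seq_chars(seq)
  n <- nchar(s)
  if (iv$start < 0L || iv$end > n)
    stop(sprintf("interval [%d,%d) out of bounds for sequence of length %d",
                 iv$start, iv$end, n))
  out <- substr(s, iv$start + 1L, iv$end)
  if (iv$strand == "-") out <- reverse_complement(out)
  out
}
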