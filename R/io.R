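## GFF3 export of element annotations (element + core/acquired/hairpin
## child features), via rtracklayer.

#' Write annotations as GFF3
#'
#' One `mobile_genetic_element` feature per element with `region` children
#' for the conserved core and the acquired sequence and a `hairpin` child
#' when present. Coordinates are converted to the 1-based inclusive GFF
#' convention on output.
#'
#' @param anns List of `lep1_annotation` objects.
#' @param path Output path.
#' @param source Value of the GFF source column.
#' @return `path`, invisibly.
#' @export
write_annotations_gff3 <- function(anns, path, source = "lepscan") {
  rows <- list()
  add <- function(seqid, iv, type, id, parent = NA_character_, note = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seqid = seqid, start = iv$start + 1L, end = iv$end,
      strand = iv$strand, type = type, ID = id, Parent = parent,
      Note = note, stringsAsFactors = FALSE)
  }
  for (i in seq_along(anns)) {
    a <- anns[[i]]
    eid <- sprintf("element_%03d", i)
    note <- sprintf("full_length=%s;identity_to_consensus=%.4f",
                    a$full_length, a$identity_to_consensus)
    add(a$element_iv$seq_id, a$element_iv, "mobile_genetic_element", eid,
        note = note)
    add(a$element_iv$seq_id, a$core_iv, "region", paste0(eid, "_core"), eid,
        note = "conserved core")
    if (!is.null(a$acquired_iv))
      add(a$element_iv$seq_id, a$acquired_iv, "region",
          paste0(eid, "_acquired"), eid, note = "acquired sequence")
    if (!is.null(a$hairpin)) {
      hp_local <- interval("element", a$hairpin$left_arm$start,
                           a$hairpin$right_arm$end)
      add(a$element_iv$seq_id, local_to_subject(hp_local, a$element_iv),
          "hairpin", paste0(eid, "_hairpin"), eid,
          note = sprintf("arm=%d;loop=%d;mismatches=%d",
                         interval_length(a$hairpin$left_arm),
                         a$hairpin$loop_len, a$hairpin$mismatches))
    }
  }
  if (!length(rows)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(parent, function(p) if (nzchar(p)) p else character(0)))
  S4Vectors::mcols(gr)$Note <- df$Note
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Export element sequences as FASTA
#'
#' @param anns List of `lep1_annotation` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_element_fasta <- function(anns, path) {
  recs <- lapply(seq_along(anns), function(i) {
    a <- anns[[i]]
    dna_record(sprintf("element_%03d", i), a$element_seq,
               description = sprintf("%s:%d-%d(%s)", a$element_iv$seq_id,
                                     a$element_iv$start + 1L, a$element_iv$end,
                                     a$element_iv$strand))
  })
  write_fasta(recs, path)
}
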