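# lncRNA identification: length filter, strand-aware positional
# classification against a reference annotation, and ORF-based coding
# potential filtering. Thresholds are strict ("longer than"): a 200-nt
# transcript is dropped, a 100-aa internal ORF is tolerated.

#' Discovery configuration
#'
#' @param min_length_nt Spliced length must be strictly greater (default 200).
#' @param max_internal_orf_aa Internal ORFs strictly longer disqualify
#'   (default 100).
#' @param max_terminal_orf_aa Terminal ORFs strictly longer disqualify
#'   (default 50).
#' @param homology_hook Optional predicate `function(id, sequence)` that
#'   returns `TRUE` for transcripts with protein-database homology; the
#'   default never fires (external database searches are out of scope).
#' @return A list of class `discovery_config`.
#' @export
discovery_config <- function(min_length_nt = 200L,
                             max_internal_orf_aa = 100L,
                             max_terminal_orf_aa = 50L,
                             homology_hook = NULL) {
  stopifnot(min_length_nt > 0L, max_internal_orf_aa > 0L,
            max_terminal_orf_aa > 0L)
  structure(list(min_length_nt = as.integer(min_length_nt),
                 max_internal_orf_aa = as.integer(max_internal_orf_aa),
                 max_terminal_orf_aa = as.integer(max_terminal_orf_aa),
                 homology_hook = homology_hook),
            class = "discovery_config")
}

#' Find ATG-initiated ORFs in a spliced transcript sequence
#'
#' Scans the three forward frames of the given 5'->3' sequence. An ORF
#' closed by an in-frame stop is `internal` (length in amino acids, ATG
#' codon included, stop excluded); an ORF reaching the 3' end without a
#' stop is `terminal`. Frames that open without an ATG and run into a stop
#' (5' runoff of a putative upstream start) are also reported as `terminal`,
#' counted in full codons. Nested ATGs inside a longer same-frame ORF are
#' not reported separately. Codons containing N never count as ATG or stop.
#'
#' @param sequence Character string over A/C/G/T/U/N (case-insensitive).
#' @return Data frame with columns `start_nt` (1-based offset of the first
#'   codon base), `length_aa`, `kind` (`internal`/`terminal`), `frame` (0-2).
#' @export
find_orfs <- function(sequence) {
  s <- toupper(as.character(sequence))
  s <- gsub("U", "T", s, fixed = TRUE)
  if (grepl("[^ACGTN]", s))
    stop("sequence contains non-nucleotide symbols other than N")
  n <- nchar(s)
  if (n < 3L) stop("sequence shorter than one codon")
  out <- list()
  for (f in 0:2) {
    n_cod <- (n - f) %/% 3L
    if (n_cod < 1L) next
    codons <- substring(s, f + 1L + 3L * (seq_len(n_cod) - 1L),
                        f + 3L * seq_len(n_cod))
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    first_stop <- if (any(is_stop)) which(is_stop)[1L] else NA_integer_
    # 5' runoff: frame opens mid-ORF and terminates at the first stop
    if (!is.na(first_stop) && first_stop > 1L && !is_atg[1L])
      out[[length(out) + 1L]] <- data.frame(
        start_nt = f + 1L, length_aa = first_stop - 1L,
        kind = "terminal", frame = f)
    i <- 1L
    while (i <= n_cod) {
      if (is_atg[i]) {
        nxt <- which(is_stop & seq_len(n_cod) > i)
        if (length(nxt)) {
          out[[length(out) + 1L]] <- data.frame(
            start_nt = f + 1L + 3L * (i - 1L), length_aa = nxt[1L] - i,
            kind = "internal", frame = f)
          i <- nxt[1L] + 1L
        } else {
          out[[length(out) + 1L]] <- data.frame(
            start_nt = f + 1L + 3L * (i - 1L), length_aa = n_cod - i + 1L,
            kind = "terminal", frame = f)
          break
        }
      } else i <- i + 1L
    }
  }
  if (length(out) == 0L)
    return(data.frame(start_nt = integer(0), length_aa = integer(0),
                      kind = character(0), frame = integer(0)))
  do.call(rbind, out)
}

#' Positionally classify a transcript against the reference annotation
#'
#' Decision tree, in priority order: any same-strand base overlap with a
#' reference exon discards the transcript (`dropped_sense_overlap`); an
#' opposite-strand overlap touching at least one exon base is `exonAS`; an
#' opposite-strand overlap confined to intronic bases is `intronAS`; a
#' same-strand transcript fully contained in one intron is `INTRONIC`; a
#' transcript overlapping no gene span is `LINC`. A same-strand overlap
#' that is neither exonic nor intron-contained (e.g. straddling a gene
#' boundary through an intron) is discarded, with the evidence string
#' recording why.
#'
#' @param transcript A [GenomicRanges::GRanges] of the transcript's exons
#'   (one chromosome, explicit strand).
#' @param annotation An [annotation_set()].
#' @return List with `class` (one of `LINC`, `INTRONIC`, `exonAS`,
#'   `intronAS`, `discard`) and `evidence` (character).
#' @export
classify_position <- function(transcript, annotation) {
  check_one_chrom_strand(transcript, "transcript")
  tx <- GenomicRanges::sort(transcript)
  tx_strand <- as.character(BiocGenerics::strand(tx))[1L]
  exons_flat <- unlist(annotation$exons)
  spans <- annotation$spans
  same_gene <- as.character(BiocGenerics::strand(spans)) == tx_strand
  same_ex <- exons_flat[as.character(BiocGenerics::strand(exons_flat)) ==
                          tx_strand]
  anti_ex <- exons_flat[as.character(BiocGenerics::strand(exons_flat)) !=
                          tx_strand]
  ov_bases <- function(a, b) {
    if (length(b) == 0L) return(0L)
    sum(GenomicRanges::width(GenomicRanges::intersect(
      a, GenomicRanges::reduce(b, ignore.strand = TRUE),
      ignore.strand = TRUE)))
  }
  if (ov_bases(tx, same_ex) > 0L)
    return(list(class = "discard",
                evidence = "same-strand exonic overlap with a reference gene"))
  if (ov_bases(tx, anti_ex) > 0L)
    return(list(class = "exonAS",
                evidence = "opposite-strand overlap touching >=1 exonic base"))
  anti_spans <- spans[!same_gene]
  if (ov_bases(tx, anti_spans) > 0L)
    return(list(class = "intronAS",
                evidence = "opposite-strand overlap confined to intronic bases"))
  # same-strand, non-exonic: INTRONIC iff fully inside a single intron
  introns_flat <- unlist(annotation$introns)
  same_intr <- introns_flat[as.character(BiocGenerics::strand(introns_flat)) ==
                              tx_strand]
  span <- range(tx)
  if (length(same_intr) > 0L) {
    inside <- GenomicRanges::start(same_intr) <= GenomicRanges::start(span) &
      GenomicRanges::end(same_intr) >= GenomicRanges::end(span) &
      as.character(GenomicRanges::seqnames(same_intr)) ==
        as.character(GenomicRanges::seqnames(span))
    if (any(inside))
      return(list(class = "INTRONIC",
                  evidence = "same-strand, fully contained in a single intron"))
  }
  if (ov_bases(tx, spans) == 0L)
    return(list(class = "LINC", evidence = "no overlap with any gene span"))
  list(class = "discard",
       evidence = "same-strand gene overlap neither exonic nor intron-contained")
}

#' Apply the ORF-based coding-potential filter
#'
#' @param orfs ORF table from [find_orfs()].
#' @param config A [discovery_config()].
#' @param id Transcript id (for the homology hook).
#' @param sequence Spliced sequence (for the homology hook).
#' @return List with `verdict` (`"kept"` or `"dropped_coding"`) and
#'   `evidence`.
#' @export
coding_filter <- function(orfs, config = discovery_config(), id = NA,
                          sequence = NULL) {
  max_int <- suppressWarnings(max(orfs$length_aa[orfs$kind == "internal"], 0L))
  max_ter <- suppressWarnings(max(orfs$length_aa[orfs$kind == "terminal"], 0L))
  if (max_int > config$max_internal_orf_aa)
    return(list(verdict = "dropped_coding",
                evidence = sprintf("internal ORF of %d aa > %d", max_int,
                                   config$max_internal_orf_aa)))
  if (max_ter > config$max_terminal_orf_aa)
    return(list(verdict = "dropped_coding",
                evidence = sprintf("terminal ORF of %d aa > %d", max_ter,
                                   config$max_terminal_orf_aa)))
  if (!is.null(config$homology_hook) &&
      isTRUE(config$homology_hook(id, sequence)))
    return(list(verdict = "dropped_coding",
                evidence = "homology hook fired"))
  list(verdict = "kept",
       evidence = sprintf("max internal ORF %d aa, max terminal ORF %d aa",
                          max_int, max_ter))
}

#' Run the full lncRNA identification pipeline
#'
#' Applies, in order: spliced-length filter (> `min_length_nt`), positional
#' classification, ORF-based coding filter. A transcript failing a step
#' carries the first failing verdict; kept transcripts carry their
#' positional class.
#'
#' @param transcripts Named [GenomicRanges::GRangesList] of novel
#'   transcript exon models.
#' @param annotation An [annotation_set()].
#' @param sequences Named [Biostrings::DNAStringSet] (or character) of
#'   spliced sequences; every transcript must have one.
#' @param config A [discovery_config()].
#' @return A data frame catalog with one row per input transcript: `id`,
#'   `chrom`, `start`, `end`, `strand`, `class`, `spliced_length`,
#'   `max_internal_orf_aa`, `max_terminal_orf_aa`, `verdict`, `evidence`.
#' @export
discover_lncrnas <- function(transcripts, annotation, sequences,
                             config = discovery_config()) {
  ids <- names(transcripts)
  if (length(ids) == 0L)
    return(data.frame(id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), class = character(0),
                      spliced_length = integer(0),
                      max_internal_orf_aa = integer(0),
                      max_terminal_orf_aa = integer(0),
                      verdict = character(0), evidence = character(0)))
  seqs <- setNames(as.character(sequences), names(sequences))
  missing <- setdiff(ids, names(seqs))
  if (length(missing))
    stop("transcripts without sequence: ", paste(missing, collapse = ", "))
  rows <- lapply(ids, function(id) {
    ex <- transcripts[[id]]
    span <- range(ex)
    len <- sum(GenomicRanges::width(ex))
    row <- data.frame(
      id = id, chrom = as.character(GenomicRanges::seqnames(span)),
      start = GenomicRanges::start(span), end = GenomicRanges::end(span),
      strand = as.character(BiocGenerics::strand(span)),
      class = NA_character_, spliced_length = len,
      max_internal_orf_aa = NA_integer_, max_terminal_orf_aa = NA_integer_,
      verdict = NA_character_, evidence = NA_character_,
      stringsAsFactors = FALSE)
    if (len <= config$min_length_nt) {
      row$verdict <- "dropped_length"
      row$evidence <- sprintf("spliced length %d <= %d nt", len,
                              config$min_length_nt)
      return(row)
    }
    cls <- classify_position(ex, annotation)
    if (cls$class == "discard") {
      row$verdict <- "dropped_sense_overlap"
      row$evidence <- cls$evidence
      return(row)
    }
    row$class <- cls$class
    orfs <- find_orfs(seqs[[id]])
    row$max_internal_orf_aa <-
      as.integer(suppressWarnings(max(orfs$length_aa[orfs$kind == "internal"], 0L)))
    row$max_terminal_orf_aa <-
      as.integer(suppressWarnings(max(orfs$length_aa[orfs$kind == "terminal"], 0L)))
    cf <- coding_filter(orfs, config, id, seqs[[id]])
    row$verdict <- cf$verdict
    row$evidence <- paste0(cls$evidence, "; ", cf$evidence)
    row
  })
  do.call(rbind, rows)
}
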