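#' @import methods
#' @importFrom stats cor median prcomp quantile rnbinom rnorm runif sd
#'   setNames var wilcox.test phyper hclust cutree as.dist dist p.adjust
#' @importFrom utils head read.delim write.table
NULL

# All genomic coordinates in this package follow the Bioconductor convention:
# 1-based, closed intervals (GRanges/IRanges). Conversion to 0-based half-open
# happens only when writing BED.

#' Build an annotation set from per-gene exon models
#'
#' An annotation set is the in-memory form of a reference annotation: one
#' exon-structured model per protein-coding gene, plus derived gene spans and
#' introns (the gaps between consecutive exons of one gene). It is the
#' reference against which novel assembled transcripts are positionally
#' classified.
#'
#' @param exons_by_gene A named [GenomicRanges::GRangesList], one element per
#'   gene holding its exons. Exons of one gene must share chromosome and
#'   strand; strand must be `+` or `-`.
#' @return An object of class `annotation_set` with elements `exons`
#'   (GRangesList), `spans` (GRanges, one per gene), and `introns`
#'   (GRangesList, possibly empty per gene).
#' @export
annotation_set <- function(exons_by_gene) {
  if (is.null(names(exons_by_gene)) || anyDuplicated(names(exons_by_gene)))
    stop("exons_by_gene must be uniquely named by gene id")
  if (any(lengths(exons_by_gene) < 1L))
    stop("every gene must have at least one exon")
  exons_by_gene <- GenomicRanges::GRangesList(lapply(exons_by_gene, function(gr) {
    check_one_chrom_strand(gr, "gene")
    GenomicRanges::sort(gr)
  }))
  spans <- unlist(range(exons_by_gene))
  introns <- GenomicRanges::psetdiff(spans, exons_by_gene)
  structure(list(exons = exons_by_gene, spans = spans, introns = introns),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d genes on %d sequence(s), %d introns\n",
              length(x$spans), length(unique(as.character(
                GenomicRanges::seqnames(x$spans)))),
              sum(lengths(x$introns))))
  invisible(x)
}

check_one_chrom_strand <- function(gr, what) {
  if (length(unique(as.character(GenomicRanges::seqnames(gr)))) != 1L)
    stop(sprintf("%s has exons on more than one chromosome", what))
  s <- unique(as.character(BiocGenerics::strand(gr)))
  if (length(s) != 1L || !s %in% c("+", "-"))
    stop(sprintf("%s must be on a single explicit strand (+/-), got: %s",
                 what, paste(s, collapse = ",")))
  invisible(TRUE)
}

# cheap syntactic pre-scan so parse failures name the offending line
check_gff_syntax <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 8L)) {
    bad <- which(body)[which(nf < 8L)[1L]]
    stop(sprintf("malformed line %d in %s: fewer than 8 tab-separated fields",
                 bad, path))
  }
  invisible(TRUE)
}

#' Read a GFF3 reference annotation
#'
#' Reads gene/mRNA/exon features and assembles one exon model per gene
#' (exons of all mRNA isoforms of a gene are unioned). Exons may parent
#' either an mRNA or directly a gene.
#'
#' @param path Path to a GFF3 file.
#' @return An [annotation_set()].
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_gff_syntax(path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- tolower(as.character(gr$type))
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  genes <- gr[typ == "gene"]
  mrnas <- gr[typ == "mrna"]
  exons <- gr[typ == "exon"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  mrna2gene <- setNames(vapply(mrnas$Parent, `[`, "", 1L),
                        as.character(mrnas$ID))
  ex_par <- vapply(exons$Parent, function(p) if (length(p)) p[1L] else NA_character_, "")
  if (anyNA(ex_par)) stop("exon without a Parent attribute in ", path)
  gene_ids <- as.character(genes$ID)
  ex_gene <- ifelse(ex_par %in% names(mrna2gene), mrna2gene[ex_par], ex_par)
  if (!all(ex_gene %in% gene_ids))
    stop("exon Parent does not resolve to a gene: ",
         paste(unique(ex_par[!ex_gene %in% gene_ids]), collapse = ", "))
  grl <- lapply(split(exons, factor(ex_gene, levels = gene_ids)), function(e) {
    GenomicRanges::reduce(GenomicRanges::sort(granges_bare(e)))
  })
  # genes without exon children become single-exon models over their span
  none <- lengths(grl) == 0L
  if (any(none)) grl[none] <- as.list(S4Vectors::split(
    granges_bare(genes[match(names(grl)[none], gene_ids)]),
    seq_len(sum(none))))
  annotation_set(GenomicRanges::GRangesList(grl))
}

granges_bare <- function(gr) {
  GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                         IRanges::ranges(gr),
                         strand = BiocGenerics::strand(gr))
}

#' Write an annotation set as GFF3
#'
#' Emits one `gene` feature per gene and its `exon` children (exons parent
#' the gene directly). `read_gff3(write_gff3(x))` reproduces `x` exactly.
#'
#' @param annotation An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  gid <- names(annotation$exons)
  rows <- character(0)
  for (i in seq_along(gid)) {
    sp <- annotation$spans[i]
    rows <- c(rows, sprintf("%s\tlincberry\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                            as.character(GenomicRanges::seqnames(sp)),
                            GenomicRanges::start(sp), GenomicRanges::end(sp),
                            as.character(BiocGenerics::strand(sp)), gid[i]))
    ex <- annotation$exons[[i]]
    rows <- c(rows, sprintf("%s\tlincberry\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                            as.character(GenomicRanges::seqnames(ex)),
                            GenomicRanges::start(ex), GenomicRanges::end(ex),
                            as.character(BiocGenerics::strand(ex)), gid[i]))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read assembled transcript models from GTF
#'
#' One model per `transcript_id`, built from its exon records, labelled
#' `biotype = "novel"`. Transcripts with exons on mixed chromosomes or
#' strands, or without an explicit strand, are rejected: downstream
#' positional classification is strand-dependent and guessing would be
#' silent corruption.
#'
#' @param path Path to a GTF file with exon features carrying
#'   `transcript_id` attributes.
#' @return A named [GenomicRanges::GRangesList] (possibly empty), exons
#'   sorted by start, with a `biotype` column set to `"novel"` in its
#'   metadata.
#' @export
read_gtf_transcripts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_gff_syntax(path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L)
    return(GenomicRanges::GRangesList(setNames(list(), character(0))))
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stop("exon feature without transcript_id in ", path)
  grl <- S4Vectors::split(granges_bare(gr), as.character(gr$transcript_id))
  for (id in names(grl)) {
    s <- unique(as.character(BiocGenerics::strand(grl[[id]])))
    if (any(s == "*"))
      stop("transcript ", id, " is unstranded ('.'); strand is required")
    tryCatch(check_one_chrom_strand(grl[[id]], paste("transcript", id)),
             error = function(e) stop(conditionMessage(e), call. = FALSE))
  }
  grl <- GenomicRanges::GRangesList(lapply(grl, GenomicRanges::sort))
  S4Vectors::metadata(grl)$biotype <- "novel"
  grl
}

#' Read a multi-record FASTA file
#'
#' @param path Path to a (optionally gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the first whitespace-free
#'   token of each header. Duplicate ids are an error.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate FASTA ids: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  x
}

#' Write a lncRNA catalog as BED6
#'
#' Rows are sorted by (chrom, start) and coordinates are converted to the
#' BED convention (0-based half-open). Score is 0 for every record.
#'
#' @param calls A data frame with columns `id`, `chrom`, `start`, `end`
#'   (1-based, closed) and `strand`, e.g. the catalog from
#'   [discover_lncrnas()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(calls, path) {
  need <- c("id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(calls)))
    stop("calls must have columns: ", paste(need, collapse = ", "))
  o <- order(calls$chrom, calls$start)
  bed <- data.frame(chrom = calls$chrom[o],
                    start = calls$start[o] - 1L,
                    end = calls$end[o],
                    name = calls$id[o],
                    score = 0L,
                    strand = calls$strand[o])
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV count table
#'
#' Features in rows (first column = feature id), samples in columns with a
#' header row of sample ids. Entries must be non-negative integers.
#'
#' @param path Path to the TSV file.
#' @return An integer matrix with feature row names and sample column names.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in count table ", path)
  if (any(m < 0)) stop("negative count in ", path)
  if (any(m != round(m))) stop("non-integer count in ", path)
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix as TSV
#'
#' @param counts Integer matrix, features x samples.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract spliced transcript sequences
#'
#' Concatenates exon sequences in genomic order and reverse-complements the
#' result for minus-strand transcripts, so every returned sequence reads
#' 5'->3' in transcript space (where ORF and miRNA scans operate).
#'
#' @param transcripts A named [GenomicRanges::GRangesList] of exons.
#' @param genome A named [Biostrings::DNAStringSet] of chromosome sequences.
#' @return A [Biostrings::DNAStringSet], one spliced sequence per transcript.
#' @export
spliced_seq <- function(transcripts, genome) {
  out <- lapply(names(transcripts), function(id) {
    ex <- GenomicRanges::sort(transcripts[[id]])
    chrom <- as.character(GenomicRanges::seqnames(ex))[1L]
    if (!chrom %in% names(genome))
      stop("chromosome ", chrom, " absent from genome for transcript ", id)
    pieces <- Biostrings::extractAt(
      genome[[chrom]], IRanges::IRanges(GenomicRanges::start(ex),
                                        GenomicRanges::end(ex)))
    s <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
    if (as.character(BiocGenerics::strand(ex))[1L] == "-")
      s <- Biostrings::reverseComplement(s)
    s
  })
  setNames(Biostrings::DNAStringSet(out), names(transcripts))
}

#' Spliced length of transcript models
#'
#' @param transcripts A [GenomicRanges::GRangesList] of exons.
#' @return Integer vector of summed exon widths, named by transcript.
#' @export
spliced_length <- function(transcripts) {
  setNames(as.integer(sum(GenomicRanges::width(transcripts))),
           names(transcripts))
}

#' Write transcript models as GTF
#'
#' @param transcripts A named [GenomicRanges::GRangesList] of exons.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path, source = "lincberry") {
  rows <- character(0)
  for (id in names(transcripts)) {
    ex <- GenomicRanges::sort(transcripts[[id]])
    chrom <- as.character(GenomicRanges::seqnames(ex))[1L]
    st <- as.character(BiocGenerics::strand(ex))[1L]
    attr <- sprintf('gene_id "%s"; transcript_id "%s";', id, id)
    rows <- c(rows,
              sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s", chrom,
                      source, min(GenomicRanges::start(ex)),
                      max(GenomicRanges::end(ex)), st, attr),
              sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s", chrom, source,
                      GenomicRanges::start(ex), GenomicRanges::end(ex), st,
                      attr))
  }
  writeLines(rows, path)
  invisible(path)
}
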