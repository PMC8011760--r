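# Independent brute-force oracles. These deliberately avoid the package's
# data structures and algorithms: per-base integer scans instead of
# interval algebra, nested-loop codon walks instead of the vectorized ORF
# finder, and a recursive alignment enumerator instead of the banded
# scorer.

# ---- per-base positional classification oracle ----
# Expands every gene to plain integer base vectors and applies the class
# decision tree by set membership.
oracle_classify <- function(tx, ann) {
  tx_chrom <- as.character(GenomicRanges::seqnames(tx))[1L]
  tx_strand <- as.character(BiocGenerics::strand(tx))[1L]
  tx_bases <- unlist(lapply(seq_along(tx), function(i)
    GenomicRanges::start(tx)[i]:GenomicRanges::end(tx)[i]))
  genes <- lapply(seq_along(ann$spans), function(g) {
    ex <- ann$exons[[g]]
    list(chrom = as.character(GenomicRanges::seqnames(ann$spans))[g],
         strand = as.character(BiocGenerics::strand(ann$spans))[g],
         exon = unlist(lapply(seq_along(ex), function(i)
           GenomicRanges::start(ex)[i]:GenomicRanges::end(ex)[i])),
         span = GenomicRanges::start(ann$spans)[g]:GenomicRanges::end(ann$spans)[g],
         introns = if (length(ann$introns[[g]]) == 0L) list() else
           lapply(seq_along(ann$introns[[g]]), function(i)
             GenomicRanges::start(ann$introns[[g]])[i]:GenomicRanges::end(ann$introns[[g]])[i]))
  })
  genes <- Filter(function(g) g$chrom == tx_chrom, genes)
  same <- Filter(function(g) g$strand == tx_strand, genes)
  anti <- Filter(function(g) g$strand != tx_strand, genes)
  hits <- function(gs, what) any(vapply(gs, function(g)
    length(intersect(tx_bases, g[[what]])) > 0L, logical(1)))
  if (length(same) && hits(same, "exon")) return("discard")
  if (length(anti) && hits(anti, "exon")) return("exonAS")
  if (length(anti) && hits(anti, "span")) return("intronAS")
  contained <- any(vapply(same, function(g)
    any(vapply(g$introns, function(ib) all(tx_bases %in% ib), logical(1))),
    logical(1)))
  if (contained) return("INTRONIC")
  if (!hits(genes, "span")) return("LINC")
  "discard"
}

# ---- brute-force codon-scan ORF oracle ----
oracle_orfs <- function(seq) {
  s <- toupper(gsub("U", "T", seq))
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  out <- data.frame(start_nt = integer(0), length_aa = integer(0),
                    kind = character(0), frame = integer(0))
  for (f in 0:2) {
    pos <- seq(f + 1L, n - 2L, by = 3L)
    if (length(pos) == 0L) next
    cods <- vapply(pos, function(p) substr(s, p, p + 2L), "")
    stop_i <- which(cods %in% stops)
    # 5' runoff
    if (length(stop_i) && stop_i[1L] > 1L && cods[1L] != "ATG")
      out <- rbind(out, data.frame(start_nt = f + 1L,
                                   length_aa = stop_i[1L] - 1L,
                                   kind = "terminal", frame = f))
    shadow_until <- 0L
    for (i in seq_along(cods)) {
      if (cods[i] != "ATG" || i <= shadow_until) next
      later_stops <- stop_i[stop_i > i]
      if (length(later_stops)) {
        out <- rbind(out, data.frame(start_nt = pos[i],
                                     length_aa = later_stops[1L] - i,
                                     kind = "internal", frame = f))
        shadow_until <- later_stops[1L]
      } else {
        out <- rbind(out, data.frame(start_nt = pos[i],
                                     length_aa = length(cods) - i + 1L,
                                     kind = "terminal", frame = f))
        shadow_until <- length(cods)
      }
    }
  }
  out
}

# ---- exhaustive duplex alignment enumerator ----
# Enumerates every admissible pairing layout (contiguous; one target bulge
# of the length the window imposes at each interior gap; one 1-nt miRNA
# bulge at each interior position) and scores it by direct character
# comparison.
oracle_duplex_score <- function(mirna, window, scheme) {
  m <- strsplit(toupper(gsub("U", "T", mirna)), "")[[1L]]
  t <- strsplit(toupper(gsub("U", "T", window)), "")[[1L]]
  L <- length(m); Lw <- length(t)
  reg_end <- if (scheme == "A") 13L else 12L
  in_reg <- function(i) i >= 2L && i <= reg_end
  pen_pair <- function(mb, tb) {
    wc <- (mb == "A" && tb == "T") || (mb == "C" && tb == "G") ||
      (mb == "G" && tb == "C") || (mb == "T" && tb == "A")
    gu <- (mb == "G" && tb == "T") || (mb == "T" && tb == "G")
    if (wc) 0 else if (gu) 0.5 else 1
  }
  layout_score <- function(tpos, bulge_pen) {
    s <- bulge_pen
    for (i in seq_len(L)) {
      if (is.na(tpos[i])) next   # bulged miRNA nt charged via bulge_pen
      s <- s + pen_pair(m[i], t[tpos[i]]) * (if (in_reg(i)) 2 else 1)
    }
    s
  }
  best <- Inf
  d <- Lw - L
  if (d == 0L) best <- min(best, layout_score(Lw - seq_len(L) + 1L, 0))
  if (d >= 1L) for (k in 1:(L - 1L)) {
    tpos <- ifelse(seq_len(L) <= k, Lw - seq_len(L) + 1L,
                   Lw - seq_len(L) + 1L - d)
    best <- min(best, layout_score(tpos, 2 * d))
  }
  if (d == -1L) for (k in 2:(L - 1L)) {
    tpos <- ifelse(seq_len(L) < k, Lw - seq_len(L) + 1L,
                   ifelse(seq_len(L) == k, NA, Lw - seq_len(L) + 2L))
    best <- min(best, layout_score(tpos, 2))
  }
  best
}

# adjusted Rand index (independent of mclust, plain contingency formula)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# shared small fixture: annotation + planted transcripts, built once per run
fixture_env <- new.env()
default_fixture <- function() {
  if (!is.null(fixture_env$fx)) return(fixture_env$fx)
  ann <- sim_annotation(seed = 1)
  tx <- sim_transcripts(ann$annotation, ann$genome, seed = 1)
  fixture_env$fx <- list(ann = ann$annotation, genome = ann$genome,
                         tx = tx$transcripts,
                         labels = tx$truth$class_labels,
                         seqs = spliced_seq(tx$transcripts, ann$genome))
  fixture_env$fx
}

MIR21 <- "UCAUUGAGUGCAGCGUUGAUG"   # 21-nt miR397-like guide used across tests

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
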