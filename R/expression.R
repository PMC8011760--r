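# Count normalization, presence filtering, temporal pattern calling, and the
# genomic-landscape statistics (correlations, densities, feature metrics,
# neighbour distances).

#' TMM-style normalization to CPM
#'
#' Computes per-sample scaling factors as precision-weighted, doubly trimmed
#' means of M-values (log2 count ratios against a reference sample), then
#' counts per million against the factor-adjusted library size:
#' `cpm = count / (lib_size * factor) * 1e6`. The reference sample is the
#' one whose upper-quartile expression is closest to the mean upper
#' quartile across samples. M-values are taken on raw counts, so the factor
#' absorbs both sequencing depth and composition bias (a size-factor-style
#' variant of trimmed-mean normalization; columns that are exact scalar
#' multiples of one another recover those scalars). Factors are rescaled to
#' geometric mean 1.
#'
#' @param counts Non-negative matrix, features x samples.
#' @param trim_M Two-sided trim fraction on M-values (default 0.30).
#' @param trim_A Two-sided trim fraction on A-values (default 0.05).
#' @return List of class `tmm_expr` with `cpm` (matrix), `factors`
#'   (named, geometric mean 1), `lib_sizes`, and `ref_sample`.
#' @export
tmm_normalize <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("all-zero sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  uq <- apply(counts, 2L, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(k) {
    if (k == ref) return(1)
    yk <- counts[, k]; yr <- counts[, ref]
    use <- yk > 0 & yr > 0
    yk <- yk[use]; yr <- yr[use]
    if (length(yk) == 0L) stop("no co-expressed features against reference")
    M <- log2(yk / yr)
    A <- 0.5 * (log2(yk) + log2(yr))
    w <- 1 / ((lib[k] - yk) / (lib[k] * yk) + (lib[ref] - yr) / (lib[ref] * yr))
    n <- length(M)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) keep <- rep(TRUE, n)   # degenerate: nothing survives trim
    2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  cpm <- sweep(counts, 2L, lib * f, "/") * 1e6
  structure(list(cpm = cpm, factors = f, lib_sizes = lib,
                 ref_sample = colnames(counts)[ref]),
            class = "tmm_expr")
}

#' Presence filter on a count matrix
#'
#' A feature is kept iff it has strictly more than `min_reads` reads in
#' strictly more than `min_fraction` of the samples: with
#' `k = floor(min_fraction * n_samples)`, keeping requires at least `k + 1`
#' qualifying samples. For 72 samples at fraction 0.6 the threshold is 43
#' (a kept feature needs 44 or more).
#'
#' @param counts Matrix, features x samples.
#' @param min_reads Strict read-count threshold per sample (default 10).
#' @param min_fraction Strict sample-fraction threshold in (0,1)
#'   (default 0.6).
#' @return List with `kept` (feature ids) and `threshold_k` (integer).
#' @export
presence_filter <- function(counts, min_reads = 10L, min_fraction = 0.6) {
  if (min_fraction <= 0 || min_fraction >= 1)
    stop("min_fraction must be in (0,1)")
  k <- as.integer(floor(min_fraction * ncol(counts)))
  hits <- rowSums(counts > min_reads)
  list(kept = rownames(counts)[hits >= k + 1L], threshold_k = k)
}

#' Call temporal expression patterns
#'
#' Per feature, stage means of CPM are compared against `expressed_cpm`:
#' expressed in exactly one stage gives `stage_specific:<stage>`, in all
#' stages `constitutive`, in none `silent`, otherwise `other`.
#'
#' @param cpm CPM matrix, features x samples.
#' @param design Data frame with `sample` and `stage` columns covering the
#'   CPM columns.
#' @param expressed_cpm Expression threshold on the stage mean (default 1).
#' @return Data frame with `id` and `label`.
#' @export
call_patterns <- function(cpm, design, expressed_cpm = 1.0) {
  stages <- unique(design$stage)
  if (length(stages) < 2L) stop("need at least two stages")
  stage_means <- vapply(stages, function(s) {
    cols <- design$sample[design$stage == s]
    rowMeans(cpm[, cols, drop = FALSE])
  }, numeric(nrow(cpm)))
  on <- stage_means >= expressed_cpm
  n_on <- rowSums(on)
  label <- rep("other", nrow(cpm))
  label[n_on == length(stages)] <- "constitutive"
  label[n_on == 0L] <- "silent"
  one <- which(n_on == 1L)
  label[one] <- paste0("stage_specific:",
                       stages[apply(on[one, , drop = FALSE], 1L, which)])
  data.frame(id = rownames(cpm), label = label, stringsAsFactors = FALSE)
}

#' Pairwise sample correlation of log-stabilized expression
#'
#' Pearson correlation on `log2(cpm + 1)`. Zero-variance samples yield NA
#' against all others (recorded, not an error); the diagonal is 1.
#'
#' @param cpm CPM matrix, features x samples.
#' @return Symmetric samples x samples correlation matrix.
#' @export
sample_correlation <- function(cpm) {
  if (ncol(cpm) < 2L) stop("need at least two samples")
  x <- log2(cpm + 1)
  r <- suppressWarnings(cor(x))
  diag(r) <- 1
  r
}

#' Per-feature length, exon count and GC content
#'
#' @param transcripts Named [GenomicRanges::GRangesList] of exon models.
#' @param sequences Named spliced sequences (DNAStringSet or character).
#' @return Data frame with `id`, `length` (spliced nt), `n_exons`,
#'   `gc_percent` (100 x (G+C)/length, N bases excluded from both counts).
#' @export
feature_stats <- function(transcripts, sequences) {
  seqs <- setNames(toupper(as.character(sequences)), names(sequences))
  ids <- names(transcripts)
  gc <- vapply(ids, function(id) {
    s <- strsplit(seqs[[id]], "")[[1L]]
    s <- s[s != "N"]
    if (length(s) == 0L) return(NA_real_)
    100 * sum(s %in% c("G", "C")) / length(s)
  }, numeric(1))
  data.frame(id = ids,
             length = as.integer(sum(GenomicRanges::width(transcripts))),
             n_exons = lengths(transcripts),
             gc_percent = gc, row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare lncRNA and gene feature metrics
#'
#' Two-sided Wilcoxon rank-sum tests on length, exon count and GC content;
#' no multiplicity correction (each metric reported at face value).
#'
#' @param lnc_stats,gene_stats Data frames from [feature_stats()].
#' @return Named numeric vector of p-values (`length`, `n_exons`,
#'   `gc_percent`).
#' @export
compare_to_genes <- function(lnc_stats, gene_stats) {
  if (nrow(lnc_stats) < 2L || nrow(gene_stats) < 2L)
    stop("both groups need at least two features")
  vapply(c("length", "n_exons", "gc_percent"), function(m) {
    suppressWarnings(wilcox.test(lnc_stats[[m]], gene_stats[[m]],
                                 alternative = "two.sided"))$p.value
  }, numeric(1))
}

#' Genomic bin density of features
#'
#' Each feature is assigned to the bin containing its start; the last
#' partial bin is included. Bin totals conserve the feature count.
#'
#' @param features Data frame with `chrom` and `start` (1-based) columns,
#'   or a GRanges.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param bin Bin width in nt (default 100 kb).
#' @return Named list per chromosome of integer bin-count vectors.
#' @export
bin_density <- function(features, chrom_sizes, bin = 100000L) {
  if (bin <= 0L) stop("bin must be > 0")
  if (methods::is(features, "GRanges"))
    features <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(features)),
      start = GenomicRanges::start(features))
  out <- lapply(names(chrom_sizes), function(ch) {
    n_bins <- as.integer(ceiling(chrom_sizes[[ch]] / bin))
    v <- integer(max(n_bins, 1L))
    st <- features$start[features$chrom == ch]
    if (any(st > chrom_sizes[[ch]] | st < 1L))
      stop("feature start beyond chromosome ", ch)
    if (length(st)) {
      tab <- table(((st - 1L) %/% bin) + 1L)
      v[as.integer(names(tab))] <- as.integer(tab)
    }
    v
  })
  setNames(out, names(chrom_sizes))
}

#' Signed distance from intergenic lncRNAs to their nearest gene
#'
#' The nearest gene is chosen by genomic gap between spans (0 if they
#' overlap). The value is measured from the lincRNA transcription start
#' site (strand-aware) to the near gene boundary, negative when the
#' lincRNA lies on the gene's 5' side and positive on its 3' side (sides
#' taken in the gene's orientation). Chromosomes without genes yield NA.
#'
#' @param lincs [GenomicRanges::GRanges] of lincRNA spans (stranded).
#' @param genes [GenomicRanges::GRanges] of gene spans (stranded).
#' @return Data frame with `id` (names of `lincs` if any), `nearest_gene`,
#'   `distance`.
#' @export
neighbor_distance <- function(lincs, genes) {
  ids <- if (!is.null(names(lincs))) names(lincs)
         else sprintf("linc%d", seq_along(lincs))
  res <- data.frame(id = ids, nearest_gene = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  if (length(genes) == 0L) return(res)
  gnames <- if (!is.null(names(genes))) names(genes)
            else sprintf("gene%d", seq_along(genes))
  hit <- GenomicRanges::distanceToNearest(lincs, genes, ignore.strand = TRUE)
  for (r in seq_along(hit)) {
    i <- S4Vectors::queryHits(hit)[r]
    j <- S4Vectors::subjectHits(hit)[r]
    l <- lincs[i]; g <- genes[j]
    res$nearest_gene[i] <- gnames[j]
    if (S4Vectors::mcols(hit)$distance[r] == 0L) { res$distance[i] <- 0; next }
    g_plus <- as.character(BiocGenerics::strand(g)) != "-"
    l_tss <- if (as.character(BiocGenerics::strand(l)) == "-")
      GenomicRanges::end(l) else GenomicRanges::start(l)
    left_of_gene <- GenomicRanges::end(l) < GenomicRanges::start(g)
    on_5prime <- left_of_gene == g_plus
    if (on_5prime) {
      g5 <- if (g_plus) GenomicRanges::start(g) else GenomicRanges::end(g)
      res$distance[i] <- -abs(g5 - l_tss)
    } else {
      g3 <- if (g_plus) GenomicRanges::end(g) else GenomicRanges::start(g)
      res$distance[i] <- abs(l_tss - g3)
    }
  }
  res
}
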