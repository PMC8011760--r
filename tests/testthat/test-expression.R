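test_that("TMM factors: identical columns, scalar multiples, cpm algebra", {
  set.seed(21)
  base <- rpois(1000, 60) + 1L
  m_id <- matrix(base, 1000, 3,
                 dimnames = list(paste0("f", 1:1000), paste0("s", 1:3)))
  expect_equal(unname(tmm_normalize(m_id)$factors), rep(1, 3))
  # columns that are exact scalar multiples recover the scalars
  sc <- c(1, 2, 4, 3)
  m_sc <- sweep(matrix(base, 1000, 4), 2, sc, "*")
  dimnames(m_sc) <- list(paste0("f", 1:1000), paste0("s", 1:4))
  e <- tmm_normalize(m_sc)
  expect_equal(unname(e$factors), sc / exp(mean(log(sc))), tolerance = 1e-6)
  expect_equal(unname(e$factors[2] / e$factors[1]), 2, tolerance = 1e-6)
  # cpm column sums are 1e6 / factor
  expect_equal(unname(colSums(e$cpm)), unname(1e6 / e$factors))
  expect_equal(exp(mean(log(e$factors))), 1, tolerance = 1e-9)
  m0 <- m_id; m0[, 2] <- 0L
  expect_error(tmm_normalize(m0), "s2")
})

test_that("TMM agrees with edgeR on equal-depth libraries", {
  skip_if_not_installed("edgeR")
  # when library sizes are equal, raw-count M-values coincide with
  # depth-adjusted ones, so the factors must match edgeR's
  cm <- sim_counts(n_features = 500, n_specific_per_stage = 0,
                   dispersion = 0.2, seed = 13)
  counts <- cm$counts + 1L
  lib <- colSums(counts)
  eq <- round(sweep(counts, 2, mean(lib) / lib, "*"))
  storage.mode(eq) <- "integer"
  # force exactly equal library sizes by padding a balance feature
  pad <- max(colSums(eq)) - colSums(eq)
  eq <- rbind(eq, balance = pad)
  ours <- tmm_normalize(eq)$factors
  theirs <- edgeR::calcNormFactors(eq, method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 0.02)
})

test_that("presence filter reproduces the 43-of-72 arithmetic and is monotone", {
  set.seed(3)
  n <- 72L
  counts <- matrix(rpois(100 * n, 30), 100, n,
                   dimnames = list(paste0("f", 1:100), paste0("s", 1:n)))
  counts["f1", ] <- c(rep(11L, 44L), rep(0L, 28L))
  counts["f2", ] <- c(rep(11L, 43L), rep(0L, 29L))
  counts["f3", ] <- rep(10L, n)       # "more than 10" is strict
  pf <- presence_filter(counts)
  expect_equal(pf$threshold_k, 43L)
  expect_true("f1" %in% pf$kept)
  expect_false("f2" %in% pf$kept)
  expect_false("f3" %in% pf$kept)
  small <- presence_filter(counts[, 1:10])
  expect_equal(small$threshold_k, 6L)
  # monotone: raising either threshold never adds features
  for (mr in c(10, 20, 40)) for (mf in c(0.4, 0.6, 0.8)) {
    a <- presence_filter(counts, mr, mf)$kept
    b <- presence_filter(counts, mr + 5, mf)$kept
    d <- presence_filter(counts, mr, min(mf + 0.1, 0.99))$kept
    expect_true(all(b %in% a)); expect_true(all(d %in% a))
  }
})

test_that("pattern calling matches definitions and recovers planted truth", {
  cpm <- rbind(a = c(5, 5, 0, 0, 0, 0), b = c(5, 5, 6, 6, 7, 7),
               c = c(0, 0, 0, 0, 0, 0), d = c(5, 5, 6, 6, 0, 0))
  colnames(cpm) <- paste0(rep(c("Fv1", "Fv2", "Fv3"), each = 2), "_R",
                          1:2)
  design <- data.frame(sample = colnames(cpm),
                       stage = rep(c("Fv1", "Fv2", "Fv3"), each = 2))
  pc <- call_patterns(cpm, design)
  expect_equal(pc$label,
               c("stage_specific:Fv1", "constitutive", "silent", "other"))
  cm <- sim_counts(seed = 1)   # default design: 3 stages x 3 reps, n = 200
  expr <- tmm_normalize(cm$counts)
  got <- call_patterns(expr$cpm, cm$design)
  acc <- mean(got$label == unname(cm$truth$pattern[got$id]))
  cat(sprintf("\n  pattern recovery rate: %.3f\n", acc))
  expect_gte(acc, 0.95)
})

test_that("sample correlations: duplicates, nulls, symmetry, zero variance", {
  set.seed(5)
  cpm <- matrix(2^rnorm(1000 * 4, 5), 1000, 4,
                dimnames = list(NULL, paste0("s", 1:4)))
  cpm[, 2] <- cpm[, 1]
  r <- sample_correlation(cpm)
  expect_equal(r["s1", "s2"], 1.0)
  expect_identical(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 4))
  offdiag <- r[upper.tri(r)][-1]      # exclude the duplicated pair
  expect_true(all(abs(offdiag) < 0.1))
  cpm0 <- cpm; cpm0[, 3] <- 7
  r0 <- sample_correlation(cpm0)
  expect_true(is.na(r0["s3", "s1"]))
  expect_equal(r0["s3", "s3"], 1)
})

test_that("feature stats and group comparison behave", {
  grl <- GenomicRanges::GRangesList(
    a = GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 11), c(4, 12)),
                               strand = "+"),
    b = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 4), strand = "+"))
  fs <- feature_stats(grl, c(a = "GCGCAT", b = "ATAT"))
  expect_equal(fs$gc_percent, c(2 / 3 * 100, 0))
  expect_equal(fs$length, c(6L, 4L))
  expect_equal(fs$n_exons, c(2L, 1L))
  gc_oracle <- function(s) {
    v <- strsplit(s, "")[[1]]
    100 * sum(v %in% c("G", "C")) / sum(v != "N")
  }
  expect_equal(fs$gc_percent[1], gc_oracle("GCGCAT"))

  set.seed(9)
  g1 <- data.frame(length = rpois(100, 500), n_exons = rpois(100, 2) + 1,
                   gc_percent = rnorm(100, 40, 3))
  same <- compare_to_genes(g1, g1)
  expect_true(all(same > 0.99))
  g2 <- g1; g2$length <- g2$length + 10000
  expect_lt(compare_to_genes(g1, g2)[["length"]], 1e-10)
  # invariance to within-group relabeling
  expect_equal(compare_to_genes(g1[sample(100), ], g2),
               compare_to_genes(g1, g2))
})

test_that("bin density conserves counts and flags out-of-range features", {
  feats <- data.frame(chrom = "chr1", start = c(10, 150050, 150060))
  bd <- bin_density(feats, c(chr1 = 200000), bin = 100000)
  expect_equal(bd$chr1, c(1L, 2L))
  expect_equal(sum(unlist(bd)), 3L)
  empty <- bin_density(feats[0, ], c(chr1 = 200000, chr2 = 50000))
  expect_true(all(unlist(empty) == 0L))
  fx <- default_fixture()
  spans <- unlist(range(fx$tx))
  sizes <- setNames(Biostrings::width(fx$genome), names(fx$genome))
  bd2 <- bin_density(data.frame(
    chrom = as.character(GenomicRanges::seqnames(spans)),
    start = GenomicRanges::start(spans)), sizes, bin = 10000)
  expect_equal(sum(unlist(bd2)), length(spans))
  expect_error(bin_density(data.frame(chrom = "chr1", start = 300000),
                           c(chr1 = 200000)), "beyond")
})

test_that("neighbour distances follow the sign convention and the all-pairs oracle", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 8000),
                                  strand = "+")
  up <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4000, 4500),
                               strand = "+")
  expect_equal(neighbor_distance(up, genes)$distance, -1000)
  down <- GenomicRanges::GRanges("chr1", IRanges::IRanges(8500, 9000),
                                 strand = "+")
  expect_equal(neighbor_distance(down, genes)$distance, 500)
  over <- GenomicRanges::GRanges("chr1", IRanges::IRanges(7900, 8200),
                                 strand = "+")
  expect_equal(neighbor_distance(over, genes)$distance, 0)
  # nearest-gene choice equals the exhaustive all-pairs minimum gap
  fx <- default_fixture()
  linc_ids <- names(fx$labels)[fx$labels == "LINC"]
  lincs <- unlist(range(fx$tx[linc_ids]))
  spans <- fx$ann$spans
  nd <- neighbor_distance(lincs, spans)
  for (i in seq_along(lincs)) {
    gaps <- vapply(seq_along(spans), function(j) {
      if (as.character(GenomicRanges::seqnames(spans))[j] !=
          as.character(GenomicRanges::seqnames(lincs))[i]) return(Inf)
      max(0, max(GenomicRanges::start(spans)[j] -
                   GenomicRanges::end(lincs)[i],
                 GenomicRanges::start(lincs)[i] -
                   GenomicRanges::end(spans)[j]))
    }, numeric(1))
    j_got <- match(nd$nearest_gene[i], names(spans))
    expect_equal(gaps[j_got], min(gaps))   # tie-safe: same minimal gap
  }
  none <- GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 100),
                                 strand = "+")
  expect_true(is.na(neighbor_distance(none, genes[0])$distance))
})
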