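revcomp_dna <- function(s) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(gsub("U", "T", toupper(s)))))

test_that("duplex scoring worked examples: perfect, wobble, seed mismatch", {
  win <- revcomp_dna(MIR21)
  sd0 <- score_duplex(MIR21, win, "A")
  expect_equal(sd0$score, 0)
  expect_true(all(sd0$alignment$states == "match"))
  # single G:U wobble outside both seed regions scores 0.5: place it at
  # the first miRNA U past position 13 by pairing it with a target G
  m <- strsplit(MIR21, "")[[1]]
  w <- strsplit(win, "")[[1]]
  u_pos <- which(m == "U" & seq_along(m) >= 14)[1]
  w2 <- w; w2[21 - u_pos + 1] <- "G"
  sd1 <- score_duplex(MIR21, paste(w2, collapse = ""), "A")
  expect_equal(sd1$score, 0.5)
  expect_equal(sd1$alignment$states[u_pos], "GU")
  # single mismatch at position 5: doubled inside the seed region
  w3 <- w
  w3[21 - 5 + 1] <- switch(m[5], A = "A", C = "C", G = "A", U = "C")
  sd2 <- score_duplex(MIR21, paste(w3, collapse = ""), "A")
  expect_equal(sd2$score, 2.0)
  expect_equal(sd2$alignment$states[5], "mismatch")
})

test_that("scheme A and B differ only at miRNA position 13", {
  win <- strsplit(revcomp_dna(MIR21), "")[[1]]
  m <- strsplit(MIR21, "")[[1]]
  w13 <- win
  w13[21 - 13 + 1] <- switch(m[13], A = "A", C = "C", G = "A", U = "C")
  sA <- score_duplex(MIR21, paste(w13, collapse = ""), "A")$score
  sB <- score_duplex(MIR21, paste(w13, collapse = ""), "B")$score
  expect_equal(sA, 2.0)      # doubled in region 2-13
  expect_equal(sB, 1.0)      # outside region 2-12
})

test_that("duplex scorer equals the exhaustive enumerator on short windows", {
  set.seed(31)
  core <- revcomp_dna(MIR21)
  windows <- c(
    core,
    vapply(1:8, function(i) {                          # mutated contiguous
      w <- strsplit(core, "")[[1]]
      idx <- sample(21, sample(1:3, 1))
      w[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
      paste(w, collapse = "")
    }, ""),
    vapply(1:6, function(i) {                          # bulged windows
      w <- strsplit(core, "")[[1]]
      b <- sample(1:4, 1)
      at <- sample(2:19, 1)
      paste(append(w, sample(c("A", "C", "G", "T"), b, replace = TRUE),
                   after = at), collapse = "")
    }, ""),
    vapply(1:4, function(i) {                          # 1-nt deletion
      w <- strsplit(core, "")[[1]]
      paste(w[-sample(2:20, 1)], collapse = "")
    }, ""))
  for (scheme in c("A", "B")) for (w in windows) {
    expect_equal(score_duplex(MIR21, w, scheme)$score,
                 oracle_duplex_score(MIR21, w, scheme),
                 label = sprintf("scheme %s window %s", scheme, w))
  }
})

test_that("score is monotone in the number of planted seed mismatches", {
  w <- strsplit(revcomp_dna(MIR21), "")[[1]]
  m <- strsplit(MIR21, "")[[1]]
  positions <- c(3, 5, 7, 9, 11, 12)
  scores <- numeric(0)
  for (k in 0:length(positions)) {
    wk <- w
    for (p in head(positions, k))
      wk[21 - p + 1] <- switch(m[p], A = "A", C = "C", G = "A", U = "C")
    scores <- c(scores, score_duplex(MIR21, paste(wk, collapse = ""),
                                     "A")$score)
  }
  expect_true(all(diff(scores) >= 0))
})

test_that("target scan finds planted consensus sites and nothing else", {
  set.seed(41)
  flank1 <- random_seq(150, 42); flank2 <- random_seq(120, 43)
  seqs <- c(hit = paste0(substr(flank1, 1, 100), revcomp_dna(MIR21),
                         substr(flank1, 101, 150)),
            null = random_seq(400, 44))
  sites <- scan_targets(MIR21, seqs)
  tab <- sites_table(sites)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$transcript, "hit")
  expect_equal(c(tab$start, tab$end), c(101L, 121L))
  expect_equal(tab$score_A, 0); expect_equal(tab$score_B, 0)
  # consensus sites pass both schemes by construction
  expect_true(all(tab$score_A <= 4 & tab$score_B <= 4))
  # six seed mismatches (mut3-style disruption) abolish the site
  w6 <- strsplit(revcomp_dna(MIR21), "")[[1]]
  m <- strsplit(MIR21, "")[[1]]
  for (p in c(3, 5, 7, 9, 11, 13))
    w6[21 - p + 1] <- switch(m[p], A = "A", C = "C", G = "A", U = "C")
  mut3 <- c(mut = paste0(substr(flank1, 1, 100), paste(w6, collapse = ""),
                         substr(flank1, 101, 150)))
  expect_length(scan_targets(MIR21, mut3), 0L)
})

test_that("consensus set is contained in each scheme's hit set", {
  set.seed(51)
  # a site with one non-seed mismatch passes both schemes; verify the
  # consensus site also appears in per-scheme scans run at the same cutoff
  w <- strsplit(revcomp_dna(MIR21), "")[[1]]
  m <- strsplit(MIR21, "")[[1]]
  w[21 - 16 + 1] <- switch(m[16], A = "A", C = "C", G = "A", U = "C")
  seqs <- c(t1 = paste0(random_seq(60, 52), paste(w, collapse = ""),
                        random_seq(60, 53)))
  sites <- scan_targets(MIR21, seqs)
  expect_equal(length(sites), 1L)
  s <- sites[[1]]
  expect_lte(s$score_A, 4); expect_lte(s$score_B, 4)
  expect_true(s$consensus)
})

test_that("duplex energies order as expected and bulges destabilize", {
  win <- revcomp_dna(MIR21)
  perfect <- score_duplex(MIR21, win, "A")
  e_perfect <- duplex_energy(perfect$alignment, MIR21)
  w <- strsplit(win, "")[[1]]
  m <- strsplit(MIR21, "")[[1]]
  w[21 - 11 + 1] <- switch(m[11], A = "A", C = "C", G = "A", U = "C")
  central <- score_duplex(MIR21, paste(w, collapse = ""), "A")
  expect_lt(e_perfect, duplex_energy(central$alignment, MIR21))
  # contiguous decoy is at least as stable as the 3-nt-bulged eTM site
  etm_win <- paste(append(strsplit(win, "")[[1]], c("C", "A", "C"),
                          after = 21 - 11 + 1), collapse = "")
  etm <- score_duplex(MIR21, etm_win, "A")
  expect_lte(e_perfect, duplex_energy(etm$alignment, MIR21))
  # an alignment with no paired positions carries zero energy
  no_pairs <- list(states = rep("mismatch", 21), target_pos = 21:1,
                   bulge = NULL)
  expect_equal(duplex_energy(no_pairs, MIR21), 0)
})

test_that("cleavage prediction: canonical bond, bulge blocks, strand-invariant", {
  seqs <- c(t1 = paste0(random_seq(100, 61), revcomp_dna(MIR21),
                        random_seq(80, 62)))
  site <- scan_targets(MIR21, seqs)[[1]]
  pc <- predict_cleavage(site)
  expect_equal(pc$five_prime_mirna_nt, 10L)
  expect_equal(pc$target_bond, c(111L, 112L))
  # miRNA nt k pairs target 122 - k: nt 10 -> 112, nt 11 -> 111
  expect_equal(site$alignment$target_pos[10], 112L)
  expect_equal(site$alignment$target_pos[11], 111L)
  # an eTM bulge between 10 and 11 interrupts the scissile bond
  ps <- plant_target_sites(c(tb = random_seq(200, 63)), MIR21,
                           data.frame(transcript = "tb", position = 40L,
                                      type = "eTM_bulge"), seed = 1)
  etm_win <- substr(ps$sequences[["tb"]], 40L, 40L + 23L)
  etm_site <- list(transcript = "tb", start = 40L, end = 40L + 23L,
                   score_A = 6, score_B = 6,
                   alignment = score_duplex(MIR21, etm_win, "A")$alignment,
                   mirna = MIR21, consensus = TRUE)
  expect_null(predict_cleavage(etm_site))
  # transcript-space result is strand-independent: the same spliced
  # sequence extracted from a minus-strand gene scores identically
  genome <- Biostrings::DNAStringSet(c(chr1 = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seqs[["t1"]])))))
  tx <- GenomicRanges::GRangesList(t1 = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, nchar(seqs[["t1"]])), strand = "-"))
  s2 <- as.character(spliced_seq(tx, genome)[[1]])
  expect_identical(s2, unname(seqs[["t1"]]))
  site2 <- scan_targets(MIR21, c(t1 = s2))[[1]]
  expect_equal(predict_cleavage(site2)$target_bond, c(111L, 112L))
})

test_that("mimic classification: cleavable, canonical eTM, noncanonical", {
  seqs <- c(t1 = paste0(random_seq(100, 71), revcomp_dna(MIR21),
                        random_seq(80, 72)))
  site <- scan_targets(MIR21, seqs)[[1]]
  expect_equal(classify_mimic(site)$category, "cleavable_target")
  # canonical eTM: 3-nt target bulge between miRNA positions 10 and 11
  ps <- plant_target_sites(c(t2 = random_seq(300, 73)), MIR21,
                           data.frame(transcript = "t2", position = 120L,
                                      type = "eTM_bulge"), seed = 1)
  win <- substr(ps$sequences[["t2"]], 120L, 120L + 23L)
  aln <- score_duplex(MIR21, win, "A")
  etm_site <- list(transcript = "t2", start = 120L, end = 120L + 23L,
                   score_A = aln$score, score_B = aln$score,
                   alignment = aln$alignment, mirna = MIR21,
                   consensus = TRUE)
  etm_site$alignment$target_pos <- etm_site$alignment$target_pos + 119L
  expect_equal(classify_mimic(etm_site)$category, "canonical_eTM")
  # RACE with modal offset 12 upgrades a contiguous site
  clones <- sim_race_clones("t1", site$start, site$end, 21L,
                            modal_offset = 12L, n_clones = 20L, noise = 0,
                            seed = 1)
  tal <- tally_cleavage(clones, site)
  mc <- classify_mimic(site, tal)
  expect_equal(mc$category, "noncanonical_mimic")
  # canonical offset 10 does not upgrade
  clones10 <- sim_race_clones("t1", site$start, site$end, 21L,
                              modal_offset = 10L, n_clones = 20L, noise = 0,
                              seed = 1)
  expect_equal(classify_mimic(site, tally_cleavage(clones10, site))$category,
               "cleavable_target")
  wrong <- tal; wrong$transcript <- "other"
  expect_error(classify_mimic(site, wrong), "other")
})

test_that("conservation window: identity, substitutions, alignment score", {
  ref <- random_seq(200, 81)
  cw <- conservation_window(ref, c(h1 = ref, h2 = ref), 50, 70)
  expect_equal(cw$window_mean, 1.0)
  expect_equal(unname(cw$per_column), rep(1, 21))
  h2 <- ref
  substr(h2, 55, 55) <- if (substr(ref, 55, 55) == "A") "C" else "A"
  substr(h2, 60, 60) <- if (substr(ref, 60, 60) == "G") "T" else "G"
  cw2 <- conservation_window(ref, c(hom = h2), 50, 70)
  expect_equal(cw2$window_mean, 19 / 21)
  expect_equal(alignment_score("ACGU", "ACGU"), 4)
  expect_error(conservation_window(ref, c(h = ""), 50, 70), "empty")
})
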