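# Plant miRNA target-site scanning under two position-weighted penalty
# schemes with consensus intersection, duplex free energy, canonical
# cleavage-bond prediction, endogenous target-mimic classification, and
# target-site conservation across homologs.
#
# Conventions: miRNA positions are numbered 1..L from the 5' end; the
# duplex is antiparallel, so miRNA nt 1 pairs the 3'-most base of the
# target window. Target coordinates are transcript-space, 1-based.
# Pairing logic treats T and U as equivalent.

base_code <- function(s) {
  x <- strsplit(toupper(gsub("U", "T", s)), "")[[1L]]
  m <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  if (any(!x %in% names(m))) stop("non-ACGT/U symbol in sequence")
  unname(m[x])
}

# pair state between miRNA base (ACGU as 1..4, U coded as T=4) and target
# DNA base: 0 = WC match, 1 = G:U wobble, 2 = mismatch
PAIR_STATE <- local({
  m <- matrix(2L, 4L, 4L)     # rows: miRNA A C G U; cols: target A C G T
  m[1L, 4L] <- 0L  # A:U(T)
  m[2L, 3L] <- 0L  # C:G
  m[3L, 2L] <- 0L  # G:C
  m[4L, 1L] <- 0L  # U:A
  m[3L, 4L] <- 1L  # G:U wobble (target T read as U)
  m[4L, 3L] <- 1L  # U:G wobble
  m
})

scheme_region <- function(scheme) switch(scheme, A = c(2L, 13L),
                                         B = c(2L, 12L),
                                         stop("scheme must be 'A' or 'B'"))

#' Score a miRNA/target duplex under a position-weighted penalty scheme
#'
#' Finds the optimal banded alignment of the miRNA against a target window
#' (at most one bulge of up to 4 nt, on either strand), minimizing the total
#' penalty: mismatch 1, G:U wobble 0.5, bulged nucleotide 2. Pairing
#' penalties are doubled inside the scheme's seed-proximal region (miRNA
#' positions 2-13 for scheme A, 2-12 for scheme B); bulge penalties are
#' position-independent, since a bulge sits between miRNA positions rather
#' than at one. The window length fixes the bulge size:
#' `length(window) - L` extra target nt form a target bulge, a one-nt
#' deficit forms a miRNA bulge.
#'
#' @param mirna miRNA sequence, 5'->3' (RNA or DNA alphabet), length 20-24.
#' @param target_window Target subsequence, 5'->3', length in
#'   `[L - 1, L + 4]`.
#' @param scheme `"A"` or `"B"`.
#' @return List with `score` and `alignment`; the alignment has `states`
#'   (per miRNA position: `match`, `GU`, `mismatch`, `mirna_bulge`),
#'   `target_pos` (window-relative 1-based position paired by each miRNA
#'   nt, NA for bulged miRNA nt), and `bulge`
#'   (`list(kind, len, after_mirna_pos)` or NULL).
#' @export
score_duplex <- function(mirna, target_window, scheme = "A") {
  m <- base_code(mirna); t <- base_code(target_window)
  L <- length(m); Lw <- length(t)
  if (L < 20L || L > 24L) stop("miRNA length must be 20-24 nt")
  if (Lw < L - 1L || Lw > L + 4L)
    stop("window length must be within [L-1, L+4]")
  region <- scheme_region(scheme)
  wt <- ifelse(seq_len(L) >= region[1L] & seq_len(L) <= region[2L], 2, 1)
  pair_pen <- c(`0` = 0, `1` = 0.5, `2` = 1)
  best <- NULL
  consider <- function(states, target_pos, bulge, score) {
    if (is.null(best) || score < best$score)
      best <<- list(score = score,
                    alignment = list(states = states, target_pos = target_pos,
                                     bulge = bulge))
  }
  delta <- Lw - L
  if (delta == 0L) {
    tp <- Lw - seq_len(L) + 1L
    st <- PAIR_STATE[cbind(m, t[tp])]
    consider(c("match", "GU", "mismatch")[st + 1L], tp, NULL,
             sum(pair_pen[st + 1L] * wt))
  } else if (delta >= 1L) {
    b <- delta
    for (k in seq_len(L - 1L)) {       # target bulge between miRNA k, k+1
      tp <- ifelse(seq_len(L) <= k, Lw - seq_len(L) + 1L,
                   Lw - seq_len(L) + 1L - b)
      st <- PAIR_STATE[cbind(m, t[tp])]
      consider(c("match", "GU", "mismatch")[st + 1L], tp,
               list(kind = "target_bulge", len = b, after_mirna_pos = k),
               sum(pair_pen[st + 1L] * wt) + 2 * b)
    }
  } else {                              # delta == -1: one-nt miRNA bulge
    for (k in 2:(L - 1L)) {
      tp <- ifelse(seq_len(L) < k, Lw - seq_len(L) + 1L,
                   ifelse(seq_len(L) == k, NA_integer_,
                          Lw - seq_len(L) + 2L))
      paired <- !is.na(tp)
      st <- integer(L); st[paired] <- PAIR_STATE[cbind(m[paired], t[tp[paired]])]
      states <- c("match", "GU", "mismatch")[st + 1L]
      states[!paired] <- "mirna_bulge"
      pen <- sum(pair_pen[st[paired] + 1L] * wt[paired]) + 2
      consider(states, tp,
               list(kind = "mirna_bulge", len = 1L, after_mirna_pos = k - 1L),
               pen)
    }
  }
  best
}

# vectorized penalty of all contiguous placements of one pairing layout:
# scores every window start at once for a fixed (window length, bulge
# config). Used by scan_targets; score_duplex is the per-window reference.
scan_scheme <- function(tcode, mcode, scheme, Lw, bulge_kind = "none",
                        k = NA_integer_, b = 0L) {
  L <- length(mcode)
  n_start <- length(tcode) - Lw + 1L
  if (n_start < 1L) return(numeric(0))
  region <- scheme_region(scheme)
  wt <- ifelse(seq_len(L) >= region[1L] & seq_len(L) <= region[2L], 2, 1)
  pair_pen <- c(0, 0.5, 1)
  starts <- seq_len(n_start)
  total <- numeric(n_start)
  for (i in seq_len(L)) {
    off <- switch(bulge_kind,
                  none = Lw - i + 1L,
                  target = if (i <= k) Lw - i + 1L else Lw - i + 1L - b,
                  mirna = if (i < k) Lw - i + 1L
                          else if (i == k) NA_integer_ else Lw - i + 2L)
    if (is.na(off)) next
    st <- PAIR_STATE[cbind(i0 = mcode[i], tcode[starts + off - 1L])]
    total <- total + pair_pen[st + 1L] * wt[i]
  }
  if (bulge_kind == "target") total <- total + 2 * b
  else if (bulge_kind == "mirna") total <- total + 2
  total
}

# all (start, width, score) hits of one scheme on one transcript sequence
scheme_hits <- function(tcode, mcode, scheme, cutoff) {
  L <- length(mcode)
  hits <- list()
  add <- function(start, width, score) {
    keep <- score <= cutoff
    if (any(keep))
      hits[[length(hits) + 1L]] <<- data.frame(start = which(keep),
                                               width = width,
                                               score = score[keep])
  }
  add(NA, L, scan_scheme(tcode, mcode, scheme, L, "none"))
  for (b in 1:4) {
    Lw <- L + b
    if (length(tcode) < Lw) break
    best <- NULL
    for (k in seq_len(L - 1L)) {
      sc <- scan_scheme(tcode, mcode, scheme, Lw, "target", k, b)
      best <- if (is.null(best)) sc else pmin(best, sc)
    }
    add(NA, Lw, best)
  }
  if (length(tcode) >= L - 1L) {
    best <- NULL
    for (k in 2:(L - 1L)) {
      sc <- scan_scheme(tcode, mcode, scheme, L - 1L, "mirna", k)
      best <- if (is.null(best)) sc else pmin(best, sc)
    }
    add(NA, L - 1L, best)
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(0), width = integer(0),
                      score = numeric(0)))
  do.call(rbind, hits)
}

# collapse overlapping window hits to local best (min score, then smallest
# start, then shortest window)
collapse_hits <- function(h) {
  if (nrow(h) == 0L) return(h)
  h <- h[order(h$start, h$width), ]
  ir <- IRanges::IRanges(h$start, width = h$width)
  grp <- S4Vectors::subjectHits(IRanges::findOverlaps(
    ir, IRanges::reduce(ir)))
  keep <- unlist(lapply(split(seq_len(nrow(h)), grp), function(idx) {
    sub <- h[idx, ]
    idx[order(sub$score, sub$start, sub$width)[1L]]
  }))
  h[sort(keep), ]
}

#' Scan transcripts for consensus miRNA target sites
#'
#' Slides all admissible windows over every transcript, scores them under
#' scheme A and, independently, scheme B, and keeps only consensus sites:
#' a scheme-A hit whose span midpoint lies within +/- 3 nt of a scheme-B
#' hit midpoint (the two-predictor intersection rule). Sites are returned
#' in deterministic (transcript, start) order.
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param sequences Named character vector or DNAStringSet of transcript
#'   sequences.
#' @param cutoff_A,cutoff_B Maximum penalty per scheme (default 4.0 each).
#' @return List of `target_site` objects; each has `transcript`, `start`,
#'   `end` (1-based, closed, transcript space), `score_A`, `score_B`,
#'   `alignment` (scheme-A optimal, with `target_pos` lifted to transcript
#'   coordinates), `mirna`, and `consensus = TRUE`.
#' @export
scan_targets <- function(mirna, sequences, cutoff_A = 4.0, cutoff_B = 4.0) {
  seqs <- setNames(as.character(sequences), names(sequences))
  mcode <- base_code(mirna)
  sites <- list()
  for (id in sort(names(seqs))) {
    tcode <- base_code(seqs[[id]])
    if (length(tcode) < length(mcode) - 1L) next
    hA <- collapse_hits(scheme_hits(tcode, mcode, "A", cutoff_A))
    hB <- collapse_hits(scheme_hits(tcode, mcode, "B", cutoff_B))
    if (nrow(hA) == 0L || nrow(hB) == 0L) next
    midA <- hA$start + (hA$width - 1) / 2
    midB <- hB$start + (hB$width - 1) / 2
    for (r in seq_len(nrow(hA))) {
      match_b <- which(abs(midB - midA[r]) <= 3)
      if (length(match_b) == 0L) next
      bscore <- min(hB$score[match_b])
      win <- substr(seqs[[id]], hA$start[r], hA$start[r] + hA$width[r] - 1L)
      sd <- score_duplex(mirna, win, "A")
      aln <- sd$alignment
      aln$target_pos <- aln$target_pos + hA$start[r] - 1L
      sites[[length(sites) + 1L]] <- structure(
        list(transcript = id, start = hA$start[r],
             end = hA$start[r] + hA$width[r] - 1L,
             score_A = sd$score, score_B = bscore,
             alignment = aln, mirna = toupper(gsub("T", "U", mirna)),
             consensus = TRUE),
        class = "target_site")
    }
  }
  sites
}

#' Tabulate scanned sites
#'
#' @param sites List of `target_site` objects from [scan_targets()].
#' @return Data frame with one row per site.
#' @export
sites_table <- function(sites) {
  if (length(sites) == 0L)
    return(data.frame(transcript = character(0), start = integer(0),
                      end = integer(0), score_A = numeric(0),
                      score_B = numeric(0)))
  do.call(rbind, lapply(sites, function(s)
    data.frame(transcript = s$transcript, start = s$start, end = s$end,
               score_A = s$score_A, score_B = s$score_B,
               stringsAsFactors = FALSE)))
}

# reduced RNA/RNA nearest-neighbour stacking table (kcal/mol), indexed by
# the miRNA-strand 5'->3' dinucleotide step, Watson-Crick stacks
STACK_DG <- c(
  AA = -0.93, AC = -2.24, AG = -2.08, AU = -1.10,
  CA = -2.11, CC = -3.26, CG = -2.36, CU = -2.08,
  GA = -2.35, GC = -3.42, GG = -3.26, GU = -2.24,
  UA = -1.33, UC = -2.35, UG = -2.11, UU = -0.93)
GU_STACK_DG <- -0.5    # flat value for stacks involving a wobble pair
LOOP_DG <- 2.0         # fixed destabilizing term per mismatched/bulged nt

#' Duplex free energy from a scored alignment
#'
#' Simplified nearest-neighbour sum: every pair of consecutive paired
#' miRNA positions that are also contiguous on the target contributes a
#' stacking term from a 16-entry table (a flat mild term when either pair
#' is a G:U wobble); each mismatched or bulged nucleotide contributes a
#' fixed destabilizing +2 kcal/mol. Absolute values are not comparable to
#' full Turner-parameter tools; only orderings are meaningful.
#'
#' @param alignment Alignment from [score_duplex()] (or a `target_site`'s
#'   `alignment`).
#' @param mirna miRNA sequence 5'->3'.
#' @return Free energy in kcal/mol (0 for an alignment with no pairs).
#' @export
duplex_energy <- function(alignment, mirna) {
  mv <- strsplit(toupper(gsub("T", "U", mirna)), "")[[1L]]
  st <- alignment$states
  tp <- alignment$target_pos
  L <- length(st)
  paired <- st %in% c("match", "GU")
  if (!any(paired)) return(0)
  dg <- 0
  for (i in seq_len(L - 1L)) {
    if (paired[i] && paired[i + 1L] && !is.na(tp[i]) && !is.na(tp[i + 1L]) &&
        tp[i + 1L] == tp[i] - 1L) {
      if (st[i] == "GU" || st[i + 1L] == "GU") dg <- dg + GU_STACK_DG
      else dg <- dg + STACK_DG[[paste0(mv[i], mv[i + 1L])]]
    }
  }
  dg <- dg + LOOP_DG * sum(st == "mismatch")
  dg <- dg + LOOP_DG * sum(st == "mirna_bulge")
  if (!is.null(alignment$bulge) && alignment$bulge$kind == "target_bulge")
    dg <- dg + LOOP_DG * alignment$bulge$len
  dg
}

#' Predict the canonical cleavage bond of a target site
#'
#' AGO-mediated cleavage canonically occurs between the target bases
#' pairing miRNA nucleotides 10 and 11. Requires matches at miRNA
#' positions 9-11 with contiguous target pairing through 10-11; a bulge or
#' unpaired base there yields a no-prediction marker (`NULL`).
#'
#' @param site A `target_site` from [scan_targets()] (or a compatible list
#'   with an `alignment` whose `target_pos` is in transcript coordinates).
#' @return `NULL` when no prediction is possible, else a list with
#'   `five_prime_mirna_nt = 10` and `target_bond`, the two transcript
#'   positions (ascending) flanking the scissile bond.
#' @export
predict_cleavage <- function(site) {
  aln <- site$alignment
  if (any(aln$states[9:11] != "match")) return(NULL)
  t10 <- aln$target_pos[10L]; t11 <- aln$target_pos[11L]
  if (is.na(t10) || is.na(t11) || t11 != t10 - 1L) return(NULL)
  list(five_prime_mirna_nt = 10L, target_bond = c(t11, t10))
}

#' Classify a target site as cleavable target or target mimic
#'
#' A canonical endogenous target mimic (eTM) carries a 3-nt target bulge
#' between miRNA positions 10 and 11, which blocks cleavage. A site that is
#' contiguous through positions 10-11 is a `cleavable_target`; it is
#' upgraded to `noncanonical_mimic` when RACE evidence shows a modal
#' scissile bond away from the canonical 10/11 position.
#'
#' @param site A consensus `target_site`.
#' @param race_tally Optional `race_tally` from [tally_cleavage()]; must
#'   concern the same transcript.
#' @return List of class `mimic_call` with `category`
#'   (`cleavable_target`, `canonical_eTM`, or `noncanonical_mimic`),
#'   `site`, and `race_evidence`.
#' @export
classify_mimic <- function(site, race_tally = NULL) {
  if (!isTRUE(site$consensus)) stop("site must be a consensus site")
  if (!is.null(race_tally) &&
      !identical(race_tally$transcript, site$transcript))
    stop("RACE tally is for transcript ", race_tally$transcript,
         " but site is on ", site$transcript)
  b <- site$alignment$bulge
  is_eTM <- !is.null(b) && b$kind == "target_bulge" && b$len == 3L &&
    b$after_mirna_pos == 10L
  category <- if (is_eTM) "canonical_eTM" else "cleavable_target"
  if (!is_eTM && !is.null(race_tally)) {
    contiguous <- all(site$alignment$states[10:11] %in% c("match", "GU")) &&
      site$alignment$target_pos[11L] == site$alignment$target_pos[10L] - 1L
    off <- race_tally$modal_mirna_offset
    if (contiguous && !is.na(off) && off != 10L)
      category <- "noncanonical_mimic"
  }
  structure(list(category = category, site = site,
                 race_evidence = race_tally), class = "mimic_call")
}

#' Per-column conservation of a target-site window across homologs
#'
#' Each homolog is globally aligned to the reference (match +1, mismatch
#' -1, gap -2 per nt); for each reference position inside the window the
#' fraction of homologs carrying the identical base is reported.
#'
#' @param ref_seq Reference sequence (character, DNA or RNA).
#' @param homolog_seqs Named character vector of >= 1 homolog sequences.
#' @param window_start,window_end 1-based closed window on the reference
#'   (e.g. the miRNA target site span).
#' @return List with `per_column` (identity fraction per reference
#'   position in the window) and `window_mean`.
#' @export
conservation_window <- function(ref_seq, homolog_seqs, window_start,
                                window_end) {
  to_dna <- function(s) gsub("U", "T", toupper(as.character(s)))
  ref <- to_dna(ref_seq)
  homs <- vapply(homolog_seqs, to_dna, "")
  if (any(nchar(homs) == 0L) || nchar(ref) == 0L)
    stop("empty sequence")
  cols <- window_start:window_end
  ident <- matrix(0, nrow = length(homs), ncol = length(cols))
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                      mismatch = -1)
  for (h in seq_along(homs)) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = homs[h], subject = ref, type = "global",
      substitutionMatrix = sub_mat, gapOpening = 0, gapExtension = 2)
    alh <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    alr <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    ref_idx <- cumsum(alr != "-")
    for (ci in seq_along(cols)) {
      j <- which(ref_idx == cols[ci] & alr != "-")
      if (length(j) == 1L && alh[j] == alr[j]) ident[h, ci] <- 1
    }
  }
  per_column <- colMeans(ident)
  names(per_column) <- cols
  list(per_column = per_column, window_mean = mean(per_column))
}

#' Global pairwise alignment score (match +1, mismatch -1, gap -2)
#'
#' Convenience wrapper exposing the scoring used by
#' [conservation_window()].
#'
#' @param a,b Sequences (character, DNA or RNA alphabet).
#' @return Numeric alignment score.
#' @export
alignment_score <- function(a, b) {
  to_dna <- function(s) gsub("U", "T", toupper(as.character(s)))
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                      mismatch = -1)
  as.numeric(Biostrings::score(Biostrings::pairwiseAlignment(
    pattern = to_dna(a), subject = to_dna(b), type = "global",
    substitutionMatrix = sub_mat, gapOpening = 0, gapExtension = 2)))
}
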