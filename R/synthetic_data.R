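# Seeded generators for every input class the pipeline consumes, with planted
# ground truth. Each generator is a pure function of (parameters, seed): the
# caller's RNG state is saved and restored.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n, gc = 0.40) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

random_codons <- function(n) {
  if (n <= 0L) return(character(0))
  all64 <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                             c("A","C","G","T")), 1, paste, collapse = "")
  sample(setdiff(all64, STOP_CODONS), n, replace = TRUE)
}

#' Simulate a small multi-chromosome reference annotation and genome
#'
#' Genes with 1-5 exons are laid out left to right on each chromosome,
#' separated by intergenic gaps; the genome is uniform random sequence at
#' the requested GC content. Deterministic under a fixed seed.
#'
#' @param seed Integer seed.
#' @param n_chrom Number of chromosomes.
#' @param n_genes Total number of genes (>= 1), distributed round-robin.
#' @param intergenic_gap Gap (nt) between consecutive gene spans and at
#'   chromosome ends (>= 1).
#' @param exon_range,intron_range Integer length ranges for exons/introns.
#' @param gc GC fraction of the simulated genome.
#' @return A list with `annotation` ([annotation_set()]) and `genome`
#'   (named [Biostrings::DNAStringSet]).
#' @export
sim_annotation <- function(seed, n_chrom = 2L, n_genes = 10L,
                           intergenic_gap = 2000L,
                           exon_range = c(150L, 400L),
                           intron_range = c(400L, 900L),
                           gc = 0.40) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (intergenic_gap < 1L) stop("intergenic_gap must be >= 1")
  with_seed(seed, {
    chrom_of <- rep(seq_len(n_chrom), length.out = n_genes)
    exons <- list(); chrom_len <- integer(n_chrom)
    cursor <- rep(intergenic_gap + 1L, n_chrom)
    for (g in seq_len(n_genes)) {
      ch <- chrom_of[g]
      n_ex <- sample.int(5L, 1L)
      ex_w <- sample(seq(exon_range[1], exon_range[2]), n_ex, replace = TRUE)
      in_w <- if (n_ex > 1L)
        sample(seq(intron_range[1], intron_range[2]), n_ex - 1L, replace = TRUE)
      else integer(0)
      st <- cursor[ch]
      starts <- st + cumsum(c(0L, head(ex_w, -1L) + in_w))
      gr <- GenomicRanges::GRanges(
        paste0("chr", ch),
        IRanges::IRanges(starts, width = ex_w),
        strand = sample(c("+", "-"), 1L))
      exons[[sprintf("gene%04d", g)]] <- gr
      cursor[ch] <- max(GenomicRanges::end(gr)) + intergenic_gap + 1L
    }
    chrom_len <- cursor + intergenic_gap
    genome <- Biostrings::DNAStringSet(vapply(
      seq_len(n_chrom), function(i) random_dna(chrom_len[i], gc), ""))
    names(genome) <- paste0("chr", seq_len(n_chrom))
    list(annotation = annotation_set(GenomicRanges::GRangesList(exons)),
         genome = genome)
  })
}

pick_gap_interval <- function(spans, chrom_len, chrom, len, margin = 5L) {
  sp <- spans[as.character(GenomicRanges::seqnames(spans)) == chrom]
  occ <- IRanges::reduce(IRanges::ranges(sp))
  free <- IRanges::setdiff(IRanges::IRanges(1L, chrom_len), occ)
  free <- free[IRanges::width(free) >= len + 2L * margin]
  if (length(free) == 0L) return(NULL)
  f <- free[sample.int(length(free), 1L)]
  lo <- IRanges::start(f) + margin
  hi <- IRanges::end(f) - margin - len + 1L
  s <- if (hi > lo) sample(seq(lo, hi), 1L) else lo
  IRanges::IRanges(s, width = len)
}

#' Plant novel transcripts of each positional class
#'
#' Emits single-exon (occasionally two-exon intergenic) novel transcripts
#' that provably satisfy their class definitions against `annotation`:
#' `LINC` overlaps no gene base; `INTRONIC` sits same-strand fully inside
#' one intron; `exonAS` overlaps at least one exon base on the opposite
#' strand; `intronAS` overlaps only intronic bases on the opposite strand;
#' `discard` decoys overlap an exon on the sense strand. Placements whose
#' extracted sequence happens to contain a disqualifying ORF (internal
#' > `max_internal_aa` or terminal > `max_terminal_aa`) are re-drawn, so
#' planted lncRNAs survive the coding filter by construction.
#'
#' @param annotation An [annotation_set()].
#' @param genome Genome [Biostrings::DNAStringSet] (for the ORF-cleanliness
#'   check).
#' @param class_counts Named integer vector over
#'   `c(LINC, INTRONIC, exonAS, intronAS, discard)`.
#' @param seed Integer seed.
#' @param length_range Length range (nt) for planted transcripts; intron
#'   classes are additionally capped by the host intron width.
#' @param max_internal_aa,max_terminal_aa ORF-cleanliness bounds matching
#'   the discovery defaults.
#' @param max_tries Bounded retries per transcript before a placement error.
#' @return A list with `transcripts` (named GRangesList) and `truth`
#'   (list with `class_labels`, a named character vector).
#' @export
sim_transcripts <- function(annotation, genome,
                            class_counts = c(LINC = 5L, INTRONIC = 2L,
                                             exonAS = 3L, intronAS = 1L,
                                             discard = 2L),
                            seed = 1L,
                            length_range = c(220L, 480L),
                            max_internal_aa = 100L, max_terminal_aa = 50L,
                            max_tries = 200L) {
  stopifnot(all(class_counts >= 0L))
  classes <- rep(names(class_counts), times = class_counts)
  if (length(classes) == 0L)
    return(list(transcripts = GenomicRanges::GRangesList(
      setNames(list(), character(0))), truth = list(class_labels = character(0))))
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  spans <- annotation$spans
  introns_flat <- unlist(annotation$introns)
  if (any(classes %in% c("INTRONIC", "intronAS")) && length(introns_flat) == 0L)
    stop("annotation has no introns; cannot plant INTRONIC/intronAS")
  with_seed(seed, {
    out <- list(); labels <- character(0)
    for (i in seq_along(classes)) {
      cl <- classes[i]
      placed <- NULL
      for (try in seq_len(max_tries)) {
        cand <- switch(cl,
          LINC = {
            chrom <- sample(names(genome), 1L)
            len <- sample(seq(length_range[1], length_range[2]), 1L)
            ir <- pick_gap_interval(spans, chrom_len[[chrom]], chrom, len)
            if (is.null(ir)) NULL else {
              strand <- sample(c("+", "-"), 1L)
              if (runif(1) < 0.3 && len >= 300L) {
                # two-exon intergenic transcript within the same free gap
                e1 <- sample(120L:(len - 150L), 1L)
                gap <- sample(30L:60L, 1L)
                if (IRanges::start(ir) + e1 + gap + (len - e1) - 1L <=
                    IRanges::end(ir) + 90L)
                  GenomicRanges::GRanges(chrom, IRanges::IRanges(
                    c(IRanges::start(ir),
                      IRanges::start(ir) + e1 + gap),
                    width = c(e1, len - e1)), strand = strand)
                else GenomicRanges::GRanges(chrom, ir, strand = strand)
              } else GenomicRanges::GRanges(chrom, ir, strand = strand)
            }
          },
          INTRONIC = ,
          intronAS = {
            ok <- IRanges::width(introns_flat) >= length_range[1] + 4L
            if (!any(ok)) stop("no intron wide enough for planted transcripts")
            intr <- introns_flat[ok][sample.int(sum(ok), 1L)]
            len <- sample(seq(length_range[1],
                              min(length_range[2],
                                  GenomicRanges::width(intr) - 4L)), 1L)
            s <- sample(seq(GenomicRanges::start(intr) + 2L,
                            GenomicRanges::end(intr) - 1L - len), 1L)
            host <- as.character(BiocGenerics::strand(intr))
            strand <- if (cl == "INTRONIC") host else flip_strand(host)
            GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(intr)),
                                   IRanges::IRanges(s, width = len),
                                   strand = strand)
          },
          exonAS = ,
          discard = {
            exf <- unlist(annotation$exons)
            ex <- exf[sample.int(length(exf), 1L)]
            len <- sample(seq(length_range[1], length_range[2]), 1L)
            # start inside the exon so >= 1 exon base overlaps
            s <- sample(seq(GenomicRanges::start(ex),
                            GenomicRanges::end(ex)), 1L)
            host <- as.character(BiocGenerics::strand(ex))
            strand <- if (cl == "exonAS") flip_strand(host) else host
            GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(ex)),
                                   IRanges::IRanges(s, width = len),
                                   strand = strand)
          })
        if (is.null(cand)) next
        if (max(GenomicRanges::end(cand)) >
            chrom_len[[as.character(GenomicRanges::seqnames(cand))[1L]]]) next
        if (!placement_matches_class(cand, cl, annotation)) next
        seq <- as.character(spliced_seq(
          GenomicRanges::GRangesList(x = cand), genome)[[1L]])
        orfs <- find_orfs(seq)
        bad <- any(orfs$length_aa > max_internal_aa & orfs$kind == "internal") ||
               any(orfs$length_aa > max_terminal_aa & orfs$kind == "terminal")
        if (cl != "discard" && bad) next
        placed <- cand
        break
      }
      if (is.null(placed))
        stop("could not place a ", cl, " transcript after ", max_tries,
             " tries")
      id <- sprintf("NOVEL%04d", i)
      out[[id]] <- placed
      labels[id] <- cl
    }
    list(transcripts = GenomicRanges::GRangesList(out),
         truth = list(class_labels = labels))
  })
}

flip_strand <- function(s) if (s == "+") "-" else "+"

# construction-time check that a candidate placement satisfies its class
placement_matches_class <- function(tx, cl, annotation) {
  got <- tryCatch(classify_position(tx, annotation)$class, error = function(e) NA)
  if (cl == "discard") identical(got, "discard") else identical(got, cl)
}

#' Plant an ORF of exact amino-acid length into a sequence
#'
#' Writes an ATG-initiated reading frame of exactly `length_aa` codons
#' (Met included, stop excluded) starting at `start_nt` (1-based). Internal
#' ORFs are closed with TAA; terminal ORFs run to the 3' end with no stop
#' (up to two trailing partial-codon bases are tolerated). When there is
#' room, an in-frame TAA is written immediately upstream of the ATG so that
#' no upstream start codon can absorb the planted ORF. Interior codons
#' alternate GCC/CTC, a filler that introduces no start or stop codon in
#' any reading frame, so the planted ORF is exactly what the coordinates
#' say it is.
#'
#' @param sequence Character DNA sequence.
#' @param start_nt 1-based position of the A of the planted ATG.
#' @param length_aa ORF length in amino acids (>= 1).
#' @param terminal If `TRUE`, omit the stop codon and require the frame to
#'   run off the 3' end.
#' @return The modified sequence (character).
#' @export
plant_orf <- function(sequence, start_nt, length_aa, terminal = FALSE) {
  n <- nchar(sequence)
  stopifnot(length_aa >= 1L, start_nt >= 1L)
  filler <- rep(c("GCC", "CTC"), length.out = max(length_aa - 1L, 0L))
  body <- c("ATG", filler)
  if (terminal) {
    tail_nt <- n - (start_nt + 3L * length_aa - 1L)
    if (tail_nt < 0L || tail_nt > 2L)
      stop("terminal ORF of ", length_aa,
           " aa at position ", start_nt, " does not run to the 3' end")
    ins <- paste0(paste(body, collapse = ""),
                  substr("GC", 1L, tail_nt))
  } else {
    if (start_nt + 3L * (length_aa + 1L) - 1L > n)
      stop("insufficient room for a ", length_aa, " aa internal ORF at ",
           start_nt)
    ins <- paste0(paste(body, collapse = ""), "TAA")
  }
  out <- sequence
  substr(out, start_nt, start_nt + nchar(ins) - 1L) <- ins
  if (start_nt > 3L) substr(out, start_nt - 3L, start_nt - 1L) <- "TAA"
  out
}

#' Simulate a stage-structured negative-binomial count matrix
#'
#' Emulates a small fruit-ripening RNA-seq design: `n_reps` biological
#' replicates at each developmental stage. Designated features are
#' stage-specific (mean `specific_mean` in one stage, `off_mean` ~ 0
#' elsewhere); the rest are constitutive with log-normal baseline means.
#' Optionally, features can be grouped into co-expression modules that share
#' a per-sample latent factor (planted module structure), and a
#' multiplicative batch factor can be applied to a subset of samples.
#'
#' @param n_features Number of features.
#' @param stages Stage labels, in temporal order.
#' @param n_reps Replicates per stage.
#' @param n_specific_per_stage Number of stage-specific features per stage.
#' @param base_meanlog,base_sdlog Log-normal parameters of constitutive means.
#' @param specific_mean,off_mean Stage-specific on/off design means.
#' @param dispersion NB dispersion (size = 1/dispersion); > 0.
#' @param n_modules,module_size,module_amp Planted module structure: features
#'   of one module share a per-sample N(0,1) latent factor scaled by
#'   `module_amp` on the log scale.
#' @param batch_samples,batch_factor Optional multiplicative batch shift.
#' @param seed Integer seed.
#' @return A list with `counts` (integer matrix), `design` (data frame with
#'   sample/stage/replicate/batch), and `truth` (list with `pattern`, a
#'   named vector of `"stage_specific:<stage>"`/`"constitutive"`, and
#'   `module`, a named vector of module ids or `"none"`).
#' @export
sim_counts <- function(n_features = 200L,
                       stages = c("Fv1", "Fv2", "Fv3"),
                       n_reps = 3L,
                       n_specific_per_stage = 20L,
                       base_meanlog = log(100), base_sdlog = 0.8,
                       specific_mean = 500, off_mean = 0.001,
                       dispersion = 0.1,
                       n_modules = 0L, module_size = 30L, module_amp = 1.5,
                       batch_samples = NULL, batch_factor = 1,
                       seed = 1L) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  n_samples <- length(stages) * n_reps
  design <- data.frame(
    sample = paste0(rep(stages, each = n_reps), "_R", seq_len(n_reps)),
    stage = rep(stages, each = n_reps),
    replicate = rep(seq_len(n_reps), times = length(stages)),
    batch = "B1", stringsAsFactors = FALSE)
  with_seed(seed, {
    fid <- sprintf("feat%04d", seq_len(n_features))
    pattern <- rep("constitutive", n_features)
    spec_idx <- seq_len(min(n_features,
                            n_specific_per_stage * length(stages)))
    pattern[spec_idx] <- paste0("stage_specific:",
                                rep(stages, each = n_specific_per_stage)[
                                  seq_along(spec_idx)])
    mu <- matrix(0, n_features, n_samples)
    base <- exp(rnorm(n_features, base_meanlog, base_sdlog))
    for (f in seq_len(n_features)) {
      if (startsWith(pattern[f], "stage_specific:")) {
        s <- sub("stage_specific:", "", pattern[f])
        mu[f, ] <- ifelse(design$stage == s, specific_mean, off_mean)
      } else mu[f, ] <- base[f]
    }
    module <- rep("none", n_features)
    if (n_modules > 0L) {
      const_idx <- which(pattern == "constitutive")
      need <- n_modules * module_size
      if (length(const_idx) < need)
        stop("not enough constitutive features for the requested modules")
      take <- const_idx[seq_len(need)]
      module[take] <- rep(sprintf("mod%d", seq_len(n_modules)),
                          each = module_size)
      for (m in seq_len(n_modules)) {
        z <- rnorm(n_samples)   # shared per-sample latent factor
        idx <- take[module[take] == sprintf("mod%d", m)]
        mu[idx, ] <- mu[idx, ] * matrix(exp(module_amp * z), length(idx),
                                        n_samples, byrow = TRUE)
      }
    }
    if (!is.null(batch_samples))
      mu[, batch_samples] <- mu[, batch_samples] * batch_factor
    counts <- matrix(as.integer(rnbinom(length(mu), mu = mu,
                                        size = 1 / dispersion)),
                     n_features, n_samples,
                     dimnames = list(fid, design$sample))
    list(counts = counts, design = design,
         truth = list(pattern = setNames(pattern, fid),
                      module = setNames(module, fid)))
  })
}

MIRNA_PAIR <- c(A = "T", C = "G", G = "C", U = "A")

revcomp_rna_to_dna <- function(mirna) {
  # DNA reverse complement of an RNA guide (T written for A partners)
  paste(rev(unname(MIRNA_PAIR[strsplit(toupper(mirna), "")[[1L]]])),
        collapse = "")
}

#' Plant miRNA binding sites into transcript sequences
#'
#' Site types: `perfect` (exact reverse complement of the miRNA,
#' occupying L target nt), `mismatched` (perfect site with non-pairing
#' substitutions at the stated miRNA positions), `eTM_bulge` (a canonical
#' target-mimic site: 3 extra target nt inserted between the bases pairing
#' miRNA positions 10 and 11, occupying L+3 nt), and `cleavable_mimic`
#' (contiguous perfect site whose truth records a noncanonical RACE modal
#' offset, default 12).
#'
#' @param sequences Named character vector (or DNAStringSet) of transcript
#'   sequences.
#' @param mirna miRNA sequence, RNA alphabet, 5'->3', length 20-24.
#' @param site_specs Data frame with columns `transcript`, `position`
#'   (1-based start of the site in transcript space), `type`, and
#'   optionally `mismatch_at` (list column of miRNA positions) and
#'   `race_modal_offset`.
#' @param seed Integer seed (bulge/mismatch base choice).
#' @return List with `sequences` (modified, character) and `truth` (the
#'   site table augmented with `end`, occupied span and offsets).
#' @export
plant_target_sites <- function(sequences, mirna, site_specs, seed = 1L) {
  sequences <- setNames(as.character(sequences), names(sequences))
  mirna <- toupper(mirna)
  L <- nchar(mirna)
  if (L < 20L || L > 24L) stop("miRNA length must be 20-24 nt")
  mvec <- strsplit(mirna, "")[[1L]]
  with_seed(seed, {
    truth <- site_specs
    truth$end <- NA_integer_
    for (r in seq_len(nrow(site_specs))) {
      id <- site_specs$transcript[r]
      if (!id %in% names(sequences)) stop("unknown transcript ", id)
      pos <- site_specs$position[r]
      type <- site_specs$type[r]
      core <- strsplit(revcomp_rna_to_dna(mirna), "")[[1L]]  # pairs nt L..1
      site <- switch(type,
        perfect = ,
        cleavable_mimic = core,
        mismatched = {
          at <- site_specs$mismatch_at[[r]]
          for (k in at) {
            tpos <- L - k + 1L          # index in site pairing miRNA nt k
            core[tpos] <- sample(mismatch_bases(mvec[k]), 1L)
          }
          core
        },
        eTM_bulge = {
          # choose insertion bases so the optimal duplex alignment keeps
          # the 3-nt bulge between miRNA positions 10 and 11 under both
          # scoring schemes (random bases can pair coincidentally and let
          # the bulge relocate); deterministic first-fit over ACGT^3
          cand <- NULL
          bases <- c("A", "C", "G", "T")
          for (b1 in bases) { for (b2 in bases) { for (b3 in bases) {
            trial <- append(core, c(b1, b2, b3), after = L - 11L + 1L)
            win <- paste(trial, collapse = "")
            ok <- all(vapply(c("A", "B"), function(sch) {
              al <- score_duplex(mirna, win, sch)$alignment
              !is.null(al$bulge) && al$bulge$kind == "target_bulge" &&
                al$bulge$len == 3L && al$bulge$after_mirna_pos == 10L &&
                all(al$states == "match")
            }, logical(1)))
            if (ok) { cand <- trial; break }
          }; if (!is.null(cand)) break }; if (!is.null(cand)) break }
          if (is.null(cand))
            stop("no unambiguous 3-nt eTM bulge insertion exists for this miRNA")
          cand
        },
        stop("unknown site type: ", type))
      w <- length(site)
      if (pos < 1L || pos + w - 1L > nchar(sequences[[id]]))
        stop("site at position ", pos, " falls outside transcript ", id)
      s <- sequences[[id]]
      substr(s, pos, pos + w - 1L) <- paste(site, collapse = "")
      sequences[[id]] <- s
      truth$end[r] <- pos + w - 1L
    }
    if (is.null(truth$race_modal_offset))
      truth$race_modal_offset <- ifelse(truth$type == "cleavable_mimic", 12L,
                                        NA_integer_)
    list(sequences = sequences, truth = truth)
  })
}

# target bases that neither Watson-Crick nor G:U pair with miRNA base b
mismatch_bases <- function(b) {
  switch(b,
         A = c("A", "C", "G"),
         C = c("C", "T", "A"),
         G = c("G", "A"),          # G pairs C (WC) and T (wobble)
         U = c("T", "C"),          # U pairs A (WC) and G (wobble)
         stop("bad miRNA base ", b))
}

#' Simulate 5' RLM-RACE clone ends for a planted contiguous site
#'
#' Clone 5' ends (first base of the 3' cleavage fragment, transcript
#' coordinates) are placed at the target base pairing miRNA nucleotide
#' `modal_offset`; a `noise` fraction is scattered within +/- 2 nt. The
#' modal bond always retains the plurality of clones.
#'
#' @param transcript Transcript id (recorded in the table).
#' @param site_start,site_end 1-based span of the contiguous site (miRNA
#'   nt 1 pairs the base at `site_end`).
#' @param mirna_length miRNA length L.
#' @param modal_offset 5'-side miRNA nucleotide of the planted scissile
#'   bond, in `[1, L-1]`.
#' @param n_clones Number of clones (>= 1).
#' @param noise Fraction of clones scattered +/- 1..2 nt.
#' @param seed Integer seed.
#' @return Data frame with one row per clone: `transcript`, `position`.
#' @export
sim_race_clones <- function(transcript, site_start, site_end,
                            mirna_length = 21L, modal_offset = 10L,
                            n_clones = 20L, noise = 0, seed = 1L) {
  if (modal_offset < 1L || modal_offset >= mirna_length)
    stop("modal_offset must be in [1, miRNA length - 1]")
  if (n_clones < 1L) stop("n_clones must be >= 1")
  modal_pos <- site_end - modal_offset + 1L   # base pairing miRNA nt k
  with_seed(seed, {
    n_noise <- floor(noise * n_clones)
    pos <- rep(modal_pos, n_clones - n_noise)
    if (n_noise > 0L)
      pos <- c(pos, modal_pos + sample(c(-2L, -1L, 1L, 2L), n_noise,
                                       replace = TRUE))
    data.frame(transcript = transcript, position = pos,
               stringsAsFactors = FALSE)
  })
}

#' Emit a complete synthetic input bundle to a directory
#'
#' Convenience orchestrator: annotation GFF3 + genome FASTA + novel
#' transcript GTF + counts TSV + miRNA FASTA + RACE clone TSV + truth JSON.
#'
#' @param seed Integer seed driving all generators.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list of file paths and the truth objects.
#' @export
simulate_dataset <- function(seed, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("simulate_dataset requires the jsonlite package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- sim_annotation(seed)
  tx <- sim_transcripts(ann$annotation, ann$genome, seed = seed + 1L)
  cm <- sim_counts(seed = seed + 2L)
  mirna <- "UCAUUGAGUGCAGCGUUGAUG"   # 21-nt miR397-like guide
  seqs <- spliced_seq(tx$transcripts, ann$genome)
  linc <- names(tx$truth$class_labels)[tx$truth$class_labels == "LINC"][1L]
  ps <- plant_target_sites(
    seqs, mirna,
    data.frame(transcript = linc, position = 101L, type = "cleavable_mimic",
               stringsAsFactors = FALSE),
    seed = seed + 3L)
  race <- sim_race_clones(linc, 101L, 101L + nchar(mirna) - 1L,
                          nchar(mirna), modal_offset = 12L,
                          n_clones = 20L, noise = 0.2, seed = seed + 4L)
  paths <- list(
    gff3 = file.path(dir, "annotation.gff3"),
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "transcripts.gtf"),
    counts = file.path(dir, "counts.tsv"),
    mirna = file.path(dir, "mirna.fa"),
    race = file.path(dir, "race.tsv"),
    truth = file.path(dir, "truth.json"))
  write_gff3(ann$annotation, paths$gff3)
  Biostrings::writeXStringSet(ann$genome, paths$genome)
  write_gtf(tx$transcripts, paths$gtf)
  write_counts(cm$counts, paths$counts)
  writeLines(c(">mir397like", gsub("T", "U", mirna)), paths$mirna)
  write.table(race, paths$race, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(class_labels = as.list(tx$truth$class_labels),
                pattern = as.list(cm$truth$pattern),
                module = as.list(cm$truth$module),
                planted_site = list(transcript = linc, start = 101,
                                    type = "cleavable_mimic",
                                    race_modal_offset = 12))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(paths = paths, annotation = ann, transcripts = tx,
                 counts = cm, race = race))
}
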