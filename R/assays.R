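# Quantitative assay computations: 5' RLM-RACE cleavage tallying with
# miRNA-coordinate offset mapping, and the spectrophotometric anthocyanin
# index.

#' Tally 5' RLM-RACE clone ends and map the modal scissile bond
#'
#' A clone's 5' end marks the first base of the 3' cleavage fragment, so
#' the scissile bond lies immediately 5' of that base on the transcript.
#' A clone end at the target base pairing miRNA nucleotide `k` therefore
#' implies a bond between miRNA nucleotides `k` and `k+1`, reported as
#' offset `k` (the 5'-side nucleotide: offset 10 means "between the 10th
#' and 11th"). Ties on the modal position are broken toward the smaller
#' transcript position and flagged.
#'
#' @param clone_positions Integer vector (or data frame with a `position`
#'   column) of clone 5'-end positions, 1-based transcript coordinates.
#' @param site A `target_site` from [scan_targets()] (alignment in
#'   transcript coordinates) for the same transcript.
#' @param max_slop Clones farther than this from the site span are
#'   rejected (default 10 nt).
#' @return List of class `race_tally`: `transcript`, `counts` (data frame
#'   `position`, `count`, `mirna_offset`), `modal_position`,
#'   `modal_mirna_offset` (NA when the modal clone end is outside the
#'   pairable range), `tie`.
#' @export
tally_cleavage <- function(clone_positions, site, max_slop = 10L) {
  if (is.data.frame(clone_positions)) {
    if (!is.null(clone_positions$transcript) &&
        !all(clone_positions$transcript == site$transcript))
      stop("clone table is for a different transcript than the site")
    clone_positions <- clone_positions$position
  }
  if (length(clone_positions) == 0L) stop("empty clone list")
  if (any(clone_positions < site$start - max_slop |
          clone_positions > site$end + max_slop))
    stop("clone position(s) more than ", max_slop, " nt outside the site")
  tab <- table(clone_positions)
  pos <- as.integer(names(tab))
  cnt <- as.integer(tab)
  tp <- site$alignment$target_pos
  offset_of <- function(p) {
    k <- which(!is.na(tp) & tp == p)
    if (length(k) == 1L) k else NA_integer_
  }
  offs <- vapply(pos, offset_of, integer(1))
  top <- which(cnt == max(cnt))
  modal_i <- top[which.min(pos[top])]
  structure(list(transcript = site$transcript,
                 counts = data.frame(position = pos, count = cnt,
                                     mirna_offset = offs),
                 modal_position = pos[modal_i],
                 modal_mirna_offset = offs[modal_i],
                 tie = length(top) > 1L),
            class = "race_tally")
}

#' @export
print.race_tally <- function(x, ...) {
  cat(sprintf(
    "race_tally on %s: %d clone(s); modal position %d -> miRNA offset %s%s\n",
    x$transcript, sum(x$counts$count), x$modal_position,
    ifelse(is.na(x$modal_mirna_offset), "none", x$modal_mirna_offset),
    if (x$tie) " (tie)" else ""))
  invisible(x)
}

#' Total anthocyanin index from absorbance readings
#'
#' `(A530 - 0.25 * A657) / M`: the 657 nm reading, scaled by 0.25,
#' corrects the 530 nm absorbance for chlorophyll interference before
#' normalizing by tissue mass. Negative results are reported as-is with a
#' warning (no clipping).
#'
#' @param a530,a657 Absorbances at 530 and 657 nm (>= 0).
#' @param mass Tissue mass in grams (> 0).
#' @return Numeric index (absorbance units per gram).
#' @export
anthocyanin_index <- function(a530, a657, mass) {
  if (any(mass <= 0)) stop("mass must be > 0")
  if (any(a530 < 0) || any(a657 < 0)) stop("absorbances must be >= 0")
  out <- (a530 - 0.25 * a657) / mass
  if (any(out < 0))
    warning("negative anthocyanin index; A657 correction exceeds A530")
  out
}
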