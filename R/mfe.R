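# Simplified nearest-neighbour duplex energy model
#
# The duplex free energy is a sum of stacking energies over consecutive
# paired positions (consecutive on both strands), plus fixed penalties per
# internal loop/bulge event and per unpaired internal nucleotide, plus a
# duplex-initiation constant. The stack table is additive in the two pairs
# forming the stack, with per-pair half energies (kcal/mol):
# G:C -1.6, A:U -0.55, G:U wobble -0.25. These values reproduce the
# standard ordering of RNA/RNA stack stabilities (GC-rich >> AU-rich > GU)
# and make every duplex with at least one stack negative in energy; only
# energy ratios and orderings are contractual for target scoring, not the
# absolute kcal/mol figures.

# half energy by pair class: 2 = WC (depends on bases), 1 = G:U, 0 = none
.half_energy <- function(srna_base, pair_class) {
  ifelse(pair_class == 2L,
         ifelse(srna_base %in% c("G", "C"), -1.6, -0.55),
         ifelse(pair_class == 1L, -0.25, NA_real_))
}

#' Duplex minimum free energy under the built-in stack model
#'
#' @param pairs Data.frame with `srna_pos`, `target_pos`, `pair_class`
#'   (2 = Watson-Crick, 1 = G:U, 0 = mismatch) describing an antiparallel
#'   duplex alignment.
#' @param srna Small RNA sequence (sense, 5'->3', DNA letters).
#' @param initiation Duplex-initiation constant (kcal/mol), default 0.
#' @param loop_penalty,loop_nt_penalty Penalty per internal loop/bulge event
#'   and per internal unpaired nucleotide.
#' @return Energy in kcal/mol (<= 0 for any duplex with >= 2 stacked pairs
#'   under the defaults).
#' @export
duplex_mfe <- function(pairs, srna, initiation = 0,
                       loop_penalty = 2.0, loop_nt_penalty = 0.5) {
  bases <- strsplit(toupper(chartr("U", "T", srna)), "")[[1]]
  pr <- pairs[pairs$pair_class > 0L, , drop = FALSE]
  pr <- pr[order(pr$srna_pos), , drop = FALSE]
  e <- initiation
  if (nrow(pr) >= 2L) {
    for (k in seq_len(nrow(pr) - 1L)) {
      # a stack needs adjacency on both strands
      if (pr$srna_pos[k + 1L] == pr$srna_pos[k] + 1L &&
          pr$target_pos[k + 1L] == pr$target_pos[k] - 1L) {
        e <- e + .half_energy(bases[pr$srna_pos[k]], pr$pair_class[k]) +
          .half_energy(bases[pr$srna_pos[k + 1L]], pr$pair_class[k + 1L])
      }
    }
  }
  # internal disruptions: each interval between consecutive paired
  # positions that skips nucleotides on either strand (mismatched columns
  # or bulged nucleotides) is one loop event whose size is the larger skip
  if (nrow(pr) >= 2L) {
    gaps_s <- diff(pr$srna_pos) - 1L
    gaps_t <- -diff(pr$target_pos) - 1L
    events <- sum(gaps_s > 0 | gaps_t > 0)
    nts <- sum(pmax(gaps_s, gaps_t, 0))
    e <- e + loop_penalty * events + loop_nt_penalty * nts
  }
  e
}

#' Perfect-complement minimum free energy of a small RNA
#'
#' Energy of the small RNA paired against its exact Watson-Crick
#' complement: the normalising reference for `mfe_ratio`.
#'
#' @inheritParams duplex_mfe
#' @return Energy in kcal/mol (< 0 for any sequence of length >= 2).
#' @export
perfect_mfe <- function(srna, initiation = 0) {
  bases <- strsplit(toupper(chartr("U", "T", srna)), "")[[1]]
  m <- length(bases)
  if (m < 2L) return(initiation)
  half <- .half_energy(bases, rep(2L, m))
  initiation + sum(half[-m] + half[-1L])
}

#' Ratio of duplex energy to the perfect-complement energy
#'
#' Clamped to `[0, 1]`; 1 for a perfect complement, decreasing
#' monotonically as pairs are removed from the duplex.
#'
#' @param mfe,perfect Energies from [duplex_mfe()] and [perfect_mfe()].
#' @return Ratio in `[0, 1]`.
#' @export
mfe_ratio <- function(mfe, perfect) {
  if (perfect >= 0) return(0)
  max(0, min(1, mfe / perfect))
}
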