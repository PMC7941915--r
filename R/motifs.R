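# IUPAC ambiguity sets and the two built-in phosphate-responsive elements:
# P1BS (PHR1 binding sequence, GnATATnC) and the PHO element (ATGCCAT).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

MOTIF_CONSENSUS <- c(P1BS = "GNATATNC", PHO = "ATGCCAT")

#' Define an IUPAC motif to scan for
#'
#' @param name Motif name.
#' @param consensus IUPAC consensus string (e.g. `"GNATATNC"`).
#' @param scan_both_strands Scan the reverse complement too (default
#'   `TRUE`).
#' @return A `motif_spec` list.
#' @export
motif_spec <- function(name, consensus, scan_both_strands = TRUE) {
  consensus <- toupper(consensus)
  bad <- setdiff(strsplit(consensus, "")[[1]], names(IUPAC_SETS))
  if (length(bad))
    stop("non-IUPAC character in consensus: ", paste(bad, collapse = ", "))
  structure(list(name = name, consensus = consensus,
                 scan_both_strands = isTRUE(scan_both_strands)),
            class = "motif_spec")
}

#' Scan upstream sequences for an IUPAC consensus motif
#'
#' Every occurrence is reported, overlapping occurrences included;
#' ambiguous reference bases (`N` etc. in the scanned sequence) never
#' match. Minus-strand hits are found by scanning the reverse complement
#' and are reported at the TSS-relative coordinate of their plus-strand
#' footprint. Positions are TSS-relative: the last upstream base is -1.
#'
#' @param upstream Named character vector of upstream (promoter)
#'   sequences, 3' end adjacent to the TSS.
#' @param spec A [motif_spec()] (or a name in the built-in set:
#'   `"P1BS"`, `"PHO"`).
#' @return Data.frame: `gene_id`, `motif`, `strand`, `start` (TSS-relative
#'   start of the plus-strand footprint), `match` (matched sequence as
#'   read on the hit strand).
#' @export
scan_iupac_motif <- function(upstream, spec) {
  if (is.character(spec) && length(spec) == 1L)
    spec <- motif_spec(spec, MOTIF_CONSENSUS[[spec]])
  cons <- Biostrings::DNAString(spec$consensus)
  ml <- length(cons)
  rows <- list()
  for (g in names(upstream)) {
    seq <- toupper(chartr("U", "T", upstream[[g]]))
    W <- nchar(seq)
    subj <- Biostrings::DNAString(seq)
    scan_one <- function(s, strand) {
      hits <- Biostrings::matchPattern(cons, s, fixed = FALSE)
      if (length(hits) == 0L) return(NULL)
      st <- Biostrings::start(hits)
      matched <- as.character(hits)
      keep <- !grepl("[^ACGT]", matched)
      st <- st[keep]; matched <- matched[keep]
      if (!length(st)) return(NULL)
      plus_start <- if (strand == "+") st else W - (st + ml - 1L) + 1L
      data.frame(gene_id = g, motif = spec$name, strand = strand,
                 start = plus_start - W - 1L, match = matched,
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- scan_one(subj, "+")
    if (spec$scan_both_strands)
      rows[[length(rows) + 1L]] <-
        scan_one(Biostrings::reverseComplement(subj), "-")
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), motif = character(0),
                      strand = character(0), start = integer(0),
                      match = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin motif hits by TSS-relative position
#'
#' Bins of `bin` bases over a `window`-base upstream region (defaults: four
#' 500-bp bins over 2000 bp: \[-500,-1\], \[-1000,-501\], \[-1500,-1001\],
#' \[-2000,-1501\]); a hit's bin is determined by its start coordinate.
#' When `regulation` is given (named log2 fold changes per gene), counts
#' are split into induced (`log2fc > 0`) and repressed (`log2fc < 0`)
#' genes.
#'
#' @param hits Data.frame from [scan_iupac_motif()].
#' @param bin,window Bin and window sizes in bases.
#' @param regulation Optional named numeric vector of per-gene log2 fold
#'   changes.
#' @return Data.frame of per-bin counts split by motif (and by regulation
#'   sign when available).
#' @export
bin_motif_positions <- function(hits, bin = 500L, window = 2000L,
                                regulation = NULL) {
  n_bins <- ceiling(window / bin)
  if (nrow(hits) && any(hits$start < -window | hits$start > -1L))
    stop("motif coordinate outside the upstream window")
  bin_of <- function(start) as.integer(ceiling(-start / bin))
  labels <- sprintf("[%d,%d]", -(seq_len(n_bins)) * bin,
                    -(seq_len(n_bins) - 1L) * bin - 1L)
  out <- expand.grid(bin = seq_len(n_bins),
                     motif = unique(hits$motif),
                     stringsAsFactors = FALSE)
  if (nrow(out) == 0L)
    out <- data.frame(bin = seq_len(n_bins), motif = NA_character_)
  out$range <- labels[out$bin]
  if (is.null(regulation)) {
    out$n <- mapply(function(b, m)
      sum(bin_of(hits$start) == b & hits$motif == m), out$bin, out$motif)
  } else {
    sign_of <- ifelse(regulation[hits$gene_id] > 0, "induced",
                      ifelse(regulation[hits$gene_id] < 0, "repressed", NA))
    out$n_induced <- mapply(function(b, m)
      sum(bin_of(hits$start) == b & hits$motif == m &
            sign_of == "induced", na.rm = TRUE), out$bin, out$motif)
    out$n_repressed <- mapply(function(b, m)
      sum(bin_of(hits$start) == b & hits$motif == m &
            sign_of == "repressed", na.rm = TRUE), out$bin, out$motif)
    out$n <- out$n_induced + out$n_repressed
  }
  out
}

#' Count genes carrying motifs
#'
#' A gene counts once per motif regardless of hit multiplicity; the
#' any-motif count is the union over motifs.
#'
#' @param hits Data.frame from [scan_iupac_motif()] (possibly several
#'   motifs row-bound).
#' @param genes Character vector: the gene universe scanned.
#' @return List: `per_motif` (named counts), `any_motif` (integer), and
#'   `genes_per_motif` (list of gene id vectors).
#' @export
count_genes_with_motifs <- function(hits, genes) {
  per <- lapply(split(hits$gene_id, hits$motif), unique)
  per <- lapply(per, intersect, x = genes)
  list(per_motif = vapply(per, length, integer(1)),
       any_motif = length(unique(unlist(per))),
       genes_per_motif = per)
}

#' GO over-representation by upper-tail binomial test
#'
#' For each term, `p = P(X >= k)` with `X ~ Binomial(input_size,
#' term_size / background_size)` and `k` the number of input genes
#' annotated to the term; Bonferroni adjustment is over the tested terms.
#' Fold enrichment is `(k / term_size) / (input_size / background_size)`.
#'
#' @param input Character vector of selected genes (must be a subset of
#'   `background`).
#' @param annotation Named list: term id -> character vector of genes.
#' @param background Character vector: the gene universe.
#' @return Data.frame: `term`, `term_size`, `annotated_in_input`,
#'   `input_size`, `background_size`, `fold_enrichment`, `p_binomial`,
#'   `p_bonferroni`, sorted by p.
#' @export
go_overrepresentation <- function(input, annotation, background) {
  if (!all(input %in% background))
    stop("input genes must be a subset of the background")
  N <- length(unique(background))
  n <- length(unique(input))
  rows <- list()
  for (term in names(annotation)) {
    tg <- intersect(annotation[[term]], background)
    K <- length(tg)
    if (K == 0L) {
      warning("term ", term, " has no genes in the background; skipped")
      next
    }
    k <- length(intersect(tg, input))
    p <- pbinom(k - 1L, size = n, prob = K / N, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      term = term, term_size = K, annotated_in_input = k, input_size = n,
      background_size = N,
      fold_enrichment = (k / K) / (n / N),
      p_binomial = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), term_size = integer(0),
                      annotated_in_input = integer(0), input_size = integer(0),
                      background_size = integer(0), fold_enrichment = numeric(0),
                      p_binomial = numeric(0), p_bonferroni = numeric(0)))
  out$p_bonferroni <- adjust_pvalues(out$p_binomial, "bonferroni")
  out <- out[order(out$p_binomial), , drop = FALSE]
  rownames(out) <- NULL
  out
}
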