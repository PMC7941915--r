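#' RPKM and TPM quantification
#'
#' `RPKM = total exon reads / (mapped reads (millions) x exon length (kb))`
#' and `TPM = RPKM * 1e6 / sum(RPKM)`, both computed per sample.
#'
#' @param counts Matrix (transcripts x samples) of exon read counts.
#' @param exon_length Named vector of exon lengths in bases (matched to
#'   rownames of `counts`).
#' @param mapped_reads Per-sample mapped read totals; defaults to column
#'   sums of `counts`.
#' @return List of matrices `counts`, `rpkm`, `tpm`, plus `exon_length`
#'   and `mapped_reads`.
#' @export
compute_rpkm_tpm <- function(counts, exon_length,
                             mapped_reads = colSums(counts)) {
  el <- exon_length[rownames(counts)]
  if (any(is.na(el))) stop("exon_length missing for some transcripts")
  if (any(el <= 0)) stop("exon_length must be positive")
  if (any(mapped_reads == 0)) stop("zero mapped reads in sample: ",
                                   colnames(counts)[mapped_reads == 0][1L])
  rpkm <- sweep(counts / (el / 1e3), 2L, mapped_reads / 1e6, `/`)
  colsum <- colSums(rpkm)
  tpm <- sweep(rpkm, 2L, ifelse(colsum > 0, 1e6 / colsum, 0), `*`)
  list(counts = counts, rpkm = rpkm, tpm = tpm, exon_length = el,
       mapped_reads = mapped_reads)
}

# NB log-likelihood with known dispersion, valid for non-integer
# (library-size-equalised) pseudo-counts.
.nb_loglik <- function(y, mu, dispersion) {
  mu <- pmax(mu, 1e-8)
  if (dispersion == 0) return(sum(y * log(mu) - mu - lgamma(y + 1)))
  r <- 1 / dispersion
  sum(lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
        r * log(r / (r + mu)) + y * log(mu / (r + mu)))
}

#' Negative-binomial likelihood-ratio DEG test
#'
#' Two-group NB test of the condition effect on library-size-equalised
#' pseudo-counts: per feature, the likelihood of per-group means is
#' compared against a common mean (dispersion shared across features, from
#' [estimate_common_dispersion()] unless supplied), and the likelihood
#' ratio referred to a chi-square with one degree of freedom. Genes with
#' Bonferroni-adjusted p strictly below `alpha` are reported as DEGs.
#'
#' @param counts Gene x sample count matrix.
#' @param design From [two_group_design()].
#' @param alpha Bonferroni threshold (strict `<`), default 0.05.
#' @param dispersion Optional fixed dispersion.
#' @param chromosomes Optional named chromosome labels for the DEG records.
#' @return List: `results` (all tested genes: `gene_id`, `log2fc`,
#'   `exclusive_expression`, `p_value`, `p_bonferroni`) and `degs` (the
#'   selected subset with `direction`).
#' @export
test_deg <- function(counts, design, alpha = 0.05, dispersion = NULL,
                     chromosomes = NULL) {
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0L) stop("all-zero count matrix")
  if (is.null(dispersion))
    dispersion <- estimate_common_dispersion(counts, design)
  pseudo <- .equalize_libsizes(counts)
  ga <- design$groups == design$control
  mA <- rowMeans(pseudo[, ga, drop = FALSE])
  mB <- rowMeans(pseudo[, !ga, drop = FALSE])
  m0 <- rowMeans(pseudo)
  lrt <- vapply(seq_len(nrow(pseudo)), function(i) {
    l1 <- .nb_loglik(pseudo[i, ga], mA[i], dispersion) +
      .nb_loglik(pseudo[i, !ga], mB[i], dispersion)
    l0 <- .nb_loglik(pseudo[i, ], m0[i], dispersion)
    max(0, 2 * (l1 - l0))
  }, numeric(1))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  lfc <- compute_log2fc(mB, mA)
  res <- data.frame(gene_id = rownames(counts),
                    mean_normalized_A = mA, mean_normalized_B = mB,
                    log2fc = lfc$log2fc,
                    exclusive_expression = lfc$exclusive,
                    p_value = p,
                    p_bonferroni = adjust_pvalues(p, "bonferroni"),
                    stringsAsFactors = FALSE, row.names = NULL)
  sel <- res$p_bonferroni < alpha
  degs <- res[sel, , drop = FALSE]
  degs$direction <- ifelse(degs$exclusive_expression,
                           ifelse(degs$mean_normalized_B > 0, "up", "down"),
                           ifelse(degs$log2fc > 0, "up", "down"))
  if (!is.null(chromosomes)) degs$chromosome <- chromosomes[degs$gene_id]
  list(results = res, degs = degs, dispersion = dispersion)
}

#' Chromosome distribution of DEGs
#'
#' Counts up/down-regulated DEGs per chromosome; percentages relate each
#' chromosome's DEG count to its total number of protein-coding genes.
#' Unknown chromosome labels are counted under `"0H"` (unplaced) with a
#' warning.
#'
#' @param degs DEG data.frame with `gene_id` and `direction`.
#' @param transcripts A `transcript_models` data.frame (the protein-coding
#'   universe and chromosome labels).
#' @return Data.frame: `chromosome`, `n_up`, `n_down`, `n_genes`,
#'   `percent_of_chromosome_genes`.
#' @export
chromosome_distribution <- function(degs, transcripts) {
  pc <- transcripts[transcripts$cdna_class == "protein-coding", , drop = FALSE]
  chroms <- sort(unique(pc$chromosome))
  lab <- pc$chromosome[match(degs$gene_id, pc$id)]
  if (any(is.na(lab))) {
    warning(sum(is.na(lab)), " DEG(s) with unknown chromosome counted as 0H")
    lab[is.na(lab)] <- "0H"
    chroms <- union(chroms, "0H")
  }
  out <- data.frame(chromosome = chroms, stringsAsFactors = FALSE)
  out$n_up <- vapply(chroms, function(ch)
    sum(lab == ch & degs$direction == "up"), integer(1))
  out$n_down <- vapply(chroms, function(ch)
    sum(lab == ch & degs$direction == "down"), integer(1))
  out$n_genes <- vapply(chroms, function(ch)
    sum(pc$chromosome == ch), integer(1))
  out$percent_of_chromosome_genes <-
    round(ifelse(out$n_genes > 0,
                 100 * (out$n_up + out$n_down) / out$n_genes, 0), 2)
  rownames(out) <- NULL
  out
}
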