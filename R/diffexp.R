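#' Two-group design helper
#'
#' @param groups Character vector of group labels per sample (exactly two
#'   distinct labels, each with at least two samples).
#' @param control Which label is the reference (control) group; default the
#'   first label in sorted order, with `"control"` preferred when present.
#' @return List with `groups`, `control`, `treated`.
#' @export
two_group_design <- function(groups, control = NULL) {
  lv <- sort(unique(groups))
  if (length(lv) != 2L) stop("design must have exactly two groups")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  if (is.null(control)) control <- if ("control" %in% lv) "control" else lv[1L]
  if (!control %in% lv) stop("unknown control label: ", control)
  list(groups = groups, control = control, treated = setdiff(lv, control))
}

# Effective library sizes, robust to composition bias: median-of-ratios to
# a per-feature geometric-mean reference (computed over features observed
# in every sample), rescaled so their geometric mean equals that of the
# column totals. Falls back to column totals when too few features are
# observed everywhere.
.effective_libsizes <- function(counts) {
  libs <- colSums(counts)
  if (all(libs == 0)) stop("all-zero count matrix")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (sum(all_pos) >= 5L) {
    lc <- log(counts[all_pos, , drop = FALSE])
    ref <- rowMeans(lc)
    s <- apply(lc - ref, 2L, stats::median)
    s <- exp(s - mean(s))
    libs <- s * exp(mean(log(pmax(libs, 1))))
  }
  libs
}

# Library-size equalisation: scale each sample's counts to the geometric
# mean effective library size, giving the pseudo-counts the conditional
# tests assume.
.equalize_libsizes <- function(counts) {
  libs <- .effective_libsizes(counts)
  geo <- exp(mean(log(libs[libs > 0])))
  sweep(counts, 2L, ifelse(libs > 0, geo / libs, 0), `*`)
}

# Conditional NB log-likelihood of all features' pseudo-counts in one group
# given their group totals, as a function of r = 1/dispersion (gamma
# functions accept the non-integer pseudo-counts). Vectorised over features.
.cml_group <- function(Y, r) {
  z <- rowSums(Y)
  n <- ncol(Y)
  nf <- nrow(Y)
  sum(lgamma(Y + r)) - nf * n * lgamma(r) - sum(lgamma(Y + 1)) -
    sum(lgamma(z + n * r) - lgamma(n * r) - lgamma(z + 1))
}

#' Estimate a common NB dispersion by conditional maximum likelihood
#'
#' Quantile-adjusted conditional maximum-likelihood estimation on
#' library-size-equalised pseudo-counts: each sample is scaled to the
#' geometric-mean library size, then the conditional likelihood of the
#' within-group splits given the group totals is maximised over a single
#' dispersion shared by all features.
#'
#' @param counts Non-negative integer matrix (features x samples).
#' @param design From [two_group_design()].
#' @return Common dispersion estimate (floored at 0).
#' @export
estimate_common_dispersion <- function(counts, design) {
  if (any(counts < 0)) stop("counts must be non-negative")
  pseudo <- .equalize_libsizes(counts)
  pseudo <- pseudo[rowSums(pseudo) > 0, , drop = FALSE]
  ga <- design$groups == design$control
  YA <- pseudo[, ga, drop = FALSE]
  YB <- pseudo[, !ga, drop = FALSE]
  loglik <- function(delta) {
    r <- (1 - delta) / delta   # delta = phi/(1+phi)
    .cml_group(YA, r) + .cml_group(YB, r)
  }
  opt <- optimize(loglik, interval = c(1e-6, 0.95), maximum = TRUE)
  delta <- opt$maximum
  phi <- delta / (1 - delta)
  # boundary solutions (no biological variance) collapse to zero
  if (delta <= 2e-6 || loglik(1e-6) >= opt$objective) phi <- 0
  max(phi, 0)
}

#' Exact negative-binomial test for two-group count data
#'
#' For each feature the test conditions on the feature's total pseudo-count
#' across library-size-equalised samples and computes the two-sided exact
#' p-value as the summed probability of all group-A totals no more likely
#' than the observed one under the NB split (binomial/Poisson split when
#' `dispersion = 0`). p-values lie in (0, 1].
#'
#' @inheritParams estimate_common_dispersion
#' @param dispersion Common dispersion (>= 0).
#' @return Numeric p-value vector (NA for all-zero features).
#' @export
exact_nb_test <- function(counts, design, dispersion) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  pseudo <- .equalize_libsizes(counts)
  ga <- design$groups == design$control
  nA <- sum(ga); nB <- sum(!ga)
  sA <- round(rowSums(pseudo[, ga, drop = FALSE]))
  sB <- round(rowSums(pseudo[, !ga, drop = FALSE]))
  s <- sA + sB
  p <- rep(NA_real_, nrow(counts))
  for (i in seq_len(nrow(counts))) {
    if (s[i] == 0) next
    a <- 0:s[i]
    if (dispersion == 0) {
      # Poisson limit: conditional distribution is binomial
      lp <- dpois(a, lambda = nA * s[i] / (nA + nB), log = TRUE) +
        dpois(s[i] - a, lambda = nB * s[i] / (nA + nB), log = TRUE)
    } else {
      r <- 1 / dispersion
      mu <- s[i] / (nA + nB)
      lp <- dnbinom(a, size = nA * r, mu = nA * mu, log = TRUE) +
        dnbinom(s[i] - a, size = nB * r, mu = nB * mu, log = TRUE)
    }
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    obs <- pr[sA[i] + 1L]
    p[i] <- min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
  }
  names(p) <- rownames(counts)
  p
}

#' Multiple-testing adjustment
#'
#' Bonferroni: `min(1, m * p)`. Benjamini-Hochberg: step-up with
#' monotonicity enforcement.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs passed through and
#'   excluded from `m`).
#' @param method `"bonferroni"` or `"fdr_bh"`.
#' @return Adjusted p-value vector of the same length.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "fdr_bh")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (method == "bonferroni") {
    out[ok] <- pmin(1, m * p[ok])
  } else {
    pp <- p[ok]
    o <- order(pp, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(m / (m:1) * pp[o]))[ro]
    out[ok] <- adj
  }
  out
}

#' Log2 fold change with exclusive-expression flagging
#'
#' `log2(mean_treated / mean_control)` when both means are positive; `NaN`
#' with `exclusive = TRUE` when exactly one mean is zero (the feature is
#' expressed exclusively in one condition); `NA` when both are zero
#' (feature carries no information and is excluded upstream).
#'
#' @param mean_treated,mean_control Non-negative normalised group means.
#' @return Data.frame with `log2fc` and `exclusive`.
#' @export
compute_log2fc <- function(mean_treated, mean_control) {
  stopifnot(length(mean_treated) == length(mean_control))
  if (any(c(mean_treated, mean_control) < 0, na.rm = TRUE))
    stop("means must be non-negative")
  lfc <- rep(NA_real_, length(mean_treated))
  both <- mean_treated > 0 & mean_control > 0
  one <- xor(mean_treated > 0, mean_control > 0)
  lfc[both] <- log2(mean_treated[both] / mean_control[both])
  lfc[one] <- NaN
  data.frame(log2fc = lfc, exclusive = one)
}

#' Two-group differential expression of count features
#'
#' Runs the full differential pipeline: drop all-zero features, estimate a
#' common dispersion (unless supplied), exact NB test, Bonferroni and BH
#' adjustment over the features passing the nonzero filter, CPM group
#' means and log2 fold changes with exclusive-expression flags.
#'
#' @inheritParams estimate_common_dispersion
#' @param dispersion Optional fixed dispersion; estimated when `NULL`.
#' @return Data.frame (one row per retained feature): `feature_id`,
#'   `mean_normalized_A` (control), `mean_normalized_B` (treated),
#'   `log2fc`, `exclusive_expression`, `p_value`, `p_bonferroni`, `p_fdr`.
#' @export
run_diffexp <- function(counts, design, dispersion = NULL) {
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0L) stop("all-zero count matrix")
  if (is.null(dispersion))
    dispersion <- estimate_common_dispersion(counts, design)
  ga <- design$groups == design$control
  libs <- .effective_libsizes(counts)
  cpm <- sweep(counts, 2L, 1e6 / pmax(libs, 1), `*`)
  mA <- rowMeans(cpm[, ga, drop = FALSE])
  mB <- rowMeans(cpm[, !ga, drop = FALSE])
  lfc <- compute_log2fc(mB, mA)
  p <- exact_nb_test(counts, design, dispersion)
  data.frame(feature_id = rownames(counts),
             mean_normalized_A = mA, mean_normalized_B = mB,
             log2fc = lfc$log2fc, exclusive_expression = lfc$exclusive,
             p_value = p,
             p_bonferroni = adjust_pvalues(p, "bonferroni"),
             p_fdr = adjust_pvalues(p, "fdr_bh"),
             dispersion = dispersion,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select DEMs and DESs at a Bonferroni threshold
#'
#' DEMs are features annotated exactly to a miRNA reference
#' (`mirbase_exact`) with Bonferroni-adjusted p strictly below `alpha`;
#' DESs are all other features passing the same threshold.
#'
#' @param results Data.frame from [run_diffexp()].
#' @param layers Named character vector (feature_id -> annotation layer).
#' @param alpha Significance threshold (strict `<`), default 0.05.
#' @return List: `dem`, `des` (subsets of `results`), and `tally`
#'   (up/down counts per set; exclusive features count by the expressed
#'   condition).
#' @export
select_dems_dess <- function(results, layers, alpha = 0.05) {
  lay <- layers[results$feature_id]
  sig <- !is.na(results$p_bonferroni) & results$p_bonferroni < alpha
  is_dem <- sig & !is.na(lay) & lay == "mirbase_exact"
  is_des <- sig & !is_dem
  dir <- ifelse(results$exclusive_expression,
                ifelse(results$mean_normalized_B > 0, "up", "down"),
                ifelse(results$log2fc > 0, "up",
                       ifelse(results$log2fc < 0, "down", "flat")))
  tally <- rbind(dem = table(factor(dir[is_dem], levels = c("up", "down", "flat"))),
                 des = table(factor(dir[is_des], levels = c("up", "down", "flat"))))
  list(dem = results[is_dem, , drop = FALSE],
       des = results[is_des, , drop = FALSE],
       tally = tally)
}
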