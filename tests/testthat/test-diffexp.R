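test_that("common dispersion estimation recovers the truth", {
  # Poisson data: estimate collapses toward zero
  y0 <- simulate_count_matrix(runif(2000, 20, 200), rep(0, 2000),
                              n_rep = 3L, dispersion = 0, seed = 21L)
  design <- two_group_design(attr(y0, "groups"))
  expect_lt(estimate_common_dispersion(y0, design), 0.05)

  # NB dispersion 0.4 recovered within [0.3, 0.5]
  y4 <- simulate_count_matrix(runif(2000, 20, 200), rep(0, 2000),
                              n_rep = 3L, dispersion = 0.4, seed = 22L)
  d4 <- estimate_common_dispersion(y4, design)
  expect_gt(d4, 0.3); expect_lt(d4, 0.5)

  # duplicated replicate columns: no biological variance
  base <- matrix(rpois(600, 50), ncol = 1)
  ydup <- cbind(base, base, base, base, base, base)
  colnames(ydup) <- c(paste0("c", 1:3), paste0("t", 1:3))
  expect_lt(estimate_common_dispersion(ydup, design), 0.01)

  expect_error(estimate_common_dispersion(matrix(0, 3, 6), design),
               "all-zero")
})

test_that("exact NB test matches the conditional binomial oracle at phi=0", {
  set.seed(31)
  y <- simulate_count_matrix(runif(200, 10, 100), rep(0, 200),
                             n_rep = 3L, dispersion = 0, seed = 31L)
  design <- two_group_design(attr(y, "groups"))
  p <- exact_nb_test(y, design, dispersion = 0)
  # oracle: two-sided exact binomial split of the total (small-p method);
  # equal library sizes are forced so pseudo-counts equal raw counts
  pseudo <- srnadeg:::.equalize_libsizes(y)
  oracle <- vapply(seq_len(nrow(y)), function(i) {
    sA <- round(sum(pseudo[i, design$groups == design$control]))
    sB <- round(sum(pseudo[i, design$groups != design$control]))
    s <- sA + sB
    if (s == 0) return(NA_real_)
    pr <- dbinom(0:s, s, 0.5)
    obs <- pr[sA + 1L]
    min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
  }, numeric(1))
  expect_equal(unname(p), oracle, tolerance = 1e-8)
})

test_that("exact NB test agrees with edgeR's exact test as a cross-check", {
  y <- simulate_count_matrix(runif(500, 20, 200),
                             c(rep(3, 50), rep(0, 450)),
                             n_rep = 3L, dispersion = 0.1, seed = 33L)
  design <- two_group_design(attr(y, "groups"))
  p <- exact_nb_test(y, design, dispersion = 0.1)
  d <- edgeR::DGEList(counts = y, group = attr(y, "groups"))
  d <- edgeR::calcNormFactors(d)
  pe <- edgeR::exactTest(d, dispersion = 0.1)$table$PValue
  # methods differ in two-sided convention and normalisation detail;
  # rankings and significance calls must agree closely
  expect_gt(cor(log10(p), log10(pe), method = "spearman"), 0.97)
  expect_gt(mean((p < 0.001) == (pe < 0.001)), 0.95)
})

test_that("equal counts with equal library sizes give p = 1", {
  y <- matrix(rep(c(10L, 20L, 30L), 2), nrow = 1)
  colnames(y) <- paste0("s", 1:6)
  design <- two_group_design(rep(c("control", "low-Pi"), each = 3))
  expect_equal(unname(exact_nb_test(y, design, 0.1)), 1)
  expect_error(exact_nb_test(y, design, -0.1), "dispersion")
})

test_that("p-value adjustment matches hand computations and stats::p.adjust", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)  # m = 1
  expect_equal(adjust_pvalues(rep(0.01, 5), "bonferroni"), rep(0.05, 5))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "fdr_bh"),
               c(0.03, 0.03, 0.03))
  set.seed(41)
  p <- runif(100)^2
  expect_equal(adjust_pvalues(p, "bonferroni"),
               p.adjust(p, "bonferroni"))
  expect_equal(adjust_pvalues(p, "fdr_bh"), p.adjust(p, "BH"))
  expect_identical(adjust_pvalues(numeric(0), "fdr_bh"), numeric(0))
})

test_that("log2 fold change flags exclusive expression", {
  r <- compute_log2fc(c(8, 5, 4, 0, 0), c(1, 0, 4, 3, 0))
  expect_equal(r$log2fc[1], 3)
  expect_true(is.nan(r$log2fc[2]) && r$exclusive[2])
  expect_equal(r$log2fc[3], 0)
  expect_true(is.nan(r$log2fc[4]) && r$exclusive[4])
  expect_true(is.na(r$log2fc[5]) && !r$exclusive[5])
})

test_that("label swap flips log2fc and preserves p-values; Bonferroni within BH", {
  y <- simulate_count_matrix(runif(300, 20, 200),
                             c(rep(3, 30), rep(0, 270)),
                             n_rep = 3L, dispersion = 0.1, seed = 51L)
  d1 <- two_group_design(attr(y, "groups"), control = "control")
  d2 <- two_group_design(attr(y, "groups"), control = "low-Pi")
  r1 <- run_diffexp(y, d1, dispersion = 0.1)
  r2 <- run_diffexp(y, d2, dispersion = 0.1)
  fin <- is.finite(r1$log2fc)
  expect_equal(r1$log2fc[fin], -r2$log2fc[fin])
  expect_equal(r1$p_value, r2$p_value)
  alpha <- 0.05
  expect_true(all(r1$feature_id[r1$p_bonferroni < alpha] %in%
                    r1$feature_id[r1$p_fdr < alpha]))
})

test_that("DEM/DES selection splits by layer at strict alpha", {
  res <- data.frame(feature_id = c("a", "b", "c", "d"),
                    mean_normalized_A = c(1, 1, 1, 2),
                    mean_normalized_B = c(9, 9, 9, 0),
                    log2fc = c(3.17, 3.17, 3.17, NaN),
                    exclusive_expression = c(FALSE, FALSE, FALSE, TRUE),
                    p_value = c(0.001, 0.001, 0.002, 0.001),
                    p_bonferroni = c(0.04, 0.04, 0.05, 0.01),
                    p_fdr = c(0.01, 0.01, 0.02, 0.01))
  layers <- c(a = "mirbase_exact", b = "unannotated", c = "mirbase_exact",
              d = "cdna_class")
  sel <- select_dems_dess(res, layers)
  expect_identical(sel$dem$feature_id, "a")
  expect_setequal(sel$des$feature_id, c("b", "d"))   # c: p == alpha, excluded
  expect_equal(unname(sel$tally["des", "down"]), 1L) # d exclusive in control
})
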