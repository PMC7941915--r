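test_that("IUPAC scan finds consensus-forced hits on both strands", {
  # plus-strand P1BS instance inside a neutral context
  h <- scan_iupac_motif(c(g1 = "TTGAATATACTT"),
                        motif_spec("P1BS", "GNATATNC",
                                   scan_both_strands = FALSE))
  expect_identical(nrow(h), 1L)
  expect_identical(h$match, "GAATATAC")
  expect_identical(h$strand, "+")
  expect_identical(h$start, 3L - 12L - 1L)  # footprint start 3, W = 12

  # ATGGCAT = reverse complement of the PHO element -> one minus-strand hit
  h2 <- scan_iupac_motif(c(g1 = "CCCCATGGCATCCCC"), "PHO")
  expect_identical(nrow(h2), 1L)
  expect_identical(h2$strand, "-")
  expect_identical(h2$match, "ATGCCAT")
  expect_identical(h2$start, 5L - 15L - 1L)

  # ambiguous reference bases never match
  expect_identical(nrow(scan_iupac_motif(c(g = "TTGANTATACTT"),
                                         motif_spec("P1BS", "GNATATNC"))), 0L)
  expect_error(motif_spec("bad", "GXATATNC"), "non-IUPAC")
})

test_that("scan equals the sliding-window oracle on random sequences", {
  set.seed(91)
  for (i in 1:200) {
    seq <- rand_dna(2000L)
    for (m in c("P1BS", "PHO")) {
      cons <- c(P1BS = "GNATATNC", PHO = "ATGCCAT")[[m]]
      hits <- scan_iupac_motif(setNames(seq, "g"), m)
      orc <- oracle_motif_scan(seq, cons)
      W <- 2000L; ml <- nchar(cons)
      exp_plus <- orc$plus - W - 1L
      exp_minus <- (W - (orc$minus + ml - 1L) + 1L) - W - 1L
      expect_setequal(hits$start[hits$strand == "+"], exp_plus)
      expect_setequal(hits$start[hits$strand == "-"], exp_minus)
    }
  }
})

test_that("planted promoter motifs are recovered at exact coordinates", {
  sim <- shared_sim()
  hits <- rbind(scan_iupac_motif(sim$ref$promoters, "P1BS"),
                scan_iupac_motif(sim$ref$promoters, "PHO"))
  for (g in names(sim$truth$motif_positions)) {
    planted <- sim$truth$motif_positions[[g]]
    for (k in seq_len(nrow(planted))) {
      expect_true(any(hits$gene_id == g &
                        hits$motif == planted$motif[k] &
                        hits$start == planted$start[k]))
    }
  }
})

test_that("positional binning respects the 500-bp boundary convention", {
  hits <- data.frame(gene_id = "g", motif = "P1BS",
                     strand = "+", start = c(-499L, -500L, -501L, -2000L),
                     match = "GAATATAC")
  b <- bin_motif_positions(hits)
  expect_equal(b$n[b$bin == 1L], 2L)   # -499 and -500
  expect_equal(b$n[b$bin == 2L], 1L)   # -501
  expect_equal(b$n[b$bin == 4L], 1L)   # -2000
  expect_equal(sum(b$n), nrow(hits))
  hits$start[1] <- -2001L
  expect_error(bin_motif_positions(hits), "outside")
  # regulation split
  hits2 <- data.frame(gene_id = c("up1", "dn1"), motif = "PHO", strand = "+",
                      start = c(-10L, -10L), match = "ATGCCAT")
  b2 <- bin_motif_positions(hits2, regulation = c(up1 = 2.1, dn1 = -1.3))
  expect_equal(b2$n_induced[b2$bin == 1L], 1L)
  expect_equal(b2$n_repressed[b2$bin == 1L], 1L)
})

test_that("gene-level motif counts deduplicate hits and union motifs", {
  hits <- data.frame(
    gene_id = c("a", "a", "a", "b", "b", "c"),
    motif = c("P1BS", "P1BS", "P1BS", "P1BS", "PHO", "PHO"),
    strand = "+", start = -10L, match = "x")
  gc <- count_genes_with_motifs(hits, c("a", "b", "c", "d"))
  expect_equal(unname(gc$per_motif[c("P1BS", "PHO")]), c(2L, 2L))
  expect_equal(gc$any_motif, 3L)
  gc0 <- count_genes_with_motifs(hits[0, ], c("a", "b"))
  expect_equal(gc0$any_motif, 0L)
})

test_that("fold enrichment and binomial p follow the quoted formulas", {
  ann <- list(T1 = sprintf("g%05d", 1:100))
  bg <- sprintf("g%05d", 1:20000)
  input <- c(sprintf("g%05d", 1:10), sprintf("g%05d", 19001:19040))
  enr <- go_overrepresentation(input, ann, bg)
  expect_equal(enr$fold_enrichment, (10 / 100) / (50 / 20000))  # = 40
  expect_equal(enr$fold_enrichment, 40)

  # annotated count exactly at expectation -> fold enrichment 1
  ann2 <- list(T2 = sprintf("g%05d", 1:2000))   # rate 0.1
  input2 <- c(sprintf("g%05d", 1:5), sprintf("g%05d", 10001:10045))
  enr2 <- go_overrepresentation(input2, ann2, bg)
  expect_equal(enr2$fold_enrichment, 1)

  expect_error(go_overrepresentation(c("zzz"), ann, bg), "subset")
  expect_warning(go_overrepresentation(input, c(ann, list(T0 = "absent")), bg),
                 "skipped")
})

test_that("small-case binomial p equals exhaustive enumeration", {
  # background 20, term size 5, input 4, annotated 3; binomial model:
  # each of the 4 input genes hits the term independently at rate 5/20
  bg <- sprintf("g%02d", 1:20)
  ann <- list(T = bg[1:5])
  input <- c(bg[1:3], bg[10])
  enr <- go_overrepresentation(input, ann, bg)
  outcomes <- expand.grid(rep(list(c(0, 1)), 4))
  pr <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, 0.25, 0.75)))
  oracle <- sum(pr[rowSums(outcomes) >= 3])
  expect_equal(enr$p_binomial, oracle)
})
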