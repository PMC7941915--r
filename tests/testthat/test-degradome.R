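test_that("cleavage profiles count 5' ends with both normalisations", {
  tx <- transcript_models("t1", "protein-coding", "1H", rand_dna(200L))
  tag <- substr(tx$sequence, 100L, 119L)
  prof <- build_cleavage_profile(tag, tx)
  expect_equal(prof$t1$raw[100L], 1L)
  expect_equal(prof$t1$fraction[100L], 1)
  expect_equal(prof$t1$depth_normalized[100L], 1e7)
  # 14-nt tag is excluded by the length filter
  expect_warning(
    p14 <- build_cleavage_profile(substr(tag, 1, 14), tx), "length filter")
  expect_equal(sum(p14$t1$raw), 0L)
  # fraction sums to 1 where there is signal
  tags <- substring(tx$sequence, c(10L, 10L, 50L), c(29L, 29L, 69L))
  p3 <- build_cleavage_profile(tags, tx)
  expect_equal(sum(p3$t1$fraction), 1)
  expect_equal(p3$t1$raw[10L], 2L)
})

test_that("planted degradome peaks are the profile argmax", {
  sim <- shared_sim()
  dg <- simulate_degradome_reads(sim$ref, sim$truth, sim$cfg,
                                 tempfile(fileext = ".fastq"))
  prof <- build_cleavage_profile(dg$fastq, sim$ref$transcripts)
  tp <- sim$truth$target_pairs
  am <- vapply(seq_len(nrow(tp)), function(k)
    which.max(prof[[tp$transcript_id[k]]]$raw), integer(1))
  expect_true(mean(am == tp$cleavage_pos) >= 0.9)
  .shared_env$profiles <- prof   # reused below
})

test_that("duplex enumeration matches a brute-force inventory recount", {
  set.seed(61)
  n_checked <- 0L
  for (rep_i in 1:60) {
    srna <- rand_dna(sample(18:25, 1L))
    pl <- plant_site(srna, 120L, n_mut = sample(0:3, 1L))
    cands <- enumerate_candidate_duplexes(srna, pl$transcript,
                                          min_pair_score = nchar(srna) - 8)
    for (cd in cands) {
      inv <- oracle_inventory(cd, srna, pl$transcript)
      expect_identical(cd$n_mismatch, inv$n_mismatch)
      expect_identical(cd$n_gu, inv$n_gu)
      expect_identical(cd$n_bulge_nt, inv$n_bulge_nt)
      expect_identical(cd$n_loop, inv$n_loop)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 50L)
})

test_that("exact reverse-complement sites give one clean full-span duplex", {
  set.seed(62)
  srna <- rand_dna(21L)
  pl <- plant_site(srna, 150L, n_mut = 0L)
  cands <- enumerate_candidate_duplexes(srna, pl$transcript)
  best <- cands[[which.max(vapply(cands, `[[`, numeric(1), "pair_score"))]]
  expect_equal(best$site_start, pl$site_start)
  expect_equal(best$site_end - best$site_start + 1L, 21L)
  expect_equal(best$n_mismatch + best$n_gu + best$n_bulge_nt, 0L)
  expect_equal(best$cleavage_pos, pl$site_start + 21L - 10L)
  # max_bulge = 0 restricts spans to the sRNA length
  c0 <- enumerate_candidate_duplexes(srna, pl$transcript, max_bulge = 0L,
                                     min_pair_score = 10)
  spans <- vapply(c0, function(cc) cc$site_end - cc$site_start + 1L, integer(1))
  expect_true(all(spans == 21L))
  # transcript shorter than the sRNA yields nothing
  expect_length(enumerate_candidate_duplexes(srna, rand_dna(15L)), 0L)
})

test_that("Allen scoring honours core doubling and position-10 relaxation", {
  set.seed(63)
  srna <- rand_dna(21L)
  pl <- plant_site(srna, 120L)
  best_of <- function(s, tx) {
    cd <- enumerate_candidate_duplexes(s, tx)
    cd[[which.max(vapply(cd, `[[`, numeric(1), "pair_score"))]]
  }
  expect_equal(score_alignment_allen(best_of(srna, pl$transcript)), 0)

  mk_site <- function(s, pos, target_base) {
    p2 <- plant_site(s, 120L)
    j <- p2$site_start + nchar(s) - pos
    substr(p2$transcript, j, j) <- target_base
    p2$transcript
  }
  # G:U at position 15 (undoubled region): 0.5
  s15 <- srna; substr(s15, 15, 15) <- "G"
  expect_equal(score_alignment_allen(best_of(s15, mk_site(s15, 15L, "T"))), 0.5)
  # mismatch at position 5 (doubled region): 2
  s5 <- srna; substr(s5, 5, 5) <- "A"
  expect_equal(score_alignment_allen(best_of(s5, mk_site(s5, 5L, "C"))), 2)
  # G:U at position 10: relaxed 0.5 vs doubled 1.0
  s10 <- srna; substr(s10, 10, 10) <- "G"
  d10 <- best_of(s10, mk_site(s10, 10L, "T"))
  expect_equal(score_alignment_allen(d10, permit_pos10_relaxation = TRUE), 0.5)
  expect_equal(score_alignment_allen(d10, permit_pos10_relaxation = FALSE), 1)
  # Allen score is a brute-force recount on random corrupted sites
  for (i in 1:25) {
    s <- rand_dna(21L)
    pl2 <- plant_site(s, 120L, n_mut = sample(1:3, 1L))
    cands <- enumerate_candidate_duplexes(s, pl2$transcript,
                                          min_pair_score = 13)
    for (cd in cands)
      expect_equal(score_alignment_allen(cd),
                   oracle_allen(cd, s, pl2$transcript))
  }
})

test_that("duplex energies order as expected and ratios are monotone", {
  gc21 <- paste0(strrep("GC", 10L), "G")
  au21 <- paste0(strrep("AT", 10L), "A")
  expect_lt(perfect_mfe(gc21), perfect_mfe(au21))
  expect_lt(perfect_mfe(au21), 0)

  set.seed(64)
  srna <- rand_dna(21L)
  pl <- plant_site(srna, 120L)
  best_of <- function(s, tx, min_score = 13) {
    cd <- enumerate_candidate_duplexes(s, tx, min_pair_score = min_score)
    cd[[which.max(vapply(cd, `[[`, numeric(1), "pair_score"))]]
  }
  perfect <- best_of(srna, pl$transcript)
  e_perfect <- duplex_mfe(perfect$pairs, srna)
  expect_equal(mfe_ratio(e_perfect, perfect_mfe(srna)), 1)
  # removing two pairs (two target mutations) strictly raises the energy
  tx2 <- pl$transcript
  for (pos in c(4L, 16L)) {
    j <- pl$site_start + 21L - pos
    sb <- substr(srna, pos, pos)
    bad <- setdiff(c("A", "C", "G", "T"),
                   c(chartr("ACGT", "TGCA", sb),
                     if (sb == "G") "T" else if (sb == "T") "G"))
    substr(tx2, j, j) <- bad[1L]
  }
  worse <- best_of(srna, tx2)
  e_worse <- duplex_mfe(worse$pairs, srna)
  expect_gt(e_worse, e_perfect)
  expect_lt(mfe_ratio(e_worse, perfect_mfe(srna)), 1)
})

test_that("targetseek filter rejects weak duplexes and scores inventories", {
  d_perfect <- list(pairs = NULL, n_mismatch = 0L, n_gu = 0L,
                    n_bulge_nt = 0L, n_loop = 0L, overhang5 = 0L,
                    overhang3 = 0L, mfe_ratio = 1)
  expect_equal(targetseek_score_filter(d_perfect), 0)
  d_weak <- d_perfect; d_weak$mfe_ratio <- 0.5
  expect_true(is.na(targetseek_score_filter(d_weak)))
  d_mixed <- d_perfect; d_mixed$n_gu <- 1L; d_mixed$n_mismatch <- 1L
  expect_equal(targetseek_score_filter(d_mixed), 3)
  expect_error(targetseek_score_filter(d_perfect, weights = c(
    mismatch = -1, gu = 1, bulge = 3, loop = 1)), "non-negative")
})

test_that("peak categories follow the max/mean rules", {
  raw <- integer(50L); raw[1L] <- 10L; raw[4L] <- 2L
  expect_equal(assign_peak_category(raw, 1L), 0L)
  expect_equal(assign_peak_category(raw, 4L), 3L)   # mean 6, c = 2 <= 6
  expect_equal(assign_peak_category(c(1L, integer(9L)), 1L), 4L)
  raw2 <- integer(20L); raw2[c(2L, 9L)] <- 5L; raw2[15L] <- 4L
  raw2[c(16L, 17L)] <- 1L
  expect_equal(assign_peak_category(raw2, 2L), 1L)  # shared maximum
  expect_equal(assign_peak_category(raw2, 15L), 2L) # mean 3.2 < 4 < max 5
  expect_error(assign_peak_category(raw, 2L), "no signal")
})

test_that("permutation p-values separate planted sites from background", {
  sim <- shared_sim()
  prof <- .shared_env$profiles
  tp <- sim$truth$target_pairs[1L, ]
  tx <- sim$ref$transcripts
  txseq <- tx$sequence[tx$id == tp$transcript_id]
  p <- site_pvalue_permutation(prof[[tp$transcript_id]],
                               sim$ref$mature_mirnas[[tp$srna_id]],
                               txseq, observed_score = 0,
                               observed_category = 0L, n_perm = 99L,
                               seed = 9L)
  expect_lte(p, 0.05)
  p2 <- site_pvalue_permutation(prof[[tp$transcript_id]],
                                sim$ref$mature_mirnas[[tp$srna_id]],
                                txseq, 0, 0L, n_perm = 99L, seed = 9L)
  expect_identical(p, p2)   # same seed, same p
  expect_error(site_pvalue_permutation(prof[[tp$transcript_id]], "ACGT",
                                       txseq, 0, 0L, n_perm = 0L), "n_perm")
})

test_that("target prediction recovers planted pairs at exact coordinates", {
  sim <- shared_sim()
  prof <- .shared_env$profiles
  tp <- sim$truth$target_pairs
  srnas <- sim$ref$mature_mirnas[unique(tp$srna_id)]
  preds <- predict_targets(srnas, prof, sim$ref$transcripts, track = "allen")
  hit <- merge(tp, preds, by = c("srna_id", "transcript_id"))
  expect_gte(nrow(hit) / nrow(tp), 0.9)
  expect_true(all(hit$cleavage_pos.x == hit$cleavage_pos.y))
  # the same sites pass the targetseek track with score 0
  ts <- predict_targets(srnas, prof, sim$ref$transcripts,
                        track = "targetseek")
  expect_gte(nrow(merge(tp, ts, by = c("srna_id", "transcript_id"))) /
               nrow(tp), 0.9)
  expect_true(all(ts$mfe_ratio >= 0.6))
  # a perfect site without degradome signal yields no prediction
  srna <- rand_dna(21L)
  pl <- plant_site(srna, 200L)
  tx1 <- transcript_models("fresh", "protein-coding", "1H", pl$transcript)
  empty_prof <- suppressWarnings(build_cleavage_profile(character(0), tx1))
  expect_identical(nrow(predict_targets(c(q = srna), empty_prof, tx1)), 0L)
})

test_that("t-plot export writes signal rows and marks the coordinate", {
  sim <- shared_sim()
  prof <- .shared_env$profiles
  tp <- sim$truth$target_pairs
  srnas <- sim$ref$mature_mirnas[unique(tp$srna_id)]
  preds <- predict_targets(srnas, prof, sim$ref$transcripts)
  top <- preds[1L, ]
  prefix <- file.path(tempdir(), "tplot_test")
  out <- export_tplot(prof[[top$transcript_id]], top, prefix)
  tab <- read.delim(out[["tsv"]])
  expect_identical(nrow(tab), sum(prof[[top$transcript_id]]$raw > 0L))
  expect_true(file.exists(out[["pdf"]]))
  out2 <- export_tplot(prof[[top$transcript_id]], top,
                       file.path(tempdir(), "tplot_test2"))
  expect_identical(unname(tools::md5sum(out[["pdf"]])),
                   unname(tools::md5sum(out2[["pdf"]])))
  expect_error(export_tplot(prof[[top$transcript_id]], top,
                            "/nonexistent-dir/x"), "unwritable")
})
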