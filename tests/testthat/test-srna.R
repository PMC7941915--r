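test_that("preprocessing trims adapters, filters lengths, and logs reasons", {
  ad <- "TGGAATTCTCGGGTGCCAAGG"
  ins21 <- rand_dna(21L)
  ins17 <- rand_dna(17L)
  reads <- data.frame(
    id = c("full", "short_insert", "partial_adapter"),
    sequence = c(paste0(ins21, ad), paste0(ins17, ad),
                 paste0(ins21, substr(ad, 1, 8))),
    stringsAsFactors = FALSE)
  reads$quality <- strrep("I", nchar(reads$sequence))
  pp <- preprocess_reads(reads, ad)
  expect_identical(pp$reads$sequence, c(ins21, ins21))
  expect_identical(unname(pp$log["too_short"]), 1L)

  # quality trimming: read whose best-quality segment is 16 nt is discarded
  lowq <- data.frame(id = "lq", sequence = rand_dna(40L),
                     quality = paste0(strrep("I", 16L), strrep("#", 24L)),
                     stringsAsFactors = FALSE)
  pp2 <- preprocess_reads(lowq, ad)
  expect_identical(nrow(pp2$reads), 0L)
  expect_identical(unname(pp2$log["too_short"]), 1L)

  # low-quality tail after the adapter is removed before adapter matching
  tail_read <- data.frame(
    id = "t", sequence = paste0(ins21, ad, "ACGTA"),
    quality = paste0(strrep("I", 21L + nchar(ad)), strrep("#", 5L)),
    stringsAsFactors = FALSE)
  expect_identical(preprocess_reads(tail_read, ad)$reads$sequence, ins21)

  expect_error(preprocess_reads(reads, ad, quality_limit = 1.5), "quality_limit")
  expect_error(preprocess_reads(reads, ""), "adapter")
})

test_that("collapse recovers simulator truth counts exactly", {
  sim <- shared_sim()
  trimmed <- lapply(sim$srna$fastq, function(f)
    preprocess_reads(f, sim$cfg$adapter)$reads)
  us <- collapse_and_count(trimmed, sim$srna$sheet)
  counts <- attr(us, "counts")
  truth <- sim$srna$truth_counts
  truth <- truth[rowSums(truth) > 0, , drop = FALSE]
  expect_setequal(rownames(counts), rownames(truth))
  expect_equal(counts[rownames(truth), colnames(truth)], truth,
               ignore_attr = TRUE)
  # deterministic id order: descending total count, lexicographic ties
  tot <- rowSums(counts)
  expect_true(all(diff(tot) <= 0))
})

test_that("collapse handles disjoint and empty samples", {
  sheet <- sample_sheet(c("s1", "s2", "s3", "s4"),
                        rep(c("control", "low-Pi"), each = 2))
  tr <- list(s1 = c("ACGTACGTACGTACGTAC"), s2 = c("TTTTGGGGCCCCAAAATT"),
             s3 = character(0), s4 = c("ACGTACGTACGTACGTAC"))
  us <- collapse_and_count(tr, sheet)
  counts <- attr(us, "counts")
  expect_equal(dim(counts), c(2L, 4L))
  expect_equal(unname(counts["ACGTACGTACGTACGTAC", ]), c(1L, 0L, 0L, 1L))
  expect_equal(unname(colSums(counts)[3L]), 0L)
})

test_that("cpm sums to 1e6 per non-empty sample and is scale invariant", {
  sheet <- sample_sheet(c("s1", "s2", "s3", "s4"),
                        rep(c("control", "low-Pi"), each = 2))
  tr <- list(s1 = rep(c("ACGTACGTACGTACGTAC", "TTTTGGGGCCCCAAAATT"), c(5, 5)),
             s2 = rep("ACGTACGTACGTACGTAC", 3L),
             s3 = rep("TTTTGGGGCCCCAAAATT", 7L),
             s4 = character(0))
  us <- NULL
  expect_warning(us <- cpm_normalize(collapse_and_count(tr, sheet)),
                 "zero-total")
  cpm <- attr(us, "cpm")
  expect_equal(unname(colSums(cpm)[1:3]), rep(1e6, 3))
  expect_equal(unname(cpm[, "s1"]), c(500000, 500000))
  expect_equal(unname(colSums(cpm)[4L]), 0)
  # doubling all counts leaves cpm unchanged
  tr2 <- lapply(tr, rep, each = 2L)
  us2 <- NULL
  expect_warning(us2 <- cpm_normalize(collapse_and_count(tr2, sheet)))
  expect_equal(attr(us2, "cpm"), attr(us, "cpm"), ignore_attr = TRUE)
})

test_that("miRNA reference annotation is strand-specific with mismatch budget", {
  mat <- c(mirA = "ACGGTTACGGATCCGGATCGG")
  pre <- c(MIRA = paste0(rand_dna(20L), mat, rand_dna(20L)))
  hit <- annotate_mirbase(unname(mat), mat, pre, max_mismatch = 0L)
  expect_setequal(hit$ref_id, c("mirA", "MIRA"))
  expect_true(all(hit$layer == "mirbase_exact"))

  mut <- mat
  substr(mut, 5, 5) <- "C"   # one substitution
  expect_identical(nrow(annotate_mirbase(unname(mut), mat, pre, 0L)), 0L)
  h1 <- annotate_mirbase(unname(mut), mat, pre, 1L)
  expect_true(all(h1$mismatches == 1L))
  expect_true(all(h1$layer == "mirbase_mismatch"))

  anti <- rc_chr(unname(mat))
  expect_identical(nrow(annotate_mirbase(anti, mat, pre, 0L)), 0L)
})

test_that("isomiR offsets follow the precursor coordinates", {
  pre <- paste0(rand_dna(30L), "ACGGTTACGGATCCGGATCGG", rand_dna(30L))
  mat <- substr(pre, 31L, 51L)
  expect_identical(classify_isomir(mat, mat, pre)$kind, "exact")
  plus3 <- substr(pre, 31L, 52L)      # one templated 3' base
  call <- classify_isomir(plus3, mat, pre)
  expect_equal(unlist(call[1:2]), c(five_prime_offset = 0L,
                                    three_prime_offset = 1L))
  expect_identical(call$kind, "isomiR")
  sub5 <- substr(pre, 32L, 51L)       # missing first base
  expect_equal(unlist(classify_isomir(sub5, mat, pre)[1:2]),
               c(five_prime_offset = -1L, three_prime_offset = 0L))
  expect_null(classify_isomir(rand_dna(21L), mat, pre))
})

test_that("cDNA-class annotation honours priority and records strand", {
  tx <- transcript_models(
    c("r1", "p1"), c("rRNA", "protein-coding"), c("1H", "2H"),
    c(paste0(rand_dna(40L), "ACGGTTACGGATCCGGATCGG", rand_dna(40L)),
      paste0(rand_dna(10L), "ACGGTTACGGATCCGGATCGG", rand_dna(10L))))
  frag <- "ACGGTTACGGATCCGGATCGG"
  ann <- annotate_cdna_classes(frag, tx)
  expect_setequal(ann$per_class$cdna_class, c("rRNA", "protein-coding"))
  expect_identical(unname(ann$combined[frag]), "rRNA")  # priority-forced
  # antisense-only fragment is found and flagged
  anti <- rc_chr(frag)
  ann2 <- annotate_cdna_classes(anti, tx)
  expect_true(all(ann2$per_class$strand == "antisense"))
  # unmatched sequence stays unannotated
  expect_true(is.na(annotate_cdna_classes(rand_dna(22L), tx)$combined))
  # input order invariance of combined assignment
  ann3 <- annotate_cdna_classes(frag, tx[2:1, ])
  expect_identical(unname(ann3$combined[frag]), "rRNA")
})

test_that("annotation layering is a partition with the documented order", {
  sim <- shared_sim()
  trimmed <- lapply(sim$srna$fastq, function(f)
    preprocess_reads(f, sim$cfg$adapter)$reads)
  us <- collapse_and_count(trimmed, sim$srna$sheet)
  rep <- annotation_report(us, sim$ref$mature_mirnas,
                           sim$ref$precursor_mirnas, sim$ref$transcripts)
  expect_identical(nrow(rep), nrow(us))
  expect_true(all(rep$layer %in% c("mirbase_exact", "cdna_class",
                                   "mirbase_mismatch", "unannotated")))
  # miRNA-derived population members are annotated as exact matches
  pop <- sim$truth$srna_population
  mir_seqs <- pop$sequence[pop$origin %in% c("mature", "isomir")]
  got <- rep$layer[match(intersect(mir_seqs, rep$sequence), rep$sequence)]
  expect_true(all(got == "mirbase_exact"))
})

test_that("distribution summaries match the percentage definition", {
  seqs <- c(rep(strrep("A", 18L), 274L), rep(strrep("C", 21L), 1796L - 274L))
  d <- summarize_distributions(seqs)
  expect_equal(d$length_distribution$percent[d$length_distribution$length == 18L],
               15.26)
  expect_equal(sum(d$length_distribution$percent), 100, tolerance = 0.01)
  single <- summarize_distributions(rep(strrep("G", 20L), 7L))
  expect_equal(single$length_distribution$percent[
    single$length_distribution$length == 20L], 100)
  empty <- summarize_distributions(character(0))
  expect_identical(nrow(empty$length_distribution), 0L)
})
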