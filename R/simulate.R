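#' Simulation configuration for the planted-truth data generator
#'
#' Defines the study conditions the generator emulates: two conditions
#' (`low-Pi` vs `control`) with three biological replicates each, unique
#' 18-25 nt small RNAs with negative-binomial counts and planted fold
#' changes, degradome tags whose 5' ends mark cleavage sites opposite small
#' RNA nucleotide 10 on planted targets, mRNA counts with planted DEGs, and
#' 2-kb promoters with planted P1BS/PHO elements.
#'
#' @param seed Integer seed; identical configurations reproduce
#'   byte-identical outputs. Keep below 2^31 - 16.
#' @param n_mirnas Number of mature miRNAs in the reference.
#' @param n_transcripts_per_class Named integer vector over the eight cDNA
#'   classes (`non-translating`, `protein-coding`, `pseudogene`, `rRNA`,
#'   `snoRNA`, `snRNA`, `SRP-RNA`, `tRNA`).
#' @param n_replicates_per_group Replicates per condition (default 3).
#' @param mean_library_size Expected small RNA reads per sample.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2). The source libraries' dispersion is unknown;
#'   this is a free parameter, defaulting to 0.1 (a typical value for
#'   three-replicate plant RNA-seq).
#' @param planted_dem_fraction Fraction of miRNA-derived small RNAs given a
#'   true fold change.
#' @param planted_des_fraction Fraction of non-miRNA small RNAs given a true
#'   fold change.
#' @param planted_deg_fraction Fraction of protein-coding genes given a true
#'   fold change in the mRNA count simulation.
#' @param planted_log2fc_range Absolute log2 fold-change interval from which
#'   planted effects are drawn (sign randomised).
#' @param n_planted_targets Number of planted miRNA:transcript cleavage
#'   pairs.
#' @param degradome_signal_to_noise Ratio of cleavage-site tag abundance to
#'   the per-position background rate.
#' @param degradome_background_depth Mean background tags per transcript
#'   position.
#' @param promoter_length Upstream sequence length in bases (default 2000).
#' @param planted_motif_counts Named vector: motifs planted per promoter
#'   (names must be `P1BS` and/or `PHO`).
#' @param planted_site_mismatches Mismatches introduced into each planted
#'   target site, placed outside small RNA positions 4-14 so the core around
#'   positions 9-11 stays perfectly complementary.
#' @param mirna_length Mature miRNA length (default 21, the canonical plant
#'   DCL1 product).
#' @param adapter 3' adapter ligated to simulated small RNA reads.
#' @param low_quality_tail If `TRUE`, reads carry a low-quality random 3'
#'   tail after the adapter, to exercise quality trimming.
#' @param degradome_five_prime_bias If `TRUE`, background degradome tags are
#'   biased toward transcript 5' ends; default is a uniform background (the
#'   simplest null for peak-category tests).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_mirnas = 30L,
                       n_transcripts_per_class = c(
                         "non-translating" = 8L, "protein-coding" = 30L,
                         "pseudogene" = 5L, "rRNA" = 4L, "snoRNA" = 4L,
                         "snRNA" = 4L, "SRP-RNA" = 3L, "tRNA" = 6L),
                       n_replicates_per_group = 3L,
                       mean_library_size = 5e4,
                       nb_dispersion = 0.1,
                       planted_dem_fraction = 0.3,
                       planted_des_fraction = 0.2,
                       planted_deg_fraction = 0.15,
                       planted_log2fc_range = c(3, 6),
                       n_planted_targets = 10L,
                       degradome_signal_to_noise = 50,
                       degradome_background_depth = 2,
                       promoter_length = 2000L,
                       planted_motif_counts = c(P1BS = 2L, PHO = 1L),
                       planted_site_mismatches = 0L,
                       mirna_length = 21L,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       low_quality_tail = FALSE,
                       degradome_five_prime_bias = FALSE) {
  cfg <- list(seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
              n_transcripts_per_class = n_transcripts_per_class,
              n_replicates_per_group = as.integer(n_replicates_per_group),
              mean_library_size = mean_library_size,
              nb_dispersion = nb_dispersion,
              planted_dem_fraction = planted_dem_fraction,
              planted_des_fraction = planted_des_fraction,
              planted_deg_fraction = planted_deg_fraction,
              planted_log2fc_range = planted_log2fc_range,
              n_planted_targets = as.integer(n_planted_targets),
              degradome_signal_to_noise = degradome_signal_to_noise,
              degradome_background_depth = degradome_background_depth,
              promoter_length = as.integer(promoter_length),
              planted_motif_counts = planted_motif_counts,
              planted_site_mismatches = as.integer(planted_site_mismatches),
              mirna_length = as.integer(mirna_length),
              adapter = adapter,
              low_quality_tail = isTRUE(low_quality_tail),
              degradome_five_prime_bias = isTRUE(degradome_five_prime_bias))
  .validate_sim_config(cfg)
  class(cfg) <- c("sim_config", "list")
  cfg
}

.validate_sim_config <- function(cfg) {
  if (cfg$seed < 0L || cfg$seed > .Machine$integer.max - 16L)
    stop("seed must be a non-negative integer below 2^31 - 16")
  if (!setequal(names(cfg$n_transcripts_per_class), CDNA_CLASSES))
    stop("n_transcripts_per_class must name exactly the eight cDNA classes")
  if (any(cfg$n_transcripts_per_class < 1L))
    stop("zero transcripts requested in class: ",
         names(cfg$n_transcripts_per_class)[cfg$n_transcripts_per_class < 1L][1L])
  counts <- c(cfg$n_mirnas, cfg$n_replicates_per_group, cfg$mean_library_size,
              cfg$n_planted_targets, cfg$promoter_length)
  if (any(counts < 0)) stop("counts must be non-negative")
  props <- c(cfg$planted_dem_fraction, cfg$planted_des_fraction,
             cfg$planted_deg_fraction)
  if (any(props < 0 | props > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be non-negative")
  if (cfg$degradome_signal_to_noise < 0)
    stop("degradome_signal_to_noise must be non-negative")
  if (length(cfg$planted_log2fc_range) != 2L ||
      cfg$planted_log2fc_range[1L] > cfg$planted_log2fc_range[2L])
    stop("planted_log2fc_range must be an ordered interval")
  if (cfg$n_planted_targets > cfg$n_mirnas)
    stop("n_planted_targets cannot exceed n_mirnas")
  if (cfg$n_planted_targets > cfg$n_transcripts_per_class[["protein-coding"]])
    stop("n_planted_targets cannot exceed the number of protein-coding transcripts")
  invisible(cfg)
}

.rand_seq <- function(n, len) {
  if (length(len) == 1L) len <- rep(len, n)
  vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

# Sample a signed log2 fold change from the configured magnitude interval.
.rand_lfc <- function(n, range) {
  runif(n, range[1L], range[2L]) * sample(c(-1, 1), n, replace = TRUE)
}

#' Generate a planted-truth reference bundle
#'
#' Builds mature/precursor miRNA references, class-labelled transcripts,
#' 2-kb promoters and a GO annotation map, together with the planted truth:
#' differentially expressed small RNAs and genes, miRNA:target cleavage
#' pairs (the cleavage coordinate is the transcript position paired to small
#' RNA nucleotide 10), and motif positions.
#'
#' @param config A [sim_config()].
#' @return A list with elements `ref` (`mature_mirnas`, `precursor_mirnas`,
#'   `transcripts`, `promoters`, `go_annotation`) and `truth` (`de_srnas`,
#'   `de_genes`, `target_pairs`, `motif_positions`, `srna_population`).
#' @export
generate_reference <- function(config) {
  .validate_sim_config(config)
  for (m in names(config$planted_motif_counts)) {
    cons <- MOTIF_CONSENSUS[[m]]
    if (is.null(cons)) stop("unknown motif name: ", m)
    if (nchar(cons) > config$promoter_length)
      stop("motif '", m, "' is longer than the promoter")
  }
  set.seed(config$seed)
  m <- config$mirna_length

  ## miRNA references: mature embedded in a random precursor
  mature <- .rand_seq(config$n_mirnas, m)
  names(mature) <- sprintf("sim-miR%03d", seq_len(config$n_mirnas))
  flank5 <- .rand_seq(config$n_mirnas, 40L)
  flank3 <- .rand_seq(config$n_mirnas, 40L)
  precursor <- paste0(flank5, mature, flank3)
  names(precursor) <- sub("miR", "MIR", names(mature))

  ## class-labelled transcripts
  cls <- rep(names(config$n_transcripts_per_class),
             config$n_transcripts_per_class)
  len_range <- list("protein-coding" = c(600L, 1200L), "rRNA" = c(300L, 600L),
                    "tRNA" = c(200L, 300L))
  lens <- vapply(cls, function(cl) {
    r <- len_range[[cl]]
    if (is.null(r)) r <- c(300L, 800L)
    sample(r[1L]:r[2L], 1L)
  }, integer(1))
  ids <- sprintf("tx-%s-%03d", gsub("[^A-Za-z]", "", cls),
                 unlist(lapply(config$n_transcripts_per_class, seq_len)))
  chroms <- sample(paste0(1:7, "H"), length(cls), replace = TRUE)
  seqs <- .rand_seq(length(cls), lens)

  ## plant miRNA target sites into distinct protein-coding transcripts
  pc_idx <- which(cls == "protein-coding")
  tgt_tx <- sample(pc_idx, config$n_planted_targets)
  tgt_mir <- sample(config$n_mirnas, config$n_planted_targets)
  target_pairs <- data.frame(srna_id = character(0), transcript_id = character(0),
                             cleavage_pos = integer(0), site_start = integer(0),
                             stringsAsFactors = FALSE)
  for (k in seq_len(config$n_planted_targets)) {
    ti <- tgt_tx[k]; L <- nchar(seqs[ti])
    a_max <- L - m - 10L          # leave room for a >=20-nt degradome tag
    a <- sample(seq(11L, a_max), 1L)
    site <- revcomp(mature[tgt_mir[k]])
    if (config$planted_site_mismatches > 0L) {
      # corrupt only positions whose paired sRNA position is outside 4..14,
      # keeping >=10 contiguous complementary bases across positions 9-11
      srna_pos_ok <- setdiff(seq_len(m), 4:14)
      mut <- sample(srna_pos_ok,
                    min(config$planted_site_mismatches, length(srna_pos_ok)))
      for (p in mut) {
        j <- m - p + 1L  # site-local coordinate paired to sRNA position p
        sb <- substr(mature[tgt_mir[k]], p, p)
        forbidden <- c(chartr("ACGT", "TGCA", sb),
                       if (sb == "G") "T" else if (sb == "T") "G" else NULL)
        repl <- sample(setdiff(c("A", "C", "G", "T"), forbidden), 1L)
        substr(site, j, j) <- repl
      }
    }
    substr(seqs[ti], a, a + m - 1L) <- site
    target_pairs <- rbind(target_pairs, data.frame(
      srna_id = names(mature)[tgt_mir[k]], transcript_id = ids[ti],
      cleavage_pos = a + m - 10L, site_start = a, stringsAsFactors = FALSE))
  }
  transcripts <- transcript_models(ids, cls, chroms, seqs)

  ## small RNA population: exact matures, isomiRs, cDNA fragments, random
  pop <- data.frame(sequence = unname(mature), origin = "mature",
                    ref_id = names(mature), stringsAsFactors = FALSE)
  iso_parent <- sample(config$n_mirnas, max(1L, config$n_mirnas %/% 2L))
  for (i in iso_parent) {
    off5 <- sample(c(-2L, -1L, 0L, 1L, 2L), 1L)
    off3 <- sample(c(-2L, -1L, 0L, 1L, 2L), 1L)
    if (off5 == 0L && off3 == 0L) off3 <- 1L
    s <- 41L + off5                # mature occupies 41..(40+m) in precursor
    e <- 40L + m + off3
    iso <- substr(precursor[i], s, e)
    if (nchar(iso) >= 18L && nchar(iso) <= 25L)
      pop <- rbind(pop, data.frame(sequence = iso, origin = "isomir",
                                   ref_id = names(mature)[i],
                                   stringsAsFactors = FALSE))
  }
  for (cl in CDNA_CLASSES) {
    cl_idx <- which(transcripts$cdna_class == cl)
    n_frag <- max(3L, length(cl_idx))
    src <- sample(cl_idx, n_frag, replace = TRUE)
    for (ti in src) {
      fl <- sample(18:25, 1L)
      fs <- sample(nchar(transcripts$sequence[ti]) - fl + 1L, 1L)
      pop <- rbind(pop, data.frame(
        sequence = substr(transcripts$sequence[ti], fs, fs + fl - 1L),
        origin = paste0("cdna:", cl), ref_id = transcripts$id[ti],
        stringsAsFactors = FALSE))
    }
  }
  pop <- rbind(pop, data.frame(sequence = .rand_seq(30L, sample(18:25, 30L, TRUE)),
                               origin = "random", ref_id = NA_character_,
                               stringsAsFactors = FALSE))
  pop <- pop[!duplicated(pop$sequence), ]
  rownames(pop) <- NULL

  ## planted differential expression among sRNAs
  is_mir <- pop$origin %in% c("mature", "isomir")
  n_dem <- round(config$planted_dem_fraction * sum(is_mir))
  n_des <- round(config$planted_des_fraction * sum(!is_mir))
  de_idx <- c(sample(which(is_mir), n_dem), sample(which(!is_mir), n_des))
  de_srnas <- setNames(.rand_lfc(length(de_idx), config$planted_log2fc_range),
                       pop$sequence[de_idx])

  ## promoters for protein-coding genes, with planted motifs
  genes <- transcripts$id[transcripts$cdna_class == "protein-coding"]
  promoters <- setNames(.rand_seq(length(genes), config$promoter_length), genes)
  motif_positions <- list()
  W <- config$promoter_length
  for (g in genes) {
    placed <- data.frame(motif = character(0), strand = character(0),
                         start = integer(0), stringsAsFactors = FALSE)
    occupied <- integer(0)
    for (mn in names(config$planted_motif_counts)) {
      cons <- MOTIF_CONSENSUS[[mn]]
      ml <- nchar(cons)
      for (k in seq_len(config$planted_motif_counts[[mn]])) {
        for (try in 1:50) {
          p <- sample(W - ml + 1L, 1L)
          if (!any((p:(p + ml - 1L)) %in% occupied)) break
        }
        occupied <- c(occupied, p:(p + ml - 1L))
        inst <- .instantiate_iupac(cons)
        strand <- sample(c("+", "-"), 1L)
        substr(promoters[g], p, p + ml - 1L) <-
          if (strand == "+") inst else revcomp(inst)
        placed <- rbind(placed, data.frame(
          motif = mn, strand = strand, start = p - W - 1L,
          stringsAsFactors = FALSE))
      }
    }
    motif_positions[[g]] <- placed
  }

  ## planted DEGs and a GO annotation map (two terms biased toward DEGs)
  n_deg <- round(config$planted_deg_fraction * length(genes))
  deg_ids <- sample(genes, n_deg)
  de_genes <- setNames(.rand_lfc(n_deg, config$planted_log2fc_range), deg_ids)
  go <- list()
  for (t in 1:18) {
    sz <- sample(5:min(30L, length(genes)), 1L)
    go[[sprintf("GO:SIM%04d", t)]] <- sample(genes, sz)
  }
  if (n_deg >= 2L) {
    for (t in 19:20) {
      n_in <- max(2L, round(0.6 * n_deg))
      go[[sprintf("GO:SIM%04d", t)]] <-
        unique(c(sample(deg_ids, n_in), sample(genes, 4L)))
    }
  }

  list(ref = list(mature_mirnas = mature, precursor_mirnas = precursor,
                  transcripts = transcripts, promoters = promoters,
                  go_annotation = go),
       truth = list(de_srnas = de_srnas, de_genes = de_genes,
                    target_pairs = target_pairs,
                    motif_positions = motif_positions,
                    srna_population = pop))
}

# Replace IUPAC ambiguity codes with concrete bases, uniformly at random.
.instantiate_iupac <- function(cons) {
  ch <- strsplit(cons, "")[[1]]
  paste(vapply(ch, function(c) {
    opts <- IUPAC_SETS[[c]]
    if (is.null(opts)) stop("non-IUPAC character in consensus: ", c)
    sample(opts, 1L)
  }, character(1)), collapse = "")
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' The core count engine shared by the read-level and count-level
#' simulators. Group A is `control`, group B is `low-Pi`; a feature's
#' low-Pi mean is its control mean times `2^log2fc`.
#'
#' @param means_control Per-feature control-group mean counts.
#' @param log2fc Per-feature true log2 fold changes (0 = null feature).
#' @param n_rep Replicates per group.
#' @param dispersion NB dispersion; 0 gives Poisson counts.
#' @param seed Integer seed.
#' @param feature_ids Optional rownames.
#' @return Integer matrix (features x 2*n_rep) with a `groups` attribute.
#' @export
simulate_count_matrix <- function(means_control, log2fc, n_rep = 3L,
                                  dispersion = 0.1, seed = 1L,
                                  feature_ids = NULL) {
  stopifnot(length(means_control) == length(log2fc), dispersion >= 0)
  set.seed(seed)
  nf <- length(means_control)
  means <- cbind(matrix(rep(means_control, n_rep), ncol = n_rep),
                 matrix(rep(means_control * 2^log2fc, n_rep), ncol = n_rep))
  draw <- function(mu) {
    if (dispersion == 0) rpois(length(mu), mu)
    else rnbinom(length(mu), size = 1 / dispersion, mu = mu)
  }
  mat <- matrix(draw(as.vector(means)), nrow = nf)
  colnames(mat) <- c(paste0("control_", seq_len(n_rep)),
                     paste0("lowPi_", seq_len(n_rep)))
  rownames(mat) <- if (is.null(feature_ids)) {
    sprintf("feat%05d", seq_len(nf))
  } else feature_ids
  attr(mat, "groups") <- rep(c("control", "low-Pi"), each = n_rep)
  mat
}

#' Simulate small RNA sequencing reads with planted truth
#'
#' Per unique small RNA and sample, counts are drawn negative-binomially
#' with group means differing by the planted log2 fold change; each read is
#' the small RNA sequence followed by the 3' adapter at constant high
#' quality (Phred 40), optionally with a low-quality random tail.
#'
#' @param ref,truth From [generate_reference()] (same generation).
#' @param config The same [sim_config()].
#' @param out_dir Directory for per-sample FASTQ files.
#' @return List: `fastq` (named paths), `sheet` (sample sheet),
#'   `truth_counts` (unique-sequence x sample matrix of true counts).
#' @export
simulate_srna_reads <- function(ref, truth, config, out_dir) {
  .validate_sim_config(config)
  if (config$mean_library_size <= 0) stop("library size must be positive")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 1L)
  pop <- truth$srna_population
  nf <- nrow(pop)

  ## relative abundances scaled to the mean library size; planted features
  ## are re-assigned control means in [50, 200] so effects are detectable
  base <- rlnorm(nf, meanlog = log(20), sdlog = 1)
  base <- base * config$mean_library_size / sum(base)
  lfc <- rep(0, nf)
  planted <- match(names(truth$de_srnas), pop$sequence)
  lfc[planted] <- truth$de_srnas
  base[planted] <- runif(length(planted), 50, 200)
  base <- pmax(base, 0.5)

  n_rep <- config$n_replicates_per_group
  counts <- simulate_count_matrix(base, lfc, n_rep, config$nb_dispersion,
                                  seed = config$seed + 2L,
                                  feature_ids = pop$sequence)
  sheet <- sample_sheet(colnames(counts),
                        group = rep(c("control", "low-Pi"), each = n_rep))
  paths <- character(0)
  for (j in seq_len(ncol(counts))) {
    cnt <- counts[, j]
    seqs <- rep(pop$sequence, cnt)
    n <- length(seqs)
    reads <- paste0(seqs, config$adapter)
    qual <- strrep("I", nchar(reads))
    if (config$low_quality_tail) {
      tail_seq <- .rand_seq(n, 5L)
      reads <- paste0(reads, tail_seq)
      qual <- paste0(qual, strrep("#", 5L))
    }
    df <- data.frame(id = sprintf("%s_read%06d", colnames(counts)[j], seq_len(n)),
                     sequence = reads, quality = qual,
                     stringsAsFactors = FALSE)
    p <- file.path(out_dir, paste0(colnames(counts)[j], ".fastq"))
    write_fastq(df, p)
    paths[colnames(counts)[j]] <- p
  }
  sheet$path <- unname(paths[sheet$sample_id])
  list(fastq = paths, sheet = sheet, truth_counts = counts)
}

#' Simulate degradome (PARE) 5'-end tags
#'
#' Background tags are drawn uniformly along each transcript (optionally
#' 5'-biased); for each planted target pair, tags of length 20 whose 5' end
#' sits exactly at the planted cleavage coordinate are added with abundance
#' `signal_to_noise` times the per-position background rate.
#'
#' @inheritParams simulate_srna_reads
#' @param out_file Path for the degradome FASTQ.
#' @return List: `fastq` path and `tags` data.frame.
#' @export
simulate_degradome_reads <- function(ref, truth, config, out_file) {
  .validate_sim_config(config)
  set.seed(config$seed + 3L)
  tx <- ref$transcripts
  tag_len <- 20L
  seqs <- character(0)
  for (i in seq_len(nrow(tx))) {
    L <- tx$exon_length[i]
    npos <- L - tag_len + 1L
    if (npos < 1L) next
    n_bg <- rpois(1L, config$degradome_background_depth * npos)
    if (n_bg > 0L) {
      if (config$degradome_five_prime_bias) {
        w <- rev(seq_len(npos)); pos <- sample(npos, n_bg, TRUE, prob = w)
      } else {
        pos <- sample(npos, n_bg, TRUE)
      }
      seqs <- c(seqs, substring(tx$sequence[i], pos, pos + tag_len - 1L))
    }
  }
  for (k in seq_len(nrow(truth$target_pairs))) {
    ti <- match(truth$target_pairs$transcript_id[k], tx$id)
    c0 <- truth$target_pairs$cleavage_pos[k]
    n_sig <- rpois(1L, config$degradome_signal_to_noise *
                     config$degradome_background_depth)
    if (n_sig > 0L)
      seqs <- c(seqs, rep(substr(tx$sequence[ti], c0, c0 + tag_len - 1L), n_sig))
  }
  df <- data.frame(id = sprintf("pare_read%07d", seq_along(seqs)),
                   sequence = seqs, quality = strrep("I", nchar(seqs)),
                   stringsAsFactors = FALSE)
  write_fastq(df, out_file)
  list(fastq = out_file, tags = df)
}

#' Simulate an mRNA count table with planted DEGs
#'
#' Counts are simulated at count level (no reads); planted DEGs have group
#' means offset by their true log2 fold change. Exon lengths come from the
#' transcript models.
#'
#' @inheritParams simulate_srna_reads
#' @return List: `counts` (gene x sample matrix), `exon_length` (named),
#'   `sheet` (sample sheet).
#' @export
simulate_mrna_counts <- function(ref, truth, config) {
  .validate_sim_config(config)
  set.seed(config$seed + 4L)
  genes <- ref$transcripts$id[ref$transcripts$cdna_class == "protein-coding"]
  nf <- length(genes)
  base <- rlnorm(nf, meanlog = log(100), sdlog = 1)
  lfc <- rep(0, nf)
  planted <- match(names(truth$de_genes), genes)
  lfc[planted] <- truth$de_genes
  base[planted] <- runif(length(planted), 50, 300)
  counts <- simulate_count_matrix(base, lfc, config$n_replicates_per_group,
                                  config$nb_dispersion,
                                  seed = config$seed + 5L, feature_ids = genes)
  sheet <- sample_sheet(colnames(counts),
                        group = rep(c("control", "low-Pi"),
                                    each = config$n_replicates_per_group))
  el <- setNames(ref$transcripts$exon_length[match(genes, ref$transcripts$id)],
                 genes)
  list(counts = counts, exon_length = el, sheet = sheet)
}
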