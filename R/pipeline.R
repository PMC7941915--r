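#' Build and validate a pipeline configuration
#'
#' Aggregates every stage's thresholds with their documented defaults:
#' significance `alpha = 0.05` (strict `<`), small RNA lengths 18-25,
#' quality limit 0.02, degradome minimum tag length 15, Allen threshold
#' 4.0, MFE-ratio minimum 0.6, 2000-bp promoter window with 500-bp bins.
#' Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults (see source or the pipeline
#'   vignette for the full key list).
#' @param file Optional YAML file whose keys are applied before `...`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(..., file = NULL) {
  defaults <- list(
    out_dir = "srnadeg_out",
    seed = 1L,
    adapter = "TGGAATTCTCGGGTGCCAAGG",
    quality_limit = 0.02,
    min_len = 18L, max_len = 25L,
    alpha = 0.05,
    degradome_min_len = 15L,
    allen_threshold = 4.0,
    mfe_ratio_min = 0.6,
    category_max = 4L,
    max_bulge = 2L,
    n_perm = 0L,
    motifs = c("P1BS", "PHO"),
    promoter_window = 2000L,
    motif_bin = 500L,
    sim = list())
  over <- list(...)
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    over <- utils::modifyList(y, over)
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (cfg$quality_limit <= 0 || cfg$quality_limit >= 1)
    stop("quality_limit must lie in (0, 1)")
  if (cfg$min_len > cfg$max_len) stop("min_len must not exceed max_len")
  if (cfg$degradome_min_len < 1L) stop("degradome_min_len must be >= 1")
  if (cfg$allen_threshold < 0) stop("allen_threshold must be >= 0")
  if (cfg$mfe_ratio_min < 0 || cfg$mfe_ratio_min > 1)
    stop("mfe_ratio_min must lie in [0, 1]")
  if (!all(cfg$motifs %in% names(MOTIF_CONSENSUS)))
    stop("unknown motif name(s): ",
         paste(setdiff(cfg$motifs, names(MOTIF_CONSENSUS)), collapse = ", "))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

.stage_file <- function(cfg, ...) file.path(cfg$out_dir, ...)

.require_stage <- function(cfg, files, stage) {
  missing <- files[!file.exists(.stage_file(cfg, files))]
  if (length(missing))
    stop("missing output of prior stage '", stage, "': ",
         paste(missing, collapse = ", "), "; run that stage first")
}

#' Run pipeline stages
#'
#' Subcommands mirror the analysis branches: `simulate` writes a
#' planted-truth dataset; `srna` preprocesses, collapses and annotates
#' small RNA reads; `diffexp` runs the exact NB test and selects DEMs and
#' DESs; `degradome` builds cleavage profiles and predicts targets;
#' `quant` computes RPKM/TPM and DEGs; `motifs` scans DEG promoters;
#' `enrich` runs GO over-representation; `all` runs everything in
#' dependency order. Every output file is listed in a manifest with its
#' MD5 content hash.
#'
#' @param subcommand One of `"simulate"`, `"srna"`, `"diffexp"`,
#'   `"degradome"`, `"quant"`, `"motifs"`, `"enrich"`, `"all"`.
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest data.frame (`file`, `md5`).
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "srna", "diffexp",
                                        "degradome", "quant", "motifs",
                                        "enrich"),
                         config = pipeline_config()) {
  subcommand <- match.arg(subcommand)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (subcommand == "all")
    c("simulate", "srna", "diffexp", "degradome", "quant", "motifs", "enrich")
  else subcommand
  for (st in stages) {
    message("[srnadeg] stage: ", st)
    switch(st,
           simulate = .stage_simulate(cfg),
           srna = .stage_srna(cfg),
           diffexp = .stage_diffexp(cfg),
           degradome = .stage_degradome(cfg),
           quant = .stage_quant(cfg),
           motifs = .stage_motifs(cfg),
           enrich = .stage_enrich(cfg))
  }
  files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.tsv"]
  manifest <- data.frame(file = substring(files, nchar(cfg$out_dir) + 2L),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.table(manifest, .stage_file(cfg, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

.stage_simulate <- function(cfg) {
  sc <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  gen <- generate_reference(sc)
  d <- .stage_file(cfg, "sim")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  write_fasta(gen$ref$mature_mirnas, file.path(d, "mature.fa"))
  write_fasta(gen$ref$precursor_mirnas, file.path(d, "precursor.fa"))
  write_transcript_models(gen$ref$transcripts, file.path(d, "transcripts.fa"),
                          file.path(d, "transcripts.tsv"))
  write_fasta(gen$ref$promoters, file.path(d, "promoters.fa"))
  go <- data.frame(term = rep(names(gen$ref$go_annotation),
                              lengths(gen$ref$go_annotation)),
                   gene_id = unlist(gen$ref$go_annotation, use.names = FALSE))
  write.table(go, file.path(d, "go_annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  sr <- simulate_srna_reads(gen$ref, gen$truth, sc, file.path(d, "srna_fastq"))
  write_sample_sheet(sr$sheet, file.path(d, "sample_sheet.tsv"))
  write_count_table(sr$truth_counts, file.path(d, "srna_truth_counts.tsv"),
                    "sequence")
  simulate_degradome_reads(gen$ref, gen$truth, sc,
                           file.path(d, "degradome.fastq"))
  mr <- simulate_mrna_counts(gen$ref, gen$truth, sc)
  write_count_table(mr$counts, file.path(d, "mrna_counts.tsv"), "gene_id")
  write.table(data.frame(sequence = names(gen$truth$de_srnas),
                         log2fc = unname(gen$truth$de_srnas)),
              file.path(d, "truth_de_srnas.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene_id = names(gen$truth$de_genes),
                         log2fc = unname(gen$truth$de_genes)),
              file.path(d, "truth_de_genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(gen$truth$target_pairs, file.path(d, "truth_targets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

.read_sim <- function(cfg) {
  d <- .stage_file(cfg, "sim")
  list(dir = d,
       mature = read_fasta(file.path(d, "mature.fa")),
       precursor = read_fasta(file.path(d, "precursor.fa")),
       transcripts = read_transcript_models(file.path(d, "transcripts.fa"),
                                            file.path(d, "transcripts.tsv")),
       promoters = read_fasta(file.path(d, "promoters.fa")),
       sheet = read_sample_sheet(file.path(d, "sample_sheet.tsv")))
}

.stage_srna <- function(cfg) {
  .require_stage(cfg, "sim/sample_sheet.tsv", "simulate")
  sim <- .read_sim(cfg)
  trimmed <- list()
  for (i in seq_len(nrow(sim$sheet))) {
    pp <- preprocess_reads(sim$sheet$path[i], cfg$adapter, cfg$quality_limit,
                           cfg$min_len, cfg$max_len)
    message("  sample ", sim$sheet$sample_id[i], ": ",
            paste(names(pp$log), pp$log, sep = "=", collapse = " "))
    trimmed[[sim$sheet$sample_id[i]]] <- pp$reads
  }
  us <- cpm_normalize(collapse_and_count(trimmed, sim$sheet))
  rep <- annotation_report(us, sim$mature, sim$precursor, sim$transcripts)
  counts <- attr(us, "counts")
  cpm <- attr(us, "cpm")
  tab <- data.frame(us, counts, check.names = FALSE)
  colnames(tab)[-(1:2)] <- paste0("raw_", colnames(counts))
  tab <- cbind(tab, setNames(as.data.frame(cpm),
                             paste0("cpm_", colnames(cpm))))
  write.table(tab, .stage_file(cfg, "unique_srnas.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(rep, .stage_file(cfg, "srna_annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

.stage_diffexp <- function(cfg) {
  .require_stage(cfg, c("unique_srnas.tsv", "srna_annotation.tsv"), "srna")
  sim <- .read_sim(cfg)
  tab <- read.delim(.stage_file(cfg, "unique_srnas.tsv"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  raw <- as.matrix(tab[, grep("^raw_", colnames(tab)), drop = FALSE])
  colnames(raw) <- sub("^raw_", "", colnames(raw))
  rownames(raw) <- tab$sequence
  design <- two_group_design(sim$sheet$group[match(colnames(raw),
                                                   sim$sheet$sample_id)])
  res <- run_diffexp(raw, design)
  ann <- read.delim(.stage_file(cfg, "srna_annotation.tsv"),
                    stringsAsFactors = FALSE)
  layers <- setNames(ann$layer, ann$sequence)
  sel <- select_dems_dess(res, layers, cfg$alpha)
  write.table(res, .stage_file(cfg, "diffexp_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sel$dem, .stage_file(cfg, "dem.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sel$des, .stage_file(cfg, "des.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message("  DEMs: ", nrow(sel$dem), "  DESs: ", nrow(sel$des))
  invisible(NULL)
}

.stage_degradome <- function(cfg) {
  .require_stage(cfg, c("sim/degradome.fastq", "dem.tsv", "des.tsv"),
                 "diffexp")
  sim <- .read_sim(cfg)
  profiles <- build_cleavage_profile(.stage_file(cfg, "sim/degradome.fastq"),
                                     sim$transcripts,
                                     min_tag_len = cfg$degradome_min_len)
  dem <- read.delim(.stage_file(cfg, "dem.tsv"), stringsAsFactors = FALSE)
  des <- read.delim(.stage_file(cfg, "des.tsv"), stringsAsFactors = FALSE)
  q <- unique(c(dem$feature_id, des$feature_id))
  q <- q[nchar(q) >= 18L & nchar(q) <= 25L]
  preds <- predict_targets(setNames(q, q), profiles, sim$transcripts,
                           track = "allen",
                           allen_threshold = cfg$allen_threshold,
                           category_max = cfg$category_max,
                           max_bulge = cfg$max_bulge, n_perm = cfg$n_perm,
                           seed = cfg$seed)
  write.table(preds, .stage_file(cfg, "target_predictions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  prof_tab <- do.call(rbind, lapply(names(profiles), function(id) {
    p <- profiles[[id]]
    idx <- which(p$raw > 0L)
    if (!length(idx)) return(NULL)
    data.frame(transcript_id = id, position = idx, raw = p$raw[idx],
               depth_normalized = p$depth_normalized[idx],
               fraction = p$fraction[idx], stringsAsFactors = FALSE)
  }))
  write.table(prof_tab, .stage_file(cfg, "cleavage_profiles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(preds)) {
    top <- preds[1L, ]
    export_tplot(profiles[[top$transcript_id]], top,
                 .stage_file(cfg, paste0("tplot_", top$srna_id, "_",
                                         top$transcript_id)))
  }
  message("  predictions: ", nrow(preds))
  invisible(NULL)
}

.stage_quant <- function(cfg) {
  .require_stage(cfg, "sim/mrna_counts.tsv", "simulate")
  sim <- .read_sim(cfg)
  counts <- read_count_table(.stage_file(cfg, "sim/mrna_counts.tsv"))
  el <- setNames(sim$transcripts$exon_length, sim$transcripts$id)
  quant <- compute_rpkm_tpm(counts, el)
  design <- two_group_design(ifelse(grepl("^control", colnames(counts)),
                                    "control", "low-Pi"))
  deg <- test_deg(counts, design, alpha = cfg$alpha,
                  chromosomes = setNames(sim$transcripts$chromosome,
                                         sim$transcripts$id))
  write_count_table(quant$tpm, .stage_file(cfg, "tpm.tsv"), "gene_id")
  write_count_table(quant$rpkm, .stage_file(cfg, "rpkm.tsv"), "gene_id")
  write.table(deg$degs, .stage_file(cfg, "degs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  chrom <- chromosome_distribution(deg$degs, sim$transcripts)
  write.table(chrom, .stage_file(cfg, "deg_chromosomes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message("  DEGs: ", nrow(deg$degs))
  invisible(NULL)
}

.stage_motifs <- function(cfg) {
  .require_stage(cfg, c("degs.tsv", "sim/promoters.fa"), "quant")
  sim <- .read_sim(cfg)
  degs <- read.delim(.stage_file(cfg, "degs.tsv"), stringsAsFactors = FALSE)
  proms <- sim$promoters[intersect(degs$gene_id, names(sim$promoters))]
  hits <- do.call(rbind, lapply(cfg$motifs, function(m)
    scan_iupac_motif(proms, m)))
  reg <- setNames(degs$log2fc, degs$gene_id)
  bins <- bin_motif_positions(hits, cfg$motif_bin, cfg$promoter_window, reg)
  gc <- count_genes_with_motifs(hits, names(proms))
  write.table(hits, .stage_file(cfg, "motif_hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bins, .stage_file(cfg, "motif_bins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(motif = c(names(gc$per_motif), "any"),
                         n_genes = c(unname(gc$per_motif), gc$any_motif)),
              .stage_file(cfg, "motif_gene_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message("  genes with any motif: ", gc$any_motif, " / ", length(proms))
  invisible(NULL)
}

.stage_enrich <- function(cfg) {
  .require_stage(cfg, c("degs.tsv", "sim/go_annotation.tsv"), "quant")
  sim <- .read_sim(cfg)
  degs <- read.delim(.stage_file(cfg, "degs.tsv"), stringsAsFactors = FALSE)
  go <- read.delim(.stage_file(cfg, "sim/go_annotation.tsv"),
                   stringsAsFactors = FALSE)
  annotation <- split(go$gene_id, go$term)
  background <- sim$transcripts$id[sim$transcripts$cdna_class ==
                                     "protein-coding"]
  enr <- go_overrepresentation(intersect(degs$gene_id, background),
                               annotation, background)
  write.table(enr, .stage_file(cfg, "go_enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message("  enriched terms (Bonferroni < ", cfg$alpha, "): ",
          sum(enr$p_bonferroni < cfg$alpha))
  invisible(NULL)
}
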