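#' Preprocess small RNA reads: quality trim, adapter trim, length filter
#'
#' Quality trimming keeps the maximal-scoring segment under the running-sum
#' rule `score += (limit - P_error(base))` (the modified-Mott rule with
#' error-probability limit 0.02 by default). The 3' adapter is then removed
#' at the leftmost position where the adapter prefix matches the read
#' suffix, allowing one mismatch per 10 aligned bases. Finally, reads
#' outside the retained length window are discarded.
#'
#' @param reads Data.frame with `id`, `sequence`, `quality` (Phred+33), as
#'   returned by [read_fastq()], or a FASTQ path.
#' @param adapter Non-empty 3' adapter sequence.
#' @param quality_limit Error-probability limit in (0, 1); default 0.02.
#' @param min_len,max_len Retained insert length window (default 18-25 nt).
#' @param min_overlap Minimum read/adapter overlap to trim (default 5).
#' @return List: `reads` (trimmed data.frame) and `log` (named counts of
#'   discarded reads by reason: `quality`, `too_short`, `too_long`).
#' @export
preprocess_reads <- function(reads, adapter, quality_limit = 0.02,
                             min_len = 18L, max_len = 25L, min_overlap = 5L) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  if (quality_limit <= 0 || quality_limit >= 1)
    stop("quality_limit must lie in (0, 1)")
  n0 <- nrow(reads)
  if (n0 == 0L)
    return(list(reads = reads,
                log = c(input = 0L, quality = 0L, too_short = 0L,
                        too_long = 0L, kept = 0L)))

  seg <- .mott_trim_cpp(reads$quality, quality_limit)
  keep_q <- seg[, 2L] >= seg[, 1L]
  n_quality <- sum(!keep_q)
  reads <- reads[keep_q, , drop = FALSE]
  seg <- seg[keep_q, , drop = FALSE]
  reads$sequence <- substr(reads$sequence, seg[, 1L], seg[, 2L])
  reads$quality <- substr(reads$quality, seg[, 1L], seg[, 2L])

  ins <- .adapter_find_cpp(reads$sequence, adapter, as.integer(min_overlap))
  reads$sequence <- substr(reads$sequence, 1L, ins)
  reads$quality <- substr(reads$quality, 1L, ins)

  len <- nchar(reads$sequence)
  n_short <- sum(len < min_len)
  n_long <- sum(len > max_len)
  reads <- reads[len >= min_len & len <= max_len, , drop = FALSE]
  rownames(reads) <- NULL
  list(reads = reads,
       log = c(input = n0, quality = n_quality, too_short = n_short,
               too_long = n_long, kept = nrow(reads)))
}

#' Collapse trimmed reads into unique small RNAs with per-sample counts
#'
#' One record per distinct sequence. Internal ids are assigned in a
#' deterministic order: descending total count, then lexicographic.
#'
#' @param trimmed Named list (one element per sample) of trimmed read
#'   data.frames (or character vectors of sequences).
#' @param sheet Sample sheet; element names must match `sample_id`.
#' @return A `unique_srnas` object: data.frame with `id`, `sequence`, and a
#'   `counts` matrix attribute (sequences x samples); `cpm` filled by
#'   [cpm_normalize()].
#' @export
collapse_and_count <- function(trimmed, sheet) {
  if (length(trimmed) < 1L) stop("need at least one sample")
  if (is.null(names(trimmed)) ||
      !all(names(trimmed) %in% sheet$sample_id))
    stop("trimmed list must be named by sample_id")
  seqs_per_sample <- lapply(trimmed, function(x)
    if (is.data.frame(x)) x$sequence else as.character(x))
  all_seq <- sort(unique(unlist(seqs_per_sample, use.names = FALSE)))
  counts <- vapply(seqs_per_sample, function(s) {
    tab <- table(factor(s, levels = all_seq))
    as.integer(tab)
  }, integer(length(all_seq)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(all_seq))
  colnames(counts) <- names(trimmed)
  rownames(counts) <- all_seq
  ord <- order(-rowSums(counts), all_seq)
  counts <- counts[ord, , drop = FALSE]
  us <- data.frame(id = seq_len(nrow(counts)), sequence = rownames(counts),
                   stringsAsFactors = FALSE)
  attr(us, "counts") <- counts
  attr(us, "cpm") <- NULL
  class(us) <- c("unique_srnas", "data.frame")
  us
}

#' Counts-per-million normalisation of unique small RNAs
#'
#' `cpm = raw * 1e6 / (per-sample sum of raw over retained sequences)`; the
#' denominator is the post-length-filter library size.
#'
#' @param us A `unique_srnas` object.
#' @return The same object with its `cpm` attribute filled.
#' @export
cpm_normalize <- function(us) {
  counts <- attr(us, "counts")
  tot <- colSums(counts)
  if (any(tot == 0)) {
    warning("zero-total sample(s): ",
            paste(colnames(counts)[tot == 0], collapse = ", "),
            "; cpm set to 0")
  }
  scale <- ifelse(tot > 0, 1e6 / tot, 0)
  cpm <- sweep(counts, 2L, scale, `*`)
  attr(us, "cpm") <- cpm
  us
}

#' Annotate unique small RNAs against miRNA references
#'
#' A sequence matches when it occurs as an ungapped sense-strand substring
#' of a mature or precursor reference with at most `max_mismatch`
#' substitutions. All matching references are reported; matching is
#' strand-specific (antisense occurrences do not count).
#'
#' @param us A `unique_srnas` object (or character vector of sequences).
#' @param mature,precursor Named character vectors of reference sequences.
#' @param max_mismatch Allowed substitutions, 0-3.
#' @return Data.frame: `srna_id`, `sequence`, `ref_id`, `ref_type`
#'   (`mature`/`precursor`), `mismatches`, `layer` (`mirbase_exact` when
#'   `max_mismatch = 0`, else `mirbase_mismatch`), `strand` (always
#'   `sense`).
#' @export
annotate_mirbase <- function(us, mature, precursor = character(0),
                             max_mismatch = 0L) {
  if (length(mature) + length(precursor) == 0L)
    stop("references must be non-empty")
  stopifnot(max_mismatch >= 0L, max_mismatch <= 3L)
  seqs <- if (is.data.frame(us)) us$sequence else as.character(us)
  ids <- if (is.data.frame(us)) us$id else seq_along(seqs)
  refs <- c(mature, precursor)
  ref_type <- c(rep("mature", length(mature)),
                rep("precursor", length(precursor)))
  ref_set <- Biostrings::DNAStringSet(chartr("U", "T", toupper(refs)))
  out <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    pat <- Biostrings::DNAString(seqs[k])
    hits <- which(Biostrings::vcountPattern(
      pat, ref_set, max.mismatch = max_mismatch, with.indels = FALSE) > 0)
    if (!length(hits)) next
    mm <- vapply(hits, function(h) {
      for (k in 0:max_mismatch) {
        if (Biostrings::countPattern(pat, ref_set[[h]], max.mismatch = k) > 0)
          return(k)
      }
      max_mismatch
    }, integer(1))
    out[[k]] <- data.frame(
      srna_id = ids[k], sequence = seqs[k], ref_id = names(refs)[hits],
      ref_type = ref_type[hits], mismatches = as.integer(mm),
      layer = ifelse(mm == 0L, "mirbase_exact", "mirbase_mismatch"),
      strand = "sense", stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(srna_id = integer(0), sequence = character(0),
                      ref_id = character(0), ref_type = character(0),
                      mismatches = integer(0), layer = character(0),
                      strand = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Classify an isomiR relative to its annotated mature miRNA
#'
#' Offsets are computed from the small RNA's start/end positions in the
#' precursor relative to the mature miRNA's positions. Positive offsets
#' denote end extensions ("super"), negative offsets shortenings ("sub");
#' the call is `exact` iff both offsets are zero.
#'
#' @param srna Small RNA sequence.
#' @param mature,precursor Mature and precursor reference sequences (the
#'   mature must be a substring of the precursor).
#' @param max_mismatch Substitutions allowed when locating the small RNA in
#'   the precursor.
#' @return A one-row data.frame (`five_prime_offset`, `three_prime_offset`,
#'   `kind`), or `NULL` when the small RNA does not map to the precursor.
#' @export
classify_isomir <- function(srna, mature, precursor, max_mismatch = 0L) {
  srna <- chartr("U", "T", toupper(srna))
  mature <- chartr("U", "T", toupper(mature))
  precursor <- chartr("U", "T", toupper(precursor))
  mpos <- stringi::stri_locate_first_fixed(precursor, mature)
  if (is.na(mpos[1L])) stop("mature is not a substring of its precursor")
  hit <- Biostrings::matchPattern(Biostrings::DNAString(srna),
                                  Biostrings::DNAString(precursor),
                                  max.mismatch = max_mismatch)
  if (length(hit) == 0L) return(NULL)
  s <- Biostrings::start(hit)[1L]
  e <- Biostrings::end(hit)[1L]
  five <- mpos[1L] - s
  three <- e - mpos[2L]
  data.frame(five_prime_offset = as.integer(five),
             three_prime_offset = as.integer(three),
             kind = if (five == 0L && three == 0L) "exact" else "isomiR",
             stringsAsFactors = FALSE)
}

#' Annotate unique small RNAs against cDNA classes
#'
#' Exact substring matching (sense or antisense, strand recorded) of each
#' unique sequence against class-labelled transcripts. Per-class mode
#' reports every class with at least one match; combined mode assigns one
#' class by a fixed priority.
#'
#' @param us A `unique_srnas` object (or character vector).
#' @param transcripts A `transcript_models` data.frame.
#' @param priority Class priority for combined mode.
#' @return List: `per_class` (data.frame `srna_id`, `sequence`,
#'   `cdna_class`, `strand`) and `combined` (named character vector of
#'   classes, `NA` for unannotated sequences).
#' @export
annotate_cdna_classes <- function(us, transcripts,
                                  priority = DEFAULT_CLASS_PRIORITY) {
  seqs <- if (is.data.frame(us)) us$sequence else as.character(us)
  ids <- if (is.data.frame(us)) us$id else seq_along(seqs)
  rc <- revcomp(seqs)
  hit_class <- vector("list", length(seqs))
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts$sequence[i]
    sense <- stringi::stri_detect_fixed(tx, seqs)
    anti <- stringi::stri_detect_fixed(tx, rc)
    for (k in which(sense | anti)) {
      hit_class[[k]] <- rbind(hit_class[[k]], data.frame(
        cdna_class = transcripts$cdna_class[i],
        strand = if (sense[k]) "sense" else "antisense",
        stringsAsFactors = FALSE))
    }
  }
  per <- do.call(rbind, lapply(seq_along(seqs), function(k) {
    h <- hit_class[[k]]
    if (is.null(h)) return(NULL)
    h <- unique(h)
    data.frame(srna_id = ids[k], sequence = seqs[k], h,
               stringsAsFactors = FALSE)
  }))
  if (is.null(per))
    per <- data.frame(srna_id = integer(0), sequence = character(0),
                      cdna_class = character(0), strand = character(0),
                      stringsAsFactors = FALSE)
  combined <- setNames(rep(NA_character_, length(seqs)), seqs)
  for (k in seq_along(seqs)) {
    h <- hit_class[[k]]
    if (is.null(h)) next
    pr <- priority[priority %in% h$cdna_class]
    combined[k] <- pr[1L]
  }
  list(per_class = per, combined = combined)
}

#' Layered annotation report for unique small RNAs
#'
#' Applies the annotation layers in order: exact miRNA reference match
#' beats cDNA-class annotation, which beats miRNA re-annotation with 1-3
#' mismatches, which beats `unannotated`. Every sequence receives exactly
#' one layer.
#'
#' @inheritParams annotate_mirbase
#' @param transcripts A `transcript_models` data.frame.
#' @param priority Class priority for combined-mode cDNA assignment.
#' @return Data.frame: one row per unique small RNA with `srna_id`,
#'   `sequence`, `layer`, `assigned_name`, `cdna_class`, `mismatches`,
#'   `strand`.
#' @export
annotation_report <- function(us, mature, precursor, transcripts,
                              priority = DEFAULT_CLASS_PRIORITY) {
  seqs <- us$sequence
  rep0 <- data.frame(srna_id = us$id, sequence = seqs,
                     layer = "unannotated", assigned_name = NA_character_,
                     cdna_class = NA_character_, mismatches = NA_integer_,
                     strand = NA_character_, stringsAsFactors = FALSE)
  exact <- annotate_mirbase(us, mature, precursor, max_mismatch = 0L)
  if (nrow(exact)) {
    first <- exact[!duplicated(exact$srna_id), ]
    idx <- match(first$srna_id, rep0$srna_id)
    rep0$layer[idx] <- "mirbase_exact"
    rep0$assigned_name[idx] <- first$ref_id
    rep0$mismatches[idx] <- 0L
    rep0$strand[idx] <- "sense"
  }
  open <- rep0$layer == "unannotated"
  if (any(open)) {
    cdna <- annotate_cdna_classes(us[open, , drop = FALSE], transcripts,
                                  priority)
    hit <- !is.na(cdna$combined)
    idx <- which(open)[hit]
    rep0$layer[idx] <- "cdna_class"
    rep0$cdna_class[idx] <- unname(cdna$combined[hit])
  }
  open <- rep0$layer == "unannotated"
  if (any(open)) {
    mm <- annotate_mirbase(us[open, , drop = FALSE], mature, precursor,
                           max_mismatch = 3L)
    mm <- mm[mm$mismatches >= 1L, , drop = FALSE]
    if (nrow(mm)) {
      mm <- mm[order(mm$mismatches), ]
      first <- mm[!duplicated(mm$srna_id), ]
      idx <- match(first$srna_id, rep0$srna_id)
      rep0$layer[idx] <- "mirbase_mismatch"
      rep0$assigned_name[idx] <- first$ref_id
      rep0$mismatches[idx] <- first$mismatches
      rep0$strand[idx] <- "sense"
    }
  }
  rep0
}

#' Length and class distribution summaries
#'
#' Percentages per length `= 100 * n_length / n_total`, rounded to two
#' decimals; class percentages are computed over annotated sequences in
#' combined mode.
#'
#' @param sequences Character vector of (differentially expressed) small
#'   RNA sequences.
#' @param classes Optional named class assignment (combined mode) for the
#'   class table.
#' @param lengths Length range to tabulate.
#' @return List of data.frames `length_distribution` and
#'   `class_distribution`.
#' @export
summarize_distributions <- function(sequences, classes = NULL,
                                    lengths = 18:25) {
  if (length(sequences) == 0L)
    return(list(length_distribution = data.frame(length = integer(0),
                                                 n = integer(0),
                                                 percent = numeric(0)),
                class_distribution = data.frame(cdna_class = character(0),
                                                n = integer(0),
                                                percent = numeric(0))))
  len <- nchar(sequences)
  tab <- table(factor(len, levels = lengths))
  ldist <- data.frame(length = as.integer(names(tab)), n = as.integer(tab),
                      percent = round(100 * as.integer(tab) / length(sequences),
                                      2))
  cdist <- data.frame(cdna_class = character(0), n = integer(0),
                      percent = numeric(0))
  if (!is.null(classes)) {
    cl <- classes[!is.na(classes)]
    if (length(cl)) {
      ct <- sort(table(cl), decreasing = TRUE)
      cdist <- data.frame(cdna_class = names(ct), n = as.integer(ct),
                          percent = round(100 * as.integer(ct) / length(cl), 2))
    }
  }
  list(length_distribution = ldist, class_distribution = cdist)
}
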