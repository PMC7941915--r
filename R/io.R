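#' @useDynLib srnadeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnbinom rpois runif optimize dnbinom pbinom rlnorm
#'   setNames dpois pchisq
#' @importFrom utils read.delim write.table modifyList
#' @importFrom graphics abline
NULL

# Eight cDNA classes recognised throughout the package.
CDNA_CLASSES <- c("non-translating", "protein-coding", "pseudogene",
                  "rRNA", "snoRNA", "snRNA", "SRP-RNA", "tRNA")

# Default priority used to resolve multi-class hits in combined annotation.
DEFAULT_CLASS_PRIORITY <- c("rRNA", "tRNA", "snoRNA", "snRNA", "SRP-RNA",
                            "non-translating", "protein-coding", "pseudogene")

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased on read. `U` is converted to `T` when
#' `alphabet = "DNA"` (the package-internal convention) and `T` to `U` for
#' `alphabet = "RNA"`.
#'
#' @param path Path to a FASTA file (gzip transparent).
#' @param alphabet `"DNA"` (default) or `"RNA"`.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- names(set)
  # keep only the first whitespace-delimited token as the identifier
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate FASTA identifier: ", dup)
  }
  seqs <- toupper(as.character(set))
  seqs <- if (alphabet == "DNA") chartr("U", "T", seqs) else chartr("T", "U", seqs)
  names(seqs) <- ids
  if (length(seqs) == 0L) warning("empty FASTA file: ", path)
  seqs
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Destination path.
#' @param width Line wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  set <- Biostrings::BStringSet(toupper(unname(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Path to a FASTQ file (gzip transparent).
#' @return A data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  res <- tryCatch({
    set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
    data.frame(id = sub("\\s.*$", "", names(set)),
               sequence = as.character(set),
               quality = as.character(S4Vectors::mcols(set)$qualities),
               stringsAsFactors = FALSE, row.names = NULL)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    idx <- .locate_bad_fastq_record(path)
    stop("malformed FASTQ record at record ", idx, " in ", path,
         " (", conditionMessage(res), ")")
  }
  bad <- which(nchar(res$sequence) != nchar(res$quality))
  if (length(bad))
    stop("sequence/quality length mismatch at record ", bad[1L], " in ", path)
  res
}

# Diagnostic pass run only when the parser fails: find the first record whose
# 4-line block is structurally broken, so the error can name it.
.locate_bad_fastq_record <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  rec <- 0L
  repeat {
    block <- readLines(con, n = 4L)
    if (length(block) == 0L) return(rec + 1L)
    rec <- rec + 1L
    if (length(block) < 4L ||
        !startsWith(block[1L], "@") ||
        !startsWith(block[3L], "+") ||
        nchar(block[2L]) != nchar(block[4L]))
      return(rec)
  }
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads A data.frame with columns `id`, `sequence`, `quality`.
#' @param path Destination path (a trailing `.gz` triggers gzip output).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    stop("sequence/quality length mismatch at record ",
         which(nchar(reads$sequence) != nchar(reads$quality))[1L])
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(reads)) {
    lines <- rbind(paste0("@", reads$id), reads$sequence, "+", reads$quality)
    writeLines(as.vector(lines), con)
  }
  invisible(path)
}

#' Read a features-by-samples count table
#'
#' TSV with a header line; first column holds feature identifiers, the rest
#' numeric non-negative counts.
#'
#' @param path Path to a TSV count table.
#' @param sample_sheet Optional sample sheet; if given, every `sample_id`
#'   must be present as a column.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_count_table <- function(path, sample_sheet = NULL) {
  if (!file.exists(path)) stop("count table not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs a feature column plus >=1 sample")
  feats <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
    badrow <- which(is.na(suppressWarnings(as.numeric(df[[bad + 1L]]))))[1L]
    stop("non-numeric cell at row ", badrow, ", column '",
         colnames(df)[bad + 1L], "'")
  }
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative count at row ", neg[1L, 1L], ", column '",
         colnames(mat)[neg[1L, 2L]], "'")
  rownames(mat) <- feats
  if (!is.null(sample_sheet)) {
    missing <- setdiff(sample_sheet$sample_id, colnames(mat))
    if (length(missing))
      stop("sample sheet columns missing from count table: ",
           paste(missing, collapse = ", "))
  }
  mat
}

#' Write a count table to TSV
#'
#' @param mat Numeric matrix (features x samples) with dimnames.
#' @param path Destination path.
#' @param feature_col Name of the identifier column in the output header.
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(mat, path, feature_col = "feature") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- feature_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct/validate a transcript-model table
#'
#' The transcript model is a data.frame sidecar to the transcript FASTA:
#' one row per transcript with its cDNA class, chromosome label and exon
#' length, working entirely in transcript space (coordinates are 1-based,
#' fully closed, sense strand).
#'
#' @param id,cdna_class,chromosome,sequence Character vectors of equal length.
#' @return A validated data.frame with class `transcript_models`.
#' @export
transcript_models <- function(id, cdna_class, chromosome, sequence) {
  sequence <- toupper(sequence)
  df <- data.frame(id = as.character(id),
                   cdna_class = as.character(cdna_class),
                   chromosome = as.character(chromosome),
                   exon_length = nchar(sequence),
                   sequence = sequence,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate transcript id: ",
                                 df$id[duplicated(df$id)][1L])
  bad <- setdiff(unique(df$cdna_class), CDNA_CLASSES)
  if (length(bad)) stop("unknown cDNA class: ", paste(bad, collapse = ", "))
  class(df) <- c("transcript_models", "data.frame")
  df
}

#' Write / read transcript models (FASTA + TSV sidecar)
#'
#' @param models A `transcript_models` data.frame.
#' @param fasta,tsv Paths for the sequence FASTA and attribute TSV.
#' @return Invisibly (write) / a `transcript_models` data.frame (read).
#' @export
write_transcript_models <- function(models, fasta, tsv) {
  write_fasta(setNames(models$sequence, models$id), fasta)
  write.table(models[, c("id", "cdna_class", "chromosome", "exon_length")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta, tsv = tsv))
}

#' @rdname write_transcript_models
#' @export
read_transcript_models <- function(fasta, tsv) {
  seqs <- read_fasta(fasta)
  attrs <- read.delim(tsv, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  if (!setequal(attrs$id, names(seqs)))
    stop("transcript FASTA and TSV sidecar disagree on identifiers")
  seqs <- seqs[attrs$id]
  if (any(attrs$exon_length != nchar(seqs)))
    stop("exon_length disagrees with sequence length for: ",
         attrs$id[which(attrs$exon_length != nchar(seqs))[1L]])
  transcript_models(attrs$id, attrs$cdna_class, attrs$chromosome, seqs)
}

#' Construct/read/write a sample sheet
#'
#' @param sample_id,group,organ,path Character vectors describing samples.
#' @return A validated data.frame.
#' @export
sample_sheet <- function(sample_id, group, organ = "shoot", path = NA_character_) {
  df <- data.frame(sample_id = as.character(sample_id),
                   group = as.character(group),
                   organ = as.character(organ),
                   path = as.character(path),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample id")
  if (length(unique(df$group)) != 2L)
    stop("sample sheet must define exactly two groups")
  if (any(table(df$group) < 2L))
    stop("each group needs >= 2 samples for a differential test")
  df
}

#' @rdname sample_sheet
#' @param file Path to a TSV sample sheet.
#' @export
read_sample_sheet <- function(file) {
  df <- read.delim(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(df)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  sample_sheet(df$sample_id, df$group,
               organ = if ("organ" %in% names(df)) df$organ else "shoot",
               path = if ("path" %in% names(df)) df$path else NA_character_)
}

#' @rdname sample_sheet
#' @param sheet A sample sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, file) {
  write.table(sheet, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# Reverse complement for plain character vectors (DNA alphabet).
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTUacgtu", "TGCAAtgcaa", x))
}
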