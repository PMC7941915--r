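#' Build per-transcript cleavage profiles from degradome (PARE) tags
#'
#' Tags are optionally adapter/quality trimmed like small RNA reads,
#' length-filtered (15 nt and above by default), collapsed, and each tag's
#' 5' end is counted at every transcript position where the tag matches
#' exactly on the sense strand (multimapping tags count at all loci; the
#' multiplicity is logged). Two normalisations are computed: per
#' `depth_scale` total mapped tags (default 1e7), and the fraction of each
#' transcript's total signal.
#'
#' @param tags Data.frame with a `sequence` column (e.g. from
#'   [read_fastq()]), a FASTQ path, or a character vector of tag sequences.
#' @param transcripts A `transcript_models` data.frame.
#' @param min_tag_len Minimum retained tag length (default 15).
#' @param adapter Optional 3' adapter to trim before filtering.
#' @param quality_limit Error-probability limit for quality trimming (used
#'   only when `adapter` is given and qualities are present).
#' @param depth_scale Denominator scale for depth normalisation.
#' @return A `cleavage_profiles` list: per transcript, `raw` (integer
#'   per-position counts), `depth_normalized`, `fraction`, `total`;
#'   attributes `total_mapped` and `multimap` (tags mapping to > 1 locus).
#' @export
build_cleavage_profile <- function(tags, transcripts, min_tag_len = 15L,
                                   adapter = NULL, quality_limit = 0.02,
                                   depth_scale = 1e7) {
  if (is.character(tags) && length(tags) == 1L && file.exists(tags))
    tags <- read_fastq(tags)
  if (is.data.frame(tags)) {
    if (!is.null(adapter)) {
      pp <- preprocess_reads(tags, adapter, quality_limit,
                             min_len = min_tag_len, max_len = .Machine$integer.max)
      seqs <- pp$reads$sequence
    } else {
      seqs <- tags$sequence
    }
  } else {
    seqs <- as.character(tags)
  }
  seqs <- seqs[nchar(seqs) >= min_tag_len]
  profiles <- setNames(vector("list", nrow(transcripts)), transcripts$id)
  for (i in seq_len(nrow(transcripts)))
    profiles[[i]] <- list(raw = integer(transcripts$exon_length[i]))
  if (length(seqs) == 0L) {
    warning("no degradome tags passed the length filter; profiles are empty")
  }
  tab <- table(seqs)
  uniq <- names(tab)
  cnt <- as.integer(tab)
  n_loci <- integer(length(uniq))
  for (i in seq_len(nrow(transcripts))) {
    if (length(uniq) == 0L) break
    loc <- stringi::stri_locate_all_fixed(transcripts$sequence[i], uniq,
                                          overlap = TRUE)
    for (k in seq_along(uniq)) {
      st <- loc[[k]][, 1L]
      if (all(is.na(st))) next
      n_loci[k] <- n_loci[k] + length(st)
      for (p in st) {
        profiles[[i]]$raw[p] <- profiles[[i]]$raw[p] + cnt[k]
      }
    }
  }
  total_mapped <- sum(vapply(profiles, function(p) sum(p$raw), numeric(1)))
  if (total_mapped == 0 && length(seqs) > 0L)
    warning("no degradome tags mapped to the transcripts")
  for (i in seq_along(profiles)) {
    raw <- profiles[[i]]$raw
    tot <- sum(raw)
    profiles[[i]]$depth_normalized <-
      if (total_mapped > 0) raw * depth_scale / total_mapped else raw * 0
    profiles[[i]]$fraction <- if (tot > 0) raw / tot else raw * 0
    profiles[[i]]$total <- tot
  }
  attr(profiles, "total_mapped") <- total_mapped
  attr(profiles, "multimap") <- sum(n_loci > 1L)
  class(profiles) <- c("cleavage_profiles", "list")
  profiles
}

# Independent recount of a duplex alignment's inventory from its paired
# positions. Terminal unpaired stretches are overhangs; internal gap runs
# are bulges (events counted in n_loop, nucleotides in n_bulge_nt).
.duplex_inventory <- function(pairs, srna_len, site_start, site_end) {
  pr <- pairs[order(pairs$srna_pos), , drop = FALSE]
  n_mismatch <- sum(pr$pair_class == 0L)
  n_gu <- sum(pr$pair_class == 1L)
  n_bulge_nt <- 0L
  n_loop <- 0L
  if (nrow(pr) >= 2L) {
    gs <- diff(pr$srna_pos) - 1L
    gt <- -diff(pr$target_pos) - 1L
    n_bulge_nt <- sum(pmax(gs, 0L)) + sum(pmax(gt, 0L))
    n_loop <- sum(gs > 0L | gt > 0L)
  }
  # sRNA 5' end aligns at the 3' end of the site and vice versa
  ov5 <- max(pr$srna_pos[1L] - 1L, site_end - max(pr$target_pos))
  ov3 <- max(srna_len - pr$srna_pos[nrow(pr)], min(pr$target_pos) - site_start)
  list(n_mismatch = n_mismatch, n_gu = n_gu, n_bulge_nt = n_bulge_nt,
       n_loop = n_loop, overhang5 = ov5, overhang3 = ov3)
}

#' Enumerate candidate sRNA:transcript duplexes
#'
#' Slides every transcript window of length `len(srna) - max_bulge` to
#' `len(srna) + max_bulge` and computes the optimal antiparallel pairing by
#' global alignment of the small RNA against the window's reverse
#' complement (match +1, G:U +0.5, mismatch 0, gap -2). Candidates sharing
#' the same cleavage anchor (the transcript position paired to small RNA
#' nucleotide 10) are deduplicated, keeping the best pairing score.
#'
#' @param srna Small RNA sequence, 18-25 nt.
#' @param transcript Transcript sequence (sense strand).
#' @param max_bulge Maximum bulged nucleotides, i.e. window-length slack.
#' @param min_pair_score Minimum pairing score to keep a window (defaults
#'   to `nchar(srna) - 6`, generous relative to downstream score filters).
#' @return List of duplex records: `site_start`, `site_end`, `pair_score`,
#'   `pairs` (data.frame `srna_pos`, `target_pos`, `pair_class`),
#'   `cleavage_pos` (NA when nucleotide 10 is unpaired), and the inventory
#'   fields (`n_mismatch`, `n_gu`, `n_bulge_nt`, `n_loop`, `overhang5`,
#'   `overhang3`).
#' @export
enumerate_candidate_duplexes <- function(srna, transcript, max_bulge = 2L,
                                         min_pair_score = NULL) {
  srna <- chartr("U", "T", toupper(srna))
  transcript <- chartr("U", "T", toupper(transcript))
  m <- nchar(srna)
  if (m < 18L || m > 25L) stop("srna must be 18-25 nt")
  if (nchar(transcript) < m) return(list())
  if (is.null(min_pair_score)) min_pair_score <- m - 6
  raw <- .duplex_scan_cpp(srna, transcript, as.integer(max_bulge),
                          as.double(min_pair_score))
  if (length(raw) == 0L) return(list())
  cands <- lapply(raw, function(c) {
    pairs <- data.frame(srna_pos = c$srna_pos, target_pos = c$target_pos,
                        pair_class = c$pair_class)
    inv <- .duplex_inventory(pairs, m, c$site_start, c$site_end)
    anchor <- pairs$target_pos[match(10L, pairs$srna_pos)]
    c(list(site_start = c$site_start, site_end = c$site_end,
           pair_score = c$pair_score, pairs = pairs,
           cleavage_pos = if (length(anchor) && !is.na(anchor)) anchor
                          else NA_integer_),
      inv)
  })
  # deduplicate by cleavage anchor, preferring higher pairing score, then
  # span closer to the sRNA length, then smaller start
  key <- vapply(cands, function(c)
    if (is.na(c$cleavage_pos)) paste0("s", c$site_start)
    else paste0("a", c$cleavage_pos), character(1))
  ord <- order(-vapply(cands, `[[`, numeric(1), "pair_score"),
               abs(vapply(cands, function(c) c$site_end - c$site_start + 1L,
                          integer(1)) - m),
               vapply(cands, `[[`, integer(1), "site_start"))
  cands <- cands[ord]
  key <- key[ord]
  cands[!duplicated(key)]
}

#' Allen-rule alignment score
#'
#' Penalties: mismatch 1, bulged nucleotide 1, G:U wobble 0.5, each doubled
#' within the small RNA core (positions 2-13 from the 5' end). When
#' `permit_pos10_relaxation` is on, a mismatch or G:U exactly at position
#' 10 incurs the undoubled penalty (the Fahlgren-Carrington allowance).
#' Bulged transcript nucleotides take the position of the next aligned
#' small RNA nucleotide.
#'
#' @param duplex A duplex record from [enumerate_candidate_duplexes()].
#' @param permit_pos10_relaxation Logical, default `TRUE`.
#' @return Non-negative score in 0.5 steps; lower is better.
#' @export
score_alignment_allen <- function(duplex, permit_pos10_relaxation = TRUE) {
  pr <- duplex$pairs[order(duplex$pairs$srna_pos), , drop = FALSE]
  score <- 0
  core <- function(pos) pos >= 2L & pos <= 13L
  for (k in seq_len(nrow(pr))) {
    base_pen <- if (pr$pair_class[k] == 0L) 1
                else if (pr$pair_class[k] == 1L) 0.5 else 0
    if (base_pen == 0) next
    pos <- pr$srna_pos[k]
    mult <- if (core(pos)) 2 else 1
    if (permit_pos10_relaxation && pos == 10L) mult <- 1
    score <- score + base_pen * mult
  }
  if (nrow(pr) >= 2L) {
    gs <- diff(pr$srna_pos) - 1L
    gt <- -diff(pr$target_pos) - 1L
    for (k in which(gs > 0L)) {          # bulged sRNA nucleotides
      for (pos in (pr$srna_pos[k] + 1L):(pr$srna_pos[k + 1L] - 1L))
        score <- score + ifelse(core(pos), 2, 1)
    }
    for (k in which(gt > 0L)) {          # bulged transcript nucleotides
      pos <- pr$srna_pos[k + 1L]
      score <- score + gt[k] * ifelse(core(pos), 2, 1)
    }
  }
  score
}

#' Score or reject a duplex under the MFE-filtered penalty schema
#'
#' Rejects unless `mfe_ratio >= mfe_ratio_min`, bulged nucleotides
#' `<= max_bulge_nt` and both overhangs `<= max_overhang`; otherwise the
#' score is a weighted penalty sum over the duplex inventory (lower is
#' better).
#'
#' @param duplex Duplex record with `mfe`, `perfect_mfe`, `mfe_ratio`
#'   filled (see [predict_targets()]), or a bare record whose energies are
#'   computed on the fly from `pairs` when `srna` is given.
#' @param weights Named penalty weights `mismatch`, `gu`, `bulge`, `loop`
#'   (defaults 2, 1, 3, 1).
#' @param mfe_ratio_min,max_bulge_nt,max_overhang Filter thresholds.
#' @param srna Small RNA sequence, needed when energies are not filled.
#' @return The score (>= 0), or `NA` when the duplex is rejected.
#' @export
targetseek_score_filter <- function(duplex,
                                    weights = c(mismatch = 2, gu = 1,
                                                bulge = 3, loop = 1),
                                    mfe_ratio_min = 0.6, max_bulge_nt = 3L,
                                    max_overhang = 2L, srna = NULL) {
  if (any(weights < 0)) stop("weights must be non-negative")
  ratio <- duplex$mfe_ratio
  if (is.null(ratio)) {
    if (is.null(srna)) stop("srna needed to compute duplex energies")
    e <- duplex_mfe(duplex$pairs, srna)
    ratio <- mfe_ratio(e, perfect_mfe(srna))
  }
  if (ratio < mfe_ratio_min) return(NA_real_)
  if (duplex$n_bulge_nt > max_bulge_nt) return(NA_real_)
  if (max(duplex$overhang5, duplex$overhang3) > max_overhang) return(NA_real_)
  unname(weights["mismatch"] * duplex$n_mismatch +
           weights["gu"] * duplex$n_gu +
           weights["bulge"] * duplex$n_bulge_nt +
           weights["loop"] * duplex$n_loop)
}

#' Degradome peak category at a transcript position
#'
#' With `c` the raw count at the position, `M` the transcript maximum and
#' `A` the mean over positions with at least one read: category 4 when
#' `c = 1`; 0 when `c > 1` and `c` is the unique maximum; 1 when `c > 1`
#' equals a shared maximum; 2 when `1 < c < M` and `c > A`; 3 when
#' `1 < c <= A`. Category 0 is the best support for cleavage.
#'
#' @param profile One element of a `cleavage_profiles` list (or an integer
#'   vector of raw counts).
#' @param position 1-based transcript position.
#' @return Integer category 0-4.
#' @export
assign_peak_category <- function(profile, position) {
  raw <- if (is.list(profile)) profile$raw else profile
  if (position < 1L || position > length(raw))
    stop("position outside transcript bounds")
  cc <- raw[position]
  if (cc == 0L) stop("no signal at position ", position)
  if (cc == 1L) return(4L)
  M <- max(raw)
  A <- mean(raw[raw >= 1L])
  if (cc == M) {
    if (sum(raw == M) == 1L) return(0L) else return(1L)
  }
  if (cc > A) return(2L)
  3L
}

# Mononucleotide shuffle (sampling without replacement); dinucleotide
# shuffle preserves the dinucleotide multiset by random transition-walk.
.shuffle_seq <- function(seq, mode = c("mono", "di")) {
  mode <- match.arg(mode)
  ch <- strsplit(seq, "")[[1]]
  if (mode == "mono")
    return(paste(sample(ch), collapse = ""))
  # simple Eulerian-walk dinucleotide shuffle; falls back to mono shuffle
  # when the walk dead-ends
  for (try in 1:20) {
    succ <- split(ch[-1L], ch[-length(ch)])
    succ <- lapply(succ, sample)
    out <- character(length(ch))
    out[1L] <- ch[1L]
    ok <- TRUE
    for (i in 2:length(ch)) {
      nxt <- succ[[out[i - 1L]]]
      if (is.null(nxt) || !length(nxt)) { ok <- FALSE; break }
      out[i] <- nxt[1L]
      succ[[out[i - 1L]]] <- nxt[-1L]
    }
    if (ok) return(paste(out, collapse = ""))
  }
  paste(sample(ch), collapse = "")
}

#' Permutation p-value for a predicted cleavage site
#'
#' The null distribution is built from shuffled versions of the small RNA:
#' the p-value is `(1 + k) / (n_perm + 1)` where `k` counts shuffles that
#' achieve an Allen score no worse than observed at a site on this
#' transcript whose cleavage-position peak category is no worse than
#' observed.
#'
#' @param profile Cleavage profile of the transcript.
#' @param srna Small RNA sequence.
#' @param transcript Transcript sequence.
#' @param observed_score,observed_category The prediction's Allen score and
#'   category.
#' @param n_perm Number of shuffles (>= 1), default 1000.
#' @param seed Integer seed for the shuffles.
#' @param shuffle `"mono"` (default) or `"di"` for dinucleotide shuffles.
#' @param max_bulge Passed to [enumerate_candidate_duplexes()].
#' @return Permutation p-value in (0, 1].
#' @export
site_pvalue_permutation <- function(profile, srna, transcript,
                                    observed_score, observed_category,
                                    n_perm = 1000L, seed = 1L,
                                    shuffle = c("mono", "di"),
                                    max_bulge = 2L) {
  shuffle <- match.arg(shuffle)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  set.seed(seed)
  raw <- if (is.list(profile)) profile$raw else profile
  hits <- 0L
  for (b in seq_len(n_perm)) {
    sh <- .shuffle_seq(srna, shuffle)
    cands <- enumerate_candidate_duplexes(sh, transcript, max_bulge,
                                          min_pair_score = nchar(sh) - 6)
    for (cd in cands) {
      if (is.na(cd$cleavage_pos)) next
      sc <- score_alignment_allen(cd)
      if (sc > observed_score) next
      pos <- cd$cleavage_pos
      cat_ok <- FALSE
      for (p in intersect(c(pos, pos - 1L, pos + 1L), seq_along(raw))) {
        if (raw[p] > 0L && assign_peak_category(raw, p) <= observed_category) {
          cat_ok <- TRUE; break
        }
      }
      if (cat_ok) { hits <- hits + 1L; break }
    }
  }
  (1 + hits) / (n_perm + 1)
}

#' Predict small RNA targets from degradome evidence
#'
#' For each small RNA x transcript pair, candidate duplexes are scored by
#' the chosen track. The predicted cleavage coordinate is the transcript
#' position paired to small RNA nucleotide 10; a prediction is kept when a
#' degradome position within +-1 of that coordinate carries signal, its
#' peak category is at most `category_max`, and the score passes the
#' track's threshold. Results are sorted by score (then p-value when
#' permutations are requested).
#'
#' @param srnas Named character vector of small RNA sequences (names are
#'   reported as `srna_id`).
#' @param profiles A `cleavage_profiles` list.
#' @param transcripts A `transcript_models` data.frame.
#' @param track `"allen"` or `"targetseek"`.
#' @param allen_threshold Maximum Allen score (default 4.0).
#' @param category_max Maximum peak category (default 4: report all, filter
#'   downstream).
#' @param max_bulge Window slack for duplex enumeration.
#' @param permit_pos10_relaxation Allen-track position-10 allowance.
#' @param weights,mfe_ratio_min,max_bulge_nt,max_overhang Passed to
#'   [targetseek_score_filter()] for the targetseek track.
#' @param n_perm Permutations for per-site p-values; 0 skips them.
#' @param seed Seed for the permutation null.
#' @return Data.frame of `TargetPrediction` records: `srna_id`,
#'   `transcript_id`, `cleavage_pos`, `category`, `score`, `p_value`,
#'   `track`, site span, inventory and energy columns.
#' @export
predict_targets <- function(srnas, profiles, transcripts,
                            track = c("allen", "targetseek"),
                            allen_threshold = 4.0, category_max = 4L,
                            max_bulge = 2L, permit_pos10_relaxation = TRUE,
                            weights = c(mismatch = 2, gu = 1, bulge = 3,
                                        loop = 1),
                            mfe_ratio_min = 0.6, max_bulge_nt = 3L,
                            max_overhang = 2L, n_perm = 0L, seed = 1L) {
  track <- match.arg(track)
  if (is.null(names(srnas))) names(srnas) <- paste0("srna", seq_along(srnas))
  rows <- list()
  for (si in seq_along(srnas)) {
    srna <- srnas[[si]]
    pm <- perfect_mfe(srna)
    for (ti in seq_len(nrow(transcripts))) {
      tx_id <- transcripts$id[ti]
      prof <- profiles[[tx_id]]
      if (is.null(prof) || prof$total == 0) next
      cands <- enumerate_candidate_duplexes(srna, transcripts$sequence[ti],
                                            max_bulge)
      for (cd in cands) {
        if (is.na(cd$cleavage_pos)) next
        cd$mfe <- duplex_mfe(cd$pairs, srna)
        cd$perfect_mfe <- pm
        cd$mfe_ratio <- mfe_ratio(cd$mfe, pm)
        if (track == "allen") {
          sc <- score_alignment_allen(cd, permit_pos10_relaxation)
          if (sc > allen_threshold) next
        } else {
          sc <- targetseek_score_filter(cd, weights, mfe_ratio_min,
                                        max_bulge_nt, max_overhang)
          if (is.na(sc)) next
        }
        # degradome evidence within +-1 of the nt-10 pairing position
        pos0 <- cd$cleavage_pos
        cand_pos <- intersect(c(pos0, pos0 - 1L, pos0 + 1L),
                              seq_along(prof$raw))
        cand_pos <- cand_pos[prof$raw[cand_pos] > 0L]
        if (!length(cand_pos)) next
        ev <- cand_pos[which.max(prof$raw[cand_pos])]
        categ <- assign_peak_category(prof, ev)
        if (categ > category_max) next
        pv <- NA_real_
        if (n_perm > 0L)
          pv <- site_pvalue_permutation(prof, srna, transcripts$sequence[ti],
                                        if (track == "allen") sc else
                                          score_alignment_allen(cd, permit_pos10_relaxation),
                                        categ, n_perm = n_perm,
                                        seed = seed + si, max_bulge = max_bulge)
        rows[[length(rows) + 1L]] <- data.frame(
          srna_id = names(srnas)[si], transcript_id = tx_id,
          cleavage_pos = pos0, evidence_pos = ev, category = categ,
          score = sc, p_value = pv, track = track,
          site_start = cd$site_start, site_end = cd$site_end,
          n_mismatch = cd$n_mismatch, n_gu = cd$n_gu,
          n_bulge_nt = cd$n_bulge_nt, n_loop = cd$n_loop,
          overhang5 = cd$overhang5, overhang3 = cd$overhang3,
          mfe = cd$mfe, perfect_mfe = cd$perfect_mfe,
          mfe_ratio = cd$mfe_ratio, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(srna_id = character(0), transcript_id = character(0),
               cleavage_pos = integer(0), evidence_pos = integer(0),
               category = integer(0), score = numeric(0),
               p_value = numeric(0), track = character(0),
               site_start = integer(0), site_end = integer(0),
               n_mismatch = integer(0), n_gu = integer(0),
               n_bulge_nt = integer(0), n_loop = integer(0),
               overhang5 = integer(0), overhang3 = integer(0),
               mfe = numeric(0), perfect_mfe = numeric(0),
               mfe_ratio = numeric(0), stringsAsFactors = FALSE)
  out[order(out$score, out$p_value), , drop = FALSE]
}

#' Export a target plot (t-plot) for a prediction
#'
#' Writes a per-position abundance TSV (positions with signal only) and a
#' rendered figure with the predicted cleavage coordinate marked by a
#' vertical red line.
#'
#' @param profile Cleavage profile of the transcript.
#' @param prediction One row of the [predict_targets()] output.
#' @param path_prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.pdf`.
#' @return Invisibly, the two file paths.
#' @export
export_tplot <- function(profile, prediction, path_prefix) {
  dir <- dirname(path_prefix)
  if (!dir.exists(dir)) stop("unwritable path: directory does not exist: ", dir)
  raw <- profile$raw
  idx <- which(raw > 0L)
  df <- data.frame(position = idx, raw = raw[idx],
                   depth_normalized = profile$depth_normalized[idx],
                   fraction = profile$fraction[idx])
  tsv <- paste0(path_prefix, ".tsv")
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  pdf_path <- paste0(path_prefix, ".pdf")
  grDevices::pdf(pdf_path, width = 7, height = 4)
  on.exit(grDevices::dev.off())
  plot(seq_along(raw), raw, type = "h", col = "black",
       xlab = sprintf("position on %s", prediction$transcript_id),
       ylab = "degradome tag abundance",
       main = sprintf("%s -> %s (category %d)", prediction$srna_id,
                      prediction$transcript_id, prediction$category))
  graphics::abline(v = prediction$cleavage_pos, col = "red", lwd = 2)
  grDevices::dev.off()
  on.exit()
  .strip_pdf_dates(pdf_path)
  invisible(c(tsv = tsv, pdf = pdf_path))
}

# Overwrite the embedded creation/modification timestamps with a constant
# of equal byte length so re-exports are byte-identical.
.strip_pdf_dates <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  at <- grepRaw("D:[0-9]{14}", raw, all = TRUE)
  zero <- charToRaw("D:00000000000000")
  for (p in at) raw[p:(p + 15L)] <- zero
  writeBin(raw, path)
  invisible(path)
}
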