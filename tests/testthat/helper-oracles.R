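# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the implementation's code paths (no C++ pair classes, no Biostrings
# matching) so they can serve as second routes.

rc_chr <- function(x) {
  vapply(strsplit(chartr("ACGTU", "TGCAA", x), ""), function(ch)
    paste(rev(ch), collapse = ""), character(1))
}

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# independent base-pair classification from raw characters
oracle_pair_kind <- function(s_base, t_base) {
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  if (wc[[s_base]] == t_base) return("wc")
  if ((s_base == "G" && t_base == "T") || (s_base == "T" && t_base == "G"))
    return("gu")
  "mm"
}

# brute-force recount of a duplex inventory from its paired positions and
# the underlying sequences
oracle_inventory <- function(duplex, srna, transcript) {
  pr <- duplex$pairs[order(duplex$pairs$srna_pos), , drop = FALSE]
  kinds <- mapply(function(i, j) oracle_pair_kind(substr(srna, i, i),
                                                  substr(transcript, j, j)),
                  pr$srna_pos, pr$target_pos)
  n_mm <- sum(kinds == "mm")
  n_gu <- sum(kinds == "gu")
  bulge <- 0L; loops <- 0L
  if (nrow(pr) >= 2L) {
    for (k in seq_len(nrow(pr) - 1L)) {
      ds <- pr$srna_pos[k + 1L] - pr$srna_pos[k] - 1L
      dt <- pr$target_pos[k] - pr$target_pos[k + 1L] - 1L
      bulge <- bulge + ds + dt
      if (ds > 0L || dt > 0L) loops <- loops + 1L
    }
  }
  list(n_mismatch = n_mm, n_gu = n_gu, n_bulge_nt = bulge, n_loop = loops)
}

# brute-force Allen-rule rescoring from paired positions and sequences
oracle_allen <- function(duplex, srna, transcript, relax10 = TRUE) {
  pr <- duplex$pairs[order(duplex$pairs$srna_pos), , drop = FALSE]
  w <- function(pos, pen, is_pair) {
    mult <- if (pos >= 2 && pos <= 13) 2 else 1
    if (relax10 && is_pair && pos == 10) mult <- 1
    pen * mult
  }
  sc <- 0
  for (k in seq_len(nrow(pr))) {
    kind <- oracle_pair_kind(substr(srna, pr$srna_pos[k], pr$srna_pos[k]),
                             substr(transcript, pr$target_pos[k],
                                    pr$target_pos[k]))
    if (kind == "mm") sc <- sc + w(pr$srna_pos[k], 1, TRUE)
    if (kind == "gu") sc <- sc + w(pr$srna_pos[k], 0.5, TRUE)
  }
  if (nrow(pr) >= 2L) {
    for (k in seq_len(nrow(pr) - 1L)) {
      ds <- pr$srna_pos[k + 1L] - pr$srna_pos[k] - 1L
      dt <- pr$target_pos[k] - pr$target_pos[k + 1L] - 1L
      if (ds > 0L)
        for (pos in (pr$srna_pos[k] + 1L):(pr$srna_pos[k + 1L] - 1L))
          sc <- sc + w(pos, 1, FALSE)
      if (dt > 0L)
        sc <- sc + dt * w(pr$srna_pos[k + 1L], 1, FALSE)
    }
  }
  sc
}

# sliding-window IUPAC scan over both strands, overlaps included
oracle_motif_scan <- function(seq, consensus) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  ml <- nchar(consensus)
  cch <- strsplit(consensus, "")[[1]]
  scan_strand <- function(s) {
    W <- nchar(s)
    hits <- integer(0)
    if (W < ml) return(hits)
    sch <- strsplit(s, "")[[1]]
    for (p in 1:(W - ml + 1L)) {
      ok <- TRUE
      for (k in seq_len(ml)) {
        if (!(sch[p + k - 1L] %in% sets[[cch[k]]])) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, p)
    }
    hits
  }
  list(plus = scan_strand(seq), minus = scan_strand(rc_chr(seq)))
}

# plant a (possibly corrupted) target site for srna into a random
# transcript; returns the transcript and the site start
plant_site <- function(srna, tx_len = 120L, n_mut = 0L) {
  m <- nchar(srna)
  tx <- rand_dna(tx_len)
  a <- sample(10:(tx_len - m - 10L), 1L)
  site <- rc_chr(srna)
  if (n_mut > 0L) {
    pos <- sample(m, n_mut)
    for (p in pos) {
      cur <- substr(site, p, p)
      substr(site, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  substr(tx, a, a + m - 1L) <- site
  list(transcript = tx, site_start = a)
}

# one small shared simulation reused across test files (memoised)
.shared_env <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (!is.null(.shared_env$sim)) return(.shared_env$sim)
  cfg <- sim_config(seed = 101L, n_mirnas = 15L,
                    n_transcripts_per_class = c(
                      "non-translating" = 4L, "protein-coding" = 15L,
                      "pseudogene" = 3L, "rRNA" = 3L, "snoRNA" = 3L,
                      "snRNA" = 3L, "SRP-RNA" = 3L, "tRNA" = 3L),
                    mean_library_size = 8e3, n_planted_targets = 8L)
  gen <- generate_reference(cfg)
  out <- file.path(tempdir(), "srnadeg_shared_sim")
  sr <- simulate_srna_reads(gen$ref, gen$truth, cfg, out)
  .shared_env$sim <- list(cfg = cfg, ref = gen$ref, truth = gen$truth,
                          srna = sr)
  .shared_env$sim
}
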