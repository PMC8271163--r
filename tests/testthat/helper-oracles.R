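# Independent oracles: brute-force or enumerative implementations kept
# deliberately naive so they share no code path with the package.

# exhaustive aligner: every transcript, every start, every gap placement,
# same scoring as align_reads (score = n - mismatches - gap_penalty per
# deletion; at most max_mismatch substitutions and one interior 1-nt
# deletion). Returns best score and all best placements.
oracle_align <- function(read, sequences, max_mismatch = 1, gap_penalty = 2) {
  n <- nchar(read)
  rch <- strsplit(read, "")[[1]]
  best_score <- -Inf
  best <- list()
  for (tx in names(sequences)) {
    tch <- strsplit(sequences[[tx]], "")[[1]]
    L <- length(tch)
    for (st in 0:(L - n)) {
      mism <- sum(rch != tch[(st + 1):(st + n)])
      if (mism <= max_mismatch) {
        sc <- n - mism
        if (sc > best_score) { best_score <- sc; best <- list() }
        if (sc == best_score)
          best[[length(best) + 1]] <- list(tx = tx, start = st,
                                           cigar = paste0(n, "M"))
      }
    }
    if (L >= n + 1) {
      for (st in 0:(L - n - 1)) {
        for (g in 1:(n - 1)) {
          ref <- c(tch[seq_len(g) + st],
                   tch[(st + g + 2):(st + n + 1)])
          mism <- sum(rch != ref)
          if (mism <= max_mismatch) {
            sc <- n - mism - gap_penalty
            if (sc > best_score) { best_score <- sc; best <- list() }
            if (sc == best_score)
              best[[length(best) + 1]] <-
                list(tx = tx, start = st,
                     cigar = paste0(g, "M1D", n - g, "M"))
          }
        }
      }
    }
  }
  list(score = best_score, placements = best)
}

# naive order-N windowed local-maximum scan with the leftmost-plateau rule
oracle_peak_candidates <- function(coverage, order, min_coverage) {
  L <- length(coverage)
  cand <- integer(0)
  for (i in seq_len(L)) {
    lo <- max(1, i - order); hi <- min(L, i + order)
    if (coverage[i] >= min_coverage && coverage[i] == max(coverage[lo:hi]))
      cand <- c(cand, i)
  }
  keep <- rep(TRUE, length(cand))
  if (length(cand) > 1)
    for (j in 2:length(cand))
      keep[j] <- !(cand[j] - cand[j - 1] == 1 &&
                   coverage[cand[j]] == coverage[cand[j - 1]])
  cand[keep] - 1L
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mann_whitney <- function(x, y) {
  m <- length(x); n <- length(y)
  all_v <- c(x, y)
  u_stat <- function(idx) {
    xx <- all_v[idx]; yy <- all_v[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  obs <- u_stat(seq_len(m))
  us <- apply(utils::combn(m + n, m), 2, u_stat)
  p <- 2 * min(mean(us <= obs), mean(us >= obs))
  list(U = obs, p_value = min(1, p))
}

# tiny FASTQ fixture builder
make_reads <- function(seqs, ids = sprintf("read%d", seq_along(seqs))) {
  data.frame(read_id = ids, sequence = seqs,
             quality = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
}

# minimal transcript-model table
make_models <- function(ids, len, biotype = "mRNA",
                        utr5 = 0L, cds = 0L, utr3 = 0L,
                        gene = sub("^TX", "G", ids)) {
  m <- data.frame(transcript_id = ids, gene_id = gene, biotype = biotype,
                  utr5_len = utr5, cds_len = cds, utr3_len = utr3,
                  sequence_length = len, stringsAsFactors = FALSE)
  class(m) <- c("transcript_models", "data.frame")
  m
}

# profiles object built directly from an alignment table (bypasses aligner)
profiles_from <- function(alignments, models, replicate_id = 1) {
  build_profiles(alignments, models, replicate_id)
}
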