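# Small-scale transcriptome aligner: exact k-mer seeding, ungapped extension
# allowing a bounded number of substitutions, plus at most one 1-nt deletion
# (every gap placement between matched blocks is scored). Designed for the
# crosslink-induced single-nucleotide deletions CRAC reads carry; not a
# general-purpose aligner.

#' Build an exact k-mer index over a transcriptome
#'
#' @param sequences named character vector of transcript sequences (DNA).
#' @param k seed length (default 12).
#' @return list of class `kmer_index`.
#' @export
build_kmer_index <- function(sequences, k = 12L) {
  if (!length(sequences)) stop("empty transcript set: cannot build index")
  if (is.null(names(sequences))) stop("sequences must be named")
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    grp <- split(starts - 1L, kmers)  # 0-based hit positions
    for (km in names(grp)) {
      entry <- cbind(i, grp[[km]])
      prev <- env[[km]]
      env[[km]] <- if (is.null(prev)) entry else rbind(prev, entry)
    }
  }
  structure(list(index = env, k = as.integer(k),
                 tx_names = names(sequences),
                 raw = lapply(sequences, charToRaw),
                 lengths = stats::setNames(nchar(sequences),
                                           names(sequences))),
            class = "kmer_index")
}

# score and place one read against one candidate (transcript, start);
# returns NULL or list(score, cigar)
score_candidate <- function(rraw, traw, st, L, max_mismatch, gap_penalty) {
  n <- length(rraw)
  best <- NULL
  if (st + n <= L) {
    mism <- sum(rraw != traw[(st + 1L):(st + n)])
    if (mism <= max_mismatch)
      best <- list(score = n - mism, cigar = paste0(n, "M"))
  }
  if (st + n + 1L <= L) {
    ne1 <- cumsum(rraw != traw[(st + 1L):(st + n)])
    ne2 <- cumsum(rraw != traw[(st + 2L):(st + n + 1L)])
    g <- seq_len(n - 1L)  # deletion of transcript base st+g (0-based)
    mg <- ne1[g] + (ne2[n] - ne2[g])
    ok <- mg <= max_mismatch
    if (any(ok)) {
      gbest <- g[ok][which.min(mg[ok])]  # leftmost minimum: left-aligned gap
      sc <- n - min(mg[ok]) - gap_penalty
      if (is.null(best) || sc > best$score)
        best <- list(score = sc,
                     cigar = paste0(gbest, "M1D", n - gbest, "M"))
    }
  }
  best
}

#' Align reads to the transcriptome (seed-and-extend)
#'
#' Alignments allow at most `max_mismatch` substitutions and at most one
#' single-nucleotide deletion (gap opening scored at every interior position;
#' within homopolymers the leftmost placement wins). The best-scoring
#' alignment is reported; score ties across loci are broken by a random
#' choice under the run seed, so multi-mapped assignment is reproducible.
#'
#' @param reads read data.frame (`read_id`, `sequence`).
#' @param index a [build_kmer_index()] object.
#' @param max_mismatch maximum substitutions (default 1).
#' @param gap_penalty score penalty for opening the deletion (default 2).
#' @param seed optional integer seed for the tie-break RNG.
#' @return list with `alignments` (data.frame `read_id`, `transcript_id`,
#'   `start`, `cigar`), `n_unaligned`, and `unaligned_ids`.
#' @export
align_reads <- function(reads, index, max_mismatch = 1L, gap_penalty = 2L,
                        seed = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  if (!is.null(seed)) set.seed(seed)
  k <- index$k
  nr <- nrow(reads)
  out_tx <- character(nr); out_start <- integer(nr); out_cigar <- character(nr)
  hit <- logical(nr)
  for (ri in seq_len(nr)) {
    s <- reads$sequence[ri]
    n <- nchar(s)
    if (n < k) next
    rraw <- charToRaw(s)
    offs <- unique(c(0L, (n - k) %/% 2L, n - k))
    cand <- NULL
    for (o in offs) {
      h <- index$index[[substr(s, o + 1L, o + k)]]
      if (is.null(h)) next
      # candidate starts: exact placement, and one shifted for a deletion
      # upstream of the seed (transcript consumes one extra base)
      cand <- rbind(cand, cbind(h[, 1L], h[, 2L] - o),
                    cbind(h[, 1L], h[, 2L] - o - 1L))
    }
    if (is.null(cand)) next
    cand <- unique(cand[cand[, 2L] >= 0L, , drop = FALSE])
    if (!nrow(cand)) next
    best_score <- -Inf
    recs <- list()
    for (ci in seq_len(nrow(cand))) {
      ti <- cand[ci, 1L]; st <- cand[ci, 2L]
      r <- score_candidate(rraw, index$raw[[ti]], st,
                           index$lengths[[ti]], max_mismatch, gap_penalty)
      if (is.null(r)) next
      if (r$score > best_score) {
        best_score <- r$score
        recs <- list(list(ti = ti, st = st, cigar = r$cigar))
      } else if (r$score == best_score) {
        recs[[length(recs) + 1L]] <- list(ti = ti, st = st, cigar = r$cigar)
      }
    }
    if (!length(recs)) next
    pick <- if (length(recs) == 1L) recs[[1L]] else
      recs[[sample.int(length(recs), 1L)]]
    hit[ri] <- TRUE
    out_tx[ri] <- index$tx_names[pick$ti]
    out_start[ri] <- pick$st
    out_cigar[ri] <- pick$cigar
  }
  list(alignments = data.frame(read_id = reads$read_id[hit],
                               transcript_id = out_tx[hit],
                               start = out_start[hit],
                               cigar = out_cigar[hit],
                               stringsAsFactors = FALSE),
       n_unaligned = sum(!hit),
       unaligned_ids = reads$read_id[!hit])
}
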