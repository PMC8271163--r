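# Deletion-centered motif discovery: DREME-style exact-word seeding with
# presence/absence Fisher enrichment against mononucleotide-shuffled windows,
# greedy generalization to 2-letter IUPAC codes, and Centrimo-style central
# positional enrichment. Given strand only; widths 6-10; E < 0.05.

#' Extract deletion-centered sequence windows
#'
#' One window per deletion-bearing read on a top-target transcript, centered
#' on the deleted transcript position. Windows are cut from the transcript
#' sequence (so the crosslinked base itself is present at the center), are
#' clipped at transcript ends, and are reported in the RNA alphabet.
#'
#' @param alignments alignment data.frame (typically both replicates pooled).
#' @param sequences named character vector of transcript sequences (DNA).
#' @param transcripts character vector of top-target transcript ids.
#' @param flank half-window size: 10 (21-nt window) or 50 (101-nt window).
#' @return data.frame of class `motif_windows`: `read_id`, `transcript_id`,
#'   `center`, `sequence` (RNA), `center_offset`; attribute `n_transcripts`
#'   counts contributing transcripts.
#' @export
extract_windows <- function(alignments, sequences, transcripts, flank = 10L) {
  if (!flank %in% c(10L, 50L))
    stop("flank must be 10 or 50 (window spanning 20 or 100 bases)")
  keep <- alignments$transcript_id %in% transcripts
  aln <- alignments[keep, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(aln))) {
    ops <- parse_cigar(aln$cigar[i])
    d <- deletion_offsets(ops)
    if (length(d$del) != 1L || d$multi) next  # exactly one 1-nt deletion
    pos <- aln$start[i] + d$del
    L <- nchar(sequences[[aln$transcript_id[i]]])
    lo <- max(0L, pos - flank)
    hi <- min(L, pos + flank + 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = aln$read_id[i], transcript_id = aln$transcript_id[i],
      center = pos,
      sequence = dna_to_rna(substr(sequences[[aln$transcript_id[i]]],
                                   lo + 1L, hi)),
      center_offset = pos - lo, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(), transcript_id = character(),
               center = integer(), sequence = character(),
               center_offset = integer(), stringsAsFactors = FALSE)
  attr(out, "n_transcripts") <- length(unique(out$transcript_id))
  attr(out, "flank") <- flank
  class(out) <- c("motif_windows", "data.frame")
  out
}

# one-sided Fisher enrichment p for presence/absence counts, computed as the
# exact hypergeometric tail (equals fisher.test alternative = "greater");
# log = TRUE returns log(p), which never underflows and is what the
# discovery search compares internally
fisher_presence_p <- function(a, b, n_fg, n_bg, log = FALSE) {
  stats::phyper(a - 1, a + b, n_fg + n_bg - a - b, n_fg, lower.tail = FALSE,
                log.p = log)
}

# fraction-of-windows presence counts for every exact w-mer
kmer_presence <- function(windows, w) {
  per_window <- lapply(windows, function(s) {
    n <- nchar(s)
    if (n < w) return(character(0))
    unique(substring(s, 1:(n - w + 1L), w:n))
  })
  table(unlist(per_window))
}

consensus_presence <- function(windows, consensus) {
  rx <- iupac_regex(consensus)
  sum(grepl(rx, windows, perl = TRUE))
}

# greedy position-by-position generalization of an exact word to 2-letter
# IUPAC codes; a generalization is accepted iff it lowers the enrichment p
# (compared on the log scale so deeply significant words keep improving)
generalize_word <- function(word, fg, bg, log_p_word) {
  two_letter <- c("R", "Y", "S", "W", "K", "M")
  cur <- strsplit(word, "")[[1]]
  lp_cur <- log_p_word
  n_tested <- 0L
  for (i in seq_along(cur)) {
    base <- cur[i]
    if (!base %in% c("A", "C", "G", "U")) next
    cands <- two_letter[vapply(two_letter,
                               function(cc) base %in% IUPAC_RNA[[cc]],
                               logical(1))]
    best_code <- NULL
    for (cc in cands) {
      trial <- cur; trial[i] <- cc
      cons <- paste(trial, collapse = "")
      a <- consensus_presence(fg, cons)
      b <- consensus_presence(bg, cons)
      lp_new <- fisher_presence_p(a, b, length(fg), length(bg), log = TRUE)
      n_tested <- n_tested + 1L
      if (lp_new < lp_cur) { lp_cur <- lp_new; best_code <- cc }
    }
    if (!is.null(best_code)) cur[i] <- best_code
  }
  list(consensus = paste(cur, collapse = ""), log_p = lp_cur,
       n_tested = n_tested)
}

# position-probability matrix from the best-matching site in each window
build_pwm <- function(windows, consensus) {
  w <- nchar(consensus)
  rx <- iupac_regex(consensus)
  sites <- character(0)
  for (s in windows) {
    m <- regexpr(rx, s, perl = TRUE)
    if (m[1] > 0) sites <- c(sites, substr(s, m[1], m[1] + w - 1L))
  }
  if (!length(sites)) return(NULL)
  mat <- vapply(seq_len(w), function(i) {
    tab <- table(factor(substr(sites, i, i), levels = c("A", "C", "G", "U")))
    as.numeric(tab) / length(sites)
  }, numeric(4))
  rownames(mat) <- c("A", "C", "G", "U")
  mat
}

#' Discover an enriched degenerate motif in deletion-centered windows
#'
#' Background: each window mononucleotide-shuffled once under the run seed.
#' For each width in `width_range`, every exact w-mer present in at least
#' `min_count` windows is scored by a one-sided Fisher test on
#' presence/absence (0-1 occurrence counting) versus the background; the
#' top-ranked exact words are greedily generalized position-by-position to
#' 2-letter IUPAC codes, accepting a generalization only when it lowers the
#' p-value (all comparisons on the log scale, so deeply enriched words keep
#' improving). The E-value is the best p times the number of candidates at
#' that width — every exact w-mer present in the windows (the implicit
#' search space of the seeding step) plus every generalization evaluated;
#' results with E below `e_threshold` are returned, best first. Only the
#' given strand is scanned.
#'
#' @param windows a [extract_windows()] data.frame (or character vector of
#'   RNA windows).
#' @param width_range motif widths to scan (default 6:10).
#' @param e_threshold E-value cutoff (default 0.05).
#' @param min_count minimum windows containing an exact word (default 5).
#' @param min_windows minimum number of windows required (default 50).
#' @param n_seeds exact words taken forward to generalization per width.
#' @param seed optional seed for the background shuffle.
#' @return list of class `motif_results`; each element has `consensus`,
#'   `width`, `p_enrichment`, `e_value` (with `log_p_enrichment` and
#'   `log_e_value` for underflow-free precision), `site_count`,
#'   `n_candidates`, `pwm`.
#' @export
discover_motif <- function(windows, width_range = 6:10, e_threshold = 0.05,
                           min_count = 5L, min_windows = 50L, n_seeds = 5L,
                           seed = NULL) {
  fg <- if (is.data.frame(windows)) windows$sequence else windows
  if (length(fg) < min_windows)
    stop("only ", length(fg), " windows (< ", min_windows,
         "); increase flank or sequencing depth")
  if (!is.null(seed)) set.seed(seed)
  bg <- vapply(fg, function(s)
    paste(sample(strsplit(s, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)

  results <- list()
  for (w in width_range) {
    fg_tab <- kmer_presence(fg, w)
    cand_words <- names(fg_tab)[fg_tab >= min_count]
    if (!length(cand_words)) next
    bg_tab <- kmer_presence(bg, w)
    a <- as.numeric(fg_tab[cand_words])
    b <- as.numeric(bg_tab[cand_words]); b[is.na(b)] <- 0
    lpv <- fisher_presence_p(a, b, length(fg), length(bg), log = TRUE)
    # multiplicity: the search implicitly ranges over every exact w-mer
    # present in the foreground (the >= min_count rule only prunes hopeless
    # words), so all of them count as candidates, plus every generalization
    # actually evaluated
    n_tested <- length(fg_tab)
    ord <- order(lpv)
    best <- NULL
    for (si in utils::head(ord, n_seeds)) {
      g <- generalize_word(cand_words[si], fg, bg, lpv[si])
      n_tested <- n_tested + g$n_tested
      if (is.null(best) || g$log_p < best$log_p) best <- g
    }
    log_e <- best$log_p + log(n_tested)
    if (log_e < log(e_threshold)) {
      results[[length(results) + 1L]] <- list(
        consensus = best$consensus, width = w,
        p_enrichment = exp(best$log_p), log_p_enrichment = best$log_p,
        e_value = exp(log_e), log_e_value = log_e,
        site_count = consensus_presence(fg, best$consensus),
        n_candidates = n_tested,
        pwm = build_pwm(fg, best$consensus))
    }
  }
  results <- results[order(vapply(results, `[[`, numeric(1), "log_e_value"))]
  class(results) <- "motif_results"
  results
}

#' Central positional enrichment of a consensus around the crosslink
#'
#' Records the best (nearest-center) match offset per window and tests, by a
#' one-sided binomial test, whether matches covering the central (deleted)
#' position are more frequent than the uniform expectation
#' p0 = width / window length.
#'
#' @param windows a [extract_windows()] data.frame.
#' @param consensus IUPAC consensus to scan.
#' @return list with `positional_p`, `n_matched`, `n_central`, and
#'   `offset_histogram` (table of match-start offsets relative to the
#'   window center).
#' @export
central_enrichment <- function(windows, consensus) {
  w <- nchar(consensus)
  n_matched <- 0L
  n_central <- 0L
  rel_offsets <- integer(0)
  p0s <- numeric(0)
  for (i in seq_len(nrow(windows))) {
    offs <- match_consensus(windows$sequence[i], consensus)
    if (!length(offs)) next
    co <- windows$center_offset[i]
    best <- offs[which.min(abs(offs + (w - 1) / 2 - co))]
    n_matched <- n_matched + 1L
    if (best <= co && co <= best + w - 1L) n_central <- n_central + 1L
    rel_offsets <- c(rel_offsets, best - co)
    p0s <- c(p0s, min(1, w / nchar(windows$sequence[i])))
  }
  if (n_matched == 0L)
    return(list(positional_p = 1, n_matched = 0L, n_central = 0L,
                offset_histogram = table(integer(0))))
  p0 <- mean(p0s)
  list(positional_p = stats::binom.test(n_central, n_matched, p0,
                                        alternative = "greater")$p.value,
       n_matched = n_matched, n_central = n_central,
       offset_histogram = table(rel_offsets))
}

#' Write motif windows as FASTA (ids encode transcript and center)
#'
#' @param windows a `motif_windows` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_windows_fasta <- function(windows, path) {
  ids <- sprintf("%s|%s|%d", windows$read_id, windows$transcript_id,
                 windows$center)
  seqs <- stats::setNames(rna_to_dna(windows$sequence), ids)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write motif results in MEME minimal text format
#'
#' @param results a `motif_results` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(results, path) {
  out <- c("MEME version 4", "", "ALPHABET= ACGU", "",
           "Background letter frequencies",
           "A 0.25 C 0.25 G 0.25 U 0.25", "")
  for (r in results) {
    out <- c(out, sprintf("MOTIF %s", r$consensus),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= %.3g",
                     r$width, r$site_count, r$e_value),
             apply(t(r$pwm), 1, function(x) paste(sprintf("%.6f", x),
                                                  collapse = " ")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}
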