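# Per-transcript coverage and crosslink-deletion profiles, RNA-class
# distribution of mapped reads, and replicate concordance.

# deletion positions (0-based) of length-1 D ops in one parsed CIGAR,
# relative to the alignment start; NULL when none
deletion_offsets <- function(ops) {
  refoff <- 0L
  del <- integer(0)
  multi <- FALSE
  for (i in seq_len(nrow(ops))) {
    if (ops$op[i] %in% c("M", "D")) {
      if (ops$op[i] == "D") {
        if (ops$len[i] == 1L) del <- c(del, refoff) else multi <- TRUE
      }
      refoff <- refoff + ops$len[i]
    }
  }
  list(del = del, multi = multi)
}

#' Build coverage and deletion profiles from alignments
#'
#' Coverage is incremented over every M/D position of each read's footprint;
#' the deletion vector is incremented at the position of each length-1 D op
#' (the deleted base's transcript position, i.e. the crosslink site).
#' Multi-nucleotide deletions are counted but excluded from crosslink
#' evidence, while their footprint still contributes to coverage.
#'
#' @param alignments data.frame `read_id`, `transcript_id`, `start`, `cigar`.
#' @param models `transcript_models` data.frame.
#' @param replicate_id identifier stored with the profiles.
#' @return object of class `crosslink_profiles`: per-transcript
#'   `coverage`/`deletions` integer vectors, per-transcript read footprints
#'   (`start`, `ref_len`, for the permutation null), `library_size`, and a
#'   `deletion_events` table (`read_id`, `transcript_id`, `position`) for
#'   motif windowing.
#' @export
build_profiles <- function(alignments, models, replicate_id = NA) {
  L <- stats::setNames(models$sequence_length, models$transcript_id)
  unknown <- setdiff(unique(alignments$transcript_id), names(L))
  if (length(unknown))
    stop("alignment(s) reference unknown transcript(s): ",
         paste(unknown, collapse = ", "))
  na <- nrow(alignments)
  ref_len <- integer(na)
  del_list <- vector("list", na)
  n_multi <- 0L
  for (i in seq_len(na)) {
    ops <- parse_cigar(alignments$cigar[i])
    ref_len[i] <- cigar_ref_len(ops)
    d <- deletion_offsets(ops)
    if (d$multi) n_multi <- n_multi + 1L
    if (length(d$del)) del_list[[i]] <- alignments$start[i] + d$del
  }
  over <- alignments$start < 0L |
    alignments$start + ref_len > L[alignments$transcript_id]
  if (any(over))
    stop("alignment footprint exceeds transcript length for read(s): ",
         paste(utils::head(alignments$read_id[over], 5L), collapse = ", "))

  txs <- names(L)
  profs <- stats::setNames(vector("list", length(txs)), txs)
  idx_by_tx <- split(seq_len(na), factor(alignments$transcript_id,
                                         levels = txs))
  for (tx in txs) {
    l <- L[[tx]]
    cov <- integer(l); del <- integer(l)
    ii <- idx_by_tx[[tx]]
    if (length(ii)) {
      st <- alignments$start[ii]
      en <- st + ref_len[ii]
      add <- tabulate(st + 1L, l + 1L)
      sub <- tabulate(en + 1L, l + 1L)
      cov <- cumsum(add - sub)[seq_len(l)]
      dpos <- unlist(del_list[ii])
      if (length(dpos)) del <- tabulate(dpos + 1L, l)
    }
    profs[[tx]] <- list(coverage = as.integer(cov), deletions = as.integer(del),
                        reads = data.frame(start = alignments$start[ii],
                                           ref_len = ref_len[ii]))
  }
  devents <- data.frame(
    read_id = rep(alignments$read_id, lengths(del_list)),
    transcript_id = rep(alignments$transcript_id, lengths(del_list)),
    position = as.integer(unlist(del_list) %||% integer(0)),
    stringsAsFactors = FALSE)
  structure(list(transcripts = profs, models = models,
                 replicate_id = replicate_id, library_size = na,
                 n_multi_deletion = n_multi, deletion_events = devents),
            class = "crosslink_profiles")
}

#' RNA-class distribution of mapped reads
#'
#' Each read counts once toward its transcript's biotype; fractions are over
#' all mapped reads.
#'
#' @param alignments alignment data.frame.
#' @param models `transcript_models` data.frame.
#' @return named numeric vector of fractions (sums to 1).
#' @export
class_distribution <- function(alignments, models) {
  bio <- stats::setNames(models$biotype, models$transcript_id)
  b <- bio[alignments$transcript_id]
  if (anyNA(b)) stop("aligned transcript without a biotype")
  tab <- table(factor(b, levels = BIOTYPES))
  frac <- as.numeric(tab) / sum(tab)
  stats::setNames(frac, names(tab))[frac > 0 | names(tab) %in% unique(b)]
}

#' Spearman concordance between two replicates
#'
#' Correlates per-transcript total read counts (ties mid-ranked).
#'
#' @param profile_a,profile_b `crosslink_profiles` objects over the same
#'   transcript universe.
#' @return list with `rho` and `n` (number of transcripts).
#' @export
replicate_correlation <- function(profile_a, profile_b) {
  txs <- names(profile_a$transcripts)
  if (!identical(sort(txs), sort(names(profile_b$transcripts))))
    stop("profiles cover different transcript universes")
  ca <- vapply(profile_a$transcripts[txs], function(p) nrow(p$reads), integer(1))
  cb <- vapply(profile_b$transcripts[txs], function(p) nrow(p$reads), integer(1))
  if (sum(ca > 0 | cb > 0) < 3L)
    stop("fewer than 3 transcripts with nonzero counts")
  list(rho = stats::cor(ca, cb, method = "spearman"), n = length(txs))
}
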