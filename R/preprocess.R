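# CRAC read pre-processing in the published order: PCR-duplicate collapsing
# on full-length raw reads FIRST, then in-line barcode removal, then 3'
# adapter trimming with a minimum-length filter.

#' Collapse PCR duplicates
#'
#' One representative per identical full-length sequence (collapsing happens
#' before barcode removal); the first-seen read id is kept.
#'
#' @param reads read data.frame (`read_id`, `sequence`, optionally `quality`).
#' @return list with `reads` (collapsed) and `report`
#'   (`n_input`, `n_after_collapse`).
#' @export
collapse_duplicates <- function(reads) {
  keep <- !duplicated(reads$sequence)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out,
       report = list(n_input = nrow(reads), n_after_collapse = nrow(out)))
}

#' Demultiplex reads by 5' in-line barcode
#'
#' A read is assigned to the barcode exactly matching its 5' prefix, which is
#' then stripped; reads matching no barcode go to the `unmatched` bin.
#'
#' @param reads read data.frame.
#' @param barcode_set character vector of equal-length, distinct barcodes.
#' @return named list of read data.frames, one per barcode plus `unmatched`.
#' @export
split_by_barcode <- function(reads, barcode_set) {
  bl <- unique(nchar(barcode_set))
  if (length(bl) != 1L) stop("barcodes must all have the same length")
  if (anyDuplicated(barcode_set)) stop("barcodes must be mutually distinct")
  prefix <- substr(reads$sequence, 1L, bl)
  bins <- stats::setNames(vector("list", length(barcode_set) + 1L),
                          c(barcode_set, "unmatched"))
  for (bc in barcode_set) {
    sel <- reads[prefix == bc, , drop = FALSE]
    sel$sequence <- substring(sel$sequence, bl + 1L)
    if ("quality" %in% names(sel)) sel$quality <- substring(sel$quality, bl + 1L)
    rownames(sel) <- NULL
    bins[[bc]] <- sel
  }
  un <- reads[!prefix %in% barcode_set, , drop = FALSE]
  rownames(un) <- NULL
  bins$unmatched <- un
  bins
}

#' Trim 3' adapters and filter short reads
#'
#' Removes the longest read suffix exactly matching a prefix of the adapter
#' (at least `min_overlap` nt); reads shorter than `min_len` after trimming
#' are discarded and counted.
#'
#' @param reads read data.frame.
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum adapter overlap (nt).
#' @param min_len minimum retained read length after trimming (nt).
#' @return list with `reads` (trimmed, filtered) and `report`
#'   (`n_input`, `n_after_trim`, `min_len_filtered`).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L, min_len = 18L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  seqs <- reads$sequence
  n <- nchar(seqs)
  trim_at <- n  # keep positions 1..trim_at
  jmax <- if (length(n)) min(nchar(adapter), max(n)) else 0L
  for (j in if (jmax >= min_overlap) seq(jmax, min_overlap) else integer(0)) {
    ap <- substr(adapter, 1L, j)
    hit <- trim_at == n & n >= j & substr(seqs, n - j + 1L, n) == ap
    trim_at[hit] <- n[hit] - j
  }
  out <- reads
  out$sequence <- substr(seqs, 1L, trim_at)
  if ("quality" %in% names(out))
    out$quality <- substr(out$quality, 1L, trim_at)
  keep <- trim_at >= min_len
  discarded <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out,
       report = list(n_input = length(seqs), n_after_trim = nrow(out),
                     min_len_filtered = discarded))
}

#' Run the full CRAC pre-processing chain on one library
#'
#' collapse -> demultiplex -> per-barcode adapter trim, with a conservation
#' report (`n_input = assigned + unmatched + discarded` at every stage).
#'
#' @param reads raw read data.frame.
#' @param barcode_set 5' in-line barcodes.
#' @param adapter 3' adapter sequence.
#' @param min_overlap,min_len see [trim_adapter()].
#' @return list with `bins` (named list of trimmed read data.frames) and
#'   `report` (a `PreprocessReport`-style list).
#' @export
preprocess_reads <- function(reads, barcode_set, adapter,
                             min_overlap = 5L, min_len = 18L) {
  col <- collapse_duplicates(reads)
  bins <- split_by_barcode(col$reads, barcode_set)
  n_barcode <- vapply(bins[barcode_set], nrow, integer(1))
  trimmed <- stats::setNames(vector("list", length(barcode_set)), barcode_set)
  filtered <- 0L
  for (bc in barcode_set) {
    tr <- trim_adapter(bins[[bc]], adapter, min_overlap, min_len)
    trimmed[[bc]] <- tr$reads
    filtered <- filtered + tr$report$min_len_filtered
  }
  report <- list(n_input = col$report$n_input,
                 n_after_collapse = col$report$n_after_collapse,
                 n_barcode_matched = n_barcode,
                 n_unmatched = nrow(bins$unmatched),
                 min_len_filtered = filtered,
                 n_after_trim = sum(vapply(trimmed, nrow, integer(1))))
  list(bins = trimmed, unmatched = bins$unmatched, report = report)
}
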