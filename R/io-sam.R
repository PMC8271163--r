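# Text SAM input/output restricted to transcript-space, primary, mapped
# alignments, plus bedGraph coverage tracks (the text substitute for BigWig).

FLAG_UNMAPPED <- 0x4L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

#' Read transcript-space alignments from a SAM file
#'
#' Consumes only primary, mapped records. POS is converted from 1-based to the
#' internal 0-based convention. Supported CIGAR ops are M, D, I, S; spliced
#' (N) or other ops raise an error naming the op, since genomic alignment is
#' out of scope.
#'
#' @param path path to a SAM text file with `@SQ` headers naming transcripts.
#' @return data.frame with columns `read_id`, `transcript_id`, `start`
#'   (0-based), `cigar`; attribute `seq_lengths` is the named `@SQ` LN vector.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  seq_lengths <- integer(0)
  for (h in sq) {
    f <- strsplit(h, "\t", fixed = TRUE)[[1]]
    sn <- sub("^SN:", "", f[startsWith(f, "SN:")][1])
    ln <- as.integer(sub("^LN:", "", f[startsWith(f, "LN:")][1]))
    seq_lengths[sn] <- ln
  }
  rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
  out <- list()
  for (i in seq_along(rec)) {
    f <- strsplit(rec[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) stop("SAM record ", i, " has fewer than 11 fields")
    flag <- as.integer(f[2])
    if (bitwAnd(flag, FLAG_UNMAPPED) != 0L ||
        bitwAnd(flag, FLAG_SECONDARY) != 0L ||
        bitwAnd(flag, FLAG_SUPPLEMENTARY) != 0L) next
    tx <- f[3]
    if (!tx %in% names(seq_lengths))
      stop("alignment references unknown transcript '", tx, "'")
    ops <- parse_cigar(f[6])
    bad <- setdiff(ops$op, c("M", "D", "I", "S"))
    if (length(bad))
      stop("unsupported CIGAR op '", bad[1], "' in SAM record ", i,
           " (transcript-space alignments only)")
    start <- as.integer(f[4]) - 1L
    if (start < 0L || start + cigar_ref_len(ops) > seq_lengths[tx])
      stop("alignment footprint exceeds transcript '", tx,
           "' in SAM record ", i)
    out[[length(out) + 1L]] <- data.frame(
      read_id = f[1], transcript_id = tx, start = start, cigar = f[6],
      stringsAsFactors = FALSE)
  }
  aln <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(), transcript_id = character(),
               start = integer(), cigar = character(),
               stringsAsFactors = FALSE)
  attr(aln, "seq_lengths") <- seq_lengths
  aln
}

#' Write transcript-space alignments to a SAM file
#'
#' @param alignments data.frame with columns `read_id`, `transcript_id`,
#'   `start` (0-based), `cigar`.
#' @param seq_lengths named integer vector of transcript lengths for `@SQ`.
#' @param path output path.
#' @param program optional named character vector recorded on an `@PG` line
#'   (e.g. `c(ID = "cracDecay", PN = "align_reads", CL = "...")`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, seq_lengths, path, program = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths), seq_lengths))
  if (!is.null(program))
    hdr <- c(hdr, paste0("@PG\t", paste(names(program), program,
                                        sep = ":", collapse = "\t")))
  rec <- sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
                 alignments$read_id, alignments$transcript_id,
                 alignments$start + 1L, alignments$cigar)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write per-transcript coverage (or deletion) vectors as bedGraph
#'
#' Emits 0-based half-open intervals; adjacent equal-value intervals are
#' merged and zero-valued runs are omitted, so interval lengths sum to the
#' number of nonzero positions per transcript.
#'
#' @param profiles a `crosslink_profiles` object (see [build_profiles()]) or a
#'   named list of numeric vectors.
#' @param path output path.
#' @param what `"coverage"` or `"deletions"` when `profiles` is a
#'   `crosslink_profiles` object.
#' @return `path`, invisibly.
#' @export
write_coverage_bedgraph <- function(profiles, path, what = "coverage") {
  vecs <- if (inherits(profiles, "crosslink_profiles"))
    lapply(profiles$transcripts, `[[`, what) else profiles
  out <- character(0)
  for (tx in names(vecs)) {
    r <- rle(vecs[[tx]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      out <- c(out, sprintf("%s\t%d\t%d\t%g", tx, starts[keep], ends[keep],
                            r$values[keep]))
  }
  writeLines(out, path)
  invisible(path)
}
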