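# FASTQ reading/writing. Reads are plain data.frames with columns read_id,
# sequence, quality so the preprocessing ops can be vectorised over them.

#' Read a FASTQ file
#'
#' Expects standard 4-line records. Round-tripping through [write_fastq()]
#' preserves id, sequence and quality strings byte-for-byte.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return data.frame with columns `read_id`, `sequence`, `quality`
#'   (one row per read, file order). An empty file yields zero rows.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L)
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  if (n %% 4L != 0L)
    stop("truncated FASTQ record ", n %/% 4L + 1L, " in '", path, "'")
  hdr <- lines[seq(1L, n, 4L)]
  seqs <- lines[seq(2L, n, 4L)]
  plus <- lines[seq(3L, n, 4L)]
  qual <- lines[seq(4L, n, 4L)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], " in '", path, "'")
  bad <- which(nchar(seqs) != nchar(qual) | nchar(seqs) < 1L)
  if (length(bad))
    stop("sequence/quality length mismatch in FASTQ record ", bad[1],
         " of '", path, "'")
  data.frame(read_id = substring(hdr, 2L), sequence = seqs, quality = qual,
             stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with columns `read_id`, `sequence` and optionally
#'   `quality` (filled with "I" when absent).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  qual <- if ("quality" %in% names(reads) && !all(is.na(reads$quality)))
    reads$quality else strrep("I", nchar(reads$sequence))
  out <- character(4L * nrow(reads))
  if (nrow(reads)) {
    out[seq(1L, length(out), 4L)] <- paste0("@", reads$read_id)
    out[seq(2L, length(out), 4L)] <- reads$sequence
    out[seq(3L, length(out), 4L)] <- "+"
    out[seq(4L, length(out), 4L)] <- qual
  }
  writeLines(out, path)
  invisible(path)
}
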