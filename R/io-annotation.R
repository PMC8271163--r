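# Transcript annotation: a GTF subset giving, per transcript, its biotype and
# (for mRNAs) the 5'UTR/CDS/3'UTR partition in mature-transcript coordinates.

BIOTYPES <- c("mRNA", "rRNA", "tRNA", "snoRNA", "snRNA", "miscRNA", "other")

normalize_biotype <- function(x) {
  x <- ifelse(x %in% c("protein_coding", "mRNA"), "mRNA", x)
  ifelse(x %in% BIOTYPES, x, "other")
}

parse_gtf_attributes <- function(attr, line_no) {
  m <- regmatches(attr, gregexpr('(\\w+)\\s+"([^"]*)"', attr))[[1]]
  if (length(m) == 0L)
    stop("malformed GTF attribute string at line ", line_no, ": '", attr, "'")
  keys <- sub('^(\\w+)\\s+.*$', "\\1", m)
  vals <- sub('^\\w+\\s+"([^"]*)".*$', "\\1", m)
  stats::setNames(as.list(vals), keys)
}

#' Load a transcript annotation (GTF subset)
#'
#' Consumes records with feature types `transcript`, `five_prime_utr`, `CDS`
#' and `three_prime_utr` carrying `transcript_id`, `gene_id` and (on the
#' transcript feature) `biotype` attributes. GTF spans are 1-based inclusive
#' and are converted to the package's 0-based half-open convention; segment
#' lengths are sums of feature spans. Transcripts violating the region
#' partition invariant (mRNA: utr5+cds+utr3 == transcript length; non-mRNA:
#' no UTR/CDS features) are rejected and listed in the `rejected` attribute.
#'
#' @param path path to the GTF file.
#' @return data.frame of class `transcript_models` with columns
#'   `transcript_id`, `gene_id`, `biotype`, `utr5_len`, `cds_len`, `utr3_len`,
#'   `sequence_length`; attribute `rejected` is a data.frame listing offenders.
#' @export
load_annotation <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  feats <- list()
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("expected 9 tab-separated GTF fields at line ", i)
    type <- f[3]
    if (!type %in% c("transcript", "five_prime_utr", "CDS", "three_prime_utr"))
      next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start < 1L || end < start)
      stop("invalid GTF coordinates at line ", i)
    at <- parse_gtf_attributes(f[9], i)
    if (is.null(at$transcript_id) || is.null(at$gene_id))
      stop("missing transcript_id/gene_id attribute at line ", i)
    feats[[length(feats) + 1L]] <- data.frame(
      transcript_id = at$transcript_id, gene_id = at$gene_id, type = type,
      # 1-based inclusive -> 0-based half-open; span length is end0 - start0
      len = end - start + 1L,
      biotype = at$biotype %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(feats)) stop("no usable records in '", path, "'")
  feats <- do.call(rbind, feats)

  tx <- feats[feats$type == "transcript", ]
  if (anyDuplicated(tx$transcript_id))
    stop("duplicated transcript_id in '", path, "': ",
         paste(unique(tx$transcript_id[duplicated(tx$transcript_id)]),
               collapse = ", "))
  orphans <- setdiff(feats$transcript_id, tx$transcript_id)
  if (length(orphans))
    stop("feature(s) without a transcript record: ",
         paste(orphans, collapse = ", "))

  seg_len <- function(type) {
    s <- feats[feats$type == type, ]
    v <- stats::setNames(rep(0L, nrow(tx)), tx$transcript_id)
    if (nrow(s)) {
      agg <- tapply(s$len, s$transcript_id, sum)
      v[names(agg)] <- as.integer(agg)
    }
    v
  }
  models <- data.frame(
    transcript_id = tx$transcript_id,
    gene_id = tx$gene_id,
    biotype = normalize_biotype(tx$biotype),
    utr5_len = unname(seg_len("five_prime_utr")[tx$transcript_id]),
    cds_len = unname(seg_len("CDS")[tx$transcript_id]),
    utr3_len = unname(seg_len("three_prime_utr")[tx$transcript_id]),
    sequence_length = tx$len,
    stringsAsFactors = FALSE)

  seg_sum <- models$utr5_len + models$cds_len + models$utr3_len
  bad_mrna <- models$biotype == "mRNA" & seg_sum != models$sequence_length
  bad_nc <- models$biotype != "mRNA" & seg_sum != 0L
  rejected <- data.frame(
    transcript_id = models$transcript_id[bad_mrna | bad_nc],
    reason = c(rep("mRNA segment lengths do not sum to transcript length",
                   sum(bad_mrna)),
               rep("non-mRNA transcript carries UTR/CDS features",
                   sum(bad_nc))),
    stringsAsFactors = FALSE)
  models$utr5_len[models$biotype != "mRNA"] <- 0L
  models$cds_len[models$biotype != "mRNA"] <- 0L
  models$utr3_len[models$biotype != "mRNA"] <- 0L
  models <- models[!(bad_mrna | bad_nc), , drop = FALSE]
  rownames(models) <- NULL
  if (nrow(rejected))
    warning("rejected ", nrow(rejected), " transcript(s): ",
            paste(rejected$transcript_id, collapse = ", "))
  attr(models, "rejected") <- rejected
  class(models) <- c("transcript_models", "data.frame")
  models
}

#' Write transcript models as a GTF subset
#'
#' Inverse of [load_annotation()] for the supported feature types; coordinate
#' conversion (0-based half-open to 1-based inclusive) round-trips exactly.
#'
#' @param models a `transcript_models` data.frame.
#' @param path output path.
#' @param source source field for column 2 (default "cracDecay").
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(models, path, source = "cracDecay") {
  line <- function(tx, type, start0, end0, gene, biotype = NULL) {
    at <- sprintf('gene_id "%s"; transcript_id "%s";', gene, tx)
    if (!is.null(biotype)) at <- paste0(at, sprintf(' biotype "%s";', biotype))
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t+\t.\t%s",
            tx, source, type, start0 + 1L, end0, at)
  }
  out <- character(0)
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    out <- c(out, line(m$transcript_id, "transcript", 0L, m$sequence_length,
                       m$gene_id, m$biotype))
    if (m$biotype == "mRNA") {
      if (m$utr5_len > 0L)
        out <- c(out, line(m$transcript_id, "five_prime_utr", 0L, m$utr5_len,
                           m$gene_id))
      if (m$cds_len > 0L)
        out <- c(out, line(m$transcript_id, "CDS", m$utr5_len,
                           m$utr5_len + m$cds_len, m$gene_id))
      if (m$utr3_len > 0L)
        out <- c(out, line(m$transcript_id, "three_prime_utr",
                           m$utr5_len + m$cds_len, m$sequence_length,
                           m$gene_id))
    }
  }
  writeLines(out, path)
  invisible(path)
}
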