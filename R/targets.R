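# Gene-level peak scores (rpm), FPKM normalization, target ranking, region
# annotation and the metagene profile.

#' Sum peak intensities per gene across two replicates
#'
#' Per gene and replicate the score is the sum of intensity_rpm over that
#' gene's retained peaks; the gene score is the mean of the two replicates.
#' A gene detected in only one replicate contributes 0 from the other (the
#' evidence is down-weighted, not erased). Genes with no peaks in either
#' replicate are omitted.
#'
#' @param peaks_rep1,peaks_rep2 retained [call_peaks()] tables for the two
#'   replicates (the published averaging is defined over exactly two).
#' @param models `transcript_models` data.frame.
#' @return data.frame `gene_id`, `peak_score_rep1_rpm`, `peak_score_rep2_rpm`,
#'   `mean_peak_score_rpm`.
#' @export
gene_peak_scores <- function(peaks_rep1, peaks_rep2, models) {
  if (missing(peaks_rep2))
    stop("exactly 2 replicates are required")
  gene <- stats::setNames(models$gene_id, models$transcript_id)
  score_one <- function(pk) {
    if (!nrow(pk)) return(numeric(0))
    tapply(pk$intensity_rpm, gene[pk$transcript_id], sum)
  }
  s1 <- score_one(peaks_rep1)
  s2 <- score_one(peaks_rep2)
  genes <- as.character(sort(union(names(s1), names(s2))))
  v1 <- ifelse(genes %in% names(s1), s1[genes], 0)
  v2 <- ifelse(genes %in% names(s2), s2[genes], 0)
  data.frame(gene_id = genes,
             peak_score_rep1_rpm = unname(v1),
             peak_score_rep2_rpm = unname(v2),
             mean_peak_score_rpm = unname((v1 + v2) / 2),
             stringsAsFactors = FALSE)
}

#' Rank targets by FPKM-normalized peak score
#'
#' `normalized_score = mean_peak_score_rpm / mean_fpkm` with `mean_fpkm` the
#' mean of the two expression replicates; non-expressed genes (mean FPKM 0)
#' are eliminated. Sorting is by descending normalized score, ties broken by
#' higher mean peak score then lexicographic gene id.
#'
#' @param scores a [gene_peak_scores()] table.
#' @param expression data.frame `gene_id`, `fpkm_rep1`, `fpkm_rep2`.
#' @param top_n size of the head set flagged as targets (default 500).
#' @return data.frame of class `target_ranking` with a `rank` column and
#'   logical `top`; genes with peaks but absent from the expression table are
#'   removed and listed in attribute `removed`.
#' @export
rank_targets <- function(scores, expression, top_n = 500L) {
  stopifnot(all(c("gene_id", "fpkm_rep1", "fpkm_rep2") %in% names(expression)))
  missing_expr <- setdiff(scores$gene_id, expression$gene_id)
  r <- merge(scores, expression, by = "gene_id")
  r$mean_fpkm <- (r$fpkm_rep1 + r$fpkm_rep2) / 2
  r <- r[r$mean_fpkm > 0, , drop = FALSE]
  r$normalized_score <- r$mean_peak_score_rpm / r$mean_fpkm
  ord <- order(-r$normalized_score, -r$mean_peak_score_rpm, r$gene_id)
  r <- r[ord, c("gene_id", "peak_score_rep1_rpm", "peak_score_rep2_rpm",
                "mean_peak_score_rpm", "mean_fpkm", "normalized_score")]
  r$rank <- seq_len(nrow(r))
  r$top <- r$rank <= top_n
  rownames(r) <- NULL
  attr(r, "removed") <- missing_expr
  attr(r, "top_n") <- as.integer(top_n)
  class(r) <- c("target_ranking", "data.frame")
  r
}

# region of a transcript position under the [0,utr5) / [utr5,utr5+cds) /
# [utr5+cds, len) partition; NA for non-mRNA
position_region <- function(position, model) {
  if (model$biotype != "mRNA") return(NA_character_)
  if (position < model$utr5_len) "UTR5"
  else if (position < model$utr5_len + model$cds_len) "CDS"
  else "UTR3"
}

#' Annotate peaks with transcript regions
#'
#' Assigns each peak to 5'UTR, CDS or 3'UTR by interval membership of its
#' position; peaks on non-mRNA transcripts get region NA and are excluded
#' from the fractions. Also reports the peaks-per-transcript histogram.
#'
#' @param peaks a retained peaks data.frame (one or both replicates).
#' @param models `transcript_models` data.frame.
#' @return list with `peaks` (region column added), `region_fractions`
#'   (named numeric over UTR5/CDS/UTR3), and `peaks_per_transcript` (table).
#' @export
annotate_regions <- function(peaks, models) {
  rownames(models) <- models$transcript_id
  reg <- vapply(seq_len(nrow(peaks)), function(i)
    position_region(peaks$position[i],
                    models[peaks$transcript_id[i], ]), character(1))
  peaks$region <- reg
  tab <- table(factor(reg[!is.na(reg)], levels = c("UTR5", "CDS", "UTR3")))
  fr <- if (sum(tab) > 0) as.numeric(tab) / sum(tab) else rep(NA_real_, 3)
  list(peaks = peaks,
       region_fractions = stats::setNames(fr, names(tab)),
       peaks_per_transcript = table(table(peaks$transcript_id)))
}

#' Metagene profile of peaks over scaled 5'UTR|CDS|3'UTR axes
#'
#' Each mRNA peak's position is mapped to its fractional position within its
#' region and histogrammed into `bins_per_region` bins per region; the
#' density is normalized to unit area over the whole three-region axis.
#'
#' @param peaks retained peaks.
#' @param models `transcript_models` data.frame.
#' @param bins_per_region histogram bins per region (default 25).
#' @return list with `profile` (data.frame `region`, `bin`, `count`,
#'   `density`) and `mean_region_lengths`.
#' @export
metagene_profile <- function(peaks, models, bins_per_region = 25L) {
  ann <- annotate_regions(peaks, models)$peaks
  ann <- ann[!is.na(ann$region), , drop = FALSE]
  rownames(models) <- models$transcript_id
  regions <- c("UTR5", "CDS", "UTR3")
  counts <- matrix(0L, nrow = bins_per_region, ncol = 3,
                   dimnames = list(NULL, regions))
  for (i in seq_len(nrow(ann))) {
    m <- models[ann$transcript_id[i], ]
    rs <- switch(ann$region[i], UTR5 = 0L, CDS = m$utr5_len,
                 UTR3 = m$utr5_len + m$cds_len)
    rl <- switch(ann$region[i], UTR5 = m$utr5_len, CDS = m$cds_len,
                 UTR3 = m$utr3_len)
    frac <- (ann$position[i] - rs) / rl
    b <- min(bins_per_region, floor(frac * bins_per_region) + 1L)
    counts[b, ann$region[i]] <- counts[b, ann$region[i]] + 1L
  }
  total <- sum(counts)
  bin_width <- 1 / bins_per_region  # each region spans 1 unit of the axis
  dens <- if (total > 0) counts / (total * bin_width) else counts * NA_real_
  mrna <- models[models$biotype == "mRNA", ]
  list(profile = data.frame(
         region = rep(regions, each = bins_per_region),
         bin = rep(seq_len(bins_per_region), 3L),
         count = as.integer(counts),
         density = as.numeric(dens),
         stringsAsFactors = FALSE),
       mean_region_lengths = c(UTR5 = mean(mrna$utr5_len),
                               CDS = mean(mrna$cds_len),
                               UTR3 = mean(mrna$utr3_len)))
}
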