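# End-to-end CRAC pipeline over a synthetic library: simulate -> preprocess
# -> align -> profiles -> peaks -> ranking -> region annotation -> motif.

#' Run the full CRAC target-identification pipeline on simulated data
#'
#' Convenience wrapper chaining the synthetic generator and every analysis
#' stage with the package defaults; returned intermediates allow each stage
#' to be inspected or re-run with different parameters.
#'
#' @param cfg a [simulate_config()] object.
#' @param params a [peak_params()] object (seeded from `cfg$seed` when NULL).
#' @param top_n ranking head size (default 500).
#' @param flank motif window half-size (default 10).
#' @param run_motif set FALSE to skip window extraction/motif discovery.
#' @return list with the simulation, per-replicate preprocessing reports,
#'   alignments, profiles and peaks, plus `scores`, `ranking`, `regions`
#'   (annotation of pooled retained peaks), `windows` and `motifs`.
#' @export
run_crac_pipeline <- function(cfg = simulate_config(), params = NULL,
                              top_n = 500L, flank = 10L, run_motif = TRUE) {
  if (is.null(params))
    params <- peak_params(seed = cfg$seed + 30L)
  sim <- simulate_transcriptome(cfg)
  reads <- simulate_crac_reads(cfg, sim)
  expr <- simulate_expression(cfg, sim)
  index <- build_kmer_index(sim$sequences)

  reps <- vector("list", 2L)
  for (r in 1:2) {
    pre <- preprocess_reads(reads$replicates[[r]], cfg$barcode_set,
                            cfg$adapter)
    lib <- pre$bins[[cfg$barcode_set[r]]]
    aln <- align_reads(lib, index, seed = cfg$seed + 10L + r)
    prof <- build_profiles(aln$alignments, sim$models, replicate_id = r)
    pk <- call_peaks(prof, params)
    reps[[r]] <- list(report = pre$report, alignments = aln$alignments,
                      n_unaligned = aln$n_unaligned, profiles = prof,
                      peaks = pk)
  }

  scores <- gene_peak_scores(reps[[1]]$peaks, reps[[2]]$peaks, sim$models)
  ranking <- rank_targets(scores, expr, top_n = top_n)
  pooled_peaks <- rbind(as.data.frame(reps[[1]]$peaks),
                        as.data.frame(reps[[2]]$peaks))
  regions <- annotate_regions(pooled_peaks, sim$models)

  windows <- NULL; motifs <- NULL
  if (run_motif) {
    gene2tx <- stats::setNames(sim$models$transcript_id, sim$models$gene_id)
    top_tx <- unname(gene2tx[ranking$gene_id[ranking$top]])
    pooled_aln <- rbind(reps[[1]]$alignments, reps[[2]]$alignments)
    windows <- extract_windows(pooled_aln, sim$sequences, top_tx, flank)
    motifs <- if (nrow(windows) >= 50L)
      discover_motif(windows, seed = cfg$seed + 20L) else list()
  }

  list(cfg = cfg, sim = sim, expression = expr, replicates = reps,
       scores = scores, ranking = ranking, regions = regions,
       windows = windows, motifs = motifs)
}
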