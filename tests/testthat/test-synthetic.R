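test_that("config validation enforces fractions, rates and motif alphabet", {
  expect_error(simulate_config(biotype_fractions = c(mRNA = 0.9, rRNA = 0.2)),
               "sum to 1")
  expect_error(simulate_config(del_rate = 1.5), "del_rate")
  expect_error(simulate_config(motif = "AUJAAWU"), "unknown IUPAC")
  expect_error(simulate_config(region_site_probs = c(0.5, 0.5, 0.5)),
               "sum to 1")
})

test_that("transcriptome simulation is deterministic and honours ground truth", {
  cfg <- simulate_config(n_transcripts = 50L, n_bound = 10L, seed = 7L)
  s1 <- simulate_transcriptome(cfg)
  s2 <- simulate_transcriptome(cfg)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$truth, s2$truth)

  # every planted instance matches the consensus and sits where claimed
  for (j in seq_len(nrow(s1$truth$sites))) {
    st <- s1$truth$sites[j, ]
    expect_gt(length(match_consensus(
      dna_to_rna(s1$sequences[[st$transcript_id]]), cfg$motif)), 0)
    # crosslink base is a U (T in DNA)
    expect_equal(substr(s1$sequences[[st$transcript_id]],
                        st$position + 1L, st$position + 1L), "T")
  }
  # mRNA region partition invariant
  m <- s1$models[s1$models$biotype == "mRNA", ]
  expect_true(all(m$utr5_len + m$cds_len + m$utr3_len == m$sequence_length))

  # degenerate region distribution: everything in the 3'UTR
  cfg3 <- simulate_config(n_transcripts = 50L, n_bound = 10L,
                          region_site_probs = c(0, 0, 1), seed = 7L)
  s3 <- simulate_transcriptome(cfg3)
  expect_true(all(s3$truth$sites$region == "UTR3"))
})

test_that("degenerate deletion rates produce all-or-none deletions", {
  base <- list(n_transcripts = 30L, n_bound = 6L, site_reads = 15L,
               pcr_dup_mean = 0, depth_per_fpkm = 0, seed = 13L)
  for (dr in c(1, 0)) {
    cfg <- do.call(simulate_config, c(base, list(del_rate = dr)))
    sim <- simulate_transcriptome(cfg)
    reads <- simulate_crac_reads(cfg, sim)
    pre <- preprocess_reads(reads$replicates[[1]], cfg$barcode_set,
                            cfg$adapter)
    aln <- align_reads(pre$bins[[cfg$barcode_set[1]]],
                       build_kmer_index(sim$sequences), seed = 3)
    prof <- build_profiles(aln$alignments, sim$models, 1)
    ndel <- sum(vapply(prof$transcripts, function(p) sum(p$deletions),
                       numeric(1)))
    if (dr == 0) {
      expect_equal(ndel, 0)
    } else {
      # with del_rate = 1, recovered deletion positions coincide exactly
      # with the planted crosslink sites
      expect_gt(ndel, 0)
      dpos <- unique(prof$deletion_events[, c("transcript_id", "position")])
      truth <- sim$truth$sites[, c("transcript_id", "position")]
      expect_true(all(do.call(paste, dpos) %in% do.call(paste, truth)))
    }
  }
})

test_that("PCR duplication inflates totals; ledger matches exactly", {
  cfg <- simulate_config(n_transcripts = 60L, n_bound = 12L, site_reads = 40L,
                         pcr_dup_mean = 2, seed = 17L)
  sim <- simulate_transcriptome(cfg)
  reads <- simulate_crac_reads(cfg, sim)
  r1 <- reads$replicates[[1]]
  expect_equal(nrow(r1), reads$ledger$n_total[1])
  col <- collapse_duplicates(r1)
  expect_equal(nrow(col$reads), reads$ledger$n_unique[1])
  expect_gt(reads$ledger$n_total[1], reads$ledger$n_unique[1])
})

test_that("expression table: zero noise copies truth, zeros follow the ledger", {
  cfg <- simulate_config(n_transcripts = 100L, n_bound = 10L,
                         fpkm_zero_fraction = 0.1, seed = 23L)
  sim <- simulate_transcriptome(cfg)
  e0 <- simulate_expression(cfg, sim, noise_sd = 0)
  expect_equal(e0$fpkm_rep1, sim$truth$expression$true_fpkm)
  expect_equal(e0$fpkm_rep2, sim$truth$expression$true_fpkm)

  e <- simulate_expression(cfg, sim)
  expect_true(all(e$fpkm_rep1 >= 0 & e$fpkm_rep2 >= 0))
  zeros <- sim$truth$expression$gene_id[sim$truth$expression$true_fpkm == 0]
  expect_equal(length(zeros), 10L)
  expect_true(all(e$fpkm_rep1[e$gene_id %in% zeros] == 0))
  expect_true(all(e$fpkm_rep1[!e$gene_id %in% zeros] > 0))
  # bound transcripts are never unexpressed
  expect_false(any(sim$truth$sites$gene_id %in% zeros))
})

test_that("SLAM-seq counts follow the binomial decay model", {
  hl <- data.frame(gene_id = "G1", t_half = 180)
  # large coverage: empirical rate within 3 binomial SE at every timepoint
  counts <- simulate_slamseq_counts(hl, timepoints = c(0, 30, 180, 540, 1440),
                                    coverage = 1e6L, r0 = 0.02,
                                    n_tech_reps = 1L, seed = 29L)
  expected <- 0.02 * 2^(-counts$timepoint / 180)
  se <- sqrt(expected * (1 - expected) / counts$t_coverage)
  expect_true(all(abs(counts$tc_count / counts$t_coverage - expected)
                  <= 3 * se))
  # t = 0 has expectation r0; t = t_half has exactly r0/2
  expect_equal(expected[counts$timepoint == 0], 0.02)
  expect_equal(expected[counts$timepoint == 180], 0.01)

  expect_error(simulate_slamseq_counts(data.frame(gene_id = "G", t_half = -1)),
               "positive")
  expect_error(simulate_slamseq_counts(hl, timepoints = c(30, 60)),
               "include 0")
  expect_error(simulate_slamseq_counts(hl, r0 = 1.2), "r0")
})

test_that("read-class composition follows the simulator's ledger", {
  p <- default_pipeline()
  aln <- p$replicates[[1]]$alignments
  cd <- class_distribution(aln, p$sim$models)
  # expected mRNA read share from the ledger: all site reads plus the
  # FPKM-proportional background on mRNA transcripts
  tf <- p$sim$truth$expression$true_fpkm
  is_m <- p$sim$models$biotype == "mRNA"
  n_site <- p$cfg$site_reads * nrow(p$sim$truth$sites)
  bg <- p$cfg$depth_per_fpkm * tf
  expected_mrna <- (n_site + sum(bg[is_m])) / (n_site + sum(bg))
  expect_lt(abs(cd[["mRNA"]] - expected_mrna), 0.05)
  expect_gt(cd[["mRNA"]], 0.85)
})
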