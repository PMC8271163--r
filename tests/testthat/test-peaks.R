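cand <- function(cov, order = 20, min_cov = 5)
  cracDecay:::peak_candidates(cov, order, min_cov)

test_that("windowed-maximum candidates match the brute-force scan", {
  # a single spike in flat background is the only candidate
  cov <- rep(0L, 200); cov[77] <- 50L
  expect_equal(cand(cov), 76L)

  # two spikes 10 nt apart within one order-20 window: only the higher wins
  cov <- rep(0L, 200); cov[100] <- 50L; cov[110] <- 30L
  expect_equal(cand(cov), 99L)

  # uniform plateau: leftmost position only
  expect_equal(cand(rep(7L, 300)), 0L)

  # property: equality with the naive scan on random vectors
  set.seed(99)
  for (len in c(60, 500, 2000, 10000)) {
    v <- rpois(len, 2) + rbinom(len, 1, 0.01) * rpois(len, 40)
    for (ord in c(3, 20)) {
      expect_equal(cand(v, ord, 5), oracle_peak_candidates(v, ord, 5),
                   info = sprintf("len=%d order=%d", len, ord))
    }
  }
})

test_that("permutation screen rejects uniform coverage and keeps a spike", {
  models <- make_models("TX1", 600L, utr5 = 100L, cds = 300L, utr3 = 200L)
  # 200 reads piled on one site + 50 background reads
  set.seed(5)
  aln <- data.frame(
    read_id = sprintf("r%d", 1:250),
    transcript_id = "TX1",
    start = c(sample(280:299, 200, TRUE), sample(0:570, 50, TRUE)),
    cigar = "30M", stringsAsFactors = FALSE)
  prof <- build_profiles(aln, models, 1)
  pk <- call_peaks(prof, peak_params(seed = 17))
  expect_gte(nrow(pk), 1L)
  expect_true(any(abs(pk$position - 300) <= 15))
  expect_true(all(pk$q_value <= 0.001))
  expect_equal(pk$intensity_rpm, pk$height * 1e6 / 250)

  # uniformly spread reads: the lone plateau candidate fails the screen
  set.seed(6)
  alnu <- data.frame(
    read_id = sprintf("u%d", 1:120),
    transcript_id = "TX1",
    start = sample(0:570, 120, TRUE),
    cigar = "30M", stringsAsFactors = FALSE)
  pku <- call_peaks(build_profiles(alnu, models, 1), peak_params(seed = 18))
  expect_equal(nrow(pku), 0L)
})

test_that("gene peak scores sum, average, and zero-fill single-replicate hits", {
  models <- make_models(c("TX1", "TX2"), c(500L, 500L))
  mk_peaks <- function(df) { class(df) <- c("peaks", "data.frame"); df }
  p1 <- mk_peaks(data.frame(transcript_id = c("TX1", "TX1", "TX2"),
                            position = c(10L, 200L, 50L),
                            height = c(30L, 12L, 20L),
                            intensity_rpm = c(30, 12, 20),
                            p_value = 1e-4, q_value = 1e-4,
                            stringsAsFactors = FALSE))
  p2 <- mk_peaks(data.frame(transcript_id = "TX1", position = 12L,
                            height = 38L, intensity_rpm = 38,
                            p_value = 1e-4, q_value = 1e-4,
                            stringsAsFactors = FALSE))
  sc <- gene_peak_scores(p1, p2, models)
  g1 <- sc[sc$gene_id == "G1", ]
  expect_equal(g1$peak_score_rep1_rpm, 42)   # 30 + 12
  expect_equal(g1$peak_score_rep2_rpm, 38)
  expect_equal(g1$mean_peak_score_rpm, 40)
  g2 <- sc[sc$gene_id == "G2", ]
  expect_equal(g2$peak_score_rep2_rpm, 0)    # zero-filled, not dropped
  expect_equal(g2$mean_peak_score_rpm, 10)
  expect_error(gene_peak_scores(p1, models = models), "2 replicates")
})

test_that("ranking normalizes by mean FPKM and eliminates FPKM = 0", {
  scores <- data.frame(gene_id = c("G1", "G2", "G3"),
                       peak_score_rep1_rpm = c(40, 40, 10),
                       peak_score_rep2_rpm = c(40, 40, 10),
                       mean_peak_score_rpm = c(40, 40, 10),
                       stringsAsFactors = FALSE)
  expr <- data.frame(gene_id = c("G1", "G2", "G3"),
                     fpkm_rep1 = c(10, 0, 1), fpkm_rep2 = c(10, 0, 1),
                     stringsAsFactors = FALSE)
  r <- rank_targets(scores, expr, top_n = 2)
  expect_false("G2" %in% r$gene_id)          # FPKM = 0 eliminated
  expect_equal(r$normalized_score[r$gene_id == "G1"], 4)
  expect_equal(r$gene_id[1], "G3")           # 10/1 beats 40/10
  expect_equal(r$rank, seq_len(nrow(r)))
  expect_true(all(diff(r$normalized_score) <= 0))

  # gene with peaks but absent from the expression table is reported
  scores2 <- rbind(scores, data.frame(gene_id = "G9",
                                      peak_score_rep1_rpm = 5,
                                      peak_score_rep2_rpm = 5,
                                      mean_peak_score_rpm = 5))
  r2 <- rank_targets(scores2, expr)
  expect_equal(attr(r2, "removed"), "G9")
})

test_that("ranking is invariant to a global library-size rescale", {
  # rpm self-normalization: multiplying both replicates' library sizes by a
  # constant multiplies every intensity by the same factor and leaves the
  # ordering (and top set) unchanged
  p <- default_pipeline()
  sc <- p$scores
  sc2 <- sc
  sc2$peak_score_rep1_rpm <- sc$peak_score_rep1_rpm * 3
  sc2$peak_score_rep2_rpm <- sc$peak_score_rep2_rpm * 3
  sc2$mean_peak_score_rpm <- sc$mean_peak_score_rpm * 3
  r1 <- rank_targets(sc, p$expression)
  r2 <- rank_targets(sc2, p$expression)
  expect_equal(r2$gene_id, r1$gene_id)
  expect_equal(r2$normalized_score, 3 * r1$normalized_score)
})

test_that("region annotation uses half-open boundaries; metagene has unit area", {
  models <- make_models("TX1", 560L, utr5 = 60L, cds = 300L, utr3 = 200L)
  pk <- data.frame(transcript_id = "TX1", position = c(59L, 60L, 359L, 360L),
                   height = 10L, intensity_rpm = 10, p_value = 1e-4,
                   q_value = 1e-4, stringsAsFactors = FALSE)
  ann <- annotate_regions(pk, models)
  expect_equal(ann$peaks$region, c("UTR5", "CDS", "CDS", "UTR3"))
  expect_equal(sum(ann$region_fractions), 1)

  # non-mRNA peaks get NA and are excluded from fractions
  models2 <- rbind(models, make_models("TX2", 100L, biotype = "rRNA"))
  class(models2) <- c("transcript_models", "data.frame")
  pk2 <- rbind(pk, data.frame(transcript_id = "TX2", position = 5L,
                              height = 10L, intensity_rpm = 10,
                              p_value = 1e-4, q_value = 1e-4))
  ann2 <- annotate_regions(pk2, models2)
  expect_true(is.na(ann2$peaks$region[5]))
  expect_equal(sum(ann2$region_fractions), 1)

  mg <- metagene_profile(pk, models)
  area <- sum(mg$profile$density) / 25  # bin width = 1/25 region units
  expect_equal(area, 1)
})
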