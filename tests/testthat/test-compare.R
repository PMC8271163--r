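mk_groups <- function(bound, not_bound) {
  data.frame(gene_id = c(bound, not_bound),
             group = rep(c("Bound", "Not bound"),
                         c(length(bound), length(not_bound))),
             stringsAsFactors = FALSE)
}

test_that("group assignment: top-N bound, peak-free unbound, rest excluded", {
  models <- make_models(sprintf("TX%d", 1:6), 500L)
  mk_peaks <- function(tx) {
    df <- data.frame(transcript_id = tx, position = 10L, height = 20L,
                     intensity_rpm = 20, p_value = 1e-4, q_value = 1e-4,
                     stringsAsFactors = FALSE)
    class(df) <- c("peaks", "data.frame"); df
  }
  p1 <- mk_peaks(c("TX1", "TX2", "TX3"))
  p2 <- mk_peaks(c("TX1", "TX2"))
  sc <- gene_peak_scores(p1, p2, models)
  expr <- data.frame(gene_id = models$gene_id, fpkm_rep1 = c(1, 2, 50, 1, 1, 1),
                     fpkm_rep2 = c(1, 2, 50, 1, 1, 1))
  rk <- rank_targets(sc, expr, top_n = 2)
  grp <- assign_groups(rk, p1, p2, models)
  g <- stats::setNames(grp$group, grp$gene_id)
  expect_equal(unname(g[rk$gene_id[1]]), "Bound")
  expect_equal(unname(g["G4"]), "Not bound")   # no peaks anywhere
  # the gene ranked top_n + 1 has peaks but is in neither group
  expect_equal(unname(g[rk$gene_id[3]]), "Unassigned")
})

test_that("Mann-Whitney matches exact enumeration for small groups", {
  # canonical example: complete separation of 3 vs 3
  cmp <- cracDecay:::mann_whitney_u(c(1, 2, 3), c(10, 20, 30))
  expect_equal(unname(cmp$U), 0)
  expect_equal(cmp$p_value, 0.1)

  set.seed(31)
  for (i in 1:8) {
    m <- sample(3:6, 1); n <- sample(3:6, 1)
    x <- round(runif(m, 0, 100), 1); y <- round(runif(n, 0, 100), 1)
    ours <- cracDecay:::mann_whitney_u(x, y)
    orc <- oracle_mann_whitney(x, y)
    expect_equal(unname(ours$U), orc$U, info = i)
    expect_equal(ours$p_value, orc$p_value, tolerance = 1e-12, info = i)
  }
})

test_that("identical groups give p = 1 and equal medians", {
  fits <- data.frame(gene_id = sprintf("G%d", 1:8),
                     lambda = 1, t_half = rep(c(100, 150, 200, 250), 2),
                     rss = 0, n_points = 6L, status = "ok")
  grp <- mk_groups(sprintf("G%d", 1:4), sprintf("G%d", 5:8))
  cmp <- compare_half_lives(fits, grp)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$summaries$Bound$median, cmp$summaries$`Not bound`$median)
  expect_error(compare_half_lives(fits[1:5, ], grp), "at least 3")
})

test_that("ECDF summaries are sorted, complete, order-invariant", {
  fits <- data.frame(gene_id = sprintf("G%d", 1:10), lambda = 1,
                     t_half = c(5, 3, 9, 1, 7, 2, 8, 4, 10, 6),
                     rss = 0, n_points = 6L, status = "ok")
  grp <- mk_groups(sprintf("G%d", 1:5), sprintf("G%d", 6:10))
  cmp <- compare_half_lives(fits, grp)
  e <- cmp$summaries$Bound$ecdf
  expect_equal(e, sort(e))
  expect_equal(length(e), 5)
  F <- stats::ecdf(e)
  expect_equal(F(max(e)), 1)           # reaches 1
  grp2 <- grp[sample(nrow(grp)), ]
  cmp2 <- compare_half_lives(fits, grp2)
  expect_equal(cmp2$summaries$Bound$ecdf, e)
})

test_that("fold-change comparison recovers constructed shifts", {
  genes <- sprintf("G%03d", 1:40)
  grp <- mk_groups(genes[1:20], genes[21:40])
  b <- data.frame(gene_id = genes, fpkm_rep1 = 20, fpkm_rep2 = 20)
  # A = B everywhere: all log2FC = 0, p = 1
  cmp0 <- compare_fold_change(b, b, grp)
  expect_true(all(cmp0$log2fc$log2fc == 0))
  expect_equal(cmp0$p_value, 1)

  # A = 2B on bound genes only: bound median ~1, unbound 0
  a <- b
  a$fpkm_rep1[1:20] <- 40; a$fpkm_rep2[1:20] <- 40
  cmp1 <- compare_fold_change(a, b, grp, pseudocount = 0)
  expect_equal(cmp1$summaries$Bound$median, 1)
  expect_equal(cmp1$summaries$`Not bound`$median, 0)
  expect_lt(cmp1$p_value, 1e-6)

  expect_error(compare_fold_change(
    data.frame(gene_id = "X1", fpkm_rep1 = 1, fpkm_rep2 = 1), b, grp),
    "no shared genes")
})

test_that("a planted 20% half-life reduction is detected at cohort scale", {
  set.seed(55)
  n <- 150
  hl <- data.frame(
    gene_id = sprintf("G%03d", 1:(2 * n)),
    t_half = c(rlnorm(n, log(224 * 0.8), 0.4), rlnorm(n, log(224), 0.4)))
  counts <- simulate_slamseq_counts(hl, coverage = 5000L, seed = 19L)
  fits <- fit_decay_all(normalize_series(collapse_technical(counts)))
  grp <- mk_groups(hl$gene_id[1:n], hl$gene_id[(n + 1):(2 * n)])
  cmp <- compare_half_lives(fits, grp)
  expect_lt(cmp$p_value, 1e-4)
  expect_lt(cmp$summaries$Bound$median, cmp$summaries$`Not bound`$median)
})
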