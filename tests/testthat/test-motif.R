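random_rna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, TRUE), collapse = ""),
    character(1))
}

mk_windows <- function(seqs, flank = 10L) {
  w <- data.frame(read_id = sprintf("r%d", seq_along(seqs)),
                  transcript_id = "TX1", center = 100L, sequence = seqs,
                  center_offset = flank, stringsAsFactors = FALSE)
  attr(w, "flank") <- flank
  class(w) <- c("motif_windows", "data.frame")
  w
}

test_that("IUPAC consensus matching follows code semantics", {
  expect_equal(match_consensus("AUGAAUU", "AUKAAWU"), 0L)
  expect_equal(length(match_consensus("AUCAAUU", "AUKAAWU")), 0L)  # C not in K
  expect_equal(match_consensus("AUUAAAU", "AUKAAWU"), 0L)  # K=U, W=A
  expect_equal(match_consensus("GGAUGAAUUGGAUGAAUUGG", "AUKAAWU"), c(2L, 11L))
  expect_equal(match_consensus("ATGAATT", "AUKAAWU"), 0L)  # DNA accepted
  expect_error(match_consensus("AUGAAUU", "AUJAAWU"), "unknown IUPAC")
})

test_that("windows are deletion-centered, clipped, and RNA-alphabet", {
  seqs <- c(TX1 = paste(rep("ACGT", 60), collapse = ""))
  aln <- data.frame(read_id = c("r1", "r2"), transcript_id = "TX1",
                    start = c(100L, 0L), cigar = c("10M1D15M", "3M1D20M"),
                    stringsAsFactors = FALSE)
  w <- extract_windows(aln, seqs, "TX1", flank = 10L)
  # r1: deletion at 110, window [100, 121), center offset 10
  expect_equal(w$center[1], 110L)
  expect_equal(nchar(w$sequence[1]), 21L)
  expect_equal(w$center_offset[1], 10L)
  expect_equal(substr(w$sequence[1], 11, 11),
               dna_to_rna(substr(seqs[["TX1"]], 111, 111)))
  # r2: deletion 3 nt from the start -> clipped, center offset 3
  expect_equal(w$center[2], 3L)
  expect_equal(nchar(w$sequence[2]), 14L)
  expect_equal(w$center_offset[2], 3L)
  expect_false(grepl("T", w$sequence[1]))

  expect_error(extract_windows(aln, seqs, "TX1", flank = 25L),
               "flank must be 10 or 50")
  # reads without a single 1-nt deletion yield no window
  aln2 <- data.frame(read_id = "r3", transcript_id = "TX1", start = 10L,
                     cigar = "25M", stringsAsFactors = FALSE)
  expect_equal(nrow(extract_windows(aln2, seqs, "TX1", 10L)), 0L)
})

test_that("presence/absence Fisher p equals the hypergeometric oracle", {
  for (a in c(3, 10, 25)) for (b in c(0, 2, 12)) {
    n_fg <- 50; n_bg <- 50
    ours <- cracDecay:::fisher_presence_p(a, b, n_fg, n_bg)
    ft <- fisher.test(matrix(c(a, n_fg - a, b, n_bg - b), 2),
                      alternative = "greater")$p.value
    expect_equal(ours, ft, tolerance = 1e-12, info = paste(a, b))
  }
})

test_that("a planted consensus is discovered and generalization only improves p", {
  set.seed(41)
  n <- 120
  insts <- vapply(seq_len(n), function(i)
    cracDecay:::expand_iupac("AUKAAWU"), character(1))
  seqs <- random_rna(n, 21)
  substr(seqs, 8, 14) <- insts
  w <- mk_windows(seqs)
  res <- discover_motif(w, seed = 13)
  expect_gt(length(res), 0)
  best <- res[[1]]
  expect_lt(best$e_value, 0.05)
  expect_true(best$e_value >= best$p_enrichment)
  # the discovered consensus matches planted instances
  hits <- vapply(insts, function(s)
    length(match_consensus(s, best$consensus)) > 0 ||
      length(match_consensus(paste0("NN", s, "NN"), best$consensus)) > 0,
    logical(1))
  expect_gt(mean(hits), 0.5)
  expect_true(all(abs(colSums(best$pwm) - 1) < 1e-9))

  # merge-acceptance rule: a generalization is kept only if it lowers p
  fg <- seqs; bg <- vapply(fg, function(s)
    paste(sample(strsplit(s, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
  word <- "AUGAAUU"
  lp_word <- cracDecay:::fisher_presence_p(
    cracDecay:::consensus_presence(fg, word),
    cracDecay:::consensus_presence(bg, word), n, n, log = TRUE)
  g <- cracDecay:::generalize_word(word, fg, bg, lp_word)
  expect_lte(g$log_p, lp_word)
})

test_that("discovery needs a minimum number of windows", {
  w <- mk_windows(random_rna(10, 21))
  expect_error(discover_motif(w), "increase flank")
})

test_that("central enrichment separates centered from uniform matches", {
  # all matches covering the center at n = 100: overwhelming significance
  set.seed(42)
  seqs <- random_rna(100, 21)
  substr(seqs, 8, 14) <- "AUGAAUU"  # spans the center (offset 10)
  ce <- central_enrichment(mk_windows(seqs), "AUKAAWU")
  expect_lt(ce$positional_p, 1e-20)
  expect_equal(ce$n_central, ce$n_matched)

  # no matches: p = 1, empty histogram
  ce0 <- central_enrichment(mk_windows(random_rna(20, 21)), "CCCCCCC")
  expect_equal(ce0$positional_p, 1)
  expect_equal(ce0$n_matched, 0L)
  expect_equal(length(ce0$offset_histogram), 0L)
})

test_that("motif discovery is seed-reproducible end-to-end", {
  set.seed(77)
  seqs <- random_rna(80, 21)
  substr(seqs, 6, 12) <- "AUGAAUU"
  w <- mk_windows(seqs)
  r1 <- discover_motif(w, seed = 5)
  r2 <- discover_motif(w, seed = 5)
  expect_identical(r1, r2)
})
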