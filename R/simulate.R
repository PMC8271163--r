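# Synthetic-data generator: transcriptomes with planted crosslink sites,
# CRAC read libraries (crosslink-induced 1-nt deletions, in-line barcodes,
# 3' adapters, PCR duplication), expression tables and SLAM-seq T->C count
# series, with a ground-truth ledger for recovery tests.

#' Simulation configuration
#'
#' Defaults define the study conditions the analysis is tested against:
#' 300 transcripts, 60 bound with an AUKAAWU-family site (region probabilities
#' 0.1/0.1/0.8 for 5'UTR/CDS/3'UTR), crosslink deletion rate 0.3 per
#' site-spanning read, 200 site reads per site and replicate, lognormal FPKM
#' with expression-proportional background reads, and per-transcript
#' half-lives lognormal around the global median with bound transcripts
#' shortened by 20%.
#'
#' @param n_transcripts number of transcripts.
#' @param n_bound number of transcripts given a planted crosslink site.
#' @param biotype_fractions named fractions per biotype (must sum to 1).
#' @param utr5_range,cds_range,utr3_range mRNA region length ranges (nt).
#' @param nc_len_range length range for non-mRNA transcripts (nt).
#' @param region_site_probs probabilities that a planted site falls in the
#'   5'UTR, CDS or 3'UTR (sums to 1).
#' @param motif IUPAC consensus planted at bound sites (RNA alphabet).
#' @param del_rate probability that a site-spanning read carries a 1-nt
#'   deletion at the crosslink position.
#' @param site_reads site-spanning reads per planted site and replicate.
#' @param pcr_dup_mean mean extra PCR copies per unique fragment
#'   (k ~ Poisson(pcr_dup_mean) + 1 total copies).
#' @param barcode_set 5' in-line barcodes, one per replicate (equal length).
#' @param adapter 3' adapter sequence.
#' @param read_len raw read length (nt).
#' @param frag_len_range insert (cDNA fragment) length range (nt).
#' @param depth_per_fpkm expected background reads per FPKM unit per
#'   transcript and replicate.
#' @param fpkm_meanlog,fpkm_sdlog lognormal parameters of true FPKM.
#' @param fpkm_zero_fraction fraction of genes with true FPKM 0 (these are
#'   never selected as bound: crosslinking requires expression).
#' @param expr_noise_sd lognormal sd of replicate FPKM noise.
#' @param half_life_meanlog,half_life_sdlog lognormal parameters of true
#'   half-life (minutes); defaults centre on 224 min.
#' @param bound_half_life_factor multiplier applied to bound transcripts'
#'   half-life (default 0.8, i.e. a 20% reduction).
#' @param seed integer seed; all generator randomness derives from it.
#' @return list of class `sim_config`.
#' @export
simulate_config <- function(n_transcripts = 300L,
                            n_bound = 60L,
                            biotype_fractions = c(mRNA = 0.85, rRNA = 0.05,
                                                  tRNA = 0.04, snoRNA = 0.03,
                                                  snRNA = 0.02, miscRNA = 0.01),
                            utr5_range = c(50L, 150L),
                            cds_range = c(300L, 900L),
                            utr3_range = c(150L, 500L),
                            nc_len_range = c(80L, 300L),
                            region_site_probs = c(utr5 = 0.1, cds = 0.1,
                                                  utr3 = 0.8),
                            motif = "AUKAAWU",
                            del_rate = 0.3,
                            site_reads = 200L,
                            pcr_dup_mean = 1,
                            barcode_set = c("AGTCA", "CTGAC"),
                            adapter = "AGATCGGAAGAGC",
                            read_len = 50L,
                            frag_len_range = c(26L, 36L),
                            depth_per_fpkm = 2,
                            fpkm_meanlog = log(20), fpkm_sdlog = 1,
                            fpkm_zero_fraction = 0.05,
                            expr_noise_sd = 0.2,
                            half_life_meanlog = log(224),
                            half_life_sdlog = 0.4,
                            bound_half_life_factor = 0.8,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(biotype_fractions) - 1) > 1e-9)
    stop("biotype_fractions must sum to 1")
  if (abs(sum(region_site_probs) - 1) > 1e-9)
    stop("region_site_probs must sum to 1")
  if (del_rate < 0 || del_rate > 1) stop("del_rate must lie in [0, 1]")
  iupac_chars(motif)  # errors on non-IUPAC characters
  if (length(unique(nchar(barcode_set))) != 1L)
    stop("barcodes must have equal length")
  if (anyDuplicated(barcode_set)) stop("barcodes must be distinct")
  if (read_len <= nchar(barcode_set[1]) + nchar(motif))
    stop("read_len must exceed barcode length + motif width")
  w <- nchar(motif)
  eligible <- c(utr5_range[1], cds_range[1], utr3_range[1])[region_site_probs > 0]
  if (length(eligible) && min(eligible) < w + 2L)
    stop("motif (", w, " nt) longer than the shortest eligible region")
  structure(cfg, class = "sim_config")
}

# crosslink position within a planted instance: the U nearest the motif
# center (ties -> leftmost), reflecting the pyrimidine preference of UV
# crosslinking; by construction the deleted base is always a U
crosslink_offset <- function(instance) {
  us <- which(strsplit(instance, "")[[1]] == "U") - 1L
  if (!length(us)) stop("planted instance carries no U: ", instance)
  center <- (nchar(instance) - 1L) %/% 2L
  us[which.min(abs(us - center))]
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate a transcriptome with planted crosslink sites
#'
#' Sequences are i.i.d. uniform over A/C/G/T except for planted motif
#' instances (concrete IUPAC expansions, DNA alphabet). Site regions are
#' drawn from `region_site_probs`; the crosslink position is the uridine of
#' the instance nearest the motif center. Deterministic under `cfg$seed`.
#'
#' @param cfg a [simulate_config()] object.
#' @return list of class `crac_simulation` with elements `models`
#'   (`transcript_models`), `sequences` (named DNA character vector), `truth`
#'   (ground-truth ledger: `sites`, `expression`, `half_life`) and `cfg`.
#' @export
simulate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_transcripts
  tx_id <- sprintf("TX%04d", seq_len(n))
  gene_id <- sprintf("G%04d", seq_len(n))
  biotype <- sample(names(cfg$biotype_fractions), n, replace = TRUE,
                    prob = cfg$biotype_fractions)

  ru <- function(rng, m) rng[1] + floor(stats::runif(m) * (rng[2] - rng[1] + 1L))
  is_m <- biotype == "mRNA"
  utr5 <- ifelse(is_m, ru(cfg$utr5_range, n), 0L)
  cds <- ifelse(is_m, 3L * (ru(cfg$cds_range, n) %/% 3L), 0L)
  utr3 <- ifelse(is_m, ru(cfg$utr3_range, n), 0L)
  len <- ifelse(is_m, utr5 + cds + utr3, ru(cfg$nc_len_range, n))
  sequences <- stats::setNames(vapply(len, random_seq, character(1)), tx_id)

  true_fpkm <- stats::rlnorm(n, cfg$fpkm_meanlog, cfg$fpkm_sdlog)
  n_zero <- round(cfg$fpkm_zero_fraction * n)
  zero_idx <- if (n_zero > 0L) sample(n, n_zero) else integer(0)
  true_fpkm[zero_idx] <- 0

  t_half <- stats::rlnorm(n, cfg$half_life_meanlog, cfg$half_life_sdlog)

  # bound transcripts: expressed mRNAs only
  w <- nchar(cfg$motif)
  frag_max <- cfg$frag_len_range[2]
  eligible <- which(is_m & true_fpkm > 0 & len >= 2L * frag_max + w)
  if (length(eligible) < cfg$n_bound)
    stop("only ", length(eligible), " transcripts eligible for ",
         cfg$n_bound, " planted sites")
  bound <- sort(sample(eligible, cfg$n_bound))
  t_half[bound] <- t_half[bound] * cfg$bound_half_life_factor

  sites <- NULL
  if (cfg$n_bound > 0L) {
    region <- sample(c("UTR5", "CDS", "UTR3"), cfg$n_bound, replace = TRUE,
                     prob = cfg$region_site_probs)
    pos <- integer(cfg$n_bound)
    inst <- character(cfg$n_bound)
    for (j in seq_len(cfg$n_bound)) {
      i <- bound[j]
      rs <- switch(region[j], UTR5 = 0L, CDS = utr5[i],
                   UTR3 = utr5[i] + cds[i])
      re <- switch(region[j], UTR5 = utr5[i], CDS = utr5[i] + cds[i],
                   UTR3 = len[i])
      # instance must fit in the region and the crosslink must admit a
      # fully-interior fragment: keep the instance away from transcript ends
      lo <- max(rs, frag_max)
      hi <- min(re, len[i] - frag_max) - w
      if (hi < lo) { lo <- max(rs, 1L); hi <- min(re, len[i] - 2L) - w }
      start <- lo + floor(stats::runif(1) * (hi - lo + 1L))
      instance <- expand_iupac(cfg$motif)
      substr(sequences[i], start + 1L, start + w) <- rna_to_dna(instance)
      p0 <- start + crosslink_offset(instance)
      # a deletion inside a homopolymer run is only identifiable up to the
      # run, and alignment left-aligns it; the ground-truth site is
      # therefore the leftmost T of the run containing the crosslinked U
      while (p0 > 0L && substr(sequences[i], p0, p0) == "T") p0 <- p0 - 1L
      pos[j] <- p0
      inst[j] <- instance
    }
    sites <- data.frame(transcript_id = tx_id[bound], gene_id = gene_id[bound],
                        position = pos, region = region, instance = inst,
                        stringsAsFactors = FALSE)
  } else {
    sites <- data.frame(transcript_id = character(), gene_id = character(),
                        position = integer(), region = character(),
                        instance = character(), stringsAsFactors = FALSE)
  }

  models <- data.frame(transcript_id = tx_id, gene_id = gene_id,
                       biotype = biotype, utr5_len = as.integer(utr5),
                       cds_len = as.integer(cds), utr3_len = as.integer(utr3),
                       sequence_length = as.integer(len),
                       stringsAsFactors = FALSE)
  class(models) <- c("transcript_models", "data.frame")

  structure(list(
    models = models,
    sequences = sequences,
    truth = list(
      sites = sites,
      expression = data.frame(gene_id = gene_id, true_fpkm = true_fpkm,
                              stringsAsFactors = FALSE),
      half_life = data.frame(gene_id = gene_id, t_half = t_half,
                             stringsAsFactors = FALSE)),
    cfg = cfg), class = "crac_simulation")
}

#' Write a simulated transcriptome as FASTA
#'
#' @param sim a `crac_simulation` object.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(sim, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$sequences), path)
  invisible(path)
}

#' Simulate CRAC read libraries (two replicates)
#'
#' For each planted site, `site_reads` fragments are drawn with the crosslink
#' strictly interior; with probability `del_rate` the crosslinked base is
#' deleted from the read. Background fragments are placed uniformly along
#' each expressed transcript at a rate proportional to its FPKM. Each unique
#' fragment is PCR-duplicated k ~ Poisson(pcr_dup_mean) + 1 times; reads are
#' barcode + insert + adapter truncated to `read_len`. Ground truth is
#' retained in the read id (`site`/`bg`, transcript, crosslink position,
#' deletion flag).
#'
#' @param cfg a [simulate_config()] object.
#' @param sim the matching [simulate_transcriptome()] output.
#' @return list with `replicates` (list of two read data.frames) and `ledger`
#'   (per-replicate unique-fragment and total counts).
#' @export
simulate_crac_reads <- function(cfg, sim) {
  stopifnot(inherits(sim, "crac_simulation"))
  set.seed(cfg$seed + 1L)
  len <- stats::setNames(sim$models$sequence_length, sim$models$transcript_id)
  fpkm <- stats::setNames(sim$truth$expression$true_fpkm,
                          sim$models$transcript_id)
  fr <- cfg$frag_len_range
  reps <- vector("list", 2L)
  ledger <- data.frame(replicate = 1:2, n_unique = NA_integer_,
                       n_total = NA_integer_)

  for (r in 1:2) {
    bc <- cfg$barcode_set[r]
    frag_tx <- character(0); frag_seq <- character(0)
    frag_tag <- character(0)

    for (j in seq_len(nrow(sim$truth$sites))) {
      s <- sim$truth$sites[j, ]
      L <- len[[s$transcript_id]]
      m <- cfg$site_reads
      fl <- fr[1] + floor(stats::runif(m) * (fr[2] - fr[1] + 1L))
      smin <- pmax(0L, s$position - fl + 2L)
      smax <- pmin(s$position - 1L, L - fl)
      st <- smin + floor(stats::runif(m) * (smax - smin + 1L))
      del <- stats::runif(m) < cfg$del_rate
      seqs <- substring(sim$sequences[[s$transcript_id]], st + 1L, st + fl)
      k <- s$position - st  # 1-based index of the crosslinked base in frag
      seqs[del] <- paste0(substr(seqs[del], 1L, k[del]),
                          substr(seqs[del], k[del] + 2L, fl[del]))
      frag_tx <- c(frag_tx, rep(s$transcript_id, m))
      frag_seq <- c(frag_seq, seqs)
      frag_tag <- c(frag_tag, sprintf("site:%s:%d:%d", s$transcript_id,
                                      s$position, as.integer(del)))
    }

    for (tx in names(len)) {
      if (fpkm[[tx]] <= 0) next
      nb <- stats::rpois(1, cfg$depth_per_fpkm * fpkm[[tx]])
      if (nb == 0L) next
      L <- len[[tx]]
      fl <- pmin(fr[1] + floor(stats::runif(nb) * (fr[2] - fr[1] + 1L)), L)
      st <- floor(stats::runif(nb) * (L - fl + 1L))
      frag_tx <- c(frag_tx, rep(tx, nb))
      frag_seq <- c(frag_seq, substring(sim$sequences[[tx]], st + 1L, st + fl))
      frag_tag <- c(frag_tag, sprintf("bg:%s:%d:0", tx, st))
    }

    raw <- substr(paste0(bc, frag_seq, cfg$adapter), 1L, cfg$read_len)
    nf <- length(raw)
    ids <- sprintf("r%d_%06d|%s", r, seq_len(nf), frag_tag)
    ledger$n_unique[r] <- length(unique(raw))

    k <- stats::rpois(nf, cfg$pcr_dup_mean) + 1L
    idx <- rep(seq_len(nf), k)
    copy <- sequence(k)
    ord <- sample(length(idx))
    reads <- data.frame(
      read_id = paste0(ids[idx], "/", copy)[ord],
      sequence = raw[idx][ord],
      quality = strrep("I", nchar(raw[idx][ord])),
      stringsAsFactors = FALSE)
    ledger$n_total[r] <- nrow(reads)
    reps[[r]] <- reads
  }
  list(replicates = reps, ledger = ledger)
}

#' Simulate a two-replicate expression table
#'
#' Replicate FPKM = true FPKM times lognormal noise; genes with true FPKM 0
#' (the configured zero fraction) stay 0 in both replicates.
#'
#' @param cfg a [simulate_config()] object.
#' @param sim the matching simulation.
#' @param noise_sd lognormal sd of replicate noise (defaults to
#'   `cfg$expr_noise_sd`).
#' @return data.frame `gene_id`, `fpkm_rep1`, `fpkm_rep2`.
#' @export
simulate_expression <- function(cfg, sim, noise_sd = cfg$expr_noise_sd) {
  set.seed(cfg$seed + 2L)
  tf <- sim$truth$expression$true_fpkm
  n <- length(tf)
  data.frame(gene_id = sim$truth$expression$gene_id,
             fpkm_rep1 = tf * stats::rlnorm(n, 0, noise_sd),
             fpkm_rep2 = tf * stats::rlnorm(n, 0, noise_sd),
             stringsAsFactors = FALSE)
}

#' Simulate SLAM-seq T->C conversion counts
#'
#' Per gene, timepoint and technical replicate,
#' `tc_count ~ Binomial(t_coverage, r0 * 2^(-t / t_half))`: the labeled
#' fraction decays exponentially with the transcript's half-life from the
#' baseline conversion rate r0 at chase time 0.
#'
#' @param half_life data.frame with columns `gene_id`, `t_half` (minutes), or
#'   a `crac_simulation` whose truth ledger supplies it.
#' @param timepoints chase times in minutes; must include 0. Defaults to the
#'   0, 30 min, 1, 2, 9, 24 h design.
#' @param coverage T coverage per gene/timepoint/replicate.
#' @param r0 baseline conversion rate at t = 0 (0 < r0 < 1).
#' @param n_tech_reps technical replicates per timepoint.
#' @param seed RNG seed.
#' @return data.frame `gene_id`, `timepoint`, `tech_rep`, `t_coverage`,
#'   `tc_count`.
#' @export
simulate_slamseq_counts <- function(half_life,
                                    timepoints = c(0, 30, 60, 120, 540, 1440),
                                    coverage = 5000L, r0 = 0.02,
                                    n_tech_reps = 2L, seed = 1L) {
  if (inherits(half_life, "crac_simulation"))
    half_life <- half_life$truth$half_life
  stopifnot(all(c("gene_id", "t_half") %in% names(half_life)))
  if (any(half_life$t_half <= 0)) stop("t_half must be positive")
  if (!0 %in% timepoints) stop("timepoints must include 0")
  if (r0 <= 0 || r0 >= 1) stop("r0 must lie in (0, 1)")
  set.seed(seed)
  g <- expand.grid(tech_rep = seq_len(n_tech_reps), timepoint = timepoints,
                   gene_id = half_life$gene_id, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  th <- stats::setNames(half_life$t_half, half_life$gene_id)
  rate <- r0 * 2^(-g$timepoint / th[g$gene_id])
  data.frame(gene_id = g$gene_id, timepoint = g$timepoint,
             tech_rep = g$tech_rep, t_coverage = as.integer(coverage),
             tc_count = stats::rbinom(nrow(g), coverage, rate),
             stringsAsFactors = FALSE)
}
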