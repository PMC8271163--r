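# Bound vs unbound group comparisons: half-life and expression fold change,
# via two-sided Mann-Whitney U tests with medians/quartiles and ECDFs.

#' Assign genes to Bound / Not bound groups
#'
#' Bound = the top-N head of the target ranking; Not bound = genes with zero
#' retained peaks in both replicates. Genes with peaks but outside the top-N
#' are assigned to neither group (excluded from comparisons).
#'
#' @param ranking a [rank_targets()] table.
#' @param peaks_rep1,peaks_rep2 retained peaks per replicate.
#' @param models `transcript_models` data.frame; mRNA genes define the
#'   universe.
#' @param top_n head size (defaults to the ranking's `top_n` attribute).
#' @return data.frame `gene_id`, `group` in
#'   {"Bound", "Not bound", "Unassigned"}.
#' @export
assign_groups <- function(ranking, peaks_rep1, peaks_rep2, models,
                          top_n = attr(ranking, "top_n")) {
  gene <- stats::setNames(models$gene_id, models$transcript_id)
  universe <- unique(models$gene_id[models$biotype == "mRNA"])
  bound <- ranking$gene_id[ranking$rank <= top_n]
  peaked <- unique(gene[c(peaks_rep1$transcript_id,
                          peaks_rep2$transcript_id)])
  not_bound <- setdiff(universe, union(peaked, bound))
  stopifnot(length(intersect(bound, not_bound)) == 0L)
  grp <- rep("Unassigned", length(universe))
  names(grp) <- universe
  grp[intersect(bound, universe)] <- "Bound"
  grp[not_bound] <- "Not bound"
  data.frame(gene_id = universe, group = unname(grp),
             stringsAsFactors = FALSE)
}

# two-sided Mann-Whitney U (exact when both groups are small and untied,
# normal approximation with tie correction otherwise)
mann_whitney_u <- function(x, y) {
  if (length(unique(c(x, y))) == 1L)  # fully tied: no evidence either way
    return(list(U = length(x) * length(y) / 2, p_value = 1))
  exact <- length(x) <= 8L && length(y) <= 8L
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

group_summary <- function(values, labels) {
  lapply(split(values, labels), function(v)
    list(n = length(v),
         median = stats::median(v),
         q1 = unname(stats::quantile(v, 0.25)),
         q3 = unname(stats::quantile(v, 0.75)),
         ecdf = sort(v)))
}

compare_two_groups <- function(values, labels, what) {
  stopifnot(all(labels %in% c("Bound", "Not bound")))
  x <- values[labels == "Bound"]
  y <- values[labels == "Not bound"]
  if (!length(x) || !length(y)) stop("empty group in comparison")
  mw <- mann_whitney_u(x, y)
  structure(list(what = what, summaries = group_summary(values, labels),
                 U = mw$U, p_value = mw$p_value),
            class = "group_comparison")
}

#' Compare half-lives between bound and unbound transcripts
#'
#' Two-sided Mann-Whitney U on status-ok fitted half-lives, with per-group
#' medians, quartiles and ECDF point sets.
#'
#' @param fits a [fit_decay_all()] table.
#' @param groups an [assign_groups()] table.
#' @return object of class `group_comparison`.
#' @export
compare_half_lives <- function(fits, groups) {
  d <- merge(fits[fits$status == "ok", c("gene_id", "t_half")], groups,
             by = "gene_id")
  d <- d[d$group %in% c("Bound", "Not bound"), , drop = FALSE]
  n_by <- table(d$group)
  if (length(n_by) < 2L || any(n_by < 3L))
    stop("need at least 3 ok fits per group")
  compare_two_groups(d$t_half, d$group, "t_half_min")
}

#' Compare expression log2 fold change between bound and unbound genes
#'
#' Per-gene log2((A + pc)/(B + pc)) on replicate-mean FPKM, then group
#' medians/quartiles and a two-sided Mann-Whitney U test.
#'
#' @param expression_a,expression_b expression tables (`gene_id`,
#'   `fpkm_rep1`, `fpkm_rep2`) for the two conditions (e.g. overexpression
#'   vs wild type).
#' @param groups an [assign_groups()] table.
#' @param pseudocount FPKM pseudocount (default 1) avoiding division by zero.
#' @return object of class `group_comparison` with a `log2fc` data.frame
#'   attached.
#' @export
compare_fold_change <- function(expression_a, expression_b, groups,
                                pseudocount = 1) {
  mean_fpkm <- function(e) data.frame(
    gene_id = e$gene_id, fpkm = (e$fpkm_rep1 + e$fpkm_rep2) / 2,
    stringsAsFactors = FALSE)
  m <- merge(mean_fpkm(expression_a), mean_fpkm(expression_b),
             by = "gene_id", suffixes = c("_a", "_b"))
  if (!nrow(m)) stop("no shared genes between expression tables")
  m$log2fc <- log2((m$fpkm_a + pseudocount) / (m$fpkm_b + pseudocount))
  d <- merge(m[, c("gene_id", "log2fc")], groups, by = "gene_id")
  d <- d[d$group %in% c("Bound", "Not bound"), , drop = FALSE]
  out <- compare_two_groups(d$log2fc, d$group, "log2_fold_change")
  out$log2fc <- d
  out$pseudocount <- pseudocount
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (", x$what, ")\n", sep = "")
  for (g in names(x$summaries)) {
    s <- x$summaries[[g]]
    cat(sprintf("  %-10s n = %4d  median = %8.3f  [Q1 %8.3f, Q3 %8.3f]\n",
                g, s$n, s$median, s$q1, s$q3))
  }
  cat(sprintf("  Mann-Whitney U = %g, two-sided p = %.3g\n", x$U, x$p_value))
  invisible(x)
}
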