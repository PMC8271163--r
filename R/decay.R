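# SLAM-seq half-life estimation: technical replicates are pooled at the
# count level, conversion rates normalized to t = 0, and a first-order decay
# y(t) = exp(-lambda t) fitted by nonlinear least squares (lambda >= 0); the
# log-linear regression serves only as the initializer.

#' Pool technical replicates at the count level
#'
#' Counts are summed across technical replicates BEFORE rates are computed
#' (sum-of-counts, not mean-of-rates: the pooled rate weights replicates by
#' their coverage).
#'
#' @param counts data.frame `gene_id`, `timepoint`, `tech_rep`, `t_coverage`,
#'   `tc_count`.
#' @return data.frame `gene_id`, `timepoint`, `t_coverage`, `tc_count`, with
#'   logical `missing` flagging zero pooled coverage.
#' @export
collapse_technical <- function(counts) {
  stopifnot(all(c("gene_id", "timepoint", "t_coverage", "tc_count")
                %in% names(counts)))
  dt <- data.table::as.data.table(counts)
  out <- dt[, list(t_coverage = sum(t_coverage), tc_count = sum(tc_count)),
            by = c("gene_id", "timepoint")]
  out <- as.data.frame(out)
  out$missing <- out$t_coverage == 0L
  out[order(out$gene_id, out$timepoint), ]
}

#' Conversion rates normalized to the t = 0 baseline
#'
#' rate = tc_count / t_coverage per gene and timepoint; normalized =
#' rate / rate(0). Genes with missing t = 0 or rate(0) = 0 are excluded with
#' status `insufficient` (listed in attribute `excluded`).
#'
#' @param collapsed output of [collapse_technical()].
#' @return data.frame `gene_id`, `timepoint`, `rate`, `normalized`.
#' @export
normalize_series <- function(collapsed) {
  collapsed$rate <- ifelse(collapsed$t_coverage > 0,
                           collapsed$tc_count / collapsed$t_coverage, NA_real_)
  r0 <- collapsed[collapsed$timepoint == 0, c("gene_id", "rate")]
  r0v <- stats::setNames(r0$rate, r0$gene_id)
  genes <- unique(collapsed$gene_id)
  bad <- genes[!genes %in% names(r0v) | is.na(r0v[genes]) | r0v[genes] == 0]
  out <- collapsed[!collapsed$gene_id %in% bad, , drop = FALSE]
  out$normalized <- out$rate / r0v[out$gene_id]
  out <- out[order(out$gene_id, out$timepoint),
             c("gene_id", "timepoint", "rate", "normalized")]
  rownames(out) <- NULL
  attr(out, "excluded") <- data.frame(gene_id = bad,
                                      status = rep("insufficient",
                                                   length(bad)),
                                      stringsAsFactors = FALSE)
  out
}

#' Fit a first-order decay to one normalized series
#'
#' Least-squares fit of y(t) = exp(-lambda t) with lambda >= 0, initialized
#' from the log-linear regression of ln(y) on t over y > 0 points;
#' t_half = ln(2)/lambda. lambda at the zero boundary is reported as status
#' `degenerate` (infinite half-life), never as a numeric t_half.
#'
#' @param timepoints chase times (minutes).
#' @param normalized normalized conversion rates (1 at t = 0).
#' @return list `lambda`, `t_half`, `rss`, `n_points`,
#'   `status` in ok / no_converge / insufficient / degenerate.
#' @export
fit_decay <- function(timepoints, normalized) {
  ok <- is.finite(timepoints) & is.finite(normalized)
  t <- timepoints[ok]; y <- normalized[ok]
  res <- list(lambda = NA_real_, t_half = NA_real_, rss = NA_real_,
              n_points = length(t), status = "insufficient")
  if (length(t) < 4L || !0 %in% t) return(res)
  pos <- y > 0
  lambda0 <- if (sum(pos) >= 2L) {
    sl <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))[2]
    max(-sl, 1e-8)
  } else 1e-3
  lambda <- tryCatch({
    fit <- stats::nls(y ~ exp(-lambda * t),
                      start = list(lambda = lambda0),
                      algorithm = "port", lower = 0,
                      control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                                   warnOnly = FALSE))
    unname(stats::coef(fit))
  }, error = function(e) NULL)
  if (is.null(lambda)) {
    # profile the 1-D least-squares objective directly
    rss_fun <- function(l) sum((y - exp(-l * t))^2)
    opt <- tryCatch(stats::optimize(rss_fun, c(0, 1), tol = 1e-12),
                    error = function(e) NULL)
    if (is.null(opt)) { res$status <- "no_converge"; return(res) }
    lambda <- opt$minimum
  }
  res$lambda <- lambda
  res$rss <- sum((y - exp(-lambda * t))^2)
  if (lambda < 1e-7) {  # t_half > ~13 years of minutes: no measurable decay
    res$lambda <- 0
    res$status <- "degenerate"
  } else {
    res$t_half <- log(2) / lambda
    res$status <- "ok"
  }
  res
}

#' Fit first-order decays for every gene in a normalized table
#'
#' @param normalized output of [normalize_series()].
#' @return data.frame `gene_id`, `lambda`, `t_half`, `rss`, `n_points`,
#'   `status` (excluded genes appear with status `insufficient`).
#' @export
fit_decay_all <- function(normalized) {
  by_gene <- split(normalized, normalized$gene_id)
  rows <- lapply(names(by_gene), function(g) {
    f <- fit_decay(by_gene[[g]]$timepoint, by_gene[[g]]$normalized)
    data.frame(gene_id = g, lambda = f$lambda, t_half = f$t_half,
               rss = f$rss, n_points = f$n_points, status = f$status,
               stringsAsFactors = FALSE)
  })
  excl <- attr(normalized, "excluded")
  out <- do.call(rbind, c(rows, list(
    if (!is.null(excl) && nrow(excl))
      data.frame(gene_id = excl$gene_id, lambda = NA_real_,
                 t_half = NA_real_, rss = NA_real_, n_points = 0L,
                 status = "insufficient", stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' Median decay curves with interquartile bands
#'
#' Pointwise median, first and third quartile of the normalized conversion
#' rates at each timepoint, per group, plus the group median half-life over
#' status-ok fits.
#'
#' @param normalized output of [normalize_series()].
#' @param fits output of [fit_decay_all()].
#' @param groups optional data.frame `gene_id`, `group`; all genes form one
#'   group when omitted.
#' @return list with `curves` (data.frame `group`, `timepoint`, `median`,
#'   `q1`, `q3`, `n`) and `half_life` (data.frame `group`, `median_t_half`,
#'   `n`).
#' @export
median_decay_curve <- function(normalized, fits, groups = NULL) {
  if (is.null(groups))
    groups <- data.frame(gene_id = unique(normalized$gene_id), group = "all",
                         stringsAsFactors = FALSE)
  nm <- merge(normalized, groups, by = "gene_id")
  if (!nrow(nm)) stop("no genes in common between series and groups")
  grp_sizes <- tapply(nm$gene_id, nm$group, function(x) length(unique(x)))
  if (any(grp_sizes < 3L)) stop("each group needs at least 3 series")
  agg <- do.call(rbind, lapply(split(nm, list(nm$group, nm$timepoint),
                                     drop = TRUE), function(d) {
    q <- stats::quantile(d$normalized, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(group = d$group[1], timepoint = d$timepoint[1],
               median = unname(q[2]), q1 = unname(q[1]), q3 = unname(q[3]),
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$group, agg$timepoint), ]
  rownames(agg) <- NULL
  fm <- merge(fits[fits$status == "ok", ], groups, by = "gene_id")
  hl <- do.call(rbind, lapply(split(fm, fm$group), function(d)
    data.frame(group = d$group[1], median_t_half = stats::median(d$t_half),
               n = nrow(d), stringsAsFactors = FALSE)))
  rownames(hl) <- NULL
  list(curves = agg, half_life = hl)
}
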