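#' @title Cross-cell-type meta-analysis
#' @description Fisher's-method combination of per-cell-type association
#'   p-values (chi-square with 2k degrees of freedom, evaluated in log space
#'   so that extreme p-values do not underflow), Benjamini-Hochberg FDR,
#'   ranked meta tables, top-k overlaps, Braak-stage group contrasts and a
#'   hierarchical-clustering sanity check.
#' @name meta
NULL

#' Combine p-values by Fisher's method
#'
#' `chi_sq = -2 * sum(log(p))` referred to a chi-square distribution with
#' `2k` degrees of freedom. The survival probability is computed in log
#' space, so combined p-values far below the double underflow threshold are
#' still resolved via the `log_p` element. Component p-values of zero (or
#' below `floor`) are clamped to `floor` with a warning.
#'
#' @param p_values Numeric vector of k p-values in (0, 1\].
#' @param floor Lower clamp for component p-values (default 1e-300).
#' @return A list: `chi_sq`, `df` (= 2k), `p_combined`, `log_p` (natural log
#'   of the combined p).
#' @export
fisher_combine <- function(p_values, floor = 1e-300) {
  k <- length(p_values)
  if (k < 1L) abort_contract("fisher_combine needs at least one p-value")
  if (any(is.na(p_values)) || any(p_values > 1))
    abort_contract("p-values must be in (0, 1]")
  if (any(p_values < floor)) {
    warning(sprintf("%d p-value(s) below the floor %g were clamped",
                    sum(p_values < floor), floor))
    p_values <- pmax(p_values, floor)
  }
  chi_sq <- -2 * sum(log(p_values))
  log_p <- stats::pchisq(chi_sq, df = 2 * k, lower.tail = FALSE, log.p = TRUE)
  list(chi_sq = chi_sq, df = 2L * k,
       p_combined = max(exp(log_p), .Machine$double.xmin),
       log_p = log_p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1 and
#' mapped back to the input order. `m` defaults to the vector length but may
#' be set larger when the supplied p-values are a slice of a bigger family.
#'
#' @param p Vector of p-values in (0, 1\].
#' @param m Multiple-testing denominator (default `length(p)`).
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(p, m = length(p)) {
  if (length(p) == 0L) abort_contract("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    abort_contract("p-values must be in (0, 1]")
  if (m == length(p)) return(stats::p.adjust(p, method = "BH"))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / seq(length(p), 1) * p[o]))[ro]
}

#' Combine neuron and glia association tables into a meta-analysis
#'
#' Per probe shared by both tables, combines the two predictor p-values by
#' Fisher's method (4 df), attaches BH FDR over all combined probes, and
#' ranks by ascending combined p (ties broken by probe id). Probes present
#' in only one table are excluded with a message.
#'
#' @param neuron,glia Ranked result tables from [run_ewas()] (or any table
#'   with `probe_id` and `p` columns).
#' @param floor Component p-value clamp passed to the combination.
#' @return A ranked `data.frame`: probe_id, p_neuron, p_glia, chi_sq, df,
#'   p_combined, log_p, fdr_q, rank.
#' @export
combine_cell_types <- function(neuron, glia, floor = 1e-300) {
  shared <- intersect(neuron$probe_id, glia$probe_id)
  dropped <- length(neuron$probe_id) + length(glia$probe_id) - 2 * length(shared)
  if (dropped > 0L)
    message(sprintf("%d probe(s) present in only one cell type were excluded",
                    dropped))
  if (length(shared) == 0L) abort_contract("no shared probes to combine")
  pn <- neuron$p[match(shared, neuron$probe_id)]
  pg <- glia$p[match(shared, glia$probe_id)]
  n_clamped <- sum(pn < floor) + sum(pg < floor)
  if (n_clamped > 0L)
    warning(sprintf("%d component p-value(s) clamped to the floor %g",
                    n_clamped, floor))
  pn_c <- pmax(pn, floor); pg_c <- pmax(pg, floor)
  chi_sq <- -2 * (log(pn_c) + log(pg_c))
  log_p <- stats::pchisq(chi_sq, df = 4, lower.tail = FALSE, log.p = TRUE)
  p_combined <- pmax(exp(log_p), .Machine$double.xmin)
  tab <- data.frame(probe_id = shared, p_neuron = pn, p_glia = pg,
                    chi_sq = chi_sq, df = 4L, p_combined = p_combined,
                    log_p = log_p, stringsAsFactors = FALSE, row.names = NULL)
  tab$fdr_q <- bh_fdr(tab$p_combined)
  ord <- order(tab$log_p, tab$probe_id)
  tab$rank <- integer(nrow(tab))
  tab$rank[ord] <- seq_len(nrow(tab))
  tab[ord, , drop = FALSE]
}

#' Overlap of the top-k probes of two ranked tables
#'
#' @param table_a,table_b Ranked result tables (must carry `probe_id` and
#'   `rank`).
#' @param k Number of top-ranked probes to compare (default 1000).
#' @return A list: `n_overlap`, `n_only_a`, `n_only_b`, and the shared ids.
#' @export
top_k_overlap <- function(table_a, table_b, k = 1000L) {
  if (k > nrow(table_a) || k > nrow(table_b))
    abort_contract("k exceeds table size")
  top <- function(tab) tab$probe_id[order(tab$rank)][seq_len(k)]
  a <- top(table_a); b <- top(table_b)
  shared <- intersect(a, b)
  list(n_overlap = length(shared), n_only_a = k - length(shared),
       n_only_b = k - length(shared), shared = shared)
}

#' Braak stage grouping
#'
#' The conventional three-group partition of Braak stages: low (0-II),
#' medium (III-IV), high (V-VI).
#'
#' @param low,mid,high Integer stage sets forming a partition of 0-6.
#' @return A named list of stage vectors.
#' @export
braak_grouping <- function(low = 0:2, mid = 3:4, high = 5:6) {
  if (!setequal(c(low, mid, high), 0:6) ||
      length(c(low, mid, high)) != 7L)
    abort_config("low/mid/high must partition stages 0..6")
  list(low = low, mid = mid, high = high)
}

#' Mean beta per Braak group and pairwise group deltas
#'
#' @param beta Beta matrix.
#' @param sheet Sample sheet.
#' @param probes Probe ids to summarize.
#' @param grouping A [braak_grouping()].
#' @return A `data.frame` per probe: mean_low, mean_mid, mean_high,
#'   delta_high_low, delta_mid_low.
#' @export
braak_group_deltas <- function(beta, sheet, probes,
                               grouping = braak_grouping()) {
  idx <- match(colnames(beta), sheet$sample_id)
  if (anyNA(idx)) abort_contract("sheet does not cover all beta columns")
  sheet <- sheet[idx, , drop = FALSE]
  grp <- lapply(grouping, function(st) which(sheet$braak %in% st))
  if (any(lengths(grp) == 0L)) abort_contract("a Braak group is empty")
  B <- beta[probes, , drop = FALSE]
  mlow <- rowMeans(B[, grp$low, drop = FALSE])
  mmid <- rowMeans(B[, grp$mid, drop = FALSE])
  mhigh <- rowMeans(B[, grp$high, drop = FALSE])
  data.frame(probe_id = probes, mean_low = mlow, mean_mid = mmid,
             mean_high = mhigh, delta_high_low = mhigh - mlow,
             delta_mid_low = mmid - mlow,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hierarchical-clustering sanity check on a probe subset
#'
#' Average-linkage agglomerative clustering of samples on Euclidean distance
#' over the given probes (the classical dendrogram check that top markers
#' split the cell fractions). Reports whether the two-cluster cut separates
#' neuron from glia samples perfectly; identical samples yield a degenerate
#' tree reported as inconclusive.
#'
#' @param beta Beta matrix restricted (or restrictable) to the probe set.
#' @param sheet Sample sheet.
#' @param probes Optional probe ids (default: all rows of `beta`).
#' @return A list: `hclust` (the tree), `clusters` (two-cut labels),
#'   `perfect_split` (TRUE/FALSE/NA), `inconclusive`.
#' @export
hierarchical_cluster_check <- function(beta, sheet, probes = rownames(beta)) {
  if (length(probes) < 2L) abort_contract("need at least 2 probes")
  if (ncol(beta) < 4L) abort_contract("need at least 4 samples")
  idx <- match(colnames(beta), sheet$sample_id)
  if (anyNA(idx)) abort_contract("sheet does not cover all beta columns")
  sheet <- sheet[idx, , drop = FALSE]
  d <- stats::dist(t(beta[probes, , drop = FALSE]))
  if (max(d) < 1e-12) {
    return(list(hclust = NULL, clusters = NULL, perfect_split = NA,
                inconclusive = TRUE))
  }
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = 2L)
  frac <- sheet$cell_fraction
  perfect <- length(unique(frac)) == 2L &&
    all(tapply(frac, cl, function(x) length(unique(x)) == 1L)) &&
    length(unique(tapply(frac, cl, function(x) x[1L]))) == 2L
  list(hclust = hc, clusters = cl, perfect_split = perfect,
       inconclusive = FALSE)
}
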