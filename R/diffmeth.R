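#' @title Per-probe differential methylation tests
#' @description Neuron-versus-glia Welch t-tests with effect-size and
#'   Bonferroni filtering for cell-type marker calling, and per-probe ordinary
#'   least squares of beta values on age or Braak stage with sex and
#'   leading-principal-component adjustment, run separately within each cell
#'   fraction.
#' @name diffmeth
NULL

attach_adjustment <- function(tab) {
  m <- nrow(tab)
  tab$bonferroni_p <- pmin(1, tab$p * m)
  tab$fdr_q <- bh_fdr(tab$p)
  ord <- order(tab$p, tab$probe_id)              # ties broken by probe_id
  tab$rank <- integer(m)
  tab$rank[ord] <- seq_len(m)
  tab[ord, , drop = FALSE]
}

#' Neuron-versus-glia t-test per probe
#'
#' Two-sided two-sample t-test of every probe between the neuron and glia
#' fractions, by default restricted to control samples and using the Welch
#' unequal-variance statistic (`pooled = TRUE` gives the classical pooled
#' test). Effect is mean(neuron) - mean(glia). Probes with zero variance in
#' both groups and zero mean difference get t = 0, p = 1; p-values are
#' Bonferroni- and BH-adjusted over the tested probes and ranked ascending.
#'
#' @param beta Beta matrix covering both fractions.
#' @param sheet Sample sheet for the columns of `beta`.
#' @param controls_only Restrict to `diagnosis == "control"` (default TRUE).
#' @param pooled Use the pooled-variance t instead of Welch (default FALSE).
#' @return A ranked `data.frame`: probe_id, effect, se, statistic, df, p,
#'   bonferroni_p, fdr_q, rank.
#' @export
celltype_ttest <- function(beta, sheet, controls_only = TRUE, pooled = FALSE) {
  idx <- match(colnames(beta), sheet$sample_id)
  if (anyNA(idx)) abort_contract("sheet does not cover all beta columns")
  sheet <- sheet[idx, , drop = FALSE]
  use <- if (controls_only) sheet$diagnosis == "control" else rep(TRUE, nrow(sheet))
  gn <- use & sheet$cell_fraction == "neuron"
  gg <- use & sheet$cell_fraction == "glia"
  if (sum(gn) < 2L || sum(gg) < 2L)
    abort_contract("need >= 2 samples per cell fraction (after any control filter)")
  xn <- beta[, gn, drop = FALSE]
  xg <- beta[, gg, drop = FALSE]
  n1 <- ncol(xn); n2 <- ncol(xg)
  m1 <- rowMeans(xn); m2 <- rowMeans(xg)
  v1 <- rowSums((xn - m1)^2) / (n1 - 1)
  v2 <- rowSums((xg - m2)^2) / (n2 - 1)
  effect <- m1 - m2
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(effect))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))  # Welch-Satterthwaite
  }
  tstat <- effect / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se == 0
  tstat[degenerate & effect == 0] <- 0
  p[degenerate & effect == 0] <- 1
  df[degenerate] <- n1 + n2 - 2
  p[degenerate & effect != 0] <- .Machine$double.xmin
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  tab <- data.frame(probe_id = rownames(beta), effect = effect, se = se,
                    statistic = tstat, df = df, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attach_adjustment(tab)
}

#' Call cell-type differentially methylated CpGs
#'
#' Applies the marker definition: autosomal probes with Bonferroni-adjusted
#' p below `alpha` and an absolute mean beta difference of at least
#' `delta_min` (20% methylation). Each call is labeled hyper- or
#' hypomethylated in neurons by the sign of the effect.
#'
#' @param results Ranked table from [celltype_ttest()].
#' @param annotation Probe annotation covering every tested probe.
#' @param delta_min Minimum |mean(neuron) - mean(glia)| (default 0.20).
#' @param alpha Bonferroni significance level (default 0.05).
#' @return Subset of `results` with added `chromosome` and `direction`
#'   ("hyper"/"hypo" in neurons) columns.
#' @export
call_ct_dmcgs <- function(results, annotation, delta_min = 0.20, alpha = 0.05) {
  idx <- match(results$probe_id, annotation$probe_id)
  if (anyNA(idx))
    abort_contract("annotation is missing tested probe(s)")
  keep <- annotation$autosomal[idx] &
    results$bonferroni_p < alpha &
    abs(results$effect) >= delta_min
  out <- results[keep, , drop = FALSE]
  out$chromosome <- annotation$chromosome[idx][keep]
  out$direction <- ifelse(out$effect > 0, "hyper", "hypo")
  out
}

#' Regression specification for a per-probe association analysis
#'
#' @param predictor "age" or "braak" — the term whose coefficient and p-value
#'   populate the result table.
#' @param covariates Subset of "age", "braak", "sex", "pc1" to adjust for;
#'   must not contain the predictor. Sex enters as female = 0, male = 1;
#'   Braak as a numeric 0-6 score.
#' @param fraction Cell fraction to analyze: "neuron", "glia" or "bulk".
#' @param diagnosis Sample subset: "control", "AD" or "all" (default "all"
#'   for the Braak predictor, "control" for age).
#' @return A `ctewas_regression_spec` object.
#' @export
regression_spec <- function(predictor = c("age", "braak"),
                            covariates = NULL,
                            fraction = c("neuron", "glia", "bulk"),
                            diagnosis = NULL) {
  predictor <- match.arg(predictor)
  fraction <- match.arg(fraction)
  if (is.null(covariates))
    covariates <- setdiff(c("braak", "age", "sex", "pc1"), predictor)
  if (is.null(diagnosis))
    diagnosis <- if (predictor == "age") "control" else "all"
  bad <- setdiff(covariates, c("age", "braak", "sex", "pc1"))
  if (length(bad) > 0L)
    abort_config(sprintf("unknown covariate(s): %s", paste(bad, collapse = ", ")))
  if (predictor %in% covariates)
    abort_config("predictor must not appear among the covariates")
  if (!diagnosis %in% c("control", "AD", "all"))
    abort_config("diagnosis must be 'control', 'AD' or 'all'")
  structure(list(predictor = predictor, covariates = covariates,
                 fraction = fraction, diagnosis = diagnosis),
            class = "ctewas_regression_spec")
}

# Numeric design matrix (with intercept) for a sample-sheet subset.
build_design_matrix <- function(sheet, pcs, terms) {
  cols <- lapply(terms, function(v) {
    switch(v,
      age   = sheet$age,
      braak = as.numeric(sheet$braak),
      sex   = as.numeric(sheet$sex == "male"),
      pc1   = {
        if (is.null(pcs)) abort_contract("spec uses pc1 but no PC scores supplied")
        i <- match(sheet$sample_id, rownames(pcs$scores))
        if (anyNA(i)) abort_contract("PC scores do not cover the analysis subset")
        pcs$scores[i, 1L]
      })
  })
  X <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  colnames(X) <- c("(Intercept)", terms)
  X
}

#' Ordinary least squares for one probe
#'
#' Fits `y ~ X` by OLS and returns per-term coefficients, standard errors,
#' t statistics and two-sided p-values on n - k residual degrees of freedom.
#'
#' @param y Numeric response (beta values of one probe).
#' @param X Design matrix including the intercept column.
#' @return A `data.frame` (term, estimate, se, statistic, p) with the
#'   residual df as attribute `df`.
#' @export
fit_cpg_regression <- function(y, X) {
  n <- length(y); k <- ncol(X)
  if (n != nrow(X)) abort_contract("length(y) must match nrow(X)")
  if (n < k + 2L) abort_contract("need n >= number of terms + 2")
  if (qr(X)$rank < k) abort_contract("design matrix is rank-deficient")
  XtXinv <- solve(crossprod(X))
  coef <- XtXinv %*% crossprod(X, y)
  res <- y - X %*% coef
  df <- n - k
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(XtXinv))
  tstat <- coef / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  out <- data.frame(term = colnames(X), estimate = as.numeric(coef),
                    se = se, statistic = as.numeric(tstat),
                    p = as.numeric(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "df") <- df
  out
}

# Vectorized OLS across all probes sharing one design matrix.
fit_all_probes <- function(Y, X, term) {
  n <- ncol(Y); k <- ncol(X)
  if (qr(X)$rank < k) abort_contract("design matrix is rank-deficient")
  XtXinv <- solve(crossprod(X))
  H <- X %*% XtXinv                    # n x k
  B <- Y %*% H                         # probes x k coefficients
  fitted <- B %*% t(X)
  rss <- rowSums((Y - fitted)^2)
  df <- n - k
  sigma2 <- rss / df
  j <- match(term, colnames(X))
  se <- sqrt(sigma2 * XtXinv[j, j])
  est <- B[, j]
  tstat <- est / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  zero_var <- rowSums((Y - rowMeans(Y))^2) < 1e-24
  p[zero_var] <- 1; tstat[zero_var] <- 0; est[zero_var] <- 0
  se[zero_var] <- NA_real_
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(probe_id = rownames(Y), effect = est, se = se,
             statistic = tstat, df = df, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Epigenome-wide association scan within one cell fraction
#'
#' Fits the covariate-adjusted linear model per probe (beta ~ predictor +
#' covariates) within the specified cell fraction and diagnosis subset, then
#' attaches Bonferroni and BH adjustment over the tested probes and ranks by
#' ascending predictor p-value (ties broken by probe id). Probes with zero
#' variance in the subset keep p = 1 rather than being dropped, preserving
#' the multiple-testing denominator.
#'
#' @param beta Beta matrix.
#' @param sheet Sample sheet for the columns of `beta`.
#' @param pcs Optional `ctewas_pcs` scores (required when the spec adjusts
#'   for pc1).
#' @param spec A [regression_spec()].
#' @return A ranked `data.frame` with the same layout as [celltype_ttest()].
#' @export
run_ewas <- function(beta, sheet, pcs = NULL, spec) {
  stopifnot(inherits(spec, "ctewas_regression_spec"))
  idx <- match(colnames(beta), sheet$sample_id)
  if (anyNA(idx)) abort_contract("sheet does not cover all beta columns")
  sheet <- sheet[idx, , drop = FALSE]
  use <- sheet$cell_fraction == spec$fraction
  if (spec$diagnosis != "all") use <- use & sheet$diagnosis == spec$diagnosis
  if (!any(use)) abort_contract("sample filter leaves an empty subset")
  sub <- sheet[use, , drop = FALSE]
  Y <- beta[, use, drop = FALSE]
  X <- build_design_matrix(sub, pcs, c(spec$predictor, spec$covariates))
  tab <- fit_all_probes(Y, X, spec$predictor)
  attach_adjustment(tab)
}

#' Label probes by methylation direction between extreme sample groups
#'
#' Mode "aging": contrasts the `n_extreme` youngest against the oldest
#' samples. Mode "braak": contrasts the youngest controls against the oldest
#' samples of the highest Braak stage present. If fewer than `n_extreme`
#' samples are available in a group, all available are used with a message.
#'
#' @param beta Beta matrix.
#' @param sheet Sample sheet.
#' @param probes Probe ids to label.
#' @param mode "aging" or "braak".
#' @param n_extreme Target extreme-group size (default 8).
#' @return A `data.frame` (probe_id, delta, direction) with direction
#'   "hyper", "hypo" or "unchanged" (change from the young/low to the
#'   old/high group).
#' @export
classify_direction <- function(beta, sheet, probes,
                               mode = c("aging", "braak"), n_extreme = 8L) {
  mode <- match.arg(mode)
  idx <- match(colnames(beta), sheet$sample_id)
  if (anyNA(idx)) abort_contract("sheet does not cover all beta columns")
  sheet <- sheet[idx, , drop = FALSE]
  if (mode == "aging") {
    lo_pool <- hi_pool <- seq_len(nrow(sheet))
  } else {
    lo_pool <- which(sheet$diagnosis == "control")
    hi_pool <- which(sheet$braak == max(sheet$braak))
  }
  if (length(lo_pool) == 0L || length(hi_pool) == 0L)
    abort_contract("an extreme group is empty")
  take <- function(pool, decreasing) {
    k <- min(n_extreme, length(pool))
    if (k < n_extreme)
      message(sprintf("extreme group has only %d sample(s); using all", k))
    pool[order(sheet$age[pool], decreasing = decreasing)][seq_len(k)]
  }
  young <- take(lo_pool, decreasing = FALSE)
  old <- take(hi_pool, decreasing = TRUE)
  B <- beta[probes, , drop = FALSE]
  delta <- rowMeans(B[, old, drop = FALSE]) - rowMeans(B[, young, drop = FALSE])
  data.frame(probe_id = probes, delta = delta,
             direction = ifelse(delta > 0, "hyper",
                                ifelse(delta < 0, "hypo", "unchanged")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genomic-region distribution of a probe set versus its background
#'
#' Tallies a probe set across region classes and relates the set's class
#' fractions to those of the background (e.g. all tested probes, i.e. the
#' array design).
#'
#' @param probes Probe ids in the set.
#' @param annotation Probe annotation.
#' @param background Probe ids of the background (default: all annotated
#'   probes).
#' @return A `data.frame` (region, n_set, frac_set, frac_background, ratio).
#' @export
region_distribution <- function(probes, annotation,
                                background = annotation$probe_id) {
  reg_set <- annotation$region[match(probes, annotation$probe_id)]
  reg_bg <- annotation$region[match(background, annotation$probe_id)]
  if (anyNA(reg_set) || anyNA(reg_bg))
    abort_contract("annotation is missing probe(s)")
  lev <- .REGIONS
  n_set <- as.integer(table(factor(reg_set, levels = lev)))
  n_bg <- as.integer(table(factor(reg_bg, levels = lev)))
  frac_set <- n_set / length(reg_set)
  frac_bg <- n_bg / length(reg_bg)
  data.frame(region = lev, n_set = n_set, frac_set = frac_set,
             frac_background = frac_bg,
             ratio = ifelse(frac_bg > 0, frac_set / frac_bg, NA_real_),
             stringsAsFactors = FALSE)
}
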