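#' @title Probe filtering, normalization and principal components
#' @description Detection-p probe filtering, between-array quantile
#'   normalization, and PCA of the probe-centered beta matrix. The leading
#'   principal component serves as the technical batch covariate in the
#'   per-probe regression model.
#' @name preprocess
NULL

#' Filter probes by detection p-value
#'
#' Retains exactly the probes whose detection p-value is at or below
#' `threshold` in every sample, the standard array QC rule.
#'
#' @param beta Beta matrix (probes x samples).
#' @param detection_p Matrix of detection p-values, same shape and dimnames.
#' @param threshold Maximum tolerated detection p (default 0.01).
#' @return The filtered beta matrix.
#' @export
filter_probes_by_detection <- function(beta, detection_p, threshold = 0.01) {
  if (!identical(dim(beta), dim(detection_p)))
    abort_contract("beta and detection_p must have identical shape")
  keep <- rowSums(detection_p > threshold) == 0L
  beta[keep, , drop = FALSE]
}

#' Quantile-normalize a beta matrix
#'
#' Forces every column (sample) onto the common distribution whose sorted
#' values are the per-rank means across columns; ties are resolved by
#' average rank. Idempotent, and column means are equal afterwards.
#'
#' @param beta Beta matrix without missing values (drop incomplete probes
#'   first).
#' @return The normalized matrix with the original dimnames.
#' @export
quantile_normalize <- function(beta) {
  validate_beta_matrix(beta)
  if (anyNA(beta))
    abort_contract("quantile_normalize requires a missing-free matrix; drop incomplete probes first")
  out <- limma::normalizeQuantiles(beta, ties = TRUE)
  dimnames(out) <- dimnames(beta)
  out
}

#' Principal components of a beta matrix
#'
#' PCA of the probe-centered matrix: samples are scored on the top
#' `n_components` components. The sign of each component is fixed by forcing
#' its largest-magnitude probe loading to be positive, so scores are
#' reproducible across runs.
#'
#' @param beta Missing-free beta matrix (probes x samples), >= 2 samples.
#' @param n_components Number of components to keep (at most
#'   `ncol(beta) - 1`).
#' @return An object of class `ctewas_pcs`: list with `scores` (samples x
#'   components, centered), `explained_variance` (fractions), and `loadings`.
#' @export
compute_principal_components <- function(beta, n_components = 10L) {
  if (ncol(beta) < 2L) abort_contract("PCA requires >= 2 samples")
  if (anyNA(beta)) abort_contract("PCA requires a missing-free matrix")
  max_k <- ncol(beta) - 1L
  if (n_components > max_k)
    abort_contract(sprintf("n_components (%d) exceeds n_samples - 1 (%d)",
                           n_components, max_k))
  pc <- stats::prcomp(t(beta), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {       # deterministic sign convention
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores,
                 explained_variance = ev[seq_len(k)],
                 loadings = loadings),
            class = "ctewas_pcs")
}

#' @export
print.ctewas_pcs <- function(x, ...) {
  cat(sprintf("ctewas principal components: %d samples x %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  explained variance:",
      paste(sprintf("%.3f", x$explained_variance), collapse = " "), "\n")
  invisible(x)
}

#' Associate principal components with sample covariates
#'
#' For each kept component and each covariate: Pearson correlation test for
#' continuous covariates (age, Braak stage treated as numeric), one-way
#' ANOVA F-test for categoricals (sex, batch, cell fraction, diagnosis,
#' cohort). Covariates with a single level are skipped with a warning.
#'
#' @param pcs A `ctewas_pcs` object.
#' @param sheet Sample sheet aligned to the score rows by `sample_id`.
#' @return A `data.frame` (pc, covariate, type, statistic, p), ordered by
#'   ascending p within each component.
#' @export
correlate_pcs_with_covariates <- function(pcs, sheet) {
  stopifnot(inherits(pcs, "ctewas_pcs"))
  idx <- match(rownames(pcs$scores), sheet$sample_id)
  if (anyNA(idx))
    abort_contract("sample sheet does not cover all scored samples")
  sheet <- sheet[idx, , drop = FALSE]
  continuous <- c("age", "braak")
  categorical <- intersect(c("cell_fraction", "sex", "batch", "diagnosis",
                             "cohort"), colnames(sheet))
  usable <- function(v) {
    ok <- length(unique(sheet[[v]])) >= 2L
    if (!ok) warning(sprintf("covariate '%s' has a single level; skipped", v))
    ok
  }
  continuous <- Filter(usable, continuous)
  categorical <- Filter(usable, categorical)
  rows <- list()
  for (j in seq_len(ncol(pcs$scores))) {
    pc_name <- colnames(pcs$scores)[j]
    s <- pcs$scores[, j]
    for (v in continuous) {
      ct <- stats::cor.test(s, as.numeric(sheet[[v]]))
      rows[[length(rows) + 1L]] <- data.frame(
        pc = pc_name, covariate = v, type = "continuous",
        statistic = unname(ct$estimate), p = ct$p.value)
    }
    for (v in categorical) {
      fit <- stats::aov(s ~ factor(sheet[[v]]))
      tab <- summary(fit)[[1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        pc = pc_name, covariate = v, type = "categorical",
        statistic = tab[["F value"]][1L], p = tab[["Pr(>F)"]][1L])
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$pc, colnames(pcs$scores)), out$p), ]
  rownames(out) <- NULL
  out
}

#' Put the batch-associated principal component first
#'
#' The regression model adjusts for the leading component because it tracks
#' technical batch structure; that association is verified, not assumed.
#' This helper reorders the score matrix so the component most strongly
#' associated with `batch` (smallest ANOVA p) comes first, leaving the
#' remaining columns in their original order. When batch has a single level
#' the scores are returned unchanged.
#'
#' @param pcs A `ctewas_pcs` object.
#' @param sheet Sample sheet aligned by `sample_id`.
#' @return A `ctewas_pcs` object with reordered columns.
#' @export
pick_batch_component <- function(pcs, sheet) {
  assoc <- suppressWarnings(correlate_pcs_with_covariates(pcs, sheet))
  assoc <- assoc[assoc$covariate == "batch", , drop = FALSE]
  if (nrow(assoc) == 0L) return(pcs)
  best <- assoc$pc[which.min(assoc$p)]
  j <- match(best, colnames(pcs$scores))
  ord <- c(j, setdiff(seq_len(ncol(pcs$scores)), j))
  out <- pcs
  out$scores <- pcs$scores[, ord, drop = FALSE]
  out$loadings <- pcs$loadings[, ord, drop = FALSE]
  out$explained_variance <- pcs$explained_variance[ord]
  out
}
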