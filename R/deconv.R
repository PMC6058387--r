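#' @title Reference-based cell-proportion deconvolution
#' @description Estimates the neuronal proportion of bulk samples by
#'   constrained projection onto neuron/glia reference methylation profiles:
#'   least squares with nonnegative weights summing to at most one, the
#'   classical surrogate-proportion construction for methylation mixtures.
#'   Includes the reference-age bias experiment: marker CpGs with
#'   cell-type-specific aging dynamics make proportion estimates depend
#'   systematically on the age of the reference cohort.
#' @name deconvolution
NULL

#' Select reference marker probes from a sorted cohort
#'
#' Runs the neuron-versus-glia t-test on control samples and keeps the `k`
#' probes with the smallest p-values (ties broken by probe id). The panel
#' stores per-cell-type mean betas over the control samples. With
#' `balanced = TRUE`, half the markers are taken from each effect direction
#' (neuron-hyper / neuron-hypo).
#'
#' @param beta Sorted-cohort beta matrix.
#' @param sheet Sample sheet.
#' @param k Number of markers (default 600).
#' @param balanced Balance marker directions (default FALSE: raw p ranking).
#' @return A `ctewas_panel`: list with `markers`, `reference` (markers x 2
#'   matrix, columns neuron/glia), `ttest` (the ranked marker rows) and
#'   `metadata` (n per fraction, age range of the reference samples).
#' @export
select_reference_markers <- function(beta, sheet, k = 600L, balanced = FALSE) {
  res <- celltype_ttest(beta, sheet, controls_only = TRUE)
  if (k > nrow(res)) abort_contract("k exceeds the number of tested probes")
  res <- res[order(res$rank), , drop = FALSE]
  if (balanced) {
    hyper <- res[res$effect > 0, , drop = FALSE]
    hypo <- res[res$effect <= 0, , drop = FALSE]
    k2 <- k %/% 2L
    chosen <- rbind(hyper[seq_len(min(k2, nrow(hyper))), ],
                    hypo[seq_len(min(k - k2, nrow(hypo))), ])
  } else {
    chosen <- res[seq_len(k), , drop = FALSE]
  }
  markers <- chosen$probe_id
  idx <- match(colnames(beta), sheet$sample_id)
  sub <- sheet[idx, , drop = FALSE]
  ctrl <- sub$diagnosis == "control"
  ref <- cbind(
    neuron = rowMeans(beta[markers, ctrl & sub$cell_fraction == "neuron",
                           drop = FALSE]),
    glia   = rowMeans(beta[markers, ctrl & sub$cell_fraction == "glia",
                           drop = FALSE]))
  structure(list(
    markers = markers, reference = ref, ttest = chosen,
    metadata = list(
      n_neuron = sum(ctrl & sub$cell_fraction == "neuron"),
      n_glia = sum(ctrl & sub$cell_fraction == "glia"),
      age_range = range(sub$age[ctrl]))
  ), class = "ctewas_panel")
}

#' @export
print.ctewas_panel <- function(x, ...) {
  cat(sprintf("ctewas reference panel: %d markers, %d neuron / %d glia controls, ages %.0f-%.0f\n",
              length(x$markers), x$metadata$n_neuron, x$metadata$n_glia,
              x$metadata$age_range[1L], x$metadata$age_range[2L]))
  invisible(x)
}

# Exact solver for min ||b - R w||^2 s.t. w >= 0, sum(w) <= 1, for a small
# number of cell types: enumerates every active set (zeroed weights x
# sum-constraint active) and returns the feasible candidate with the smallest
# residual, which is the global optimum of this convex program.
solve_mixture <- function(b, R, tol = 1e-9) {
  K <- ncol(R)
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^K - 1L)) {
    free <- which(bitwAnd(mask, 2^(seq_len(K) - 1L)) == 0L)
    for (sum_active in c(FALSE, TRUE)) {
      nf <- length(free)
      if (nf == 0L) {
        if (sum_active) next
        w <- numeric(K)
      } else {
        Rf <- R[, free, drop = FALSE]
        A <- crossprod(Rf)
        rhs <- crossprod(Rf, b)
        wf <- tryCatch({
          if (sum_active) {
            M <- rbind(cbind(A, rep(1, nf)), c(rep(1, nf), 0))
            sol <- solve(M, c(rhs, 1))
            sol[seq_len(nf)]
          } else {
            as.numeric(solve(A, rhs))
          }
        }, error = function(e) NULL)
        if (is.null(wf)) next
        w <- numeric(K)
        w[free] <- wf
      }
      if (any(w < -tol) || sum(w) > 1 + 1e-8) next
      obj <- sum((b - R %*% w)^2)
      if (obj < best_obj - 1e-15) {
        best_obj <- obj
        best <- w
      }
    }
  }
  if (is.null(best)) abort_contract("mixture solver found no feasible solution")
  list(w = pmax(best, 0), residual_norm = sqrt(best_obj))
}

#' Estimate cell-type proportions in bulk samples
#'
#' For each bulk sample, projects its marker betas onto the panel's
#' reference profiles under nonnegativity and sum-to-at-most-one
#' constraints; the remainder (1 - sum of weights) is unexplained signal.
#' Markers missing from the bulk matrix, or missing in an individual
#' sample, are dropped for that estimate.
#'
#' @param bulk Bulk beta matrix (must cover at least some panel markers).
#' @param panel A `ctewas_panel`.
#' @return A `data.frame`: sample_id, w_neuron, w_glia, w_total,
#'   residual_norm, n_markers.
#' @export
estimate_proportions <- function(bulk, panel) {
  stopifnot(inherits(panel, "ctewas_panel"))
  present <- intersect(panel$markers, rownames(bulk))
  if (length(present) == 0L) abort_contract("no panel markers present in bulk matrix")
  if (length(present) < length(panel$markers))
    message(sprintf("%d marker(s) absent from the bulk matrix were dropped",
                    length(panel$markers) - length(present)))
  R <- panel$reference[present, , drop = FALSE]
  B <- bulk[present, , drop = FALSE]
  out <- lapply(seq_len(ncol(B)), function(s) {
    b <- B[, s]
    ok <- !is.na(b)
    fit <- solve_mixture(b[ok], R[ok, , drop = FALSE])
    data.frame(sample_id = colnames(B)[s],
               w_neuron = fit$w[1L], w_glia = fit$w[2L],
               w_total = sum(fit$w), residual_norm = fit$residual_norm,
               n_markers = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Reference-age bias experiment
#'
#' Builds two reference panels from synthetic sorted cohorts restricted to a
#' young and an old age window, estimates the neuronal proportion of one
#' bulk cohort with each, and reports the per-sample paired difference
#' (young-reference minus old-reference estimate). When marker CpGs carry
#' cell-type-specific age slopes the two panels disagree systematically;
#' with zero slopes the difference vanishes.
#'
#' @param design A `ctewas_design`; defaults to a 2000-probe design whose
#'   age-slope probes sit on cell-type markers with opposing slopes in the
#'   two cell types (the divergent-aging-marker condition).
#' @param young_range,old_range Age windows for the two reference cohorts
#'   (defaults 30-50 and 70-95 years).
#' @param n_reference Donors per reference cohort (default 30).
#' @param n_bulk Bulk samples to estimate (default 50).
#' @param k_markers Panel size (default 200).
#' @param seed Seed controlling all cohort draws (default: design seed).
#' @return A list: `diff` (per-sample paired differences), `mean_diff`,
#'   `estimates_young`, `estimates_old`, and the two panels.
#' @export
reference_age_bias_experiment <- function(design = NULL,
                                          young_range = c(30, 50),
                                          old_range = c(70, 95),
                                          n_reference = 30L,
                                          n_bulk = 50L,
                                          k_markers = 200L,
                                          seed = NULL) {
  if (is.null(design))
    design <- make_default_design(2000L, seed = seed %||% 1L,
                                  frac_age = 0.05, frac_age_on_ct = 1,
                                  frac_age_opposing = 1,
                                  ct_age_converging = 1)
  seed <- seed %||% design$seed
  if (diff(young_range) <= 0 || diff(old_range) <= 0)
    abort_config("age windows must be non-empty")
  make_panel <- function(rng, s) {
    d <- design
    d$age_range <- rng
    d$age_center <- design$age_center  # effects stay anchored to the study cohort
    cohort <- generate_sorted_cohort(d, n_reference, seed = s)
    select_reference_markers(cohort$beta, cohort$sheet, k = k_markers)
  }
  panel_young <- make_panel(young_range, seed + 11L)
  panel_old <- make_panel(old_range, seed + 12L)
  bulk <- generate_bulk_cohort(design, n_bulk, seed = seed + 13L)
  est_y <- estimate_proportions(bulk$beta, panel_young)
  est_o <- estimate_proportions(bulk$beta, panel_old)
  diff <- est_y$w_neuron - est_o$w_neuron
  list(diff = diff, mean_diff = mean(diff),
       estimates_young = est_y, estimates_old = est_o,
       panel_young = panel_young, panel_old = panel_old,
       truth = bulk$sheet$true_neuron_prop)
}
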