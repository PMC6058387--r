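#' @title Synthetic sorted and bulk methylome cohorts
#' @description Generates neuron/glia sorted cohorts and bulk mixtures with
#'   the statistical structure the sorted-brain EWAS assumes: ~12% of probes
#'   differing by >= 20% beta between cell types (54% hypermethylated in
#'   neurons), sparse cell-type-specific (optionally opposing) linear age
#'   slopes, sparse per-cell-type Braak-stage effects, sex and batch offsets,
#'   age/stage-confounded Braak assignment, and bulk samples formed as
#'   proportion-weighted mixtures whose neuronal fraction drifts with age and
#'   disease. Full ground truth is retained for recovery analyses.
#' @name synthetic
NULL

# Approximate 450k array design shares per genomic region class.
.REGION_PROBS <- c(TSS1500 = 0.15, TSS200 = 0.13, `5UTR` = 0.12,
                   `1stExon` = 0.07, Body = 0.31, `3UTR` = 0.04,
                   intergenic = 0.18)

#' Construct the default synthetic cohort design
#'
#' Draws per-probe generative parameters: baseline neuron/glia beta means,
#' sparse age slopes (beta units per year), sparse Braak-stage effects
#' (beta units per stage), sex and batch offsets, plus the bulk-mixture
#' proportion model. Effects act additively on the beta scale around
#' centered covariates (age centered at the cohort midpoint, Braak at
#' stage 3), so `mu_*` is the expected beta of a mid-age, mid-stage, female
#' sample and planted effects survive the \[0.01, 0.99\] mean clipping.
#'
#' @param n_probes Number of probes (>= 100).
#' @param seed Integer seed; all randomness in the design and in cohorts
#'   generated from it flows from this single seed.
#' @param frac_ct Fraction of probes with a cell-type difference of at least
#'   `ct_delta_range[1]` beta (default 0.12).
#' @param frac_ct_hyper Fraction of cell-type-different probes hypermethylated
#'   in neurons (default 0.54).
#' @param ct_delta_range Range the planted |neuron - glia| differences are
#'   drawn from (uniform; default 0.25-0.60).
#' @param frac_age Fraction of probes with a nonzero age slope per cell type
#'   (default 0.01).
#' @param age_slope Magnitude of planted age slopes, beta/year (default 0.002).
#' @param frac_age_opposing Fraction of each cell type's age-slope probes that
#'   carry the opposite-sign slope in the other cell type (default 0.25).
#' @param frac_age_on_ct Fraction of age-slope probes placed on
#'   cell-type-different probes, emulating markers with divergent aging
#'   (default 0.25).
#' @param ct_age_converging For opposing-slope probes that sit on
#'   cell-type-different probes: probability that the slopes shrink the
#'   neuron-glia contrast with age (cell-type differences fading in old
#'   individuals) rather than widen it (default 0.7).
#' @param frac_hypo_age Probability a planted age slope is negative
#'   (age-associated hypomethylation dominates; default 0.6).
#' @param frac_braak Fraction of probes with a nonzero Braak effect per cell
#'   type (default 0.005).
#' @param braak_effect Magnitude of planted Braak effects, beta/stage
#'   (default 0.02).
#' @param frac_braak_shared Fraction of Braak-effect probes carrying the same
#'   effect in both cell types (default 0; remaining probes are
#'   cell-type-exclusive and disjoint between cell types).
#' @param frac_hypo_braak Probability a planted Braak effect is negative
#'   (default 0.6).
#' @param frac_sex Fraction of probes with a sex offset (default 0.01).
#' @param sex_effect Magnitude of the male-vs-female offset (default 0.05).
#' @param n_batches Number of technical batches (default 3).
#' @param batch_sd SD of per-probe, per-batch offsets (default 0.01).
#' @param null_delta_sd SD of small, sub-threshold neuron-glia differences on
#'   probes not planted as cell-type-different (default 0.03; truncated at
#'   |0.15| so ground-truth labels stay unambiguous).
#' @param phi Beta-distribution concentration of measurement noise
#'   (default 200, i.e. sd ~ 0.035 at beta 0.5); `phi >= 1e6` is the
#'   noise-free limit and returns the mean exactly.
#' @param age_range Donor age range, years (uniform; default 30-95).
#' @param age_braak_cor Correlation between age and the latent score that
#'   determines Braak stage (default 0.5).
#' @param w0,w_age,w_braak Bulk neuronal-proportion model
#'   `w = clip(w0 + w_age*age + w_braak*braak, 0, 1)` (defaults 0.55,
#'   -0.002/yr, -0.015/stage: a mid-cohort neuronal content near 0.38,
#'   declining with age and pathology, matching the minority neuronal share
#'   of cortical nuclei).
#' @param w_jitter_sd SD of per-sample Gaussian jitter on `w` (default 0.05).
#' @return An object of class `ctewas_design` carrying the per-probe truth
#'   table (`$probes`), batch offset matrix, probe annotation and all cohort
#'   parameters.
#' @export
make_default_design <- function(n_probes, seed,
                                frac_ct = 0.12, frac_ct_hyper = 0.54,
                                ct_delta_range = c(0.25, 0.60),
                                frac_age = 0.01, age_slope = 0.002,
                                frac_age_opposing = 0.25,
                                frac_age_on_ct = 0.25,
                                ct_age_converging = 0.7,
                                frac_hypo_age = 0.6,
                                frac_braak = 0.005, braak_effect = 0.02,
                                frac_braak_shared = 0,
                                frac_hypo_braak = 0.6,
                                frac_sex = 0.01, sex_effect = 0.05,
                                n_batches = 3, batch_sd = 0.01,
                                null_delta_sd = 0.03,
                                phi = 200,
                                age_range = c(30, 95),
                                age_braak_cor = 0.5,
                                w0 = 0.55, w_age = -0.002, w_braak = -0.015,
                                w_jitter_sd = 0.05) {
  if (n_probes < 100) abort_config("n_probes must be >= 100")
  if (phi <= 0) abort_config("phi must be positive")
  fr <- c(frac_ct, frac_ct_hyper, frac_age, frac_age_opposing, frac_age_on_ct,
          frac_braak, frac_braak_shared, frac_sex)
  if (any(fr < 0 | fr > 1)) abort_config("fraction parameters must be in [0,1]")

  withr::with_seed(seed, {
    probe_id <- sprintf("cg%08d", seq_len(n_probes))

    # -- cell-type differences -----------------------------------------------
    is_ct <- stats::rbinom(n_probes, 1L, frac_ct) == 1L
    delta <- numeric(n_probes)
    delta[is_ct] <- stats::runif(sum(is_ct), ct_delta_range[1L], ct_delta_range[2L])
    hyper_neuron <- rep(NA, n_probes)
    hyper_neuron[is_ct] <- stats::runif(sum(is_ct)) < frac_ct_hyper

    # baselines: ct probes sit in a window that accommodates the delta plus
    # any later effect excursions; null probes get a bimodal array-like base
    # with small sub-threshold cell differences
    base <- stats::rbeta(n_probes, 0.85, 0.85)
    base <- pmin(pmax(base, 0.03), 0.97)
    mu_neuron <- mu_glia <- base
    if (any(is_ct)) {
      d <- delta[is_ct]
      lo <- stats::runif(sum(is_ct), 0.15, pmax(0.15, 0.85 - d))
      hi <- lo + d
      mu_neuron[is_ct] <- ifelse(hyper_neuron[is_ct], hi, lo)
      mu_glia[is_ct]   <- ifelse(hyper_neuron[is_ct], lo, hi)
    }
    nd <- pmin(pmax(stats::rnorm(n_probes, 0, null_delta_sd), -0.15), 0.15)
    mu_neuron[!is_ct] <- pmin(pmax(base[!is_ct] + nd[!is_ct] / 2, 0.02), 0.98)
    mu_glia[!is_ct]   <- pmin(pmax(base[!is_ct] - nd[!is_ct] / 2, 0.02), 0.98)

    # -- age slopes ----------------------------------------------------------
    n_age <- round(frac_age * n_probes)
    age_slope_neuron <- age_slope_glia <- numeric(n_probes)
    draw_from <- function(pool, k) pool[sample.int(length(pool), k)]
    pick_effect_probes <- function(n_needed, exclude) {
      pool_ct  <- setdiff(which(is_ct), exclude)
      pool_nct <- setdiff(which(!is_ct), exclude)
      n_ct <- min(round(frac_age_on_ct * n_needed), length(pool_ct))
      c(draw_from(pool_ct, n_ct), draw_from(pool_nct, n_needed - n_ct))
    }
    if (n_age > 0) {
      n_opp <- round(frac_age_opposing * n_age)
      idx_opp <- pick_effect_probes(n_opp, integer(0))
      idx_n   <- pick_effect_probes(n_age - n_opp, idx_opp)
      idx_g   <- pick_effect_probes(n_age - n_opp, c(idx_opp, idx_n))
      sgn <- function(k) ifelse(stats::runif(k) < frac_hypo_age, -1, 1)
      s_opp <- sgn(length(idx_opp))
      # on ct probes, opposing slopes preferentially erode the neuron-glia
      # contrast over lifetime (markers fading with age)
      conv <- is_ct[idx_opp] & stats::runif(length(idx_opp)) < ct_age_converging
      s_opp[conv] <- -sign(mu_neuron[idx_opp] - mu_glia[idx_opp])[conv]
      age_slope_neuron[idx_opp] <- s_opp * age_slope
      age_slope_glia[idx_opp]   <- -s_opp * age_slope
      age_slope_neuron[idx_n]   <- sgn(length(idx_n)) * age_slope
      age_slope_glia[idx_g]     <- sgn(length(idx_g)) * age_slope
    }

    # -- Braak effects (disjoint from age probes and from ct probes) ---------
    n_braak <- round(frac_braak * n_probes)
    braak_effect_neuron <- braak_effect_glia <- numeric(n_probes)
    if (n_braak > 0) {
      taken <- which(age_slope_neuron != 0 | age_slope_glia != 0 | is_ct)
      pool <- setdiff(seq_len(n_probes), taken)
      n_sh <- round(frac_braak_shared * n_braak)
      idx_sh <- draw_from(pool, n_sh)
      pool <- setdiff(pool, idx_sh)
      idx_bn <- draw_from(pool, n_braak - n_sh)
      pool <- setdiff(pool, idx_bn)
      idx_bg <- draw_from(pool, n_braak - n_sh)
      sgn <- function(k) ifelse(stats::runif(k) < frac_hypo_braak, -1, 1)
      s_sh <- sgn(length(idx_sh))
      braak_effect_neuron[idx_sh] <- s_sh * braak_effect
      braak_effect_glia[idx_sh]   <- s_sh * braak_effect
      braak_effect_neuron[idx_bn] <- sgn(length(idx_bn)) * braak_effect
      braak_effect_glia[idx_bg]   <- sgn(length(idx_bg)) * braak_effect
    }

    # Dynamic CpGs sit at intermediate methylation: re-anchor non-ct probes
    # carrying age or Braak effects so the planted excursions (<= ~0.13 beta
    # over the covariate range) never hit the [0.01, 0.99] mean clip.
    dynamic <- !is_ct & (age_slope_neuron != 0 | age_slope_glia != 0 |
                           braak_effect_neuron != 0 | braak_effect_glia != 0)
    if (any(dynamic)) {
      mid <- (mu_neuron[dynamic] + mu_glia[dynamic]) / 2
      shift <- pmin(pmax(mid, 0.20), 0.80) - mid
      mu_neuron[dynamic] <- mu_neuron[dynamic] + shift
      mu_glia[dynamic] <- mu_glia[dynamic] + shift
    }

    # -- sex and batch -------------------------------------------------------
    sex_off <- numeric(n_probes)
    n_sex <- round(frac_sex * n_probes)
    if (n_sex > 0) {
      idx_sex <- sample(seq_len(n_probes), n_sex)
      sex_off[idx_sex] <- sample(c(-1, 1), n_sex, replace = TRUE) * sex_effect
    }
    batch_effects <- matrix(stats::rnorm(n_probes * n_batches, 0, batch_sd),
                            nrow = n_probes,
                            dimnames = list(probe_id,
                                            paste0("batch", seq_len(n_batches))))

    # -- annotation: chromosomes 1-22 round-robin, array-like region mix -----
    chrom <- rep(as.character(1:22), length.out = n_probes)
    pos <- integer(n_probes)
    for (ch in unique(chrom)) {
      k <- which(chrom == ch)
      pos[k] <- 10000L + 1000L * seq_along(k)
    }
    region <- sample(names(.REGION_PROBS), n_probes, replace = TRUE,
                     prob = .REGION_PROBS)
    gene <- ifelse(region == "intergenic", NA_character_,
                   sprintf("GENE%05d", 1L + (seq_len(n_probes) - 1L) %/% 10L))
    annotation <- data.frame(probe_id = probe_id, chromosome = chrom,
                             position = pos, gene = gene, region = region,
                             autosomal = TRUE, stringsAsFactors = FALSE)

    probes <- data.frame(
      probe_id = probe_id,
      mu_neuron = mu_neuron, mu_glia = mu_glia,
      age_slope_neuron = age_slope_neuron, age_slope_glia = age_slope_glia,
      braak_effect_neuron = braak_effect_neuron,
      braak_effect_glia = braak_effect_glia,
      sex_effect = sex_off,
      is_ct = abs(mu_neuron - mu_glia) >= 0.20,
      hyper_neuron = mu_neuron > mu_glia,
      stringsAsFactors = FALSE
    )
  })

  structure(list(
    n_probes = n_probes, seed = seed, probes = probes,
    batch_effects = batch_effects, annotation = annotation,
    phi = phi, age_range = age_range, age_center = mean(age_range),
    braak_center = 3, age_braak_cor = age_braak_cor,
    n_batches = n_batches,
    w0 = w0, w_age = w_age, w_braak = w_braak, w_jitter_sd = w_jitter_sd
  ), class = "ctewas_design")
}

#' @export
print.ctewas_design <- function(x, ...) {
  cat("ctewas synthetic design\n")
  cat(sprintf("  probes: %d (ct-different: %d, %.0f%% hyper in neurons)\n",
              x$n_probes, sum(x$probes$is_ct),
              100 * mean(x$probes$hyper_neuron[x$probes$is_ct])))
  cat(sprintf("  age-slope probes: neuron %d, glia %d; Braak-effect probes: neuron %d, glia %d\n",
              sum(x$probes$age_slope_neuron != 0),
              sum(x$probes$age_slope_glia != 0),
              sum(x$probes$braak_effect_neuron != 0),
              sum(x$probes$braak_effect_glia != 0)))
  cat(sprintf("  phi = %g, ages %g-%g, seed = %d\n",
              x$phi, x$age_range[1L], x$age_range[2L], x$seed))
  invisible(x)
}

# Donor covariates: age uniform; Braak from an age-correlated latent normal
# binned into 7 equal-mass stages; AD diagnosis for stages IV-VI.
make_donors <- function(design, n) {
  age <- stats::runif(n, design$age_range[1L], design$age_range[2L])
  sd_age <- diff(design$age_range) / sqrt(12)
  z_age <- (age - mean(design$age_range)) / sd_age
  r <- design$age_braak_cor
  latent <- r * z_age + sqrt(1 - r^2) * stats::rnorm(n)
  braak <- findInterval(stats::pnorm(latent), seq(1, 6) / 7)
  data.frame(
    donor_id  = sprintf("d%03d", seq_len(n)),
    age       = age,
    braak     = as.integer(braak),
    sex       = sample(rep_len(c("female", "male"), n)),
    batch     = paste0("batch", 1L + (seq_len(n) - 1L) %% design$n_batches),
    diagnosis = ifelse(braak >= 4L, "AD", "control"),
    stringsAsFactors = FALSE
  )
}

# Expected beta for every probe x donor in one cell fraction, before noise.
fraction_means <- function(design, donors, fraction) {
  p <- design$probes
  mu    <- if (fraction == "neuron") p$mu_neuron else p$mu_glia
  a_sl  <- if (fraction == "neuron") p$age_slope_neuron else p$age_slope_glia
  b_sl  <- if (fraction == "neuron") p$braak_effect_neuron else p$braak_effect_glia
  m <- outer(mu, rep(1, nrow(donors))) +
    outer(a_sl, donors$age - design$age_center) +
    outer(b_sl, donors$braak - design$braak_center) +
    outer(p$sex_effect, as.numeric(donors$sex == "male")) +
    design$batch_effects[, match(donors$batch, colnames(design$batch_effects)),
                         drop = FALSE]
  pmin(pmax(m, 0.01), 0.99)
}

# Beta-distributed noise with mean m and concentration phi; phi >= 1e6 is the
# exact noise-free limit.
add_beta_noise <- function(m, phi) {
  if (phi >= 1e6) return(m)
  obs <- matrix(stats::rbeta(length(m), m * phi, (1 - m) * phi), nrow = nrow(m))
  dimnames(obs) <- dimnames(m)
  obs
}

#' Generate a sorted neuron/glia cohort
#'
#' Each donor contributes one neuron and one glia sample sharing age, sex,
#' Braak stage, diagnosis and batch, emulating NeuN-sorted profiling of the
#' same individuals.
#'
#' @param design A `ctewas_design`.
#' @param n_per_fraction Number of donors (= samples per cell fraction).
#' @param seed Seed for this cohort draw (defaults to the design seed, so two
#'   cohorts from the same design and seed are identical).
#' @return A list with `beta` (probes x 2n matrix), `sheet` (sample sheet),
#'   `annotation`, and `donors`.
#' @export
generate_sorted_cohort <- function(design, n_per_fraction,
                                   seed = design$seed) {
  stopifnot(inherits(design, "ctewas_design"))
  withr::with_seed(seed, {
    donors <- make_donors(design, n_per_fraction)
    mats <- list()
    sheets <- list()
    for (fraction in c("neuron", "glia")) {
      m <- fraction_means(design, donors, fraction)
      obs <- add_beta_noise(m, design$phi)
      colnames(obs) <- paste0(donors$donor_id, "_", fraction)
      rownames(obs) <- design$probes$probe_id
      mats[[fraction]] <- obs
      sheets[[fraction]] <- data.frame(
        sample_id = colnames(obs), cohort = "synthetic",
        cell_fraction = fraction, age = donors$age, sex = donors$sex,
        braak = donors$braak, diagnosis = donors$diagnosis,
        batch = donors$batch, stringsAsFactors = FALSE)
    }
  })
  beta <- cbind(mats$neuron, mats$glia)
  sheet <- rbind(sheets$neuron, sheets$glia)
  validate_beta_matrix(beta)
  validate_sample_sheet(sheet)
  list(beta = beta, sheet = sheet, annotation = design$annotation,
       donors = donors)
}

#' Generate a bulk (unsorted) cohort of proportion-weighted mixtures
#'
#' Per sample, the neuronal proportion is the design's proportion model
#' evaluated at the donor's age and Braak stage plus Gaussian jitter, clipped
#' to \[0, 1\]; the expected bulk beta is the proportion-weighted mixture of
#' the two cell-fraction means (linear mixing on the beta scale). The true
#' proportion is recorded in the sheet.
#'
#' @param design A `ctewas_design`.
#' @param n Number of bulk samples.
#' @param seed Seed (defaults to the design seed).
#' @param w_override Optional fixed neuronal proportion (scalar or length-n),
#'   bypassing the proportion model and jitter.
#' @return A list with `beta`, `sheet` (including `true_neuron_prop`),
#'   `annotation`, and `donors`.
#' @export
generate_bulk_cohort <- function(design, n, seed = design$seed,
                                 w_override = NULL) {
  stopifnot(inherits(design, "ctewas_design"))
  withr::with_seed(seed, {
    donors <- make_donors(design, n)
    if (is.null(w_override)) {
      w <- design$w0 + design$w_age * donors$age + design$w_braak * donors$braak
      w <- pmin(pmax(w + stats::rnorm(n, 0, design$w_jitter_sd), 0), 1)
    } else {
      w <- rep_len(w_override, n)
    }
    m_n <- fraction_means(design, donors, "neuron")
    m_g <- fraction_means(design, donors, "glia")
    m <- sweep(m_n, 2, w, `*`) + sweep(m_g, 2, 1 - w, `*`)
    m <- pmin(pmax(m, 0.01), 0.99)
    obs <- add_beta_noise(m, design$phi)
  })
  colnames(obs) <- paste0(donors$donor_id, "_bulk")
  rownames(obs) <- design$probes$probe_id
  sheet <- data.frame(
    sample_id = colnames(obs), cohort = "synthetic", cell_fraction = "bulk",
    age = donors$age, sex = donors$sex, braak = donors$braak,
    diagnosis = donors$diagnosis, batch = donors$batch,
    true_neuron_prop = w, stringsAsFactors = FALSE)
  validate_beta_matrix(obs)
  validate_sample_sheet(sheet)
  list(beta = obs, sheet = sheet, annotation = design$annotation,
       donors = donors)
}
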