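test_that("Fisher combination reproduces published worked examples", {
  # spot checks from the bundled combined-analysis tables (3 s.f. inputs)
  expect_equal(fisher_combine(c(6.58e-9, 1.00e-20))$p_combined, 4.34e-27,
               tolerance = 0.02)
  expect_equal(fisher_combine(c(9.09e-14, 1.17e-13))$p_combined, 6.46e-25,
               tolerance = 0.02)
  expect_equal(fisher_combine(c(1.15e-6, 3.83e-9))$p_combined, 1.50e-13,
               tolerance = 0.02)
})

test_that("Fisher combination: identities, symmetry, monotonicity, guards", {
  # k = 1 is the chi-square(2) identity
  expect_equal(fisher_combine(0.037)$p_combined, 0.037, tolerance = 1e-12)
  z <- fisher_combine(c(1, 1))
  expect_identical(z$chi_sq, 0)
  expect_equal(z$p_combined, 1)
  expect_identical(z$df, 4L)

  expect_equal(fisher_combine(c(0.01, 0.3))$p_combined,
               fisher_combine(c(0.3, 0.01))$p_combined)   # symmetric
  # monotone: decreasing any component never increases the combination
  p_base <- fisher_combine(c(0.05, 0.2))$p_combined
  expect_lte(fisher_combine(c(0.01, 0.2))$p_combined, p_base)

  # closed form for k = 2: exp(-x/2) * (1 + x/2)
  for (pair in list(c(0.03, 0.4), c(1e-8, 1e-3), c(0.9, 0.99))) {
    f <- fisher_combine(pair)
    closed <- exp(-f$chi_sq / 2) * (1 + f$chi_sq / 2)
    expect_equal(f$p_combined, closed, tolerance = 1e-10)
  }

  expect_error(fisher_combine(numeric(0)), class = "ctewas_contract_error")
  expect_error(fisher_combine(c(0.5, 1.2)), class = "ctewas_contract_error")
  expect_warning(f0 <- fisher_combine(c(0, 0.5)), "clamped")
  expect_gt(f0$p_combined, 0)
})

test_that("BH FDR equals brute-force step-up on random small vectors", {
  brute <- function(p, m = length(p)) {
    n <- length(p)
    o <- order(p)
    q <- numeric(n)
    for (i in seq_len(n)) {
      js <- i:n
      q[o[i]] <- min(1, min(p[o[js]] * m / js))
    }
    q
  }
  withr::with_seed(14, {
    for (rep in 1:25) {
      p <- runif(sample(3:20, 1))
      expect_equal(bh_fdr(p), brute(p), tolerance = 1e-14)
    }
  })
  # all-equal input maps to itself
  expect_equal(bh_fdr(rep(0.07, 9)), rep(0.07, 9))
  # enlarged family denominator
  p <- c(1e-6, 1e-4, 0.01)
  expect_equal(bh_fdr(p, m = 1000), brute(p, m = 1000))
  # monotone along the sorted order
  pp <- runif(50)
  qq <- bh_fdr(pp)
  expect_true(all(diff(qq[order(pp)]) >= -1e-15))
  expect_error(bh_fdr(numeric(0)), class = "ctewas_contract_error")
})

test_that("cell-type combination ranks probes and handles mismatches", {
  neuron <- data.frame(probe_id = c("cg1", "cg2", "cg3"),
                       p = c(1e-6, 0.5, 1))
  glia <- data.frame(probe_id = c("cg2", "cg3", "cg1", "cg9"),
                     p = c(0.9, 1, 1e-5, 0.1))
  expect_message(meta <- combine_cell_types(neuron, glia), "excluded")
  expect_identical(nrow(meta), 3L)
  expect_identical(meta$probe_id[1], "cg1")          # strongest combination
  expect_identical(meta$probe_id[meta$rank == 3L], "cg3")  # p = (1,1) at bottom
  expect_equal(meta$p_combined[meta$probe_id == "cg3"], 1)
  # per-row agreement with the scalar operation
  f <- fisher_combine(c(1e-6, 1e-5))
  expect_equal(meta$p_combined[meta$probe_id == "cg1"], f$p_combined,
               tolerance = 1e-12)
})

test_that("meta-analysis of synthetic scans recovers either cell type's signal", {
  d <- make_default_design(2000, seed = 12, frac_braak = 0.01)
  co <- generate_sorted_cohort(d, 50)
  pcs <- compute_principal_components(co$beta, 6)
  tn <- run_ewas(co$beta, co$sheet, pcs, regression_spec("braak", fraction = "neuron"))
  tg <- run_ewas(co$beta, co$sheet, pcs, regression_spec("braak", fraction = "glia"))
  meta <- combine_cell_types(tn, tg)
  planted <- d$probes$probe_id[d$probes$braak_effect_neuron != 0 |
                                 d$probes$braak_effect_glia != 0]
  top <- meta$probe_id[meta$rank <= 200]
  recall_meta <- mean(planted %in% top)
  recall_n <- mean(planted %in% tn$probe_id[tn$rank <= 200])
  recall_g <- mean(planted %in% tg$probe_id[tg$rank <= 200])
  expect_gte(recall_meta, max(recall_n, recall_g) - 1e-9)
})

test_that("top-k overlap equals set intersection", {
  a <- data.frame(probe_id = sprintf("cg%02d", 1:20), rank = 1:20)
  b <- data.frame(probe_id = sprintf("cg%02d", c(11:20, 1:10)), rank = 1:20)
  ov <- top_k_overlap(a, b, k = 10)
  expect_identical(ov$n_overlap, length(intersect(a$probe_id[1:10],
                                                  b$probe_id[1:10])))
  expect_identical(top_k_overlap(a, a, k = 15)$n_overlap, 15L)
  disj <- data.frame(probe_id = sprintf("cg%02d", 21:40), rank = 1:20)
  expect_identical(top_k_overlap(a, disj, k = 10)$n_overlap, 0L)
  expect_error(top_k_overlap(a, b, k = 25), class = "ctewas_contract_error")
})

test_that("Braak group deltas equal group means and recover planted effects", {
  d <- make_default_design(600, seed = 40, phi = 1e6, batch_sd = 0,
                           frac_sex = 0, frac_age = 0, frac_braak = 0.05,
                           frac_hypo_braak = 0)
  co <- generate_sorted_cohort(d, 60)
  neurons <- co$sheet[co$sheet$cell_fraction == "neuron", ]
  bn <- co$beta[, neurons$sample_id]
  planted <- d$probes$probe_id[d$probes$braak_effect_neuron > 0]
  gd <- braak_group_deltas(bn, neurons, planted)
  # oracle group means
  low <- neurons$sample_id[neurons$braak <= 2]
  high <- neurons$sample_id[neurons$braak >= 5]
  expect_equal(gd$mean_low, unname(rowMeans(bn[planted, low])), tolerance = 1e-12)
  expect_equal(gd$mean_high, unname(rowMeans(bn[planted, high])), tolerance = 1e-12)
  # noise-free planted effect: delta ~ effect * (mean stage_high - mean stage_low)
  stage_gap <- mean(neurons$braak[neurons$braak >= 5]) -
    mean(neurons$braak[neurons$braak <= 2])
  expect_equal(mean(gd$delta_high_low), 0.02 * stage_gap, tolerance = 0.01)
  # constant probe: all deltas zero
  bc <- bn; bc[1, ] <- 0.4
  gd0 <- braak_group_deltas(bc, neurons, rownames(bc)[1])
  expect_identical(gd0$delta_high_low, 0)
})

test_that("clustering splits cell fractions on markers, degenerates gracefully", {
  d <- make_default_design(1000, seed = 90)
  co <- generate_sorted_cohort(d, 15)
  markers <- utils::head(d$probes$probe_id[d$probes$is_ct], 80)
  chk <- hierarchical_cluster_check(co$beta, co$sheet, markers)
  expect_true(chk$perfect_split)

  same <- co$beta[markers[1:10], ]
  same[] <- 0.5
  chk0 <- hierarchical_cluster_check(same, co$sheet)
  expect_true(chk0$inconclusive)
  expect_true(is.na(chk0$perfect_split))
})

test_that("average-linkage heights match a hand computation on a toy", {
  # 5 samples on 2 probes with known pairwise distances
  m <- matrix(c(0, 0, 1, 0, 4, 0, 10, 0, 10.5, 0), nrow = 2,
              dimnames = list(c("cgA", "cgB"), sprintf("s%d", 1:5)))
  sheet <- data.frame(sample_id = sprintf("s%d", 1:5), cohort = "t",
                      cell_fraction = c("neuron", "neuron", "neuron",
                                        "glia", "glia"),
                      age = 50, sex = "female", braak = 0L,
                      diagnosis = "control", batch = "b",
                      stringsAsFactors = FALSE)
  chk <- hierarchical_cluster_check(m, sheet)
  # manual average linkage: merge (s4,s5) at 0.5, (s1,s2) at 1,
  # s3 joins {s1,s2} at mean(4, 3) = 3.5, final merge at the mean of the six
  # cross distances (10, 10.5, 9, 9.5, 6, 6.5)/6 = 51.5/6
  expect_equal(sort(chk$hclust$height), c(0.5, 1, 3.5, 51.5 / 6),
               tolerance = 1e-12)
  expect_true(chk$perfect_split)
})
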