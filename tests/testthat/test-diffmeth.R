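make_two_group <- function(n1 = 8, n2 = 8, n_probes = 30, seed = 10,
                           shift = 0) {
  set.seed(seed)
  probes <- sprintf("cg%03d", seq_len(n_probes))
  beta <- matrix(runif(n_probes * (n1 + n2), 0.2, 0.8), nrow = n_probes,
                 dimnames = list(probes, sprintf("s%02d", seq_len(n1 + n2))))
  beta[, seq_len(n1)] <- pmin(beta[, seq_len(n1)] + shift, 1)
  sheet <- data.frame(
    sample_id = colnames(beta), cohort = "t",
    cell_fraction = rep(c("neuron", "glia"), c(n1, n2)),
    age = runif(n1 + n2, 40, 90), sex = rep_len(c("female", "male"), n1 + n2),
    braak = rep_len(0:6, n1 + n2), diagnosis = "control", batch = "b1",
    stringsAsFactors = FALSE)
  list(beta = beta, sheet = sheet)
}

test_that("Welch t-test matches stats::t.test per probe to 1e-12", {
  d <- make_two_group(n1 = 7, n2 = 9)
  res <- celltype_ttest(d$beta, d$sheet)
  res <- res[match(rownames(d$beta), res$probe_id), ]
  for (i in c(1, 5, 17, 30)) {
    or <- stats::t.test(d$beta[i, 1:7], d$beta[i, 8:16])
    expect_equal(res$p[i], or$p.value, tolerance = 1e-12)
    expect_equal(res$statistic[i], unname(or$statistic), tolerance = 1e-12)
    expect_equal(res$df[i], unname(or$parameter), tolerance = 1e-9)
  }
  # pooled variant against var.equal oracle
  resp <- celltype_ttest(d$beta, d$sheet, pooled = TRUE)
  resp <- resp[match(rownames(d$beta), resp$probe_id), ]
  orp <- stats::t.test(d$beta[3, 1:7], d$beta[3, 8:16], var.equal = TRUE)
  expect_equal(resp$p[3], orp$p.value, tolerance = 1e-12)
  # with equal group sizes and equal sample variances the Welch and pooled
  # tests coincide (and both equal the two-group OLS t)
  d2 <- make_two_group(n1 = 18, n2 = 18, seed = 77)
  d2$beta[, 19:36] <- d2$beta[, 1:18] + 0.05   # same spread, shifted mean
  w <- celltype_ttest(d2$beta, d2$sheet)
  p <- celltype_ttest(d2$beta, d2$sheet, pooled = TRUE)
  expect_lt(max(abs(w$p[match(p$probe_id, w$probe_id)] - p$p)), 1e-6)
  X2 <- cbind(`(Intercept)` = 1,
              neuron = as.numeric(d2$sheet$cell_fraction == "neuron"))
  ols <- fit_cpg_regression(d2$beta[4, ], X2)
  expect_equal(abs(ols$statistic[2]),
               abs(p$statistic[p$probe_id == rownames(d2$beta)[4]]),
               tolerance = 1e-9)
})

test_that("degenerate probes and small groups are handled", {
  d <- make_two_group()
  d$beta[1, ] <- 0.5                       # zero variance, zero effect
  res <- celltype_ttest(d$beta, d$sheet)
  row <- res[res$probe_id == "cg001", ]
  expect_identical(row$p, 1)
  expect_identical(row$statistic, 0)

  few <- d$sheet
  few$diagnosis[few$cell_fraction == "glia"] <- "AD"
  expect_error(celltype_ttest(d$beta, few), class = "ctewas_contract_error")
})

test_that("ct-DMCG calling enforces delta, Bonferroni and autosomal rules", {
  probes <- sprintf("cg%03d", 1:4)
  res <- data.frame(
    probe_id = probes,
    effect = c(0.19, 0.25, -0.30, 0.50),
    se = 0.01, statistic = 10, df = 20,
    p = c(1e-30, 1e-12, 1e-12, 0.5),
    bonferroni_p = c(4e-30, 4e-12, 4e-12, 1),
    fdr_q = 1e-10, rank = 1:4, stringsAsFactors = FALSE)
  ann <- tiny_annotation(probes, chromosome = c("1", "2", "X", "4"))
  calls <- call_ct_dmcgs(res, ann)
  # cg001: delta below 0.20 despite tiny p; cg003: chromosome X; cg004: not significant
  expect_identical(calls$probe_id, "cg002")
  expect_identical(calls$direction, "hyper")
  # boundary: |effect| exactly at the threshold is included
  res$effect[1] <- 0.20
  expect_true("cg001" %in% call_ct_dmcgs(res, ann)$probe_id)
  expect_error(call_ct_dmcgs(res, ann[1:2, ]), class = "ctewas_contract_error")
})

test_that("per-probe OLS matches the normal-equations and lm oracles", {
  set.seed(20)
  n <- 40
  X <- cbind(`(Intercept)` = 1, age = runif(n, 30, 90),
             sex = rep_len(0:1, n), pc1 = rnorm(n))
  y <- 0.4 + 0.003 * X[, "age"] - 0.02 * X[, "sex"] + rnorm(n, 0, 0.02)
  fit <- fit_cpg_regression(y, X)
  # explicit normal-equations solve
  bhat <- solve(t(X) %*% X) %*% t(X) %*% y
  expect_lt(max(abs(fit$estimate - bhat)), 1e-10)
  # lm as an independent route
  lmfit <- summary(stats::lm(y ~ X[, -1]))$coefficients
  expect_equal(fit$estimate, unname(lmfit[, 1]), tolerance = 1e-10)
  expect_equal(fit$se, unname(lmfit[, 2]), tolerance = 1e-10)
  expect_equal(fit$p, unname(lmfit[, 4]), tolerance = 1e-10)

  # exact linear response: slope recovered, p underflows toward 0
  y2 <- 0.1 + 0.004 * X[, "age"]
  fit2 <- fit_cpg_regression(y2, X)
  expect_equal(fit2$estimate[2], 0.004, tolerance = 1e-12)
  expect_lt(fit2$p[2], 1e-200)

  expect_error(fit_cpg_regression(y, cbind(X, X[, 2])),
               class = "ctewas_contract_error")  # rank-deficient
})

test_that("adding a constant to the response only shifts the intercept", {
  set.seed(21)
  X <- cbind(`(Intercept)` = 1, age = runif(30, 30, 90), sex = rep_len(0:1, 30))
  y <- runif(30, 0.2, 0.6)
  f1 <- fit_cpg_regression(y, X)
  f2 <- fit_cpg_regression(y + 0.1, X)
  expect_equal(f2$estimate[-1], f1$estimate[-1], tolerance = 1e-12)
  expect_equal(f2$estimate[1] - f1$estimate[1], 0.1, tolerance = 1e-12)
})

test_that("EWAS recovers planted aging probes and their slopes", {
  d <- make_default_design(4000, seed = 42)
  co <- generate_sorted_cohort(d, 50)
  pcs <- compute_principal_components(co$beta, 10)
  tab <- run_ewas(co$beta, co$sheet, pcs,
                  regression_spec("age", fraction = "neuron"))
  planted <- d$probes$probe_id[d$probes$age_slope_neuron != 0]
  recall <- mean(planted %in% tab$probe_id[tab$rank <= 1000])
  expect_gte(recall, 0.8)
  est <- tab$effect[match(planted, tab$probe_id)]
  true <- d$probes$age_slope_neuron[match(planted, d$probes$probe_id)]
  expect_lt(stats::median(abs(est - true) / abs(true)), 0.25)

  # vectorized path agrees with the single-probe fit
  spec <- regression_spec("age", fraction = "neuron")
  ctrl_n <- co$sheet$sample_id[co$sheet$cell_fraction == "neuron" &
                                 co$sheet$diagnosis == "control"]
  sub <- co$sheet[match(ctrl_n, co$sheet$sample_id), ]
  X <- cbind(`(Intercept)` = 1, age = sub$age,
             braak = as.numeric(sub$braak),
             sex = as.numeric(sub$sex == "male"),
             pc1 = pcs$scores[match(ctrl_n, rownames(pcs$scores)), 1])
  one <- fit_cpg_regression(co$beta[planted[1], ctrl_n], X)
  row <- tab[tab$probe_id == planted[1], ]
  expect_equal(row$effect, one$estimate[one$term == "age"], tolerance = 1e-10)
  expect_equal(row$p, one$p[one$term == "age"], tolerance = 1e-10)
})

test_that("permuting the predictor destroys planted aging signal", {
  d <- make_default_design(2000, seed = 8)
  co <- generate_sorted_cohort(d, 40)
  pcs <- compute_principal_components(co$beta, 5)
  planted <- d$probes$probe_id[d$probes$age_slope_neuron != 0]
  tab <- run_ewas(co$beta, co$sheet, pcs,
                  regression_spec("age", fraction = "neuron"))
  recall <- mean(planted %in% tab$probe_id[tab$rank <= 200])
  perm <- co$sheet
  withr::with_seed(99, {
    idx <- perm$cell_fraction == "neuron"
    perm$age[idx] <- sample(perm$age[idx])
  })
  tabp <- run_ewas(co$beta, perm, pcs,
                   regression_spec("age", fraction = "neuron"))
  recall_perm <- mean(planted %in% tabp$probe_id[tabp$rank <= 200])
  expect_gt(recall, 0.8)
  expect_lt(recall_perm, 0.1)   # back to background (200/2000 = 0.1)
})

test_that("null Braak scans stay globally non-significant across seeds", {
  hits <- 0L
  for (s in 1:10) {
    d <- make_default_design(600, seed = 300 + s, frac_braak = 0,
                             frac_age = 0, frac_ct = 0, frac_sex = 0,
                             batch_sd = 0, null_delta_sd = 0)
    co <- generate_sorted_cohort(d, 30)
    pcs <- compute_principal_components(co$beta, 4)
    tab <- run_ewas(co$beta, co$sheet, pcs,
                    regression_spec("braak", fraction = "glia"))
    if (min(tab$bonferroni_p) < 0.05) hits <- hits + 1L
  }
  expect_lte(hits, 1L)
})

test_that("direction classification agrees with a group-mean oracle", {
  d <- make_default_design(500, seed = 55, frac_age = 0.1, frac_hypo_age = 1)
  co <- generate_sorted_cohort(d, 30)
  neurons <- co$sheet[co$sheet$cell_fraction == "neuron", ]
  bn <- co$beta[, neurons$sample_id]
  planted <- d$probes$probe_id[d$probes$age_slope_neuron < 0]
  lab <- classify_direction(bn, neurons, planted, mode = "aging")
  # oracle: means of the 8 youngest vs 8 oldest
  ord <- order(neurons$age)
  young <- neurons$sample_id[ord[1:8]]
  old <- neurons$sample_id[rev(ord)[1:8]]
  delta_or <- rowMeans(bn[planted, old]) - rowMeans(bn[planted, young])
  expect_equal(lab$delta, unname(delta_or), tolerance = 1e-12)
  # negative slopes are predominantly labeled hypo
  expect_gte(mean(lab$direction == "hypo"), 0.9)

  # monotone increasing probe is hyper
  mono <- matrix(seq(0.1, 0.9, length.out = ncol(bn)), nrow = 1,
                 dimnames = list("cgX", neurons$sample_id[order(neurons$age)]))
  expect_identical(
    classify_direction(mono, neurons, "cgX", mode = "aging")$direction,
    "hyper")
})

test_that("region distribution matches a tally oracle and flags enrichment", {
  d <- make_default_design(2000, seed = 66)
  ann <- d$annotation
  set <- ann$probe_id[ann$region == "Body"][1:50]
  rd <- region_distribution(set, ann)
  tally <- table(factor(ann$region[match(set, ann$probe_id)],
                        levels = rd$region))
  expect_identical(rd$n_set, as.integer(tally))
  expect_gt(rd$ratio[rd$region == "Body"], 1)    # constructed enrichment
  # set == background: all ratios 1
  rd_bg <- region_distribution(ann$probe_id, ann)
  expect_true(all(abs(rd_bg$ratio - 1) < 1e-12))
})
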