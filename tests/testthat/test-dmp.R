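test_that("OLS effects match the normal-equations oracle on random designs", {
  set.seed(41)
  for (rep in 1:300) {
    n <- sample(8:20, 1)
    dx <- sample(0:1, n, replace = TRUE)
    if (length(unique(dx)) < 2) next
    age <- runif(n, 10, 70)
    y <- 0.4 + 0.002 * age + 0.05 * dx + rnorm(n, 0, 0.05)
    ph <- toy_pheno(ifelse(dx == 1, "iASD", "CTL"), age = age)
    r <- fit_probe_ols(matrix(y, 1, dimnames = list("p1", ph$sample_id)), ph,
                       region = "PFC", covariates = "age")
    X <- cbind(1, age, dx)
    bet <- solve(crossprod(X), crossprod(X, y))
    s2 <- sum((y - X %*% bet)^2) / (n - 3)
    se <- sqrt(s2 * solve(crossprod(X))[3, 3])
    expect_equal(r$effect, bet[3], tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(r$se, se, tolerance = 1e-8)
    expect_equal(r$p, 2 * pt(-abs(bet[3] / se), n - 3), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("OLS conventions: constant probes, worked 4-sample example, power", {
  ph <- toy_pheno(c("CTL", "CTL", "iASD", "iASD"))
  y_const <- matrix(0.5, 1, 4, dimnames = list("p1", ph$sample_id))
  r <- fit_probe_ols(y_const, ph, region = "PFC", covariates = character(0))
  expect_equal(r$effect, 0)
  expect_equal(r$p, 1)

  y <- matrix(c(0.1, 0.1, 0.3, 0.3), 1, dimnames = list("p1", ph$sample_id))
  r2 <- fit_probe_ols(y, ph, region = "PFC", covariates = character(0))
  expect_equal(r2$effect, 0.2)

  # planted delta-beta 0.1 at n = 30/30, sd 0.03: strong recovery
  set.seed(43)
  ph3 <- toy_pheno(rep(c("CTL", "iASD"), each = 30))
  y3 <- 0.4 + 0.1 * (ph3$diagnosis == "iASD") + rnorm(60, 0, 0.03)
  r3 <- fit_probe_ols(matrix(y3, 1, dimnames = list("p1", ph3$sample_id)), ph3,
                      region = "PFC", covariates = character(0))
  expect_lt(abs(r3$effect - 0.1), 0.02)
  expect_lt(r3$p, 1.198e-7)

  # bank perfectly confounded with diagnosis: flagged, p missing
  ph4 <- toy_pheno(rep(c("CTL", "iASD"), each = 4),
                   bank = rep(c("BankA", "BankB"), each = 4))
  y4 <- matrix(runif(8), 1, dimnames = list("p1", ph4$sample_id))
  r4 <- fit_probe_ols(y4, ph4, region = "PFC", covariates = "bank")
  expect_identical(r4$flag, "singular_design")
  expect_true(is.na(r4$p))

  # listwise deletion per probe
  ph5 <- toy_pheno(rep(c("CTL", "iASD"), each = 6))
  Y5 <- matrix(runif(24), 2, dimnames = list(c("a", "b"), ph5$sample_id))
  Y5[2, 1] <- NA
  r5 <- fit_probe_ols(Y5, ph5, region = "PFC", covariates = character(0))
  expect_equal(r5$n_used, c(12, 11))
})

test_that("p-values are uniform and calls calibrated under the global null", {
  set.seed(47)
  ph <- toy_pheno(rep(c("CTL", "iASD"), each = 30), age = runif(60, 5, 70))
  P <- 4000
  Y <- matrix(0.5 + rnorm(P * 60, 0, 0.03), P,
              dimnames = list(sprintf("p%04d", 1:P), ph$sample_id))
  r <- fit_probe_ols(Y, ph, region = "PFC", covariates = "age")
  expect_gt(ks.test(r$p, "punif")$p.value, 0.01)
  calls <- call_dmps(r)
  expect_lte(sum(calls$tier != ""), qbinom(0.999, P, 5e-05))
})

test_that("the mixed model matches a dense REML grid and its OLS limit", {
  coh <- two_region_cohort(n_donors = 16, n_probes = 12, donor_sd = 0.05,
                           seed = 53)
  fit <- fit_probe_lme(coh$beta, coh$pheno)
  # brute-force oracle: REML criterion minimized over a dense ratio grid
  ph <- coh$pheno
  X <- cbind(methcortex:::build_design(ph, c("age", "sex", "bank", "cets"),
                                       include_region = TRUE),
             dx = as.numeric(ph$diagnosis == "iASD"))
  st <- methcortex:::reml_setup(X, coh$beta, ph$donor_id)
  grid <- seq(0, 20, 1e-3)
  for (i in c(1, 5, 12)) {
    crit_grid <- vapply(grid, function(l) methcortex:::reml_crit_one(st, l, i),
                        numeric(1))
    expect_lte(methcortex:::reml_crit_one(st, fit$var_ratio[i], i),
               min(crit_grid) + 1e-8)
    expect_equal(fit$var_ratio[i], grid[which.min(crit_grid)], tolerance = 0.05)
  }

  # zero-donor-variance data: boundary fits equal pooled OLS exactly
  coh0 <- two_region_cohort(n_donors = 16, n_probes = 40, donor_sd = 0,
                            seed = 59)
  f0 <- fit_probe_lme(coh0$beta, coh0$pheno)
  o0 <- fit_probe_ols(coh0$beta, coh0$pheno, region = c("PFC", "TC"))
  i0 <- f0$var_ratio == 0
  expect_gt(sum(i0), 5)
  expect_lt(max(abs(f0$effect[i0] - o0$effect[i0])), 1e-6)

  # one region only reduces to OLS with the region term dropped
  ph1 <- coh$pheno[coh$pheno$region == "PFC", ]
  f1 <- fit_probe_lme(coh$beta[, ph1$sample_id], ph1, regions = "PFC")
  o1 <- fit_probe_ols(coh$beta[, ph1$sample_id], ph1, region = "PFC")
  expect_equal(f1$effect, o1$effect, tolerance = 1e-6)
})

test_that("the mixed model agrees with lme4 on balanced data", {
  skip_if_not_installed("lme4")
  coh <- two_region_cohort(n_donors = 16, n_probes = 5, donor_sd = 0.05,
                           delta = 0.05, seed = 61)
  fit <- fit_probe_lme(coh$beta, coh$pheno)
  ph <- coh$pheno
  for (i in 1:5) {
    d <- data.frame(y = coh$beta[i, ], age = ph$age, sex = ph$sex,
                    bank = ph$bank, cets = ph$neuronal_proportion,
                    region = ph$region, donor = ph$donor_id,
                    dx = as.numeric(ph$diagnosis == "iASD"))
    m <- lme4::lmer(y ~ age + sex + bank + cets + region + dx + (1 | donor),
                    data = d, REML = TRUE)
    expect_equal(fit$effect[i], unname(lme4::fixef(m)["dx"]), tolerance = 1e-5)
    expect_equal(fit$se[i], sqrt(as.numeric(vcov(m)["dx", "dx"])),
                 tolerance = 1e-4)
  }
})

test_that("DMP tiers use strict thresholds and the Bonferroni rule", {
  res <- data.frame(probe_id = c("a", "b", "c", "d"),
                    p = c(5e-05, 4.9e-05, 1e-09, NA))
  calls <- call_dmps(res, experiment_wide = 1.198e-7)
  expect_equal(calls$tier, c("", "discovery", "experiment-wide", ""))
  # experiment-wide calls are a subset of discovery-level significance
  expect_true(all(calls$p[calls$tier == "experiment-wide"] < 5e-05))
  expect_equal(signif(0.05 / 417460, 4), 1.198e-7)
  empty <- call_dmps(res[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("global methylation summaries behave on degenerate input", {
  ph <- toy_pheno(rep(c("CTL", "iASD"), each = 4))
  Y <- matrix(0.5, 10, 8, dimnames = list(sprintf("p%02d", 1:10), ph$sample_id))
  g <- global_methylation_summary(Y, ph)
  expect_equal(g$mean_a, 0.5)
  expect_equal(g$mean_b, 0.5)
  expect_equal(g$p, 1)

  set.seed(67)
  Y2 <- Y + rnorm(80, 0, 0.01) + 0.01 * rep(ph$diagnosis == "iASD", each = 10)
  g2 <- global_methylation_summary(Y2, ph)
  expect_gt(g2$mean_a, g2$mean_b)
})

test_that("sample clustering at DMPs separates planted groups", {
  set.seed(71)
  ph <- toy_pheno(rep(c("CTL", "iASD"), each = 15))
  base <- runif(50, 0.35, 0.65)   # per-probe baseline shared by all samples
  Y <- base + matrix(rnorm(50 * 30, 0, 0.02), 50)
  dimnames(Y) <- list(sprintf("p%02d", 1:50), ph$sample_id)
  # a mix of hyper- and hypomethylated DMPs, as correlation distance needs
  delta <- 0.2 * rep(c(1, -1), 10)
  Y[1:20, ph$diagnosis == "iASD"] <- Y[1:20, ph$diagnosis == "iASD"] + delta
  cl <- cluster_samples_at_dmps(Y, rownames(Y)[1:20], ph)
  expect_setequal(round(cl$case_fraction, 6), c(0, 1))
  expect_error(cluster_samples_at_dmps(Y, "p01", ph), "2 DMPs")
})

test_that("effect concordance and Fisher's Z behave as expected", {
  set.seed(73)
  a <- data.frame(probe_id = sprintf("p%03d", 1:100), effect = rnorm(100, 0, 0.05))
  same <- effect_concordance(a, a)
  expect_equal(same$r, 1)
  neg <- a; neg$effect <- -neg$effect
  expect_equal(effect_concordance(a, neg)$r, -1)
  b <- a; b$effect <- rnorm(100, 0, 0.05)
  ind <- effect_concordance(a, b)
  expect_lt(abs(ind$r), 0.3)

  # interval stratification
  man <- toy_manifest(pos = (1:100) * 100)
  man$probe_id <- a$probe_id
  strat <- effect_concordance(a, a, manifest = man,
                              interval = list(chrom = "chr1", start = 1,
                                              end = 5000))
  expect_equal(strat$n[strat$stratum == "inside"], 50)

  fz <- fisher_z_diff(0.5, 103, 0, 103)
  expect_equal(fz$z, atanh(0.5) * sqrt(50), tolerance = 1e-10)
  expect_equal(fz$p, 1.03e-4, tolerance = 0.01)
  expect_equal(fisher_z_diff(0.4, 50, 0.4, 60)$p, 1)
  expect_error(fisher_z_diff(0.5, 3, 0, 103), "n > 3")
})

test_that("expression integration counts overlaps and recovers sign", {
  des <- synth_design(n_probes = 2000, seed = 79)
  man <- generate_manifest(des)
  ann <- annotate_probes(man$probe_id, man, collapse = FALSE)
  probes <- unique(ann$probe_id)[1:80]
  set.seed(80)
  res <- data.frame(probe_id = probes, effect = rnorm(80, 0, 0.05))
  genes <- annotate_probes(probes, man)
  de <- data.frame(gene = genes,
                   log_fold_change = NA_real_, fdr = runif(length(genes), 0, 0.05))
  eff_by_gene <- vapply(genes, function(g) {
    mean(res$effect[res$probe_id %in% ann$probe_id[ann$gene == g]])
  }, numeric(1))
  de$log_fold_change <- -2 * eff_by_gene + rnorm(length(genes), 0, 0.01)
  ie <- integrate_expression(res, man, de)
  expect_equal(ie$n_overlap, length(unique(res$probe_id[res$probe_id %in%
    ann$probe_id[ann$gene %in% de$gene]])))
  expect_lt(ie$r, 0)

  # empty DE table
  ie0 <- integrate_expression(res, man, de[0, ])
  expect_equal(ie0$n_overlap, 0)
  expect_true(is.na(ie0$r))

  # probe annotated to two DE genes contributes two pairs
  man2 <- toy_manifest(pos = c(100, 200))
  man2$genes <- c("gA;gB", "")
  man2$tss_distance <- c("10;20", "")
  res2 <- data.frame(probe_id = "p001", effect = 0.1)
  de2 <- data.frame(gene = c("gA", "gB"), log_fold_change = c(-1, -2),
                    fdr = c(0.01, 0.02))
  ie2 <- integrate_expression(res2, man2, de2)
  expect_equal(nrow(ie2$pairs), 2)
  expect_error(integrate_expression(res2, man2,
                                    data.frame(gene = "gA",
                                               log_fold_change = 1, fdr = 2)),
               "fdr")
})
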