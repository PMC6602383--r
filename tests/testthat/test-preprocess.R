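test_that("detection p filter applies the ceil-based failure rule", {
  dp <- matrix(0, 3, 100, dimnames = list(c("a", "b", "c"), NULL))
  dp["b", 1] <- 0.2              # fails in exactly 1 of 100 samples
  r <- detection_p_filter(dp, alpha = 0.05, frac = 0.01)
  expect_identical(r$removed, "b")   # ceil(0.01 * 100) = 1
  expect_true(all(c("a", "c") %in% r$keep))

  # all-zero probe retained even at frac = 0; any failure still removes
  r0 <- detection_p_filter(dp, frac = 0)
  expect_identical(r0$removed, "b")
  expect_true("a" %in% r0$keep)
  expect_error(detection_p_filter(dp + 2), "\\[0, 1\\]")
})

test_that("blacklist filter removes flagged probes and is order-independent", {
  man <- toy_manifest(pos = (1:10) * 100)
  expect_identical(blacklist_filter(man)$keep, man$probe_id)
  man$flag_cross_reactive[3] <- TRUE
  man$flag_snp_within_10bp[7] <- TRUE
  r <- blacklist_filter(man)
  expect_setequal(r$removed, man$probe_id[c(3, 7)])

  # order independence of the probe filters
  dp <- matrix(0, 10, 50, dimnames = list(man$probe_id, NULL))
  dp[5, 1:10] <- 1
  keep_ab <- intersect(detection_p_filter(dp)$keep, blacklist_filter(man)$keep)
  keep_ba <- intersect(blacklist_filter(man)$keep, detection_p_filter(dp)$keep)
  expect_setequal(keep_ab, keep_ba)
})

test_that("sex check flags swapped labels via MDS clustering", {
  des <- synth_design(n_probes = 1000,
                      n_donors_per_group = c(CTL = 10, iASD = 10, dup15q = 0),
                      regions = "PFC", seed = 17)
  man <- generate_manifest(des)
  coh <- generate_cohort(des, man)
  expect_length(sex_check(coh$beta, man, coh$pheno)$mismatch, 0)

  ph_swapped <- coh$pheno
  i <- which(ph_swapped$sex == "M")[1]
  ph_swapped$sex[i] <- "F"
  sc <- sex_check(coh$beta, man, ph_swapped)
  expect_identical(sc$mismatch, ph_swapped$sample_id[i])

  ph_same <- coh$pheno; ph_same$sex <- "M"
  expect_warning(sc2 <- sex_check(coh$beta, man, ph_same), "same sex")
  expect_length(sc2$mismatch, 0)
  expect_error(sex_check(coh$beta[1:5, ], man, coh$pheno), "sex-chromosome")
})

test_that("SNP fingerprints separate same-donor from cross-donor pairs", {
  des <- synth_design(n_probes = 800,
                      n_donors_per_group = c(CTL = 8, iASD = 8, dup15q = 0),
                      seed = 19)
  man <- generate_manifest(des)
  coh <- generate_cohort(des, man)
  fp <- fingerprint_match(coh$beta, man, coh$pheno)
  ids <- colnames(fp$cor)
  donor <- coh$pheno$donor_id[match(ids, coh$pheno$sample_id)]
  same <- outer(donor, donor, "==") & upper.tri(fp$cor)
  cross <- !outer(donor, donor, "==") & upper.tri(fp$cor)
  expect_gt(min(fp$cor[same]), max(fp$cor[cross]))
  expect_equal(nrow(fp$flagged), 0)

  dup <- coh$beta; dup[, 2] <- dup[, 1]
  expect_equal(fingerprint_match(dup, man)$cor[1, 2], 1)
  man1 <- man[man$flag_snp_probe, ][1, ]
  expect_error(fingerprint_match(coh$beta, man1), "SNP")
})

test_that("probe-type normalization equalizes distributions per stratum", {
  set.seed(23)
  n <- 400
  man <- toy_manifest(pos = (1:n) * 50)
  man$design_type <- rep(c("I", "II"), length.out = n)
  M <- matrix(rexp(n * 2, 1 / 3000), n, dimnames = list(man$probe_id, c("s1", "s2")))
  U <- matrix(rexp(n * 2, 1 / 3000), n, dimnames = dimnames(M))

  # identical samples are unchanged
  Mi <- cbind(s1 = M[, 1], s2 = M[, 1]); Ui <- cbind(s1 = U[, 1], s2 = U[, 1])
  r <- normalize_by_probe_type(Mi, Ui, man)
  expect_equal(r$beta[, 1], Mi[, 1] / (Mi[, 1] + Ui[, 1] + 100))

  # one sample globally scaled x2: post-normalization distributions equal
  M2 <- M; M2[, 2] <- 2 * M[, 1]; U2 <- U; U2[, 2] <- 2 * U[, 1]
  M2[, 1] <- M[, 1]; U2[, 1] <- U[, 1]
  r2 <- normalize_by_probe_type(M2, U2, man)
  for (tt in c("I", "II")) {
    i <- man$design_type == tt
    expect_equal(sort(r2$beta[i, 1]), sort(r2$beta[i, 2]), tolerance = 1e-10)
  }

  # single stratum equals plain quantile normalization
  man1 <- man; man1$design_type <- "II"
  r3 <- normalize_by_probe_type(M, U, man1)
  qn <- limma::normalizeQuantiles(M) /
    (limma::normalizeQuantiles(M) + limma::normalizeQuantiles(U) + 100)
  expect_equal(r3$beta, qn)
  expect_error(normalize_by_probe_type(-M, U, man), "negative")
})

test_that("rank order within sample and stratum survives normalization", {
  set.seed(29)
  n <- 300
  man <- toy_manifest(pos = (1:n) * 50)
  man$design_type <- rep(c("I", "II"), length.out = n)
  M <- matrix(rexp(n * 6, 1 / 3000), n, dimnames = list(man$probe_id, paste0("s", 1:6)))
  U <- matrix(rexp(n * 6, 1 / 3000), n, dimnames = dimnames(M))
  r <- normalize_by_probe_type(M, U, man)
  for (tt in c("I", "II")) {
    i <- man$design_type == tt
    expect_gt(min(diag(cor(apply(r$M[i, ], 2, rank), apply(M[i, ], 2, rank)))),
              0.999)
  }
})

test_that("EB batch adjustment removes shifts and matches ComBat", {
  set.seed(31)
  P <- 300; n <- 40
  batch <- rep(c("A", "B"), each = n / 2)
  dx <- rep(rep(0:1, each = n / 4), 2)
  Y <- matrix(0.5 + rnorm(P * n, 0, 0.05), P, n,
              dimnames = list(sprintf("p%03d", 1:P), sprintf("s%02d", 1:n)))
  Y[, batch == "B"] <- Y[, batch == "B"] + 0.1
  Y[1:20, dx == 1] <- Y[1:20, dx == 1] + 0.05

  # single batch is the identity
  expect_identical(eb_batch_adjust(Y, rep("A", n)), Y)
  expect_error(eb_batch_adjust(Y, c("Z", rep("A", n - 1))), "Z")

  # no-shrinkage mode equalizes per-batch means exactly
  ns <- eb_batch_adjust(Y, batch, covariates = data.frame(dx = dx),
                        shrink = FALSE)
  expect_lt(max(abs(rowMeans(ns[, batch == "A"]) -
                      rowMeans(ns[, batch == "B"]))), 1e-6)

  # batch-mean variance never increases
  v_pre <- apply(cbind(rowMeans(Y[, batch == "A"]), rowMeans(Y[, batch == "B"])),
                 1, var)
  adj <- eb_batch_adjust(Y, batch, covariates = data.frame(dx = dx))
  v_post <- apply(cbind(rowMeans(adj[, batch == "A"]),
                        rowMeans(adj[, batch == "B"])), 1, var)
  expect_lt(mean(v_post), mean(v_pre))
  expect_true(all(adj >= 0 & adj <= 1))

  skip_if_not_installed("sva")
  cb <- suppressMessages(sva::ComBat(Y, batch = batch,
                                     mod = model.matrix(~dx)))
  expect_equal(adj, pmin(pmax(cb, 0), 1), tolerance = 1e-8)
})

test_that("planted bank shift is recovered within 20% by the batch model", {
  des <- synth_design(n_probes = 1200,
                      n_donors_per_group = c(CTL = 12, iASD = 12, dup15q = 0),
                      regions = "PFC", batch_effects = c(BankA = 0, BankB = 0.05),
                      noise_sd = 0.02, donor_sd = 0, seed = 37)
  man <- generate_manifest(des)
  coh <- generate_cohort(des, man)
  ph <- coh$pheno
  plain <- man$probe_id[!man$flag_snp_probe & !man$flag_sex_chrom]
  est <- mean(coh$beta[plain, ph$bank == "BankB"]) -
    mean(coh$beta[plain, ph$bank == "BankA"])
  expect_lt(abs(est - 0.05), 0.2 * 0.05)
  adj <- eb_batch_adjust(coh$beta[plain, ], ph$bank,
                         covariates = data.frame(dx = ph$diagnosis,
                                                 age = ph$age, sex = ph$sex))
  res <- mean(adj[, ph$bank == "BankB"]) - mean(adj[, ph$bank == "BankA"])
  expect_lt(abs(res), 0.005)
})
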