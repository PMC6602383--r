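test_that("variable-probe filter uses the q10-q90 spread with strict >", {
  exact <- seq(0.5, 0.55, length.out = 10)   # its q90 - q10 is the test range
  q <- quantile(exact, c(0.1, 0.9), names = FALSE)
  b <- rbind(const = rep(0.5, 10), wide = seq(0, 1, length.out = 10),
             exact = exact)
  keep <- variable_probe_filter(b, min_range = q[2] - q[1])
  expect_false("exact" %in% keep)      # boundary sits at equality: strict >
  expect_false("const" %in% keep)
  expect_true("wide" %in% keep)
  # default 5% rule keeps a probe spanning the unit interval
  expect_true("wide" %in% variable_probe_filter(b))
})

test_that("residualize removes only the requested covariate effects", {
  set.seed(113)
  n <- 50
  age <- runif(n, 10, 70)
  dx <- rep(0:1, each = n / 2)
  Y <- matrix(0.5 + rnorm(3 * n, 0, 0.01), 3, n)
  Y[1, ] <- Y[1, ] + 0.002 * age + 0.05 * dx
  rownames(Y) <- c("a", "b", "c"); colnames(Y) <- sprintf("s%02d", 1:n)
  cov <- data.frame(age = age, dx = dx)
  out <- residualize(Y, cov, remove = "age", keep = "dx")
  # age effect gone: partialling out the kept diagnosis term leaves
  # residuals exactly orthogonal to age
  expect_lt(abs(cor(residuals(lm(out[1, ] ~ dx)), age)), 1e-8)
  # diagnosis effect survives
  expect_lt(abs(mean(out[1, dx == 1]) - mean(out[1, dx == 0]) - 0.05), 0.01)
  # empty removal set is the identity
  expect_identical(residualize(Y, cov, remove = character(0)), Y)
  # zero-coefficient covariate leaves the data unchanged (up to noise fit)
  Z <- matrix(rep(0.4, 2 * n), 2, n)
  expect_equal(residualize(Z, cov, remove = "age"), Z, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("bicor is robust, bounded, and collapses to Pearson when clean", {
  set.seed(127)
  x <- rnorm(200)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, -x), -1)
  y <- 0.5 * x + sqrt(0.75) * rnorm(200)
  expect_equal(bicor(x, y), cor(x, y), tolerance = 0.08)
  xg <- rnorm(5000); yg <- 0.5 * xg + sqrt(0.75) * rnorm(5000)
  expect_lt(abs(bicor(xg, yg) - 0.5), 0.03)

  # no observations beyond |u| >= 1: all weights active but bounded
  expect_true(all(abs(bicor(matrix(rnorm(600), 100, 6))) <= 1))

  # an extreme outlier barely moves bicor but wrecks Pearson
  x2 <- c(rnorm(50), 20); y2 <- c(rnorm(50), 20)
  expect_lt(abs(bicor(x2, y2)), abs(cor(x2, y2)))

  # zero-MAD column falls back to Pearson weighting
  z <- rep(c(0, 0, 0, 1), 25)
  expect_true(is.finite(bicor(z, rnorm(100))))
})

test_that("signed adjacency and TOM match their defining formulas", {
  cc <- matrix(c(1, 0, 0, 1), 2)
  a <- signed_adjacency(cc, 7)
  expect_equal(a[1, 2], 0.5^7)
  expect_equal(diag(a), c(0, 0))
  expect_equal(signed_adjacency(matrix(c(1, 1, 1, 1), 2), 7)[1, 2], 1)
  expect_equal(signed_adjacency(matrix(c(1, -1, -1, 1), 2), 7)[1, 2], 0)

  # 2-node network: TOM equals the adjacency off-diagonal
  a2 <- matrix(c(0, 0.3, 0.3, 0), 2)
  expect_equal(topological_overlap(a2)[1, 2], 0.3)
  # complete graph: TOM is 1 everywhere
  ac <- matrix(1, 4, 4); diag(ac) <- 0
  expect_true(all(abs(topological_overlap(ac) - 1) < 1e-12))

  # brute-force triple loop oracle on a random 50-node network
  set.seed(131)
  X <- matrix(rnorm(40 * 50), 40, 50)
  a3 <- signed_adjacency(bicor(X), 7)
  tom <- topological_overlap(a3)
  k <- rowSums(a3)
  bf <- matrix(0, 50, 50)
  for (i in 1:50) for (j in 1:50) {
    s <- 0
    for (u in 1:50) s <- s + a3[i, u] * a3[u, j]
    bf[i, j] <- (s + a3[i, j]) / (min(k[i], k[j]) + 1 - a3[i, j])
  }
  diag(bf) <- 1
  expect_lt(max(abs(tom - bf)), 1e-10)
  expect_true(isSymmetric(tom, tol = 1e-12))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
})

planted_block_data <- function(ns = 60, block = 150, rho = 0.7, seed = 1) {
  set.seed(seed)
  f1 <- rnorm(ns); f2 <- rnorm(ns)
  D <- cbind(sapply(seq_len(block), function(i) sqrt(rho) * f1 +
                      sqrt(1 - rho) * rnorm(ns)),
             sapply(seq_len(block), function(i) sqrt(rho) * f2 +
                      sqrt(1 - rho) * rnorm(ns)))
  dimnames(D) <- list(sprintf("s%02d", 1:ns), sprintf("p%03d", 1:(2 * block)))
  list(dat = D, truth = rep(1:2, each = block), f1 = f1, f2 = f2)
}

test_that("module detection recovers planted blocks and merges duplicates", {
  skip_if_not_installed("mclust")
  pb <- planted_block_data(seed = 137)
  tom <- topological_overlap(signed_adjacency(bicor(pb$dat), 7))
  dimnames(tom) <- list(colnames(pb$dat), colnames(pb$dat))
  det <- detect_modules(tom, pb$dat, minModuleSize = 100)
  expect_equal(length(det$sizes), 2)
  expect_gte(mclust::adjustedRandIndex(det$labels, pb$truth), 0.8)

  # invariance to probe input order
  o <- sample(ncol(tom))
  det2 <- detect_modules(tom[o, o], pb$dat[, o], minModuleSize = 100)
  expect_equal(det2$labels[names(det$labels)], det$labels)

  # identical duplicate blocks merge into one module
  D2 <- cbind(pb$dat[, 1:150], pb$dat[, 1:150] + matrix(rnorm(60 * 150, 0, 0.01), 60))
  colnames(D2) <- sprintf("q%03d", 1:300)
  tom2 <- topological_overlap(signed_adjacency(bicor(D2), 7))
  dimnames(tom2) <- list(colnames(D2), colnames(D2))
  det3 <- detect_modules(tom2, D2, minModuleSize = 100)
  expect_equal(length(det3$sizes), 1)

  # pure noise yields no modules
  set.seed(139)
  N <- matrix(rnorm(60 * 250), 60, 250,
              dimnames = list(sprintf("s%02d", 1:60), sprintf("n%03d", 1:250)))
  tomn <- topological_overlap(signed_adjacency(bicor(N), 7))
  dimnames(tomn) <- list(colnames(N), colnames(N))
  detn <- detect_modules(tomn, N, minModuleSize = 100)
  expect_lte(length(detn$sizes), 1)

  expect_warning(detect_modules(tomn[1:10, 1:10], N[, 1:10],
                                minModuleSize = 100), "minModuleSize")
})

test_that("eigengenes are unit variance, sign-anchored, and track factors", {
  pb <- planted_block_data(seed = 149)
  eg <- module_eigengene(pb$dat[, 1:150])
  expect_equal(sd(eg), 1)
  expect_gt(abs(cor(eg, pb$f1)), 0.99)
  expect_gt(cor(eg, rowMeans(scale(pb$dat[, 1:150]))), 0)

  # module of identical probes: the standardized probe itself
  one <- matrix(rep(pb$f1, 5), ncol = 5,
                dimnames = list(sprintf("s%02d", 1:60), paste0("r", 1:5)))
  expect_equal(abs(cor(module_eigengene(one), pb$f1)), 1)
  expect_equal(unname(module_eigengene(one[, 1, drop = FALSE])),
               as.numeric(scale(pb$f1)))
})

test_that("module-trait association flags the loaded module only", {
  set.seed(151)
  nd <- 30
  don <- sprintf("d%03d", 1:nd)
  dx <- rep(c("CTL", "iASD"), each = nd / 2)
  ph <- do.call(rbind, lapply(c("PFC", "TC"), function(r)
    toy_pheno(dx, region = r, donor = don, age = runif(nd, 10, 70),
              cets = runif(nd, 0.3, 0.6))))
  for (v in c("age", "neuronal_proportion")) ph[[v]] <- rep(ph[[v]][1:nd], 2)
  ns <- nrow(ph)
  eg <- cbind(m1 = rnorm(ns) + 0.5 * (ph$diagnosis == "iASD"),
              m2 = rnorm(ns), m3 = rnorm(ns))
  rownames(eg) <- ph$sample_id
  res <- module_trait_association(eg, ph,
                                  contrasts = list(iASD = c("iASD", "CTL")),
                                  covariates = c("age", "cets"))
  expect_lt(res$fdr[res$module == "m1"], 0.05)
  expect_gt(min(res$fdr[res$module != "m1"]), 0.05)
  # BH q-values are monotone in p
  o <- order(res$p)
  expect_true(all(diff(res$fdr[o]) >= -1e-12))
  expect_error(module_trait_association(eg, ph,
                                        contrasts = list(x = c("dup15q", "CTL"))),
               "empty group")
})
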