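test_that("compute_A matches the centred cross-product oracle", {
  set.seed(3)
  M <- matrix(rbinom(20 * 60, 2, 0.5), 20, 60,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  A <- compute_A(M)
  # oracle: direct VanRaden method-1 formula computed independently
  p <- colMeans(M) / 2
  W <- M - matrix(2 * p, 20, 60, byrow = TRUE)
  A0 <- (W %*% t(W)) / (2 * sum(p * (1 - p)))
  expect_equal(A, A0, tolerance = 1e-10)
  expect_equal(A, t(A))
  expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  # duplicated genotype rows: A[i,j] = A[i,i]
  M2 <- rbind(M, M[1, , drop = FALSE])
  A2 <- compute_A(M2)
  expect_equal(A2[21, 1], A2[21, 21])

  # monomorphic markers dropped; all-monomorphic errors
  M3 <- cbind(M, 2)
  expect_warning(A3 <- compute_A(M3), "monomorphic")
  expect_equal(A3, A, tolerance = 1e-12)
  expect_error(suppressWarnings(compute_A(matrix(2, 5, 3))), "monomorphic")
})

test_that("REML on a balanced one-way layout matches closed-form ANOVA", {
  set.seed(4)
  q <- 40; r <- 5
  g <- rep(seq_len(q), each = r)
  y <- rnorm(q, 0, sqrt(2))[g] + rnorm(q * r)
  f <- fit_reml(y, random = list(genotype = list(Z = incidence(g))))
  a <- anova(lm(y ~ factor(g)))
  msg <- a[1, 3]; mse <- a[2, 3]
  expect_equal(unname(f$vc["genotype"]), (msg - mse) / r, tolerance = 1e-6)
  expect_equal(unname(f$vc["residual"]), mse, tolerance = 1e-6)
  expect_true(f$converged)
  # AIC bookkeeping: -2 logLik + 2 (1 fixed + 2 variance components)
  expect_equal(f$aic, -2 * f$loglik + 2 * 3)
})

test_that("constant response gives zero genetic variance and zero BLUPs", {
  g <- rep(1:10, each = 3)
  f <- fit_reml(rep(5, 30), random = list(genotype = list(Z = incidence(g))))
  expect_equal(unname(f$vc["genotype"]), 0)
  expect_true(all(f$blup$genotype == 0))
})

test_that("BLUPs shrink toward zero relative to genotype means when A = I", {
  set.seed(6)
  q <- 30; r <- 4
  g <- rep(seq_len(q), each = r)
  y <- rnorm(q, 0, 1)[g] + rnorm(q * r, 0, 2)
  f <- fit_reml(y, random = list(genotype = list(Z = incidence(g))))
  dev <- tapply(y, g, mean) - mean(y)
  expect_true(all(abs(f$blup$genotype) <= abs(dev) + 1e-8))
  expect_lt(abs(sum(f$blup$genotype)), 1e-6)
})

test_that("REML recovers variance components with an A matrix", {
  set.seed(8)
  n <- 120
  M <- matrix(rbinom(n * 200, 2, 0.5), n, 200,
              dimnames = list(sprintf("g%03d", 1:n), NULL))
  A <- compute_A(M)
  L <- t(chol(A + diag(1e-6, n)))
  u <- drop(L %*% rnorm(n, 0, sqrt(3)))
  y <- u + rnorm(n, 0, 1)
  f <- fit_reml(y, random = list(genotype = list(Z = diag(n), K = A)))
  h2 <- heritability(f$vc["genotype"], f$vc["residual"])
  expect_gt(h2, 0.4)   # truth 0.75; single replicate, loose sanity band
  expect_lt(h2, 1)
  expect_gt(cor(f$blup$genotype, u), 0.6)
})

test_that("heritability formulas and their invariants", {
  expect_equal(heritability(3, 1), 0.75)
  expect_equal(heritability(1, 1, sigma_ge2 = 1, n_years = 2,
                            across_year = TRUE), 0.5)
  expect_equal(heritability(0, 1), 0)
  expect_error(heritability(-1, 1), ">= 0")
  expect_warning(h <- heritability(0, 0), "undefined")
  expect_true(is.na(h))

  # h2 in [0,1] on a grid; across-year >= within-year when
  # sigma_ge2 <= sigma_e2 * (n - 1)
  grid <- expand.grid(a = c(0, 0.5, 1, 3), e = c(0.5, 1, 3),
                      ge = c(0, 0.5, 1, 3), n = 1:3)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    hw <- heritability(g$a, g$e)
    ha <- heritability(g$a, g$e, g$ge, g$n, across_year = TRUE)
    expect_true(hw >= 0 && hw <= 1)
    expect_true(ha >= 0 && ha <= 1)
    if (g$ge <= g$e * (g$n - 1)) expect_gte(ha, hw - 1e-12)
  }
})

test_that("AIC search keeps real spatial structure and drops noise terms", {
  set.seed(12)
  n_row <- 8; n_col <- 10
  dat <- expand.grid(row = 1:n_row, col = 1:n_col)
  g <- seq_len(nrow(dat))
  base <- list(genotype = list(Z = incidence(rep(g, each = 2) %% 20)))
  optional <- function(d) list(row = list(Z = incidence(rep(d$row, each = 2))),
                               col = list(Z = incidence(rep(d$col, each = 2))))
  # strong row effect
  keep_row <- 0
  for (s in 1:10) {
    re <- rnorm(n_row, 0, 2)
    y <- re[rep(dat$row, each = 2)] + rnorm(2 * nrow(dat))
    sel <- select_model_aic(y, base = base, optional = optional(dat))
    if ("row" %in% sel$terms) keep_row <- keep_row + 1
  }
  expect_gte(keep_row, 8)
  # pure noise: smallest model preferred most often
  none <- 0
  for (s in 1:10) {
    y <- rnorm(2 * nrow(dat))
    sel <- select_model_aic(y, base = base, optional = optional(dat))
    if (length(sel$terms) == 0) none <- none + 1
  }
  expect_gte(none, 6)
  # single candidate returned unchanged
  sel1 <- select_model_aic(rnorm(40), base = list(g = list(Z = incidence(rep(1:10, 4)))))
  expect_equal(sel1$terms, character(0))
})

test_that("GxY likelihood-ratio gate has the boundary-mixture behaviour", {
  set.seed(14)
  q <- 25; ny <- 3; nr <- 3   # replicates within genotype-year identify GxY
  g <- rep(seq_len(q), each = ny * nr)
  yr <- rep(rep(seq_len(ny), each = nr), q)
  Zg <- incidence(g); Zge <- incidence(interaction(g, yr))
  X <- stats::model.matrix(~ factor(yr))
  fit2 <- function(y) {
    fw <- fit_reml(y, X, list(genotype = list(Z = Zg), gxy = list(Z = Zge)))
    fo <- fit_reml(y, X, list(genotype = list(Z = Zg)))
    gate_gxy(fw, fo)
  }
  # identical fits: delta = 0 -> p = 1, term dropped
  y <- rnorm(q)[g] + rnorm(length(g))
  fw <- fit_reml(y, X, list(genotype = list(Z = Zg)))
  same <- gate_gxy(fw, fw)
  expect_equal(same$p, 1)
  expect_false(same$keep)

  # large GxY variance: kept
  ge <- matrix(rnorm(q * ny, 0, 2), q, ny)
  yg <- rnorm(q)[g] + ge[cbind(g, yr)] + rnorm(length(g), 0, 0.5)
  expect_true(fit2(yg)$keep)

  # null GxY: retention should be rare (checked over a few sims)
  kept <- 0
  for (s in 1:10) {
    y0 <- rnorm(q)[g] + rnorm(length(g))
    if (fit2(y0)$keep) kept <- kept + 1
  }
  expect_lte(kept, 3)
})

test_that("fit_blup_model runs end to end on simulated data", {
  set.seed(16)
  map <- simulate_map(5, 30, 80, seed = 1)   # enough markers for a usable A
  geno <- simulate_cross(map, 80, seed = 2)
  layout <- simulate_layout(rownames(geno), seed = 3)
  arch <- trait_architecture(polygenic_variance = 2, residual_variance = 1,
                             gxy_variance = 0.3, mu = 10,
                             year_effects = c("2011" = 0, "2012" = 1))
  A <- compute_A(fourway_dosage(geno))
  sim <- simulate_traits(geno, map, arch, layout, c("2011", "2012"), 5,
                         seed = 4, polygenic_K = A)
  means <- upright_means(sim$phenotypes)
  means <- merge(means, layout, by = "genotype")
  res <- fit_blup_model(means, A, model = "across",
                        spatial_terms = character(0))
  expect_true(res$h2 > 0 && res$h2 < 1)
  expect_equal(res$n_years, 2)
  expect_equal(length(res$blup), 80)
  expect_gt(res$spearman, 0.5)
  tv <- sim$truth$components$polygenic[match(names(res$blup),
                                             sim$truth$components$genotype)]
  expect_gt(cor(res$blup, tv), 0.5)

  within <- fit_blup_model(means, A, model = "2011",
                           spatial_terms = character(0))
  expect_equal(within$n_years, 1)
  expect_error(fit_blup_model(means, A, model = "1999"), "no data")
})
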