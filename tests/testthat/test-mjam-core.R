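test_that("HWE diagonal and marginal-effect identity give the documented statistics", {
  # single SNP, eaf 0.5, n 100, beta 0: d = 100 * 2 * 0.5 * 0.5 = 50
  id <- "chr1:100:A:G"
  ss <- sumstats(data.frame(snp_id = id, effect_allele = "G",
                            other_allele = "A", eaf = 0.5, beta = 0,
                            se = 0.1, n = 100L), quiet = TRUE)
  panel <- ref_panel(corr = matrix(1, 1, 1, dimnames = list(id, id)),
                     eaf = stats::setNames(0.5, id), n_ref = 100,
                     population_id = "pop1", snp_ids = id)
  st <- estimate_population_stats(ss, panel, snp_union = id)[[1L]]
  expect_equal(unname(st$XtX[1L, 1L]), 50)
  expect_equal(unname(st$Xty[1L]), 0)
  expect_equal(st$yty, 99)
})

test_that("uncorrelated panel SNPs yield zero off-diagonal cross-products", {
  ids <- toy_ids(2L)
  ss <- sumstats(data.frame(snp_id = ids, effect_allele = "G",
                            other_allele = "A", eaf = c(0.2, 0.4),
                            beta = c(0.1, -0.2), se = 0.05, n = 1000L),
                 quiet = TRUE)
  co <- diag(2); dimnames(co) <- list(ids, ids)
  panel <- ref_panel(corr = co, eaf = stats::setNames(c(0.2, 0.4), ids),
                     n_ref = 500, population_id = "pop1", snp_ids = ids)
  st <- estimate_population_stats(ss, panel, snp_union = ids)[[1L]]
  expect_equal(unname(st$XtX[1L, 2L]), 0)
  d <- 1000 * 2 * c(0.2, 0.4) * c(0.8, 0.6)
  expect_equal(unname(diag(st$XtX)), d)
  expect_equal(unname(st$Xty), d * c(0.1, -0.2))
})

test_that("summary-level cross-products match individual-level ones", {
  ti <- toy_individual(n = 5000, p = 5, r = 0.6, seed = 3)
  panel <- ref_panel(dosage = ti$G, population_id = "pop1")
  st <- estimate_population_stats(ti$sumstats, panel,
                                  snp_union = ti$ids)[[1L]]
  XtX_true <- crossprod(ti$Gc)
  Xty_true <- drop(crossprod(ti$Gc, ti$y))
  rel <- norm(st$XtX - XtX_true, "F") / norm(XtX_true, "F")
  expect_lt(rel, 0.05)   # HWE diagonal vs empirical variance: sampling noise
  expect_equal(unname(st$Xty), unname(Xty_true), tolerance = 0.05)

  # with panel-derived diagonals and panel == study data the match is exact
  st2 <- estimate_population_stats(ti$sumstats, panel, snp_union = ti$ids,
                                   diag_from_panel = TRUE)[[1L]]
  scale_fix <- 5000 / (5000 - 1)
  expect_equal(st2$XtX, XtX_true * scale_fix, tolerance = 1e-10)
})

test_that("stacking is an elementwise sum with zero padding for missing SNPs", {
  ids <- toy_ids(3L)
  mk <- function(pop, betas, drop_snp = NULL) {
    keep <- setdiff(ids, drop_snp)
    ss <- sumstats(data.frame(snp_id = keep, effect_allele = "G",
                              other_allele = "A", eaf = 0.3,
                              beta = betas[match(keep, ids)], se = 0.05,
                              n = 1000L),
                   study_id = paste0(pop, "_s1"), population_id = pop,
                   quiet = TRUE)
    co <- make_ld_matrix(length(keep), 1L, 0.4)
    dimnames(co) <- list(keep, keep)
    panel <- ref_panel(corr = co,
                       eaf = stats::setNames(rep(0.3, length(keep)), keep),
                       n_ref = 500, population_id = pop, snp_ids = keep)
    estimate_population_stats(ss, panel, snp_union = ids)[[1L]]
  }
  s1 <- mk("pop1", c(0.1, 0.2, 0.3))
  s2 <- mk("pop2", c(0.1, 0.2, 0.3), drop_snp = ids[2L])
  s3 <- mk("pop3", c(0.1, 0.2, 0.3))
  stacked <- stack_populations(list(s1, s2, s3), snp_union = ids)

  expect_equal(stacked$A, s1$XtX + s2$XtX + s3$XtX)
  expect_equal(stacked$b, s1$Xty + s2$Xty + s3$Xty)
  expect_equal(stacked$N, 3000)
  # SNP 2 is missing in pop2: its row receives pop1 + pop3 only
  expect_equal(stacked$A[2L, ], (s1$XtX + s3$XtX)[2L, ])
  expect_true(all(s2$XtX[2L, ] == 0))

  # single component: stacking is the identity
  solo <- stack_populations(list(s1), snp_union = ids)
  expect_equal(solo$A, s1$XtX)

  # linearity over disjoint component lists
  part <- stack_populations(list(s1, s2), snp_union = ids)
  expect_equal(part$A + s3$XtX, stacked$A)
  expect_equal(part$b + s3$Xty, stacked$b)
})

test_that("stacked statistics approximate the pooled mega-regression", {
  set.seed(5)
  parts <- lapply(1:3, function(i) {
    ti <- toy_individual(n = 3000, p = 4, r = 0.5,
                         beta = c(0.05, 0, 0, 0), seed = 10 + i)
    ss <- ti$sumstats
    attr(ss, "population_id") <- paste0("pop", i)
    panel <- ref_panel(dosage = ti$G, population_id = paste0("pop", i))
    list(stat = estimate_population_stats(ss, panel,
                                          snp_union = ti$ids)[[1L]],
         Gc = ti$Gc, y = ti$y)
  })
  stacked <- stack_populations(lapply(parts, `[[`, "stat"))
  A_mega <- Reduce(`+`, lapply(parts, function(p) crossprod(p$Gc)))
  b_mega <- Reduce(`+`, lapply(parts, function(p) drop(crossprod(p$Gc, p$y))))
  expect_lt(norm(stacked$A - A_mega, "F") / norm(A_mega, "F"), 0.05)
  expect_equal(unname(stacked$b), unname(b_mega), tolerance = 0.05)
})

test_that("ridge regularization activates only when needed and restores PD", {
  A <- diag(3)
  r <- regularize_to_pd(A)
  expect_identical(r$A, A)
  expect_equal(r$ridge_applied, 0)

  # duplicated SNP column: rank deficient, must become PD
  M <- matrix(c(1, 1, 0.5, 1, 1, 0.5, 0.5, 0.5, 2), 3, 3)
  r2 <- regularize_to_pd(M)
  expect_gt(min(eigen(r2$A, symmetric = TRUE)$values), 0)
  expect_gt(r2$ridge_applied, 0)

  # PSD with a zero eigenvalue: first-pass ridge is eps_rel * mean(diag)
  P <- matrix(c(1, 1, 1, 1), 2, 2)
  r3 <- regularize_to_pd(P, eps_rel = 1e-6)
  expect_equal(r3$ridge_applied, 1e-6 * 1)
  expect_equal(diag(r3$A), diag(P) + 1e-6)

  expect_error(regularize_to_pd(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
})

test_that("g-prior fit has the closed form under orthogonality and shrinks to zero on null data", {
  d <- c(40, 90, 160)
  b <- c(4, -9, 0.8)
  st <- toy_stats(diag(d), b, yty = 999, N = 1000)
  g <- 50
  fit <- gprior_fit(st, st$snp_union, g = g)
  expect_equal(unname(fit$beta_global), (g / (1 + g)) * b / d)

  st0 <- toy_stats(diag(d), rep(0, 3), yty = 999, N = 1000)
  fit0 <- gprior_fit(st0, st0$snp_union)
  expect_equal(unname(fit0$beta_global), rep(0, 3))
  expect_equal(unname(fit0$pvalues), rep(1, 3))

  expect_error(gprior_fit(st, character(0)), "null model")
})

test_that("shrinkage is monotone in g for a diagonal design", {
  d <- c(40, 90)
  st <- toy_stats(diag(d), c(4, -9), yty = 999, N = 1000)
  g_grid <- c(1, 10, 100, 1e4)
  betas <- sapply(g_grid, function(g) {
    abs(gprior_fit(st, st$snp_union, g = g)$beta_global)
  })
  expect_true(all(diff(t(betas)) >= 0))
})

test_that("the g -> infinity joint fit reproduces individual-level least squares", {
  ti <- toy_individual(n = 2000, p = 6, r = 0.5,
                       beta = c(0.08, 0, -0.05, 0, 0, 0), seed = 8)
  panel <- ref_panel(dosage = ti$G, population_id = "pop1")
  st <- stack_populations(estimate_population_stats(
    ti$sumstats, panel, snp_union = ti$ids, diag_from_panel = TRUE))
  fit <- gprior_fit(st, st$snp_union, g = 1e12)
  ols <- stats::lm(ti$y ~ ti$Gc)
  co <- summary(ols)$coefficients[-1L, ]
  expect_equal(unname(fit$beta_global), unname(co[, 1L]), tolerance = 1e-3)
  expect_equal(unname(fit$se), unname(co[, 2L]), tolerance = 1e-2)
})

test_that("conditional p-values match two-covariate regression and flag collinearity", {
  ti <- toy_individual(n = 4000, p = 2, r = 0.5, beta = c(0.07, 0.02),
                       seed = 13)
  panel <- ref_panel(dosage = ti$G, population_id = "pop1")
  st <- stack_populations(estimate_population_stats(
    ti$sumstats, panel, snp_union = ti$ids, diag_from_panel = TRUE))
  cp <- conditional_pvalues(st, ti$ids[1L], ti$ids[2L], g = 1e12)
  lm2 <- summary(stats::lm(ti$y ~ ti$Gc))$coefficients
  expect_equal(cp$p, lm2[3L, 4L], tolerance = 1e-2)
  expect_equal(cp$beta, lm2[3L, 1L], tolerance = 1e-6)

  # an exact duplicate of the index SNP cannot be conditioned on
  ids3 <- c(ti$ids, "chr1:999:A:G")
  A3 <- st$A[c(1, 2, 1), c(1, 2, 1)]
  b3 <- st$b[c(1, 2, 1)]
  st3 <- toy_stats(A3, b3, yty = st$yty_total, N = st$N, ids = ids3)
  cp3 <- conditional_pvalues(st3, ids3[1L], ids3[3L])
  expect_true(cp3$flagged)
  expect_equal(cp3$p, 1)
})

test_that("a candidate orthogonal to the index keeps its marginal p-value", {
  d <- c(100, 80)
  b <- c(30, 10)
  st <- toy_stats(diag(d), b, yty = 9999, N = 10000)
  marg <- conditional_pvalues(st, character(0), st$snp_union[2L])
  cond <- conditional_pvalues(st, st$snp_union[1L], st$snp_union[2L])
  # identical up to the residual-variance update from adding the index
  expect_equal(cond$p, marg$p, tolerance = 0.05)
  expect_equal(cond$beta, marg$beta, tolerance = 1e-10)
})

test_that("marginal p-values are uniform under the global null", {
  cfg <- scenario_config(p = 50L, n_blocks = 5L, r_within = 0,
                         causal_idx = 25L, beta_causal = 0,
                         n_per_study = 2000L, n_ref = 2000L)
  pvals <- unlist(lapply(1:200, function(r) {
    sim <- simulate_sumstats_fast(cfg, seed = 5000 + r)
    st <- region_mjam_stats(sim)
    conditional_pvalues(st, character(0), st$snp_union)$p
  }))
  expect_equal(length(pvals), 10000L)
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("log odds ratios transform to the linear scale consistently", {
  tr <- logistic_to_linear(0, 0.1, 500, 500)
  expect_equal(tr$beta_lin, 0)
  expect_equal(sign(logistic_to_linear(0.3, 0.1, 300, 700)$beta_lin), 1)
  expect_equal(sign(logistic_to_linear(-0.3, 0.1, 300, 700)$beta_lin), -1)

  # dual-analysis oracle: logistic and linear fits of the same binary trait
  set.seed(21)
  n <- 20000
  g <- stats::rbinom(n, 2L, 0.3)
  eta <- -0.0 + 0.15 * g
  y <- stats::rbinom(n, 1L, stats::plogis(eta - mean(eta)))
  b_log <- stats::glm(y ~ g, family = stats::binomial())$coefficients[2L]
  b_lin <- stats::lm(y ~ g)$coefficients[2L]
  tr2 <- logistic_to_linear(b_log, 0.05, sum(y), sum(1 - y))
  expect_equal(unname(tr2$beta_lin), unname(b_lin), tolerance = 0.005)
})
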