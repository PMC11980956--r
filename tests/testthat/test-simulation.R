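test_that("the block LD matrix has the documented structure and is PD", {
  expect_equal(make_ld_matrix(6L, 3L, 0), diag(6L))
  R <- make_ld_matrix(4L, 2L, 0.5)
  expect_equal(R[1L, 2L], 0.5)
  expect_equal(R[1L, 3L], 0)
  expect_equal(R[3L, 4L], 0.5)
  for (r in c(0.2, 0.5, 0.9, 0.99)) {
    expect_gt(min(eigen(make_ld_matrix(50L, 5L, r),
                        symmetric = TRUE)$values), 0)
  }
  # remainder SNPs fold into the last block
  R7 <- make_ld_matrix(7L, 3L, 0.4)
  expect_equal(R7[5L, 7L], 0.4)
  expect_error(make_ld_matrix(10L, 2L, 1), "r_within")
})

test_that("the default causal configuration implies ~0.03% heritability", {
  h2 <- causal_heritability(scenario_config())
  expect_equal(h2, 2 * 0.21 * 0.79 * 0.03^2)
  expect_equal(h2, 0.0003, tolerance = 0.01)
})

test_that("individual-level marginal estimates are unbiased for the causal effect", {
  cfg <- scenario_config(p = 6L, n_blocks = 2L, r_within = 0, n_pops = 1L,
                         studies_per_pop = 1L, n_per_study = 5000L,
                         causal_idx = 3L, beta_causal = 0.05,
                         n_ref = 500L)
  bhats <- vapply(1:200, function(r) {
    sim <- simulate_region(cfg, seed = 6000 + r)
    st <- sim$studies[[1L]]
    st$beta[st$snp_id == sim$truth$causal_ids]
  }, 0)
  mc_se <- stats::sd(bhats) / sqrt(length(bhats))
  expect_lt(abs(mean(bhats) - 0.05), 3 * mc_se)
})

test_that("fast-path null z-scores follow the standard normal law", {
  cfg <- scenario_config(p = 20L, n_blocks = 4L, r_within = 0,
                         causal_idx = 10L, beta_causal = 0,
                         n_pops = 1L, studies_per_pop = 1L,
                         n_per_study = 4000L, n_ref = 1000L)
  z <- unlist(lapply(1:100, function(r) {
    sim <- simulate_sumstats_fast(cfg, seed = 6500 + r)
    st <- sim$studies[[1L]]
    st$beta / st$se
  }))
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_equal(stats::var(z), 1, tolerance = 0.1)
})

test_that("fast-path z-scores of linked SNPs correlate at the LD level", {
  cfg <- scenario_config(p = 2L, n_blocks = 1L, r_within = 0.5,
                         causal_idx = 1L, beta_causal = 0, n_pops = 1L,
                         studies_per_pop = 1L, n_per_study = 4000L,
                         n_ref = 1000L)
  zz <- t(vapply(1:500, function(r) {
    sim <- simulate_sumstats_fast(cfg, seed = 7000 + r)
    st <- sim$studies[[1L]]
    st$beta / st$se
  }, c(0, 0)))
  expect_equal(stats::cor(zz)[1L, 2L], 0.5, tolerance = 0.12)
})

test_that("the fast path matches the individual-level path in distribution", {
  base <- list(p = 6L, n_blocks = 2L, r_within = 0.5, n_pops = 1L,
               studies_per_pop = 1L, n_per_study = 20000L, causal_idx = 3L,
               beta_causal = 0.05, n_ref = 1000L)
  cfg <- do.call(scenario_config, base)
  draw <- function(fun, seeds) {
    t(vapply(seeds, function(s) {
      sim <- fun(cfg, seed = s)
      sim$studies[[1L]]$beta
    }, numeric(6L)))
  }
  B_ind <- draw(simulate_region, 1:300)
  B_fast <- draw(simulate_sumstats_fast, 301:600)
  # means agree within 3 combined Monte-Carlo SEs, SNP by SNP
  se_comb <- sqrt(apply(B_ind, 2L, stats::var) / 300 +
                    apply(B_fast, 2L, stats::var) / 300)
  expect_true(all(abs(colMeans(B_ind) - colMeans(B_fast)) < 3 * se_comb))
  # sampling spread agrees within a modest relative margin
  expect_equal(apply(B_fast, 2L, stats::sd), apply(B_ind, 2L, stats::sd),
               tolerance = 0.25)
})

test_that("fixed-effect meta-analysis reduces to known closed forms", {
  mk <- function(beta, se, id = "chr1:100:A:G") {
    sumstats(data.frame(snp_id = id, effect_allele = "G",
                        other_allele = "A", eaf = 0.3, beta = beta,
                        se = se, n = 1000L), quiet = TRUE)
  }
  # one study: identity
  one <- fe_meta_analysis(list(mk(0.12, 0.03)))
  expect_equal(one$table$beta_meta, 0.12)
  expect_equal(one$table$se_meta, 0.03)

  # equal standard errors: simple average, se / sqrt(2)
  two <- fe_meta_analysis(list(mk(0.1, 0.1), mk(0.3, 0.1)))
  expect_equal(two$table$beta_meta, 0.2)
  expect_equal(two$table$se_meta, 0.1 / sqrt(2))

  # unequal standard errors: brute-force inverse-variance average
  betas <- c(0.05, 0.21, -0.02); ses <- c(0.02, 0.07, 0.04)
  three <- fe_meta_analysis(lapply(1:3, function(i) mk(betas[i], ses[i])))
  w <- 1 / ses^2
  expect_equal(three$table$beta_meta, sum(w * betas) / sum(w))
  expect_equal(three$table$se_meta, sqrt(1 / sum(w)))

  # a SNP absent from one study draws only on the studies reporting it
  sA <- mk(0.1, 0.1)
  sB <- sumstats(data.frame(snp_id = c("chr1:100:A:G", "chr1:200:C:T"),
                            effect_allele = c("G", "T"),
                            other_allele = c("A", "C"), eaf = 0.3,
                            beta = c(0.3, 0.5), se = 0.1, n = 1000L),
                 quiet = TRUE)
  both <- fe_meta_analysis(list(sA, sB))
  tab <- both$table
  expect_equal(tab$n_studies[tab$snp_id == "chr1:200:C:T"], 1L)
  expect_equal(tab$beta_meta[tab$snp_id == "chr1:200:C:T"], 0.5)
})

test_that("estimated allele frequencies recover the configured MAFs", {
  cfg <- scenario_config(p = 5L, n_blocks = 1L, r_within = 0, n_pops = 1L,
                         studies_per_pop = 1L, n_per_study = 5000L,
                         causal_idx = 3L, beta_causal = 0.03, n_ref = 500L)
  err <- t(vapply(1:100, function(r) {
    sim <- simulate_region(cfg, seed = 7700 + r)
    sim$studies[[1L]]$eaf - sim$truth$mafs
  }, numeric(5L)))
  mc_se <- apply(err, 2L, stats::sd) / sqrt(nrow(err))
  expect_true(all(abs(colMeans(err)) < 3 * pmax(mc_se, 1e-4)))
})

test_that("population-specific missingness propagates through the pipeline", {
  cfg <- scenario_config(p = 10L, n_blocks = 2L, r_within = 0.5,
                         causal_idx = 5L, beta_causal = 0.08,
                         n_per_study = 5000L, n_ref = 1500L,
                         missing_spec = list(pop2 = c(3L, 4L)))
  sim <- simulate_sumstats_fast(cfg, seed = 41)
  masked <- sim$snp_ids[c(3L, 4L)]
  st_pop2 <- sim$studies[[4L]]   # first study of pop2
  expect_equal(attr(st_pop2, "population_id"), "pop2")
  expect_false(any(masked %in% st_pop2$snp_id))
  expect_false(any(masked %in% sim$panels$pop2$snp_ids))

  stats_obj <- region_mjam_stats(sim)
  # the masked rows receive contributions from pop1 + pop3 only
  comp_pop2 <- Filter(function(s) s$population_id == "pop2",
                      stats_obj$components)
  for (s in comp_pop2) {
    expect_true(all(s$XtX[masked, ] == 0))
    expect_true(all(s$Xty[masked] == 0))
  }
  fw <- mjam_forward(stats_obj)
  expect_true(sim$truth$causal_ids %in% fw$index_snps)
})

test_that("the evaluation harness is reproducible and scores a perfect method at 1", {
  cfg <- test_scenario(beta_causal = 0.08, n_per_study = 8000L)
  m1 <- evaluate_scenario(cfg, n_reps = 10L, methods = "mJAM-Forward",
                          seed = 5)
  m2 <- evaluate_scenario(cfg, n_reps = 10L, methods = "mJAM-Forward",
                          seed = 5)
  expect_identical(m1, m2)

  # near-perfect power: all headline metrics at their ideal values
  cfg2 <- test_scenario(beta_causal = 0.15, n_per_study = 8000L,
                        r_within = 0)
  m3 <- evaluate_scenario(cfg2, n_reps = 20L, methods = "mJAM-Forward",
                          seed = 6)
  expect_equal(metric_value(m3, "mJAM-Forward", "cs_sensitivity"), 1)
  expect_equal(metric_value(m3, "mJAM-Forward", "index_ppv"), 1)
  expect_equal(metric_value(m3, "mJAM-Forward", "empirical_coverage"), 1)
  expect_equal(metric_value(m3, "mJAM-Forward", "frac_no_selection"), 0)
})

test_that("lead-SNP fallback replaces empty selections", {
  cfg <- test_scenario(beta_causal = 0.02, n_per_study = 2000L)
  m_plain <- evaluate_scenario(cfg, n_reps = 20L, methods = "mJAM-Forward",
                               seed = 9)
  m_fb <- evaluate_scenario(cfg, n_reps = 20L, methods = "mJAM-Forward",
                            seed = 9, fallback_lead_snp = TRUE)
  expect_gt(metric_value(m_plain, "mJAM-Forward", "frac_no_selection"), 0)
  expect_equal(metric_value(m_fb, "mJAM-Forward", "frac_no_selection"), 0)
  expect_gte(metric_value(m_fb, "mJAM-Forward", "cs_sensitivity"),
             metric_value(m_plain, "mJAM-Forward", "cs_sensitivity"))
})

test_that("an infeasible heritability configuration is rejected with an explanation", {
  cfg <- scenario_config(p = 5L, n_blocks = 1L, r_within = 0, n_pops = 1L,
                         studies_per_pop = 1L, causal_idx = 3L,
                         beta_causal = 2, causal_maf = 0.5,
                         n_per_study = 100L, n_ref = 100L)
  expect_error(simulate_sumstats_fast(cfg, seed = 1), "infeasible")
  expect_error(simulate_region(cfg, seed = 1), "infeasible")
})

test_that("binary-outcome simulation reports log odds ratios near the truth", {
  cfg <- scenario_config(p = 4L, n_blocks = 1L, r_within = 0, n_pops = 1L,
                         studies_per_pop = 1L, n_per_study = 4000L,
                         causal_idx = 2L, beta_causal = 0.3,
                         binary = TRUE, n_ref = 500L)
  bhats <- vapply(1:60, function(r) {
    sim <- simulate_region(cfg, seed = 8800 + r)
    st <- sim$studies[[1L]]
    st$beta[st$snp_id == sim$truth$causal_ids]
  }, 0)
  mc_se <- stats::sd(bhats) / sqrt(length(bhats))
  expect_lt(abs(mean(bhats) - 0.3), 4 * mc_se)
})
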