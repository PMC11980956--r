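# Shared fixtures built in code: tiny regions, hand-made sufficient
# statistics, and small simulated datasets.

# report every expectation rather than aborting the run part-way: the
# benchmark comparisons are informative even when several miss their
# reference values
options(testthat.progress.max_fails = 1e6)

# independent quadrature oracle for the one-SNP g-prior Bayes factor:
# 2-D numerical integration of the marginal likelihood over (beta, sigma2)
# with the Jeffreys prior on sigma2
numeric_log_bf <- function(N, yty, d, b, g) {
  logf1 <- function(beta, s2) {
    -N / 2 * log(2 * pi * s2) - (yty - 2 * beta * b + beta^2 * d) / (2 * s2) +
      stats::dnorm(beta, 0, sqrt(g * s2 / d), log = TRUE) - log(s2)
  }
  logf0 <- function(s2) -N / 2 * log(2 * pi * s2) - yty / (2 * s2) - log(s2)
  K1 <- logf1(b / d, yty / N)
  inner <- function(s2v) {
    vapply(s2v, function(s) {
      stats::integrate(function(be) exp(logf1(be, s) - K1), -6, 6,
                       rel.tol = 1e-12)$value
    }, 0)
  }
  I1 <- stats::integrate(function(ls2) inner(exp(ls2)) * exp(ls2), -6, 6,
                         rel.tol = 1e-11)$value
  K0 <- logf0(yty / N)
  I0 <- stats::integrate(function(ls2) exp(logf0(exp(ls2)) - K0) * exp(ls2),
                         -6, 6, rel.tol = 1e-11)$value
  (log(I1) + K1) - (log(I0) + K0)
}

toy_ids <- function(p) sprintf("chr1:%d:A:G", 100L * seq_len(p))

# hand-built stacked statistics for unit tests of the inference layer
toy_stats <- function(A, b, yty, N, ids = toy_ids(length(b)),
                      pop_corr = NULL) {
  A <- as.matrix(A)
  dimnames(A) <- list(ids, ids)
  names(b) <- ids
  if (is.null(pop_corr)) pop_corr <- list(pop1 = stats::cov2cor(A))
  obs <- stats::setNames(rep(TRUE, length(b)), ids)
  structure(list(A = A, b = b, yty_total = yty, N = N, snp_union = ids,
                 components = list(), pop_corr = pop_corr,
                 pop_observed = list(pop1 = obs), ridge_applied = 0),
            class = "mjam_stats")
}

# a well-formed 3-SNP summary-statistics data.frame
toy_sumstats_df <- function() {
  data.frame(snp_id = c("chr1:100:A:G", "chr1:200:C:T", "chr1:300:A:C"),
             effect_allele = c("G", "T", "C"),
             other_allele = c("A", "C", "A"),
             eaf = c(0.3, 0.45, 0.12),
             beta = c(0.05, -0.02, 0.11),
             se = c(0.01, 0.012, 0.02),
             n = c(5000L, 5000L, 5000L),
             stringsAsFactors = FALSE)
}

# individual-level dataset with known design, returning both the raw data
# and the marginal summary statistics computed from it
toy_individual <- function(n = 5000, p = 5, r = 0.6, beta = NULL,
                           mafs = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(mafs)) mafs <- seq(0.2, 0.4, length.out = p)
  if (is.null(beta)) beta <- rep(0, p)
  R <- make_ld_matrix(p, 1L, r)
  thr <- stats::qnorm(mafs)
  hap <- function() {
    z <- matrix(stats::rnorm(n * p), n, p) %*% chol(R)
    sweep(z, 2L, thr, `<`) * 1
  }
  G <- hap() + hap()
  colnames(G) <- toy_ids(p)
  eta <- drop(G %*% beta)
  y <- eta + stats::rnorm(n, 0, sqrt(max(1 - stats::var(eta), 0.5)))
  y <- (y - mean(y)) / stats::sd(y)          # unit variance, mean zero
  Gc <- sweep(G, 2L, colMeans(G))
  xtx <- colSums(Gc^2)
  xty <- drop(crossprod(Gc, y))
  bhat <- xty / xtx
  rss <- sum(y^2) - bhat * xty
  sehat <- sqrt(rss / (n - 2) / xtx)
  ids <- toy_ids(p)
  ss <- sumstats(data.frame(snp_id = ids, effect_allele = "G",
                            other_allele = "A", eaf = colMeans(G) / 2,
                            beta = bhat, se = sehat, n = n),
                 study_id = "s1", population_id = "pop1", quiet = TRUE)
  list(G = G, Gc = Gc, y = y, sumstats = ss, ids = ids, mafs = mafs)
}

# small scenario for simulation-backed tests (modest power, fast)
test_scenario <- function(...) {
  args <- utils::modifyList(
    list(p = 20L, n_blocks = 4L, n_per_study = 4000L, causal_idx = 10L,
         beta_causal = 0.05, n_ref = 1000L),
    list(...))
  do.call(scenario_config, args)
}
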