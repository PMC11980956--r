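# Sum-of-single-effects regression on stacked sufficient statistics.
#
# Iterative Bayesian single-effect selection (IBSS) operating directly on
# (X'X, X'y, y'y, n): the joint effect vector is modeled as a sum of L
# vectors, each with exactly one non-zero coordinate. Deterministic
# coordinate ascent from a zero initialization; convergence is monitored by
# the evidence lower bound (ELBO), which is non-decreasing across sweeps.

#' Configuration for the sum-of-single-effects engine
#'
#' @param L maximum number of single effects (default 10).
#' @param coverage credible-set coverage level (default 0.95).
#' @param purity_min minimum absolute pairwise correlation within a
#'   reported set (default 0.5); impure sets are discarded.
#' @param max_iter maximum IBSS sweeps (default 100).
#' @param tol ELBO convergence tolerance (default 1e-3).
#' @param prior_variance fixed scaled prior effect variance, or `NULL` to
#'   estimate it per effect by empirical Bayes.
#' @param estimate_residual_variance re-estimate the residual variance each
#'   sweep (default TRUE).
#' @return A `susie_config` list.
#' @export
susie_config <- function(L = 10L, coverage = 0.95, purity_min = 0.5,
                         max_iter = 100L, tol = 1e-3, prior_variance = NULL,
                         estimate_residual_variance = TRUE) {
  stopifnot(L >= 1L, coverage > 0, coverage <= 1)
  structure(list(L = as.integer(L), coverage = coverage,
                 purity_min = purity_min, max_iter = as.integer(max_iter),
                 tol = tol, prior_variance = prior_variance,
                 estimate_residual_variance = estimate_residual_variance),
            class = "susie_config")
}

# single-effect regression on residualized score r_l: returns posterior
# inclusion weights, moments and the log marginal likelihood gain over the
# null, under prior effect variance V (on the raw effect scale)
.ser_fit <- function(r_l, d, sigma2, V, log_pi) {
  shat2 <- sigma2 / d
  bhat <- r_l / d
  if (V <= 0) {
    alpha <- exp(log_pi - max(log_pi))
    alpha <- alpha / sum(alpha)
    return(list(alpha = alpha, mu1 = rep(0, length(d)),
                var1 = rep(0, length(d)), lbf_model = 0, V = 0))
  }
  lbf <- stats::dnorm(bhat, 0, sqrt(V + shat2), log = TRUE) -
    stats::dnorm(bhat, 0, sqrt(shat2), log = TRUE)
  lw <- lbf + log_pi
  m <- max(lw)
  w <- exp(lw - m)
  alpha <- w / sum(w)
  var1 <- 1 / (1 / V + d / sigma2)
  mu1 <- var1 * r_l / sigma2
  list(alpha = alpha, mu1 = mu1, var1 = var1,
       lbf_model = m + log(sum(w)), V = V)
}

# empirical-Bayes choice of the prior variance for one single effect:
# maximizes the SER log marginal likelihood over V >= 0
.ser_optimize_V <- function(r_l, d, sigma2, log_pi, V_init) {
  obj <- function(logV) {
    .ser_fit(r_l, d, sigma2, exp(logV), log_pi)$lbf_model
  }
  opt <- stats::optimize(obj, interval = c(-30, 10), maximum = TRUE)
  if (opt$objective <= 0) 0 else exp(opt$maximum)
}

#' Fit the sum-of-single-effects model on stacked sufficient statistics
#'
#' @param stats a `mjam_stats` object (`A` is ridge-regularized here if
#'   needed).
#' @param config a [susie_config].
#' @return A `susie_fit`: `alpha` (L x p, rows sum to 1), `mu` (L x p
#'   posterior means given inclusion), `pip`, `V` (per-effect prior
#'   variances), `sigma2`, `elbo_trace`, `converged`, `credible_sets`,
#'   `index_per_set`, `snp_union`.
#' @export
susie_fit_sufficient <- function(stats, config = susie_config()) {
  stopifnot(inherits(stats, "mjam_stats"))
  stats <- regularize_stats(stats)
  A <- stats$A
  b <- stats$b
  n <- stats$N
  yty <- stats$yty_total
  p <- length(b)
  L <- config$L
  log_pi <- rep(-log(p), p)
  d <- diag(A)

  alpha <- matrix(1 / p, L, p)
  mu1 <- matrix(0, L, p)
  var1 <- matrix(0, L, p)
  V <- rep(if (is.null(config$prior_variance)) 0.2 * yty / n else
    config$prior_variance, L)
  sigma2 <- yty / n
  beta_bar_l <- matrix(0, L, p)  # alpha * mu per effect
  beta_bar <- rep(0, p)

  erss <- function() {
    bb <- colSums(beta_bar_l)
    quad <- drop(t(bb) %*% A %*% bb)
    quad <- quad - sum(vapply(seq_len(L), function(l) {
      drop(t(beta_bar_l[l, ]) %*% A %*% beta_bar_l[l, ])
    }, 0))
    quad <- quad + sum(vapply(seq_len(L), function(l) {
      sum(alpha[l, ] * (mu1[l, ]^2 + var1[l, ]) * d)
    }, 0))
    yty - 2 * sum(bb * b) + quad
  }
  kl_terms <- function() {
    sum(vapply(seq_len(L), function(l) {
      a <- alpha[l, ]
      nz <- a > 0
      ent <- sum(a[nz] * (log(a[nz]) - log_pi[nz]))
      if (V[l] > 0) {
        gauss <- 0.5 * (log(V[l] / pmax(var1[l, nz], 1e-300)) +
                          (var1[l, nz] + mu1[l, nz]^2) / V[l] - 1)
        ent <- ent + sum(a[nz] * gauss)
      }
      ent
    }, 0))
  }

  elbo_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    Abar <- drop(A %*% beta_bar)
    for (l in seq_len(L)) {
      r_l <- b - Abar + drop(A %*% beta_bar_l[l, ])
      if (is.null(config$prior_variance)) {
        V[l] <- .ser_optimize_V(r_l, d, sigma2, log_pi, V[l])
      }
      ser <- .ser_fit(r_l, d, sigma2, V[l], log_pi)
      alpha[l, ] <- ser$alpha
      mu1[l, ] <- ser$mu1
      var1[l, ] <- ser$var1
      new_bl <- ser$alpha * ser$mu1
      Abar <- Abar + drop(A %*% (new_bl - beta_bar_l[l, ]))
      beta_bar_l[l, ] <- new_bl
    }
    beta_bar <- colSums(beta_bar_l)
    e <- erss()
    if (config$estimate_residual_variance) sigma2 <- max(e / n, 1e-12)
    elbo <- -0.5 * n * log(2 * pi * sigma2) - 0.5 * e / sigma2 - kl_terms()
    elbo_trace <- c(elbo_trace, elbo)
    if (it > 1L && abs(elbo - elbo_trace[it - 1L]) < config$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("sum-of-single-effects fit did not converge in ",
            config$max_iter, " sweeps")
  }

  dimnames(alpha) <- dimnames(mu1) <- list(NULL, stats$snp_union)
  pip <- 1 - apply(1 - alpha, 2L, prod)
  fit <- structure(list(alpha = alpha, mu = mu1, posterior_sd = sqrt(var1),
                        pip = stats::setNames(pip, stats$snp_union),
                        V = V, sigma2 = sigma2, elbo_trace = elbo_trace,
                        converged = converged, snp_union = stats$snp_union,
                        config = config),
                   class = "susie_fit")
  cs <- susie_credible_sets(fit, stats, config)
  fit$credible_sets <- cs
  fit$index_per_set <- vapply(cs, function(s) s$index_snp, "")
  fit
}

#' Credible sets from a sum-of-single-effects fit
#'
#' Per single effect, the smallest group of SNPs (by descending posterior
#' inclusion weight) whose cumulative weight reaches the coverage level.
#' Sets whose minimum absolute pairwise pooled-LD correlation falls below
#' `purity_min` are discarded; duplicate member sets are merged. Each
#' surviving set's index SNP is its member with the highest overall PIP.
#'
#' @param fit a `susie_fit`.
#' @param stats the `mjam_stats` the fit was computed from (pooled LD for
#'   the purity filter is `cov2cor(A)`, the sample-size-weighted
#'   combination of the population panels).
#' @param config a [susie_config].
#' @return List of sets: `members`, `member_probs`, `coverage`, `purity`,
#'   `index_snp`, `effect`.
#' @export
susie_credible_sets <- function(fit, stats, config = fit$config) {
  pooled <- stats::cov2cor(stats$A)
  sets <- list()
  seen <- character(0)
  for (l in seq_len(nrow(fit$alpha))) {
    if (fit$V[l] <= 0) next  # effect switched off by empirical Bayes
    a <- fit$alpha[l, ]
    ord <- order(-a, fit$snp_union)
    cum <- cumsum(a[ord])
    n_take <- which(cum >= config$coverage - 1e-12)[1L]
    if (is.na(n_take)) n_take <- length(a)
    members <- fit$snp_union[ord][seq_len(n_take)]
    key <- paste(sort(members), collapse = "|")
    if (key %in% seen) next
    purity <- if (length(members) == 1L) 1 else {
      sub <- abs(pooled[members, members])
      min(sub[upper.tri(sub)])
    }
    if (!is.finite(purity) || purity < config$purity_min) next
    seen <- c(seen, key)
    sets[[length(sets) + 1L]] <-
      list(members = members, member_probs = unname(a[ord][seq_len(n_take)]),
           coverage = unname(cum[n_take]), purity = purity,
           index_snp = members[which.max(fit$pip[members])], effect = l)
  }
  sets
}

#' @export
print.susie_fit <- function(x, ...) {
  cat("<susie_fit> L =", nrow(x$alpha), "-", length(x$credible_sets),
      "credible set(s),", if (x$converged) "converged" else "NOT converged",
      "in", length(x$elbo_trace), "sweep(s)\n")
  for (s in x$credible_sets) {
    cat("  set (effect", s$effect, "): index", s$index_snp, "-",
        length(s$members), "member(s), purity",
        format(s$purity, digits = 3), "\n")
  }
  invisible(x)
}
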