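# Stacked multipopulation sufficient statistics and g-prior inference.
#
# Each study contributes summary-level estimates of X'X, X'y and y'y for its
# population's (mean-centered) genotype design; stacking them yields the
# cross-products of the fixed-effect mega-regression across populations, on
# which all joint/conditional inference operates.

#' Per-study sufficient statistics from summary data and a reference panel
#'
#' For each study of one population, reconstructs the linear-model
#' cross-products over `snp_union`:
#' \itemize{
#'   \item diagonal `d_j = n * 2 * eaf_j * (1 - eaf_j)` (Hardy-Weinberg
#'     dosage variance at the study's own EAF), or, with
#'     `diag_from_panel = TRUE`, the panel's raw centered cross-product
#'     scaled by `n / (n_ref - 1)`;
#'   \item off-diagonals `XtX[j,k] = r_jk * sqrt(d_j d_k)` with `r` the
#'     panel dosage correlation;
#'   \item `Xty_j = d_j * beta_j` (the marginal-effect identity);
#'   \item `yty = n - 1` (phenotype standardized to unit variance).
#' }
#' SNPs unobserved in the study or the panel (or with zero panel dosage
#' variance, which triggers a warning) are masked and their rows/columns
#' zero-padded.
#'
#' @param study_group list of [sumstats] tables from one population.
#' @param panel the population's [ref_panel].
#' @param snp_union ordered ids defining the region (defaults to the union
#'   of the studies' SNPs).
#' @param diag_from_panel use panel empirical variances instead of the HWE
#'   diagonal.
#' @return List of `population_stats` objects (fields `XtX`, `Xty`, `yty`,
#'   `n`, `observed`, `corr`, `population_id`, `study_id`).
#' @export
estimate_population_stats <- function(study_group, panel, snp_union = NULL,
                                      diag_from_panel = FALSE) {
  if (inherits(study_group, "sumstats")) study_group <- list(study_group)
  if (is.null(snp_union)) {
    snp_union <- unique(unlist(lapply(study_group, `[[`, "snp_id")))
  }
  p <- length(snp_union)
  corr_full <- panel_correlation(panel)
  pe <- panel_eaf(panel)
  corr <- matrix(NA_real_, p, p, dimnames = list(snp_union, snp_union))
  in_panel <- snp_union %in% panel$snp_ids
  ip <- snp_union[in_panel]
  corr[ip, ip] <- corr_full[ip, ip]
  zero_var <- ip[is.na(diag(corr_full)[ip])]
  if (length(zero_var) > 0L) {
    warning(length(zero_var), " panel SNP(s) with zero dosage variance ",
            "masked as missing in population ", panel$population_id)
  }
  panel_ok <- stats::setNames(in_panel, snp_union)
  panel_ok[zero_var] <- FALSE

  lapply(study_group, function(st) {
    n <- stats::median(st$n)
    m <- match(snp_union, st$snp_id)
    observed <- !is.na(m) & panel_ok
    d <- rep(0, p)
    eaf <- ifelse(is.na(m), NA_real_, st$eaf[m])
    eaf[is.na(eaf) & observed] <- pe[snp_union[is.na(eaf) & observed]]
    if (diag_from_panel) {
      pv <- apply(panel$dosage[, snp_union[observed], drop = FALSE], 2L,
                  function(g) sum((g - mean(g))^2))
      d[observed] <- pv * n / (panel$n_ref - 1)
    } else {
      d[observed] <- n * 2 * eaf[observed] * (1 - eaf[observed])
    }
    XtX <- matrix(0, p, p, dimnames = list(snp_union, snp_union))
    obs_idx <- which(observed)
    if (length(obs_idx) > 0L) {
      r_obs <- corr[obs_idx, obs_idx, drop = FALSE]
      sd_obs <- sqrt(d[obs_idx])
      XtX[obs_idx, obs_idx] <- r_obs * tcrossprod(sd_obs)
      diag(XtX)[obs_idx] <- d[obs_idx]
    }
    Xty <- rep(0, p)
    Xty[obs_idx] <- d[obs_idx] * st$beta[m[obs_idx]]
    names(Xty) <- snp_union
    structure(list(population_id = attr(st, "population_id"),
                   study_id = attr(st, "study_id"),
                   XtX = XtX, Xty = Xty, yty = n - 1, n = n,
                   observed = stats::setNames(observed, snp_union),
                   corr = corr),
              class = "population_stats")
  })
}

#' Stack per-study statistics into multipopulation sufficient statistics
#'
#' Elementwise sums of the per-study cross-products: `A = sum XtX`,
#' `b = sum Xty`, `yty_total = sum yty`, `N = sum n`. Rows/columns of SNPs
#' missing in a study contribute exactly zero. Per-population panel
#' correlations and observation masks are carried along for LD pruning and
#' purity computations.
#'
#' @param all_stats list of `population_stats` (from
#'   [estimate_population_stats], possibly over several populations).
#' @param snp_union ordered ids; must match every component's alignment.
#' @return A `mjam_stats` object with fields `A`, `b`, `yty_total`, `N`,
#'   `snp_union`, `components`, `pop_corr`, `pop_observed`,
#'   `ridge_applied`.
#' @export
stack_populations <- function(all_stats, snp_union = NULL) {
  stopifnot(length(all_stats) >= 1L)
  if (is.null(snp_union)) snp_union <- colnames(all_stats[[1L]]$XtX)
  for (s in all_stats) {
    if (!identical(colnames(s$XtX), snp_union)) {
      stop("component SNP ordering does not match snp_union")
    }
  }
  A <- Reduce(`+`, lapply(all_stats, `[[`, "XtX"))
  b <- Reduce(`+`, lapply(all_stats, `[[`, "Xty"))
  yty_total <- sum(vapply(all_stats, `[[`, 0, "yty"))
  N <- sum(vapply(all_stats, `[[`, 0, "n"))
  pops <- unique(vapply(all_stats, `[[`, "", "population_id"))
  pop_corr <- lapply(stats::setNames(pops, pops), function(pop) {
    all_stats[[which(vapply(all_stats, `[[`, "", "population_id") == pop)[1L]]]$corr
  })
  pop_observed <- lapply(stats::setNames(pops, pops), function(pop) {
    Reduce(`|`, lapply(all_stats[vapply(all_stats, `[[`, "",
                                        "population_id") == pop],
                       `[[`, "observed"))
  })
  structure(list(A = A, b = b, yty_total = yty_total, N = N,
                 snp_union = snp_union, components = all_stats,
                 pop_corr = pop_corr, pop_observed = pop_observed,
                 ridge_applied = 0),
            class = "mjam_stats")
}

#' @export
print.mjam_stats <- function(x, ...) {
  cat("<mjam_stats>", length(x$snp_union), "SNPs,",
      length(x$components), "studies,", length(x$pop_corr),
      "populations, N =", x$N,
      if (x$ridge_applied > 0) paste("(ridge", signif(x$ridge_applied, 3), ")")
      else "", "\n")
  invisible(x)
}

#' Ridge-regularize a symmetric matrix to positive definiteness
#'
#' If the Cholesky factorization already succeeds, the matrix is returned
#' unchanged with ridge 0. Otherwise `eps_rel * mean(diag(A))` is added to
#' the diagonal, doubling `eps_rel` until the factorization succeeds.
#'
#' @param A symmetric matrix.
#' @param eps_rel initial relative ridge (default 1e-6).
#' @return List `(A, ridge_applied)`.
#' @export
regularize_to_pd <- function(A, eps_rel = 1e-6) {
  if (!isSymmetric(unname(A), tol = 1e-8)) {
    stop("regularize_to_pd: input matrix is not symmetric")
  }
  if (.chol_ok(A)) return(list(A = A, ridge_applied = 0))
  base <- mean(diag(A))
  if (base <= 0) base <- 1
  eps <- eps_rel
  repeat {
    ridge <- eps * base
    Ar <- A + diag(ridge, nrow(A))
    if (.chol_ok(Ar)) return(list(A = Ar, ridge_applied = ridge))
    eps <- eps * 2
    if (eps > 1e6) stop("regularize_to_pd: failed to reach positive definiteness")
  }
}

.chol_ok <- function(M) {
  !inherits(tryCatch(chol(M), error = function(e) e), "error")
}

#' Regularize stacked statistics in place
#'
#' Convenience wrapper applying [regularize_to_pd] to the `A` matrix of a
#' `mjam_stats` object.
#'
#' @param stats a `mjam_stats` object.
#' @param eps_rel passed to [regularize_to_pd].
#' @return The `mjam_stats` object with `A` positive definite and
#'   `ridge_applied` recorded.
#' @export
regularize_stats <- function(stats, eps_rel = 1e-6) {
  r <- regularize_to_pd(stats$A, eps_rel)
  stats$A <- r$A
  stats$ridge_applied <- r$ridge_applied
  stats
}

#' Joint fit of selected SNPs under a Zellner g-prior
#'
#' Posterior inference for the pooled (fixed-effect) joint coefficients of
#' `model_snps` from the stacked sufficient statistics: posterior mean
#' `beta = (g/(1+g)) * solve(A_S, b_S)`, covariance
#' `sigma2 * (g/(1+g)) * solve(A_S)` with the residual variance estimated
#' from `yty_total` (clamped to at least 1e-8, with a warning when the
#' implied residual sum of squares is negative), and two-sided normal
#' p-values. `g` defaults to `N` (unit-information prior).
#'
#' @param stats a `mjam_stats` object (regularize first for rank-deficient
#'   regions).
#' @param model_snps character vector of SNP ids to fit jointly.
#' @param g g-prior scale; `NULL` means `stats$N`.
#' @return A `joint_fit`: `model_snps`, `beta_global`, `se`, `zvalues`,
#'   `pvalues`, `sigma2`, `g`.
#' @export
gprior_fit <- function(stats, model_snps, g = NULL) {
  if (length(model_snps) == 0L) stop("null model has no coefficients")
  if (!all(model_snps %in% stats$snp_union)) {
    stop("model_snps not all present in snp_union")
  }
  if (is.null(g)) g <- stats$N
  k <- length(model_snps)
  A_S <- stats$A[model_snps, model_snps, drop = FALSE]
  b_S <- stats$b[model_snps]
  ch <- tryCatch(chol(A_S), error = function(e) NULL)
  if (is.null(ch)) {
    A_S <- regularize_to_pd(A_S)$A
    ch <- chol(A_S)
  }
  Ainv <- chol2inv(ch)
  shrink <- g / (1 + g)
  beta_ols <- drop(Ainv %*% b_S)
  beta <- shrink * beta_ols
  rss <- stats$yty_total - shrink * (2 - shrink) * sum(b_S * beta_ols)
  if (rss < 0) {
    warning("negative residual sum of squares from summary inputs; clamped")
  }
  sigma2 <- max(rss / (stats$N - k), 1e-8)
  se <- sqrt(pmax(sigma2 * shrink * diag(Ainv), .Machine$double.xmin))
  z <- beta / se
  pvalues <- 2 * stats::pnorm(-abs(z))
  structure(list(model_snps = model_snps,
                 beta_global = stats::setNames(beta, model_snps),
                 se = stats::setNames(se, model_snps),
                 zvalues = stats::setNames(z, model_snps),
                 pvalues = stats::setNames(pmin(pmax(pvalues,
                                                     .Machine$double.xmin), 1),
                                           model_snps),
                 sigma2 = sigma2, g = g),
            class = "joint_fit")
}

#' @export
print.joint_fit <- function(x, ...) {
  df <- data.frame(snp = x$model_snps, beta = x$beta_global, se = x$se,
                   z = x$zvalues, p = x$pvalues)
  rownames(df) <- NULL
  cat("<joint_fit> g =", format(x$g), " sigma2 =", format(x$sigma2), "\n")
  print(df, digits = 4)
  invisible(x)
}

#' Conditional p-values given a set of index SNPs
#'
#' For each candidate `c`, the two-sided p-value of `c`'s coefficient in
#' the g-prior joint fit of `index_set + c`. With an empty `index_set`
#' these are the marginal (one-SNP-model) p-values. Candidates whose
#' augmented design is numerically singular even after ridge regularization
#' are assigned p = 1 and flagged.
#'
#' @param stats a `mjam_stats` object.
#' @param index_set character vector of current index SNPs (may be empty).
#' @param candidates character vector of candidate SNPs, disjoint from
#'   `index_set`.
#' @param g g-prior scale; `NULL` means `stats$N`.
#' @return data.frame with `snp_id`, `p`, `z`, `beta`, `flagged`.
#' @export
conditional_pvalues <- function(stats, index_set, candidates, g = NULL) {
  stopifnot(!any(candidates %in% index_set))
  out <- data.frame(snp_id = candidates, p = 1, z = 0, beta = 0,
                    flagged = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(candidates)) {
    cand <- candidates[i]
    fit <- tryCatch(gprior_fit(stats, c(index_set, cand), g = g),
                    error = function(e) NULL)
    # variance inflation of the candidate relative to its marginal design;
    # astronomical values mean near-perfect collinearity with the index set
    vif <- if (is.null(fit)) Inf else {
      shrink <- fit$g / (1 + fit$g)
      fit$se[[cand]]^2 * diag(stats$A)[[cand]] / (fit$sigma2 * shrink)
    }
    bad <- is.null(fit) || !is.finite(fit$pvalues[[cand]]) || vif > 1e5
    if (bad) {
      out$flagged[i] <- TRUE
    } else {
      out$p[i] <- fit$pvalues[[cand]]
      out$z[i] <- fit$zvalues[[cand]]
      out$beta[i] <- fit$beta_global[[cand]]
    }
  }
  out
}

#' Transform a log odds ratio to the linear (observed) scale
#'
#' Standard observed-scale approximation for a balanced-design GWAS of a
#' binary trait analyzed by logistic regression: with case proportion
#' `phi = n_case / (n_case + n_control)`, `beta_lin = beta_logOR * phi *
#' (1 - phi)` and the standard error is scaled identically. Zero maps to
#' zero and the sign is preserved.
#'
#' @param beta_logOR log odds ratio(s).
#' @param se standard error(s) on the log-OR scale.
#' @param n_case,n_control case and control counts (> 0).
#' @return List `(beta_lin, se_lin)`.
#' @export
logistic_to_linear <- function(beta_logOR, se, n_case, n_control) {
  stopifnot(n_case > 0, n_control > 0)
  phi <- n_case / (n_case + n_control)
  scale <- phi * (1 - phi)
  list(beta_lin = beta_logOR * scale, se_lin = se * scale)
}
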