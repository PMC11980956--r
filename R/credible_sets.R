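# Mediation-weighted credible sets around index SNPs.
#
# Each candidate SNP W in the region of an index SNP X receives a posterior
# credible set probability (PCSP): the product of (i) the posterior
# probability of the one-SNP model containing W among all one-SNP models
# and (ii) the probability that X mediates W's marginal effect, judged from
# the gap between W's total effect (model without X) and direct effect
# (model with X). Scaled PCSPs define the rho-level credible set.

# log Bayes factor of the model holding `model_snps` against the null,
# under the Zellner g-prior with the residual variance integrated out
# (Jeffreys prior), for the intercept-free likelihood on centered data.
# Written to avoid cancellation at small R^2:
#   log BF = -k/2 log(1+g) - N/2 log(1 - g R^2 / (1+g))
.log_bf_gprior <- function(stats, model_snps, g) {
  A_S <- stats$A[model_snps, model_snps, drop = FALSE]
  b_S <- stats$b[model_snps]
  ch <- tryCatch(chol(A_S), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(regularize_to_pd(A_S)$A)
  ssr <- sum(backsolve(ch, b_S, transpose = TRUE)^2)
  R2 <- min(max(ssr / stats$yty_total, 0), 1 - 1e-12)
  k <- length(model_snps)
  -0.5 * k * log1p(g) - 0.5 * stats$N * log1p(-g * R2 / (1 + g))
}

#' Posterior probabilities of one-SNP models
#'
#' Closed-form g-prior Bayes factors of each one-SNP model against the
#' null, normalized over the candidate pool (optionally including the null
#' model). Computed in log space; exact ties are preserved.
#'
#' @param stats a `mjam_stats` object.
#' @param candidates non-empty character vector of SNP ids.
#' @param g g-prior scale; `NULL` means `stats$N`.
#' @param prior per-model prior weights (default uniform); recycled and
#'   renormalized.
#' @param include_null also place the null model in the denominator.
#' @return List with `model_prob` (named, sums to 1 over candidates),
#'   `log_bf` (named), and `null_prob` (0 unless `include_null`).
#' @export
one_snp_posteriors <- function(stats, candidates, g = NULL, prior = NULL,
                               include_null = FALSE) {
  stopifnot(length(candidates) >= 1L)
  if (is.null(g)) g <- stats$N
  if (is.null(prior)) prior <- rep(1, length(candidates))
  prior <- prior / sum(prior)
  log_bf <- vapply(candidates, function(w) .log_bf_gprior(stats, w, g), 0)
  lw <- log_bf + log(prior)
  if (include_null) lw <- c(lw, 0)  # BF(null:null) = 1, unit prior weight
  m <- max(lw)
  w <- exp(lw - m)
  post <- w / sum(w)
  null_prob <- if (include_null) post[[length(post)]] else 0
  model_prob <- post[seq_along(candidates)]
  list(model_prob = stats::setNames(model_prob, candidates),
       log_bf = stats::setNames(log_bf, candidates),
       null_prob = null_prob)
}

#' Mediation probability of an index SNP for a candidate SNP
#'
#' Fits two g-prior models for candidate `W`: the "total" model (`W` plus
#' any earlier index SNPs) and the "direct" model (the same plus the
#' current index SNP). `t_obs` is the difference between `W`'s total and
#' direct coefficients; its standard error comes from the delta method
#' using the model-based covariance of the two estimators (both are linear
#' maps of the shared score vector `b`, with `Var(b) = sigma2 * A`). The
#' default operationalization is monotone increasing in `|t_obs| / SE`:
#' `1 - (two-sided normal p-value)`, so a candidate whose marginal effect
#' vanishes once the index is in the model gets probability near 1.
#' `printed_form = TRUE` returns the two-sided p-value itself instead
#' (small when mediation is strong).
#'
#' If `W` is numerically collinear with the conditioning set (a perfect
#' proxy of the index), the probability is set to 1 and flagged.
#'
#' @param stats a `mjam_stats` object.
#' @param candidate SNP id `W` (not in the conditioning set).
#' @param index_snp the current index SNP `X`.
#' @param prior_indices earlier index SNPs entering both models.
#' @param g g-prior scale; `NULL` means `stats$N`.
#' @param printed_form use the p-value-direction form.
#' @return List `(tau_total, tau_direct, t_obs, se_t, mediation_prob,
#'   flagged)`.
#' @export
mediation_probability <- function(stats, candidate, index_snp,
                                  prior_indices = character(0), g = NULL,
                                  printed_form = FALSE) {
  stopifnot(!(candidate %in% c(index_snp, prior_indices)))
  if (is.null(g)) g <- stats$N
  S1 <- c(candidate, prior_indices)
  S2 <- c(candidate, prior_indices, index_snp)
  shrink <- g / (1 + g)
  A2 <- stats$A[S2, S2, drop = FALSE]
  ch2 <- tryCatch(chol(A2), error = function(e) NULL)
  if (is.null(ch2)) {
    r <- tryCatch(regularize_to_pd(A2), error = function(e) NULL)
    if (is.null(r)) {
      return(list(tau_total = NA_real_, tau_direct = NA_real_,
                  t_obs = NA_real_, se_t = NA_real_, mediation_prob = 1,
                  flagged = TRUE))
    }
    A2 <- r$A
    ch2 <- chol(A2)
  }
  A2inv <- chol2inv(ch2)
  A1inv <- chol2inv(chol(A2[seq_along(S1), seq_along(S1), drop = FALSE]))
  fit2 <- gprior_fit(stats, S2, g = g)
  # near-perfect proxy: candidate carries no independent information
  vif <- A2inv[1L, 1L] * A2[1L, 1L]
  if (!is.finite(vif) || vif > 1e5) {
    return(list(tau_total = NA_real_, tau_direct = NA_real_, t_obs = NA_real_,
                se_t = NA_real_, mediation_prob = 1, flagged = TRUE))
  }
  b1 <- stats$b[S1]
  b2 <- stats$b[S2]
  tau_total <- shrink * drop(A1inv %*% b1)[1L]
  tau_direct <- shrink * drop(A2inv %*% b2)[1L]
  t_obs <- tau_total - tau_direct
  # weight vector of t_obs as a linear function of b over S2
  w1 <- c(A1inv[1L, ], 0)
  w2 <- A2inv[1L, ]
  w <- shrink * (w1 - w2)
  var_t <- fit2$sigma2 * drop(t(w) %*% A2 %*% w)
  se_t <- sqrt(max(var_t, 0))
  zt <- if (se_t > 0) t_obs / se_t else 0
  pval <- 2 * stats::pnorm(-abs(zt))
  med <- if (printed_form) pval else 1 - pval
  list(tau_total = tau_total, tau_direct = tau_direct, t_obs = t_obs,
       se_t = se_t, mediation_prob = min(max(med, 0), 1), flagged = FALSE)
}

#' Posterior credible set probabilities around an index SNP
#'
#' Combines the one-SNP model probabilities over the candidate pool with
#' each candidate's mediation probability for the index SNP; the index
#' itself gets mediation probability 1 (perfect self-mediation) so it can
#' belong to its own credible set. `pcsp_scaled` renormalizes the raw
#' products over the pool.
#'
#' @param stats a `mjam_stats` object.
#' @param index_snp index SNP id.
#' @param candidates candidate pool (other index SNPs excluded); the index
#'   is added if absent.
#' @param prior_indices earlier index SNPs (conditioning set for the
#'   mediation models).
#' @param g g-prior scale; `NULL` means `stats$N`.
#' @param prior per-model prior weights over the pool (default uniform).
#' @param printed_form passed to [mediation_probability].
#' @param use_mediation set to `FALSE` to weight by the model probability
#'   alone (all mediation probabilities fixed at 1), e.g. for ablation.
#' @return A `pcsp_result`: `index_snp`, `candidates`, `model_prob`,
#'   `tau_total`, `tau_direct`, `t_obs`, `mediation_prob`, `pcsp_raw`,
#'   `pcsp_scaled`, `marginal_p`.
#' @export
compute_pcsp <- function(stats, index_snp, candidates,
                         prior_indices = character(0), g = NULL,
                         prior = NULL, printed_form = FALSE,
                         use_mediation = TRUE) {
  if (is.null(g)) g <- stats$N
  pool <- union(index_snp, candidates)
  osp <- one_snp_posteriors(stats, pool, g = g, prior = prior)
  med <- rep(NA_real_, length(pool))
  tau_t <- tau_d <- t_obs <- rep(NA_real_, length(pool))
  names(med) <- names(tau_t) <- names(tau_d) <- names(t_obs) <- pool
  med[index_snp] <- 1
  for (w in setdiff(pool, index_snp)) {
    if (!use_mediation) {
      med[w] <- 1
      next
    }
    mw <- mediation_probability(stats, w, index_snp, prior_indices, g = g,
                                printed_form = printed_form)
    med[w] <- mw$mediation_prob
    tau_t[w] <- mw$tau_total
    tau_d[w] <- mw$tau_direct
    t_obs[w] <- mw$t_obs
  }
  pcsp_raw <- osp$model_prob * med
  total <- sum(pcsp_raw)
  if (total <= 0) {
    stop("all posterior credible set probabilities are zero: ",
         "region carries no signal around ", index_snp)
  }
  marg <- conditional_pvalues(stats, character(0), pool, g = g)
  structure(list(index_snp = index_snp, candidates = pool,
                 model_prob = osp$model_prob, log_bf = osp$log_bf,
                 tau_total = tau_t, tau_direct = tau_d, t_obs = t_obs,
                 mediation_prob = med, pcsp_raw = pcsp_raw,
                 pcsp_scaled = pcsp_raw / total,
                 marginal_p = stats::setNames(marg$p, marg$snp_id)),
            class = "pcsp_result")
}

#' @export
print.pcsp_result <- function(x, n = 10L, ...) {
  ord <- order(-x$pcsp_scaled)
  df <- data.frame(snp = x$candidates[ord],
                   model_prob = x$model_prob[ord],
                   mediation_prob = x$mediation_prob[ord],
                   pcsp_scaled = x$pcsp_scaled[ord])
  rownames(df) <- NULL
  cat("<pcsp_result> index", x$index_snp, "-", length(x$candidates),
      "candidates; top", min(n, nrow(df)), "by scaled PCSP:\n")
  print(utils::head(df, n), digits = 4)
  invisible(x)
}

#' Build a rho-level credible set from scaled PCSPs
#'
#' Members are the top-ranked SNPs by scaled PCSP whose cumulative sum
#' first reaches `rho`. Ties are broken by smaller marginal p-value, then
#' lexicographic SNP id, for determinism.
#'
#' @param pcsp a `pcsp_result`.
#' @param rho coverage level in (0, 1\].
#' @return A `credible_set`: `index_snp`, `members`, `member_probs`,
#'   `cumulative`, `rho`, plus the `pcsp_result` it came from.
#' @export
build_credible_set <- function(pcsp, rho = 0.95) {
  if (!(rho > 0 && rho <= 1)) stop("rho must be in (0, 1]")
  marg_p <- pcsp$marginal_p[pcsp$candidates]
  ord <- order(-pcsp$pcsp_scaled, marg_p, pcsp$candidates)
  probs <- pcsp$pcsp_scaled[ord]
  cum <- cumsum(probs)
  n_take <- which(cum >= rho - 1e-12)[1L]
  if (is.na(n_take)) n_take <- length(probs)
  take <- seq_len(n_take)
  structure(list(index_snp = pcsp$index_snp,
                 members = pcsp$candidates[ord][take],
                 member_probs = unname(probs[take]),
                 cumulative = unname(cum[take]),
                 rho = rho, pcsp = pcsp),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat("<credible_set> index", x$index_snp, "- rho =", x$rho, "-",
      length(x$members), "member(s); cumulative PCSP",
      format(max(x$cumulative), digits = 4), "\n")
  df <- data.frame(member = x$members, pcsp_scaled = x$member_probs,
                   cumulative = x$cumulative)
  print(df, digits = 4)
  invisible(x)
}
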