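# Multipopulation GWAS summary-statistics simulator and evaluation harness.
#
# Regions of p SNPs in block LD, shared block structure across populations,
# several studies per population with balanced sample size, one or more
# common causal SNPs with a fixed pooled effect (optional between-population
# heterogeneity), and per-population reference panels. Two statistically
# matched paths: an individual-level generator (Gaussian-copula haplotypes
# thresholded to Hardy-Weinberg dosages) and a fast path drawing marginal
# estimates from their asymptotic sampling law.

#' Scenario configuration
#'
#' Defaults reproduce the single-causal baseline region: 50 SNPs in five LD
#' blocks, one causal SNP with pooled effect 0.03 at MAF 0.21 (per-SNP
#' heritability 2*0.21*0.79*0.03^2, about 0.03% of a unit-variance trait),
#' three studies in each of three populations with 16,000 samples per study,
#' and 5,000-sample reference panels. `r_within` is the within-block dosage
#' correlation: 0 (independent), 0.5 (moderate) or 0.9 (high) in the
#' shipped scenario levels.
#'
#' @param p SNPs per region.
#' @param n_blocks number of LD blocks (the last absorbs any remainder).
#' @param r_within within-block dosage correlation in \[0, 1).
#' @param n_pops,studies_per_pop population/study layout.
#' @param n_per_study GWAS sample size per study.
#' @param causal_idx positions (1-based) of causal SNPs in the region.
#' @param beta_causal pooled per-allele effect size(s), recycled over
#'   causal SNPs.
#' @param causal_maf allele frequency of causal SNPs.
#' @param maf_range range of non-causal MAFs (drawn uniformly).
#' @param heterogeneity_sd between-population effect deviation, as a
#'   fraction of the pooled effect (0 = fixed-effect truth).
#' @param missing_spec named list `population id -> SNP positions` masked
#'   in that population's studies and panel.
#' @param binary simulate a binary trait (balanced case/control via a
#'   logistic link; effects are log odds ratios).
#' @param n_ref reference-panel size per population.
#' @param seed default RNG seed used by the simulators.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(p = 50L, n_blocks = 5L, r_within = 0,
                            n_pops = 3L, studies_per_pop = 3L,
                            n_per_study = 16000L, causal_idx = 25L,
                            beta_causal = 0.03, causal_maf = 0.21,
                            maf_range = c(0.1, 0.5), heterogeneity_sd = 0,
                            missing_spec = NULL, binary = FALSE,
                            n_ref = 5000L, seed = NULL) {
  stopifnot(r_within >= 0, r_within < 1, heterogeneity_sd >= 0,
            all(causal_idx >= 1L), all(causal_idx <= p))
  beta_causal <- rep_len(beta_causal, length(causal_idx))
  structure(list(p = as.integer(p), n_blocks = as.integer(n_blocks),
                 r_within = r_within, n_pops = as.integer(n_pops),
                 studies_per_pop = as.integer(studies_per_pop),
                 n_per_study = as.integer(n_per_study),
                 causal_idx = as.integer(causal_idx),
                 beta_causal = beta_causal, causal_maf = causal_maf,
                 maf_range = maf_range, heterogeneity_sd = heterogeneity_sd,
                 missing_spec = missing_spec, binary = binary,
                 n_ref = as.integer(n_ref), seed = seed),
            class = "scenario_config")
}

#' Shipped LD scenario levels
#'
#' @param level one of "independent" (baseline), "moderate", "high".
#' @param ... overrides passed to [scenario_config].
#' @return A `scenario_config`.
#' @export
scenario_preset <- function(level = c("independent", "moderate", "high"),
                            ...) {
  level <- match.arg(level)
  r <- c(independent = 0, moderate = 0.5, high = 0.9)[[level]]
  scenario_config(r_within = r, ...)
}

#' Per-SNP heritability implied by a scenario
#'
#' `2 * maf * (1 - maf) * beta^2` summed over causal SNPs (unit trait
#' variance).
#'
#' @param config a `scenario_config`.
#' @return Scalar heritability fraction.
#' @export
causal_heritability <- function(config) {
  sum(2 * config$causal_maf * (1 - config$causal_maf) *
        config$beta_causal^2)
}

#' Block compound-symmetry LD matrix
#'
#' @param p number of SNPs.
#' @param n_blocks number of equal blocks (last absorbs the remainder).
#' @param r_within within-block correlation in \[0, 1).
#' @return p x p positive-definite correlation matrix.
#' @export
make_ld_matrix <- function(p, n_blocks, r_within) {
  if (r_within >= 1) stop("r_within must be < 1")
  if (r_within < 0) stop("r_within must be >= 0")
  R <- diag(p)
  sizes <- rep(p %/% n_blocks, n_blocks)
  if (p %% n_blocks > 0) sizes[n_blocks] <- sizes[n_blocks] + p %% n_blocks
  start <- 1L
  for (s in sizes) {
    idx <- start:(start + s - 1L)
    R[idx, idx] <- r_within
    diag(R)[idx] <- 1
    start <- start + s
  }
  R
}

.snp_ids <- function(p) sprintf("chr1:%d:A:G", 10000L + 500L * seq_len(p))

# P(Z1 < t1, Z2 < t2) for standard bivariate normal with correlation rho,
# by one-dimensional quadrature
.orthant2 <- function(t1, t2, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(t1) * stats::pnorm(t2))
  f <- function(z) {
    stats::dnorm(z) * stats::pnorm((t2 - rho * z) / sqrt(1 - rho^2))
  }
  stats::integrate(f, -8, t1, rel.tol = 1e-10)$value
}

# correlation of the two threshold indicators 1{Z1<t1}, 1{Z2<t2}
.indicator_corr <- function(rho, maf1, maf2) {
  t1 <- stats::qnorm(maf1); t2 <- stats::qnorm(maf2)
  p11 <- .orthant2(t1, t2, rho)
  (p11 - maf1 * maf2) /
    sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

# maximal dosage correlation attainable between two biallelic SNPs with
# these allele frequencies (comonotonic haplotypes)
.dosage_corr_cap <- function(maf1, maf2) {
  (pmin(maf1, maf2) - maf1 * maf2) /
    sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

# latent copula correlation achieving a target dosage correlation
.latent_rho <- function(target, maf1, maf2) {
  if (abs(target) < 1e-12) return(0)
  f <- function(rho) .indicator_corr(rho, maf1, maf2) - target
  upper <- 1 - 1e-7
  if (f(upper) < 0) stop("target dosage correlation unattainable at these MAFs")
  stats::uniroot(f, c(0, upper), tol = 1e-8)$root
}

# latent correlation matrix whose thresholded dosages have (approximately)
# the target pairwise correlations
.latent_matrix <- function(R_target, mafs) {
  p <- nrow(R_target)
  L <- diag(p)
  for (j in seq_len(p - 1L)) {
    for (k in (j + 1L):p) {
      if (R_target[j, k] != 0) {
        L[j, k] <- L[k, j] <- .latent_rho(R_target[j, k], mafs[j], mafs[k])
      }
    }
  }
  L
}

# draw n HWE dosage rows with target dosage correlation (two independent
# haplotype layers from the latent Gaussian copula)
.draw_dosages <- function(n, mafs, latent_chol) {
  p <- length(mafs)
  thr <- stats::qnorm(mafs)
  h <- function() {
    z <- matrix(stats::rnorm(n * p), n, p) %*% latent_chol
    sweep(z, 2L, thr, `<`) * 1
  }
  h() + h()
}

.region_frame <- function(config) {
  mafs <- stats::runif(config$p, config$maf_range[1L], config$maf_range[2L])
  mafs[config$causal_idx] <- config$causal_maf
  beta <- rep(0, config$p)
  beta[config$causal_idx] <- config$beta_causal
  R <- make_ld_matrix(config$p, config$n_blocks, config$r_within)
  if (config$r_within > 0) {
    # LD between biallelic SNPs is bounded by their frequency mismatch;
    # cap each target pairwise so HWE dosages can realize it
    cap <- 0.98 * outer(mafs, mafs, .dosage_corr_cap)
    R <- pmin(R, cap)
    diag(R) <- 1
    R <- stats::cov2cor(regularize_to_pd(R, eps_rel = 1e-8)$A)
  }
  list(snp_ids = .snp_ids(config$p), mafs = mafs, beta = beta, R = R)
}

.pop_betas <- function(config, beta) {
  lapply(seq_len(config$n_pops), function(i) {
    if (config$heterogeneity_sd > 0) {
      beta + stats::rnorm(length(beta), 0,
                          config$heterogeneity_sd * abs(beta))
    } else beta
  })
}

.observed_positions <- function(config, pop_label) {
  out <- seq_len(config$p)
  ms <- config$missing_spec
  if (!is.null(ms) && pop_label %in% names(ms)) {
    out <- setdiff(out, ms[[pop_label]])
  }
  out
}

#' Simulate a region at the individual level
#'
#' Draws genotypes through a Gaussian copula thresholded to Hardy-Weinberg
#' dosages (the latent correlation is solved so realized dosage LD matches
#' `r_within`), phenotypes from the linear model with the residual variance
#' set for unit trait variance, then computes per-study marginal summary
#' statistics by single-SNP regression and per-population reference panels
#' from the same genotype process. With `binary = TRUE`, case/control
#' status is drawn through a logistic link (balanced design) and per-SNP
#' logistic regressions report log odds ratios.
#'
#' @param config a `scenario_config`.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A `simulated_region`: `truth` (causal ids, pooled and
#'   per-population effects), `studies` (list of [sumstats]), `panels`
#'   (list of [ref_panel]), `snp_ids`, `config`, `seed_used`.
#' @export
simulate_region <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  fr <- .region_frame(config)
  D <- 2 * fr$mafs * (1 - fr$mafs)
  Sigma <- sqrt(D) * t(sqrt(D) * fr$R)  # dosage covariance
  var_g <- drop(t(fr$beta) %*% Sigma %*% fr$beta)
  if (!config$binary && var_g >= 1) {
    stop("infeasible scenario: genetic variance ", signif(var_g, 3),
         " >= 1; reduce beta_causal or causal_maf")
  }
  sd_e <- if (config$binary) NA_real_ else sqrt(1 - var_g)
  latent_chol <- chol(regularize_to_pd(.latent_matrix(fr$R, fr$mafs))$A)

  pop_beta <- .pop_betas(config, fr$beta)
  studies <- list()
  panels <- list()
  for (i in seq_len(config$n_pops)) {
    pop <- paste0("pop", i)
    obs <- .observed_positions(config, pop)
    for (s in seq_len(config$studies_per_pop)) {
      n <- config$n_per_study
      G <- .draw_dosages(n, fr$mafs, latent_chol)
      eta <- drop(G %*% pop_beta[[i]])
      if (config$binary) {
        y <- stats::rbinom(n, 1L, stats::plogis(eta - mean(eta)))
      } else {
        y <- eta + stats::rnorm(n, 0, sd_e)
      }
      Gc <- sweep(G, 2L, colMeans(G))
      eaf_hat <- colMeans(G) / 2
      if (config$binary) {
        bhat <- sehat <- rep(NA_real_, config$p)
        for (j in obs) {
          fit <- stats::glm(y ~ G[, j], family = stats::binomial())
          co <- summary(fit)$coefficients
          bhat[j] <- co[2L, 1L]; sehat[j] <- co[2L, 2L]
        }
      } else {
        yc <- y - mean(y)
        xtx <- colSums(Gc^2)
        xty <- drop(crossprod(Gc, yc))
        bhat <- xty / xtx
        rss <- sum(yc^2) - bhat * xty
        sehat <- sqrt(rss / (n - 2) / xtx)
      }
      df <- data.frame(snp_id = fr$snp_ids[obs], effect_allele = "G",
                       other_allele = "A", eaf = eaf_hat[obs],
                       beta = bhat[obs], se = sehat[obs], n = n)
      studies[[length(studies) + 1L]] <-
        sumstats(df, study_id = paste0(pop, "_study", s),
                 population_id = pop, quiet = TRUE)
    }
    P <- .draw_dosages(config$n_ref, fr$mafs, latent_chol)[, obs, drop = FALSE]
    colnames(P) <- fr$snp_ids[obs]
    panels[[pop]] <- ref_panel(dosage = P, population_id = pop)
  }
  structure(list(truth = list(causal_ids = fr$snp_ids[config$causal_idx],
                              beta_global = config$beta_causal,
                              pop_beta = pop_beta, mafs = fr$mafs),
                 studies = studies, panels = panels, snp_ids = fr$snp_ids,
                 config = config, seed_used = seed),
            class = "simulated_region")
}

#' Simulate summary statistics directly from their sampling law
#'
#' Statistically equivalent fast path for the large-n regime: per study,
#' the vector of marginal effect estimates is drawn from its asymptotic
#' normal distribution (mean = LD-projected marginal effects, covariance =
#' `sigma2/n * S^-1 R S^-1` with `S = diag(sd of dosage)`), estimated
#' allele frequencies from their binomial law, and per-population panel
#' correlations from a Wishart draw with `n_ref - 1` degrees of freedom.
#' No individual-level data are materialized.
#'
#' @param config a `scenario_config` (`binary` is not supported here).
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A `simulated_region` whose panels are summary-level
#'   (correlation + allele frequencies).
#' @export
simulate_sumstats_fast <- function(config, seed = config$seed) {
  if (config$binary) stop("fast path supports continuous outcomes only")
  if (!is.null(seed)) set.seed(seed)
  fr <- .region_frame(config)
  D <- 2 * fr$mafs * (1 - fr$mafs)
  Sigma <- sqrt(D) * t(sqrt(D) * fr$R)
  var_g <- drop(t(fr$beta) %*% Sigma %*% fr$beta)
  if (var_g >= 1) {
    stop("infeasible scenario: genetic variance ", signif(var_g, 3),
         " >= 1; reduce beta_causal or causal_maf")
  }
  sigma2_e <- 1 - var_g
  Rchol <- chol(fr$R)

  pop_beta <- .pop_betas(config, fr$beta)
  studies <- list()
  panels <- list()
  for (i in seq_len(config$n_pops)) {
    pop <- paste0("pop", i)
    obs <- .observed_positions(config, pop)
    marg_mean <- drop(Sigma %*% pop_beta[[i]]) / diag(Sigma)
    marg_resid <- pmax(1 - marg_mean^2 * diag(Sigma), 1e-8)
    for (s in seq_len(config$studies_per_pop)) {
      n <- config$n_per_study
      noise <- drop(crossprod(Rchol, stats::rnorm(config$p))) *
        sqrt(sigma2_e / (n * diag(Sigma)))
      bhat <- marg_mean + noise
      eaf_hat <- stats::rnorm(config$p, fr$mafs,
                              sqrt(fr$mafs * (1 - fr$mafs) / (2 * n)))
      eaf_hat <- pmin(pmax(eaf_hat, 1e-3), 1 - 1e-3)
      d_hat <- 2 * eaf_hat * (1 - eaf_hat)
      sehat <- sqrt(marg_resid / (n * d_hat))
      df <- data.frame(snp_id = fr$snp_ids[obs], effect_allele = "G",
                       other_allele = "A", eaf = eaf_hat[obs],
                       beta = bhat[obs], se = sehat[obs], n = n)
      studies[[length(studies) + 1L]] <-
        sumstats(df, study_id = paste0(pop, "_study", s),
                 population_id = pop, quiet = TRUE)
    }
    W <- stats::rWishart(1L, config$n_ref - 1L, fr$R)[, , 1L]
    corr_hat <- stats::cov2cor(W)[obs, obs, drop = FALSE]
    dimnames(corr_hat) <- list(fr$snp_ids[obs], fr$snp_ids[obs])
    panel_eaf <- stats::rnorm(config$p, fr$mafs,
                              sqrt(fr$mafs * (1 - fr$mafs) /
                                     (2 * config$n_ref)))
    panel_eaf <- pmin(pmax(panel_eaf, 1e-3), 1 - 1e-3)
    panels[[pop]] <- ref_panel(corr = corr_hat,
                               eaf = stats::setNames(panel_eaf[obs],
                                                     fr$snp_ids[obs]),
                               n_ref = config$n_ref, population_id = pop,
                               snp_ids = fr$snp_ids[obs])
  }
  structure(list(truth = list(causal_ids = fr$snp_ids[config$causal_idx],
                              beta_global = config$beta_causal,
                              pop_beta = pop_beta, mafs = fr$mafs),
                 studies = studies, panels = panels, snp_ids = fr$snp_ids,
                 config = config, seed_used = seed),
            class = "simulated_region")
}

#' Stacked sufficient statistics of a simulated region
#'
#' Convenience wrapper: per population, [estimate_population_stats] with
#' that population's panel, then [stack_populations] over the full SNP
#' union (no filtering, alleles already aligned).
#'
#' @param sim a `simulated_region`.
#' @param ... passed to [estimate_population_stats].
#' @return A `mjam_stats`.
#' @export
region_mjam_stats <- function(sim, ...) {
  pops <- vapply(sim$studies, attr, "", "population_id")
  comps <- list()
  for (pop in names(sim$panels)) {
    comps <- c(comps, estimate_population_stats(
      sim$studies[pops == pop], sim$panels[[pop]], snp_union = sim$snp_ids,
      ...))
  }
  stack_populations(comps, snp_union = sim$snp_ids)
}

#' Fixed-effect meta-analysis of per-study marginal estimates
#'
#' Inverse-variance weighted average per SNP; studies not reporting a SNP
#' contribute nothing for it; SNPs absent from all studies are excluded.
#'
#' @param studies list of [sumstats] tables.
#' @param bonferroni_alpha family-wise level defining the significant set
#'   (default 0.05, corrected by the number of meta-analyzed SNPs).
#' @return List: `table` (data.frame `snp_id`, `beta_meta`, `se_meta`,
#'   `z_meta`, `p_meta`, `n_studies`), `significant` (Bonferroni-passing
#'   ids), `lead_snp` (smallest meta p).
#' @export
fe_meta_analysis <- function(studies, bonferroni_alpha = 0.05) {
  if (inherits(studies, "sumstats")) studies <- list(studies)
  all_ids <- unique(unlist(lapply(studies, `[[`, "snp_id")))
  rows <- lapply(all_ids, function(id) {
    bs <- unlist(lapply(studies, function(st) st$beta[st$snp_id == id]))
    ss <- unlist(lapply(studies, function(st) st$se[st$snp_id == id]))
    if (length(bs) == 0L) return(NULL)
    w <- 1 / ss^2
    beta <- sum(w * bs) / sum(w)
    se <- sqrt(1 / sum(w))
    data.frame(snp_id = id, beta_meta = beta, se_meta = se,
               z_meta = beta / se,
               p_meta = 2 * stats::pnorm(-abs(beta / se)),
               n_studies = length(bs), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  thr <- bonferroni_alpha / nrow(tab)
  list(table = tab, significant = tab$snp_id[tab$p_meta <= thr],
       lead_snp = tab$snp_id[which.min(tab$p_meta)])
}

.rep_metrics <- function(indices, sets, causal_ids) {
  set_sizes <- vapply(sets, length, 0L)
  in_any_set <- unique(unlist(sets))
  n_causal_in_sets <- sum(causal_ids %in% in_any_set)
  list(
    n_index = length(indices),
    index_hit = mean(causal_ids %in% indices),
    index_ppv = if (length(indices) > 0L)
      sum(indices %in% causal_ids) / length(indices) else NA_real_,
    cs_hit = mean(causal_ids %in% in_any_set),
    cs_ppv = if (length(sets) > 0L)
      n_causal_in_sets / sum(set_sizes) else NA_real_,
    cs_total_size = sum(set_sizes),
    n_sets = length(sets),
    sets_covering = sum(vapply(sets, function(m) any(causal_ids %in% m), TRUE)),
    no_selection = length(sets) == 0L
  )
}

#' Evaluate fine-mapping methods over simulation replicates
#'
#' Runs `n_reps` independent replicates of a scenario and computes the
#' operating characteristics of each method: index-SNP sensitivity
#' (fraction of replicates whose index list contains the causal SNP) and
#' PPV (causal indices over all indices, averaged over replicates with at
#' least one index), mean number of indices, credible-set sensitivity and
#' PPV, mean total credible-set size (0 when none returned), empirical
#' coverage (fraction of returned sets containing a causal SNP), and the
#' fraction of replicates with no selection. The fixed-effect baseline
#' treats its Bonferroni-significant group as a single credible set and
#' reports no index metrics. `fallback_lead_snp` substitutes the
#' fixed-effect lead SNP (as a singleton set and index) whenever a method
#' returns nothing.
#'
#' @param config a `scenario_config`.
#' @param n_reps number of replicates.
#' @param methods subset of `c("FE", "mJAM-Forward", "mJAM-SuSiE")`.
#' @param seed master seed; per-replicate substreams are derived from it.
#' @param fast use [simulate_sumstats_fast] (default) or [simulate_region].
#' @param fallback_lead_snp substitute the FE lead SNP on empty returns.
#' @param forward_cfg,susie_cfg method configurations.
#' @return A `metrics_table` data.frame (`method`, `metric`, `value`) with
#'   attribute `n_reps`.
#' @export
evaluate_scenario <- function(config, n_reps = 500L,
                              methods = c("FE", "mJAM-Forward", "mJAM-SuSiE"),
                              seed = 1L, fast = TRUE,
                              fallback_lead_snp = FALSE,
                              forward_cfg = forward_config(),
                              susie_cfg = susie_config()) {
  methods <- match.arg(methods, several.ok = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  acc <- stats::setNames(vector("list", length(methods)), methods)
  for (m in methods) acc[[m]] <- vector("list", n_reps)
  n_failed <- stats::setNames(integer(length(methods)), methods)

  for (r in seq_len(n_reps)) {
    sim <- if (fast) simulate_sumstats_fast(config, seed = rep_seeds[r])
    else simulate_region(config, seed = rep_seeds[r])
    causal <- sim$truth$causal_ids
    stats_obj <- region_mjam_stats(sim)
    meta <- fe_meta_analysis(sim$studies)
    for (m in methods) {
      res <- tryCatch({
        if (m == "FE") {
          sets <- if (length(meta$significant) > 0L) list(meta$significant)
          else list()
          list(indices = character(0), sets = sets, fe = TRUE)
        } else if (m == "mJAM-Forward") {
          fw <- mjam_forward(stats_obj, forward_cfg)
          list(indices = fw$index_snps,
               sets = lapply(fw$credible_sets, `[[`, "members"), fe = FALSE)
        } else {
          sf <- susie_fit_sufficient(stats_obj, susie_cfg)
          list(indices = unname(sf$index_per_set),
               sets = lapply(sf$credible_sets, `[[`, "members"), fe = FALSE)
        }
      }, error = function(e) NULL)
      if (is.null(res)) {
        n_failed[m] <- n_failed[m] + 1L
        next
      }
      if (fallback_lead_snp && length(res$sets) == 0L) {
        res$sets <- list(meta$lead_snp)
        res$indices <- meta$lead_snp
      }
      rm_ <- .rep_metrics(res$indices, res$sets, causal)
      if (isTRUE(res$fe)) rm_$index_ppv <- rm_$index_hit <- rm_$n_index <- NA_real_
      acc[[m]][[r]] <- rm_
    }
  }

  rows <- list()
  for (m in methods) {
    reps <- Filter(Negate(is.null), acc[[m]])
    get <- function(f) vapply(reps, `[[`, 0, f)
    vals <- c(
      index_sensitivity = mean(get("index_hit")),
      index_ppv = mean(get("index_ppv"), na.rm = TRUE),
      n_index = mean(get("n_index")),
      cs_sensitivity = mean(get("cs_hit")),
      cs_ppv = mean(get("cs_ppv"), na.rm = TRUE),
      mean_cs_size = mean(get("cs_total_size")),
      empirical_coverage =
        sum(get("sets_covering")) / max(sum(get("n_sets")), 1L),
      frac_no_selection = mean(get("no_selection")),
      n_failed = unname(n_failed[m])
    )
    rows[[m]] <- data.frame(method = m, metric = names(vals),
                            value = unname(vals), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "n_reps") <- n_reps
  class(out) <- c("metrics_table", "data.frame")
  out
}

#' Extract one metric from a metrics table
#'
#' @param metrics a `metrics_table`.
#' @param method,metric row selectors.
#' @return Scalar value.
#' @export
metric_value <- function(metrics, method, metric) {
  v <- metrics$value[metrics$method == method & metrics$metric == metric]
  if (length(v) != 1L) stop("metric not found: ", method, " / ", metric)
  v
}
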