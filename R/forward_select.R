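# Forward index-SNP selection with per-iteration credible sets and
# population-aware LD pruning.

#' Configuration for forward selection
#'
#' @param p_threshold conditional p-value cutoff for adding an index SNP
#'   (default 5e-8, the conventional genome-wide significance level).
#' @param prune_within_r2 a SNP is pruned when its r^2 with the new index
#'   reaches this value in ANY population (default 0.5).
#' @param prune_across_r2 ... or reaches this value in ALL populations
#'   (default 0.2).
#' @param rho credible-set coverage level (default 0.95).
#' @param g g-prior scale; `NULL` means the total sample size N.
#' @param use_mediation weight credible-set members by their mediation
#'   probability (the default); `FALSE` uses model probabilities alone.
#' @return A `forward_config` list.
#' @export
forward_config <- function(p_threshold = 5e-8, prune_within_r2 = 0.5,
                           prune_across_r2 = 0.2, rho = 0.95, g = NULL,
                           use_mediation = TRUE) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            prune_within_r2 >= 0, prune_within_r2 <= 1,
            prune_across_r2 >= 0, prune_across_r2 <= 1,
            rho > 0, rho <= 1)
  structure(list(p_threshold = p_threshold,
                 prune_within_r2 = prune_within_r2,
                 prune_across_r2 = prune_across_r2, rho = rho, g = g,
                 use_mediation = use_mediation),
            class = "forward_config")
}

#' Prune SNPs in LD with a newly selected index SNP
#'
#' A remaining SNP is pruned iff its squared correlation with the index
#' reaches `prune_within_r2` in ANY population, or reaches
#' `prune_across_r2` in ALL populations. Populations where either SNP is
#' unobserved are skipped for the "any" rule and count as non-satisfying
#' for the "all" rule (missing evidence does not prune).
#'
#' @param index index SNP id.
#' @param remaining candidate SNP ids still in play.
#' @param pop_corr named list of per-population correlation matrices
#'   (NA where unobserved).
#' @param config a [forward_config].
#' @return List `kept` (character) and `pruned` (data.frame with the
#'   per-population r^2 and the rule that fired).
#' @export
prune_after_index <- function(index, remaining, pop_corr, config) {
  if (length(remaining) == 0L) {
    return(list(kept = character(0),
                pruned = data.frame(snp_id = character(0), rule = character(0))))
  }
  r2 <- sapply(pop_corr, function(co) co[index, remaining]^2)
  r2 <- matrix(r2, nrow = length(remaining),
               dimnames = list(remaining, names(pop_corr)))
  within_hit <- apply(r2, 1L, function(v) {
    any(v >= config$prune_within_r2, na.rm = TRUE)
  })
  across_hit <- apply(r2, 1L, function(v) {
    all(!is.na(v)) && all(v >= config$prune_across_r2)
  })
  pruned <- within_hit | across_hit
  rule <- ifelse(within_hit, "within", ifelse(across_hit, "across", ""))
  pr <- data.frame(snp_id = remaining[pruned], rule = rule[pruned],
                   stringsAsFactors = FALSE)
  pr <- cbind(pr, r2[pruned, , drop = FALSE])
  rownames(pr) <- NULL
  list(kept = remaining[!pruned], pruned = pr)
}

#' Forward index-SNP selection with credible sets
#'
#' Iterates: (1) find the remaining SNP with the smallest conditional
#' (round one: marginal) p-value under the g-prior joint model; (2) if it
#' passes `p_threshold`, declare it an index SNP; (3) build its
#' mediation-weighted credible set from the current candidate pool (before
#' pruning); (4) prune SNPs in LD with the new index; (5) recompute
#' conditional p-values for the survivors. Stops when no remaining SNP is
#' conditionally significant. Ties in the minimal p-value are broken by
#' larger |z|, then lexicographic id.
#'
#' @param stats a `mjam_stats` object; its `A` matrix is ridge-regularized
#'   here if not already positive definite.
#' @param config a [forward_config].
#' @return A `mjam_forward` result: `index_snps`, `conditional_pvalues`
#'   (selection-time), `joint_fit` (final model over all indices),
#'   `credible_sets`, `pruned`, `trace`.
#' @export
mjam_forward <- function(stats, config = forward_config()) {
  stopifnot(inherits(stats, "mjam_stats"))
  stats <- regularize_stats(stats)
  g <- if (is.null(config$g)) stats$N else config$g

  remaining <- stats$snp_union
  indices <- character(0)
  sel_p <- numeric(0)
  sets <- list()
  pruned_all <- list()
  trace <- list()
  cp <- conditional_pvalues(stats, character(0), remaining, g = g)

  while (length(remaining) > 0L) {
    ord <- order(cp$p, -abs(cp$z), cp$snp_id)
    best <- cp[ord[1L], ]
    if (best$p > config$p_threshold) break
    idx <- best$snp_id
    indices <- c(indices, idx)
    sel_p <- c(sel_p, best$p)

    pool <- setdiff(remaining, idx)
    pcsp <- compute_pcsp(stats, idx, pool,
                         prior_indices = indices[-length(indices)], g = g,
                         use_mediation = isTRUE(config$use_mediation))
    sets[[idx]] <- build_credible_set(pcsp, rho = config$rho)

    remaining <- setdiff(remaining, idx)
    pr <- prune_after_index(idx, remaining, stats$pop_corr, config)
    if (nrow(pr$pruned) > 0L) {
      pr$pruned$pruned_by <- idx
      pruned_all[[idx]] <- pr$pruned
    }
    remaining <- pr$kept
    trace[[length(trace) + 1L]] <-
      list(index = idx, p = best$p, n_remaining = length(remaining),
           n_pruned = nrow(pr$pruned))
    if (length(remaining) == 0L) break
    cp <- conditional_pvalues(stats, indices, remaining, g = g)
  }

  joint <- if (length(indices) > 0L) gprior_fit(stats, indices, g = g) else NULL
  structure(list(index_snps = indices,
                 conditional_pvalues = stats::setNames(sel_p, indices),
                 joint_fit = joint, credible_sets = sets,
                 pruned = if (length(pruned_all))
                   do.call(rbind, c(pruned_all, make.row.names = FALSE))
                 else NULL,
                 trace = trace, config = config),
            class = "mjam_forward")
}

#' @export
print.mjam_forward <- function(x, ...) {
  cat("<mjam_forward>", length(x$index_snps), "index SNP(s)\n")
  if (length(x$index_snps) > 0L) {
    df <- data.frame(index_snp = x$index_snps,
                     conditional_p = signif(x$conditional_pvalues, 3),
                     cs_size = vapply(x$credible_sets[x$index_snps],
                                      function(s) length(s$members), 0L))
    rownames(df) <- NULL
    print(df)
  }
  invisible(x)
}
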