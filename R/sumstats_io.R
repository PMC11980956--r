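# Tabular input/output shared by all analysis modules: per-study marginal
# summary statistics, reference dosage panels, and region harmonization.

.SUMSTATS_COLS <- c("snp_id", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "n")

#' Construct a per-study summary-statistics table
#'
#' One row per SNP of a single GWAS (one study, one population): marginal
#' per-allele effect estimate, its standard error, effect-allele frequency
#' and sample size. Rows violating the invariants (duplicated `snp_id`,
#' `eaf` outside (0,1), `se <= 0`, `n < 2`, non-finite numbers) are dropped
#' with a message.
#'
#' @param df data.frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `n`.
#' @param study_id,population_id labels attached as attributes.
#' @param quiet suppress the dropped-row message.
#' @return A `sumstats` data.frame (attributes `study_id`, `population_id`).
#' @export
sumstats <- function(df, study_id = "study1", population_id = "pop1",
                     quiet = FALSE) {
  missing_cols <- setdiff(.SUMSTATS_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("summary-statistics table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[, .SUMSTATS_COLS]
  df$snp_id <- as.character(df$snp_id)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  ok <- !is.na(df$snp_id) &
    is.finite(df$eaf) & df$eaf > 0 & df$eaf < 1 &
    is.finite(df$beta) &
    is.finite(df$se) & df$se > 0 &
    is.finite(df$n) & df$n >= 2
  ok[duplicated(df$snp_id)] <- FALSE
  if (!all(ok) && !quiet) {
    message(sum(!ok), " row(s) dropped while validating summary statistics (",
            study_id, ")")
  }
  df <- df[ok, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, study_id = study_id, population_id = population_id,
            class = c("sumstats", "data.frame"))
}

#' Read a summary-statistics file
#'
#' Reads delimited text with a header. Non-standard column names are mapped
#' through `dialect`, a named character vector `c(standard = "file_column")`
#' for any of `snp_id`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#' `se`, `n`.
#'
#' @param path file path (TSV by default).
#' @param dialect optional named character vector mapping standard column
#'   names to the file's column names.
#' @param study_id,population_id labels for the resulting table.
#' @param sep field separator.
#' @return A validated [sumstats] table.
#' @export
read_sumstats <- function(path, dialect = NULL, study_id = "study1",
                          population_id = "pop1", sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      if (dialect[[std]] %in% names(raw)) {
        names(raw)[names(raw) == dialect[[std]]] <- std
      }
    }
  }
  sumstats(raw, study_id = study_id, population_id = population_id)
}

#' Write a summary-statistics table
#'
#' @param x a [sumstats] table.
#' @param path output path; tab-separated, full double precision.
#' @export
write_sumstats <- function(x, path) {
  df <- as.data.frame(x)
  for (col in c("eaf", "beta", "se")) df[[col]] <- format(df[[col]], digits = 17)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a reference dosage panel
#'
#' Holds per-population reference genotypes used to estimate LD. Either a
#' dosage matrix (individuals x SNPs, values in \[0,2\]) or a precomputed
#' dosage correlation matrix plus allele frequencies (the summary-level
#' representation produced by the fast simulator) can be supplied.
#'
#' @param dosage numeric matrix `n_ref x p` with column names = SNP ids, or
#'   `NULL` when `corr` and `eaf` are given directly.
#' @param population_id label.
#' @param snp_ids SNP ids (defaults to `colnames(dosage)`).
#' @param corr,eaf,n_ref summary-level alternative to `dosage`.
#' @return A `ref_panel` object.
#' @export
ref_panel <- function(dosage = NULL, population_id = "pop1", snp_ids = NULL,
                      corr = NULL, eaf = NULL, n_ref = NULL) {
  if (!is.null(dosage)) {
    dosage <- as.matrix(dosage)
    if (is.null(snp_ids)) snp_ids <- colnames(dosage)
    if (is.null(snp_ids)) stop("snp_ids required when dosage has no colnames")
    colnames(dosage) <- snp_ids
    n_ref <- nrow(dosage)
  } else {
    if (is.null(corr) || is.null(eaf) || is.null(n_ref)) {
      stop("either dosage or (corr, eaf, n_ref) must be supplied")
    }
    if (is.null(snp_ids)) snp_ids <- colnames(corr)
    dimnames(corr) <- list(snp_ids, snp_ids)
    names(eaf) <- snp_ids
  }
  structure(list(population_id = population_id, snp_ids = snp_ids,
                 dosage = dosage, corr = corr, eaf = eaf, n_ref = n_ref),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("<ref_panel> population", x$population_id, "-", length(x$snp_ids),
      "SNPs, n_ref =", x$n_ref,
      if (is.null(x$dosage)) "(summary-level)" else "(dosage)", "\n")
  invisible(x)
}

#' Dosage correlation of a reference panel
#'
#' Zero-variance SNPs yield `NA` rows/columns (they are masked as missing
#' downstream).
#'
#' @param panel a [ref_panel].
#' @return p x p correlation matrix with SNP-id dimnames.
#' @export
panel_correlation <- function(panel) {
  if (!is.null(panel$corr)) return(panel$corr)
  v <- apply(panel$dosage, 2L, stats::var)
  co <- suppressWarnings(stats::cor(panel$dosage))
  co[v == 0, ] <- NA_real_
  co[, v == 0] <- NA_real_
  diag(co)[v > 0] <- 1
  dimnames(co) <- list(panel$snp_ids, panel$snp_ids)
  co
}

#' Effect-allele frequency implied by a reference panel
#'
#' @param panel a [ref_panel].
#' @return named vector of dosage means / 2.
#' @export
panel_eaf <- function(panel) {
  if (!is.null(panel$eaf)) return(panel$eaf)
  stats::setNames(colMeans(panel$dosage) / 2, panel$snp_ids)
}

#' Read a dosage panel from delimited text
#'
#' Plain matrix layout: header row of SNP ids, one row per reference
#' individual, dosages in \[0,2\].
#'
#' @param path file path.
#' @param population_id label.
#' @param sep field separator.
#' @return A [ref_panel].
#' @export
read_panel <- function(path, population_id = "pop1", sep = "\t") {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = sep,
                                   check.names = FALSE))
  ref_panel(dosage = m, population_id = population_id)
}

#' Read a dosage panel from a VCF file
#'
#' Uses the DS FORMAT field when present, otherwise the GT allele count.
#' SNP ids are formed as `chr:pos:ref:alt`. Requires the vcfR package.
#'
#' @param path VCF path (plain or bgzipped).
#' @param population_id label.
#' @return A [ref_panel].
#' @export
read_panel_vcf <- function(path, population_id = "pop1") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_panel_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- paste(v@fix[, "CHROM"], v@fix[, "POS"], v@fix[, "REF"],
               v@fix[, "ALT"], sep = ":")
  fmt <- unique(unlist(strsplit(v@gt[, 1L], ":", fixed = TRUE)))[1L]
  has_ds <- any(grepl("DS", v@gt[, 1L], fixed = TRUE))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1L, 2L), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.numeric(strsplit(g, "[/|]")[[1L]]))
    })
  }
  dosage <- t(ds)
  colnames(dosage) <- ids
  ref_panel(dosage = dosage, population_id = population_id)
}

.parse_snp_id <- function(id) {
  parts <- strsplit(id, ":", fixed = TRUE)
  data.frame(chr = vapply(parts, `[`, "", 1L),
             pos = suppressWarnings(as.integer(vapply(parts, `[`, "", 2L))),
             ref = toupper(vapply(parts, `[`, "", 3L)),
             alt = toupper(vapply(parts, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

.is_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize studies and panels over a region
#'
#' Aligns every study to a single effect allele per SNP (the panel/`alt`
#' allele of the `chr:pos:ref:alt` id): where a study's effect allele is the
#' other allele, `beta` is sign-flipped and `eaf` replaced by `1 - eaf`.
#' SNPs whose alleles neither match nor swap are dropped with a warning, as
#' are multi-allelic ids and (by default) strand-ambiguous A/T / C/G SNPs
#' with MAF > 0.4 in any source. SNPs are then filtered on MAF (must reach
#' `maf_min` in at least one population) and on the fixed-effect
#' meta-analysis p-value (`meta_p_max`). Missing EAF entries are imputed
#' from the population's panel frequency. Per-population observed/missing
#' masks are recorded; a retained SNP must be observed in at least one
#' population's summary statistics and that population's panel.
#'
#' @param studies list of [sumstats] tables.
#' @param panels list of [ref_panel]s, one per population named in the
#'   studies.
#' @param maf_min minor-allele-frequency floor (default 0.02).
#' @param meta_p_max fixed-effect meta p-value ceiling (default 1e-3).
#' @param drop_ambiguous drop strand-ambiguous SNPs with MAF > 0.4.
#' @return A `harmonized_region`: `snp_union`, aligned `studies`, `panels`,
#'   and per-population logical `observed` masks.
#' @export
harmonize_region <- function(studies, panels, maf_min = 0.02,
                             meta_p_max = 1e-3, drop_ambiguous = TRUE) {
  stopifnot(length(studies) >= 1L, length(panels) >= 1L)
  pop_of_study <- vapply(studies, attr, "", "population_id")
  pop_of_panel <- vapply(panels, function(p) p$population_id, "")
  names(panels) <- pop_of_panel

  snp_union <- sort(unique(unlist(lapply(studies, `[[`, "snp_id"))))
  parsed <- .parse_snp_id(snp_union)
  bad_id <- is.na(parsed$pos) | is.na(parsed$ref) | is.na(parsed$alt)
  if (any(bad_id)) {
    warning(sum(bad_id), " SNP id(s) not parseable as chr:pos:ref:alt; dropped")
    snp_union <- snp_union[!bad_id]
    parsed <- parsed[!bad_id, , drop = FALSE]
  }
  if (length(snp_union) == 0L) stop("no SNPs with parseable ids in region")

  # align each study: effect allele := alt of the id
  aligned <- vector("list", length(studies))
  dropped_alleles <- character(0)
  for (k in seq_along(studies)) {
    st <- as.data.frame(studies[[k]])
    m <- match(st$snp_id, snp_union)
    keep <- !is.na(m)
    st <- st[keep, , drop = FALSE]
    m <- m[keep]
    ref <- parsed$ref[m]; alt <- parsed$alt[m]
    match_ok <- st$effect_allele == alt & st$other_allele == ref
    swap_ok <- st$effect_allele == ref & st$other_allele == alt
    irreconcilable <- !(match_ok | swap_ok)
    if (any(irreconcilable)) {
      dropped_alleles <- union(dropped_alleles, st$snp_id[irreconcilable])
    }
    st$beta[swap_ok] <- -st$beta[swap_ok]
    st$eaf[swap_ok] <- 1 - st$eaf[swap_ok]
    st$effect_allele[swap_ok] <- alt[swap_ok]
    st$other_allele[swap_ok] <- ref[swap_ok]
    st <- st[!irreconcilable, , drop = FALSE]
    aligned[[k]] <- st
  }
  if (length(dropped_alleles) > 0L) {
    warning(length(dropped_alleles),
            " SNP(s) dropped: alleles neither match nor swap")
    snp_union <- setdiff(snp_union, dropped_alleles)
    parsed <- .parse_snp_id(snp_union)
  }

  if (drop_ambiguous && length(snp_union) > 0L) {
    amb <- .is_ambiguous(parsed$ref, parsed$alt)
    if (any(amb)) {
      maf_any_high <- vapply(snp_union, function(id) {
        fr <- unlist(lapply(aligned, function(st) st$eaf[st$snp_id == id]))
        for (p in panels) {
          if (id %in% p$snp_ids) fr <- c(fr, panel_eaf(p)[[id]])
        }
        any(pmin(fr, 1 - fr) > 0.4)
      }, TRUE)
      drop <- amb & maf_any_high
      if (any(drop)) {
        warning(sum(drop), " strand-ambiguous SNP(s) with MAF > 0.4 dropped")
        snp_union <- snp_union[!drop]
      }
    }
  }
  aligned <- lapply(aligned, function(st) st[st$snp_id %in% snp_union, ,
                                             drop = FALSE])

  # impute missing EAF from the population's panel
  for (k in seq_along(aligned)) {
    st <- aligned[[k]]
    pop <- pop_of_study[k]
    miss <- is.na(st$eaf)
    if (any(miss) && pop %in% names(panels)) {
      pf <- panel_eaf(panels[[pop]])
      fill <- pf[st$snp_id[miss]]
      st$eaf[miss] <- fill
      message(sum(!is.na(fill)), " EAF value(s) imputed from the ", pop,
              " panel for study ", attr(studies[[k]], "study_id"))
      aligned[[k]] <- st[!is.na(st$eaf), , drop = FALSE]
    }
  }

  # per-population MAF filter: a SNP survives if MAF >= maf_min in >= 1 pop
  pops <- unique(pop_of_study)
  maf_by_pop <- sapply(pops, function(pop) {
    vapply(snp_union, function(id) {
      fr <- unlist(lapply(which(pop_of_study == pop), function(k) {
        st <- aligned[[k]]; st$eaf[st$snp_id == id]
      }))
      if (length(fr) == 0L && pop %in% names(panels) &&
          id %in% panels[[pop]]$snp_ids) {
        fr <- panel_eaf(panels[[pop]])[[id]]
      }
      if (length(fr) == 0L) NA_real_ else min(pmin(fr, 1 - fr))
    }, 0)
  })
  maf_by_pop <- matrix(maf_by_pop, nrow = length(snp_union),
                       dimnames = list(snp_union, pops))
  pass_maf <- apply(maf_by_pop, 1L, function(v) any(v >= maf_min, na.rm = TRUE))

  # fixed-effect meta-analysis prefilter
  meta <- fe_meta_analysis(lapply(aligned, function(st) {
    structure(st, class = c("sumstats", "data.frame"))
  }))$table
  pass_p <- stats::setNames(rep(FALSE, length(snp_union)), snp_union)
  pass_p[meta$snp_id] <- meta$p_meta <= meta_p_max

  # observed in >= 1 population's sumstats AND that population's panel
  observed_ok <- vapply(snp_union, function(id) {
    any(vapply(seq_along(aligned), function(k) {
      pop <- pop_of_study[k]
      id %in% aligned[[k]]$snp_id &&
        (pop %in% names(panels) && id %in% panels[[pop]]$snp_ids)
    }, TRUE))
  }, TRUE)

  keep <- pass_maf & pass_p[snp_union] & observed_ok
  if (!any(keep)) stop("no SNPs survive harmonization filters")
  snp_union <- snp_union[keep]

  aligned <- lapply(seq_along(aligned), function(k) {
    st <- aligned[[k]][aligned[[k]]$snp_id %in% snp_union, , drop = FALSE]
    rownames(st) <- NULL
    structure(st, study_id = attr(studies[[k]], "study_id"),
              population_id = pop_of_study[k],
              class = c("sumstats", "data.frame"))
  })

  observed <- lapply(stats::setNames(pops, pops), function(pop) {
    in_stud <- Reduce(`|`, lapply(which(pop_of_study == pop), function(k) {
      snp_union %in% aligned[[k]]$snp_id
    }))
    in_panel <- if (pop %in% names(panels)) {
      snp_union %in% panels[[pop]]$snp_ids
    } else rep(FALSE, length(snp_union))
    stats::setNames(in_stud & in_panel, snp_union)
  })

  structure(list(snp_union = snp_union, studies = aligned,
                 panels = panels[intersect(names(panels), pops)],
                 observed = observed),
            class = "harmonized_region")
}

#' @export
print.harmonized_region <- function(x, ...) {
  cat("<harmonized_region>", length(x$snp_union), "SNPs,",
      length(x$studies), "studies,", length(x$panels), "panels\n")
  invisible(x)
}

#' Write fine-mapping results to TSV files
#'
#' For a forward-selection result: `index.tsv` (one row per index SNP with
#' selection-time conditional p, joint estimate and SE) and `members.tsv`
#' (one row per credible-set member with model probability, mediation
#' probability, scaled PCSP and cumulative PCSP). For a SuSiE fit:
#' `pip.tsv` and `susie_sets.tsv`. For a metrics table: `metrics.tsv` (one
#' row per method x metric). Output is bit-stable given fixed inputs.
#'
#' @param results a `mjam_forward` result, `susie_fit`, or `metrics_table`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  if (inherits(results, "mjam_forward")) {
    idx <- data.frame(index_snp = results$index_snps,
                      conditional_p = results$conditional_pvalues,
                      joint_beta = if (length(results$index_snps))
                        results$joint_fit$beta_global else numeric(0),
                      joint_se = if (length(results$index_snps))
                        results$joint_fit$se else numeric(0))
    mem <- do.call(rbind, lapply(results$credible_sets, function(cs) {
      pr <- cs$pcsp
      m <- match(cs$members, pr$candidates)
      data.frame(index_snp = cs$index_snp, member = cs$members,
                 model_prob = pr$model_prob[m],
                 mediation_prob = pr$mediation_prob[m],
                 pcsp_scaled = cs$member_probs, cumulative = cs$cumulative)
    }))
    if (is.null(mem)) {
      mem <- data.frame(index_snp = character(0), member = character(0),
                        model_prob = numeric(0), mediation_prob = numeric(0),
                        pcsp_scaled = numeric(0), cumulative = numeric(0))
    }
    paths <- c(wt(idx, "index.tsv"), wt(mem, "members.tsv"))
  } else if (inherits(results, "susie_fit")) {
    pip <- data.frame(snp_id = names(results$pip), pip = results$pip)
    sets <- do.call(rbind, lapply(seq_along(results$credible_sets),
                                  function(i) {
      cs <- results$credible_sets[[i]]
      data.frame(set = i, index_snp = cs$index_snp, member = cs$members,
                 alpha = cs$member_probs, purity = cs$purity)
    }))
    if (is.null(sets)) {
      sets <- data.frame(set = integer(0), index_snp = character(0),
                         member = character(0), alpha = numeric(0),
                         purity = numeric(0))
    }
    paths <- c(wt(pip, "pip.tsv"), wt(sets, "susie_sets.tsv"))
  } else if (inherits(results, "metrics_table")) {
    paths <- wt(as.data.frame(results), "metrics.tsv")
  } else {
    stop("write_results: unsupported result type: ", class(results)[1L])
  }
  invisible(paths)
}
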