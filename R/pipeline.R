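#' Pipeline configuration
#'
#' One structured configuration object for the end-to-end analysis. Every
#' stochastic stage has an explicit seed derived from `seed` and recorded in
#' the output manifest.
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort (or
#'   `NULL` when `data` is passed to [run_all()]).
#' @param rarefaction_depth fixed subsampling depth (default 6247).
#' @param index_spec dysbiosis index specification.
#' @param alpha,lda_threshold,lda_boot differential-abundance parameters.
#' @param rf_resamples,rf_top_k,rf_ntree bootstrap random-forest parameters
#'   (defaults 200 resamples, top 20 per direction, 500 trees).
#' @param mediation_boot bootstrap iterations for mediation (default 1000).
#' @param permanova_permutations permutations for PERMANOVA (default 999).
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            rarefaction_depth = 6247L,
                            index_spec = cad_index_spec(),
                            alpha = 0.05, lda_threshold = 2, lda_boot = 30L,
                            rf_resamples = 200L, rf_top_k = 20L,
                            rf_ntree = 500L,
                            mediation_boot = 1000L,
                            permanova_permutations = 999L,
                            seed = 1L) {
  structure(list(cohort = cohort, rarefaction_depth = as.integer(rarefaction_depth),
                 index_spec = index_spec, alpha = alpha,
                 lda_threshold = lda_threshold, lda_boot = as.integer(lda_boot),
                 rf_resamples = as.integer(rf_resamples),
                 rf_top_k = as.integer(rf_top_k),
                 rf_ntree = as.integer(rf_ntree),
                 mediation_boot = as.integer(mediation_boot),
                 permanova_permutations = as.integer(permanova_permutations),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full dysbiosis/ImP analysis pipeline
#'
#' Chains rarefaction, alpha/beta diversity with pairwise PERMANOVA,
#' differential abundance, the dysbiosis index with its correlations and
#' quartile analysis, the bootstrap random-forest ImP ranking, the adjusted
#' logistic models with ROC curves, the bootstrap mediation analysis, and a
#' grouped cohort summary. Re-running with the same configuration and seed
#' reproduces all outputs bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param data optional pre-loaded input list with elements `counts`,
#'   `taxonomy`, `tree`, `metadata` (e.g. from [read_cohort()]); when
#'   `NULL` the synthetic cohort in `config$cohort` is generated.
#' @return list of class `pipeline_result` with per-stage results and a
#'   `manifest` (config, seeds, per-stage shapes).
#' @export
run_all <- function(config = pipeline_config(), data = NULL) {
  seeds <- derive_seeds(config$seed,
                        c("rarefy", "permanova", "diffabund", "rf",
                          "mediation"))
  if (is.null(data)) {
    data <- run_stage("simulate", generate_cohort(config$cohort))
  }
  md <- data$metadata

  rare <- run_stage("rarefy",
                    rarefy(data$counts, config$rarefaction_depth,
                           seed = seeds[["rarefy"]]))
  kept <- rownames(rare)
  md <- md[match(kept, md$sample_id), , drop = FALSE]

  alpha <- run_stage("alpha", data.frame(
    sample_id = kept,
    observed_asvs = alpha_observed(rare),
    shannon = alpha_shannon(rare),
    faith_pd = alpha_faith_pd(rare, data$tree),
    row.names = NULL))

  bc <- run_stage("beta", bray_curtis(rare))
  ord <- pcoa(bc, n_axes = 2L)
  pair_permanova <- function(g1, g2) {
    sel <- md$cad_group %in% c(g1, g2)
    permanova(bc[sel, sel], droplevels(md$cad_group[sel]),
              n_permutations = config$permanova_permutations,
              seed = seeds[["permanova"]])
  }
  perm <- run_stage("permanova", list(
    obstructive_vs_nonobstructive = pair_permanova("obstructive", "nonobstructive"),
    obstructive_vs_no_cad = pair_permanova("obstructive", "no_cad"),
    nonobstructive_vs_no_cad = pair_permanova("nonobstructive", "no_cad")))

  genus <- run_stage("aggregate", aggregate_to_genus(rare, data$taxonomy))

  da <- run_stage("diffabund", list(
    obstructive_vs_nonobstructive = diff_abundance(
      genus, md$cad_group, c("nonobstructive", "obstructive"),
      alpha = config$alpha, lda_threshold = config$lda_threshold,
      n_boot = config$lda_boot, seed = seeds[["diffabund"]]),
    obstructive_vs_no_cad = diff_abundance(
      genus, md$cad_group, c("no_cad", "obstructive"),
      alpha = config$alpha, lda_threshold = config$lda_threshold,
      n_boot = config$lda_boot, seed = seeds[["diffabund"]])))

  quart <- NULL
  index <- run_stage("index", {
    v <- cad_dysbiosis_index(genus, config$index_spec)
    # the stage expression evaluates in this frame, so this assigns locally
    quart <- imp_by_index_quartile(unname(v), md$imp_nM)
    data.frame(sample_id = kept, index = unname(v),
               quartile = quart$quartile,
               elevated = flag_elevated(v), row.names = NULL)
  })

  cors <- run_stage("correlations", list(
    index_vs_il6 = spearman_assoc(index$index, md$il6_pg_ml),
    index_vs_imp = spearman_assoc(index$index, md$imp_nM)))

  ranking <- run_stage("imprank",
                       rf_bootstrap_rank(genus, md$imp_nM,
                                         n_resamples = config$rf_resamples,
                                         top_k = config$rf_top_k,
                                         ntree = config$rf_ntree,
                                         seed = seeds[["rf"]]))

  outcome <- md$cad_group == "obstructive"
  imp_elev <- flag_elevated(md$imp_nM)
  fits <- run_stage("assoc", {
    # a separated fit is recorded as an explicit failure entry (class
    # "logistic_failure") so the remaining models still run
    try_fit <- function(expos, cov, mdl) {
      tryCatch(fit_logistic(outcome, expos, cov, mdl),
               error = function(e) structure(
                 list(model_label = mdl, error = conditionMessage(e)),
                 class = "logistic_failure"))
    }
    out <- list()
    for (mdl in c("unadjusted", "model1", "model2")) {
      cov <- model_covariates(md, mdl)
      cov <- if (ncol(cov)) cov else NULL
      out[[paste0("index_", mdl)]] <- try_fit(index$elevated, cov, mdl)
      out[[paste0("imp_", mdl)]] <- try_fit(imp_elev, cov, mdl)
    }
    out
  })
  roc <- list(index = roc_auc(index$index, outcome),
              imp = roc_auc(md$imp_nM, outcome))

  med <- run_stage("mediation",
                   mediate_bootstrap(index$index, md$imp_nM, outcome,
                                     n_boot = config$mediation_boot,
                                     seed = seeds[["mediation"]]))

  summary_tab <- run_stage("summary", summarize_cohort(md))

  manifest <- list(config = config, seeds = as.list(seeds),
                   n_samples = nrow(md),
                   group_sizes = as.list(table(md$cad_group)),
                   n_asvs = ncol(rare), n_genera = ncol(genus),
                   dropped_samples = attr(rare, "dropped"))

  structure(list(alpha = alpha, distances = bc, ordination = ord,
                 permanova = perm, diffabund = da, index = index,
                 correlations = cors, imp_quartiles = quart,
                 ranking = ranking, fits = fits, roc = roc,
                 mediation = med, cohort_summary = summary_tab,
                 metadata = md, genus_table = genus, manifest = manifest),
            class = "pipeline_result")
}

#' Grouped cohort characteristics table
#'
#' Median (IQR) with a Kruskal-Wallis p-value for continuous variables;
#' n (%) with a Fisher exact p-value for binary variables, compared across
#' CAD groups.
#'
#' @param metadata cohort metadata data.frame with a `cad_group` factor.
#' @return data.frame `variable`, `type`, one summary column per group, `p`.
#' @export
summarize_cohort <- function(metadata) {
  g <- droplevels(as.factor(metadata$cad_group))
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  cont <- intersect(c("age_y", "framingham", "hiv_duration_y", "il6_pg_ml",
                      "imp_nM"), names(metadata))
  bin <- intersect(c("sex_male", "msm", "cd4_nadir_lt200", "statins",
                     "abacavir", "antibiotics"), names(metadata))
  rows <- list()
  for (v in cont) {
    x <- metadata[[v]]
    cells <- vapply(levels(g), function(lv) {
      q <- stats::quantile(x[g == lv], c(0.25, 0.5, 0.75))
      sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
    }, character(1))
    p <- stats::kruskal.test(x, g)$p.value
    rows[[v]] <- data.frame(variable = v, type = "continuous",
                            t(cells), p = p, stringsAsFactors = FALSE)
  }
  for (v in bin) {
    x <- as.integer(metadata[[v]])
    cells <- vapply(levels(g), function(lv) {
      n1 <- sum(x[g == lv]); n <- sum(g == lv)
      sprintf("%d (%.0f%%)", n1, 100 * n1 / n)
    }, character(1))
    tab <- table(g, factor(x, levels = 0:1))
    p <- if (min(dim(tab)) < 2 || any(rowSums(tab) == 0)) NA_real_
         else stats::fisher.test(tab)$p.value
    rows[[v]] <- data.frame(variable = v, type = "categorical",
                            t(cells), p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[3:(2 + nlevels(g))] <- levels(g)
  rownames(out) <- NULL
  out
}
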