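#' Default CAD dysbiosis index specification
#'
#' The log-ratio index contrasting genera enriched in obstructive coronary
#' artery disease (numerator: Veillonella, Ruminococcus gnavus, Alistipes)
#' against genera depleted in obstructive CAD (denominator: Prevotella 9,
#' Megasphaera, Moryella, Catenibacterium, Fusicatenibacter, Ruminococcaceae
#' UCG-005, Ruminococcaceae UCG-009, Lachnospiraceae ND3007 group,
#' Eubacterium xylanophilum group).
#'
#' @param pseudocount positive value added to both the numerator and the
#'   denominator sum so the index stays finite on sparse samples. Default
#'   `1e-6`, small enough to perturb typical index values by well under 1%;
#'   0 is allowed for exact log-ratio evaluation on dense tables.
#' @return an object of class `dysbiosis_spec` with fields `numerator`,
#'   `denominator`, `pseudocount`.
#' @export
cad_index_spec <- function(pseudocount = 1e-6) {
  stopifnot(is.numeric(pseudocount), pseudocount >= 0)
  structure(list(
    numerator = c("Veillonella", "Ruminococcus gnavus", "Alistipes"),
    denominator = c("Prevotella 9", "Megasphaera", "Moryella",
                    "Catenibacterium", "Fusicatenibacter",
                    "Ruminococcaceae UCG-005", "Ruminococcaceae UCG-009",
                    "Lachnospiraceae ND3007 group",
                    "Eubacterium xylanophilum group"),
    pseudocount = pseudocount
  ), class = "dysbiosis_spec")
}

#' Genera treated as imidazole propionate producers in the simulator
#'
#' R. gnavus and Veillonella, the two index genera most consistently reported
#' as ImP producers.
#' @return character vector of genus names.
#' @export
imp_producer_genera <- function() c("Ruminococcus gnavus", "Veillonella")

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic HIV/CAD cohort generator. Defaults emulate the
#' study design the pipeline targets: three CAD groups of 114 (no CAD),
#' 80 (nonobstructive) and 60 (obstructive) participants, sparse compositional
#' 16S counts, enrichment of the index-numerator genera and depletion of the
#' index-denominator genera in the obstructive group, plasma ImP coupled to
#' producer-taxon abundance, and age/Framingham/HIV-duration confounding.
#'
#' @param n_no_cad,n_nonobstructive,n_obstructive group sizes (default
#'   114/80/60).
#' @param n_asvs,n_genera table dimensions; `n_asvs >= n_genera >= 12`
#'   (the index needs its 3 numerator and 9 denominator genera).
#' @param depth_mean mean sequencing depth (reads/sample), negative-binomial.
#' @param depth_dispersion NB size parameter (smaller = more dispersed).
#' @param depth_floor minimum depth; default 6248 keeps every sample above
#'   the default rarefaction depth of 6247 so no sample is dropped.
#' @param effect_up multiplicative enrichment of the numerator genera in the
#'   obstructive group. The default 1.2 is calibrated so the resulting
#'   dysbiosis index discriminates obstructive CAD moderately (AUC roughly
#'   0.7-0.8, single-digit odds ratios), the scale reported for real
#'   cohorts; use 3 for the strong planted configuration of the detection
#'   benchmarks.
#' @param effect_down depletion factor in (0, 1] for the denominator genera
#'   in the obstructive group (default 0.85; 0.3 in the strong planted
#'   configuration).
#' @param imp_coupling slope of log-ImP on the standardised summed producer
#'   relative abundance.
#' @param imp_noise_sd SD of Gaussian noise on log-ImP.
#' @param confounding_shift confounder-outcome association strength in the
#'   obstructive group: continuous confounders (age, Framingham, HIV
#'   duration) are shifted by `confounding_shift` SDs; binary confounder
#'   rates (CD4 nadir < 200, statins, abacavir) by `confounding_shift` on the
#'   log-odds scale.
#' @param dirichlet_conc symmetric Dirichlet concentration for filler-genus
#'   base proportions (default 0.3 for realistic sparsity).
#' @param overdispersion per-sample Dirichlet-multinomial concentration
#'   (total); smaller = more sample-to-sample compositional variability.
#' @param seed master seed; named sub-streams (counts, tree, covariates, imp)
#'   are derived from it so stages can be regenerated independently.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_no_cad = 114L, n_nonobstructive = 80L,
                          n_obstructive = 60L,
                          n_asvs = 500L, n_genera = 60L,
                          depth_mean = 20000, depth_dispersion = 5,
                          depth_floor = 6248L,
                          effect_up = 1.2, effect_down = 0.85,
                          imp_coupling = 0.4, imp_noise_sd = 0.8,
                          confounding_shift = 0.5,
                          dirichlet_conc = 0.3, overdispersion = 200,
                          seed = 1L) {
  cfg <- structure(list(
    n_no_cad = as.integer(n_no_cad),
    n_nonobstructive = as.integer(n_nonobstructive),
    n_obstructive = as.integer(n_obstructive),
    n_asvs = as.integer(n_asvs), n_genera = as.integer(n_genera),
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    depth_floor = as.integer(depth_floor),
    effect_up = effect_up, effect_down = effect_down,
    imp_coupling = imp_coupling, imp_noise_sd = imp_noise_sd,
    confounding_shift = confounding_shift,
    dirichlet_conc = dirichlet_conc, overdispersion = overdispersion,
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  check_field(cfg$n_no_cad >= 1L, "n_no_cad", "group size must be >= 1")
  check_field(cfg$n_nonobstructive >= 1L, "n_nonobstructive",
              "group size must be >= 1")
  check_field(cfg$n_obstructive >= 1L, "n_obstructive",
              "group size must be >= 1")
  check_field(cfg$n_genera >= 12L, "n_genera",
              "index needs 3 numerator + 9 denominator genera")
  check_field(cfg$n_asvs >= cfg$n_genera, "n_asvs", "need n_asvs >= n_genera")
  check_field(cfg$depth_mean > cfg$depth_floor - 1L, "depth_mean",
              "must exceed the depth floor (rarefaction depth)")
  check_field(cfg$depth_dispersion > 0, "depth_dispersion", "must be > 0")
  check_field(cfg$effect_up > 0, "effect_up", "must be > 0")
  check_field(cfg$effect_down > 0 && cfg$effect_down <= 1, "effect_down",
              "must be in (0, 1]")
  check_field(cfg$imp_noise_sd >= 0, "imp_noise_sd", "must be >= 0")
  check_field(cfg$dirichlet_conc > 0, "dirichlet_conc", "must be > 0")
  check_field(cfg$overdispersion > 0, "overdispersion", "must be > 0")
  invisible(cfg)
}

# Genus vocabulary: the 12 index genera first, then named fillers.
cohort_genera <- function(n_genera) {
  spec <- cad_index_spec()
  core <- c(spec$numerator, spec$denominator)
  n_fill <- n_genera - length(core)
  c(core, sprintf("Genus%03d", seq_len(n_fill)))
}

#' Generate a synthetic HIV/CAD microbiome cohort
#'
#' Draws an ASV count table, taxonomy map, random phylogeny, clinical
#' metadata and plasma ImP with the dependence structure the downstream
#' analysis assumes: a compositional genus model with multiplicative
#' enrichment/depletion of the index genera in the obstructive group,
#' Dirichlet-multinomial sampling at a dispersed per-sample depth, log-ImP
#' coupled to producer-taxon abundance, and group-shifted confounders.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return a list of class `synthetic_cohort` with elements `counts`
#'   (samples x ASVs integer matrix), `taxonomy` (data.frame asv_id/genus/
#'   family), `tree` (an `ape` phylo with tips = ASV ids), `metadata`
#'   (data.frame of clinical covariates, CAD group and ImP), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  seeds <- derive_seeds(config$seed, c("counts", "tree", "covariates", "imp"))

  n <- config$n_no_cad + config$n_nonobstructive + config$n_obstructive
  cad_group <- factor(rep(c("no_cad", "nonobstructive", "obstructive"),
                          times = c(config$n_no_cad, config$n_nonobstructive,
                                    config$n_obstructive)),
                      levels = c("no_cad", "nonobstructive", "obstructive"))
  sample_ids <- sprintf("S%04d", seq_len(n))
  genera <- cohort_genera(config$n_genera)
  spec <- cad_index_spec()
  idx_num <- match_genus(spec$numerator, genera)
  idx_den <- match_genus(spec$denominator, genera)

  counts_bundle <- withr::with_seed(seeds[["counts"]], {
    # base genus proportions: index genera get a guaranteed floor (a
    # dysbiosis index can only be built from consistently detected genera);
    # fillers sparse via symmetric Dirichlet
    base <- numeric(config$n_genera)
    base[c(idx_num, idx_den)] <- stats::runif(12, 0.005, 0.03)
    fill <- setdiff(seq_len(config$n_genera), c(idx_num, idx_den))
    if (length(fill)) {
      g <- stats::rgamma(length(fill), shape = config$dirichlet_conc)
      if (sum(g) == 0) g <- rep(1, length(fill))
      base[fill] <- (1 - sum(base[c(idx_num, idx_den)])) * g / sum(g)
    }
    base <- base / sum(base)

    # ASVs per genus: at least one each, extras favour abundant genera;
    # within-genus split by stick breaking
    k <- rep(1L, config$n_genera)
    extra <- config$n_asvs - config$n_genera
    if (extra > 0) {
      tab <- tabulate(sample.int(config$n_genera, extra, replace = TRUE,
                                 prob = base), nbins = config$n_genera)
      k <- k + tab
    }
    genus_of_asv <- rep.int(seq_len(config$n_genera), k)
    split_within <- unlist(lapply(k, function(m) {
      if (m == 1L) return(1)
      v <- stats::rbeta(m - 1L, 1, 5)
      stick <- numeric(m)
      rem <- 1
      for (j in seq_len(m - 1L)) { stick[j] <- rem * v[j]; rem <- rem * (1 - v[j]) }
      stick[m] <- rem
      stick
    }), use.names = FALSE)
    p_asv_base <- base[genus_of_asv] * split_within

    # group-level perturbation: obstructive enriches numerator genera,
    # depletes denominator genera, then renormalise
    mult <- rep(1, config$n_genera)
    mult[idx_num] <- config$effect_up
    mult[idx_den] <- config$effect_down
    p_groups <- list(
      no_cad = p_asv_base,
      nonobstructive = p_asv_base,
      obstructive = {
        p <- p_asv_base * mult[genus_of_asv]
        p / sum(p)
      })

    depth <- pmax(stats::rnbinom(n, mu = config$depth_mean,
                                 size = config$depth_dispersion),
                  config$depth_floor)
    counts <- matrix(0L, n, config$n_asvs,
                     dimnames = list(sample_ids,
                                     sprintf("ASV%04d", seq_len(config$n_asvs))))
    theta <- config$overdispersion
    for (i in seq_len(n)) {
      pg <- p_groups[[as.character(cad_group[i])]]
      a <- stats::rgamma(config$n_asvs, shape = theta * pg)
      if (sum(a) == 0) a <- pg
      counts[i, ] <- stats::rmultinom(1, depth[i], a / sum(a))[, 1]
    }
    list(counts = counts, genus_of_asv = genus_of_asv)
  })
  counts <- counts_bundle$counts

  taxonomy <- data.frame(
    asv_id = colnames(counts),
    genus = genera[counts_bundle$genus_of_asv],
    family = paste0("Family", sprintf("%02d",
                    ((counts_bundle$genus_of_asv - 1L) %/% 5L) + 1L)),
    stringsAsFactors = FALSE)

  # random bifurcating topology with exponential branch lengths; rtree's
  # t1..tn tips are relabelled with the ASV ids in tip order
  tree <- withr::with_seed(seeds[["tree"]],
                           ape::rtree(config$n_asvs, br = stats::rexp))
  tree$tip.label <- colnames(counts)[seq_len(config$n_asvs)]

  shift <- config$confounding_shift
  obstr <- cad_group == "obstructive"
  covs <- withr::with_seed(seeds[["covariates"]], {
    data.frame(
      sample_id = sample_ids,
      cad_group = cad_group,
      framingham = stats::rnorm(n, 12, 8) + shift * 8 * obstr,
      hiv_duration_y = pmax(stats::rnorm(n, 15, 8) + shift * 8 * obstr, 0),
      cd4_nadir_lt200 = stats::rbinom(n, 1, stats::plogis(stats::qlogis(0.30) + shift * obstr)),
      msm = stats::rbinom(n, 1, 0.60),
      statins = stats::rbinom(n, 1, stats::plogis(stats::qlogis(0.20) + shift * obstr)),
      abacavir = stats::rbinom(n, 1, stats::plogis(stats::qlogis(0.25) + shift * obstr)),
      antibiotics = stats::rbinom(n, 1, 0.10),
      il6_pg_ml = stats::rlnorm(n, log(1.5) + 0.2 * shift * obstr, 0.5),
      age_y = stats::rnorm(n, 52, 10) + shift * 10 * obstr,
      sex_male = stats::rbinom(n, 1, 0.9),
      stringsAsFactors = FALSE)
  })

  genus_rel <- aggregate_to_genus(counts, taxonomy)
  covs$imp_nM <- generate_imp(genus_rel, imp_producer_genera(),
                              coupling = config$imp_coupling,
                              noise_sd = config$imp_noise_sd,
                              seed = seeds[["imp"]])
  covs <- covs[, c("sample_id", "cad_group", "imp_nM", "il6_pg_ml",
                   "framingham", "hiv_duration_y", "cd4_nadir_lt200", "msm",
                   "statins", "abacavir", "antibiotics", "age_y", "sex_male")]

  structure(list(counts = counts, taxonomy = taxonomy, tree = tree,
                 metadata = covs, config = config, seeds = seeds),
            class = "synthetic_cohort")
}

#' Simulate plasma imidazole propionate coupled to producer taxa
#'
#' log-ImP = baseline + coupling x (standardised summed producer relative
#' abundance) + Gaussian noise; the returned concentrations (nM) are strictly
#' positive by construction.
#'
#' @param genus_relabund samples x genera relative-abundance matrix.
#' @param producer_genera genus names treated as ImP producers; must be
#'   present in the table (after name normalisation).
#' @param coupling slope on the standardised producer abundance.
#' @param noise_sd Gaussian noise SD on the log scale (>= 0).
#' @param seed integer seed.
#' @param baseline_log baseline of log-ImP; default `log(15)` puts the
#'   cohort median near 15 nM.
#' @return numeric vector of per-sample ImP (nM).
#' @export
generate_imp <- function(genus_relabund, producer_genera = imp_producer_genera(),
                         coupling = 0.4, noise_sd = 0.8, seed = 1L,
                         baseline_log = log(15)) {
  stopifnot(noise_sd >= 0)
  idx <- match_genus(producer_genera, colnames(genus_relabund))
  s <- rowSums(genus_relabund[, idx, drop = FALSE])
  z <- if (stats::sd(s) > 0) (s - mean(s)) / stats::sd(s) else s * 0
  eps <- withr::with_seed(as.integer(seed),
                          stats::rnorm(length(s), 0, noise_sd))
  out <- exp(baseline_log + coupling * z + eps)
  names(out) <- rownames(genus_relabund)
  out
}

#' Write a synthetic cohort to plain-text files
#'
#' Counts as TSV (`sample_id` column + ASVs as columns), taxonomy as TSV,
#' tree as Newick, metadata as CSV, and a JSON manifest recording the
#' configuration and master seed.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             tree = file.path(dir, "tree.nwk"),
             metadata = file.path(dir, "metadata.csv"),
             manifest = file.path(dir, "manifest.json"))
  cdf <- data.frame(sample_id = rownames(cohort$counts), cohort$counts,
                    check.names = FALSE)
  utils::write.table(cdf, paths[["counts"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$taxonomy, paths[["taxonomy"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(cohort$tree, paths[["tree"]])
  utils::write.csv(cohort$metadata, paths[["metadata"]], row.names = FALSE)
  jsonlite::write_json(list(config = unclass(cohort$config),
                            seeds = as.list(cohort$seeds)),
                       paths[["manifest"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir directory containing counts.tsv, taxonomy.tsv, tree.nwk,
#'   metadata.csv.
#' @return a list with `counts`, `taxonomy`, `tree`, `metadata`.
#' @export
read_cohort <- function(dir) {
  cdf <- utils::read.delim(file.path(dir, "counts.tsv"), check.names = FALSE)
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- cdf$sample_id
  md <- utils::read.csv(file.path(dir, "metadata.csv"))
  md$cad_group <- factor(md$cad_group,
                         levels = c("no_cad", "nonobstructive", "obstructive"))
  list(counts = counts,
       taxonomy = utils::read.delim(file.path(dir, "taxonomy.tsv")),
       tree = ape::read.tree(file.path(dir, "tree.nwk")),
       metadata = md)
}
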