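#' Kruskal-Wallis screen for differentially abundant taxa
#'
#' First stage of the LEfSe-style procedure: a per-taxon Kruskal-Wallis
#' rank test across groups. Taxa constant across all samples get p = 1 by
#' convention (no variance to test) with a message.
#'
#' @param genus_table samples x taxa relative-abundance matrix.
#' @param labels group factor (>= 2 samples per group).
#' @param alpha screen significance level (default 0.05, the original
#'   method's convention; no multiplicity correction, as in LEfSe).
#' @return data.frame `taxon`, `kw_p`, `passed`.
#' @export
kw_screen <- function(genus_table, labels, alpha = 0.05) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(labels) < 2L))
    stop("every group needs at least two samples", call. = FALSE)
  p <- apply(genus_table, 2, function(v) {
    if (max(v) == min(v)) return(NA_real_)
    stats::kruskal.test(v, labels)$p.value
  })
  if (anyNA(p)) {
    message(sum(is.na(p)), " constant taxon/taxa assigned p = 1")
    p[is.na(p)] <- 1
  }
  data.frame(taxon = colnames(genus_table), kw_p = unname(p),
             passed = unname(p) < alpha, stringsAsFactors = FALSE)
}

# two-class Fisher discriminant direction with ridge regularisation of the
# pooled within-class scatter (LEfSe regularises similarly to keep the fit
# defined on sparse features)
lda_direction <- function(X, y, ridge = 1e-6) {
  m1 <- colMeans(X[y == levels(y)[1], , drop = FALSE])
  m2 <- colMeans(X[y == levels(y)[2], , drop = FALSE])
  Sw <- 0
  for (g in levels(y)) {
    Xg <- X[y == g, , drop = FALSE]
    Sw <- Sw + crossprod(scale(Xg, center = TRUE, scale = FALSE))
  }
  Sw <- Sw / (nrow(X) - 2)
  lambda <- ridge * max(mean(diag(Sw)), .Machine$double.eps)
  w <- solve(Sw + diag(lambda, ncol(X)), m2 - m1)
  w / sqrt(sum(w^2))
}

#' LEfSe-style LDA effect size for screened taxa
#'
#' For each of `n_boot` subsampled two-class linear-discriminant fits on the
#' screened features (scaled to per-million relative abundance, the original
#' method's convention), the per-feature effect is the average of the raw
#' class-mean difference and the feature's share of the class-mean difference
#' along the discriminant axis; effects are averaged over bootstraps and
#' reported as a signed log10 score. `enriched_in` is the class with the
#' higher feature mean. A feature's discriminant component is its own
#' contribution |w_f x (mean difference)_f| to the class-mean gap along the
#' unit discriminant axis, so a feature with identical class distributions
#' cannot inherit the score of a co-fitted signal feature. Before each fit a
#' small amount of feature-scaled Gaussian noise (SD = 0.01% of the feature's
#' mean magnitude) is added, so near-constant features cannot destabilise
#' the within-class scatter.
#'
#' @param genus_table samples x taxa relative-abundance matrix.
#' @param labels two-level group factor.
#' @param passed_taxa taxa that passed [kw_screen()].
#' @param n_boot number of subsampled LDA fits (default 30).
#' @param seed integer seed.
#' @param subsample_frac per-class subsampling fraction (default 2/3).
#' @param ridge relative ridge added to the within-class scatter when it is
#'   singular or near-singular.
#' @return data.frame `taxon`, `lda_score` (signed log10), `enriched_in`.
#' @export
lda_effect_size <- function(genus_table, labels, passed_taxa, n_boot = 30L,
                            seed = 1L, subsample_frac = 2 / 3, ridge = 1e-6) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L)
    stop("LDA effect size is defined for exactly two classes", call. = FALSE)
  passed_taxa <- intersect(passed_taxa, colnames(genus_table))
  if (!length(passed_taxa))
    return(data.frame(taxon = character(), lda_score = numeric(),
                      enriched_in = character(), stringsAsFactors = FALSE))
  X <- genus_table[, passed_taxa, drop = FALSE] * 1e6   # per-million scale
  p <- ncol(X)
  noise_sd <- pmax(1e-4 * colMeans(abs(X)), 0.1)
  eff <- withr::with_seed(as.integer(seed), {
    acc <- matrix(0, n_boot, p)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(levels(labels), function(g) {
        i <- which(labels == g)
        sample(i, max(2L, floor(length(i) * subsample_frac)))
      }))
      Xb <- X[idx, , drop = FALSE] +
        matrix(stats::rnorm(length(idx) * p), length(idx), p) %*%
          diag(noise_sd, p)
      yb <- droplevels(labels[idx])
      raw_diff <- colMeans(Xb[yb == levels(yb)[2], , drop = FALSE]) -
        colMeans(Xb[yb == levels(yb)[1], , drop = FALSE])
      w <- lda_direction(Xb, yb, ridge)
      lda_part <- abs(w * raw_diff)   # feature's own share of the projected gap
      acc[b, ] <- (abs(raw_diff) + lda_part) / 2
    }
    colMeans(acc)
  })
  overall_diff <- colMeans(X[labels == levels(labels)[2], , drop = FALSE]) -
    colMeans(X[labels == levels(labels)[1], , drop = FALSE])
  sgn <- ifelse(overall_diff >= 0, 1, -1)
  data.frame(taxon = passed_taxa,
             lda_score = sgn * log10(1 + eff),
             enriched_in = levels(labels)[ifelse(overall_diff >= 0, 2, 1)],
             stringsAsFactors = FALSE)
}

#' One-vs-one differential abundance between two named groups
#'
#' Kruskal-Wallis screen at `alpha` followed by the LDA effect size;
#' reported taxa satisfy `kw_p < alpha` and `|lda_score| >= lda_threshold`.
#'
#' @param genus_table samples x taxa relative-abundance matrix (all groups).
#' @param labels group factor over all samples.
#' @param groups length-2 character vector naming the two groups compared.
#' @param alpha screen level (default 0.05).
#' @param lda_threshold minimum absolute log10 LDA score (default 2).
#' @param n_boot,seed passed to [lda_effect_size()].
#' @return data.frame `taxon`, `kw_p`, `lda_score`, `enriched_in`, sorted by
#'   decreasing `|lda_score|`.
#' @export
diff_abundance <- function(genus_table, labels,
                           groups = c("no_cad", "obstructive"),
                           alpha = 0.05, lda_threshold = 2,
                           n_boot = 30L, seed = 1L) {
  labels <- as.factor(labels)
  stopifnot(length(groups) == 2L, all(groups %in% levels(labels)))
  sel <- labels %in% groups
  sub <- genus_table[sel, , drop = FALSE]
  lab <- factor(as.character(labels[sel]), levels = groups)
  screen <- kw_screen(sub, lab, alpha)
  passed <- screen$taxon[screen$passed]
  lda <- lda_effect_size(sub, lab, passed, n_boot = n_boot, seed = seed)
  out <- merge(screen[, c("taxon", "kw_p")], lda, by = "taxon")
  out <- out[abs(out$lda_score) >= lda_threshold, , drop = FALSE]
  out[order(-abs(out$lda_score)), , drop = FALSE]
}
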