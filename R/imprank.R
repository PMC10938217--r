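#' Bootstrap random-forest ranking of taxa predictive of plasma ImP
#'
#' For each of `n_resamples` bootstrap resamples (rows drawn with
#' replacement, size n) a random-forest regression of ImP on genus
#' abundances is fitted (ranger, out-of-bag permutation importance,
#' single-threaded for reproducibility). Within each
#' resample a taxon's direction is the sign of its Spearman correlation with
#' ImP in that resample, and the `top_k` taxa by importance within each
#' direction are recorded. Taxa are finally ranked by how often they were
#' selected (selection frequency), ties broken by mean importance; the
#' reported direction is the sign of the full-sample Spearman correlation.
#'
#' Taxon columns are sorted by name internally, so the ranking is invariant
#' to the column order of the input.
#'
#' @param genus_table samples x taxa abundance matrix (relative abundance by
#'   default; see `log_transform`), n >= 30.
#' @param imp per-sample ImP values.
#' @param n_resamples number of bootstrap resamples (default 200).
#' @param top_k taxa recorded per direction per resample (default 20;
#'   clipped with a warning when fewer taxa are available).
#' @param seed integer seed (per-resample sub-seeds are derived from it).
#' @param ntree trees per forest (default 500).
#' @param mtry variables per split; default `floor(p / 3)` (regression
#'   convention).
#' @param log_transform if `TRUE`, abundances are log10-transformed with a
#'   half-minimum pseudocount before fitting.
#' @return data.frame `taxon`, `selection_frequency`, `direction`,
#'   `mean_importance`, sorted by decreasing frequency.
#' @export
rf_bootstrap_rank <- function(genus_table, imp, n_resamples = 200L,
                              top_k = 20L, seed = 1L, ntree = 500L,
                              mtry = NULL, log_transform = FALSE) {
  stopifnot(nrow(genus_table) == length(imp))
  if (nrow(genus_table) < 30L) stop("need at least 30 samples", call. = FALSE)
  X <- genus_table[, order(colnames(genus_table)), drop = FALSE]
  p <- ncol(X)
  if (top_k > p) {
    warning("top_k clipped from ", top_k, " to ", p, " available taxa",
            call. = FALSE)
    top_k <- p
  }
  if (log_transform) {
    pmin_half <- min(X[X > 0]) / 2
    X <- log10(X + pmin_half)
  }
  mtry <- mtry %||% max(1L, floor(p / 3))
  taxa <- colnames(X)
  sel_count <- stats::setNames(numeric(p), taxa)
  imp_sum <- stats::setNames(numeric(p), taxa)

  sub_seeds <- derive_seeds(seed, paste0("rf", seq_len(n_resamples)))
  n <- nrow(X)
  for (r in seq_len(n_resamples)) {
    withr::with_seed(sub_seeds[[r]], {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- ranger::ranger(x = X[idx, , drop = FALSE], y = imp[idx],
                            num.trees = ntree, mtry = mtry,
                            importance = "permutation", num.threads = 1L,
                            seed = sub_seeds[[r]])
      vi <- fit$variable.importance   # OOB permutation importance
      dir <- vapply(seq_len(p), function(j) {
        xj <- X[idx, j]
        if (stats::sd(xj) == 0) return(0)
        suppressWarnings(stats::cor(xj, imp[idx], method = "spearman"))
      }, numeric(1))
      dir[is.na(dir)] <- 0
      for (s in c(1, -1)) {
        cand <- which(if (s > 0) dir >= 0 else dir < 0)
        if (length(cand)) {
          top <- cand[order(vi[cand], decreasing = TRUE)][seq_len(min(top_k, length(cand)))]
          sel_count[top] <- sel_count[top] + 1
        }
      }
      imp_sum <- imp_sum + vi
    })
  }
  full_dir <- vapply(seq_len(p), function(j) {
    if (stats::sd(X[, j]) == 0) return(0)
    suppressWarnings(stats::cor(X[, j], imp, method = "spearman"))
  }, numeric(1))
  full_dir[is.na(full_dir)] <- 0
  out <- data.frame(
    taxon = taxa,
    selection_frequency = sel_count / n_resamples,
    direction = ifelse(full_dir >= 0, "positive", "negative"),
    mean_importance = imp_sum / n_resamples,
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$selection_frequency, -out$mean_importance), , drop = FALSE]
}
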