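#' Rarefy an ASV count table to a fixed depth
#'
#' Uniform without-replacement subsampling of each sample's reads to exactly
#' `depth` counts (one draw per analysis, seeded). Samples whose total is
#' below `depth` are dropped with a warning; their ids are recorded in the
#' `"dropped"` attribute of the result.
#'
#' @param counts samples x ASVs nonnegative integer matrix.
#' @param depth target depth; default 6247.
#' @param seed integer seed.
#' @return the rarefied integer matrix (every row sums to `depth`), with
#'   attribute `dropped`.
#' @export
rarefy <- function(counts, depth = 6247L, seed = 1L) {
  if (length(depth) != 1L || !is.finite(depth) || depth < 1)
    stop("depth must be a positive integer", call. = FALSE)
  depth <- as.integer(depth)
  totals <- rowSums(counts)
  keep <- totals >= depth
  dropped <- rownames(counts)[!keep]
  if (length(dropped))
    warning(length(dropped), " sample(s) below depth ", depth, " dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (!any(keep)) stop("no sample reaches the rarefaction depth", call. = FALSE)
  out <- withr::with_seed(as.integer(seed), withCallingHandlers(
    vegan::rrarefy(counts[keep, , drop = FALSE], depth),
    # advisory only: fires whenever the smallest nonzero entry is > 1
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  storage.mode(out) <- "integer"
  attr(out, "dropped") <- dropped
  out
}

#' Observed ASV richness per sample
#' @param counts samples x ASVs count matrix.
#' @return integer vector of per-sample nonzero-ASV counts.
#' @export
alpha_observed <- function(counts) {
  out <- as.integer(rowSums(counts > 0))
  names(out) <- rownames(counts)
  out
}

#' Shannon diversity per sample
#'
#' H = -sum p_i log p_i over nonzero proportions; natural log by default.
#'
#' @param counts samples x ASVs count matrix; every row sum must be > 0.
#' @param base logarithm base (default `exp(1)`).
#' @return numeric vector of per-sample Shannon indices.
#' @export
alpha_shannon <- function(counts, base = exp(1)) {
  if (any(rowSums(counts) == 0))
    stop("empty sample(s): ", paste(rownames(counts)[rowSums(counts) == 0],
                                    collapse = ", "), call. = FALSE)
  vegan::diversity(counts, index = "shannon", base = base)
}

#' Faith phylogenetic diversity per sample
#'
#' Total branch length of the minimal subtree connecting a sample's observed
#' tips to the root (root-inclusive convention). Empty samples return 0.
#'
#' @param counts samples x ASVs count matrix.
#' @param tree rooted `phylo`; its tip set must cover all table ASVs.
#' @return numeric vector of per-sample PD values.
#' @export
alpha_faith_pd <- function(counts, tree) {
  missing <- setdiff(colnames(counts), tree$tip.label)
  if (length(missing))
    stop("ASV(s) missing from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  pd <- rep(0, nrow(counts))
  names(pd) <- rownames(counts)
  nonempty <- rowSums(counts > 0) > 0
  if (any(nonempty)) {
    res <- picante::pd(counts[nonempty, , drop = FALSE], tree,
                       include.root = TRUE)
    pd[nonempty] <- res$PD
  }
  pd
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = 1 - 2 sum min(x_i, y_i) / (sum x + sum y), conventionally
#' computed on rarefied counts.
#'
#' @param counts samples x ASVs count matrix with nonzero rows.
#' @return symmetric square matrix with zero diagonal, entries in [0, 1].
#' @export
bray_curtis <- function(counts) {
  if (any(rowSums(counts) == 0))
    stop("zero-sum sample(s): ", paste(rownames(counts)[rowSums(counts) == 0],
                                       collapse = ", "), call. = FALSE)
  as.matrix(vegan::vegdist(counts, method = "bray"))
}

#' Principal coordinates analysis (classical MDS)
#'
#' Eigendecomposition of the double-centred Gram matrix of squared
#' distances. Negative eigenvalues are reported but excluded from the
#' denominator of `proportion_explained`; no Cailliez correction.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param n_axes number of axes to return (default 2).
#' @return list of class `pcoa_result` with `coordinates` (samples x axes),
#'   `eigenvalues` (all, descending) and `proportion_explained` (per
#'   returned axis, over the positive-eigenvalue total).
#' @export
pcoa <- function(d, n_axes = 2L) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  n <- nrow(d)
  n_axes <- min(as.integer(n_axes), n - 1L)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  pos <- pmax(ev[seq_len(n_axes)], 0)
  coords <- e$vectors[, seq_len(n_axes), drop = FALSE] %*% diag(sqrt(pos), n_axes)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  pos_total <- sum(ev[ev > 0])
  prop <- if (pos_total > 0) pmax(ev[seq_len(n_axes)], 0) / pos_total
          else rep(0, n_axes)
  structure(list(coordinates = coords, eigenvalues = ev,
                 proportion_explained = prop), class = "pcoa_result")
}

# pseudo-F and R2 from a squared-distance matrix and a grouping
permanova_stats <- function(d2, labels) {
  labels <- as.factor(labels)
  n <- nrow(d2)
  a <- nlevels(droplevels(labels))
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (g in levels(droplevels(labels))) {
    i <- which(labels == g)
    ss_within <- ss_within + sum(d2[i, i]) / (2 * length(i))
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  c(f = f, r2 = ss_between / ss_total)
}

#' PERMANOVA on a distance matrix (one factor)
#'
#' Anderson's permutational MANOVA: pseudo-F and R2 from within/between
#' sums of squared distances, with a permutation p-value. For a two-group
#' design whose number of distinct label splits C(n, n1) does not exceed
#' `n_permutations`, the null distribution is enumerated exhaustively over
#' all splits (p = proportion of splits with F >= observed, the observed
#' split included); otherwise `n_permutations` random label permutations are
#' drawn and the add-one estimator p = (1 + #{F_perm >= F_obs}) /
#' (1 + n_permutations) is used, which can never return 0.
#'
#' @param d distance matrix (or `dist`).
#' @param labels group factor; every group needs >= 2 samples and >= 2
#'   groups must be present.
#' @param n_permutations default 999.
#' @param seed integer seed for the permutation draw.
#' @return list of class `permanova_result`: `pseudo_f`, `r2`, `p`,
#'   `n_permutations`, `exhaustive`.
#' @export
permanova <- function(d, labels, n_permutations = 999L, seed = 1L) {
  d <- as.matrix(d)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(labels) < 2L))
    stop("every group needs at least two samples", call. = FALSE)
  stopifnot(length(labels) == nrow(d))
  d2 <- d^2
  obs <- permanova_stats(d2, labels)
  n <- nrow(d)

  a <- nlevels(labels)
  lab_int <- as.integer(labels)
  sizes <- tabulate(lab_int, nbins = a)
  ss_total <- sum(d2) / (2 * n)
  # F for many label assignments at once: for indicator matrix Z (n x B) of
  # one group, the within-group SS contribution is colSums(Z * (d2 Z)) / 2n_g
  f_batch <- function(P) {
    ssw <- numeric(ncol(P))
    for (g in seq_len(a)) {
      Z <- (P == g) * 1
      ssw <- ssw + colSums(Z * (d2 %*% Z)) / (2 * sizes[g])
    }
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }

  if (a == 2L) {
    n1 <- sizes[1]
    n_splits <- choose(n, n1)
    if (n_splits <= n_permutations) {
      splits <- utils::combn(n, n1)
      P <- matrix(2L, n, ncol(splits))
      P[cbind(as.vector(splits), rep(seq_len(ncol(splits)),
                                     each = n1))] <- 1L
      fs <- f_batch(P)
      p <- mean(fs >= obs[["f"]] - 1e-12)
      return(structure(list(pseudo_f = obs[["f"]], r2 = obs[["r2"]], p = p,
                            n_permutations = as.integer(n_splits),
                            exhaustive = TRUE),
                       class = "permanova_result"))
    }
  }
  P <- withr::with_seed(as.integer(seed),
                        replicate(n_permutations, sample(lab_int)))
  fs <- f_batch(P)
  p <- (1 + sum(fs >= obs[["f"]] - 1e-12)) / (1 + n_permutations)
  exhaustive <- FALSE
  structure(list(pseudo_f = obs[["f"]], r2 = obs[["r2"]], p = p,
                 n_permutations = as.integer(n_permutations),
                 exhaustive = exhaustive),
            class = "permanova_result")
}
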