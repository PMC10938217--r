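#' Aggregate an ASV table to genus-level relative abundances
#'
#' Per-sample genus counts are the sums of member-ASV counts, divided by the
#' sample total; every row sums to 1 within 1e-12.
#'
#' @param counts samples x ASVs count matrix.
#' @param taxonomy data.frame with columns `asv_id` and `genus` covering
#'   every ASV in the table.
#' @return samples x genera relative-abundance matrix.
#' @export
aggregate_to_genus <- function(counts, taxonomy) {
  idx <- match(colnames(counts), taxonomy$asv_id)
  if (anyNA(idx))
    stop("unmapped ASV(s): ", paste(colnames(counts)[is.na(idx)],
                                    collapse = ", "), call. = FALSE)
  genus <- factor(taxonomy$genus[idx])
  agg <- t(rowsum(t(counts), genus))
  totals <- rowSums(agg)
  if (any(totals == 0))
    stop("zero-sum sample(s): ", paste(rownames(counts)[totals == 0],
                                       collapse = ", "), call. = FALSE)
  agg / totals
}

#' CAD-related dysbiosis index
#'
#' Natural-log ratio of summed relative abundances of the disease-enriched
#' (numerator) genera over the disease-depleted (denominator) genera:
#' index = ln((sum numerator + pseudocount) / (sum denominator +
#' pseudocount)). Genera absent from the table are treated as all-zero
#' columns with a warning; the pseudocount keeps the index finite on sparse
#' samples.
#'
#' @param genus_table samples x genera relative-abundance matrix.
#' @param spec a `dysbiosis_spec`, default [cad_index_spec()].
#' @return named numeric vector of per-sample index values (all finite).
#' @export
cad_dysbiosis_index <- function(genus_table, spec = cad_index_spec()) {
  stopifnot(length(spec$numerator) > 0, length(spec$denominator) > 0,
            !any(normalize_genus(spec$numerator) %in%
                   normalize_genus(spec$denominator)))
  sum_genera <- function(gs) {
    idx <- match_genus(gs, colnames(genus_table), error = FALSE)
    if (anyNA(idx))
      warning("index genus/genera absent, treated as zero: ",
              paste(gs[is.na(idx)], collapse = ", "), call. = FALSE)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) return(rep(0, nrow(genus_table)))
    rowSums(genus_table[, idx, drop = FALSE])
  }
  num <- sum_genera(spec$numerator)
  den <- sum_genera(spec$denominator)
  out <- log((num + spec$pseudocount) / (den + spec$pseudocount))
  names(out) <- rownames(genus_table)
  out
}

# type-7 quantile (linear interpolation between order statistics)
index_quantile <- function(values, q) {
  stats::quantile(values, probs = q, type = 7, names = FALSE)
}

#' Flag samples above an empirical quantile
#'
#' Elevation is strict: a value is flagged iff it exceeds the empirical
#' `quantile` (linear interpolation between order statistics). With the
#' default 0.75 this is the "highest quartile versus the others" coding.
#'
#' @param values numeric vector, length >= 4.
#' @param quantile probability in (0, 1); default 0.75.
#' @return logical vector.
#' @export
flag_elevated <- function(values, quantile = 0.75) {
  if (length(values) < 4L) stop("need at least 4 values", call. = FALSE)
  values > index_quantile(values, quantile)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; p from the t-distribution approximation
#' (`stats::cor.test`, exact = FALSE).
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list `rho`, `p`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4L) stop("need at least 4 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' ImP by dysbiosis-index quartile
#'
#' Assigns samples to index quartiles (same quantile convention as
#' [flag_elevated()]), summarises ImP per quartile (median, IQR bounds), and
#' tests for a monotone trend via the Spearman correlation of quartile rank
#' with ImP.
#'
#' @param index per-sample index values.
#' @param imp per-sample ImP (paired with `index`), n >= 8.
#' @return list `summary` (data.frame quartile/n/median/q1/q3),
#'   `trend_rho`, `trend_p`, `quartile` (per-sample assignment 1-4).
#' @export
imp_by_index_quartile <- function(index, imp) {
  stopifnot(length(index) == length(imp))
  if (length(index) < 8L) stop("need at least 8 paired values", call. = FALSE)
  br <- index_quantile(index, c(0.25, 0.5, 0.75))
  quart <- 1L + (index > br[1]) + (index > br[2]) + (index > br[3])
  sm <- do.call(rbind, lapply(1:4, function(q) {
    v <- imp[quart == q]
    data.frame(quartile = q, n = length(v),
               median = if (length(v)) stats::median(v) else NA_real_,
               q1 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
               q3 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_)
  }))
  trend <- if (stats::sd(imp) == 0 || stats::sd(quart) == 0) {
    list(rho = 0, p = 1)
  } else {
    spearman_assoc(as.numeric(quart), imp)
  }
  list(summary = sm, trend_rho = trend$rho, trend_p = trend$p,
       quartile = quart)
}
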