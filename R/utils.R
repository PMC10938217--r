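#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive independent named sub-seeds from one master seed so that stages
# (counts, tree, covariates, ImP, ...) can be regenerated in isolation.
derive_seeds <- function(master, streams) {
  stopifnot(length(master) == 1L, is.finite(master))
  out <- withr::with_seed(as.integer(master),
                          sample.int(.Machine$integer.max - 1L, length(streams)))
  names(out) <- streams
  out
}

# Canonical genus-name form: lower case, alphanumerics only. Catches
# punctuation/spacing variants ("Ruminococcaceae UCG-005" vs "Ruminococcaceae
# UCG 005"); known spelling variants are mapped explicitly.
.genus_aliases <- c(
  megashpaera                = "megasphaera",
  ruminococcaceaucg005       = "ruminococcaceaeucg005",
  ruminococcaceaucg009       = "ruminococcaceaeucg009",
  lachnospiraceand3007group  = "lachnospiraceaend3007group"
)

normalize_genus <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(x))
  hit <- match(key, names(.genus_aliases))
  key[!is.na(hit)] <- .genus_aliases[hit[!is.na(hit)]]
  key
}

#' Match genus names against a vocabulary
#'
#' Exact match after name normalisation (case, punctuation, spacing, and a
#' small table of known spelling variants).
#'
#' @param query character vector of genus names to look up.
#' @param vocabulary character vector of available genus names (e.g. the
#'   columns of a genus table).
#' @param error if `TRUE` (default), unknown names raise an error listing
#'   the missing entries; otherwise `NA` indices are returned.
#' @return integer indices into `vocabulary`.
#' @export
match_genus <- function(query, vocabulary, error = TRUE) {
  idx <- match(normalize_genus(query), normalize_genus(vocabulary))
  if (error && anyNA(idx)) {
    stop("genus name(s) not found: ", paste(query[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}

# validation helper: raise an error naming the offending config field
check_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid config field '%s': %s", field, msg),
                        call. = FALSE)
}
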