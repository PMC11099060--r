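#' Canonicalize gene symbols
#'
#' Gene symbols are stored uppercase with surrounding whitespace removed, so
#' that comparisons throughout the package are case-insensitive. No alias or
#' HGNC resolution is attempted.
#'
#' @param x Character vector of gene symbols.
#' @param drop_empty Drop empty strings after trimming? Default `TRUE`.
#' @return A character vector of canonical symbols.
#' @examples
#' canonicalize_symbols(c(" dysf", "Ttn", "TTN"))
#' @export
canonicalize_symbols <- function(x, drop_empty = TRUE) {
  stopifnot(is.character(x) || length(x) == 0)
  out <- toupper(trimws(as.character(x)))
  if (any(grepl("\\s", out))) {
    stop("gene symbols must not contain internal whitespace: ",
         paste(utils::head(out[grepl("\\s", out)], 3L), collapse = ", "))
  }
  if (drop_empty) out <- out[nzchar(out)]
  out
}

# Deterministically derive a per-stage seed from a global seed so each stage
# of a pipeline run is reproducible standalone. Kept below 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 69069 + h * 12345) %% .Machine$integer.max)
}

# Shared argument check: a set of gene symbols as a character vector.
as_gene_set <- function(x, arg = "genes") {
  if (is.null(x)) return(character())
  if (is.factor(x)) x <- as.character(x)
  if (!is.character(x)) stop("`", arg, "` must be a character vector of gene symbols")
  sort(unique(canonicalize_symbols(x)))
}
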