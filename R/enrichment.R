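#' Read a GMT annotation collection
#'
#' Standard GMT: one term per line, tab-separated as term id, description,
#' then member genes. Gene symbols are canonicalized and duplicates within
#' a term collapsed; rows with fewer than three fields are skipped with a
#' warning. The annotation background is the union of all term gene sets
#' (the "only annotated genes" domain scope).
#'
#' @param path Path to a GMT file.
#' @return An `annotation_db`: list with `terms` (named list of
#'   `list(name, genes)`) and `background` (character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short)) {
    warning("skipping ", sum(short), " GMT row(s) with fewer than 3 fields")
    parts <- parts[!short]
  }
  if (length(parts) == 0L) stop("no terms in GMT file: ", path)
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate term ids in GMT file")
  terms <- lapply(parts, function(p) {
    list(name = p[[2L]],
         genes = sort(unique(canonicalize_symbols(p[-c(1L, 2L)]))))
  })
  names(terms) <- ids
  new_annotation_db(terms)
}

new_annotation_db <- function(terms) {
  empty <- vapply(terms, function(t) length(t$genes) == 0L, logical(1))
  if (any(empty)) stop("empty term(s): ", paste(names(terms)[empty], collapse = ", "))
  background <- sort(unique(unlist(lapply(terms, `[[`, "genes"),
                                   use.names = FALSE)))
  structure(list(terms = terms, background = background),
            class = "annotation_db")
}

#' Build an annotation database from a named list of gene sets
#'
#' @param sets Named list: term id -> character vector of genes.
#' @param names Optional named character vector of human-readable term
#'   names; defaults to the ids.
#' @return An `annotation_db`.
#' @export
annotation_db <- function(sets, names = NULL) {
  stopifnot(length(sets) > 0L, !is.null(base::names(sets)))
  terms <- lapply(base::names(sets), function(id) {
    list(name = if (!is.null(names) && id %in% base::names(names))
      unname(names[[id]]) else id,
      genes = sort(unique(canonicalize_symbols(sets[[id]]))))
  })
  base::names(terms) <- base::names(sets)
  new_annotation_db(terms)
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("Annotation database:", length(x$terms), "terms,",
      length(x$background), "background genes\n")
  invisible(x)
}

#' Upper-tail hypergeometric p-value for an annotation overlap
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a background of `N` genes of which `K`
#' carry the annotation: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Observed overlap.
#' @param n Query size.
#' @param K Term size.
#' @param N Background size.
#' @return The upper-tail probability.
#' @examples
#' hypergeometric_p(4, 5, 5, 20)  # 76 / 15504
#' @export
hypergeometric_p <- function(k, n, K, N) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(K) == 1L, length(N) == 1L)
  if (k < 0 || k > min(n, K) || n > N || K > N) {
    stop("invalid hypergeometric parameters: require 0 <= k <= min(n, K) <= N")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis against an annotation database
#'
#' Tests the query gene set against every term of the database with the
#' upper-tail hypergeometric test, after intersecting the query with the
#' annotation background ("only annotated genes"). P-values are adjusted
#' with Benjamini-Hochberg across all tested terms; rows are reported for
#' terms with at least one overlapping gene, sorted by adjusted p-value.
#'
#' @param query Character vector of gene symbols.
#' @param db An `annotation_db`.
#' @param alpha Significance threshold on the adjusted p-value (default
#'   0.05).
#' @param background Optional custom background (character vector);
#'   defaults to the database's annotated-gene universe. Term gene sets are
#'   intersected with it.
#' @return An `enrichment_result` tibble: `term_id`, `term_name`,
#'   `query_size`, `term_size`, `background_size`, `overlap`,
#'   `overlap_genes` (list-column), `p_raw`, `p_adjusted`, `significant`.
#' @export
enrich <- function(query, db, alpha = 0.05, background = NULL) {
  stopifnot(inherits(db, "annotation_db"))
  bg <- if (is.null(background)) db$background
        else as_gene_set(background, "background")
  q <- intersect(as_gene_set(query, "query"), bg)
  if (length(q) == 0L) {
    warning("query has no gene in the annotation background")
    return(empty_enrichment(alpha))
  }
  rows <- purrr::imap_dfr(db$terms, function(t, id) {
    tg <- intersect(t$genes, bg)
    ov <- intersect(q, tg)
    tibble::tibble(term_id = id, term_name = t$name,
                   query_size = length(q), term_size = length(tg),
                   background_size = length(bg), overlap = length(ov),
                   overlap_genes = list(ov),
                   p_raw = if (length(tg) == 0L) 1
                           else hypergeometric_p(length(ov), length(q),
                                                 length(tg), length(bg)))
  })
  rows$p_adjusted <- stats::p.adjust(rows$p_raw, method = "BH")
  rows <- rows[rows$overlap >= 1L, , drop = FALSE]
  rows$significant <- rows$p_adjusted <= alpha
  rows <- dplyr::arrange(rows, .data$p_adjusted, .data$p_raw, .data$term_id)
  structure(rows, class = c("enrichment_result", class(rows)),
            alpha = alpha)
}

empty_enrichment <- function(alpha) {
  out <- tibble::tibble(term_id = character(), term_name = character(),
                        query_size = integer(), term_size = integer(),
                        background_size = integer(), overlap = integer(),
                        overlap_genes = list(), p_raw = double(),
                        p_adjusted = double(), significant = logical())
  structure(out, class = c("enrichment_result", class(out)), alpha = alpha)
}

#' @export
tidy.enrichment_result <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(n_terms_reported = nrow(x),
                 n_significant = sum(x$significant),
                 alpha = attr(x, "alpha"),
                 min_p_adjusted = if (nrow(x)) min(x$p_adjusted) else NA_real_)
}

#' Write an enrichment result as TSV
#'
#' @param x An `enrichment_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  flat <- tibble::as_tibble(x)
  flat$overlap_genes <- vapply(flat$overlap_genes, paste, character(1),
                               collapse = ",")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
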