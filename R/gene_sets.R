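#' Read a gene list from a plain-text file
#'
#' One gene symbol per line; blank lines and lines starting with `#` are
#' ignored; if a line holds several tab-separated fields only the first is
#' used. Symbols are canonicalized to uppercase.
#'
#' @param path Path to the file.
#' @return Character vector of unique canonical gene symbols, sorted.
#' @seealso [assign_onset_groups()]
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  syms <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  as_gene_set(syms, arg = path)
}

#' Read gene-disease evidence records
#'
#' Reads a GenCC-style tab-separated table with columns `gene`, `onset` and
#' `classification` (extra columns are kept but unused).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `gene`, `onset`, `classification`.
#' @export
read_evidence <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene", "onset", "classification")
  names(ev) <- tolower(names(ev))
  if (!all(need %in% names(ev))) {
    stop("evidence table must have columns: ", paste(need, collapse = ", "))
  }
  ev$gene <- canonicalize_symbols(ev$gene, drop_empty = FALSE)
  tibble::as_tibble(ev)
}

# closed classification vocabulary (GenCC evidence levels)
evidence_levels <- c("Definitive", "Strong", "Moderate", "Limited",
                     "Disputed", "Refuted", "Other")
qualifying_levels <- c("Definitive", "Strong", "Moderate")

#' Filter candidate genes by curated evidence level
#'
#' Retains candidates that have at least one evidence record for the stated
#' onset with classification Moderate, Strong or Definitive, plus any
#' candidate on an explicit whitelist (genes kept on literature support even
#' without a qualifying curated assertion). Classification strings are
#' matched case-insensitively after trimming; records with a classification
#' outside the recognised vocabulary are dropped with a warning. Any single
#' qualifying record suffices: conflicting assertions for the same gene are
#' not reconciled (see the methods vignette).
#'
#' @param candidates Character vector of candidate gene symbols.
#' @param onset Onset the candidate list refers to, `"distal"` or
#'   `"proximal"`.
#' @param records A tibble of evidence records as returned by
#'   [read_evidence()] (may have zero rows).
#' @param whitelist Character vector of genes retained regardless of records.
#' @return Sorted character vector, a subset of `candidates`.
#' @examples
#' recs <- tibble::tibble(
#'   gene = c("G1", "G2"), onset = "distal",
#'   classification = c("Strong", "Limited")
#' )
#' filter_by_evidence(c("G1", "G2"), "distal", recs)
#' @export
filter_by_evidence <- function(candidates, onset = c("distal", "proximal"),
                               records = NULL, whitelist = character()) {
  onset <- match.arg(onset)
  candidates <- as_gene_set(candidates, "candidates")
  whitelist <- as_gene_set(whitelist, "whitelist")
  if (length(candidates) == 0L) return(character())
  if (is.null(records) || nrow(records) == 0L) {
    return(intersect(candidates, whitelist))
  }
  cls <- trimws(as.character(records$classification))
  ok_vocab <- tolower(cls) %in% tolower(evidence_levels)
  if (any(!ok_vocab)) {
    warning("dropping ", sum(!ok_vocab), " record(s) with unrecognised ",
            "classification: ",
            paste(unique(cls[!ok_vocab]), collapse = ", "))
  }
  keep <- ok_vocab &
    tolower(cls) %in% tolower(qualifying_levels) &
    tolower(trimws(records$onset)) == onset
  supported <- unique(canonicalize_symbols(records$gene[keep],
                                           drop_empty = FALSE))
  sort(intersect(candidates, union(supported, whitelist)))
}

#' Assign curated genes to onset groups
#'
#' Partitions the distal- and proximal-onset gene lists into three disjoint
#' groups: genes only on the distal list (DoGs), genes only on the proximal
#' list (PoGs), and genes on both lists (CoGs).
#'
#' @param distal,proximal Character vectors of curated gene symbols.
#' @return An `onset_groups` object: a list with sorted character vectors
#'   `dogs`, `pogs` and `cogs`.
#' @examples
#' assign_onset_groups(c("MYH7", "TTN"), c("LMNA", "TTN"))
#' @export
assign_onset_groups <- function(distal, proximal) {
  distal <- as_gene_set(distal, "distal")
  proximal <- as_gene_set(proximal, "proximal")
  out <- list(
    dogs = setdiff(distal, proximal),
    pogs = setdiff(proximal, distal),
    cogs = intersect(distal, proximal)
  )
  structure(out, class = "onset_groups")
}

#' @export
print.onset_groups <- function(x, ...) {
  cat("Onset groups:", sum(lengths(x)), "genes\n")
  for (g in names(x)) {
    cat(sprintf("  %-5s (%2d): %s\n", g, length(x[[g]]),
                paste(utils::head(x[[g]], 8L), collapse = ", ")))
  }
  invisible(x)
}

#' Tidy an onset-group assignment into a gene/group table
#'
#' @param x An `onset_groups` object.
#' @param ... Unused.
#' @return A tibble with columns `gene` and `group` (`"dogs"`, `"pogs"`,
#'   `"cogs"`).
#' @export
tidy.onset_groups <- function(x, ...) {
  tibble::tibble(
    gene = unlist(x, use.names = FALSE),
    group = rep(names(x), lengths(x))
  )
}

#' @export
glance.onset_groups <- function(x, ...) {
  tibble::tibble(
    n_genes = sum(lengths(x)),
    n_dogs = length(x$dogs),
    n_pogs = length(x$pogs),
    n_cogs = length(x$cogs)
  )
}

#' Write onset groups as TSV and JSON
#'
#' @param groups An `onset_groups` object.
#' @param path Output path; `.tsv` gives a two-column gene/group table,
#'   `.json` a JSON object keyed by group.
#' @return `path`, invisibly.
#' @export
write_onset_groups <- function(groups, path) {
  stopifnot(inherits(groups, "onset_groups"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lapply(unclass(groups), as.character), path,
                         pretty = TRUE)
  } else {
    readr::write_tsv(tidy.onset_groups(groups), path, progress = FALSE)
  }
  invisible(path)
}

#' Curated muscular dystrophy onset gene lists
#'
#' Returns the packaged curated gene lists for distal-onset and
#' proximal-onset muscular dystrophies (40 genes in total after onset-group
#' assignment: 11 distal-only, 22 proximal-only, 7 common), or the
#' corresponding onset-group assignment.
#'
#' @param as `"lists"` for the two curated input lists, `"groups"` for the
#'   assigned `onset_groups` object.
#' @return A list with elements `distal` and `proximal`, or an
#'   `onset_groups` object.
#' @examples
#' md_onset_genes("groups")
#' @export
md_onset_genes <- function(as = c("groups", "lists")) {
  as <- match.arg(as)
  distal <- read_gene_list(system.file("extdata", "md_distal_genes.txt",
                                       package = "onsetnet", mustWork = TRUE))
  proximal <- read_gene_list(system.file("extdata", "md_proximal_genes.txt",
                                         package = "onsetnet", mustWork = TRUE))
  if (as == "lists") return(list(distal = distal, proximal = proximal))
  assign_onset_groups(distal, proximal)
}
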