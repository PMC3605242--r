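# split ";"-joined evidence fields into sets, tolerant of empties
split_set <- function(x) {
  out <- stringr::str_split(dplyr::coalesce(x, ""), ";")
  lapply(out, function(v) unique(v[nzchar(v)]))
}

join_set <- function(x) vapply(x, paste, character(1), collapse = ";")

#' Merge duplicate interaction-evidence records
#'
#' Canonicalizes each record to an unordered protein pair, drops
#' self-interactions with a warning, and unions the evidence sets
#' (databases, detection methods, PMIDs; domain support is OR-ed) across
#' duplicates, producing one coherent record per pair.
#'
#' @param records Data frame with columns `protein_a`, `protein_b`,
#'   `databases`, `methods`, `pmids` (";"-joined strings, possibly empty)
#'   and `domain_support` (0/1).
#'
#' @return Tibble with one row per unordered pair, same columns.
#' @export
merge_evidence <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) return(records)
  self <- records$protein_a == records$protein_b
  if (any(self)) {
    warn(sprintf("dropping %d self-interaction record(s)", sum(self)))
    records <- records[!self, , drop = FALSE]
  }
  if (nrow(records) == 0) return(records)
  a <- pmin(records$protein_a, records$protein_b)
  b <- pmax(records$protein_a, records$protein_b)
  tibble::tibble(
    protein_a = a, protein_b = b,
    databases = split_set(records$databases),
    methods = split_set(records$methods),
    pmids = split_set(records$pmids),
    domain_support = as.integer(records$domain_support)
  ) |>
    dplyr::group_by(.data$protein_a, .data$protein_b) |>
    dplyr::summarise(
      databases = join_set(list(unique(unlist(.data$databases)))),
      methods = join_set(list(unique(unlist(.data$methods)))),
      pmids = join_set(list(unique(unlist(.data$pmids)))),
      domain_support = as.integer(any(.data$domain_support == 1L)),
      .groups = "drop"
    )
}

#' High-confidence filter for interaction evidence
#'
#' An interaction is retained as high confidence when any of four rules
#' fires: (1) reported by more than one source database; (2) verified by
#' more than one detection-method class (biochemical, biophysical,
#' imaging, protein complementation assay); (3) supported by a known
#' domain-domain interaction; (4) confirmed by more than one independent
#' publication (PMID). The rules are combined disjunctively; per-rule
#' provenance columns are kept so a stricter conjunctive re-filter remains
#' possible downstream.
#'
#' @param records Merged evidence records (see [merge_evidence()]).
#'
#' @return Tibble of the records passing at least one rule, with logical
#'   provenance columns `rule_multi_db`, `rule_multi_method`,
#'   `rule_domain`, `rule_multi_pmid`.
#' @export
hc_filter <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(dplyr::mutate(records, rule_multi_db = logical(),
                         rule_multi_method = logical(),
                         rule_domain = logical(),
                         rule_multi_pmid = logical()))
  }
  out <- dplyr::mutate(
    records,
    rule_multi_db = lengths(split_set(.data$databases)) >= 2L,
    rule_multi_method = lengths(split_set(.data$methods)) >= 2L,
    rule_domain = .data$domain_support == 1L,
    rule_multi_pmid = lengths(split_set(.data$pmids)) >= 2L
  )
  dplyr::filter(out, .data$rule_multi_db | .data$rule_multi_method |
                  .data$rule_domain | .data$rule_multi_pmid)
}

#' Build an undirected network from an edge table
#'
#' @param edges Data frame whose first two columns are the interacting
#'   node IDs (e.g. the output of [hc_filter()]).
#'
#' @return An igraph undirected simple graph.
#' @export
hc_network <- function(edges) {
  el <- as.data.frame(edges[, 1:2])
  igraph::graph_from_data_frame(el, directed = FALSE) |>
    igraph::simplify()
}

#' Call hub proteins by node degree
#'
#' Hubs are nodes whose degree in the high-confidence network reaches the
#' threshold (default 5, i.e. "more than four interactions" — the
#' empirical hub definition used for the Hub attribute bit).
#'
#' @param network An igraph graph or an edge data frame (first two
#'   columns = node pair).
#' @param threshold Minimum degree for a hub (inclusive).
#'
#' @return Tibble with `node`, `degree`, logical `hub`.
#' @export
#' @examples
#' star <- data.frame(a = "c", b = paste0("l", 1:5))
#' call_hubs(star)
call_hubs <- function(network, threshold = 5) {
  g <- if (igraph::is_igraph(network)) network else hc_network(network)
  deg <- igraph::degree(g)
  tibble::tibble(node = names(deg), degree = as.integer(unname(deg)),
                 hub = unname(deg >= threshold)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$node)
}
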