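#' Collapse a probe-level table to one expression row per gene
#'
#' Validation-set preprocessing: raw probe intensities are log2
#' transformed, probes without a gene ID (or mapping to several genes,
#' ";"-separated) are dropped, and for genes measured by several probes
#' the probe with the highest variance across samples is retained.
#'
#' @param probes Data frame with columns `probe`, `gene` and one numeric
#'   column per sample. `gene` may be `NA` or contain ";" for ambiguous
#'   mappings; such probes are removed.
#' @param log2_transform Apply log2 to the sample columns (default TRUE;
#'   requires strictly positive values).
#'
#' @return Tibble with `gene` plus the sample columns (log2 scale), one
#'   row per gene; carries attribute `scale = "log2"`.
#' @export
preprocess_validation <- function(probes, log2_transform = TRUE) {
  probes <- tibble::as_tibble(probes)
  sample_cols <- setdiff(names(probes), c("probe", "gene"))
  if (length(sample_cols) == 0) abort("no sample columns found")
  keep <- !is.na(probes$gene) & nzchar(probes$gene) &
    !grepl(";", probes$gene, fixed = TRUE)
  probes <- probes[keep, , drop = FALSE]
  mat <- as.matrix(probes[sample_cols])
  if (log2_transform) {
    if (any(mat <= 0)) abort("expression must be positive for the log2 step")
    mat <- log2(mat)
  }
  v <- apply(mat, 1, var)
  ord <- order(probes$gene, -v, probes$probe)
  first <- !duplicated(probes$gene[ord])
  sel <- ord[first]
  out <- dplyr::bind_cols(tibble::tibble(gene = probes$gene[sel]),
                          tibble::as_tibble(mat[sel, , drop = FALSE]))
  attr(out, "scale") <- "log2"
  dplyr::arrange(out, .data$gene)
}

#' Build a co-expression network from pairwise Pearson correlation
#'
#' Links every unordered gene pair whose Pearson correlation across
#' samples strictly exceeds the threshold. The correlation is signed:
#' strong anti-correlation does not create an edge. Genes with zero
#' variance cannot be correlated and are excluded with a warning.
#'
#' @param expr Tibble with a `gene` column and one numeric column per
#'   sample (>= 3 samples), e.g. from [preprocess_validation()].
#' @param r_threshold Strict lower bound on r (default 0.5).
#'
#' @return Tibble of edges: `gene_a`, `gene_b`, `r` (with `r >
#'   r_threshold`).
#' @export
build_coexpression <- function(expr, r_threshold = 0.5) {
  expr <- tibble::as_tibble(expr)
  genes <- expr$gene
  mat <- as.matrix(expr[, setdiff(names(expr), "gene"), drop = FALSE])
  if (ncol(mat) < 3) abort("need at least 3 samples for correlation")
  v <- apply(mat, 1, var)
  if (any(v == 0)) {
    warn(sprintf("excluding %d zero-variance gene(s) from correlation",
                 sum(v == 0)))
    mat <- mat[v > 0, , drop = FALSE]
    genes <- genes[v > 0]
  }
  if (length(genes) < 2) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          r = numeric()))
  }
  cc <- cor(t(mat))
  idx <- which(upper.tri(cc) & cc > r_threshold, arr.ind = TRUE)
  tibble::tibble(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                 r = cc[idx]) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Betweenness/eigenvector centralities and their regression residual
#'
#' For an undirected network: betweenness centrality counts the shortest
#' paths on which a node lies as a bridge (raw counts, each unordered pair
#' counted once, no normalization — a star centre over m leaves scores
#' `choose(m, 2)`); eigenvector centrality is the principal-eigenvector
#' score, computed per connected component and scaled to max 1 within the
#' component; the residual is that of the ordinary least-squares fit of
#' betweenness on eigenvector centrality, which highlights bridge-like
#' nodes whose betweenness exceeds what their connectivity to influential
#' nodes predicts.
#'
#' @param network An igraph graph or an edge data frame (first two
#'   columns = node pair).
#'
#' @return Tibble with `node`, `betweenness`, `eigenvector`, `residual`.
#' @export
#' @examples
#' path <- data.frame(a = c("A", "B"), b = c("B", "C"))
#' network_centralities(path)
network_centralities <- function(network) {
  g <- if (igraph::is_igraph(network)) network else hc_network(network)
  if (igraph::vcount(g) == 0) abort("graph is empty")
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  comp <- igraph::components(g)
  eig <- numeric(igraph::vcount(g))
  names(eig) <- igraph::V(g)$name
  for (m in seq_len(comp$no)) {
    nodes <- which(comp$membership == m)
    sub <- igraph::induced_subgraph(g, nodes)
    if (igraph::vcount(sub) == 1 || igraph::ecount(sub) == 0) {
      eig[igraph::V(sub)$name] <- 0
    } else {
      # deterministic dense eigendecomposition of the component adjacency
      # (principal eigenvector, Perron-Frobenius non-negative, max = 1)
      adj <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
      es <- eigen(adj, symmetric = TRUE)
      v <- abs(es$vectors[, which.max(es$values)])
      eig[rownames(adj)] <- v / max(v)
    }
  }
  fit <- lm(btw ~ eig)
  tibble::tibble(node = names(eig),
                 betweenness = unname(btw[names(eig)]),
                 eigenvector = unname(eig),
                 residual = unname(resid(fit)[names(eig)]))
}
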