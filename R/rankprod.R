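#' Rank products from pre-computed rank lists
#'
#' Low-level kernel: given a genes-by-lists matrix of ranks (rank 1 = most
#' extreme in the direction of interest), returns per-gene rank products
#' `RP = prod_i(r_i / n)` where `n` is the number of genes. Exposed so the
#' product can be checked directly on hand-built rank configurations.
#'
#' @param ranks Numeric matrix, genes x lists.
#'
#' @return Numeric vector of rank products in (0, 1].
#' @export
#' @examples
#' rp_from_rank_lists(rbind(gA = c(1, 2), gB = c(2, 1), gC = c(3, 3)))
rp_from_rank_lists <- function(ranks) {
  ranks <- as.matrix(ranks)
  n <- nrow(ranks)
  exp(rowSums(log(ranks / n)))
}

#' Rank-product differential expression with permutation-based pfp
#'
#' Unpaired two-class rank product: every tumor sample is paired with
#' every normal sample, giving `K = n_tumor * n_normal` log2-ratio lists.
#' Within each list genes are ranked descending (up-regulation) and
#' ascending (down-regulation), ties broken by average rank, and the rank
#' product `RP = prod_i(r_i / n)` is taken across lists. Significance is
#' the percentage of false prediction (pfp), the rank-product analogue of
#' the FDR: the null RP distribution is estimated by `n_perm` random
#' permutations of the gene labels within each sample, re-deriving the
#' rank lists each time, and
#' `pfp(g) = E[#null RP <= RP(g)] / rank(g)`. Permuting whole sample
#' columns (rather than each derived ratio list independently) preserves
#' the correlation among lists that share a sample, which is what keeps
#' pfp calibrated on null data.
#'
#' @param expr Expression tibble as produced by [sim_expression()] (gene
#'   column + sample columns, `sample_class` attribute) — or any data
#'   frame in that layout with `classes` supplied explicitly.
#' @param n_perm Number of null permutations (>= 1).
#' @param seed Integer seed for the permutation draw.
#' @param classes Named character vector mapping sample column names to
#'   "tumor"/"normal"; defaults to the tibble's `sample_class` attribute.
#' @param log2_input Set `TRUE` if `expr` is already on the log2 scale;
#'   by default the `scale` attribute is consulted (linear values are
#'   log2-transformed first).
#'
#' @return Tibble of class `boolerank_rp`: `gene`, `rp_up`, `rp_down`,
#'   `rank_up`, `rank_down`, `pfp_up`, `pfp_down`.
#' @export
#' @examples
#' sim <- sim_expression(synthetic_config(n_genes = 100, seed = 2))
#' rp <- rank_product(sim$expression, n_perm = 20, seed = 9)
rank_product <- function(expr, n_perm = 100, seed = 1L, classes = NULL,
                         log2_input = NULL) {
  classes <- classes %||% attr(expr, "sample_class")
  if (is.null(classes)) abort("sample classes not found: supply `classes`")
  if (n_perm < 1) abort("n_perm must be >= 1")
  genes <- expr[[1]]
  mat <- as.matrix(expr[, names(classes), drop = FALSE])
  if (anyNA(mat)) abort("expression matrix contains missing values")
  log2_input <- log2_input %||% identical(attr(expr, "scale"), "log2")
  if (!log2_input) {
    if (any(mat <= 0)) abort("linear-scale expression must be positive")
    mat <- log2(mat)
  }
  tumor <- which(classes == "tumor")
  normal <- which(classes == "normal")
  if (length(tumor) == 0 || length(normal) == 0) {
    abort("both tumor and normal samples are required")
  }
  n <- length(genes)
  # genes x K matrix of log2 tumor/normal ratios over all pairs
  ratios <- matrix(0, nrow = n, ncol = length(tumor) * length(normal))
  k <- 0L
  for (i in tumor) for (j in normal) {
    k <- k + 1L
    ratios[, k] <- mat[, i] - mat[, j]
  }
  rank_up <- apply(-ratios, 2, rank, ties.method = "average")
  rank_dn <- apply(ratios, 2, rank, ties.method = "average")
  log_rp_up <- rowSums(log(rank_up / n))
  log_rp_dn <- rowSums(log(rank_dn / n))

  null_log_rp <- withr::with_seed(seed, {
    vals <- numeric(n_perm * n)
    perm_ratio <- matrix(0, nrow = n, ncol = ncol(ratios))
    for (b in seq_len(n_perm)) {
      pmat <- mat
      for (s in seq_len(ncol(pmat))) pmat[, s] <- pmat[sample.int(n), s]
      k <- 0L
      for (i in tumor) for (j in normal) {
        k <- k + 1L
        perm_ratio[, k] <- pmat[, i] - pmat[, j]
      }
      # one direction suffices: the null is symmetric in up vs down
      pr <- apply(-perm_ratio, 2, rank, ties.method = "average")
      vals[(b - 1L) * n + seq_len(n)] <- rowSums(log(pr / n))
    }
    sort(vals)
  })
  pfp_of <- function(log_rp) {
    cnt <- findInterval(log_rp, null_log_rp) / n_perm
    r <- rank(log_rp, ties.method = "average")
    cnt / r
  }
  out <- tibble::tibble(
    gene = genes,
    rp_up = exp(log_rp_up), rp_down = exp(log_rp_dn),
    rank_up = rank(log_rp_up, ties.method = "average"),
    rank_down = rank(log_rp_dn, ties.method = "average"),
    pfp_up = pfp_of(log_rp_up), pfp_down = pfp_of(log_rp_dn)
  )
  class(out) <- c("boolerank_rp", class(out))
  attr(out, "n_perm") <- n_perm
  attr(out, "n_lists") <- ncol(ratios)
  out
}

#' Call up/down-regulated genes at a pfp cutoff
#'
#' A gene is called "up" when `pfp_up <= cutoff`, "down" when
#' `pfp_down <= cutoff`, otherwise "none". Genes significant in both
#' directions (possible with few lists) are resolved to the direction with
#' the smaller rank product and flagged in `both_directions`.
#'
#' @param results Output of [rank_product()].
#' @param pfp_cutoff Percentage-of-false-prediction threshold in (0, 1];
#'   default 0.05.
#'
#' @return The input tibble with `call` and `both_directions` columns.
#' @export
call_de <- function(results, pfp_cutoff = 0.05) {
  if (pfp_cutoff <= 0 || pfp_cutoff > 1) abort("pfp_cutoff must be in (0, 1]")
  up <- results$pfp_up <= pfp_cutoff
  dn <- results$pfp_down <= pfp_cutoff
  call <- dplyr::case_when(
    up & dn & results$rp_up <= results$rp_down ~ "up",
    up & dn ~ "down",
    up ~ "up",
    dn ~ "down",
    .default = "none"
  )
  dplyr::mutate(results, call = call, both_directions = up & dn)
}

#' @export
glance.boolerank_rp <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_lists = attr(x, "n_lists"),
    n_perm = attr(x, "n_perm"),
    n_up = if ("call" %in% names(x)) sum(x$call == "up") else NA_integer_,
    n_down = if ("call" %in% names(x)) sum(x$call == "down") else NA_integer_
  )
}
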