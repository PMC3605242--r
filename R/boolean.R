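#' Enumerate the Boolean roots of an attribute pattern
#'
#' A gene with `k` functional attributes present has `2^k` Boolean states,
#' of which the `2^k - 1` non-empty ones (all combinations of the set bits,
#' excluding the all-zero state) are its roots.
#'
#' @param pattern A 7-character "0/1" string (bit order as in
#'   [attribute_order()]) or a logical/0-1 vector of length 7.
#'
#' @return Character vector of 7-character sub-patterns in lexicographic
#'   order, length `2^k - 1`.
#' @export
#' @examples
#' enumerate_roots("0000011")
enumerate_roots <- function(pattern) {
  bits <- parse_pattern(pattern)
  pos <- which(bits)
  k <- length(pos)
  if (k == 0L) abort("pattern has no attributes set: no roots exist")
  roots <- character(2^k - 1L)
  for (m in seq_len(2^k - 1L)) {
    sub <- rep(FALSE, 7L)
    sub[pos[bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) > 0L]] <- TRUE
    roots[m] <- format_pattern(sub)
  }
  sort(roots)
}

#' Probability of a single Boolean root
#'
#' The probability assigned to a root is the arithmetic mean of the phi
#' weights of the attributes present in it.
#'
#' @param root A root pattern (string or 7-vector, as in
#'   [enumerate_roots()]).
#' @param weights A weight table from [build_weight_table()] /
#'   [table1_weights()], or a named numeric vector over the attributes.
#'
#' @return A single numeric probability.
#' @export
#' @examples
#' root_probability("0000001", table1_weights())  # Hub alone
root_probability <- function(root, weights) {
  bits <- parse_pattern(root)
  if (!any(bits)) abort("root must be non-empty")
  w <- weights_vector(weights)
  mean(w[bits])
}

#' Boolean root-decomposition score of an attribute pattern
#'
#' Decomposes the pattern into its `2^k - 1` roots, scores each root as the
#' mean weight of its member attributes, and sums the root probabilities.
#' The sum has the closed form `((2^k - 1) / k) * sum(w[set bits])`, which
#' the test suite verifies against this brute-force enumeration.
#'
#' @inheritParams enumerate_roots
#' @param weights See [root_probability()].
#'
#' @return One-row tibble with `pattern`, `k`, `n_roots`, `score`.
#' @export
#' @examples
#' boolean_score("0011011", table1_weights())
boolean_score <- function(pattern, weights) {
  bits <- parse_pattern(pattern)
  roots <- enumerate_roots(bits)
  w <- weights_vector(weights)
  score <- sum(vapply(roots, function(r) mean(w[parse_pattern(r)]),
                      numeric(1)))
  tibble::tibble(
    pattern = format_pattern(bits),
    k = sum(bits),
    n_roots = length(roots),
    score = score
  )
}

#' Score a table of genes by Boolean root decomposition
#'
#' @param attributes Data frame with a `gene` column and the seven 0/1
#'   attribute columns named as in [attribute_order()], or columns `gene`
#'   and `pattern` (7-character strings).
#' @param weights See [root_probability()].
#'
#' @return Tibble with `gene`, `pattern`, `k`, `n_roots`, `score`. Genes
#'   whose pattern is all-zero get `k = 0`, `n_roots = 0` and `score = 0`.
#' @export
score_genes <- function(attributes, weights) {
  attrs <- attribute_order()
  if ("pattern" %in% names(attributes)) {
    pats <- as.character(attributes$pattern)
  } else {
    missing_cols <- setdiff(attrs, names(attributes))
    if (length(missing_cols) > 0) {
      abort(paste0("missing attribute column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    pats <- apply(as.matrix(attributes[attrs]) == 1, 1, format_pattern)
  }
  # only <= 127 distinct non-zero patterns exist; score each once
  uniq <- unique(pats)
  scored <- purrr::map_dfr(uniq, function(p) {
    if (!grepl("1", p)) {
      return(tibble::tibble(pattern = p, k = 0L, n_roots = 0L, score = 0))
    }
    boolean_score(p, weights)
  })
  tibble::tibble(gene = attributes$gene, pattern = pats) |>
    dplyr::left_join(scored, by = "pattern")
}

#' Shortlist genes by Boolean score, split by differential-expression call
#'
#' Keeps genes whose score strictly exceeds the cutoff (default 0.5, the
#' empirical threshold of the published analysis) and records the
#' DE call so the shortlist can be partitioned into differentially and
#' non-differentially expressed sets.
#'
#' @param scores Output of [score_genes()].
#' @param de_calls Optional data frame with columns `gene` and `call`
#'   (values `"up"`, `"down"`, `"none"`), e.g. from [call_de()].
#' @param cutoff Strict score threshold; must be >= 0.
#'
#' @return Tibble of scored genes with logical `shortlisted` and (when DE
#'   calls are supplied) `de_call` columns.
#' @export
shortlist <- function(scores, de_calls = NULL, cutoff = 0.5) {
  if (cutoff < 0) abort("cutoff must be non-negative")
  out <- dplyr::mutate(tibble::as_tibble(scores),
                       shortlisted = .data$score > cutoff)
  if (!is.null(de_calls)) {
    out <- dplyr::left_join(
      out, dplyr::select(de_calls, "gene", de_call = "call"), by = "gene")
    out$de_call <- dplyr::coalesce(out$de_call, "none")
  }
  out
}

#' Reconcile published pattern scores with the attribute-to-bit assignment
#'
#' Exhaustively searches all 5040 assignments of the seven attributes to
#' the seven bit positions, scoring each published pattern under the
#' closed form and keeping assignments that reproduce the published scores
#' within `tol`. With the published weights, the four patterns that do not
#' involve the methylation bit pin positions 2, 5, 6, 7 to SP, PTM, TF and
#' Hub and positions 3-4 to \{PK, TS\} (interchangeable: the two are always
#' jointly set). The two methylation-containing patterns reproduce under no
#' assignment; pass `patterns` to restrict the constraint set.
#'
#' @param weights Weight table or named vector (see [root_probability()]).
#' @param patterns Character vector of 7-bit patterns to constrain on.
#' @param target_scores Published scores, same length as `patterns`.
#' @param tol Absolute tolerance on each score.
#'
#' @return Tibble with one row per consistent assignment; columns
#'   `pos1`..`pos7` give the attribute at each bit position, and
#'   `max_abs_err` the worst score deviation.
#' @export
infer_attribute_order <- function(weights,
                                  patterns = c("0011011", "0011101",
                                               "0011110", "0111010"),
                                  target_scores = c(0.743532, 0.735481,
                                                    0.644578, 0.607561),
                                  tol = 1e-4) {
  stopifnot(length(patterns) == length(target_scores))
  w <- weights_vector(weights)
  attrs <- attribute_order()
  bit_sets <- lapply(patterns, function(p) which(parse_pattern(p)))
  ks <- lengths(bit_sets)
  mult <- (2^ks - 1) / ks
  perms <- permutations_of(7L)
  hits <- purrr::map_dfr(seq_len(nrow(perms)), function(i) {
    asg <- perms[i, ]                      # position j holds attrs[asg[j]]
    wpos <- unname(w[attrs[asg]])
    sc <- vapply(seq_along(bit_sets),
                 function(j) mult[j] * sum(wpos[bit_sets[[j]]]), numeric(1))
    err <- max(abs(sc - target_scores))
    if (err <= tol) {
      row <- as.list(attrs[asg])
      names(row) <- paste0("pos", 1:7)
      tibble::as_tibble(c(row, list(max_abs_err = err)))
    } else {
      NULL
    }
  })
  hits
}

# All permutations of 1..n as a matrix (n! rows); n is small (7 here).
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[r, ] <- c(k, rest[sub[i, ]])
      r <- r + 1L
    }
  }
  out
}

#' Compare computed pattern scores against the published shortlist
#'
#' Scores every pattern of the published 17-gene shortlist with the given
#' weights and reports computed vs published values. The two
#' methylation-containing patterns (1011001, 1011010) are known not to
#' reproduce under the mean-root scoring model with any attribute-to-bit
#' assignment; they come back with `reproduced = FALSE` and both values so
#' the discrepancy stays visible rather than being absorbed.
#'
#' @param weights Weight table (defaults to the packaged published
#'   weights).
#' @param tol Absolute tolerance for `reproduced`.
#'
#' @return Tibble with `pattern`, `printed_rank`, `score`, `delta`,
#'   `reproduced` for the distinct shortlist patterns.
#' @export
#' @examples
#' check_table2_scores()
check_table2_scores <- function(weights = table1_weights(), tol = 1e-4) {
  ref <- dplyr::distinct(table2_patterns(), .data$pattern,
                         .data$printed_rank)
  scored <- purrr::map_dfr(ref$pattern, boolean_score, weights = weights)
  dplyr::bind_cols(ref["pattern"],
                   printed_rank = ref$printed_rank,
                   scored[c("k", "score")]) |>
    dplyr::mutate(delta = .data$score - .data$printed_rank,
                  reproduced = abs(.data$delta) <= tol)
}
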