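#' Default gene-signature definition from the published shortlist
#'
#' @return List with character vectors `up_genes` (7 genes) and
#'   `down_genes` (10 genes).
#' @export
signature_definition <- function() {
  t2 <- table2_patterns()
  list(up_genes = t2$gene_symbol[t2$up == 1],
       down_genes = t2$gene_symbol[t2$down == 1])
}

#' Per-sample gene-signature score
#'
#' The signature score of a sample is the sum of its expression values
#' over the up-regulated signature genes minus the sum over the
#' down-regulated ones. Signature genes absent from the expression table
#' are skipped with a warning (validation cohorts may lack probes for
#' some genes); the score is computed on whatever expression scale the
#' input carries, recorded in the `scale` attribute of the result.
#'
#' @param expr Tibble with a `gene` column and one numeric column per
#'   sample.
#' @param sigdef List with `up_genes` and `down_genes` (disjoint ID
#'   sets); defaults to [signature_definition()].
#'
#' @return Tibble with `sample`, `score`.
#' @export
#' @examples
#' expr <- tibble::tibble(gene = c("A", "B"), s1 = c(2, 1), s2 = c(3, 4))
#' signature_score(expr, list(up_genes = "A", down_genes = "B"))
signature_score <- function(expr, sigdef = signature_definition()) {
  if (length(intersect(sigdef$up_genes, sigdef$down_genes)) > 0) {
    abort("up_genes and down_genes must be disjoint")
  }
  expr <- tibble::as_tibble(expr)
  sample_cols <- setdiff(names(expr), "gene")
  present_up <- intersect(sigdef$up_genes, expr$gene)
  present_dn <- intersect(sigdef$down_genes, expr$gene)
  missing <- setdiff(c(sigdef$up_genes, sigdef$down_genes), expr$gene)
  if (length(present_up) + length(present_dn) == 0) {
    abort("no signature gene present in the expression table")
  }
  if (length(missing) > 0) {
    warn(paste0("signature gene(s) absent from expression table: ",
                paste(missing, collapse = ", ")))
  }
  mat <- as.matrix(expr[, sample_cols, drop = FALSE])
  rownames(mat) <- expr$gene
  score <- colSums(mat[present_up, , drop = FALSE]) -
    colSums(mat[present_dn, , drop = FALSE])
  out <- tibble::tibble(sample = sample_cols, score = unname(score))
  attr(out, "scale") <- attr(expr, "scale") %||% "unspecified"
  out
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and two-sided p-value, used to contrast signature scores
#' between tumor and normal samples.
#'
#' @param x,y Numeric vectors (>= 2 values each).
#'
#' @return One-row tibble with `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
#' @examples
#' welch_t(c(0, 1), c(10, 11))
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("need >= 2 values per group")
  if (sd(x) == 0 && sd(y) == 0) {
    abort("both groups have zero variance: Welch t is undefined")
  }
  ht <- t.test(x, y, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_x = mean(x), mean_y = mean(y))
}

#' Median split of samples into low/high expression groups
#'
#' Samples are ranked from lowest to highest value; the lower 50% are
#' labelled "low", the rest "high". Ties are broken deterministically by
#' (value, sample ID) stable order, and an odd middle sample goes to
#' "low".
#'
#' @param values Numeric vector (>= 4 values).
#' @param ids Sample identifiers; defaults to `names(values)` or
#'   positional IDs.
#'
#' @return Tibble with `sample`, `value`, `group` ("low"/"high").
#' @export
#' @examples
#' median_split(c(a = 1, b = 2, c = 3, d = 4))
median_split <- function(values, ids = NULL) {
  if (length(values) < 4) abort("median split needs >= 4 samples")
  ids <- ids %||% names(values) %||% as.character(seq_along(values))
  ord <- order(values, ids)
  n_low <- ceiling(length(values) / 2)
  group <- character(length(values))
  group[ord] <- rep(c("low", "high"),
                    c(n_low, length(values) - n_low))
  tibble::tibble(sample = ids, value = unname(values), group = group)
}

#' Kaplan-Meier product-limit survival estimate
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event observed, 0 = right
#'   censored).
#'
#' @return Tibble with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
#' @examples
#' km_curve(c(1, 2, 3), c(1, 1, 1))
km_curve <- function(times, events) {
  if (any(times < 0)) abort("survival times must be non-negative")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 survival = fit$surv)
}

#' Cox-Mantel log-rank test between two survival groups
#'
#' Compares observed versus expected event counts across the distinct
#' event times (hypergeometric variance, simultaneous risk-set accounting
#' for ties); the statistic is chi-square with one degree of freedom.
#'
#' @param time Follow-up times.
#' @param event Event indicators (1/0).
#' @param group Two-level group labels (e.g. "low"/"high").
#'
#' @return Object of class `boolerank_logrank` with elements `chi2`,
#'   `df`, `p_value`, `observed`, `expected`, `n` (per group); has
#'   [tidy()] and [glance()] methods.
#' @export
#' @examples
#' cl <- sim_clinical(40, hazard_ratio = 3, seed = 2)
#' logrank_test(cl$time, cl$event, cl$group)
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2) abort("log-rank test requires exactly two groups")
  if (sum(event) < 1) abort("log-rank test requires at least one event")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  structure(list(
    chi2 = unname(sd_fit$chisq), df = 1L,
    p_value = pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE),
    observed = setNames(sd_fit$obs, levels(group)),
    expected = setNames(sd_fit$exp, levels(group)),
    n = setNames(as.vector(sd_fit$n), levels(group))
  ), class = "boolerank_logrank")
}

#' @export
print.boolerank_logrank <- function(x, ...) {
  cat("Cox-Mantel log-rank test\n")
  cat(sprintf("  chi2 = %.4f on %d df, p = %.4g\n", x$chi2, x$df, x$p_value))
  invisible(x)
}

#' @export
tidy.boolerank_logrank <- function(x, ...) {
  tibble::tibble(group = names(x$n), n = x$n,
                 observed = x$observed, expected = x$expected)
}

#' @export
glance.boolerank_logrank <- function(x, ...) {
  tibble::tibble(statistic = x$chi2, df = x$df, p_value = x$p_value)
}

#' Combined three-gene prognostic score
#'
#' Per-sample combination `x[first] + x[second] - x[third]`; the default
#' genes CHEK1, AR and LYN form the published combined prognostic marker
#' (CHEK1 + AR - LYN). All three genes must be present.
#'
#' @param expr Tibble with a `gene` column and one numeric column per
#'   sample.
#' @param genes Character vector of three gene IDs: the two added, then
#'   the one subtracted.
#'
#' @return Tibble with `sample`, `score`.
#' @export
combined_score <- function(expr, genes = c("CHEK1", "AR", "LYN")) {
  if (length(genes) != 3) abort("combined score needs exactly three genes")
  missing <- setdiff(genes, expr$gene)
  if (length(missing) > 0) {
    abort(paste0("gene(s) missing from expression table: ",
                 paste(missing, collapse = ", ")))
  }
  sample_cols <- setdiff(names(expr), "gene")
  mat <- as.matrix(expr[, sample_cols, drop = FALSE])
  rownames(mat) <- expr$gene
  score <- mat[genes[1], ] + mat[genes[2], ] - mat[genes[3], ]
  tibble::tibble(sample = sample_cols, score = unname(score))
}

#' Median-split survival stratification for a per-sample score
#'
#' Convenience wrapper chaining [median_split()] and [logrank_test()]:
#' samples are dichotomized at the median of `score` and the two groups'
#' survival compared.
#'
#' @param scores Tibble with `sample` and `score` (e.g. from
#'   [signature_score()] or [combined_score()]).
#' @param clinical Tibble with `sample`, `time`, `event`.
#'
#' @return List with `groups` (the median-split tibble joined to the
#'   clinical records) and `logrank` (a `boolerank_logrank`).
#' @export
stratify_survival <- function(scores, clinical) {
  clinical <- tibble::as_tibble(clinical)
  if ("group" %in% names(clinical)) {
    # keep any pre-existing cohort grouping out of the way of the split
    clinical <- dplyr::rename(clinical, cohort_group = "group")
  }
  groups <- median_split(scores$score, ids = scores$sample) |>
    dplyr::inner_join(clinical, by = "sample")
  if (nrow(groups) < 4) abort("fewer than 4 samples with clinical records")
  list(groups = groups,
       logrank = logrank_test(groups$time, groups$event, groups$group))
}
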