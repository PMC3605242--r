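#' Phi correlation between two binary variables from a 2x2 table
#'
#' Measures the association between a binary functional attribute and the
#' cancer-gene label. The magnitude equals `sqrt(chi2 / N)` where `chi2` is
#' the (uncorrected) Pearson chi-square statistic of the 2x2 table and `N`
#' the total count; the p-value comes from the chi-square distribution with
#' one degree of freedom. The reported `r_phi` is unsigned; the enrichment
#' direction (`+1` when the attribute is enriched in the positive class,
#' `-1` when depleted, `0` at exact independence) is returned separately.
#'
#' @param a Count of observations with attribute present and label positive.
#' @param b Attribute present, label negative.
#' @param c Attribute absent, label positive.
#' @param d Attribute absent, label negative.
#'
#' @return A one-row tibble with columns `r_phi`, `p_value`, `direction`,
#'   `chi2` and `n`.
#' @export
#' @examples
#' phi_correlation(10, 20, 30, 40)
phi_correlation <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (anyNA(counts) || any(counts < 0)) {
    abort("all four cell counts must be non-negative")
  }
  n <- sum(counts)
  if (n < 1) abort("table is empty: a + b + c + d must be >= 1")
  margins <- c(
    "attribute present (a + b)" = a + b,
    "attribute absent (c + d)"  = c + d,
    "label positive (a + c)"    = a + c,
    "label negative (b + d)"    = b + d
  )
  if (any(margins == 0)) {
    zero <- names(margins)[margins == 0][1]
    abort(sprintf("phi is undefined: margin %s is zero", zero))
  }
  num <- a * d - b * c
  r_phi <- abs(num) / sqrt(prod(margins))
  chi2 <- r_phi^2 * n
  tibble::tibble(
    r_phi = r_phi,
    p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
    direction = sign(num),
    chi2 = chi2,
    n = n
  )
}

#' Phi weights for the seven functional attributes
#'
#' Cross-tabulates each binary attribute column against the cancer/
#' non-cancer gene label and computes the phi correlation for each. The
#' resulting table of weights drives the Boolean root scoring in
#' [boolean_score()].
#'
#' @param attributes Data frame with one row per gene, the seven attribute
#'   columns named as in [attribute_order()] (values 0/1), and a binary
#'   label column.
#' @param label Name of the label column (default `"cancer"`).
#'
#' @return A tibble with columns `attribute`, `r_phi`, `p_value`,
#'   `direction`, one row per attribute in canonical order.
#' @export
#' @examples
#' cfg <- synthetic_config(n_genes = 500, seed = 1)
#' attrs <- sim_attributes(cfg)
#' build_weight_table(attrs)
build_weight_table <- function(attributes, label = "cancer") {
  attrs <- attribute_order()
  missing_cols <- setdiff(c(attrs, label), names(attributes))
  if (length(missing_cols) > 0) {
    abort(paste0("missing attribute column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  lab <- as.integer(attributes[[label]])
  purrr::map_dfr(attrs, function(at) {
    x <- as.integer(attributes[[at]])
    res <- phi_correlation(
      a = sum(x == 1 & lab == 1), b = sum(x == 1 & lab == 0),
      c = sum(x == 0 & lab == 1), d = sum(x == 0 & lab == 0)
    )
    dplyr::bind_cols(tibble::tibble(attribute = at),
                     res[c("r_phi", "p_value", "direction")])
  })
}

#' Published phi weights for the seven attributes
#'
#' Loads the packaged reference weight table (phi correlation and p-value
#' per attribute, as published for the ovarian tumor study). The source
#' gene-by-attribute counts behind these weights are not public, so the
#' table ships as input data rather than being re-derived.
#'
#' @return A tibble with columns `attribute`, `r_phi`, `p_value`.
#' @export
#' @examples
#' table1_weights()
table1_weights <- function() {
  path <- system.file("extdata", "table1_weights.tsv", package = "boolerank")
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Published 17-gene shortlist: patterns and scores
#'
#' Loads the packaged reference shortlist: the 17 differentially expressed
#' genes, their up/down calls, 7-bit Boolean attribute patterns and
#' published probability scores.
#'
#' @return A tibble with columns `gene_symbol`, `gene_id`, `up`, `down`,
#'   `pattern`, `printed_rank`.
#' @export
#' @examples
#' table2_patterns()
table2_patterns <- function() {
  path <- system.file("extdata", "table2_patterns.tsv", package = "boolerank")
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(pattern = readr::col_character()))
}

# Named weight vector in attribute order, from a weight table or a named
# numeric vector.
weights_vector <- function(weights) {
  attrs <- attribute_order()
  if (is.data.frame(weights)) {
    if (!all(c("attribute", "r_phi") %in% names(weights))) {
      abort("weight table must have columns 'attribute' and 'r_phi'")
    }
    w <- setNames(weights$r_phi, weights$attribute)
  } else {
    w <- weights
  }
  if (!all(attrs %in% names(w))) {
    abort(paste0("weights missing for attribute(s): ",
                 paste(setdiff(attrs, names(w)), collapse = ", ")))
  }
  w[attrs]
}
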