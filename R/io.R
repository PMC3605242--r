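#' Write / read an expression table with embedded class labels
#'
#' Expression TSVs carry the sample class in the header: each sample
#' column is named `<sample>:<class>`. `write_expression_tsv()` encodes
#' the `sample_class` attribute that way; `read_expression_tsv()` decodes
#' it back.
#'
#' @param expr Expression tibble (`gene` column + sample columns, with a
#'   `sample_class` attribute).
#' @param path File path.
#'
#' @return `write_expression_tsv()` returns `expr` invisibly;
#'   `read_expression_tsv()` returns the expression tibble with
#'   `sample_class` and `scale` attributes restored.
#' @export
write_expression_tsv <- function(expr, path) {
  classes <- attr(expr, "sample_class")
  out <- expr
  if (!is.null(classes)) {
    samp <- setdiff(names(out), "gene")
    names(out)[match(samp, names(out))] <-
      paste0(samp, ":", classes[samp])
  }
  hdr <- attr(expr, "scale") %||% "linear"
  readr::write_tsv(dplyr::mutate(out, .scale = hdr) |>
                     dplyr::relocate(".scale", .after = dplyr::last_col()),
                   path)
  invisible(expr)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  scale <- raw$.scale[1]
  raw$.scale <- NULL
  samp_cols <- setdiff(names(raw), "gene")
  parts <- stringr::str_split_fixed(samp_cols, ":", 2)
  names(raw)[match(samp_cols, names(raw))] <- parts[, 1]
  attr(raw, "sample_class") <- setNames(parts[, 2], parts[, 1])
  attr(raw, "scale") <- scale
  raw
}
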