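#' Pipeline configuration with the published default thresholds
#'
#' Collects every stage threshold in one place, defaulted to the values
#' of the published workflow: pfp cutoff 0.05 for differential
#' expression, Boolean score cutoff 0.5 for shortlisting, Pearson r
#' threshold 0.5 for co-expression edges, hub degree threshold 5, and
#' log-rank alpha 0.1 for the clinical stage.
#'
#' @param synthetic A [synthetic_config()] describing the simulated
#'   inputs.
#' @param pfp_cutoff,score_cutoff,r_threshold,hub_threshold,logrank_alpha
#'   Stage thresholds (see above).
#' @param n_perm Rank-product permutations.
#' @param stages Character vector of stages to run, in order, from
#'   `c("simulate", "de", "weights", "score", "interactome", "network",
#'   "clinical")`.
#' @param seed Integer master seed.
#'
#' @return List of class `boolerank_pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(seed = seed),
                            pfp_cutoff = 0.05, score_cutoff = 0.5,
                            r_threshold = 0.5, hub_threshold = 5,
                            logrank_alpha = 0.1, n_perm = 100,
                            stages = c("simulate", "de", "weights",
                                       "score", "interactome", "network",
                                       "clinical"),
                            seed = 1L) {
  if (pfp_cutoff <= 0 || pfp_cutoff > 1) abort("pfp_cutoff must be in (0, 1]")
  if (score_cutoff < 0) abort("score_cutoff must be >= 0")
  structure(list(synthetic = synthetic, pfp_cutoff = pfp_cutoff,
                 score_cutoff = score_cutoff, r_threshold = r_threshold,
                 hub_threshold = hub_threshold,
                 logrank_alpha = logrank_alpha, n_perm = n_perm,
                 stages = stages, seed = as.integer(seed)),
            class = "boolerank_pipeline_config")
}

#' Run the end-to-end synthetic prioritization workflow
#'
#' Executes the stages in order — simulate inputs, rank-product DE,
#' phi-weight estimation, Boolean scoring and shortlisting,
#' high-confidence interactome filtering and hub calls, co-expression
#' network with centralities, and clinical stratification of the
#' signature score — writing each stage's tables as TSV under `out_dir`
#' together with a JSON provenance manifest (config hash, seed, package
#' version). Stages not listed in the config are skipped; downstream
#' stages consume in-memory upstream results.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#'
#' @return Invisibly, a list with the per-stage results and
#'   `manifest_path`.
#' @export
#' @examples
#' cfg <- pipeline_config(synthetic = synthetic_config(n_genes = 60,
#'                                                     seed = 5),
#'                        n_perm = 10, seed = 5)
#' res <- run_pipeline(cfg, out_dir = tempfile("boolerank_run"))
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "boolerank_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  res <- list()
  tsv <- function(x, name) readr::write_tsv(x, file.path(out_dir, name))

  if ("simulate" %in% stages) {
    sim <- sim_expression(config$synthetic)
    res$expression <- sim$expression
    res$truth <- sim$truth
    res$attributes <- sim_attributes(config$synthetic)
    res$interactions <- sim_interactions(
      n_proteins = 60, n_edges = 150, seed = config$seed + 2L)
    res$clinical <- sim_clinical(
      n_samples = 2 * config$synthetic$n_tumor,
      hazard_ratio = config$synthetic$hazard_ratio,
      seed = config$seed + 3L)
    write_expression_tsv(res$expression, file.path(out_dir,
                                                   "expression.tsv"))
    tsv(res$truth, "truth.tsv")
    tsv(res$attributes, "attributes.tsv")
    tsv(res$interactions, "interactions.tsv")
    tsv(res$clinical, "clinical.tsv")
  }
  if ("de" %in% stages) {
    need(res, "expression", "de")
    res$de <- rank_product(res$expression, n_perm = config$n_perm,
                           seed = config$seed) |>
      call_de(pfp_cutoff = config$pfp_cutoff)
    tsv(dplyr::select(res$de, -"both_directions"), "rank_product.tsv")
  }
  if ("weights" %in% stages) {
    need(res, "attributes", "weights")
    res$weights <- build_weight_table(res$attributes)
    tsv(res$weights, "weights.tsv")
  }
  if ("score" %in% stages) {
    need(res, "weights", "score")
    res$scores <- score_genes(res$attributes, res$weights) |>
      shortlist(de_calls = res$de, cutoff = config$score_cutoff)
    tsv(res$scores, "boolean_scores.tsv")
  }
  if ("interactome" %in% stages) {
    need(res, "interactions", "interactome")
    res$hc_edges <- merge_evidence(res$interactions) |> hc_filter()
    res$hubs <- call_hubs(res$hc_edges, threshold = config$hub_threshold)
    tsv(res$hc_edges, "hc_edges.tsv")
    tsv(res$hubs, "hubs.tsv")
  }
  if ("network" %in% stages) {
    need(res, "expression", "network")
    log2_expr <- res$expression
    samp <- setdiff(names(log2_expr), "gene")
    log2_expr[samp] <- log2(log2_expr[samp])
    keep <- if (!is.null(res$scores)) {
      union(res$scores$gene[res$scores$shortlisted],
            head(res$truth$gene[res$truth$truth != "null"], 50))
    } else log2_expr$gene
    res$coexpression <- build_coexpression(
      dplyr::filter(log2_expr, .data$gene %in% keep),
      r_threshold = config$r_threshold)
    tsv(res$coexpression, "coexpression_edges.tsv")
    if (nrow(res$coexpression) > 0) {
      res$centralities <- network_centralities(res$coexpression)
      tsv(res$centralities, "centralities.tsv")
    }
  }
  if ("clinical" %in% stages) {
    need(res, "clinical", "clinical")
    need(res, "truth", "clinical")
    up <- res$truth$gene[res$truth$truth == "up"]
    dn <- res$truth$gene[res$truth$truth == "down"]
    tumor_expr <- res$expression[, c(TRUE, attr(res$expression,
                                                "sample_class") == "tumor")]
    # align the simulated cohort with the tumor samples by position
    n_use <- min(nrow(res$clinical), ncol(tumor_expr) - 1L)
    sig <- signature_score(tumor_expr[, c(1, 1 + seq_len(n_use))],
                           list(up_genes = up, down_genes = dn))
    sig$sample <- res$clinical$sample[seq_len(n_use)]
    res$signature <- sig
    res$survival <- stratify_survival(sig,
                                      res$clinical[seq_len(n_use), ])
    tsv(sig, "signature_scores.tsv")
    tsv(glance(res$survival$logrank), "logrank.tsv")
  }

  manifest <- list(
    package = "boolerank",
    version = as.character(utils::packageVersion("boolerank")),
    seed = config$seed,
    stages = stages,
    config_hash = rlang::hash(config),
    thresholds = config[c("pfp_cutoff", "score_cutoff", "r_threshold",
                          "hub_threshold", "logrank_alpha", "n_perm")]
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  res$manifest_path <- manifest_path
  invisible(res)
}

need <- function(res, what, stage) {
  if (is.null(res[[what]])) {
    abort(sprintf("stage '%s' requires upstream output '%s'; run the %s",
                  stage, what,
                  "producing stage first or enable it in `stages`"))
  }
  invisible(TRUE)
}
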