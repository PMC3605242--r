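#' Configuration for the synthetic-data generators
#'
#' Bundles and validates the knobs of the simulation module: a two-class
#' (tumor/normal) expression matrix with planted up/down genes, a binary
#' attribute table with class-conditional prevalences, and survival
#' records with group-dependent hazards.
#'
#' @param n_genes Number of genes.
#' @param n_tumor,n_normal Samples per class (each >= 2).
#' @param frac_up,frac_down Fractions of genes planted up-/down-regulated;
#'   their sum must be <= 1.
#' @param effect_size Mean shift, in log2 units, applied to planted genes
#'   in the tumor class (+ for up, - for down).
#' @param noise_sd Per-gene Gaussian noise standard deviation (log2 units).
#' @param attribute_prevalence List with numeric vectors `cancer` and
#'   `non_cancer`, each giving the per-attribute Bernoulli prevalence for
#'   the seven attributes (recycled if length 1).
#' @param n_cancer_genes Number of genes labelled as known cancer genes.
#' @param hazard_ratio Hazard multiplier of the poor-prognosis group in
#'   the survival simulation (> 0).
#' @param seed Integer seed; every generator consuming the config is
#'   bit-reproducible given the same seed.
#'
#' @return A list of class `boolerank_config`.
#' @export
#' @examples
#' synthetic_config(n_genes = 100, seed = 42)
synthetic_config <- function(n_genes = 1000,
                             n_tumor = 10, n_normal = 10,
                             frac_up = 0.05, frac_down = 0.05,
                             effect_size = 2, noise_sd = 1,
                             attribute_prevalence = list(
                               cancer = c(Meth = 0.35, SP = 0.40, PK = 0.35,
                                          TS = 0.45, PTM = 0.55, TF = 0.35,
                                          Hub = 0.50),
                               non_cancer = c(Meth = 0.30, SP = 0.33,
                                              PK = 0.28, TS = 0.37,
                                              PTM = 0.46, TF = 0.26,
                                              Hub = 0.36)),
                             n_cancer_genes = round(0.05 * n_genes),
                             hazard_ratio = 2,
                             seed = 1L) {
  if (n_genes < 1) abort("n_genes must be positive")
  if (n_tumor < 2 || n_normal < 2) abort("need >= 2 samples per class")
  if (frac_up < 0 || frac_down < 0 || frac_up + frac_down > 1) {
    abort("frac_up and frac_down must be >= 0 with frac_up + frac_down <= 1")
  }
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (hazard_ratio <= 0) abort("hazard_ratio must be positive")
  prev <- lapply(attribute_prevalence, function(p) {
    if (length(p) == 1L) p <- rep(p, 7L)
    if (is.null(names(p))) names(p) <- attribute_order()
    p <- p[attribute_order()]
    if (anyNA(p) || any(p < 0) || any(p > 1)) {
      abort("attribute prevalences must cover all 7 attributes and lie in [0, 1]")
    }
    p
  })
  if (!all(c("cancer", "non_cancer") %in% names(prev))) {
    abort("attribute_prevalence needs elements 'cancer' and 'non_cancer'")
  }
  if (n_cancer_genes < 0 || n_cancer_genes > n_genes) {
    abort("n_cancer_genes must be between 0 and n_genes")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_tumor = as.integer(n_tumor),
    n_normal = as.integer(n_normal), frac_up = frac_up,
    frac_down = frac_down, effect_size = effect_size, noise_sd = noise_sd,
    attribute_prevalence = prev,
    n_cancer_genes = as.integer(n_cancer_genes),
    hazard_ratio = hazard_ratio, seed = as.integer(seed)
  ), class = "boolerank_config")
}

#' Simulate a two-class expression matrix with planted DE genes
#'
#' Expression is simulated on the log2 scale: gene baselines are uniform
#' on (6, 12), noise is Gaussian with `noise_sd`, and the first
#' `round(frac_up * n_genes)` genes get `+effect_size` in tumor samples
#' while the next `round(frac_down * n_genes)` get `-effect_size`. Values
#' are exported on the linear scale (attribute `scale = "linear"`) so the
#' log2 preprocessing path is exercised downstream.
#'
#' @param cfg A [synthetic_config()].
#'
#' @return List with `expression` (tibble: `gene` column then one column
#'   per sample; attributes `sample_class` — named vector of
#'   "tumor"/"normal" — and `scale`) and `truth` (tibble: `gene`,
#'   `truth` in up/down/null).
#' @export
#' @examples
#' sim <- sim_expression(synthetic_config(n_genes = 50, seed = 3))
#' dplyr::count(sim$truth, truth)
sim_expression <- function(cfg) {
  stopifnot(inherits(cfg, "boolerank_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_genes
    n_up <- round(cfg$frac_up * n)
    n_dn <- round(cfg$frac_down * n)
    truth <- rep("null", n)
    truth[seq_len(n_up)] <- "up"
    if (n_dn > 0) truth[n_up + seq_len(n_dn)] <- "down"
    genes <- sprintf("g%04d", seq_len(n))
    samples <- c(sprintf("T%02d", seq_len(cfg$n_tumor)),
                 sprintf("N%02d", seq_len(cfg$n_normal)))
    classes <- setNames(rep(c("tumor", "normal"),
                            c(cfg$n_tumor, cfg$n_normal)), samples)
    base <- runif(n, 6, 12)
    shift <- cfg$effect_size * (truth == "up") -
      cfg$effect_size * (truth == "down")
    log2mat <- matrix(rnorm(n * length(samples), sd = cfg$noise_sd),
                      nrow = n) + base
    tumor_cols <- which(classes == "tumor")
    log2mat[, tumor_cols] <- log2mat[, tumor_cols] + shift
    expr <- tibble::as_tibble(as.data.frame(2^log2mat,
                                            col.names = samples))
    names(expr) <- samples
    expr <- dplyr::bind_cols(tibble::tibble(gene = genes), expr)
    attr(expr, "sample_class") <- classes
    attr(expr, "scale") <- "linear"
    list(expression = expr,
         truth = tibble::tibble(gene = genes, truth = truth))
  })
}

#' Simulate a binary attribute table with class-conditional prevalence
#'
#' The first `n_cancer_genes` genes are labelled cancer genes; each of the
#' seven attributes is an independent Bernoulli draw at the prevalence
#' configured for the gene's class, so the population phi per attribute is
#' known analytically from the two prevalences and the class fraction (see
#' [analytic_phi()]).
#'
#' @param cfg A [synthetic_config()].
#'
#' @return Tibble with `gene`, the seven 0/1 attribute columns, and
#'   `cancer` (0/1 label).
#' @export
sim_attributes <- function(cfg) {
  stopifnot(inherits(cfg, "boolerank_config"))
  withr::with_seed(cfg$seed + 1L, {
    n <- cfg$n_genes
    cancer <- as.integer(seq_len(n) <= cfg$n_cancer_genes)
    out <- tibble::tibble(gene = sprintf("g%04d", seq_len(n)))
    for (at in attribute_order()) {
      p <- ifelse(cancer == 1L,
                  cfg$attribute_prevalence$cancer[[at]],
                  cfg$attribute_prevalence$non_cancer[[at]])
      out[[at]] <- rbinom(n, 1L, p)
    }
    out$cancer <- cancer
    out
  })
}

#' Population phi for a class-conditional Bernoulli attribute
#'
#' Closed-form phi correlation between an attribute with prevalence
#' `p_pos` in the positive class and `p_neg` in the negative class, when a
#' fraction `frac_pos` of genes is positive. Used as the analytic oracle
#' for [sim_attributes()] recovery tests.
#'
#' @param p_pos,p_neg Class-conditional prevalences in \[0, 1\].
#' @param frac_pos Fraction of positive-class genes in (0, 1).
#'
#' @return Numeric phi magnitude.
#' @export
analytic_phi <- function(p_pos, p_neg, frac_pos) {
  pbar <- frac_pos * p_pos + (1 - frac_pos) * p_neg
  abs(p_pos - p_neg) * sqrt(frac_pos * (1 - frac_pos)) /
    sqrt(pbar * (1 - pbar))
}

#' Simulate protein-interaction evidence records
#'
#' Draws `n_edges` distinct unordered protein pairs (no self-loops) and
#' attaches evidence per edge: the number of source databases, number of
#' detection-method classes and number of supporting publications are each
#' `1 + Binomial(2, p)` with the profile's probability, and domain support
#' is Bernoulli. The profile probabilities therefore directly control how
#' often each high-confidence rule fires.
#'
#' @param n_proteins Number of proteins.
#' @param n_edges Number of distinct interactions; must not exceed
#'   `n_proteins * (n_proteins - 1) / 2`.
#' @param evidence_profile List with probabilities `p_multi_db`,
#'   `p_multi_method`, `p_domain`, `p_multi_pmid` in \[0, 1\].
#' @param seed Integer seed.
#'
#' @return Tibble of evidence records: `protein_a`, `protein_b`,
#'   `databases`, `methods`, `pmids` (";"-joined), `domain_support` (0/1).
#' @export
sim_interactions <- function(n_proteins, n_edges,
                             evidence_profile = list(p_multi_db = 0.3,
                                                     p_multi_method = 0.3,
                                                     p_domain = 0.2,
                                                     p_multi_pmid = 0.3),
                             seed = 1L) {
  max_edges <- n_proteins * (n_proteins - 1) / 2
  if (n_edges > max_edges) {
    abort(sprintf("n_edges = %d exceeds the %d possible pairs",
                  n_edges, max_edges))
  }
  prof <- evidence_profile
  dbs <- c("BIND", "BioGrid", "DIP", "HPRD", "IntAct", "MINT")
  meths <- c("biochemical", "biophysical", "imaging", "PCA")
  withr::with_seed(seed, {
    if (n_edges == 0) {
      return(tibble::tibble(protein_a = character(), protein_b = character(),
                            databases = character(), methods = character(),
                            pmids = character(), domain_support = integer()))
    }
    # sample distinct unordered pairs by index into the strict upper triangle
    idx <- sample.int(max_edges, n_edges)
    j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)  # column (larger node)
    i <- idx - (j - 1) * (j - 2) / 2           # row (smaller node)
    draw_multi <- function(p) 1L + rbinom(n_edges, 2L, p)
    n_db <- draw_multi(prof$p_multi_db)
    n_me <- draw_multi(prof$p_multi_method)
    n_pm <- draw_multi(prof$p_multi_pmid)
    tibble::tibble(
      protein_a = sprintf("P%03d", i),
      protein_b = sprintf("P%03d", j),
      databases = vapply(n_db, function(k)
        paste(sample(dbs, k), collapse = ";"), character(1)),
      methods = vapply(n_me, function(k)
        paste(sample(meths, k), collapse = ";"), character(1)),
      pmids = vapply(n_pm, function(k)
        paste(sample(1e6:2e6, k), collapse = ";"), character(1)),
      domain_support = rbinom(n_edges, 1L, prof$p_domain)
    )
  })
}

#' Simulate right-censored survival records for two prognosis groups
#'
#' Event times are exponential; the "poor" group's hazard is
#' `hazard_ratio` times the baseline. Censoring times are independent
#' exponentials calibrated so that roughly `censor_rate` of baseline
#' events are censored (`censor_rate = 0` disables censoring).
#'
#' @param n_samples Number of subjects (>= 4); split evenly between
#'   groups, extras to "good".
#' @param hazard_ratio Positive hazard multiplier for the poor group.
#' @param censor_rate Target censoring fraction in \[0, 1).
#' @param seed Integer seed.
#' @param baseline_hazard Baseline event rate per day.
#'
#' @return Tibble with `sample`, `time` (days), `event` (1 = observed,
#'   0 = censored) and `group` ("good"/"poor").
#' @export
sim_clinical <- function(n_samples, hazard_ratio, censor_rate = 0.2,
                         seed = 1L, baseline_hazard = 1 / 365) {
  if (n_samples < 4) abort("n_samples must be >= 4")
  if (hazard_ratio <= 0) abort("hazard_ratio must be positive")
  if (censor_rate < 0 || censor_rate >= 1) {
    abort("censor_rate must be in [0, 1)")
  }
  withr::with_seed(seed, {
    n_poor <- n_samples %/% 2
    group <- rep(c("good", "poor"), c(n_samples - n_poor, n_poor))
    haz <- baseline_hazard * ifelse(group == "poor", hazard_ratio, 1)
    event_time <- rexp(n_samples, rate = haz)
    if (censor_rate > 0) {
      # P(censor before event) = c_rate/(c_rate + h) for indep exponentials
      cens_haz <- baseline_hazard * censor_rate / (1 - censor_rate)
      cens_time <- rexp(n_samples, rate = cens_haz)
    } else {
      cens_time <- rep(Inf, n_samples)
    }
    tibble::tibble(
      sample = sprintf("s%03d", seq_len(n_samples)),
      time = pmin(event_time, cens_time),
      event = as.integer(event_time <= cens_time),
      group = group
    )
  })
}
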