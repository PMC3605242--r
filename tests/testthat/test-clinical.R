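test_that("signature score is the up-sum minus down-sum, with gene skipping", {
  expr <- tibble::tibble(gene = c("u1", "u2", "d1", "d2"),
                         s1 = c(2, 3, 1, 4), s2 = c(0, 0, 0, 0))
  sig <- list(up_genes = c("u1", "u2"), down_genes = c("d1", "d2"))
  sc <- signature_score(expr, sig)
  expect_equal(sc$score, c((2 + 3) - (1 + 4), 0))
  # absent genes are skipped with a warning, as in validation cohorts
  # lacking probes for part of the signature
  sig2 <- list(up_genes = c("u1", "u2", "uX"), down_genes = c("d1", "d2"))
  expect_warning(sc2 <- signature_score(expr, sig2), "uX")
  expect_equal(sc2$score, sc$score)
  expect_error(signature_score(expr, list(up_genes = "zz",
                                          down_genes = "yy")),
               "no signature gene")
  expect_error(signature_score(expr, list(up_genes = "u1",
                                          down_genes = "u1")), "disjoint")
})

test_that("signature score is linear in the expression values", {
  withr::with_seed(26, {
    sig <- list(up_genes = c("a", "b"), down_genes = c("c"))
    mk <- function(m) dplyr::bind_cols(tibble::tibble(gene = c("a", "b", "c")),
                                       tibble::as_tibble(as.data.frame(m)))
    x <- matrix(rnorm(9), 3); y <- matrix(rnorm(9), 3)
    sx <- signature_score(mk(x), sig)$score
    sy <- signature_score(mk(y), sig)$score
    sxy <- signature_score(mk(x + y), sig)$score
    expect_equal(sxy, sx + sy)
  })
})

test_that("default signature definition splits the published 17 genes 7/10", {
  sd_ <- signature_definition()
  expect_length(sd_$up_genes, 7)
  expect_length(sd_$down_genes, 10)
  expect_true(all(c("IRAK1", "CHEK1", "BUB1") %in% sd_$up_genes))
  expect_true(all(c("AR", "LYN", "DAB2") %in% sd_$down_genes))
})

test_that("Welch t matches hand computation and flips sign on group swap", {
  res <- welch_t(c(0, 1), c(10, 11))
  # equal variances s^2 = 0.5 each: t = -10 / sqrt(0.5), df = 2
  expect_equal(res$t, -10 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(res$df, 2)
  swap <- welch_t(c(10, 11), c(0, 1))
  expect_equal(swap$t, -res$t)
  expect_equal(swap$p_value, res$p_value)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), ">= 2 values")
})

test_that("median split labels the lower half low, median sample included", {
  ms <- median_split(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(ms$group, c("low", "low", "high", "high"))
  odd <- median_split(c(5, 3, 1, 4, 2), ids = letters[1:5])
  expect_equal(sum(odd$group == "low"), 3)  # odd n: median goes low
  expect_equal(odd$group[odd$value <= 3], rep("low", 3))
  ties <- median_split(c(5, 5, 5, 5), ids = c("s1", "s2", "s3", "s4"))
  expect_equal(ties$group, c("low", "low", "high", "high"))  # by ID order
  n38 <- median_split(rnorm(38), ids = sprintf("p%02d", 1:38))
  expect_equal(unname(table(n38$group)["low"]), 19L)
  expect_error(median_split(1:3), ">= 4")
})

test_that("KM curve matches the hand-computed product-limit table", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  cens <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(cens$survival == 1))
  # mixed 6-sample fixture, hand product-limit:
  # t=1 (6 at risk, 1 event) S=5/6; t=2 (5 at risk, 1 event, 1 censored)
  # S=5/6*4/5=2/3; t=3 (3 at risk, 1 event) S=2/3*2/3=4/9;
  # t=4 censored; t=5 (1 at risk, 1 event) S=0
  km6 <- km_curve(c(1, 2, 2, 3, 4, 5), c(1, 1, 0, 1, 0, 1))
  ev <- km6[km6$n_event > 0, ]
  expect_equal(ev$time, c(1, 2, 3, 5))
  expect_equal(ev$survival, c(5 / 6, 2 / 3, 4 / 9, 0))
  expect_error(km_curve(c(-1, 2), c(1, 1)), "non-negative")
  # non-increasing step function starting at 1
  cl <- sim_clinical(50, 2, seed = 27)
  kms <- km_curve(cl$time, cl$event)
  expect_true(all(diff(kms$survival) <= 1e-12))
  expect_lte(kms$survival[1], 1)
})

test_that("log-rank is zero for identical groups and symmetric in labels", {
  time <- c(1, 2, 3, 4, 1, 2, 3, 4)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  grp <- rep(c("low", "high"), each = 4)
  lr <- logrank_test(time, event, grp)
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-10)
  cl <- sim_clinical(60, 3, seed = 28)
  l1 <- logrank_test(cl$time, cl$event, cl$group)
  l2 <- logrank_test(cl$time, cl$event,
                     ifelse(cl$group == "good", "poor", "good"))
  expect_equal(l1$chi2, l2$chi2)
  expect_error(logrank_test(cl$time, cl$event, rep("a", 60)), "two groups")
  g <- glance(l1)
  expect_named(g, c("statistic", "df", "p_value"))
  td <- tidy(l1)
  expect_equal(sum(td$observed), sum(cl$event))
  expect_equal(sum(td$observed), sum(td$expected), tolerance = 1e-8)
})

test_that("log-rank p agrees with a label-permutation oracle on 8 samples", {
  time <- c(1, 3, 5, 7, 2, 4, 6, 8)
  event <- c(1, 1, 1, 0, 1, 1, 0, 1)
  grp <- rep(c("A", "B"), each = 4)
  lr <- logrank_test(time, event, grp)
  obs <- lr$chi2
  withr::with_seed(29, {
    n_perm <- 10000
    hits <- 0
    for (b in seq_len(n_perm)) {
      pg <- sample(grp)
      if (logrank_test(time, event, pg)$chi2 >= obs - 1e-12) hits <- hits + 1
    }
    p_perm <- hits / n_perm
  })
  # the chi-square p is asymptotic; at n=8 agreement is loose but the
  # permutation estimate must fall within Monte-Carlo error of a
  # small-sample-consistent band around it
  se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(p_perm - lr$p_value), 0.15 + 3 * se)
  expect_gt(p_perm, 0)
})

test_that("combined three-gene score adds two genes and subtracts the third", {
  expr <- tibble::tibble(gene = c("CHEK1", "AR", "LYN"),
                         s1 = c(1, 1, 0), s2 = c(2, 2, 0))
  cs <- combined_score(expr)
  expect_equal(cs$score, c(2, 4))
  const <- tibble::tibble(gene = c("CHEK1", "AR", "LYN"),
                          s1 = c(3, 3, 3), s2 = c(3, 3, 3))
  expect_equal(combined_score(const)$score, c(3, 3))
  expect_error(combined_score(expr[1:2, ]), "LYN")
})

test_that("a combined-score-driven hazard beats single genes on average", {
  # cohort where the hazard is driven by CHEK1 + AR - LYN: the combined
  # median split should separate survival at least as well as any single
  # constituent, in the majority of replicates
  wins <- 0; reps <- 60
  for (s in seq_len(reps)) {
    res <- withr::with_seed(3000 + s, {
      n <- 80
      chek1 <- rnorm(n); ar <- rnorm(n); lyn <- rnorm(n)
      comb <- chek1 + ar - lyn
      rate <- (1 / 365) * exp(0.9 * scale(comb)[, 1])
      time <- rexp(n, rate)
      expr <- dplyr::bind_cols(
        tibble::tibble(gene = c("CHEK1", "AR", "LYN")),
        tibble::as_tibble(as.data.frame(rbind(chek1, ar, lyn))))
      names(expr)[-1] <- sprintf("s%03d", 1:n)
      clin <- tibble::tibble(sample = sprintf("s%03d", 1:n),
                             time = time, event = 1L)
      p_of <- function(scores) stratify_survival(scores, clin)$logrank$p_value
      p_comb <- p_of(combined_score(expr))
      p_single <- vapply(c("CHEK1", "AR", "LYN"), function(g) {
        v <- unlist(expr[expr$gene == g, -1])
        p_of(tibble::tibble(sample = names(v), score = unname(v)))
      }, numeric(1))
      p_comb <= min(p_single)
    })
    wins <- wins + res
  }
  expect_gt(wins / reps, 0.5)
})
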