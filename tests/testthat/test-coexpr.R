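test_that("probe collapse keeps the highest-variance probe per gene", {
  probes <- tibble::tibble(
    probe = paste0("p", 1:5),
    gene = c("G1", "G1", "G2", NA, "G2;G3"),
    s1 = c(2, 4, 1, 5, 3), s2 = c(2, 6, 2, 5, 3), s3 = c(2, 9, 6, 5, 3))
  out <- preprocess_validation(probes, log2_transform = FALSE)
  expect_equal(out$gene, c("G1", "G2"))
  # for G1 probe p2 has the larger variance; p4 (no gene) and p5
  # (multi-gene) are dropped
  expect_equal(unlist(out[out$gene == "G1", -1], use.names = FALSE),
               c(4, 6, 9))
})

test_that("log2 transform is applied and guards against non-positives", {
  probes <- tibble::tibble(probe = "p1", gene = "G1",
                           s1 = 8, s2 = 16, s3 = 32)
  out <- preprocess_validation(probes)
  expect_equal(unlist(out[1, -1], use.names = FALSE), c(3, 4, 5))
  expect_equal(attr(out, "scale"), "log2")
  bad <- tibble::tibble(probe = "p1", gene = "G1", s1 = 0, s2 = 1, s3 = 2)
  expect_error(preprocess_validation(bad), "positive")
})

test_that("hand-built 5-probe/3-gene table collapses to hand selection", {
  withr::with_seed(18, {
    probes <- tibble::tibble(
      probe = paste0("p", 1:5),
      gene = c("A", "A", "B", "C", "C"))
    vals <- matrix(2^rnorm(5 * 4, mean = 6), 5, 4)
    probes <- dplyr::bind_cols(probes, tibble::as_tibble(as.data.frame(vals)))
    out <- preprocess_validation(probes)
    v <- apply(log2(vals), 1, var)
    expect_equal(nrow(out), 3)
    pick <- c(A = which.max(v[1:2]), B = 3,
              C = 3 + which.max(v[4:5]))
    for (g in c("A", "B", "C")) {
      expect_equal(unlist(out[out$gene == g, -1], use.names = FALSE),
                   log2(vals[pick[[g]], ]))
    }
  })
})

test_that("co-expression edges use a strict signed threshold", {
  expr <- tibble::tibble(gene = c("u", "v", "w"),
                         s1 = c(1, 2, 3), s2 = c(2, 4, 2), s3 = c(3, 6, 1))
  edges <- build_coexpression(expr, r_threshold = 0.5)
  # u-v perfectly correlated (r = 1); u-w and v-w are r = -1: excluded
  expect_equal(nrow(edges), 1)
  expect_equal(edges$gene_a, "u")
  expect_equal(edges$gene_b, "v")
  expect_equal(edges$r, 1)
  expect_error(build_coexpression(expr[, 1:3]), "3 samples")
  flat <- tibble::tibble(gene = c("u", "z"), s1 = c(1, 1), s2 = c(2, 1),
                         s3 = c(3, 1))
  expect_warning(out <- build_coexpression(flat), "zero-variance")
  expect_equal(nrow(out), 0)
})

test_that("block-design edge set equals the all-pairs correlation oracle", {
  withr::with_seed(19, {
    n_s <- 12
    latent <- rnorm(n_s)
    block <- t(replicate(4, latent + rnorm(n_s, sd = 0.4)))
    noise <- matrix(rnorm(6 * n_s), 6, n_s)
    mat <- rbind(block, noise)
    expr <- dplyr::bind_cols(
      tibble::tibble(gene = sprintf("g%02d", 1:10)),
      tibble::as_tibble(as.data.frame(mat)))
    edges <- build_coexpression(expr, r_threshold = 0.5)
    # oracle: brute-force loop over all pairs
    expected <- list()
    for (i in 1:9) for (j in (i + 1):10) {
      r <- cor(mat[i, ], mat[j, ])
      if (r > 0.5) expected[[length(expected) + 1]] <-
          c(sprintf("g%02d", i), sprintf("g%02d", j))
    }
    expect_equal(nrow(edges), length(expected))
    got <- paste(edges$gene_a, edges$gene_b)
    want <- vapply(expected, paste, character(1), collapse = " ")
    expect_setequal(got, want)
    # the correlated block should be densely connected
    expect_gte(sum(edges$gene_a %in% sprintf("g%02d", 1:4) &
                     edges$gene_b %in% sprintf("g%02d", 1:4)), 5)
  })
})

test_that("star betweenness matches the closed form; leaves are zero", {
  star <- tibble::tibble(a = "ctr", b = paste0("L", 1:4))
  rep_ <- network_centralities(star)
  expect_equal(rep_$betweenness[rep_$node == "ctr"], choose(4, 2))
  expect_true(all(rep_$betweenness[rep_$node != "ctr"] == 0))
  expect_equal(max(rep_$eigenvector), 1)
})

test_that("path-graph centralities match a 3-node eigen decomposition", {
  path <- tibble::tibble(a = c("A", "B"), b = c("B", "C"))
  rep_ <- network_centralities(path)
  expect_equal(rep_$betweenness[rep_$node == "B"], 1)
  # oracle: principal eigenvector of the path adjacency matrix
  adj <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  ev <- eigen(adj)$vectors[, 1]
  ev <- abs(ev) / max(abs(ev))
  expect_equal(setNames(rep_$eigenvector, rep_$node)[c("A", "B", "C")],
               setNames(ev, c("A", "B", "C")), tolerance = 1e-6)
  expect_equal(which.max(setNames(rep_$eigenvector, rep_$node)[c("A", "B", "C")]),
               c(B = 2), ignore_attr = TRUE)
})

test_that("betweenness agrees with exhaustive path enumeration on small graphs", {
  withr::with_seed(23, {
    for (trial in 1:5) {
      n <- 7
      full <- t(combn(n, 2))
      keep <- full[runif(nrow(full)) < 0.45, , drop = FALSE]
      if (nrow(keep) < 2) next
      edges <- tibble::tibble(a = paste0("n", keep[, 1]),
                              b = paste0("n", keep[, 2]))
      rep_ <- network_centralities(edges)
      g <- igraph::graph_from_data_frame(edges, directed = FALSE)
      nodes <- igraph::V(g)$name
      # oracle: enumerate shortest paths between every pair and count
      # pass-throughs, splitting equally among tied geodesics
      btw <- setNames(numeric(length(nodes)), nodes)
      for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
        if (i >= j) next
        sp <- suppressWarnings(igraph::all_shortest_paths(
          g, from = nodes[i], to = nodes[j])$vpaths)
        if (length(sp) == 0) next
        for (p in sp) {
          inner <- setdiff(names(p), c(nodes[i], nodes[j]))
          btw[inner] <- btw[inner] + 1 / length(sp)
        }
      }
      expect_equal(setNames(rep_$betweenness, rep_$node)[nodes], btw,
                   tolerance = 1e-9)
    }
  })
})

test_that("residuals sum to zero and vanish when betweenness is linear in eigenvector", {
  # complete graph: all centralities equal, residuals identically 0
  cmpl <- tibble::tibble(a = c("A", "A", "A", "B", "B", "C"),
                         b = c("B", "C", "D", "C", "D", "D"))
  rep_ <- network_centralities(cmpl)
  expect_equal(rep_$residual, rep(0, 4), tolerance = 1e-10)
  edges <- merge_evidence(sim_interactions(25, 60, seed = 24))
  rep2 <- network_centralities(edges[, 1:2])
  expect_equal(sum(rep2$residual), 0, tolerance = 1e-8)
  expect_error(network_centralities(cmpl[0, ]), "empty")
})
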