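test_that("multiplex layers are exactly the per-channel HVGs, in channel order", {
  x <- simulate_cml(cml_params(M = 3, epsilon = 0.1, N = 256, seed = 1))
  mux <- build_multiplex(x)
  expect_length(mux$layers, 3)
  expect_equal(mux$labels, colnames(x))
  for (a in 1:3) {
    expect_identical(mux$layers[[a]]$edges, build_hvg(x[, a])$edges)
    expect_identical(edge_key_string(mux$layers[[a]]$edges),
                     edge_key_string(brute_hvg_edges(x[, a])))
  }
  # single-channel multiplex is allowed
  m1 <- build_multiplex(matrix(c(3, 1, 2), ncol = 1))
  expect_length(m1$layers, 1)
})

test_that("edge overlap attains its extremes and matches hand counts", {
  # identical layers -> omega = 1, for several M
  for (M in c(2, 3, 5)) {
    layers <- replicate(M, build_hvg(c(3, 1, 4, 1, 5)), simplify = FALSE)
    expect_identical(average_edge_overlap(multiplex_from_layers(layers)), 1)
  }

  # hand count: layers {(1,2),(2,3)} and {(1,2)} -> 3 / (2 * 2)
  l1 <- build_hvg(c(1, 2, 3))
  l2 <- l1; l2$edges <- cbind(1L, 2L)
  mux <- multiplex_from_layers(list(l1, l2))
  expect_equal(average_edge_overlap(mux), 3 / 4)
})

test_that("overlap is 1/M when every union edge lives in a single layer", {
  # layers with disjoint edge sets on a shared node set
  for (M in c(2, 3, 5)) {
    base <- build_hvg(rep(0.5, M + 1))  # path graph, M edges
    layers <- lapply(seq_len(M), function(a) {
      g <- base
      g$edges <- cbind(a, a + 1L)
      storage.mode(g$edges) <- "integer"
      g
    })
    expect_equal(average_edge_overlap(multiplex_from_layers(layers)), 1 / M)
  }
})

test_that("overlap stays within [1/M, 1] and ignores simultaneous relabelling", {
  set.seed(707)
  for (trial in 1:20) {
    M <- sample(2:6, 1)
    n <- sample(8:64, 1)
    x <- matrix(runif(n * M), n, M)
    mux <- build_multiplex(x)
    om <- average_edge_overlap(mux)
    expect_gte(om, 1 / M)
    expect_lte(om, 1)

    # apply one permutation to every layer: omega is unchanged
    perm <- sample(n)
    relabelled <- lapply(mux$layers, function(g) {
      e <- matrix(perm[g$edges], ncol = 2)
      g$edges <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      g
    })
    expect_equal(average_edge_overlap(multiplex_from_layers(relabelled)), om)
  }
})

test_that("overlap is undefined on an empty union edge set", {
  g <- build_hvg(c(1, 2))
  g$edges <- g$edges[0, , drop = FALSE]
  expect_error(average_edge_overlap(multiplex_from_layers(list(g, g))),
               "undefined")
})

test_that("joint degree counts sum to N and marginalise to layer degree counts", {
  set.seed(808)
  x <- matrix(runif(400), 100, 4)
  mux <- build_multiplex(x)
  for (pair in list(c(1, 2), c(2, 4), c(3, 3))) {
    jdd <- joint_degree_distribution(mux, pair[1], pair[2])
    expect_equal(sum(jdd$counts$n), mux$n_nodes)
    ka <- degree_sequence(mux$layers[[pair[1]]])
    kb <- degree_sequence(mux$layers[[pair[2]]])
    row_marg <- tapply(jdd$counts$n, jdd$counts$k_alpha, sum)
    expect_equal(row_marg[order(as.integer(names(row_marg)))],
                 table(ka)[order(as.integer(names(table(ka))))],
                 ignore_attr = TRUE)
    col_marg <- tapply(jdd$counts$n, jdd$counts$k_beta, sum)
    expect_equal(col_marg[order(as.integer(names(col_marg)))],
                 table(kb)[order(as.integer(names(table(kb))))],
                 ignore_attr = TRUE)
  }
  # same layer twice: all mass on the diagonal
  jdd <- joint_degree_distribution(mux, 2, 2)
  expect_true(all(jdd$counts$k_alpha == jdd$counts$k_beta))
  expect_error(joint_degree_distribution(mux, 1, 9), "out of range")
})

test_that("hand-built joint degree tables are tabulated correctly", {
  # two path-graph layers on 4 nodes: degrees [1,2,2,1] in both
  path4 <- build_hvg(c(1, 2, 3, 4))
  jdd <- joint_degree_distribution(multiplex_from_layers(list(path4, path4)), 1, 2)
  expect_equal(jdd$counts,
               data.frame(k_alpha = c(1L, 2L), k_beta = c(1L, 2L),
                          n = c(2L, 2L)))

  # degrees [2,2,2] against [1,2,1]
  tri <- build_hvg(c(3, 1, 2))
  path3 <- tri; path3$edges <- cbind(1:2, 2:3)
  storage.mode(path3$edges) <- "integer"
  jdd <- joint_degree_distribution(multiplex_from_layers(list(tri, path3)), 1, 2)
  expect_equal(jdd$counts,
               data.frame(k_alpha = c(2L, 2L), k_beta = c(1L, 2L),
                          n = c(2L, 1L)))
})

test_that("interlayer mutual information obeys its information identities", {
  set.seed(909)
  for (trial in 1:10) {
    M <- sample(2:5, 1)
    x <- matrix(runif(80 * M), 80, M)
    mux <- build_multiplex(x)
    a <- sample(M, 1); b <- sample(M, 1)
    iab <- interlayer_mi(mux, a, b)
    expect_gte(iab, -1e-12)
    expect_equal(iab, interlayer_mi(mux, b, a))
    # matches the independently coded estimator
    expect_equal(iab, brute_mi(degree_sequence(mux$layers[[a]]),
                               degree_sequence(mux$layers[[b]])))
    # bounded by either marginal entropy
    ha <- interlayer_mi(mux, a, a)
    hb <- interlayer_mi(mux, b, b)
    expect_lte(iab, min(ha, hb) + 1e-12)
  }
})

test_that("self-information equals the degree entropy and log base rescales", {
  set.seed(1010)
  x <- matrix(runif(300), 100, 3)
  mux <- build_multiplex(x)
  p <- degree_distribution(mux$layers[[1]])
  expect_equal(interlayer_mi(mux, 1, 1), -sum(p * log(p)))
  expect_equal(interlayer_mi(mux, 1, 2, base = 2),
               interlayer_mi(mux, 1, 2) / log(2))
})

test_that("independent and perfectly coupled degree pairings give 0 and log 2", {
  # product joint: degrees (1,1),(1,2),(2,1),(2,2) once each
  expect_equal(brute_mi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  # half the nodes have degrees (1,1), half (2,2): MI = log 2
  a <- rep(c(1L, 2L), each = 50)
  expect_equal(brute_mi(a, a), log(2))
  # the package's estimator agrees on the same sequences
  x <- simulate_cml(cml_params(M = 2, epsilon = 0.3, N = 100, seed = 4))
  mux <- build_multiplex(x)
  expect_equal(interlayer_mi(mux, 1, 2),
               brute_mi(degree_sequence(mux$layers[[1]]),
                        degree_sequence(mux$layers[[2]])))
})

test_that("mean interlayer MI averages unordered pairs", {
  set.seed(1111)
  x <- matrix(runif(240), 80, 3)
  mux <- build_multiplex(x)
  manual <- mean(c(interlayer_mi(mux, 1, 2), interlayer_mi(mux, 1, 3),
                   interlayer_mi(mux, 2, 3)))
  expect_equal(mean_interlayer_mi(mux), manual)
  # M = 2 reduces to the single pair
  m2 <- build_multiplex(x[, 1:2])
  expect_equal(mean_interlayer_mi(m2), interlayer_mi(m2, 1, 2))
  # identical layers: every pair is the self-information case
  ident <- multiplex_from_layers(replicate(4, build_hvg(x[, 1]), simplify = FALSE))
  expect_equal(mean_interlayer_mi(ident), interlayer_mi(ident, 1, 1))
  expect_error(mean_interlayer_mi(build_multiplex(x[, 1, drop = FALSE])),
               "at least 2")
})

test_that("multiplex writers produce the documented formats", {
  x <- simulate_cml(cml_params(M = 3, epsilon = 0.2, N = 64, seed = 6))
  mux <- build_multiplex(x)
  stem <- file.path(withr::local_tempdir(), "mux")
  write_multiplex(mux, stem)
  manifest <- read.table(paste0(stem, ".manifest"), sep = "\t")
  expect_equal(manifest[[1]], mux$labels)
  combined <- read.table(paste0(stem, ".layers"), sep = "\t")
  expect_equal(nrow(combined), sum(sapply(mux$layers, function(g) nrow(g$edges))))
  g1 <- read_edgelist(file.path(dirname(stem), manifest[1, 2]))
  expect_identical(g1$edges, mux$layers[[1]]$edges)

  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_metrics(mux, mpath)
  kv <- read.table(mpath, sep = "\t")
  expect_equal(kv[kv[[1]] == "omega", 2], average_edge_overlap(mux))
  expect_equal(kv[kv[[1]] == "I", 2], mean_interlayer_mi(mux))
})

test_that("unequal channel lengths and malformed input are rejected", {
  expect_error(build_multiplex(data.frame(a = c("x", "y"), b = 1:2)),
               "numeric")
  expect_error(multiplex_from_layers(list(build_hvg(1:3), build_hvg(1:4))),
               "same number of nodes")
})
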