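test_that("convolutional triple scorer matches hand-computed values", {
  # single filter [1,1,-1], zero bias, linear activation, unit weights:
  # score is the summed translational residual
  mdl <- make_kg_model(m = 2, filters = matrix(c(1, 1, -1), 1, 3),
                       bias = 0, score_weights = c(1, 1))
  expect_equal(convkb_score(c(1, 0), c(0, 1), c(2, 2), mdl), -2)
  # s + p = o elementwise gives exactly zero
  expect_equal(convkb_score(c(0.3, -1), c(0.7, 2), c(1, 1), mdl), 0)
  # determinism
  s <- rnorm(2); p <- rnorm(2); o <- rnorm(2)
  expect_identical(convkb_score(s, p, o, mdl), convkb_score(s, p, o, mdl))
  expect_error(convkb_score(c(1, 2, 3), c(0, 1), c(2, 2), mdl),
               "dimension")
})

test_that("scorer with the fixed translation filter equals the TransE residual", {
  set.seed(3)
  m <- 7
  mdl <- make_kg_model(m = m, filters = matrix(c(1, 1, -1), 1, 3),
                       bias = 0, score_weights = rep(1, m))
  for (i in 1:200) {
    s <- rnorm(m); p <- rnorm(m); o <- rnorm(m)
    expect_equal(convkb_score(s, p, o, mdl), sum(s + p - o),
                 tolerance = 1e-12)
  }
})

test_that("multi-filter nonlinear scorer follows its definition", {
  set.seed(9)
  m <- 4; nf <- 3
  mdl <- make_kg_model(m = m, filters = matrix(rnorm(nf * 3), nf, 3),
                       bias = rnorm(nf), score_weights = rnorm(m * nf),
                       activation = "relu")
  s <- rnorm(m); p <- rnorm(m); o <- rnorm(m)
  feats <- c()
  for (j in 1:nf) {
    w <- mdl$filters[j, ]
    feats <- c(feats, pmax(w[1] * s + w[2] * p + w[3] * o + mdl$bias[j], 0))
  }
  expect_equal(convkb_score(s, p, o, mdl), sum(feats * mdl$score_weights),
               tolerance = 1e-12)
})

test_that("graph constructor and TSV round-trip validate triples", {
  tri <- data.frame(subject = c("a", "b"), predicate = c("r", "r"),
                    object = c("b", "c"), stringsAsFactors = FALSE)
  g <- knowledge_graph(tri)
  expect_setequal(g$nodes, c("a", "b", "c"))
  tf <- tempfile()
  write_triples(g, tf)
  g2 <- read_triples(tf)
  expect_equal(g2$triples, g$triples)
  expect_error(knowledge_graph(tri, nodes = c("a", "b")), "outside")
  # duplicates collapse
  expect_equal(nrow(knowledge_graph(rbind(tri, tri))$triples), 2L)
})

test_that("training rejects degenerate graphs and epochs = 0 returns init", {
  tri <- data.frame(subject = "a", predicate = "r", object = "b")
  expect_error(train_convkb(knowledge_graph(tri, nodes = c("a")),
                            epochs = 1),
               "outside")
  single <- knowledge_graph(data.frame(subject = "a", predicate = "r",
                                       object = "a"), nodes = "a")
  expect_error(train_convkb(single, epochs = 1), "at least 2 nodes")
  g <- knowledge_graph(tri)
  m0 <- train_convkb(g, m = 4, epochs = 0, seed = 1)
  expect_true(all(is.finite(score_triples(m0, g$triples))))
  expect_equal(ncol(m0$node_vecs), 4)
})

test_that("trained model separates true from corrupted triples and ranks well", {
  kgp <- gen_kg(n_nodes = 12, n_relations = 3, n_triples = 22, seed = 5)
  mdl <- train_convkb(kgp$graph, m = 10, lr = 0.001, epochs = 600,
                      n_filters = 20, seed = 5)
  expect_equal(ncol(mdl$node_vecs), 10)
  expect_true(all(is.finite(mdl$node_vecs)))
  true_scores <- score_triples(mdl, kgp$graph$triples)
  set.seed(2)
  corr <- kgp$graph$triples
  corr$object <- sample(kgp$graph$nodes, nrow(corr), replace = TRUE)
  keep <- !(paste(corr$subject, corr$predicate, corr$object) %in%
              paste(kgp$graph$triples$subject, kgp$graph$triples$predicate,
                    kgp$graph$triples$object))
  expect_gt(mean(true_scores), mean(score_triples(mdl, corr[keep, ])))
  expect_lt(mdl$loss[length(mdl$loss)], mdl$loss[1])
})

test_that("concept vectors look up semantic-type nodes with zero fallback", {
  kgp <- gen_kg(n_nodes = 6, n_relations = 2, n_triples = 6, seed = 2)
  mdl <- train_convkb(kgp$graph, m = 5, epochs = 5, seed = 1)
  tm <- c(C1 = "st01", C2 = "st02", C3 = "st01", C9 = "not_a_node")
  expect_equal(concept_vector("C1", tm, mdl),
               unname(mdl$node_vecs["st01", ]))
  expect_equal(concept_vector("C3", tm, mdl), concept_vector("C1", tm, mdl))
  expect_equal(concept_vector("C9", tm, mdl), rep(0, 5))
  expect_equal(concept_vector("unseen", tm, mdl), rep(0, 5))
})

test_that("kg model JSON serialization round-trips scores", {
  kgp <- gen_kg(n_nodes = 6, n_relations = 2, n_triples = 6, seed = 3)
  mdl <- train_convkb(kgp$graph, m = 4, epochs = 10, seed = 2)
  tf <- tempfile(fileext = ".json")
  write_kg_model(mdl, tf)
  back <- read_kg_model(tf)
  expect_equal(score_triples(back, kgp$graph$triples),
               score_triples(mdl, kgp$graph$triples), tolerance = 1e-12)
})
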