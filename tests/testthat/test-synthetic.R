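test_that("knowledge-graph generator honors its count and determinism contracts", {
  kgp <- gen_kg(20, 5, 60, seed = 7)
  expect_equal(nrow(kgp$graph$triples), 60L)
  expect_equal(length(kgp$graph$nodes), 20L)
  expect_equal(length(kgp$graph$relations), 5L)
  expect_equal(anyDuplicated(kgp$graph$triples), 0L)
  kgp2 <- gen_kg(20, 5, 60, seed = 7)
  expect_identical(kgp$graph$triples, kgp2$graph$triples)
  expect_identical(kgp$latent, kgp2$latent)
  expect_error(gen_kg(2, 2, 5), "n_nodes")
  expect_error(gen_kg(4, 1, 1000), "infeasible")
})

test_that("planted residuals beat corrupted residuals almost always", {
  kgp <- gen_kg(20, 5, 60, seed = 7)
  N <- kgp$latent$node; R <- kgp$latent$rel
  tri <- kgp$graph$triples
  true_key <- paste(tri$subject, tri$predicate, tri$object)
  resid <- function(s, p, o) {
    d <- N[s, ] + R[p, ] - N[o, ]
    sqrt(sum(d * d))
  }
  wins <- 0L; total <- 0L
  for (i in seq_len(nrow(tri))) {
    for (repl in kgp$graph$nodes) {
      for (slot in c("subject", "object")) {
        cand <- tri[i, ]
        cand[[slot]] <- repl
        if (paste(cand$subject, cand$predicate, cand$object) %in% true_key)
          next
        total <- total + 1L
        if (resid(cand$subject, cand$predicate, cand$object) >
            kgp$residuals[i]) wins <- wins + 1L
      }
    }
  }
  expect_gte(wins / total, 0.95)
})

test_that("corpus generator meets its coverage and flag contracts", {
  cfg <- generator_config(n_instances = 400, seed = 3,
                          knowledge_signal_fraction = 0.3)
  cp <- gen_corpus(cfg)
  labs <- vapply(cp$instances, `[[`, "", "label")
  expect_length(labs, 400L)
  expect_setequal(unique(labs), relation_classes())
  kdep <- vapply(cp$instances, `[[`, TRUE, "knowledge_dependent")
  # binomial tolerance: 0.3 +/- 4 sd
  expect_lt(abs(mean(kdep) - 0.3), 4 * sqrt(0.3 * 0.7 / 400))
  # noise-free: knowledge-dependent instances are Increase/Decrease-forward
  expect_true(all(labs[kdep] %in% c("Increase-forward", "Decrease-forward")))
  # determinism
  cp2 <- gen_corpus(cfg)
  expect_identical(lapply(cp$instances, `[[`, "tokens"),
                   lapply(cp2$instances, `[[`, "tokens"))
  expect_identical(cp$parses, cp2$parses)
})

test_that("instances are long enough for the widest filter and parses align", {
  cp <- gen_corpus(generator_config(n_instances = 50, seed = 5))
  for (inst in cp$instances) {
    expect_gte(sum(inst$tokens != "<pad>"), 23L)
  }
  # context-free variant omits the disease slot
  cf <- gen_corpus(generator_config(n_instances = 30,
                                    corpus_kind = "context-free", seed = 5))
  expect_true(all(vapply(cf$instances, `[[`, "", "corpus_kind") ==
                    "context-free"))
  expect_false(any(unlist(lapply(cf$instances, `[[`, "tokens")) ==
                     "<context>"))
  # parses parse and only reference tokens in the tagged sentences
  pairs <- extract_dep_contexts(cp$parses)
  expect_gt(nrow(pairs), 0)
  vocab <- unique(unlist(lapply(cp$instances, `[[`, "tokens")))
  expect_true(all(pairs$word %in% vocab))
})

test_that("label noise flips the requested fraction of gold labels", {
  cfg0 <- generator_config(n_instances = 300, seed = 8, noise_rate = 0)
  cfg1 <- generator_config(n_instances = 300, seed = 8, noise_rate = 0.2)
  l0 <- vapply(gen_corpus(cfg0)$instances, `[[`, "", "label")
  l1 <- vapply(gen_corpus(cfg1)$instances, `[[`, "", "label")
  flipped <- mean(l0 != l1)
  expect_gt(flipped, 0.1)
  expect_lt(flipped, 0.3)
})

test_that("generated knowledge matrices reflect semantic types", {
  kgp <- gen_kg(20, 5, 60, seed = 2)
  mdl <- train_convkb(kgp$graph, m = 10, epochs = 10, seed = 2)
  cp <- gen_corpus(generator_config(n_instances = 40, seed = 4),
                   kg_model = mdl)
  for (inst in cp$instances) {
    ty <- cp$type_map[[inst$molA$concept_id]]
    expect_equal(inst$knowledge_matrix[1, ],
                 unname(mdl$node_vecs[ty, ]))
  }
  # attach_knowledge after the fact gives the same matrices
  cp0 <- gen_corpus(generator_config(n_instances = 40, seed = 4))
  cp0 <- attach_knowledge(cp0, mdl)
  expect_equal(lapply(cp0$instances, `[[`, "knowledge_matrix"),
               lapply(cp$instances, `[[`, "knowledge_matrix"))
})

test_that("standoff fixtures are reproducible and decompose to their golds", {
  d1 <- gen_standoff(6, seed = 9)
  d2 <- gen_standoff(6, seed = 9)
  expect_identical(d1, d2)
  expect_length(gen_standoff(1, seed = 1), 1L)
  for (d in gen_standoff(14, seed = 10)) {
    p <- parse_standoff(d$txt, d$a1, d$a2)
    dec <- decompose_events(p$events)
    expect_equal(dec[order(dec$cause), ], d$gold[order(d$gold$cause), ],
                 ignore_attr = TRUE)
  }
  # file output round-trips
  od <- file.path(tempdir(), "standoff-fixtures")
  docs <- gen_standoff(2, seed = 3, out_dir = od)
  expect_true(file.exists(file.path(od, "doc-001.txt")))
  txt <- readLines(file.path(od, "doc-001.txt"))
  expect_equal(txt, docs[[1]]$txt)
})
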