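simple_doc <- function() {
  txt <- "GENA activates GENB."
  a1 <- c("T1\tGene_or_gene_product 0 4\tGENA",
          "T2\tGene_or_gene_product 15 19\tGENB")
  a2 <- c("T3\tPositive_regulation 5 14\tactivates",
          "E1\tPositive_regulation:T3 Cause:T1 Theme:T2")
  list(txt = txt, a1 = a1, a2 = a2)
}

test_that("standoff parsing resolves references and validates spans", {
  d <- simple_doc()
  p <- parse_standoff(d$txt, d$a1, d$a2)
  expect_equal(nrow(p$entities), 3L)
  expect_length(p$events, 1L)
  expect_equal(p$events$E1$args[["Cause"]], "T1")

  # empty a2: entities only
  p0 <- parse_standoff(d$txt, d$a1, character())
  expect_equal(nrow(p0$entities), 2L)
  expect_length(p0$events, 0L)

  # dangling reference is named in the error
  bad <- c(d$a2[1], "E1\tPositive_regulation:T3 Cause:T9 Theme:T2")
  expect_error(parse_standoff(d$txt, d$a1, bad), "unresolved T9")

  # span/surface mismatch
  a1bad <- c("T1\tGene_or_gene_product 0 4\tXXXX", d$a1[2])
  expect_error(parse_standoff(d$txt, a1bad, d$a2), "mismatch")
})

test_that("standoff writer round-trips through the parser", {
  docs <- gen_standoff(n_docs = 7, seed = 4)
  for (d in docs) {
    p <- parse_standoff(d$txt, d$a1, d$a2)
    back <- write_standoff(p)
    expect_setequal(back$a1, d$a1)
    expect_setequal(back$a2, d$a2)
  }
})

test_that("nested events flatten by sign composition", {
  rules <- default_event_rules()
  ev <- function(id, type, ...) {
    args <- c(...)
    list(id = id, type = type, trigger = "T0", args = args)
  }
  # Neg(Cause=A, Theme=Pos(Theme=B)) -> (A, B, -)
  events <- list(E1 = ev("E1", "Positive_regulation", Theme = "T2"),
                 E2 = ev("E2", "Negative_regulation", Cause = "T1",
                         Theme = "E1"))
  out <- decompose_events(events, rules)
  expect_equal(out, data.frame(cause = "T1", theme = "T2", sign = "-",
                               stringsAsFactors = FALSE))
  # Neg(Cause=A, Theme=Neg(Theme=B)) -> (A, B, +)
  events$E1$type <- "Negative_regulation"
  expect_equal(decompose_events(events, rules)$sign, "+")
  # Regulation absorbs any sign
  events$E1$type <- "Regulation"
  expect_equal(decompose_events(events, rules)$sign, "0")
  # Binding yields unordered theme pairs
  b <- list(E1 = ev("E1", "Binding", Theme = "T1", Theme2 = "T2",
                    Theme3 = "T3"))
  out <- decompose_events(b, rules)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$sign == "bind"))
  # cause chains through events compose on the cause side too
  events2 <- list(E1 = ev("E1", "Negative_regulation", Theme = "T5"),
                  E2 = ev("E2", "Positive_regulation", Cause = "E1",
                          Theme = "T2"))
  out2 <- decompose_events(events2, rules)
  expect_equal(out2$cause, "T5")
  expect_equal(out2$sign, "-")
  # cycle detection
  cyc <- list(E1 = ev("E1", "Positive_regulation", Theme = "E2"),
              E2 = ev("E2", "Positive_regulation", Cause = "T1",
                      Theme = "E1"))
  expect_error(decompose_events(cyc, rules), "cycle")
})

test_that("sign composition matches a brute-force evaluator on random trees", {
  set.seed(13)
  types <- c("Positive_regulation", "Negative_regulation", "Regulation")
  for (rep in 1:40) {
    depth <- sample(1:4, 1)
    events <- list()
    inner <- "T2"
    for (dpt in seq_len(depth)) {
      id <- paste0("E", dpt)
      args <- c(Theme = inner)
      if (dpt == depth) args <- c(Cause = "T1", args)
      events[[id]] <- list(id = id, type = sample(types, 1),
                           trigger = "T0", args = args)
      inner <- id
    }
    got <- decompose_events(events)
    want <- brute_force_sign(events)
    expect_equal(got[order(got$cause), ], want[order(want$cause), ],
                 ignore_attr = TRUE)
  }
})

test_that("sign-to-label mapping encodes class and textual direction", {
  expect_equal(to_label("+", 0, 4), "Increase-forward")
  expect_equal(to_label("-", 6, 1), "Decrease-backward")
  expect_equal(to_label("0", 2, 7), "Regulate-forward")
  expect_equal(to_label("bind", 5, 1), "Binding")
  expect_equal(to_label("bind", 1, 5), "Binding")
  expect_error(to_label("?", 1, 2), "unknown sign")
})

test_that("direction flips under mention swap for all directed signs", {
  for (sg in c("+", "-", "0")) {
    fwd <- to_label(sg, 1, 5)
    bwd <- to_label(sg, 5, 1)
    expect_true(endsWith(fwd, "forward"))
    expect_true(endsWith(bwd, "backward"))
    expect_equal(sub("-.*$", "", fwd), sub("-.*$", "", bwd))
  }
})

test_that("instance building tags entities, pads, and stacks knowledge rows", {
  toks <- c("tp53", "activates", "mdm2", "in", "melanoma")
  molA <- data.frame(start = 1L, end = 2L, concept_id = "CG1")
  molB <- data.frame(start = 3L, end = 4L, concept_id = "CG2")
  ctx <- data.frame(start = 5L, end = 6L, concept_id = "CD1")
  inst <- build_instance(toks, molA, molB, ctx, "Increase-forward")
  expect_equal(inst$tokens[1:5],
               c("<mol_a>", "activates", "<mol_b>", "in", "<context>"))
  expect_gte(length(inst$tokens), 23L)
  expect_true(all(inst$tokens[6:23] == "<pad>"))
  expect_equal(inst$corpus_kind, "context-specific")

  # no context: middle knowledge row zero, kind context-free
  kgp <- gen_kg(6, 2, 6, seed = 1)
  mdl <- train_convkb(kgp$graph, m = 4, epochs = 5, seed = 1)
  tm <- c(CG1 = "st01", CG2 = "st02", CD1 = "st03")
  i2 <- build_instance(toks, molA, molB, NULL, "Binding", kg_model = mdl,
                       type_map = tm)
  expect_equal(i2$corpus_kind, "context-free")
  expect_equal(i2$knowledge_matrix[2, ], rep(0, 4))
  expect_equal(i2$knowledge_matrix[1, ], unname(mdl$node_vecs["st01", ]))
  expect_equal(i2$knowledge_matrix[3, ], unname(mdl$node_vecs["st02", ]))

  # multi-token mentions collapse into one placeholder
  toks2 <- c("breast", "cancer", "needs", "tp53", "badly")
  i3 <- build_instance(toks2, data.frame(start = 4L, end = 5L,
                                         concept_id = "CG1"),
                       data.frame(start = 5L, end = 6L, concept_id = "CG2"),
                       data.frame(start = 1L, end = 3L, concept_id = "CD1"),
                       "False")
  expect_equal(i3$tokens[1:4], c("<context>", "needs", "<mol_a>", "<mol_b>"))

  expect_error(build_instance(toks, molA,
                              data.frame(start = 1L, end = 3L,
                                         concept_id = "X"),
                              NULL, "False"),
               "overlap")
})

test_that("negative sampling enumerates unannotated tuples deterministically", {
  men <- data.frame(start = c(1L, 3L, 5L), end = c(2L, 4L, 6L),
                    surface = c("a", "b", "c"),
                    concept_id = c("CA", "CB", "CC"),
                    semantic_type = "gngm", semantic_group = "GENE",
                    role = "molecule", stringsAsFactors = FALSE)
  sent <- list(tokens = c("a", "x", "b", "y", "c", "z",
                          rep("w", 18)),
               mentions = men)
  # 3 molecules -> C(3,2) = 3 pairs; 1 annotated -> 2 negatives
  neg <- make_negatives(list(sent),
                        annotated_keys = "1|CA|CB|",
                        ratio = 1, seed = 2, context_specific = FALSE)
  expect_length(neg, 2L)
  expect_true(all(vapply(neg, `[[`, "", "label") == "False"))
  expect_length(make_negatives(list(sent), ratio = 0), 0L)
  n1 <- make_negatives(list(sent), character(), ratio = 0.5, seed = 7,
                       context_specific = FALSE)
  n2 <- make_negatives(list(sent), character(), ratio = 0.5, seed = 7,
                       context_specific = FALSE)
  expect_identical(lapply(n1, `[[`, "tokens"), lapply(n2, `[[`, "tokens"))
})

test_that("every produced label lies in the 8-class set", {
  cp <- gen_corpus(generator_config(n_instances = 60, seed = 9))
  labs <- vapply(cp$instances, `[[`, "", "label")
  expect_true(all(labs %in% relation_classes()))
  docs <- gen_standoff(7, seed = 3)
  for (d in docs) {
    p <- parse_standoff(d$txt, d$a1, d$a2)
    dec <- decompose_events(p$events)
    for (i in seq_len(nrow(dec))) {
      expect_true(to_label(dec$sign[i], 1, 2) %in% relation_classes())
    }
  }
})
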