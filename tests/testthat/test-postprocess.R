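test_that("frequency threshold returns the top-quantile support value", {
  expect_equal(frequency_threshold(rep(7, 20), 0.01), 7)
  expect_equal(frequency_threshold(1:100, 0.01), 100)
  expect_equal(frequency_threshold(c(1, 1, 1, 9), 0.5), 1)
  expect_equal(frequency_threshold(c(5, 5, 9, 9), 0.5), 9)
  expect_error(frequency_threshold(numeric(0)), "empty")
  expect_error(frequency_threshold(1:5, 0))
  expect_error(frequency_threshold(1:5, 1))
})

test_that("voting takes strict majorities and abstracts ties", {
  expect_equal(vote(c("Increase-forward", "Increase-forward",
                      "Decrease-forward")), "Increase-forward")
  # tie, same direction, opposite signs -> Regulate with that direction
  expect_equal(vote(c("Increase-forward", "Decrease-forward")),
               "Regulate-forward")
  expect_equal(vote(c("Increase-backward", "Decrease-backward")),
               "Regulate-backward")
  # tie with contradictory directions -> Binding
  expect_equal(vote(c("Increase-forward", "Increase-backward")), "Binding")
  expect_equal(vote(c("Decrease-forward", "Regulate-backward")), "Binding")
  # tie against Binding -> Binding
  expect_equal(vote(c("Increase-forward", "Binding")), "Binding")
  # signed class tied with Regulate, same direction -> Regulate
  expect_equal(vote(c("Increase-forward", "Regulate-forward")),
               "Regulate-forward")
  # multi-way tie, same direction -> Regulate; mixed directions -> Binding
  expect_equal(vote(c("Increase-forward", "Decrease-forward",
                      "Regulate-forward")), "Regulate-forward")
  expect_equal(vote(c("Increase-forward", "Decrease-backward",
                      "Regulate-forward")), "Binding")
  expect_error(vote(character()), "empty")
  expect_error(vote("False"))
})

test_that("voting is permutation-invariant", {
  set.seed(21)
  pool <- setdiff(relation_classes(), "False")
  for (i in 1:30) {
    labs <- sample(pool, sample(2:9, 1), replace = TRUE)
    expect_identical(vote(labs), vote(sample(labs)))
  }
})

test_that("aggregation groups, thresholds, votes, and sorts", {
  rel <- data.frame(context_id = "CTX", molA_id = "A", molB_id = "B",
                    label = rep("Increase-forward", 20),
                    stringsAsFactors = FALSE)
  out <- aggregate_relations(rel, q = 0.01)
  expect_equal(nrow(out), 1L)
  expect_equal(out$support, 20L)
  expect_equal(out$label, "Increase-forward")

  # a key below the threshold disappears
  rel2 <- rbind(rel,
                data.frame(context_id = "CTX", molA_id = "A", molB_id = "C",
                           label = "Binding", stringsAsFactors = FALSE))
  out2 <- aggregate_relations(rel2, q = 0.01)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$molB_id, "B")
  # absolute override keeps it
  out3 <- aggregate_relations(rel2, min_support = 1)
  expect_equal(nrow(out3), 2L)

  expect_equal(nrow(aggregate_relations(rel[0, ])), 0L)
})

test_that("Binding keys are symmetric; directed keys are not", {
  rel <- data.frame(
    context_id = "CTX",
    molA_id = c("B", "A", "A", "B"),
    molB_id = c("A", "B", "B", "A"),
    label = c("Binding", "Binding", "Increase-forward", "Increase-forward"),
    stringsAsFactors = FALSE)
  out <- aggregate_relations(rel, min_support = 1)
  # the two Binding records canonicalize to (A, B) and join the directed
  # (A, B) record in one group of three, where Binding wins the vote; the
  # directed (B, A) record keeps its own key
  expect_equal(nrow(out), 2L)
  ab <- out[out$molA_id == "A", ]
  expect_equal(ab$label, "Binding")
  expect_equal(ab$support, 3L)
  ba <- out[out$molA_id == "B", ]
  expect_equal(ba$label, "Increase-forward")
  expect_equal(ba$support, 1L)
})

test_that("aggregation equals the literal brute-force oracle on random multisets", {
  classes <- setdiff(relation_classes(), "False")
  for (seed in 0:9) {
    set.seed(seed)
    n <- 1000
    rel <- data.frame(
      context_id = sample(sprintf("CTX%d", 1:5), n, replace = TRUE),
      molA_id = sample(sprintf("M%d", 1:8), n, replace = TRUE),
      molB_id = sample(sprintf("M%d", 1:8), n, replace = TRUE),
      label = sample(classes, n, replace = TRUE,
                     prob = c(3, 1, 3, 1, 1, 1, 4)),
      stringsAsFactors = FALSE)
    got <- aggregate_relations(rel, q = 0.01)
    want <- brute_force_aggregate(rel, q = 0.01)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("aggregate output keys are a subset of input keys", {
  set.seed(5)
  rel <- data.frame(
    context_id = sample(c("C1", "C2"), 200, replace = TRUE),
    molA_id = sample(c("A", "B", "C"), 200, replace = TRUE),
    molB_id = sample(c("A", "B", "C"), 200, replace = TRUE),
    label = sample(setdiff(relation_classes(), "False"), 200,
                   replace = TRUE),
    stringsAsFactors = FALSE)
  out <- aggregate_relations(rel, q = 0.1)
  expect_lte(sum(out$support), nrow(rel))
  # every output key has sorted-or-original support in the input
  for (i in seq_len(nrow(out))) {
    hits <- sum(rel$context_id == out$context_id[i] &
                  ((rel$molA_id == out$molA_id[i] &
                      rel$molB_id == out$molB_id[i]) |
                     (rel$molA_id == out$molB_id[i] &
                        rel$molB_id == out$molA_id[i])))
    expect_gte(hits, out$support[i])
  }
})
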