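# Shared fixture builders for the test suite. Everything is generated in
# code; no files are read.

# small embedding tables over an explicit vocabulary
make_tables <- function(vocab, dim = 6, seed = 42) {
  set.seed(seed)
  V <- matrix(rnorm(length(vocab) * dim), length(vocab), dim)
  list(N = ctxrel:::new_embedding_table(V, vocab, "ngram"),
       D = ctxrel:::new_embedding_table(0.5 * V, vocab, "dependency"))
}

# a relation instance with arbitrary tokens and a random knowledge matrix
make_instance <- function(label, vocab, m = 2, n_tokens = 26, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(tokens = sample(vocab, n_tokens, replace = TRUE),
                 label = label,
                 knowledge_matrix = matrix(rnorm(3 * m), 3, m),
                 corpus_kind = "context-specific"),
            class = "relation_instance")
}

# hand-built kg_model with chosen filters/weights (for scorer oracles)
make_kg_model <- function(m, filters, bias, score_weights,
                          activation = "linear", node_vecs = NULL,
                          rel_vecs = NULL) {
  structure(list(m = m, node_vecs = node_vecs, rel_vecs = rel_vecs,
                 filters = filters, bias = bias,
                 score_weights = score_weights, activation = activation),
            class = "kg_model")
}

# literal brute-force re-implementation of the post-processing rules,
# independent of aggregate_relations(): group, threshold, vote
brute_force_aggregate <- function(relations, q = 0.01) {
  if (nrow(relations) == 0) {
    return(data.frame(context_id = character(), molA_id = character(),
                      molB_id = character(), label = character(),
                      support = integer(), stringsAsFactors = FALSE))
  }
  rel <- relations
  for (i in seq_len(nrow(rel))) {
    if (rel$label[i] == "Binding" && rel$molA_id[i] > rel$molB_id[i]) {
      tmp <- rel$molA_id[i]
      rel$molA_id[i] <- rel$molB_id[i]
      rel$molB_id[i] <- tmp
    }
  }
  keys <- unique(rel[, c("context_id", "molA_id", "molB_id")])
  supports <- integer(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    supports[i] <- sum(rel$context_id == keys$context_id[i] &
                         rel$molA_id == keys$molA_id[i] &
                         rel$molB_id == keys$molB_id[i])
  }
  # threshold: largest support v with fraction(support >= v) >= q
  thr <- NA
  for (v in sort(unique(supports), decreasing = TRUE)) {
    if (mean(supports >= v) >= q) { thr <- v; break }
  }
  if (is.na(thr)) thr <- min(supports)
  out <- NULL
  for (i in seq_len(nrow(keys))) {
    if (supports[i] < thr) next
    sel <- rel$context_id == keys$context_id[i] &
      rel$molA_id == keys$molA_id[i] & rel$molB_id == keys$molB_id[i]
    labs <- rel$label[sel]
    tb <- table(labs)
    winners <- names(tb)[tb == max(tb)]
    lab <- if (length(winners) == 1) {
      winners
    } else if ("Binding" %in% winners) {
      "Binding"
    } else {
      dirs <- unique(sub("^.*-", "", winners))
      if (length(dirs) > 1) "Binding" else paste0("Regulate-", dirs)
    }
    out <- rbind(out, data.frame(context_id = keys$context_id[i],
                                 molA_id = keys$molA_id[i],
                                 molB_id = keys$molB_id[i], label = lab,
                                 support = supports[i],
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    return(data.frame(context_id = character(), molA_id = character(),
                      molB_id = character(), label = character(),
                      support = integer(), stringsAsFactors = FALSE))
  }
  out[order(-out$support, out$context_id, out$molA_id, out$molB_id), ,
      drop = FALSE]
}

# brute-force recursive sign evaluator over a nested event list (used to
# cross-check decompose_events on random trees)
brute_force_sign <- function(events, rules = default_event_rules()) {
  sgn <- function(ref) {
    if (!startsWith(ref, "E")) return(list(entity = ref, s = 1))
    ev <- events[[ref]]
    s0 <- rules$signs[ev$type]
    if (is.na(s0)) s0 <- 1
    inner <- sgn(unname(ev$args[names(ev$args) == "Theme"][1]))
    list(entity = inner$entity, s = s0 * inner$s)
  }
  out <- NULL
  for (ev in events) {
    s0 <- rules$signs[ev$type]
    if (is.na(s0)) next
    cause <- ev$args[names(ev$args) == "Cause"]
    theme <- ev$args[names(ev$args) == "Theme"]
    if (length(cause) == 0 || length(theme) == 0) next
    th <- sgn(unname(theme[1]))
    ca <- sgn(unname(cause[1]))
    s <- s0 * th$s * ca$s
    out <- rbind(out, data.frame(
      cause = ca$entity, theme = th$entity,
      sign = if (s > 0) "+" else if (s < 0) "-" else "0",
      stringsAsFactors = FALSE))
  }
  out
}

cosine <- function(a, b) {
  sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}
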