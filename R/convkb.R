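# Knowledge-graph embedding with a convolutional triple scorer. A triple
# (subject, predicate, object) is stacked into an m x 3 matrix of embedding
# vectors; 1 x 3 filters convolve over the m rows, the activated feature
# maps are concatenated and dotted with a score-weight vector. With the
# single fixed filter [1, 1, -1], zero bias, linear activation and unit
# score weights, the score reduces to the summed translational residual
# sum_i(s_i + p_i - o_i), i.e. the scorer generalizes translation-based
# embedding. Higher scores mean more plausible triples.

#' Construct a knowledge graph
#'
#' @param triples Data.frame with columns `subject`, `predicate`, `object`.
#' @param nodes Optional node universe (defaults to nodes seen in triples).
#' @param relations Optional relation universe.
#' @return A `knowledge_graph` object.
#' @export
knowledge_graph <- function(triples, nodes = NULL, relations = NULL) {
  stopifnot(all(c("subject", "predicate", "object") %in% names(triples)))
  triples <- unique(triples[, c("subject", "predicate", "object")])
  if (is.null(nodes)) nodes <- sort(unique(c(triples$subject, triples$object)))
  if (is.null(relations)) relations <- sort(unique(triples$predicate))
  if (!all(triples$subject %in% nodes) || !all(triples$object %in% nodes)) {
    stop("triple endpoint outside node set")
  }
  if (!all(triples$predicate %in% relations)) {
    stop("triple predicate outside relation set")
  }
  structure(list(nodes = nodes, relations = relations, triples = triples),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph nodes=%d relations=%d triples=%d>\n",
              length(x$nodes), length(x$relations), nrow(x$triples)))
  invisible(x)
}

#' Read knowledge-graph triples from TSV
#'
#' Expects three tab-separated columns: subject, predicate, object
#' (no header).
#'
#' @param path TSV path.
#' @return A `knowledge_graph`.
#' @export
read_triples <- function(path) {
  df <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE,
                   col.names = c("subject", "predicate", "object"))
  knowledge_graph(df)
}

#' Write knowledge-graph triples to TSV
#' @param graph A `knowledge_graph`.
#' @param path Output path.
#' @export
write_triples <- function(graph, path) {
  write.table(graph$triples, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

kg_activate <- function(x, activation) {
  switch(activation,
         linear = x,
         relu = pmax(x, 0),
         tanh = tanh(x),
         stop("unknown activation: ", activation))
}

kg_activate_deriv <- function(pre, activation) {
  switch(activation,
         linear = array(1, dim = dim(pre)),
         relu = (pre > 0) * 1,
         tanh = 1 - tanh(pre)^2)
}

#' Score a single triple with the convolutional scorer
#'
#' For each 1x3 filter `w` and each embedding row i, the feature is
#' `g(w1*s_i + w2*p_i + w3*o_i + b)`; the score is the dot product of the
#' concatenated (filter-major) features with the score weights.
#'
#' @param s_vec,p_vec,o_vec Length-m subject/predicate/object vectors.
#' @param model A `kg_model` (from [train_convkb()] or built by hand with
#'   fields `m`, `filters` (n_filters x 3), `bias`, `score_weights`,
#'   `activation`).
#' @return Scalar score (higher = more plausible).
#' @export
convkb_score <- function(s_vec, p_vec, o_vec, model) {
  m <- model$m
  if (length(s_vec) != m || length(p_vec) != m || length(o_vec) != m) {
    stop("vector length does not match embedding dimension m")
  }
  drop(score_triple_matrix(matrix(s_vec, 1), matrix(p_vec, 1),
                           matrix(o_vec, 1), model))
}

# batched scorer: S, P, O are n x m matrices; returns n scores
score_triple_matrix <- function(S, P, O, model) {
  n <- nrow(S); m <- model$m
  nf <- nrow(model$filters)
  scores <- numeric(n)
  for (j in seq_len(nf)) {
    w <- model$filters[j, ]
    pre <- w[1] * S + w[2] * P + w[3] * O + model$bias[j]
    f <- kg_activate(pre, model$activation)
    sw <- model$score_weights[((j - 1) * m + 1):(j * m)]
    scores <- scores + drop(f %*% sw)
  }
  scores
}

kg_embed <- function(model, subjects, predicates, objects) {
  list(S = model$node_vecs[subjects, , drop = FALSE],
       P = model$rel_vecs[predicates, , drop = FALSE],
       O = model$node_vecs[objects, , drop = FALSE])
}

#' Score triples given by name
#' @param model A trained `kg_model`.
#' @param triples Data.frame with `subject`, `predicate`, `object` columns.
#' @return Numeric vector of scores.
#' @export
score_triples <- function(model, triples) {
  e <- kg_embed(model, triples$subject, triples$predicate, triples$object)
  score_triple_matrix(e$S, e$P, e$O, model)
}

#' Train the convolutional knowledge-graph embedding model
#'
#' Minimizes a soft-margin (softplus) loss over true triples against
#' corrupted triples (subject or object replaced uniformly at random,
#' filtered against the true triple set), with L2 regularization on the
#' score weights, using Adam. Defaults: embedding dimension 10 and learning
#' rate 0.001.
#'
#' @param graph A `knowledge_graph` with at least 2 nodes.
#' @param m Embedding dimension.
#' @param lr Learning rate.
#' @param n_filters Number of 1x3 filters.
#' @param epochs Training epochs (0 returns the initialized model).
#' @param neg_per_pos Corrupted triples sampled per true triple per epoch.
#' @param activation Elementwise nonlinearity ("relu", "linear", "tanh").
#' @param l2 L2 penalty on the score weights.
#' @param seed Integer seed.
#' @return A `kg_model` list with node/relation vectors, filters, bias,
#'   score weights, activation name and the per-epoch loss trace.
#' @export
train_convkb <- function(graph, m = 10, lr = 0.001, n_filters = 50,
                         epochs = 1000, neg_per_pos = 5, activation = "relu",
                         l2 = 1e-3, seed = 1) {
  stopifnot(inherits(graph, "knowledge_graph"))
  if (nrow(graph$triples) == 0) stop("empty graph")
  if (length(graph$nodes) < 2) stop("graph needs at least 2 nodes to corrupt")
  nodes <- graph$nodes; rels <- graph$relations
  tri <- graph$triples
  true_key <- paste(tri$subject, tri$predicate, tri$object, sep = "\r")

  with_seed(seed, {
    params <- list(
      node = matrix(runif(length(nodes) * m, -6 / sqrt(m), 6 / sqrt(m)),
                    length(nodes), m, dimnames = list(nodes, NULL)),
      rel = matrix(runif(length(rels) * m, -6 / sqrt(m), 6 / sqrt(m)),
                   length(rels), m, dimnames = list(rels, NULL)),
      # translation-prior initialization: filters near 0.1 * [1, 1, -1]
      filters = matrix(rep(c(0.1, 0.1, -0.1), each = n_filters),
                       n_filters, 3) +
        matrix(rnorm(n_filters * 3, 0, 0.01), n_filters, 3),
      bias = numeric(n_filters),
      sw = rnorm(m * n_filters, 0, 0.1)
    )
    state <- adam_init(params)
    loss_trace <- numeric(epochs)

    si <- match(tri$subject, nodes)
    pi_ <- match(tri$predicate, rels)
    oi <- match(tri$object, nodes)
    n_pos <- nrow(tri)

    for (ep in seq_len(epochs)) {
      # corrupt subject or object, rejecting known true triples
      neg_s <- rep(si, neg_per_pos)
      neg_p <- rep(pi_, neg_per_pos)
      neg_o <- rep(oi, neg_per_pos)
      corrupt_subj <- runif(length(neg_s)) < 0.5
      repl <- sample.int(length(nodes), length(neg_s), replace = TRUE)
      neg_s[corrupt_subj] <- repl[corrupt_subj]
      neg_o[!corrupt_subj] <- repl[!corrupt_subj]
      key <- paste(nodes[neg_s], rels[neg_p], nodes[neg_o], sep = "\r")
      keep <- !(key %in% true_key)
      all_s <- c(si, neg_s[keep])
      all_p <- c(pi_, neg_p[keep])
      all_o <- c(oi, neg_o[keep])
      y <- c(rep(1, n_pos), rep(-1, sum(keep)))
      B <- length(y)

      S <- params$node[all_s, , drop = FALSE]
      P <- params$rel[all_p, , drop = FALSE]
      O <- params$node[all_o, , drop = FALSE]

      nf <- n_filters
      scores <- numeric(B)
      pre_list <- vector("list", nf)
      act_list <- vector("list", nf)
      for (j in seq_len(nf)) {
        w <- params$filters[j, ]
        pre <- w[1] * S + w[2] * P + w[3] * O + params$bias[j]
        a <- kg_activate(pre, activation)
        pre_list[[j]] <- pre; act_list[[j]] <- a
        sw_j <- params$sw[((j - 1) * m + 1):(j * m)]
        scores <- scores + drop(a %*% sw_j)
      }
      z <- -y * scores
      loss_trace[ep] <- mean(log1p(exp(pmin(z, 30)))) + l2 * sum(params$sw^2)
      dscore <- (-y) * stats::plogis(z) / B

      g <- list(node = params$node * 0, rel = params$rel * 0,
                filters = params$filters * 0, bias = numeric(nf),
                sw = params$sw * 0 + 2 * l2 * params$sw)
      dS <- S * 0; dP <- P * 0; dO <- O * 0
      for (j in seq_len(nf)) {
        sw_j <- params$sw[((j - 1) * m + 1):(j * m)]
        dact <- dscore * matrix(sw_j, B, m, byrow = TRUE)
        G <- dact * kg_activate_deriv(pre_list[[j]], activation)
        g$sw[((j - 1) * m + 1):(j * m)] <-
          g$sw[((j - 1) * m + 1):(j * m)] + drop(crossprod(act_list[[j]], dscore))
        w <- params$filters[j, ]
        g$filters[j, ] <- c(sum(G * S), sum(G * P), sum(G * O))
        g$bias[j] <- sum(G)
        dS <- dS + w[1] * G
        dP <- dP + w[2] * G
        dO <- dO + w[3] * G
      }
      # scatter-add endpoint gradients into the node/relation tables
      ns <- rowsum(dS, all_s)
      g$node[as.integer(rownames(ns)), ] <-
        g$node[as.integer(rownames(ns)), , drop = FALSE] + ns
      no <- rowsum(dO, all_o)
      g$node[as.integer(rownames(no)), ] <-
        g$node[as.integer(rownames(no)), , drop = FALSE] + no
      np <- rowsum(dP, all_p)
      g$rel[as.integer(rownames(np)), ] <-
        g$rel[as.integer(rownames(np)), , drop = FALSE] + np

      upd <- adam_step(params, g, state, lr)
      params <- upd$params
      state <- upd$state
    }

    structure(list(m = m, node_vecs = params$node, rel_vecs = params$rel,
                   filters = params$filters, bias = params$bias,
                   score_weights = params$sw, activation = activation,
                   loss = loss_trace),
              class = "kg_model")
  })
}

#' @export
print.kg_model <- function(x, ...) {
  cat(sprintf("<kg_model m=%d nodes=%d relations=%d filters=%d act=%s>\n",
              x$m, nrow(x$node_vecs), nrow(x$rel_vecs), nrow(x$filters),
              x$activation))
  invisible(x)
}

#' Embedding vector for a concept
#'
#' Concepts are embedded at the semantic-type level: the vector of a concept
#' is the trained node vector of its semantic type. Concepts whose type is
#' unknown (or absent from the graph) map to the all-zeros vector.
#'
#' @param concept_id Concept identifier.
#' @param type_map Named character vector or list mapping concept_id to
#'   semantic type.
#' @param model A `kg_model`.
#' @return Numeric vector of length `model$m`.
#' @export
concept_vector <- function(concept_id, type_map, model) {
  ty <- if (is.list(type_map)) type_map[[concept_id]]
        else unname(type_map[concept_id])
  if (is.null(ty) || length(ty) != 1 || is.na(ty) ||
      !(ty %in% rownames(model$node_vecs))) {
    return(numeric(model$m))
  }
  model$node_vecs[ty, ]
}

#' Ranking evaluation by exhaustive corruption
#'
#' For each evaluation triple, ranks the true subject against all possible
#' subject replacements and the true object against all object replacements
#' (raw ranking, ties counted pessimistically), and reports the fraction of
#' slots where the truth lands in the top k.
#'
#' @param model A `kg_model`.
#' @param graph The `knowledge_graph` supplying the node universe.
#' @param triples Evaluation triples (data.frame).
#' @param k Cutoff.
#' @return `hits@k` as a fraction in \[0, 1\].
#' @export
kg_hits_at_k <- function(model, graph, triples, k = 5) {
  nodes <- graph$nodes
  hits <- 0L; slots <- 0L
  for (i in seq_len(nrow(triples))) {
    s <- triples$subject[i]; p <- triples$predicate[i]; o <- triples$object[i]
    cand_s <- data.frame(subject = nodes, predicate = p, object = o,
                         stringsAsFactors = FALSE)
    sc <- score_triples(model, cand_s)
    rank_s <- sum(sc >= sc[match(s, nodes)])
    cand_o <- data.frame(subject = s, predicate = p, object = nodes,
                         stringsAsFactors = FALSE)
    so <- score_triples(model, cand_o)
    rank_o <- sum(so >= so[match(o, nodes)])
    hits <- hits + (rank_s <= k) + (rank_o <= k)
    slots <- slots + 2L
  }
  hits / slots
}

#' Serialize a kg_model to JSON
#' @param model A `kg_model`.
#' @param path Output path.
#' @export
write_kg_model <- function(model, path) {
  obj <- list(m = model$m,
              nodes = rownames(model$node_vecs),
              node_vecs = unname(model$node_vecs),
              relations = rownames(model$rel_vecs),
              rel_vecs = unname(model$rel_vecs),
              filters = model$filters, bias = model$bias,
              score_weights = model$score_weights,
              activation = model$activation)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a kg_model from JSON
#' @param path Input path.
#' @return A `kg_model`.
#' @export
read_kg_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  node_vecs <- as.matrix(obj$node_vecs)
  rownames(node_vecs) <- obj$nodes
  rel_vecs <- as.matrix(obj$rel_vecs)
  rownames(rel_vecs) <- obj$relations
  structure(list(m = obj$m, node_vecs = node_vecs, rel_vecs = rel_vecs,
                 filters = as.matrix(obj$filters), bias = obj$bias,
                 score_weights = obj$score_weights,
                 activation = obj$activation),
            class = "kg_model")
}
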