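# Evaluation: micro-averaged F1 (pooled TP/FP/FN over the seven non-False
# classes by default, since the corpora are heavily skewed toward False),
# stratified 3-fold cross-validation with 2:1 train:test folds, and the
# representation-group ablation runner.

#' Micro-averaged F1
#'
#' With `exclude_false = TRUE` (default) pools TP/FP/FN over the seven
#' non-False classes, treating False as the negative class; with
#' `exclude_false = FALSE` pooling runs over all eight classes, which for
#' single-label multi-class prediction is exactly the accuracy.
#'
#' @param gold,pred Equal-length character vectors of class labels.
#' @param exclude_false Exclude the False class from pooling.
#' @return Micro-F1 in \[0, 1\]. When gold and pred contain no positive
#'   labels the value is degenerate; it is reported as 1.0 with attribute
#'   `degenerate = TRUE` and a warning.
#' @export
micro_f1 <- function(gold, pred, exclude_false = TRUE) {
  if (length(gold) != length(pred)) stop("gold/pred length mismatch")
  classes <- relation_classes()
  stopifnot(all(gold %in% classes), all(pred %in% classes))
  pos <- if (exclude_false) setdiff(classes, "False") else classes
  tp <- sum(gold == pred & gold %in% pos)
  fp <- sum(pred %in% pos & gold != pred)
  fn <- sum(gold %in% pos & gold != pred)
  if (tp + fp + fn == 0) {
    warning("no positive labels in gold or pred; micro-F1 is degenerate")
    return(structure(1.0, degenerate = TRUE))
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Per-class evaluation report
#'
#' @param gold,pred Label vectors.
#' @param exclude_false Convention passed to [micro_f1()].
#' @return List with `micro_f1`, `per_class` (precision/recall/F1
#'   data.frame) and the 8 x 8 `confusion` matrix (rows = gold).
#' @export
eval_report <- function(gold, pred, exclude_false = TRUE) {
  classes <- relation_classes()
  conf <- table(factor(gold, classes), factor(pred, classes))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(gold == cl & pred == cl)
    fp <- sum(pred == cl & gold != cl)
    fn <- sum(gold == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(class = cl, precision = p, recall = r, f1 = f, support = tp + fn,
               stringsAsFactors = FALSE)
  }))
  list(micro_f1 = as.numeric(micro_f1(gold, pred, exclude_false)),
       per_class = per_class, confusion = unclass(conf))
}

#' Stratified fold assignment
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k. Classes with fewer than k
#'   instances are pooled and assigned unstratified (with a warning).
#' @export
stratified_folds <- function(labels, k = 3, seed = 1) {
  n <- length(labels)
  if (n < k) stop("fewer instances than folds")
  with_seed(seed, {
    fold <- integer(n)
    tab <- table(labels)
    small <- names(tab)[tab < k]
    if (length(small)) {
      warning("class(es) with fewer than k instances pooled unstratified: ",
              paste(small, collapse = ", "))
    }
    # cyclic assignment continues across strata, so per-class fold counts
    # differ by at most one AND global fold sizes stay balanced
    cursor <- 0L
    assign_cyclic <- function(ix) {
      f <- ((cursor + seq_along(ix) - 1L) %% k) + 1L
      cursor <<- cursor + length(ix)
      fold[ix] <<- f
    }
    for (cl in setdiff(names(tab), small)) {
      assign_cyclic(sample(which(labels == cl)))
    }
    pool <- which(labels %in% small)
    if (length(pool)) assign_cyclic(sample(pool))
    fold
  })
}

#' k-fold cross-validation of a relation classifier
#'
#' Stratified k folds; each fold trains on the other k - 1 folds (2/3 of
#' the data at the default k = 3) and tests on the held-out third.
#'
#' @param instances List of `relation_instance` with gold labels.
#' @param trainer Function(train_instances, test_instances) returning
#'   predicted labels for the test instances.
#' @param k Number of folds.
#' @param seed Integer seed (fold assignment).
#' @param exclude_false Metric convention, see [micro_f1()].
#' @return List with `folds` (assignment vector), `reports` (per-fold
#'   [eval_report()]s) and `mean_micro_f1`.
#' @export
cross_validate <- function(instances, trainer, k = 3, seed = 1,
                           exclude_false = TRUE) {
  gold <- vapply(instances, `[[`, "", "label")
  fold <- stratified_folds(gold, k, seed)
  reports <- lapply(seq_len(k), function(f) {
    tr <- instances[fold != f]
    te <- instances[fold == f]
    pred <- trainer(tr, te)
    eval_report(vapply(te, `[[`, "", "label"), pred, exclude_false)
  })
  list(folds = fold, reports = reports,
       mean_micro_f1 = mean(vapply(reports, `[[`, 0, "micro_f1")))
}

#' Representation-group ablation
#'
#' Runs one cross-validation per representation subset per seed and
#' tabulates mean micro-F1. The knowledge-only subset is rejected: without
#' any linguistic group the model has no access to the sentence.
#'
#' @param instances List of `relation_instance`.
#' @param group_subsets List of character vectors over c("N", "D", "K").
#' @param seeds Integer seeds; one cross-validation per (subset, seed).
#' @param trainer_factory Function(groups, seed) returning a trainer for
#'   [cross_validate()].
#' @param k Folds per run.
#' @return List with `runs` (data.frame: groups, seed, mean_micro_f1) and
#'   `summary` (data.frame: groups, mean, sd, median).
#' @export
ablation <- function(instances, group_subsets, seeds, trainer_factory,
                     k = 3) {
  for (gs in group_subsets) {
    if (length(gs) == 1 && gs == "K") {
      stop("knowledge-only subset is excluded: it carries no linguistic ",
           "information about the sentence")
    }
  }
  runs <- list()
  for (gs in group_subsets) {
    for (s in seeds) {
      cv <- cross_validate(instances, trainer_factory(gs, s), k = k,
                           seed = s)
      runs[[length(runs) + 1L]] <- data.frame(
        groups = paste(gs, collapse = "+"), seed = s,
        mean_micro_f1 = cv$mean_micro_f1, stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, runs)
  summ <- do.call(rbind, lapply(split(runs, runs$groups), function(d) {
    data.frame(groups = d$groups[1], mean = mean(d$mean_micro_f1),
               sd = stats::sd(d$mean_micro_f1),
               median = stats::median(d$mean_micro_f1),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(runs = runs, summary = summ)
}

#' Train embedding tables for a generated corpus
#'
#' Convenience wrapper: trains the n-gram table over the tagged token
#' sequences of the instances and the dependency table over the contexts
#' extracted from the generated parses.
#'
#' @param corpora One corpus or a list of corpora from [gen_corpus()]
#'   (pooled, as pre-training and fine-tuning share embedding spaces).
#' @param dim Embedding dimension.
#' @param epochs_ngram,epochs_dep Training epochs for the two tables.
#' @param subsample Frequent-word subsampling threshold for the n-gram
#'   table. Template corpora have a small vocabulary with ubiquitous filler
#'   words, so the threshold sits higher (1e-3) than on natural-scale text:
#'   it must down-weight words that appear in every sentence, which would
#'   otherwise act as co-occurrence hubs and collapse the embedding space.
#' @param seed Integer seed.
#' @return Named list of embedding tables `N` and `D`.
#' @export
corpus_embeddings <- function(corpora, dim = 200, epochs_ngram = 50,
                              epochs_dep = 50, subsample = 1e-3, seed = 1) {
  if (!is.null(corpora$instances)) corpora <- list(corpora)
  toks <- unlist(lapply(corpora, function(cp) {
    lapply(cp$instances, function(x) x$tokens[x$tokens != PAD_TOKEN])
  }), recursive = FALSE)
  ngram <- train_skipgram(toks, dim = dim, epochs = epochs_ngram,
                          subsample = subsample,
                          seed = derive_seed(seed, 1))
  pairs <- do.call(rbind, lapply(corpora, function(cp) {
    extract_dep_contexts(cp$parses)
  }))
  dep <- train_depembed(pairs, dim = dim, epochs = epochs_dep,
                        seed = derive_seed(seed, 2))
  list(N = ngram, D = dep)
}

#' End-to-end synthetic experiment
#'
#' Generates a context-free and a context-specific corpus, trains the
#' knowledge-graph embedding and both linguistic embedding tables,
#' pre-trains the classifier on the context-free corpus (mini-batch 50),
#' fine-tunes on the context-specific training split (mini-batch 5), and
#' reports held-out micro-F1 before and after fine-tuning.
#'
#' @param n_free,n_specific Corpus sizes.
#' @param groups Representation groups to enable.
#' @param seed Master seed for every stage.
#' @param test_fraction Held-out fraction of the context-specific corpus.
#' @param embed_dim Linguistic embedding dimension.
#' @param embed_epochs Skip-gram epochs for both embedding tables.
#' @param knowledge_signal_fraction Passed to [generator_config()].
#' @return List with the trained `model`, `tables`, `kg` model, the
#'   held-out `report` (from [eval_report()]), `pretrain_f1` (micro-F1 of
#'   the pre-trained model on the held-out context-specific split) and
#'   `finetune_f1`.
#' @export
run_synthetic_experiment <- function(n_free = 2000, n_specific = 600,
                                     groups = c("N", "D", "K"), seed = 3,
                                     test_fraction = 1 / 3,
                                     embed_dim = 200, embed_epochs = 50,
                                     knowledge_signal_fraction = 0.3) {
  kg <- gen_kg(n_nodes = 20, n_relations = 5, n_triples = 60,
               seed = derive_seed(seed, 11))
  kg_model <- train_convkb(kg$graph, m = 10, lr = 0.001,
                           seed = derive_seed(seed, 12))
  cfg_free <- generator_config(
    n_instances = n_free, corpus_kind = "context-free",
    knowledge_signal_fraction = knowledge_signal_fraction,
    seed = derive_seed(seed, 13))
  cfg_spec <- generator_config(
    n_instances = n_specific, corpus_kind = "context-specific",
    knowledge_signal_fraction = knowledge_signal_fraction,
    seed = derive_seed(seed, 14))
  free <- gen_corpus(cfg_free, kg_model = kg_model)
  spec <- gen_corpus(cfg_spec, kg_model = kg_model)
  tables <- corpus_embeddings(list(free, spec), dim = embed_dim,
                              epochs_ngram = embed_epochs,
                              epochs_dep = embed_epochs,
                              seed = derive_seed(seed, 15))
  gold <- vapply(spec$instances, `[[`, "", "label")
  fold <- stratified_folds(gold, k = round(1 / test_fraction),
                           seed = derive_seed(seed, 16))
  test_idx <- which(fold == 1)
  train_idx <- which(fold != 1)

  model <- mgnc_init(groups = groups, emb_dim = embed_dim, m = kg_model$m,
                     seed = derive_seed(seed, 17))
  model <- pretrain(model, free$instances, tables,
                    train_config(batch_size = 50L,
                                 seed = derive_seed(seed, 18)))
  pre_pred <- mgnc_predict(model, spec$instances[test_idx], tables)
  pretrain_f1 <- as.numeric(micro_f1(gold[test_idx], pre_pred$labels))
  model <- finetune(model, spec$instances[train_idx], tables,
                    train_config(batch_size = 5L,
                                 seed = derive_seed(seed, 19)))
  pred <- mgnc_predict(model, spec$instances[test_idx], tables)
  report <- eval_report(gold[test_idx], pred$labels)
  list(model = model, tables = tables, kg = kg, kg_model = kg_model,
       free = free, spec = spec, test_idx = test_idx,
       pretrain_f1 = pretrain_f1, finetune_f1 = report$micro_f1,
       report = report)
}
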