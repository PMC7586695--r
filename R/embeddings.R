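# Linguistic representation models: n-gram skip-gram embeddings trained over
# token windows, and dependency-based embeddings trained over syntactic
# (word, context) pairs extracted from CoNLL-U parses. Both use the C++
# skip-gram-with-negative-sampling core (single worker, seeded, so training
# is bit-reproducible).

new_embedding_table <- function(vectors, vocab, kind) {
  rownames(vectors) <- vocab
  structure(list(vectors = vectors, vocab = setNames(seq_along(vocab), vocab),
                 dim = ncol(vectors), kind = kind),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table kind=%s vocab=%d dim=%d>\n",
              x$kind, length(x$vocab), x$dim))
  invisible(x)
}

#' Look up embedding vectors
#'
#' @param table An `embedding_table`.
#' @param tokens Character vector of tokens.
#' @return Matrix `length(tokens) x dim`; unknown tokens map to zero rows.
#' @export
embedding_lookup <- function(table, tokens) {
  out <- matrix(0, nrow = length(tokens), ncol = table$dim)
  idx <- table$vocab[tokens]
  hit <- !is.na(idx)
  if (any(hit)) out[hit, ] <- table$vectors[idx[hit], , drop = FALSE]
  out
}

#' Train n-gram skip-gram word embeddings
#'
#' Skip-gram with negative sampling over linear token windows. Defaults
#' follow the biomedical-NLP settings used throughout the pipeline:
#' dimension 200, window 16, 50 epochs, learning rate 0.05, frequent-word
#' subsampling 1e-5 and 10 negative samples, with negatives drawn from the
#' unigram distribution raised to 0.75.
#'
#' @param sentences List of character vectors (token lists).
#' @param dim,window,epochs,lr,subsample,negatives Skip-gram
#'   hyperparameters.
#' @param min_count Minimum token frequency to enter the vocabulary.
#' @param seed Integer seed; training is single-threaded and reproducible.
#' @return An `embedding_table` (kind "ngram") with attribute `loss`, the
#'   mean negative-sampling loss per epoch.
#' @export
train_skipgram <- function(sentences, dim = 200, window = 16, epochs = 50,
                           lr = 0.05, subsample = 1e-5, negatives = 10,
                           min_count = 1, seed = 1) {
  sentences <- Filter(length, sentences)
  if (length(sentences) == 0) stop("empty corpus")
  all_tokens <- unlist(sentences, use.names = FALSE)
  counts <- table(all_tokens)
  counts <- counts[counts >= min_count]
  if (length(counts) == 0) stop("empty corpus")
  vocab <- names(counts)
  vmap <- setNames(seq_along(vocab), vocab)
  ids <- lapply(sentences, function(s) {
    v <- vmap[s]
    as.integer(v[!is.na(v)] - 1L)
  })
  ids <- Filter(length, ids)
  fit <- sgns_train_corpus_cpp(ids, as.numeric(counts), as.integer(dim),
                               as.integer(window), as.integer(epochs),
                               lr, subsample, as.integer(negatives),
                               as.integer(seed))
  out <- new_embedding_table(fit$vectors, vocab, "ngram")
  attr(out, "loss") <- fit$loss
  out
}

#' Extract dependency contexts from a CoNLL-U parse
#'
#' For every dependency arc head -> modifier with label L, emits the pair
#' (head, "modifier/L") and the inverse pair (modifier, "head/LI"), so a
#' word is characterized by its syntactic neighborhood regardless of linear
#' distance (a verb "saw" governing "cat" as direct object yields the
#' context "cat/dobj" for "saw" and "saw/dobjI" for "cat"). Arcs whose
#' modifier is labeled `punct` are skipped.
#'
#' @param conllu CoNLL-U text (single string or character vector of lines).
#' @return A data.frame with columns `word` and `context`, one row per
#'   emitted pair, in sentence order.
#' @export
extract_dep_contexts <- function(conllu) {
  lines <- if (length(conllu) == 1) strsplit(conllu, "\n", fixed = TRUE)[[1]]
           else conllu
  words <- list()
  pairs <- list()
  sent_form <- character()
  sent_head <- integer()
  sent_dep <- character()
  flush_sentence <- function() {
    if (length(sent_form) == 0) return()
    for (i in seq_along(sent_form)) {
      h <- sent_head[i]
      if (is.na(h) || h == 0) next
      if (sent_dep[i] == "punct") next
      if (h < 1 || h > length(sent_form)) {
        stop("dependency head out of range in parse")
      }
      pairs[[length(pairs) + 1L]] <<- c(
        sent_form[h], paste0(sent_form[i], "/", sent_dep[i]))
      pairs[[length(pairs) + 1L]] <<- c(
        sent_form[i], paste0(sent_form[h], "/", sent_dep[i], "I"))
    }
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (startsWith(line, "#")) next
    if (!nzchar(trimws(line))) {
      flush_sentence()
      sent_form <- character(); sent_head <- integer(); sent_dep <- character()
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 10) {
      stop(sprintf("malformed CoNLL-U at line %d: expected 10 fields, got %d",
                   ln, length(fields)))
    }
    id <- fields[1]
    if (grepl("[-.]", id)) next  # multiword ranges and empty nodes
    if (is.na(suppressWarnings(as.integer(id)))) {
      stop(sprintf("malformed CoNLL-U at line %d: bad token id '%s'", ln, id))
    }
    head_id <- suppressWarnings(as.integer(fields[7]))
    if (is.na(head_id) && fields[7] != "_") {
      stop(sprintf("malformed CoNLL-U at line %d: bad head '%s'",
                   ln, fields[7]))
    }
    sent_form <- c(sent_form, fields[2])
    sent_head <- c(sent_head, head_id)
    sent_dep <- c(sent_dep, fields[8])
  }
  flush_sentence()
  if (length(pairs) == 0) {
    return(data.frame(word = character(), context = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, pairs)
  data.frame(word = m[, 1], context = m[, 2], stringsAsFactors = FALSE)
}

#' Train dependency-based word embeddings
#'
#' Skip-gram with negative sampling where the contexts are the syntactic
#' (word, context) pairs from [extract_dep_contexts()] rather than window
#' co-occurrences. Words and contexts have separate vocabularies; the word
#' vectors are returned.
#'
#' @param pairs Data.frame with columns `word`, `context`.
#' @param dim,epochs,lr,negatives Hyperparameters (dimension defaults
#'   to 200 to match the n-gram table; the classifier's linguistic filter
#'   width assumes it).
#' @param seed Integer seed.
#' @return An `embedding_table` (kind "dependency") with a `loss` attribute.
#' @export
train_depembed <- function(pairs, dim = 200, epochs = 50, lr = 0.05,
                           negatives = 10, seed = 1) {
  if (is.null(pairs) || nrow(pairs) == 0) stop("empty pair list")
  words <- sort(unique(pairs$word))
  ctxs <- sort(unique(pairs$context))
  wmap <- setNames(seq_along(words), words)
  cmap <- setNames(seq_along(ctxs), ctxs)
  ctx_counts <- as.numeric(table(factor(pairs$context, levels = ctxs)))
  fit <- sgns_train_pairs_cpp(as.integer(wmap[pairs$word] - 1L),
                              as.integer(cmap[pairs$context] - 1L),
                              length(words), length(ctxs), ctx_counts,
                              as.integer(dim), as.integer(epochs), lr,
                              as.integer(negatives), as.integer(seed))
  out <- new_embedding_table(fit$vectors, words, "dependency")
  attr(out, "loss") <- fit$loss
  out
}

#' Write an embedding table in word2vec text format
#'
#' Header line "V D", then one line per token: the token followed by D
#' space-separated floats.
#'
#' @param table An `embedding_table`.
#' @param path Output path.
#' @export
write_word2vec <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(table$vocab), table$dim), con)
  toks <- names(table$vocab)
  for (i in seq_along(toks)) {
    writeLines(paste(toks[i],
                     paste(format(table$vectors[i, ], scientific = FALSE,
                                  trim = TRUE, digits = 8),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Read an embedding table from word2vec text format
#' @param path Input path.
#' @param kind Table kind label ("ngram" or "dependency").
#' @return An `embedding_table`.
#' @export
read_word2vec <- function(path, kind = "ngram") {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  v <- hdr[1]; d <- hdr[2]
  vocab <- character(v)
  vecs <- matrix(0, v, d)
  for (i in seq_len(v)) {
    parts <- strsplit(lines[i + 1], " ", fixed = TRUE)[[1]]
    vocab[i] <- parts[1]
    vecs[i, ] <- as.numeric(parts[-1])
  }
  new_embedding_table(vecs, vocab, kind)
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
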