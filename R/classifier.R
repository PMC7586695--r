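# Multi-group norm-constraint CNN (MGNC-CNN). Each representation group
# (N: n-gram embeddings, D: dependency embeddings, K: knowledge matrix) has
# its own convolutional feature extractor; the per-group max-pooled features
# are concatenated at the penultimate layer, dropped out, and fed to an
# 8-way softmax. After every optimizer step the softmax weight block of each
# group is projected onto its own L2 ball (norm cap lambda_g). Linguistic
# filters span the full embedding width (200) with lengths 21/22/23, 100
# filters each; the knowledge group convolves the 3 x m knowledge matrix
# once (no stride) with 50 filters. Pre-trained embeddings are frozen;
# the pad token embeds to zeros and positions beyond the true sentence
# length are masked out of the max-pool.

#' Initialize an MGNC-CNN model
#'
#' @param groups Subset of c("N", "D", "K") in feature-concatenation order.
#' @param emb_dim Linguistic embedding width (filter width).
#' @param m Knowledge embedding dimension (knowledge matrix is 3 x m).
#' @param filter_lengths Linguistic filter lengths.
#' @param n_filters_ling Filters per linguistic length.
#' @param n_filters_k Knowledge filters.
#' @param lambda Named norm caps per group (L2 ball radius for each group's
#'   block of softmax weights).
#' @param seed Integer seed for parameter initialization.
#' @return An `mgnc_model`.
#' @export
mgnc_init <- function(groups = c("N", "D", "K"), emb_dim = 200, m = 10,
                      filter_lengths = c(21L, 22L, 23L),
                      n_filters_ling = 100L, n_filters_k = 50L,
                      lambda = c(N = 3, D = 3, K = 3), seed = 1) {
  stopifnot(all(groups %in% c("N", "D", "K")), length(groups) >= 1)
  n_classes <- length(relation_classes())
  with_seed(seed, {
    params <- list()
    blocks <- list()
    off <- 0L
    for (g in groups) {
      if (g %in% c("N", "D")) {
        for (l in filter_lengths) {
          # filters stored transposed, (l * emb_dim) x n_filters, so the
          # convolution is a single crossprod with the window matrix
          nm <- paste0("W_", g, "_", l)
          sd <- sqrt(2 / (l * emb_dim))
          params[[nm]] <- matrix(rnorm(n_filters_ling * l * emb_dim, 0, sd),
                                 l * emb_dim, n_filters_ling)
          params[[paste0("b_", g, "_", l)]] <- numeric(n_filters_ling)
        }
        blocks[[g]] <- off + seq_len(n_filters_ling * length(filter_lengths))
        off <- off + n_filters_ling * length(filter_lengths)
      } else {
        sd <- sqrt(2 / (3 * m))
        params$W_K <- matrix(rnorm(n_filters_k * 3 * m, 0, sd),
                             3 * m, n_filters_k)
        params$b_K <- numeric(n_filters_k)
        blocks$K <- off + seq_len(n_filters_k)
        off <- off + n_filters_k
      }
    }
    n_feat <- off
    params$U <- matrix(rnorm(n_feat * n_classes, 0, sqrt(1 / n_feat)),
                       n_feat, n_classes)
    params$b_out <- numeric(n_classes)
    structure(list(groups = groups, emb_dim = emb_dim, m = m,
                   filter_lengths = as.integer(filter_lengths),
                   n_filters_ling = as.integer(n_filters_ling),
                   n_filters_k = as.integer(n_filters_k),
                   lambda = lambda, n_feat = n_feat, blocks = blocks,
                   params = params),
              class = "mgnc_model")
  })
}

#' @export
print.mgnc_model <- function(x, ...) {
  cat(sprintf("<mgnc_model groups=%s features=%d filters=%s x%d + K x%d>\n",
              paste(x$groups, collapse = ","), x$n_feat,
              paste(x$filter_lengths, collapse = "/"), x$n_filters_ling,
              x$n_filters_k))
  invisible(x)
}

# Encode instances against the embedding tables: per linguistic group an
# integer id matrix B x L (0 = pad/unknown -> zero vector), true lengths,
# and the flattened knowledge matrices.
mgnc_encode <- function(instances, model, tables) {
  B <- length(instances)
  toks <- lapply(instances, `[[`, "tokens")
  true_len <- vapply(toks, function(tt) sum(tt != PAD_TOKEN), 0L)
  L <- max(MIN_INSTANCE_TOKENS, max(lengths(toks)))
  enc <- list(B = B, L = L, true_len = true_len)
  for (g in intersect(model$groups, c("N", "D"))) {
    tab <- tables[[g]]
    if (is.null(tab)) stop("missing embedding table for group ", g)
    ids <- matrix(0L, B, L)
    for (b in seq_len(B)) {
      tt <- toks[[b]]
      v <- tab$vocab[tt]
      v[is.na(v)] <- 0L
      v[tt == PAD_TOKEN] <- 0L
      ids[b, seq_along(tt)] <- v
    }
    # transposed embedding matrix with a leading zero column; id i maps to
    # column i + 1, so window matrices assemble by column gather alone
    enc[[g]] <- list(ids = ids,
                     emb_t = t(rbind(numeric(tab$dim), tab$vectors)))
  }
  if ("K" %in% model$groups) {
    enc$K <- t(vapply(instances, function(x) as.numeric(x$knowledge_matrix),
                      numeric(3 * model$m)))
  }
  y <- match(vapply(instances, `[[`, "", "label"), relation_classes())
  if (anyNA(y)) stop("instance label outside the 8-class set")
  enc$y <- y
  enc
}

# forward pass over an encoded batch (row subset `rows`), returning
# probabilities and (if wanted) the cache for backprop
mgnc_forward_enc <- function(model, enc, rows = seq_len(enc$B),
                             dropout_mask = NULL, cache = FALSE) {
  p <- model$params
  B <- length(rows)
  feats <- matrix(0, B, model$n_feat)
  cc <- list()
  for (g in intersect(model$groups, c("N", "D"))) {
    ids <- enc[[g]]$ids[rows, , drop = FALSE]
    L <- ncol(ids)
    D <- model$emb_dim
    idvec <- as.vector(t(ids))  # instance-major token order
    Et <- enc[[g]]$emb_t[, idvec + 1L, drop = FALSE]  # D x (B*L)
    col0 <- 0L
    for (l in model$filter_lengths) {
      np <- L - l + 1L
      # window column indices: instance b, position q, offset k; stacking l
      # consecutive token columns gives one (D*l) window column
      base <- rep((seq_len(B) - 1L) * L, each = np * l)
      qoff <- rep(rep(seq_len(np), each = l), times = B)
      koff <- rep(seq_len(l) - 1L, times = np * B)
      idx <- base + qoff + koff
      Wmat <- matrix(Et[, idx, drop = FALSE], nrow = D * l)  # (D*l) x (B*np)
      Wnm <- paste0("W_", g, "_", l)
      pre <- crossprod(Wmat, p[[Wnm]])  # (B*np) x nf
      pre <- sweep(pre, 2, p[[paste0("b_", g, "_", l)]], "+")
      # mask positions past the true (unpadded) sentence length
      valid_np <- pmax(enc$true_len[rows] - l + 1L, 1L)
      qpos <- rep(seq_len(np), times = B)
      bad <- qpos > rep(valid_np, each = np)
      if (any(bad)) pre[bad, ] <- -Inf
      nf <- model$n_filters_ling
      arr <- array(pre, c(np, B, nf))  # q fastest
      mx <- arr[1, , , drop = TRUE]
      if (B == 1 || nf == 1) mx <- matrix(mx, B, nf)
      amax <- matrix(1L, B, nf)
      if (np > 1) for (q in 2:np) {
        sl <- arr[q, , , drop = TRUE]
        if (B == 1 || nf == 1) sl <- matrix(sl, B, nf)
        upd <- sl > mx
        amax[upd] <- q
        mx[upd] <- sl[upd]
      }
      f <- pmax(mx, 0)
      cols <- col0 + seq_len(nf) + model$blocks[[g]][1] - 1L
      feats[, cols] <- f
      if (cache) {
        cc[[paste(g, l)]] <- list(Wmat = Wmat, mx = mx, amax = amax,
                                  np = np, cols = cols, l = l)
      }
      col0 <- col0 + nf
    }
  }
  if ("K" %in% model$groups) {
    Kin <- enc$K[rows, , drop = FALSE]
    preK <- sweep(Kin %*% p$W_K, 2, p$b_K, "+")
    fK <- pmax(preK, 0)
    feats[, model$blocks$K] <- fK
    if (cache) cc$K <- list(Kin = Kin, preK = preK)
  }
  phi <- feats
  if (!is.null(dropout_mask)) phi <- phi * dropout_mask
  logits <- sweep(phi %*% p$U, 2, p$b_out, "+")
  logits <- logits - apply(logits, 1, max)
  ex <- exp(logits)
  probs <- ex / rowSums(ex)
  if (!cache) return(list(probs = probs, feats = feats))
  cc$feats <- feats
  cc$phi <- phi
  list(probs = probs, feats = feats, cache = cc)
}

# gradient of mean cross-entropy for an encoded batch
mgnc_backward <- function(model, enc, rows, fwd, dropout_mask) {
  p <- model$params
  B <- length(rows)
  n_classes <- ncol(fwd$probs)
  Y <- matrix(0, B, n_classes)
  Y[cbind(seq_len(B), enc$y[rows])] <- 1
  dlogit <- (fwd$probs - Y) / B
  g <- list()
  g$U <- crossprod(fwd$cache$phi, dlogit)
  g$b_out <- colSums(dlogit)
  dphi <- dlogit %*% t(p$U)
  if (!is.null(dropout_mask)) dphi <- dphi * dropout_mask
  for (gg in intersect(model$groups, c("N", "D"))) {
    for (l in model$filter_lengths) {
      cc <- fwd$cache[[paste(gg, l)]]
      nf <- model$n_filters_ling
      dfeat <- dphi[, cc$cols, drop = FALSE] * (cc$mx > 0)
      np <- cc$np
      dpre <- matrix(0, B * np, nf)
      ridx <- (rep(seq_len(B), times = nf) - 1L) * np + as.vector(cc$amax)
      cidx <- rep(seq_len(nf), each = B)
      dpre[cbind(ridx, cidx)] <- as.vector(dfeat)
      Wnm <- paste0("W_", gg, "_", l)
      g[[Wnm]] <- cc$Wmat %*% dpre
      g[[paste0("b_", gg, "_", l)]] <- colSums(dpre)
    }
  }
  if ("K" %in% model$groups) {
    cc <- fwd$cache$K
    dfK <- dphi[, model$blocks$K, drop = FALSE] * (cc$preK > 0)
    g$W_K <- crossprod(cc$Kin, dfK)
    g$b_K <- colSums(dfK)
  }
  g
}

# project each group's softmax weight block onto its L2 ball
mgnc_project <- function(model) {
  for (g in model$groups) {
    lam <- model$lambda[[g]]
    if (is.null(lam) || !is.finite(lam)) next
    rows <- model$blocks[[g]]
    blk <- model$params$U[rows, , drop = FALSE]
    nrm <- sqrt(sum(blk^2))
    if (nrm > lam) model$params$U[rows, ] <- blk * (lam / nrm)
  }
  model
}

mean_ce <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
}

#' Training configuration for the classifier
#'
#' @param lr Learning rate (Adam).
#' @param dropout Dropout probability on the concatenated features.
#' @param batch_size Mini-batch size (50 for pre-training, 5 for
#'   fine-tuning).
#' @param max_epochs Hard epoch cap (early stopping keeps this below 10).
#' @param patience Early-stopping patience on held-out loss.
#' @param val_fraction Fraction of instances held out for early stopping.
#' @param seed Integer seed (shuffling, dropout, validation split).
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.001, dropout = 0.5, batch_size = 50L,
                         max_epochs = 10L, patience = 2L,
                         val_fraction = 0.1, seed = 1) {
  stopifnot(batch_size >= 1)
  structure(list(lr = lr, dropout = dropout,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

mgnc_train <- function(model, instances, tables, cfg) {
  if (length(instances) == 0) stop("empty corpus")
  enc <- mgnc_encode(instances, model, tables)
  if (cfg$max_epochs == 0) {
    attr(model, "epochs_run") <- 0L
    return(model)
  }
  with_seed(cfg$seed, {
    B <- enc$B
    n_val <- max(1L, min(B - 1L, round(cfg$val_fraction * B)))
    # stratified validation split
    val_idx <- unlist(lapply(split(seq_len(B), enc$y), function(ix) {
      k <- max(0L, round(length(ix) * cfg$val_fraction))
      if (k == 0) integer() else sample(ix, k)
    }))
    if (length(val_idx) == 0) val_idx <- sample.int(B, n_val)
    tr_idx <- setdiff(seq_len(B), val_idx)
    if (length(tr_idx) == 0) { tr_idx <- seq_len(B); val_idx <- seq_len(B) }

    # deep-copy parameters: the Adam step updates them in place
    model$params <- lapply(model$params, function(x) x + 0)
    adam_m <- lapply(model$params, function(x) x * 0)
    adam_v <- lapply(model$params, function(x) x * 0)
    step <- 0L
    best <- list(loss = Inf, params = model$params, epoch = 0L)
    bad <- 0L
    hist <- numeric(0)
    for (ep in seq_len(cfg$max_epochs)) {
      ord <- sample(tr_idx)
      nb <- ceiling(length(ord) / cfg$batch_size)
      for (bi in seq_len(nb)) {
        rows <- ord[((bi - 1L) * cfg$batch_size + 1L):
                      min(bi * cfg$batch_size, length(ord))]
        mask <- if (cfg$dropout > 0) {
          matrix((runif(length(rows) * model$n_feat) >= cfg$dropout) /
                   (1 - cfg$dropout), length(rows), model$n_feat)
        } else NULL
        fwd <- mgnc_forward_enc(model, enc, rows, dropout_mask = mask,
                                cache = TRUE)
        grads <- mgnc_backward(model, enc, rows, fwd, mask)
        step <- step + 1L
        for (nm in names(grads)) {
          adam_update_cpp(model$params[[nm]], grads[[nm]], adam_m[[nm]],
                          adam_v[[nm]], cfg$lr, step, 0.9, 0.999, 1e-8)
        }
        model <- mgnc_project(model)
      }
      vfwd <- mgnc_forward_enc(model, enc, val_idx)
      vloss <- mean_ce(vfwd$probs, enc$y[val_idx])
      hist <- c(hist, vloss)
      if (vloss < best$loss - 1e-6) {
        # deep copy: the live parameters keep being updated in place
        best <- list(loss = vloss,
                     params = lapply(model$params, function(x) x + 0),
                     epoch = ep)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= cfg$patience) break
      }
    }
    model$params <- best$params
    model <- mgnc_project(model)
    attr(model, "epochs_run") <- best$epoch
    attr(model, "val_loss") <- hist
    model
  })
}

#' Pre-train the classifier on context-free instances
#'
#' Transfer-learning stage 1: trains all parameters on context-free source
#' instances (mini-batch 50 by default) with Adam, dropout, early stopping
#' on a held-out split, and per-group norm projection after every step.
#'
#' @param model An `mgnc_model`.
#' @param instances Context-free `relation_instance` list.
#' @param tables Named list of embedding tables (`N`, `D`) for the enabled
#'   linguistic groups.
#' @param cfg A [train_config()] (batch size defaults to 50).
#' @return The trained model; attribute `epochs_run` records the early-stop
#'   epoch.
#' @export
pretrain <- function(model, instances, tables,
                     cfg = train_config(batch_size = 50L)) {
  if (length(instances) == 0) stop("empty corpus")
  kinds <- vapply(instances, `[[`, "", "corpus_kind")
  if (!all(kinds == "context-free")) {
    stop("pretrain expects context-free instances only")
  }
  mgnc_train(model, instances, tables, cfg)
}

#' Fine-tune the classifier on context-specific instances
#'
#' Transfer-learning stage 2: continues training (all parameters, including
#' the softmax layer — the label sets of the two corpora are identical) on
#' the context-specific target corpus with mini-batch 5 by default.
#' Cold-start fine-tuning of a freshly initialized model is allowed (used
#' by the ablation runner).
#'
#' @inheritParams pretrain
#' @param cfg A [train_config()] (batch size defaults to 5).
#' @return The trained model.
#' @export
finetune <- function(model, instances, tables,
                     cfg = train_config(batch_size = 5L)) {
  if (length(instances) == 0) stop("empty corpus")
  mgnc_train(model, instances, tables, cfg)
}

#' Forward pass: class probabilities for instances
#'
#' Evaluation-mode forward (no dropout): per linguistic group, tokens are
#' embedded, convolved with every filter, ReLU-activated and max-pooled
#' over valid positions; the knowledge group convolves the 3 x m knowledge
#' matrix once; the concatenated features go through the softmax layer.
#'
#' @param model A trained `mgnc_model`.
#' @param instances A `relation_instance` or list of them.
#' @param tables Named list of embedding tables for enabled groups.
#' @return Matrix of probabilities (instances x 8), rows summing to 1.
#' @export
mgnc_forward <- function(model, instances, tables) {
  if (inherits(instances, "relation_instance")) instances <- list(instances)
  enc <- mgnc_encode(instances, model, tables)
  out <- mgnc_forward_enc(model, enc)$probs
  colnames(out) <- relation_classes()
  out
}

#' Predict class labels
#'
#' Argmax of the forward probabilities; ties break toward the earlier class
#' in canonical order.
#'
#' @inheritParams mgnc_forward
#' @return List with `labels` (character) and `probs` (matrix).
#' @export
mgnc_predict <- function(model, instances, tables) {
  probs <- mgnc_forward(model, instances, tables)
  labels <- relation_classes()[max.col(probs, ties.method = "first")]
  list(labels = labels, probs = probs)
}

#' Extract the concatenated feature vector(s)
#'
#' Penultimate-layer features (before dropout/softmax); 650-dimensional
#' with all three groups at the default filter counts (3 x 100 + 3 x 100 +
#' 50).
#'
#' @inheritParams mgnc_forward
#' @return Matrix instances x n_feat.
#' @export
mgnc_features <- function(model, instances, tables) {
  if (inherits(instances, "relation_instance")) instances <- list(instances)
  enc <- mgnc_encode(instances, model, tables)
  mgnc_forward_enc(model, enc)$feats
}

#' Group-block softmax weight norms
#'
#' L2 norm of each group's block of softmax weights; always bounded by the
#' group's norm cap after training.
#'
#' @param model An `mgnc_model`.
#' @return Named numeric vector of block norms.
#' @export
mgnc_group_norms <- function(model) {
  vapply(model$groups, function(g) {
    sqrt(sum(model$params$U[model$blocks[[g]], , drop = FALSE]^2))
  }, numeric(1))
}

#' Save / load a model checkpoint as JSON
#' @param model An `mgnc_model`.
#' @param path Output path.
#' @export
write_mgnc_model <- function(model, path) {
  obj <- list(groups = model$groups, emb_dim = model$emb_dim, m = model$m,
              filter_lengths = model$filter_lengths,
              n_filters_ling = model$n_filters_ling,
              n_filters_k = model$n_filters_k,
              lambda = as.list(model$lambda), n_feat = model$n_feat,
              blocks = model$blocks,
              params = model$params)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mgnc_model
#' @export
read_mgnc_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    if (is.list(p)) p <- do.call(rbind, lapply(p, unlist))
    p
  })
  blocks <- lapply(obj$blocks, as.integer)
  structure(list(groups = obj$groups, emb_dim = obj$emb_dim, m = obj$m,
                 filter_lengths = as.integer(obj$filter_lengths),
                 n_filters_ling = as.integer(obj$n_filters_ling),
                 n_filters_k = as.integer(obj$n_filters_k),
                 lambda = unlist(obj$lambda), n_feat = obj$n_feat,
                 blocks = blocks, params = params),
            class = "mgnc_model")
}
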