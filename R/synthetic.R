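# Synthetic-data generators. These define the study conditions for every
# stage of the pipeline without external downloads: a toy semantic network
# with planted translational structure (object ~ subject + predicate in a
# latent space), a template corpus whose relation class is determined
# jointly by lexical triggers and entity semantic types, deterministic
# dependency parses for those templates, a matching lexicon, and BioNLP-ST
# standoff fixtures with nested events of known flattened gold relations.
# All generators are bit-reproducible per seed.

#' Generate a toy knowledge graph with planted transitional structure
#'
#' Nodes live on a latent 2-D grid spanned by two random base directions u
#' and v (plus per-node jitter); relations are u, v, u + v and near-aliases
#' of these (cycled, each with a small perturbation). True triples are the
#' `n_triples` grid moves (subject, predicate, object) with the smallest
#' latent residuals ||s + p - o||, which are tiny by construction —
#' corrupting either endpoint breaks the grid geometry, so corrupted
#' triples have residuals on the order of a grid step.
#'
#' @param n_nodes Number of nodes (>= 3); named `st01`, `st02`, ...
#' @param n_relations Number of relation labels (`rel1`, ...).
#' @param n_triples Number of true triples.
#' @param m_latent Latent dimension.
#' @param noise Jitter / relation-alias perturbation scale (sd).
#' @param seed Integer seed.
#' @return List with `graph` (a [knowledge_graph()]), `latent` (node and
#'   relation latent matrices) and `residuals` of the chosen triples.
#' @export
gen_kg <- function(n_nodes = 20, n_relations = 5, n_triples = 60,
                   m_latent = 10, noise = 0.05, seed = 1) {
  if (n_nodes < 3) stop("n_nodes must be >= 3")
  with_seed(seed, {
    nodes <- sprintf("st%02d", seq_len(n_nodes))
    rels <- sprintf("rel%d", seq_len(n_relations))
    u <- rnorm(m_latent); u <- u / sqrt(sum(u^2)) * 2
    v <- rnorm(m_latent); v <- v / sqrt(sum(v^2)) * 2
    n1 <- ceiling(sqrt(n_nodes))
    n2 <- ceiling(n_nodes / n1)
    coords <- expand.grid(a = seq_len(n1) - 1L, b = seq_len(n2) - 1L)
    coords <- coords[seq_len(n_nodes), ]
    N <- outer(coords$a, u) + outer(coords$b, v) +
      matrix(rnorm(n_nodes * m_latent, 0, noise), n_nodes, m_latent)
    rownames(N) <- nodes
    # relation latent steps cycle through u, v, u + v with small aliases
    steps <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L))
    R <- matrix(0, n_relations, m_latent, dimnames = list(rels, NULL))
    rel_step <- vector("list", n_relations)
    for (p in seq_len(n_relations)) {
      st <- steps[[(p - 1L) %% 3L + 1L]]
      rel_step[[p]] <- st
      R[p, ] <- st[1] * u + st[2] * v + rnorm(m_latent, 0, noise)
    }
    # candidate triples: exact grid moves for each relation's step
    cand <- do.call(rbind, lapply(seq_len(n_relations), function(p) {
      st <- rel_step[[p]]
      oa <- coords$a + st[1]; ob <- coords$b + st[2]
      o <- match(paste(oa, ob), paste(coords$a, coords$b))
      ok <- which(!is.na(o) & o != seq_len(n_nodes))
      if (length(ok) == 0) return(NULL)
      data.frame(s = ok, p = p, o = o[ok])
    }))
    if (is.null(cand) || nrow(cand) < n_triples) {
      stop("infeasible: grid supports only ",
           if (is.null(cand)) 0 else nrow(cand), " planted triples")
    }
    res <- vapply(seq_len(nrow(cand)), function(i) {
      d <- N[cand$s[i], ] + R[cand$p[i], ] - N[cand$o[i], ]
      sqrt(sum(d * d))
    }, numeric(1))
    pick <- order(res)[seq_len(n_triples)]
    triples <- data.frame(subject = nodes[cand$s[pick]],
                          predicate = rels[cand$p[pick]],
                          object = nodes[cand$o[pick]],
                          stringsAsFactors = FALSE)
    list(graph = knowledge_graph(triples, nodes = nodes, relations = rels),
         latent = list(node = N, rel = R),
         residuals = res[pick])
  })
}

TRIGGER_LEXICON <- list(
  Increase = list(active = c("activates", "upregulates", "enhances",
                             "induces"),
                  passive = c("activated", "upregulated", "enhanced",
                              "induced")),
  Decrease = list(active = c("inhibits", "suppresses", "reduces",
                             "represses"),
                  passive = c("inhibited", "suppressed", "reduced",
                              "repressed")),
  Regulate = list(active = c("regulates", "modulates", "controls"),
                  passive = c("regulated", "modulated", "controlled")),
  Binding = list(active = c("binds", "contacts"), passive = character()),
  ambiguous = list(active = "targets", passive = character())
)

# Filler clauses bringing every sentence to >= 23 tokens; the %E% slot
# carries a class-correlated "echo" noun (as in real abstracts, where
# sentences about inhibition use decrease-themed vocabulary), attached to
# the root in the template parse.
FILLER_TAILS <- list(
  list(tokens = c("and", "this", "effect", "was", "linked", "to", "clear",
                  "%E%", "across", "many", "independent", "replicates",
                  "in", "our", "recent", "comprehensive", "longitudinal",
                  "cohort", "study", "."),
       echo_slot = 8L),
  list(tokens = c("and", "the", "resulting", "%E%", "remained", "stable",
                  "across", "all", "tested", "conditions", "in", "several",
                  "separate", "validation", "cohort", "analyses",
                  "performed", "last", "year", "."),
       echo_slot = 4L),
  list(tokens = c("which", "was", "confirmed", "as", "%E%", "by",
                  "multiple", "independent", "assays", "performed",
                  "under", "carefully", "controlled", "laboratory",
                  "conditions", "during", "this", "extensive",
                  "investigation", "."),
       echo_slot = 5L)
)

ECHO_WORDS <- list(
  Increase = c("elevation", "upregulation", "enhancement"),
  Decrease = c("reduction", "suppression", "decline"),
  Regulate = c("modulation", "rebalancing", "adjustment"),
  Binding = c("association", "complexes", "interaction"),
  False = c("measurements", "profiles", "values"),
  neutral = c("outcomes", "observations", "findings")
)

#' Generator configuration for the synthetic relation corpus
#'
#' @param n_instances Number of instances to generate.
#' @param corpus_kind "context-specific" (disease mention present) or
#'   "context-free".
#' @param n_genes,n_diseases Entity vocabulary sizes.
#' @param knowledge_signal_fraction Fraction of instances using the
#'   ambiguous trigger, whose class is resolvable only through the
#'   molecule's semantic type (the knowledge modality).
#' @param noise_rate Label-flip probability.
#' @param class_probs Optional named sampling weights over the 8 classes.
#' @param type_a,type_b Semantic types (knowledge-graph nodes) that decide
#'   the class of knowledge-dependent instances.
#' @param ctx_type Semantic type of context (disease) entities.
#' @param min_tokens Sentences are padded with filler clauses to at least
#'   this many tokens (the longest classifier filter is 23).
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_instances = 600,
                             corpus_kind = c("context-specific",
                                             "context-free"),
                             n_genes = 30, n_diseases = 6,
                             knowledge_signal_fraction = 0.3,
                             noise_rate = 0, class_probs = NULL,
                             type_a = "st01", type_b = "st02",
                             ctx_type = "st03", min_tokens = 23L,
                             seed = 1) {
  stopifnot(n_instances >= 1, n_genes >= 2, n_diseases >= 1,
            knowledge_signal_fraction >= 0, knowledge_signal_fraction <= 1,
            noise_rate >= 0, noise_rate <= 1)
  structure(list(n_instances = as.integer(n_instances),
                 corpus_kind = match.arg(corpus_kind),
                 n_genes = as.integer(n_genes),
                 n_diseases = as.integer(n_diseases),
                 knowledge_signal_fraction = knowledge_signal_fraction,
                 noise_rate = noise_rate, class_probs = class_probs,
                 type_a = type_a, type_b = type_b, ctx_type = ctx_type,
                 min_tokens = as.integer(min_tokens),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# deterministic template parse: core arcs plus a filler chain, one root
template_conllu <- function(tokens, heads, deprels, sent_id) {
  lines <- c(sprintf("# sent_id = %s", sent_id))
  for (i in seq_along(tokens)) {
    lines <- c(lines, paste(i, tokens[i], "_", "_", "_", "_", heads[i],
                            deprels[i], "_", "_", sep = "\t"))
  }
  c(lines, "")
}

# assemble tokens/heads/deprels for one instance sentence
build_template <- function(label, trig, molA, molB, disease, tail_idx,
                           echo, context_specific) {
  tail_spec <- FILLER_TAILS[[tail_idx]]
  tail <- tail_spec$tokens
  tail[tail_spec$echo_slot] <- echo
  backward <- grepl("-backward$", label)
  if (label == "False") {
    core <- c(molA, "and", molB, "were", "measured")
    heads <- c(5, 3, 1, 5, 0)
    deps <- c("nsubj", "cc", "conj", "aux", "root")
    root <- 5L
  } else if (!backward) {
    core <- c(molA, trig, molB)
    heads <- c(2, 0, 2)
    deps <- c("nsubj", "root", "obj")
    root <- 2L
  } else {
    core <- c(molB, "was", trig, "by", molA)
    heads <- c(3, 3, 0, 5, 3)
    deps <- c("nsubjpass", "aux", "root", "case", "obl")
    root <- 3L
  }
  n0 <- length(core)
  if (context_specific) {
    core <- c(core, "in", disease)
    heads <- c(heads, n0 + 2L, root)
    deps <- c(deps, "case", "obl")
    n0 <- n0 + 2L
  }
  nt <- length(tail)
  tail_heads <- c(root, n0 + seq_len(nt - 1L))
  tail_deps <- c(rep("dep", nt - 1L), "punct")
  # the echo noun hangs off the root, so the trigger's dependency contexts
  # carry the class-correlated signal too
  tail_heads[tail_spec$echo_slot] <- root
  tail_deps[tail_spec$echo_slot] <- "obl"
  tokens <- c(core, tail)
  heads <- c(heads, tail_heads)
  deps <- c(deps, tail_deps)
  mol_a_pos <- match(molA, tokens)
  mol_b_pos <- match(molB, tokens)
  list(tokens = tokens, heads = heads, deprels = deps,
       mol_a_pos = which(tokens == molA)[1],
       mol_b_pos = which(tokens == molB)[1],
       ctx_pos = if (context_specific) which(tokens == disease)[1]
                 else NA_integer_)
}

#' Generate a synthetic relation corpus
#'
#' Each instance realizes one of the eight classes through a class-specific
#' trigger phrase and entity slots from fixed sentence templates. A
#' `knowledge_signal_fraction` of instances instead use an ambiguous
#' trigger ("targets"), whose class (Increase-forward vs Decrease-forward)
#' is determined solely by the subject molecule's semantic type — in the
#' tagged token sequence those instances are indistinguishable, so only the
#' knowledge modality can resolve them. Deterministic dependency parses are
#' emitted in CoNLL-U for every (entity-tagged) sentence.
#'
#' @param cfg A [generator_config()].
#' @param kg_model Optional trained [train_convkb()] model; when given, the
#'   instances carry semantic-type knowledge matrices, otherwise zeros
#'   (attach later with [attach_knowledge()]).
#' @return A list with `instances` (list of `relation_instance`, each with
#'   gold `label` and `knowledge_dependent` flag), `sentences` (data.frame
#'   of raw token strings), `parses` (CoNLL-U lines over tagged tokens),
#'   `lexicon` (entity lexicon data.frame), `type_map` (concept ->
#'   semantic type), and `config`.
#' @export
gen_corpus <- function(cfg, kg_model = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  classes <- relation_classes()
  probs <- rep(1 / 8, 8)
  names(probs) <- classes
  if (!is.null(cfg$class_probs)) {
    probs[names(cfg$class_probs)] <- cfg$class_probs
    probs <- probs / sum(probs)
  }
  for (cl in c("Increase", "Decrease", "Regulate", "Binding")) {
    if (length(TRIGGER_LEXICON[[cl]]$active) == 0) {
      stop("empty trigger lexicon for class ", cl)
    }
  }
  genes <- sprintf("gene%02d", seq_len(cfg$n_genes))
  gene_ids <- sprintf("CG%04d", seq_len(cfg$n_genes))
  gene_types <- ifelse(seq_len(cfg$n_genes) %% 2 == 1, cfg$type_a,
                       cfg$type_b)
  diseases <- sprintf("disease%02d", seq_len(cfg$n_diseases))
  disease_ids <- sprintf("CD%04d", seq_len(cfg$n_diseases))
  lexicon <- data.frame(
    surface = c(genes, diseases),
    concept_id = c(gene_ids, disease_ids),
    semantic_type = c(gene_types, rep(cfg$ctx_type, cfg$n_diseases)),
    semantic_group = c(rep("GENE", cfg$n_genes),
                       rep("DISO", cfg$n_diseases)),
    stringsAsFactors = FALSE)
  type_map <- setNames(lexicon$semantic_type, lexicon$concept_id)
  ctx_specific <- cfg$corpus_kind == "context-specific"

  with_seed(cfg$seed, {
    instances <- vector("list", cfg$n_instances)
    sent_rows <- vector("list", cfg$n_instances)
    parses <- character(0)
    for (i in seq_len(cfg$n_instances)) {
      kdep <- runif(1) < cfg$knowledge_signal_fraction
      if (kdep) {
        # subject type decides the class; tagged tokens are identical
        a_type_a <- runif(1) < 0.5
        cand <- which(gene_types == if (a_type_a) cfg$type_a else cfg$type_b)
        ai <- cand[sample.int(length(cand), 1)]
        bi <- sample(setdiff(seq_len(cfg$n_genes), ai), 1)
        label <- if (a_type_a) "Increase-forward" else "Decrease-forward"
        trig <- TRIGGER_LEXICON$ambiguous$active
      } else {
        label <- sample(classes, 1, prob = probs)
        ab <- sample.int(cfg$n_genes, 2)
        ai <- ab[1]; bi <- ab[2]
        base <- sub("-.*$", "", label)
        trig <- if (label == "False") ""
        else if (grepl("-backward$", label))
          sample(TRIGGER_LEXICON[[base]]$passive, 1)
        else sample(TRIGGER_LEXICON[[base]]$active, 1)
      }
      di <- sample.int(cfg$n_diseases, 1)
      tail_idx <- sample.int(length(FILLER_TAILS), 1)
      echo_class <- if (kdep) "neutral" else
        if (label == "False") "False" else sub("-.*$", "", label)
      echo <- sample(ECHO_WORDS[[echo_class]], 1)
      tpl <- build_template(label, trig, genes[ai], genes[bi],
                            diseases[di], tail_idx, echo, ctx_specific)
      # both draws always consumed so corpora differing only in noise_rate
      # share every other random choice
      flip <- runif(1) < cfg$noise_rate
      alt <- sample(setdiff(classes, label), 1)
      gold <- if (flip) alt else label
      molA <- data.frame(start = tpl$mol_a_pos, end = tpl$mol_a_pos + 1L,
                         surface = genes[ai], concept_id = gene_ids[ai],
                         semantic_type = gene_types[ai],
                         semantic_group = "GENE", role = "molecule",
                         stringsAsFactors = FALSE)
      molB <- data.frame(start = tpl$mol_b_pos, end = tpl$mol_b_pos + 1L,
                         surface = genes[bi], concept_id = gene_ids[bi],
                         semantic_type = gene_types[bi],
                         semantic_group = "GENE", role = "molecule",
                         stringsAsFactors = FALSE)
      ctx <- if (ctx_specific) {
        data.frame(start = tpl$ctx_pos, end = tpl$ctx_pos + 1L,
                   surface = diseases[di], concept_id = disease_ids[di],
                   semantic_type = cfg$ctx_type, semantic_group = "DISO",
                   role = "context", stringsAsFactors = FALSE)
      } else NULL
      inst <- build_instance(tpl$tokens, molA, molB, ctx, gold,
                             kg_model = kg_model, type_map = type_map,
                             knowledge_dependent = kdep)
      instances[[i]] <- inst
      sent_rows[[i]] <- data.frame(doc_id = sprintf("syn%05d", i),
                                   index = 0L,
                                   raw = detokenize(tpl$tokens),
                                   stringsAsFactors = FALSE)
      # parse over the tagged tokens so placeholder embeddings get trained
      tagged_no_pad <- inst$tokens[inst$tokens != PAD_TOKEN]
      parses <- c(parses, template_conllu(tagged_no_pad, tpl$heads,
                                          tpl$deprels,
                                          sprintf("syn%05d", i)))
    }
    list(instances = instances, sentences = do.call(rbind, sent_rows),
         parses = parses, lexicon = lexicon, type_map = type_map,
         config = cfg)
  })
}

#' Attach knowledge matrices to generated instances
#'
#' Rebuilds each instance's 3 x m knowledge matrix from a trained
#' knowledge-graph model (rows: molA, context or zeros, molB, embedded at
#' the semantic-type level).
#'
#' @param corpus Output of [gen_corpus()].
#' @param kg_model A `kg_model`.
#' @return The corpus with updated instances.
#' @export
attach_knowledge <- function(corpus, kg_model) {
  corpus$instances <- lapply(corpus$instances, function(inst) {
    km <- matrix(0, 3, kg_model$m)
    km[1, ] <- concept_vector(inst$molA$concept_id, corpus$type_map,
                              kg_model)
    if (!is.null(inst$context)) {
      km[2, ] <- concept_vector(inst$context$concept_id, corpus$type_map,
                                kg_model)
    }
    km[3, ] <- concept_vector(inst$molB$concept_id, corpus$type_map,
                              kg_model)
    inst$knowledge_matrix <- km
    inst
  })
  corpus
}

STANDOFF_PATTERNS <- list(
  list(words = c("GENA", "enhances", "GENB", "expression", "."),
       trig = c(tok = 2L, type = "Positive_regulation"),
       nesting = character(), sign = "+"),
  list(words = c("GENA", "inhibits", "GENB", "strongly", "."),
       trig = c(tok = 2L, type = "Negative_regulation"),
       nesting = character(), sign = "-"),
  list(words = c("GENA", "regulates", "GENB", "levels", "."),
       trig = c(tok = 2L, type = "Regulation"),
       nesting = character(), sign = "0"),
  list(words = c("GENA", "binds", "GENB", "directly", "."),
       trig = c(tok = 2L, type = "Binding"),
       nesting = character(), sign = "bind"),
  # depth 2: Neg_reg(Cause = A, Theme = Pos_reg(Theme = B)) -> minus
  list(words = c("GENA", "blocks", "the", "activation", "of", "GENB", "."),
       trig = c(tok = 2L, type = "Negative_regulation"),
       nesting = c(tok = 4L, type = "Positive_regulation"), sign = "-"),
  # depth 2: Neg_reg(Cause = A, Theme = Neg_reg(Theme = B)) -> plus
  list(words = c("GENA", "blocks", "the", "inhibition", "of", "GENB", "."),
       trig = c(tok = 2L, type = "Negative_regulation"),
       nesting = c(tok = 4L, type = "Negative_regulation"), sign = "+"),
  # depth 3: Pos(Cause = A, Theme = Neg(Theme = Neg(Theme = B))) -> plus
  list(words = c("GENA", "promotes", "suppression", "of", "inhibition",
                 "of", "GENB", "."),
       trig = c(tok = 2L, type = "Positive_regulation"),
       nesting = c(tok = 3L, type = "Negative_regulation",
                   tok2 = 5L, type2 = "Negative_regulation"),
       sign = "+")
)

#' Generate BioNLP-ST standoff fixtures with nested events
#'
#' Emits text/.a1/.a2 layer triples containing flat and nested (depth up to
#' 3) regulation events and Binding events with known flattened gold
#' relations: running [parse_standoff()] and [decompose_events()] on the
#' output recovers the golds exactly.
#'
#' @param n_docs Number of documents (>= 1).
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, writes
#'   `doc-<i>.txt/.a1/.a2` files.
#' @return A list of documents, each with `doc_id`, `txt`, `a1`, `a2`
#'   (character vectors of lines) and `gold` (data.frame cause/theme/sign
#'   with T# ids).
#' @export
gen_standoff <- function(n_docs = 5, seed = 1, out_dir = NULL) {
  stopifnot(n_docs >= 1)
  gene_pool <- sprintf("PROT%s", LETTERS[1:10])
  docs <- with_seed(seed, {
    lapply(seq_len(n_docs), function(d) {
      pat <- STANDOFF_PATTERNS[[(d - 1L) %% length(STANDOFF_PATTERNS) + 1L]]
      gn <- sample(gene_pool, 2)
      words <- pat$words
      words[words == "GENA"] <- gn[1]
      words[words == "GENB"] <- gn[2]
      starts <- cumsum(c(0L, nchar(head(words, -1)) + 1L))
      ends <- starts + nchar(words)
      txt <- paste(words, collapse = " ")
      a_tok <- which(words == gn[1])[1]
      b_tok <- which(words == gn[2])[1]
      ents <- data.frame(
        id = c("T1", "T2"), type = "Gene_or_gene_product",
        start = c(starts[a_tok], starts[b_tok]),
        end = c(ends[a_tok], ends[b_tok]),
        surface = c(gn[1], gn[2]), stringsAsFactors = FALSE)
      trig_tok <- as.integer(pat$trig["tok"])
      tid <- 3L
      ents <- rbind(ents, data.frame(
        id = paste0("T", tid), type = unname(pat$trig["type"]),
        start = starts[trig_tok], end = ends[trig_tok],
        surface = words[trig_tok], stringsAsFactors = FALSE))
      events <- list()
      if (pat$trig["type"] == "Binding") {
        events$E1 <- list(id = "E1", type = "Binding", trigger = "T3",
                          args = c(Theme = "T1", Theme2 = "T2"))
      } else if (length(pat$nesting) == 0) {
        events$E1 <- list(id = "E1", type = unname(pat$trig["type"]),
                          trigger = "T3",
                          args = c(Cause = "T1", Theme = "T2"))
      } else if (!("tok2" %in% names(pat$nesting))) {
        ntok <- as.integer(pat$nesting["tok"])
        ents <- rbind(ents, data.frame(
          id = "T4", type = unname(pat$nesting["type"]),
          start = starts[ntok], end = ends[ntok], surface = words[ntok],
          stringsAsFactors = FALSE))
        events$E1 <- list(id = "E1", type = unname(pat$nesting["type"]),
                          trigger = "T4", args = c(Theme = "T2"))
        events$E2 <- list(id = "E2", type = unname(pat$trig["type"]),
                          trigger = "T3",
                          args = c(Cause = "T1", Theme = "E1"))
      } else {
        n1 <- as.integer(pat$nesting["tok"])
        n2 <- as.integer(pat$nesting["tok2"])
        ents <- rbind(ents,
          data.frame(id = "T4", type = unname(pat$nesting["type"]),
                     start = starts[n1], end = ends[n1],
                     surface = words[n1], stringsAsFactors = FALSE),
          data.frame(id = "T5", type = unname(pat$nesting["type2"]),
                     start = starts[n2], end = ends[n2],
                     surface = words[n2], stringsAsFactors = FALSE))
        events$E1 <- list(id = "E1", type = unname(pat$nesting["type2"]),
                          trigger = "T5", args = c(Theme = "T2"))
        events$E2 <- list(id = "E2", type = unname(pat$nesting["type"]),
                          trigger = "T4", args = c(Theme = "E1"))
        events$E3 <- list(id = "E3", type = unname(pat$trig["type"]),
                          trigger = "T3",
                          args = c(Cause = "T1", Theme = "E2"))
      }
      layers <- write_standoff(list(entities = ents, events = events))
      gold <- if (pat$sign == "bind") {
        data.frame(cause = "T1", theme = "T2", sign = "bind",
                   stringsAsFactors = FALSE)
      } else {
        data.frame(cause = "T1", theme = "T2", sign = pat$sign,
                   stringsAsFactors = FALSE)
      }
      list(doc_id = sprintf("doc-%03d", d), txt = txt, a1 = layers$a1,
           a2 = layers$a2, gold = gold)
    })
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (doc in docs) {
      writeLines(doc$txt, file.path(out_dir, paste0(doc$doc_id, ".txt")))
      writeLines(doc$a1, file.path(out_dir, paste0(doc$doc_id, ".a1")))
      writeLines(doc$a2, file.path(out_dir, paste0(doc$doc_id, ".a2")))
    }
  }
  docs
}
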