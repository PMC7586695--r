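# Conversion of BioNLP-ST standoff event annotations into 8-class relation
# instances: standoff parsing, nested-event decomposition by sign
# composition, trigger-to-class and direction mapping, entity tagging, and
# negative-instance sampling. The decomposition and trigger-mapping rules
# ship as an editable configuration (default_event_rules) so alternative
# rule tables can be dropped in.

#' Default event decomposition rules
#'
#' Maps regulation trigger types to signs (+1, -1, 0) and names the binding
#' type. Nesting composes signs multiplicatively; Regulation's 0 absorbs.
#'
#' @return A list with `signs` (named numeric) and `binding_types`.
#' @export
default_event_rules <- function() {
  list(signs = c(Positive_regulation = 1, Negative_regulation = -1,
                 Regulation = 0),
       binding_types = "Binding")
}

#' Parse BioNLP-ST standoff files
#'
#' Reads the text, entity (.a1) and event (.a2) layers. Entity/trigger lines
#' are `T# <TAB> Type start end <TAB> surface`; event lines are
#' `E# <TAB> Type:T# Role1:Ref1 Role2:Ref2 ...` where refs are T# or E#.
#' All references must resolve and every span must reproduce its surface
#' from the text.
#'
#' @param txt Document text (single string).
#' @param a1 Entity layer: character vector of lines (or single string).
#' @param a2 Event/trigger layer: character vector of lines (or single
#'   string; may be empty).
#' @return A list with `entities` (data.frame: id, type, start, end,
#'   surface; offsets 0-based half-open as in the standoff convention) and
#'   `events` (named list: each has `id`, `type`, `trigger`, `args` —
#'   a named character vector of role -> reference).
#' @export
parse_standoff <- function(txt, a1, a2 = character()) {
  split_lines <- function(x) {
    if (length(x) == 1 && grepl("\n", x)) x <- strsplit(x, "\n")[[1]]
    x[nzchar(trimws(x))]
  }
  a1 <- split_lines(a1); a2 <- split_lines(a2)

  parse_t <- function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed entity line: ", line)
    mid <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    data.frame(id = parts[1], type = mid[1],
               start = as.integer(mid[2]), end = as.integer(mid[3]),
               surface = parts[3], stringsAsFactors = FALSE)
  }
  t_lines <- c(a1[startsWith(a1, "T")], a2[startsWith(a2, "T")])
  entities <- if (length(t_lines))
    do.call(rbind, lapply(t_lines, parse_t))
  else data.frame(id = character(), type = character(), start = integer(),
                  end = integer(), surface = character(),
                  stringsAsFactors = FALSE)

  for (i in seq_len(nrow(entities))) {
    span_text <- substr(txt, entities$start[i] + 1, entities$end[i])
    if (span_text != entities$surface[i]) {
      stop(sprintf("span/surface mismatch for %s: span '%s' vs surface '%s'",
                   entities$id[i], span_text, entities$surface[i]))
    }
  }

  e_lines <- a2[startsWith(a2, "E")]
  events <- list()
  for (line in e_lines) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed event line: ", line)
    toks <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    kv <- strsplit(toks, ":", fixed = TRUE)
    roles <- vapply(kv, `[`, "", 1)
    refs <- vapply(kv, `[`, "", 2)
    events[[parts[1]]] <- list(id = parts[1], type = roles[1],
                               trigger = refs[1],
                               args = setNames(refs[-1], roles[-1]))
  }

  known <- c(entities$id, names(events))
  for (ev in events) {
    refs <- c(ev$trigger, unname(ev$args))
    bad <- setdiff(refs, known)
    if (length(bad)) stop("unresolved ", paste(bad, collapse = ", "))
  }
  list(entities = entities, events = events)
}

#' Write standoff layers
#'
#' Inverse of [parse_standoff()]; used by the fixture generator.
#'
#' @param parsed A list with `entities` and `events` as from
#'   [parse_standoff()].
#' @return A list with `a1` and `a2` character vectors of lines (triggers —
#'   entities referenced as event triggers — go to a2, the rest to a1).
#' @export
write_standoff <- function(parsed) {
  ents <- parsed$entities
  trig_ids <- unique(vapply(parsed$events, function(e) e$trigger, ""))
  fmt_t <- function(i) sprintf("%s\t%s %d %d\t%s", ents$id[i], ents$type[i],
                               ents$start[i], ents$end[i], ents$surface[i])
  a1 <- vapply(which(!(ents$id %in% trig_ids)), fmt_t, "")
  a2_t <- vapply(which(ents$id %in% trig_ids), fmt_t, "")
  a2_e <- vapply(parsed$events, function(e) {
    args <- if (length(e$args))
      paste(" ", paste(names(e$args), unname(e$args), sep = ":",
                       collapse = " "), sep = "")
    else ""
    sprintf("%s\t%s:%s%s", e$id, e$type, e$trigger, args)
  }, "")
  list(a1 = unname(a1), a2 = unname(c(a2_t, a2_e)))
}

# follow a reference down Theme chains to a physical entity, composing signs
resolve_to_entity <- function(ref, events, rules, visiting = character()) {
  if (!startsWith(ref, "E")) return(list(entity = ref, sign = 1))
  if (ref %in% visiting) stop("event cycle involving ", ref)
  ev <- events[[ref]]
  sg <- rules$signs[ev$type]
  if (is.na(sg)) {
    # non-regulation event (e.g. Binding) as an argument: descend through
    # its first Theme without a sign contribution
    sg <- 1
  }
  theme <- ev$args[names(ev$args) == "Theme"]
  if (length(theme) == 0) stop("event ", ref, " has no Theme to resolve")
  inner <- resolve_to_entity(unname(theme[1]), events, rules,
                             c(visiting, ref))
  list(entity = inner$entity, sign = sg * inner$sign)
}

#' Flatten nested events into signed binary relations
#'
#' Regulation events contribute their sign (+ for positive regulation, - for
#' negative, 0 for plain regulation); nesting composes signs
#' multiplicatively (so negative regulation of a negative regulation is an
#' increase) and 0 absorbs. The Theme chain is followed to its innermost
#' physical entity; a Cause that is itself an event is resolved the same
#' way, composing its signs too. Binding events yield one `bind` record per
#' unordered Theme pair. Regulation events with no Cause only matter as
#' nested Themes; on their own they yield no binary relation.
#'
#' @param events Named event list from [parse_standoff()].
#' @param rules Rule configuration, see [default_event_rules()].
#' @return Data.frame with columns `cause`, `theme` (entity T# ids) and
#'   `sign` (one of "+", "-", "0", "bind").
#' @export
decompose_events <- function(events, rules = default_event_rules()) {
  out <- list()
  sign_chr <- function(s) if (s > 0) "+" else if (s < 0) "-" else "0"
  for (ev in events) {
    if (ev$type %in% rules$binding_types) {
      themes <- unname(ev$args[startsWith(names(ev$args), "Theme")])
      themes <- vapply(themes, function(r)
        resolve_to_entity(r, events, rules)$entity, "")
      if (length(themes) >= 2) {
        cmb <- utils::combn(themes, 2)
        for (k in seq_len(ncol(cmb))) {
          out[[length(out) + 1L]] <- data.frame(
            cause = cmb[1, k], theme = cmb[2, k], sign = "bind",
            stringsAsFactors = FALSE)
        }
      }
      next
    }
    sg0 <- rules$signs[ev$type]
    if (is.na(sg0)) next
    cause <- ev$args[names(ev$args) == "Cause"]
    if (length(cause) == 0) next  # no Cause and no enclosing handling here
    theme <- ev$args[names(ev$args) == "Theme"]
    if (length(theme) == 0) next
    th <- resolve_to_entity(unname(theme[1]), events, rules)
    ca <- resolve_to_entity(unname(cause[1]), events, rules)
    out[[length(out) + 1L]] <- data.frame(
      cause = ca$entity, theme = th$entity,
      sign = sign_chr(sg0 * th$sign * ca$sign), stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(cause = character(), theme = character(),
                      sign = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Map a signed relation to its class label
#'
#' `+` -> Increase, `-` -> Decrease, `0` -> Regulate, `bind` -> Binding.
#' Directed classes get `-forward` when the cause mention precedes the theme
#' mention in token order, `-backward` otherwise; Binding is undirected.
#'
#' @param sign One of "+", "-", "0", "bind".
#' @param cause_pos,theme_pos Token start positions of the cause and theme
#'   mentions in the same sentence.
#' @return A class label from [relation_classes()].
#' @export
to_label <- function(sign, cause_pos, theme_pos) {
  if (sign == "bind") return("Binding")
  base <- switch(sign, "+" = "Increase", "-" = "Decrease", "0" = "Regulate",
                 stop("unknown sign: ", sign))
  dir <- if (cause_pos < theme_pos) "forward" else "backward"
  paste0(base, "-", dir)
}

PAD_TOKEN <- "<pad>"
MIN_INSTANCE_TOKENS <- 23L

#' Build a relation instance
#'
#' Applies entity tagging (the mention tokens of the two molecules and the
#' optional context are replaced by the role placeholders `<mol_a>`,
#' `<mol_b>`, `<context>`), pads the token list to at least 23 tokens with
#' the reserved pad token (so the longest linguistic filter always fits),
#' and stacks the 3 x m knowledge matrix with rows (molA, context-or-zeros,
#' molB) from the semantic-type embeddings.
#'
#' @param tokens Normalized sentence tokens.
#' @param molA,molB Mention rows (1-row data.frames with `start`, `end`,
#'   `concept_id`) as from [recognize_entities()]; must not overlap.
#' @param context Optional context mention (or NULL for a context-free
#'   instance).
#' @param label Class label.
#' @param kg_model Optional `kg_model`; NULL gives a zero knowledge matrix.
#' @param type_map Named map concept_id -> semantic type (for
#'   [concept_vector()]).
#' @param knowledge_dependent Flag carried through from the generator.
#' @return A `relation_instance` list.
#' @export
build_instance <- function(tokens, molA, molB, context = NULL, label,
                           kg_model = NULL, type_map = NULL,
                           knowledge_dependent = FALSE) {
  spans <- list(mol_a = molA, mol_b = molB)
  if (!is.null(context)) spans$context <- context
  sm <- t(vapply(spans, function(s) c(s$start, s$end), numeric(2)))
  ord <- order(sm[, 1])
  for (i in seq_len(nrow(sm) - 1)) {
    if (sm[ord[i + 1], 1] < sm[ord[i], 2]) stop("overlapping mentions")
  }
  # replace spans right-to-left so earlier indices stay valid
  tagged <- tokens
  for (i in rev(ord)) {
    nm <- rownames(sm)[i]
    tagged <- append(tagged[-(sm[i, 1]:(sm[i, 2] - 1))],
                     paste0("<", nm, ">"), after = sm[i, 1] - 1)
  }
  if (length(tagged) < MIN_INSTANCE_TOKENS) {
    tagged <- c(tagged, rep(PAD_TOKEN, MIN_INSTANCE_TOKENS - length(tagged)))
  }
  m <- if (is.null(kg_model)) 10L else kg_model$m
  km <- matrix(0, 3, m)
  if (!is.null(kg_model) && !is.null(type_map)) {
    km[1, ] <- concept_vector(molA$concept_id, type_map, kg_model)
    if (!is.null(context)) {
      km[2, ] <- concept_vector(context$concept_id, type_map, kg_model)
    }
    km[3, ] <- concept_vector(molB$concept_id, type_map, kg_model)
  }
  structure(list(tokens = tagged, label = label,
                 molA = molA, molB = molB, context = context,
                 knowledge_matrix = km,
                 corpus_kind = if (is.null(context)) "context-free"
                               else "context-specific",
                 knowledge_dependent = knowledge_dependent),
            class = "relation_instance")
}

#' @export
print.relation_instance <- function(x, ...) {
  cat(sprintf("<relation_instance label=%s kind=%s tokens=%d>\n",
              x$label, x$corpus_kind, length(x$tokens)))
  invisible(x)
}

#' Sample negative (False) relation instances
#'
#' Enumerates molecule pairs (with each available context, or no context for
#' context-free corpora) that co-occur in a sentence but are not annotated,
#' and samples them without replacement as False instances.
#'
#' @param sentences List of lists, each with `tokens` and `mentions` (a
#'   role-assigned mention data.frame).
#' @param annotated_keys Character vector of keys
#'   `"<sent>|<cidA>|<cidB>|<ctx>"` (ctx empty when absent) already
#'   annotated; both molecule orders are checked.
#' @param ratio Number of negatives to sample, as a fraction of the number
#'   of candidates (ratio >= 1 keeps all).
#' @param seed Integer seed for the sample.
#' @param kg_model,type_map Passed to [build_instance()].
#' @param context_specific Enumerate (pair, context) tuples instead of bare
#'   pairs.
#' @return List of `relation_instance` objects with label "False".
#' @export
make_negatives <- function(sentences, annotated_keys = character(),
                           ratio = 1, seed = 1, kg_model = NULL,
                           type_map = NULL, context_specific = TRUE) {
  if (ratio <= 0) return(list())
  cands <- list()
  for (si in seq_along(sentences)) {
    sent <- sentences[[si]]
    men <- sent$mentions
    mols <- which(men$role == "molecule")
    ctxs <- which(men$role == "context")
    if (length(mols) < 2) next
    cmb <- utils::combn(mols, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      ctx_set <- if (context_specific && length(ctxs)) ctxs else NA_integer_
      for (cx in ctx_set) {
        ctx_id <- if (is.na(cx)) "" else men$concept_id[cx]
        k1 <- paste(si, men$concept_id[a], men$concept_id[b], ctx_id,
                    sep = "|")
        k2 <- paste(si, men$concept_id[b], men$concept_id[a], ctx_id,
                    sep = "|")
        if (k1 %in% annotated_keys || k2 %in% annotated_keys) next
        cands[[length(cands) + 1L]] <- list(si = si, a = a, b = b, cx = cx)
      }
    }
  }
  if (length(cands) == 0) return(list())
  n_take <- min(length(cands), ceiling(ratio * length(cands)))
  take <- with_seed(seed, sample.int(length(cands), n_take))
  lapply(sort(take), function(i) {
    cd <- cands[[i]]
    sent <- sentences[[cd$si]]
    men <- sent$mentions
    build_instance(sent$tokens, men[cd$a, ], men[cd$b, ],
                   if (is.na(cd$cx)) NULL else men[cd$cx, ],
                   label = "False", kg_model = kg_model, type_map = type_map)
  })
}

#' Serialize relation instances as JSON lines
#' @param instances List of `relation_instance` objects.
#' @param path Output path.
#' @export
write_instances_jsonl <- function(instances, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (inst in instances) {
    rec <- list(tokens = inst$tokens, label = inst$label,
                corpus_kind = inst$corpus_kind,
                knowledge_matrix = inst$knowledge_matrix)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
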