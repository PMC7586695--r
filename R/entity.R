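# Dictionary entity recognition and role assignment. The NER backend is
# pluggable; the shipped backend is greedy leftmost-longest gazetteer match
# over normalized surfaces, with exact-match concept normalization from a
# pre-disambiguated lexicon.

#' Load an entity lexicon
#'
#' Reads a tab-separated lexicon with columns `surface`, `concept_id`,
#' `semantic_type`, `semantic_group`. Surfaces must be in normalized form
#' (lowercase, spared punctuation separated) and pre-disambiguated: a surface
#' mapped to more than one concept is a loader error, because exact-match
#' normalization must yield a single concept.
#'
#' @param path Path to the TSV file, or a data.frame with the same columns.
#' @return A validated lexicon data.frame.
#' @export
read_lexicon <- function(path) {
  lex <- if (is.data.frame(path)) path else
    read.delim(path, header = TRUE, sep = "\t", quote = "",
               stringsAsFactors = FALSE)
  need <- c("surface", "concept_id", "semantic_type", "semantic_group")
  if (!all(need %in% names(lex))) {
    stop("lexicon must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!nzchar(lex$concept_id))) stop("empty concept_id in lexicon")
  dup <- tapply(lex$concept_id, lex$surface, function(x) length(unique(x)))
  if (any(dup > 1)) {
    stop("ambiguous lexicon surface(s): ",
         paste(names(dup)[dup > 1], collapse = ", "),
         " (one concept_id per surface required)")
  }
  lex[!duplicated(lex$surface), , drop = FALSE]
}

#' Recognize entity mentions by dictionary lookup
#'
#' Greedy leftmost-longest matching over the token sequence: at each
#' position the longest lexicon surface (as a space-joined token n-gram)
#' wins, scanning resumes after the match, so matched spans never overlap.
#'
#' @param tokens Character vector of normalized tokens.
#' @param lexicon A lexicon from [read_lexicon()].
#' @return A data.frame of mentions with columns `start`, `end` (half-open,
#'   1-based token indices, end exclusive), `surface`, `concept_id`,
#'   `semantic_type`, `semantic_group`, `role` (NA; see [assign_roles()]),
#'   sorted by `start`.
#' @export
recognize_entities <- function(tokens, lexicon) {
  empty <- data.frame(start = integer(), end = integer(),
                      surface = character(), concept_id = character(),
                      semantic_type = character(), semantic_group = character(),
                      role = character(), stringsAsFactors = FALSE)
  if (length(tokens) == 0 || nrow(lexicon) == 0) return(empty)
  max_len <- max(lengths(strsplit(lexicon$surface, " ", fixed = TRUE)))
  idx <- setNames(seq_len(nrow(lexicon)), lexicon$surface)
  n <- length(tokens)
  rows <- list()
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      j <- idx[key]
      if (!is.na(j)) { hit <- j; hit_len <- len; break }
    }
    if (hit > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = i, end = i + hit_len,
        surface = lexicon$surface[hit],
        concept_id = lexicon$concept_id[hit],
        semantic_type = lexicon$semantic_type[hit],
        semantic_group = lexicon$semantic_group[hit],
        role = NA_character_, stringsAsFactors = FALSE)
      i <- i + hit_len
    } else {
      i <- i + 1L
    }
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Assign molecule/context roles by semantic group filtering
#'
#' A mention is a molecule if its semantic group is GENE or CHEM, or if its
#' semantic type is `celc` (cell component; included to cover protein
#' complexes). It is a context if its group is DISO and its type is not
#' `fndg` (findings name the diagnosis, not the disease, and are excluded).
#' Mentions matching neither rule are dropped; an unknown semantic group is
#' dropped with a warning.
#'
#' @param mentions Mentions from [recognize_entities()].
#' @return The surviving mentions with `role` set to "molecule" or "context".
#' @export
assign_roles <- function(mentions) {
  if (nrow(mentions) == 0) return(mentions)
  known <- c("GENE", "CHEM", "ANAT", "DISO", "OTHER")
  unknown <- !(mentions$semantic_group %in% known)
  if (any(unknown)) {
    warning("dropping mention(s) with unknown semantic group: ",
            paste(unique(mentions$semantic_group[unknown]), collapse = ", "))
  }
  role <- rep(NA_character_, nrow(mentions))
  mol <- !unknown &
    (mentions$semantic_group %in% c("GENE", "CHEM") |
       mentions$semantic_type == "celc")
  ctx <- !unknown & !mol &
    mentions$semantic_group == "DISO" & mentions$semantic_type != "fndg"
  role[mol] <- "molecule"
  role[ctx] <- "context"
  mentions$role <- role
  mentions[!is.na(role), , drop = FALSE]
}
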