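# Text preprocessing: sentence splitting on raw text (capitalization cues are
# needed, so splitting precedes lowercasing), then normalization and
# whitespace tokenization.

# punctuation spared from deletion and separated into standalone tokens:
# parentheses, comma, slash, hyphen, exclamation mark, question mark,
# quotation mark
SPARED_MARKS <- c("(", ")", ",", "/", "-", "!", "?", "\"")

DEFAULT_ABBREVIATIONS <- c(
  "e.g.", "i.e.", "al.", "fig.", "figs.", "cf.", "vs.", "ca.",
  "dr.", "no.", "approx.", "resp."
)

#' Split a document into sentences
#'
#' Rule-based sentence splitter: a boundary is a terminator (`.`, `!`, `?`)
#' followed by whitespace and a character that is not a lowercase letter.
#' Decimal points and abbreviation periods (guard list) are not boundaries.
#' Splitting runs on the raw text, before any lowercasing, so that
#' capitalization evidence is preserved.
#'
#' @param text Raw document text (single string).
#' @param doc_id Document identifier carried into the output.
#' @param abbreviations Character vector of abbreviation strings (compared
#'   case-insensitively) whose trailing period never ends a sentence.
#' @return A data.frame with columns `doc_id`, `index` (0-based), `raw`
#'   (the sentence substring), `start`, `end` (half-open, 1-based character
#'   offsets into `text`, end exclusive).
#' @export
split_sentences <- function(text, doc_id = "doc",
                            abbreviations = DEFAULT_ABBREVIATIONS) {
  stopifnot(is.character(text), length(text) == 1)
  empty <- data.frame(doc_id = character(), index = integer(),
                      raw = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (!nzchar(trimws(text))) return(empty)

  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  abbrev <- tolower(abbreviations)

  is_boundary <- logical(n)
  for (i in seq_len(n)) {
    if (!chars[i] %in% c(".", "!", "?")) next
    if (i == n) { is_boundary[i] <- TRUE; next }
    if (!grepl("^\\s$", chars[i + 1])) next   # decimals, abbrev-internal dots
    # first non-space character after the terminator
    j <- i + 1
    while (j <= n && grepl("^\\s$", chars[j])) j <- j + 1
    if (j <= n && grepl("^[a-z]$", chars[j])) next
    if (chars[i] == ".") {
      # abbreviation guard: word ending at i (including the period)
      k <- i - 1
      while (k >= 1 && !grepl("^\\s$", chars[k])) k <- k - 1
      word <- tolower(paste(chars[(k + 1):i], collapse = ""))
      if (word %in% abbrev) next
    }
    is_boundary[i] <- TRUE
  }
  if (!any(is_boundary)) is_boundary[n] <- TRUE
  if (!is_boundary[n]) is_boundary[n] <- TRUE  # trailing text forms a sentence

  bounds <- which(is_boundary)
  out <- empty
  seg_start <- 1L
  idx <- 0L
  for (b in bounds) {
    s <- seg_start
    while (s <= b && grepl("^\\s$", chars[s])) s <- s + 1L
    e <- b
    while (e >= s && grepl("^\\s$", chars[e])) e <- e - 1L
    if (s <= e) {
      raw <- paste(chars[s:e], collapse = "")
      out <- rbind(out, data.frame(doc_id = doc_id, index = idx, raw = raw,
                                   start = s, end = e + 1L,
                                   stringsAsFactors = FALSE))
      idx <- idx + 1L
    }
    seg_start <- b + 1L
  }
  out
}

#' Normalize a sentence
#'
#' Lowercases, removes characters other than `[a-z0-9']`, whitespace, the
#' spared punctuation set and the period, pads each spared mark with spaces
#' so it becomes a standalone token, and (optionally) separates a
#' sentence-final period into its own token. Idempotent.
#'
#' @param x Character vector of raw sentence strings.
#' @param keep_final_period Keep a trailing period as its own token (periods
#'   elsewhere stay attached, preserving decimals and abbreviations).
#' @return Normalized string(s).
#' @export
normalize_text <- function(x, keep_final_period = TRUE) {
  vapply(x, function(s) {
    s <- tolower(s)
    s <- gsub("[^a-z0-9'[:space:]().,/!?\"-]", "", s)
    for (m in SPARED_MARKS) {
      s <- gsub(m, paste0(" ", m, " "), s, fixed = TRUE)
    }
    s <- gsub("[[:space:]]+", " ", s)
    s <- trimws(s)
    if (keep_final_period) {
      # expose the final period as a token; "x ." is already in that form
      s <- sub("(?<![ .])\\.$", " .", s, perl = TRUE)
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Tokenize a normalized string
#'
#' Whitespace split; the inverse of [detokenize()] on normalized input.
#'
#' @param x A normalized string.
#' @return Character vector of tokens (empty for empty input).
#' @export
tokenize <- function(x) {
  stopifnot(length(x) == 1)
  if (!nzchar(x)) return(character())
  strsplit(trimws(x), "[[:space:]]+")[[1]]
}

#' Join tokens back into a normalized string
#' @param tokens Character vector of tokens.
#' @return Single string with tokens joined by single spaces.
#' @export
detokenize <- function(tokens) paste(tokens, collapse = " ")

#' Split, normalize and tokenize a document
#'
#' @inheritParams split_sentences
#' @param keep_final_period See [normalize_text()].
#' @return A data.frame as from [split_sentences()] with extra columns
#'   `normalized` and `tokens` (list column).
#' @export
prepare_document <- function(text, doc_id = "doc",
                             abbreviations = DEFAULT_ABBREVIATIONS,
                             keep_final_period = TRUE) {
  sents <- split_sentences(text, doc_id, abbreviations)
  sents$normalized <- normalize_text(sents$raw, keep_final_period)
  sents$tokens <- I(lapply(sents$normalized, tokenize))
  sents
}

#' Read title and abstract text from a PubMed-style XML file
#'
#' Extracts `<ArticleTitle>` and `<AbstractText>` nodes only and joins them
#' with a space into one document string per article.
#'
#' @param path Path to an XML file.
#' @return A data.frame with columns `doc_id` (PMID when present, else a
#'   running number) and `text`.
#' @export
read_pubmed_xml <- function(path) {
  doc <- xml2::read_xml(path)
  articles <- xml2::xml_find_all(doc, ".//PubmedArticle")
  if (length(articles) == 0) articles <- xml2::xml_find_all(doc, ".//Article")
  if (length(articles) == 0) articles <- list(doc)
  out <- lapply(seq_along(articles), function(i) {
    a <- articles[[i]]
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abst <- paste(xml2::xml_text(xml2::xml_find_all(a, ".//AbstractText")),
                  collapse = " ")
    id <- if (!is.na(pmid) && nzchar(pmid)) pmid else as.character(i)
    data.frame(doc_id = id,
               text = trimws(paste(ifelse(is.na(title), "", title), abst)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write sentences as JSON lines
#'
#' One JSON object per sentence with `doc_id`, `index`, `tokens` and
#' `char_span`.
#'
#' @param sentences Output of [prepare_document()].
#' @param path Output file path.
#' @export
write_sentences_jsonl <- function(sentences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(sentences))) {
    rec <- list(doc_id = sentences$doc_id[i],
                index = sentences$index[i],
                tokens = sentences$tokens[[i]],
                char_span = c(sentences$start[i], sentences$end[i]))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}
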