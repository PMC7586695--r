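# Post-processing of predicted context-specific relations: group by the
# (context, moleculeA, moleculeB) concept-ID triple, discard rare groups by
# a top-quantile frequency threshold, and resolve class conflicts within a
# group by majority voting with tie abstraction (Increase vs Decrease with
# one direction abstracts to Regulate with that direction; contradictory
# directions abstract to Binding).

#' Frequency threshold at a top quantile
#'
#' Returns the largest support value v such that the fraction of keys with
#' support >= v is at least q; keys below the threshold are discarded by
#' [aggregate_relations()]. With q = 0.01 this keeps (at least) the top 1%
#' of the support distribution.
#'
#' @param counts Named or unnamed numeric vector of per-key supports.
#' @param q Quantile in (0, 1).
#' @return The threshold support (scalar).
#' @export
frequency_threshold <- function(counts, q = 0.01) {
  if (length(counts) == 0) stop("empty counts")
  stopifnot(q > 0, q < 1)
  vals <- sort(unique(as.numeric(counts)), decreasing = TRUE)
  for (v in vals) {
    if (mean(counts >= v) >= q) return(v)
  }
  min(vals)
}

label_parts <- function(label) {
  if (label == "Binding") return(list(base = "Binding", dir = NA_character_))
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  list(base = parts[1], dir = parts[2])
}

#' Resolve a multiset of relation classes by voting
#'
#' A strict majority class wins. Ties are resolved by abstraction:
#' Binding among the tied classes (or tied classes with contradictory
#' directions) gives Binding; tied classes sharing a direction but
#' differing in sign (Increase/Decrease, or a signed class with Regulate)
#' abstract to Regulate with that direction. Multi-way ties apply the same
#' rules (direction check first, then sign), terminating at Binding.
#'
#' @param labels Character vector (multiset) of non-False class labels.
#' @return The final class label.
#' @export
vote <- function(labels) {
  if (length(labels) == 0) stop("empty label multiset")
  stopifnot(all(labels %in% setdiff(relation_classes(), "False")))
  tab <- table(labels)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1) return(top)
  if ("Binding" %in% top) return("Binding")
  parts <- lapply(top, label_parts)
  dirs <- unique(vapply(parts, `[[`, "", "dir"))
  if (length(dirs) > 1) return("Binding")  # contradictory directions
  paste0("Regulate", "-", dirs)            # same direction, signs differ
}

#' Aggregate predicted relations into an extracted-relation table
#'
#' Groups predictions by the concept-ID triple (context, molA, molB) —
#' molecule IDs are sorted within Binding predictions, since Binding is
#' symmetric, while directed classes keep their order — computes supports,
#' applies the frequency threshold, and votes within each surviving group.
#'
#' @param relations Data.frame with columns `context_id`, `molA_id`,
#'   `molB_id`, `label` (non-False classes).
#' @param q Frequency quantile (see [frequency_threshold()]).
#' @param min_support Optional absolute support override; when given it
#'   replaces the quantile-derived threshold.
#' @return Data.frame `context_id`, `molA_id`, `molB_id`, `label`,
#'   `support`, sorted by support descending.
#' @export
aggregate_relations <- function(relations, q = 0.01, min_support = NULL) {
  empty <- data.frame(context_id = character(), molA_id = character(),
                      molB_id = character(), label = character(),
                      support = integer(), stringsAsFactors = FALSE)
  if (is.null(relations) || nrow(relations) == 0) return(empty)
  stopifnot(all(relations$label %in% setdiff(relation_classes(), "False")))
  a <- relations$molA_id
  b <- relations$molB_id
  swap <- relations$label == "Binding" & a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(relations$context_id, a, b, sep = "\r")
  counts <- table(key)
  thr <- if (!is.null(min_support)) min_support
         else frequency_threshold(as.numeric(counts), q)
  keep_keys <- names(counts)[counts >= thr]
  if (length(keep_keys) == 0) return(empty)
  out <- lapply(keep_keys, function(k) {
    rows <- which(key == k)
    ids <- strsplit(k, "\r", fixed = TRUE)[[1]]
    data.frame(context_id = ids[1], molA_id = ids[2], molB_id = ids[3],
               label = vote(relations$label[rows]),
               support = length(rows), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(-out$support, out$context_id, out$molA_id, out$molB_id), ,
      drop = FALSE]
}

#' Write extracted relations as TSV
#' @param extracted Output of [aggregate_relations()].
#' @param path Output path.
#' @export
write_relations_tsv <- function(extracted, path) {
  write.table(extracted, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
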