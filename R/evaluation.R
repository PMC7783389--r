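#' Precision, recall and F1 from TP/FP/FN counts
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = harmonic mean
#' 2PR/(P+R).  Any metric with a zero denominator is defined as 0.
#'
#' @param tp,fp,fn Non-negative counts (or a list/data.frame with those
#'   fields passed as \code{tp}).
#' @return Named numeric vector \code{c(precision, recall, f1)}.
#' @export
prf <- function(tp, fp = NULL, fn = NULL) {
  if (is.list(tp)) { fp <- tp$fp; fn <- tp$fn; tp <- tp$tp }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(precision = p, recall = r, f1 = f1_score(p, r))
}

#' @rdname prf
#' @param precision,recall Metric values in [0, 1].
#' @return \code{f1_score}: the harmonic mean, 0 when both inputs are 0.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Assemble a metrics report from per-label values or counts
#'
#' The macro row is always the unweighted arithmetic mean of the per-label
#' columns, including the O class when present.
#'
#' @param per_label Data frame with rownames = labels and columns
#'   \code{precision}, \code{recall}, \code{f1} (and optionally count
#'   columns \code{tp}, \code{fp}, \code{fn}).
#' @return Object of class \code{ner_metrics}: list with \code{per_label},
#'   \code{macro} (named numeric) and \code{counts} (NULL if absent).
#' @export
metrics_report <- function(per_label) {
  stopifnot(all(c("precision", "recall", "f1") %in% names(per_label)))
  macro <- c(precision = mean(per_label$precision),
             recall = mean(per_label$recall),
             f1 = mean(per_label$f1))
  counts <- if (all(c("tp", "fp", "fn") %in% names(per_label))) {
    per_label[, c("tp", "fp", "fn")]
  }
  structure(list(per_label = per_label, macro = macro, counts = counts),
            class = "ner_metrics")
}

#' @export
print.ner_metrics <- function(x, digits = 4L, ...) {
  tab <- rbind(round(x$per_label[, c("precision", "recall", "f1")], digits),
               Avg = round(x$macro, digits))
  print(tab)
  invisible(x)
}

#' Token-level one-vs-rest metrics over aligned label sequences
#'
#' For every label (including O) counts TP (both gold and prediction carry
#' the label at a position), FP (prediction only) and FN (gold only), then
#' reports per-label precision/recall/F1 and their unweighted macro mean.
#'
#' @param gold,pred Lists of character label vectors, aligned
#'   token-for-token (or single vectors).
#' @param labels Optional label set; defaults to labels observed in gold or
#'   prediction, in order of first appearance sorted.
#' @return A \code{\link{metrics_report}} object.
#' @export
token_label_metrics <- function(gold, pred, labels = NULL) {
  if (!is.list(gold)) gold <- list(gold)
  if (!is.list(pred)) pred <- list(pred)
  if (length(gold) != length(pred) || any(lengths(gold) != lengths(pred))) {
    stop("gold and predicted sequences are not aligned token-for-token")
  }
  g <- unlist(gold, use.names = FALSE)
  p <- unlist(pred, use.names = FALSE)
  if (is.null(labels)) labels <- sort(unique(c(g, p)))
  rows <- lapply(labels, function(lab) {
    tp <- sum(g == lab & p == lab)
    fp <- sum(g != lab & p == lab)
    fn <- sum(g == lab & p != lab)
    m <- prf(tp, fp, fn)
    data.frame(precision = m[["precision"]], recall = m[["recall"]],
               f1 = m[["f1"]], tp = tp, fp = fp, fn = fn)
  })
  per_label <- do.call(rbind, rows)
  rownames(per_label) <- labels
  metrics_report(per_label)
}

#' Exact-match entity-level metrics
#'
#' A predicted span counts as a true positive only when a gold span with the
#' same document, section, start and end exists; every unmatched prediction
#' is a false positive and every unmatched gold span a false negative.
#'
#' @param gold_spans,pred_spans Data frames with columns \code{section},
#'   \code{start}, \code{end} and optionally \code{doc_id} (absent = single
#'   document).
#' @return List with \code{tp}, \code{fp}, \code{fn}, \code{precision},
#'   \code{recall}, \code{f1}.
#' @export
entity_metrics <- function(gold_spans, pred_spans) {
  key <- function(sp) {
    if (is.null(sp) || nrow(sp) == 0L) return(character())
    doc <- if ("doc_id" %in% names(sp)) sp$doc_id else ""
    paste(doc, sp$section, sp$start, sp$end, sep = "\r")
  }
  gk <- key(gold_spans); pk <- key(pred_spans)
  tp <- sum(pk %in% gk)
  fp <- sum(!pk %in% gk)
  fn <- sum(!gk %in% pk)
  m <- prf(tp, fp, fn)
  list(tp = tp, fp = fp, fn = fn,
       precision = m[["precision"]], recall = m[["recall"]], f1 = m[["f1"]])
}

#' Collect the spans of a corpus into one table
#'
#' @param docs List of documents.
#' @param layer \code{"entities"} (gold) or \code{"predicted"}.
#' @param entity_class Optional filter (\code{"CHEMICAL"}, \code{"GENE"}).
#' @return Data frame of spans with a \code{doc_id} column.
#' @export
corpus_spans <- function(docs, layer = c("entities", "predicted"),
                         entity_class = NULL) {
  layer <- match.arg(layer)
  rows <- lapply(docs, function(d) {
    sp <- d[[layer]]
    if (is.null(sp) || nrow(sp) == 0L) return(NULL)
    if (!is.null(entity_class)) {
      sp <- sp[sp$entity_class %in% entity_class, , drop = FALSE]
      if (nrow(sp) == 0L) return(NULL)
    }
    cbind(doc_id = d$doc_id, sp, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    return(cbind(doc_id = character(), empty_entities()))
  }
  do.call(rbind, rows)
}

#' Document-level name evaluation for candidate inhibitors
#'
#' Per document: every recognized name absent from the gold inhibitor set
#' adds one false positive; every gold inhibitor not recognized adds one
#' false negative; recognized names present in gold are true positives.
#' Gold names must be normalized the same way as predictions (see
#' \code{\link{normalize_name}}).
#'
#' @param recognized Named list: doc_id -> character vector of recognized
#'   (normalized) chemical names.
#' @param gold Named list: doc_id -> character vector of true inhibitor
#'   names.  Documents missing from either list contribute only FPs or FNs.
#' @return As \code{\link{entity_metrics}}: counts plus precision, recall,
#'   F1.
#' @export
inhibitor_eval <- function(recognized, gold) {
  ids <- union(names(recognized), names(gold))
  tp <- fp <- fn <- 0L
  for (id in ids) {
    rec <- unique(recognized[[id]])
    gd <- unique(gold[[id]])
    tp <- tp + sum(rec %in% gd)
    fp <- fp + sum(!rec %in% gd)
    fn <- fn + sum(!gd %in% rec)
  }
  m <- prf(tp, fp, fn)
  list(tp = tp, fp = fp, fn = fn,
       precision = m[["precision"]], recall = m[["recall"]], f1 = m[["f1"]])
}
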