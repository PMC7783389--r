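## Span taggers (chemical, gene/protein), the chemical-type tagger, their
## sequential combination, and the document-level cross-validation harness.
## Sequences are built per section (title and abstract separately), so
## context windows never cross section boundaries.

#' Tokenize and featurize a corpus once, for reuse across models
#'
#' @param docs List of \code{\link{ner_document}}.
#' @param lexicons,pos_tagger Feature extraction inputs; see
#'   \code{\link{sequence_features}}.
#' @param sections Which sections become sequences (default title and
#'   abstract).
#' @return Object of class \code{ner_sequences}: list of records with
#'   \code{doc_id}, \code{section}, \code{tokens}, \code{atoms}.
#' @export
featurize_corpus <- function(docs, lexicons = default_lexicons(),
                             pos_tagger = rule_pos_tagger,
                             sections = c("TITLE", "ABSTRACT")) {
  out <- list()
  for (d in docs) {
    for (sec in sections) {
      txt <- section_text(d, sec)
      toks <- wp_tokenize(txt)
      if (nrow(toks) == 0L) next
      out[[length(out) + 1L]] <- list(
        doc_id = d$doc_id, section = sec, tokens = toks,
        atoms = sequence_atoms(toks$text, pos_tagger, lexicons))
    }
  }
  structure(out, class = "ner_sequences")
}

## Per-sequence gold labels for a span model (SOBIE restricted to one
## entity class) or the type model (chemical subtype per token, else O).
sequence_labels <- function(seqs, docs, mode, entity_class = "CHEMICAL") {
  by_id <- stats::setNames(docs, vapply(docs, `[[`, character(1L), "doc_id"))
  lapply(seqs, function(s) {
    doc <- by_id[[s$doc_id]]
    sp <- doc$entities
    sp <- sp[sp$section == s$section & sp$entity_class %in% entity_class, ,
             drop = FALSE]
    if (mode == "sobie") {
      sobie_encode(s$tokens, sp)
    } else {
      lab <- rep("O", nrow(s$tokens))
      for (i in seq_len(nrow(sp))) {
        hit <- which(s$tokens$end > sp$start[i] & s$tokens$start < sp$end[i])
        lab[hit] <- sp$entity_type[i]
      }
      lab
    }
  })
}

#' Train a SOBIE span tagger for one entity class
#'
#' Builds one labeled sequence per document section, encodes the gold spans
#' of \code{entity_class} with SOBIE, featurizes with the +/-1 context
#' window, and fits a CRF over the alphabet S, O, B, I, E.
#'
#' @param corpus List of \code{\link{ner_document}} (or a prebuilt
#'   \code{ner_sequences} passed via \code{seqs}).
#' @param entity_class \code{"CHEMICAL"} or \code{"GENE"}.
#' @param config A \code{\link{crf_config}}.
#' @param lexicons,pos_tagger,sections See \code{\link{featurize_corpus}}.
#' @param seqs Optional precomputed \code{\link{featurize_corpus}} result.
#' @return A fitted \code{\link{crf_fit}} object.
#' @export
train_span_model <- function(corpus, entity_class = c("CHEMICAL", "GENE"),
                             config = crf_config(),
                             lexicons = default_lexicons(),
                             pos_tagger = rule_pos_tagger,
                             sections = c("TITLE", "ABSTRACT"),
                             seqs = NULL) {
  entity_class <- match.arg(entity_class)
  n_ann <- sum(vapply(corpus, function(d) {
    sum(d$entities$entity_class == entity_class)
  }, numeric(1L)))
  if (n_ann == 0L) {
    stop("corpus has no annotated entities of class ", entity_class)
  }
  if (is.null(seqs)) seqs <- featurize_corpus(corpus, lexicons, pos_tagger, sections)
  y <- sequence_labels(seqs, corpus, "sobie", entity_class)
  x <- lapply(seqs, `[[`, "atoms")
  crf_fit(x, y, config, labels = sobie_labels)
}

#' Train the chemical-type tagger
#'
#' Token labels are the CHEMDNER subtype of the chemical span covering the
#' token (ABBREVIATION, FAMILY, FORMULA, IDENTIFIER, MULTIPLE, SYSTEMATIC,
#' TRIVIAL) and O elsewhere; the fitted alphabet is O plus the types
#' observed in training.
#'
#' @inheritParams train_span_model
#' @return A fitted \code{crf} over the type alphabet.
#' @export
train_type_model <- function(corpus, config = crf_config(),
                             lexicons = default_lexicons(),
                             pos_tagger = rule_pos_tagger,
                             sections = c("TITLE", "ABSTRACT"),
                             seqs = NULL) {
  typed <- sum(vapply(corpus, function(d) {
    sum(d$entities$entity_class == "CHEMICAL" &
          d$entities$entity_type %in% chem_types)
  }, numeric(1L)))
  if (typed == 0L) stop("corpus has no typed chemical annotations")
  if (is.null(seqs)) seqs <- featurize_corpus(corpus, lexicons, pos_tagger, sections)
  y <- sequence_labels(seqs, corpus, "type")
  x <- lapply(seqs, `[[`, "atoms")
  alphabet <- c("O", sort(setdiff(unique(unlist(y)), "O")))
  crf_fit(x, y, config, labels = alphabet)
}

#' Bundle the three taggers into one applicable model
#'
#' @param chem_model,gene_model SOBIE \code{crf} models for chemical and
#'   gene/protein spans.
#' @param type_model Chemical-type \code{crf} model.
#' @param lexicons Lexicons the models were featurized with; stored (and
#'   fingerprinted) so a bundle is never applied with mismatched cue lists.
#' @param pos_tagger POS provider function used at feature time.
#' @param pos_provider_id Short id string recorded for logs.
#' @param version Free-form version tag.
#' @return Object of class \code{ner_tagger}.
#' @export
ner_tagger <- function(chem_model, gene_model, type_model,
                       lexicons = default_lexicons(),
                       pos_tagger = rule_pos_tagger,
                       pos_provider_id = "rule", version = "0.1.0") {
  stopifnot(identical(chem_model$label_alphabet, sobie_labels),
            identical(gene_model$label_alphabet, sobie_labels),
            type_model$label_alphabet[1L] == "O")
  structure(list(chem_model = chem_model, gene_model = gene_model,
                 type_model = type_model, lexicons = lexicons,
                 pos_tagger = pos_tagger, pos_provider_id = pos_provider_id,
                 lexicon_hash = lexicon_fingerprint(lexicons),
                 version = version),
            class = "ner_tagger")
}

#' @export
print.ner_tagger <- function(x, ...) {
  cat(sprintf("<ner_tagger v%s: chem %d atoms, gene %d atoms, type alphabet {%s}; pos=%s>\n",
              x$version, length(x$chem_model$feature_index),
              length(x$gene_model$feature_index),
              paste(x$type_model$label_alphabet, collapse = ","),
              x$pos_provider_id))
  invisible(x)
}

lexicon_fingerprint <- function(lexicons) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(unlist(lapply(names(lexicons), function(n) {
    c(n, lexicons[[n]]$tag, lexicons[[n]]$entries)
  })), f, useBytes = TRUE)
  unname(tools::md5sum(f))
}

#' Save / load a tagger bundle
#'
#' \code{load_tagger} refuses to load a bundle whose lexicon fingerprint
#' does not match \code{lexicons} when those are supplied: CRF weights are
#' tied to the feature atoms the lexicons induce.
#'
#' @param bundle A \code{\link{ner_tagger}}.
#' @param path File path.
#' @param lexicons Optional lexicons to verify against the stored
#'   fingerprint.
#' @return \code{load_tagger}: the restored bundle.
#' @export
save_tagger <- function(bundle, path) {
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path, lexicons = NULL) {
  bundle <- readRDS(path)
  if (!inherits(bundle, "ner_tagger")) stop("not a ner_tagger archive: ", path)
  if (!is.null(lexicons) &&
      !identical(lexicon_fingerprint(lexicons), bundle$lexicon_hash)) {
    stop("lexicon mismatch: bundle was trained with different cue lists")
  }
  bundle
}

## Majority-vote type for one decoded chemical span; tie -> the type of the
## earliest token carrying a tied type; all-O -> UNSPECIFIED.
vote_type <- function(type_labels) {
  tl <- type_labels[type_labels != "O"]
  if (!length(tl)) return("UNSPECIFIED")
  tab <- table(tl)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) return(winners)
  tl[tl %in% winners][1L]
}

#' Apply the combined tagger to one document
#'
#' Sequential recognition, per section: chemical spans are decoded from the
#' chemical SOBIE model, each decoded span is assigned a subtype by majority
#' vote of the type model's labels over its tokens, and gene/protein spans
#' are decoded independently from the gene model.  Both layers are kept even
#' where they overlap.  The input document is not mutated; the result is a
#' copy whose \code{predicted} layer holds the new spans (gold annotations,
#' if any, are untouched).
#'
#' @param bundle A \code{\link{ner_tagger}}.
#' @param doc A \code{\link{ner_document}}.
#' @param sections Sections to tag.
#' @return The document copy with a populated \code{predicted} layer.
#' @export
apply_combined <- function(bundle, doc, sections = c("TITLE", "ABSTRACT")) {
  pred <- list()
  for (sec in sections) {
    txt <- section_text(doc, sec)
    toks <- wp_tokenize(txt)
    if (nrow(toks) == 0L) next
    atoms <- sequence_atoms(toks$text, bundle$pos_tagger, bundle$lexicons)
    chem_lab <- viterbi_decode(bundle$chem_model, atoms)
    type_lab <- viterbi_decode(bundle$type_model, atoms)
    gene_lab <- viterbi_decode(bundle$gene_model, atoms)
    chem_sp <- sobie_decode(toks, chem_lab, source = txt)
    if (nrow(chem_sp)) {
      chem_sp$entity_type <- vapply(seq_len(nrow(chem_sp)), function(i) {
        hit <- which(toks$end > chem_sp$start[i] & toks$start < chem_sp$end[i])
        vote_type(type_lab[hit])
      }, character(1L))
      pred[[length(pred) + 1L]] <- data.frame(
        section = sec, start = chem_sp$start, end = chem_sp$end,
        text = chem_sp$text, entity_class = "CHEMICAL",
        entity_type = chem_sp$entity_type, stringsAsFactors = FALSE)
    }
    gene_sp <- sobie_decode(toks, gene_lab, source = txt)
    if (nrow(gene_sp)) {
      pred[[length(pred) + 1L]] <- data.frame(
        section = sec, start = gene_sp$start, end = gene_sp$end,
        text = gene_sp$text, entity_class = "GENE",
        entity_type = "UNSPECIFIED", stringsAsFactors = FALSE)
    }
  }
  doc$predicted <- if (length(pred)) do.call(rbind, pred) else empty_entities()
  validate_document(doc)
  doc
}

#' @rdname apply_combined
#' @param docs A list of documents.
#' @export
tag_corpus <- function(bundle, docs, sections = c("TITLE", "ABSTRACT")) {
  lapply(docs, apply_combined, bundle = bundle, sections = sections)
}

#' Cross-validation configuration
#'
#' @param k Number of folds (>= 2); documents are the split unit and fold
#'   sizes differ by at most one.
#' @param seed Integer seed for the fold assignment.
#' @return Object of class \code{cv_config}.
#' @export
cv_config <- function(k = 5L, seed = 1L) {
  stopifnot(k >= 2)
  structure(list(k = as.integer(k), seed = as.integer(seed)),
            class = "cv_config")
}

#' k-fold cross-validation of a span tagger
#'
#' Documents are partitioned into seeded folds; for each fold a model is
#' trained on the remainder and held-out token labels are scored one-vs-rest
#' (per label and macro, O included).  The summary row is the unweighted
#' mean of the fold macro metrics.
#'
#' @inheritParams train_span_model
#' @param cv A \code{\link{cv_config}}.
#' @return Object of class \code{ner_cv}: list with \code{fold_reports}
#'   (one \code{ner_metrics} per fold), \code{fold_assignment},
#'   \code{mean_macro} and \code{mean_per_label}.
#' @export
cross_validate <- function(corpus, entity_class = c("CHEMICAL", "GENE"),
                           config = crf_config(), cv = cv_config(),
                           lexicons = default_lexicons(),
                           pos_tagger = rule_pos_tagger,
                           sections = c("TITLE", "ABSTRACT")) {
  entity_class <- match.arg(entity_class)
  n <- length(corpus)
  if (n < cv$k) stop("fewer documents (", n, ") than folds (", cv$k, ")")
  folds <- make_folds(n, cv$k, cv$seed)
  seqs <- featurize_corpus(corpus, lexicons, pos_tagger, sections)
  seq_doc <- vapply(seqs, `[[`, character(1L), "doc_id")
  doc_ids <- vapply(corpus, `[[`, character(1L), "doc_id")
  y <- sequence_labels(seqs, corpus, "sobie", entity_class)
  x <- lapply(seqs, `[[`, "atoms")
  reports <- vector("list", cv$k)
  for (fi in seq_len(cv$k)) {
    hold_docs <- doc_ids[folds == fi]
    hold <- seq_doc %in% hold_docs
    m <- crf_fit(x[!hold], y[!hold], config, labels = sobie_labels)
    pred <- predict(m, x[hold])
    reports[[fi]] <- token_label_metrics(y[hold], pred, labels = sobie_labels)
  }
  macro <- do.call(rbind, lapply(reports, `[[`, "macro"))
  per_label <- Reduce(`+`, lapply(reports, function(r) {
    as.matrix(r$per_label[, c("precision", "recall", "f1")])
  })) / cv$k
  structure(list(fold_reports = reports, fold_assignment = folds,
                 mean_macro = colMeans(macro),
                 mean_per_label = per_label,
                 entity_class = entity_class, k = cv$k, seed = cv$seed),
            class = "ner_cv")
}

#' @export
print.ner_cv <- function(x, digits = 4L, ...) {
  cat(sprintf("%d-fold cross-validation, %s spans (seed %d)\n",
              x$k, x$entity_class, x$seed))
  cat("Mean per-label metrics:\n")
  print(round(x$mean_per_label, digits))
  cat("Mean macro: ")
  cat(sprintf("%s=%.*f", names(x$mean_macro), digits, x$mean_macro), sep = "  ")
  cat("\n")
  invisible(x)
}
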