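## Standoff corpus reading/writing: CHEMDNER-like and ChemProt-like dialects.
## A corpus is a list of ner_document objects; annotations are data frames of
## character-offset spans validated against the section text they address.

chem_types <- c("ABBREVIATION", "FAMILY", "FORMULA", "IDENTIFIER",
                "MULTIPLE", "SYSTEMATIC", "TRIVIAL")
gene_types <- c("GENE-Y", "GENE-N")

empty_entities <- function() {
  data.frame(section = character(), start = integer(), end = integer(),
             text = character(), entity_class = character(),
             entity_type = character(), stringsAsFactors = FALSE)
}

#' Construct a document with standoff entity annotations
#'
#' @param doc_id Non-empty identifier, unique within a corpus and containing
#'   no tab or newline.
#' @param title,abstract Section texts (UTF-8).
#' @param entities Data frame with columns \code{section} (\code{"TITLE"} or
#'   \code{"ABSTRACT"}), \code{start}, \code{end} (0-based half-open
#'   code-point offsets into the section), \code{text} (the mention string,
#'   which must equal the addressed slice), \code{entity_class}
#'   (\code{"CHEMICAL"} or \code{"GENE"}) and \code{entity_type}.
#' @param predicted Optional data frame of the same shape holding predicted
#'   spans; kept separate from the gold layer.
#' @return An object of class \code{ner_document}.
#' @export
ner_document <- function(doc_id, title = "", abstract = "",
                         entities = empty_entities(), predicted = NULL) {
  doc <- structure(
    list(doc_id = doc_id, title = enc2utf8(title),
         abstract = enc2utf8(abstract), entities = entities,
         predicted = predicted),
    class = "ner_document")
  validate_document(doc)
  doc
}

#' @export
print.ner_document <- function(x, ...) {
  cat(sprintf("<ner_document %s: %d title chars, %d abstract chars, %d gold, %s predicted>\n",
              x$doc_id, nchar(x$title), nchar(x$abstract), nrow(x$entities),
              if (is.null(x$predicted)) "no" else nrow(x$predicted)))
  invisible(x)
}

section_text <- function(doc, section) {
  if (section == "TITLE") doc$title else doc$abstract
}

validate_spans <- function(doc, spans, layer = "entities") {
  if (is.null(spans) || nrow(spans) == 0L) return(invisible(TRUE))
  need <- c("section", "start", "end", "text", "entity_class", "entity_type")
  miss <- setdiff(need, names(spans))
  if (length(miss)) stop("entity layer missing columns: ", paste(miss, collapse = ", "))
  for (i in seq_len(nrow(spans))) {
    s <- spans[i, ]
    if (!s$section %in% c("TITLE", "ABSTRACT"))
      stop(sprintf("doc %s: bad section %s", doc$doc_id, s$section))
    if (is.na(s$start) || is.na(s$end) || s$start >= s$end)
      stop(sprintf("doc %s: span [%s,%s) has start >= end", doc$doc_id, s$start, s$end))
    txt <- section_text(doc, s$section)
    if (s$end > nchar(txt))
      stop(sprintf("doc %s: span [%d,%d) outside %s of length %d",
                   doc$doc_id, s$start, s$end, s$section, nchar(txt)))
    slice <- substr(txt, s$start + 1L, s$end)
    if (slice != s$text)
      stop(sprintf("doc %s %s span [%d,%d): text %s does not match slice %s",
                   doc$doc_id, s$section, s$start, s$end,
                   dQuote(s$text), dQuote(slice)))
    ok_type <- switch(s$entity_class,
      CHEMICAL = s$entity_type %in% c(chem_types, "UNSPECIFIED"),
      GENE = s$entity_type %in% c(gene_types, "UNSPECIFIED"),
      FALSE)
    if (!isTRUE(ok_type))
      stop(sprintf("doc %s: entity_type %s invalid for class %s",
                   doc$doc_id, s$entity_type, s$entity_class))
  }
  invisible(TRUE)
}

#' Validate a document against the standoff invariants
#'
#' Checks that the id is non-empty and delimiter-safe and that every span in
#' the gold and predicted layers addresses a valid slice whose text equals
#' the span's \code{text} field.  Violations raise errors naming the span;
#' nothing is silently repaired.
#'
#' @param doc A \code{ner_document}.
#' @return Invisibly \code{TRUE}; errors otherwise.
#' @export
validate_document <- function(doc) {
  if (!nzchar(doc$doc_id)) stop("doc_id must be non-empty")
  if (grepl("[\t\n]", doc$doc_id)) stop("doc_id contains a tab or newline")
  if (grepl("[\t\n]", doc$title) || grepl("[\t\n]", doc$abstract))
    stop(sprintf("doc %s: section text contains a tab or newline", doc$doc_id))
  validate_spans(doc, doc$entities)
  validate_spans(doc, doc$predicted, "predicted")
  invisible(TRUE)
}

#' Validate a corpus
#' @param docs List of \code{ner_document}.
#' @return Invisibly \code{TRUE}.
#' @export
validate_corpus <- function(docs) {
  ids <- vapply(docs, `[[`, character(1L), "doc_id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate doc_ids: ", paste(unique(dup), collapse = ", "))
  for (d in docs) validate_document(d)
  invisible(TRUE)
}

read_tsv_lines <- function(path, n_fields, what) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_fields)
  if (length(bad)) {
    stop(sprintf("%s line %d: expected %d tab-separated fields, got %d",
                 what, bad[1L], n_fields, lengths(parts)[bad[1L]]))
  }
  parts
}

class_from_type <- function(type) {
  if (type %in% gene_types) "GENE" else "CHEMICAL"
}

#' Read a standoff abstract corpus
#'
#' Both dialects share the abstracts file format
#' \code{doc_id<TAB>title<TAB>abstract}, one record per line.  Annotation
#' grammars differ:
#' \describe{
#'   \item{chemdner}{\code{doc_id<TAB>{T|A}<TAB>start<TAB>end<TAB>text<TAB>type};
#'     offsets are 0-based half-open against the named section.}
#'   \item{chemprot}{\code{doc_id<TAB>T<n><TAB>type<TAB>start<TAB>end<TAB>text};
#'     offsets run over the concatenation \code{title + TAB + abstract} and the
#'     section is recovered from the offset position.}
#' }
#' Every span is checked against its section text (slice-equals-text); a
#' mismatch is an error naming the span, never a silent repair.  Offsets
#' count Unicode code points.
#'
#' @param abstracts_path,annotations_path Paths to the two files.
#' @param dialect \code{"chemdner"} or \code{"chemprot"}.
#' @return List of \code{\link{ner_document}}.
#' @export
read_corpus <- function(abstracts_path, annotations_path,
                        dialect = c("chemdner", "chemprot")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(abstracts_path))
  abs_parts <- read_tsv_lines(abstracts_path, 3L, "abstracts file")
  docs <- lapply(abs_parts, function(p) {
    structure(list(doc_id = p[1L], title = enc2utf8(p[2L]),
                   abstract = enc2utf8(p[3L]),
                   entities = empty_entities(), predicted = NULL),
              class = "ner_document")
  })
  names(docs) <- vapply(docs, `[[`, character(1L), "doc_id")
  if (anyDuplicated(names(docs)))
    stop("duplicate doc_ids in abstracts file")

  ann <- list()
  if (!is.null(annotations_path)) {
    stopifnot(file.exists(annotations_path))
    ann_parts <- read_tsv_lines(annotations_path, 6L, "annotations file")
    for (li in seq_along(ann_parts)) {
      p <- ann_parts[[li]]
      doc_id <- p[1L]
      if (!doc_id %in% names(docs))
        stop(sprintf("annotations line %d: unknown doc_id %s", li, doc_id))
      doc <- docs[[doc_id]]
      if (dialect == "chemdner") {
        sec_code <- p[2L]
        if (!sec_code %in% c("T", "A"))
          stop(sprintf("annotations line %d: bad section code %s", li, sec_code))
        section <- if (sec_code == "T") "TITLE" else "ABSTRACT"
        start <- suppressWarnings(as.integer(p[3L]))
        end <- suppressWarnings(as.integer(p[4L]))
        text <- p[5L]; type <- p[6L]
      } else {
        type <- p[3L]
        start <- suppressWarnings(as.integer(p[4L]))
        end <- suppressWarnings(as.integer(p[5L]))
        text <- p[6L]
        if (is.na(start) || is.na(end))
          stop(sprintf("annotations line %d: non-numeric offsets", li))
        nt <- nchar(doc$title)
        if (end <= nt) {
          section <- "TITLE"
        } else if (start >= nt + 1L) {
          section <- "ABSTRACT"; start <- start - nt - 1L; end <- end - nt - 1L
        } else {
          stop(sprintf("annotations line %d: span crosses the title/abstract boundary", li))
        }
      }
      if (is.na(start) || is.na(end))
        stop(sprintf("annotations line %d: non-numeric offsets", li))
      if (type %in% gene_types) {
        entity_class <- "GENE"
      } else if (type %in% chem_types) {
        entity_class <- "CHEMICAL"
      } else if (type %in% c("CHEMICAL", "UNSPECIFIED")) {
        entity_class <- "CHEMICAL"; type <- "UNSPECIFIED"
      } else {
        stop(sprintf("annotations line %d: unknown entity type %s", li, type))
      }
      row <- data.frame(section = section, start = start, end = end,
                        text = enc2utf8(text), entity_class = entity_class,
                        entity_type = type, stringsAsFactors = FALSE)
      ann[[doc_id]] <- rbind(ann[[doc_id]], row)
    }
  }
  for (doc_id in names(ann)) {
    docs[[doc_id]]$entities <- ann[[doc_id]]
  }
  docs <- unname(docs)
  validate_corpus(docs)
  docs
}

chemprot_global <- function(doc, spans) {
  off <- ifelse(spans$section == "TITLE", 0L, nchar(doc$title) + 1L)
  list(start = spans$start + off, end = spans$end + off)
}

#' Serialize a corpus to standoff text
#'
#' Inverse of \code{\link{read_corpus}}: \code{read_corpus(write_corpus(docs))}
#' reproduces \code{docs} field for field.  In the chemprot dialect a
#' chemical span with a known CHEMDNER subtype is written with that subtype
#' in the type column (the reader accepts both it and plain
#' \code{CHEMICAL}), so typed corpora survive the round trip.
#'
#' @param docs List of \code{ner_document}; validated before writing.
#' @param dialect \code{"chemdner"} or \code{"chemprot"}.
#' @param layer \code{"entities"} (gold) or \code{"predicted"}.
#' @return List with elements \code{abstracts} and \code{annotations}, each a
#'   single LF-terminated character scalar.
#' @export
write_corpus <- function(docs, dialect = c("chemdner", "chemprot"),
                         layer = c("entities", "predicted")) {
  dialect <- match.arg(dialect)
  layer <- match.arg(layer)
  validate_corpus(docs)
  abs_lines <- vapply(docs, function(d) {
    paste(d$doc_id, d$title, d$abstract, sep = "\t")
  }, character(1L))
  ann_lines <- character()
  for (d in docs) {
    spans <- d[[layer]]
    if (is.null(spans) || nrow(spans) == 0L) next
    if (dialect == "chemdner") {
      ann_lines <- c(ann_lines, sprintf(
        "%s\t%s\t%d\t%d\t%s\t%s", d$doc_id,
        ifelse(spans$section == "TITLE", "T", "A"),
        spans$start, spans$end, spans$text, spans$entity_type))
    } else {
      g <- chemprot_global(d, spans)
      type_col <- ifelse(spans$entity_class == "GENE", spans$entity_type,
                         ifelse(spans$entity_type == "UNSPECIFIED",
                                "CHEMICAL", spans$entity_type))
      ann_lines <- c(ann_lines, sprintf(
        "%s\tT%d\t%s\t%d\t%d\t%s", d$doc_id, seq_len(nrow(spans)),
        type_col, g$start, g$end, spans$text))
    }
  }
  join <- function(x) if (length(x)) paste0(paste(x, collapse = "\n"), "\n") else ""
  list(abstracts = join(abs_lines), annotations = join(ann_lines))
}

#' @rdname write_corpus
#' @param abstracts_path,annotations_path Output file paths.
#' @export
write_corpus_files <- function(docs, abstracts_path, annotations_path,
                               dialect = c("chemdner", "chemprot"),
                               layer = c("entities", "predicted")) {
  out <- write_corpus(docs, dialect, layer)
  writeLines(out$abstracts, abstracts_path, sep = "", useBytes = FALSE)
  writeLines(out$annotations, annotations_path, sep = "", useBytes = FALSE)
  invisible(c(abstracts_path, annotations_path))
}

#' Concatenate two corpora, disambiguating colliding ids
#'
#' Documents are concatenated; when a \code{doc_id} occurs in both inputs,
#' every occurrence of that id is prefixed with \code{"a:"} or \code{"b:"}
#' by source.  Annotation layers are untouched.
#'
#' @param a,b Lists of \code{ner_document}.
#' @return Combined list.
#' @export
merge_corpora <- function(a, b) {
  ids_a <- vapply(a, `[[`, character(1L), "doc_id")
  ids_b <- vapply(b, `[[`, character(1L), "doc_id")
  clash <- intersect(ids_a, ids_b)
  fix <- function(docs, ids, prefix) {
    lapply(seq_along(docs), function(i) {
      d <- docs[[i]]
      if (d$doc_id %in% clash) d$doc_id <- paste0(prefix, ":", d$doc_id)
      d
    })
  }
  c(fix(a, ids_a, "a"), fix(b, ids_b, "b"))
}
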