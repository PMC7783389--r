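## Application pipelines: candidate-inhibitor extraction (chemical-type
## filter + chemical/protein co-occurrence rule) and literature
## name-profile differencing between document groups.

#' Surface-form name normalization
#'
#' Case-folds, strips flanking (non-interior) punctuation and collapses
#' internal whitespace.  This is deliberately shallow: synonym merging is
#' the resolver's job (\code{\link{lookup_names}}), and profile counts are
#' over surface names.
#'
#' @param x Character vector of mention strings.
#' @return Normalized character vector.
#' @export
normalize_name <- function(x) {
  x <- tolower(x)
  x <- gsub("^[^\\p{L}\\p{N}]+|[^\\p{L}\\p{N}]+$", "", x, perl = TRUE)
  gsub("\\s+", " ", x)
}

#' Drop entities of excluded chemical types
#'
#' Used to remove FORMULA (mostly ions) and FAMILY (compound classes, not
#' specific molecules) mentions before candidate-inhibitor selection.
#' Order-preserving and idempotent.
#'
#' @param entities Entity data frame (gold or predicted layer).
#' @param excluded Character set of entity types to remove; default
#'   \code{c("FORMULA", "FAMILY")}.
#' @return The surviving rows.
#' @export
filter_by_type <- function(entities, excluded = c("FORMULA", "FAMILY")) {
  if (is.null(entities) || nrow(entities) == 0L) return(entities)
  entities[!entities$entity_type %in% excluded, , drop = FALSE]
}

#' Candidate-inhibitor names of one document
#'
#' The co-occurrence rule: a document proposes its chemical mentions as
#' candidate inhibitors only when it carries at least one predicted
#' gene/protein span and at least one chemical span surviving the type
#' filter; otherwise it proposes nothing.
#'
#' @param doc A document with a populated \code{predicted} layer.
#' @param excluded Chemical types removed before the rule is applied.
#' @return Character vector of normalized chemical names (possibly empty).
#' @export
select_candidate_inhibitors <- function(doc, excluded = c("FORMULA", "FAMILY")) {
  sp <- doc$predicted
  if (is.null(sp) || nrow(sp) == 0L) return(character())
  chem <- filter_by_type(sp[sp$entity_class == "CHEMICAL", , drop = FALSE],
                         excluded)
  gene <- sp[sp$entity_class == "GENE", , drop = FALSE]
  if (nrow(gene) == 0L || nrow(chem) == 0L) return(character())
  unique(normalize_name(chem$text))
}

#' Build a name profile for a document group
#'
#' The set of unique normalized entity names of one class across a group of
#' documents, with per-name provenance (which documents mention it).
#'
#' @param docs List of documents.
#' @param group_id Label for the group.
#' @param layer \code{"GENE"} or \code{"CHEMICAL"}.
#' @param source \code{"predicted"} (default) or \code{"entities"} (gold).
#' @return Object of class \code{name_profile}: list with \code{group_id},
#'   \code{names} (sorted character vector) and \code{provenance} (named
#'   list name -> doc_ids).
#' @export
build_profile <- function(docs, group_id, layer = c("GENE", "CHEMICAL"),
                          source = c("predicted", "entities")) {
  layer <- match.arg(layer)
  source <- match.arg(source)
  prov <- list()
  for (d in docs) {
    sp <- d[[source]]
    if (is.null(sp) || nrow(sp) == 0L) next
    nms <- unique(normalize_name(sp$text[sp$entity_class == layer]))
    nms <- nms[nzchar(nms)]
    for (nm in nms) prov[[nm]] <- union(prov[[nm]], d$doc_id)
  }
  if (length(prov)) prov <- prov[order(names(prov))]
  structure(list(group_id = group_id,
                 names = if (length(prov)) names(prov) else character(),
                 provenance = prov),
            class = "name_profile")
}

#' @export
print.name_profile <- function(x, ...) {
  cat(sprintf("<name_profile %s: %d unique names across %d documents>\n",
              x$group_id, length(x$names),
              length(unique(unlist(x$provenance)))))
  invisible(x)
}

#' Difference two name profiles
#'
#' Partitions the union of two profiles into the overlap and the names
#' unique to each side, the arithmetic behind group-versus-group literature
#' comparisons: |unique_to_a| + |overlap| = |A| and symmetrically for B.
#'
#' @param a,b \code{\link{build_profile}} results (or plain character
#'   vectors of names).
#' @return Object of class \code{profile_diff}: list with sets
#'   \code{unique_to_a}, \code{unique_to_b}, \code{overlap} and a
#'   \code{counts} summary vector.
#' @export
diff_profiles <- function(a, b) {
  na <- if (inherits(a, "name_profile")) a$names else unique(a)
  nb <- if (inherits(b, "name_profile")) b$names else unique(b)
  overlap <- intersect(na, nb)
  ua <- setdiff(na, nb)
  ub <- setdiff(nb, na)
  structure(list(unique_to_a = sort(ua), unique_to_b = sort(ub),
                 overlap = sort(overlap),
                 counts = c(a = length(na), b = length(nb),
                            overlap = length(overlap),
                            unique_to_a = length(ua),
                            unique_to_b = length(ub))),
            class = "profile_diff")
}

#' @export
print.profile_diff <- function(x, ...) {
  cat("Profile difference\n")
  print(x$counts)
  invisible(x)
}

#' Resolve entity names against an external-database interface
#'
#' The resolver is injectable: any function taking one name and returning a
#' record (list) or \code{NULL} works.  The default is an offline stub
#' backed by a local TSV of \code{name<TAB>id<TAB>synonyms} rows — names the
#' resolver cannot associate with any record are reported as \code{MISS},
#' which is the false-positive filter for extracted protein names.  A
#' resolver error yields a per-name \code{MISS} with a warning, never a
#' pipeline abort.
#'
#' @param names Character vector of (normalized) names.
#' @param resolver Function name -> record or NULL.
#' @return Named list mapping each name to its record or the string
#'   \code{"MISS"}.
#' @export
lookup_names <- function(names, resolver = stub_resolver()) {
  out <- stats::setNames(vector("list", length(names)), names)
  for (nm in names) {
    rec <- tryCatch(resolver(nm), error = function(e) {
      warning("resolver failed for ", dQuote(nm), ": ", conditionMessage(e))
      NULL
    })
    out[[nm]] <- if (is.null(rec)) "MISS" else rec
  }
  out
}

#' @rdname lookup_names
#' @param table_path TSV with columns name, id, synonyms
#'   (synonyms |-separated); lookups match the name or any synonym,
#'   case-insensitively.
#' @export
stub_resolver <- function(table_path = system.file(
                            "extdata", "resolver_stub_synthetic.tsv",
                            package = "crfner", mustWork = TRUE)) {
  tab <- utils::read.delim(table_path, header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  keys <- lapply(seq_len(nrow(tab)), function(i) {
    syn <- strsplit(tab$synonyms[i], "|", fixed = TRUE)[[1]]
    tolower(c(tab$name[i], syn[nzchar(syn)]))
  })
  function(name) {
    hit <- which(vapply(keys, function(k) tolower(name) %in% k, logical(1L)))
    if (!length(hit)) return(NULL)
    i <- hit[1L]
    list(name = tab$name[i], id = tab$id[i],
         synonyms = strsplit(tab$synonyms[i], "|", fixed = TRUE)[[1]])
  }
}

#' Remove one group's documents from another by id
#'
#' Upstream step of profile differencing: documents of group A that also
#' belong to group B (same \code{doc_id}) are dropped before profiling, so
#' the two groups are disjoint at the document level.
#'
#' @param a,b Lists of documents.
#' @return The documents of \code{a} whose ids are not in \code{b}.
#' @export
exclude_docs <- function(a, b) {
  ids_b <- vapply(b, `[[`, character(1L), "doc_id")
  a[!vapply(a, `[[`, character(1L), "doc_id") %in% ids_b]
}
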