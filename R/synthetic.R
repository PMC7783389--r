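## Synthetic annotated-corpus generator.  Emulates the structure the
## pipeline assumes in real corpora: abstracts with planted chemical
## mentions of the seven CHEMDNER surface types, gene/protein mentions
## (symbol-like and "<name> protein" bigrams), character-offset standoff
## annotations, and cue words from the C/G lexicons placed adjacent to
## mentions.  Every surface pattern is chosen so that the type is
## recoverable from orthographic features (case, digits, symbols,
## suffixes); the filler vocabulary is a fixed shipped list, so generation
## is fully reproducible offline.

.filler_words <- c(
  "study", "results", "analysis", "observed", "measured", "activity",
  "effect", "effects", "levels", "cells", "cell", "assay", "response",
  "significant", "increase", "decrease", "observed", "patients", "samples",
  "method", "approach", "data", "values", "showed", "suggest", "indicate",
  "role", "function", "structure", "model", "present", "report", "describe",
  "novel", "potent", "selective", "specific", "after", "during", "between",
  "within", "against", "under", "using", "based", "related", "associated",
  "important", "further", "however", "moreover", "therefore", "whereas",
  "experiments", "conditions", "control", "groups", "tested", "evaluated",
  "obtained", "performed", "determined", "identified", "characterized",
  "mechanism", "process", "interaction", "complex", "surface", "membrane",
  "tissue", "plasma", "serum", "vitro", "vivo", "clinical", "biological")

.family_terms <- c("steroid hormones", "benzodiazepines", "alkaloids",
                   "flavonoids", "nucleosides", "prostaglandins",
                   "corticosteroids", "opioids", "polyphenols",
                   "anthracyclines")

.syllables <- c("ba", "do", "fi", "lu", "mo", "na", "pra", "sti", "vor",
                "zi", "ke", "ran", "tol", "mex", "qui", "sa", "ne", "gli")

.elements <- c("C", "H", "O", "N", "Na", "Cl", "Ca", "Mg", "K", "Fe", "S", "P")

.default_type_mix <- c(ABBREVIATION = 0.14, FAMILY = 0.10, FORMULA = 0.14,
                       IDENTIFIER = 0.14, MULTIPLE = 0.08, SYSTEMATIC = 0.20,
                       TRIVIAL = 0.20)

#' Synthetic corpus configuration
#'
#' Defaults describe a corpus in which every pipeline stage has signal to
#' learn from: a few mentions of each class per abstract, all seven
#' chemical surface types, and cue words adjacent to half of the mentions.
#'
#' @param n_docs Number of documents.
#' @param mean_tokens Mean abstract length in words (Poisson).
#' @param chem_density Expected chemical mentions per abstract (Poisson).
#' @param gene_density Expected gene/protein mentions per abstract.
#' @param type_mix Named probability vector over the 7 chemical types;
#'   must sum to 1.
#' @param cue_rate Probability that a planted mention is immediately
#'   preceded by a cue word from the matching C/G lexicon.
#' @param seed Integer seed; the same configuration always generates the
#'   identical corpus.
#' @return Object of class \code{synth_config}.
#' @export
synth_config <- function(n_docs = 50L, mean_tokens = 60L, chem_density = 3,
                         gene_density = 3, type_mix = .default_type_mix,
                         cue_rate = 0.5, seed = 42L) {
  stopifnot(n_docs >= 1, chem_density >= 0, gene_density >= 0,
            cue_rate >= 0, cue_rate <= 1,
            setequal(names(type_mix), chem_types),
            abs(sum(type_mix) - 1) < 1e-8)
  structure(list(n_docs = as.integer(n_docs),
                 mean_tokens = as.integer(mean_tokens),
                 chem_density = chem_density, gene_density = gene_density,
                 type_mix = type_mix[chem_types], cue_rate = cue_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

rand_stem <- function(n_syll) {
  paste(sample(.syllables, n_syll, replace = TRUE), collapse = "")
}

rand_upper <- function(n) {
  paste(sample(LETTERS, n, replace = TRUE), collapse = "")
}

## One chemical mention surface of the given type.
chem_surface <- function(type) {
  switch(type,
    TRIVIAL = paste0(rand_stem(sample(2:3, 1L)),
                     sample(c("vir", "nib", "ine", "olol", "idone"), 1L)),
    SYSTEMATIC = paste0(rand_stem(sample(1:2, 1L)),
                        sample(c("yl", "oxy", "ylidene"), 1L), "-",
                        sample(1:9, 1L), "-",
                        rand_stem(1L),
                        sample(c("ol", "one", "oate", "amine"), 1L)),
    ABBREVIATION = rand_upper(sample(2:5, 1L)),
    FORMULA = {
      k <- sample(2:3, 1L)
      digits <- sample(c("", as.character(2:9)), k, replace = TRUE)
      digits[sample.int(k, 1L)] <- as.character(sample(2:9, 1L))  # >=1 digit
      paste0(sample(.elements, k, replace = TRUE), digits, collapse = "")
    },
    IDENTIFIER = paste0(rand_upper(sample(2:3, 1L)), "-",
                        paste(sample(0:9, sample(3:4, 1L), replace = TRUE),
                              collapse = "")),
    MULTIPLE = paste0(sample(c("tri", "di", "mono", "tetra"), 1L), "- and ",
                      sample(c("di", "tri", "penta"), 1L), "-",
                      rand_stem(1L),
                      sample(c("phosphates", "sulfates", "acetates"), 1L)),
    FAMILY = sample(.family_terms, 1L),
    stop("unknown chemical type ", type))
}

## One gene/protein mention surface.
gene_surface <- function() {
  if (stats::runif(1) < 0.5) {
    paste0(rand_upper(sample(2:4, 1L)), sample(1:9, 1L))
  } else {
    paste(rand_stem(2L), "protein")
  }
}

## Assemble items (filler words and mention records) into section text plus
## a standoff entity table; mentions are always space-delimited, hence
## token-aligned under word-punctuation tokenization.
assemble_section <- function(items, section) {
  pos <- 0L
  texts <- character(length(items))
  ents <- list()
  for (i in seq_along(items)) {
    it <- items[[i]]
    texts[i] <- it$text
    if (!is.null(it$class)) {
      ents[[length(ents) + 1L]] <- data.frame(
        section = section, start = pos, end = pos + nchar(it$text),
        text = it$text, entity_class = it$class, entity_type = it$type,
        stringsAsFactors = FALSE)
    }
    pos <- pos + nchar(it$text) + 1L
  }
  list(text = paste(texts, collapse = " "),
       entities = if (length(ents)) do.call(rbind, ents) else empty_entities())
}

filler_item <- function(n = 1L) {
  lapply(sample(.filler_words, n, replace = TRUE),
         function(w) list(text = w))
}

mention_items <- function(class, type, surface, cue_rate, lexicons) {
  out <- list()
  if (stats::runif(1) < cue_rate) {
    lex <- if (class == "CHEMICAL") lexicons$C else lexicons$G
    out[[1L]] <- list(text = sample(lex$entries, 1L))
  }
  out[[length(out) + 1L]] <- list(text = surface, class = class, type = type)
  out
}

generate_document <- function(doc_id, config, lexicons) {
  n_chem <- stats::rpois(1L, config$chem_density)
  n_gene <- stats::rpois(1L, config$gene_density)
  n_fill <- max(10L, stats::rpois(1L, config$mean_tokens))

  mentions <- c(
    lapply(seq_len(n_chem), function(i) {
      type <- sample(chem_types, 1L, prob = config$type_mix)
      mention_items("CHEMICAL", type, chem_surface(type),
                    config$cue_rate, lexicons)
    }),
    lapply(seq_len(n_gene), function(i) {
      mention_items("GENE", sample(gene_types, 1L), gene_surface(),
                    config$cue_rate, lexicons)
    }))
  # interleave mentions at random filler positions
  slots <- sort(sample.int(n_fill + 1L, length(mentions), replace = TRUE))
  items <- list()
  for (k in seq_len(n_fill + 1L)) {
    for (m in which(slots == k)) items <- c(items, mentions[[m]])
    if (k <= n_fill) items <- c(items, filler_item(1L))
  }
  abstract <- assemble_section(items, "ABSTRACT")

  title_items <- filler_item(sample(4:8, 1L))
  if (config$chem_density > 0 && stats::runif(1) < 0.3) {
    type <- sample(chem_types, 1L, prob = config$type_mix)
    title_items <- c(title_items,
                     mention_items("CHEMICAL", type, chem_surface(type),
                                   config$cue_rate, lexicons))
  }
  title <- assemble_section(title_items, "TITLE")

  ner_document(doc_id, title = title$text, abstract = abstract$text,
               entities = rbind(title$entities, abstract$entities))
}

#' Generate a synthetic annotated corpus
#'
#' @param config A \code{\link{synth_config}}.
#' @param lexicons Cue lexicons the generator draws adjacent cue words from
#'   (and the feature extractor later matches against).
#' @return List of \code{\link{ner_document}} with gold entity layers; all
#'   spans satisfy the standoff invariants and round-trip through
#'   \code{\link{write_corpus}} in both dialects.
#' @export
generate_corpus <- function(config = synth_config(),
                            lexicons = default_lexicons()) {
  withr_seed(config$seed, {
    lapply(seq_len(config$n_docs), function(i) {
      generate_document(sprintf("SYN%05d", i), config, lexicons)
    })
  })
}

#' Generate two document groups with prescribed gene-name inventories
#'
#' Plants gene mentions such that group A's inventory has exactly
#' \code{size_a} unique names, group B's has \code{size_b}, and exactly
#' \code{overlap} names are shared — the fixture for profile differencing.
#'
#' @param size_a,size_b Unique-name inventory sizes of the two groups.
#' @param overlap Number of shared names; must not exceed either size.
#' @param seed Integer seed.
#' @param names_per_doc Planted mentions per document (last document of a
#'   group may carry fewer).
#' @return List with document lists \code{a} and \code{b}.
#' @export
generate_grouped_profiles <- function(size_a, size_b, overlap, seed = 42L,
                                      names_per_doc = 5L) {
  if (overlap > min(size_a, size_b)) {
    stop("infeasible: overlap exceeds a group's inventory size")
  }
  n_total <- size_a + size_b - overlap
  withr_seed(seed, {
    pool <- paste0(vapply(seq_len(n_total), function(i) rand_upper(3L),
                          character(1L)), seq_len(n_total))
    names_a <- pool[seq_len(size_a)]
    names_b <- pool[seq.int(size_a - overlap + 1L, n_total)]
    mk_group <- function(nms, prefix) {
      chunks <- split(nms, ceiling(seq_along(nms) / names_per_doc))
      lapply(seq_along(chunks), function(i) {
        items <- list()
        for (nm in chunks[[i]]) {
          items <- c(items, filler_item(2L),
                     list(list(text = nm, class = "GENE", type = "GENE-Y")))
        }
        sec <- assemble_section(items, "ABSTRACT")
        ner_document(sprintf("%s%05d", prefix, i),
                     title = paste(prefix, "group document", i),
                     abstract = sec$text, entities = sec$entities)
      })
    }
    list(a = mk_group(names_a, "GA"), b = mk_group(names_b, "GB"))
  })
}
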