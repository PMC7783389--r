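## Token feature extraction: orthographic features, cue-word lexicon
## membership, suffixes, a lightweight rule-based POS tag, and +/-1 context
## windows.  Every token yields one feature map; the CRF consumes the maps
## as "name=value" indicator atoms.

#' Load a cue-word or stop-word lexicon
#'
#' One term per line; terms are lower-cased and deduplicated, and membership
#' tests are case-insensitive.  A term may legitimately appear in both the
#' chemical ("C") and gene/protein ("G") cue lexicons, in which case a token
#' matching it carries both marks.
#'
#' @param path File with one term per line (UTF-8).
#' @param tag \code{"C"} (chemical cues), \code{"G"} (gene/protein cues) or
#'   \code{"STOP"} (stop words).
#' @return An object of class \code{ner_lexicon}: list with \code{entries}
#'   (sorted lowercase character vector) and \code{tag}.
#' @export
load_lexicon <- function(path, tag = c("C", "G", "STOP")) {
  tag <- match.arg(tag)
  entries <- readLines(path, encoding = "UTF-8", warn = FALSE)
  entries <- trimws(entries)
  entries <- sort(unique(tolower(entries[nzchar(entries)])))
  if (!length(entries)) warning("empty lexicon: ", path)
  structure(list(entries = entries, tag = tag), class = "ner_lexicon")
}

#' @rdname load_lexicon
#' @param lexicon A \code{ner_lexicon}.
#' @param words Character vector to test.
#' @return \code{lexicon_has}: logical vector of case-insensitive membership.
#' @export
lexicon_has <- function(lexicon, words) {
  tolower(words) %in% lexicon$entries
}

#' Default lexicons shipped with the package
#'
#' Small curated cue lists seeded from terms that commonly flag a nearby
#' chemical ("inhibit", "chemical", ...) or gene/protein ("target", "genes",
#' ...) mention, plus a standard English stop-word list.  Users with richer
#' curated lists should load their own via \code{\link{load_lexicon}}.
#'
#' @return Named list with elements \code{C}, \code{G}, \code{STOP}.
#' @export
default_lexicons <- function() {
  path <- function(f) system.file("extdata", f, package = "crfner", mustWork = TRUE)
  list(C = load_lexicon(path("nonspecific_chemical.txt"), "C"),
       G = load_lexicon(path("nonspecific_gene.txt"), "G"),
       STOP = load_lexicon(path("stopwords_english.txt"), "STOP"))
}

## Closed-class words for the rule POS tagger.
.pos_closed <- list(
  DT = c("a", "an", "the", "this", "that", "these", "those", "each", "every",
         "some", "any", "no"),
  IN = c("of", "in", "on", "at", "by", "for", "with", "from", "to", "into",
         "against", "between", "during", "after", "before", "under", "over",
         "through", "as"),
  CC = c("and", "or", "but", "nor"),
  PRP = c("it", "its", "we", "our", "they", "their", "he", "she", "his",
          "her", "them", "us", "i", "you"),
  MD = c("can", "could", "may", "might", "must", "shall", "should", "will",
         "would"),
  VBZ = c("is", "was", "has", "does"),
  VBP = c("are", "were", "have", "do", "be", "been")
)

#' Rule-based part-of-speech tagging
#'
#' A small deterministic tagger over closed-class word lists and suffix
#' rules, returning Penn-style tag strings.  It exists so feature extraction
#' has no heavyweight model dependency; any function mapping a character
#' vector of words to a same-length character vector of tags can be supplied
#' wherever a POS provider is accepted.
#'
#' @param words Character vector of token strings.
#' @return Character vector of tags.
#' @export
rule_pos_tagger <- function(words) {
  tags <- rep("NN", length(words))
  lw <- tolower(words)
  for (tag in names(.pos_closed)) {
    tags[lw %in% .pos_closed[[tag]]] <- tag
  }
  open <- !(lw %in% unlist(.pos_closed))
  tags[open & grepl("^[0-9]+$", words)] <- "CD"
  tags[open & grepl("^[^\\p{L}\\p{N}_]+$", words, perl = TRUE)] <- "PUNCT"
  is_word <- open & grepl("^[\\p{L}\\p{N}_]+$", words, perl = TRUE)
  tags[is_word & grepl("ly$", lw)] <- "RB"
  tags[is_word & grepl("(ing)$", lw) & nchar(words) > 4L] <- "VBG"
  tags[is_word & grepl("(ed)$", lw) & nchar(words) > 3L] <- "VBN"
  tags[is_word & grepl("(ive|ous|al|ic)$", lw) & nchar(words) > 4L] <- "JJ"
  tags[is_word & tags == "NN" & grepl("s$", lw) & nchar(words) > 3L] <- "NNS"
  tags[is_word & grepl("^\\p{Lu}", words, perl = TRUE) & tags %in% c("NN", "NNS")] <- "NNP"
  tags
}

## All base features for a vector of words, as parallel character vectors.
## Single code path shared by token_features() and the CRF atom builder.
base_feature_frame <- function(words, postags, lexicons) {
  lower <- tolower(words)
  n <- nchar(words)
  suffix <- function(k) {
    s <- substr(words, pmax(1L, n - k + 1L), n)
    s
  }
  bucket <- cut(n, breaks = c(0, 1, 2, 3, 6, 10, Inf),
                labels = c("1", "2", "3", "4-6", "7-10", ">10"))
  list(
    word = words,
    lower = lower,
    isupper = words == toupper(words) & grepl("\\p{Lu}", words, perl = TRUE),
    istitle = grepl("^\\p{Lu}", words, perl = TRUE),
    isdigit = grepl("^[0-9]+$", words),
    hasdigits = grepl("[0-9]", words),
    isnonspecific_C = lexicon_has(lexicons$C, words),
    isnonspecific_G = lexicon_has(lexicons$G, words),
    isstopword = lexicon_has(lexicons$STOP, words),
    hassymbols = grepl("[^\\p{L}\\p{N}_]", words, perl = TRUE),
    suffix3 = suffix(3L),
    suffix2 = suffix(2L),
    firstchar = substr(words, 1L, 1L),
    length = as.character(n),
    length_bucket = as.character(bucket),
    postag = postags
  )
}

#' Compute the base feature map for one token
#'
#' The features are: the word itself and its lower-cased form; the
#' orthographic booleans isupper, istitle, isdigit, hasdigits, hassymbols
#' (hassymbols is true iff the word contains a character that is neither
#' alphanumeric nor underscore); cue-lexicon membership isnonspecific_C /
#' isnonspecific_G and stop-word membership; the last-three and last-two
#' character suffixes (the whole word when shorter); the first character;
#' the length in characters (raw and bucketed); and the POS tag.
#'
#' @param token Token string (or one-row token table from
#'   \code{\link{wp_tokenize}}).
#' @param postag POS tag string for the token.
#' @param lexicons Named list with \code{C}, \code{G}, \code{STOP} lexicons,
#'   as from \code{\link{default_lexicons}}.
#' @return Named character vector of feature values.
#' @export
token_features <- function(token, postag = rule_pos_tagger(token),
                           lexicons = default_lexicons()) {
  if (is.data.frame(token)) token <- token$text
  stopifnot(length(token) == 1L)
  f <- base_feature_frame(token, postag, lexicons)
  vapply(f, function(v) as.character(v[1L]), character(1L))
}

#' Feature maps for a token sequence with +/-1 context windows
#'
#' Element \code{t} of the result carries the token's own base features plus
#' full copies of the base features of tokens \code{t-1} and \code{t+1}
#' under \code{"prev:"} and \code{"next:"} prefixes.  The first token
#' carries a \code{BOS} flag instead of a \code{prev:} block and the last an
#' \code{EOS} flag instead of a \code{next:} block; every token also carries
#' a constant \code{bias} feature.
#'
#' @param tokens Token table from \code{\link{wp_tokenize}} (or character
#'   vector of words).
#' @param pos_tagger Function from words to tags; see
#'   \code{\link{rule_pos_tagger}}.
#' @param lexicons As in \code{\link{token_features}}.
#' @return List of named character vectors, one per token.
#' @export
sequence_features <- function(tokens, pos_tagger = rule_pos_tagger,
                              lexicons = default_lexicons()) {
  words <- if (is.data.frame(tokens)) tokens$text else tokens
  T <- length(words)
  if (T == 0L) return(list())
  base <- base_feature_frame(words, pos_tagger(words), lexicons)
  nm <- names(base)
  mat <- vapply(base, as.character, character(T))      # T x nfeat
  if (T == 1L) mat <- matrix(mat, nrow = 1L, dimnames = list(NULL, nm))
  out <- vector("list", T)
  for (t in seq_len(T)) {
    own <- stats::setNames(mat[t, ], nm)
    prev <- if (t > 1L) stats::setNames(mat[t - 1L, ], paste0("prev:", nm))
            else c(BOS = "TRUE")
    nxt <- if (t < T) stats::setNames(mat[t + 1L, ], paste0("next:", nm))
           else c(EOS = "TRUE")
    out[[t]] <- c(bias = "1", own, prev, nxt)
  }
  out
}

## Indicator atoms ("name=value" strings) for a whole sequence, vectorised.
## Equivalent to lapply(sequence_features(...), feature_atoms) but built
## column-wise; this is the hot path for corpus-scale training.
sequence_atoms <- function(words, pos_tagger = rule_pos_tagger,
                           lexicons = default_lexicons()) {
  T <- length(words)
  if (T == 0L) return(list())
  base <- base_feature_frame(words, pos_tagger(words), lexicons)
  nm <- names(base)
  own <- lapply(nm, function(k) paste0(k, "=", as.character(base[[k]])))
  own <- do.call(cbind, own)                           # T x nfeat
  prev <- rbind(rep(NA_character_, ncol(own)),
                matrix(paste0("prev:", own[-T, , drop = FALSE]), nrow = T - 1L))
  nxt <- rbind(matrix(paste0("next:", own[-1L, , drop = FALSE]), nrow = T - 1L),
               rep(NA_character_, ncol(own)))
  out <- vector("list", T)
  for (t in seq_len(T)) {
    a <- c("bias=1", own[t, ],
           if (t == 1L) "BOS=TRUE" else prev[t, ],
           if (t == T) "EOS=TRUE" else nxt[t, ])
    out[[t]] <- a[!is.na(a)]
  }
  out
}

#' Convert a feature map to CRF indicator atoms
#'
#' Each \code{name=value} pair becomes one string atom; the CRF indexes
#' atoms, not raw feature values.
#'
#' @param fmap Named character vector from \code{\link{token_features}} or
#'   one element of \code{\link{sequence_features}}.
#' @return Character vector of atoms.
#' @export
feature_atoms <- function(fmap) {
  paste0(names(fmap), "=", unname(fmap))
}
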