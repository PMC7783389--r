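#' Word-punctuation tokenization with character offsets
#'
#' Splits text into maximal runs of word characters (letters, digits,
#' underscore) or of non-word, non-space characters, the same segmentation
#' rule as NLTK's \code{wordpunct_tokenize}.  Offsets are 0-based, half-open
#' and count Unicode code points, so \code{substr}-style slicing of the
#' source text at \code{[start, end)} always reproduces \code{text}.
#'
#' @param text Character scalar (UTF-8).  \code{NA} or empty input gives an
#'   empty token table.
#' @return A data frame with columns \code{text}, \code{start}, \code{end},
#'   one row per token, in source order.
#' @examples
#' wp_tokenize("sphingosine-1-phosphate")$text
#' @export
wp_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  text <- enc2utf8(text)
  m <- gregexpr("[\\p{L}\\p{N}_]+|[^\\p{L}\\p{N}_\\s]+", text, perl = TRUE)[[1]]
  if (m[1L] == -1L) return(empty)
  start <- as.integer(m) - 1L                       # to 0-based
  len <- attr(m, "match.length")
  data.frame(text = substring(text, start + 1L, start + len),
             start = start, end = start + as.integer(len),
             stringsAsFactors = FALSE)
}

#' @rdname wp_tokenize
#' @param tokens A token table as returned by \code{wp_tokenize}.
#' @param source The original text; used to check losslessness.
#' @return \code{tokens_consistent}: TRUE if every token equals its source
#'   slice and tokens are ordered and non-overlapping.
#' @export
tokens_consistent <- function(tokens, source) {
  if (nrow(tokens) == 0L) return(TRUE)
  slices <- substring(source, tokens$start + 1L, tokens$end)
  all(slices == tokens$text) &&
    all(tokens$start < tokens$end) &&
    all(diff(tokens$start) > 0) &&
    all(tokens$start[-1L] >= tokens$end[-nrow(tokens)])
}

sobie_labels <- c("S", "O", "B", "I", "E")

#' Encode character-offset entity spans as per-token SOBIE labels
#'
#' SOBIE (equivalently BIOES/IOBES) marks a single-token entity \code{S}, the
#' first and last tokens of a multi-token entity \code{B} and \code{E}, its
#' interior tokens \code{I}, and all other tokens \code{O}.
#'
#' A span whose boundary falls strictly inside a token is widened to cover
#' the whole token, with a warning: labels stay total and recall is
#' preserved.  Overlapping spans are rejected.
#'
#' @param tokens Token table from \code{\link{wp_tokenize}}.
#' @param spans Data frame with columns \code{start}, \code{end} (0-based,
#'   half-open, same coordinate system as \code{tokens}).
#' @return Character vector of labels, one per token.
#' @export
sobie_encode <- function(tokens, spans) {
  labels <- rep("O", nrow(tokens))
  if (is.null(spans) || nrow(spans) == 0L) return(labels)
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  if (nrow(spans) > 1L) {
    prev_end <- spans$end[-nrow(spans)]
    nxt_start <- spans$start[-1L]
    bad <- which(nxt_start < prev_end)
    if (length(bad)) {
      stop(sprintf("overlapping spans: [%d,%d) and [%d,%d)",
                   spans$start[bad[1L]], spans$end[bad[1L]],
                   spans$start[bad[1L] + 1L], spans$end[bad[1L] + 1L]))
    }
  }
  for (i in seq_len(nrow(spans))) {
    hit <- which(tokens$end > spans$start[i] & tokens$start < spans$end[i])
    if (!length(hit)) {
      stop(sprintf("span [%d,%d) does not cover any token",
                   spans$start[i], spans$end[i]))
    }
    if (tokens$start[hit[1L]] < spans$start[i] ||
        tokens$end[hit[length(hit)]] > spans$end[i]) {
      warning(sprintf(
        "span [%d,%d) not token-aligned; widened to token boundaries",
        spans$start[i], spans$end[i]))
    }
    if (any(labels[hit] != "O")) stop("overlapping spans after widening")
    n <- length(hit)
    labels[hit] <- if (n == 1L) "S" else c("B", rep("I", n - 2L), "E")
  }
  labels
}

#' Decode SOBIE labels back to character-offset spans
#'
#' Inverse of \code{\link{sobie_encode}} on well-formed label sequences.
#' Ill-formed sequences (as produced by an imperfect tagger) are repaired
#' leniently and deterministically: an \code{I} or \code{E} with no open
#' entity opens one; a \code{B} not followed by \code{I}/\code{E} closes as a
#' single-token entity; an open entity is closed by the first \code{E} or by
#' the token before the next \code{O}/\code{S}/\code{B}.
#'
#' @param tokens Token table.
#' @param labels Character vector of SOBIE labels, one per token.
#' @param source Optional source text; when given, each decoded span's
#'   \code{text} is the source slice from first to last token (interior
#'   punctuation and spacing preserved), otherwise tokens are joined with
#'   single spaces.
#' @return Data frame with columns \code{start}, \code{end}, \code{text};
#'   spans are ordered and non-overlapping.
#' @export
sobie_decode <- function(tokens, labels, source = NULL) {
  if (nrow(tokens) != length(labels)) {
    stop(sprintf("length mismatch: %d tokens vs %d labels",
                 nrow(tokens), length(labels)))
  }
  bad <- setdiff(unique(labels), sobie_labels)
  if (length(bad)) stop("unknown SOBIE labels: ", paste(bad, collapse = ", "))
  starts <- integer(); ends <- integer()
  open <- NA_integer_  # index of first token of an open entity
  for (t in seq_along(labels)) {
    lab <- labels[t]
    if (!is.na(open) && lab %in% c("O", "S", "B")) {
      starts <- c(starts, open); ends <- c(ends, t - 1L); open <- NA_integer_
    }
    if (lab == "S") {
      starts <- c(starts, t); ends <- c(ends, t)
    } else if (lab == "B") {
      open <- t
    } else if (lab == "I") {
      if (is.na(open)) open <- t            # lenient: I with no B opens
    } else if (lab == "E") {
      if (is.na(open)) open <- t            # lenient: E with no B opens
      starts <- c(starts, open); ends <- c(ends, t); open <- NA_integer_
    }
  }
  if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, length(labels)) }
  if (!length(starts)) {
    return(data.frame(start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  cs <- tokens$start[starts]
  ce <- tokens$end[ends]
  txt <- if (!is.null(source)) {
    substring(source, cs + 1L, ce)
  } else {
    vapply(seq_along(starts), function(i) {
      paste(tokens$text[starts[i]:ends[i]], collapse = " ")
    }, character(1L))
  }
  data.frame(start = cs, end = ce, text = txt, stringsAsFactors = FALSE)
}
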