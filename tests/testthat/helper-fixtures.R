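## Shared fixtures and independent oracles.

## Write a two-file corpus to tempfiles; returns the two paths.
write_corpus_fixture <- function(abstract_lines, annotation_lines) {
  ap <- tempfile(fileext = ".tsv"); np <- tempfile(fileext = ".tsv")
  writeLines(abstract_lines, ap)
  writeLines(annotation_lines, np)
  c(abstracts = ap, annotations = np)
}

## A tiny two-document corpus with one chemical and one gene span.
tiny_corpus <- function() {
  list(
    ner_document("D1", title = "ATP study",
                 abstract = "ATP binds the RT1 enzyme",
                 entities = data.frame(
                   section = c("ABSTRACT", "ABSTRACT"),
                   start = c(0L, 14L), end = c(3L, 17L),
                   text = c("ATP", "RT1"),
                   entity_class = c("CHEMICAL", "GENE"),
                   entity_type = c("ABBREVIATION", "GENE-Y"),
                   stringsAsFactors = FALSE)),
    ner_document("D2", title = "control document",
                 abstract = "no mentions here at all"))
}

## Random small CRF instance for enumeration oracles: returns the model
## plus a sequence of atom vectors drawn from its index.
random_crf_instance <- function(T_len, L, n_atoms = 6L) {
  alphabet <- LETTERS[seq_len(L)]
  index <- paste0("f=", letters[seq_len(n_atoms)])
  Ws <- matrix(stats::rnorm(n_atoms * L), n_atoms, L)
  Wt <- matrix(stats::rnorm(L * L), L, L)
  model <- crf_manual(index, alphabet, Ws, Wt)
  feats <- lapply(seq_len(T_len), function(t) {
    sample(index, sample(1:3, 1L), replace = FALSE)
  })
  list(model = model, feats = feats)
}

## Brute-force enumeration over all |L|^T labelings using the plain R
## scorer; returns log-partition, the best score, and the argmax labeling
## under the reversed-lexicographic tie-break (earliest alphabet label at
## the latest differing position).
enumerate_crf <- function(model, feats) {
  alphabet <- model$label_alphabet
  T_len <- length(feats); L <- length(alphabet)
  grid <- as.matrix(expand.grid(rep(list(seq_len(L)), T_len)))
  scores <- apply(grid, 1L, function(idx) {
    sequence_score(model, feats, alphabet[idx])
  })
  logZ <- {
    m <- max(scores)
    m + log(sum(exp(scores - m)))
  }
  tied <- which(scores >= max(scores) - 1e-12)
  cand <- grid[tied, , drop = FALSE]
  ord <- do.call(order, as.data.frame(cand[, rev(seq_len(T_len)), drop = FALSE]))
  list(logZ = logZ, best_score = max(scores),
       best_labels = alphabet[cand[ord[1L], ]])
}

## Separable toy training set: the cue atom uniquely identifies the label.
separable_toyset <- function(n = 20L) {
  x <- vector("list", n); y <- vector("list", n)
  for (i in seq_len(n)) {
    x[[i]] <- list(c("w=drugx", "bias=1"), c("w=the", "bias=1"),
                   c("w=geney", "bias=1"))
    y[[i]] <- c("S", "O", "O")
  }
  list(x = x, y = y)
}
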