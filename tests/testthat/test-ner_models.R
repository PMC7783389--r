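## Shared small training setup (built once for this file).
train_docs <- generate_corpus(synth_config(n_docs = 60, seed = 101))
lexs <- default_lexicons()
train_seqs <- featurize_corpus(train_docs, lexs)
quiet_fit <- function(expr) suppressWarnings(expr)  # iteration-cap warnings
chem_m <- quiet_fit(train_span_model(train_docs, "CHEMICAL", seqs = train_seqs))
gene_m <- quiet_fit(train_span_model(train_docs, "GENE", seqs = train_seqs))
type_m <- quiet_fit(train_type_model(train_docs, seqs = train_seqs))
bundle <- ner_tagger(chem_m, gene_m, type_m, lexicons = lexs)

test_that("a span model recovers nearly all planted training mentions", {
  y <- crfner:::sequence_labels(train_seqs, train_docs, "sobie", "CHEMICAL")
  pred <- predict(chem_m, lapply(train_seqs, `[[`, "atoms"))
  exact <- 0L; total <- 0L
  for (i in seq_along(y)) {
    toks <- train_seqs[[i]]$tokens
    g <- sobie_decode(toks, y[[i]])
    p <- sobie_decode(toks, pred[[i]])
    total <- total + nrow(g)
    exact <- exact + sum(paste(g$start, g$end) %in% paste(p$start, p$end))
  }
  expect_gt(total, 100)
  expect_gte(exact / total, 0.9)
})

test_that("training demands annotations of the requested class", {
  no_chem <- generate_corpus(synth_config(n_docs = 5, chem_density = 0,
                                          gene_density = 2, seed = 8))
  expect_error(train_span_model(no_chem, "CHEMICAL"), "no annotated entities")
  expect_error(train_type_model(no_chem), "no typed chemical")
})

test_that("training is deterministic: same data and config give identical models", {
  small <- train_docs[1:12]
  f1 <- quiet_fit(train_span_model(small, "CHEMICAL",
                                   crf_config(max_iterations = 30)))
  f2 <- quiet_fit(train_span_model(small, "CHEMICAL",
                                   crf_config(max_iterations = 30)))
  expect_identical(f1$state_weights, f2$state_weights)
  expect_identical(f1$transition_weights, f2$transition_weights)
})

test_that("the type model's alphabet is O plus the observed types", {
  expect_equal(type_m$label_alphabet[1], "O")
  expect_true(all(type_m$label_alphabet[-1] %in% crfner:::chem_types))
  y <- crfner:::sequence_labels(train_seqs, train_docs, "type")
  expect_setequal(type_m$label_alphabet, unique(unlist(y)))
  # a document without chemicals contributes only O labels
  plain <- ner_document("P", "only filler words", "more filler words here")
  sq <- featurize_corpus(list(plain), lexs)
  yy <- crfner:::sequence_labels(sq, list(plain), "type")
  expect_true(all(unlist(yy) == "O"))
})

test_that("the combined tagger predicts both layers without touching inputs", {
  doc <- generate_corpus(synth_config(n_docs = 30, seed = 777))[[3]]
  before <- doc
  out <- apply_combined(bundle, doc)
  expect_identical(doc, before)               # no mutation
  expect_identical(out$entities, doc$entities)  # gold layer untouched
  expect_silent(validate_document(out))         # slice-equals-text holds
  expect_true(all(out$predicted$entity_class %in% c("CHEMICAL", "GENE")))
  chem_pred <- out$predicted[out$predicted$entity_class == "CHEMICAL", ]
  expect_true(all(chem_pred$entity_type %in% c(crfner:::chem_types, "UNSPECIFIED")))
  # an empty document yields no predictions
  empty <- ner_document("E", "", "")
  expect_equal(nrow(apply_combined(bundle, empty)$predicted), 0L)
})

test_that("some tagged document carries both a chemical and a gene prediction", {
  docs <- generate_corpus(synth_config(n_docs = 10, seed = 555))
  tagged <- tag_corpus(bundle, docs)
  both <- vapply(tagged, function(d) {
    length(unique(d$predicted$entity_class)) == 2L
  }, logical(1L))
  expect_true(any(both))
})

test_that("a saved and reloaded bundle reproduces predictions exactly", {
  path <- tempfile(fileext = ".rds")
  save_tagger(bundle, path)
  back <- load_tagger(path, lexicons = lexs)
  doc <- generate_corpus(synth_config(n_docs = 2, seed = 31))[[1]]
  expect_identical(apply_combined(back, doc)$predicted,
                   apply_combined(bundle, doc)$predicted)
  # mismatched lexicons are refused
  other <- lexs
  other$C <- structure(list(entries = "something", tag = "C"),
                       class = "ner_lexicon")
  expect_error(load_tagger(path, lexicons = other), "lexicon mismatch")
  expect_error(suppressWarnings(load_tagger(tempfile(), lexicons = lexs)))
})

test_that("cross-validation partitions documents evenly and is seed-stable", {
  docs <- train_docs[1:25]
  cv1 <- quiet_fit(cross_validate(docs, "CHEMICAL",
                                  crf_config(max_iterations = 40),
                                  cv_config(k = 5, seed = 11)))
  expect_length(cv1$fold_reports, 5L)
  expect_equal(as.numeric(table(cv1$fold_assignment)), rep(5, 5))
  cv2 <- quiet_fit(cross_validate(docs, "CHEMICAL",
                                  crf_config(max_iterations = 40),
                                  cv_config(k = 5, seed = 11)))
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_equal(cv1$mean_macro, cv2$mean_macro)
  expect_equal(unname(cv1$mean_macro["f1"]),
               mean(vapply(cv1$fold_reports, function(r) r$macro[["f1"]],
                           numeric(1L))))
  # uneven division: sizes differ by at most one
  folds7 <- crfner:::make_folds(25, 7, 3)
  expect_lte(diff(range(table(folds7))), 1)
  expect_error(cross_validate(docs[1:3], "CHEMICAL", cv = cv_config(k = 5)),
               "fewer documents")
})
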