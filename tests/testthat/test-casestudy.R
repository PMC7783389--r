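test_that("name normalization case-folds and strips flanking punctuation only", {
  expect_equal(normalize_name(c("Dasatinib", "(AZT)", "HIV-1 RT,")),
               c("dasatinib", "azt", "hiv-1 rt"))
  expect_equal(normalize_name("  gag-pol   protein "), "gag-pol protein")
})

test_that("type filtering removes excluded classes, preserves order, is idempotent", {
  ents <- data.frame(
    section = "ABSTRACT", start = c(0L, 5L, 10L, 15L), end = c(3L, 8L, 13L, 18L),
    text = c("aaa", "bbb", "ccc", "ddd"), entity_class = "CHEMICAL",
    entity_type = c("TRIVIAL", "FORMULA", "FAMILY", "SYSTEMATIC"),
    stringsAsFactors = FALSE)
  out <- filter_by_type(ents)
  expect_equal(out$entity_type, c("TRIVIAL", "SYSTEMATIC"))
  expect_equal(filter_by_type(out), out)
  expect_equal(filter_by_type(ents, character()), ents)
  expect_equal(nrow(filter_by_type(ents[0, ])), 0L)
})

test_that("the co-occurrence rule requires a protein and a surviving chemical", {
  mk <- function(types, classes) {
    n <- length(types)
    d <- ner_document("D1", "t", paste(rep("xxxxx", n), collapse = " "))
    d$predicted <- data.frame(
      section = "ABSTRACT", start = seq(0L, by = 6L, length.out = n),
      end = seq(5L, by = 6L, length.out = n), text = rep("xxxxx", n),
      entity_class = classes, entity_type = types, stringsAsFactors = FALSE)
    d
  }
  both <- mk(c("TRIVIAL", "SYSTEMATIC", "GENE-Y"),
             c("CHEMICAL", "CHEMICAL", "GENE"))
  expect_length(select_candidate_inhibitors(both), 1L)  # same surface name
  no_gene <- mk(c("TRIVIAL", "SYSTEMATIC"), c("CHEMICAL", "CHEMICAL"))
  expect_length(select_candidate_inhibitors(no_gene), 0L)
  no_chem <- mk("GENE-Y", "GENE")
  expect_length(select_candidate_inhibitors(no_chem), 0L)
  # chemicals all filtered out -> empty
  filtered <- mk(c("FORMULA", "GENE-Y"), c("CHEMICAL", "GENE"))
  expect_length(select_candidate_inhibitors(filtered), 0L)
  empty <- ner_document("D2", "t", "abstract text")
  expect_length(select_candidate_inhibitors(empty), 0L)
})

test_that("profiles collect unique normalized names with provenance", {
  docs <- generate_grouped_profiles(6, 4, 2, seed = 3)$a
  prof <- build_profile(docs, "g1", "GENE", source = "entities")
  expect_length(prof$names, 6L)
  expect_true(all(prof$names == tolower(prof$names)))
  expect_setequal(names(prof$provenance), prof$names)
  # same name in several docs -> one entry, several provenance ids
  d1 <- ner_document("P1", "t", "ABC1 here",
                     entities = data.frame(section = "ABSTRACT", start = 0L,
                                           end = 4L, text = "ABC1",
                                           entity_class = "GENE",
                                           entity_type = "GENE-Y",
                                           stringsAsFactors = FALSE))
  d2 <- d1; d2$doc_id <- "P2"
  d3 <- d1; d3$doc_id <- "P3"
  p <- build_profile(list(d1, d2, d3), "g", "GENE", source = "entities")
  expect_length(p$names, 1L)
  expect_length(p$provenance[["abc1"]], 3L)
  expect_length(build_profile(list(), "empty", "GENE")$names, 0L)
})

test_that("profile differencing satisfies its count identities on random sets", {
  set.seed(23)
  for (rep in 1:20) {
    a <- unique(replicate(sample(0:30, 1L),
                          paste(sample(letters, 4), collapse = "")))
    b <- unique(replicate(sample(0:30, 1L),
                          paste(sample(letters, 4), collapse = "")))
    d <- diff_profiles(a, b)
    expect_equal(length(d$unique_to_a) + length(d$overlap), length(a))
    expect_equal(length(d$unique_to_b) + length(d$overlap), length(b))
    expect_length(intersect(d$unique_to_a, d$overlap), 0L)
    expect_length(intersect(d$unique_to_b, d$overlap), 0L)
    expect_length(intersect(d$unique_to_a, d$unique_to_b), 0L)
  }
  same <- diff_profiles(c("x", "y"), c("y", "x"))
  expect_length(same$unique_to_a, 0L)
  expect_setequal(same$overlap, c("x", "y"))
  disjoint <- diff_profiles("x", "y")
  expect_length(disjoint$overlap, 0L)
})

test_that("the offline resolver resolves known names and reports MISS otherwise", {
  res <- lookup_names(c("gag-pol protein", "GAG-POL", "unseen-protein-xyz"))
  expect_equal(res[["gag-pol protein"]]$id, "SYN:P0001")
  expect_equal(res[["GAG-POL"]]$id, "SYN:P0001")   # synonym, case-insensitive
  expect_identical(res[["unseen-protein-xyz"]], "MISS")
  expect_length(lookup_names(character()), 0L)
  # resolver failure degrades to MISS with a warning, not an abort
  boom <- function(name) stop("backend down")
  expect_warning(r2 <- lookup_names("anything", boom), "resolver failed")
  expect_identical(r2[["anything"]], "MISS")
})

test_that("group subtraction removes shared documents before profiling", {
  a <- list(ner_document("X1", "t", "a"), ner_document("X2", "t", "b"))
  b <- list(ner_document("X2", "t", "b"), ner_document("X3", "t", "c"))
  kept <- exclude_docs(a, b)
  expect_equal(vapply(kept, `[[`, character(1L), "doc_id"), "X1")
  expect_length(exclude_docs(a, list()), 2L)
})
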