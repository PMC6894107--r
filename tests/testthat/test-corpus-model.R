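test_that("tokenizer splits edge punctuation but preserves compounds and abbreviations", {
  tk <- tokenize("blood pressure 134/75")
  expect_equal(tk$text, c("blood", "pressure", "134/75"))

  tk <- tokenize("q p.m.")
  expect_equal(tk$text, c("q", "p.m."))

  tk <- tokenize("Denied any chest pain.")
  expect_equal(tk$text, c("Denied", "any", "chest", "pain", "."))
  expect_equal(tk$start, c(0L, 7L, 11L, 17L, 21L))
  expect_equal(tk$end, c(6L, 10L, 16L, 21L, 22L))

  expect_equal(nrow(tokenize("")), 0L)
  expect_equal(nrow(tokenize("   ")), 0L)

  tk <- tokenize("(mild) x-ray, etc.")
  expect_equal(tk$text, c("(", "mild", ")", "x-ray", ",", "etc", "."))

  # offsets shift by the sentence offset and always recover the substring
  s <- "urine blood - NEG"
  tk <- tokenize(s, 100L)
  expect_equal(tk$start[1], 100L)
  expect_equal(substring(s, tk$start - 100L + 1L, tk$end - 100L), tk$text)
})

test_that("span alignment finds covering token ranges and enforces strict mode", {
  tk <- tokenize("Denied any chest pain.")
  expect_equal(align_span(11L, 21L, tk), c(3L, 4L))    # "chest pain"
  expect_equal(align_span(0L, 6L, tk), c(1L, 1L))      # single token
  # mid-token boundary: strict errors, expand covers
  expect_error(align_span(11L, 19L, tk, "strict"), class = "attrseq_alignment_error")
  expect_equal(align_span(11L, 19L, tk, "expand"), c(3L, 4L))
  # monotone: enlarging a span never shrinks the range
  r1 <- align_span(11L, 16L, tk, "expand")
  r2 <- align_span(7L, 21L, tk, "expand")
  expect_true(r2[1] <= r1[1] && r2[2] >= r1[2])
})

test_that("standoff reading reproduces mentions, types and relations", {
  paths <- write_denied_standoff()
  doc <- read_standoff(paths["txt"], paths["ann"])
  expect_s3_class(doc, "attrseq_document")
  expect_equal(nrow(doc$concepts), 1L)
  expect_equal(doc$concepts$text, "chest pain")
  expect_equal(doc$attributes$attr_type, "NEG")
  expect_equal(doc$attributes$text, "Denied")
  expect_equal(nrow(doc$relations), 1L)
})

test_that("empty annotation file yields an empty document", {
  dir <- withr::local_tempdir()
  writeChar("Nothing here.", file.path(dir, "e.txt"), eos = NULL)
  writeLines(character(0), file.path(dir, "e.ann"))
  doc <- read_standoff(file.path(dir, "e.txt"))
  expect_equal(nrow(doc$concepts), 0L)
  expect_equal(nrow(doc$attributes), 0L)
  expect_equal(nrow(doc$relations), 0L)
})

test_that("offset/text mismatch and malformed lines are rejected with context", {
  paths <- write_denied_standoff()
  lines <- readLines(paths["ann"])
  lines[1] <- "T1\tDisorder 10 20\tchest pain"   # perturbed offset
  writeLines(lines, paths["ann"])
  expect_error(read_standoff(paths["txt"], paths["ann"]),
               class = "attrseq_integrity_error")

  paths <- write_denied_standoff()
  lines <- readLines(paths["ann"])
  lines[2] <- "T2\tNEG zero six\tDenied"
  writeLines(lines, paths["ann"])
  expect_error(read_standoff(paths["txt"], paths["ann"]),
               class = "attrseq_parse_error")

  # unresolvable relation endpoint
  paths <- write_denied_standoff()
  cat("R9\tAttrOf Arg1:T1 Arg2:T99\n", file = paths["ann"], append = TRUE)
  expect_error(read_standoff(paths["txt"], paths["ann"]),
               class = "attrseq_integrity_error")
})

test_that("discontiguous mentions are dropped with a warning", {
  dir <- withr::local_tempdir()
  writeChar("left and right arm pain today.", file.path(dir, "d.txt"),
            eos = NULL)
  writeLines(c(
    "T1\tDisorder 19 23\tpain",
    "T2\tBDL 0 4;9 18\tleft right arm",
    "R1\tAttrOf Arg1:T1 Arg2:T2"), file.path(dir, "d.ann"))
  expect_warning(doc <- read_standoff(file.path(dir, "d.txt")),
                 "discontiguous")
  expect_equal(nrow(doc$attributes), 0L)
  expect_equal(nrow(doc$relations), 0L)
  expect_equal(nrow(doc$concepts), 1L)
})

test_that("write/read standoff round-trips generated corpora exactly", {
  gen <- small_corpus(n = 4, seed = 9)
  dir <- withr::local_tempdir()
  write_corpus(gen$documents, dir)
  back <- read_corpus(dir)
  expect_equal(length(back), length(gen$documents))
  for (i in seq_along(back)) {
    expect_equal(unclass(back[[i]]), unclass(gen$documents[[i]]))
  }
})

test_that("an attribute linked to two concepts emits two relation lines", {
  doc <- kidney_document()
  doc$relations <- tibble::add_row(doc$relations,
                                   concept_id = "C2", attribute_id = "A1")
  dir <- withr::local_tempdir()
  write_standoff(doc, dir)
  ann <- readLines(file.path(dir, "kidney.ann"))
  expect_equal(sum(grepl("Arg2:A1", ann)), 2L)
  # zero-mention document produces an empty .ann
  empty <- annotated_document("nil", "just text here.")
  write_standoff(empty, dir)
  expect_equal(length(readLines(file.path(dir, "nil.ann"))), 0L)
})

test_that("document construction enforces corpus invariants", {
  # cross-sentence mention rejected
  expect_error(
    annotated_document("x", "one line\nsecond line",
                       concepts = tibble::tibble(id = "C1",
                                                 concept_type = "Disorder",
                                                 start = 4L, end = 14L)),
    class = "attrseq_integrity_error")
  # duplicate mention ids rejected
  expect_error(
    annotated_document("x", "pain and pain",
      concepts = tibble::tibble(id = c("T1", "T1"), concept_type = "Disorder",
                                start = c(0L, 9L), end = c(4L, 13L))),
    class = "attrseq_integrity_error")
  # duplicate relations rejected
  expect_error(
    annotated_document("x", "no pain",
      concepts = tibble::tibble(id = "C", concept_type = "Disorder",
                                start = 3L, end = 7L),
      attributes = tibble::tibble(id = "A", attr_type = "NEG",
                                  start = 0L, end = 2L),
      relations = tibble::tibble(concept_id = c("C", "C"),
                                 attribute_id = c("A", "A"))),
    class = "attrseq_integrity_error")
  # unknown attribute type rejected
  expect_error(
    annotated_document("x", "no pain",
      attributes = tibble::tibble(id = "A", attr_type = "XYZ",
                                  start = 0L, end = 2L)),
    class = "attrseq_integrity_error")
})

test_that("token spans tile sentences and match the document text", {
  gen <- small_corpus(n = 3, seed = 77)
  for (doc in gen$documents) {
    expect_equal(attrseq:::substr0(doc$text, doc$tokens$start, doc$tokens$end),
                 doc$tokens$text)
  }
})

test_that("sentence splitting is newline-based with an opt-in period rule", {
  s <- split_sentences("first line\nsecond line")
  expect_equal(nrow(s), 2L)
  expect_equal(s$text, c("first line", "second line"))
  p <- split_sentences("One sent. Two sent.\nThree", method = "period")
  expect_equal(nrow(p), 3L)
  expect_equal(p$text[2], "Two sent.")
})
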