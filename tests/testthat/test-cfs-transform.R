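test_that("CFS transformation labels only the target's attributes", {
  doc <- kidney_document()
  seqs <- expand_document(doc)
  expect_length(seqs, 2L)

  # sequence focused on "enlarged R kidney"
  cfs1 <- seqs[[which(vapply(seqs, function(s) s$target_id, "") == "C1")]]
  tok <- cfs1$tokens
  labeled <- tok$text[tok$label != "O"]
  expect_setequal(labeled, c("markedly", "R", "kidney"))
  expect_equal(tok$label[tok$text == "markedly"], "B-SEV")
  expect_equal(tok$label[tok$text == "R"], "B-BDL")
  expect_equal(tok$label[tok$text == "kidney"], "I-BDL")
  # the other concept's cues are O here
  expect_equal(tok$label[tok$text %in% c("no", "small", "bowel")],
               rep("O", 3L))
  # roles: target tokens Target, other concept NotTarget, rest Outside
  expect_equal(tok$role[tok$text %in% c("enlarged", "R", "kidney")],
               rep("Target", 3L))
  expect_equal(tok$role[tok$text %in% c("air", "fluid", "level")],
               rep("NotTarget", 3L))
  expect_equal(tok$role[tok$text == "markedly"], "Outside")

  # attribute overlapping the target keeps role Target AND carries B/I
  expect_equal(tok$role[tok$label %in% c("B-BDL", "I-BDL")],
               rep("Target", 2L))

  # the mirror sequence: only "no" and "small bowel" labeled
  cfs2 <- seqs[[which(vapply(seqs, function(s) s$target_id, "") == "C2")]]
  labeled2 <- cfs2$tokens$text[cfs2$tokens$label != "O"]
  expect_setequal(labeled2, c("no", "small", "bowel"))
  expect_equal(cfs2$tokens$label[cfs2$tokens$text == "no"], "B-NEG")
})

test_that("a concept with no relations gets an all-O sequence", {
  doc <- annotated_document(
    "x", "chronic edema noted",
    concepts = tibble::tibble(id = "C1", concept_type = "Disorder",
                              start = 8L, end = 13L))
  cfs <- make_cfs(doc, 1L, "C1")
  expect_true(all(cfs$tokens$label == "O"))
  expect_equal(cfs$tokens$role[cfs$tokens$text == "edema"], "Target")
})

test_that("a two-token target-linked attribute is exactly B then I of one type", {
  doc <- denied_document()
  doc2 <- annotated_document(
    "y", "left arm pain today",
    concepts = tibble::tibble(id = "C1", concept_type = "Disorder",
                              start = 9L, end = 13L),
    attributes = tibble::tibble(id = "A1", attr_type = "BDL",
                                start = 0L, end = 8L),
    relations = tibble::tibble(concept_id = "C1", attribute_id = "A1"))
  cfs <- make_cfs(doc2, 1L, "C1")
  expect_equal(cfs$tokens$label, c("B-BDL", "I-BDL", "O", "O"))
})

test_that("make_cfs validates its target and detects label conflicts", {
  doc <- kidney_document()
  expect_error(make_cfs(doc, 1L, "C9"))
  # two target-linked attributes of different types on the same token
  clash <- annotated_document(
    "z", "severe pain",
    concepts = tibble::tibble(id = "C1", concept_type = "Disorder",
                              start = 7L, end = 11L),
    attributes = tibble::tibble(id = c("A1", "A2"),
                                attr_type = c("SEV", "COU"),
                                start = c(0L, 0L), end = c(6L, 6L)),
    relations = tibble::tibble(concept_id = c("C1", "C1"),
                               attribute_id = c("A1", "A2")))
  expect_error(make_cfs(clash, 1L, "C1"), class = "attrseq_label_conflict")
})

test_that("document expansion yields one sequence per concept per sentence", {
  # 3 sentences carrying 1, 0, 2 concepts
  doc <- annotated_document(
    "multi", "mild rash seen\nno concepts here\nedema and pain",
    concepts = tibble::tibble(
      id = c("C1", "C2", "C3"), concept_type = "Disorder",
      start = c(5L, 32L, 42L), end = c(9L, 37L, 46L)))
  seqs <- expand_document(doc)
  expect_length(seqs, 3L)
  expect_equal(vapply(seqs, function(s) s$sentence, 1L), c(1L, 3L, 3L))

  gen <- small_corpus(n = 5, seed = 3)
  seqs <- expand_document(gen$documents)
  expect_length(seqs, sum(vapply(gen$documents,
                                 function(d) nrow(d$concepts), 1L)))

  # permuting the stored concept order changes nothing
  doc2 <- doc
  doc2$concepts <- doc2$concepts[c(3, 1, 2), ]
  expect_equal(lapply(expand_document(doc2), unclass),
               lapply(seqs <- expand_document(doc), unclass))
})

test_that("decoding recovers mentions from BIO runs with repair", {
  doc <- kidney_document()
  cfs <- make_cfs(doc, 1L, "C1")
  n <- nrow(cfs$tokens)

  lab <- rep("O", n); lab[3] <- "B-SEV"; lab[5] <- "B-BDL"; lab[6] <- "I-BDL"
  dec <- decode_cfs(cfs, lab)
  expect_equal(nrow(dec), 2L)
  expect_setequal(dec$attr_type, c("SEV", "BDL"))
  expect_true(all(dec$concept_id == "C1"))
  expect_equal(dec$attr_start[dec$attr_type == "BDL"], cfs$tokens$start[5])
  expect_equal(dec$attr_end[dec$attr_type == "BDL"], cfs$tokens$end[6])

  expect_equal(nrow(decode_cfs(cfs, rep("O", n))), 0L)

  # dangling I- repaired to a fresh mention
  lab <- rep("O", n); lab[1] <- "I-NEG"
  dec <- decode_cfs(cfs, lab)
  expect_equal(dec$attr_type, "NEG")
  expect_equal(dec$attr_start, cfs$tokens$start[1])

  # I after a different type starts a new mention
  lab <- rep("O", n); lab[2] <- "B-SEV"; lab[3] <- "I-BDL"
  dec <- decode_cfs(cfs, lab)
  expect_equal(dec$attr_type, c("SEV", "BDL"))

  expect_error(decode_cfs(cfs, rep("B-???", n)),
               class = "attrseq_decode_error")
  expect_error(decode_cfs(cfs, "O"))
})

test_that("gold encode/decode is the identity on generated corpora", {
  gen <- small_corpus(n = 6, seed = 21)
  gold <- gold_pairs(gen$documents)
  for (cfs in expand_document(gen$documents)) {
    dec <- decode_cfs(cfs)
    g <- gold[gold$doc_id == cfs$doc_id & gold$concept_id == cfs$target_id, ]
    expect_setequal(paste(dec$attr_type, dec$attr_start, dec$attr_end),
                    paste(g$attr_type, g$attr_start, g$attr_end))
  }
})

test_that("CoNLL-style sequence files round-trip", {
  gen <- small_corpus(n = 3, seed = 5)
  seqs <- expand_document(gen$documents)
  path <- withr::local_tempfile(fileext = ".conll")
  write_cfs_conll(seqs, path)
  back <- read_cfs_conll(path)
  expect_length(back, length(seqs))
  for (i in seq_along(back)) {
    expect_equal(unclass(back[[i]]), unclass(seqs[[i]]))
  }
})
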