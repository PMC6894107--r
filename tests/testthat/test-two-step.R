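test_that("candidate generation is the per-sentence Cartesian product", {
  # 2 concepts x 3 attributes in one sentence -> 6 pairs
  doc <- annotated_document(
    "c", "no severe pain and mild edema",
    concepts = tibble::tibble(id = c("C1", "C2"), concept_type = "Disorder",
                              start = c(10L, 24L), end = c(14L, 29L)),
    attributes = tibble::tibble(id = c("A1", "A2", "A3"),
                                attr_type = c("NEG", "SEV", "SEV"),
                                start = c(0L, 3L, 19L),
                                end = c(2L, 9L, 23L)),
    relations = tibble::tibble(concept_id = c("C1", "C1", "C2"),
                               attribute_id = c("A1", "A2", "A3")))
  pairs <- generate_candidates(doc)
  expect_equal(nrow(pairs), 6L)
  expect_equal(sum(pairs$related), 3L)

  # the two-concept/four-attribute radiology sentence: 8 pairs, 4 positive
  pairs <- generate_candidates(kidney_document())
  expect_equal(nrow(pairs), 8L)
  expect_equal(sum(pairs$related), 4L)

  # no attributes -> no candidates
  empty <- annotated_document(
    "e", "pain only",
    concepts = tibble::tibble(id = "C1", concept_type = "Disorder",
                              start = 0L, end = 4L))
  expect_equal(nrow(generate_candidates(empty)), 0L)

  # candidate count identity on generated corpora
  gen <- small_corpus(n = 4, seed = 31)
  for (doc in gen$documents) {
    pairs <- generate_candidates(doc)
    per_sentence <- vapply(doc$sentences$sentence, function(si) {
      sum(doc$concepts$sentence == si) * sum(doc$attributes$sentence == si)
    }, 1L)
    expect_equal(nrow(pairs), sum(per_sentence))
  }
})

test_that("pair features encode bags, distance sign and overlap", {
  doc <- annotated_document(
    "f", "severe pain in the liver",
    concepts = tibble::tibble(id = "C1", concept_type = "Disorder",
                              start = 7L, end = 11L),
    attributes = tibble::tibble(id = c("A1", "A2"),
                                attr_type = c("SEV", "BDL"),
                                start = c(0L, 19L), end = c(6L, 24L)),
    relations = tibble::tibble(concept_id = c("C1", "C1"),
                               attribute_id = c("A1", "A2")))
  pairs <- generate_candidates(doc)
  tokens <- doc$tokens

  # adjacent attribute left of the concept: empty between bag, negative dist
  f1 <- featurize_pair(pairs[pairs$attr_id == "A1", ], tokens)
  expect_equal(attr(f1, "distance"), -1L)
  expect_false(any(startsWith(f1, "wbtw=")))
  expect_true("dir=left" %in% f1)

  # attribute right of the concept with material between
  f2 <- featurize_pair(pairs[pairs$attr_id == "A2", ], tokens)
  expect_gt(attr(f2, "distance"), 0L)
  expect_true(all(c("wbtw=in", "wbtw=the", "dir=right") %in% f2))

  # overlapping mentions: distance 0 and the overlap flag
  doc2 <- kidney_document()
  pairs2 <- generate_candidates(doc2)
  ov <- pairs2[pairs2$attr_id == "A2" & pairs2$concept_id == "C1", ]
  f3 <- featurize_pair(ov, doc2$tokens)
  expect_equal(attr(f3, "distance"), 0L)
  expect_true("dir=overlap" %in% f3)
})

test_that("the margin classifier separates separable pairs and degrades gracefully", {
  gen <- small_corpus(n = 10, seed = 17)
  docs <- gen$documents
  pairs <- purrr::map_dfr(docs, generate_candidates)
  expect_gt(nrow(pairs), 20)
  suppressWarnings(clf <- train_margin_classifier(pairs, docs))
  acc <- mean(predict_margin_classifier(clf, pairs, docs) == pairs$related)
  expect_gt(acc, 0.95)

  # single-class training data: constant predictor with a warning
  one <- pairs[pairs$related & pairs$attr_type == "NEG", ][1:2, ]
  expect_warning(clf1 <- train_margin_classifier(one, docs), "single-class")
  expect_true(all(predict_margin_classifier(clf1, one, docs)))

  # contradictory duplicated pairs are non-separable but train fine
  contra <- dplyr::bind_rows(pairs[1:4, ], pairs[1:4, ])
  contra$related <- rep(c(TRUE, FALSE), each = 4)
  expect_no_error(suppressWarnings(train_margin_classifier(contra, docs)))
})

test_that("the Bi-LSTM pair classifier learns and needs its position channel", {
  gen <- small_corpus(n = 10, seed = 29, distractor_prob = 0)
  docs <- gen$documents
  pairs <- purrr::map_dfr(docs, generate_candidates)
  cfg <- pair_lstm_config(word_dim = 20L, pos_dim = 8L, hidden = 20L,
                          epochs = 30L, learning_rate = 0.1, seed = 3L)
  suppressWarnings(clf <- train_lstm_pair_classifier(pairs, docs, cfg))
  acc <- mean(predict_lstm_pair_classifier(clf, pairs, docs) == pairs$related)
  expect_gt(acc, 0.9)

  # determinism under a fixed seed
  suppressWarnings(clf2 <- train_lstm_pair_classifier(pairs, docs, cfg))
  expect_identical(
    predict_lstm_pair_classifier(clf, pairs, docs),
    predict_lstm_pair_classifier(clf2, pairs, docs))

  # a position-only task: same words everywhere, relation determined by
  # adjacency; ablating position embeddings forfeits the signal
  docs3 <- lapply(1:8, function(i) {
    annotated_document(
      sprintf("p%02d", i), "mild pain and edema",
      concepts = tibble::tibble(id = c("C1", "C2"),
                                concept_type = "Disorder",
                                start = c(5L, 14L), end = c(9L, 19L)),
      attributes = tibble::tibble(id = "A1", attr_type = "SEV",
                                  start = 0L, end = 4L),
      relations = tibble::tibble(concept_id = "C1", attribute_id = "A1"))
  })
  pairs3 <- purrr::map_dfr(docs3, generate_candidates)
  clf_pos <- train_lstm_pair_classifier(pairs3, docs3, cfg)
  acc_pos <- mean(predict_lstm_pair_classifier(clf_pos, pairs3, docs3) ==
                    pairs3$related)
  clf_abl <- train_lstm_pair_classifier(pairs3, docs3, cfg,
                                        use_positions = FALSE)
  acc_abl <- mean(predict_lstm_pair_classifier(clf_abl, pairs3, docs3) ==
                    pairs3$related)
  expect_equal(acc_pos, 1)
  # without positions the two candidates of each sentence are identical
  # inputs with opposite labels: accuracy cannot beat one of the two classes
  expect_lte(acc_abl, 0.5)
})

test_that("concept-blind NER overfits a clean corpus but not an ambiguous one", {
  gen <- small_corpus(n = 8, seed = 37, distractor_prob = 0)
  docs <- gen$documents
  cfg <- tagger_config(learning_rate = 0.3, dropout = 0, epochs = 30L,
                       seed = 5L)
  ner <- ner_train(docs, "disorder", cfg)
  mentions <- ner_predict(ner, docs)
  gold <- purrr::map_dfr(docs, function(d)
    tibble::tibble(doc_id = d$doc_id, attr_type = d$attributes$attr_type,
                   attr_start = d$attributes$start,
                   attr_end = d$attributes$end))
  key <- function(m) paste(m$doc_id, m$attr_type, m$attr_start, m$attr_end)
  tp <- sum(key(mentions) %in% key(gold))
  f1 <- 2 * tp / (nrow(mentions) + nrow(gold))
  expect_equal(f1, 1)

  # omitted annotations: the same sentence annotated in one note and not
  # in another (the cue modifies nothing there) gives the concept-blind
  # tagger contradictory labels for identical inputs — its loss has an
  # irreducible floor of log(2) per contradicted sequence pair
  mk <- function(id, text, annotate, cue_span, con_span, ty) {
    if (annotate) {
      annotated_document(id, text,
        concepts = tibble::tibble(id = "C1", concept_type = "Disorder",
                                  start = con_span[1], end = con_span[2]),
        attributes = tibble::tibble(id = "A1", attr_type = ty,
                                    start = cue_span[1], end = cue_span[2]),
        relations = tibble::tibble(concept_id = "C1", attribute_id = "A1"))
    } else annotated_document(id, text)
  }
  contradictory <- c(
    lapply(1:1, function(i) mk("a1", "severe edema noted", TRUE,
                               c(0L, 6L), c(7L, 12L), "SEV")),
    list(mk("a2", "severe edema noted", FALSE, NULL, NULL, NULL),
         mk("b1", "no rash today", TRUE, c(0L, 2L), c(3L, 7L), "NEG"),
         mk("b2", "no rash today", FALSE, NULL, NULL, NULL)))
  ner2 <- ner_train(contradictory, "disorder", cfg)
  expect_gt(ner2$loss[length(ner2$loss)], log(2) - 0.05)

  expect_error(ner_train(list(), "disorder"))
})

test_that("the cascade composes and propagates mention deletions", {
  gen <- small_corpus(n = 10, seed = 41)
  docs <- gen$documents
  cfg <- tagger_config(learning_rate = 0.3, dropout = 0, epochs = 25L,
                       seed = 5L)
  suppressWarnings(
    model <- two_step_fit(docs, "disorder", "margin", ner_config = cfg))
  pred <- predict(model, docs)
  expect_true(all(c("doc_id", "concept_id", "attr_type", "attr_start",
                    "attr_end") %in% names(pred)))

  gold <- gold_pairs(docs)
  base <- strict_prf(gold, pred)
  # two-step recall is bounded above by NER recall on attribute mentions
  mentions <- ner_predict(model$ner, docs)
  gk <- paste(gold$doc_id, gold$attr_type, gold$attr_start, gold$attr_end)
  mk <- paste(mentions$doc_id, mentions$attr_type, mentions$attr_start,
              mentions$attr_end)
  ner_recall <- mean(gk %in% mk)
  pooled_recall <- sum(base$tp) / sum(base$n_gold)
  expect_lte(pooled_recall, ner_recall + 1e-12)

  # deleting predicted mentions can only lose the pairs they carried
  pred_half <- predict(model, docs, drop_mentions = 0.5, seed = 11L)
  rec_full <- sum(strict_prf(gold, pred)$tp) / nrow(gold)
  rec_half <- sum(strict_prf(gold, pred_half)$tp) / nrow(gold)
  expect_lte(rec_half, rec_full + 1e-12)
})
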