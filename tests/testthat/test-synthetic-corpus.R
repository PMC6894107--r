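test_that("generation is deterministic under the config seed", {
  g1 <- small_corpus(n = 4, seed = 33)
  g2 <- small_corpus(n = 4, seed = 33)
  expect_identical(lapply(g1$documents, unclass),
                   lapply(g2$documents, unclass))
  expect_identical(g1$ledger$mentions, g2$ledger$mentions)
  g3 <- small_corpus(n = 4, seed = 34)
  expect_false(identical(lapply(g1$documents, unclass),
                         lapply(g3$documents, unclass)))
})

test_that("the ledger matches the emitted annotations exactly", {
  gen <- small_corpus(n = 5, seed = 45)
  led <- gen$ledger$mentions
  for (doc in gen$documents) {
    lm <- led[led$doc_id == doc$doc_id, ]
    expect_setequal(
      paste(lm$id, lm$type, lm$start, lm$end),
      c(paste(doc$concepts$id, doc$concepts$concept_type,
              doc$concepts$start, doc$concepts$end),
        paste(doc$attributes$id, doc$attributes$attr_type,
              doc$attributes$start, doc$attributes$end)))
  }
  ledr <- gen$ledger$relations
  all_rel <- purrr::map_dfr(gen$documents, function(d) {
    r <- d$relations; if (nrow(r)) r$doc_id <- d$doc_id; r
  })
  expect_equal(nrow(ledr), nrow(all_rel))
  # distractor spans are never annotated
  for (i in seq_len(nrow(gen$ledger$distractors))) {
    d <- gen$ledger$distractors[i, ]
    doc <- gen$documents[[match(d$doc_id,
                                vapply(gen$documents, function(x) x$doc_id, ""))]]
    expect_false(any(doc$attributes$start == d$start &
                       doc$attributes$end == d$end))
  }
})

test_that("corpus statistics agree with the ledger counts", {
  gen <- small_corpus(n = 5, seed = 50)
  st <- corpus_stats(gen$documents)
  led <- gen$ledger$mentions
  expect_equal(st$n[st$item == "concepts"], sum(led$kind == "concept"))
  for (ty in setdiff(st$item, c("concepts", "relations"))) {
    expect_equal(st$n[st$item == ty], sum(led$type == ty))
  }
  expect_equal(corpus_stats(list())$n, c(0L, 0L))
})

test_that("degenerate configurations behave as documented", {
  # zero attachment: concepts only
  p0 <- setNames(rep(0, 7), task_attributes("disorder"))
  gen <- generate_corpus(gen_config(task = "disorder", n_documents = 4,
                                    attach_prob = p0, shared_prob = 0,
                                    crossing_prob = 0, distractor_prob = 0,
                                    seed = 3))
  expect_true(all(vapply(gen$documents,
                         function(d) nrow(d$attributes), 1L) == 0L))
  expect_gt(sum(vapply(gen$documents, function(d) nrow(d$concepts), 1L)), 0L)

  expect_error(gen_config(task = "disorder", shared_prob = 2))
  expect_error(gen_config(task = "nope"))
})

test_that("without distractors every attribute-cue occurrence is annotated", {
  gen <- small_corpus(n = 8, seed = 55, distractor_prob = 0)
  lex <- attrseq:::default_lexicons("disorder")
  for (doc in gen$documents) {
    ann <- paste(doc$attributes$start, doc$attributes$end)
    for (ty in names(lex$cues)) {
      for (cue in lex$cues[[ty]]) {
        hits <- gregexpr(paste0("(?<![a-z])", gsub(" ", " ", cue),
                                "(?![a-z])"), doc$text, perl = TRUE)[[1]]
        if (hits[1] == -1) next
        for (h in hits) {
          st <- as.integer(h) - 1L
          expect_true(paste(st, st + nchar(cue)) %in% ann,
                      label = sprintf("cue '%s' at %d in %s annotated",
                                      cue, st, doc$doc_id))
        }
      }
    }
  }
})

test_that("attachment rates land within binomial tolerance", {
  p <- c(NEG = 0.5, SUB = 0, CON = 0, SEV = 0, COU = 0, UNC = 0, BDL = 0)
  gen <- generate_corpus(gen_config(
    task = "disorder", n_documents = 120, sentences_per_document = c(3, 4),
    attach_prob = p, shared_prob = 0, crossing_prob = 0,
    distractor_prob = 0, seed = 8))
  n_con <- sum(vapply(gen$documents, function(d) nrow(d$concepts), 1L))
  n_neg <- nrow(gen$ledger$relations)
  rate <- n_neg / n_con
  sigma <- sqrt(0.5 * 0.5 / n_con)
  expect_lt(abs(rate - 0.5), 3 * sigma)
})

test_that("crossing sentences plant genuinely crossing relation arcs", {
  gen <- generate_corpus(gen_config(
    task = "disorder", n_documents = 10, crossing_prob = 1,
    concept_dist = c(0, 0, 1, 0), shared_prob = 0, distractor_prob = 0,
    seed = 12))
  found <- FALSE
  for (doc in gen$documents) {
    g <- gold_pairs(doc)
    if (nrow(g) < 2) next
    for (i in seq_len(nrow(g) - 1)) for (j in (i + 1):nrow(g)) {
      a <- sort(c(g$concept_start[i], g$attr_start[i]))
      b <- sort(c(g$concept_start[j], g$attr_start[j]))
      if (a[1] < b[1] && b[1] < a[2] && a[2] < b[2]) found <- TRUE
    }
  }
  expect_true(found)
  # every attribute sits farther from its own concept than from the other
  # listed concept: the nearest-concept heuristic fails here by design
  mis <- 0; tot <- 0
  for (doc in gen$documents) {
    g <- gold_pairs(doc)
    cons <- doc$concepts
    for (i in seq_len(nrow(g))) {
      others <- cons[cons$sentence ==
                       cons$sentence[match(g$concept_id[i], cons$id)], ]
      if (nrow(others) < 2) next
      dmine <- abs(g$attr_start[i] - g$concept_start[i])
      tot <- tot + 1
      if (any(abs(g$attr_start[i] - others$start[others$id != g$concept_id[i]])
              < dmine)) mis <- mis + 1
    }
  }
  expect_gt(mis / tot, 0.4)
})

test_that("generated corpora for every task pass standoff validation", {
  for (task in c("disorder", "medication", "labtest")) {
    gen <- generate_corpus(gen_config(task = task, n_documents = 3,
                                      seed = 14))
    dir <- withr::local_tempdir()
    write_corpus(gen$documents, dir)
    expect_no_error(back <- read_corpus(dir))
    expect_equal(length(back), 3L)
    # and they expand/decode coherently
    for (cfs in expand_document(gen$documents)) {
      expect_no_error(decode_cfs(cfs))
    }
    # the tagger trains and predicts over each task's label inventory
    seqs <- expand_document(gen$documents)
    m <- train_tagger(seqs, task, tiny_tagger_config(epochs = 1L, seed = 2L))
    labs <- predict(m, seqs)
    expect_true(all(unlist(labs) %in% label_set(task)))
  }
})
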