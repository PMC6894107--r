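default_lexicons <- function(task) {
  switch(task,
    disorder = list(
      concepts = c("chest pain", "edema", "pneumonia", "nausea", "rash",
                   "fracture", "infection", "mass", "effusion", "bleeding",
                   "headache", "cyst"),
      cues = list(
        NEG = c("no", "denies", "denied", "without", "not"),
        SUB = c("mother", "father", "brother", "sister"),
        CON = c("on exertion", "with activity", "when standing"),
        SEV = c("mild", "moderate", "severe", "markedly", "slight"),
        COU = c("worsening", "improving", "resolved", "increasing"),
        UNC = c("possible", "probable", "suspected", "questionable"),
        BDL = c("pelvis", "abdomen", "head", "left arm", "right kidney",
                "liver", "lung", "small bowel", "lower back"))),
    medication = list(
      concepts = c("insulin", "aspirin", "lisinopril", "metformin",
                   "warfarin", "amoxicillin", "ibuprofen", "atorvastatin"),
      cues = list(
        DOS = c("12 units", "81 mg", "500 mg", "20 mg", "10 ml", "250 mg",
                "40 mg", "5 mg"),
        MOD = c("po", "iv", "subcu", "topical", "oral"),
        FRE = c("daily", "bid", "tid", "q p.m.", "prn", "nightly"),
        DUR = c("for 5 days", "for 2 weeks", "x 10 days", "for 1 month"),
        REA = c("for fever", "for hypertension", "for cough",
                "for dizziness"))),
    labtest = list(
      concepts = c("blood pressure", "heart rate", "glucose", "hemoglobin",
                   "urine blood", "creatinine", "wbc", "sodium"),
      cues = list(
        VAL = c("134/75", "98", "7.2", "140", "88", "13.5", "5.4",
                "NEG", "POS", "normal", "elevated", "trace"))))
}

default_attach_prob <- function(task) {
  switch(task,
    disorder = c(NEG = 0.25, SUB = 0.05, CON = 0.08, SEV = 0.15,
                 COU = 0.10, UNC = 0.10, BDL = 0.45),
    medication = c(DOS = 0.5, MOD = 0.4, FRE = 0.45, DUR = 0.1, REA = 0.1),
    labtest = c(VAL = 0.85))
}

#' Configuration of the synthetic corpus generator
#'
#' Describes a clinical-style corpus with the structural properties the
#' attribute-detection methods face in real notes: sentences with 0-3
#' target concepts, per-concept attribute sets drawn per type with the
#' given attachment probabilities, attributes occasionally shared between
#' two conjoined concepts, attribute-like distractor spans that are left
#' unannotated (the omitted-annotation phenomenon that breaks
#' concept-blind NER), and "respectively"-style crossing sentences in
#' which each attribute belongs to the farther of two concepts — the hard
#' case for proximity heuristics.
#'
#' @param task `"disorder"`, `"medication"` or `"labtest"`.
#' @param n_documents Number of documents.
#' @param sentences_per_document Integer range `c(min, max)`.
#' @param concept_dist Probabilities of 0, 1, 2, 3 concepts per sentence.
#' @param attach_prob Named per-attribute-type attachment probability.
#' @param shared_prob Probability that a multi-concept sentence realizes
#'   two concepts conjoined under one shared attribute.
#' @param distractor_prob Probability that a sentence carries an
#'   unannotated attribute-like cue.
#' @param crossing_prob Probability that an eligible sentence is realized
#'   as a crossing "respectively" construction.
#' @param lexicons Vocabulary tables (concept surface forms and per-type
#'   cue lexicons); defaults built in per task.
#' @param seed Generator seed.
#' @return A `gen_config` list.
#' @export
gen_config <- function(task = "disorder", n_documents = 50L,
                       sentences_per_document = c(3L, 6L),
                       concept_dist = c(0.10, 0.40, 0.30, 0.20),
                       attach_prob = NULL, shared_prob = 0.1,
                       distractor_prob = 0.2, crossing_prob = 0.25,
                       lexicons = NULL, seed = 1L) {
  task <- match.arg(task, names(TASK_ATTRIBUTES))
  if (is.null(attach_prob)) attach_prob <- default_attach_prob(task)
  if (is.null(lexicons)) lexicons <- default_lexicons(task)
  stopifnot(length(concept_dist) == 4L, abs(sum(concept_dist) - 1) < 1e-8,
            all(attach_prob >= 0 & attach_prob <= 1),
            shared_prob >= 0, shared_prob <= 1,
            distractor_prob >= 0, distractor_prob <= 1,
            crossing_prob >= 0, crossing_prob <= 1,
            n_documents >= 1,
            all(names(attach_prob) %in% task_attributes(task)),
            length(lexicons$concepts) > 0,
            all(lengths(lexicons$cues[names(attach_prob)]) > 0))
  structure(list(task = task, n_documents = as.integer(n_documents),
                 sentences_per_document = as.integer(sentences_per_document),
                 concept_dist = concept_dist, attach_prob = attach_prob,
                 shared_prob = shared_prob, distractor_prob = distractor_prob,
                 crossing_prob = crossing_prob, lexicons = lexicons,
                 seed = as.integer(seed)),
            class = "attrseq_gen_config")
}

sample1 <- function(x) x[[sample.int(length(x), 1L)]]

# Mutable sentence builder: words plus mention bookkeeping in local offsets.
new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$words <- character(0)
  env$mentions <- list()
  env
}

builder_len <- function(b) {
  if (!length(b$words)) 0L
  else nchar(paste(b$words, collapse = " "))
}

builder_add <- function(b, phrase, kind = NULL, type = NULL,
                        annotated = TRUE) {
  ws <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  start <- if (length(b$words)) builder_len(b) + 1L else 0L
  b$words <- c(b$words, ws)
  end <- start + nchar(paste(ws, collapse = " "))
  if (!is.null(kind)) {
    b$mentions[[length(b$mentions) + 1L]] <-
      list(kind = kind, type = type, start = start, end = end,
           text = phrase, annotated = annotated)
  }
  invisible(c(start, end))
}

# One concept segment with its sampled attribute cues; returns relation
# bookkeeping through the builder's mention list. With annotate = FALSE the
# identical surface is realized but nothing is annotated — an
# omitted-annotation distractor: the noun is a concept surface form that is
# not a given target concept, so its cues relate to nothing and stay
# unannotated, exactly as in gold corpora where attributes are only
# annotated when linked to a concept.
realize_concept <- function(b, cfg, concept_surface, annotate = TRUE) {
  task <- cfg$task
  lex <- cfg$lexicons
  p <- cfg$attach_prob
  types <- names(p)
  attached <- types[runif(length(types)) < p]
  if (!annotate && !length(attached)) attached <- sample1(types)
  n_before <- length(b$mentions)
  add <- function(phrase, kind, type) {
    builder_add(b, phrase, if (annotate) kind else "distractor", type,
                annotated = annotate)
  }
  if (task == "disorder") {
    for (ty in intersect(c("SUB", "NEG", "UNC", "SEV", "COU"), attached)) {
      add(sample1(lex$cues[[ty]]), "attribute", ty)
    }
    add(concept_surface, "concept", task_concept_type(task))
    if ("BDL" %in% attached) {
      builder_add(b, "in the")
      add(sample1(lex$cues$BDL), "attribute", "BDL")
    }
    if ("CON" %in% attached) {
      add(sample1(lex$cues$CON), "attribute", "CON")
    }
  } else if (task == "medication") {
    add(concept_surface, "concept", task_concept_type(task))
    for (ty in intersect(c("DOS", "MOD", "FRE", "DUR", "REA"), attached)) {
      add(sample1(lex$cues[[ty]]), "attribute", ty)
    }
  } else {
    add(concept_surface, "concept", task_concept_type(task))
    if ("VAL" %in% attached) {
      builder_add(b, "was")
      add(sample1(lex$cues$VAL), "attribute", "VAL")
    }
  }
  new_mentions <- b$mentions[seq(n_before + 1L, length(b$mentions))]
  ci <- which(vapply(new_mentions, function(m) m$kind == "concept", logical(1)))
  list(concept_idx = n_before + ci,
       attr_idx = setdiff(seq(n_before + 1L, length(b$mentions)),
                          n_before + ci))
}

# "no <c1> or <c2>": one cue related to both conjoined concepts.
realize_shared <- function(b, cfg, surfaces) {
  lex <- cfg$lexicons
  ty <- switch(cfg$task, disorder = sample1(c("NEG", "SEV")),
               medication = "FRE", labtest = "VAL")
  n0 <- length(b$mentions)
  if (cfg$task == "labtest") {
    builder_add(b, surfaces[1], "concept", task_concept_type(cfg$task))
    builder_add(b, "and")
    builder_add(b, surfaces[2], "concept", task_concept_type(cfg$task))
    builder_add(b, "were both")
    builder_add(b, sample1(lex$cues[[ty]]), "attribute", ty)
    cidx <- n0 + c(1L, 2L); aidx <- n0 + 3L
  } else {
    builder_add(b, sample1(lex$cues[[ty]]), "attribute", ty)
    builder_add(b, surfaces[1], "concept", task_concept_type(cfg$task))
    builder_add(b, "or")
    builder_add(b, surfaces[2], "concept", task_concept_type(cfg$task))
    cidx <- n0 + c(2L, 3L); aidx <- n0 + 1L
  }
  list(concept_idx = cidx, attr_idx = aidx)
}

# "in the <C1> , <C2> and <C3> , <A1> , <A2> and <A3> ... respectively":
# attribute k relates to concept k. With 2- and 3-item lists mixed in one
# corpus the same signed attribute-concept distance is sometimes related
# and sometimes not, so nearest-concept and distance-bucket heuristics
# cannot resolve these sentences; the listing order can.
realize_crossing <- function(b, cfg, surfaces) {
  lex <- cfg$lexicons
  k <- length(surfaces)
  tys <- switch(cfg$task,
                disorder = sample(c("SEV", "COU"), k, replace = TRUE),
                medication = rep("MOD", k), labtest = rep("VAL", k))
  n0 <- length(b$mentions)
  intro <- switch(cfg$task, disorder = "in the", medication = "continue",
                  labtest = "the")
  builder_add(b, intro)
  for (i in seq_len(k)) {
    if (i > 1L) builder_add(b, if (i == k) "and" else ",")
    builder_add(b, surfaces[i], "concept", task_concept_type(cfg$task))
  }
  builder_add(b, switch(cfg$task, disorder = ",", medication = ",",
                        labtest = "were"))
  for (i in seq_len(k)) {
    if (i > 1L) builder_add(b, if (i == k) "and" else ",")
    builder_add(b, sample1(lex$cues[[tys[i]]]), "attribute", tys[i])
  }
  builder_add(b, "respectively")
  list(concept_idx = n0 + seq_len(k), attr_idx = n0 + k + seq_len(k),
       relations = cbind(concept = n0 + seq_len(k),
                         attr = n0 + k + seq_len(k)))
}

# Surface-identical to a normal concept segment; nothing annotated.
realize_distractor <- function(b, cfg) {
  realize_concept(b, cfg, sample1(cfg$lexicons$concepts), annotate = FALSE)
  invisible(NULL)
}

#' Generate a synthetic annotated corpus
#'
#' Template-realized clinical-style documents with gold concepts,
#' attribute mentions and relations, deterministic under the config seed.
#' The generation ledger records every planted item — annotated mentions,
#' relations and unannotated distractor cues — for oracle checks against
#' the emitted annotations.
#'
#' @param config A [gen_config()].
#' @return List with `documents` (list of [annotated_document()]) and
#'   `ledger` (list of tibbles `mentions`, `relations`, `distractors`).
#' @export
generate_corpus <- function(config = gen_config()) {
  if (!inherits(config, "attrseq_gen_config")) {
    abort("config must come from gen_config()")
  }
  set.seed(config$seed)
  docs <- list()
  led_m <- list(); led_r <- list(); led_d <- list()
  prefixes <- switch(config$task,
    disorder = c("patient reports", "exam shows", "assessment :"),
    medication = c("started", "continue home", "medications include"),
    labtest = c("labs today :", "vitals :", "results :"))

  for (d in seq_len(config$n_documents)) {
    doc_id <- sprintf("doc%03d", d)
    rng <- config$sentences_per_document
    n_sent <- if (rng[1] == rng[2]) rng[1] else sample1(seq(rng[1], rng[2]))
    sent_texts <- character(0)
    concepts <- list(); attributes <- list(); relations <- list()
    tcount <- 0L
    offset <- 0L

    for (si in seq_len(n_sent)) {
      b <- new_builder()
      builder_add(b, sample1(prefixes))
      n_con <- sample(0:3, 1L, prob = config$concept_dist)
      rels <- NULL   # rows (concept mention index, attr mention index)

      if (n_con >= 2 && runif(1) < config$crossing_prob) {
        k <- min(n_con, 3L)
        surfaces <- sample(config$lexicons$concepts, k)
        r <- realize_crossing(b, config, surfaces)
        rels <- r$relations
        n_con <- n_con - k
      } else if (n_con >= 2 && runif(1) < config$shared_prob) {
        surfaces <- sample(config$lexicons$concepts, 2L)
        r <- realize_shared(b, config, surfaces)
        rels <- cbind(concept = r$concept_idx,
                      attr = rep(r$attr_idx, length(r$concept_idx)))
        n_con <- n_con - 2L
      }
      while (n_con > 0L) {
        if (length(b$mentions)) builder_add(b, sample1(c("and", "with", ";")))
        r <- realize_concept(b, config, sample1(config$lexicons$concepts))
        if (length(r$attr_idx)) {
          rels <- rbind(rels, cbind(concept = rep(r$concept_idx,
                                                  length(r$attr_idx)),
                                    attr = r$attr_idx))
        }
        n_con <- n_con - 1L
      }
      if (runif(1) < config$distractor_prob) {
        if (length(b$mentions)) builder_add(b, sample1(c("and", "with", ";")))
        realize_distractor(b, config)
      }

      stext <- paste(b$words, collapse = " ")
      if (!grepl("[.]$", stext)) stext <- paste0(stext, " .")
      # assign global ids/offsets for this sentence's mentions
      local_ids <- character(length(b$mentions))
      for (mi in seq_along(b$mentions)) {
        m <- b$mentions[[mi]]
        gs <- offset + m$start; ge <- offset + m$end
        if (m$kind == "distractor") {
          led_d[[length(led_d) + 1L]] <- tibble(
            doc_id = doc_id, sentence = si, type = m$type,
            start = gs, end = ge, text = m$text)
          next
        }
        tcount <- tcount + 1L
        id <- paste0("T", tcount)
        local_ids[mi] <- id
        row <- tibble(id = id, start = gs, end = ge, text = m$text)
        if (m$kind == "concept") {
          row$concept_type <- m$type
          concepts[[length(concepts) + 1L]] <- row
        } else {
          row$attr_type <- m$type
          attributes[[length(attributes) + 1L]] <- row
        }
        led_m[[length(led_m) + 1L]] <- tibble(
          doc_id = doc_id, sentence = si, id = id, kind = m$kind,
          type = m$type, start = gs, end = ge, text = m$text)
      }
      for (ri in seq_len(NROW(rels))) {
        relations[[length(relations) + 1L]] <- tibble(
          concept_id = local_ids[rels[ri, "concept"]],
          attribute_id = local_ids[rels[ri, "attr"]])
        led_r[[length(led_r) + 1L]] <- tibble(
          doc_id = doc_id,
          concept_id = local_ids[rels[ri, "concept"]],
          attribute_id = local_ids[rels[ri, "attr"]])
      }
      sent_texts <- c(sent_texts, stext)
      offset <- offset + nchar(stext) + 1L   # newline-joined
    }

    text <- paste(sent_texts, collapse = "\n")
    docs[[d]] <- annotated_document(
      doc_id, text,
      concepts = dplyr::bind_rows(concepts),
      attributes = dplyr::bind_rows(attributes),
      relations = dplyr::bind_rows(relations))
  }
  list(documents = docs,
       ledger = list(mentions = dplyr::bind_rows(led_m),
                     relations = dplyr::bind_rows(led_r),
                     distractors = if (length(led_d)) dplyr::bind_rows(led_d)
                                   else distractor_proto(),
                     seed = config$seed))
}

distractor_proto <- function() {
  tibble(doc_id = character(), sentence = integer(), type = character(),
         start = integer(), end = integer(), text = character())
}

#' Corpus summary counts
#'
#' Counts of target concepts, relations, and attribute mentions per type —
#' the shape of a corpus-statistics table.
#'
#' @param docs A document or list of documents.
#' @return Tibble with columns `item` and `n`.
#' @export
corpus_stats <- function(docs) {
  docs <- as_doclist(docs)
  types <- sort(unique(unlist(lapply(docs, function(d) d$attributes$attr_type))))
  n_con <- sum(vapply(docs, function(d) nrow(d$concepts), integer(1)))
  n_rel <- sum(vapply(docs, function(d) nrow(d$relations), integer(1)))
  per_type <- vapply(types, function(ty)
    sum(vapply(docs, function(d) sum(d$attributes$attr_type == ty),
               integer(1))), integer(1))
  tibble(item = c("concepts", "relations", types),
         n = c(n_con, n_rel, as.integer(per_type)))
}
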