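#' Sentence sequences for concept-blind attribute NER
#'
#' The two-step baseline's first stage is an ordinary attribute NER: one
#' sequence per sentence, every token's concept-role tag fixed to
#' `Outside`, and BIO labels covering every annotated attribute mention
#' regardless of which concept (if any) it relates to. An attribute linked
#' to several concepts is labeled once (mention-level NER; duplication
#' happens only at evaluation).
#'
#' @param docs A document or list of documents.
#' @return List of `attrseq_cfs` objects (with empty target fields).
#' @export
sentence_sequences <- function(docs) {
  docs <- as_doclist(docs)
  out <- list()
  for (doc in docs) {
    for (si in doc$sentences$sentence) {
      tokens <- sentence_tokens(doc, si)
      if (!nrow(tokens)) next
      label <- rep("O", nrow(tokens))
      atts <- doc$attributes[doc$attributes$sentence == si, , drop = FALSE]
      if (nrow(atts)) atts <- atts[order(atts$start), , drop = FALSE]
      for (k in seq_len(nrow(atts))) {
        rng <- tryCatch(
          align_span(atts$start[k], atts$end[k], tokens, mode = "strict"),
          attrseq_alignment_error = function(e)
            align_span(atts$start[k], atts$end[k], tokens, mode = "expand"))
        idx <- rng[1]:rng[2]
        if (any(label[idx] != "O")) {
          warn(sprintf(
            "document '%s' sentence %d: overlapping attribute mentions; keeping the first",
            doc$doc_id, si))
          next
        }
        label[idx] <- c(paste0("B-", atts$attr_type[k]),
                        rep(paste0("I-", atts$attr_type[k]), length(idx) - 1L))
      }
      tokens$role <- "Outside"
      tokens$label <- label
      out[[length(out) + 1L]] <- new_cfs(
        doc$doc_id, si, "", "", -1L, -1L,
        tokens[, c("text", "start", "end", "role", "label")])
    }
  }
  out
}

#' Train / apply the concept-blind attribute NER
#'
#' Same Bi-LSTM-CRF stack as the target-aware tagger with the role-tag
#' channel removed (per-token input width 100 instead of 110).
#'
#' @param docs Training documents.
#' @param task Task name.
#' @param config A [tagger_config()].
#' @return `ner_train()`: an `attrseq_tagger` with `use_role = FALSE`.
#' @export
ner_train <- function(docs, task, config = tagger_config()) {
  docs <- as_doclist(docs)
  if (!length(docs)) abort("empty document list")
  train_tagger(sentence_sequences(docs), task, config, use_role = FALSE)
}

#' @rdname ner_train
#' @param model Trained NER model.
#' @return `ner_predict()`: tibble of predicted attribute mentions with
#'   columns `doc_id`, `sentence`, `attr_id`, `attr_type`, `attr_start`,
#'   `attr_end`, `attr_text`.
#' @export
ner_predict <- function(model, docs) {
  docs <- as_doclist(docs)
  seqs <- sentence_sequences(docs)
  if (!length(seqs)) return(empty_mentions())
  labels <- predict(model, seqs)
  out <- purrr::map2_dfr(seqs, labels, function(s, lab) {
    runs <- parse_bio_runs(lab)
    if (!nrow(runs)) return(NULL)
    tibble(doc_id = s$doc_id, sentence = s$sentence,
           attr_type = runs$attr_type,
           attr_start = s$tokens$start[runs$first],
           attr_end = s$tokens$end[runs$last],
           attr_text = vapply(seq_len(nrow(runs)), function(i)
             paste(s$tokens$text[runs$first[i]:runs$last[i]], collapse = " "),
             character(1)))
  })
  if (!nrow(out)) return(empty_mentions())
  out$attr_id <- paste0("P", seq_len(nrow(out)))
  out[, c("doc_id", "sentence", "attr_id", "attr_type", "attr_start",
          "attr_end", "attr_text")]
}

empty_mentions <- function() {
  tibble(doc_id = character(), sentence = integer(), attr_id = character(),
         attr_type = character(), attr_start = integer(),
         attr_end = integer(), attr_text = character())
}

#' Generate candidate concept-attribute pairs
#'
#' Cartesian product, per sentence, of concept mentions and attribute
#' mentions — every attribute-concept pair within one sentence is a
#' candidate. With gold attributes (`attributes = NULL`) each pair carries
#' a binary `related` label from the document's gold relations; with
#' predicted attributes the label is `NA`.
#'
#' @param doc An [annotated_document()].
#' @param attributes Optional tibble of (predicted) attribute mentions in
#'   the [ner_predict()] shape; default uses the document's gold mentions.
#' @return Tibble of candidate pairs, one row per (concept, attribute)
#'   combination sharing a sentence.
#' @export
generate_candidates <- function(doc, attributes = NULL) {
  stopifnot(inherits(doc, "attrseq_document"))
  provenance <- if (is.null(attributes)) "gold" else "predicted"
  if (is.null(attributes)) {
    attributes <- tibble(
      doc_id = doc$doc_id, sentence = doc$attributes$sentence,
      attr_id = doc$attributes$id, attr_type = doc$attributes$attr_type,
      attr_start = doc$attributes$start, attr_end = doc$attributes$end,
      attr_text = doc$attributes$text)
  } else {
    attributes <- attributes[attributes$doc_id == doc$doc_id, , drop = FALSE]
  }
  con <- tibble(
    sentence = doc$concepts$sentence, concept_id = doc$concepts$id,
    concept_start = doc$concepts$start, concept_end = doc$concepts$end)
  out <- dplyr::inner_join(con, attributes, by = "sentence",
                           relationship = "many-to-many")
  if (!nrow(out)) return(empty_candidates())
  out$doc_id <- doc$doc_id
  out$provenance <- provenance
  if (provenance == "gold") {
    key <- paste(out$concept_id, out$attr_id)
    gold_key <- paste(doc$relations$concept_id, doc$relations$attribute_id)
    out$related <- key %in% gold_key
  } else {
    out$related <- NA
  }
  out[, c("doc_id", "sentence", "concept_id", "concept_start", "concept_end",
          "attr_id", "attr_type", "attr_start", "attr_end", "attr_text",
          "provenance", "related")]
}

empty_candidates <- function() {
  tibble(doc_id = character(), sentence = integer(), concept_id = character(),
         concept_start = integer(), concept_end = integer(),
         attr_id = character(), attr_type = character(),
         attr_start = integer(), attr_end = integer(), attr_text = character(),
         provenance = character(), related = logical())
}

# -------------------------------------------------------------- features

#' Contextual features of one candidate pair
#'
#' Bags of word identities before, between and after the pair, words inside
#' the attribute and inside the concept, and the signed token distance of
#' the attribute relative to the concept (negative when the attribute
#' precedes the concept, 0 for overlapping mentions, with an overlap flag).
#'
#' @param pair One-row tibble from [generate_candidates()].
#' @param tokens Token tibble of the pair's sentence.
#' @param window Context window (tokens) for the before/after bags.
#' @return Character vector of feature strings, with the signed distance in
#'   attribute `"distance"`.
#' @export
featurize_pair <- function(pair, tokens, window = 5L) {
  crng <- align_span(pair$concept_start, pair$concept_end, tokens, "expand")
  arng <- align_span(pair$attr_start, pair$attr_end, tokens, "expand")
  overlap <- crng[1] <= arng[2] && arng[1] <= crng[2]
  dist <- if (overlap) 0L
          else if (arng[1] > crng[2]) arng[1] - crng[2]
          else arng[2] - crng[1]
  lo <- min(crng[1], arng[1]); hi <- max(crng[2], arng[2])
  before <- tokens$text[max(1L, lo - window):max(1L, lo - 1L)]
  if (lo == 1L) before <- character(0)
  after <- if (hi >= nrow(tokens)) character(0) else
    tokens$text[(hi + 1L):min(nrow(tokens), hi + window)]
  between <- if (overlap || abs(dist) <= 1L) character(0) else
    tokens$text[(min(crng[2], arng[2]) + 1L):(max(crng[1], arng[1]) - 1L)]
  bag <- function(prefix, words) {
    if (!length(words)) return(character(0))
    paste0(prefix, tolower(words))
  }
  feats <- c(
    bag("wb=", before),
    bag("wbtw=", between),
    bag("wa=", after),
    bag("in_attr=", tokens$text[arng[1]:arng[2]]),
    bag("in_con=", tokens$text[crng[1]:crng[2]]),
    paste0("dist=", pmax(pmin(dist, 15L), -15L)),
    paste0("dir=", if (overlap) "overlap" else if (dist > 0) "right" else "left")
  )
  attr(feats, "distance") <- dist
  feats
}

# Deterministic string hashing into 1..width (polynomial rolling hash).
hash_features <- function(feats, width) {
  vapply(feats, function(f) {
    h <- 0
    for (cc in utf8ToInt(f)) h <- (h * 31 + cc) %% 1048573
    as.integer(h %% width) + 1L
  }, integer(1), USE.NAMES = FALSE)
}

pair_feature_matrix <- function(pairs, docs, width = 1024L, window = 5L) {
  docs <- as_doclist(docs)
  names(docs) <- vapply(docs, function(d) d$doc_id, character(1))
  X <- matrix(0, nrow(pairs), width)
  for (i in seq_len(nrow(pairs))) {
    doc <- docs[[pairs$doc_id[i]]]
    tokens <- sentence_tokens(doc, pairs$sentence[i])
    idx <- hash_features(featurize_pair(pairs[i, ], tokens, window), width)
    X[i, unique(idx)] <- 1
  }
  X
}

# ------------------------------------------------- margin (SVM) classifier

#' Train per-type margin relation classifiers
#'
#' One linear hinge-loss (SVM) binary classifier per attribute type over
#' hashed sparse contextual features, decision threshold 0 (cost `C = 1`).
#' A type whose training pairs are all one class yields a constant
#' predictor with a warning.
#'
#' @param pairs Candidate pairs with gold `related` labels.
#' @param docs The documents the pairs come from.
#' @param width Hashed feature space width.
#' @return List of per-type models, class `attrseq_margin_clf`.
#' @export
train_margin_classifier <- function(pairs, docs, width = 1024L) {
  docs <- as_doclist(docs)
  models <- list()
  for (ty in unique(pairs$attr_type)) {
    sub <- pairs[pairs$attr_type == ty, , drop = FALSE]
    y <- sub$related
    if (length(unique(y)) < 2L) {
      warn(sprintf(
        "attribute type %s: single-class training data; constant predictor", ty))
      models[[ty]] <- list(kind = "constant", value = y[1])
      next
    }
    X <- pair_feature_matrix(sub, docs, width)
    fit <- e1071::svm(X, factor(y, levels = c(FALSE, TRUE)),
                      kernel = "linear", cost = 1, scale = FALSE)
    models[[ty]] <- list(kind = "svm", fit = fit)
  }
  structure(list(models = models, width = width),
            class = "attrseq_margin_clf")
}

#' @rdname train_margin_classifier
#' @param model A fitted classifier set.
#' @return `predict_margin_classifier()`: logical vector, one per pair.
#'   Types unseen at training default to `TRUE` (attach), mirroring the
#'   positive skew of sparse attribute types.
#' @export
predict_margin_classifier <- function(model, pairs, docs) {
  docs <- as_doclist(docs)
  out <- logical(nrow(pairs))
  for (ty in unique(pairs$attr_type)) {
    rows <- which(pairs$attr_type == ty)
    m <- model$models[[ty]]
    if (is.null(m)) { out[rows] <- TRUE; next }
    if (m$kind == "constant") { out[rows] <- m$value; next }
    X <- pair_feature_matrix(pairs[rows, , drop = FALSE], docs, model$width)
    out[rows] <- predict(m$fit, X) == "TRUE"
  }
  out
}

# ------------------------------------------------- Bi-LSTM pair classifier

#' Hyperparameters of the Bi-LSTM relation classifier
#'
#' Word and position embeddings are randomly initialized; each token's
#' input concatenates its word embedding with embeddings of its bucketed
#' distance to the concept and to the attribute (clipped to ±15 tokens,
#' bucket 0 inside the mention). Final Bi-LSTM states feed a 2-way
#' softmax.
#'
#' @param word_dim,pos_dim,hidden Embedding / hidden sizes.
#' @param learning_rate,epochs,clip,seed Optimization settings.
#' @export
pair_lstm_config <- function(word_dim = 50L, pos_dim = 10L, hidden = 100L,
                             learning_rate = 0.005, epochs = 20L,
                             clip = 5, seed = 1L) {
  list(word_dim = as.integer(word_dim), pos_dim = as.integer(pos_dim),
       hidden = as.integer(hidden), learning_rate = learning_rate,
       epochs = as.integer(epochs), clip = clip, seed = as.integer(seed))
}

POS_CLIP <- 15L   # distance buckets -15..15 -> 31 buckets

pos_bucket <- function(n_tokens, rng) {
  d <- integer(n_tokens)
  idx <- seq_len(n_tokens)
  d[idx < rng[1]] <- idx[idx < rng[1]] - rng[1]
  d[idx > rng[2]] <- idx[idx > rng[2]] - rng[2]
  pmax(pmin(d, POS_CLIP), -POS_CLIP) + POS_CLIP  # 0-based bucket index
}

encode_pair <- function(pair, tokens, vocab, use_positions = TRUE) {
  w <- match(tolower(tokens$text), vocab)
  w[is.na(w)] <- 1L
  crng <- align_span(pair$concept_start, pair$concept_end, tokens, "expand")
  arng <- align_span(pair$attr_start, pair$attr_end, tokens, "expand")
  n <- nrow(tokens)
  list(words = w - 1L,
       posc = if (use_positions) pos_bucket(n, crng) else rep(POS_CLIP, n),
       posa = if (use_positions) pos_bucket(n, arng) else rep(POS_CLIP, n),
       label = 0L)
}

#' Train per-type Bi-LSTM relation classifiers
#'
#' @param pairs Candidate pairs with gold `related` labels.
#' @param docs Source documents.
#' @param config A [pair_lstm_config()].
#' @param use_positions Set `FALSE` to ablate the position-embedding
#'   channels (both distances collapse to a constant bucket).
#' @return Object of class `attrseq_lstm_clf`.
#' @export
train_lstm_pair_classifier <- function(pairs, docs,
                                       config = pair_lstm_config(),
                                       use_positions = TRUE) {
  docs <- as_doclist(docs)
  names(docs) <- vapply(docs, function(d) d$doc_id, character(1))
  vocab <- c("<unk>", sort(unique(tolower(unlist(
    lapply(docs, function(d) d$tokens$text))))))
  models <- list()
  for (ty in unique(pairs$attr_type)) {
    sub <- pairs[pairs$attr_type == ty, , drop = FALSE]
    if (length(unique(sub$related)) < 2L) {
      warn(sprintf(
        "attribute type %s: single-class training data; constant predictor", ty))
      models[[ty]] <- list(kind = "constant", value = sub$related[1])
      next
    }
    insts <- lapply(seq_len(nrow(sub)), function(i) {
      doc <- docs[[sub$doc_id[i]]]
      e <- encode_pair(sub[i, ], sentence_tokens(doc, sub$sentence[i]),
                       vocab, use_positions)
      e$label <- as.integer(sub$related[i])
      e
    })
    set.seed(config$seed)
    D <- config$word_dim + 2L * config$pos_dim
    params <- list(
      Ew = embed_init(length(vocab), config$word_dim),
      Epc = embed_init(2L * POS_CLIP + 1L, config$pos_dim),
      Epa = embed_init(2L * POS_CLIP + 1L, config$pos_dim),
      Wf_W = glorot(4L * config$hidden, D),
      Wf_U = glorot(4L * config$hidden, config$hidden),
      Wf_b = rep(0, 4L * config$hidden),
      Wb_W = glorot(4L * config$hidden, D),
      Wb_U = glorot(4L * config$hidden, config$hidden),
      Wb_b = rep(0, 4L * config$hidden),
      So_W = glorot(2L, 2L * config$hidden),
      So_b = rep(0, 2L))
    fit <- cpp_pair_train(insts, params, list(
      learning_rate = config$learning_rate, clip = config$clip,
      epochs = config$epochs, seed = config$seed))
    models[[ty]] <- list(kind = "lstm", params = fit$params,
                         loss = as.numeric(fit$loss))
  }
  structure(list(models = models, vocab = vocab, config = config,
                 use_positions = use_positions),
            class = "attrseq_lstm_clf")
}

#' @rdname train_lstm_pair_classifier
#' @param model A fitted classifier set.
#' @return `predict_lstm_pair_classifier()`: logical vector (probability of
#'   relatedness thresholded at 0.5).
#' @export
predict_lstm_pair_classifier <- function(model, pairs, docs) {
  docs <- as_doclist(docs)
  names(docs) <- vapply(docs, function(d) d$doc_id, character(1))
  out <- logical(nrow(pairs))
  for (ty in unique(pairs$attr_type)) {
    rows <- which(pairs$attr_type == ty)
    m <- model$models[[ty]]
    if (is.null(m)) { out[rows] <- TRUE; next }
    if (m$kind == "constant") { out[rows] <- m$value; next }
    insts <- lapply(rows, function(i) {
      doc <- docs[[pairs$doc_id[i]]]
      encode_pair(pairs[i, ], sentence_tokens(doc, pairs$sentence[i]),
                  model$vocab, model$use_positions)
    })
    out[rows] <- cpp_pair_predict(insts, m$params) >= 0.5
  }
  out
}

# ------------------------------------------------------------ full cascade

#' Fit the traditional two-step cascade
#'
#' Stage 1 trains the concept-blind attribute NER; stage 2 trains one
#' binary relation classifier per attribute type on gold-mention candidate
#' pairs (standard cascade protocol: train on gold mentions, apply to
#' predicted mentions).
#'
#' @param docs Training documents.
#' @param task Task name.
#' @param relation_model `"margin"` (linear SVM over hashed contextual
#'   features) or `"lstm"` (Bi-LSTM over word + position embeddings).
#' @param ner_config [tagger_config()] for the NER stage.
#' @param pair_config [pair_lstm_config()] for the LSTM relation stage.
#' @param width Hashed feature width for the margin classifier.
#' @param ner Optional pre-trained NER model (`use_role = FALSE`), so the
#'   two relation models can share one first stage.
#' @return Object of class `attrseq_two_step`.
#' @export
two_step_fit <- function(docs, task, relation_model = c("margin", "lstm"),
                         ner_config = tagger_config(),
                         pair_config = pair_lstm_config(), width = 1024L,
                         ner = NULL) {
  relation_model <- match.arg(relation_model)
  docs <- as_doclist(docs)
  if (!length(docs)) abort("empty document list")
  if (is.null(ner)) ner <- ner_train(docs, task, ner_config)
  pairs <- purrr::map_dfr(docs, generate_candidates)
  clf <- if (!nrow(pairs)) NULL
  else if (relation_model == "margin") {
    train_margin_classifier(pairs, docs, width)
  } else {
    train_lstm_pair_classifier(pairs, docs, pair_config)
  }
  structure(list(ner = ner, clf = clf, relation_model = relation_model,
                 task = task),
            class = "attrseq_two_step")
}

#' @export
print.attrseq_two_step <- function(x, ...) {
  cat(sprintf("<attrseq_two_step task='%s', relation model: %s>\n",
              x$task, x$relation_model))
  invisible(x)
}

#' Run the two-step cascade
#'
#' NER output feeds candidate generation; classifier positives become
#' relations. `drop_mentions` deletes that fraction of NER-predicted
#' mentions (uniformly at random under `seed`) before relation
#' classification — the knob used to study error propagation through the
#' cascade.
#'
#' @param object A fitted `attrseq_two_step`.
#' @param docs Documents to annotate (gold concepts are given; attributes
#'   and relations are predicted).
#' @param drop_mentions Fraction in `[0, 1]` of predicted mentions to
#'   delete before relation classification.
#' @param seed Seed for the deletion draw.
#' @param ... Unused.
#' @return Predicted pair tibble in the [gold_pairs()] shape.
#' @export
predict.attrseq_two_step <- function(object, docs, drop_mentions = 0,
                                     seed = 1L, ...) {
  docs <- as_doclist(docs)
  mentions <- ner_predict(object$ner, docs)
  if (drop_mentions > 0 && nrow(mentions)) {
    set.seed(seed)
    keep <- runif(nrow(mentions)) >= drop_mentions
    mentions <- mentions[keep, , drop = FALSE]
  }
  two_step_relate(object, docs, mentions)
}

# Relation stage only: classify candidates built from the given mentions.
two_step_relate <- function(object, docs, mentions) {
  docs <- as_doclist(docs)
  pairs <- purrr::map_dfr(docs, generate_candidates, attributes = mentions)
  if (!nrow(pairs)) return(empty_pairs())
  pos <- if (is.null(object$clf)) rep(TRUE, nrow(pairs))
  else if (object$relation_model == "margin") {
    predict_margin_classifier(object$clf, pairs, docs)
  } else {
    predict_lstm_pair_classifier(object$clf, pairs, docs)
  }
  pred <- pairs[pos, , drop = FALSE]
  tibble(doc_id = pred$doc_id, concept_id = pred$concept_id,
         concept_start = pred$concept_start, concept_end = pred$concept_end,
         attr_type = pred$attr_type, attr_start = pred$attr_start,
         attr_end = pred$attr_end, attr_text = pred$attr_text)
}
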