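pair_key <- function(p) {
  paste(p$doc_id, p$concept_start, p$concept_end, p$attr_type,
        p$attr_start, p$attr_end)
}

concept_key <- function(p) paste(p$doc_id, p$concept_start, p$concept_end)

#' Strict concept-aligned precision / recall / F-measure
#'
#' A predicted (concept, attribute) pair is a true positive iff the concept
#' identity (offsets within the document), the attribute's exact character
#' span and its type all match a gold pair. An attribute mention linked to
#' several concepts is counted once per concept on both sides. Empty
#' denominators yield metric 0 (flagged in the `undefined` column).
#'
#' `match = "overlap"` relaxes the attribute-span requirement to character
#' overlap (same concept and type); strict matching is the default and the
#' reported criterion.
#'
#' @param gold,pred Pair tibbles in the [gold_pairs()] shape.
#' @param attr_type Optional single type to restrict to.
#' @param match `"strict"` (default) or `"overlap"`.
#' @return Tibble with one row per attribute type: `tp`, `n_pred`,
#'   `n_gold`, `precision`, `recall`, `f1`, `undefined`.
#' @export
strict_prf <- function(gold, pred, attr_type = NULL,
                       match = c("strict", "overlap")) {
  match <- match.arg(match)
  if (!is.null(attr_type)) {
    gold <- gold[gold$attr_type %in% attr_type, , drop = FALSE]
    pred <- pred[pred$attr_type %in% attr_type, , drop = FALSE]
  }
  gold <- dplyr::distinct(as_tibble(gold))
  pred <- dplyr::distinct(as_tibble(pred))
  types <- sort(unique(c(gold$attr_type, pred$attr_type, attr_type)))
  purrr::map_dfr(types, function(ty) {
    g <- gold[gold$attr_type == ty, , drop = FALSE]
    p <- pred[pred$attr_type == ty, , drop = FALSE]
    tp <- if (match == "strict") {
      sum(pair_key(p) %in% pair_key(g))
    } else {
      gk <- paste(g$doc_id, g$concept_start, g$concept_end)
      sum(vapply(seq_len(nrow(p)), function(i) {
        cand <- which(gk == paste(p$doc_id[i], p$concept_start[i],
                                  p$concept_end[i]))
        any(g$attr_start[cand] < p$attr_end[i] &
              p$attr_start[i] < g$attr_end[cand])
      }, logical(1)))
    }
    prec <- if (nrow(p)) tp / nrow(p) else 0
    rec <- if (nrow(g)) tp / nrow(g) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble(attr_type = ty, tp = tp, n_pred = nrow(p), n_gold = nrow(g),
           precision = prec, recall = rec, f1 = f1,
           undefined = nrow(p) == 0L || nrow(g) == 0L)
  })
}

#' Concept-level accuracy
#'
#' For one attribute type, a gold concept counts as correct iff its
#' predicted attribute set (exact spans) equals its gold set — including
#' the case where both are empty, so correctly predicting "no attribute of
#' this type" counts. `Acc = N_correct_predict / N` with `N` the total
#' number of gold concepts.
#'
#' @param concepts Gold concept tibble from [concept_table()] — required so
#'   concepts with no attributes enter `N`.
#' @param gold,pred Pair tibbles.
#' @param attr_type Attribute type(s); defaults to all types present.
#' @return Tibble with `attr_type`, `n_concepts`, `n_correct`, `accuracy`.
#' @export
concept_accuracy <- function(concepts, gold, pred, attr_type = NULL) {
  gold <- dplyr::distinct(as_tibble(gold))
  pred <- dplyr::distinct(as_tibble(pred))
  if (is.null(attr_type)) {
    attr_type <- sort(unique(c(gold$attr_type, pred$attr_type)))
  }
  ck <- concept_key(concepts)
  purrr::map_dfr(attr_type, function(ty) {
    g <- gold[gold$attr_type == ty, , drop = FALSE]
    p <- pred[pred$attr_type == ty, , drop = FALSE]
    gset <- split(paste(g$attr_start, g$attr_end), concept_key(g))
    pset <- split(paste(p$attr_start, p$attr_end), concept_key(p))
    correct <- vapply(ck, function(k) {
      setequal(gset[[k]] %||% character(0), pset[[k]] %||% character(0))
    }, logical(1))
    tibble(attr_type = ty, n_concepts = length(ck),
           n_correct = sum(correct),
           accuracy = if (length(ck)) sum(correct) / length(ck) else 0)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full evaluation report
#'
#' Strict P/R/F and concept-level accuracy per attribute type of the task,
#' from gold documents and a predicted pair table.
#'
#' @param docs Gold documents.
#' @param pred Predicted pair tibble.
#' @param task Task name (fixes the attribute-type inventory).
#' @param match Matching mode, see [strict_prf()].
#' @return A tibble of class `attrseq_eval` with per-type columns `tp`,
#'   `n_pred`, `n_gold`, `precision`, `recall`, `f1`, `n_concepts`,
#'   `n_correct`, `accuracy`.
#' @export
evaluate_attributes <- function(docs, pred, task, match = "strict") {
  docs <- as_doclist(docs)
  types <- task_attributes(task)
  gold <- gold_pairs(docs)
  concepts <- concept_table(docs)
  prf <- strict_prf(gold, pred, attr_type = types, match = match)
  acc <- concept_accuracy(concepts, gold, pred, attr_type = types)
  out <- dplyr::left_join(
    tibble(attr_type = types), dplyr::left_join(prf, acc, by = "attr_type"),
    by = "attr_type")
  class(out) <- c("attrseq_eval", class(out))
  out
}

#' @export
autoplot.attrseq_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("attr_type", "precision", "recall", "f1", "accuracy")],
    -"attr_type", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$attr_type, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "attribute type", y = NULL,
                  title = "Attribute detection performance")
}

# ------------------------------------------------------------------ systems

#' Attribute-detection systems with a common fit/predict surface
#'
#' `cfs_system()` wraps the one-step sequence-labeling approach: documents
#' are expanded into concept-focused sequences, the target-aware tagger is
#' trained on them, and predictions are decoded back into concept-attached
#' attribute pairs. `two_step_system()` wraps the NER + relation-classifier
#' cascade. Both return an object whose `$fit(docs)` trains on documents
#' and whose `$predict(model, docs)` returns a pair tibble, the interface
#' [cross_validate()] consumes.
#'
#' @param task Task name.
#' @param config A [tagger_config()].
#' @return An `attrseq_system` object.
#' @export
cfs_system <- function(task, config = tagger_config()) {
  structure(list(
    name = "sequence-labeling (one-step)",
    fit = function(docs) train_tagger(expand_document(docs), task, config),
    predict = function(model, docs) {
      seqs <- expand_document(docs)
      if (!length(seqs)) return(empty_pairs())
      labels <- predict(model, seqs)
      purrr::map2_dfr(seqs, labels, decode_cfs)
    }), class = "attrseq_system")
}

#' @rdname cfs_system
#' @inheritParams two_step_fit
#' @export
two_step_system <- function(task, relation_model = c("margin", "lstm"),
                            ner_config = tagger_config(),
                            pair_config = pair_lstm_config(),
                            width = 1024L) {
  relation_model <- match.arg(relation_model)
  structure(list(
    name = paste0("two-step (", relation_model, ")"),
    fit = function(docs) two_step_fit(docs, task, relation_model,
                                      ner_config, pair_config, width),
    predict = function(model, docs) predict(model, docs)),
    class = "attrseq_system")
}

#' k-fold cross-validation with micro-averaged report
#'
#' Documents (the fold unit, to avoid leakage within a note) are
#' partitioned into `k` folds under `seed`; each fold is predicted by a
#' system trained on the others. The micro-average pools raw TP /
#' predicted / gold counts — and the concept counts for accuracy — across
#' folds before computing ratios.
#'
#' @param docs Gold documents (at least `k`).
#' @param system An `attrseq_system` from [cfs_system()] or
#'   [two_step_system()].
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @param task Task name.
#' @return Object of class `attrseq_cv`: `folds` (per-fold report rows),
#'   `micro` (pooled `attrseq_eval`), `predictions`.
#' @export
cross_validate <- function(docs, system, task, k = 10L, seed = 1L) {
  docs <- as_doclist(docs)
  if (length(docs) < k) {
    abort(sprintf("need at least k = %d documents, got %d", k, length(docs)))
  }
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), length(docs)))
  fold_rows <- list(); preds <- list()
  for (f in seq_len(k)) {
    train <- docs[fold != f]
    test <- docs[fold == f]
    model <- system$fit(train)
    pred <- system$predict(model, test)
    preds[[f]] <- pred
    rep_f <- evaluate_attributes(test, pred, task)
    rep_f$fold <- f
    fold_rows[[f]] <- as_tibble(rep_f)
  }
  folds <- dplyr::bind_rows(fold_rows)
  pooled <- folds |>
    dplyr::group_by(.data$attr_type) |>
    dplyr::summarise(
      tp = sum(.data$tp), n_pred = sum(.data$n_pred),
      n_gold = sum(.data$n_gold), n_concepts = sum(.data$n_concepts),
      n_correct = sum(.data$n_correct), .groups = "drop") |>
    dplyr::mutate(
      precision = ifelse(.data$n_pred > 0, .data$tp / .data$n_pred, 0),
      recall = ifelse(.data$n_gold > 0, .data$tp / .data$n_gold, 0),
      f1 = ifelse(.data$precision + .data$recall > 0,
                  2 * .data$precision * .data$recall /
                    (.data$precision + .data$recall), 0),
      accuracy = ifelse(.data$n_concepts > 0,
                        .data$n_correct / .data$n_concepts, 0))
  class(pooled) <- c("attrseq_eval", class(pooled))
  structure(list(folds = folds, micro = pooled,
                 predictions = dplyr::bind_rows(preds),
                 k = k, seed = seed, system = system$name),
            class = "attrseq_cv")
}

#' @export
print.attrseq_cv <- function(x, ...) {
  cat(sprintf("<attrseq_cv: %s, %d folds (seed %d)>\nMicro-averaged:\n",
              x$system, x$k, x$seed))
  print(as_tibble(x$micro))
  invisible(x)
}

#' @export
tidy.attrseq_cv <- function(x, ...) x$folds

#' @export
glance.attrseq_cv <- function(x, ...) {
  tibble(system = x$system, k = x$k,
         macro_f1 = mean(x$micro$f1), macro_acc = mean(x$micro$accuracy),
         pooled_gold = sum(x$micro$n_gold))
}

#' @export
autoplot.attrseq_cv <- function(object, ...) autoplot(object$micro, ...)
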