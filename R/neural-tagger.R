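ROLE_TAGS <- c("Target", "NotTarget", "Outside")
UNK_WORD <- "<unk>"
UNK_CHAR <- "<unk>"

#' Tagger hyperparameters
#'
#' Defaults follow the architecture's published settings: word embeddings of
#' size 50, character embeddings of size 25, a word-level Bi-LSTM with
#' hidden size 100 per direction, a character-level Bi-LSTM with hidden
#' size 25 per direction, a concept-role-tag embedding of size 10,
#' plain stochastic gradient descent at learning rate 0.005 with one
#' sequence per update, and dropout with probability 0.5 applied to the
#' word-LSTM input and output during training. Epoch count (default 30),
#' gradient clipping (global norm 5) and the rare-word UNK policy (words
#' seen fewer than `unk_threshold` times are replaced by the unknown token
#' with probability `unk_prob` during training) are this implementation's
#' own documented choices.
#'
#' @param word_dim,char_dim,role_dim Embedding sizes.
#' @param word_hidden,char_hidden LSTM hidden sizes per direction.
#' @param learning_rate SGD learning rate.
#' @param dropout Dropout probability in `[0, 1)`.
#' @param epochs Number of passes over the training data.
#' @param clip Global gradient-norm clip; `0` disables.
#' @param unk_threshold,unk_prob Rare-word UNK training policy.
#' @param seed Integer seed controlling initialization, shuffling, dropout
#'   and UNK replacement.
#' @return A list of class `attrseq_tagger_config`.
#' @export
tagger_config <- function(word_dim = 50L, char_dim = 25L,
                          word_hidden = 100L, char_hidden = 25L,
                          role_dim = 10L, learning_rate = 0.005,
                          dropout = 0.5, epochs = 30L, clip = 5,
                          unk_threshold = 2L, unk_prob = 0.5, seed = 1L) {
  stopifnot(word_dim > 0, char_dim > 0, word_hidden > 0, char_hidden > 0,
            role_dim > 0, dropout >= 0, dropout < 1, epochs >= 0,
            learning_rate > 0)
  structure(list(word_dim = as.integer(word_dim),
                 char_dim = as.integer(char_dim),
                 word_hidden = as.integer(word_hidden),
                 char_hidden = as.integer(char_hidden),
                 role_dim = as.integer(role_dim),
                 learning_rate = learning_rate, dropout = dropout,
                 epochs = as.integer(epochs), clip = clip,
                 unk_threshold = as.integer(unk_threshold),
                 unk_prob = unk_prob, seed = as.integer(seed)),
            class = "attrseq_tagger_config")
}

#' Build the vocabulary of a training set
#'
#' Word lookup is over lowercased surface forms (the character channel sees
#' the original case); both word and character maps contain an unknown
#' token. Also records training frequencies for the rare-word UNK policy.
#'
#' @param cfs_list Training sequences (`attrseq_cfs` objects).
#' @return List with `words`, `chars`, `word_freq`.
#' @export
build_vocab <- function(cfs_list) {
  toks <- unlist(lapply(cfs_list, function(s) s$tokens$text))
  if (!length(toks)) abort("empty training set")
  lw <- tolower(toks)
  tab <- table(lw)
  words <- c(UNK_WORD, sort(names(tab)))
  chars <- c(UNK_CHAR, sort(unique(unlist(strsplit(toks, "")))))
  freq <- c(1e9, as.numeric(tab[words[-1]]))  # UNK itself is never replaced
  list(words = words, chars = chars, word_freq = freq)
}

encode_cfs <- function(cfs, vocab, labels) {
  tok <- cfs$tokens
  w <- match(tolower(tok$text), vocab$words)
  w[is.na(w)] <- 1L
  ch <- lapply(strsplit(tok$text, ""), function(cs) {
    i <- match(cs, vocab$chars); i[is.na(i)] <- 1L; i - 1L
  })
  r <- match(tok$role, ROLE_TAGS)
  if (anyNA(r)) abort("unknown concept-role tag")
  y <- if (is.null(labels)) rep(0L, nrow(tok)) else {
    yy <- match(tok$label, labels)
    if (anyNA(yy)) abort(paste0("label outside the label set: ",
                                tok$label[which(is.na(yy))[1]]))
    yy - 1L
  }
  list(words = w - 1L, chars = ch, roles = r - 1L, labels = y)
}

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -r, r), nr, nc)
}

embed_init <- function(nr, nc) {
  r <- sqrt(3 / nc)
  matrix(runif(nr * nc, -r, r), nr, nc)
}

#' CRF transition matrix with start/stop states
#'
#' Returns the `(L+2) x (L+2)` score matrix used by [crf_log_likelihood()]
#' and [viterbi_decode()]: label rows/columns first, then the start state
#' (row `L+1`) and stop state (column `L+2`). Transitions into start and
#' out of stop are masked with a large negative score.
#'
#' @param n_labels Number of labels `L`.
#' @return Numeric matrix.
#' @export
new_transition_matrix <- function(n_labels) {
  L <- n_labels
  tr <- matrix(0, L + 2L, L + 2L)
  tr[, L + 1L] <- -1e4     # nothing enters the start state
  tr[L + 2L, ] <- -1e4     # nothing leaves the stop state
  tr
}

init_tagger_params <- function(vocab, labels, config, use_role) {
  set.seed(config$seed)
  D <- config$word_dim + 2L * config$char_hidden +
    if (use_role) config$role_dim else 0L
  L <- length(labels)
  list(
    Ew = embed_init(length(vocab$words), config$word_dim),
    Ec = embed_init(length(vocab$chars), config$char_dim),
    Er = embed_init(length(ROLE_TAGS), config$role_dim),
    Cf_W = glorot(4L * config$char_hidden, config$char_dim),
    Cf_U = glorot(4L * config$char_hidden, config$char_hidden),
    Cf_b = rep(0, 4L * config$char_hidden),
    Cb_W = glorot(4L * config$char_hidden, config$char_dim),
    Cb_U = glorot(4L * config$char_hidden, config$char_hidden),
    Cb_b = rep(0, 4L * config$char_hidden),
    Wf_W = glorot(4L * config$word_hidden, D),
    Wf_U = glorot(4L * config$word_hidden, config$word_hidden),
    Wf_b = rep(0, 4L * config$word_hidden),
    Wb_W = glorot(4L * config$word_hidden, D),
    Wb_U = glorot(4L * config$word_hidden, config$word_hidden),
    Wb_b = rep(0, 4L * config$word_hidden),
    P = glorot(L, 2L * config$word_hidden),
    pb = rep(0, L),
    trans = new_transition_matrix(L)
  )
}

#' Train the target-aware Bi-LSTM-CRF tagger
#'
#' Trains the sequence labeler on concept-focused sequences. Each token's
#' input vector concatenates its word embedding, the final states of a
#' bidirectional character LSTM over its characters, and (when `use_role`)
#' the embedding of its concept-role tag — the channel that tells the model
#' which concept the sequence is focused on. A linear-chain CRF output
#' layer is trained by the forward algorithm; decoding uses Viterbi.
#'
#' With `use_role = FALSE` the same stack becomes the concept-blind
#' attribute NER used by the two-step baseline (input width drops by the
#' role-embedding size).
#'
#' @param cfs_list Training sequences (`attrseq_cfs` objects with gold
#'   labels).
#' @param task Task name; fixes the BIO label set.
#' @param config A [tagger_config()].
#' @param use_role Include the concept-role-tag channel (default `TRUE`).
#' @return An object of class `attrseq_tagger` with elements `params`,
#'   `vocab`, `labels`, `config`, `use_role` and `loss` (per-epoch mean
#'   negative log-likelihood).
#' @export
train_tagger <- function(cfs_list, task, config = tagger_config(),
                         use_role = TRUE) {
  if (!length(cfs_list)) abort("empty training set")
  labels <- label_set(task)
  vocab <- build_vocab(cfs_list)
  params <- init_tagger_params(vocab, labels, config, use_role)
  enc <- lapply(cfs_list, encode_cfs, vocab = vocab, labels = labels)
  singleton <- vocab$word_freq < config$unk_threshold
  singleton[1] <- FALSE
  fit <- cpp_tagger_train(enc, params, list(
    learning_rate = config$learning_rate, dropout = config$dropout,
    clip = config$clip, epochs = config$epochs, use_role = use_role,
    unk_prob = config$unk_prob, unk_index = 0L, singleton = singleton,
    seed = config$seed))
  structure(list(params = fit$params, vocab = vocab, labels = labels,
                 task = task, config = config, use_role = use_role,
                 loss = as.numeric(fit$loss)),
            class = "attrseq_tagger")
}

#' @export
print.attrseq_tagger <- function(x, ...) {
  cat(sprintf(
    "<attrseq_tagger task='%s'%s: |V|=%d, %d labels, %d epochs, final loss %.4f>\n",
    x$task, if (x$use_role) "" else " (concept-blind NER)",
    length(x$vocab$words), length(x$labels), length(x$loss),
    if (length(x$loss)) x$loss[length(x$loss)] else NA_real_))
  invisible(x)
}

#' Predict BIO labels for sequences
#'
#' Viterbi decoding with dropout disabled; deterministic given the model.
#'
#' @param object A trained `attrseq_tagger`.
#' @param cfs_list Sequences to label.
#' @param ... Unused.
#' @return List of character label vectors, one per sequence.
#' @export
predict.attrseq_tagger <- function(object, cfs_list, ...) {
  if (!length(cfs_list)) return(list())
  enc <- lapply(cfs_list, encode_cfs, vocab = object$vocab, labels = NULL)
  paths <- cpp_tagger_predict(enc, object$params, object$use_role)
  lapply(paths, function(p) object$labels[p + 1L])
}

#' Per-token input vectors of a sequence
#'
#' Exposes the embedding layer: each row is the token's word embedding,
#' character-LSTM final states and (for target-aware models) role-tag
#' embedding, concatenated. Deterministic; dropout is never applied here.
#'
#' @param cfs An `attrseq_cfs`.
#' @param model A trained or initialized `attrseq_tagger`.
#' @return Numeric matrix, one row per token.
#' @export
embed_sequence <- function(cfs, model) {
  enc <- encode_cfs(cfs, model$vocab, NULL)
  cpp_embed_sequence(enc, model$params, model$use_role)
}

#' CRF log-likelihood of a label path
#'
#' Computes `score(gold path) - log Z` for a linear-chain CRF with the
#' given per-token emission scores and transition scores, using
#' log-sum-exp-stabilized forward recursion. Non-positive (up to float
#' error) for any valid path.
#'
#' @param emissions `T x L` matrix of per-token label scores.
#' @param transitions `(L+2) x (L+2)` matrix, see
#'   [new_transition_matrix()].
#' @param gold Integer label path (1-based) or character labels with
#'   `labels` supplied.
#' @param labels Optional label vocabulary for character `gold`.
#' @return Scalar log-likelihood.
#' @export
crf_log_likelihood <- function(emissions, transitions, gold, labels = NULL) {
  emissions <- as.matrix(emissions)
  if (is.character(gold)) {
    stopifnot(!is.null(labels))
    gold <- match(gold, labels)
  }
  gold <- as.integer(gold)
  L <- ncol(emissions)
  if (anyNA(gold) || any(gold < 1L) || any(gold > L)) {
    abort("gold labels outside the label set")
  }
  stopifnot(length(gold) == nrow(emissions),
            all(dim(transitions) == L + 2L))
  -cpp_crf_nll(emissions, transitions, gold - 1L)
}

#' @rdname crf_log_likelihood
#' @return `crf_log_partition()`: the log partition function `log Z`.
#' @export
crf_log_partition <- function(emissions, transitions) {
  cpp_crf_logZ(as.matrix(emissions), transitions)
}

#' Viterbi decoding
#'
#' Maximum-score label path under the CRF; ties are broken toward the
#' lower label index at every step, so decoding is deterministic.
#'
#' @inheritParams crf_log_likelihood
#' @return List with `path` (1-based integer labels; empty for empty
#'   input) and `score`.
#' @export
viterbi_decode <- function(emissions, transitions) {
  emissions <- as.matrix(emissions)
  if (nrow(emissions) == 0L) return(list(path = integer(0), score = 0))
  stopifnot(all(dim(transitions) == ncol(emissions) + 2L))
  v <- cpp_viterbi(emissions, transitions)
  list(path = as.integer(v$path) + 1L, score = v$score)
}

#' Sequence negative log-likelihood under a trained tagger
#'
#' @param model `attrseq_tagger`.
#' @param cfs An `attrseq_cfs` with gold labels.
#' @return Scalar NLL (dropout disabled).
#' @export
tagger_sequence_nll <- function(model, cfs) {
  enc <- encode_cfs(cfs, model$vocab, model$labels)
  cpp_tagger_seq_nll(enc, model$params, model$use_role, enc$labels)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.attrseq_tagger <- function(x, ...) {
  tibble(epoch = seq_along(x$loss), loss = x$loss)
}

#' @export
glance.attrseq_tagger <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  tibble(task = x$task, use_role = x$use_role,
         vocab_size = length(x$vocab$words), n_labels = length(x$labels),
         epochs = length(x$loss),
         final_loss = if (length(x$loss)) x$loss[length(x$loss)] else NA_real_,
         n_parameters = n_par)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.attrseq_tagger <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = "mean negative log-likelihood",
                  title = "Tagger training loss")
}

#' Save / load a tagger checkpoint
#'
#' Single JSON archive with a versioned header holding the configuration,
#' vocabulary and parameter tensors.
#'
#' @param model `attrseq_tagger`.
#' @param path File path.
#' @export
write_tagger <- function(model, path) {
  payload <- list(
    format = "attrseq_tagger", version = 1L,
    task = model$task, use_role = model$use_role,
    config = unclass(model$config), vocab = model$vocab,
    labels = model$labels, loss = model$loss,
    params = model$params)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_tagger
#' @export
read_tagger <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "attrseq_tagger")) {
    abort("not an attrseq tagger checkpoint")
  }
  params <- x$params
  vecs <- c("Cf_b", "Cb_b", "Wf_b", "Wb_b", "pb")
  params[vecs] <- lapply(params[vecs], as.numeric)
  params[setdiff(names(params), vecs)] <-
    lapply(params[setdiff(names(params), vecs)], function(m) {
      storage.mode(m) <- "double"; m
    })
  x$vocab$word_freq <- as.numeric(x$vocab$word_freq)
  structure(list(params = params, vocab = x$vocab, labels = x$labels,
                 task = x$task,
                 config = do.call(tagger_config, x$config[names(formals(tagger_config))]),
                 use_role = x$use_role, loss = as.numeric(x$loss)),
            class = "attrseq_tagger")
}
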