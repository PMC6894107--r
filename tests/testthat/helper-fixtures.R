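# Shared fixtures, all built in code.

# Radiology-style sentence with two disorder concepts, each with its own
# attribute set; the attribute cues of one concept must stay O in the
# other's concept-focused sequence. "R kidney" nests inside the concept
# span "enlarged R kidney" (overlap is legal).
kidney_document <- function() {
  text <- "There was a markedly enlarged R kidney with no air fluid level in the small bowel ."
  loc <- function(s) {
    st <- as.integer(regexpr(s, text, fixed = TRUE)) - 1L
    c(st, st + nchar(s))
  }
  c1 <- loc("enlarged R kidney"); c2 <- loc("air fluid level")
  a1 <- loc("markedly"); a2 <- loc("R kidney")
  a3 <- loc("no "); a3[2] <- a3[1] + 2L
  a4 <- loc("small bowel")
  annotated_document(
    "kidney", text,
    concepts = tibble::tibble(
      id = c("C1", "C2"), concept_type = "Disorder",
      start = c(c1[1], c2[1]), end = c(c1[2], c2[2])),
    attributes = tibble::tibble(
      id = c("A1", "A2", "A3", "A4"),
      attr_type = c("SEV", "BDL", "NEG", "BDL"),
      start = c(a1[1], a2[1], a3[1], a4[1]),
      end = c(a1[2], a2[2], a3[2], a4[2])),
    relations = tibble::tibble(
      concept_id = c("C1", "C1", "C2", "C2"),
      attribute_id = c("A1", "A2", "A3", "A4")))
}

# Minimal negation example: "Denied any chest pain ."
denied_document <- function() {
  annotated_document(
    "denied", "Denied any chest pain.",
    concepts = tibble::tibble(id = "T1", concept_type = "Disorder",
                              start = 11L, end = 21L),
    attributes = tibble::tibble(id = "T2", attr_type = "NEG",
                                start = 0L, end = 6L),
    relations = tibble::tibble(concept_id = "T1", attribute_id = "T2"))
}

# Write the denied example as standoff files and return their paths.
write_denied_standoff <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  txt <- file.path(dir, "denied.txt")
  ann <- file.path(dir, "denied.ann")
  writeChar("Denied any chest pain.", txt, eos = NULL)
  writeLines(c(
    "T1\tDisorder 11 21\tchest pain",
    "T2\tNEG 0 6\tDenied",
    "R1\tAttrOf Arg1:T1 Arg2:T2"), ann)
  c(txt = txt, ann = ann)
}

small_corpus <- function(n = 6, seed = 42, task = "disorder", ...) {
  generate_corpus(gen_config(task = task, n_documents = n,
                             sentences_per_document = c(2L, 3L),
                             seed = seed, ...))
}

# Brute-force CRF oracles: enumerate all label paths.
enumerate_paths <- function(em, tr) {
  T <- nrow(em); L <- ncol(em); S <- L + 1L; E <- L + 2L
  paths <- as.matrix(expand.grid(rep(list(seq_len(L)), T)))
  scores <- apply(paths, 1L, function(y) {
    s <- tr[S, y[1]] + em[1, y[1]]
    if (T > 1) for (t in 2:T) s <- s + tr[y[t - 1], y[t]] + em[t, y[t]]
    s + tr[y[T], E]
  })
  list(paths = paths, scores = scores,
       logZ = log(sum(exp(scores - max(scores)))) + max(scores),
       best_score = max(scores),
       best_path = paths[which.max(scores), ])
}

random_crf_instance <- function(T, L) {
  em <- matrix(rnorm(T * L), T, L)
  tr <- new_transition_matrix(L)
  tr[seq_len(L), seq_len(L)] <- rnorm(L * L)
  tr[L + 1L, seq_len(L)] <- rnorm(L)
  tr[seq_len(L), L + 2L] <- rnorm(L)
  list(em = em, tr = tr)
}

tiny_tagger_config <- function(...) {
  tagger_config(word_dim = 8L, char_dim = 4L, word_hidden = 8L,
                char_hidden = 4L, role_dim = 3L, ...)
}

pair_f1 <- function(gold, pred) {
  gk <- attrseq:::pair_key(gold); pk <- attrseq:::pair_key(pred)
  tp <- sum(pk %in% gk)
  if (!nrow(gold) && !nrow(pred)) return(1)
  2 * tp / (nrow(gold) + nrow(pred))
}
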