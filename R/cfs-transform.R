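#' BIO label set for a task
#'
#' Ordered label vocabulary used by the taggers: `O` first, then `B-`/`I-`
#' labels per attribute type in inventory order.
#'
#' @param task Task name, see [task_attributes()].
#' @return Character vector of labels.
#' @export
label_set <- function(task) {
  types <- task_attributes(task)
  c("O", as.vector(rbind(paste0("B-", types), paste0("I-", types))))
}

new_cfs <- function(doc_id, sentence, target_id, target_type,
                    target_start, target_end, tokens) {
  structure(
    list(doc_id = doc_id, sentence = sentence, target_id = target_id,
         target_type = target_type, target_start = target_start,
         target_end = target_end, tokens = tokens),
    class = "attrseq_cfs")
}

#' @export
print.attrseq_cfs <- function(x, ...) {
  cat(sprintf("<attrseq_cfs doc='%s' sentence=%d target='%s' (%s), %d tokens>\n",
              x$doc_id, x$sentence, x$target_id, x$target_type, nrow(x$tokens)))
  print(x$tokens)
  invisible(x)
}

#' Build the concept-focused sequence for one target concept
#'
#' Produces one copy of a sentence dedicated to a single target concept.
#' Every token carries two independent channels: a concept-role tag
#' (`Target` on the target concept's tokens, `NotTarget` on other concept
#' mentions' tokens, `Outside` elsewhere) and a BIO attribute label.
#' Only attributes related to the target receive `B-`/`I-` labels of their
#' type; attributes of other concepts and unassociated spans are `O`. The
#' two channels never veto each other: a token may be `Target` and carry a
#' `B`/`I` label when an attribute overlaps the target span, and a token of
#' a non-target concept that is an attribute of the target keeps
#' `NotTarget` alongside its `B`/`I` label.
#'
#' @param doc An [annotated_document()].
#' @param sentence_index Sentence index (1-based) within the document.
#' @param target_id Concept mention id; must lie in the indexed sentence.
#' @return An `attrseq_cfs` object: token tibble with `text`, `start`,
#'   `end`, `role`, `label`, plus target bookkeeping.
#' @export
make_cfs <- function(doc, sentence_index, target_id) {
  stopifnot(inherits(doc, "attrseq_document"))
  ci <- match(target_id, doc$concepts$id)
  if (is.na(ci)) abort(paste0("no such concept: ", target_id))
  if (doc$concepts$sentence[ci] != sentence_index) {
    abort(sprintf("concept '%s' is not in sentence %d", target_id,
                  sentence_index))
  }
  tokens <- sentence_tokens(doc, sentence_index)
  n <- nrow(tokens)
  role <- rep("Outside", n)
  sent_concepts <- doc$concepts[doc$concepts$sentence == sentence_index, ]
  for (k in seq_len(nrow(sent_concepts))) {
    rng <- align_span(sent_concepts$start[k], sent_concepts$end[k], tokens,
                      mode = "expand")
    if (sent_concepts$id[k] != target_id) {
      idx <- rng[1]:rng[2]
      role[idx][role[idx] == "Outside"] <- "NotTarget"
    }
  }
  # target last so its tokens always read Target even under concept overlap
  rng <- align_span(doc$concepts$start[ci], doc$concepts$end[ci], tokens,
                    mode = "expand")
  role[rng[1]:rng[2]] <- "Target"

  label <- rep("O", n)
  rel_attr <- doc$relations$attribute_id[doc$relations$concept_id == target_id]
  atts <- doc$attributes[match(rel_attr, doc$attributes$id), , drop = FALSE]
  if (nrow(atts)) {
    cross <- atts$sentence != sentence_index
    if (any(cross)) {
      warn(sprintf(
        "document '%s': dropped %d cross-sentence relation(s) for target '%s'",
        doc$doc_id, sum(cross), target_id))
      atts <- atts[!cross, , drop = FALSE]
    }
  }
  if (nrow(atts)) atts <- atts[order(atts$start), , drop = FALSE]
  for (k in seq_len(nrow(atts))) {
    rng <- tryCatch(
      align_span(atts$start[k], atts$end[k], tokens, mode = "strict"),
      attrseq_alignment_error = function(e)
        align_span(atts$start[k], atts$end[k], tokens, mode = "expand"))
    idx <- rng[1]:rng[2]
    clash <- label[idx] != "O"
    if (any(clash)) {
      abort(sprintf(
        "document '%s' sentence %d: attributes of target '%s' claim overlapping tokens (%s vs %s)",
        doc$doc_id, sentence_index, target_id, atts$attr_type[k],
        sub("^[BI]-", "", label[idx][clash][1])),
        class = "attrseq_label_conflict")
    }
    label[idx] <- c(paste0("B-", atts$attr_type[k]),
                    rep(paste0("I-", atts$attr_type[k]), length(idx) - 1L))
  }
  tokens$role <- role
  tokens$label <- label
  new_cfs(doc$doc_id, sentence_index, target_id,
          doc$concepts$concept_type[ci], doc$concepts$start[ci],
          doc$concepts$end[ci],
          tokens[, c("text", "start", "end", "role", "label")])
}

#' Expand a document into concept-focused sequences
#'
#' One sentence with several target concepts yields several training
#' samples, one per target. Order is deterministic: sentences in document
#' order, concepts within a sentence by start offset (ties by id).
#'
#' @param doc An [annotated_document()], or a list of them.
#' @return A list of `attrseq_cfs` objects;
#'   `length == sum over sentences of concepts per sentence`.
#' @export
expand_document <- function(doc) {
  if (!inherits(doc, "attrseq_document")) {
    return(unlist(lapply(doc, expand_document), recursive = FALSE))
  }
  con <- doc$concepts
  if (!nrow(con)) return(list())
  ord <- order(con$sentence, con$start, con$id)
  con <- con[ord, ]
  purrr::map(seq_len(nrow(con)),
             function(k) make_cfs(doc, con$sentence[k], con$id[k]))
}

#' Decode predicted BIO labels of a CFS back into attribute mentions
#'
#' Maximal `B-t I-t ...` runs become attribute mentions of type `t`; the
#' character span runs from the first token's start to the last token's end.
#' A dangling `I-t` (sequence start, after `O`, or after a different type)
#' is repaired by treating it as `B-t`. Every decoded mention is related to
#' the CFS's target concept.
#'
#' @param cfs An `attrseq_cfs`.
#' @param labels Character vector of BIO labels, one per token. Defaults to
#'   the gold labels stored in the CFS.
#' @return Tibble with columns `doc_id`, `concept_id`, `concept_start`,
#'   `concept_end`, `attr_type`, `attr_start`, `attr_end`, `attr_text` —
#'   one row per decoded (attribute, target) pair.
#' @export
decode_cfs <- function(cfs, labels = cfs$tokens$label) {
  stopifnot(inherits(cfs, "attrseq_cfs"))
  n <- nrow(cfs$tokens)
  if (length(labels) != n) {
    abort(sprintf("expected %d labels, got %d", n, length(labels)))
  }
  bad <- !grepl("^(O|[BI]-[A-Z]+)$", labels) |
    (labels != "O" & !(sub("^[BI]-", "", labels) %in% all_attr_types()))
  if (any(bad)) {
    abort(paste0("unknown label: ", labels[which(bad)[1]]),
          class = "attrseq_decode_error")
  }
  runs <- parse_bio_runs(labels)
  if (!nrow(runs)) return(empty_pairs())
  tibble(
    doc_id = cfs$doc_id,
    concept_id = cfs$target_id,
    concept_start = cfs$target_start,
    concept_end = cfs$target_end,
    attr_type = runs$attr_type,
    attr_start = cfs$tokens$start[runs$first],
    attr_end = cfs$tokens$end[runs$last],
    attr_text = vapply(seq_len(nrow(runs)), function(i)
      paste(cfs$tokens$text[runs$first[i]:runs$last[i]], collapse = " "),
      character(1))
  )
}

# Maximal B..I runs of one type; a dangling I- opens a fresh run (repair).
parse_bio_runs <- function(labels) {
  n <- length(labels)
  type <- character(0); first <- integer(0); last <- integer(0)
  cur_type <- NULL; cur_first <- NA_integer_
  close_run <- function(end_at) {
    if (!is.null(cur_type)) {
      type <<- c(type, cur_type); first <<- c(first, cur_first)
      last <<- c(last, end_at)
    }
    cur_type <<- NULL
  }
  for (t in seq_len(n)) {
    lab <- labels[[t]]
    if (lab == "O") { close_run(t - 1L); next }
    typ <- sub("^[BI]-", "", lab)
    if (startsWith(lab, "B-") || is.null(cur_type) || cur_type != typ) {
      close_run(t - 1L)
      cur_type <- typ; cur_first <- t
    }
  }
  close_run(n)
  tibble(attr_type = type, first = first, last = last)
}

#' Write / read concept-focused sequences in a CoNLL-style format
#'
#' One token per line (`token TAB start TAB end TAB role TAB label`), blank
#' line between sequences, and a `# doc=... sentence=... target=...` header
#' comment per sequence carrying the target concept's identity.
#'
#' @param cfs_list List of `attrseq_cfs` objects.
#' @param path Output file.
#' @export
write_cfs_conll <- function(cfs_list, path) {
  out <- unlist(lapply(cfs_list, function(cfs) {
    c(sprintf("# doc=%s sentence=%d target=%s target_type=%s target_start=%d target_end=%d",
              cfs$doc_id, cfs$sentence, cfs$target_id, cfs$target_type,
              cfs$target_start, cfs$target_end),
      sprintf("%s\t%d\t%d\t%s\t%s", cfs$tokens$text, cfs$tokens$start,
              cfs$tokens$end, cfs$tokens$role, cfs$tokens$label),
      "")
  }))
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_cfs_conll
#' @export
read_cfs_conll <- function(path) {
  lines <- readLines(path)
  out <- list(); header <- NULL; rows <- list()
  flush_seq <- function() {
    if (is.null(header)) return()
    tok <- dplyr::bind_rows(rows)
    out[[length(out) + 1L]] <<- new_cfs(
      header[["doc"]], as.integer(header[["sentence"]]), header[["target"]],
      header[["target_type"]], as.integer(header[["target_start"]]),
      as.integer(header[["target_end"]]), tok)
    header <<- NULL; rows <<- list()
  }
  for (line in lines) {
    if (!nzchar(line)) { flush_seq(); next }
    if (startsWith(line, "# ")) {
      kv <- strsplit(strsplit(sub("^# ", "", line), " ")[[1]], "=")
      header <- setNames(vapply(kv, `[`, character(1), 2L),
                         vapply(kv, `[`, character(1), 1L))
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 5L) abort(paste0("malformed CoNLL line: ", line),
                               class = "attrseq_parse_error")
    rows[[length(rows) + 1L]] <- tibble(
      text = f[1], start = as.integer(f[2]), end = as.integer(f[3]),
      role = f[4], label = f[5])
  }
  flush_seq()
  out
}
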