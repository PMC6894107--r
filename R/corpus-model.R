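#' Tokenize a sentence
#'
#' Whitespace tokenization with leading/trailing punctuation split off into
#' separate tokens. Internal punctuation is never split, so numeric compounds
#' such as `"134/75"` and hyphenated words survive intact, and a trailing
#' period is kept attached when the token already contains an internal period
#' (dotted abbreviations such as `"p.m."` or `"q.a.m."`).
#'
#' Offsets are 0-based half-open character offsets. `sentence_offset` shifts
#' them so tokens carry document-global offsets.
#'
#' @param text Sentence text.
#' @param sentence_offset Character offset of the sentence start within the
#'   document (0-based). Default 0.
#' @return A tibble with columns `text`, `start`, `end`, one row per token.
#'   Whitespace-only input yields zero rows.
#' @export
#' @examples
#' tokenize("blood pressure 134/75")
#' tokenize("Denied any chest pain.")
tokenize <- function(text, sentence_offset = 0L) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- tibble(text = character(), start = integer(), end = integer())
  if (!nzchar(trimws(text))) return(empty)

  m <- gregexpr("\\S+", text)[[1]]
  chunks <- regmatches(text, gregexpr("\\S+", text))[[1]]
  starts <- as.integer(m) - 1L              # to 0-based
  out_text <- character(0); out_start <- integer(0)

  for (i in seq_along(chunks)) {
    chunk <- chunks[[i]]
    pos <- starts[[i]]
    # peel leading punctuation
    while (nchar(chunk) > 1L && grepl("^[[:punct:]]", chunk)) {
      out_text <- c(out_text, substr(chunk, 1L, 1L))
      out_start <- c(out_start, pos)
      chunk <- substr(chunk, 2L, nchar(chunk))
      pos <- pos + 1L
    }
    # peel trailing punctuation, respecting dotted abbreviations
    trail <- character(0)
    while (nchar(chunk) > 1L && grepl("[[:punct:]]$", chunk)) {
      last <- substr(chunk, nchar(chunk), nchar(chunk))
      core <- substr(chunk, 1L, nchar(chunk) - 1L)
      if (last == "." && grepl("\\.", core)) break
      trail <- c(last, trail)
      chunk <- core
    }
    out_text <- c(out_text, chunk)
    out_start <- c(out_start, pos)
    if (length(trail)) {
      tpos <- pos + nchar(chunk) + seq_along(trail) - 1L
      out_text <- c(out_text, trail)
      out_start <- c(out_start, tpos)
    }
  }
  tibble(
    text = out_text,
    start = out_start + as.integer(sentence_offset),
    end = out_start + nchar(out_text) + as.integer(sentence_offset)
  )
}

#' Align a character span to a token range
#'
#' Finds the smallest contiguous run of tokens covering the span
#' `[start, end)`. In `"strict"` mode the span must coincide exactly with
#' token boundaries; in `"expand"` mode the returned range may overtop the
#' span (used when a mention boundary falls mid-token).
#'
#' @param start,end 0-based half-open character offsets.
#' @param tokens Token tibble as produced by [tokenize()].
#' @param mode `"strict"` or `"expand"`.
#' @return Integer vector `c(first, last)` of 1-based token indices.
#' @export
align_span <- function(start, end, tokens, mode = c("strict", "expand")) {
  mode <- match.arg(mode)
  stopifnot(start < end, nrow(tokens) > 0L)
  first <- which(tokens$end > start)[1L]
  last <- tail(which(tokens$start < end), 1L)
  if (is.na(first) || length(last) == 0L || first > last) {
    abort(sprintf("span [%d,%d) does not overlap any token", start, end),
          class = "attrseq_alignment_error")
  }
  if (mode == "strict" &&
      (tokens$start[first] != start || tokens$end[last] != end)) {
    abort(sprintf(
      "span [%d,%d) does not coincide with token boundaries [%d,%d)",
      start, end, tokens$start[first], tokens$end[last]),
      class = "attrseq_alignment_error")
  }
  c(first, last)
}

#' Split document text into sentences
#'
#' Clinical notes are line-oriented, so the default treats each non-blank
#' line as one sentence. `method = "period"` additionally splits lines after
#' `". "` boundaries.
#'
#' @param text Document text.
#' @param method `"newline"` (default) or `"period"`.
#' @return Tibble with columns `sentence`, `start`, `end`, `text`
#'   (0-based half-open offsets into `text`).
#' @export
split_sentences <- function(text, method = c("newline", "period")) {
  method <- match.arg(method)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L) lines <- ""
  line_start <- c(0L, cumsum(nchar(lines) + 1L))[seq_along(lines)]

  pieces_start <- integer(0); pieces_end <- integer(0)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (method == "period") {
      cut <- gregexpr("\\. +", ln)[[1]]
      bounds <- if (cut[1] == -1) integer(0) else
        as.integer(cut) + attr(cut, "match.length") - 1L  # 0-based piece start
      seg_start <- c(0L, bounds)
    } else {
      seg_start <- 0L
    }
    seg_end <- c(seg_start[-1], nchar(ln))
    for (j in seq_along(seg_start)) {
      seg <- substr(ln, seg_start[j] + 1L, seg_end[j])
      lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
      trailn <- nchar(seg) - nchar(sub("\\s+$", "", seg))
      s <- seg_start[j] + lead
      e <- seg_end[j] - trailn
      if (e > s) {
        pieces_start <- c(pieces_start, line_start[i] + s)
        pieces_end <- c(pieces_end, line_start[i] + e)
      }
    }
  }
  tibble(
    sentence = seq_along(pieces_start),
    start = pieces_start,
    end = pieces_end,
    text = substring(text, pieces_start + 1L, pieces_end)
  )
}

substr0 <- function(text, start, end) {
  if (!length(start)) return(character(0))
  substring(text, start + 1L, end)
}

#' Construct an annotated document
#'
#' Core container for one clinical note: raw text, sentence and token
#' segmentation, concept mentions, attribute mentions and concept-attribute
#' relations. All offsets are 0-based half-open over the raw text. Mention
#' `text` fields are re-derived from offsets. Construction validates the
#' corpus invariants: mention spans inside exactly one sentence, resolvable
#' non-duplicate relations, unique mention ids, known type codes.
#'
#' @param doc_id Document identifier.
#' @param text Raw document text.
#' @param concepts Tibble/data.frame with columns `id`, `concept_type`,
#'   `start`, `end`.
#' @param attributes Tibble/data.frame with columns `id`, `attr_type`,
#'   `start`, `end`.
#' @param relations Tibble/data.frame with columns `concept_id`,
#'   `attribute_id`.
#' @param sentence_method Sentence splitting rule, see [split_sentences()].
#' @return An object of class `attrseq_document`.
#' @export
annotated_document <- function(doc_id, text,
                               concepts = NULL, attributes = NULL,
                               relations = NULL,
                               sentence_method = "newline") {
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            is.character(text), length(text) == 1L)
  concepts <- normalize_mentions(concepts, c("id", "concept_type", "start", "end"))
  attributes <- normalize_mentions(attributes, c("id", "attr_type", "start", "end"))
  relations <- if (is.null(relations) || nrow(as_tibble(relations)) == 0L) {
    tibble(concept_id = character(), attribute_id = character())
  } else {
    as_tibble(relations)[, c("concept_id", "attribute_id")]
  }
  relations$concept_id <- as.character(relations$concept_id)
  relations$attribute_id <- as.character(relations$attribute_id)

  bad_type <- setdiff(concepts$concept_type, CONCEPT_TYPES)
  if (length(bad_type)) {
    abort(paste0("unknown concept type(s): ", paste(bad_type, collapse = ", ")),
          class = "attrseq_integrity_error")
  }
  bad_attr <- setdiff(attributes$attr_type, all_attr_types())
  if (length(bad_attr)) {
    abort(paste0("unknown attribute type(s): ", paste(bad_attr, collapse = ", ")),
          class = "attrseq_integrity_error")
  }
  ids <- c(concepts$id, attributes$id)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate mention id in document '%s'", doc_id),
          class = "attrseq_integrity_error")
  }

  n <- nchar(text)
  for (df in list(concepts, attributes)) {
    if (nrow(df) && any(df$start < 0L | df$start >= df$end | df$end > n)) {
      abort(sprintf("mention with invalid offsets in document '%s'", doc_id),
            class = "attrseq_integrity_error")
    }
  }
  concepts$text <- substr0(text, concepts$start, concepts$end)
  attributes$text <- substr0(text, attributes$start, attributes$end)

  sentences <- split_sentences(text, sentence_method)
  tokens <- purrr::map_dfr(seq_len(nrow(sentences)), function(i) {
    tk <- tokenize(sentences$text[i], sentences$start[i])
    if (nrow(tk)) tk$sentence <- sentences$sentence[i]
    tk
  })
  if (nrow(tokens)) tokens <- tokens[, c("sentence", "text", "start", "end")]
  else tokens <- tibble(sentence = integer(), text = character(),
                        start = integer(), end = integer())

  locate_sentence <- function(df, what) {
    if (!nrow(df)) { df$sentence <- integer(0); return(df) }
    df$sentence <- purrr::map2_int(df$start, df$end, function(s, e) {
      hit <- which(sentences$start <= s & sentences$end >= e)
      if (length(hit) != 1L) {
        abort(sprintf(
          "%s mention [%d,%d) in document '%s' does not lie inside exactly one sentence",
          what, s, e, doc_id), class = "attrseq_integrity_error")
      }
      hit
    })
    df
  }
  concepts <- locate_sentence(concepts, "concept")
  attributes <- locate_sentence(attributes, "attribute")

  if (nrow(relations)) {
    if (anyDuplicated(relations)) {
      abort("duplicate relations", class = "attrseq_integrity_error")
    }
    unresolved <- !(relations$concept_id %in% concepts$id) |
      !(relations$attribute_id %in% attributes$id)
    if (any(unresolved)) {
      abort(sprintf("relation with unresolvable endpoint in document '%s'",
                    doc_id), class = "attrseq_integrity_error")
    }
  }

  structure(
    list(doc_id = doc_id, text = text, sentences = sentences, tokens = tokens,
         concepts = concepts[, c("id", "concept_type", "start", "end", "text", "sentence")],
         attributes = attributes[, c("id", "attr_type", "start", "end", "text", "sentence")],
         relations = relations),
    class = "attrseq_document"
  )
}

normalize_mentions <- function(df, cols) {
  if (is.null(df) || nrow(as_tibble(df)) == 0L) {
    out <- tibble::as_tibble(setNames(
      list(character(), character(), integer(), integer()), cols))
    return(out)
  }
  df <- as_tibble(df)[, cols]
  df[[1]] <- as.character(df[[1]])
  df[[2]] <- as.character(df[[2]])
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' @export
print.attrseq_document <- function(x, ...) {
  cat(sprintf(
    "<attrseq_document '%s': %d sentences, %d concepts, %d attributes, %d relations>\n",
    x$doc_id, nrow(x$sentences), nrow(x$concepts), nrow(x$attributes),
    nrow(x$relations)))
  invisible(x)
}

#' @export
format.attrseq_document <- function(x, ...) {
  sprintf("<attrseq_document '%s'>", x$doc_id)
}

parse_ann_lines <- function(lines, ann_path) {
  t_rows <- list(); r_rows <- list(); disjoint_ids <- character(0)
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    lead <- substr(line, 1L, 1L)
    if (lead == "T") {
      m <- regmatches(line, regexec("^(T[^\t]+)\t(\\S+) ([0-9; ]+)\t(.*)$", line))[[1]]
      if (length(m) == 0L) {
        abort(sprintf("%s:%d: malformed T line", ann_path, i),
              class = "attrseq_parse_error")
      }
      if (grepl(";", m[4])) {            # discontiguous mention
        disjoint_ids <- c(disjoint_ids, m[2])
        next
      }
      off <- strsplit(trimws(m[4]), " +")[[1]]
      if (length(off) != 2L || anyNA(suppressWarnings(as.integer(off)))) {
        abort(sprintf("%s:%d: malformed offsets", ann_path, i),
              class = "attrseq_parse_error")
      }
      t_rows[[length(t_rows) + 1L]] <- tibble(
        id = m[2], type = m[3],
        start = as.integer(off[1]), end = as.integer(off[2]), surface = m[5])
    } else if (lead == "R") {
      m <- regmatches(line, regexec(
        "^(R[^\t]+)\t(\\S+) Arg1:(\\S+) Arg2:(\\S+)\\s*$", line))[[1]]
      if (length(m) == 0L) {
        abort(sprintf("%s:%d: malformed R line", ann_path, i),
              class = "attrseq_parse_error")
      }
      r_rows[[length(r_rows) + 1L]] <- tibble(concept_id = m[4], attribute_id = m[5])
    } else if (lead %in% c("#", "A", "E", "N")) {
      next                               # notes and other standoff line kinds
    } else {
      abort(sprintf("%s:%d: unrecognized annotation line", ann_path, i),
            class = "attrseq_parse_error")
    }
  }
  list(mentions = dplyr::bind_rows(t_rows), relations = dplyr::bind_rows(r_rows),
       disjoint = disjoint_ids)
}

#' Read a BRAT-style standoff document
#'
#' Reads a `.txt`/`.ann` pair: `T` lines are mentions
#' (`T<id>\tTYPE start end\ttext`), `R` lines relations
#' (`R<id>\tREL Arg1:T<concept> Arg2:T<attribute>`). Mentions whose type is a
#' concept type (`Disorder`, `Medication`, `LabTest`) become concept
#' mentions; all others must carry a known attribute-type code.
#' Discontiguous mentions (semicolon offsets) are dropped with a warning,
#' together with relations touching them. The surface string on each T line
#' is checked against the text at its offsets; a mismatch is an integrity
#' error.
#'
#' @param text_path Path to the `.txt` file.
#' @param ann_path Path to the `.ann` file (default: same path with `.ann`).
#' @param sentence_method See [split_sentences()].
#' @return An [annotated_document()].
#' @export
read_standoff <- function(text_path, ann_path = NULL,
                          sentence_method = "newline") {
  if (is.null(ann_path)) ann_path <- sub("\\.txt$", ".ann", text_path)
  if (!file.exists(text_path)) abort(paste0("no such file: ", text_path))
  if (!file.exists(ann_path)) abort(paste0("no such file: ", ann_path))
  text <- readChar(text_path, file.info(text_path)$size, useBytes = FALSE)
  lines <- readLines(ann_path, warn = FALSE)
  parsed <- parse_ann_lines(lines, ann_path)
  if (length(parsed$disjoint)) {
    warn(sprintf("%s: dropped %d discontiguous mention(s): %s", ann_path,
                 length(parsed$disjoint), paste(parsed$disjoint, collapse = ", ")))
  }
  mentions <- parsed$mentions
  relations <- parsed$relations
  if (nrow(relations) && length(parsed$disjoint)) {
    keep <- !(relations$concept_id %in% parsed$disjoint |
                relations$attribute_id %in% parsed$disjoint)
    relations <- relations[keep, ]
  }

  doc_id <- sub("\\.txt$", "", basename(text_path))
  if (nrow(mentions) == 0L) {
    return(annotated_document(doc_id, text, sentence_method = sentence_method))
  }
  actual <- substr0(text, mentions$start, mentions$end)
  bad <- which(actual != mentions$surface)
  if (length(bad)) {
    abort(sprintf(
      "%s: mention %s surface text '%s' does not match text at [%d,%d) ('%s')",
      ann_path, mentions$id[bad[1]], mentions$surface[bad[1]],
      mentions$start[bad[1]], mentions$end[bad[1]], actual[bad[1]]),
      class = "attrseq_integrity_error")
  }
  is_concept <- mentions$type %in% CONCEPT_TYPES
  concepts <- mentions[is_concept, ]
  names(concepts)[names(concepts) == "type"] <- "concept_type"
  attributes <- mentions[!is_concept, ]
  names(attributes)[names(attributes) == "type"] <- "attr_type"

  annotated_document(doc_id, text,
                     concepts = concepts[, c("id", "concept_type", "start", "end")],
                     attributes = attributes[, c("id", "attr_type", "start", "end")],
                     relations = relations,
                     sentence_method = sentence_method)
}

#' Write a document as BRAT-style standoff files
#'
#' Inverse of [read_standoff()]: emits `<doc_id>.txt` with the raw text and
#' `<doc_id>.ann` with one T line per mention and one R line per relation
#' (an attribute linked to several concepts yields several R lines).
#' Round-trips exactly.
#'
#' @param doc An [annotated_document()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the two file paths written.
#' @export
write_standoff <- function(doc, out_dir) {
  stopifnot(inherits(doc, "attrseq_document"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  txt_path <- file.path(out_dir, paste0(doc$doc_id, ".txt"))
  ann_path <- file.path(out_dir, paste0(doc$doc_id, ".ann"))
  writeChar(doc$text, txt_path, eos = NULL)

  t_lines <- c(
    sprintf("%s\t%s %d %d\t%s", doc$concepts$id, doc$concepts$concept_type,
            doc$concepts$start, doc$concepts$end, doc$concepts$text),
    sprintf("%s\t%s %d %d\t%s", doc$attributes$id, doc$attributes$attr_type,
            doc$attributes$start, doc$attributes$end, doc$attributes$text))
  r_lines <- if (nrow(doc$relations)) {
    sprintf("R%d\tAttrOf Arg1:%s Arg2:%s", seq_len(nrow(doc$relations)),
            doc$relations$concept_id, doc$relations$attribute_id)
  } else character(0)
  writeLines(c(t_lines, r_lines), ann_path)
  invisible(c(txt = txt_path, ann = ann_path))
}

#' Read or write a whole standoff corpus directory
#'
#' @param dir Directory of `.txt`/`.ann` pairs.
#' @param sentence_method See [split_sentences()].
#' @return `read_corpus()`: a list of [annotated_document()]s, ordered by
#'   file name. `write_corpus()`: invisibly, the directory.
#' @export
read_corpus <- function(dir, sentence_method = "newline") {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(txts)) abort(paste0("no .txt files found in ", dir))
  lapply(txts, read_standoff, sentence_method = sentence_method)
}

#' @rdname read_corpus
#' @param docs List of documents.
#' @export
write_corpus <- function(docs, dir) {
  for (doc in docs) write_standoff(doc, dir)
  invisible(dir)
}

#' Gold concept-attribute pairs of a corpus
#'
#' Flattens documents' relations into the pair table used throughout
#' evaluation: one row per (concept, attribute) link, carrying the concept
#' identity (id and offsets) and the attribute span and type. An attribute
#' linked to several concepts appears once per concept.
#'
#' @param docs A document or list of documents.
#' @return Tibble with columns `doc_id`, `concept_id`, `concept_start`,
#'   `concept_end`, `attr_type`, `attr_start`, `attr_end`, `attr_text`.
#' @export
gold_pairs <- function(docs) {
  docs <- as_doclist(docs)
  purrr::map_dfr(docs, function(doc) {
    if (!nrow(doc$relations)) return(empty_pairs())
    con <- doc$concepts[match(doc$relations$concept_id, doc$concepts$id), ]
    att <- doc$attributes[match(doc$relations$attribute_id, doc$attributes$id), ]
    tibble(doc_id = doc$doc_id,
           concept_id = con$id, concept_start = con$start, concept_end = con$end,
           attr_type = att$attr_type, attr_start = att$start,
           attr_end = att$end, attr_text = att$text)
  })
}

#' All gold concepts of a corpus
#'
#' @param docs A document or list of documents.
#' @return Tibble with one row per concept mention.
#' @export
concept_table <- function(docs) {
  docs <- as_doclist(docs)
  purrr::map_dfr(docs, function(doc) {
    if (!nrow(doc$concepts)) {
      return(tibble(doc_id = character(), concept_id = character(),
                    concept_start = integer(), concept_end = integer(),
                    concept_type = character()))
    }
    tibble(doc_id = doc$doc_id, concept_id = doc$concepts$id,
           concept_start = doc$concepts$start, concept_end = doc$concepts$end,
           concept_type = doc$concepts$concept_type)
  })
}

empty_pairs <- function() {
  tibble(doc_id = character(), concept_id = character(),
         concept_start = integer(), concept_end = integer(),
         attr_type = character(), attr_start = integer(),
         attr_end = integer(), attr_text = character())
}

as_doclist <- function(docs) {
  if (inherits(docs, "attrseq_document")) list(docs) else docs
}

sentence_tokens <- function(doc, sentence_index) {
  doc$tokens[doc$tokens$sentence == sentence_index, , drop = FALSE]
}
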