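# Story containers, text cleaning, sentence segmentation, manifest and table I/O.

#' Construct a story
#'
#' A `story` holds one text at one point in a retelling lineage: the stimulus
#' (day 0) or one of a participant's retellings (day 1..T). Sentences are the
#' unit of analysis (a proxy for events) and stay `NULL` until the text is
#' segmented with [segment_sentences()] or [prepare_lineages()].
#'
#' @param raw_text Character scalar, the full story text (may be `NULL` when
#'   `sentences` are supplied directly).
#' @param sentences Optional character vector of pre-segmented, non-empty
#'   sentences in story order.
#' @param story_id Identifier; generated from participant/condition/day when
#'   missing.
#' @param participant_id Participant identifier, or `NA` for stimulus stories.
#' @param condition Condition label.
#' @param day Integer day index: 0 is the initial stimulus, 1..T retellings.
#' @param event_ids Optional integer vector (one per sentence) carrying
#'   generator-side event identities; `NA` for real data.
#' @return An object of class `story`.
#' @export
story <- function(raw_text = NULL, sentences = NULL, story_id = NULL,
                  participant_id = NA_character_, condition = NA_character_,
                  day = NA_integer_, event_ids = NULL) {
  if (is.null(raw_text) && is.null(sentences)) {
    stop("story() needs `raw_text` or `sentences`")
  }
  if (!is.null(sentences)) {
    sentences <- as.character(sentences)
    if (any(!nzchar(trimws(sentences)))) {
      stop("story sentences must be non-empty")
    }
    if (!is.null(event_ids) && length(event_ids) != length(sentences)) {
      stop("event_ids length must match sentences")
    }
  }
  if (is.null(raw_text)) raw_text <- paste(sentences, collapse = " ")
  day <- as.integer(day)
  if (!is.na(day) && day < 0L) stop("day must be >= 0")
  if (is.null(story_id)) {
    story_id <- paste(
      ifelse(is.na(participant_id), "stim", participant_id),
      ifelse(is.na(condition), "none", condition),
      ifelse(is.na(day), "x", day),
      sep = "_"
    )
  }
  structure(
    list(
      story_id = as.character(story_id),
      participant_id = as.character(participant_id),
      condition = as.character(condition),
      day = day,
      raw_text = as.character(raw_text),
      sentences = sentences,
      event_ids = event_ids
    ),
    class = "story"
  )
}

#' @export
print.story <- function(x, ...) {
  cat(sprintf(
    "<story %s> participant=%s condition=%s day=%s, %s\n",
    x$story_id, x$participant_id, x$condition, x$day,
    if (is.null(x$sentences)) "unsegmented" else
      sprintf("%d sentences", length(x$sentences))
  ))
  invisible(x)
}

#' Construct a retelling lineage
#'
#' One participant's day-ordered stories within one condition: the stimulus at
#' day 0 (when present) followed by the retellings.
#'
#' @param stories List of [story()] objects sharing participant and condition.
#' @return An object of class `retelling_lineage`.
#' @export
lineage <- function(stories) {
  if (!length(stories) || !all(vapply(stories, inherits, TRUE, "story"))) {
    stop("lineage() needs a non-empty list of story objects")
  }
  days <- vapply(stories, function(s) s$day, integer(1))
  if (anyNA(days)) stop("all lineage stories need a day index")
  if (anyDuplicated(days)) {
    stop(sprintf("duplicate day indices in lineage: %s",
                 paste(days[duplicated(days)], collapse = ", ")))
  }
  stories <- stories[order(days)]
  structure(
    list(
      participant_id = stories[[1]]$participant_id,
      condition = stories[[1]]$condition,
      stories = stories
    ),
    class = "retelling_lineage"
  )
}

#' @export
print.retelling_lineage <- function(x, ...) {
  cat(sprintf(
    "<retelling_lineage> participant=%s condition=%s days=%s\n",
    x$participant_id, x$condition,
    paste(vapply(x$stories, function(s) s$day, integer(1)), collapse = ",")
  ))
  invisible(x)
}

#' Meta-commentary cleaning configuration
#'
#' Retellings often contain meta-commentary about the act of remembering
#' ("if I remember correctly", "I think", ...) which is not story content and
#' is stripped before analysis. Matching is case-insensitive and
#' word-boundary anchored; a sentence left with fewer than
#' `min_content_tokens` word tokens after stripping is dropped entirely (this
#' is how whole task-difficulty remarks are removed).
#'
#' @param meta_phrases Extra phrases to strip, added to the defaults.
#' @param min_content_tokens Minimum surviving word tokens for a sentence to
#'   be kept (default 2).
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(meta_phrases = character(), min_content_tokens = 2L) {
  min_content_tokens <- as.integer(min_content_tokens)
  if (is.na(min_content_tokens) || min_content_tokens < 1L) {
    stop("min_content_tokens must be an integer >= 1")
  }
  structure(
    list(
      meta_phrases = unique(c(default_meta_phrases(), tolower(meta_phrases))),
      min_content_tokens = min_content_tokens
    ),
    class = "cleaning_config"
  )
}

#' Default meta-commentary phrases
#' @return Character vector of phrases stripped by default.
#' @export
default_meta_phrases <- function() {
  c("if i remember correctly", "i recall", "i believe", "i think")
}

#' Remove meta-commentary from a story text
#'
#' Deletes every occurrence of each configured meta phrase
#' (case-insensitively, at word boundaries), repairs stranded punctuation and
#' whitespace, and drops sentences left with fewer than
#' `min_content_tokens` word tokens. Idempotent: cleaning a cleaned text is a
#' no-op.
#'
#' @param text Character scalar.
#' @param config A [cleaning_config()].
#' @return Cleaned character scalar (possibly empty).
#' @export
clean_text <- function(text, config = cleaning_config()) {
  stopifnot(inherits(config, "cleaning_config"))
  if (is.null(text) || !nzchar(trimws(text))) return("")
  sents <- segment_sentences(text)
  kept <- character(0)
  for (s in sents) {
    for (ph in config$meta_phrases) {
      pat <- paste0("(?i)\\b", escape_regex(ph), "\\b")
      s <- gsub(pat, " ", s, perl = TRUE)
    }
    s <- gsub("\\s+", " ", s)
    s <- gsub("\\s*,(\\s*,)+", ",", s)          # collapse stranded commas
    s <- gsub("^[[:space:],;:]+", "", s)        # phrase removed at start
    s <- gsub("\\s+([.!?,;:])", "\\1", s)       # space before punctuation
    s <- trimws(s)
    ntok <- length(word_tokens(s))
    if (ntok >= config$min_content_tokens) kept <- c(kept, s)
  }
  paste(kept, collapse = " ")
}

escape_regex <- function(x) {
  gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", x, perl = TRUE)
}

word_tokens <- function(x) {
  regmatches(x, gregexpr("[[:alpha:]]+", x))[[1]]
}

#' Default abbreviation list for sentence segmentation
#' @return Lowercase abbreviations (without the final period) after which a
#'   period does not end a sentence.
#' @export
default_abbreviations <- function() {
  c("mr", "mrs", "ms", "dr", "prof", "st", "vs", "etc", "jr", "sr",
    "fig", "no", "al", "approx")
}

#' Segment a text into sentences
#'
#' Rule-based, deterministic splitter: a run of terminal punctuation
#' (`.`, `!`, `?`) followed by whitespace or end-of-text closes a sentence,
#' except after a known abbreviation or a single-letter initial. Sentences
#' keep their terminal punctuation; surrounding whitespace is trimmed.
#' Sentences serve as the proxy for story events throughout the package.
#'
#' @param text Character scalar.
#' @param abbreviations Lowercase abbreviation list (see
#'   [default_abbreviations()]).
#' @return Character vector of non-empty sentences in original order
#'   (length 0 for empty input).
#' @export
segment_sentences <- function(text, abbreviations = default_abbreviations()) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(character(0))
  text <- gsub("[\r\n]+", " ", text)
  m <- gregexpr("[.!?]+(?=\\s|$)", text, perl = TRUE)[[1]]
  cuts <- integer(0)
  if (m[1] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    starts <- as.integer(m)
    for (k in seq_along(starts)) {
      punct <- substr(text, starts[k], ends[k])
      if (!grepl("\\.", punct) || grepl("[!?]", punct)) {
        cuts <- c(cuts, ends[k])
        next
      }
      before <- substr(text, 1L, starts[k] - 1L)
      word <- tolower(sub("^.*?([[:alpha:]]+)$", "\\1", before))
      is_word <- grepl("[[:alpha:]]$", before)
      if (is_word && (word %in% abbreviations || nchar(word) == 1L)) next
      cuts <- c(cuts, ends[k])
    }
  }
  bounds <- unique(c(cuts, nchar(text)))
  from <- c(1L, head(bounds, -1L) + 1L)
  pieces <- trimws(substring(text, from, bounds))
  pieces[nzchar(pieces)]
}

#' Load a retelling manifest
#'
#' Reads a CSV manifest with columns `participant_id`, `condition`, `day`,
#' `path`, loads each story file, and groups stories into
#' [lineage()] objects by (participant, condition). Relative paths are
#' resolved against the manifest's directory. Stories come back unsegmented;
#' run [prepare_lineages()] before analysis.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return Named list of `retelling_lineage` objects
#'   (names `participant.condition`).
#' @export
load_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("manifest not found: %s", manifest_path))
  }
  df <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  required <- c("participant_id", "condition", "day", "path")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("manifest is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  key <- paste(df$participant_id, df$condition, df$day, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop(sprintf("duplicate (participant, condition, day) rows in manifest: %s",
                 paste(gsub("\r", "/", dups), collapse = "; ")))
  }
  base_dir <- dirname(manifest_path)
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  stories <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    p <- resolve(df$path[i])
    if (!file.exists(p)) stop(sprintf("story file not readable: %s", df$path[i]))
    txt <- paste(readLines(p, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
    stories[[i]] <- story(
      raw_text = txt,
      participant_id = df$participant_id[i],
      condition = df$condition[i],
      day = df$day[i]
    )
  }
  grp <- paste(df$participant_id, df$condition, sep = ".")
  out <- lapply(split(stories, grp), lineage)
  out[unique(grp)]
}

#' Clean and segment every story in a set of lineages
#'
#' Applies [clean_text()] then [segment_sentences()] to each story. Stories
#' whose cleaned text segments to zero sentences are kept but flagged with a
#' warning; analysis functions reject empty stories.
#'
#' @param lineages List of `retelling_lineage` objects (e.g. from
#'   [load_manifest()]).
#' @param config A [cleaning_config()].
#' @return The lineages with `sentences` populated.
#' @export
prepare_lineages <- function(lineages, config = cleaning_config()) {
  lapply(lineages, function(ln) {
    ln$stories <- lapply(ln$stories, function(s) {
      cleaned <- clean_text(s$raw_text, config)
      sents <- segment_sentences(cleaned)
      if (!length(sents)) {
        warning(sprintf("story %s is empty after cleaning", s$story_id))
        s$sentences <- character(0)
      } else {
        s$sentences <- sents
      }
      s
    })
    ln
  })
}

#' Write a square score matrix as CSV
#'
#' Writes ids as header row and first column, with full (17 significant
#' digit) precision so that [read_similarity_matrix()] round-trips the values
#' bit-exactly.
#'
#' @param m Square numeric matrix.
#' @param path Output file path.
#' @param ids Row/column identifiers (default from `rownames`).
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(m, path, ids = rownames(m)) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("matrix must be square, got %dx%d", nrow(m), ncol(m)))
  }
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(m)))
  if (length(ids) != nrow(m)) stop("ids length must match matrix dimension")
  header <- paste(c("id", ids), collapse = ",")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(ids[i], sprintf("%.17g", m[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a score matrix written by [write_similarity_matrix()]
#' @param path File path.
#' @return Numeric matrix with ids as dimnames.
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  colnames(m) <- rownames(m)
  m
}
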