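# The core story-similarity measure: content similarity via per-sentence
# within-story thresholds (Remembered/Forgotten classification), sequence
# similarity via Spearman correlation of best-match event order, and their
# multiplicative combination.

#' Within-story similarity thresholds
#'
#' For each sentence i of a story, the threshold is the highest similarity
#' between sentence i and any *other* sentence of the same story: the most
#' similar sentence i can be to a sentence describing a different occurrence.
#' A best cross-story match must strictly exceed this value to count as the
#' same event. Single-sentence stories get threshold 0. The `"global"` mode
#' applies the maximum of the per-sentence thresholds to every sentence (a
#' sensitivity-analysis variant).
#'
#' @param sentences Non-empty character vector of sentences.
#' @param backend A `similarity_backend`.
#' @param mode `"per_sentence"` (default) or `"global"`.
#' @return Numeric vector of thresholds, one per sentence.
#' @export
within_story_thresholds <- function(sentences, backend,
                                    mode = c("per_sentence", "global")) {
  mode <- match.arg(mode)
  if (!length(sentences)) stop("within_story_thresholds needs >= 1 sentence")
  rep_ <- backend$prepare(as.list(sentences))
  thresholds_prepared(backend, rep_, mode)
}

thresholds_prepared <- function(backend, rep_, mode = "per_sentence") {
  n <- length(rep_)
  if (n == 1L) return(0)
  th <- numeric(n)
  for (i in seq_len(n)) {
    best <- -Inf
    for (j in seq_len(n)) {
      if (j == i) next
      s <- backend$sim_prepared(rep_[[i]], rep_[[j]])
      if (s > best) best <- s
    }
    th[i] <- best
  }
  if (mode == "global") th <- rep(max(th), n)
  th
}

# One direction ref -> target on prepared representations. Returns best-match
# indices (ties -> lowest target index), best similarities, and Remembered
# flags (best strictly above the reference sentence's threshold).
match_prepared <- function(backend, rep_ref, rep_tgt, thresholds) {
  n <- length(rep_ref)
  best_index <- integer(n)
  best_sim <- numeric(n)
  for (i in seq_len(n)) {
    bi <- 1L
    bs <- backend$sim_prepared(rep_ref[[i]], rep_tgt[[1]])
    for (j in seq_along(rep_tgt)[-1]) {
      s <- backend$sim_prepared(rep_ref[[i]], rep_tgt[[j]])
      if (s > bs) {
        bs <- s
        bi <- j
      }
    }
    best_index[i] <- bi
    best_sim[i] <- bs
  }
  list(
    best_index = best_index,
    best_sim = best_sim,
    remembered = best_sim > thresholds
  )
}

story_sentences <- function(x, what = "story") {
  if (inherits(x, "story")) {
    s <- x$sentences
    if (is.null(s)) stop(sprintf("%s is not segmented", what))
  } else {
    s <- as.character(x)
  }
  if (!length(s)) stop(sprintf("%s has no sentences", what))
  s
}

#' Match events of a reference story in a target story
#'
#' For every reference sentence, finds the most similar target sentence
#' (ties broken by lowest target index) and classifies the event as
#' *Remembered* when that best similarity strictly exceeds the reference
#' sentence's within-story threshold, else *Forgotten*. A target sentence may
#' be the best match of several reference sentences.
#'
#' @param ref,target [story()] objects (segmented) or character vectors of
#'   sentences.
#' @param backend A `similarity_backend`.
#' @param threshold_mode See [within_story_thresholds()].
#' @return A list of class `match_result` with `direction`, `thresholds`,
#'   `best_index`, `best_sim`, `remembered`.
#' @export
match_events <- function(ref, target, backend,
                         threshold_mode = c("per_sentence", "global")) {
  threshold_mode <- match.arg(threshold_mode)
  sr <- story_sentences(ref, "reference story")
  st <- story_sentences(target, "target story")
  rr <- backend$prepare(as.list(sr))
  rt <- backend$prepare(as.list(st))
  th <- thresholds_prepared(backend, rr, threshold_mode)
  m <- match_prepared(backend, rr, rt, th)
  structure(
    list(
      direction = c(
        if (inherits(ref, "story")) ref$story_id else "ref",
        if (inherits(target, "story")) target$story_id else "target"
      ),
      thresholds = th,
      best_index = m$best_index,
      best_sim = m$best_sim,
      remembered = m$remembered
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result %s -> %s> %d/%d events remembered\n",
    x$direction[1], x$direction[2], sum(x$remembered), length(x$remembered)
  ))
  invisible(x)
}

spearman_safe <- function(pos, matched) {
  if (length(pos) < 2L) return(0)
  if (length(unique(matched)) < 2L || length(unique(pos)) < 2L) return(0)
  rx <- rank(pos)
  ry <- rank(matched)
  # exact rank (anti-)concordance: return the bound exactly rather than the
  # 1-ulp value floating arithmetic can produce
  if (identical(rx, ry)) return(1)
  if (identical(rx, max(ry) + min(ry) - ry)) return(-1)
  stats::cor(pos, matched, method = "spearman")
}

# Both directions of content + sequence from prepared representations;
# the workhorse behind story_similarity() and all_pairs_matrix().
pair_components <- function(backend, ra, rb, tha, thb) {
  mab <- match_prepared(backend, ra, rb, tha)
  mba <- match_prepared(backend, rb, ra, thb)
  content_ab <- mean(mab$remembered)
  content_ba <- mean(mba$remembered)
  sequence_ab <- spearman_safe(seq_along(ra), mab$best_index)
  sequence_ba <- spearman_safe(seq_along(rb), mba$best_index)
  content <- (content_ab + content_ba) / 2
  sequence <- (sequence_ab + sequence_ba) / 2
  list(
    content_ab = content_ab, content_ba = content_ba, content = content,
    sequence_ab = sequence_ab, sequence_ba = sequence_ba, sequence = sequence,
    combined = content * sequence
  )
}

#' Content similarity between two stories
#'
#' Directional content similarity is the number of reference events
#' classified Remembered in the other story divided by the number of
#' reference events; the final measure averages both directions so that A is
#' exactly as similar to B as B is to A.
#'
#' @inheritParams match_events
#' @param a,b Segmented [story()] objects or sentence vectors.
#' @return List with `content_ab`, `content_ba`, `content` (all in \[0, 1\]).
#' @export
content_similarity <- function(a, b, backend,
                               threshold_mode = c("per_sentence", "global")) {
  threshold_mode <- match.arg(threshold_mode)
  res <- story_similarity(a, b, backend, threshold_mode)
  res[c("content_ab", "content_ba", "content")]
}

#' Sequence similarity between two stories
#'
#' Each reference sentence is mapped to its most similar sentence in the
#' other story (no threshold: the best available match is always used; ties
#' go to the lowest index). The directional score is the Spearman rank-order
#' correlation (average ranks on ties) between reference positions and
#' matched positions; single-sentence stories and constant match vectors
#' score 0. The final measure averages the two directions.
#'
#' @inheritParams content_similarity
#' @return List with `sequence_ab`, `sequence_ba`, `sequence`
#'   (all in \[-1, 1\]).
#' @export
sequence_similarity <- function(a, b, backend,
                                threshold_mode = c("per_sentence", "global")) {
  threshold_mode <- match.arg(threshold_mode)
  res <- story_similarity(a, b, backend, threshold_mode)
  res[c("sequence_ab", "sequence_ba", "sequence")]
}

#' Combined story similarity
#'
#' The overall structural similarity of two stories: symmetrized content
#' similarity multiplied by symmetrized sequence similarity. Ranges from -1
#' to 1; higher values mean the two texts retain more events in common *and*
#' in a more similar order.
#'
#' @inheritParams content_similarity
#' @return An object of class `story_similarity` with fields `content_ab`,
#'   `content_ba`, `content`, `sequence_ab`, `sequence_ba`, `sequence`,
#'   `combined`.
#' @export
story_similarity <- function(a, b, backend,
                             threshold_mode = c("per_sentence", "global")) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(inherits(backend, "similarity_backend"))
  sa <- story_sentences(a, "story a")
  sb <- story_sentences(b, "story b")
  ra <- backend$prepare(as.list(sa))
  rb <- backend$prepare(as.list(sb))
  tha <- thresholds_prepared(backend, ra, threshold_mode)
  thb <- thresholds_prepared(backend, rb, threshold_mode)
  comp <- pair_components(backend, ra, rb, tha, thb)
  structure(
    c(
      list(story_a = if (inherits(a, "story")) a$story_id else "a",
           story_b = if (inherits(b, "story")) b$story_id else "b"),
      comp
    ),
    class = "story_similarity"
  )
}

#' @export
print.story_similarity <- function(x, ...) {
  cat(sprintf(
    "<story_similarity %s vs %s>\n  content  %.4f  (a->b %.4f, b->a %.4f)\n  sequence %.4f  (a->b %.4f, b->a %.4f)\n  combined %.4f\n",
    x$story_a, x$story_b, x$content, x$content_ab, x$content_ba,
    x$sequence, x$sequence_ab, x$sequence_ba, x$combined
  ))
  invisible(x)
}
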