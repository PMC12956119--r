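# Evolution of story similarity over a retelling lineage: stabilization
# (adjacent days), consistency (similarity to the final retelling),
# modification (similarity to the stimulus), cross-reference comparisons,
# group curves, and permutation contrasts between conditions.

day_label <- function(day) ifelse(day == 0L, "Initial", paste0("Day", day))

series_tibble <- function(lin, metric, labels, values) {
  tibble::tibble(
    participant_id = lin$participant_id,
    condition = lin$condition,
    metric = metric,
    label = labels,
    value = values
  )
}

lineage_pair_value <- function(a, b, backend, threshold_mode) {
  story_similarity(a, b, backend, threshold_mode)$combined
}

check_lineage <- function(lin, min_stories = 2L) {
  if (!inherits(lin, "retelling_lineage")) stop("expected a retelling_lineage")
  if (length(lin$stories) < min_stories) {
    stop(sprintf("lineage %s/%s needs >= %d stories",
                 lin$participant_id, lin$condition, min_stories))
  }
  lin
}

#' Stabilization: similarity between subsequent retellings
#'
#' Combined story similarity of every adjacent day pair in a lineage,
#' starting with (Initial, Day 1) when the day-0 stimulus is present. Rising
#' values over days mean the story is settling into a stable form.
#'
#' @param lin A `retelling_lineage` with at least 2 stories.
#' @param backend A `similarity_backend`.
#' @param threshold_mode See [within_story_thresholds()].
#' @return A tibble (participant_id, condition, metric, label, value), one
#'   row per adjacent day pair.
#' @export
stabilization_series <- function(lin, backend,
                                 threshold_mode = c("per_sentence", "global")) {
  threshold_mode <- match.arg(threshold_mode)
  check_lineage(lin)
  n <- length(lin$stories)
  days <- vapply(lin$stories, function(s) s$day, integer(1))
  vals <- vapply(seq_len(n - 1L), function(t) {
    lineage_pair_value(lin$stories[[t]], lin$stories[[t + 1L]], backend,
                       threshold_mode)
  }, numeric(1))
  labs <- paste(day_label(days[-n]), day_label(days[-1L]), sep = "-")
  series_tibble(lin, "stabilization", labs, vals)
}

#' Consistency: similarity to the final retelling
#'
#' Combined similarity of every earlier story (including the day-0 stimulus)
#' to the last-day retelling; the final retelling's trivial self-comparison
#' is excluded. Rising values mean the story evolved in a consistent
#' direction toward its final form.
#'
#' @inheritParams stabilization_series
#' @return A tibble with one row per earlier story.
#' @export
consistency_series <- function(lin, backend,
                               threshold_mode = c("per_sentence", "global")) {
  threshold_mode <- match.arg(threshold_mode)
  check_lineage(lin)
  n <- length(lin$stories)
  days <- vapply(lin$stories, function(s) s$day, integer(1))
  last <- lin$stories[[n]]
  vals <- vapply(seq_len(n - 1L), function(t) {
    lineage_pair_value(lin$stories[[t]], last, backend, threshold_mode)
  }, numeric(1))
  labs <- paste(day_label(days[-n]), day_label(days[n]), sep = "-")
  series_tibble(lin, "consistency", labs, vals)
}

#' Modification: similarity to the initial story
#'
#' Combined similarity of the day-0 stimulus to each retelling (days 1..T).
#' Lower values mean the initial story was modified more in memory.
#'
#' @inheritParams stabilization_series
#' @return A tibble with one row per retelling.
#' @export
modification_series <- function(lin, backend,
                                threshold_mode = c("per_sentence", "global")) {
  threshold_mode <- match.arg(threshold_mode)
  check_lineage(lin)
  days <- vapply(lin$stories, function(s) s$day, integer(1))
  if (days[1] != 0L) {
    stop(sprintf("lineage %s/%s has no day-0 initial story",
                 lin$participant_id, lin$condition))
  }
  init <- lin$stories[[1]]
  rest <- lin$stories[-1]
  vals <- vapply(rest, function(s) {
    lineage_pair_value(init, s, backend, threshold_mode)
  }, numeric(1))
  labs <- paste("Initial", day_label(days[-1]), sep = "-")
  series_tibble(lin, "modification", labs, vals)
}

#' Similarity of retellings to an arbitrary reference story
#'
#' Combined similarity of each retelling (days >= 1) to a reference story,
#' e.g. the *other* condition's stimulus, to ask which structure the
#' retellings gravitate toward. With the lineage's own day-0 story as
#' reference this reproduces [modification_series()] values exactly.
#'
#' @inheritParams stabilization_series
#' @param reference A segmented [story()] (non-empty).
#' @param ref_label Label prefix used in the comparison labels.
#' @return A tibble with one row per retelling.
#' @export
cross_reference_series <- function(lin, reference, backend,
                                   threshold_mode = c("per_sentence", "global"),
                                   ref_label = "Ref") {
  threshold_mode <- match.arg(threshold_mode)
  check_lineage(lin, min_stories = 1L)
  story_sentences(reference, "reference story")
  days <- vapply(lin$stories, function(s) s$day, integer(1))
  keep <- days >= 1L
  if (!any(keep)) stop("lineage has no retellings (days >= 1)")
  vals <- vapply(lin$stories[keep], function(s) {
    lineage_pair_value(reference, s, backend, threshold_mode)
  }, numeric(1))
  labs <- paste(ref_label, day_label(days[keep]), sep = "-")
  series_tibble(lin, "cross_reference", labs, vals)
}

#' Evolution series for a whole corpus
#'
#' Convenience wrapper applying one or more evolution metrics to every
#' lineage and binding the results into one long-format table.
#'
#' @param lineages List of `retelling_lineage` objects.
#' @param backend A `similarity_backend`.
#' @param metrics Subset of `c("stabilization", "consistency",
#'   "modification")`.
#' @param threshold_mode See [within_story_thresholds()].
#' @return A long tibble (participant_id, condition, metric, label, value).
#' @export
evolution_series <- function(lineages, backend,
                             metrics = c("stabilization", "consistency",
                                         "modification"),
                             threshold_mode = c("per_sentence", "global")) {
  threshold_mode <- match.arg(threshold_mode)
  metrics <- match.arg(metrics, several.ok = TRUE)
  fns <- list(
    stabilization = stabilization_series,
    consistency = consistency_series,
    modification = modification_series
  )
  out <- lapply(lineages, function(lin) {
    dplyr::bind_rows(lapply(metrics, function(m) {
      fns[[m]](lin, backend, threshold_mode)
    }))
  })
  dplyr::bind_rows(out)
}

#' Per-condition group curves
#'
#' Mean and standard error of the series values across participants, per
#' condition, metric, and comparison label. With a single participant the SE
#' is reported as 0 and `n = 1` flags the degenerate group.
#'
#' @param series Long tibble as produced by [evolution_series()] (or any of
#'   the `*_series()` functions row-bound across participants).
#' @return Tibble (condition, metric, label, n, mean, se), labels in first-
#'   appearance order.
#' @export
group_curves <- function(series) {
  if (!nrow(series)) stop("empty series collection")
  key <- paste(series$metric, series$label, sep = "\r")
  key_order <- unique(key)  # first-appearance order, per metric
  out <- dplyr::summarise(
    dplyr::group_by(series, .data$condition, .data$metric, .data$label),
    n = dplyr::n(),
    mean = mean(.data$value),
    se = if (dplyr::n() > 1L) stats::sd(.data$value) / sqrt(dplyr::n()) else 0,
    .groups = "drop"
  )
  out$.ord <- match(paste(out$metric, out$label, sep = "\r"), key_order)
  out <- dplyr::arrange(out, .data$condition, .data$.ord)
  out$.ord <- NULL
  out
}

#' Permutation contrast between two conditions at one comparison label
#'
#' Nonparametric test of the between-condition difference in mean series
#' value at one label: participant condition labels are shuffled `n_perm`
#' times and the two-sided add-one p-value
#' `(count(|perm| >= |observed|) + 1) / (n_perm + 1)` is reported.
#' Deterministic given `seed`.
#'
#' @param series Long tibble of per-participant values (one metric).
#' @param label The comparison label to test (e.g. `"Initial-Day1"`).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `observed` (condition-1 mean minus condition-2 mean,
#'   conditions in sorted order), `p_value`, `conditions`, `n_perm`, `seed`.
#' @export
condition_permutation_test <- function(series, label, n_perm = 1000L,
                                       seed = 1L) {
  d <- series[series$label == label, , drop = FALSE]
  if (!nrow(d)) stop(sprintf("no series values at label '%s'", label))
  if (length(unique(d$metric)) > 1L) {
    stop("series mixes metrics; filter to one metric first")
  }
  conds <- sort(unique(d$condition))
  if (length(conds) != 2L) stop("need exactly 2 conditions")
  counts <- table(d$condition)
  if (any(counts < 2L)) stop("each condition needs >= 2 participants")
  g <- d$condition
  v <- d$value
  delta <- function(lab) mean(v[lab == conds[1]]) - mean(v[lab == conds[2]])
  obs <- delta(g)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(k) delta(sample(g)), numeric(1))
  })
  p <- (sum(abs(perm) >= abs(obs)) + 1) / (n_perm + 1)
  list(observed = obs, p_value = p, conditions = conds,
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}
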