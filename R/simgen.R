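# Synthetic serial-reproduction corpus generator: a stimulus of n_events
# single-action sentences and chained daily retellings with event forgetting,
# adjacent-transposition reordering (optionally biased toward a shared
# attractor order, modeling schema convergence), token paraphrase, and
# intrusions. Event vocabularies are pairwise disjoint and purely alphabetic,
# so under the lexical backend cross-event similarities are exactly 0 and
# closed-form properties of the similarity measure hold exactly.

# bijective base-16 over letters a..p; "q", "z", "w" never appear, so they
# are safe as separator / synonym prefix / intrusion prefix
int_to_alpha <- function(i) {
  stopifnot(i >= 1)
  i <- i - 1L
  s <- character(0)
  repeat {
    s <- c(letters[(i %% 16L) + 1L], s)
    i <- i %/% 16L
    if (i == 0L) break
    i <- i - 1L
  }
  paste(s, collapse = "")
}

event_token <- function(event, slot) {
  paste0(int_to_alpha(event), "q", int_to_alpha(slot))
}

#' Generator configuration
#'
#' Parameters of the synthetic retelling process. The noise schedule is a
#' per-day multiplier applied to `p_forget` and `n_transpositions`
#' (default halving each day, so day 1 carries full noise and later days
#' less — the qualitative stabilization pattern of repeated reproduction).
#'
#' @param n_events Number of single-action sentences in the stimulus (>= 2).
#' @param tokens_per_event Content tokens per sentence (>= 2).
#' @param p_forget Per-event drop probability per retelling, in \[0, 1).
#' @param n_transpositions Adjacent-swap count per retelling (before the
#'   schedule multiplier).
#' @param p_paraphrase Per-token synonym substitution probability.
#' @param p_intrude Probability of inserting one intrusion sentence per
#'   retelling (drawn from a vocabulary disjoint from all event
#'   vocabularies).
#' @param convergence Probability that a transposition is attractor-biased
#'   (one sorting step toward the condition's attractor order) rather than a
#'   random adjacent swap; models convergence toward a shared schema.
#' @param noise_schedule Numeric vector of per-day multipliers (length
#'   `n_days`); default `0.5^(0:(n_days-1))`.
#' @param n_days Number of retellings per participant (>= 1).
#' @param attractor `"identity"` (the attractor is the stimulus event order)
#'   or `"random"` (one random permutation drawn per condition).
#' @param scramble_stimulus Present each participant a randomly shuffled
#'   stimulus (the incoherent-condition manipulation) while the attractor
#'   stays defined on the unscrambled order.
#' @param from_stimulus Generate every retelling from the day-0 stimulus
#'   instead of chaining from the previous day.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_events = 25L, tokens_per_event = 3L,
                             p_forget = 0.15, n_transpositions = 2L,
                             p_paraphrase = 0, p_intrude = 0,
                             convergence = 0, noise_schedule = NULL,
                             n_days = 5L, attractor = c("identity", "random"),
                             scramble_stimulus = FALSE,
                             from_stimulus = FALSE) {
  attractor <- match.arg(attractor)
  n_events <- as.integer(n_events)
  tokens_per_event <- as.integer(tokens_per_event)
  n_days <- as.integer(n_days)
  n_transpositions <- as.integer(n_transpositions)
  if (n_events < 2L) stop("n_events must be >= 2")
  if (tokens_per_event < 2L) stop("tokens_per_event must be >= 2")
  if (n_days < 1L) stop("n_days must be >= 1")
  if (n_transpositions < 0L) stop("n_transpositions must be >= 0")
  probs <- c(p_forget = p_forget, p_paraphrase = p_paraphrase,
             p_intrude = p_intrude, convergence = convergence)
  if (any(probs < 0) || any(probs > 1) || p_forget >= 1) {
    stop("probabilities must lie in [0, 1] (p_forget in [0, 1))")
  }
  if (is.null(noise_schedule)) noise_schedule <- 0.5^(seq_len(n_days) - 1L)
  noise_schedule <- as.numeric(noise_schedule)
  if (length(noise_schedule) != n_days || any(noise_schedule < 0)) {
    stop("noise_schedule must be n_days non-negative multipliers")
  }
  structure(
    list(
      n_events = n_events, tokens_per_event = tokens_per_event,
      p_forget = p_forget, n_transpositions = n_transpositions,
      p_paraphrase = p_paraphrase, p_intrude = p_intrude,
      convergence = convergence, noise_schedule = noise_schedule,
      n_days = n_days, attractor = attractor,
      scramble_stimulus = scramble_stimulus, from_stimulus = from_stimulus
    ),
    class = "generator_config"
  )
}

#' Read a generator configuration from YAML or JSON
#' @param path Config file (schema identical in both formats: top-level keys
#'   as in [generator_config()]).
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  vals <- vals[names(vals) %in% names(formals(generator_config))]
  do.call(generator_config, vals)
}

seeded <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' Generate a base (stimulus) story
#'
#' `n_events` sentences, each built from `tokens_per_event` unique content
#' tokens drawn from that event's private vocabulary. Vocabularies are
#' pairwise disjoint, so under [lexical_backend()] all cross-sentence
#' similarities (and hence all within-story thresholds) are exactly 0.
#' Deterministic given `seed`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param condition,story_id Metadata for the resulting [story()].
#' @return A segmented [story()] with `day = 0`.
#' @export
generate_base_story <- function(config, seed = NULL, condition = NA_character_,
                                story_id = NULL) {
  stopifnot(inherits(config, "generator_config"))
  seeded(seed, {
    sents <- vapply(seq_len(config$n_events), function(e) {
      slots <- sample.int(4096L, config$tokens_per_event)
      paste0(paste(vapply(slots, function(s) event_token(e, s), character(1)),
                   collapse = " "), ".")
    }, character(1))
    story(
      sentences = sents, story_id = story_id, condition = condition,
      day = 0L, event_ids = seq_len(config$n_events)
    )
  })
}

#' Randomly shuffle the sentences of a story
#'
#' Uniform random permutation of the sentence order (for stories with more
#' than one sentence the identity permutation is redrawn), preserving the
#' sentence multiset — the incoherent-stimulus manipulation.
#'
#' @param s A segmented [story()].
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return The story with permuted sentences (and `event_ids`).
#' @export
scramble_story <- function(s, seed = NULL) {
  sents <- story_sentences(s)
  n <- length(sents)
  seeded(seed, {
    perm <- sample.int(n)
    while (n > 1L && all(perm == seq_len(n))) perm <- sample.int(n)
    s$sentences <- sents[perm]
    if (!is.null(s$event_ids)) s$event_ids <- s$event_ids[perm]
    s$raw_text <- paste(s$sentences, collapse = " ")
    s$story_id <- paste0(s$story_id, "_scrambled")
    s
  })
}

# one attractor-biased sorting step: swap a random adjacent pair that is
# inverted relative to the attractor ranks; no-op when already sorted
biased_swap <- function(ids, order_idx, ranks) {
  r <- ranks[as.character(ids)]
  inv <- which(!is.na(r[-length(r)]) & !is.na(r[-1]) &
                 r[-length(r)] > r[-1])
  if (!length(inv)) return(order_idx)
  k <- if (length(inv) == 1L) inv else sample(inv, 1L)
  order_idx[c(k, k + 1L)] <- order_idx[c(k + 1L, k)]
  order_idx
}

#' Generate one retelling of a source story
#'
#' The forward model of recall distortion, applied in order: (1) each event
#' dropped with the day-scaled forget probability (redrawn if all would
#' drop), (2) day-scaled adjacent transpositions, each attractor-biased with
#' probability `convergence` (one sorting step toward the attractor order)
#' or a random adjacent swap otherwise, (3) per-token paraphrase into a
#' disjoint synonym vocabulary, (4) with probability `p_intrude` one
#' intrusion sentence from a distractor vocabulary inserted at a random
#' position. Deterministic given `seed`.
#'
#' @param source A segmented [story()] (typically the previous day's
#'   retelling).
#' @param config A [generator_config()].
#' @param day Day index of the retelling (>= 1; selects the noise-schedule
#'   multiplier).
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param attractor Named rank vector over event ids (names = event id,
#'   value = target position); `NULL` means ranks follow the event ids
#'   (identity attractor).
#' @param participant_id,condition Metadata for the resulting [story()].
#' @return A segmented [story()] at `day`.
#' @export
generate_retelling <- function(source, config, day, seed = NULL,
                               attractor = NULL,
                               participant_id = source$participant_id,
                               condition = source$condition) {
  stopifnot(inherits(config, "generator_config"))
  sents <- story_sentences(source, "source story")
  day <- as.integer(day)
  if (day < 1L) stop("day must be >= 1")
  mult <- config$noise_schedule[min(day, length(config$noise_schedule))]
  ids <- if (!is.null(source$event_ids)) source$event_ids else
    rep(NA_integer_, length(sents))
  if (is.null(attractor)) {
    known <- ids[!is.na(ids)]
    attractor <- stats::setNames(seq_along(sort(unique(known))),
                                 sort(unique(known)))
  }
  seeded(seed, {
    n <- length(sents)
    p_eff <- min(config$p_forget * mult, 0.999)
    repeat {
      keep <- stats::runif(n) >= p_eff
      if (any(keep)) break
    }
    sents <- sents[keep]
    ids <- ids[keep]
    n <- length(sents)
    # transpositions (stochastic rounding of the scaled count)
    n_eff <- config$n_transpositions * mult
    n_swaps <- floor(n_eff) + stats::rbinom(1L, 1L, n_eff - floor(n_eff))
    if (n > 1L && n_swaps > 0L) {
      idx <- seq_len(n)
      for (k in seq_len(n_swaps)) {
        if (stats::runif(1) < config$convergence) {
          idx <- biased_swap(ids[idx], idx, attractor)
        } else {
          pos <- sample.int(n - 1L, 1L)
          idx[c(pos, pos + 1L)] <- idx[c(pos + 1L, pos)]
        }
      }
      sents <- sents[idx]
      ids <- ids[idx]
    }
    # paraphrase: substitute tokens into the disjoint synonym vocabulary
    if (config$p_paraphrase > 0) {
      sents <- vapply(sents, function(s) {
        toks <- tokenize(s)
        sub_ <- stats::runif(length(toks)) < config$p_paraphrase
        toks[sub_] <- paste0("z", toks[sub_])
        paste0(paste(toks, collapse = " "), ".")
      }, character(1), USE.NAMES = FALSE)
    }
    # intrusion: one novel sentence from the distractor vocabulary
    if (stats::runif(1) < config$p_intrude) {
      slots <- sample.int(4096L, config$tokens_per_event)
      intruder <- paste0(paste(
        paste0("w", vapply(slots, int_to_alpha, character(1))),
        collapse = " "), ".")
      at <- sample.int(length(sents) + 1L, 1L)
      sents <- append(sents, intruder, after = at - 1L)
      ids <- append(ids, NA_integer_, after = at - 1L)
    }
    story(
      sentences = sents,
      participant_id = participant_id,
      condition = condition,
      day = day,
      event_ids = ids
    )
  })
}

#' Generate a synthetic serial-reproduction corpus
#'
#' Emulates the study design: per condition, a shared stimulus (the same
#' base story across conditions, scrambled for conditions with
#' `scramble_stimulus = TRUE`) and, per participant, `n_days` chained
#' retellings (day t generated from day t-1, or from the stimulus when
#' `from_stimulus = TRUE`). Fully reproducible from `seed`; optionally
#' writes story files, a manifest CSV consumable by [load_manifest()], and
#' the resolved configuration JSON.
#'
#' @param config Baseline [generator_config()].
#' @param n_participants Participants per condition (>= 1).
#' @param conditions Named list of per-condition overrides of `config`
#'   fields (e.g. `list(coherent = list(), incoherent =
#'   list(scramble_stimulus = TRUE))`).
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param dir Optional output directory for story files + `manifest.csv` +
#'   `config.json`.
#' @return Named list of `retelling_lineage` objects (one per participant x
#'   condition), with the per-condition stimuli in attribute `"stimuli"` and
#'   the manifest tibble in attribute `"manifest"` when `dir` is given.
#' @export
generate_corpus <- function(config, n_participants,
                            conditions = list(control = list()),
                            seed = NULL, dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  n_participants <- as.integer(n_participants)
  if (n_participants < 1L) stop("n_participants must be >= 1")
  if (is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    stop("conditions must be a named list")
  }
  out <- seeded(seed, {
    base <- generate_base_story(config)
    lineages <- list()
    stimuli <- list()
    for (cond in names(conditions)) {
      override <- conditions[[cond]]
      cfg <- utils::modifyList(unclass(config), override)
      if ("n_days" %in% names(override) && !"noise_schedule" %in% names(override)) {
        cfg$noise_schedule <- NULL  # let the default rescale to the new n_days
      }
      cfg <- do.call(generator_config, cfg[names(cfg) %in%
                                             names(formals(generator_config))])
      stim <- base
      stim$condition <- cond
      stim$story_id <- paste0("stim_", cond)
      if (cfg$scramble_stimulus) stim <- scramble_story(stim)
      att_ids <- sort(unique(stats::na.omit(base$event_ids)))
      att <- if (cfg$attractor == "random") {
        stats::setNames(sample(seq_along(att_ids)), att_ids)
      } else {
        stats::setNames(seq_along(att_ids), att_ids)
      }
      stimuli[[cond]] <- stim
      for (p in seq_len(n_participants)) {
        pid <- sprintf("P%02d", p)
        day0 <- stim
        day0$participant_id <- pid
        day0$story_id <- sprintf("%s_%s_d0", pid, cond)
        stories <- list(day0)
        prev <- day0
        for (d in seq_len(cfg$n_days)) {
          src <- if (cfg$from_stimulus) day0 else prev
          ret <- generate_retelling(src, cfg, day = d, attractor = att)
          ret$story_id <- sprintf("%s_%s_d%d", pid, cond, d)
          stories <- c(stories, list(ret))
          prev <- ret
        }
        lineages[[paste(pid, cond, sep = ".")]] <- lineage(stories)
      }
    }
    list(lineages = lineages, stimuli = stimuli)
  })
  lineages <- out$lineages
  attr(lineages, "stimuli") <- out$stimuli
  if (!is.null(dir)) {
    attr(lineages, "manifest") <- write_corpus(lineages, dir, config, seed)
  }
  lineages
}

write_corpus <- function(lineages, dir, config, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (ln in lineages) {
    for (s in ln$stories) {
      fname <- paste0(s$story_id, ".txt")
      writeLines(s$raw_text, file.path(dir, fname))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = s$participant_id,
        condition = s$condition,
        day = s$day,
        path = fname
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    c(unclass(config), list(seed = if (is.null(seed)) NA else seed)),
    file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  manifest
}
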