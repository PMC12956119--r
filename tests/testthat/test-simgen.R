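lex <- lexical_backend()

test_that("base stories have disjoint event vocabularies and are seed-deterministic", {
  cfg <- generator_config(n_events = 8, tokens_per_event = 3, n_days = 1)
  s1 <- generate_base_story(cfg, seed = 61)
  expect_length(s1$sentences, 8)
  expect_equal(within_story_thresholds(s1$sentences, lex), rep(0, 8))
  expect_identical(generate_base_story(cfg, seed = 61)$sentences, s1$sentences)
  expect_false(identical(generate_base_story(cfg, seed = 62)$sentences,
                         s1$sentences))
  big <- generate_base_story(generator_config(n_events = 25, n_days = 1),
                             seed = 63)
  sim <- story_similarity(big, big, lex)
  expect_identical(c(sim$content, sim$sequence, sim$combined), c(1, 1, 1))
  expect_error(generator_config(n_events = 1), ">= 2")
})

test_that("scrambling permutes the sentence multiset and breaks order only", {
  cfg <- generator_config(n_events = 10, tokens_per_event = 3, n_days = 1)
  base <- generate_base_story(cfg, seed = 64)
  sc <- scramble_story(base, seed = 65)
  expect_equal(sort(sc$sentences), sort(base$sentences))
  expect_false(identical(sc$sentences, base$sentences))
  ss <- story_similarity(base, sc, lex)
  expect_equal(ss$content, 1)
  expect_lt(abs(ss$sequence), 1)
  # mean sequence similarity of a uniform permutation is ~0
  seqs <- withr::with_seed(66, {
    vapply(1:300, function(k) {
      story_similarity(base, scramble_story(base), lex)$sequence
    }, numeric(1))
  })
  expect_lt(abs(mean(seqs)), 0.05)
})

test_that("retellings are the identity under zero noise and exact under pure deletion", {
  quiet <- generator_config(n_events = 8, tokens_per_event = 3, n_days = 2,
                            p_forget = 0, n_transpositions = 0,
                            noise_schedule = c(1, 1))
  base <- generate_base_story(quiet, seed = 67)
  ret <- generate_retelling(base, quiet, day = 1, seed = 68)
  expect_identical(ret$sentences, base$sentences)
  expect_equal(story_similarity(base, ret, lex)$combined, 1)

  drop_only <- generator_config(n_events = 8, tokens_per_event = 3, n_days = 1,
                                p_forget = 0.4, n_transpositions = 0,
                                noise_schedule = 1)
  withr::with_seed(69, {
    for (k in 1:25) {
      r <- generate_retelling(base, drop_only, day = 1)
      d <- 8 - length(r$sentences)
      expect_identical(story_similarity(base, r, lex)$content, 1 - d / 16)
    }
  })

  # enough adjacent swaps to mix the order (~n^2 log n): sequence ~ 0 on average
  swap_only <- generator_config(n_events = 8, tokens_per_event = 3, n_days = 1,
                                p_forget = 0, n_transpositions = 200,
                                noise_schedule = 1)
  withr::with_seed(70, {
    vals <- vapply(1:50, function(k) {
      r <- generate_retelling(base, swap_only, day = 1)
      s <- story_similarity(base, r, lex)
      expect_equal(s$content, 1)
      s$sequence
    }, numeric(1))
    expect_lt(abs(mean(vals)), 0.15)
  })
})

test_that("attractor-biased transpositions sort retellings toward the attractor order", {
  cfg <- generator_config(n_events = 6, tokens_per_event = 2, n_days = 1,
                          p_forget = 0, n_transpositions = 30,
                          convergence = 1, noise_schedule = 1)
  base <- generate_base_story(cfg, seed = 71)
  scrambled <- scramble_story(base, seed = 72)
  # identity attractor: enough biased steps fully restore the base order
  ret <- generate_retelling(scrambled, cfg, day = 1, seed = 73)
  expect_identical(ret$event_ids, 1:6)
  expect_equal(story_similarity(base, ret, lex)$combined, 1)
})

test_that("intrusions come from a disjoint vocabulary and are never Remembered", {
  cfg <- generator_config(n_events = 6, tokens_per_event = 3, n_days = 1,
                          p_forget = 0, n_transpositions = 0, p_intrude = 1,
                          noise_schedule = 1)
  base <- generate_base_story(cfg, seed = 74)
  ret <- generate_retelling(base, cfg, day = 1, seed = 75)
  expect_length(ret$sentences, 7)
  intruder <- ret$sentences[is.na(ret$event_ids)]
  m <- match_events(ret, base, lex)
  expect_false(m$remembered[is.na(ret$event_ids)])
  expect_equal(vapply(base$sentences, lexical_similarity, numeric(1), intruder),
               rep(0, 6), ignore_attr = TRUE)
})

test_that("corpus generation is reproducible and writes a loadable corpus", {
  cfg <- generator_config(n_events = 5, tokens_per_event = 2, n_days = 5,
                          p_paraphrase = 0.1)
  conds <- list(c1 = list(), c2 = list(scramble_stimulus = TRUE))
  corp <- generate_corpus(cfg, n_participants = 25, conditions = conds, seed = 76)
  expect_length(corp, 50)
  expect_equal(sum(vapply(corp, function(l) length(l$stories), 0L)), 300)
  # byte-identical regeneration
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_corpus(cfg, 3, conds, seed = 77, dir = d1)
  generate_corpus(cfg, 3, conds, seed = 77, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # scrambled stimulus shares the sentence multiset with the plain one
  stim <- attr(corp, "stimuli")
  expect_equal(sort(stim$c2$sentences), sort(stim$c1$sentences))
  expect_false(identical(stim$c2$sentences, stim$c1$sentences))
})
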