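test_that("sentence segmentation splits on terminal punctuation and handles edge cases", {
  expect_equal(segment_sentences("A ran. B sat! C slept?"),
               c("A ran.", "B sat!", "C slept?"))
  expect_equal(segment_sentences(""), character(0))
  expect_equal(segment_sentences("   \n "), character(0))
  expect_equal(segment_sentences("No terminal punctuation"),
               "No terminal punctuation")
  expect_equal(segment_sentences("Dr. Smith ran. He fell."),
               c("Dr. Smith ran.", "He fell."))
  expect_equal(segment_sentences("She cited Smith et al. often. Then left."),
               c("She cited Smith et al. often.", "Then left."))
})

test_that("segmentation of concatenated single-sentence strings recovers each sentence", {
  withr::with_seed(11, {
    for (k in c(1, 3, 7, 25)) {
      sents <- vapply(seq_len(k), function(i) {
        paste0(paste(sample(story_vocab, 3), collapse = " "), ".")
      }, character(1))
      got <- segment_sentences(paste(sents, collapse = " "))
      expect_equal(got, sents)
    }
  })
  # sentences concatenate (up to whitespace) back to the input text
  txt <- "the cat sat.  the dog ran!   birds sing?"
  expect_equal(gsub("\\s+", "", paste(segment_sentences(txt), collapse = "")),
               gsub("\\s+", "", txt))
})

test_that("clean_text strips meta-commentary and drops near-empty sentences", {
  expect_equal(clean_text("I believe the dog ran home."), "the dog ran home.")
  expect_equal(clean_text("The dog ran home."), "The dog ran home.")
  cfg <- cleaning_config(meta_phrases = "this task is hard")
  expect_equal(
    clean_text("If I remember correctly, she won. This task is hard.", cfg),
    "she won."
  )
  # word-boundary anchoring: no partial-word matches
  expect_equal(clean_text("The thinker ran home."), "The thinker ran home.")
  # case-insensitive
  expect_equal(clean_text("i THINK the cat sat there."), "the cat sat there.")
})

test_that("clean_text is idempotent on a generated corpus", {
  cfg <- cleaning_config()
  withr::with_seed(21, {
    for (i in 1:40) {
      sents <- random_story_sentences(max_sent = 5)
      # inject meta phrases into some sentences
      meta <- sample(default_meta_phrases(), 2)
      sents[1] <- paste(meta[1], sents[1])
      sents[2] <- paste0(sub("\\.$", "", sents[2]), ", ", meta[2], ".")
      txt <- paste(sents, collapse = " ")
      once <- clean_text(txt, cfg)
      expect_equal(clean_text(once, cfg), once)
      expect_false(grepl("believe|think|recall|remember correctly", once,
                         ignore.case = TRUE))
    }
  })
})

test_that("manifests round-trip story counts, day order, and condition labels", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(n_events = 4, tokens_per_event = 2, n_days = 5)
  gen <- generate_corpus(cfg, n_participants = 2,
                         conditions = list(alpha = list(), beta = list()),
                         seed = 5, dir = dir)
  lin <- load_manifest(file.path(dir, "manifest.csv"))
  expect_length(lin, 4)                 # 2 participants x 2 conditions
  expect_equal(sum(vapply(lin, function(l) length(l$stories), 0L)), 24)
  for (l in lin) {
    days <- vapply(l$stories, function(s) s$day, 0L)
    expect_equal(days, 0:5)
    expect_length(unique(vapply(l$stories, function(s) s$condition, "")), 1)
  }
  expect_setequal(unique(vapply(lin, function(l) l$condition, "")),
                  c("alpha", "beta"))
  # raw text loaded, sentences empty until segmentation
  expect_null(lin[[1]]$stories[[1]]$sentences)
  prepped <- prepare_lineages(lin)
  expect_gt(length(prepped[[1]]$stories[[1]]$sentences), 0)
})

test_that("a 55-participant 6-day synthetic manifest yields 55 lineages and 330 stories", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(n_events = 3, tokens_per_event = 2, n_days = 5)
  generate_corpus(cfg, n_participants = 55, seed = 9, dir = dir)
  lin <- load_manifest(file.path(dir, "manifest.csv"))
  expect_length(lin, 55)
  expect_equal(sum(vapply(lin, function(l) length(l$stories), 0L)), 330)
})

test_that("manifest loading rejects malformed input", {
  dir <- withr::local_tempdir()
  writeLines("hello there.", file.path(dir, "s1.txt"))
  # duplicate (participant, condition, day)
  writeLines(c("participant_id,condition,day,path",
               "P1,a,0,s1.txt", "P1,a,1,s1.txt", "P1,a,1,s1.txt"),
             file.path(dir, "m_dup.csv"))
  expect_error(load_manifest(file.path(dir, "m_dup.csv")), "duplicate")
  # missing column
  writeLines(c("participant_id,day,path", "P1,0,s1.txt"),
             file.path(dir, "m_col.csv"))
  expect_error(load_manifest(file.path(dir, "m_col.csv")), "condition")
  # unreadable story file
  writeLines(c("participant_id,condition,day,path", "P1,a,0,absent.txt"),
             file.path(dir, "m_io.csv"))
  expect_error(load_manifest(file.path(dir, "m_io.csv")), "absent.txt")
})

test_that("score matrices round-trip bit-exactly through CSV", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "m.csv")
  write_similarity_matrix(diag(2), p, ids = c("a", "b"))
  expect_length(readLines(p), 3)
  m <- withr::with_seed(3, matrix(stats::rnorm(100), 10, 10))
  ids <- sprintf("s%02d", 1:10)
  write_similarity_matrix(m, p, ids = ids)
  back <- read_similarity_matrix(p)
  expect_identical(unname(back), unname(m))
  expect_equal(rownames(back), ids)
  expect_error(write_similarity_matrix(matrix(0, 2, 3), p), "square")
})
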