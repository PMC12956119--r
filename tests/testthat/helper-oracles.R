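# Independent brute-force reference implementations used to cross-check the
# package's similarity machinery, plus small random-story generators.
# These deliberately avoid the package's internal code paths: plain double
# loops, hand-rolled rank/Pearson arithmetic.

oracle_tokens <- function(s) {
  toks <- strsplit(gsub("[^a-z]+", " ", tolower(s)), " +")[[1]]
  unique(toks[nzchar(toks)])
}

oracle_jaccard <- function(s1, s2) {
  a <- oracle_tokens(s1)
  b <- oracle_tokens(s2)
  if (length(a) == 0 || length(b) == 0) return(0)
  length(intersect(a, b)) / length(union(a, b))
}

oracle_thresholds <- function(sents) {
  n <- length(sents)
  if (n == 1) return(0)
  th <- numeric(n)
  for (i in 1:n) {
    vals <- c()
    for (j in 1:n) if (j != i) vals <- c(vals, oracle_jaccard(sents[i], sents[j]))
    th[i] <- max(vals)
  }
  th
}

# first index attaining the maximum similarity (tie -> lowest index)
oracle_match <- function(ref, tgt) {
  th <- oracle_thresholds(ref)
  best_index <- integer(length(ref))
  best_sim <- numeric(length(ref))
  for (i in seq_along(ref)) {
    sims <- vapply(tgt, function(t) oracle_jaccard(ref[i], t), numeric(1))
    best_index[i] <- which(sims == max(sims))[1]
    best_sim[i] <- max(sims)
  }
  list(thresholds = th, best_index = best_index, best_sim = best_sim,
       remembered = best_sim > th)
}

# Spearman with average ranks via hand-rolled Pearson on ranks
oracle_spearman <- function(x, y) {
  if (length(x) < 2) return(0)
  if (length(unique(y)) < 2 || length(unique(x)) < 2) return(0)
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

oracle_story_similarity <- function(sa, sb) {
  mab <- oracle_match(sa, sb)
  mba <- oracle_match(sb, sa)
  content_ab <- sum(mab$remembered) / length(sa)
  content_ba <- sum(mba$remembered) / length(sb)
  sequence_ab <- oracle_spearman(seq_along(sa), mab$best_index)
  sequence_ba <- oracle_spearman(seq_along(sb), mba$best_index)
  content <- (content_ab + content_ba) / 2
  sequence <- (sequence_ab + sequence_ba) / 2
  list(content_ab = content_ab, content_ba = content_ba, content = content,
       sequence_ab = sequence_ab, sequence_ba = sequence_ba,
       sequence = sequence, combined = content * sequence)
}

oracle_sdd <- function(points) {
  x <- points[, 1]
  y <- points[, 2]
  acc <- 0
  for (i in seq_len(nrow(points))) {
    acc <- acc + (x[i] - mean(x))^2 + (y[i] - mean(y))^2
  }
  sqrt(acc / nrow(points))
}

# toy stories used throughout (hand-derived expectations)
toy_A <- c("the cat sat.", "the dog ran.", "birds sing loudly.")
toy_B <- c("the cat sat.", "birds sing loudly.")

story_vocab <- c("cat", "dog", "bird", "ran", "sat", "slept", "house",
                 "tree", "river", "ball", "red", "blue")

# overlapping-vocabulary story: duplicate sentences and similarity ties are
# possible, which is exactly what the oracle-equivalence checks need
random_story_sentences <- function(max_sent = 6, vocab = story_vocab) {
  n <- sample(2:max_sent, 1)
  vapply(seq_len(n), function(i) {
    paste0(paste(sample(vocab, sample(2:4, 1)), collapse = " "), ".")
  }, character(1))
}

# pairwise-distinct sentences: a unique tag token per sentence guarantees
# distinct token sets, so self-similarity is exactly (1, 1, 1)
random_distinct_story <- function(max_sent = 6, vocab = story_vocab) {
  n <- sample(2:max_sent, 1)
  sents <- vapply(seq_len(n), function(i) {
    paste0(paste(c(sprintf("tag%s", paste(rep(letters[i], 2), collapse = "")),
                   sample(vocab, sample(2:3, 1))), collapse = " "), ".")
  }, character(1))
  storysim::story(sentences = sents)
}
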