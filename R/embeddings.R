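# Sentence-pair similarity backends: lexical overlap (deterministic test
# backend) and averaged word vectors with cosine (production backend).
# A backend carries three functions so callers can amortize per-sentence work:
#   prepare(sentences)      -> list of per-sentence representations
#   sim_prepared(ra, rb)    -> similarity of two representations
#   sim(s1, s2)             -> convenience one-shot similarity
# The contract: sim is symmetric, finite, in [-1, 1], and 1 for a sentence
# compared with itself whenever it has at least one in-vocabulary token.

#' Tokenize a sentence
#'
#' Shared tokenization for all backends: lowercase and keep maximal runs of
#' ASCII letters (punctuation and digits act as separators).
#'
#' @param x Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(x) {
  if (is.null(x) || is.na(x)) return(character(0))
  regmatches(tolower(x), gregexpr("[a-z]+", tolower(x)))[[1]]
}

new_backend <- function(name, prepare, sim_prepared) {
  structure(
    list(
      name = name,
      prepare = prepare,
      sim_prepared = sim_prepared,
      sim = function(s1, s2) {
        sim_prepared(prepare(list(s1))[[1]], prepare(list(s2))[[1]])
      }
    ),
    class = "similarity_backend"
  )
}

#' @export
print.similarity_backend <- function(x, ...) {
  cat(sprintf("<similarity_backend: %s>\n", x$name))
  invisible(x)
}

#' Lexical-overlap similarity backend
#'
#' Deterministic backend scoring a sentence pair by the Jaccard index of
#' their lowercased alphabetic token sets: 1 for equal non-empty sets, 0 for
#' disjoint sets, 0 when either set is empty. Output is in \[0, 1\], so it
#' satisfies the general backend contract (range \[-1, 1\]).
#'
#' @return A `similarity_backend`.
#' @export
lexical_backend <- function() {
  prepare <- function(sentences) lapply(sentences, function(s) unique(tokenize(s)))
  sim_prepared <- function(ra, rb) {
    na <- length(ra); nb <- length(rb)
    if (na == 0L || nb == 0L) return(0)
    u <- length(unique(c(ra, rb)))
    (na + nb - u) / u
  }
  new_backend("lexical", prepare, sim_prepared)
}

#' Lexical similarity of two sentences
#'
#' Jaccard index of lowercased alphabetic token sets; see
#' [lexical_backend()].
#'
#' @param s1,s2 Sentences (character scalars).
#' @return Score in \[0, 1\].
#' @export
lexical_similarity <- function(s1, s2) {
  b <- lexical_backend()
  b$sim(s1, s2)
}

#' Load a word-vector table from text format
#'
#' One line per token: the token followed by its `d` float components,
#' whitespace-separated. An optional leading `count dim` header line is
#' auto-detected and skipped. Tokens are lowercased; on duplicates the first
#' entry wins.
#'
#' @param path File path.
#' @return Numeric matrix (tokens x dimensions) with lowercase rownames,
#'   of class `word_vector_table`.
#' @export
load_word_vectors <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty word-vector file")
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first)))) {
    lines <- lines[-1]  # "count dim" header
  }
  parts <- strsplit(trimws(lines), "\\s+")
  toks <- tolower(vapply(parts, `[`, character(1), 1L))
  d <- length(parts[[1]]) - 1L
  if (d < 1L) stop("word-vector lines need at least one component")
  vecs <- t(vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[-1]))
    if (length(v) != d || anyNA(v)) {
      stop("inconsistent word-vector line: ", paste(p, collapse = " "))
    }
    v
  }, numeric(d)))
  keep <- !duplicated(toks)
  vecs <- vecs[keep, , drop = FALSE]
  rownames(vecs) <- toks[keep]
  class(vecs) <- c("word_vector_table", class(vecs))
  vecs
}

#' Create a word-vector table from a matrix
#' @param m Numeric matrix with token rownames.
#' @return A `word_vector_table`.
#' @export
word_vector_table <- function(m) {
  m <- as.matrix(m)
  if (!nrow(m) || is.null(rownames(m))) {
    stop("word-vector table needs a non-empty matrix with token rownames")
  }
  rownames(m) <- tolower(rownames(m))
  storage.mode(m) <- "double"
  class(m) <- c("word_vector_table", class(m))
  m
}

sentence_vector <- function(tokens, table) {
  hit <- tokens[tokens %in% rownames(table)]
  if (!length(hit)) return(NULL)
  v <- colMeans(table[hit, , drop = FALSE])
  if (all(v == 0)) return(NULL)
  v
}

#' Word-vector (averaged cosine) similarity backend
#'
#' Each sentence is represented by the mean of its in-vocabulary token
#' vectors; the pair score is the cosine of the two means, clipped to
#' \[-1, 1\] against rounding. A sentence with no in-vocabulary token (or a
#' zero mean vector) scores 0 against everything, keeping downstream
#' thresholds well-defined.
#'
#' @param table A `word_vector_table` (see [load_word_vectors()]).
#' @return A `similarity_backend`.
#' @export
vector_backend <- function(table) {
  if (!inherits(table, "word_vector_table")) table <- word_vector_table(table)
  prepare <- function(sentences) {
    lapply(sentences, function(s) sentence_vector(tokenize(s), table))
  }
  sim_prepared <- function(ra, rb) {
    if (is.null(ra) || is.null(rb)) return(0)
    x <- sum(ra * rb) / (sqrt(sum(ra^2)) * sqrt(sum(rb^2)))
    max(-1, min(1, x))
  }
  new_backend("vectors", prepare, sim_prepared)
}

#' Word-vector similarity of two sentences
#'
#' Cosine of the mean in-vocabulary token vectors; see [vector_backend()].
#'
#' @param s1,s2 Sentences.
#' @param table A `word_vector_table`.
#' @return Score in \[-1, 1\]; 0 when either sentence has no in-vocabulary
#'   token.
#' @export
vector_similarity <- function(s1, s2, table) {
  b <- vector_backend(table)
  b$sim(s1, s2)
}

#' Pairwise sentence similarity matrix
#'
#' Entry (i, j) is `backend$sim(sents_a[i], sents_b[j])`; computing the
#' matrix for the swapped arguments yields the transpose.
#'
#' @param backend A `similarity_backend`.
#' @param sents_a,sents_b Non-empty character vectors of sentences.
#' @return `length(sents_a)` x `length(sents_b)` numeric matrix.
#' @export
pairwise_matrix <- function(backend, sents_a, sents_b) {
  stopifnot(inherits(backend, "similarity_backend"))
  if (!length(sents_a) || !length(sents_b)) {
    stop("pairwise_matrix needs non-empty sentence lists")
  }
  ra <- backend$prepare(as.list(sents_a))
  rb <- backend$prepare(as.list(sents_b))
  cross_sim_matrix(backend, ra, rb)
}

# prepared-representation cross matrix (internal, reused by similarity_core)
cross_sim_matrix <- function(backend, ra, rb) {
  n <- length(ra); m <- length(rb)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      out[i, j] <- backend$sim_prepared(ra[[i]], rb[[j]])
    }
  }
  out
}
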