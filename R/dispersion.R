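# Cross-participant convergence: all-pairs combined similarity -> distance
# matrix -> 2-D multidimensional scaling -> Standard Distance Deviation per
# condition -> permutation test of the condition difference.

#' All-pairs combined similarity matrix
#'
#' Combined story similarity between every pair of stories. Per-story
#' sentence representations and within-story thresholds are computed once
#' and reused, and the matrix is symmetric by construction (the measure is
#' symmetric in its arguments). The diagonal is the self-similarity, 1 for
#' stories with pairwise-distinct sentences.
#'
#' @param stories List of segmented [story()] objects (>= 2).
#' @param backend A `similarity_backend`.
#' @param threshold_mode See [within_story_thresholds()].
#' @return Symmetric numeric matrix with story ids as dimnames.
#' @export
all_pairs_matrix <- function(stories, backend,
                             threshold_mode = c("per_sentence", "global")) {
  threshold_mode <- match.arg(threshold_mode)
  n <- length(stories)
  if (n < 2L) stop("all_pairs_matrix needs >= 2 stories")
  sents <- lapply(stories, story_sentences)
  reps <- lapply(sents, function(s) backend$prepare(as.list(s)))
  ths <- lapply(reps, function(r) thresholds_prepared(backend, r, threshold_mode))
  ids <- vapply(stories, function(s) {
    if (inherits(s, "story")) s$story_id else "story"
  }, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    m[i, i] <- pair_components(backend, reps[[i]], reps[[i]],
                               ths[[i]], ths[[i]])$combined
    if (i == n) break
    for (j in seq((i + 1L), n)) {
      v <- pair_components(backend, reps[[i]], reps[[j]],
                           ths[[i]], ths[[j]])$combined
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

#' Convert a similarity matrix to a distance matrix
#'
#' Entry-wise `d = 1 - s` (default), mapping combined similarities in
#' \[-1, 1\] to distances in \[0, 2\]; `normalize = TRUE` uses
#' `d = (1 - s) / 2` for a \[0, 1\] range. The diagonal is forced to 0.
#'
#' @param m Symmetric similarity matrix.
#' @param normalize Use the \[0, 1\] normalization.
#' @param tol Symmetry tolerance.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
similarity_to_distance <- function(m, normalize = FALSE, tol = 1e-9) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > tol) {
    stop("similarity matrix must be symmetric")
  }
  d <- 1 - m
  if (normalize) d <- d / 2
  diag(d) <- 0
  d
}

#' Embed stories in two dimensions
#'
#' Maps a story distance matrix into a shared 2-D space. The default
#' `"classical"` method is classical (Torgerson) multidimensional scaling —
#' double-centering plus the top-2 eigenpairs, with negative eigenvalues
#' truncated — and is fully deterministic. The `"stress"` method refines the
#' classical solution by Sammon stress minimization; `seed` fixes the jitter
#' used to separate coincident points, keeping it reproducible.
#'
#' @param distances Symmetric distance matrix with zero diagonal.
#' @param method `"classical"` or `"stress"`.
#' @param seed Integer seed (used by `"stress"` only).
#' @return An n x 2 coordinate matrix (rownames preserved) with attribute
#'   `"stress"`: Kruskal raw stress of the configuration, 0 reported for an
#'   exact fit.
#' @export
embed_2d <- function(distances, method = c("classical", "stress"), seed = 1L) {
  method <- match.arg(method)
  d <- as.matrix(distances)
  if (any(!is.finite(d))) stop("distances must be finite")
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  n <- nrow(d)
  pts <- stats::cmdscale(d, k = min(2L, n - 1L))
  if (ncol(pts) < 2L) {
    pts <- cbind(pts, matrix(0, n, 2L - ncol(pts)))
  }
  if (method == "stress") {
    dv <- d[lower.tri(d)]
    if (any(dv <= 0)) {
      # Sammon mapping needs positive dissimilarities; jitter coincident pairs
      eps <- max(dv[dv > 0], 1) * 1e-6
      d[d <= 0] <- eps
      diag(d) <- 0
      pts <- pts + withr::with_seed(seed, matrix(stats::rnorm(2 * n, 0, eps),
                                                 n, 2))
    }
    fit <- MASS::sammon(stats::as.dist(d), y = pts, k = 2, trace = FALSE)
    pts <- fit$points
  }
  rownames(pts) <- rownames(d)
  emb <- as.matrix(stats::dist(pts))
  attr(pts, "stress") <- sqrt(sum((emb - as.matrix(distances))^2) / 2)
  pts
}

#' Standard Distance Deviation of a point set
#'
#' Root-mean-square distance of the points from their centroid:
#' `sqrt(sum((x - mean(x))^2 + (y - mean(y))^2) / N)`. Zero iff all points
#' coincide; invariant under translation and rotation. Lower SDD within a
#' condition's embedded stories means greater cross-participant convergence.
#'
#' @param points An n x 2 numeric matrix of coordinates.
#' @return Non-negative scalar.
#' @export
standard_distance_deviation <- function(points) {
  points <- as.matrix(points)
  if (!nrow(points)) stop("standard_distance_deviation needs >= 1 point")
  if (ncol(points) != 2L) stop("points must be n x 2")
  x <- points[, 1]
  y <- points[, 2]
  sqrt(sum((x - mean(x))^2 + (y - mean(y))^2) / nrow(points))
}

#' Permutation test of condition dispersion difference
#'
#' On fixed embedded coordinates, computes the SDD of each condition's
#' points and tests the observed difference by shuffling the condition
#' labels `n_perm` times; two-sided add-one p-value, deterministic given
#' `seed`.
#'
#' @param points n x 2 coordinate matrix (e.g. from [embed_2d()]).
#' @param labels Condition label per point (exactly 2 distinct values, each
#'   with >= 2 points).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return An object of class `dispersion_result`: `story_ids`,
#'   `coordinates`, `sdd` (named per condition), `observed_delta`
#'   (condition-1 SDD minus condition-2 SDD, sorted condition order),
#'   `p_value`, `n_perm`, `seed`.
#' @export
dispersion_permutation_test <- function(points, labels, n_perm = 10000L,
                                        seed = 1L) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  if (nrow(points) != length(labels)) stop("one label per point required")
  conds <- sort(unique(labels))
  if (length(conds) != 2L) stop("need exactly 2 conditions")
  if (any(table(labels) < 2L)) stop("each condition needs >= 2 points")
  sdd_by <- function(lab) {
    vapply(conds, function(cc) {
      standard_distance_deviation(points[lab == cc, , drop = FALSE])
    }, numeric(1))
  }
  sdd <- sdd_by(labels)
  obs <- sdd[[1]] - sdd[[2]]
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      s <- sdd_by(sample(labels))
      s[[1]] - s[[2]]
    }, numeric(1))
  })
  p <- (sum(abs(perm) >= abs(obs)) + 1) / (n_perm + 1)
  structure(
    list(
      story_ids = rownames(points),
      coordinates = points,
      sdd = sdd,
      observed_delta = obs,
      p_value = p,
      n_perm = as.integer(n_perm),
      seed = as.integer(seed)
    ),
    class = "dispersion_result"
  )
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf(
    "<dispersion_result> SDD %s; delta = %.4f, p = %.4g (%d permutations)\n",
    paste(sprintf("%s = %.4f", names(x$sdd), x$sdd), collapse = ", "),
    x$observed_delta, x$p_value, x$n_perm
  ))
  invisible(x)
}
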