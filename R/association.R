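#' Pairwise association estimators
#'
#' Seven symmetric gene-gene similarity estimators on two expression
#' profiles of equal length. Every correlation-type estimator returns 0
#' (never `NA`) when either profile has zero variance: constant probes carry
#' no association evidence and downstream matrices must stay finite.
#'
#' * `assoc_pearson()` — product-moment correlation.
#' * `assoc_spearman()` — Pearson on average ranks (ties -> mean rank).
#' * `assoc_kendall()` — Kendall's tau-b (tie-corrected).
#' * `assoc_theil_sen()` — both profiles are standardized, the median of all
#'   pairwise slopes is taken in each regression direction, and the score is
#'   `sign(b_yx) * min(1, sqrt(b_yx * b_xy))`, or 0 when the two medians
#'   disagree in sign. A bounded, symmetric robust-slope association.
#' * `assoc_weighted_rank()` — weighted Pearson on the two rank vectors with
#'   top-emphasis weights: rank r receives weight `m - r + 1`, and each
#'   observation is weighted by the mean of its two per-profile weights so
#'   the score is symmetric in x and y. Pass `weights` (indexed by rank,
#'   rank 1 = largest weight first) to change the emphasis profile.
#' * `assoc_mutual_information()` — plug-in mutual information in bits from
#'   a joint histogram of `bins` equal-width bins per axis over each
#'   profile's observed range; default `bins = ceiling(sqrt(m))` clamped to
#'   `[2, 20]`.
#' * `assoc_mic()` — maximal information coefficient: the maximum over grid
#'   resolutions `a x b` with `a * b <= m^alpha` of the grid mutual
#'   information normalized by `log2(min(a, b))`. Two-row (or two-column)
#'   grids are optimized exactly over both cut points; finer grids use
#'   equipartition of one axis and dynamic-programming optimization of the
#'   other, with at most `c * a` candidate clumps per axis.
#'
#' @param x,y numeric vectors of equal length `m >= 3` (`m >= 10`
#'   recommended for `assoc_mic`), all values finite.
#' @param bins number of equal-width bins per axis (mutual information).
#' @param weights optional weight-by-rank vector of length `m`
#'   (weighted rank correlation).
#' @param alpha grid-budget exponent for MIC; resolutions satisfy
#'   `a * b <= max(m^alpha, 4)`.
#' @param c candidate-clump multiplier for the MIC column search.
#' @return a single numeric score: correlations in `[-1, 1]`, mutual
#'   information `>= 0`, MIC in `[0, 1]`.
#' @name association_estimators
#' @examples
#' x <- c(1, 2, 3, 4, 5)
#' assoc_pearson(x, x^3)
#' assoc_spearman(x, x^3)
NULL

check_pair <- function(x, y, min_m = 3L) {
  if (length(x) != length(y)) {
    stop("profiles have different lengths (", length(x), " vs ", length(y),
         ")", call. = FALSE)
  }
  if (length(x) < min_m) {
    stop("need at least ", min_m, " samples", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("profiles must be finite", call. = FALSE)
  }
  invisible(NULL)
}

zero_var <- function(v) isTRUE(min(v) == max(v))

#' @rdname association_estimators
#' @export
assoc_pearson <- function(x, y) {
  check_pair(x, y)
  if (zero_var(x) || zero_var(y)) return(0)
  stats::cor(x, y, method = "pearson")
}

#' @rdname association_estimators
#' @export
assoc_spearman <- function(x, y) {
  check_pair(x, y)
  if (zero_var(x) || zero_var(y)) return(0)
  stats::cor(x, y, method = "spearman")
}

#' @rdname association_estimators
#' @export
assoc_kendall <- function(x, y) {
  check_pair(x, y)
  if (zero_var(x) || zero_var(y)) return(0)
  # O(m log m) merge-sort tau-b; agrees with stats::cor(method = "kendall")
  kendall_tau_b_cpp(as.numeric(x), as.numeric(y))
}

#' @rdname association_estimators
#' @export
assoc_theil_sen <- function(x, y) {
  check_pair(x, y)
  if (zero_var(x) || zero_var(y)) return(0)
  xs <- (x - mean(x)) / stats::sd(x)
  ys <- (y - mean(y)) / stats::sd(y)
  theil_sen_score_cpp(xs, ys)
}

#' @rdname association_estimators
#' @export
assoc_weighted_rank <- function(x, y, weights = NULL) {
  check_pair(x, y)
  if (zero_var(x) || zero_var(y)) return(0)
  m <- length(x)
  if (is.null(weights)) {
    weights <- m:1  # rank 1 (smallest value) .. rank m; top ranks emphasized
  } else if (length(weights) != m || any(!is.finite(weights)) ||
             any(weights < 0) || sum(weights) == 0) {
    stop("'weights' must be ", m, " finite non-negative values", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  # symmetric per-observation weight: mean of the two rank weights
  wr <- function(r) {
    lo <- weights[floor(r)]
    hi <- weights[ceiling(r)]
    (lo + hi) / 2  # tied (half-integer) ranks get interpolated weight
  }
  w <- (wr(rx) + wr(ry)) / 2
  w <- w / sum(w)
  mx <- sum(w * rx)
  my <- sum(w * ry)
  vx <- sum(w * (rx - mx)^2)
  vy <- sum(w * (ry - my)^2)
  if (vx == 0 || vy == 0) return(0)
  sum(w * (rx - mx) * (ry - my)) / sqrt(vx * vy)
}

#' @rdname association_estimators
#' @export
assoc_mutual_information <- function(x, y, bins = NULL) {
  check_pair(x, y)
  if (is.null(bins)) bins <- min(20L, max(2L, ceiling(sqrt(length(x)))))
  bins <- as.integer(bins)
  if (bins < 2L) stop("'bins' must be >= 2", call. = FALSE)
  ix <- bin_index(x, bins)
  iy <- bin_index(y, bins)
  mi_from_bins(ix, iy, bins)
}

# Equal-width binning over the observed range; a constant vector collapses
# into a single occupied bin.
bin_index <- function(v, bins) {
  lo <- min(v)
  hi <- max(v)
  if (lo == hi) return(rep.int(1L, length(v)))
  i <- floor((v - lo) / (hi - lo) * bins) + 1L
  pmin.int(i, bins)
}

mi_from_bins <- function(ix, iy, bins) {
  joint <- tabulate(ix + bins * (iy - 1L), nbins = bins * bins)
  p <- joint / length(ix)
  px <- tabulate(ix, nbins = bins) / length(ix)
  py <- tabulate(iy, nbins = bins) / length(ix)
  pxy <- as.vector(outer(px, py))
  keep <- p > 0
  sum(p[keep] * log2(p[keep] / pxy[keep]))
}

#' @rdname association_estimators
#' @export
assoc_mic <- function(x, y, alpha = 0.6, c = 15) {
  check_pair(x, y, min_m = 4L)
  if (zero_var(x) || zero_var(y)) return(0)
  mic_score_cpp(as.numeric(x), as.numeric(y), alpha, as.integer(c))
}

#' Names of the available association estimators
#'
#' @return character vector of the seven method names accepted by
#'   [association_matrix()] and [infer_network()].
#' @export
association_methods <- function() {
  c("pearson", "spearman", "kendall", "theil_sen", "weighted_rank",
    "mutual_information", "mic")
}

assoc_fun <- function(method, params = list()) {
  switch(method,
    pearson = assoc_pearson,
    spearman = assoc_spearman,
    kendall = assoc_kendall,
    theil_sen = assoc_theil_sen,
    weighted_rank = function(x, y)
      assoc_weighted_rank(x, y, weights = params$weights),
    mutual_information = function(x, y)
      assoc_mutual_information(x, y, bins = params$bins),
    mic = function(x, y)
      assoc_mic(x, y, alpha = params$alpha %||% 0.6, c = params$c %||% 15),
    stop("unknown association method '", method, "'; valid methods: ",
         paste(association_methods(), collapse = ", "), call. = FALSE)
  )
}

#' Compute the symmetric association matrix for one estimator
#'
#' Evaluates the chosen estimator on every unordered gene pair exactly once,
#' following the balanced circular partition plan ([partition_rows()]), and
#' mirrors the scores into a symmetric matrix with a zero diagonal. The
#' result is identical for every worker count: parallelism only changes who
#' computes a pair, never its value or its place.
#'
#' @param m numeric expression matrix, genes in rows (see
#'   [read_expression_matrix()]).
#' @param method one of [association_methods()].
#' @param workers number of forked workers (see [parallel::mclapply()]);
#'   1 = serial.
#' @param params optional list of estimator parameters (`bins`, `weights`,
#'   `alpha`, `c`).
#' @return symmetric numeric n x n matrix with gene IDs as dimnames, zero
#'   diagonal, and attributes `method` and `params`.
#' @export
#' @examples
#' m <- matrix(rnorm(30), 5, 6, dimnames = list(paste0("g", 1:5), NULL))
#' a <- association_matrix(m, "spearman")
#' all(a == t(a))
association_matrix <- function(m, method = association_methods(),
                               workers = 1L, params = list()) {
  method <- match.arg(method)
  validate_expression_matrix(m)
  f <- assoc_fun(method, params)
  n <- nrow(m)
  plan <- partition_rows(n, min(workers, n))
  per_worker <- split(seq_len(n), plan$worker_of_row)
  compute_rows <- function(rows) {
    lapply(rows, function(i) {
      js <- plan$owned[[i]]
      if (length(js) == 0L) return(numeric(0))
      vapply(js, function(j) f(m[i, ], m[j, ]), numeric(1L))
    })
  }
  chunks <- if (workers > 1L) {
    parallel::mclapply(per_worker, compute_rows, mc.cores = workers,
                       mc.preschedule = FALSE)
  } else {
    lapply(per_worker, compute_rows)
  }
  scores <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (w in seq_along(per_worker)) {
    rows <- per_worker[[w]]
    for (r in seq_along(rows)) {
      i <- rows[r]
      js <- plan$owned[[i]]
      v <- chunks[[w]][[r]]
      scores[cbind(i, js)] <- v
      scores[cbind(js, i)] <- v
    }
  }
  structure(scores, method = method, params = params)
}
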