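#' Number of gene pairs
#'
#' Closed-form count of the pairwise association evaluations a network of
#' `n` genes requires: `n(n-1)/2` unordered pairs, or `n(n-1)` ordered
#' evaluations. Computed in doubles, which are exact for every genome-scale
#' `n` (counts stay far below 2^53).
#'
#' @param n number of genes (`>= 2`).
#' @param ordered count ordered pairs instead of unordered.
#' @return pair count as a double.
#' @export
#' @examples
#' pair_count(50)          # 1225
#' pair_count(35000, ordered = TRUE)
pair_count <- function(n, ordered = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != floor(n)) {
    stop("'n' must be a single integer >= 2", call. = FALSE)
  }
  n <- as.numeric(n)
  if (ordered) n * (n - 1) else n * (n - 1) / 2
}

#' Balanced circular partition of gene pairs over rows and workers
#'
#' Assigns every unordered gene pair to exactly one owning row so that the
#' pairwise workload can be distributed without duplication: row `i`
#' (0-based) owns the pairs `{i, (i + d) mod n}` for `d = 1 ..
#' floor((n-1)/2)`; when `n` is even, the antipodal pairs at `d = n/2` are
#' owned by the rows `i < n/2`. Per-row loads differ by at most one, and
#' rows are dealt to the `p` workers round-robin, so each worker receives
#' `ceiling(n/p)` or `floor(n/p)` rows.
#'
#' @param n number of genes (`>= 2`).
#' @param p number of workers (`1 <= p <= n`).
#' @return an object of class `partition_plan`: a list with `n`, `p`,
#'   `owned` (for each 1-based row `i`, the 1-based column indices of the
#'   pairs it owns) and `worker_of_row` (1-based worker id per row).
#' @export
#' @examples
#' plan <- partition_rows(4, 2)
#' lengths(plan$owned)  # per-row loads (2, 2, 1, 1)
partition_rows <- function(n, p = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != floor(n)) {
    stop("'n' must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != floor(p)) {
    stop("'p' must be a single integer >= 1", call. = FALSE)
  }
  if (p > n) stop("'p' must not exceed 'n'", call. = FALSE)
  n <- as.integer(n)
  p <- as.integer(p)
  dmax <- (n - 1L) %/% 2L
  owned <- vector("list", n)
  for (i0 in 0:(n - 1L)) {
    js <- if (dmax >= 1L) (i0 + 1:dmax) %% n else integer(0)
    if (n %% 2L == 0L && i0 < n %/% 2L) js <- c(js, (i0 + n %/% 2L) %% n)
    owned[[i0 + 1L]] <- as.integer(js) + 1L
  }
  structure(
    list(n = n, p = p, owned = owned,
         worker_of_row = rep_len(seq_len(p), n)),
    class = "partition_plan"
  )
}

#' @export
print.partition_plan <- function(x, ...) {
  cat("Partition plan:", x$n, "genes,", pair_count(x$n), "pairs,",
      x$p, "worker(s)\n")
  cat("  per-row loads:", paste(range(lengths(x$owned)), collapse = "-"),
      "pairs\n")
  invisible(x)
}

#' CLR background correction of an association matrix
#'
#' Context-likelihood-of-relatedness transform: each gene's off-diagonal
#' association scores form its background; the score of pair (i, j) is
#' standardized against gene i's background (`u_i = max(0, (a_ij - mu_i) /
#' sigma_i)`, with `u_i = 0` when `sigma_i = 0`) and against gene j's, and
#' the two rectified z-like values are combined in quadrature:
#' `z_ij = sqrt(u_i^2 + u_j^2)`. Backgrounds are the full rows (no
#' trimming); `sigma_i` is the sample standard deviation.
#'
#' @param a symmetric numeric association matrix (see
#'   [association_matrix()]); asymmetric input is a hard error.
#' @return symmetric non-negative matrix of CLR scores, zero diagonal, with
#'   the `method` attribute carried over.
#' @export
clr_transform <- function(a) {
  if (!is.matrix(a) || !is.numeric(a) || nrow(a) != ncol(a)) {
    stop("'a' must be a square numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(a))) stop("association matrix must be finite", call. = FALSE)
  if (any(a != t(a))) stop("association matrix is not symmetric", call. = FALSE)
  n <- nrow(a)
  if (n < 2L) stop("need at least 2 genes", call. = FALSE)
  off_sum <- rowSums(a) - diag(a)
  mu <- off_sum / (n - 1)
  if (n > 2L) {
    off_sq <- rowSums(a^2) - diag(a)^2
    varr <- pmax(0, (off_sq - (n - 1) * mu^2) / (n - 2))
    sigma <- sqrt(varr)
  } else {
    sigma <- rep(0, n)  # a single background point has no spread
  }
  u <- (a - mu) / ifelse(sigma > 0, sigma, Inf)
  u[u < 0] <- 0
  diag(u) <- 0
  z <- sqrt(u^2 + t(u)^2)
  dimnames(z) <- dimnames(a)
  structure(z, method = attr(a, "method"))
}

#' Standardize CLR scores into pair-level z-scores
#'
#' The empirical distribution of CLR scores over all gene pairs is close to
#' normal for large networks, so pair scores are reduced to z-scores against
#' their own mean and standard deviation. Network cutoffs (for example 4.3
#' or 3.8) are applied on this scale. Negative standardized values are
#' retained; thresholding removes them later. A constant input yields an
#' all-zero matrix.
#'
#' @param z symmetric non-negative matrix from [clr_transform()]; at least
#'   2 gene pairs (3 genes) are required.
#' @return symmetric matrix of standardized scores (zero diagonal) with
#'   attribute `standardized = TRUE`.
#' @export
standardize_scores <- function(z) {
  if (!is.matrix(z) || nrow(z) != ncol(z)) {
    stop("'z' must be a square matrix", call. = FALSE)
  }
  n <- nrow(z)
  if (pair_count_safe(n) < 2) {
    stop("need at least 2 gene pairs to standardize", call. = FALSE)
  }
  vals <- z[upper.tri(z)]
  s <- stats::sd(vals)
  out <- if (s == 0) {
    matrix(0, n, n, dimnames = dimnames(z))
  } else {
    r <- (z - mean(vals)) / s
    diag(r) <- 0
    r
  }
  structure(out, method = attr(z, "method"), standardized = TRUE)
}

pair_count_safe <- function(n) if (n < 2) 0 else n * (n - 1) / 2

#' Threshold a standardized score matrix into an edge list
#'
#' Keeps every gene pair whose standardized z-score is greater than or equal
#' to `cutoff` (ties at the cutoff are retained). Edges are canonically
#' ordered: within an edge the lexicographically smaller gene ID comes
#' first, and edges are sorted.
#'
#' @param z standardized symmetric score matrix ([standardize_scores()]).
#' @param cutoff finite z-score threshold.
#' @return an `edge_list`: a data frame with columns `from`, `to`, `score`
#'   and attribute `cutoff`.
#' @export
threshold_network <- function(z, cutoff) {
  if (!is.matrix(z) || nrow(z) != ncol(z)) {
    stop("'z' must be a square matrix", call. = FALSE)
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff)) {
    stop("'cutoff' must be a single finite number", call. = FALSE)
  }
  ids <- rownames(z) %||% as.character(seq_len(nrow(z)))
  ut <- which(upper.tri(z) & z >= cutoff, arr.ind = TRUE)
  a <- ids[ut[, 1L]]
  b <- ids[ut[, 2L]]
  swap <- a > b
  from <- ifelse(swap, b, a)
  to <- ifelse(swap, a, b)
  ord <- order(from, to, method = "radix")
  edge_list(data.frame(from = from[ord], to = to[ord],
                       score = z[ut][ord], stringsAsFactors = FALSE),
            cutoff = cutoff, method = attr(z, "method"))
}

edge_list <- function(df, cutoff = NULL, method = NULL) {
  rownames(df) <- NULL
  structure(df, cutoff = cutoff, method = method,
            class = c("edge_list", "data.frame"))
}

#' @export
print.edge_list <- function(x, ...) {
  cat("Edge list:", nrow(x), "edge(s)")
  if (!is.null(attr(x, "cutoff"))) cat(", cutoff", attr(x, "cutoff"))
  if (!is.null(attr(x, "method"))) cat(", method", attr(x, "method"))
  cat("\n")
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more\n")
  invisible(x)
}

#' Infer a thresholded gene network from an expression matrix
#'
#' The full pipeline: [association_matrix()] (every unordered pair computed
#' once, under the balanced partition plan) -> [clr_transform()] ->
#' [standardize_scores()] -> [threshold_network()]. Output is bit-identical
#' for every `workers` value.
#'
#' By default the CLR background correction operates on the association
#' *magnitude* `|a|`: a strong negative correlation is strong evidence of a
#' (repressive) regulatory link, and an association network scores evidence
#' strength, not direction of co-variation. `evidence = "signed"` feeds the
#' signed scores through instead, in which case strongly negative pairs fall
#' below their background and are lost.
#'
#' @inheritParams association_matrix
#' @param cutoff z-score threshold for [threshold_network()].
#' @param evidence `"magnitude"` (default) or `"signed"`: what the CLR
#'   background correction sees.
#' @return an `edge_list` with attributes `method`, `cutoff`, `n_genes`,
#'   `n_samples`.
#' @export
#' @examples
#' m <- matrix(rnorm(200), 10, 20,
#'             dimnames = list(paste0("g", 1:10), NULL))
#' infer_network(m, method = "spearman", cutoff = 1.5)
infer_network <- function(m, method = association_methods(), cutoff = 2,
                          workers = 1L, params = list(),
                          evidence = c("magnitude", "signed")) {
  method <- match.arg(method)
  evidence <- match.arg(evidence)
  a <- association_matrix(m, method = method, workers = workers,
                          params = params)
  if (evidence == "magnitude") a <- association_magnitude(a)
  el <- threshold_network(standardize_scores(clr_transform(a)), cutoff)
  attr(el, "n_genes") <- nrow(m)
  attr(el, "n_samples") <- ncol(m)
  el
}

# |a| with the association attributes kept
association_magnitude <- function(a) {
  structure(abs(a), method = attr(a, "method"), params = attr(a, "params"))
}

#' Write an edge list as Cytoscape-importable tab-delimited text
#'
#' One edge per line. `format = "score"` writes `geneA<TAB>score<TAB>geneB`;
#' `format = "sif"` writes `geneA<TAB>label<TAB>geneB` with a constant
#' interaction label. Provenance (or any metadata) can be prepended as
#' `#`-prefixed comment lines.
#'
#' @param el an `edge_list`.
#' @param path output file.
#' @param format `"score"` or `"sif"`.
#' @param label interaction label used by the `"sif"` format.
#' @param header optional character vector written as leading `# ` comments.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(el, path, format = c("score", "sif"),
                            label = "assoc", header = NULL) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  mid <- if (format == "score") {
    format(el$score, digits = 15, trim = TRUE, scientific = FALSE)
  } else {
    rep.int(label, nrow(el))
  }
  if (nrow(el) > 0) writeLines(paste(el$from, mid, el$to, sep = "\t"), con)
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' Accepts the `geneA<TAB>score<TAB>geneB` dialect; `#` comment lines are
#' skipped. A non-numeric middle column (the `"sif"` variant) is read with
#' all scores set to 1.
#'
#' @inheritParams read_expression_matrix
#' @return an `edge_list`.
#' @export
read_edge_list <- function(source) {
  lines <- read_text_lines(source)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(edge_list(data.frame(from = character(), to = character(),
                                score = numeric(), stringsAsFactors = FALSE)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("edge lines must have 3 tab-separated fields", call. = FALSE)
  }
  a <- vapply(parts, `[[`, character(1L), 1L)
  mid <- vapply(parts, `[[`, character(1L), 2L)
  b <- vapply(parts, `[[`, character(1L), 3L)
  score <- suppressWarnings(as.numeric(mid))
  if (anyNA(score)) score <- rep(1, length(a))
  swap <- a > b
  from <- ifelse(swap, b, a)
  to <- ifelse(swap, a, b)
  ord <- order(from, to, method = "radix")
  edge_list(data.frame(from = from[ord], to = to[ord], score = score[ord],
                       stringsAsFactors = FALSE))
}
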