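# Synthetic regulatory topologies and expression compendia. The generator
# stands in for a curated seed network (e.g. an E. coli-derived regulatory
# graph): scale-free-ish out-degrees, ~30% repression, >= 10% source genes,
# and a DAG by construction so signal propagation is well defined.

topology_obj <- function(genes, edges) {
  regulated <- unique(edges$target)
  structure(list(genes = genes,
                 edges = edges,
                 source_genes = setdiff(genes, regulated)),
            class = "reg_topology")
}

#' @export
print.reg_topology <- function(x, ...) {
  cat("Regulatory topology:", length(x$genes), "genes,", nrow(x$edges),
      "edges (", sum(x$edges$sign == "repress"), "repressing ),",
      length(x$source_genes), "source genes\n")
  invisible(x)
}

#' Generate a synthetic seed regulatory topology
#'
#' Builds a directed acyclic regulatory network over `n_genes` genes:
#' roughly 12% of genes are sources (no regulators); each remaining gene is
#' regulated by one to three earlier genes chosen preferentially towards
#' genes that already regulate many targets (preferential attachment, which
#' yields the heavy-tailed out-degree distribution of transcriptional
#' networks); about `p_repress` of edges repress, the rest activate. Each
#' edge carries fixed Hill-transfer parameters: half-saturation
#' `K ~ Uniform(0.2, 0.8)` and coefficient `h` in `{1, 2, 4}`. Every gene
#' is reachable from a source gene. Deterministic given `seed`.
#'
#' @param n_genes number of genes (`>= 20`).
#' @param seed RNG seed.
#' @param p_repress probability an edge is repressing.
#' @return a `reg_topology`: list with `genes`, `edges` (data frame
#'   `regulator`, `target`, `sign`, `K`, `h`) and `source_genes`.
#' @export
#' @examples
#' topo <- make_seed_topology(50, seed = 1)
#' topo
make_seed_topology <- function(n_genes, seed = 1L, p_repress = 0.3) {
  if (!is.numeric(n_genes) || n_genes < 20) {
    stop("'n_genes' must be >= 20", call. = FALSE)
  }
  n_genes <- as.integer(n_genes)
  with_seed(seed, {
    genes <- sprintf("G%03d", seq_len(n_genes))
    n_src <- max(2L, ceiling(0.12 * n_genes))
    reg <- integer(0)
    tgt <- integer(0)
    outdeg <- rep(0, n_genes)
    for (g in (n_src + 1L):n_genes) {
      k <- sample(1:3, 1L, prob = c(0.55, 0.3, 0.15))
      pool <- seq_len(g - 1L)
      k <- min(k, length(pool))
      pr <- (outdeg[pool] + 1)^1.2  # rich-get-richer; heavy-tailed out-degree
      r <- sample(pool, k, prob = pr / sum(pr))
      reg <- c(reg, r)
      tgt <- c(tgt, rep.int(g, k))
      outdeg[r] <- outdeg[r] + 1
    }
    sgn <- ifelse(stats::rbinom(length(reg), 1L, p_repress) == 1L,
                  "repress", "activate")
    edges <- data.frame(regulator = genes[reg], target = genes[tgt],
                        sign = sgn,
                        K = stats::runif(length(reg), 0.2, 0.8),
                        h = sample(c(1, 2, 4), length(reg), replace = TRUE),
                        stringsAsFactors = FALSE)
    topology_obj(genes, edges)
  })
}

#' Sample a connected subnetwork topology by neighbor addition
#'
#' Starting from one random gene, repeatedly adds a uniformly chosen
#' neighbor (ignoring edge direction) of the current gene set until `k`
#' genes are collected, then keeps the induced edges — the subnetwork
#' sampling strategy of seed-topology expression simulators. If the
#' frontier empties before `k` genes (disconnected remainder), a random
#' unvisited gene restarts the walk.
#'
#' @param topology a `reg_topology`.
#' @param k subnetwork size (`<=` number of genes).
#' @param seed RNG seed.
#' @return a `reg_topology` on `k` genes.
#' @export
sample_subnetwork_topology <- function(topology, k, seed = 1L) {
  genes <- topology$genes
  if (k > length(genes)) {
    stop("'k' exceeds the number of genes (", length(genes), ")",
         call. = FALSE)
  }
  if (k == length(genes)) return(topology)
  e <- topology$edges
  with_seed(seed, {
    members <- sample(genes, 1L)
    while (length(members) < k) {
      nb <- unique(c(e$target[e$regulator %in% members],
                     e$regulator[e$target %in% members]))
      frontier <- setdiff(nb, members)
      nxt <- if (length(frontier) > 0L) {
        sample(frontier, 1L)
      } else {
        sample(setdiff(genes, members), 1L)
      }
      members <- c(members, nxt)
    }
    keep <- e$regulator %in% members & e$target %in% members
    topology_obj(sort(members), e[keep, , drop = FALSE])
  })
}

# Kahn topological order of the targets; NULL if the graph has a cycle.
topological_order <- function(genes, edges) {
  indeg <- stats::setNames(rep(0L, length(genes)), genes)
  tab <- table(edges$target)
  indeg[names(tab)] <- as.integer(tab)
  out <- split(edges$target, factor(edges$regulator, levels = genes))
  order <- character(0)
  queue <- sort(genes[indeg == 0L])
  while (length(queue) > 0L) {
    g <- queue[1L]
    queue <- queue[-1L]
    order <- c(order, g)
    for (t in out[[g]]) {
      indeg[t] <- indeg[t] - 1L
      if (indeg[t] == 0L) queue <- sort(c(queue, t))
    }
  }
  if (length(order) < length(genes)) NULL else order
}

#' Drop cycle-closing edges from a topology
#'
#' Edges are scanned in their stored order; any edge that would close a
#' directed cycle (and any self-loop) is dropped with a warning. Curated
#' regulatory graphs are nearly acyclic, so few edges are lost; the
#' simulator requires a DAG.
#'
#' @param topology a `reg_topology`.
#' @return a `reg_topology` whose edge set is acyclic.
#' @export
break_cycles <- function(topology) {
  e <- topology$edges
  keep <- logical(nrow(e))
  # reaches(a, b): directed path a -> b in the currently kept edges
  reaches <- function(a, b, kept) {
    frontier <- a
    seen <- character(0)
    while (length(frontier) > 0L) {
      if (b %in% frontier) return(TRUE)
      seen <- c(seen, frontier)
      nxt <- kept$target[kept$regulator %in% frontier]
      frontier <- setdiff(nxt, seen)
    }
    FALSE
  }
  for (i in seq_len(nrow(e))) {
    if (e$regulator[i] == e$target[i]) next  # self-loop
    kept <- e[keep, , drop = FALSE]
    if (!reaches(e$target[i], e$regulator[i], kept)) keep[i] <- TRUE
  }
  if (!all(keep)) {
    warning(sum(!keep), " cycle-closing or self edge(s) dropped",
            call. = FALSE)
  }
  topology_obj(topology$genes, e[keep, , drop = FALSE])
}

hill_term <- function(x, K, h, sign) {
  if (sign == "activate") x^h / (K^h + x^h) else K^h / (K^h + x^h)
}

#' Simulate an expression compendium from a regulatory topology
#'
#' Steady-state-style simulation: for each sample, every source gene draws
#' an activity from `Uniform(0.05, 1)`; each regulated gene's activity is
#' the product of per-edge Hill transfer terms over its regulators
#' (activation `x^h / (K^h + x^h)`, repression `K^h / (K^h + x^h)`), using
#' the `K` and `h` fixed on each edge at topology creation. Multiplicative
#' log-normal biological noise (`sdlog = bio_noise`) perturbs every gene's
#' activity and propagates to its targets; measurement is `log2(activity)`
#' plus additive Gaussian experimental noise (`sd = exp_noise`).
#' Deterministic given `seed`. Cycles must be broken first (see
#' [break_cycles()]); a cyclic graph is a hard error.
#'
#' @param topology a `reg_topology` with an acyclic edge set.
#' @param m number of samples (`>= 3`).
#' @param bio_noise log-normal biological noise sd (`>= 0`).
#' @param exp_noise Gaussian experimental noise sd on the log2 scale
#'   (`>= 0`).
#' @param seed RNG seed.
#' @return numeric genes x samples expression matrix (log2 scale) in the
#'   [read_expression_matrix()] dialect.
#' @export
#' @examples
#' topo <- make_seed_topology(30, seed = 1)
#' x <- simulate_expression(topo, m = 20, seed = 7)
#' dim(x)
simulate_expression <- function(topology, m, bio_noise = 0.1,
                                exp_noise = 0.1, seed = 1L) {
  if (m < 3) stop("'m' must be >= 3", call. = FALSE)
  if (bio_noise < 0 || exp_noise < 0) {
    stop("noise levels must be >= 0", call. = FALSE)
  }
  genes <- topology$genes
  e <- topology$edges
  ord <- topological_order(genes, e)
  if (is.null(ord)) {
    stop("topology has a directed cycle; run break_cycles() first",
         call. = FALSE)
  }
  m <- as.integer(m)
  with_seed(seed, {
    act <- matrix(NA_real_, length(genes), m, dimnames = list(genes, NULL))
    by_target <- split(seq_len(nrow(e)), factor(e$target, levels = genes))
    for (g in ord) {
      idx <- by_target[[g]]
      a <- if (length(idx) == 0L) {
        stats::runif(m, 0.05, 1)
      } else {
        v <- rep(1, m)
        for (i in idx) {
          v <- v * hill_term(act[e$regulator[i], ], e$K[i], e$h[i], e$sign[i])
        }
        v
      }
      if (bio_noise > 0) a <- a * exp(stats::rnorm(m, 0, bio_noise))
      act[g, ] <- a
    }
    expr <- log2(act)
    if (exp_noise > 0) {
      expr <- expr + matrix(stats::rnorm(length(expr), 0, exp_noise),
                            nrow(expr), ncol(expr))
    }
    colnames(expr) <- sprintf("S%04d", seq_len(m))
    expr
  })
}

#' Write / read a regulatory topology as tab text
#'
#' Columns `regulator`, `target`, `sign` plus the Hill parameters `K` and
#' `h` when present, with a header line. `read_topology()` accepts files
#' with or without the Hill columns (absent values are redrawn only by the
#' caller; they default to `K = 0.5`, `h = 2`).
#'
#' @param topology a `reg_topology`.
#' @param path file path.
#' @return `write_topology()`: `path`, invisibly. `read_topology()`: a
#'   `reg_topology`.
#' @export
write_topology <- function(topology, path) {
  utils::write.table(topology$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_topology
#' @inheritParams read_expression_matrix
#' @export
read_topology <- function(source) {
  lines <- read_text_lines(source)
  df <- utils::read.table(text = paste(lines, collapse = "\n"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  need <- c("regulator", "target", "sign")
  if (!all(need %in% names(df))) {
    stop("topology file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$sign %in% c("activate", "repress"))) {
    stop("edge sign must be 'activate' or 'repress'", call. = FALSE)
  }
  if (is.null(df$K)) df$K <- 0.5
  if (is.null(df$h)) df$h <- 2
  genes <- sort(unique(c(df$regulator, df$target)))
  topology_obj(genes, df[, c("regulator", "target", "sign", "K", "h")])
}

#' Undirected reference pairs of a topology
#'
#' Logical labels over the upper-triangle gene pairs of `gene_ids` (the
#' order used by [pair_scores()]): `TRUE` where the topology has a
#' regulatory edge in either direction. Directionality is not recoverable
#' from symmetric association scores, so evaluation is undirected.
#'
#' @param topology a `reg_topology`.
#' @param gene_ids gene ordering defining the pair layout (defaults to the
#'   topology's genes).
#' @return logical vector of length `choose(n, 2)` named `"a|b"`.
#' @export
topology_pairs <- function(topology, gene_ids = topology$genes) {
  n <- length(gene_ids)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  a <- gene_ids[idx[, 1L]]
  b <- gene_ids[idx[, 2L]]
  key <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "|")
  ref <- unique(key(topology$edges$regulator, topology$edges$target))
  stats::setNames(key(a, b) %in% ref, key(a, b))
}
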