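#' Benchmark the association-based CLR methods on synthetic compendia
#'
#' Reproduces the synthetic experimental design at desk scale: from a
#' master seed topology, each replicate samples a `k`-gene subnetwork
#' ([sample_subnetwork_topology()]) and simulates expression compendia at
#' every sample size of Group A (small compendia, 30-90 samples) and Group
#' B (large compendia, 100-1000 samples). Every method runs the full
#' association + CLR pipeline on each compendium (magnitude evidence, no
#' threshold; see [infer_network()]), and its score matrix is evaluated by
#' AUC against the sampled topology's undirected skeleton. Per-group means
#' are the summary statistic.
#'
#' MIC is quadratic-ish in the sample count, so it is only evaluated on
#' compendia with `m <= mic_max_m` samples (its group means are over those
#' sizes); set `mic_max_m = Inf` to lift the restriction.
#'
#' @param group_a_sizes,group_b_sizes sample sizes of the two groups.
#' @param k genes per sampled subnetwork.
#' @param methods association estimators to benchmark.
#' @param replicates independent (topology, compendium) draws per sample
#'   size (`>= 1`).
#' @param bio_noise,exp_noise simulator noise levels
#'   ([simulate_expression()]).
#' @param master_n genes in the master seed topology.
#' @param mic_max_m largest sample size on which MIC is evaluated.
#' @param seed master RNG seed; all topology/simulation seeds derive from
#'   it.
#' @param workers forwarded to [association_matrix()].
#' @return object of class `benchmark_result`: list with `results` (data
#'   frame: `group`, `size`, `method`, `replicate`, `auc`) and the call
#'   parameters. `summary()` returns per-group mean AUCs per method.
#' @export
#' @examples
#' \donttest{
#' b <- run_benchmark(group_a_sizes = 30, group_b_sizes = 100, k = 25,
#'                    methods = c("pearson", "spearman"), replicates = 2,
#'                    seed = 1)
#' summary(b)
#' }
run_benchmark <- function(group_a_sizes = c(30, 40, 50, 60, 70, 80, 90),
                          group_b_sizes = seq(100, 1000, by = 100),
                          k = 50,
                          methods = association_methods(),
                          replicates = 5L,
                          bio_noise = 0.1, exp_noise = 0.1,
                          master_n = 200L, mic_max_m = 200L,
                          seed = 1L, workers = 1L) {
  if (replicates < 1L) stop("'replicates' must be >= 1", call. = FALSE)
  methods <- match.arg(methods, association_methods(), several.ok = TRUE)
  sizes <- data.frame(
    group = rep(c("A", "B"),
                c(length(group_a_sizes), length(group_b_sizes))),
    size = c(group_a_sizes, group_b_sizes))
  seeds <- derive_seeds(seed, 1L + replicates * (1L + nrow(sizes)))
  master <- make_seed_topology(master_n, seed = seeds[1L])
  si <- 1L
  rows <- vector("list", replicates * nrow(sizes) * length(methods))
  ri <- 0L
  for (rep_i in seq_len(replicates)) {
    si <- si + 1L
    topo <- sample_subnetwork_topology(master, k, seed = seeds[si])
    labels <- topology_pairs(topo)
    for (d in seq_len(nrow(sizes))) {
      si <- si + 1L
      m_expr <- simulate_expression(topo, m = sizes$size[d],
                                    bio_noise = bio_noise,
                                    exp_noise = exp_noise,
                                    seed = seeds[si])
      for (meth in methods) {
        if (meth == "mic" && sizes$size[d] > mic_max_m) next
        a <- association_matrix(m_expr, meth, workers = workers)
        z <- clr_transform(association_magnitude(a))
        auc <- roc_auc(pair_scores(z), labels)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(group = sizes$group[d],
                                 size = sizes$size[d], method = meth,
                                 replicate = rep_i, auc = auc,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(results = do.call(rbind, rows[seq_len(ri)]),
                 k = k, replicates = replicates, seed = seed,
                 bio_noise = bio_noise, exp_noise = exp_noise,
                 mic_max_m = mic_max_m),
            class = "benchmark_result")
}

#' @export
summary.benchmark_result <- function(object, ...) {
  r <- object$results
  agg <- stats::aggregate(auc ~ method + group, data = r, FUN = mean)
  wide <- stats::reshape(agg, idvar = "method", timevar = "group",
                         direction = "wide")
  names(wide) <- sub("^auc\\.", "mean_auc_", names(wide))
  overall <- stats::aggregate(auc ~ method, data = r, FUN = mean)
  names(overall)[2L] <- "mean_auc_overall"
  out <- merge(wide, overall, by = "method")
  out[order(-out$mean_auc_overall), , drop = FALSE]
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("CLR benchmark:", x$replicates, "replicate(s),", x$k,
      "genes per subnetwork, noise (bio/exp):", x$bio_noise, "/",
      x$exp_noise, "\n")
  s <- summary(x)
  rownames(s) <- NULL
  print(s, digits = 3)
  invisible(x)
}
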