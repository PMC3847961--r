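test_that("topology generation is deterministic and structurally sound", {
  t1 <- make_seed_topology(200, seed = 1)
  t2 <- make_seed_topology(200, seed = 1)
  expect_identical(t1, t2)
  t3 <- make_seed_topology(200, seed = 2)
  expect_false(identical(t1$edges, t3$edges))
  expect_error(make_seed_topology(10), ">= 20")
  # no self-regulation, signs everywhere, >= 10% sources
  expect_true(all(t1$edges$regulator != t1$edges$target))
  expect_true(all(t1$edges$sign %in% c("activate", "repress")))
  expect_gte(length(t1$source_genes), 0.10 * length(t1$genes))
  # repression mass near the nominal 30%
  expect_gt(mean(t1$edges$sign == "repress"), 0.15)
  expect_lt(mean(t1$edges$sign == "repress"), 0.45)
})

test_that("every gene is reachable from a source gene", {
  topo <- make_seed_topology(150, seed = 3)
  reached <- topo$source_genes
  repeat {
    nxt <- unique(c(reached,
                    topo$edges$target[topo$edges$regulator %in% reached]))
    if (length(nxt) == length(reached)) break
    reached <- nxt
  }
  expect_setequal(reached, topo$genes)
})

test_that("generated topologies are acyclic (igraph cross-check)", {
  skip_if_not_installed("igraph")
  topo <- make_seed_topology(100, seed = 4)
  g <- igraph::graph_from_data_frame(topo$edges[, 1:2])
  expect_true(igraph::is_dag(g))
})

test_that("out-degrees are heavier-tailed than an equal-density random graph", {
  # compare max out-degree against an Erdos-Renyi control with the same
  # number of edges, over repeated seeds
  wins <- 0
  n_trials <- 60
  set.seed(99)
  for (s in seq_len(n_trials)) {
    topo <- make_seed_topology(200, seed = s)
    ne <- nrow(topo$edges)
    max_pl <- max(table(topo$edges$regulator))
    er_src <- sample(200, ne, replace = TRUE)  # ER out-degree control
    max_er <- max(table(er_src))
    if (max_pl > max_er) wins <- wins + 1
  }
  expect_gte(wins / n_trials, 0.95)
})

test_that("subnetwork sampling returns connected induced topologies", {
  topo <- make_seed_topology(200, seed = 5)
  sub <- sample_subnetwork_topology(topo, 50, seed = 6)
  expect_length(sub$genes, 50)
  expect_identical(sub,
                   sample_subnetwork_topology(topo, 50, seed = 6))
  # induced edges only
  expect_true(all(sub$edges$regulator %in% sub$genes))
  expect_true(all(sub$edges$target %in% sub$genes))
  full <- sample_subnetwork_topology(topo, 200, seed = 7)
  expect_identical(full, topo)
  expect_error(sample_subnetwork_topology(topo, 201), "exceeds")
  skip_if_not_installed("igraph")
  g <- igraph::graph_from_data_frame(sub$edges[, 1:2], directed = FALSE,
                                     vertices = sub$genes)
  expect_equal(igraph::count_components(g), 1)
})

test_that("noise-free Hill transfer gives perfectly monotone regulator-target pairs", {
  act <- read_topology("regulator\ttarget\tsign\nA\tB\tactivate")
  rep_ <- read_topology("regulator\ttarget\tsign\nA\tB\trepress")
  for (m in c(3, 10, 50)) {
    xa <- simulate_expression(act, m, bio_noise = 0, exp_noise = 0, seed = m)
    expect_equal(assoc_spearman(xa["A", ], xa["B", ]), 1, info = m)
    xr <- simulate_expression(rep_, m, bio_noise = 0, exp_noise = 0, seed = m)
    expect_equal(assoc_spearman(xr["A", ], xr["B", ]), -1, info = m)
  }
})

test_that("simulation is deterministic with the documented dimensions", {
  topo <- sample_subnetwork_topology(make_seed_topology(200, seed = 8),
                                     50, seed = 8)
  x1 <- simulate_expression(topo, 100, seed = 10)
  x2 <- simulate_expression(topo, 100, seed = 10)
  expect_identical(dim(x1), c(50L, 100L))
  expect_identical(x1, x2)
  x3 <- simulate_expression(topo, 100, seed = 11)
  expect_false(identical(x1, x3))
  expect_true(all(is.finite(x1)))
})

test_that("package seed handling never disturbs the caller's RNG stream", {
  set.seed(42)
  before <- rnorm(1)
  set.seed(42)
  invisible(make_seed_topology(50, seed = 123))
  invisible(simulate_expression(make_seed_topology(30, seed = 1), 10,
                                seed = 99))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("cycle breaking drops exactly the closing edges", {
  txt <- paste("regulator\ttarget\tsign",
               "A\tB\tactivate", "B\tC\tactivate", "C\tA\tactivate",
               "A\tC\tactivate", sep = "\n")
  topo <- read_topology(txt)
  expect_error(simulate_expression(topo, 10, seed = 1), "cycle")
  expect_warning(fixed <- break_cycles(topo), "dropped")
  expect_equal(nrow(fixed$edges), 3)  # C->A closed the cycle, in input order
  expect_false(any(fixed$edges$regulator == "C" & fixed$edges$target == "A"))
  expect_silent(x <- simulate_expression(fixed, 10, seed = 1))
  expect_identical(dim(x), c(3L, 10L))
})

test_that("topology files round-trip", {
  topo <- make_seed_topology(30, seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_topology(topo, path)
  back <- read_topology(path)
  expect_identical(back$edges$regulator, topo$edges$regulator)
  expect_identical(back$edges$sign, topo$edges$sign)
  expect_equal(back$edges$K, topo$edges$K, tolerance = 1e-6)
  # the edge-list file cannot carry genes with no edges, so compare sources
  # over the genes the file can represent
  expect_setequal(back$source_genes, intersect(topo$source_genes, back$genes))
})

test_that("benchmark results are averaged correctly and bounded", {
  b <- run_benchmark(group_a_sizes = c(30, 50), group_b_sizes = c(100),
                     k = 25, methods = c("pearson", "spearman"),
                     replicates = 2, seed = 77)
  r <- b$results
  expect_true(all(r$auc >= 0 & r$auc <= 1))
  expect_equal(nrow(r), 3 * 2 * 2)  # sizes x methods x replicates
  s <- summary(b)
  # group means recomputed from per-replicate AUCs
  sp_a <- mean(r$auc[r$method == "spearman" & r$group == "A"])
  expect_equal(s$mean_auc_A[s$method == "spearman"], sp_a)
})

test_that("near-noiseless large compendia are highly recoverable by spearman-CLR", {
  topo <- sample_subnetwork_topology(make_seed_topology(200, seed = 13),
                                     50, seed = 13)
  x <- simulate_expression(topo, 1000, bio_noise = 0.01, exp_noise = 0.01,
                           seed = 14)
  a <- abs(association_matrix(x, "spearman"))
  auc <- roc_auc(pair_scores(clr_transform(a)), topology_pairs(topo))
  expect_gt(auc, 0.8)
})
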