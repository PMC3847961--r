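test_that("pair_count reproduces the closed form at toy and genome scale", {
  expect_equal(pair_count(2), 1)
  expect_equal(pair_count(50), 1225)
  # genome-scale counts stay exact in doubles; cross-checked against R's
  # binomial-coefficient evaluation
  expect_equal(pair_count(36398), choose(36398, 2))
  expect_equal(pair_count(36398), 662389003)
  expect_equal(pair_count(35000, ordered = TRUE), 35000 * 34999)
  expect_error(pair_count(1), ">= 2")
})

test_that("partition plan covers every pair exactly once for all n <= 40, p <= n", {
  for (n in 2:40) {
    all_pairs <- apply(combn(n, 2), 2, paste, collapse = ":")
    for (p in unique(c(1, 2, 3, n %/% 2, n))) {
      if (p < 1 || p > n) next
      plan <- partition_rows(n, p)
      got <- plan_pairs(plan)
      expect_identical(sort(got), sort(all_pairs),
                       info = sprintf("n=%d p=%d", n, p))
      expect_lte(diff(range(lengths(plan$owned))), 1)  # balanced rows
      per_worker <- table(plan$worker_of_row)
      expect_lte(max(per_worker) - min(per_worker), 1)
    }
  }
})

test_that("partition plan matches the documented small cases", {
  p3 <- partition_rows(3, 1)
  expect_identical(p3$owned, list(2L, 3L, 1L))  # circular d = 1
  p4 <- partition_rows(4, 2)
  expect_identical(lengths(p4$owned), c(2L, 2L, 1L, 1L))
  expect_error(partition_rows(4, 5), "must not exceed")
})

test_that("clr_transform matches the literal two-pass definition", {
  set.seed(333)
  for (i in 1:20) {
    a <- association_matrix(rand_expr(8, 10), "pearson")
    z <- clr_transform(a)
    expect_equal(unclass(z), oracle_clr(unclass(a)), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(z >= 0))
    expect_true(all(z == t(z)))
  }
})

test_that("clr_transform degenerate and error cases", {
  # flat background: all off-diagonal scores equal -> sigma = 0 -> z == 0
  a <- matrix(0.4, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(a) <- 0
  expect_true(all(clr_transform(a) == 0))
  # one elevated pair dominates
  a[1, 2] <- a[2, 1] <- 0.95
  z <- clr_transform(a)
  expect_setequal(which(z == max(z)),
                  which((row(z) == 1 & col(z) == 2) |
                        (row(z) == 2 & col(z) == 1)))
  bad <- a
  bad[1, 3] <- 99
  expect_error(clr_transform(bad), "not symmetric")
})

test_that("clr_transform is permutation-equivariant", {
  set.seed(444)
  a <- association_matrix(rand_expr(7, 9), "spearman")
  perm <- sample(7)
  expect_equal(unclass(clr_transform(a[perm, perm])),
               unclass(clr_transform(a))[perm, perm], ignore_attr = TRUE)
})

test_that("standardize_scores yields mean 0 / sd 1 over pairs and handles constants", {
  set.seed(555)
  z <- clr_transform(association_matrix(rand_expr(6, 12), "pearson"))
  s <- standardize_scores(z)
  v <- s[upper.tri(s)]
  expect_equal(mean(v), 0, tolerance = 1e-9)
  expect_equal(sd(v), 1, tolerance = 1e-9)
  expect_equal(unclass(s), oracle_standardize(unclass(z)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # documented choice: constant input standardizes to all zeros
  flat <- matrix(1, 4, 4)
  diag(flat) <- 0
  expect_true(all(standardize_scores(clr_transform(flat * 0.3)) == 0))
  expect_error(standardize_scores(matrix(0, 2, 2)), "at least 2 gene pairs")
})

test_that("threshold_network filters by definition with canonical edge order", {
  set.seed(666)
  s <- standardize_scores(clr_transform(
    association_matrix(rand_expr(20, 10, prefix = "G"), "pearson")))
  el <- threshold_network(s, 1.0)
  # filter-by-definition oracle
  idx <- which(upper.tri(s) & s >= 1.0, arr.ind = TRUE)
  expect_equal(nrow(el), nrow(idx))
  expect_setequal(paste(el$from, el$to),
                  paste(rownames(s)[pmin(idx[, 1], idx[, 2])],
                        rownames(s)[pmax(idx[, 1], idx[, 2])]))
  expect_true(all(el$score >= 1.0))
  expect_true(all(el$from < el$to))
  expect_false(is.unsorted(el$from))
  # extremes
  expect_equal(nrow(threshold_network(s, max(s) + 1)), 0)
  expect_equal(nrow(threshold_network(s, min(s) - 1)), pair_count(20))
  # raising the cutoff never adds edges
  cuts <- seq(-2, 3, by = 0.5)
  sizes <- vapply(cuts, function(ct) nrow(threshold_network(s, ct)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("infer_network equals the sequential stage composition", {
  set.seed(777)
  topo <- make_seed_topology(30, seed = 5)
  m <- simulate_expression(topo, 25, seed = 6)
  el <- infer_network(m, "spearman", cutoff = 1.5)
  a <- oracle_association_matrix(m, clrnet:::assoc_fun("spearman"))
  ref <- threshold_network(oracle_standardize(oracle_clr(abs(a))), 1.5)
  expect_equal(as.data.frame(el)$score, as.data.frame(ref)$score,
               tolerance = 1e-12)
  expect_identical(el$from, ref$from)
  expect_identical(el$to, ref$to)
})

test_that("pipeline output is identical for any worker count", {
  set.seed(888)
  m <- rand_expr(50, 20)
  base <- infer_network(m, "spearman", cutoff = 2, workers = 1)
  for (w in c(2, 4)) {
    expect_identical(as.data.frame(infer_network(m, "spearman", cutoff = 2,
                                                 workers = w)),
                     as.data.frame(base), info = paste("workers", w))
  }
})

test_that("duplicate expression profiles reach the top association score", {
  set.seed(999)
  m <- rand_expr(6, 10)
  m[2, ] <- m[1, ]  # identical profiles
  a <- association_matrix(m, "spearman")
  expect_equal(a[1, 2], 1)
  expect_equal(max(a), 1)
})

test_that("edge lists round-trip through the Cytoscape text format", {
  set.seed(123)
  s <- standardize_scores(clr_transform(
    association_matrix(rand_expr(8, 10), "pearson")))
  el <- threshold_network(s, 0.5)
  path <- withr::local_tempfile(fileext = ".txt")
  write_edge_list(el, path, header = c("demo", "cutoff=0.5"))
  back <- read_edge_list(path)
  expect_identical(back$from, el$from)
  expect_identical(back$to, el$to)
  expect_equal(back$score, el$score, tolerance = 1e-12)
  expect_true(startsWith(readLines(path, n = 1), "# "))
  # sif variant carries a constant interaction label
  write_edge_list(el, path, format = "sif", label = "assoc")
  sif <- read.table(path, sep = "\t")
  expect_true(all(sif$V2 == "assoc"))
})
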