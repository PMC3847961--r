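# Independent reference implementations ("oracles") used across the suite.
# These are deliberately naive: direct formulas, double loops, exhaustive
# enumeration. They share no code with the package internals they check.

rand_expr <- function(n, m, prefix = "g") {
  matrix(rnorm(n * m), n, m,
         dimnames = list(paste0(prefix, sprintf("%02d", seq_len(n))),
                         paste0("s", seq_len(m))))
}

# naive single-threaded double loop over all unordered pairs
oracle_association_matrix <- function(m, f) {
  n <- nrow(m)
  s <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s[i, j] <- s[j, i] <- f(m[i, ], m[j, ])
    }
  }
  s
}

# CLR by the definition: per-row background mean/sd, rectified z, quadrature
oracle_clr <- function(a) {
  n <- nrow(a)
  u <- matrix(0, n, n)
  for (i in seq_len(n)) {
    bg <- a[i, -i]
    mu <- mean(bg)
    sg <- sd(bg)
    for (j in seq_len(n)) {
      if (j != i && sg > 0) u[i, j] <- max(0, (a[i, j] - mu) / sg)
    }
  }
  z <- matrix(0, n, n, dimnames = dimnames(a))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) z[i, j] <- sqrt(u[i, j]^2 + u[j, i]^2)
    }
  }
  z
}

oracle_standardize <- function(z) {
  v <- z[upper.tri(z)]
  out <- (z - mean(v)) / sd(v)
  diag(out) <- 0
  out
}

# slope-median score from first principles
oracle_theil_sen <- function(x, y) {
  xs <- (x - mean(x)) / sd(x)
  ys <- (y - mean(y)) / sd(y)
  med_slopes <- function(u, v) {
    s <- c()
    m <- length(u)
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        if (u[j] != u[i]) s <- c(s, (v[j] - v[i]) / (u[j] - u[i]))
      }
    }
    median(s)
  }
  byx <- med_slopes(xs, ys)
  bxy <- med_slopes(ys, xs)
  if (byx * bxy <= 0) 0 else sign(byx) * min(1, sqrt(byx * bxy))
}

# weighted product-moment correlation of rank vectors, expanded longhand
oracle_weighted_rank <- function(x, y) {
  m <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  wgt <- m:1
  at_rank <- function(r) (wgt[floor(r)] + wgt[ceiling(r)]) / 2
  w <- (at_rank(rx) + at_rank(ry)) / 2
  w <- w / sum(w)
  mx <- sum(w * rx)
  my <- sum(w * ry)
  num <- sum(w * (rx - mx) * (ry - my))
  num / sqrt(sum(w * (rx - mx)^2) * sum(w * (ry - my)^2))
}

# exhaustive max over ALL 2x2 grid placements, normalized by log2(2) = 1;
# for m = 12 and alpha = 0.6 the grid budget admits only 2x2 grids, so this
# enumerates the complete MIC search space
oracle_mic_m12 <- function(x, y) {
  m <- length(x)
  xl2 <- function(p) ifelse(p > 0, p * log2(p), 0)
  best <- 0
  xs <- sort(unique(x))
  ys <- sort(unique(y))
  for (cx in xs[-length(xs)]) {
    for (cy in ys[-length(ys)]) {
      tab <- table(factor(x <= cx, c(FALSE, TRUE)),
                   factor(y <= cy, c(FALSE, TRUE))) / m
      i_val <- sum(xl2(tab)) - sum(xl2(rowSums(tab))) - sum(xl2(colSums(tab)))
      best <- max(best, i_val)
    }
  }
  best
}

# plug-in MI from an explicitly built joint table
oracle_mi <- function(x, y, bins) {
  cut_idx <- function(v) {
    if (min(v) == max(v)) return(rep(1L, length(v)))
    i <- floor((v - min(v)) / (max(v) - min(v)) * bins) + 1L
    pmin(i, bins)
  }
  ix <- cut_idx(x)
  iy <- cut_idx(y)
  total <- 0
  for (a in 1:bins) {
    for (b in 1:bins) {
      pab <- mean(ix == a & iy == b)
      pa <- mean(ix == a)
      pb <- mean(iy == b)
      if (pab > 0) total <- total + pab * log2(pab / (pa * pb))
    }
  }
  total
}

# all unordered pairs of a plan, as a canonical "i:j" character set
plan_pairs <- function(plan) {
  out <- character(0)
  for (i in seq_len(plan$n)) {
    js <- plan$owned[[i]]
    if (length(js) > 0) {
      out <- c(out, paste(pmin(i, js), pmax(i, js), sep = ":"))
    }
  }
  out
}

# trapezoid area under the threshold-sweep ROC staircase
oracle_auc_trapezoid <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
}

# tiny deterministic toy networks -------------------------------------------

clique_edges <- function(ids, score = 1) {
  cmb <- t(combn(ids, 2))
  data.frame(from = pmin(cmb[, 1], cmb[, 2]),
             to = pmax(cmb[, 1], cmb[, 2]),
             score = score, stringsAsFactors = FALSE)
}

as_edge_list <- function(df) {
  ord <- order(df$from, df$to)
  structure(df[ord, , drop = FALSE], class = c("edge_list", "data.frame"))
}

# two cliques joined by a single bridge edge
two_clique_net <- function(size1 = 10, size2 = 10) {
  c1 <- paste0("a", sprintf("%02d", seq_len(size1)))
  c2 <- paste0("b", sprintf("%02d", seq_len(size2)))
  as_edge_list(rbind(clique_edges(c1), clique_edges(c2),
                     data.frame(from = c1[size1], to = c2[1], score = 1,
                                stringsAsFactors = FALSE)))
}
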