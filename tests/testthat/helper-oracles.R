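# Independent reference implementations used to cross-check the package.
# Each is written directly from the defining formula/algorithm, not by
# calling the code path it validates.

# Periodic natural cubic spline from the tridiagonal second-derivative
# system (cyclic boundary: value, slope and curvature match across the seam).
oracle_periodic_spline <- function(x, y, xout) {
  n <- length(x)
  period <- 24
  h <- diff(c(x, x[1] + period))          # interval widths, cyclic
  # solve for second derivatives M_i with cyclic tridiagonal system:
  # (h[i-1]/6) M_{i-1} + ((h[i-1]+h[i])/3) M_i + (h[i]/6) M_{i+1} = rhs_i
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  yy <- c(y, y[1])
  for (i in seq_len(n)) {
    im1 <- if (i == 1) n else i - 1
    ip1 <- if (i == n) 1 else i + 1
    A[i, im1] <- A[i, im1] + h[im1] / 6
    A[i, i] <- A[i, i] + (h[im1] + h[i]) / 3
    A[i, ip1] <- A[i, ip1] + h[i] / 6
    d1 <- (yy[i + 1] - y[i]) / h[i]
    d0 <- (y[i] - y[im1]) / h[im1]
    rhs[i] <- d1 - d0
  }
  M <- solve(A, rhs)
  MM <- c(M, M[1])
  xx <- c(x, x[1] + period)
  vapply(xout, function(t) {
    t <- ((t - x[1]) %% period) + x[1]
    i <- findInterval(t, xx, rightmost.closed = TRUE)
    i <- min(max(i, 1L), n)
    hi <- h[i]
    a <- (xx[i + 1] - t) / hi
    b <- (t - xx[i]) / hi
    a * yy[i] + b * yy[i + 1] +
      ((a^3 - a) * MM[i] + (b^3 - b) * MM[i + 1]) * hi^2 / 6
  }, numeric(1))
}

# ranks with average ties, then Pearson
oracle_spearman <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# exhaustive circular-lag search over the 48 candidate lags (0.5-h grid),
# from the two raw 12-point profiles; same tie-break (|lag| then positive)
oracle_time_shift <- function(a_vals, b_vals, grid_step = 0.5) {
  tt <- seq(2, 24, by = 2)
  z <- function(v) (v - mean(v)) / sd(v)
  fine <- seq(grid_step, 24, by = grid_step)
  av <- oracle_periodic_spline(tt, z(a_vals), fine)
  bv <- oracle_periodic_spline(tt, z(b_vals), fine)
  n <- length(fine)
  ks <- seq.int(-(n / 2 - 1), n / 2)
  cors <- vapply(ks, function(k)
    cor(av, bv[((seq_len(n) - 1 + k) %% n) + 1]), numeric(1))
  lags <- ks * grid_step
  ord <- order(abs(lags), -sign(lags))
  best <- ord[which.max(cors[ord])]
  list(shift = lags[best], peak = cors[best])
}

# Welch t-test from the defining formulas
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# BH step-up directly from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# naive O(n^3) average-linkage agglomeration on a distance matrix;
# returns merge heights and the partition after each merge
oracle_average_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  tied <- FALSE   # a tie at any step makes the merge order arbitrary
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    dists <- c()
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      d <- mean(D[clusters[[i]], clusters[[j]]])
      dists <- c(dists, d)
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    if (sum(abs(dists - bestd) < 1e-12) > 1) tied <- TRUE
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, bestd)
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions, tied = tied)
}

# dense reference MCL, literal loop-based translation of the procedure
oracle_mcl <- function(edges, nodes, inflation = 5, cutoff = 1e-5,
                       prune = 1e-8, tol = 1e-6, max_iter = 100) {
  n <- length(nodes)
  M <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    if (edges$evalue[r] > cutoff) next
    i <- match(edges$gene_a[r], nodes); j <- match(edges$gene_b[r], nodes)
    w <- -log10(max(edges$evalue[r], 1e-180))
    M[i, j] <- w; M[j, i] <- w
  }
  for (j in seq_len(n)) {
    mx <- max(M[, j])
    M[j, j] <- if (mx > 0) mx else 1
  }
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(max_iter)) {
    M2 <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      M2[i, j] <- sum(M[i, ] * M[, j])
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    for (j in seq_len(n)) M2[, j] <- M2[, j] / sum(M2[, j])
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  adj <- (M > 0) | t(M > 0)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      if (comp[v]) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  split(nodes, comp)
}

# all clades of a rooted phylo as tip-label sets, via ape
oracle_all_clades <- function(phy) {
  ntip <- length(phy$tip.label)
  lapply((ntip + 1):(ntip + phy$Nnode), function(nd) {
    tips <- ape::extract.clade(phy, nd)$tip.label
    list(node = nd, tips = sort(tips))
  })
}

# exhaustive minimum-change count over all internal labelings
oracle_parsimony_score <- function(phy, states) {
  ntip <- length(phy$tip.label)
  states <- states[phy$tip.label]
  obs <- unique(states[!is.na(states) & !states %in% c("-", "X")])
  if (!length(obs)) return(0L)
  nint <- phy$Nnode
  combos <- expand.grid(rep(list(obs), nint), stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    lab <- c(states, unlist(combos[r, ], use.names = FALSE))
    chg <- 0L
    for (e in seq_len(nrow(phy$edge))) {
      p <- lab[phy$edge[e, 1]]; ch <- lab[phy$edge[e, 2]]
      if (is.na(ch) || ch %in% c("-", "X")) next   # missing leaf: free
      if (ch != p) chg <- chg + 1L
    }
    best <- min(best, chg)
  }
  best
}

# F statistic of polynomial-vs-flat nested regression from RSS formulas
oracle_flatline_F <- function(t, y, degree = 3) {
  X1 <- cbind(1, poly(t, degree))
  b1 <- solve(crossprod(X1), crossprod(X1, y))
  rss1 <- sum((y - X1 %*% b1)^2)
  rss0 <- sum((y - mean(y))^2)
  df1 <- length(y) - ncol(X1)
  Fst <- ((rss0 - rss1) / degree) / (rss1 / df1)
  list(F = Fst, p = pf(Fst, degree, df1, lower.tail = FALSE))
}
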