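test_that("diel_spearman matches a rank-then-Pearson oracle and its identities", {
  a <- sinusoid_profile("a", phase = 0)
  expect_equal(diel_spearman(a, a), 1)
  tt <- canonical_grid()
  inc <- diel_profile("i", "Kf", tt, 1:12)
  dec <- diel_profile("d", "Ac", tt, 12:1)
  expect_equal(diel_spearman(inc, dec), -1)

  set.seed(21)
  for (i in 1:120) {
    x <- sample(1:8, 12, replace = TRUE)   # ties included
    y <- runif(12, 0, 10)
    pa <- diel_profile("x", "Kf", tt, x)
    pb <- diel_profile("y", "Ac", tt, y)
    expect_equal(diel_spearman(pa, pb), oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("diel_spearman is invariant under strictly monotone transforms", {
  set.seed(31)
  tt <- canonical_grid()
  for (i in 1:25) {
    x <- runif(12, 0.1, 10); y <- runif(12, 0.1, 10)
    r0 <- diel_spearman(diel_profile("x", "Kf", tt, x),
                        diel_profile("y", "Ac", tt, y))
    r1 <- diel_spearman(diel_profile("x", "Kf", tt, exp(x)),
                        diel_profile("y", "Ac", tt, sqrt(y)))
    expect_equal(r0, r1, tolerance = 1e-12)
  }
})

test_that("time-shift estimation is exact on rotated noiseless sinusoids", {
  base <- sinusoid_profile("a", phase = 3)
  s0 <- estimate_time_shift(base, base)
  expect_equal(s0$shift, 0)
  expect_equal(s0$peak_correlation, 1, tolerance = 1e-9)

  lag6 <- estimate_time_shift(base, sinusoid_profile("b", phase = 9))
  expect_equal(lag6$shift, 6)

  for (d in seq(0.5, 12, by = 0.5)) {
    est <- estimate_time_shift(base, sinusoid_profile("b", phase = 3 + d))
    expect_equal(est$shift, d, info = paste("delta =", d))
  }
})

test_that("time-shift estimation matches the exhaustive-lag oracle on noisy pairs", {
  set.seed(42)
  tt <- canonical_grid()
  for (i in 1:100) {
    av <- 5 + 3 * cos(2 * pi * (tt - runif(1, 0, 24)) / 24) + rnorm(12, 0, 0.5)
    bv <- 5 + 3 * cos(2 * pi * (tt - runif(1, 0, 24)) / 24) + rnorm(12, 0, 0.5)
    est <- estimate_time_shift(diel_profile("a", "Kf", tt, pmax(av, 0)),
                               diel_profile("b", "Ac", tt, pmax(bv, 0)))
    orc <- oracle_time_shift(pmax(av, 0), pmax(bv, 0))
    expect_equal(est$shift, orc$shift)
    expect_equal(est$peak_correlation, orc$peak, tolerance = 1e-8)
  }
})

test_that("time-shift is antisymmetric and peak correlation dominates zero lag", {
  set.seed(7)
  tt <- canonical_grid()
  n_checked <- 0
  for (i in 1:200) {
    av <- pmax(4 + 2.5 * cos(2 * pi * (tt - runif(1, 0, 24)) / 24) +
                 rnorm(12, 0, 0.4), 0)
    bv <- pmax(4 + 2.5 * cos(2 * pi * (tt - runif(1, 0, 24)) / 24) +
                 rnorm(12, 0, 0.4), 0)
    a <- diel_profile("a", "Kf", tt, av); b <- diel_profile("b", "Ac", tt, bv)
    f <- estimate_time_shift(a, b); r <- estimate_time_shift(b, a)
    expect_true(f$peak_correlation >= f$cor_at_zero - 1e-12)
    # map -shift(b,a) into (-12, 12] before comparing
    back <- ((-r$shift + 12) %% 24) - 12
    if (back == -12) back <- 12
    expect_equal(f$shift, back, info = paste("pair", i))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 200)
})

test_that("expression filter applies a strict threshold at the stated counts", {
  tt <- canonical_grid()
  mk <- function(id, v) diel_profile(id, "Kf", tt, v)
  m <- diel_matrix("Kf", list(
    mk("all12", rep(0.02, 12)),
    mk("only5", c(rep(0.02, 5), rep(0, 7))),
    mk("boundary", rep(0.01, 12)),
    mk("exactly6", c(rep(0.02, 6), rep(0.001, 6)))))
  keep <- expression_filter(m, min_fpkm = 0.01, min_timepoints = 6)
  expect_setequal(keep, c("all12", "exactly6"))
})

test_that("window tests separate planted contrasts and match the Welch formula", {
  tt <- canonical_grid()
  set.seed(3)
  vals <- matrix(1, 12, 3) + matrix(rnorm(36, 0, 0.01), 12, 3)
  vals[tt %in% c(16, 18, 20), ] <- 10 + rnorm(9, 0, 0.01)
  we <- window_enrichment_test(diel_profile("g", "Kf", tt, abs(vals)))
  md <- we$contrasts[we$contrasts$contrast == "midday_vs_midnight", ]
  expect_lt(md$p, 0.01)
  expect_identical(md$larger_window, "midnight")

  # identical distributions: no enrichment signal
  set.seed(4)
  flat <- window_enrichment_test(
    diel_profile("g", "Kf", tt, matrix(abs(rnorm(36, 5, 0.5)), 12, 3)))
  q <- assign_enrichment(list(flat), fdr = 0.01)
  expect_true(all(is.na(q$enriched_window)))

  # Welch oracle on the pooled 9 vs 9 observations
  prof <- diel_profile("g", "Kf", tt, matrix(abs(rnorm(36, 3, 1)), 12, 3))
  we2 <- window_enrichment_test(prof)
  x <- as.vector(prof$values[match(c(4, 6, 8), tt), ])
  y <- as.vector(prof$values[match(c(16, 18, 20), tt), ])
  orc <- oracle_welch(x, y)
  expect_equal(we2$contrasts$p[we2$contrasts$contrast == "midday_vs_midnight"],
               orc$p, tolerance = 1e-12)
})

test_that("bh_fdr equals the step-up definition and preserves order", {
  expect_equal(bh_fdr(0.04), 0.04)
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(8)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_equal(order(q[order(p)]), seq_along(p))  # monotone in rank
  }
})

test_that("flatline test handles degenerate input and matches the RSS formula", {
  tt <- canonical_grid()
  const <- diel_profile("g", "Kf", tt, matrix(2, 12, 3))
  expect_equal(flatline_test(const), 1)

  strong <- sinusoid_profile("g", amplitude = 4, noise_sd = 0.01,
                             n_reps = 3, seed = 9)
  expect_lt(flatline_test(strong), 1e-6)

  set.seed(10)
  prof <- diel_profile("g", "Kf", tt, matrix(abs(rnorm(36, 4, 1)), 12, 3))
  t <- rep(tt, times = 3)
  y <- log2(as.vector(prof$values) + 1)
  expect_equal(flatline_test(prof), oracle_flatline_F(t, y)$p,
               tolerance = 1e-10)
})

test_that("profile clustering separates antiphase groups and matches naive linkage", {
  set.seed(12)
  day <- lapply(1:4, function(i)
    sinusoid_profile(sprintf("day%d", i), phase = 6, noise_sd = 0.1, seed = i))
  night <- lapply(1:4, function(i)
    sinusoid_profile(sprintf("night%d", i), phase = 18, noise_sd = 0.1,
                     seed = 100 + i))
  lab <- cluster_profiles(c(day, night), k = 2)
  expect_length(unique(lab[paste0("day", 1:4)]), 1)
  expect_length(unique(lab[paste0("night", 1:4)]), 1)
  expect_false(lab[["day1"]] == lab[["night1"]])

  singles <- cluster_profiles(c(day, night), k = 8)
  expect_length(unique(singles), 8)

  # merge heights/partitions equal the naive O(n^3) agglomeration
  set.seed(13)
  profs <- lapply(1:5, function(i) random_profile(sprintf("p%d", i), seed = 40 + i))
  lab2 <- cluster_profiles(profs, k = 2)
  hc <- attr(lab2, "hclust")
  mm <- sapply(profs[order(sapply(profs, `[[`, "gene_id"))], replicate_mean)
  D <- as.matrix(1 - cor(mm, method = "spearman"))
  orc <- oracle_average_linkage(D)
  expect_equal(hc$height, orc$heights, tolerance = 1e-12)
  canon <- function(p) sort(vapply(p, function(v)
    paste(sort(v), collapse = ","), character(1)))
  for (step in seq_along(orc$heights)) {
    got <- unname(split(seq_len(5), cutree(hc, k = 5 - step)))
    expect_equal(canon(got), canon(orc$partitions[[step]]))
  }
})

test_that("hierarchical clustering oracle agreement holds over random instances", {
  set.seed(14)
  n_checked <- 0
  for (i in 1:150) {
    n <- sample(4:7, 1)
    profs <- lapply(seq_len(n), function(j)
      random_profile(sprintf("p%d", j), seed = 1000 * i + j))
    mm <- sapply(profs, replicate_mean)
    D <- as.matrix(1 - cor(mm, method = "spearman"))
    # rank-based distances can tie exactly; merge order is then arbitrary
    # and implementation-specific, so tied instances are not comparable
    orc <- oracle_average_linkage(D)
    if (orc$tied) next
    hc <- attr(cluster_profiles(profs, k = 1), "hclust")
    expect_equal(hc$height, orc$heights, tolerance = 1e-10)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 100)
})
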