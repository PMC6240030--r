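test_that("Mann-Whitney U reports the larger U with complete separation giving n1*n2", {
  set.seed(1)
  a <- runif(8, 0, 1); b <- runif(9, 2, 3)
  expect_equal(mann_whitney_u(a, b)$statistic, 72)
  expect_equal(mann_whitney_u(b, a)$statistic, 72)   # order-invariant
  expect_equal(mann_whitney_u(a, b)$df, 15)
  r <- mann_whitney_u(c(1, 2), c(3))
  expect_equal(r$statistic, 2)
  expect_equal(mann_whitney_u(c(5, 5, 5), c(5, 5))$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("exact p values agree with full enumeration for small samples", {
  set.seed(42)
  for (i in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- runif(n1); b <- runif(n2) + runif(1, -0.5, 0.5)
    r <- mann_whitney_u(a, b)
    e <- enum_mw(a, b)
    expect_equal(r$p_value, e$p, tolerance = 1e-12)
    expect_equal(r$statistic, max(e$u1, e$u2))
  }
})

test_that("U(a,b) + U(b,a) = n1*n2 also under ties", {
  set.seed(7)
  for (i in 1:40) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    a <- sample(1:4, n1, replace = TRUE)
    b <- sample(1:4, n2, replace = TRUE)
    r <- rank(c(a, b))
    u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    expect_equal(u1 + (n1 * n2 - u1), n1 * n2)
    expect_lte(mann_whitney_u(a, b)$statistic, n1 * n2)
    expect_gte(mann_whitney_u(a, b)$statistic, n1 * n2 / 2)
  }
})

test_that("rank tests are invariant under strictly increasing transforms", {
  set.seed(11)
  a <- rnorm(8); b <- rnorm(9, 1)
  f <- function(x) exp(x) + x^3 / 50
  expect_equal(mann_whitney_u(a, b)$statistic, mann_whitney_u(f(a), f(b))$statistic)
  expect_equal(mann_whitney_u(a, b)$p_value, mann_whitney_u(f(a), f(b))$p_value)
  g <- list(rnorm(6), rnorm(7, 0.5), rnorm(5, 1))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, f))$statistic)
})

test_that("Kruskal-Wallis has df = k - 1 and handles the degenerate case", {
  set.seed(2)
  g4 <- lapply(1:4, function(i) rnorm(8, i / 2))
  k4 <- kruskal_wallis(g4)
  expect_equal(k4$df, 3)
  g5 <- lapply(1:5, function(i) rnorm(8, i / 2))
  expect_equal(kruskal_wallis(g5)$df, 4)
  expect_equal(kruskal_wallis(list(rep(1, 5), rep(1, 6)))$statistic, 0)
  expect_equal(kruskal_wallis(list(rep(1, 5), rep(1, 6)))$p_value, 1)
  # H against the direct rank formula on a small dataset without ties
  g <- list(c(1, 5, 8), c(2, 9, 11), c(3, 4, 12))
  r <- rank(unlist(g)); n <- 9
  h_manual <- 12 / (n * (n + 1)) *
    sum(3 * (vapply(split(r, rep(1:3, each = 3)), mean, 0) - (n + 1) / 2)^2)
  expect_equal(kruskal_wallis(g)$statistic, h_manual, tolerance = 1e-12)
})

test_that("Dunn z matches direct mean-rank arithmetic and Bonferroni caps at 1", {
  g <- list(a = c(1.1, 2.3, 3.1), b = c(2.2, 4.5, 6.1), c = c(5.0, 7.2, 8.4))
  dn <- dunn_bonferroni(g)
  expect_equal(nrow(dn), 3)
  r <- rank(unlist(g)); N <- 9
  mr <- tapply(r, rep(1:3, each = 3), mean)
  z_ab <- (mr[1] - mr[2]) / sqrt(N * (N + 1) / 12 * (1 / 3 + 1 / 3))
  expect_equal(dn$z[dn$group1 == "a" & dn$group2 == "b"], unname(z_ab))
  expect_true(all(dn$p_adjusted >= dn$p_unadjusted - 1e-15))
  expect_true(all(dn$p_adjusted <= 1))

  # identical groups inside a 3-group family: zero rank difference
  g2 <- list(x = c(1, 2, 3), y = c(1, 2, 3), z = c(10, 11, 12))
  dn2 <- dunn_bonferroni(g2)
  expect_equal(dn2$z[dn2$group1 == "x" & dn2$group2 == "y"], 0)
  expect_equal(dn2$p_adjusted[dn2$group1 == "x" & dn2$group2 == "y"], 1)

  expect_equal(nrow(dunn_bonferroni(lapply(1:4, function(i) rnorm(5)))), 6)
  expect_equal(nrow(dunn_bonferroni(lapply(1:5, function(i) rnorm(5)))), 10)
  expect_error(dunn_bonferroni(list(rnorm(5))), "at least 2")
})

test_that("Kruskal-Wallis at k = 2 is monotone in the Mann-Whitney statistic", {
  set.seed(13)
  res <- t(replicate(100, {
    a <- rnorm(sample(4:9, 1)); b <- rnorm(sample(4:9, 1), runif(1, 0, 2))
    n1 <- length(a); n2 <- length(b)
    u <- mann_whitney_u(a, b)$statistic
    z <- abs(u - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    c(z = z, h = kruskal_wallis(list(a, b))$statistic)
  }))
  expect_equal(order(res[, "z"]), order(res[, "h"]))
})

test_that("regression slope t-test follows OLS identities", {
  r <- linear_regression_t(1:5, 2 * (1:5) + 1)
  expect_equal(attr(r, "slope"), 2)
  expect_equal(r$p_value, 0)
  expect_true(is.infinite(r$statistic))
  expect_error(linear_regression_t(rep(1, 5), rnorm(5)), "constant")

  set.seed(3)
  x <- rnorm(36); y <- 0.4 * x + rnorm(36)
  r2 <- linear_regression_t(x, y)
  expect_equal(r2$df, 34)
  rr <- cor(x, y)
  expect_equal(r2$statistic, rr * sqrt(34) / sqrt(1 - rr^2), tolerance = 1e-10)
})

test_that("paired t handles the shift and degenerate cases", {
  set.seed(5)
  a <- rnorm(33); b <- rnorm(33)
  r <- paired_t(a, b)
  expect_equal(r$df, 32)
  rs <- paired_t(a, a - 3)
  expect_true(is.infinite(rs$statistic))
  expect_equal(rs$p_value, 0)
  expect_error(paired_t(a, a), "degenerate")
})

test_that("the study battery emits the expected table structure", {
  set.seed(17)
  mk <- function(gt, gr, n, f_mu, on_mu) {
    data.frame(subject_id = paste0(gt, gr, seq_len(n)), genotype = gt,
               group = gr,
               csd_frequency = round(rnorm(n, f_mu, 1)),
               propagation_speed = rnorm(n, if (gt == "WT") 3.5 else 5, 0.2),
               epi_onset = rnorm(n, on_mu, 60),
               epi_class = "bouts",
               severity = rlnorm(n, 1, 0.3),
               xc_coeff_m1s1 = runif(n, 0.7, 0.9),
               xc_coeff_m1m1r = runif(n, 0.65, 0.85),
               xc_coeff_s1m1r = runif(n, 0.5, 0.7),
               xc_lag_m1s1 = rnorm(n, 0.008, 0.002),
               xc_lag_m1m1r = rnorm(n, 0.025, 0.004),
               xc_lag_s1m1r = rnorm(n, 0.017, 0.004),
               excluded = FALSE)
  }
  s <- rbind(mk("WT", "male", 8, 5, 2400), mk("WT", "female", 8, 5, 2400),
             mk("WT", "aged_male", 7, 5, 2400), mk("WT", "PM_female", 7, 5, 2400),
             mk("G301R", "male", 9, 12, 700), mk("G301R", "female", 9, 12, 600),
             mk("G301R", "aged_male", 9, 12, 700),
             mk("G301R", "PM_female", 9, 8, 1100))
  rep <- run_study(s)
  tb <- rep$tables
  mw_freq <- tb[tb$analysis == "CSD frequency" & tb$test == "Mann-Whitney U", ]
  expect_equal(nrow(mw_freq), 4)                       # four WT-vs-G301R rows
  expect_equal(nrow(rep$dunn$epi_onset), 10)           # 5-group onset post hoc
  expect_true(any(tb$analysis == "regression (G301R)"))
  expect_equal(sum(tb$analysis == "max cross-correlation"), 3)
  expect_equal(sum(tb$analysis == "cross-correlation |lag|"), 3)

  # empty cell: drop all G301R males -> that comparison is skipped with reason
  s2 <- s[!(s$genotype == "G301R" & s$group == "male"), ]
  rep2 <- run_study(s2)
  expect_true(any(grepl("male", names(rep2$skipped))))
})
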