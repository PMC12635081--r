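# association statistics

test_that("Welch t matches the textbook formulas and t.test", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  w <- welch_t_test(x, y)
  # independent long-hand evaluation
  se2 <- var(x) / 3 + var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(w$statistic, t_hand, tolerance = 1e-10)
  expect_equal(w$df, df_hand, tolerance = 1e-10)
  ref <- t.test(x, y)
  expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(w$p, ref$p.value, tolerance = 1e-10)
  # identical samples: t = 0, g = 0
  z <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$statistic, 0)
  expect_equal(z$effect, 0)
  expect_error(welch_t_test(c(1, 1), c(2, 2)), "zero variance")
  # group swap flips the sign only
  w2 <- welch_t_test(y, x)
  expect_equal(w2$statistic, -w$statistic)
  expect_equal(w2$p, w$p)
  expect_equal(w2$effect, -w$effect)
})

test_that("Hedges' g carries the small-sample correction", {
  set.seed(2)
  x <- rnorm(12, 1); y <- rnorm(15)
  w <- welch_t_test(x, y)
  sp <- sqrt((11 * var(x) + 14 * var(y)) / 25)
  d <- (mean(x) - mean(y)) / sp
  expect_equal(w$effect, d * (1 - 3 / (4 * 27 - 9)), tolerance = 1e-12)
  expect_lt(abs(w$effect), abs(d))
  expect_true(w$CI[1] < w$effect && w$effect < w$CI[2])
})

test_that("BH adjustment matches the step-up definition and p.adjust", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(33)
  for (rep in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_equal(order(adj[order(p)]), seq_along(p))  # monotone in ranks
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Mann-Whitney U: separation, symmetry and enumeration oracle", {
  expect_equal(mann_whitney_u(1:5, 6:10)$statistic, 0)
  m <- mann_whitney_u(c(1, 3, 5), c(2, 4, 6))
  expect_equal(m$statistic + mann_whitney_u(c(2, 4, 6), c(1, 3, 5))$statistic,
               9)  # U1 + U2 = n1 n2
  # exact p equals wilcox.test exact enumeration for n1 = n2 = 5, no ties
  set.seed(44)
  for (rep in 1:10) {
    x <- sample(1:100, 5); y <- sample(101:200, 5) - sample(0:99, 5)
    if (any(duplicated(c(x, y)))) next
    got <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  # normal approximation is sane for larger samples
  set.seed(45)
  big <- mann_whitney_u(rnorm(30), rnorm(30, 1))
  expect_lt(big$p, 0.01)
})

test_that("Kaplan-Meier and log-rank match the 4-subject hand computation", {
  # times 1,2,3,4; events 1,1,0,1; groups A,A,B,B
  km <- kaplan_meier_logrank(c(1, 2, 3, 4), c(1, 1, 0, 1), c("A", "A", "B", "B"))
  expect_equal(km$curves$A$surv, c(0.5, 0))       # events at t=1,2
  expect_equal(km$curves$B$surv, 0)               # censored at 3, event at 4
  # hand Mantel-Cox: event times 1,2,4
  # t=1: n=4, n_A=2, d=1, dA=1 -> E=0.5, V=1*(0.5)(0.5)(3)/3=0.25
  # t=2: n=3, n_A=1, d=1, dA=1 -> E=1/3, V=(1/3)(2/3)(2)/2=2/9
  # t=4: n=1, n_A=0, d=1, dA=0 -> E=0,  V=0
  O <- 2; E <- 0.5 + 1 / 3; V <- 0.25 + 2 / 9
  expect_equal(km$test$statistic, (O - E)^2 / V, tolerance = 1e-12)
  expect_equal(km$test$p, pchisq((O - E)^2 / V, 1, lower.tail = FALSE))
})

test_that("log-rank agrees with survival::survdiff across random fixtures", {
  skip_if_not_installed("survival")
  set.seed(55)
  for (rep in 1:15) {
    n <- 30
    t <- round(rexp(n, 0.3), 2)
    e <- rbinom(n, 1, 0.8)
    g <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(g)) < 2 || sum(e) == 0) next
    got <- kaplan_meier_logrank(t, e, g)
    ref <- survival::survdiff(survival::Surv(t, e) ~ g)
    expect_equal(got$test$statistic, unname(ref$chisq), tolerance = 1e-8)
  }
})

test_that("correlation tests: paper statistics, monotone data, tau-b counts", {
  # t recovered from r = -0.882 at df = 3 (printed t = -3.249)
  r <- -0.882
  t_from_r <- r * sqrt(3 / (1 - r^2))
  expect_lt(abs(t_from_r - (-3.249)), 0.01)
  # perfectly monotone data: Spearman rho = 1
  x <- c(1, 3, 7, 9, 15)
  sp <- correlation_test(x, exp(x), "spearman")
  expect_equal(sp$effect, 1)
  # pearson matches cor.test
  set.seed(66)
  a <- rnorm(20); b <- a + rnorm(20)
  got <- correlation_test(a, b, "pearson")
  ref <- cor.test(a, b)
  expect_equal(got$effect, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  # tau-b by exhaustive pair counting on the fixture
  kb <- correlation_test(c(1, 2, 3, 4), c(1, 3, 2, 4), "kendall_tau_b")
  # pairs: 5 concordant, 1 discordant, no ties -> tau = 4/6
  expect_equal(kb$effect, 4 / 6, tolerance = 1e-12)
  expect_equal(kb$p, cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4),
                              method = "kendall")$p.value, tolerance = 1e-10)
  # tie-corrected tau-b matches cor(method="kendall") coefficient
  xt <- c(1, 1, 2, 3, 3, 4); yt <- c(2, 1, 1, 3, 4, 4)
  kt <- correlation_test(xt, yt, "kendall_tau_b")
  expect_equal(kt$effect, cor(xt, yt, method = "kendall"), tolerance = 1e-12)
  expect_error(correlation_test(c(1, 1, 1), c(1, 2, 3), "pearson"), "constant")
})

test_that("slope_ci reproduces the printed regression intervals", {
  ci1 <- slope_ci(-0.00221, -3.249, 3)
  expect_equal(ci1$lower, -0.00437, tolerance = 0.01)
  expect_equal(ci1$upper, -0.000045, tolerance = 0.05)
  ci2 <- slope_ci(0.275, 3.337, 22)
  expect_equal(ci2$lower, 0.104, tolerance = 0.01)
  expect_equal(ci2$upper, 0.446, tolerance = 0.01)
  # large df tends to the normal half-width
  ci3 <- slope_ci(1, 2, 10000)
  expect_equal(ci3$upper - 1, 1.96 * 0.5, tolerance = 1e-3)
  expect_error(slope_ci(1, 0, 10), "nonzero")
})

test_that("slope_ci round-trips a regression's own interval", {
  set.seed(77)
  x <- rnorm(24); y <- 0.3 * x + rnorm(24)
  fit <- lm(y ~ x)
  sm <- summary(fit)
  beta <- coef(fit)[["x"]]; tval <- sm$coefficients["x", "t value"]
  ci <- slope_ci(beta, tval, fit$df.residual)
  expect_equal(unname(confint(fit)["x", ]), c(ci$lower, ci$upper),
               tolerance = 1e-10)
})

test_that("SNP and epistasis regressions match the normal equations", {
  set.seed(88)
  for (rep in 1:10) {
    n <- 40
    g1 <- sample(0:2, n, replace = TRUE)
    g2 <- sample(0:2, n, replace = TRUE)
    y <- rnorm(n) + 0.2 * g1
    X <- cbind(1, g1, g2, g1 * g2)
    if (qr(X)$rank < 4) next
    beta_ne <- solve(t(X) %*% X, t(X) %*% y)
    e <- epistasis_pair(g1, g2, y)
    expect_equal(e$effect, beta_ne[4], tolerance = 1e-10)
    s <- snp_association(g1, y)
    Xs <- cbind(1, g1)
    expect_equal(s$effect, solve(t(Xs) %*% Xs, t(Xs) %*% y)[2],
                 tolerance = 1e-10)
    ref <- summary(lm(y ~ g1 * g2))$coefficients
    expect_equal(e$statistic, ref["g1:g2", "t value"], tolerance = 1e-8)
    expect_equal(e$p, ref["g1:g2", "Pr(>|t|)"], tolerance = 1e-8)
  }
})

test_that("exact interaction structure is recovered; collinearity flagged", {
  g1 <- rep(0:2, each = 12)
  g2 <- rep(rep(0:2, each = 4), 3)
  y <- g1 * g2
  e <- epistasis_pair(g1, g2, y)
  expect_equal(e$effect, 1, tolerance = 1e-10)
  expect_lt(e$p, 1e-20)
  e2 <- epistasis_pair(rep(0L, 36), g2, y)   # constant dosage: rank-deficient
  expect_match(e2$flag, "collinear")
  expect_error(snp_association(c(0, 3, 1), c(1, 2, 3)), "dosages")
})
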