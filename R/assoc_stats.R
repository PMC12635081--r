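#' Welch's t-test with Hedges' g
#'
#' Two-sided Welch (unequal-variance) t-test with Satterthwaite degrees of
#' freedom, plus the bias-corrected standardized mean difference (Hedges' g)
#' and its large-sample 95% CI (g +/- 1.96 * SE_g; documented as
#' approximate).
#'
#' @param x,y numeric samples (both of size >= 2)
#' @return an `AssocResult` list: `statistic` (t), `df`, `p`, `effect`
#'   (Hedges' g), `SE` (of g), `CI`
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("both samples need >= 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) stop("zero variance in both samples")
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # Hedges' g: pooled-SD standardized difference with small-sample correction
  sp <- sqrt(((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2))
  d <- (mean(x) - mean(y)) / sp
  J <- 1 - 3 / (4 * (nx + ny) - 9)
  g <- J * d
  se_g <- sqrt((nx + ny) / (nx * ny) + g^2 / (2 * (nx + ny - 2)))
  assoc_result(statistic = t, df = df, p = p, effect = g, SE = se_g,
               CI = c(g - 1.96 * se_g, g + 1.96 * se_g), method = "welch_t")
}

assoc_result <- function(statistic, df = NA_real_, p, effect = NA_real_,
                         SE = NA_real_, CI = c(NA_real_, NA_real_),
                         method = "", p_adj = NA_real_, flag = NA_character_) {
  structure(list(statistic = statistic, df = df, p = p, p_adj = p_adj,
                 effect = effect, SE = SE, CI = CI, method = method,
                 flag = flag),
            class = "AssocResult")
}

#' @export
print.AssocResult <- function(x, ...) {
  cat(sprintf("AssocResult [%s]: statistic = %.4g, df = %.4g, p = %.4g",
              x$method, x$statistic, x$df, x$p))
  if (!is.na(x$effect)) cat(sprintf(", effect = %.4g (%.4g, %.4g)",
                                    x$effect, x$CI[1], x$CI[2]))
  if (!is.na(x$flag)) cat(" [", x$flag, "]")
  cat("\n")
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: p_(i) * m / i with monotonicity enforced from the
#' largest rank down, returned in the original input order.
#'
#' @param p vector of p-values in `[0, 1]`
#' @return adjusted p-values
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(pmin(adj, 1))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. U is reported for the first sample
#' (number of (x, y) pairs with x > y, ties counting one half). The p-value
#' is exact (by complete enumeration, tie-aware) when n1 + n2 <= 16, and
#' otherwise uses the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param x,y numeric samples
#' @return an `AssocResult` with `statistic` = U
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= 16) {
    # enumeration over all C(n1+n2, n1) labelings of the pooled sample
    pool <- c(x, y)
    combs <- utils::combn(n1 + n2, n1)
    rr <- rank(pool)
    us <- colSums(matrix(rr[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
  } else {
    mu <- n1 * n2 / 2
    tie <- table(r)
    sig2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(tie^3 - tie) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  assoc_result(statistic = U, p = min(1, p), method = "mann_whitney")
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival curves per group and the Mantel-Cox log-rank
#' chi-square (df = 1) comparing exactly two groups, computed from the
#' observed-vs-expected event sums across distinct event times (standard
#' aggregated handling of ties). With no events anywhere the test is
#' undefined and returned flagged rather than as a number.
#'
#' @param times follow-up times (>= 0)
#' @param events event indicator (1 = event, 0 = censored)
#' @param groups group label per observation (exactly 2 levels for the test)
#' @return list with `curves` (per-group data.frame: time, n_risk, n_event,
#'   surv) and `test` (an `AssocResult`)
#' @export
kaplan_meier_logrank <- function(times, events, groups) {
  if (any(times < 0)) stop("times must be >= 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  groups <- as.character(groups)
  lev <- unique(groups)
  if (any(table(factor(groups, levels = lev)) == 0) || length(lev) < 1)
    stop("every group needs at least one observation")
  km <- function(t, e) {
    ut <- sort(unique(t[e == 1]))
    n_risk <- vapply(ut, function(u) sum(t >= u), numeric(1))
    n_event <- vapply(ut, function(u) sum(t == u & e == 1), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    data.frame(time = ut, n_risk = n_risk, n_event = n_event, surv = surv)
  }
  curves <- lapply(lev, function(g) km(times[groups == g], events[groups == g]))
  names(curves) <- lev
  if (length(lev) != 2) stop("log-rank test requires exactly 2 groups")
  if (sum(events) == 0) {
    return(list(curves = curves,
                test = assoc_result(statistic = NA_real_, df = 1, p = NA_real_,
                                    method = "logrank",
                                    flag = "no events: test undefined")))
  }
  ut <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (u in ut) {
    n <- sum(times >= u)
    n1 <- sum(times >= u & groups == lev[1])
    d <- sum(times == u & events == 1)
    d1 <- sum(times == u & events == 1 & groups == lev[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O1 - E1)^2 / V
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  list(curves = curves,
       test = assoc_result(statistic = chisq, df = 1, p = p,
                           method = "logrank"))
}

#' Correlation tests
#'
#' Pearson and Spearman coefficients with the t transform
#' t = r * sqrt(df / (1 - r^2)), df = n - 2; Kendall's tau-b with tie
#' correction and a normal-approximation p (exact enumeration when n <= 10
#' and there are no ties).
#'
#' @param x,y numeric vectors (n >= 3)
#' @param method `"pearson"`, `"spearman"` or `"kendall_tau_b"`
#' @return an `AssocResult` with `effect` = the coefficient
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman",
                                              "kendall_tau_b")) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need n >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  if (method %in% c("pearson", "spearman")) {
    if (method == "spearman") { x <- rank(x); y <- rank(y) }
    r <- stats::cor(x, y)
    df <- n - 2
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
    return(assoc_result(statistic = t, df = df, p = p, effect = r,
                        method = method))
  }
  # Kendall's tau-b
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  tx <- table(x); ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
  if (n <= 10 && n1 == 0 && n2 == 0) {
    perms <- combinat_perms(n)
    stats_all <- apply(perms, 1, function(py) {
      cd <- 0
      for (i in seq_len(n - 1)) for (j in (i + 1):n)
        cd <- cd + sign(x[i] - x[j]) * sign(y[py[i]] - y[py[j]])
      cd
    })
    p <- mean(abs(stats_all) >= abs(conc - disc) - 1e-9)
    z <- NA_real_
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    z <- (conc - disc) / sqrt(var_s)
    p <- 2 * stats::pnorm(-abs(z))
  }
  assoc_result(statistic = if (is.na(z)) conc - disc else z, df = NA_real_,
               p = min(1, p), effect = tau, method = "kendall_tau_b")
}

combinat_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Reconstruct the t statistic of a correlation coefficient
#'
#' t = r * sqrt(df / (1 - r^2)), the test statistic behind a printed Pearson
#' or Spearman coefficient at df = n - 2.
#'
#' @param r correlation coefficient, |r| < 1
#' @param df degrees of freedom (n - 2)
#' @return the t statistic
#' @export
t_from_correlation <- function(r, df) {
  if (abs(r) >= 1) stop("|r| must be < 1")
  r * sqrt(df / (1 - r^2))
}

#' Confidence interval of a regression slope from its t statistic
#'
#' Reconstructs SE = |beta / t| and the 95% CI
#' beta -/+ q_0.975(df) * SE from a printed slope, t statistic and degrees
#' of freedom.
#'
#' @param beta slope estimate
#' @param t_stat its t statistic (nonzero)
#' @param df residual degrees of freedom
#' @param conf confidence level (default 0.95)
#' @return list with `SE`, `lower`, `upper`
#' @export
slope_ci <- function(beta, t_stat, df, conf = 0.95) {
  if (t_stat == 0) stop("t statistic must be nonzero")
  if (df < 1) stop("df must be >= 1")
  SE <- abs(beta / t_stat)
  q <- stats::qt(1 - (1 - conf) / 2, df)
  list(SE = SE, lower = beta - q * SE, upper = beta + q * SE)
}

# least-squares fit reporting the t on one coefficient; X includes intercept
ols_t <- function(X, y, coef_index, method) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    return(assoc_result(statistic = NA_real_, df = NA_real_, p = NA_real_,
                        method = method, flag = "collinear predictors"))
  }
  beta <- qr.coef(qr_x, y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qr_x))
  se <- sqrt(s2 * diag(XtXinv))
  b <- unname(beta[coef_index])
  s <- unname(se[coef_index])
  t <- b / s
  p <- 2 * stats::pt(-abs(t), df)
  assoc_result(statistic = t, df = df, p = p, effect = b, SE = s,
               CI = b + c(-1, 1) * stats::qt(0.975, df) * s, method = method)
}

#' Single-SNP association by linear regression
#'
#' Ordinary least squares of the phenotype on the genotype dosage
#' (y ~ g); the reported statistic is the t on the dosage coefficient.
#'
#' @param genotype_dosage dosages in 0/1/2
#' @param phenotype numeric phenotype
#' @return an `AssocResult` with `effect` = the slope
#' @export
snp_association <- function(genotype_dosage, phenotype) {
  n <- length(phenotype)
  if (!all(genotype_dosage %in% 0:2)) stop("dosages must be 0, 1 or 2")
  if (n <= 2) stop("need n > number of model terms")
  X <- cbind(1, genotype_dosage)
  ols_t(X, phenotype, 2L, "snp_lm")
}

#' Epistasis test for a SNP pair
#'
#' Fits y ~ g1 + g2 + g1:g2 by ordinary least squares and reports the t test
#' on the interaction coefficient. Collinear predictor sets yield a flagged
#' result rather than an error.
#'
#' @param g1,g2 dosages in 0/1/2
#' @param phenotype numeric phenotype
#' @return an `AssocResult` with `effect` = the interaction coefficient
#' @export
epistasis_pair <- function(g1, g2, phenotype) {
  if (!all(g1 %in% 0:2) || !all(g2 %in% 0:2)) stop("dosages must be 0, 1 or 2")
  n <- length(phenotype)
  if (n <= 4) stop("need n > number of model terms")
  X <- cbind(1, g1, g2, g1 * g2)
  ols_t(X, phenotype, 4L, "epistasis_lm")
}
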