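# Residualization, Spearman machinery, BH FDR, robust regression,
# volumetry and control analyses.

test_that("residualize returns OLS residuals orthogonal to the design", {
  y <- c(3, 1, 4, 1, 5, 9)
  expect_equal(residualize(y), y - mean(y))          # intercept only

  x <- c(1, 2, 3, 4, 5, 6)
  # closed-form via normal equations
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(residualize(y, data.frame(x = x)), drop(y - X %*% beta))

  y_lin <- 2 + 3 * x
  expect_equal(residualize(y_lin, data.frame(x = x)), rep(0, 6),
               tolerance = 1e-10)

  set.seed(1)
  cov2 <- data.frame(a = rnorm(30), b = rnorm(30))
  r <- residualize(rnorm(30), cov2)
  expect_lt(abs(mean(r)), 1e-10)
  expect_lt(abs(sum(r * cov2$a)), 1e-8)
  expect_lt(abs(sum(r * cov2$b)), 1e-8)

  expect_error(residualize(y, data.frame(a = x, b = 2 * x)), "rank")
  expect_error(residualize(1:2, data.frame(a = rnorm(2), b = rnorm(2))),
               "enough")
})

test_that("spearman_assoc reproduces rank correlation, p and CI behaviour", {
  x <- 1:12
  up <- spearman_assoc(x, 2 * x + 3, B = 200, seed = 1)
  expect_equal(up$r, 1)
  expect_equal(up$ci_low, 1)
  expect_equal(up$ci_high, 1)
  down <- spearman_assoc(x, rev(x), B = 0)
  expect_equal(down$r, -1)

  # tie handling: r equals Pearson on hand-assigned average ranks
  xt <- c(1, 2, 2, 3, 4, 5, 6, 7, 8, 9)
  yt <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)
  rx <- c(1, 2.5, 2.5, 4, 5, 6, 7, 8, 9, 10)
  expect_equal(spearman_assoc(xt, yt, B = 0)$r, cor(rx, rank(yt)))

  # p from the t approximation is close to the sampled permutation p
  set.seed(2)
  xs <- rnorm(10); ys <- xs + rnorm(10, sd = 1.2)
  obs <- abs(cor(xs, ys, method = "spearman"))
  perm <- replicate(20000, abs(cor(xs, sample(ys), method = "spearman")))
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(spearman_assoc(xs, ys, B = 0)$p - p_perm), 0.02)

  expect_error(spearman_assoc(rep(1, 12), 1:12, B = 0), "constant")
  expect_error(spearman_assoc(1:5, 1:5), "at least 10")
})

test_that("spearman r is invariant under strictly monotone transforms", {
  set.seed(3)
  x <- rnorm(50); y <- x + rnorm(50)
  r0 <- spearman_assoc(x, y, B = 0)$r
  expect_equal(spearman_assoc(exp(x), y, B = 0)$r, r0)
  expect_equal(spearman_assoc(x, y^3, B = 0)$r, r0)
  expect_equal(spearman_assoc(qlogis(plogis(x)), atan(y), B = 0)$r, r0,
               tolerance = 1e-12)
})

test_that("bootstrap CI endpoints stabilise as B grows", {
  set.seed(4)
  x <- rnorm(300); y <- 0.3 * x + rnorm(300)
  a <- spearman_assoc(x, y, B = 2000, seed = 10)
  b <- spearman_assoc(x, y, B = 4000, seed = 11)
  hw_a <- (a$ci_high - a$ci_low) / 2
  hw_b <- (b$ci_high - b$ci_low) / 2
  expect_lt(abs(hw_a - hw_b), 0.01)
  expect_true(a$ci_low <= a$r && a$r <= a$ci_high)
})

test_that("bh_fdr agrees with the brute-force step-up on random inputs", {
  expect_length(bh_fdr(rep(1, 8))$rejected, 0)
  expect_length(bh_fdr(rep(0, 8))$rejected, 8)
  fix <- bh_fdr(c(.001, .01, .02, .2), q = .05)
  expect_equal(fix$rejected, 1:3)
  expect_equal(fix$critical_p, .02)

  set.seed(5)
  for (k in 1:50) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_equal(bh_fdr(p, q)$rejected, oracle_bh(p, q))
  }
  # single p-value reduces to p <= q
  expect_equal(length(bh_fdr(0.04, q = .05)$rejected), 1)
  expect_equal(length(bh_fdr(0.06, q = .05)$rejected), 0)
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("robust_r2 is exact on clean data and agrees with MASS::rlm", {
  set.seed(6)
  X <- matrix(rnorm(200 * 3), 200, 3)
  beta <- c(1, -2, 0.5)
  y <- drop(2 + X %*% beta)
  fit <- robust_r2(y, X)
  expect_equal(fit$r_squared, 1)
  expect_equal(unname(fit$coefficients), c(2, beta), tolerance = 1e-6)

  yn <- y + rnorm(200, sd = 0.7)
  fit2 <- robust_r2(yn, X)
  ref <- MASS::rlm(yn ~ X, psi = MASS::psi.bisquare, c = 4.685,
                   maxit = 100)
  expect_equal(unname(fit2$coefficients), unname(coef(ref)), tolerance = 5e-3)
  expect_true(fit2$converged)
  g <- glance(fit2)
  expect_equal(g$r_squared, fit2$r_squared)
  expect_equal(nrow(tidy(fit2)), 4)
})

test_that("null predictors explain almost nothing at large n", {
  ok <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    y <- rnorm(1000)
    X <- matrix(rnorm(1000 * 22), 1000, 22)
    robust_r2(y, X)$r_squared < 0.05
  }, logical(1))
  expect_gte(sum(ok), 9)
})

test_that("bisquare resists gross outliers better than least squares", {
  wins <- vapply(1:60, function(s) {
    set.seed(2000 + s)
    n <- 120
    x <- rnorm(n)
    y <- 1.5 * x + rnorm(n, sd = 0.5)
    out <- sample(n, 6)                       # 5% gross outliers
    y[out] <- y[out] + sample(c(-1, 1), 6, TRUE) * runif(6, 8, 15)
    b_rob <- robust_r2(y, cbind(x = x))$coefficients["x"]
    b_ols <- coef(lm(y ~ x))[2]
    abs(b_rob - 1.5) < abs(b_ols - 1.5)
  }, logical(1))
  expect_gte(sum(wins), 52)   # binomial(60, .95) lower band
})

test_that("control covariates behave as designed in the cost association", {
  set.seed(7)
  n <- 664
  cohort <- toy_cohort(n, seed = 7)
  m <- rnorm(n)
  cost <- 0.02 + 0.004 * m + rnorm(n, sd = 0.004)
  cohort$recall_total <- rbinom(n, 72, plogis(-0.8 + 0.5 * m))
  cohort$attention <- rnorm(n)                 # independent control
  cohort$working_memory <- rnorm(n)
  base <- cost_recall_association(cost, cohort, B = 0)
  ctrl <- control_analysis(cost, cohort, B = 0)
  expect_equal(nrow(ctrl), 2)
  expect_lt(max(abs(ctrl$r - base$r)), 0.02)

  # controlling for (a noisy copy of) cost removes the association
  cohort2 <- cohort
  cohort2$attention <- cost + rnorm(n, sd = 2e-4)
  ctrl2 <- control_analysis(cost, cohort2, B = 0)
  expect_lt(abs(ctrl2$r[ctrl2$control == "attention"]), 0.05)

  # controlling for recall itself leaves a degenerate residual
  cohort3 <- cohort
  cohort3$attention <- cohort3$recall_total
  expect_error(control_analysis(cost, cohort3, B = 0), "constant")
})

test_that("volume association is null on null volumes and finds planted effects", {
  atlas <- dk_atlas()
  n <- 400
  rejections <- vapply(1:5, function(s) {
    set.seed(3000 + s)
    cohort <- toy_cohort(n, seed = 3000 + s)
    cohort$recall_total <- rbinom(n, 72, 0.3)
    V <- matrix(rlnorm(n * 82, log(8000), 0.1), n, 82)
    colnames(V) <- paste0("vol_", atlas$label)
    cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(V))
    va <- volume_association(cohort, atlas, B = 0)
    sum(va$nodes$rejected)
  }, numeric(1))
  expect_gte(sum(rejections == 0), 4)

  # a single planted node effect is recovered
  set.seed(4000)
  n2 <- 664
  cohort <- toy_cohort(n2, seed = 4000)
  m <- rnorm(n2)
  cohort$recall_total <- rbinom(n2, 72, plogis(-0.8 + 0.6 * m))
  V <- matrix(rlnorm(n2 * 82, log(8000), 0.1), n2, 82)
  V[, 13] <- V[, 13] * exp(0.12 * m)      # rank-correlation ~0.3 with recall
  colnames(V) <- paste0("vol_", atlas$label)
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(V))
  va <- volume_association(cohort, atlas, B = 0)
  expect_true(va$nodes$rejected[13])

  # volumes equal to recall give near-perfect correlations
  cohortr <- toy_cohort(50, seed = 5000)
  cohortr$recall_total <- rnorm(50, 30, 5)
  Vr <- matrix(rep(cohortr$recall_total, 82), 50, 82)
  colnames(Vr) <- paste0("vol_", atlas$label)
  cohortr <- dplyr::bind_cols(cohortr, tibble::as_tibble(Vr))
  var <- volume_association(cohortr, atlas, B = 0)
  expect_true(all(var$nodes$r > 0.95))
})
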