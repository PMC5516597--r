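# Network-based statistic: edge t-tests, components, permutation FWE.

make_edge_data <- function(n, pairs, beta = NULL, seed = 1) {
  set.seed(seed)
  E <- nrow(pairs)
  X <- matrix(rnorm(n * E, mean = 0.3, sd = 0.1), n, E)
  covs <- data.frame(age = rnorm(n), gender = rbinom(n, 1, 0.5),
                     icv = rnorm(n))
  y <- rnorm(n)
  if (!is.null(beta)) y <- y + drop(X %*% beta)
  list(y = y, X = X, covs = covs)
}

grid_pairs <- function(R) {
  ind <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  tibble::tibble(i = ind[, 1], j = ind[, 2])
}

test_that("t tail probability matches the threshold correspondence", {
  expect_equal(t_threshold_p(0, 17), 0.5)
  expect_equal(round(t_threshold_p(2.5, 660), 4), 0.0063)
  # quadrature oracle
  quad <- integrate(function(x) dt(x, df = 660), 2.5, Inf,
                    rel.tol = 1e-10)$value
  expect_equal(t_threshold_p(2.5, 660), quad, tolerance = 1e-6)
  expect_error(t_threshold_p(2, 0.5), "df")
})

test_that("edge t-statistics match the closed-form simple-regression t", {
  x <- c(0.1, 0.3, 0.2, 0.5, 0.4, 0.6, 0.35, 0.25)
  y <- c(5, 9, 6, 14, 10, 15, 9, 8)
  n <- 8
  sm <- edge_t_stats(y, cbind(x), covariates = NULL)
  b <- cov(x, y) / var(x)
  a <- mean(y) - b * mean(x)
  se <- sqrt(sum((y - a - b * x)^2) / (n - 2) / sum((x - mean(x))^2))
  expect_equal(sm$t[1], b / se, tolerance = 1e-10)
  expect_equal(attr(sm, "df"), n - 2L)

  # with 3 covariates the residual df is n - 5 and t matches lm()
  dat <- make_edge_data(60, grid_pairs(5), seed = 3)
  sm2 <- edge_t_stats(dat$y, dat$X, dat$covs)
  expect_equal(attr(sm2, "df"), 55L)
  for (e in c(1, 4, 9)) {
    fit <- lm(dat$y ~ dat$X[, e] + age + gender + icv, data = dat$covs)
    expect_equal(sm2$t[e], summary(fit)$coefficients[2, "t value"],
                 tolerance = 1e-9)
  }
})

test_that("edge t-statistics respect relabeling and degenerate inputs", {
  dat <- make_edge_data(40, grid_pairs(4), seed = 4)
  sm <- edge_t_stats(dat$y, dat$X, dat$covs)
  perm <- sample(40)
  sm_p <- edge_t_stats(dat$y[perm], dat$X[perm, ], dat$covs[perm, ])
  expect_equal(sm_p$t, sm$t, tolerance = 1e-9)

  Xc <- dat$X; Xc[, 2] <- 0.5                       # constant edge
  smc <- edge_t_stats(dat$y, Xc, dat$covs)
  expect_equal(smc$t[2], 0)
  expect_true(smc$constant[2])

  yy <- 2 + 3 * dat$X[, 1]                          # exact fit
  sme <- edge_t_stats(yy, dat$X[, 1, drop = FALSE], covariates = NULL)
  expect_true(is.infinite(sme$t[1]) && sme$t[1] > 0)
})

test_that("suprathreshold components are found by connectivity", {
  pairs <- grid_pairs(8)
  t <- rep(0, nrow(pairs))
  sm <- structure(tibble::tibble(i = pairs$i, j = pairs$j, t = t,
                                 suprathreshold = t >= 2.5, constant = FALSE),
                  df = 10L, T = 2.5, sided = "one",
                  class = c("edge_stat_map", "tbl_df", "tbl", "data.frame"))
  expect_equal(nrow(suprathreshold_components(sm)), 0)

  # two disjoint clusters: a 3-edge triangle on 1-2-3 and a 2-edge path 5-6-7
  idx3 <- which((pairs$i == 1 & pairs$j %in% c(2, 3)) |
                  (pairs$i == 2 & pairs$j == 3))
  idx2 <- which((pairs$i == 5 & pairs$j == 6) | (pairs$i == 6 & pairs$j == 7))
  t[c(idx3, idx2)] <- 3
  sm$t <- t
  sm$suprathreshold <- t >= 2.5
  comps <- suprathreshold_components(sm)
  expect_equal(nrow(comps), 2)
  expect_equal(comps$n_edges, c(3, 2))
  expect_equal(sort(comps$nodes[[1]]), 1:3)
  expect_equal(sort(comps$nodes[[2]]), 5:7)
})

test_that("the union-find component sizer agrees with igraph", {
  set.seed(8)
  for (k in 1:30) {
    R <- sample(6:15, 1)
    pairs <- grid_pairs(R)
    on <- runif(nrow(pairs)) < 0.15
    ei <- pairs$i[on]; ej <- pairs$j[on]
    ref <- if (!length(ei)) 0L else {
      g <- igraph::graph_from_data_frame(data.frame(ei, ej), directed = FALSE)
      comp <- igraph::components(g)$membership
      max(table(comp[as.character(ei)]))
    }
    expect_equal(recallnet:::max_component_edges(ei, ej), as.integer(ref))
  }
})

test_that("nbs_fwe is seed-deterministic and monotone in threshold and size", {
  pairs <- grid_pairs(12)
  beta <- rep(0, nrow(pairs))
  planted <- which(pairs$i <= 5 & pairs$j <= 5)     # connected clique edges
  beta[planted] <- 6
  dat <- make_edge_data(150, pairs, beta = beta, seed = 9)

  r1 <- nbs_fwe(dat$y, dat$X, pairs, dat$covs, T = 2.5, n_perm = 300,
                alpha = 0.05, seed = 42, allow_small = TRUE)
  r2 <- nbs_fwe(dat$y, dat$X, pairs, dat$covs, T = 2.5, n_perm = 300,
                alpha = 0.05, seed = 42, allow_small = TRUE)
  expect_identical(r1$components$p_fwe, r2$components$p_fwe)
  expect_identical(r1$null_max_sizes, r2$null_max_sizes)

  # p_fwe is monotone non-increasing in component size for a fixed null
  if (nrow(r1$components) > 1) {
    ord <- order(r1$components$n_edges)
    expect_true(all(diff(r1$components$p_fwe[ord]) <= 0))
  }
  expect_true(all(r1$components$p_fwe >= 1 / 301))

  # raising T never grows a component; an infinite T leaves nothing
  big_T <- nbs_fwe(dat$y, dat$X, pairs, dat$covs, T = 5, n_perm = 100,
                   alpha = 0.05, seed = 42, allow_small = TRUE)
  max1 <- if (nrow(r1$components)) max(r1$components$n_edges) else 0
  max2 <- if (nrow(big_T$components)) max(big_T$components$n_edges) else 0
  expect_lte(max2, max1)
  smT <- edge_t_stats(dat$y, dat$X, dat$covs, T = Inf, pairs = pairs)
  expect_equal(nrow(suprathreshold_components(smT)), 0)

  expect_error(nbs_fwe(dat$y, dat$X, pairs, dat$covs, n_perm = 50),
               "meaningless")
})

test_that("a planted connected effect is detected with small FWE p", {
  pairs <- grid_pairs(10)
  hits <- vapply(1:5, function(s) {
    beta <- rep(0, nrow(pairs))
    planted <- which(pairs$j == pairs$i + 1)        # 9-edge connected path
    beta[planted] <- 4.5
    dat <- make_edge_data(300, pairs, beta = beta, seed = 100 + s)
    res <- nbs_fwe(dat$y, dat$X, pairs, dat$covs, T = 2.5, n_perm = 300,
                   alpha = 0.05, seed = s, allow_small = TRUE)
    nrow(res$components) > 0 && min(res$components$p_fwe) < 0.05
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("nbs results tidy and summarise cleanly", {
  pairs <- grid_pairs(8)
  dat <- make_edge_data(80, pairs, seed = 11)
  res <- nbs_fwe(dat$y, dat$X, pairs, dat$covs, T = 2, n_perm = 120,
                 alpha = 0.05, seed = 1, allow_small = TRUE)
  td <- tidy(res)
  gl <- glance(res)
  expect_true(all(c("component", "n_edges", "p_fwe") %in% names(td)))
  expect_equal(gl$n_perm, 120)
  expect_s3_class(autoplot(res), "ggplot")
})
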