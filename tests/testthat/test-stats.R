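test_that("SRH statistics match explicit rank-ANOVA arithmetic on a 2x2", {
  # cells (a1,b1)={1,2}, (a1,b2)={3,4}, (a2,b1)={5,6}, (a2,b2)={7,8}:
  # no ties, so ranks equal the values
  v <- 1:8
  A <- rep(c("a1", "a2"), each = 4)
  B <- rep(c("b1", "b1", "b2", "b2"), 2)
  r <- scheirerRayHare(v, A, B)
  # oracle: balanced two-way sums of squares on the explicit ranks
  rk <- rank(v)
  gm <- mean(rk)
  ssA <- sum(tapply(rk, A, function(g) length(g) * (mean(g) - gm)^2))
  ssB <- sum(tapply(rk, B, function(g) length(g) * (mean(g) - gm)^2))
  cells <- tapply(rk, list(A, B), mean)
  ssCells <- 2 * sum((cells - gm)^2)
  ms <- sum((rk - gm)^2) / 7
  expect_equal(r$table$H[1], ssA / ms)
  expect_equal(r$table$H[2], ssB / ms)
  expect_equal(r$table$H[3], (ssCells - ssA - ssB) / ms)
  expect_equal(r$table$df, c(1L, 1L, 1L))
  expect_equal(r$tie_correction, 1)
  expect_equal(r$table$p_value,
               pchisq(r$table$H, 1, lower.tail = FALSE))
})

test_that("identical values in every cell give H = 0 and p = 1", {
  r <- scheirerRayHare(rep(5, 12), rep(c("x", "y"), 6),
                       rep(c("u", "v", "w"), 4))
  expect_equal(r$table$H, c(0, 0, 0))
  expect_equal(r$table$p_value, c(1, 1, 1))
})

test_that("SRH is invariant to strictly monotone transforms", {
  set.seed(20)
  v <- rnorm(36)
  A <- sample(rep(c("g1", "g2", "g3"), 12))
  B <- sample(rep(c("o1", "o2"), 18))
  r1 <- scheirerRayHare(v, A, B)
  r2 <- scheirerRayHare(exp(3 * v) + 10, A, B)
  expect_equal(r1$table$H, r2$table$H, tolerance = 1e-12)
})

test_that("one-factor SRH reduces to the Kruskal-Wallis statistic", {
  set.seed(21)
  for (rep_i in 1:10) {
    v <- sample(1:8, 30, replace = TRUE)  # ties on purpose
    B <- sample(rep(c("l1", "l2", "l3"), 10))
    r <- suppressWarnings(scheirerRayHare(v, rep("only", 30), B))
    kw <- kruskal.test(v, factor(B))
    expect_equal(r$table$H[2], unname(kw$statistic), tolerance = 1e-9)
    expect_equal(r$table$p_value[2], kw$p.value, tolerance = 1e-9)
    expect_equal(r$table$H[1], 0)
    expect_true(is.na(r$table$p_value[1]))
  }
})

test_that("type-II and sequential sums of squares agree when balanced", {
  set.seed(22)
  d <- generateFactorialDataset(a_levels = 2, b_levels = 3, n_per_cell = 4,
                                effect_a = 1, effect_b = 0.5, seed = 3)
  r <- scheirerRayHare(d$value, d$A, d$B)
  # sequential (type-I) on ranks, computed directly
  rk <- rank(d$value)
  rss <- function(f) sum(lm(f, data = data.frame(rk = rk, A = d$A,
                                                 B = d$B))$residuals^2)
  ss_a_seq <- rss(rk ~ 1) - rss(rk ~ A)
  ss_b_seq <- rss(rk ~ A) - rss(rk ~ A + B)
  ms <- sum((rk - mean(rk))^2) / (length(rk) - 1)
  expect_equal(r$table$H[1], ss_a_seq / ms, tolerance = 1e-9)
  expect_equal(r$table$H[2], ss_b_seq / ms, tolerance = 1e-9)
})

test_that("empty cells are rejected with the cell named", {
  v <- rnorm(12)
  A <- rep(c("a1", "a2"), each = 6)
  B <- c(rep(c("b1", "b2"), 3), rep("b1", 6))  # (a2, b2) empty
  expect_error(scheirerRayHare(v, A, B), "a2.*b2|empty cell")
})

test_that("the linear PER model recovers exact noiseless weights", {
  set.seed(23)
  a <- runif(9, 0, 1); b <- runif(9, 0, 1)
  y <- 2 * a - 3 * b + 1
  fit <- fitPerModel(a, b, y)
  expect_equal(fit$weight_gr5a, 2, tolerance = 1e-9)
  expect_equal(fit$weight_gr66a, -3, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-9)
})

test_that("R^2 is near zero when the outcome is unrelated to predictors", {
  set.seed(24)
  a <- runif(500); b <- runif(500); y <- rnorm(500)
  expect_lt(fitPerModel(a, b, y)$r_squared, 0.05)
})

test_that("affine predictor rescaling rescales weights, not R^2 or fits", {
  d <- generateModelDataset(noise_sd = 0.05, seed = 9)
  f1 <- fitPerModel(d$gr5a, d$gr66a, d$per_magnitude)
  f2 <- fitPerModel(10 * d$gr5a + 3, 0.5 * d$gr66a - 7, d$per_magnitude)
  expect_equal(f2$weight_gr5a, f1$weight_gr5a / 10, tolerance = 1e-9)
  expect_equal(f2$weight_gr66a, f1$weight_gr66a / 0.5, tolerance = 1e-9)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-9)
  expect_equal(f2$fitted, f1$fitted, tolerance = 1e-9)
})

test_that("degenerate model inputs are rejected", {
  expect_error(fitPerModel(1:9, 2 * (1:9), rep(1, 9)), "constant outcome")
  expect_error(fitPerModel(1:9, 2 * (1:9), rnorm(9)), "collinear")
  expect_error(fitPerModel(1:2, 1:2, 1:2), "at least 3")
})
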