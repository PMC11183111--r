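test_that("min-max standardization maps columns onto [0,1]", {
  expect_equal(minmax_standardize(data.frame(a = c(2, 4, 6)))$a, c(0, 0.5, 1))
  expect_equal(minmax_standardize(data.frame(a = c(-1, 0, 3)))$a, c(0, 0.25, 1))
  already <- data.frame(a = c(0, 0.3, 1))
  expect_equal(minmax_standardize(already), already)
  expect_error(minmax_standardize(data.frame(ok = 1:3, flat = c(2, 2, 2))),
               "flat")
})

test_that("collinearity filter drops duplicates and respects the threshold", {
  set.seed(31)
  x <- data.frame(a = rnorm(100), b = rnorm(100))
  x$c <- x$a                                   # exact duplicate
  out <- filter_collinear(x)
  expect_equal(out$dropped, "c")               # tie -> later column dropped
  expect_setequal(names(out$kept), c("a", "b"))

  ind <- as.data.frame(matrix(rnorm(1000 * 5), 1000, 5))
  expect_length(filter_collinear(ind)$dropped, 0)

  expect_length(filter_collinear(x, threshold = 1.0)$dropped, 0)
})

test_that("Gaussian GLM recovers noiseless fits and orders nested models", {
  set.seed(41)
  d <- data.frame(x = runif(60))
  d$y <- 2 + 3 * d$x
  fit <- fit_glm(y ~ x, d)
  expect_equal(fit$deviance_explained, 100, tolerance = 1e-8)
  expect_equal(unname(coef(fit)), c(2, 3), tolerance = 1e-8)

  d$y <- d$y + rnorm(60)
  null_fit <- fit_glm(y ~ 1, d)
  expect_equal(null_fit$deviance_explained, 0)

  # deviance explained == squared correlation of fitted vs observed
  f2 <- fit_glm(y ~ x, d)
  expect_equal(f2$deviance_explained / 100,
               cor(fitted(f2$fit), d$y)^2, tolerance = 1e-10)

  # landform-only is nested in the full model
  d$landform <- factor(rep(c("Danxia", "karst", "granitic"), 20))
  lf <- fit_glm(y ~ landform, d, reference = c(landform = "Danxia"))
  full <- fit_glm(y ~ landform + x, d, reference = c(landform = "Danxia"))
  expect_gte(full$deviance_explained, lf$deviance_explained)
  expect_equal(names(coef(lf))[1], "(Intercept)")
  expect_true(all(c("landformgranitic", "landformkarst") %in% names(coef(lf))))
})

test_that("deviance explained recovers the generating signal fraction", {
  des <- vapply(1:10, function(r) {
    set.seed(800 + r)
    n <- 500
    x <- rnorm(n)
    # signal fraction 0.6: var(signal) = 0.6, var(noise) = 0.4
    y <- sqrt(0.6) * x + rnorm(n, sd = sqrt(0.4))
    fit_glm(y ~ x, data.frame(x = x, y = y))$deviance_explained
  }, numeric(1))
  expect_true(mean(des) > 50 && mean(des) < 70)
})

test_that("stepwise AIC drops noise and keeps strong predictors", {
  kept_true <- dropped_noise <- logical(50)
  for (r in seq_along(kept_true)) {
    set.seed(900 + r)
    n <- 500
    d <- data.frame(x = rnorm(n), junk = rnorm(n))
    d$y <- d$x + rnorm(n)
    sel <- step_aic(fit_glm(y ~ x + junk, d))
    labs <- attr(terms(sel$fit), "term.labels")
    kept_true[r] <- "x" %in% labs
    dropped_noise[r] <- !("junk" %in% labs)
  }
  expect_true(all(kept_true))
  # AIC keeps a single pure-noise parameter with probability
  # P(chisq_1 > 2) ~ 0.157, so the drop rate should sit near 0.84
  expect_gte(mean(dropped_noise), 0.70)
  expect_lte(mean(dropped_noise), 0.96)

  # selection never increases AIC
  set.seed(950)
  d <- data.frame(x = rnorm(100), z = rnorm(100))
  d$y <- d$x + rnorm(100)
  f0 <- fit_glm(y ~ x + z, d)
  expect_lte(step_aic(f0)$aic, f0$aic)
})

test_that("leave-one-out importance ranks the informative predictor first", {
  set.seed(61)
  n <- 500
  d <- data.frame(signal = rnorm(n), noise = rnorm(n))
  d$y <- d$signal + rnorm(n)
  imp <- loo_importance(fit_glm(y ~ signal + noise, d))
  expect_equal(imp$term[1], "signal")
  expect_lt(abs(imp$delta_deviance_explained[imp$term == "noise"]), 2)
})

test_that("knn weights are row-standardized with no self-neighbours", {
  co <- simulate_coords(100, seed = 71)
  w <- knn_weights(co, 8)
  expect_equal(unname(rowSums(w$W)), rep(1, 100))
  expect_true(all(diag(w$W) == 0))
  expect_true(all(lengths(w$neighbors) == 8))

  # k = n - 1: fully connected, all weights 1/(n-1)
  w4 <- knn_weights(simulate_coords(5, seed = 72), 4)
  expect_true(all(w4$W[upper.tri(w4$W) | lower.tri(w4$W)] == 0.25))

  expect_error(knn_weights(co, 100), "k < number of sites")
})

test_that("Moran's I matches its closed forms and a direct-formula oracle", {
  ring <- matrix(c(0, .5, 0, .5,
                   .5, 0, .5, 0,
                   0, .5, 0, .5,
                   .5, 0, .5, 0), 4, 4, byrow = TRUE)
  m <- morans_i(c(1, -1, 1, -1), ring)
  expect_equal(m$I, -1)
  expect_equal(m$expected, -1 / 3)

  co <- simulate_coords(200, seed = 81)
  w <- knn_weights(co, 8)
  set.seed(82)
  x <- rnorm(200)
  m2 <- morans_i(x, w)
  expect_equal(m2$expected, -1 / 199)
  expect_lt(abs(m2$z), 4)

  # direct-formula oracle
  xc <- x - mean(x)
  I_direct <- (200 / sum(w$W)) * as.numeric(t(xc) %*% w$W %*% xc) / sum(xc^2)
  expect_equal(m2$I, I_direct, tolerance = 1e-12)

  expect_error(morans_i(rep(1, 10), knn_weights(simulate_coords(10, seed = 8), 3)),
               "constant")
})

test_that("the SEM reduces to OLS at lambda 0 and its profile is maximal", {
  co <- simulate_coords(80, seed = 91)
  w <- knn_weights(co, 6)
  x <- as.vector(simulate_predictors(w, 0.4, seed = 92))
  y <- simulate_sem_response(cbind(1, x), c(1, 2), w, lambda_err = 0.5,
                             sigma = 1, seed = 93)
  d <- data.frame(y = y, x = x)
  sem0 <- fit_sem_ml(y ~ x, d, w, lambda = 0)
  ols <- fit_glm(y ~ x, d)
  expect_equal(unname(coef(sem0)), unname(coef(ols)), tolerance = 1e-6)

  sem <- fit_sem_ml(y ~ x, d, w)
  expect_gte(sem$logLik, sem0$logLik)
  expect_lt(abs(sem$lambda), 1)
  expect_true(is.finite(sem$aic))
  # AIC bookkeeping: -2 logL + 2 (p + 2)
  expect_equal(sem$aic, -2 * sem$logLik + 2 * (2 + 2))

  # pseudo R-squared reduces to R-squared when lambda = 0
  expect_equal(sem0$deviance_explained, ols$deviance_explained,
               tolerance = 1e-6)
})

test_that("pipeline model ordering holds on simulated survey data", {
  tr <- simulate_yule_tree(80, 1, 101)
  trait <- simulate_bm_trait(tr, 1, 0, 102)
  cfg <- assembly_config(n_species = 80, n_sites_per_landform = 8,
                         mode = "clustered", filter_strength = 5,
                         richness_range = c(8, 25), seed = 103)
  a <- simulate_assemblages(tr, trait, cfg)
  s <- ses_metrics(tr, a$matrix, engine = "montecarlo", n_rand = 199, seed = 104)
  d <- data.frame(y = log(s$SR), landform = factor(a$predictors$landform))
  set.seed(105)
  d$clim <- rnorm(nrow(d)) + s$SR / 10
  lf <- fit_glm(y ~ landform, d)
  full <- fit_glm(y ~ landform + clim, d)
  expect_gte(full$deviance_explained, lf$deviance_explained)
})
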