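test_that("MME solutions equal explicit GLS inversion on a small instance", {
  set.seed(42)
  n <- 20
  X <- cbind(1, rnorm(n))
  K <- crossprod(matrix(rnorm(n * n), n, n)) / n + diag(n) * 0.1
  y <- rnorm(n)
  s2k <- 0.7; s2e <- 0.4
  spec <- mm_spec(y, X, list(mm_random("g", diag(n), K = K, ridge = 0)))
  sol <- solve_mme(spec, c(g = s2k), s2e)
  V <- K * s2k + diag(n) * s2e
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- s2k * K %*% Vi %*% (y - X %*% b)
  expect_lt(max(abs(sol$b - b)), 1e-8)
  expect_lt(max(abs(sol$u$g - u)), 1e-8)
  expect_lt(sol$mme_residual, 1e-8)
  expect_equal(sol$yhat, as.numeric(X %*% b + u), tolerance = 1e-8)
})

test_that("identity covariance reduces to ridge regression", {
  set.seed(8)
  n <- 40; q <- 6
  Z <- matrix(rnorm(n * q), n, q)
  y <- rnorm(n)
  s2u <- 0.5; s2e <- 1.5
  spec <- mm_spec(y, NULL, list(mm_random("r", Z)))
  sol <- solve_mme(spec, c(r = s2u), s2e)
  lambda <- s2e / s2u
  X <- matrix(1, n, 1)
  # closed-form ridge with unpenalised intercept
  A <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + diag(lambda, q)))
  theta <- solve(A, c(crossprod(X, y), crossprod(Z, y)))
  expect_lt(max(abs(c(sol$b, sol$u$r) - theta)), 1e-8)
})

test_that("random solutions shrink to zero as the variance ratio vanishes", {
  set.seed(3)
  n <- 30
  Z <- matrix(rnorm(n * 4), n, 4)
  y <- rnorm(n)
  spec <- mm_spec(y, NULL, list(mm_random("r", Z)))
  sol <- solve_mme(spec, c(r = 1e-9), 1)
  expect_lt(max(abs(sol$u$r)), 1e-6)
})

test_that("REML matches the balanced half-sib ANOVA estimator", {
  set.seed(7)
  ns <- 40; no <- 10
  sire <- rep(seq_len(ns), each = no)
  y <- 1 + rnorm(ns, 0, sqrt(0.3))[sire] + rnorm(ns * no)
  Z <- outer(sire, seq_len(ns), "==") * 1
  fit <- fit_variance_components(mm_spec(y, NULL, list(mm_random("sire", Z))),
                                 "REML")
  ms <- summary(stats::aov(y ~ factor(sire)))[[1]]
  v_anova <- (ms[1, 3] - ms[2, 3]) / no
  expect_gt(v_anova, 0)   # interior at this seed, so the equivalence applies
  expect_equal(unname(fit$sigma2[["sire"]]), v_anova, tolerance = 1e-6)
  expect_equal(fit$sigma2_e, ms[2, 3], tolerance = 1e-6)
})

test_that("null data drive the genetic variance to the boundary", {
  set.seed(12)
  hits <- 0
  for (s in 1:6) {
    set.seed(s)
    n <- 150
    Z <- outer(rep(1:30, each = 5), 1:30, "==") * 1
    y <- rnorm(n)
    fit <- fit_variance_components(mm_spec(y, NULL, list(mm_random("g", Z))),
                                   "REML")
    if (fit$sigma2[["g"]] < 0.01 * fit$sigma2_e) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("AIC identity and ML monotonicity under nesting hold", {
  set.seed(21)
  n <- 120
  x <- rbinom(n, 2, 0.4)
  y <- 0.4 * x + rnorm(n)
  s1 <- mm_spec(y, NULL, list(mm_random("a", cbind(x))))
  s2 <- mm_spec(y, NULL, list(mm_random("a", cbind(x)),
                              mm_random("d", cbind(as.numeric(x == 1)))))
  f1 <- fit_variance_components(s1, "ML")
  f2 <- fit_variance_components(s2, "ML")
  expect_equal(f1$AIC, -2 * f1$logLik_ML + 2 * f1$n_parameters)
  expect_equal(f2$n_parameters, f1$n_parameters + 1)
  # the larger ML model cannot fit worse (up to optimiser tolerance at the
  # variance boundary)
  expect_gte(f2$logLik_ML, f1$logLik_ML - 0.01)
  tab <- aic_compare(list(f1, f2), labels = c("add", "add+dom"))
  expect_equal(tab$dAIC[tab$model == "add"], 0)
})

test_that("aic_compare rejects mismatched responses and REML across fixed structures", {
  set.seed(2)
  y <- rnorm(50)
  Z <- matrix(rnorm(50 * 3), 50, 3)
  f1 <- fit_variance_components(mm_spec(y, NULL, list(mm_random("r", Z))), "ML")
  f2 <- fit_variance_components(mm_spec(rnorm(50), NULL,
                                        list(mm_random("r", Z))), "ML")
  expect_error(aic_compare(list(f1, f2)), "identical response")
  g1 <- fit_variance_components(mm_spec(y, NULL, list(mm_random("r", Z))), "REML")
  g2 <- fit_variance_components(mm_spec(y, cbind(1, rnorm(50)),
                                        list(mm_random("r", Z))), "REML")
  expect_error(aic_compare(list(g1, g2)), "REML")
})

test_that("confounded fixed columns are reported by name", {
  set.seed(4)
  n <- 30
  X <- cbind(a = rep(1, n), b = rep(1, n))
  Z <- matrix(rnorm(n * 3), n, 3)
  spec <- mm_spec(rnorm(n), X, list(mm_random("r", Z)))
  expect_error(solve_mme(spec, c(r = 1), 1), "confounded.*a.*b")
})

test_that("marker variance-explained behaves at the extremes", {
  set.seed(31)
  n <- 300
  x <- rbinom(n, 2, 0.4)
  # no effect
  y0 <- rnorm(n)
  f0 <- fit_variance_components(mm_spec(y0, NULL,
                                        list(mm_random("mk", cbind(x)))), "ML")
  v0 <- variance_explained_by_marker(f0, "mk")
  expect_lt(v0$marker, 0.05)
  # fully deterministic phenotype
  y1 <- as.numeric(x >= 1)
  f1 <- fit_variance_components(mm_spec(y1, NULL,
                                        list(mm_random("mk", cbind(x)),
                                             mm_random("dd", cbind(as.numeric(x == 1))))),
                                "ML")
  v1 <- variance_explained_by_marker(f1, c("mk", "dd"))
  expect_gt(v1$marker, 0.95)
  expect_error(variance_explained_by_marker(f1, "nope"), "no term")
})

test_that("Dempster-Lerner transform matches its closed form and inverts", {
  expect_equal(observed_to_liability_h2(1, 0.5), pi / 2, tolerance = 1e-12)
  expect_equal(observed_to_liability_h2(0, 0.3), 0)
  h <- observed_to_liability_h2(0.35, 0.12)
  expect_equal(liability_to_observed_h2(h, 0.12), 0.35, tolerance = 1e-12)
  expect_error(observed_to_liability_h2(0.4, 0), "prevalence")
  expect_error(observed_to_liability_h2(0.4, 1), "prevalence")
})

test_that("every fit satisfies the Henderson residual check", {
  st <- medium_study()
  sel_fit <- fit_moi(moi_spec(2, "hnh", st$causal_marker, "pedigree_A"), st)
  expect_lt(sel_fit$mme_residual, 1e-8)
})

test_that("fits serialise to JSON with their key quantities", {
  set.seed(15)
  y <- rnorm(40)
  Z <- matrix(rnorm(40 * 3), 40, 3)
  f <- fit_variance_components(mm_spec(y, NULL, list(mm_random("r", Z))), "ML")
  js <- write_fit_json(f)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$AIC, f$AIC)
  expect_equal(parsed$sigma2$r, unname(f$sigma2[["r"]]))
  expect_equal(parsed$method, "ML")
})
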