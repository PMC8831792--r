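sim_oneway <- function(q, r, s2g, s2e, mu = 10, seed = 1) {
  set.seed(seed)
  g <- rnorm(q, 0, sqrt(s2g))
  f <- factor(rep(seq_len(q), each = r))
  y <- mu + g[as.integer(f)] + rnorm(q * r, 0, sqrt(s2e))
  list(y = y, f = f,
       spec = mixed_model_spec(y, matrix(1, q * r, 1),
                               list(gen = list(Z = incidence(f)))))
}

test_that("REML matches closed-form ANOVA estimators on balanced data", {
  d <- sim_oneway(200, 3, 4, 1, seed = 42)
  fit <- reml_fit(d$spec)
  a <- anova(lm(d$y ~ d$f))
  ms <- a$`Mean Sq`
  expect_equal(unname(fit$vc["gen"]), (ms[1] - ms[2]) / 3, tolerance = 1e-6)
  expect_equal(unname(fit$vc["residual"]), ms[2], tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("permuting the response against genotype labels kills the genetic variance", {
  d <- sim_oneway(100, 3, 4, 1, seed = 7)
  set.seed(8)
  shares <- vapply(1:5, function(i) {
    yp <- sample(d$y)
    fit <- reml_fit(mixed_model_spec(yp, matrix(1, length(yp), 1),
                                     list(gen = list(Z = incidence(d$f)))))
    unname(fit$vc["gen"] / sum(fit$vc))
  }, 0)
  expect_lt(mean(shares), 0.05)
})

test_that("accepted iterations never decrease the restricted log-likelihood", {
  d <- sim_oneway(80, 2, 3, 2, seed = 3)
  l1 <- reml_fit(d$spec, max_iter = 1)$loglik
  lfull <- reml_fit(d$spec)$loglik
  expect_gte(lfull, l1 - 1e-10)
})

test_that("REML is invariant to translating the response", {
  d <- sim_oneway(60, 2, 3, 2, seed = 5)
  f1 <- reml_fit(d$spec)
  f2 <- reml_fit(mixed_model_spec(d$y + 100, matrix(1, length(d$y), 1),
                                  list(gen = list(Z = incidence(d$f)))))
  expect_equal(f1$vc, f2$vc, tolerance = 1e-5)
})

test_that("MME solution equals direct-inversion GLS on a small instance", {
  set.seed(11)
  n <- 48; q <- 12
  f <- factor(rep(seq_len(q), each = 4))
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(5, 2)) + rnorm(q, 0, 1.5)[as.integer(f)] + rnorm(n)
  spec <- mixed_model_spec(y, X, list(gen = list(Z = incidence(f))))
  fit <- reml_fit(spec)
  Z <- incidence(f)
  V <- fit$vc["gen"] * tcrossprod(Z) + fit$vc["residual"] * diag(n)
  Vi <- solve(V)
  beta_gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  expect_equal(unname(fit$beta), unname(drop(beta_gls)), tolerance = 1e-8)
  u_gls <- fit$vc["gen"] * t(Z) %*% Vi %*% (y - X %*% beta_gls)
  expect_equal(unname(fit$blup$gen), unname(drop(u_gls)), tolerance = 1e-8)
})

test_that("BLUPs shrink toward zero relative to fixed-effect estimates", {
  d <- sim_oneway(50, 3, 2, 3, seed = 13)
  fit <- reml_fit(d$spec)
  ols <- tapply(d$y, d$f, mean) - mean(d$y)
  expect_true(all(abs(fit$blup$gen) <= abs(ols) + 1e-8))
})

test_that("Cullis H2 matches the balanced-design closed form as replication grows", {
  # vbar -> 2 s2e / r, hence H2 -> 1 - s2e / (r s2g)
  for (r in c(5, 20)) {
    d <- sim_oneway(60, r, 4, 1, seed = 17 + r)
    fit <- reml_fit(d$spec)
    h <- cullis_h2(fit)
    plug <- 1 - fit$vc["residual"] / (r * fit$vc["gen"])
    expect_equal(h$H2, unname(plug), tolerance = 0.02)
    expect_equal(h$vbar_blup_diff, unname(2 * fit$vc["residual"] / r),
                 tolerance = 0.1 * h$vbar_blup_diff + 0.02)
  }
  # vbar = 0 corresponds to H2 = 1 by construction
  d <- sim_oneway(30, 3, 4, 1, seed = 19)
  fit <- reml_fit(d$spec)
  fit$pev$gen <- matrix(0, 30, 30)
  expect_equal(cullis_h2(fit)$H2, 1)
})

test_that("zero genetic variance yields H2 = 0 with a warning", {
  set.seed(21)
  f <- factor(rep(1:40, each = 2))
  y <- rnorm(80)
  fit <- reml_fit(mixed_model_spec(sample(y), matrix(1, 80, 1),
                                   list(gen = list(Z = incidence(f)))))
  if (fit$vc["gen"] / sum(fit$vc) < 1e-6) {
    expect_warning(h <- cullis_h2(fit), "zero")
    expect_equal(h$H2, 0)
  } else succeed()
})

test_that("variance-component LRT gives p = 1 at the boundary and a sane CV", {
  set.seed(23)
  q <- 40
  f <- factor(rep(seq_len(q), each = 2))
  blk <- factor(rep(1:4, 20))
  y <- 62 + rnorm(q, 0, 2)[as.integer(f)] + rnorm(2 * q)  # no block effect
  spec <- mixed_model_spec(y, matrix(1, 2 * q, 1),
                           list(gen = list(Z = incidence(f)),
                                block = list(Z = incidence(blk))))
  fit <- reml_fit(spec)
  vt <- varcomp_tests(spec, fit)
  expect_equal(attr(vt, "cv"),
               100 * sqrt(fit$vc[["residual"]]) / mean(y))
  if (fit$vc["block"] <= 1e-6 * sum(fit$vc)) {
    expect_equal(vt$p[vt$term == "block"], 1, tolerance = 0.05)
  }
  expect_lt(vt$p[vt$term == "gen"], 0.05)
})

test_that("LRT size is near nominal for a null variance component", {
  # term simulated at zero variance: rejection rate ~ alpha
  set.seed(29)
  alpha <- 0.05
  reps <- 120
  rej <- 0L
  for (i in seq_len(reps)) {
    f <- factor(rep(1:20, each = 2))
    y <- rnorm(40)
    spec <- mixed_model_spec(y, matrix(1, 40, 1),
                             list(gen = list(Z = incidence(f))))
    fit <- reml_fit(spec)
    vt <- varcomp_tests(spec, fit)
    if (vt$p[1] < alpha) rej <- rej + 1L
  }
  # binomial 99% envelope around alpha
  expect_lt(rej / reps, alpha + 2.58 * sqrt(alpha * (1 - alpha) / reps) + 0.02)
})

test_that("simulated block variance is recovered by the augmented-design model", {
  ests <- vapply(1:15, function(i) {
    set.seed(300 + i)
    entries <- paste0("e", 1:120)
    checks <- paste0("c", 1:4)
    skel <- layout_augmented_design(entries, 6, checks, 1, seed = i)
    g <- rnorm(124, 0, 4); names(g) <- c(entries, checks)
    blk <- rnorm(6, 0, sqrt(30))
    skel$value <- 50 + g[skel$line] + blk[skel$block] + rnorm(nrow(skel), 0, 2)
    reml_fit(acbd_blup_spec(skel))$vc[["block"]]
  }, 0)
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 30), 2 * se + 8)
})
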