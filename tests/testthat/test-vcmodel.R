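test_that("direct likelihood matches closed forms on tiny pedigrees", {
  # single individual, ML, V_A = 0, V_E = 1, beta = mean: standard normal density
  ped1 <- make_founders(1)
  A1 <- additive_relationship(ped1)
  d1 <- data.frame(id = ped1$id, y = 0.7)
  spec1 <- vc_spec("y", character(), A1, method = "ML")
  ll <- vc_loglik(spec1, d1, list(V_A = 0, V_E = 1, beta = 0.2))
  expect_equal(ll, dnorm(0.7, mean = 0.2, sd = 1, log = TRUE), tolerance = 1e-12)

  # parent-offspring pair: bivariate normal with covariance 0.5 V_A
  po <- new_pedigree(family = c("P", "P"), id = c("p", "o"),
                     father = c(NA, "p"), mother = c(NA, NA),
                     sex = c("male", "female"))
  Apo <- additive_relationship(po)
  y <- c(1.3, -0.4); va <- 0.6; ve <- 0.9; mu <- 0.25
  S <- matrix(c(va + ve, 0.5 * va, 0.5 * va, va + ve), 2, 2)
  ll_hand <- -0.5 * (log(det(S)) +
                       drop(t(y - mu) %*% solve(S) %*% (y - mu)) +
                       2 * log(2 * pi))
  d2 <- data.frame(id = po$id, y = y)
  ll_pkg <- vc_loglik(vc_spec("y", character(), Apo, "ML"), d2,
                      list(V_A = va, V_E = ve, beta = mu))
  expect_equal(ll_pkg, ll_hand, tolerance = 1e-12)
})

test_that("with A = I the likelihood only sees the total variance", {
  A <- additive_relationship(make_founders(12))
  set.seed(31)
  d <- data.frame(id = rownames(A), y = rnorm(12))
  spec <- vc_spec("y", character(), A, "ML")
  l1 <- vc_loglik(spec, d, list(V_A = 0.3, V_E = 0.7, beta = 0))
  l2 <- vc_loglik(spec, d, list(V_A = 0.9, V_E = 0.1, beta = 0))
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("non-positive-definite covariance raises, not clamps", {
  A <- additive_relationship(make_trio())
  d <- data.frame(id = c("f", "m", "c"), y = c(0.1, -0.2, 0.3))
  expect_error(
    vc_loglik(vc_spec("y", character(), A, "ML"), d,
              list(V_A = 1, V_E = -1.5, beta = 0)),
    "not positive definite")
})

test_that("converged REML fit reproduces the dense restricted likelihood", {
  set.seed(32)
  ped <- make_nuclear(25, 3)
  A <- additive_relationship(ped)
  d <- sim_uni(A, 0.5, 0.5)
  spec <- vc_spec("y", "age", A)
  fit <- fit_univariate(spec, d)
  expect_equal(fit$loglik,
               vc_loglik(spec, d, list(V_A = fit$V_A, V_E = fit$V_E)),
               tolerance = 1e-8)
  specML <- vc_spec("y", "age", A, "ML")
  fitML <- fit_univariate(specML, d)
  expect_equal(fitML$loglik,
               vc_loglik(specML, d,
                         list(V_A = fitML$V_A, V_E = fitML$V_E,
                              beta = fitML$beta)),
               tolerance = 1e-8)
})

test_that("univariate REML recovers h2 = 0.5 in nuclear families", {
  set.seed(33)
  ped <- make_nuclear(60, 3)
  A <- additive_relationship(ped)
  spec <- vc_spec("y", "age", A)
  h2s <- replicate(100, fit_univariate(spec, sim_uni(A, 0.5, 0.5),
                                       se = FALSE)$h2)
  expect_lt(abs(mean(h2s) - 0.5), 0.05)
})

test_that("null data sit at the V_A = 0 boundary", {
  set.seed(34)
  ped <- make_nuclear(40, 3)
  A <- additive_relationship(ped)
  spec <- vc_spec("y", "age", A)
  fits <- lapply(1:21, function(i) fit_univariate(spec, sim_uni(A, 0, 1),
                                                  se = FALSE))
  expect_equal(median(vapply(fits, `[[`, numeric(1), "h2")), 0)
  expect_true(any(vapply(fits, `[[`, logical(1), "boundary")))
})

test_that("founders-only data flag non-identifiability; ML variance matches lm", {
  set.seed(35)
  A <- additive_relationship(make_founders(80))
  d <- sim_uni(A, 0, 1.3)
  fit <- fit_univariate(vc_spec("y", "age", A, "ML"), d, se = FALSE)
  expect_true(fit$non_identifiable)
  lmfit <- lm(y ~ age, data = d)
  expect_equal(fit$V_A + fit$V_E, mean(residuals(lmfit)^2), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(coef(lmfit)), tolerance = 1e-8)
})

test_that("degenerate designs raise informative errors", {
  A <- additive_relationship(make_nuclear(5, 2))
  d <- data.frame(id = rownames(A), y = 1, age = rnorm(nrow(A)))
  expect_error(fit_univariate(vc_spec("y", "age", A), d),
               "zero phenotypic variance")
  d$y <- rnorm(nrow(A)); d$age2 <- 2 * d$age
  expect_error(fit_univariate(vc_spec("y", c("age", "age2"), A), d),
               "collinear.*age2")
  expect_error(vc_spec(c("y", "y"), character(), A), "duplicated trait")
  expect_error(fit_multivariate(vc_spec("y", character(), A),
                                d), "use fit_univariate")
})

test_that("REML likelihood is invariant to permuting individuals", {
  set.seed(36)
  ped <- make_nuclear(15, 3)
  A <- additive_relationship(ped)
  d <- sim_uni(A, 0.4, 0.6)
  fit <- fit_univariate(vc_spec("y", "age", A), d, se = FALSE)
  perm <- sample(nrow(d))
  fit_p <- fit_univariate(vc_spec("y", "age", A), d[perm, ], se = FALSE)
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-7)
  expect_equal(fit_p$h2, fit$h2, tolerance = 1e-5)
})

test_that("mean h2 estimates track the truth across the h2 grid", {
  set.seed(37)
  ped <- make_nuclear(60, 3)
  A <- additive_relationship(ped)
  spec <- vc_spec("y", "age", A)
  for (h2 in c(0, 0.25, 0.55, 0.75)) {
    h2s <- replicate(100, fit_univariate(
      spec, sim_uni(A, h2, 1 - h2), se = FALSE)$h2)
    expect_lt(abs(mean(h2s) - h2), 0.05)
  }
})

test_that("bivariate fit matches the dense likelihood and recovers zero r_G", {
  set.seed(38)
  ped <- make_nuclear(40, 3)
  A <- additive_relationship(ped)
  sim2 <- function() {
    n <- nrow(A); L <- t(chol(A))
    data.frame(id = rownames(A), age = runif(n, 20, 60),
               y1 = drop(L %*% rnorm(n)) * sqrt(0.5) + rnorm(n, sd = sqrt(0.5)),
               y2 = drop(L %*% rnorm(n)) * sqrt(0.5) + rnorm(n, sd = sqrt(0.5)))
  }
  spec <- vc_spec(c("y1", "y2"), "age", A)
  d <- sim2()
  fit <- fit_multivariate(spec, d)
  expect_equal(fit$loglik, vc_loglik(spec, d, list(G = fit$G, E = fit$E)),
               tolerance = 1e-8)
  expect_true(all(fit$h2 >= 0 & fit$h2 <= 1))
  expect_gte(min(eigen(fit$G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  rgs <- replicate(40, fit_multivariate(spec, sim2(), se = FALSE)$r_G[1, 2])
  expect_lt(abs(mean(rgs)), 0.1)
})

test_that("duplicating a trait drives correlations to the +1 boundary", {
  set.seed(39)
  ped <- make_nuclear(20, 3)
  A <- additive_relationship(ped)
  d <- sim_uni(A, 0.5, 0.5)
  d$y_copy <- d$y
  fit <- fit_multivariate(vc_spec(c("y", "y_copy"), "age", A), d, se = FALSE)
  expect_true(fit$degenerate)
  expect_gt(fit$r_E[1, 2], 0.99)
})

test_that("observed-block likelihood uses partially phenotyped individuals", {
  set.seed(40)
  ped <- make_nuclear(15, 3)
  A <- additive_relationship(ped)
  n <- nrow(A); L <- t(chol(A))
  g <- L %*% matrix(rnorm(n * 2), n, 2) %*% chol(matrix(c(.5, .3, .3, .5), 2))
  d <- data.frame(id = rownames(A), age = runif(n, 20, 60),
                  y1 = 1 + g[, 1] + rnorm(n, sd = sqrt(.5)),
                  y2 = 2 + g[, 2] + rnorm(n, sd = sqrt(.5)))
  d$y2[sample(n, 12)] <- NA  # non-rectangular data
  spec <- vc_spec(c("y1", "y2"), "age", A)
  fit <- fit_multivariate(spec, d, se = FALSE)
  expect_equal(fit$n_used, n)  # all rows contribute their observed block
  expect_equal(fit$loglik, vc_loglik(spec, d, list(G = fit$G, E = fit$E)),
               tolerance = 1e-8)
})

test_that("boundary-mixture LRT behaves at its edge cases", {
  set.seed(42)
  ped <- make_nuclear(25, 3)
  A <- additive_relationship(ped)
  spec <- vc_spec("y", "age", A)
  d <- sim_uni(A, 0.5, 0.5)
  full <- fit_univariate(spec, d, se = FALSE)
  null <- fit_univariate(spec, d, se = FALSE, constrain = "va_zero")
  lrt <- lrt_heritability(full, null)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$statistic, 2 * (full$loglik - null$loglik), tolerance = 1e-9)
  # identical likelihoods: statistic 0, p 1
  expect_equal(lrt_heritability(null, null), list(statistic = 0, p = 1))
  # the half-chi-square mixture: statistic 2.706 gives p = 0.05
  fake <- null; fake$loglik <- null$loglik + 2.705543 / 2
  expect_equal(lrt_heritability(fake, null)$p, 0.05, tolerance = 1e-4)
  # mismatched fixed effects refuse to compare
  null2 <- fit_univariate(vc_spec("y", character(), A), d, se = FALSE,
                          constrain = "va_zero")
  expect_error(lrt_heritability(full, null2), "must share")
})

test_that("Wald fixed-effect tests match their definition and the LRT", {
  set.seed(43)
  ped <- make_nuclear(25, 3)
  A <- additive_relationship(ped)
  d <- sim_uni(A, 0.4, 0.6, beta_age = 0.05)
  fit <- fit_univariate(vc_spec("y", "age", A), d)
  w <- wald_fixed_effects(fit)
  expect_equal(w$p, 2 * pnorm(-abs(w$estimate / w$ase)), tolerance = 1e-12)
  # hand-made edge cases
  fit0 <- fit; fit0$beta <- c(x = 0); fit0$beta_se <- c(x = 0.3)
  expect_equal(wald_fixed_effects(fit0)$p, 1)
  fit0$beta <- c(x = 1.959964 * 0.3)
  expect_equal(wald_fixed_effects(fit0)$p, 0.05, tolerance = 1e-6)
  # ML Wald z^2 agrees with the likelihood-ratio drop of the term at large n
  set.seed(44)
  ped2 <- make_nuclear(150, 3)
  A2 <- additive_relationship(ped2)
  d2 <- sim_uni(A2, 0.4, 0.6, beta_age = 0.01)
  fml <- fit_univariate(vc_spec("y", "age", A2, "ML"), d2, se = FALSE)
  fml0 <- fit_univariate(vc_spec("y", character(), A2, "ML"), d2, se = FALSE)
  z <- fml$beta[["age"]] / fml$beta_se[["age"]]
  lr <- 2 * (fml$loglik - fml0$loglik)
  expect_equal(z^2, lr, tolerance = 0.15)
})
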