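#' Specify a variance-components model
#'
#' Describes a univariate or multivariate additive-genetic plus residual
#' mixed model: each trait is decomposed as fixed covariate effects plus an
#' additive genetic random effect (correlated between relatives through the
#' additive relationship matrix) plus an independent residual environmental
#' effect.  An intercept is always included.
#'
#' @param traits character vector of trait column names (1 for univariate,
#'   2-4 for multivariate).
#' @param fixed character vector of fixed-effect covariate column names
#'   (may be empty; the intercept is implicit).
#' @param relationship a \code{relationship_matrix} covering all analysed ids.
#' @param method \code{"REML"} (default) or \code{"ML"}.
#' @return an object of class \code{vc_spec}.
#' @export
vc_spec <- function(traits, fixed = character(), relationship,
                    method = c("REML", "ML")) {
  method <- match.arg(method)
  stopifnot(is.character(traits), length(traits) >= 1L)
  if (anyDuplicated(traits))
    stop2("duplicated trait name(s): ",
          paste(unique(traits[duplicated(traits)]), collapse = ", "))
  if (length(traits) > 4L) stop2("at most 4 traits are supported")
  if (!is.matrix(relationship) || is.null(rownames(relationship)))
    stop2("relationship must be a matrix with id dimnames")
  structure(list(traits = traits, fixed = fixed,
                 relationship = relationship, method = method),
            class = "vc_spec")
}

# Assemble y (n x t), X (n x p incl. intercept), aligned A submatrix.
# Univariate keeps complete cases; multivariate keeps rows with all covariates
# and at least one observed trait (observed-block likelihood downstream).
assemble_vc_data <- function(spec, data) {
  if (!"id" %in% names(data)) stop2("data must contain an 'id' column")
  miss <- setdiff(c(spec$traits, spec$fixed), names(data))
  if (length(miss)) stop2("column(s) not in data: ", paste(miss, collapse = ", "))
  t <- length(spec$traits)
  y <- as.matrix(sapply(spec$traits, function(tr) as.numeric(data[[tr]])))
  if (nrow(data) == 1L) y <- matrix(y, 1L, t, dimnames = list(NULL, spec$traits))
  fml <- if (length(spec$fixed))
    stats::reformulate(spec$fixed) else ~ 1
  mf <- stats::model.frame(fml, data = data, na.action = stats::na.pass)
  X <- stats::model.matrix(fml, mf)
  cov_ok <- stats::complete.cases(X)
  keep <- if (t == 1L) cov_ok & !is.na(y[, 1L]) else cov_ok & rowSums(!is.na(y)) > 0L
  ids <- as.character(data$id[keep])
  unknown <- setdiff(ids, rownames(spec$relationship))
  if (length(unknown))
    stop2("id(s) missing from relationship matrix: ",
          paste(utils::head(unknown, 5L), collapse = ", "))
  X <- X[keep, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop2("singular fixed-effect design; collinear term(s): ",
          paste(drop_cols, collapse = ", "))
  }
  list(y = y[keep, , drop = FALSE], X = X, ids = ids,
       A = spec$relationship[ids, ids, drop = FALSE],
       complete = !anyNA(y[keep, , drop = FALSE]))
}

# ---- univariate profile likelihood on the eigen-rotated scale ----------------
# With A = U D U', V = sigmaE (lambda D + I) after rotation; beta and sigmaE
# profile out in closed form for both REML and ML.
uni_profile <- function(lambda, d, ystar, Xstar, reml) {
  n <- length(ystar); p <- ncol(Xstar)
  w <- 1 / (lambda * d + 1)
  XtWX <- crossprod(Xstar, Xstar * w)
  XtWy <- crossprod(Xstar, ystar * w)
  beta <- solve(XtWX, XtWy)
  r <- ystar - Xstar %*% beta
  rss <- sum(w * r^2)
  df <- if (reml) n - p else n
  sigmaE <- rss / df
  ll <- if (reml) {
    -0.5 * (df * log(sigmaE) + sum(log(lambda * d + 1)) +
              determinant(XtWX, logarithm = TRUE)$modulus[1L] +
              df + df * log(2 * pi))
  } else {
    -0.5 * (n * log(sigmaE) + sum(log(lambda * d + 1)) + n + n * log(2 * pi))
  }
  list(loglik = ll, beta = drop(beta), sigmaE = sigmaE,
       cov_beta = solve(XtWX) * sigmaE)
}

#' Fit a univariate variance-components model by REML or ML
#'
#' Decomposes the phenotypic variance of one trait into additive genetic
#' (\eqn{V_A}) and residual environmental (\eqn{V_E}) components with fixed
#' covariate effects, using the eigendecomposition of the relationship matrix
#' so that the variance-ratio profile likelihood is maximised in one
#' dimension (coarse grid then Brent refinement; deterministic, no seeds).
#' Boundary solutions are reported as \eqn{V_A = 0} with a flag; when the
#' relationship matrix is the identity (unrelated individuals) heritability
#' is not identifiable and is flagged as such.
#'
#' @param spec a \code{\link{vc_spec}} with a single trait.
#' @param data data frame with columns \code{id}, the trait and covariates.
#' @param se compute standard errors (numerical observed information for the
#'   variance components, delta method for \eqn{h^2}).
#' @param constrain \code{"none"} or \code{"va_zero"} (null model with
#'   \eqn{V_A} fixed at 0, for likelihood-ratio tests).
#' @return object of class \code{vc_fit}: \code{V_A}, \code{V_E}, \code{h2}
#'   (+ SEs), \code{beta}/\code{beta_se}, \code{loglik}, \code{n_used},
#'   \code{boundary}, \code{non_identifiable}.
#' @export
fit_univariate <- function(spec, data, se = TRUE,
                           constrain = c("none", "va_zero")) {
  constrain <- match.arg(constrain)
  stopifnot(inherits(spec, "vc_spec"))
  if (length(spec$traits) != 1L)
    stop2("fit_univariate expects exactly 1 trait; use fit_multivariate")
  md <- assemble_vc_data(spec, data)
  y <- md$y[, 1L]; X <- md$X; n <- length(y)
  if (n < 2L) stop2("need >= 2 complete rows")
  if (stats::var(y) < .Machine$double.eps)
    stop2("zero phenotypic variance for trait ", spec$traits[1L])
  reml <- spec$method == "REML"
  eg <- eigen(md$A, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ystar <- drop(crossprod(U, y))
  Xstar <- crossprod(U, X)
  non_ident <- max(abs(md$A - diag(n))) < 1e-10
  f <- function(h) uni_profile(h / (1 - h), d, ystar, Xstar, reml)$loglik
  if (constrain == "va_zero" || non_ident) {
    h_hat <- 0
  } else {
    grid <- seq(0, 0.98, by = 0.02)
    lg <- vapply(grid, f, numeric(1))
    i0 <- which.max(lg)
    lo <- grid[max(1L, i0 - 1L)]; hi <- min(grid[min(length(grid), i0 + 1L)], 0.999999)
    opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE, tol = 1e-10)
    h_hat <- opt$maximum
    if (f(0) >= opt$objective - 1e-9) h_hat <- 0
  }
  boundary <- h_hat <= 1e-7
  if (boundary) h_hat <- 0
  lam <- h_hat / (1 - h_hat)
  sol <- uni_profile(lam, d, ystar, Xstar, reml)
  V_E <- sol$sigmaE
  V_A <- lam * V_E
  h2 <- V_A / (V_A + V_E)
  fit <- list(spec = spec, trait = spec$traits[1L], method = spec$method,
              V_A = V_A, V_E = V_E, h2 = h2,
              beta = stats::setNames(sol$beta, colnames(X)),
              beta_se = stats::setNames(sqrt(diag(sol$cov_beta)), colnames(X)),
              loglik = sol$loglik, n_used = n, ids = md$ids,
              boundary = boundary, non_identifiable = non_ident,
              V_A_se = NA_real_, V_E_se = NA_real_, h2_se = NA_real_)
  if (se && !boundary && !non_ident) {
    # unprofiled REML/ML in (V_A, V_E) for the observed information
    llv <- function(th) {
      VA <- th[1L]; VE <- th[2L]
      v <- VA * d + VE
      w <- 1 / v
      XtWX <- crossprod(Xstar, Xstar * w)
      beta <- solve(XtWX, crossprod(Xstar, ystar * w))
      r <- ystar - Xstar %*% beta
      quad <- sum(w * r^2)
      if (reml) {
        -0.5 * (sum(log(v)) + determinant(XtWX, logarithm = TRUE)$modulus[1L] +
                  quad + (n - ncol(X)) * log(2 * pi))
      } else {
        -0.5 * (sum(log(v)) + quad + n * log(2 * pi))
      }
    }
    H <- tryCatch(pracma::hessian(llv, c(V_A, V_E)), error = function(e) NULL)
    if (!is.null(H) && all(is.finite(H))) {
      cov_vc <- tryCatch(solve(-H), error = function(e) NULL)
      if (!is.null(cov_vc) && all(diag(cov_vc) > 0)) {
        fit$V_A_se <- sqrt(cov_vc[1L, 1L])
        fit$V_E_se <- sqrt(cov_vc[2L, 2L])
        g <- c(V_E, -V_A) / (V_A + V_E)^2  # delta method for h2
        fit$h2_se <- sqrt(drop(t(g) %*% cov_vc %*% g))
      }
    }
  }
  class(fit) <- "vc_fit"
  fit
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("Univariate variance-components fit (", x$method, "), trait ", x$trait,
      ", n = ", x$n_used, "\n", sep = "")
  cat(sprintf("  V_A = %.4g  V_E = %.4g  h2 = %.3f", x$V_A, x$V_E, x$h2))
  if (is.finite(x$h2_se)) cat(sprintf(" (SE %.3f)", x$h2_se))
  if (x$boundary) cat("  [V_A at boundary]")
  if (x$non_identifiable) cat("  [h2 not identifiable: A = I]")
  cat("\n  logLik =", format(x$loglik, digits = 8), "\n")
  invisible(x)
}

# ---- direct dense likelihood (oracle) ---------------------------------------

#' Exact dense log-likelihood of a variance-components model
#'
#' Evaluates the multivariate-normal log density of the observed trait vector
#' directly from the dense total covariance \eqn{V = A V_A + I V_E}
#' (univariate) or \eqn{V = A \otimes G + I \otimes E} (multivariate,
#' individual-major ordering), dropping rows/columns for missing trait
#' entries (observed-block likelihood).  With \code{method = "ML"} the
#' supplied fixed effects \code{beta} are used; with \code{"REML"} the
#' restricted likelihood of residual contrasts is returned (independent of
#' \code{beta}).  This evaluator is deliberately independent of the
#' rotation-based fitting path and serves as its oracle.
#'
#' @param spec a \code{\link{vc_spec}}.
#' @param data data frame with \code{id}, traits and covariates.
#' @param params list with \code{V_A}, \code{V_E} (univariate) or \code{G},
#'   \code{E} (multivariate), and \code{beta} for ML (vector, or p x t matrix).
#' @return log-likelihood (scalar).
#' @export
vc_loglik <- function(spec, data, params) {
  stopifnot(inherits(spec, "vc_spec"))
  md <- assemble_vc_data(spec, data)
  t <- length(spec$traits)
  n <- nrow(md$y)
  G <- if (t == 1L) matrix(params$V_A, 1L, 1L) else as.matrix(params$G)
  E <- if (t == 1L) matrix(params$V_E, 1L, 1L) else as.matrix(params$E)
  Sigma <- kronecker(md$A, G) + kronecker(diag(n), E)
  obs <- which(t(!is.na(md$y)))          # individual-major: (i-1)*t + k
  yv <- as.vector(t(md$y))[obs]
  p <- ncol(md$X)
  Xbig <- matrix(0, n * t, t * p)
  for (k in seq_len(t))
    Xbig[(seq_len(n) - 1L) * t + k, (k - 1L) * p + seq_len(p)] <- md$X
  Xo <- Xbig[obs, , drop = FALSE]
  So <- Sigma[obs, obs, drop = FALSE]
  ch <- tryCatch(chol(So), error = function(e)
    stop2("total covariance is not positive definite"))
  logdet <- 2 * sum(log(diag(ch)))
  N <- length(yv)
  if (spec$method == "ML") {
    beta <- params$beta
    if (is.null(beta)) stop2("ML likelihood requires params$beta")
    mu <- drop(Xo %*% as.vector(as.matrix(beta)))
    z <- backsolve(ch, yv - mu, transpose = TRUE)
    -0.5 * (logdet + sum(z^2) + N * log(2 * pi))
  } else {
    Si_X <- backsolve(ch, backsolve(ch, Xo, transpose = TRUE))
    M <- crossprod(Xo, Si_X)
    beta_hat <- solve(M, crossprod(Si_X, yv))
    r <- yv - drop(Xo %*% beta_hat)
    z <- backsolve(ch, r, transpose = TRUE)
    -0.5 * (logdet + determinant(M, logarithm = TRUE)$modulus[1L] +
              sum(z^2) + (N - ncol(Xo)) * log(2 * pi))
  }
}

# ---- multivariate fit --------------------------------------------------------

# vectorized Cholesky of n stacked t x t matrices (array n x t x t)
chol_blocks <- function(V) {
  n <- dim(V)[1L]; t <- dim(V)[2L]
  if (any(!is.finite(V))) return(NULL)
  L <- array(0, dim(V))
  for (j in seq_len(t)) {
    s <- V[, j, j]
    if (j > 1L) for (k in seq_len(j - 1L)) s <- s - L[, j, k]^2
    if (any(!is.finite(s)) || any(s <= 0)) return(NULL)
    L[, j, j] <- sqrt(s)
    if (j < t) for (i in (j + 1L):t) {
      s2 <- V[, i, j]
      if (j > 1L) for (k in seq_len(j - 1L)) s2 <- s2 - L[, i, k] * L[, j, k]
      L[, i, j] <- s2 / L[, j, j]
    }
  }
  L
}

# inverses of the same stacked matrices given their Cholesky factors
inv_blocks <- function(L) {
  n <- dim(L)[1L]; t <- dim(L)[2L]
  Li <- array(0, dim(L))
  for (j in seq_len(t)) {
    Li[, j, j] <- 1 / L[, j, j]
    if (j < t) for (i in (j + 1L):t) {
      s <- 0
      for (k in j:(i - 1L)) s <- s + L[, i, k] * Li[, k, j]
      Li[, i, j] <- -s / L[, i, i]
    }
  }
  Vi <- array(0, dim(L))
  for (a in seq_len(t)) for (b in seq_len(a)) {
    s <- 0
    for (k in a:t) s <- s + Li[, k, a] * Li[, k, b]
    Vi[, a, b] <- s; Vi[, b, a] <- s
  }
  Vi
}

theta_to_cov <- function(theta, t) {
  m <- t * (t + 1L) / 2L
  build <- function(v) {
    L <- matrix(0, t, t)
    L[lower.tri(L, diag = TRUE)] <- v
    diag(L) <- exp(diag(L))
    L %*% t(L)
  }
  list(G = build(theta[seq_len(m)]), E = build(theta[m + seq_len(m)]))
}

cov_to_theta <- function(G, E) {
  enc <- function(M) {
    L <- t(chol(M))
    diag(L) <- log(diag(L))
    L[lower.tri(L, diag = TRUE)]
  }
  c(enc(G), enc(E))
}

# rotated-block REML/ML negative log-likelihood for complete multivariate data
mv_nll_rotated <- function(theta, d, Ystar, Xstar, reml) {
  t <- ncol(Ystar); n <- nrow(Ystar); p <- ncol(Xstar)
  ge <- theta_to_cov(theta, t)
  V <- array(0, c(n, t, t))
  for (a in seq_len(t)) for (b in seq_len(t))
    V[, a, b] <- d * ge$G[a, b] + ge$E[a, b]
  L <- chol_blocks(V)
  if (is.null(L)) return(1e10)
  logdetV <- 2 * rowSums(log(matrix(vapply(seq_len(t), function(j) L[, j, j],
                                           numeric(n)), n, t)))
  Vi <- inv_blocks(L)
  M <- matrix(0, t * p, t * p)
  b <- numeric(t * p)
  for (a in seq_len(t)) for (k in seq_len(t)) {
    w <- Vi[, a, k]
    M[(a - 1L) * p + seq_len(p), (k - 1L) * p + seq_len(p)] <-
      crossprod(Xstar, Xstar * w)
    b[(a - 1L) * p + seq_len(p)] <- b[(a - 1L) * p + seq_len(p)] +
      crossprod(Xstar, w * Ystar[, k])
  }
  beta <- tryCatch(solve(M, b), error = function(e) NULL)
  if (is.null(beta)) return(1e10)
  R <- Ystar - Xstar %*% matrix(beta, p, t)
  quad <- 0
  for (a in seq_len(t)) for (k in seq_len(t))
    quad <- quad + sum(Vi[, a, k] * R[, a] * R[, k])
  N <- n * t
  nll <- if (reml) {
    0.5 * (sum(logdetV) + determinant(M, logarithm = TRUE)$modulus[1L] +
             quad + (N - t * p) * log(2 * pi))
  } else {
    0.5 * (sum(logdetV) + quad + N * log(2 * pi))
  }
  attr(nll, "beta") <- matrix(beta, p, t)
  attr(nll, "cov_beta") <- tryCatch(solve(M), error = function(e) NULL)
  nll
}

# dense observed-block negative log-likelihood (missing data path)
mv_nll_dense <- function(theta, md, traits, reml) {
  t <- length(traits); n <- nrow(md$y); p <- ncol(md$X)
  ge <- theta_to_cov(theta, t)
  Sigma <- kronecker(md$A, ge$G) + kronecker(diag(n), ge$E)
  obs <- which(t(!is.na(md$y)))
  yv <- as.vector(t(md$y))[obs]
  Xbig <- matrix(0, n * t, t * p)
  for (k in seq_len(t))
    Xbig[(seq_len(n) - 1L) * t + k, (k - 1L) * p + seq_len(p)] <- md$X
  Xo <- Xbig[obs, , drop = FALSE]
  So <- Sigma[obs, obs, drop = FALSE]
  ch <- tryCatch(chol(So), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  Si_X <- backsolve(ch, backsolve(ch, Xo, transpose = TRUE))
  M <- crossprod(Xo, Si_X)
  beta <- solve(M, crossprod(Si_X, yv))
  r <- yv - drop(Xo %*% beta)
  z <- backsolve(ch, r, transpose = TRUE)
  N <- length(yv)
  nll <- if (reml) {
    0.5 * (2 * sum(log(diag(ch))) + determinant(M, logarithm = TRUE)$modulus[1L] +
             sum(z^2) + (N - t * p) * log(2 * pi))
  } else {
    0.5 * (2 * sum(log(diag(ch))) + sum(z^2) + N * log(2 * pi))
  }
  attr(nll, "beta") <- matrix(beta, p, t)
  attr(nll, "cov_beta") <- tryCatch(solve(M), error = function(e) NULL)
  nll
}

#' Fit a multivariate variance-components model by REML or ML
#'
#' Joint additive-genetic (\eqn{G}) and environmental (\eqn{E}) covariance
#' matrices for 2-4 traits, parameterised through Cholesky factors so both
#' stay positive semi-definite by construction.  Complete data use a fast
#' eigen-rotated block likelihood; individuals missing some traits are kept
#' through the dense observed-block likelihood.  Genetic and environmental
#' correlations and per-trait heritabilities are derived from \eqn{G} and
#' \eqn{E}; correlations within \code{1e-3} of \eqn{\pm 1} are flagged
#' degenerate.
#'
#' @inheritParams fit_univariate
#' @param se compute standard errors for \eqn{h^2} and correlations
#'   (numerical observed information + delta method).
#' @return object of class \code{vc_fit_mv}: \code{G}, \code{E}, \code{r_G},
#'   \code{r_E}, \code{h2}, \code{beta} (p x t), \code{loglik},
#'   \code{n_used}, \code{degenerate}, optional \code{h2_se}, \code{r_G_se}.
#' @export
fit_multivariate <- function(spec, data, se = FALSE) {
  stopifnot(inherits(spec, "vc_spec"))
  t <- length(spec$traits)
  if (t < 2L) stop2("fewer than 2 traits: use fit_univariate")
  md <- assemble_vc_data(spec, data)
  reml <- spec$method == "REML"
  n <- nrow(md$y)
  v0 <- apply(md$y, 2L, stats::var, na.rm = TRUE)
  theta0 <- cov_to_theta(diag(v0 / 2, t), diag(v0 / 2, t))
  if (md$complete) {
    eg <- eigen(md$A, symmetric = TRUE)
    d <- pmax(eg$values, 0); U <- eg$vectors
    Ystar <- crossprod(U, md$y)
    Xstar <- crossprod(U, md$X)
    nll <- function(th) as.numeric(mv_nll_rotated(th, d, Ystar, Xstar, reml))
    nll_full <- function(th) mv_nll_rotated(th, d, Ystar, Xstar, reml)
  } else {
    nll <- function(th) as.numeric(mv_nll_dense(th, md, spec$traits, reml))
    nll_full <- function(th) mv_nll_dense(th, md, spec$traits, reml)
  }
  o1 <- stats::optim(theta0, nll, method = "Nelder-Mead",
                     control = list(maxit = 2000L * t, reltol = 1e-12))
  o2 <- stats::optim(o1$par, nll, method = "BFGS",
                     control = list(maxit = 500L, reltol = 1e-12))
  best <- if (o2$value <= o1$value) o2 else o1
  final <- nll_full(best$par)
  ge <- theta_to_cov(best$par, t)
  dimnames(ge$G) <- dimnames(ge$E) <- list(spec$traits, spec$traits)
  r_G <- stats::cov2cor(ge$G)
  r_E <- stats::cov2cor(ge$E)
  h2 <- diag(ge$G) / (diag(ge$G) + diag(ge$E))
  degen <- any(abs(r_G[upper.tri(r_G)]) > 1 - 1e-3) ||
    any(abs(r_E[upper.tri(r_E)]) > 1 - 1e-3)
  beta <- attr(final, "beta")
  dimnames(beta) <- list(colnames(md$X), spec$traits)
  cb <- attr(final, "cov_beta")
  beta_se <- if (!is.null(cb))
    matrix(sqrt(pmax(diag(cb), 0)), ncol(md$X), t,
           dimnames = dimnames(beta)) else NULL
  fit <- list(spec = spec, traits = spec$traits, method = spec$method,
              G = ge$G, E = ge$E, r_G = r_G, r_E = r_E,
              h2 = stats::setNames(h2, spec$traits),
              beta = beta, beta_se = beta_se,
              loglik = -as.numeric(final), n_used = n, ids = md$ids,
              degenerate = degen, converged = best$convergence == 0L,
              theta = best$par)
  if (se && !degen) {
    H <- tryCatch(pracma::hessian(nll, best$par), error = function(e) NULL)
    covp <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(covp)) {
      derived <- function(th) {
        g <- theta_to_cov(th, t)
        c(diag(g$G) / (diag(g$G) + diag(g$E)),
          stats::cov2cor(g$G)[upper.tri(g$G)],
          stats::cov2cor(g$E)[upper.tri(g$E)])
      }
      J <- pracma::jacobian(derived, best$par)
      vv <- diag(J %*% covp %*% t(J))
      vv[vv < 0] <- NA_real_
      m <- t * (t - 1L) / 2L
      fit$h2_se <- stats::setNames(sqrt(vv[seq_len(t)]), spec$traits)
      fit$r_G_se <- sqrt(vv[t + seq_len(m)])
      fit$r_E_se <- sqrt(vv[t + m + seq_len(m)])
    }
  }
  class(fit) <- "vc_fit_mv"
  fit
}

#' @export
print.vc_fit_mv <- function(x, ...) {
  cat("Multivariate variance-components fit (", x$method, "), traits: ",
      paste(x$traits, collapse = ", "), ", n = ", x$n_used, "\n", sep = "")
  cat("Heritabilities:\n"); print(round(x$h2, 3))
  cat("Genetic correlations:\n"); print(round(x$r_G, 3))
  cat("Environmental correlations:\n"); print(round(x$r_E, 3))
  if (x$degenerate) cat("[degenerate: correlation at boundary]\n")
  cat("logLik =", format(x$loglik, digits = 8), "\n")
  invisible(x)
}

#' Likelihood-ratio test for heritability
#'
#' Compares a fitted model against the same model with \eqn{V_A} constrained
#' to zero.  Because the null value lies on the boundary of the parameter
#' space, the statistic is referred to the mixture
#' \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1}.
#'
#' @param fit_full fit from \code{\link{fit_univariate}}.
#' @param fit_null same model fitted with \code{constrain = "va_zero"}.
#' @return list with \code{statistic} (clamped at 0) and \code{p}.
#' @export
lrt_heritability <- function(fit_full, fit_null) {
  if (!identical(fit_full$spec$fixed, fit_null$spec$fixed) ||
      !identical(fit_full$trait, fit_null$trait))
    stop2("full and null fits must share trait and fixed-effect specification")
  stat <- max(0, 2 * (fit_full$loglik - fit_null$loglik))
  p <- if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  list(statistic = stat, p = p)
}

#' Wald tests for fixed effects
#'
#' Two-sided normal tests of each fixed-effect estimate against zero using
#' its asymptotic standard error.
#'
#' @param fit a \code{vc_fit} or \code{vc_fit_mv}.
#' @return data frame with \code{term} (and \code{trait} for multivariate),
#'   \code{estimate}, \code{ase}, \code{z}, \code{p}.
#' @export
wald_fixed_effects <- function(fit) {
  if (inherits(fit, "vc_fit")) {
    z <- fit$beta / fit$beta_se
    return(data.frame(term = names(fit$beta), estimate = unname(fit$beta),
                      ase = unname(fit$beta_se), z = unname(z),
                      p = unname(2 * stats::pnorm(-abs(z))),
                      stringsAsFactors = FALSE))
  }
  if (inherits(fit, "vc_fit_mv")) {
    if (is.null(fit$beta_se)) stop2("fit carries no standard errors")
    out <- expand.grid(term = rownames(fit$beta), trait = colnames(fit$beta),
                       stringsAsFactors = FALSE)
    out$estimate <- as.vector(fit$beta)
    out$ase <- as.vector(fit$beta_se)
    out$z <- out$estimate / out$ase
    out$p <- 2 * stats::pnorm(-abs(out$z))
    return(out)
  }
  stop2("not a variance-components fit")
}
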