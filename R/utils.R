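# Dirichlet draws via normalised gammas
rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  g <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  g / rowSums(g)
}

# Per-chain (or per-task) seeds derived from one master seed; kept below
# 2^31 so they remain valid R/C++ integers.
deriveSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

clampProb <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# Logistic regression of a binary outcome on a single binary predictor:
# the ML fit is saturated, so the slope is the log odds ratio of the 2x2
# table and its Wald SE is sqrt(sum of reciprocal cell counts).
logit2x2 <- function(g, y) {
  n11 <- sum(g & y); n10 <- sum(g & !y)
  n01 <- sum(!g & y); n00 <- sum(!g & !y)
  if (min(n11, n10, n01, n00) == 0L)
    return(list(coef = c(NA, NA), p = c(NA, NA), separated = TRUE))
  b1 <- log(n11 / n10) - log(n01 / n00)
  se <- sqrt(1 / n11 + 1 / n10 + 1 / n01 + 1 / n00)
  z <- b1 / se
  list(coef = c(log(n01 / n00), b1), se = c(NA, se),
       p = c(NA, 2 * stats::pnorm(-abs(z))), separated = FALSE)
}

# Logistic regression by IRLS on a model matrix, returning Wald statistics
# for each coefficient.  Lighter than glm() for repeated fits in the power
# simulation.
fastLogit <- function(X, y, maxit = 25L, tol = 1e-8) {
  beta <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(X, z, w)
    newbeta <- fit$coefficients
    if (any(!is.finite(newbeta))) break
    done <- max(abs(newbeta - beta)) < tol
    beta <- newbeta
    if (done) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(cov)) {
    se <- rep(NA_real_, length(beta))
  } else {
    se <- sqrt(diag(cov))
  }
  z <- unname(beta / se)
  p <- 2 * stats::pnorm(-abs(z))
  list(coef = unname(beta), se = unname(se), z = z, p = p,
       separated = any(!is.finite(se)) || any(abs(beta) > 15))
}
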