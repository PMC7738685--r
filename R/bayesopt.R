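# Minimal Gaussian-process Bayesian optimization (maximization) with an
# expected-improvement acquisition, used for the (t, d) search. A Latin
# hypercube seeds the design; a squared-exponential GP with a small nugget
# is refit after every evaluation, its length-scale picked from a short grid
# by marginal likelihood. Everything is deterministic given `seed`.

dw_bayes_opt <- function(fn, lower, upper, n_calls = 30L, seed = 42L,
                         n_init = NULL, n_candidates = 512L) {
  d <- length(lower)
  if (is.null(n_init)) n_init <- min(max(d * 4L, 8L), n_calls)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  span <- upper - lower
  to_unit <- function(X) sweep(sweep(X, 2, lower), 2, span, "/")
  from_unit <- function(U) sweep(sweep(U, 2, span, "*"), 2, lower, "+")

  U <- lhs::maximinLHS(n_init, d)
  X <- from_unit(U)
  y <- apply(X, 1, fn)

  sqdist <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    pmax(outer(an, bn, "+") - 2 * tcrossprod(A, B), 0)
  }

  while (nrow(X) < n_calls) {
    Ut <- to_unit(X)
    ok <- is.finite(y)
    if (sum(ok) < 2L) {
      # too few successful evaluations to model; fall back to space filling
      u_new <- matrix(stats::runif(d), 1)
    } else {
      yy <- y[ok]
      mu_y <- mean(yy); sd_y <- stats::sd(yy)
      if (!is.finite(sd_y) || sd_y < 1e-12) sd_y <- 1
      z <- (yy - mu_y) / sd_y
      Uo <- Ut[ok, , drop = FALSE]
      D2 <- sqdist(Uo, Uo)
      best_ll <- -Inf; K_inv <- NULL; ell_best <- 0.3
      for (ell in c(0.1, 0.2, 0.35, 0.6, 1.0)) {
        K <- exp(-D2 / (2 * ell^2)) + diag(1e-6, nrow(Uo))
        ch <- tryCatch(chol(K), error = function(e) NULL)
        if (is.null(ch)) next
        alpha <- backsolve(ch, forwardsolve(t(ch), z))
        ll <- -0.5 * sum(z * alpha) - sum(log(diag(ch)))
        if (ll > best_ll) {
          best_ll <- ll; ell_best <- ell
          K_inv <- chol2inv(ch)
        }
      }
      cand <- matrix(stats::runif(n_candidates * d), ncol = d)
      Kc <- exp(-sqdist(cand, Uo) / (2 * ell_best^2))
      mu <- as.vector(Kc %*% (K_inv %*% z))
      var <- pmax(1 - rowSums((Kc %*% K_inv) * Kc), 1e-12)
      s <- sqrt(var)
      imp <- mu - max(z)
      zz <- imp / s
      ei <- imp * stats::pnorm(zz) + s * stats::dnorm(zz)
      u_new <- cand[which.max(ei), , drop = FALSE]
    }
    x_new <- from_unit(u_new)
    X <- rbind(X, x_new)
    y <- c(y, fn(as.vector(x_new)))
  }
  list(X = X, y = y, best = X[which.max(y), ], best_y = max(y[is.finite(y)]))
}
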