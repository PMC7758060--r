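#' Gumbel (type-I extreme value) distribution utilities
#'
#' Optimal local alignment scores under a random-sequence null follow a
#' Gumbel law; the package fits its location `mu` and scale `beta` to
#' empirical score samples by method of moments followed by maximum
#' likelihood. `pgumbel()`/`qgumbel()`/`rgumbel()` are the usual
#' distribution functions.
#'
#' @param x Numeric sample of scores.
#' @return `fit_gumbel()` returns a `gumbel_fit`: list with `mu`, `beta`,
#'   `n_samples`, `loglik`.
#' @examples
#' set.seed(1)
#' f <- fit_gumbel(rgumbel(5000, mu = 3, beta = 1.5))
#' c(f$mu, f$beta)
#' @export
fit_gumbel <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 100) abort("Gumbel fitting needs at least 100 samples")
  s <- sd(x)
  if (!is.finite(s) || s <= .Machine$double.eps) {
    abort("degenerate (zero-variance) score sample; increase the number of random samples")
  }
  # method-of-moments start
  beta0 <- s * sqrt(6) / pi
  mu0 <- mean(x) - euler_gamma * beta0
  nll <- function(par) {
    beta <- exp(par[2])
    z <- (x - par[1]) / beta
    n * par[2] + sum(z) + sum(exp(-z))
  }
  opt <- optim(c(mu0, log(beta0)), nll, method = "BFGS",
               control = list(reltol = 1e-12, maxit = 500))
  structure(
    list(mu = opt$par[1], beta = exp(opt$par[2]), n_samples = n,
         loglik = -opt$value),
    class = "gumbel_fit"
  )
}

#' @rdname fit_gumbel
#' @param q,p,n Quantiles, probabilities, sample size.
#' @param mu,beta Location and scale (`beta > 0`).
#' @param lower.tail If `FALSE`, return the survival probability.
#' @export
pgumbel <- function(q, mu = 0, beta = 1, lower.tail = TRUE) {
  p <- exp(-exp(-(q - mu) / beta))
  if (lower.tail) p else -expm1(-exp(-(q - mu) / beta))
}

#' @rdname fit_gumbel
#' @export
qgumbel <- function(p, mu = 0, beta = 1) mu - beta * log(-log(p))

#' @rdname fit_gumbel
#' @export
rgumbel <- function(n, mu = 0, beta = 1) qgumbel(runif(n), mu, beta)

#' @export
print.gumbel_fit <- function(x, ...) {
  cat(sprintf("<gumbel_fit> mu = %.4f, beta = %.4f (n = %d)\n",
              x$mu, x$beta, x$n_samples))
  invisible(x)
}

#' @export
tidy.gumbel_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "beta"), estimate = c(x$mu, x$beta))
}

#' @export
glance.gumbel_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, beta = x$beta, n_samples = x$n_samples,
                 logLik = x$loglik)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
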