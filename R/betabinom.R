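#' Beta-binomial distribution parameterized by mean and intraclass correlation
#'
#' Probability mass and cumulative distribution functions of the
#' beta-binomial distribution for a cluster of `size` binary outcomes with
#' marginal defect probability `prob` and pairwise within-cluster
#' correlation `rho` (the intraclass correlation, ICC).
#'
#' The latent cluster prevalence is Beta(a, b) with shapes
#' `a = prob * (1 - rho) / rho` and `b = (1 - prob) * (1 - rho) / rho`, the
#' unique beta with mean `prob` and `rho = 1 / (a + b + 1)`, so that `rho`
#' is exactly the correlation between two outcomes in the same cluster and
#' the count variance is inflated by the design effect
#' `1 + (size - 1) * rho`. `rho = 0` is the plain binomial, and
#' `prob` equal to 0 or 1 a point mass at 0 or `size`; both are handled as
#' exact special cases rather than limits. The pmf is evaluated in log
#' space and is stable for `size` well beyond 500.
#'
#' @param x,q Vector of counts, each in `0:size`. Values outside the
#'   support are an error (a count of defects cannot be negative nor
#'   exceed the cluster sample size).
#' @param size Number of trials (cluster sample size), positive integer.
#' @param prob Mean defect probability, in `[0, 1]`.
#' @param rho Intraclass correlation, in `[0, 1)`.
#' @param log,log.p If `TRUE`, probabilities are returned on the log scale.
#'
#' @return A numeric vector of probabilities, one per element of `x`
#'   (`q`).
#'
#' @examples
#' dbetabinom(0:9, size = 9, prob = 0.05, rho = 0.1)
#' # rho = 0 recovers the binomial exactly
#' all.equal(dbetabinom(0:5, 5, 0.25, 0), dbinom(0:5, 5, 0.25))
#' @export
dbetabinom <- function(x, size, prob, rho, log = FALSE) {
  check_count(size, "size", min = 1)
  check_number(prob, "prob", 0, 1)
  check_rho(rho)
  if (length(x) == 0L) return(numeric(0))
  if (any(is.na(x)) || any(x != round(x)) || any(x < 0) || any(x > size)) {
    stop("`x` must be integer counts within the support 0..", size,
         ", got ", paste(utils::head(x), collapse = ", "), call. = FALSE)
  }
  if (rho == 0) return(stats::dbinom(x, size, prob, log = log))
  lp <- betabinom_logpmf(x, size, prob, rho)
  if (log) lp else exp(lp)
}

#' @rdname dbetabinom
#' @export
pbetabinom <- function(q, size, prob, rho, log.p = FALSE) {
  check_count(size, "size", min = 1)
  check_number(prob, "prob", 0, 1)
  check_rho(rho)
  if (any(is.na(q)) || any(q != round(q)) || any(q < 0) || any(q > size)) {
    stop("`q` must be integer counts within the support 0..", size,
         call. = FALSE)
  }
  cdf <- cumsum(exp(betabinom_logpmf(0:size, size, prob, rho)))
  p <- cdf[q + 1L]
  p <- pmin(p, 1)
  if (log.p) log(p) else p
}

# log pmf over arbitrary x, exact special cases for rho = 0 and prob in {0,1}
betabinom_logpmf <- function(x, size, prob, rho) {
  if (rho == 0) return(stats::dbinom(x, size, prob, log = TRUE))
  if (prob == 0) return(ifelse(x == 0, 0, -Inf))
  if (prob == 1) return(ifelse(x == size, 0, -Inf))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  lchoose(size, x) + lbeta(a + x, b + size - x) - lbeta(a, b)
}

#' Beta shapes implied by a mean/ICC pair
#'
#' @param prob Mean defect probability in `(0, 1)`.
#' @param rho Intraclass correlation in `(0, 1)`.
#' @return Numeric vector `c(a = , b = )` of beta shape parameters.
#' @keywords internal
betabinom_shapes <- function(prob, rho) {
  c(a = prob * (1 - rho) / rho, b = (1 - prob) * (1 - rho) / rho)
}

#' Exact distribution of the pooled defect count over several clusters
#'
#' Distribution of the total number of defects across `m` independent,
#' equally sized clusters, each contributing a beta-binomial
#' (`size`, `prob`, `rho`) count. Cluster prevalences are drawn
#' independently, so the total is the `m`-fold convolution of the
#' single-cluster pmf; the convolution is carried out directly in
#' probability space (supports here are short, so this is accurate to
#' ~1e-14).
#'
#' @param m Number of clusters (positive integer).
#' @inheritParams dbetabinom
#' @param support_cap Maximum allowed total support `m * size`; guards
#'   against accidentally huge convolutions.
#'
#' @return An object of class `"cluster_total_pmf"`: a list with
#'   `support` (integers `0:(m*size)`), `mass` (probabilities summing to
#'   1), and the generating parameters `m`, `size`, `prob`, `rho`.
#'
#' @examples
#' tot <- cluster_total_pmf(m = 4, size = 9, prob = 0.25, rho = 0.1)
#' sum(tot$mass)                      # 1
#' sum(tot$mass[tot$support < 5])     # P(total < 5), the alpha risk at d = 5
#' @export
cluster_total_pmf <- function(m, size, prob, rho, support_cap = 10000) {
  check_count(m, "m", min = 1)
  check_count(size, "size", min = 1)
  if (m * size > support_cap) {
    stop("total support m * size = ", m * size, " exceeds support_cap = ",
         support_cap, call. = FALSE)
  }
  one <- dbetabinom(0:size, size, prob, rho)
  mass <- one
  if (m > 1) {
    for (i in 2:m) mass <- convolve_pmf(mass, one)
  }
  structure(
    list(support = 0:(m * size), mass = mass,
         m = as.integer(m), size = as.integer(size), prob = prob, rho = rho),
    class = "cluster_total_pmf"
  )
}

#' @export
print.cluster_total_pmf <- function(x, ...) {
  cat(sprintf(
    "pmf of the pooled count over %d cluster(s) of size %d (p = %g, rho = %g)\n",
    x$m, x$size, x$prob, x$rho))
  cat(sprintf("  support 0..%d, mean %.4f\n",
              max(x$support), sum(x$support * x$mass)))
  invisible(x)
}

# direct linear-space convolution of two pmfs
convolve_pmf <- function(x, y) {
  nx <- length(x)
  z <- numeric(nx + length(y) - 1L)
  for (i in seq_along(y)) {
    idx <- i:(i + nx - 1L)
    z[idx] <- z[idx] + y[i] * x
  }
  z
}
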