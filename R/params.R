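#' LQAS design parameters
#'
#' Bundle the four constraint parameters of a two-way LQAS classification
#' problem: the lower and upper prevalence thresholds and the maximum
#' tolerated misclassification risk at each.
#'
#' A lot (area) with defect prevalence at or above `p_u` must be classified
#' low quality with probability at least `1 - alpha_max`; a lot at or below
#' `p_l` must be classified acceptable with probability at least
#' `1 - beta_max`. Prevalences strictly between the thresholds (the "grey
#' area") are unconstrained.
#'
#' @param p_l Lower threshold proportion, in `[0, 1)`; prevalences at or
#'   below it should be classified acceptable.
#' @param p_u Upper threshold proportion, in `(p_l, 1]`; prevalences at or
#'   above it should be classified low quality.
#' @param alpha_max Maximum risk of classifying a lot at `p_u` as
#'   acceptable, in `(0, 1)`.
#' @param beta_max Maximum risk of classifying a lot at `p_l` as low
#'   quality, in `(0, 1)`.
#'
#' @return An object of class `"lqas_params"`: a named list with the four
#'   fields above.
#'
#' @examples
#' # data-quality assessment: flag cells with >= 25% register errors
#' lqas_params(p_l = 0.05, p_u = 0.25, alpha_max = 0.10, beta_max = 0.10)
#' @export
lqas_params <- function(p_l, p_u, alpha_max, beta_max) {
  check_number(p_l, "p_l", 0, 1)
  check_number(p_u, "p_u", 0, 1)
  if (p_l >= p_u) {
    stop("`p_l` (", p_l, ") must be strictly less than `p_u` (", p_u, ")",
         call. = FALSE)
  }
  check_number(alpha_max, "alpha_max", 0, 1, open = TRUE)
  check_number(beta_max, "beta_max", 0, 1, open = TRUE)
  structure(
    list(p_l = p_l, p_u = p_u, alpha_max = alpha_max, beta_max = beta_max),
    class = "lqas_params"
  )
}

#' @export
print.lqas_params <- function(x, ...) {
  cat("LQAS design parameters\n")
  cat(sprintf("  thresholds: p_l = %g, p_u = %g\n", x$p_l, x$p_u))
  cat(sprintf("  risk bounds: alpha_max = %g (at p_u), beta_max = %g (at p_l)\n",
              x$alpha_max, x$beta_max))
  invisible(x)
}

#' Cluster-LQAS design triple
#'
#' A C-LQAS system is defined by the number of clusters sampled `m`, the
#' number of individuals sampled per cluster `k`, and the decision rule
#' `d`: the total defect count over the `m * k` sampled units is compared
#' with `d`, and the lot is classified low quality when the total is `d`
#' or more.
#'
#' @param m Number of clusters sampled (positive integer).
#' @param k Individuals sampled per cluster (positive integer).
#' @param d Decision rule on the total count, `1 <= d <= m * k`.
#'
#' @return An object of class `"cluster_design"`.
#'
#' @examples
#' cluster_design(m = 4, k = 9, d = 5)
#' @export
cluster_design <- function(m, k, d) {
  check_count(m, "m", min = 1)
  check_count(k, "k", min = 1)
  check_count(d, "d", min = 1)
  if (d > m * k) {
    stop("decision rule `d` (", d, ") cannot exceed the total sample size ",
         "m * k = ", m * k, call. = FALSE)
  }
  structure(list(m = as.integer(m), k = as.integer(k), d = as.integer(d)),
            class = "cluster_design")
}

#' @export
print.cluster_design <- function(x, ...) {
  cat(sprintf("C-LQAS design: m = %d clusters, k = %d per cluster (n = %d), d = %d\n",
              x$m, x$k, x$m * x$k, x$d))
  invisible(x)
}

# internal validators ------------------------------------------------------

check_number <- function(x, name, lo, hi, open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("`", name, "` must be a single number, got ",
         deparse(substitute(x)), call. = FALSE)
  }
  bad <- if (open) (x <= lo || x >= hi) else (x < lo || x > hi)
  if (bad) {
    br <- if (open) c("(", ")") else c("[", "]")
    stop("`", name, "` must lie in ", br[1], lo, ", ", hi, br[2],
         ", got ", x, call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x != round(x) || x < min) {
    stop("`", name, "` must be a single integer >= ", min, ", got ",
         paste(x, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

check_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) ||
      rho < 0 || rho >= 1) {
    stop("intraclass correlation `rho` must lie in [0, 1), got ",
         paste(rho, collapse = ", "), call. = FALSE)
  }
  invisible(rho)
}
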