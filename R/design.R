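#' Exact misclassification risks of a cluster-LQAS design
#'
#' Computes the two classification error probabilities of a C-LQAS system
#' `{m, k, d}` under the beta-binomial model: the alpha risk
#' `P(total < d | p = p_u, rho)` of classifying a truly low-quality lot as
#' acceptable, and the beta risk `P(total >= d | p = p_l, rho)` of
#' classifying a truly acceptable lot as low quality. With `k = 1` or
#' `rho = 0` these reduce exactly to the classical binomial LQAS formulas.
#'
#' @param design A [cluster_design()].
#' @param params An [lqas_params()] object.
#' @param rho Intraclass correlation assumed for the risk calculation.
#' @param support_cap Passed to [cluster_total_pmf()].
#'
#' @return An object of class `"risk_profile"`: list with `alpha`, `beta`,
#'   and logicals `alpha_ok`, `beta_ok` comparing the (unrounded) risks
#'   against the bounds in `params`.
#'
#' @examples
#' chw <- lqas_params(0.05, 0.25, 0.10, 0.10)
#' # the k = 1 case is the plain binomial design n = 20, d = 3
#' classification_risks(cluster_design(20, 1, 3), chw, rho = 0.1)
#' classification_risks(cluster_design(4, 9, 5), chw, rho = 0.1)
#' @export
classification_risks <- function(design, params, rho,
                                 support_cap = 10000) {
  stopifnot(inherits(design, "cluster_design"), inherits(params, "lqas_params"))
  check_rho(rho)
  cdf_u <- cumsum(cluster_total_pmf(design$m, design$k, params$p_u, rho,
                                    support_cap)$mass)
  cdf_l <- cumsum(cluster_total_pmf(design$m, design$k, params$p_l, rho,
                                    support_cap)$mass)
  alpha <- cdf_u[design$d]          # P(total <= d - 1 | p_u)
  beta <- 1 - cdf_l[design$d]       # P(total >= d | p_l)
  structure(
    list(alpha = alpha, beta = beta,
         alpha_ok = alpha <= params$alpha_max,
         beta_ok = beta <= params$beta_max,
         design = design, params = params, rho = rho),
    class = "risk_profile"
  )
}

#' @export
print.risk_profile <- function(x, digits = 3, ...) {
  cat(sprintf("misclassification risks at rho = %g:\n", x$rho))
  cat(sprintf("  alpha = %.*f (bound %g) %s\n", digits, x$alpha,
              x$params$alpha_max, if (x$alpha_ok) "ok" else "EXCEEDED"))
  cat(sprintf("  beta  = %.*f (bound %g) %s\n", digits, x$beta,
              x$params$beta_max, if (x$beta_ok) "ok" else "EXCEEDED"))
  invisible(x)
}

#' Classical (simple random sampling) LQAS design
#'
#' Smallest total sample size `n` under the binomial model for which some
#' decision rule `d` keeps both misclassification risks within their
#' bounds: `P(X < d | n, p_u) <= alpha_max` and
#' `P(X >= d | n, p_l) <= beta_max`. This `n_min` is the baseline that a
#' clustered design must at least match in information.
#'
#' Because the alpha risk is nondecreasing and the beta risk nonincreasing
#' in `d`, the admissible `d` at a given `n` form a contiguous range;
#' `d_rule` selects the reported one (see [clqas_min_k()]).
#'
#' @param params An [lqas_params()] object.
#' @param n_max Search cap on `n`; infeasibility is only ever reported
#'   relative to this cap.
#' @param d_rule `"minimax"` (default) reports the admissible `d`
#'   minimizing `max(alpha, beta)`; `"smallest"` reports the smallest
#'   admissible `d`.
#'
#' @return An object of class `"lqas_design"`: list with `n`, `d`,
#'   `alpha`, `beta`.
#'
#' @examples
#' binomial_lqas_design(lqas_params(0.05, 0.25, 0.10, 0.10))  # n = 20, d = 3
#' @export
binomial_lqas_design <- function(params, n_max = 1000,
                                 d_rule = c("minimax", "smallest")) {
  stopifnot(inherits(params, "lqas_params"))
  d_rule <- match.arg(d_rule)
  for (n in seq_len(n_max)) {
    d <- seq_len(n)
    alpha <- stats::pbinom(d - 1, n, params$p_u)
    beta <- 1 - stats::pbinom(d - 1, n, params$p_l)
    sel <- pick_d(alpha, beta, params, d_rule)
    if (!is.na(sel)) {
      return(structure(
        list(n = n, d = sel, alpha = alpha[sel], beta = beta[sel],
             params = params),
        class = "lqas_design"
      ))
    }
  }
  stop("no binomial LQAS design with n <= ", n_max,
       " satisfies the risk bounds", call. = FALSE)
}

#' @export
print.lqas_design <- function(x, digits = 3, ...) {
  cat(sprintf("binomial LQAS design: n = %d, d = %d (alpha = %.*f, beta = %.*f)\n",
              x$n, x$d, digits, x$alpha, digits, x$beta))
  invisible(x)
}

#' Lower bound on the number of clusters from the intraclass correlation
#'
#' In the limit of infinitely many individuals per cluster, a C-LQAS
#' system behaves like a binomial design on the cluster prevalences, and
#' at least `rho * n_min` clusters are needed to meet the risk bounds,
#' where `n_min` is the unclustered LQAS sample size. The returned
#' `ceiling(rho * n_min)` is a search hint, not a feasibility verdict:
#' [clqas_min_k()] always decides feasibility by direct search.
#'
#' @param rho Intraclass correlation in `[0, 1)`.
#' @param n_min Minimal unclustered LQAS sample size (see
#'   [binomial_lqas_design()]).
#'
#' @return Integer lower bound on the number of clusters (0 when
#'   `rho = 0`).
#'
#' @examples
#' feasibility_min_clusters(0.1, 20)  # 2
#' feasibility_min_clusters(0.2, 20)  # 4
#' @export
feasibility_min_clusters <- function(rho, n_min) {
  check_rho(rho)
  check_count(n_min, "n_min", min = 1)
  # guard against binary-representation overshoot (0.1 * 20 > 2 in doubles)
  as.integer(ceiling(rho * n_min - 1e-9))
}

#' Minimal per-cluster sample size for a fixed number of clusters
#'
#' For `m` clusters and an assumed intraclass correlation, finds the
#' smallest per-cluster sample size `k` for which some decision rule `d`
#' keeps both misclassification risks of the pooled-count test within
#' their bounds, and reports that `d`. Minimality is certified by the
#' search itself: every `k' < k` was checked and admits no valid `d`.
#'
#' Among the admissible decision rules at the minimal `k` (a contiguous
#' range, by monotonicity of the risks in `d`), the default `"minimax"`
#' rule reports the `d` minimizing the larger of the two risks, breaking
#' exact ties toward the smaller `d`; `"smallest"` reports the smallest
#' admissible `d` (which always attains the smallest alpha risk).
#'
#' @param m Number of clusters sampled.
#' @param params An [lqas_params()] object.
#' @param rho Intraclass correlation assumed in the design.
#' @param k_max Cap on the per-cluster sample size search; infeasibility
#'   is reported relative to this cap, never absolutely.
#' @param d_rule See Details.
#' @param support_cap Passed to [cluster_total_pmf()].
#'
#' @return An object of class `"clqas_design"`: list with `m`, `k`, `d`,
#'   `alpha`, `beta`, `rho`, `feasible`. When no `k <= k_max` works,
#'   `feasible` is `FALSE` and `k`, `d`, `alpha`, `beta` are `NA`.
#'
#' @examples
#' chw <- lqas_params(0.05, 0.25, 0.10, 0.10)
#' clqas_min_k(m = 4, chw, rho = 0.1)   # k = 9, d = 5
#' clqas_min_k(m = 2, chw, rho = 0.15)  # infeasible below k_max
#' @export
clqas_min_k <- function(m, params, rho, k_max = 500,
                        d_rule = c("minimax", "smallest"),
                        support_cap = 10000) {
  check_count(m, "m", min = 1)
  stopifnot(inherits(params, "lqas_params"))
  check_rho(rho)
  check_count(k_max, "k_max", min = 1)
  d_rule <- match.arg(d_rule)
  for (k in seq_len(k_max)) {
    cdf_u <- cumsum(cluster_total_pmf(m, k, params$p_u, rho,
                                      support_cap)$mass)
    cdf_l <- cumsum(cluster_total_pmf(m, k, params$p_l, rho,
                                      support_cap)$mass)
    nd <- m * k
    alpha <- cdf_u[seq_len(nd)]
    beta <- 1 - cdf_l[seq_len(nd)]
    sel <- pick_d(alpha, beta, params, d_rule)
    if (!is.na(sel)) {
      return(structure(
        list(m = as.integer(m), k = as.integer(k), d = as.integer(sel),
             alpha = alpha[sel], beta = beta[sel], rho = rho,
             feasible = TRUE, params = params),
        class = "clqas_design"
      ))
    }
  }
  structure(
    list(m = as.integer(m), k = NA_integer_, d = NA_integer_,
         alpha = NA_real_, beta = NA_real_, rho = rho,
         feasible = FALSE, k_max = k_max, params = params),
    class = "clqas_design"
  )
}

#' @export
print.clqas_design <- function(x, digits = 3, ...) {
  if (x$feasible) {
    cat(sprintf(
      "C-LQAS design at rho = %g: m = %d, k = %d (n = %d), d = %d\n",
      x$rho, x$m, x$k, x$m * x$k, x$d))
    cat(sprintf("  alpha = %.*f, beta = %.*f\n",
                digits, x$alpha, digits, x$beta))
  } else {
    cat(sprintf(
      "no feasible C-LQAS design at rho = %g with m = %d clusters and k <= %d\n",
      x$rho, x$m, x$k_max))
  }
  invisible(x)
}

# shared d selection: admissible rules, unrounded comparison against bounds
pick_d <- function(alpha, beta, params, d_rule) {
  ok <- which(alpha <= params$alpha_max & beta <= params$beta_max)
  if (length(ok) == 0L) return(NA_integer_)
  switch(d_rule,
    smallest = ok[1L],
    minimax = ok[which.min(pmax(alpha[ok], beta[ok]))]
  )
}

#' Design table over a grid of intraclass correlations and cluster counts
#'
#' Runs the minimal-`k` search of [clqas_min_k()] for every combination of
#' assumed intraclass correlation and number of clusters, returning one
#' row per `(rho, m)` with the selected per-cluster size, decision rule,
#' exact risks, feasibility flag, and (optionally) total costs under one
#' or more cost scenarios.
#'
#' @param params An [lqas_params()] object.
#' @param rho Vector of intraclass correlations, each in `[0, 1)`.
#' @param m_range Integer vector of cluster counts. Default `2:n_min`,
#'   where `n_min` is the unclustered sample size from
#'   [binomial_lqas_design()] (at `m = n_min` the design collapses to the
#'   simple-random-sampling one with `k = 1`).
#' @param k_max,d_rule,support_cap Passed to [clqas_min_k()].
#' @param cost_scenarios Optional list of [cost_scenario()] objects; one
#'   cost column is appended per scenario.
#'
#' @return A `data.frame` with columns `rho`, `m`, `k`, `n`, `d`,
#'   `alpha`, `beta`, `feasible`, and `cost_1`, `cost_2`, ... when cost
#'   scenarios are supplied. Risks are unrounded.
#'
#' @examples
#' chw <- lqas_params(0.05, 0.25, 0.10, 0.10)
#' tab <- design_table(chw, rho = 0.1, m_range = 2:6)
#' tab
#' @export
design_table <- function(params, rho, m_range = NULL, k_max = 500,
                         d_rule = c("minimax", "smallest"),
                         support_cap = 10000, cost_scenarios = NULL) {
  stopifnot(inherits(params, "lqas_params"))
  d_rule <- match.arg(d_rule)
  for (r in rho) check_rho(r)
  if (is.null(m_range)) {
    n_min <- binomial_lqas_design(params)$n
    m_range <- seq(2L, n_min)
  }
  grid <- expand.grid(m = m_range, rho = rho)[, c("rho", "m")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    des <- clqas_min_k(grid$m[i], params, grid$rho[i], k_max = k_max,
                       d_rule = d_rule, support_cap = support_cap)
    data.frame(rho = grid$rho[i], m = des$m, k = des$k,
               n = if (des$feasible) des$m * des$k else NA_integer_,
               d = des$d, alpha = des$alpha, beta = des$beta,
               feasible = des$feasible)
  })
  out <- do.call(rbind, rows)
  if (!is.null(cost_scenarios)) {
    if (inherits(cost_scenarios, "cost_scenario")) {
      cost_scenarios <- list(cost_scenarios)
    }
    for (i in seq_along(cost_scenarios)) {
      sc <- cost_scenarios[[i]]
      stopifnot(inherits(sc, "cost_scenario"))
      out[[paste0("cost_", i)]] <-
        ifelse(out$feasible, sc$per_cluster * out$m + sc$per_individual * out$n,
               NA_real_)
    }
  }
  rownames(out) <- NULL
  out
}

#' Operating characteristic curve of a cluster-LQAS design
#'
#' Probability of classifying a lot as low quality,
#' `P(total >= d | p, rho)`, as a function of the true defect prevalence
#' `p`. The curve is nondecreasing in `p`; at `p = p_l` it equals the beta
#' risk and at `p = p_u` it equals `1 - alpha`.
#'
#' @param design A [cluster_design()].
#' @param rho Intraclass correlation.
#' @param p_grid Vector of prevalences in `[0, 1]`.
#' @param support_cap Passed to [cluster_total_pmf()].
#'
#' @return A `data.frame` with columns `p` and `prob_low_quality`.
#'
#' @examples
#' oc <- oc_curve(cluster_design(4, 9, 5), rho = 0.1,
#'                p_grid = seq(0, 0.5, by = 0.05))
#' oc
#' @export
oc_curve <- function(design, rho, p_grid = seq(0, 1, by = 0.01),
                     support_cap = 10000) {
  stopifnot(inherits(design, "cluster_design"))
  check_rho(rho)
  if (any(p_grid < 0 | p_grid > 1)) {
    stop("`p_grid` values must lie in [0, 1]", call. = FALSE)
  }
  prob <- vapply(p_grid, function(p) {
    cdf <- cumsum(cluster_total_pmf(design$m, design$k, p, rho,
                                    support_cap)$mass)
    1 - cdf[design$d]
  }, numeric(1))
  data.frame(p = p_grid, prob_low_quality = prob)
}
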