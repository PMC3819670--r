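#' Simulate clustered binary defect counts
#'
#' Draws per-cluster defect counts from the beta-binomial model: for
#' `rho > 0` each cluster first draws a latent prevalence from the beta
#' distribution with mean `prob` and ICC `rho`, then a count from the
#' conditional binomial; for `rho = 0` counts are direct binomial draws.
#' Clusters (and replicates) are independent.
#'
#' @param m Number of clusters per replicate.
#' @param k Individuals sampled per cluster.
#' @param prob Mean defect probability.
#' @param rho Intraclass correlation in `[0, 1)`.
#' @param n_reps Number of independent replicates.
#' @param seed Integer seed; mandatory so every simulated sample is
#'   reproducible.
#'
#' @return An integer matrix with `n_reps` rows and `m` columns of
#'   per-cluster counts in `0:k`, with attribute `k`.
#'
#' @examples
#' simulate_counts(m = 4, k = 9, prob = 0.25, rho = 0.1, n_reps = 3, seed = 1)
#' @export
simulate_counts <- function(m, k, prob, rho, n_reps = 1, seed) {
  if (missing(seed)) {
    stop("`seed` is required: simulated samples must be reproducible",
         call. = FALSE)
  }
  check_count(seed, "seed")
  set.seed(seed)
  draw_counts(n_reps, m, k, prob, rho)
}

# RNG-stream version used internally (no set.seed; caller owns the stream)
draw_counts <- function(n_reps, m, k, prob, rho) {
  check_count(m, "m", min = 1)
  check_count(k, "k", min = 1)
  check_number(prob, "prob", 0, 1)
  check_rho(rho)
  check_count(n_reps, "n_reps", min = 1)
  n <- n_reps * m
  if (rho > 0 && prob > 0 && prob < 1) {
    sh <- betabinom_shapes(prob, rho)
    pi_latent <- stats::rbeta(n, sh[1], sh[2])
    counts <- stats::rbinom(n, k, pi_latent)
  } else {
    counts <- stats::rbinom(n, k, prob)
  }
  out <- matrix(as.integer(counts), nrow = n_reps, ncol = m)
  attr(out, "k") <- as.integer(k)
  out
}

#' Classify a sampled lot against a decision rule
#'
#' Applies the LQAS decision rule to one or more sampled lots: a lot is
#' classified `"low_quality"` when its total defect count is `d` or more
#' (the boundary is inclusive) and `"acceptable"` otherwise.
#'
#' @param counts Per-cluster defect counts: a vector (one lot) or a
#'   matrix with one lot per row, as returned by [simulate_counts()].
#' @param d Decision rule (positive integer).
#'
#' @return A character vector with one label per lot.
#'
#' @examples
#' classify_counts(c(0, 0, 0, 0), d = 5)  # "acceptable"
#' classify_counts(c(2, 1, 2, 0), d = 5)  # "low_quality" (total 5 >= d)
#' @export
classify_counts <- function(counts, d) {
  check_count(d, "d", min = 1)
  if (is.matrix(counts)) {
    totals <- rowSums(counts)
  } else {
    totals <- sum(counts)
  }
  ifelse(totals >= d, "low_quality", "acceptable")
}

#' ANOVA estimator of the intraclass correlation for binary outcomes
#'
#' Treats the `m * k` binary outcomes of a clustered sample as a balanced
#' one-way layout and estimates the ICC by the classical analysis-of-
#' variance moment estimator
#' `rho_hat = (MSB - MSW) / (MSB + (k - 1) * MSW)`, where MSB and MSW are
#' the between- and within-cluster mean squares. For binary data the mean
#' squares are functions of the per-cluster counts alone, so only the
#' counts are needed.
#'
#' The estimator is inestimable exactly when its denominator is zero,
#' i.e. when all `m * k` outcomes are identical (no events in any
#' cluster, or events everywhere); it is not range-restricted and can be
#' negative.
#'
#' @param counts Per-cluster defect counts (vector of length `m >= 2`).
#' @param k Individuals per cluster (`k >= 2`); taken from the `k`
#'   attribute of `counts` when present.
#'
#' @return An object of class `"icc_estimate"`: list with `value` (`NA`
#'   when inestimable), `msb`, `msw`, `estimable`.
#'
#' @examples
#' anova_icc(c(3, 0), k = 3)      # perfect clustering: rho_hat = 1
#' anova_icc(c(0, 0, 0, 0), k = 9)  # all zeros: inestimable
#' @export
anova_icc <- function(counts, k = attr(counts, "k")) {
  if (is.matrix(counts)) counts <- drop(counts)
  if (is.null(k)) stop("`k` must be supplied", call. = FALSE)
  m <- length(counts)
  check_count(k, "k", min = 2)
  if (m < 2) stop("at least m = 2 clusters are required", call. = FALSE)
  if (any(counts < 0 | counts > k | counts != round(counts))) {
    stop("`counts` must be integers in 0..k", call. = FALSE)
  }
  ms <- icc_mean_squares(matrix(counts, nrow = 1), k)
  denom <- ms$msb + (k - 1) * ms$msw
  estimable <- denom > 0
  structure(
    list(value = if (estimable) (ms$msb - ms$msw) / denom else NA_real_,
         msb = ms$msb[[1]], msw = ms$msw[[1]], estimable = estimable[[1]]),
    class = "icc_estimate"
  )
}

#' @export
print.icc_estimate <- function(x, ...) {
  if (x$estimable) {
    cat(sprintf("ANOVA ICC estimate: %.4f (MSB = %.4f, MSW = %.4f)\n",
                x$value, x$msb, x$msw))
  } else {
    cat("ANOVA ICC inestimable: all outcomes identical (zero denominator)\n")
  }
  invisible(x)
}

# vectorized mean squares over replicates (rows of a counts matrix);
# for binary outcomes sum(y^2) = sum(y), so SSW = sum_i (c_i - c_i^2 / k)
icc_mean_squares <- function(counts, k) {
  m <- ncol(counts)
  means <- counts / k
  grand <- rowMeans(means)
  ssb <- k * rowSums((means - grand)^2)
  ssw <- rowSums(counts - counts^2 / k)
  list(msb = ssb / (m - 1), msw = ssw / (m * (k - 1)))
}

# vectorized estimator; returns value (NA when inestimable) and flag
anova_icc_vec <- function(counts, k) {
  ms <- icc_mean_squares(counts, k)
  denom <- ms$msb + (k - 1) * ms$msw
  estimable <- denom > 0
  value <- ifelse(estimable, (ms$msb - ms$msw) / denom, NA_real_)
  list(value = value, estimable = estimable)
}

#' Empirical misclassification risks of a design by simulation
#'
#' Monte Carlo estimate of the alpha and beta risks of a C-LQAS design
#' when the true intraclass correlation is `true_rho` (which may differ
#' from the one assumed when the design was built): `alpha_hat` is the
#' fraction of replicates at `p = p_u` classified acceptable, `beta_hat`
#' the fraction at `p = p_l` classified low quality. Both converge to the
#' exact [classification_risks()] values as `n_reps` grows.
#'
#' @param design A [cluster_design()].
#' @param params An [lqas_params()] object.
#' @param true_rho Intraclass correlation generating the data.
#' @param n_reps Number of simulation replicates per threshold.
#' @param seed Integer root seed (mandatory).
#'
#' @return An object of class `"sim_summary"`: list with `alpha_hat`,
#'   `beta_hat`, `true_rho`, `n_reps`, `seed`.
#'
#' @examples
#' chw <- lqas_params(0.05, 0.25, 0.10, 0.10)
#' empirical_risks(cluster_design(4, 9, 5), chw, true_rho = 0.1,
#'                 n_reps = 2000, seed = 1)
#' @export
empirical_risks <- function(design, params, true_rho, n_reps = 10000, seed) {
  stopifnot(inherits(design, "cluster_design"), inherits(params, "lqas_params"))
  check_rho(true_rho)
  check_count(n_reps, "n_reps", min = 1)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  check_count(seed, "seed")
  set.seed(seed)
  at_u <- draw_counts(n_reps, design$m, design$k, params$p_u, true_rho)
  at_l <- draw_counts(n_reps, design$m, design$k, params$p_l, true_rho)
  structure(
    list(alpha_hat = mean(rowSums(at_u) < design$d),
         beta_hat = mean(rowSums(at_l) >= design$d),
         true_rho = true_rho, n_reps = n_reps, seed = seed,
         design = design),
    class = "sim_summary"
  )
}

#' @export
print.sim_summary <- function(x, ...) {
  cat(sprintf(
    "empirical risks over %d replicates at true rho = %g (seed %d):\n",
    x$n_reps, x$true_rho, x$seed))
  cat(sprintf("  alpha_hat = %.3f, beta_hat = %.3f\n",
              x$alpha_hat, x$beta_hat))
  invisible(x)
}

#' Simulation study of a design under ICC misspecification
#'
#' For each candidate true intraclass correlation, simulates the design at
#' both thresholds and summarises: the empirical alpha risk (from the
#' `p_u` simulations), the empirical beta risk (from the `p_l`
#' simulations), and — separately for each threshold — the mean and
#' standard deviation of the ANOVA ICC estimates over the replicates where
#' the estimator is estimable, together with the estimable fraction.
#' Replicates with an inestimable ICC still contribute to the risk
#' estimates; they are excluded only from the ICC moments.
#'
#' The whole study runs on a single seeded RNG stream, so a given
#' (arguments, seed) pair reproduces the summary bit for bit.
#'
#' @param design A [cluster_design()] with `k >= 2` (the ICC estimator
#'   needs at least two individuals per cluster).
#' @param params An [lqas_params()] object.
#' @param true_rho Vector of true intraclass correlations to study.
#' @param n_reps Replicates per (rho, threshold) condition.
#' @param seed Integer root seed (mandatory).
#'
#' @return A `data.frame` with one row per element of `true_rho` and
#'   columns `true_rho`, `alpha_hat`, `beta_hat`, `icc_mean_pl`,
#'   `icc_sd_pl`, `pct_estimable_pl`, `icc_mean_pu`, `icc_sd_pu`,
#'   `pct_estimable_pu`, `n_reps`; the seed is kept in the `"seed"`
#'   attribute.
#'
#' @examples
#' chw <- lqas_params(0.05, 0.25, 0.10, 0.10)
#' simulation_summary(cluster_design(4, 9, 5), chw,
#'                    true_rho = c(0.05, 0.1), n_reps = 500, seed = 1)
#' @export
simulation_summary <- function(design, params, true_rho, n_reps = 10000,
                               seed) {
  stopifnot(inherits(design, "cluster_design"), inherits(params, "lqas_params"))
  if (design$k < 2) {
    stop("the ANOVA ICC estimator requires k >= 2 individuals per cluster",
         call. = FALSE)
  }
  for (r in true_rho) check_rho(r)
  check_count(n_reps, "n_reps", min = 1)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  check_count(seed, "seed")
  set.seed(seed)
  rows <- lapply(true_rho, function(rho) {
    at_l <- draw_counts(n_reps, design$m, design$k, params$p_l, rho)
    at_u <- draw_counts(n_reps, design$m, design$k, params$p_u, rho)
    icc_l <- anova_icc_vec(at_l, design$k)
    icc_u <- anova_icc_vec(at_u, design$k)
    data.frame(
      true_rho = rho,
      alpha_hat = mean(rowSums(at_u) < design$d),
      beta_hat = mean(rowSums(at_l) >= design$d),
      icc_mean_pl = mean(icc_l$value, na.rm = TRUE),
      icc_sd_pl = stats::sd(icc_l$value, na.rm = TRUE),
      pct_estimable_pl = mean(icc_l$estimable),
      icc_mean_pu = mean(icc_u$value, na.rm = TRUE),
      icc_sd_pu = stats::sd(icc_u$value, na.rm = TRUE),
      pct_estimable_pu = mean(icc_u$estimable),
      n_reps = n_reps
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}
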