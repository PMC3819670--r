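# shared fixtures and independent oracles

chw_params <- function() lqas_params(0.05, 0.25, 0.10, 0.10)

# brute-force pmf of the pooled count: enumerate every m-tuple of cluster
# counts and weight by the product of single-cluster probabilities
# (independent of the convolution code path)
enum_total_pmf <- function(m, k, p, rho) {
  one <- dbetabinom(0:k, k, p, rho)
  grid <- expand.grid(rep(list(0:k), m))
  w <- apply(as.matrix(grid), 1, function(cc) prod(one[cc + 1]))
  totals <- rowSums(grid)
  vapply(0:(m * k), function(t) sum(w[totals == t]), numeric(1))
}

# exact moments of the ANOVA ICC estimator over estimable samples, by the
# same enumeration (binary mean squares are functions of the counts alone)
enum_icc_moments <- function(m, k, p, rho) {
  one <- dbetabinom(0:k, k, p, rho)
  grid <- as.matrix(expand.grid(rep(list(0:k), m)))
  w <- apply(grid, 1, function(cc) prod(one[cc + 1]))
  means <- grid / k
  grand <- rowMeans(means)
  msb <- k * rowSums((means - grand)^2) / (m - 1)
  msw <- rowSums(grid - grid^2 / k) / (m * (k - 1))
  denom <- msb + (k - 1) * msw
  est <- denom > 0
  val <- (msb - msw)[est] / denom[est]
  we <- w[est] / sum(w[est])
  list(mean = sum(we * val),
       sd = sqrt(sum(we * val^2) - sum(we * val)^2),
       pct_estimable = sum(w[est]))
}

# reference design table for the data-quality worked example
# (p_l=0.05, p_u=0.25, alpha_max=beta_max=0.10), long format; typo_* flags
# mark the three printed cells whose values contradict the table's own
# arithmetic and are excluded from reproduction checks
reference_design_table <- function() {
  blk <- function(rho, m, k, n, d, a, b) {
    data.frame(rho = rho, m = m, k = k, n = n, d = d, alpha = a, beta = b)
  }
  out <- rbind(
    blk(0.01, 2:20,
        c(13,7,5,4,5,3,4,3,2,2,3,2,2,2,2,2,2,2,1),
        c(26,21,20,20,30,21,32,27,20,22,36,26,28,30,32,34,36,38,20),
        c(4,3,3,3,4,3,5,4,3,3,5,4,4,4,5,5,5,5,3),
        c(0.093,0.081,0.096,0.095,0.040,0.077,0.073,0.069,0.092,0.062,
          0.036,0.081,0.056,0.038,0.071,0.050,0.035,0.024,0.091),
        c(0.048,0.091,0.079,0.078,0.065,0.087,0.022,0.045,0.076,0.096,
          0.034,0.040,0.050,0.062,0.021,0.027,0.033,0.041,0.075)),
    blk(0.025, 2:20,
        c(14,7,7,4,5,3,4,3,2,2,3,2,2,2,2,2,2,2,1),
        c(28,21,28,20,30,21,32,27,20,22,36,26,28,30,32,34,36,38,20),
        c(4,3,4,3,4,3,5,4,3,3,5,4,4,4,5,5,5,5,3),
        c(0.084,0.090,0.069,0.100,0.045,0.080,0.077,0.072,0.094,0.063,
          0.038,0.083,0.057,0.039,0.072,0.051,0.036,0.025,0.091),
        c(0.074,0.098,0.062,0.083,0.070,0.090,0.025,0.048,0.078,0.097,
          0.036,0.041,0.051,0.063,0.022,0.028,0.034,0.042,0.075)),
    blk(0.05, 2:20,
        c(18,10,7,6,5,3,4,3,2,2,3,2,2,2,2,2,2,2,1),
        c(36,30,28,30,30,21,4,27,20,22,36,26,28,30,32,34,36,38,20),
        c(5,4,4,4,4,3,5,4,3,3,5,4,4,4,5,5,5,5,20),
        c(0.093,0.071,0.082,0.056,0.052,0.085,0.085,0.076,0.097,0.065,
          0.041,0.086,0.060,0.041,0.075,0.053,0.038,0.026,0.091),
        c(0.083,0.095,0.073,0.082,0.078,0.094,0.029,0.052,0.080,0.100,
          0.040,0.043,0.054,0.065,0.023,0.029,0.036,0.044,0.075)),
    blk(0.1, 2:20,
        c(68,15,9,6,5,4,4,3,3,3,3,2,2,2,2,2,2,2,1),
        c(136,45,36,30,30,28,32,27,30,33,36,26,28,30,32,34,36,38,20),
        c(17,6,5,4,4,4,5,4,4,5,5,4,4,4,5,5,5,5,3),
        c(0.096,0.092,0.090,0.075,0.067,0.082,0.099,0.086,0.052,0.077,
          0.048,0.091,0.064,0.045,0.080,0.058,0.041,0.029,0.091),
        c(0.099,0.093,0.082,0.099,0.093,0.073,0.038,0.060,0.078,0.036,
          0.047,0.047,0.058,0.070,0.026,0.033,0.040,0.048,0.075)),
    blk(0.15, 3:20,
        c(45,13,9,6,4,5,3,3,3,3,2,2,2,2,2,2,2,1),
        c(135,52,45,36,28,40,27,30,33,36,26,28,30,32,34,36,38,20),
        c(17,7,6,5,4,6,4,4,5,5,4,28,4,5,5,5,5,3),
        c(0.099,0.100,0.082,0.087,0.095,0.090,0.096,0.060,0.086,0.055,
          0.096,0.069,0.049,0.085,0.062,0.045,0.032,0.091),
        c(0.099,0.090,0.087,0.080,0.083,0.043,0.067,0.086,0.042,0.053,
          0.051,0.062,0.074,0.029,0.036,0.043,0.051,0.075)),
    blk(0.2, 4:20,
        c(40,12,9,6,6,4,3,3,3,3,2,2,2,2,2,2,1),
        c(160,60,54,42,48,36,30,33,36,39,28,30,32,34,36,38,20),
        c(20,8,7,6,7,5,4,5,5,5,4,4,5,5,5,5,3),
        c(0.096,0.099,0.077,0.098,0.091,0.077,0.068,0.095,0.063,0.041,
          0.073,0.052,0.090,0.066,0.048,0.035,0.091),
        c(0.100,0.090,0.091,0.067,0.050,0.071,0.093,0.047,0.060,0.074,
          0.066,0.078,0.032,0.039,0.047,0.055,0.075))
  )
  out$typo_n <- out$rho == 0.05 & out$m == 8    # prints n = 4 for m*k = 32
  out$typo_d <- (out$rho == 0.05 & out$m == 20) |  # prints d = 20
                (out$rho == 0.15 & out$m == 14)    # prints d = 28
  out
}

# cells the reference table marks infeasible
reference_infeasible_cells <- function() {
  data.frame(rho = c(0.15, 0.2, 0.2), m = c(2, 2, 3))
}
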