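test_that("binomial LQAS search recovers classical designs", {
  chw <- chw_params()
  base <- binomial_lqas_design(chw)
  expect_equal(base$n, 20)
  expect_equal(base$d, 3)

  # p_l = 0 kills the beta constraint: smallest n with (1-p_u)^n <= alpha_max
  des <- binomial_lqas_design(lqas_params(0, 0.5, 0.1, 0.1))
  expect_equal(des$n, ceiling(log(0.1) / log(0.5)))
  expect_equal(des$d, 1)

  # very loose risks admit a single-observation design
  des1 <- binomial_lqas_design(lqas_params(0.05, 0.95, 0.5, 0.5))
  expect_equal(des1$n, 1)
  expect_equal(des1$d, 1)

  expect_error(binomial_lqas_design(lqas_params(0.05, 0.06, 0.01, 0.01),
                                    n_max = 50), "n <= 50")
})

test_that("classification risks match the binomial baseline and table cell", {
  chw <- chw_params()
  srs <- classification_risks(cluster_design(20, 1, 3), chw, rho = 0.1)
  expect_equal(round(srs$alpha, 3), 0.091)
  expect_equal(round(srs$beta, 3), 0.075)
  # k = 1 risks are ICC-free (one draw per cluster carries no correlation)
  srs0 <- classification_risks(cluster_design(20, 1, 3), chw, rho = 0)
  expect_equal(srs$alpha, srs0$alpha, tolerance = 1e-12)

  four <- classification_risks(cluster_design(4, 9, 5), chw, rho = 0.1)
  expect_equal(round(four$alpha, 3), 0.090)
  expect_equal(round(four$beta, 3), 0.082)
})

test_that("risks reduce to binomial formulas when rho = 0", {
  chw <- chw_params()
  rp <- classification_risks(cluster_design(5, 4, 3), chw, rho = 0)
  expect_equal(rp$alpha, pbinom(2, 20, 0.25), tolerance = 1e-12)
  expect_equal(rp$beta, 1 - pbinom(2, 20, 0.05), tolerance = 1e-12)
})

test_that("risk probabilities are complementary and degenerate cases exact", {
  chw <- chw_params()
  rp <- classification_risks(cluster_design(4, 9, 5), chw, rho = 0.1)
  tot <- cluster_total_pmf(4, 9, chw$p_u, 0.1)
  expect_equal(rp$alpha + sum(tot$mass[tot$support >= 5]), 1,
               tolerance = 1e-10)
  # no defects possible at p_l = 0, so any d >= 1 has zero beta risk
  z <- classification_risks(cluster_design(3, 4, 1),
                            lqas_params(0, 0.5, 0.2, 0.2), rho = 0.3)
  expect_equal(z$beta, 0)
})

test_that("alpha rises and beta falls as the decision rule increases", {
  chw <- chw_params()
  for (spec in list(c(4, 9), c(2, 13), c(9, 3))) {
    m <- spec[1]; k <- spec[2]
    risks <- t(vapply(seq_len(m * k), function(d) {
      rp <- classification_risks(cluster_design(m, k, d), chw, 0.1)
      c(rp$alpha, rp$beta)
    }, numeric(2)))
    expect_true(all(diff(risks[, 1]) >= -1e-12))
    expect_true(all(diff(risks[, 2]) <= 1e-12))
  }
})

test_that("cluster-count lower bound matches the ICC heuristic", {
  expect_identical(feasibility_min_clusters(0.1, 20), 2L)
  expect_identical(feasibility_min_clusters(0.2, 20), 4L)
  expect_identical(feasibility_min_clusters(0.15, 20), 3L)
  expect_identical(feasibility_min_clusters(0, 123), 0L)
})

test_that("minimal-k search reproduces known designs and reports infeasibility", {
  chw <- chw_params()
  d4 <- clqas_min_k(4, chw, rho = 0.1)
  expect_true(d4$feasible)
  expect_equal(d4$k, 9L)
  expect_equal(d4$d, 5L)

  d2 <- clqas_min_k(2, chw, rho = 0.01)
  expect_equal(d2$k, 13L)

  inf <- clqas_min_k(2, chw, rho = 0.15, k_max = 500)
  expect_false(inf$feasible)
  expect_true(is.na(inf$k))
  expect_equal(inf$k_max, 500)

  # rho = 0 collapses to the binomial search over n = m * k
  d5 <- clqas_min_k(5, chw, rho = 0)
  expect_equal(d5$k, 4L)
  expect_equal(d5$d, 3L)
})

test_that("returned designs satisfy their constraints and are k-minimal", {
  chw <- chw_params()
  cases <- expand.grid(m = c(2, 4, 7, 12), rho = c(0.01, 0.1))
  for (i in seq_len(nrow(cases))) {
    des <- clqas_min_k(cases$m[i], chw, cases$rho[i])
    expect_true(des$feasible)
    expect_lte(des$alpha, chw$alpha_max)
    expect_lte(des$beta, chw$beta_max)
    if (des$k > 1) {
      # no decision rule can rescue k - 1
      m <- des$m; k1 <- des$k - 1L
      ok <- vapply(seq_len(m * k1), function(d) {
        rp <- classification_risks(cluster_design(m, k1, d), chw, des$rho)
        rp$alpha_ok && rp$beta_ok
      }, logical(1))
      expect_false(any(ok))
    }
  }
})

test_that("per-cluster sample size grows with the assumed ICC", {
  chw <- chw_params()
  for (m in c(3, 4, 7)) {
    ks <- vapply(c(0.01, 0.05, 0.1, 0.2), function(r) {
      clqas_min_k(m, chw, r, k_max = 100)$k
    }, integer(1))
    ks <- ks[!is.na(ks)]  # small-m cells can be infeasible at high ICC
    expect_true(all(diff(ks) >= 0))
  }
})

test_that("design table covers the grid and collapses to SRS at rho = 0", {
  chw <- chw_params()
  tab <- design_table(chw, rho = c(0, 0.1), m_range = c(2, 4, 20))
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$n == tab$m * tab$k))
  srs <- tab[tab$rho == 0 & tab$m == 20, ]
  expect_equal(srs$k, 1L)
  expect_equal(srs$d, 3L)
  # default m range runs 2..n_min
  full <- design_table(chw, rho = 0.1)
  expect_equal(full$m, 2:20)
  expect_equal(range(full$n), c(20, 136))
})

test_that("infeasible grid rows are flagged, not dropped", {
  chw <- chw_params()
  tab <- design_table(chw, rho = 0.2, m_range = 2:4, k_max = 100)
  expect_equal(tab$feasible, c(FALSE, FALSE, TRUE))
  expect_true(all(is.na(tab$k[!tab$feasible])))
})

test_that("OC curve is a monotone bridge between the two risks", {
  chw <- chw_params()
  des <- cluster_design(4, 9, 5)
  oc <- oc_curve(des, rho = 0.1, p_grid = seq(0, 1, by = 0.05))
  expect_equal(oc$prob_low_quality[oc$p == 0], 0)
  expect_equal(oc$prob_low_quality[oc$p == 1], 1)
  expect_true(all(diff(oc$prob_low_quality) >= -1e-12))

  rp <- classification_risks(des, chw, 0.1)
  ends <- oc_curve(des, 0.1, p_grid = c(chw$p_l, chw$p_u))$prob_low_quality
  expect_equal(ends, c(rp$beta, 1 - rp$alpha), tolerance = 1e-12)
  # a valid design keeps the curve inside both constraint boxes
  expect_lte(ends[1], chw$beta_max)
  expect_gte(ends[2], 1 - chw$alpha_max)
})

test_that("malformed design inputs are rejected with named fields", {
  expect_error(lqas_params(0.3, 0.25, 0.1, 0.1), "p_l.*p_u")
  expect_error(lqas_params(0.05, 0.25, 0, 0.1), "alpha_max")
  expect_error(cluster_design(4, 9, 37), "d")
  expect_error(clqas_min_k(4, chw_params(), rho = 1.2), "rho")
})
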