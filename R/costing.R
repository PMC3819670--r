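#' Cost scenario for a two-stage sampling design
#'
#' Per-cluster and per-individual unit costs. The total cost of a C-LQAS
#' design `{m, k}` is `per_cluster * m + per_individual * m * k`: reaching
#' a cluster (travel, supervisor time) is paid once per cluster, and each
#' sampled individual adds a fixed marginal cost.
#'
#' @param per_cluster Cost of sampling one cluster (currency units,
#'   nonnegative).
#' @param per_individual Cost of sampling one individual (currency units,
#'   nonnegative). At least one of the two must be positive.
#'
#' @return An object of class `"cost_scenario"`.
#'
#' @examples
#' cost_scenario(per_cluster = 500, per_individual = 10)
#' @export
cost_scenario <- function(per_cluster, per_individual) {
  check_number(per_cluster, "per_cluster", 0, Inf)
  check_number(per_individual, "per_individual", 0, Inf)
  if (per_cluster == 0 && per_individual == 0) {
    stop("at least one of `per_cluster`, `per_individual` must be positive",
         call. = FALSE)
  }
  structure(list(per_cluster = per_cluster, per_individual = per_individual),
            class = "cost_scenario")
}

#' @export
print.cost_scenario <- function(x, ...) {
  cat(sprintf("cost scenario: %g per cluster + %g per individual\n",
              x$per_cluster, x$per_individual))
  invisible(x)
}

#' Total implementation cost of a design
#'
#' @param design A [cluster_design()] or a feasible `"clqas_design"`.
#' @param scenario A [cost_scenario()].
#'
#' @return The total cost `per_cluster * m + per_individual * m * k`.
#'
#' @examples
#' total_cost(cluster_design(3, 15, 6), cost_scenario(500, 10))  # 1950
#' @export
total_cost <- function(design, scenario) {
  stopifnot(inherits(design, c("cluster_design", "clqas_design")),
            inherits(scenario, "cost_scenario"))
  if (inherits(design, "clqas_design") && !design$feasible) {
    stop("cannot cost an infeasible design", call. = FALSE)
  }
  scenario$per_cluster * design$m + scenario$per_individual * design$m * design$k
}

#' Cheapest feasible design(s) in a design table
#'
#' Evaluates the total cost of every feasible row of a design table (as
#' produced by [design_table()]) under a cost scenario and returns all
#' cost-minimizing rows. Ties are preserved: distinct designs can have
#' identical total costs, and the choice among them is left to the user
#' (more clusters, for instance, is the more robust option when the
#' intraclass correlation is uncertain).
#'
#' @param rows A `data.frame` with at least columns `m`, `n`, `feasible`
#'   (a [design_table()] result, possibly filtered to one `rho`).
#' @param scenario A [cost_scenario()].
#'
#' @return The cost-minimizing feasible rows, with a `cost` column
#'   appended. Zero rows (with a warning) when no row is feasible.
#'
#' @examples
#' chw <- lqas_params(0.05, 0.25, 0.10, 0.10)
#' tab <- design_table(chw, rho = 0.1)
#' cheapest_design(tab, cost_scenario(500, 10))   # {m = 3, k = 15}, 1950
#' cheapest_design(tab, cost_scenario(300, 50))   # two-way tie at 3000
#' @export
cheapest_design <- function(rows, scenario) {
  stopifnot(is.data.frame(rows), nrow(rows) > 0,
            all(c("m", "n", "feasible") %in% names(rows)),
            inherits(scenario, "cost_scenario"))
  feas <- rows[rows$feasible, , drop = FALSE]
  if (nrow(feas) == 0L) {
    warning("no feasible designs among the supplied rows")
    feas$cost <- numeric(0)
    return(feas)
  }
  feas$cost <- scenario$per_cluster * feas$m + scenario$per_individual * feas$n
  out <- feas[feas$cost == min(feas$cost), , drop = FALSE]
  rownames(out) <- NULL
  out
}
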