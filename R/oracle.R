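# Exhaustive grid enumeration of small planning instances. This is an
# independent verification path for plan_region(): it walks every
# admissible open/close configuration and every case split on an integer
# grid, pricing each cell through the accounting functions directly, with
# none of the dynamic-programming machinery of the solver.

compositions_grid <- function(B, m, step) {
  if (m == 1) return(matrix(B, ncol = 1))
  pts <- unique(c(seq(0, B, by = step), B))
  out <- list()
  for (x1 in pts) {
    rest <- compositions_grid(B - x1, m - 1, step)
    out[[length(out) + 1]] <- cbind(x1, rest)
  }
  do.call(rbind, out)
}

#' Brute-force enumeration oracle for small planning instances
#'
#' Exhaustively enumerates all admissible ward-open configurations and all
#' case splits on an integer grid of width `case_step`, evaluating each
#' candidate with [ward_contribution()] and returning the best plan found.
#' With `case_step = 1` the result equals the [plan_region()] optimum; with
#' a coarser grid it is a lower bound. Instances whose grid exceeds
#' `max_cells` cells are refused with a size report.
#'
#' @param problem A `plan_problem` with at most 3 hospitals and 2 ward
#'   types.
#' @param case_step Grid width for the case splits.
#' @param max_cells Refusal threshold for the total number of grid cells.
#' @return A list with `objective`, `x`, `beta` and `cells_evaluated`, of
#'   class `enumerated_plan`.
#' @export
enumerate_plans <- function(problem, case_step = 1, max_cells = 2e4) {
  stopifnot(inherits(problem, "plan_problem"))
  if (problem$n_hospitals > 3 || length(problem$params$wards) > 2) {
    stop_invalid("instance too large for enumeration: %d hospitals x %d ward types (max 3 x 2)", # nolint
                 problem$n_hospitals, length(problem$params$wards))
  }
  wards <- problem$params$wards
  configs <- admissible_configs(problem)
  if (length(configs) == 0) {
    stop_invalid("infeasible scenario: no admissible configuration")
  }
  # count cells before evaluating anything
  n_cells <- 0
  for (beta in configs) {
    cells <- 1
    for (j in names(wards)) {
      m <- sum(beta[j, ])
      if (m == 0) next
      pts <- length(unique(c(seq(0, problem$demand[[j]], by = case_step),
                             problem$demand[[j]])))
      cells <- cells * pts^(m - 1)
    }
    n_cells <- n_cells + cells
  }
  if (n_cells > max_cells) {
    stop_invalid("instance too large for enumeration: %g grid cells exceed max_cells = %g; increase case_step", # nolint
                 n_cells, max_cells)
  }
  best <- NULL
  cells_evaluated <- 0
  for (beta in configs) {
    splits <- list()
    for (j in names(wards)) {
      m <- sum(beta[j, ])
      splits[[j]] <- if (m == 0) {
        matrix(numeric(0), nrow = 1, ncol = 0)
      } else {
        compositions_grid(problem$demand[[j]], m, case_step)
      }
    }
    idx <- expand.grid(lapply(splits, function(sp) seq_len(nrow(sp))))
    for (r in seq_len(nrow(idx))) {
      cells_evaluated <- cells_evaluated + 1
      obj <- 0
      x <- matrix(0, nrow = length(wards), ncol = problem$n_hospitals,
                  dimnames = list(names(wards), problem$hospital_names))
      for (j in names(wards)) {
        open_k <- which(beta[j, ] == 1)
        if (length(open_k)) x[j, open_k] <- splits[[j]][idx[r, j], ]
        for (k in open_k) {
          obj <- obj + ward_contribution(x[j, k], wards[[j]],
                                         problem$params,
                                         open = TRUE)$contribution_III
        }
      }
      obj <- obj - sum(problem$hospital_fixed[colSums(beta) > 0])
      if (is.null(best) || obj > best$objective + 1e-9) {
        best <- list(objective = obj, x = x, beta = beta)
      }
    }
  }
  best$cells_evaluated <- cells_evaluated
  class(best) <- "enumerated_plan"
  best
}

#' @export
print.enumerated_plan <- function(x, ...) {
  cat(sprintf("Enumerated plan: objective %s EUR over %d grid cells\n",
              formatC(round(x$objective), big.mark = ",", format = "d"),
              x$cells_evaluated))
  print(x$x)
  invisible(x)
}
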