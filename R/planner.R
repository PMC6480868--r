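# Exact location-allocation optimiser. The planning program maximises the
# regional contribution margin over which wards to open at which hospitals
# and how the regional case load is allocated, subject to: (I) staff
# capacity, (II-IV) big-M links between activity and ward/department/
# hospital open flags, and (V) full coverage of regional demand. Staff
# units and beds are integer with open-ward minima, so ward costs are step
# functions of the allocated cases.
#
# The instance sizes of regional planning (a handful of hospitals, two
# DRGs) admit an exact combinatorial solve: enumerate the admissible
# ward-open configurations and, for each, allocate every DRG's demand by
# dynamic programming (a min-plus convolution of the integer-case step-cost
# vectors). The result is provably optimal -- every configuration is
# visited and the allocation subproblem is solved exactly.

#' Define a ward-planning problem
#'
#' Bundles parameters, regional demand and scenario constraints into a
#' problem object for [plan_region()] and [enumerate_plans()].
#'
#' @param params A `ward_params` object.
#' @param demand Named vector of annual regional case counts per ward type
#'   (names must match `names(params$wards)`).
#' @param n_hospitals Number of candidate hospital sites.
#' @param hospital_names Optional site names.
#' @param hospital_fixed Hospital-level fixed costs, recycled to
#'   `n_hospitals` (default: `params$hospital_fixed`).
#' @param n_open_hospitals Scenario constraint: exactly this many hospitals
#'   open.
#' @param open_wards_per_drg Scenario constraint: exactly this many open
#'   wards per ward type (e.g. 1 concentrates each ward type in a single
#'   hospital).
#' @param wards_follow_hospital If `TRUE`, every open hospital hosts every
#'   ward type (ward-open flags tied to the hospital-open flag).
#' @param fixed_cases Optional ward-by-hospital matrix fixing the case
#'   allocation (rows = ward types, columns = hospitals); row sums must
#'   equal `demand`.
#' @param fixed_beds Optional ward-by-hospital matrix fixing bed stocks
#'   (only meaningful together with `fixed_cases`).
#' @param big_M Big-M constant linking activity to open flags; defaults to
#'   `sum(demand) + 1`.
#' @return An object of class `plan_problem`.
#' @export
plan_problem <- function(params = default_parameters(),
                         demand = c(paediatrics = 3373, obstetrics = 1437),
                         n_hospitals = 3,
                         hospital_names = NULL,
                         hospital_fixed = NULL,
                         n_open_hospitals = NULL,
                         open_wards_per_drg = NULL,
                         wards_follow_hospital = FALSE,
                         fixed_cases = NULL,
                         fixed_beds = NULL,
                         big_M = NULL) {
  stopifnot(inherits(params, "ward_params"))
  if (any(demand < 0)) stop_invalid("demand must be >= 0")
  wnames <- names(params$wards)
  if (is.null(names(demand))) names(demand) <- wnames[seq_along(demand)]
  if (!setequal(names(demand), wnames)) {
    stop_invalid("demand names must match ward names (%s)",
                 paste(wnames, collapse = ", "))
  }
  demand <- round(demand[wnames])
  if (is.null(hospital_names)) {
    hospital_names <- paste0("hospital_", seq_len(n_hospitals))
  }
  if (is.null(hospital_fixed)) hospital_fixed <- params$hospital_fixed
  hospital_fixed <- rep_len(hospital_fixed, n_hospitals)
  if (!is.null(fixed_cases)) {
    fixed_cases <- as.matrix(fixed_cases)
    if (!all(dim(fixed_cases) == c(length(wnames), n_hospitals))) {
      stop_invalid("fixed_cases must be a %d x %d matrix",
                   length(wnames), n_hospitals)
    }
    rownames(fixed_cases) <- wnames
    colnames(fixed_cases) <- hospital_names
    if (any(abs(rowSums(fixed_cases) - demand) > 1e-9)) {
      stop_invalid("infeasible scenario: constraint V violated (fixed allocation row sums must equal regional demand)") # nolint
    }
  }
  if (!is.null(fixed_beds)) {
    fixed_beds <- as.matrix(fixed_beds)
    rownames(fixed_beds) <- wnames
    colnames(fixed_beds) <- hospital_names
  }
  big_M <- if (is.null(big_M)) sum(demand) + 1 else big_M
  if (big_M <= sum(demand)) stop_invalid("big_M must exceed total demand")
  structure(list(params = params, demand = demand,
                 n_hospitals = n_hospitals, hospital_names = hospital_names,
                 hospital_fixed = hospital_fixed,
                 n_open_hospitals = n_open_hospitals,
                 open_wards_per_drg = open_wards_per_drg,
                 wards_follow_hospital = wards_follow_hospital,
                 fixed_cases = fixed_cases, fixed_beds = fixed_beds,
                 big_M = big_M),
            class = "plan_problem")
}

# All ward-open configurations admissible under the scenario constraints,
# ordered by number of open wards then lexicographically, so that ties in
# the objective resolve to the sparsest, lowest-index configuration.
admissible_configs <- function(problem) {
  J <- length(problem$params$wards)
  s <- problem$n_hospitals
  grid <- as.matrix(expand.grid(rep(list(0:1), J * s)))
  keep <- logical(nrow(grid))
  configs <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    beta <- matrix(grid[r, ], nrow = J, ncol = s,
                   dimnames = list(names(problem$params$wards),
                                   problem$hospital_names))
    ok <- all(rowSums(beta) > 0 | problem$demand == 0)
    if (ok && !is.null(problem$open_wards_per_drg)) {
      ok <- all(rowSums(beta) == problem$open_wards_per_drg)
    }
    if (ok && problem$wards_follow_hospital && J > 1) {
      ok <- all(apply(beta, 2, function(col) all(col == col[1])))
    }
    if (ok && !is.null(problem$n_open_hospitals)) {
      ok <- sum(colSums(beta) > 0) == problem$n_open_hospitals
    }
    keep[r] <- ok
    configs[[r]] <- beta
  }
  configs <- configs[keep]
  # sparsest first; among equals, open wards at the lowest hospital
  # indices first (1-bits early in the row-major string sort last when
  # complemented)
  ord <- order(vapply(configs, sum, 0),
               vapply(configs, function(b) paste(1 - t(b), collapse = ""), ""))
  configs[ord]
}

# Exact allocation of B integer cases over m hospitals with identical
# step-cost vector costvec (cost of x = 0..B cases at one open ward),
# by repeated min-plus convolution with argmin tracking.
allocate_cases <- function(costvec, m, B) {
  if (m == 1) return(list(total = costvec[B + 1], x = B))
  f <- costvec
  choice <- vector("list", m)
  for (k in 2:m) {
    g <- numeric(B + 1)
    ch <- integer(B + 1)
    for (tot in 0:B) {
      v <- f[(tot:0) + 1] + costvec[(0:tot) + 1]
      i <- which.min(v)
      g[tot + 1] <- v[i]
      ch[tot + 1] <- i - 1L
    }
    f <- g
    choice[[k]] <- ch
  }
  x <- integer(m)
  rem <- B
  for (k in m:2) {
    x[k] <- choice[[k]][rem + 1]
    rem <- rem - x[k]
  }
  x[1] <- rem
  list(total = f[B + 1], x = x)
}

#' Solve the ward-planning problem to optimality
#'
#' Maximises the total regional contribution margin over ward-open flags,
#' integer case allocations, integer staff units and integer beds, under
#' the scenario constraints of the problem. The solve is exact: every
#' admissible open/close configuration is evaluated with an exact dynamic-
#' programming case allocation, so the returned solution is provably
#' optimal (zero optimality gap). Ties between symmetric optima are broken
#' towards the configuration with fewest open wards and lowest hospital
#' indices.
#'
#' @param problem A `plan_problem`.
#' @return An object of class `hospital_plan` with the case allocation
#'   `x`, open flags `beta`, bed and staff matrices, per-hospital and total
#'   contribution ladders, and the objective value in EUR.
#' @examples
#' p <- plan_problem(demand = c(paediatrics = 100, obstetrics = 50),
#'                   n_hospitals = 2)
#' plan_region(p)
#' @export
plan_region <- function(problem) {
  stopifnot(inherits(problem, "plan_problem"))
  wards <- problem$params$wards
  staff_by_ward <- lapply(wards, ward_staff, params_or_staff = problem$params)
  margins <- vapply(wards, function(w) w$rebate - w$variable_cost, 0)
  B <- problem$demand

  if (!is.null(problem$fixed_cases)) {
    beta <- (problem$fixed_cases > 0) * 1L
    sol <- build_solution(problem, problem$fixed_cases, beta,
                          problem$fixed_beds, configs_evaluated = 1L)
    return(sol)
  }

  configs <- admissible_configs(problem)
  if (length(configs) == 0) {
    stop_invalid("infeasible scenario: no ward-open configuration satisfies the constraints (constraint V, demand coverage, or the scenario open-count restrictions)") # nolint
  }
  # step-cost vectors (identical across hospitals) and DP cache by (ward,
  # number of open hospitals)
  costvec <- lapply(names(wards), function(j) {
    open_ward_cost(0:B[[j]], wards[[j]], staff_by_ward[[j]])
  })
  names(costvec) <- names(wards)
  dp_cache <- list()
  best <- NULL
  for (beta in configs) {
    obj <- 0
    alloc <- vector("list", length(wards))
    names(alloc) <- names(wards)
    feasible <- TRUE
    for (j in names(wards)) {
      m <- sum(beta[j, ])
      if (m == 0) {
        alloc[[j]] <- integer(0)
        next
      }
      key <- paste(j, m)
      if (is.null(dp_cache[[key]])) {
        dp_cache[[key]] <- allocate_cases(costvec[[j]], m, B[[j]])
      }
      a <- dp_cache[[key]]
      obj <- obj + B[[j]] * margins[[j]] - a$total
      alloc[[j]] <- a$x
    }
    if (!feasible) next
    open_hosp <- colSums(beta) > 0
    obj <- obj - sum(problem$hospital_fixed[open_hosp])
    if (is.null(best) || obj > best$obj + 1e-9) {
      best <- list(obj = obj, beta = beta, alloc = alloc)
    }
  }
  x <- matrix(0, nrow = length(wards), ncol = problem$n_hospitals,
              dimnames = list(names(wards), problem$hospital_names))
  for (j in names(wards)) {
    x[j, which(best$beta[j, ] == 1)] <- best$alloc[[j]]
  }
  build_solution(problem, x, best$beta, fixed_beds = NULL,
                 configs_evaluated = length(configs))
}

# Assemble the full solution object (ladders, beds, staff) from a case
# allocation and open flags, and verify the ladder profit reproduces the
# optimised objective.
build_solution <- function(problem, x, beta, fixed_beds = NULL,
                           configs_evaluated = 1L) {
  wards <- problem$params$wards
  s <- problem$n_hospitals
  ladders <- vector("list", s)
  names(ladders) <- problem$hospital_names
  beds <- x * 0L
  staff_ids <- problem$params$staff$id
  staff_units <- matrix(0L, nrow = length(staff_ids), ncol = s,
                        dimnames = list(staff_ids, problem$hospital_names))
  for (k in seq_len(s)) {
    ladders[[k]] <- vector("list", length(wards))
    names(ladders[[k]]) <- names(wards)
    for (j in names(wards)) {
      bk <- if (!is.null(fixed_beds)) fixed_beds[j, k] else NULL
      if (!is.null(bk) && (is.na(bk) || beta[j, k] == 0)) bk <- NULL
      lad <- ward_contribution(x[j, k], wards[[j]], problem$params,
                               beds = bk, open = beta[j, k] > 0)
      ladders[[k]][[j]] <- lad
      beds[j, k] <- lad$beds
      staff_units[names(lad$staff_units), k] <-
        staff_units[names(lad$staff_units), k] + lad$staff_units
    }
  }
  hospital_open <- as.integer(colSums(beta) > 0)
  hospital_totals <- lapply(seq_len(s), function(k) {
    aggregate_ladders(ladders[[k]],
                      hospital_fixed = problem$hospital_fixed[k] *
                        hospital_open[k])
  })
  names(hospital_totals) <- problem$hospital_names
  total <- aggregate_ladders(unlist(ladders, recursive = FALSE),
                             hospital_fixed =
                               sum(problem$hospital_fixed * hospital_open))
  objective <- total$profit
  M <- problem$big_M
  stopifnot(all(x <= M * beta),
            all(colSums(x) <= M * hospital_open),
            all(abs(rowSums(x) - problem$demand) < 1e-9))
  structure(list(
    x = x, beta = beta, d_open = beta, hospital_open = hospital_open,
    beds = beds, staff_units = staff_units, ladders = ladders,
    hospital_totals = hospital_totals, total = total,
    objective = objective, status = "optimal",
    configs_evaluated = configs_evaluated, problem = problem
  ), class = "hospital_plan")
}

#' @export
print.hospital_plan <- function(x, ...) {
  cat(sprintf("Optimal ward plan (status: %s)\n", x$status))
  cat(sprintf("Objective (total contribution margin): %s EUR\n",
              formatC(round(x$objective), big.mark = ",", format = "d")))
  print(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}

#' @export
summary.hospital_plan <- function(object, ...) {
  cat(sprintf("Ward plan over %d hospital(s), %d ward type(s)\n",
              object$problem$n_hospitals, nrow(object$x)))
  cat(sprintf("Open hospitals: %s\n",
              paste(object$problem$hospital_names[object$hospital_open == 1],
                    collapse = ", ")))
  cat(sprintf("Configurations evaluated: %d\n", object$configs_evaluated))
  print(object)
  cat("\nRegional ladder:\n")
  print(object$total)
  invisible(object)
}

#' @export
coef.hospital_plan <- function(object, ...) {
  xs <- as.vector(object$x)
  names(xs) <- paste0("x_", outer(rownames(object$x), colnames(object$x),
                                  paste, sep = "_"))
  c(objective = object$objective, xs)
}

#' Tabulate a ward plan
#'
#' One row per hospital-and-ward with beds, cases, capacity utilization (in
#' percent, half-up to whole percent) and contribution margin, in the
#' layout of the published scenario tables.
#'
#' @param x A `hospital_plan`.
#' @param row.names,optional,... Ignored (base-generic signature).
#' @return A data frame.
#' @export
as.data.frame.hospital_plan <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  rows <- list()
  for (k in seq_along(x$ladders)) {
    for (j in names(x$ladders[[k]])) {
      l <- x$ladders[[k]][[j]]
      rows[[length(rows) + 1]] <- data.frame(
        hospital = names(x$ladders)[k], ward = j, beds = l$beds,
        cases = l$cases,
        utilization_pct = round_half_up(100 * l$utilization),
        contribution = l$contribution_III, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
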