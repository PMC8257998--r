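#' Linear program solver
#'
#' Solves `min/max c'x` subject to `A x (<=, =, >=) rhs` and `lb <= x <= ub`
#' with the package's bounded-variable two-phase simplex. All flux-balance
#' computations in the package go through this interface.
#'
#' For repeated solves over the same constraint set (the flux variability
#' pattern), create a persistent instance with [lp_instance()] and call
#' [lp_optimize()] with different objectives; re-solves reuse the previous
#' optimal basis and skip phase 1.
#'
#' @param obj numeric objective coefficients, length `ncol(A)`.
#' @param A constraint matrix (dense or `Matrix` sparse; coerced to dense).
#' @param dir character vector of constraint directions, each one of
#'   `"<="`, `"="`, `">="`.
#' @param rhs numeric right-hand side.
#' @param lb,ub variable bounds (recycled); every variable needs at least one
#'   finite bound.
#' @param maximize logical; maximize instead of minimize.
#' @return A list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `objective`, the primal solution `x`, and the
#'   infinity-norm `residual` of the equality system at the solution.
#' @examples
#' # max x1 + x2  s.t.  x1 + 2 x2 <= 4, x1 <= 3, x >= 0
#' solve_lp(c(1, 1), rbind(c(1, 2), c(1, 0)), c("<=", "<="), c(4, 3),
#'          maximize = TRUE)$objective
#' @export
solve_lp <- function(obj, A, dir, rhs, lb = 0, ub = Inf, maximize = FALSE) {
  inst <- lp_instance(A, dir, rhs, lb, ub)
  lp_optimize(inst, obj, maximize = maximize)
}

#' Create a reusable LP instance
#'
#' Builds the equality-form tableau once; [lp_optimize()] then solves for
#' any objective over the same feasible region, warm-starting from the last
#' basis.
#'
#' @inheritParams solve_lp
#' @return An opaque instance object for [lp_optimize()].
#' @export
lp_instance <- function(A, dir, rhs, lb = 0, ub = Inf) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(dir) == m, length(rhs) == m)
  if (!all(dir %in% c("<=", "=", ">=")))
    stop("constraint directions must be one of '<=', '=', '>='")
  lb <- rep_len(as.double(lb), n)
  ub <- rep_len(as.double(ub), n)
  if (any(lb > ub)) stop("lower bound exceeds upper bound")
  slack <- which(dir != "=")
  if (length(slack)) {
    S <- matrix(0, m, length(slack))
    S[cbind(slack, seq_along(slack))] <- ifelse(dir[slack] == "<=", 1, -1)
    A <- cbind(A, S)
    lb <- c(lb, rep(0, length(slack)))
    ub <- c(ub, rep(Inf, length(slack)))
  }
  structure(
    list(ptr = .lp_instance(A, as.double(rhs), lb, ub),
         n_structural = n, n_total = ncol(A)),
    class = "gutflux_lp")
}

#' Optimize an objective over an existing LP instance
#'
#' @param instance an object from [lp_instance()].
#' @param obj objective coefficients for the structural variables.
#' @param maximize logical.
#' @return As [solve_lp()].
#' @export
lp_optimize <- function(instance, obj, maximize = FALSE) {
  stopifnot(inherits(instance, "gutflux_lp"))
  n <- instance$n_structural
  obj <- as.double(obj)
  stopifnot(length(obj) == n)
  res <- .lp_optimize(instance$ptr,
                      c(obj, rep(0, instance$n_total - n)), maximize)
  list(
    status    = c("optimal", "infeasible", "unbounded",
                  "iteration_limit")[res$status + 1L],
    objective = res$objective,
    x         = res$x[seq_len(n)],
    residual  = res$residual)
}

#' Update one variable's bounds on an LP instance
#'
#' Changes the bounds of structural variable `j` in place. The previous
#' optimal basis is kept whenever the current point remains feasible
#' (always the case when a bound is tightened no further than the
#' variable's current value, or relaxed), so subsequent [lp_optimize()]
#' calls stay warm-started. This is the flux-analysis idiom of fixing an
#' objective at its optimum, or opening a biomass window after a relaxed
#' feasibility solve.
#'
#' @param instance an object from [lp_instance()].
#' @param j structural variable index (1-based).
#' @param lb,ub new bounds.
#' @export
lp_set_bound <- function(instance, j, lb, ub) {
  stopifnot(inherits(instance, "gutflux_lp"),
            j >= 1, j <= instance$n_structural)
  .lp_set_bound(instance$ptr, as.integer(j), as.double(lb), as.double(ub))
  invisible(instance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
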