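## The LP layer: FBA, FVA, linear MoMA, single-flux minimization.
##
## Every problem is   opt c'v  s.t.  N v = 0,  alpha <= v <= beta,
## optionally with reactions pinned (lb = ub = value) by a fix
## specification. Infinite bounds are clamped to +/- BIG when the LP is
## assembled; an FBA optimum at the clamp is reported as unbounded.

BIG_BOUND <- 1e6
EPS_BAL <- 1e-9    # mass-balance residual tolerance
EPS_BND <- 1e-9    # bound-violation tolerance
EPS_W   <- 1e-9    # zero range-width threshold

## Apply a fix specification (named vector: reaction -> pinned value) to the
## bound vectors. Fixed values must lie within the original bounds.
apply_fixes <- function(model, fixes) {
  lb <- model$lower_bounds; ub <- model$upper_bounds
  if (is.null(fixes) || length(fixes) == 0L) return(list(lb = lb, ub = ub))
  if (is.null(names(fixes)) || any(names(fixes) == ""))
    stop("fixes must be a named numeric vector (reaction id -> value)")
  bad <- setdiff(names(fixes), model$reaction_ids)
  if (length(bad)) stop("fixes name unknown reactions: ",
                        paste(bad, collapse = ", "))
  for (rx in names(fixes)) {
    v <- fixes[[rx]]
    if (v < lb[[rx]] - EPS_BND || v > ub[[rx]] + EPS_BND)
      stop("fix for '", rx, "' (", v, ") lies outside its bounds [",
           lb[[rx]], ", ", ub[[rx]], "]")
    lb[[rx]] <- v; ub[[rx]] <- v
  }
  list(lb = lb, ub = ub)
}

lp_bounds <- function(model, fixes) {
  bnd <- apply_fixes(model, fixes)
  list(lb = pmax(bnd$lb, -BIG_BOUND), ub = pmin(bnd$ub, BIG_BOUND))
}

run_lp <- function(model, obj, fixes, sense) {
  bnd <- lp_bounds(model, fixes)
  A <- as.matrix(model$stoichiometry)
  simplex_solve(obj, A, rep(0, nrow(A)), bnd$lb, bnd$ub, sense)
}

#' Flux balance analysis
#'
#' Solves `opt v_obj` subject to `N v = 0` and the (possibly fixed) flux
#' bounds, the canonical growth-maximization LP when `objective` is the
#' biomass reaction. The solver, presolve-free pivoting rule and variable
#' order (the model's reaction order) are fixed, so the returned optimal
#' vertex is deterministic run to run — which matters because the external
#' fluxes at optimal growth are degenerate in general.
#'
#' @param model a [metabolic_model].
#' @param objective reaction whose flux is optimized (default: biomass).
#' @param sense `"max"` or `"min"`.
#' @param fixes optional named numeric vector pinning reactions
#'   (`lb = ub = value`); see [uptake_fix()] for uptake-oriented fixes.
#' @return A list of class `fba_solution`: `value` (optimal objective),
#'   `flux` (named optimal flux vector), `objective`, `sense`.
#' @export
solve_fba <- function(model, objective = model$biomass,
                      sense = c("max", "min"), fixes = NULL) {
  sense <- match.arg(sense)
  if (!objective %in% model$reaction_ids)
    stop("objective reaction '", objective, "' is not in the model")
  obj <- as.numeric(model$reaction_ids == objective)
  res <- run_lp(model, obj, fixes, sense)
  if (res$status != "optimal") stop("infeasible")
  if (abs(res$value) >= 0.5 * BIG_BOUND) stop("unbounded")
  structure(list(value = res$value + 0,   # normalize IEEE -0
                 flux = stats::setNames(res$x, model$reaction_ids),
                 objective = objective, sense = sense,
                 provenance = "fba"),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("<fba_solution> ", x$sense, " ", x$objective, " = ",
      format(x$value, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux under the
#' steady-state constraints, bounds and fixes: `2 * length(reactions)`
#' linear programs. Results do not depend on the iteration order over
#' reactions. Feasibility is checked once before iterating.
#'
#' @inheritParams solve_fba
#' @param reactions reactions to range over (default: all).
#' @return A data frame of class `flux_ranges` with columns `reaction`,
#'   `min`, `max`; the fix specification is attached as attribute `fixes`.
#' @export
solve_fva <- function(model, reactions = model$reaction_ids, fixes = NULL) {
  bad <- setdiff(reactions, model$reaction_ids)
  if (length(bad)) stop("unknown reactions: ", paste(bad, collapse = ", "))
  bnd <- lp_bounds(model, fixes)
  A <- as.matrix(model$stoichiometry)
  b0 <- rep(0, nrow(A))
  feas <- simplex_solve(rep(0, ncol(A)), A, b0, bnd$lb, bnd$ub, "min")
  if (feas$status != "optimal") stop("infeasible")
  idx <- match(reactions, model$reaction_ids)
  lo <- hi <- numeric(length(idx))
  for (k in seq_along(idx)) {
    obj <- numeric(ncol(A)); obj[idx[k]] <- 1
    lo[k] <- simplex_solve(obj, A, b0, bnd$lb, bnd$ub, "min")$value
    hi[k] <- simplex_solve(obj, A, b0, bnd$lb, bnd$ub, "max")$value
  }
  structure(data.frame(reaction = reactions, min = lo, max = hi,
                       stringsAsFactors = FALSE),
            fixes = fixes, class = c("flux_ranges", "data.frame"))
}

#' @export
print.flux_ranges <- function(x, ...) {
  cat("<flux_ranges> ", nrow(x), " reactions",
      if (length(attr(x, "fixes")))
        paste0(" (", length(attr(x, "fixes")), " fixed)") else "",
      "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

range_widths <- function(ranges) {
  stats::setNames(ranges$max - ranges$min, ranges$reaction)
}

#' Linear minimization of metabolic adjustment (MoMA)
#'
#' Finds the feasible flux distribution minimizing the Manhattan distance
#' `sum_i |v_i - v_i_ref|` to a reference distribution, over all reactions.
#' Implemented as an LP with split deviation variables
#' (`v_i = v_ref_i + d_i_plus - d_i_minus`, both deviations non-negative).
#'
#' @inheritParams solve_fba
#' @param v_ref named reference flux vector covering every reaction (e.g.
#'   the `flux` of an [solve_fba()] solution).
#' @return A list of class `moma_solution`: `distance` (minimal Manhattan
#'   distance) and `flux` (an attaining flux vector).
#' @export
solve_moma <- function(model, v_ref, fixes = NULL) {
  r <- length(model$reaction_ids)
  if (is.null(names(v_ref))) {
    if (length(v_ref) != r) stop("v_ref must cover every reaction")
    names(v_ref) <- model$reaction_ids
  }
  if (!all(model$reaction_ids %in% names(v_ref)))
    stop("v_ref must cover every reaction")
  vref <- as.numeric(v_ref[model$reaction_ids])
  bnd <- lp_bounds(model, fixes)
  N <- as.matrix(model$stoichiometry)
  m <- nrow(N)
  ## variables: [v, d_plus, d_minus]
  A <- rbind(cbind(N, matrix(0, m, 2 * r)),
             cbind(diag(r), -diag(r), diag(r)))
  b <- c(rep(0, m), vref)
  obj <- c(rep(0, r), rep(1, 2 * r))
  lb <- c(bnd$lb, rep(0, 2 * r))
  ub <- c(bnd$ub, rep(4 * BIG_BOUND, 2 * r))
  res <- simplex_solve(obj, A, b, lb, ub, "min")
  if (res$status != "optimal") stop("infeasible")
  structure(list(distance = res$value,
                 flux = stats::setNames(res$x[seq_len(r)],
                                        model$reaction_ids),
                 provenance = "moma"),
            class = "moma_solution")
}

#' @export
print.moma_solution <- function(x, ...) {
  cat("<moma_solution> distance = ", format(x$distance, digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Minimum attainable value of a single flux
#'
#' For internal and growth reactions, the minimum of `v_i` under the
#' constraints. For exchange reactions the minimization is performed on the
#' uptake magnitude (the flux in the uptake direction) and the result is
#' reported as a non-negative uptake when uptake occurs (negative values
#' mean the reaction must secrete).
#'
#' @inheritParams solve_fba
#' @param reaction the reaction whose flux is minimized.
#' @return The minimum value (uptake magnitude for exchanges).
#' @export
minimize_flux <- function(model, reaction, fixes = NULL) {
  if (!reaction %in% model$reaction_ids)
    stop("unknown reaction: ", reaction)
  obj <- numeric(length(model$reaction_ids))
  j <- match(reaction, model$reaction_ids)
  if (model$reaction_class[[reaction]] == "exchange") {
    obj[j] <- uptake_sign(model, reaction)
  } else {
    obj[j] <- 1
  }
  res <- run_lp(model, obj, fixes, "min")
  if (res$status != "optimal") stop("infeasible")
  res$value
}

#' Verify a flux vector against a model
#'
#' Checks the steady-state residual `max |N v|` and bound violations at the
#' package tolerances; used by tests and the invariants of MoMA solutions.
#'
#' @param model a [metabolic_model].
#' @param flux named flux vector.
#' @param tol_bal,tol_bnd tolerances for the balance residual and bound
#'   violations.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
check_flux <- function(model, flux, tol_bal = 1e-6, tol_bnd = 1e-6) {
  v <- as.numeric(flux[model$reaction_ids])
  resid <- max(abs(model$stoichiometry %*% v))
  if (resid > tol_bal) stop("mass balance violated: residual ", resid)
  low <- v - pmax(model$lower_bounds, -BIG_BOUND)
  up <- pmin(model$upper_bounds, BIG_BOUND) - v
  if (min(low, up) < -tol_bnd) stop("flux bound violated")
  invisible(TRUE)
}
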