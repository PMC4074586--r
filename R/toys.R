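## Deterministic toy networks and a brute-force polytope oracle.
##
## The toys are structural analogues of a minimal-medium metabolic model at
## desk scale: a single carbon-like source, an optional nitrogen-like
## source, secretion drains, a biomass drain, and internal branch
## redundancy, so FVA ranges and the variability decomposition are
## hand-computable. Construction is deterministic; no randomness is
## involved in any golden value.

#' Build a toy metabolic network
#'
#' Three presets:
#' \describe{
#'   \item{`chain` (TOY1)}{`EX_A -> R1 -> GRO`, 3 reactions, one linear
#'     pathway limited by the uptake bound. With `maintenance > 0`, an
#'     internal ATP-maintenance-like reaction `ATPM` (converting the
#'     pathway intermediate to a secreted waste) with that lower bound and
#'     its drain `EX_W` are added.}
#'   \item{`branched` (TOY2)}{`EX_A -> R1 -> {R2 | R3 -> R4} -> GRO`,
#'     6 reactions, 4 internal, one internal degree of freedom in how flux
#'     splits between the direct route and the route via an intermediate.}
#'   \item{`two_substrate` (TOY3)}{carbon and nitrogen sources `EX_C`,
#'     `EX_N`, internal transporters `TC`, `TN`, biomass `GRO` consuming
#'     `c_yield` carbon + `n_yield` nitrogen per unit growth, and overflow
#'     routes `OVF`/`OVN` into a secreted waste `EX_W`. The carbon
#'     overflow lets carbon uptake decouple from growth unless
#'     carbon-nitrogen coordination pins it; the nitrogen overflow keeps
#'     excess pinned nitrogen uptake feasible.}
#' }
#' Exchanges are oriented import-positive (`-> A`), so toy fluxes equal
#' uptake magnitudes directly; the package's sign machinery handles either
#' orientation.
#'
#' @param preset `"chain"`, `"branched"` or `"two_substrate"`.
#' @param uptake_limit upper bound of the (carbon) uptake.
#' @param maintenance lower bound of the maintenance demand (chain preset).
#' @param n_limit nitrogen uptake upper bound (two-substrate preset).
#' @param c_yield,n_yield biomass stoichiometry of the two substrates.
#' @return A [metabolic_model].
#' @export
make_toy <- function(preset = c("chain", "branched", "two_substrate"),
                     uptake_limit = 10, maintenance = 0, n_limit = 20,
                     c_yield = 1, n_yield = 1) {
  preset <- match.arg(preset)
  if (uptake_limit < 0 || maintenance < 0 || n_limit < 0)
    stop("toy parameters must be non-negative")
  inf <- Inf
  if (preset == "chain") {
    if (maintenance > 0) {
      mets <- c("A", "B", "W")
      rxns <- c("EX_A", "R1", "ATPM", "EX_W", "GRO")
      S <- matrix(0, 3, 5, dimnames = list(mets, rxns))
      S["A", "EX_A"] <- 1
      S["A", "R1"] <- -1; S["B", "R1"] <- 1
      S["B", "ATPM"] <- -1; S["W", "ATPM"] <- 1
      S["W", "EX_W"] <- -1
      S["B", "GRO"] <- -1
      lb <- c(0, 0, maintenance, 0, 0)
      ub <- c(uptake_limit, inf, inf, inf, inf)
    } else {
      mets <- c("A", "B")
      rxns <- c("EX_A", "R1", "GRO")
      S <- matrix(0, 2, 3, dimnames = list(mets, rxns))
      S["A", "EX_A"] <- 1
      S["A", "R1"] <- -1; S["B", "R1"] <- 1
      S["B", "GRO"] <- -1
      lb <- c(0, 0, 0)
      ub <- c(uptake_limit, inf, inf)
    }
    return(metabolic_model(mets, rxns, S, lb, ub, "GRO", name = "TOY1"))
  }
  if (preset == "branched") {
    mets <- c("A", "B", "M", "C")
    rxns <- c("EX_A", "R1", "R2", "R3", "R4", "GRO")
    S <- matrix(0, 4, 6, dimnames = list(mets, rxns))
    S["A", "EX_A"] <- 1
    S["A", "R1"] <- -1; S["B", "R1"] <- 1
    S["B", "R2"] <- -1; S["C", "R2"] <- 1
    S["B", "R3"] <- -1; S["M", "R3"] <- 1
    S["M", "R4"] <- -1; S["C", "R4"] <- 1
    S["C", "GRO"] <- -1
    lb <- rep(0, 6)
    ub <- c(uptake_limit, rep(inf, 5))
    return(metabolic_model(mets, rxns, S, lb, ub, "GRO", name = "TOY2"))
  }
  ## two_substrate: overflow routes for both substrates, so pinning an
  ## uptake in excess of what growth can use stays feasible
  mets <- c("Cx", "Nx", "Ci", "Ni", "W")
  rxns <- c("EX_C", "EX_N", "TC", "TN", "OVF", "OVN", "EX_W", "GRO")
  S <- matrix(0, 5, 8, dimnames = list(mets, rxns))
  S["Cx", "EX_C"] <- 1
  S["Nx", "EX_N"] <- 1
  S["Cx", "TC"] <- -1; S["Ci", "TC"] <- 1
  S["Nx", "TN"] <- -1; S["Ni", "TN"] <- 1
  S["Ci", "OVF"] <- -1; S["W", "OVF"] <- 1
  S["Ni", "OVN"] <- -1; S["W", "OVN"] <- 1
  S["W", "EX_W"] <- -1
  S["Ci", "GRO"] <- -c_yield; S["Ni", "GRO"] <- -n_yield
  lb <- rep(0, 8)
  ub <- c(uptake_limit, n_limit, rep(Inf, 6))
  metabolic_model(mets, rxns, S, lb, ub, "GRO", name = "TOY3")
}

#' Seedable random branched networks (fuzzing only)
#'
#' Generates a small feasible chain-with-branches network with random
#' bounds, for property fuzzing of the LP layer (monotonicity of FVA under
#' bound tightening, min <= max, oracle agreement). Never used for golden
#' values.
#'
#' @param n_branches number of parallel internal routes (1-4).
#' @param seed RNG seed (default 0).
#' @return A [metabolic_model].
#' @export
random_network <- function(n_branches = 2, seed = 0) {
  stopifnot(n_branches >= 1, n_branches <= 4)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  mets <- c("A", "B")
  rxns <- c("EX_A", "R1", paste0("BR", seq_len(n_branches)), "GRO")
  S <- matrix(0, 2, length(rxns), dimnames = list(mets, rxns))
  S["A", "EX_A"] <- 1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  for (k in seq_len(n_branches)) S["B", paste0("BR", k)] <- -1
  S["B", "GRO"] <- -1
  caps <- round(stats::runif(length(rxns), 2, 12), 1)
  lb <- rep(0, length(rxns))
  metabolic_model(mets, rxns, S, lb, caps, "GRO",
                  name = paste0("RND", n_branches, "_", seed))
}

## Reduced row echelon form with partial pivoting (homogeneous systems).
rref_pivots <- function(E, tol = 1e-10) {
  E <- as.matrix(E)
  m <- nrow(E); n <- ncol(E)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    p <- which.max(abs(E[row:m, col])) + row - 1L
    if (abs(E[p, col]) < tol) next
    if (p != row) E[c(p, row), ] <- E[c(row, p), ]
    E[row, ] <- E[row, ] / E[row, col]
    others <- setdiff(seq_len(m), row)
    E[others, ] <- E[others, ] - outer(E[others, col], E[row, ])
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(R = E, pivots = pivots)
}

#' Brute-force flux ranges (LP-independent oracle)
#'
#' Parameterizes the steady-state polytope over the free coordinates of the
#' reduced stoichiometric system, grid-searches all bound-feasible
#' combinations at the given resolution, and reports the empirical
#' per-reaction min/max. The result is an inner approximation guaranteed
#' within one grid step of the true range. The oracle shares no code with
#' the simplex backend and refuses problems with more degrees of freedom
#' than it can enumerate rather than approximating badly.
#'
#' @param model a [metabolic_model] (desk scale).
#' @param resolution grid step in flux units.
#' @param fixes optional named fix vector, as in [solve_fva()].
#' @param cap finite stand-in for infinite bounds; defaults to twice the
#'   largest finite bound magnitude in the model.
#' @param max_dof refuse models whose bounded null space has more than
#'   this many free dimensions (default 3).
#' @return A `flux_ranges` data frame.
#' @export
brute_force_ranges <- function(model, resolution = 0.05, fixes = NULL,
                               cap = NULL, max_dof = 3) {
  bnd <- apply_fixes(model, fixes)
  if (is.null(cap)) {
    fin <- c(bnd$lb[is.finite(bnd$lb)], bnd$ub[is.finite(bnd$ub)])
    cap <- 2 * max(abs(fin), 1)
  }
  lb <- pmax(bnd$lb, -cap); ub <- pmin(bnd$ub, cap)
  rr <- rref_pivots(as.matrix(model$stoichiometry))
  n <- length(model$reaction_ids)
  free <- setdiff(seq_len(n), rr$pivots)
  if (length(free) > max_dof)
    stop("too many degrees of freedom (", length(free),
         ") for brute-force enumeration")
  grids <- lapply(free, function(j) {
    g <- seq(lb[j], ub[j], by = resolution)
    if (g[length(g)] < ub[j]) g <- c(g, ub[j])
    g
  })
  npts <- prod(vapply(grids, length, numeric(1)))
  if (npts > 5e6) stop("grid too large; coarsen the resolution")
  G <- as.matrix(expand.grid(grids))
  V <- matrix(0, nrow(G), n)
  V[, free] <- G
  if (length(rr$pivots)) {
    P <- -rr$R[seq_along(rr$pivots), free, drop = FALSE]
    V[, rr$pivots] <- G %*% t(P)
  }
  tol <- 1e-7
  ok <- rep(TRUE, nrow(V))
  for (j in seq_len(n))
    ok <- ok & V[, j] >= lb[j] - tol & V[, j] <= ub[j] + tol
  if (!any(ok)) stop("no feasible grid point found")
  Vf <- V[ok, , drop = FALSE]
  structure(data.frame(reaction = model$reaction_ids,
                       min = apply(Vf, 2, min),
                       max = apply(Vf, 2, max),
                       stringsAsFactors = FALSE),
            fixes = fixes, resolution = resolution,
            class = c("flux_ranges", "data.frame"))
}
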