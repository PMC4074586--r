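## Bounded-variable two-phase primal simplex.
##
## All flux-balance LPs in this package reduce to
##     min  c'x   s.t.  A x = b,  lb <= x <= ub
## with finite bounds (infinities are clamped by the callers). The solver is
## deterministic: Bland's smallest-index rule for entering and leaving
## variables, a fixed variable order, and full recomputation of the basic
## solution each iteration. Bland's rule guarantees termination on the
## degenerate bases that FVA produces routinely.

#' Solve a bounded-variable linear program
#'
#' Minimizes (or maximizes) `obj %*% x` subject to `A %*% x == b` and
#' `lb <= x <= ub`, all bounds finite. This is the single numerical backend
#' behind [solve_fba()], [solve_fva()] and [solve_moma()]; it is exposed so
#' that the LP layer can be exercised and cross-checked directly.
#'
#' @param obj numeric objective coefficients (length `n`).
#' @param A dense numeric constraint matrix (`m` x `n`); rows are equalities.
#' @param b right-hand side (length `m`).
#' @param lb,ub finite lower/upper variable bounds (length `n`).
#' @param sense `"min"` or `"max"`.
#' @param tol pivot tolerance on reduced costs and ratio tests.
#' @param max_iter iteration cap per phase.
#' @return A list with `status` (`"optimal"` or `"infeasible"`), `value`,
#'   the primal solution `x`, and the iteration count.
#' @keywords internal
#' @export
simplex_solve <- function(obj, A, b, lb, ub, sense = c("min", "max"),
                          tol = 1e-9, max_iter = 50000L) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m,
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("simplex_solve requires finite bounds (clamp infinities first)")
  if (any(lb > ub + tol))
    return(list(status = "infeasible", value = NA_real_, x = NULL,
                iterations = 0L))
  cc <- if (sense == "max") -obj else obj
  if (m == 0L) {                         # pure box problem
    xs <- ifelse(cc >= 0, lb, ub)
    val <- sum(cc * xs)
    return(list(status = "optimal",
                value = if (sense == "max") -val else val,
                x = xs, iterations = 0L))
  }

  ## Nonbasic variables start at the bound of smaller magnitude (ties: lower).
  at_upper <- abs(ub) < abs(lb)
  x_start <- ifelse(at_upper, ub, lb)

  ## Artificial variables close the residual r = b - A x_start.
  r <- b - drop(A %*% x_start)
  s_art <- ifelse(r >= 0, 1, -1)
  A_ext <- cbind(A, diag(s_art, nrow = m))
  big <- max(1, abs(r)) * 2 + sum(abs(range(b, 0)))
  lb_e <- c(lb, rep(0, m))
  ub_e <- c(ub, abs(r) + big)            # loose cap; artificials head to 0
  ntot <- n + m
  art <- seq.int(n + 1L, ntot)

  basis <- art
  status <- ifelse(at_upper, 2L, 1L)     # 1 = at lower, 2 = at upper (nonbasic)
  status <- c(status, rep(0L, m))        # 0 = basic
  x <- c(x_start, abs(r))

  run_phase <- function(cost, basis, status, x, ban_enter) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("simplex iteration limit reached")
      Bm <- A_ext[, basis, drop = FALSE]
      nb <- which(status > 0L)
      ## basic solution for current nonbasic assignment
      rhs <- b - drop(A_ext[, nb, drop = FALSE] %*% x[nb])
      xb <- tryCatch(solve(Bm, rhs), error = function(e) NULL)
      if (is.null(xb)) stop("singular basis encountered")
      x[basis] <- xb
      ## reduced costs
      y <- tryCatch(solve(t(Bm), cost[basis]), error = function(e) NULL)
      if (is.null(y)) stop("singular basis encountered")
      d <- cost - drop(crossprod(A_ext, y))
      elig <- nb[!(nb %in% ban_enter) &
                   ((status[nb] == 1L & d[nb] < -tol) |
                    (status[nb] == 2L & d[nb] >  tol))]
      if (length(elig) == 0L)
        return(list(basis = basis, status = status, x = x,
                    value = sum(cost * x), iterations = it))
      j <- min(elig)                      # Bland: smallest index enters
      dir <- if (status[j] == 1L) 1 else -1
      w <- drop(solve(Bm, A_ext[, j])) * dir
      ## ratio test over basic variables, plus the entering bound flip
      t_lim <- rep(Inf, m)
      up <- w > tol; dn <- w < -tol
      t_lim[up] <- (x[basis[up]] - lb_e[basis[up]]) / w[up]
      t_lim[dn] <- (ub_e[basis[dn]] - x[basis[dn]]) / (-w[dn])
      t_lim <- pmax(t_lim, 0)
      t_flip <- ub_e[j] - lb_e[j]
      t_star <- min(t_lim, t_flip)
      if (!is.finite(t_star)) stop("unbounded")
      if (t_flip <= t_star + tol && t_flip <= min(t_lim)) {
        ## bound flip: basis unchanged
        x[j] <- if (status[j] == 1L) ub_e[j] else lb_e[j]
        status[j] <- if (status[j] == 1L) 2L else 1L
        next
      }
      blocking <- which(t_lim <= t_star + tol)
      k <- blocking[which.min(basis[blocking])]   # Bland: smallest index leaves
      leave <- basis[k]
      x[j] <- (if (status[j] == 1L) lb_e[j] else ub_e[j]) + dir * t_star
      status[leave] <- if (w[k] > 0) 1L else 2L
      x[leave] <- if (w[k] > 0) lb_e[leave] else ub_e[leave]
      basis[k] <- j
      status[j] <- 0L
    }
  }

  ## Phase 1: drive artificials to zero.
  c1 <- c(rep(0, n), rep(1, m))
  feas_tol <- 1e-7 * max(1, max(abs(b)))
  p1 <- run_phase(c1, basis, status, x, ban_enter = integer(0))
  if (p1$value > feas_tol)
    return(list(status = "infeasible", value = NA_real_, x = NULL,
                iterations = p1$iterations))

  ## Phase 2: original costs; artificials pinned at zero and barred from
  ## re-entering.
  ub_e[art] <- 0
  p1$x[art] <- pmin(p1$x[art], 0)
  p1$x[art] <- pmax(p1$x[art], 0)
  c2 <- c(cc, rep(0, m))
  p2 <- run_phase(c2, p1$basis, p1$status, p1$x, ban_enter = art)

  xs <- p2$x[seq_len(n)]
  val <- sum(cc * xs)
  list(status = "optimal",
       value = if (sense == "max") -val else val,
       x = pmin(pmax(xs, lb), ub),
       iterations = p1$iterations + p2$iterations)
}
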