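## MoMA-based adaptation between uptake states and the counting of large
## flux changes (global network reorganization).

#' Count large flux changes between two states
#'
#' A reaction counts as increasing when its final flux magnitude exceeds
#' `up_factor` times its initial magnitude, and as decreasing when it falls
#' below `down_factor` times the initial magnitude (defaults 2 and 1/10;
#' the asymmetry reflects that the summed flux scales roughly with uptake,
#' making decreases more likely than increases when uptake drops).
#' Comparisons are on absolute values, so sign flips are judged by
#' magnitude. Reactions whose initial magnitude is below `eps_zero` are
#' excluded from both counts and from the eligible total; set
#' `count_new = TRUE` to count a zero-to-nonzero activation as an increase
#' instead.
#'
#' @param v_init,v_final flux vectors of equal length.
#' @param up_factor,down_factor positive thresholds.
#' @param eps_zero magnitude below which an initial flux is treated as zero.
#' @param count_new count zero-initial reactions that become active
#'   (`|v_final| >= eps_zero`) as increases?
#' @return A list of class `change_counts`: `n_up`, `n_down`, `n_total`,
#'   `n_eligible`.
#' @export
count_flux_changes <- function(v_init, v_final, up_factor = 2,
                               down_factor = 0.1, eps_zero = 1e-6,
                               count_new = FALSE) {
  if (length(v_init) != length(v_final))
    stop("flux vectors differ in length")
  if (up_factor <= 0 || down_factor <= 0)
    stop("factors must be positive")
  a <- abs(as.numeric(v_init)); b <- abs(as.numeric(v_final))
  eligible <- a >= eps_zero
  n_up <- sum(eligible & b > up_factor * a)
  n_down <- sum(eligible & b < down_factor * a)
  n_eligible <- sum(eligible)
  if (count_new) {
    new_on <- !eligible & b >= eps_zero
    n_up <- n_up + sum(new_on)
    n_eligible <- n_eligible + sum(new_on)
  }
  structure(list(n_up = n_up, n_down = n_down, n_total = n_up + n_down,
                 n_eligible = n_eligible),
            class = "change_counts")
}

#' @export
print.change_counts <- function(x, ...) {
  cat(sprintf("<change_counts> up %d + down %d = %d of %d eligible\n",
              x$n_up, x$n_down, x$n_total, x$n_eligible))
  invisible(x)
}

#' MoMA adaptation scan over carbon uptake
#'
#' The initial state is the deterministic FBA optimum with the carbon
#' uptake pinned at `initial_uptake`. Each final state pins the uptake at a
#' lower grid value and finds the flux distribution of minimal Manhattan
#' distance from the initial one (linear MoMA), either leaving growth free
#' (`growth_mode = "free"`) or additionally pinning growth at the FBA
#' maximum for that uptake (`"fixed_max"`). Per grid point the MoMA
#' distance and the large-change counts against the initial state are
#' recorded. Freeing growth can only shrink the distance, since the
#' growth-fixed feasible set is contained in the growth-free one.
#'
#' @param model a [metabolic_model].
#' @param med optional `medium_spec`.
#' @param glucose_grid uptake values of the final states.
#' @param growth_mode `"free"` or `"fixed_max"`.
#' @param glucose_exchange carbon exchange id.
#' @param initial_uptake uptake of the initial reference state.
#' @param up_factor,down_factor,eps_zero passed to [count_flux_changes()].
#' @return A data frame of class `adaptation_scan`: per grid point the
#'   uptake, realized growth, `moma_distance`, and the change counts.
#' @export
adapt_moma_scan <- function(model, med = NULL, glucose_grid,
                            growth_mode = c("free", "fixed_max"),
                            glucose_exchange, initial_uptake = 10,
                            up_factor = 2, down_factor = 0.1,
                            eps_zero = 1e-6) {
  growth_mode <- match.arg(growth_mode)
  base <- if (is.null(med)) model else apply_medium(model, med)
  v_ref <- solve_fba(base, fixes = uptake_fix(base, glucose_exchange,
                                              initial_uptake))$flux
  rows <- lapply(glucose_grid, function(g) {
    fx <- uptake_fix(base, glucose_exchange, g)
    res <- tryCatch({
      if (growth_mode == "fixed_max") {
        vg <- solve_fba(base, fixes = fx)$value
        fx <- c(fx, stats::setNames(vg, base$biomass))
      }
      mm <- solve_moma(base, v_ref, fixes = fx)
      ct <- count_flux_changes(v_ref, mm$flux, up_factor, down_factor,
                               eps_zero)
      c(vgro = unname(mm$flux[base$biomass]),
        moma_distance = mm$distance, n_up = ct$n_up, n_down = ct$n_down,
        n_total = ct$n_total, n_eligible = ct$n_eligible, feasible = 1)
    }, error = function(e) c(vgro = NA, moma_distance = NA, n_up = NA,
                             n_down = NA, n_total = NA, n_eligible = NA,
                             feasible = 0))
    c(glucose = g, res)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$feasible <- out$feasible == 1
  attr(out, "growth_mode") <- growth_mode
  attr(out, "v_ref") <- v_ref
  class(out) <- c("adaptation_scan", "data.frame")
  out
}
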