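## Condition sweeps: uptake scans, carbon-nitrogen coordination, and
## growth-bound scans. The reference state is computed once per scan from
## the base medium and never recomputed per grid point, so every Delta in a
## scan is normalized against the same reference ranges.

#' Two-stage carbon-nitrogen uptake coordination
#'
#' Emulates the regulatory coupling of glucose uptake to nitrogen
#' availability (alpha-ketoglutarate inhibition of the phosphotransferase
#' system) as a lexicographic two-stage LP: with the ammonia uptake pinned
#' at `v_nh4`, growth is first maximized, then the glucose uptake is
#' minimized subject to growth staying at that maximum. The resulting
#' `v_glc_min` is the smallest carbon uptake sustaining the best growth
#' attainable at that nitrogen supply.
#'
#' @param model a [metabolic_model].
#' @param med optional `medium_spec` applied first.
#' @param v_nh4 fixed ammonia (nitrogen-source) uptake magnitude.
#' @param n_exchange,c_exchange exchange ids of the nitrogen and carbon
#'   sources.
#' @return A list of class `cn_coordination` with `v_nh4`, `v_gro_max`,
#'   `v_glc_min`.
#' @export
coordinate_carbon_nitrogen <- function(model, med = NULL, v_nh4,
                                       n_exchange, c_exchange) {
  if (v_nh4 < 0) stop("v_nh4 must be non-negative")
  base <- if (is.null(med)) model else apply_medium(model, med)
  fx_n <- uptake_fix(base, n_exchange, v_nh4)
  fba <- solve_fba(base, fixes = fx_n)
  gro_fix <- stats::setNames(fba$value, base$biomass)
  vmin <- minimize_flux(base, c_exchange, fixes = c(fx_n, gro_fix))
  structure(list(v_nh4 = v_nh4, v_gro_max = fba$value, v_glc_min = vmin),
            class = "cn_coordination")
}

#' @export
print.cn_coordination <- function(x, ...) {
  cat(sprintf("<cn_coordination> v_NH4 = %g -> v_gro_max = %g, v_Glc_min = %g\n",
              x$v_nh4, x$v_gro_max, x$v_glc_min))
  invisible(x)
}

#' Scan flux variability over an uptake rate
#'
#' For each grid value the scanned exchange is pinned at that uptake
#' (overriding the medium limit, with a warning, when the grid extends
#' beyond it) and the full internal/external/growth decomposition is
#' computed against a reference state that is established once from the
#' base medium. With `coordinate_cn = TRUE` and the scanned exchange being
#' the nitrogen source, the carbon source is additionally pinned at the
#' coordinated minimum from [coordinate_carbon_nitrogen()] at every grid
#' point.
#'
#' Infeasible grid points are flagged (`feasible = FALSE`, measures `NA`)
#' and the scan continues; a scan with no feasible point is an error.
#'
#' @param model a [metabolic_model].
#' @param med optional `medium_spec` defining the base condition.
#' @param exchange_id the scanned exchange reaction.
#' @param grid strictly increasing non-negative uptake values.
#' @param coordinate_cn impose carbon-nitrogen coordination?
#' @param n_exchange,c_exchange nitrogen/carbon source ids (required when
#'   `coordinate_cn`).
#' @param reference optional [compute_reference_ranges()] result; by
#'   default computed from `model` + `med`. Pass the aerobic reference
#'   explicitly to normalize an anaerobic scan against aerobic conditions.
#' @param sigma also compute Sigma components?
#' @return A data frame of class `uptake_scan`: one row per grid point
#'   with the uptake, `vgro_max`, the Delta components, optional Sigma
#'   components, and a `feasible` flag.
#' @export
scan_uptake <- function(model, med = NULL, exchange_id, grid,
                        coordinate_cn = FALSE, n_exchange = exchange_id,
                        c_exchange = NULL, reference = NULL,
                        sigma = FALSE) {
  base <- if (is.null(med)) model else apply_medium(model, med)
  if (base$reaction_class[[exchange_id]] != "exchange")
    stop("'", exchange_id, "' is not an exchange reaction")
  if (any(grid < 0) || any(diff(grid) <= 0))
    stop("grid must be non-negative and strictly increasing")
  if (coordinate_cn && is.null(c_exchange))
    stop("coordinate_cn requires c_exchange")
  if (is.null(reference)) reference <- compute_reference_ranges(model, med)
  s <- uptake_sign(base, exchange_id)
  lim <- if (s > 0) base$upper_bounds[[exchange_id]]
         else -base$lower_bounds[[exchange_id]]
  if (any(grid > lim + EPS_BND))
    warning("grid extends beyond the medium uptake limit (", lim,
            ") for ", exchange_id, "; the limit is overridden by the scan")
  scan_base <- base
  ## widen the scanned bound so grid fixes beyond the medium limit are legal
  if (s > 0) scan_base$upper_bounds[[exchange_id]] <-
      max(lim, grid[length(grid)])
  else scan_base$lower_bounds[[exchange_id]] <-
      min(-lim, -grid[length(grid)])
  cols <- c("delta_int", "delta_ext", "delta_gro", "delta_tot",
            if (sigma) c("sigma_int", "sigma_ext", "sigma_gro", "sigma_tot"))
  rows <- lapply(grid, function(g) {
    fx <- uptake_fix(scan_base, exchange_id, g)
    if (coordinate_cn && identical(exchange_id, n_exchange)) {
      cc <- tryCatch(
        coordinate_carbon_nitrogen(scan_base, NULL, g, n_exchange,
                                   c_exchange),
        error = function(e) NULL)
      if (is.null(cc))
        return(c(uptake = g, vgro_max = NA, stats::setNames(
          rep(NA_real_, length(cols)), cols), feasible = 0))
      fx <- c(fx, uptake_fix(scan_base, c_exchange, cc$v_glc_min))
    }
    vc <- tryCatch(decompose_variability(scan_base, reference, fixes = fx,
                                         sigma = sigma),
                   error = function(e) NULL)
    if (is.null(vc))
      return(c(uptake = g, vgro_max = NA, stats::setNames(
        rep(NA_real_, length(cols)), cols), feasible = 0))
    c(uptake = g, vgro_max = vc$vgro_max,
      vapply(cols, function(k) vc[[k]], numeric(1)), feasible = 1)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$feasible <- out$feasible == 1
  if (!any(out$feasible)) stop("every grid point is infeasible")
  structure(out, exchange = exchange_id, coordinate_cn = coordinate_cn,
            class = c("uptake_scan", "data.frame"))
}

#' Scan total variability against growth-rate bounds
#'
#' Four ways of restricting growth, mirroring the growth-flexibility
#' trade-off analysis:
#' \describe{
#'   \item{`upper_bound`}{growth confined to `[0, f * vgro_max]`.}
#'   \item{`lower_bound`}{growth confined to `[f * vgro_max, vgro_max]`.}
#'   \item{`both_bounds`}{growth pinned at `f * vgro_max`.}
#'   \item{`glucose_limited`}{the carbon uptake is pinned at grid values
#'     and growth left free; the realized maximum growth fraction is the
#'     x-coordinate.}
#' }
#' Exchanges are otherwise free under the medium, and `delta_tot` is
#' evaluated against the fixed reference.
#'
#' @param model a [metabolic_model].
#' @param med optional `medium_spec`.
#' @param mode one of the four modes above.
#' @param fractions growth fractions `f` in `[0, 1]` (bound modes).
#' @param glucose_exchange carbon exchange id (`glucose_limited` mode).
#' @param glucose_grid uptake grid for `glucose_limited`; defaults to 20
#'   points over `(0, limit]`.
#' @param reference optional reference state (see [scan_uptake()]).
#' @return A data frame of class `growth_scan` with the mode, `fraction`
#'   (`vgro/vgro_max`), `vgro`, `delta_tot` and a `feasible` flag.
#' @export
scan_growth_bounds <- function(model, med = NULL,
                               mode = c("lower_bound", "upper_bound",
                                        "both_bounds", "glucose_limited"),
                               fractions = seq(0, 1, length.out = 11),
                               glucose_exchange = NULL,
                               glucose_grid = NULL, reference = NULL) {
  mode <- match.arg(mode)
  base <- if (is.null(med)) model else apply_medium(model, med)
  if (is.null(reference)) reference <- compute_reference_ranges(model, med)
  adm <- reference$admissible
  gro <- base$biomass
  if (mode == "glucose_limited") {
    if (is.null(glucose_exchange))
      stop("glucose_limited mode requires glucose_exchange")
    s <- uptake_sign(base, glucose_exchange)
    lim <- if (s > 0) base$upper_bounds[[glucose_exchange]]
           else -base$lower_bounds[[glucose_exchange]]
    if (is.null(glucose_grid))
      glucose_grid <- seq(lim / 20, lim, length.out = 20)
    vmax0 <- solve_fba(base, fixes = uptake_fix(base, glucose_exchange,
                                                lim))$value
    rows <- lapply(glucose_grid, function(g) {
      fx <- uptake_fix(base, glucose_exchange, g)
      res <- tryCatch({
        vg <- solve_fba(base, fixes = fx)$value
        d <- delta_measure(solve_fva(base, adm, fixes = fx), reference)
        c(fraction = vg / vmax0, vgro = vg, delta_tot = d, feasible = 1)
      }, error = function(e) c(fraction = NA, vgro = NA,
                               delta_tot = NA, feasible = 0))
      c(glucose = g, res)
    })
    out <- as.data.frame(do.call(rbind, rows))
  } else {
    if (any(fractions < 0 | fractions > 1))
      stop("fractions must lie in [0, 1]")
    vmax <- solve_fba(base)$value
    rows <- lapply(fractions, function(f) {
      gb <- switch(mode,
        upper_bound = c(base$lower_bounds[[gro]], f * vmax),
        lower_bound = c(f * vmax, vmax),
        both_bounds = c(f * vmax, f * vmax))
      res <- tryCatch({
        cond <- condition_model(base, bounds = stats::setNames(list(gb), gro))
        d <- delta_measure(solve_fva(cond, adm), reference)
        c(vgro = gb[2], delta_tot = d, feasible = 1)
      }, error = function(e) c(vgro = NA, delta_tot = NA, feasible = 0))
      c(fraction = f, res)
    })
    out <- as.data.frame(do.call(rbind, rows))
  }
  out$feasible <- out$feasible == 1
  if (!any(out$feasible)) stop("every grid point is infeasible")
  attr(out, "mode") <- mode
  class(out) <- c("growth_scan", "data.frame")
  out
}
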