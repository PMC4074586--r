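## Delta and Sigma variability measures and the internal/external/growth
## decomposition.
##
## Delta is the average, over internal reactions with nonzero reference
## range (the "admissible set"), of the ratio of a condition's FVA range to
## the reference range. Sigma is the spread (max - min) of the summed
## internal flux under a condition, relative to the same spread at
## reference; one condition costs 2 LPs.

## Pin selected reactions into the model bounds (conditions travel with the
## model, unlike decomposition fixes which are per-LP).
condition_model <- function(model, fixes = NULL, bounds = NULL) {
  out <- model
  if (!is.null(fixes) && length(fixes)) {
    bnd <- apply_fixes(model, fixes)
    out$lower_bounds <- bnd$lb; out$upper_bounds <- bnd$ub
  }
  if (!is.null(bounds)) {
    for (rx in names(bounds)) {
      if (!rx %in% model$reaction_ids)
        stop("unknown reaction in bounds: ", rx)
      out$lower_bounds[[rx]] <- bounds[[rx]][1]
      out$upper_bounds[[rx]] <- bounds[[rx]][2]
    }
  }
  out
}

#' Reference flux-variability state
#'
#' Runs a full FVA under the reference medium with growth, exchanges and
#' internal reactions all free, and records the per-reaction reference
#' ranges `[V_i_min, V_i_max]`, the internal reactions, and the admissible
#' set (internal reactions whose reference width exceeds the zero-width
#' threshold). Also records the reference spread of the summed internal
#' flux, the denominator of the Sigma measure.
#'
#' @param model a [metabolic_model].
#' @param med optional `medium_spec` applied before the FVA.
#' @return An object of class `reference_state` with fields `ranges`,
#'   `internal`, `admissible`, `widths`, `sigma_spread`, and `model` (the
#'   conditioned reference model).
#' @export
compute_reference_ranges <- function(model, med = NULL) {
  ref_model <- if (is.null(med)) model else apply_medium(model, med)
  ranges <- solve_fva(ref_model)
  widths <- range_widths(ranges)
  internal <- reactions_of_class(ref_model, "internal")
  admissible <- internal[widths[internal] > EPS_W]
  ssp <- internal_sum_range(ref_model, internal)
  structure(list(ranges = ranges, widths = widths, internal = internal,
                 admissible = admissible,
                 sigma_spread = unname(ssp["max"] - ssp["min"]),
                 model = ref_model),
            class = "reference_state")
}

#' @export
print.reference_state <- function(x, ...) {
  cat("<reference_state> ", length(x$internal), " internal reactions, ",
      length(x$admissible), " admissible (nonzero reference width)\n",
      sep = "")
  invisible(x)
}

## max and min of the summed internal flux: 2 LPs.
internal_sum_range <- function(model, internal, fixes = NULL) {
  obj <- as.numeric(model$reaction_ids %in% internal)
  lo <- run_lp(model, obj, fixes, "min")
  hi <- run_lp(model, obj, fixes, "max")
  if (lo$status != "optimal" || hi$status != "optimal") stop("infeasible")
  c(min = lo$value, max = hi$value)
}

#' The Delta flux-variability measure
#'
#' `Delta = mean over admissible internal reactions of
#' (j_i_max - j_i_min) / (V_i_max - V_i_min)`, where `V` are the reference
#' ranges and `j` the ranges under the condition of interest. Equals 1 at
#' the reference by construction, 0 when every admissible reaction is
#' pinned, and may exceed 1 when conditions are relaxed beyond the
#' reference; it is not clamped. Internal reactions with zero reference
#' width are excluded from both the sum and the divisor by default
#' (`include_pinned = TRUE` switches to dividing by the full internal
#' count, the alternative reading of the average).
#'
#' @param ranges a `flux_ranges` covering at least the admissible set.
#' @param reference a [compute_reference_ranges()] result.
#' @param include_pinned divide by all internal reactions instead of the
#'   admissible count?
#' @return The scalar Delta.
#' @export
delta_measure <- function(ranges, reference, include_pinned = FALSE) {
  adm <- reference$admissible
  if (length(adm) == 0L)
    stop("reference has no variable internal reactions")
  missing <- setdiff(adm, ranges$reaction)
  if (length(missing))
    stop("ranges do not cover the admissible set: ",
         paste(utils::head(missing, 5), collapse = ", "))
  w <- range_widths(ranges)[adm]
  ratios <- w / reference$widths[adm]
  denom <- if (include_pinned) length(reference$internal) else length(adm)
  sum(ratios) / denom
}

#' The Sigma flux-variability measure
#'
#' The variability of the summed internal flux: the spread (maximum minus
#' minimum of `sum of v_i` over internal reactions) attainable under a
#' condition, divided by the same spread at reference. One condition costs
#' two LPs, which makes Sigma a fast companion check on Delta; it is never
#' a substitute for it.
#'
#' @param model the conditioned [metabolic_model] (conditions applied to
#'   its bounds).
#' @param reference a [compute_reference_ranges()] result.
#' @param fixes optional additional fixes (as in [solve_fva()]).
#' @return The scalar Sigma.
#' @export
sigma_measure <- function(model, reference, fixes = NULL) {
  if (reference$sigma_spread <= EPS_W)
    stop("reference spread of the summed internal flux is zero")
  sr <- internal_sum_range(model, reference$internal, fixes)
  (sr[["max"]] - sr[["min"]]) / reference$sigma_spread
}

#' Decompose flux variability into internal, external and growth components
#'
#' For a condition (extra fixes and/or bound overrides on top of the
#' model), performs the constraint-set cascade: (a) growth and external
#' fluxes pinned at an optimal-growth solution gives `delta_int`; (b) only
#' growth pinned gives `delta_int + delta_ext`; (c) everything free gives
#' `delta_tot`; with `delta_ext` and `delta_gro` the successive
#' differences, so `delta_tot = delta_int + delta_ext + delta_gro` holds
#' exactly. The external fluxes at optimal growth are degenerate in
#' general; the vertex actually used is recorded in the result
#' (`fixes_used`), and can be overridden via `vext_override` to probe the
#' degeneracy (the individual `delta_int`/`delta_ext` may then change, but
#' their sum and `delta_gro` do not).
#'
#' Exchanges pinned by the condition itself stay pinned in every step and
#' are not part of the optimal-growth external pattern, so `delta_ext`
#' measures only the external variation the condition leaves free.
#'
#' @param model a [metabolic_model] (typically after [apply_medium()]).
#' @param reference a [compute_reference_ranges()] result.
#' @param fixes named vector of condition fixes (`lb = ub = value`), e.g.
#'   a scanned uptake via [uptake_fix()].
#' @param bounds named list of `c(lb, ub)` bound overrides.
#' @param sigma also compute the Sigma analogues?
#' @param vext_override named vector replacing the FBA-chosen external
#'   optimum (must be feasible at maximal growth).
#' @param gamma relative slack on the fixed growth optimum: growth is
#'   constrained to `[(1 - gamma) * vgro_max, vgro_max]` instead of pinned
#'   exactly (default 0, exact pinning).
#' @param include_pinned passed to [delta_measure()].
#' @return An object of class `variability_components`.
#' @export
decompose_variability <- function(model, reference, fixes = NULL,
                                  bounds = NULL, sigma = FALSE,
                                  vext_override = NULL, gamma = 0,
                                  include_pinned = FALSE) {
  cond <- condition_model(model, fixes, bounds)
  fba <- solve_fba(cond)
  vgro_max <- fba$value
  gro <- cond$biomass
  exch <- reactions_of_class(cond, "exchange")
  fixed_by_condition <- names(fixes)[names(fixes) %in% exch]
  free_exch <- setdiff(exch, fixed_by_condition)
  vext <- fba$flux[free_exch]
  if (!is.null(vext_override)) {
    if (!all(names(vext_override) %in% free_exch))
      stop("vext_override must name exchanges left free by the condition")
    vext[names(vext_override)] <- vext_override
  }
  ## clamp onto bounds to absorb solver roundoff before pinning
  vext <- pmin(pmax(vext, cond$lower_bounds[free_exch]),
               cond$upper_bounds[free_exch])
  gro_fix <- stats::setNames(min(max(vgro_max, cond$lower_bounds[[gro]]),
                                 cond$upper_bounds[[gro]]), gro)
  adm <- reference$admissible
  fva_delta <- function(fx, bnds = NULL) {
    mdl <- if (is.null(bnds)) cond else condition_model(cond, bounds = bnds)
    delta_measure(solve_fva(mdl, adm, fixes = fx), reference,
                  include_pinned = include_pinned)
  }
  if (gamma > 0) {
    gb <- stats::setNames(list(c((1 - gamma) * vgro_max,
                                 gro_fix[[gro]])), gro)
    d_int <- fva_delta(vext, gb)
    d_ie  <- fva_delta(NULL, gb)
  } else {
    d_int <- fva_delta(c(gro_fix, vext))
    d_ie  <- fva_delta(gro_fix)
  }
  d_tot <- fva_delta(NULL)
  out <- list(delta_int = d_int,
              delta_ext = d_ie - d_int,
              delta_gro = d_tot - d_ie,
              delta_tot = d_tot,
              vgro_max = vgro_max,
              admissible_count = length(adm),
              fixes_used = c(fixes, gro_fix, vext),
              condition = fixes)
  if (sigma) {
    s_ref <- reference$sigma_spread
    sr <- function(fx) {
      x <- internal_sum_range(cond, reference$internal, fx)
      (x[["max"]] - x[["min"]]) / s_ref
    }
    s_int <- sr(c(gro_fix, vext)); s_ie <- sr(gro_fix); s_tot <- sr(NULL)
    out <- c(out, list(sigma_int = s_int, sigma_ext = s_ie - s_int,
                       sigma_gro = s_tot - s_ie, sigma_tot = s_tot))
  }
  structure(out, class = "variability_components")
}

#' @export
print.variability_components <- function(x, digits = 4, ...) {
  cat("<variability_components>\n")
  cat(sprintf("  delta_int = %.*f  delta_ext = %.*f  delta_gro = %.*f  delta_tot = %.*f\n",
              digits, x$delta_int, digits, x$delta_ext,
              digits, x$delta_gro, digits, x$delta_tot))
  if (!is.null(x$sigma_tot))
    cat(sprintf("  sigma_int = %.*f  sigma_ext = %.*f  sigma_gro = %.*f  sigma_tot = %.*f\n",
                digits, x$sigma_int, digits, x$sigma_ext,
                digits, x$sigma_gro, digits, x$sigma_tot))
  cat(sprintf("  vgro_max = %.*f over %d admissible internal reactions\n",
              digits, x$vgro_max, x$admissible_count))
  invisible(x)
}
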