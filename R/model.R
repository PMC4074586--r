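## Model container and conditioning.
##
## Sign convention: fluxes are stored model-signed (BiGG style: a negative
## exchange flux is uptake when the exchanged metabolite has coefficient -1).
## All user-facing uptake quantities are positive magnitudes; the conversion
## happens exactly once, at the medium/report boundary, via the sign of the
## single stoichiometric entry of the exchange reaction.

#' Construct a metabolic model
#'
#' Builds the container every linear program in the package is assembled
#' from: the m x r stoichiometry matrix `N`, per-reaction flux bounds
#' `[alpha_i, beta_i]`, the biomass (growth) reaction, and a per-reaction
#' class in `{internal, exchange, growth}`.
#'
#' @param metabolite_ids character vector of metabolite identifiers (length m).
#' @param reaction_ids character vector of reaction identifiers (length r).
#' @param stoichiometry an m x r matrix (dense or `Matrix` sparse) of
#'   stoichiometric coefficients.
#' @param lower_bounds,upper_bounds numeric flux bounds per reaction
#'   (mmol/gDW/h; the biomass flux is in 1/h). `-Inf`/`Inf` are allowed and
#'   clamped only when an LP is built.
#' @param biomass identifier of the growth reaction.
#' @param name optional model name.
#' @return An object of class `metabolic_model`.
#' @seealso [read_model()], [classify_reactions()], [apply_medium()]
#' @export
metabolic_model <- function(metabolite_ids, reaction_ids, stoichiometry,
                            lower_bounds, upper_bounds, biomass,
                            name = "model") {
  S <- methods::as(methods::as(Matrix::Matrix(stoichiometry, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  m <- length(metabolite_ids); r <- length(reaction_ids)
  if (nrow(S) != m || ncol(S) != r)
    stop("stoichiometry must be ", m, " x ", r)
  if (anyDuplicated(reaction_ids)) stop("duplicate reaction ids")
  if (anyDuplicated(metabolite_ids)) stop("duplicate metabolite ids")
  if (length(lower_bounds) != r || length(upper_bounds) != r)
    stop("bounds must have one entry per reaction")
  if (any(lower_bounds > upper_bounds))
    stop("lower bound exceeds upper bound for: ",
         paste(reaction_ids[lower_bounds > upper_bounds], collapse = ", "))
  if (!biomass %in% reaction_ids)
    stop("biomass reaction '", biomass, "' is not in the model")
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  mod <- structure(list(
    metabolite_ids = metabolite_ids,
    reaction_ids = reaction_ids,
    stoichiometry = S,
    lower_bounds = stats::setNames(as.numeric(lower_bounds), reaction_ids),
    upper_bounds = stats::setNames(as.numeric(upper_bounds), reaction_ids),
    biomass = biomass,
    name = name
  ), class = "metabolic_model")
  mod$reaction_class <- classify_reactions(mod, biomass)
  mod
}

#' @export
print.metabolic_model <- function(x, ...) {
  cls <- table(factor(x$reaction_class,
                      levels = c("internal", "exchange", "growth")))
  cat("<metabolic_model> ", x$name, "\n",
      "  ", length(x$metabolite_ids), " metabolites, ",
      length(x$reaction_ids), " reactions (",
      cls[["internal"]], " internal, ", cls[["exchange"]], " exchange, ",
      cls[["growth"]], " growth)\n",
      "  biomass: ", x$biomass, "\n", sep = "")
  invisible(x)
}

#' Classify reactions as internal, exchange or growth
#'
#' The growth class is the designated biomass reaction; reactions whose
#' stoichiometric column has exactly one nonzero entry (boundary reactions:
#' exchanges, sinks, demands) are external; everything else — including
#' ATP-maintenance style reactions, which touch several metabolites — is
#' internal. The classification is total: every reaction gets exactly one
#' class.
#'
#' @param model a [metabolic_model].
#' @param biomass_id identifier of the growth reaction.
#' @return Named character vector over reactions with values
#'   `"internal"`, `"exchange"` or `"growth"`.
#' @export
classify_reactions <- function(model, biomass_id = model$biomass) {
  if (!biomass_id %in% model$reaction_ids)
    stop("biomass reaction '", biomass_id, "' is not in the model")
  nz <- Matrix::colSums(model$stoichiometry != 0)
  cls <- ifelse(nz == 1, "exchange", "internal")
  names(cls) <- model$reaction_ids
  cls[biomass_id] <- "growth"
  cls
}

reactions_of_class <- function(model, class) {
  model$reaction_ids[model$reaction_class == class]
}

## Sign of the single stoichiometric entry of an exchange column. Uptake
## magnitude is  -sign * v  when the coefficient is negative (BiGG) and
## +v when positive, i.e. uptake = -coef_sign * v ... worked out below.
exchange_coef_sign <- function(model, rxn) {
  col <- model$stoichiometry[, rxn]
  nzv <- col[col != 0]
  if (length(nzv) != 1L) stop("'", rxn, "' is not an exchange reaction")
  sign(nzv[[1]])
}

## Direction multiplier s such that uptake magnitude = s * v for exchange
## reaction rxn. Coefficient -1 (BiGG "A <-> "): uptake is v < 0, so
## s = -1. Coefficient +1 (" -> A"): uptake is v > 0, s = +1. Either way
## s equals the sign of the coefficient.
uptake_sign <- function(model, rxn) exchange_coef_sign(model, rxn)

#' Uptake magnitude of exchange fluxes
#'
#' Converts model-signed exchange fluxes to positive uptake magnitudes
#' (negative values are secretion), independent of how each exchange is
#' oriented in the model.
#'
#' @param model a [metabolic_model].
#' @param flux named flux vector (model-signed).
#' @param reactions exchange reactions to report; default all exchanges.
#' @return Named numeric vector of uptake magnitudes.
#' @export
uptake_rates <- function(model, flux, reactions = NULL) {
  if (is.null(reactions)) reactions <- reactions_of_class(model, "exchange")
  vapply(reactions, function(rx) uptake_sign(model, rx) * flux[[rx]],
         numeric(1))
}

#' Specify a growth medium
#'
#' A medium is a map from exchange-reaction identifiers to non-negative
#' uptake and secretion limits. When applied ([apply_medium()]), listed
#' exchanges get their uptake-direction bound set to the uptake limit and
#' the opposite bound to the secretion limit; every unlisted exchange is
#' closed for uptake and left unbounded for secretion.
#'
#' @param uptake named numeric vector of uptake limits (positive magnitudes;
#'   `Inf` = unbounded uptake).
#' @param secretion named numeric vector of secretion limits; exchanges not
#'   named here secrete freely.
#' @return An object of class `medium_spec`.
#' @export
medium <- function(uptake, secretion = numeric(0)) {
  if (length(uptake) && (is.null(names(uptake)) || any(names(uptake) == "")))
    stop("uptake limits must be named by exchange reaction id")
  if (any(uptake < 0) || any(secretion < 0))
    stop("medium limits must be non-negative")
  structure(list(uptake = uptake, secretion = secretion),
            class = "medium_spec")
}

#' Read a medium specification from YAML
#'
#' Expected layout: a top-level `exchanges` mapping of exchange id to either
#' a single uptake limit or a `{uptake:, secretion:}` pair. `.inf` denotes an
#' unbounded limit.
#'
#' @param path path to a YAML file.
#' @return A `medium_spec`.
#' @export
read_medium <- function(path) {
  doc <- yaml::read_yaml(path)
  ex <- doc$exchanges
  if (is.null(ex)) stop("medium YAML must contain an 'exchanges' mapping")
  upt <- sec <- numeric(0)
  for (id in names(ex)) {
    e <- ex[[id]]
    if (is.list(e)) {
      if (!is.null(e$uptake)) upt[id] <- as.numeric(e$uptake)
      if (!is.null(e$secretion)) sec[id] <- as.numeric(e$secretion)
    } else {
      upt[id] <- as.numeric(e)
    }
  }
  medium(upt, sec)
}

#' The packaged glucose minimal medium
#'
#' Default condition for E. coli style reconstructions: glucose uptake
#' limited to 10 mmol/gDW/h, inorganic nutrients (ammonium, phosphate,
#' sulfate, trace ions, water, protons) freely taken up, oxygen uptake
#' unbounded when `aerobic` and closed otherwise. Identifiers follow the
#' BiGG namespace; pass `glucose`/`oxygen` to adapt to other namespaces.
#'
#' @param aerobic logical; open the oxygen exchange for uptake?
#' @param glucose,oxygen exchange identifiers of the carbon and oxygen
#'   sources.
#' @return A `medium_spec`.
#' @export
glucose_minimal_medium <- function(aerobic = TRUE,
                                   glucose = "EX_glc__D_e",
                                   oxygen = "EX_o2_e") {
  path <- system.file("extdata", "glucose_minimal_medium.yaml",
                      package = "fluxvar")
  med <- read_medium(path)
  names(med$uptake)[names(med$uptake) == "EX_glc__D_e"] <- glucose
  med$uptake[[oxygen]] <- if (aerobic) Inf else 0
  med
}

#' Apply a medium to a model
#'
#' Sets exchange bounds from a [medium()] specification. For each listed
#' exchange the uptake-direction bound becomes the uptake limit (e.g. lower
#' bound `-limit` for a BiGG-oriented exchange) and the opposite bound the
#' secretion limit; unlisted exchanges are closed for uptake and unbounded
#' for secretion. Internal reactions and the growth reaction are untouched.
#' The input model is not modified. Applying the same medium twice is a
#' no-op.
#'
#' @param model a [metabolic_model].
#' @param med a `medium_spec`.
#' @return A new, conditioned `metabolic_model`.
#' @export
apply_medium <- function(model, med) {
  stopifnot(inherits(med, "medium_spec"))
  exch <- reactions_of_class(model, "exchange")
  listed <- union(names(med$uptake), names(med$secretion))
  bad <- setdiff(listed, exch)
  if (length(bad))
    stop("medium names non-exchange reactions: ", paste(bad, collapse = ", "))
  out <- model
  for (rx in exch) {
    up <- if (rx %in% names(med$uptake)) med$uptake[[rx]] else 0
    se <- if (rx %in% names(med$secretion)) med$secretion[[rx]] else Inf
    s <- uptake_sign(model, rx)
    if (s < 0) {            # uptake is negative flux
      out$lower_bounds[[rx]] <- -up
      out$upper_bounds[[rx]] <- se
    } else {                # uptake is positive flux
      out$upper_bounds[[rx]] <- up
      out$lower_bounds[[rx]] <- -se
    }
  }
  out
}

#' Fix an exchange uptake rate
#'
#' Convenience for building fix specifications in uptake magnitudes: returns
#' the model-signed flux value at which the exchange must be pinned so that
#' its uptake equals `value`.
#'
#' @param model a [metabolic_model].
#' @param rxn exchange reaction id.
#' @param value non-negative uptake magnitude.
#' @return Named numeric length-1 vector usable inside a `fixes` argument.
#' @export
uptake_fix <- function(model, rxn, value) {
  if (value < 0) stop("uptake magnitude must be non-negative")
  stats::setNames(uptake_sign(model, rxn) * value, rxn)
}
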