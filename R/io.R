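## Model readers and writer.
##
## Two dialects: BiGG-style JSON (the exchange format of the BiGG database)
## and SBML Level 3 with the FBC v2 extension. Both are reduced to the same
## metabolic_model container; boundary-condition species in SBML are dropped
## from the stoichiometry so their reactions become single-entry boundary
## columns, matching the exchange classification rule.

#' Read a metabolic model from file
#'
#' @param path path to the model file.
#' @param format `"bigg-json"` or `"sbml-fbc"`; `"auto"` guesses from the
#'   file extension (`.json` vs `.xml`/`.sbml`).
#' @return A [metabolic_model] with the biomass reaction taken from the
#'   model objective. An objective with more than one nonzero coefficient
#'   is rejected with the candidate reactions named.
#' @export
read_model <- function(path, format = c("auto", "bigg-json", "sbml-fbc")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE))
      "bigg-json" else "sbml-fbc"
  }
  switch(format,
         "bigg-json" = read_bigg_json(path),
         "sbml-fbc"  = read_sbml_fbc(path))
}

read_bigg_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$reactions) || is.null(doc$metabolites))
    stop("not a BiGG-style JSON model: ", path)
  met_ids <- vapply(doc$metabolites, function(m) m$id, character(1))
  rxn_ids <- vapply(doc$reactions, function(r) r$id, character(1))
  r <- length(rxn_ids)
  lb <- ub <- numeric(r)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  obj <- numeric(r)
  met_index <- stats::setNames(seq_along(met_ids), met_ids)
  for (j in seq_len(r)) {
    rx <- doc$reactions[[j]]
    if (is.null(rx$lower_bound) || is.null(rx$upper_bound))
      stop("reaction '", rx$id, "' is missing bounds")
    lb[j] <- as.numeric(rx$lower_bound)
    ub[j] <- as.numeric(rx$upper_bound)
    obj[j] <- if (is.null(rx$objective_coefficient)) 0
              else as.numeric(rx$objective_coefficient)
    mets <- rx$metabolites
    for (mid in names(mets)) {
      idx <- unname(met_index[mid])
      if (is.na(idx)) stop("reaction '", rx$id,
                           "' references unknown metabolite '", mid, "'")
      trip_i <- c(trip_i, idx); trip_j <- c(trip_j, j)
      trip_x <- c(trip_x, as.numeric(mets[[mid]]))
    }
  }
  nz <- which(obj != 0)
  if (length(nz) == 0L) stop("model has no objective reaction")
  if (length(nz) > 1L)
    stop("ambiguous objective; candidates: ",
         paste(rxn_ids[nz], collapse = ", "))
  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(length(met_ids), r))
  metabolic_model(met_ids, rxn_ids, S, lb, ub, rxn_ids[nz],
                  name = if (!is.null(doc$id)) doc$id else basename(path))
}

read_sbml_fbc <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (length(sp) == 0L) stop("no species found; not an SBML L3 model?")
  sp_id <- xml2::xml_attr(sp, "id")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% c("true", "1")
  met_ids <- sp_id[!boundary]
  met_index <- stats::setNames(seq_along(met_ids), met_ids)

  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                             xml2::xml_attr(pars, "id"))

  rxns <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rxns) == 0L) stop("model has no reactions")
  rxn_ids <- xml2::xml_attr(rxns, "id")
  r <- length(rxn_ids)
  lb <- ub <- numeric(r)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  for (j in seq_len(r)) {
    rx <- rxns[[j]]
    lbid <- xml2::xml_attr(rx, "lowerFluxBound")
    ubid <- xml2::xml_attr(rx, "upperFluxBound")
    if (is.na(lbid) || is.na(ubid) ||
        !lbid %in% names(par_val) || !ubid %in% names(par_val))
      stop("reaction '", rxn_ids[j], "' is missing fbc flux bounds")
    lb[j] <- par_val[[lbid]]; ub[j] <- par_val[[ubid]]
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(
        rx, paste0("./s:", side, "/s:speciesReference"), ns)
      if (length(refs) == 0L) next
      sgn <- if (side == "listOfReactants") -1 else 1
      sids <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      for (k in seq_along(sids)) {
        idx <- unname(met_index[sids[k]])
        if (is.na(idx)) next              # boundary species: dropped
        trip_i <- c(trip_i, idx); trip_j <- c(trip_j, j)
        trip_x <- c(trip_x, sgn * st[k])
      }
    }
  }
  fobj <- xml2::xml_find_all(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (length(fobj) == 0L) stop("model has no objective reaction")
  coefs <- as.numeric(xml2::xml_attr(fobj, "coefficient"))
  coefs[is.na(coefs)] <- 1
  targets <- xml2::xml_attr(fobj, "reaction")[coefs != 0]
  if (length(targets) == 0L) stop("model has no objective reaction")
  if (length(targets) > 1L)
    stop("ambiguous objective; candidates: ", paste(targets, collapse = ", "))
  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(length(met_ids), r))
  mid <- xml2::xml_find_first(doc, ".//s:model", ns)
  nm <- xml2::xml_attr(mid, "id")
  metabolic_model(met_ids, rxn_ids, S, lb, ub, targets,
                  name = if (is.na(nm)) basename(path) else nm)
}

#' Write a model as BiGG-style JSON
#'
#' Round-trip companion of [read_model()]: re-reading the written file
#' reproduces the stoichiometry, bounds and reaction classes exactly.
#' Infinite bounds are written as +/-1e6 (the same clamp the LP layer uses).
#'
#' @param model a [metabolic_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  S <- model$stoichiometry
  reactions <- lapply(seq_along(model$reaction_ids), function(j) {
    col <- S[, j]
    nz <- which(col != 0)
    mets <- as.list(col[nz])
    names(mets) <- model$metabolite_ids[nz]
    list(id = model$reaction_ids[j],
         metabolites = mets,
         lower_bound = clamp_bound(model$lower_bounds[[j]]),
         upper_bound = clamp_bound(model$upper_bounds[[j]]),
         objective_coefficient =
           if (model$reaction_ids[j] == model$biomass) 1 else 0)
  })
  doc <- list(id = model$name,
              metabolites = lapply(model$metabolite_ids,
                                   function(m) list(id = m)),
              reactions = reactions)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

clamp_bound <- function(x, big = 1e6) max(min(x, big), -big)
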