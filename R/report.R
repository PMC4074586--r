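## Result serialization and run manifests. Tabular results go to TSV
## (tab-delimited, header row, '.' decimal, 6 significant digits) so runs
## diff cleanly; every output file is paired with a JSON manifest that
## records the solver settings and the chosen optimal vertices, making a
## deterministic run reproducible bit for bit.

#' Write a result table as TSV
#'
#' @param x a data frame (scan result, `flux_ranges`, ...).
#' @param path output path.
#' @param digits significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path, digits = 6) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, dec = ".")
  invisible(path)
}

#' Serialize a decomposition to a one-row table
#'
#' Columns: condition descriptor, the four Delta components, the Sigma
#' components when present, the admissible count and `vgro_max`.
#'
#' @param x a [decompose_variability()] result.
#' @param condition condition label for the first column.
#' @return A one-row data frame.
#' @export
components_row <- function(x, condition = "") {
  row <- data.frame(condition = condition,
                    delta_int = x$delta_int, delta_ext = x$delta_ext,
                    delta_gro = x$delta_gro, delta_tot = x$delta_tot,
                    stringsAsFactors = FALSE)
  if (!is.null(x$sigma_tot)) {
    row$sigma_int <- x$sigma_int; row$sigma_ext <- x$sigma_ext
    row$sigma_gro <- x$sigma_gro; row$sigma_tot <- x$sigma_tot
  }
  row$admissible_count <- x$admissible_count
  row$vgro_max <- x$vgro_max
  row
}

#' Build a run manifest
#'
#' Records the package version, model path and checksum, solver identity
#' and tolerances, the command and parameters, and a hash of any chosen
#' optimal vertex (the external fluxes at optimal growth are degenerate in
#' general, so the vertex actually used is part of the run's identity).
#'
#' @param command name of the operation.
#' @param model_path path of the model file (checksummed when it exists).
#' @param params named list of run parameters.
#' @param vertices optional named numeric vectors of chosen optima.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(command, model_path = NULL, params = list(),
                         vertices = NULL) {
  manifest <- list(
    tool = "fluxvar",
    version = as.character(utils::packageVersion("fluxvar")),
    command = command,
    model = if (!is.null(model_path))
      list(path = model_path,
           md5 = if (file.exists(model_path))
             unname(tools::md5sum(model_path)) else NA_character_),
    solver = list(backend = "bounded-variable two-phase simplex",
                  eps_bal = EPS_BAL, eps_bnd = EPS_BND, eps_w = EPS_W,
                  big_bound = BIG_BOUND),
    params = params)
  if (!is.null(vertices))
    manifest$vertex_hashes <- lapply(vertices, vertex_hash)
  structure(manifest, class = "run_manifest")
}

## order-stable content hash of a named numeric vector (no digest dep)
vertex_hash <- function(v) {
  s <- paste(names(v), formatC(unname(v), digits = 12, format = "g"),
             collapse = ";")
  as.character(sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 2^31)
}

#' Write a run manifest as JSON
#'
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
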