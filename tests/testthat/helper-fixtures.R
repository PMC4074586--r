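# Programmatic fixtures: BiGG-style JSON snippets written to tempfiles so
# tests exercise the real reader path.

bigg_json_text <- function(reactions, metabolites) {
  jsonlite::toJSON(list(id = "fixture",
                        metabolites = lapply(metabolites, function(m) list(id = m)),
                        reactions = reactions),
                   auto_unbox = TRUE, digits = NA)
}

write_fixture_json <- function(text) {
  path <- tempfile(fileext = ".json")
  writeLines(text, path)
  path
}

# Minimal 3-reaction chain in BiGG orientation (exchange written "A <->",
# coefficient -1, so uptake is a negative flux).
bigg_chain_path <- function(ex_lb = -10) {
  rx <- list(
    list(id = "EX_A", metabolites = list(A = -1),
         lower_bound = ex_lb, upper_bound = 1000,
         objective_coefficient = 0),
    list(id = "R1", metabolites = list(A = -1, B = 1),
         lower_bound = 0, upper_bound = 1000,
         objective_coefficient = 0),
    list(id = "GRO", metabolites = list(B = -1),
         lower_bound = 0, upper_bound = 1000,
         objective_coefficient = 1))
  write_fixture_json(bigg_json_text(rx, c("A", "B")))
}

sbml_fixture_path <- function() {
  system.file("extdata", "toy_chain_synthetic.xml", package = "fluxvar")
}

# A handful of feasible fix specifications per toy, for oracle-equivalence
# sweeps. Values chosen inside the feasible polytopes.
toy_fixspecs <- function() {
  list(
    list(preset = "chain", fixes = NULL),
    list(preset = "chain", fixes = c(EX_A = 10)),
    list(preset = "chain", fixes = c(R1 = 4)),
    list(preset = "chain", fixes = c(EX_A = 7, GRO = 7)),
    list(preset = "branched", fixes = NULL),
    list(preset = "branched", fixes = c(GRO = 10, EX_A = 10)),
    list(preset = "branched", fixes = c(GRO = 5)),
    list(preset = "branched", fixes = c(R3 = 2)),
    list(preset = "branched", fixes = c(EX_A = 6, R2 = 1)),
    list(preset = "branched", fixes = c(EX_A = 0)),
    list(preset = "two_substrate", fixes = c(EX_N = 5)),
    list(preset = "two_substrate", fixes = c(EX_N = 5, GRO = 5)),
    list(preset = "two_substrate", fixes = c(EX_C = 8, EX_N = 12))
  )
}

# Two substrate entry points feeding twin internal routes: the external
# pattern at optimal growth is degenerate, and the choice decides whether
# the internal twin split stays free (substrate via A) or is pinned
# (substrate directly to B). Exercises vertex-dependence of delta_int.
twin_route_model <- function() {
  S <- matrix(0, 2, 5,
              dimnames = list(c("A", "B"),
                              c("EX_A", "EX_B", "R1a", "R1b", "GRO")))
  S["A", "EX_A"] <- 1
  S["B", "EX_B"] <- 1
  S["A", "R1a"] <- -1; S["B", "R1a"] <- 1
  S["A", "R1b"] <- -1; S["B", "R1b"] <- 1
  S["B", "GRO"] <- -1
  metabolic_model(c("A", "B"), colnames(S), S,
                  rep(0, 5), c(10, 10, Inf, Inf, 10), "GRO",
                  name = "twin_route")
}

oracle_settings <- function(preset) {
  switch(preset,
         chain = list(resolution = 0.1, cap = 20),
         branched = list(resolution = 0.1, cap = 20),
         two_substrate = list(resolution = 0.5, cap = 30))
}
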