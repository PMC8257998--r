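# Toy genome-scale taxon models: specification, generation, strain
# variants, and standalone flux balance checks.

#' Specify a synthetic taxon
#'
#' A taxon is described by pathway-level capability tags (expanded into
#' mass-balanced reaction sets via [capability_registry()]), the dietary
#' metabolites it can take up, and its biomass precursor demands.
#'
#' @param name taxon label.
#' @param capabilities character vector of capability tags.
#' @param uptake_preferences character vector of metabolite ids the taxon
#'   can import. Water is always available and is added implicitly.
#' @param biomass_precursors named numeric vector: metabolite id ->
#'   consumption coefficient per unit biomass flux.
#' @return A `taxon_spec` object.
#' @export
taxon_spec <- function(name, capabilities, uptake_preferences,
                       biomass_precursors = c(glc = 0.1)) {
  reg <- capability_registry()
  unknown <- setdiff(capabilities, names(reg))
  if (length(unknown))
    stop("unknown capability tag(s): ", paste(unknown, collapse = ", "))
  uni <- metabolite_universe()$id
  bad <- setdiff(c(uptake_preferences, names(biomass_precursors)), uni)
  if (length(bad))
    stop("unknown metabolite(s): ", paste(bad, collapse = ", "))
  spec <- structure(
    list(name = name, capabilities = capabilities,
         uptake_preferences = union(uptake_preferences, "h2o"),
         biomass_precursors = biomass_precursors),
    class = "taxon_spec")
  # biomass may consume only metabolites reachable from the uptake set
  reach <- union(spec$uptake_preferences, .capability_products(capabilities))
  unreachable <- setdiff(names(biomass_precursors), reach)
  if (length(unreachable))
    stop("biomass precursor(s) not reachable from uptake preferences: ",
         paste(unreachable, collapse = ", "))
  spec
}

# metabolites producible by a capability set (positive stoichiometry;
# both sides for reversible templates)
.capability_products <- function(capabilities) {
  reg <- capability_registry()
  tmpl <- .reaction_templates()
  out <- character(0)
  for (rid in unique(unlist(reg[capabilities]))) {
    st <- .fix_met_names(tmpl[[rid]]$stoich)
    out <- union(out, names(st)[st > 0])
    if (tmpl[[rid]]$lb < 0) out <- union(out, names(st)[st < 0])
  }
  out
}

#' Generate a taxon metabolic model from a specification
#'
#' Expands the capability tags into internal reactions, adds one exchange
#' reaction for every uptake preference and every capability product
#' (uptake allowed only for preferences), and a biomass reaction producing
#' the biomass pseudo-metabolite. All internal reactions are elementally
#' balanced; generation fails with a diagnostic if a template is not.
#'
#' @param spec a [taxon_spec()].
#' @param seed unused (generation is deterministic); kept so all generator
#'   functions share a calling convention.
#' @return A `taxon_model`: list with `taxon`, `rxns` (named list of
#'   `stoich`/`lb`/`ub`), `biomass` (reaction id), `exchanges` (ids).
#' @examples
#' m <- gen_taxon_model(taxon_spec("toy", "homolactic_D", "glc"))
#' length(m$rxns)  # 1 conversion + 2 exchanges + biomass + biomass sink
#' @export
gen_taxon_model <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "taxon_spec"))
  reg <- capability_registry()
  tmpl <- .reaction_templates()
  rxns <- list()
  for (rid in unique(unlist(reg[spec$capabilities]))) {
    tm <- tmpl[[rid]]
    tm$stoich <- .fix_met_names(tm$stoich)
    rxns[[rid]] <- tm
  }
  products <- .capability_products(spec$capabilities)
  exch_mets <- union(spec$uptake_preferences, products)
  exch <- character(0)
  for (met in exch_mets) {
    eid <- paste0("EX_", met)
    rxns[[eid]] <- list(
      stoich = setNames(-1, met),
      lb = if (met %in% spec$uptake_preferences) -1000 else 0,
      ub = 1000)
    exch <- c(exch, eid)
  }
  bm <- spec$biomass_precursors
  rxns[["BIOMASS"]] <- list(
    stoich = c(setNames(-as.numeric(bm), names(bm)), biomass = 1),
    lb = 0, ub = 1000)
  rxns[["EX_biomass"]] <- list(stoich = c(biomass = -1), lb = 0, ub = 1000)
  model <- structure(
    list(taxon = spec$name, rxns = rxns, biomass = "BIOMASS",
         exchanges = c(exch, "EX_biomass"), spec = spec),
    class = "taxon_model")
  check_balance(model)
  model
}

#' @export
print.taxon_model <- function(x, ...) {
  cat("<taxon_model> ", x$taxon, "\n", sep = "")
  cat("  reactions: ", length(x$rxns),
      " (", length(x$exchanges), " exchanges)\n", sep = "")
  invisible(x)
}

# Stoichiometric matrix (metabolites x reactions) of a taxon model
taxon_smatrix <- function(model) {
  mets <- unique(unlist(lapply(model$rxns, function(r) names(r$stoich))))
  S <- matrix(0, length(mets), length(model$rxns),
              dimnames = list(mets, names(model$rxns)))
  for (j in seq_along(model$rxns)) {
    st <- model$rxns[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}

#' Flux balance analysis on a standalone taxon model
#'
#' Maximizes (or minimizes) the flux of one reaction at steady state under
#' a diet. The diet closes all exchange uptake except for listed
#' metabolites, whose uptake bound is set to the stated rate.
#'
#' @param model a `taxon_model`.
#' @param diet named numeric vector of maximum uptake rates (mmol/day), or
#'   a [gen_diet()] object; `NULL` leaves the model's default exchange
#'   bounds (uptake open for all preferences).
#' @param objective reaction id; default the biomass reaction.
#' @param maximize logical.
#' @return List with `objective` value, `flux` (named vector), `status`.
#' @export
taxon_fba <- function(model, diet = NULL, objective = model$biomass,
                      maximize = TRUE) {
  S <- taxon_smatrix(model)
  lb <- vapply(model$rxns, `[[`, 0, "lb")
  ub <- vapply(model$rxns, `[[`, 0, "ub")
  if (!is.null(diet)) {
    bounds <- if (inherits(diet, "diet_spec")) diet$bounds else diet
    for (eid in setdiff(model$exchanges, "EX_biomass")) {
      met <- names(model$rxns[[eid]]$stoich)
      lb[eid] <- if (met %in% names(bounds)) -abs(bounds[[met]])
                 else if (met == "h2o") -1000 else min(0, ub[eid])
      lb[eid] <- max(lb[eid], -1000)
    }
  }
  obj <- as.numeric(names(model$rxns) == objective)
  res <- solve_lp(obj, S, rep("=", nrow(S)), rep(0, nrow(S)),
                  lb = lb, ub = ub, maximize = maximize)
  list(objective = res$objective,
       flux = setNames(res$x, names(model$rxns)),
       status = res$status)
}

#' Generate strain variants of a taxon model
#'
#' Each variant is the parent model minus a random subset of non-essential
#' internal reactions (biomass and exchange reactions are never deleted).
#' A deletion set that makes biomass production infeasible under the
#' taxon's preferred diet is resampled.
#'
#' @param model parent `taxon_model`.
#' @param n number of variants (>= 1).
#' @param deletion_fraction fraction of internal reactions deleted per
#'   variant, in `[0, 0.5)`.
#' @param seed integer RNG seed.
#' @param max_resample resample attempts per variant before erroring.
#' @return List of `taxon_model` objects.
#' @export
gen_strain_variants <- function(model, n, deletion_fraction, seed,
                                max_resample = 50) {
  stopifnot(n >= 1, deletion_fraction >= 0, deletion_fraction < 0.5)
  internal <- setdiff(names(model$rxns), c(model$exchanges, model$biomass))
  ndel <- round(deletion_fraction * length(internal))
  pref_diet <- setNames(rep(10, length(model$spec$uptake_preferences)),
                        model$spec$uptake_preferences)
  old <- .seed_rng(seed)
  on.exit(.restore_rng(old))
  out <- vector("list", n)
  for (v in seq_len(n)) {
    for (try in seq_len(max_resample)) {
      drop <- if (ndel > 0) sample(internal, ndel) else character(0)
      cand <- model
      cand$rxns[drop] <- NULL
      fb <- taxon_fba(cand, diet = pref_diet)
      if (fb$status == "optimal" && fb$objective > 1e-8) break
      cand <- NULL
    }
    if (is.null(cand))
      stop("could not find a feasible deletion set for variant ", v)
    cand$taxon <- paste0(model$taxon, "_s", v)
    out[[v]] <- cand
  }
  out
}

# Scoped RNG helpers: seed reproducibly, then restore the caller's state.
.seed_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Default synthetic taxon roster
#'
#' Ten genus/family-level specifications emulating the dominant gut taxa
#' of the study system: a fiber-degrading *Bacteroides*-like generalist,
#' butyrate producers (*Faecalibacterium*, *Roseburia*, *Coprococcus*,
#' *Subdoligranulum*, unclassified *Lachnospiraceae*), a
#' *Prevotella*-like fiber fermenter, enteric mixed-acid fermenters
#' (*Escherichia*, *Shigella*) and a sulfate reducer (*Desulfovibrio*).
#' The *Faecalibacterium*-like taxon synthesizes butyrate only via an
#' acetate-consuming route, making acetate crossfeeding a designed,
#' testable property of communities that contain it.
#'
#' @return Named list of [taxon_spec()] objects.
#' @export
default_taxon_specs <- function() {
  sp <- list(
    Bacteroides = taxon_spec(
      "Bacteroides",
      c("fiber_degradation", "acetogenesis", "succinogenesis",
        "homolactic_D", "mixed_acid", "glycolysis_pyruvate",
        "cysteine_desulfhydration", "alanine_synthesis", "serine_synthesis"),
      c("fiber", "glc", "cys_L", "nh3")),
    Faecalibacterium = taxon_spec(
      "Faecalibacterium",
      c("butyrogenesis_acetate", "cysteine_synthesis",
        "methionine_synthesis"),
      c("glc", "ac", "ser_L", "so4", "h2")),
    Prevotella = taxon_spec(
      "Prevotella",
      c("fiber_degradation", "acetogenesis", "succinogenesis"),
      c("fiber", "glc")),
    Roseburia = taxon_spec(
      "Roseburia",
      c("butyrogenesis_hexose", "butyrogenesis_acetate", "homolactic_L"),
      c("glc", "ac")),
    Coprococcus = taxon_spec(
      "Coprococcus",
      c("butyrogenesis_hexose", "cysteine_synthesis"),
      c("glc", "ser_L", "so4", "h2")),
    Subdoligranulum = taxon_spec(
      "Subdoligranulum",
      c("butyrogenesis_hexose", "alanine_fermentation"),
      c("glc", "ala_D", "ala_L")),
    Lachnospiraceae_unclassified = taxon_spec(
      "Lachnospiraceae_unclassified",
      c("butyrogenesis_hexose", "acetogenesis", "glycolysis_pyruvate"),
      "glc"),
    Escherichia = taxon_spec(
      "Escherichia",
      c("mixed_acid", "homolactic_D", "glycolysis_pyruvate",
        "bcaa_fermentation", "alanine_fermentation"),
      c("glc", "val_L", "leu_L", "ala_L", "ala_D")),
    Shigella = taxon_spec(
      "Shigella",
      c("mixed_acid", "homolactic_D", "glycolysis_pyruvate",
        "bcaa_fermentation", "alanine_fermentation"),
      c("glc", "val_L", "leu_L", "ala_L", "ala_D")),
    Desulfovibrio = taxon_spec(
      "Desulfovibrio",
      c("sulfate_reduction", "lactate_oxidation"),
      c("so4", "h2", "lac_D", "lac_L"),
      biomass_precursors = c(lac_D = 0.2))
  )
  sp
}
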