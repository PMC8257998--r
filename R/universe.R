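# The toy metabolite universe and mass-balanced reaction templates that the
# synthetic community generator draws from. Small enough to audit by hand,
# rich enough to cover fiber fermentation, short-chain fatty acid production,
# amino-acid synthesis/catabolism and sulfur metabolism.

#' Metabolite universe of the synthetic communities
#'
#' Returns the table of named metabolites used by the synthetic taxon
#' models, with neutral (uncharged) elemental formulas. The fiber
#' polysaccharide is a synthetic 10-unit hexose polymer.
#'
#' @return A data.frame with columns `id`, `name`, `formula`.
#' @export
metabolite_universe <- function() {
  data.frame(
    id = c("glc", "fiber", "ac", "but", "for", "succ", "lac_D", "lac_L",
           "pyr", "ala_L", "ala_D", "ser_L", "cys_L", "met_L", "val_L",
           "leu_L", "ibut", "isoval", "h2", "h2s", "co2", "nh3", "so4",
           "h2o", "biomass"),
    name = c("D-glucose", "fiber polysaccharide", "acetate", "butyrate",
             "formate", "succinate", "D-lactate", "L-lactate", "pyruvate",
             "L-alanine", "D-alanine", "L-serine", "L-cysteine",
             "L-methionine", "L-valine", "L-leucine", "isobutyrate",
             "isovalerate", "hydrogen", "hydrogen sulfide",
             "carbon dioxide", "ammonia", "sulfate", "water",
             "biomass (pseudo-metabolite)"),
    formula = c("C6H12O6", "C60H100O50", "C2H4O2", "C4H8O2", "CH2O2",
                "C4H6O4", "C3H6O3", "C3H6O3", "C3H4O3", "C3H7NO2",
                "C3H7NO2", "C3H7NO3", "C3H7NO2S", "C5H11NO2S", "C5H11NO2",
                "C6H13NO2", "C4H8O2", "C5H10O2", "H2", "H2S", "CO2",
                "H3N", "H2SO4", "H2O", ""),
    stringsAsFactors = FALSE)
}

#' Parse an elemental formula
#'
#' @param x formula strings such as `"C6H12O6"`; an empty string gives an
#'   empty composition (used for pseudo-metabolites).
#' @return A list of named numeric vectors of element counts.
#' @export
parse_formula <- function(x) {
  lapply(x, function(f) {
    if (!nzchar(f)) return(numeric(0))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    parts <- regmatches(f, list(m))[[1]]
    el <- sub("[0-9]*$", "", parts)
    ct <- as.numeric(sub("^[A-Z][a-z]?", "", parts))
    ct[is.na(ct)] <- 1
    tapply(ct, el, sum)[unique(el)]
  })
}

# Reaction templates. Stoichiometry: negative = consumed, positive =
# produced. Every non-exchange, non-biomass template is elementally
# balanced (tested).
.reaction_templates <- function() {
  r <- function(stoich, lb = 0, ub = 1000) list(stoich = stoich, lb = lb, ub = ub)
  list(
    FIBDEG   = r(c(fiber = -1, h2o = -10, glc = 10)),
    HEX_AC   = r(c(glc = -1, h2o = -2, ac = 2, co2 = 2, h2 = 4)),
    HEX_LACD = r(c(glc = -1, lac_D = 2)),
    HEX_LACL = r(c(glc = -1, lac_L = 2)),
    HEX_SUCC = r(c(glc = -1, co2 = -2, h2 = -2, succ = 2, h2o = 2)),
    HEX_MIXED = r(c(glc = -1, h2o = -2, for. = 2, ac = 2, h2 = 2)),
    HEX_PYR  = r(c(glc = -1, pyr = 2, h2 = 2)),
    HEX_BUT  = r(c(glc = -1, but = 1, co2 = 2, h2 = 2)),
    BUT_AC   = r(c(glc = -1, ac = -2, but = 2, co2 = 2, h2o = 2)),
    CYSDEG   = r(c(cys_L = -1, h2o = -1, pyr = 1, nh3 = 1, h2s = 1)),
    PYROX    = r(c(pyr = -1, h2o = -1, ac = 1, co2 = 1, h2 = 1)),
    SERCYS   = r(c(ser_L = -1, h2s = -1, cys_L = 1, h2o = 1)),
    SULFRED  = r(c(so4 = -1, h2 = -4, h2s = 1, h2o = 4)),
    MET_SYN  = r(c(cys_L = -1, ac = -1, h2 = -2, met_L = 1, h2o = 2)),
    VALDEG   = r(c(val_L = -1, h2o = -2, ibut = 1, nh3 = 1, co2 = 1, h2 = 2)),
    LEUDEG   = r(c(leu_L = -1, h2o = -2, isoval = 1, nh3 = 1, co2 = 1, h2 = 2)),
    ALADEG   = r(c(ala_L = -1, h2o = -2, ac = 1, nh3 = 1, co2 = 1, h2 = 2)),
    ALASYN   = r(c(pyr = -1, nh3 = -1, h2 = -1, ala_L = 1, h2o = 1)),
    ALARAC   = r(c(ala_D = -1, ala_L = 1), lb = -1000),
    SERSYN   = r(c(glc = -1, nh3 = -2, ser_L = 2, h2 = 2)),
    LACDOX   = r(c(lac_D = -1, h2o = -1, ac = 1, co2 = 1, h2 = 2)),
    LACRAC   = r(c(lac_D = -1, lac_L = 1), lb = -1000)
  )
}

#' Metabolic capability registry
#'
#' Maps capability tags (pathway-level labels used in [taxon_spec()]) to
#' sets of mass-balanced reaction templates.
#'
#' @return Named list: capability tag -> character vector of reaction ids.
#' @export
capability_registry <- function() {
  list(
    fiber_degradation        = "FIBDEG",
    acetogenesis             = "HEX_AC",
    homolactic_D             = "HEX_LACD",
    homolactic_L             = "HEX_LACL",
    succinogenesis           = "HEX_SUCC",
    mixed_acid               = "HEX_MIXED",
    glycolysis_pyruvate      = "HEX_PYR",
    butyrogenesis_hexose     = "HEX_BUT",
    butyrogenesis_acetate    = "BUT_AC",
    cysteine_desulfhydration = c("CYSDEG", "PYROX"),
    cysteine_synthesis       = c("SERCYS", "SULFRED"),
    methionine_synthesis     = "MET_SYN",
    bcaa_fermentation        = c("VALDEG", "LEUDEG"),
    alanine_fermentation     = c("ALADEG", "ALARAC"),
    alanine_synthesis        = c("ALASYN", "ALARAC"),
    serine_synthesis         = "SERSYN",
    lactate_oxidation        = c("LACDOX", "LACRAC"),
    sulfate_reduction        = "SULFRED"
  )
}

# stoichiometry names use `for.` to dodge the R keyword; translate
.fix_met_names <- function(stoich) {
  names(stoich)[names(stoich) == "for."] <- "for"
  stoich
}

#' Check elemental balance of a model's reactions
#'
#' Exchange and biomass reactions are excepted (they cross the model
#' boundary / produce the biomass pseudo-metabolite).
#'
#' @param model a [taxon_model] object.
#' @param tol numeric tolerance on element counts.
#' @return Invisibly `TRUE`; otherwise an error naming the first unbalanced
#'   reaction and element.
#' @export
check_balance <- function(model, tol = 1e-9) {
  uni <- metabolite_universe()
  comp <- parse_formula(uni$formula)
  names(comp) <- uni$id
  skip <- c(model$exchanges, model$biomass)
  for (id in setdiff(names(model$rxns), skip)) {
    st <- model$rxns[[id]]$stoich
    tot <- numeric(0)
    for (k in seq_along(st)) {
      f <- comp[[names(st)[k]]]
      if (is.null(f))
        stop("reaction ", id, ": unknown metabolite '", names(st)[k], "'")
      for (el in names(f)) tot[el] <- (if (el %in% names(tot)) tot[el] else 0) +
          st[k] * f[[el]]
    }
    bad <- names(tot)[abs(tot) > tol]
    if (length(bad))
      stop("reaction ", id, " is not elementally balanced: element ",
           bad[1], " off by ", signif(tot[bad[1]], 4))
  }
  invisible(TRUE)
}
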