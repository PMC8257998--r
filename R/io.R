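# Model serialization: SBML Level 3 + FBC v2, a plain-text reaction-table
# format, and a JSON dump for assembled community models.

#' Write a taxon model as SBML Level 3 with the FBC v2 extension
#'
#' Species carry their elemental formulas (`fbc:chemicalFormula`); flux
#' bounds are emitted as parameters referenced by
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound`.
#'
#' @param model a `taxon_model`.
#' @param path output file path.
#' @export
write_sbml <- function(model, path) {
  stopifnot(inherits(model, "taxon_model"))
  uni <- metabolite_universe()
  formulas <- setNames(uni$formula, uni$id)
  mets <- unique(unlist(lapply(model$rxns, function(r) names(r$stoich))))
  esc <- function(x) gsub("&", "&amp;", x)
  ln <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    paste0('  <model id="', esc(model$taxon), '" fbc:strict="true">'),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (m in mets) {
    f <- formulas[m]
    ln <- c(ln, paste0(
      '      <species id="M_', m, '" compartment="c" constant="false" ',
      'hasOnlySubstanceUnits="false" boundaryCondition="false"',
      if (!is.na(f) && nzchar(f)) paste0(' fbc:chemicalFormula="', f, '"'),
      '/>'))
  }
  ln <- c(ln, '    </listOfSpecies>', '    <listOfParameters>')
  bvals <- unique(c(vapply(model$rxns, `[[`, 0, "lb"),
                    vapply(model$rxns, `[[`, 0, "ub")))
  pid <- function(v) paste0("fb_", gsub("[^0-9a-zA-Z]", "_", format(v)))
  for (v in bvals)
    ln <- c(ln, paste0('      <parameter id="', pid(v), '" value="', v,
                       '" constant="true"/>'))
  ln <- c(ln, '    </listOfParameters>', '    <listOfReactions>')
  for (id in names(model$rxns)) {
    r <- model$rxns[[id]]
    st <- r$stoich
    ln <- c(ln, paste0(
      '      <reaction id="R_', id, '" reversible="',
      tolower(r$lb < 0), '" fast="false" fbc:lowerFluxBound="', pid(r$lb),
      '" fbc:upperFluxBound="', pid(r$ub), '">'))
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      ln <- c(ln, '        <listOfReactants>')
      for (i in seq_along(subs))
        ln <- c(ln, paste0('          <speciesReference species="M_',
                           names(subs)[i], '" stoichiometry="', -subs[i],
                           '" constant="true"/>'))
      ln <- c(ln, '        </listOfReactants>')
    }
    if (length(prods)) {
      ln <- c(ln, '        <listOfProducts>')
      for (i in seq_along(prods))
        ln <- c(ln, paste0('          <speciesReference species="M_',
                           names(prods)[i], '" stoichiometry="', prods[i],
                           '" constant="true"/>'))
      ln <- c(ln, '        </listOfProducts>')
    }
    ln <- c(ln, '      </reaction>')
  }
  ln <- c(ln, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(ln, path)
  invisible(path)
}

#' Read a taxon model from SBML Level 3 + FBC v2
#'
#' Supports the subset written by [write_sbml()] (single compartment,
#' parameter-referenced flux bounds). Exchange reactions are recognized
#' by the `EX_` prefix; the biomass reaction by the id `BIOMASS`.
#'
#' @param path SBML file path.
#' @return A `taxon_model`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  mod <- xml2::xml_find_first(doc, ".//s:model", ns)
  pars <- xml2::xml_find_all(doc, ".//s:parameter", ns)
  pvals <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                    xml2::xml_attr(pars, "id"))
  rxns <- list()
  for (rn in xml2::xml_find_all(doc, ".//s:reaction", ns)) {
    id <- sub("^R_", "", xml2::xml_attr(rn, "id"))
    sp <- function(xp, sgn) {
      refs <- xml2::xml_find_all(rn, xp, ns)
      if (!length(refs)) return(numeric(0))
      setNames(sgn * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
               sub("^M_", "", xml2::xml_attr(refs, "species")))
    }
    st <- c(sp(".//s:listOfReactants/s:speciesReference", -1),
            sp(".//s:listOfProducts/s:speciesReference", 1))
    rxns[[id]] <- list(
      stoich = st,
      lb = pvals[[xml2::xml_attr(rn, "fbc:lowerFluxBound", ns = ns)]],
      ub = pvals[[xml2::xml_attr(rn, "fbc:upperFluxBound", ns = ns)]])
  }
  structure(
    list(taxon = xml2::xml_attr(mod, "id"), rxns = rxns,
         biomass = "BIOMASS",
         exchanges = grep("^EX_", names(rxns), value = TRUE),
         spec = NULL),
    class = "taxon_model")
}

#' Write / read a taxon model in the reaction-table format
#'
#' Plain-text TSV with columns `reaction_id`, `equation` (e.g.
#' `"1 glc + 2 h2o -> 2 ac + 2 co2 + 4 h2"`; reversible reactions use
#' `<=>`), `lower_bound`, `upper_bound`.
#'
#' @param model a `taxon_model`.
#' @param path file path.
#' @export
write_reaction_table <- function(model, path) {
  stopifnot(inherits(model, "taxon_model"))
  eqn <- vapply(model$rxns, function(r) {
    st <- r$stoich
    side <- function(s) paste(paste(format(abs(unname(s)),
                                           trim = TRUE, digits = 12),
                                    names(s)), collapse = " + ")
    arrow <- if (r$lb < 0) "<=>" else "->"
    paste(side(st[st < 0]), arrow, side(st[st > 0]))
  }, "")
  df <- data.frame(reaction_id = names(model$rxns), equation = eqn,
                   lower_bound = vapply(model$rxns, `[[`, 0, "lb"),
                   upper_bound = vapply(model$rxns, `[[`, 0, "ub"),
                   row.names = NULL, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reaction_table
#' @param taxon taxon label for the model read back.
#' @export
read_reaction_table <- function(path, taxon = basename(path)) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  parse_side <- function(s, sgn) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric(0))
    terms <- strsplit(s, " \\+ ")[[1]]
    out <- numeric(0)
    for (tm in terms) {
      p <- strsplit(trimws(tm), " +")[[1]]
      out[p[2]] <- sgn * as.numeric(p[1])
    }
    out
  }
  rxns <- list()
  for (i in seq_len(nrow(df))) {
    eq <- df$equation[i]
    arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>" else "->"
    parts <- strsplit(eq, arrow, fixed = TRUE)[[1]]
    st <- c(parse_side(parts[1], -1),
            if (length(parts) > 1) parse_side(parts[2], 1))
    # a metabolite on both sides collapses to its net coefficient
    st <- tapply(st, names(st), sum)[unique(names(st))]
    rxns[[df$reaction_id[i]]] <- list(stoich = st[st != 0],
                                      lb = df$lower_bound[i],
                                      ub = df$upper_bound[i])
  }
  structure(
    list(taxon = taxon, rxns = rxns, biomass = "BIOMASS",
         exchanges = grep("^EX_", names(rxns), value = TRUE),
         spec = NULL),
    class = "taxon_model")
}

#' Dump a community model to JSON
#'
#' Writes the reaction table (id, taxon, type, bounds), the sparse
#' stoichiometry triplets, abundances and provenance in a JSON dialect.
#'
#' @param model a `community_model`.
#' @param path output path.
#' @export
write_community_json <- function(model, path) {
  stopifnot(inherits(model, "community_model"))
  tri <- Matrix::summary(model$S)
  jsonlite::write_json(
    list(sample_id = model$sample_id,
         diet = model$diet$name,
         abundances = as.list(model$abundances),
         biomass_window = model$biomass_window,
         coupling_factor = model$coupling_factor,
         reactions = model$rxns,
         metabolites = rownames(model$S),
         stoichiometry = data.frame(met = tri$i, rxn = tri$j, coef = tri$x)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a pan-model provenance log
#'
#' @param model a pan `taxon_model` from [build_pan_model()].
#' @param path output text file.
#' @export
write_provenance <- function(model, path) {
  log <- attr(model, "provenance")
  writeLines(c(paste0("pan model: ", model$taxon),
               if (length(log)) log else "no bound changes"), path)
  invisible(path)
}
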