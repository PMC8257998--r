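# Sample-specific community LP assembly: taxon compartments around a
# shared lumen, diet inflow and fecal outflow compartments, an
# abundance-weighted community biomass reaction, and optional coupling
# constraints tying each taxon's fluxes to its biomass flux.

#' Build a community metabolic model
#'
#' Assembles one sample's community LP from pan-taxon models, normalized
#' abundances and a diet. Compartments: one internal compartment per
#' taxon, a shared lumen `[u]`, a diet compartment `[d]` and a fecal
#' compartment `[fe]`. Each taxon exchange becomes a taxon-lumen (IEX)
#' reaction; every lumen metabolite has a diet transport `[d] -> [u]`
#' (bounded by the diet), a fecal transport `[u] -> [fe]`, and boundary
#' exchanges `EX_<met>_d` (uptake only; flux is negative by the secretion-
#' positive sign convention) and `EX_<met>_fe` (outflow only).
#'
#' The community biomass reaction consumes each taxon's biomass
#' pseudo-metabolite with its abundance as coefficient and is constrained
#' to `biomass_window` (default 0.4-1.0 mmol/day). With coupling enabled,
#' each reaction flux of taxon *i* satisfies `|v| <= coupling_factor *
#' v_biomass_i`, so zero-abundance taxa can carry no flux.
#'
#' @param pan_models named list of `taxon_model` objects.
#' @param abundances named numeric fractions summing to 1; taxa with zero
#'   abundance are omitted from the model.
#' @param diet a `diet_spec` (see [gen_diet()]).
#' @param biomass_window length-2 numeric, community biomass flux bounds.
#' @param coupling_factor linear coupling constant (default 400).
#' @param coupling logical; disable to drop coupling constraints.
#' @param sample_id label carried through to results.
#' @param check_feasible verify feasibility at build time (default TRUE).
#' @return A `community_model` object.
#' @export
build_community_model <- function(pan_models, abundances, diet,
                                  biomass_window = c(0.4, 1),
                                  coupling_factor = 400,
                                  coupling = TRUE,
                                  sample_id = "sample",
                                  check_feasible = TRUE) {
  stopifnot(inherits(diet, "diet_spec"),
            abs(sum(abundances) - 1) < 1e-6,
            length(biomass_window) == 2,
            biomass_window[1] <= biomass_window[2])
  abundances <- abundances[abundances > 0]
  missing <- setdiff(names(abundances), names(pan_models))
  if (length(missing))
    stop("no pan model for taxa: ", paste(missing, collapse = ", "))
  taxa <- names(abundances)

  ri <- 0L                      # reaction (column) counter
  rid <- character(0); rtaxon <- character(0); rtype <- character(0)
  rmet <- character(0); rlb <- numeric(0); rub <- numeric(0)
  ti <- tj <- integer(0); tv <- numeric(0)   # S triplets (met x rxn)
  met_index <- new.env(parent = emptyenv())
  nmet <- 0L
  met_id <- function(m) {
    k <- met_index[[m]]
    if (is.null(k)) {
      nmet <<- nmet + 1L
      met_index[[m]] <- nmet
      k <- nmet
    }
    k
  }
  add_rxn <- function(id, stoich_ids, stoich_vals, lb, ub, taxon = NA,
                      type = "internal", met = NA) {
    ri <<- ri + 1L
    rid[ri] <<- id; rtaxon[ri] <<- taxon; rtype[ri] <<- type
    rmet[ri] <<- met; rlb[ri] <<- lb; rub[ri] <<- ub
    ti <<- c(ti, vapply(stoich_ids, met_id, 1L))
    tj <<- c(tj, rep(ri, length(stoich_ids)))
    tv <<- c(tv, stoich_vals)
    ri
  }

  lumen_mets <- character(0)
  for (t in taxa) {
    m <- pan_models[[t]]
    internal <- setdiff(names(m$rxns), c(m$exchanges, m$biomass))
    for (id in internal) {
      r <- m$rxns[[id]]
      add_rxn(paste0(id, "__", t), paste0(names(r$stoich), "[", t, "]"),
              as.numeric(r$stoich), r$lb, r$ub, taxon = t)
    }
    for (eid in setdiff(m$exchanges, "EX_biomass")) {
      r <- m$rxns[[eid]]
      met <- names(r$stoich)
      lumen_mets <- union(lumen_mets, met)
      add_rxn(paste0("IEX_", met, "__", t),
              c(paste0(met, "[", t, "]"), paste0(met, "[u]")),
              c(-1, 1), r$lb, r$ub, taxon = t, type = "iex", met = met)
    }
    bm <- m$rxns[[m$biomass]]
    add_rxn(paste0(m$biomass, "__", t),
            paste0(names(bm$stoich), "[", t, "]"),
            as.numeric(bm$stoich), bm$lb, bm$ub, taxon = t,
            type = "biomass")
  }
  lumen_mets <- union(lumen_mets, names(diet$bounds))
  add_rxn("communityBiomass", paste0("biomass[", taxa, "]"),
          -as.numeric(abundances), biomass_window[1], biomass_window[2],
          type = "community_biomass")
  for (met in lumen_mets) {
    db <- if (met %in% names(diet$bounds)) diet$bounds[[met]] else 0
    add_rxn(paste0("DUt_", met), c(paste0(met, "[d]"), paste0(met, "[u]")),
            c(-1, 1), 0, 10000, type = "diet_transport", met = met)
    add_rxn(paste0("UFEt_", met), c(paste0(met, "[u]"), paste0(met, "[fe]")),
            c(-1, 1), 0, 10000, type = "fecal_transport", met = met)
    add_rxn(paste0("EX_", met, "_d"), paste0(met, "[d]"), -1,
            -abs(db), 0, type = "exchange_diet", met = met)
    add_rxn(paste0("EX_", met, "_fe"), paste0(met, "[fe]"), -1,
            0, 10000, type = "exchange_fecal", met = met)
  }

  mets <- character(nmet)
  for (m in ls(met_index)) mets[met_index[[m]]] <- m
  S <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(nmet, ri),
                            dimnames = list(mets, rid))
  rxns <- data.frame(id = rid, taxon = rtaxon, type = rtype, met = rmet,
                     lb = rlb, ub = rub, stringsAsFactors = FALSE)

  C <- NULL
  if (coupling) {
    ci <- cj <- integer(0); cv <- numeric(0)
    row <- 0L
    bio_col <- setNames(match(paste0("BIOMASS__", taxa), rid), taxa)
    for (j in seq_len(ri)) {
      if (!(rtype[j] %in% c("internal", "iex"))) next
      bcol <- bio_col[[rtaxon[j]]]
      row <- row + 1L           # v_j - C * v_bio <= 0
      ci <- c(ci, row, row); cj <- c(cj, j, bcol)
      cv <- c(cv, 1, -coupling_factor)
      if (rlb[j] < 0) {         # -v_j - C * v_bio <= 0
        row <- row + 1L
        ci <- c(ci, row, row); cj <- c(cj, j, bcol)
        cv <- c(cv, -1, -coupling_factor)
      }
    }
    C <- Matrix::sparseMatrix(i = ci, j = cj, x = cv, dims = c(row, ri),
                              dimnames = list(NULL, rid))
  }

  model <- structure(
    list(sample_id = sample_id, taxa = taxa, abundances = abundances,
         diet = diet, biomass_window = biomass_window,
         coupling_factor = if (coupling) coupling_factor else NA,
         rxns = rxns, S = S, coupling = C,
         env = new.env(parent = emptyenv())),
    class = "community_model")

  if (check_feasible) community_lp(model)   # errors with a diagnostic
  model
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> sample ", x$sample_id, ": ", length(x$taxa),
      " taxa, ", nrow(x$rxns), " reactions, diet ", x$diet$name,
      if (!is.na(x$coupling_factor))
        paste0(", coupling factor ", x$coupling_factor), "\n", sep = "")
  invisible(x)
}

#' LP instance of a community model
#'
#' Returns (and caches on the model) a warm-startable [lp_instance()] for
#' the model's steady-state, bound and coupling constraints. Successive
#' FVA objectives on the same model reuse the instance.
#'
#' Feasibility of the biomass window is bootstrapped: the instance is
#' created with the community biomass lower bound relaxed to 0, community
#' biomass is maximized once, and the window is then re-imposed with the
#' optimal basis kept. This both verifies feasibility and leaves every
#' later objective warm-started from a feasible basis.
#'
#' @param model a `community_model`.
#' @return An [lp_instance()] object.
#' @export
community_lp <- function(model) {
  if (!is.null(model$env$inst)) return(model$env$inst)
  S <- model$S
  if (is.null(model$coupling)) {
    A <- as.matrix(S)
    dir <- rep("=", nrow(S))
  } else {
    A <- as.matrix(rbind(S, model$coupling))
    dir <- c(rep("=", nrow(S)), rep("<=", nrow(model$coupling)))
  }
  jb <- match("communityBiomass", model$rxns$id)
  lb <- model$rxns$lb
  b_lo <- lb[jb]
  lb[jb] <- 0
  inst <- lp_instance(A, dir, rep(0, nrow(A)),
                      lb = lb, ub = model$rxns$ub)
  fb <- lp_optimize(inst, as.numeric(seq_len(nrow(model$rxns)) == jb),
                    maximize = TRUE)
  if (fb$status != "optimal" || fb$objective < b_lo - 1e-9)
    stop(.infeasibility_diagnostic(model))
  lp_set_bound(inst, jb, b_lo, model$rxns$ub[jb])
  model$env$inst <- inst
  inst
}

# Why is the model infeasible? Try the obvious relaxations in order.
.infeasibility_diagnostic <- function(model) {
  relax <- function(m) {
    tryCatch({ community_lp(m); TRUE }, error = function(e) FALSE)
  }
  m2 <- model
  m2$rxns$lb[m2$rxns$id == "communityBiomass"] <- 0
  m2$env <- new.env(parent = emptyenv())
  if (relax(m2))
    return(paste0("community model ", model$sample_id,
                  " infeasible: the biomass window [",
                  model$biomass_window[1], ", ", model$biomass_window[2],
                  "] cannot be met under diet ", model$diet$name,
                  " (feasible with the biomass lower bound relaxed to 0;",
                  " a taxon's biomass precursors are likely unavailable)"))
  m3 <- model
  m3$rxns$lb[m3$rxns$type == "exchange_diet"] <- -10000
  m3$env <- new.env(parent = emptyenv())
  if (relax(m3))
    return(paste0("community model ", model$sample_id,
                  " infeasible: diet ", model$diet$name,
                  " is too restrictive (feasible with all diet bounds",
                  " opened to 10000 mmol/day)"))
  paste0("community model ", model$sample_id,
         " infeasible even with biomass window and diet relaxed;",
         " check the taxon models")
}
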