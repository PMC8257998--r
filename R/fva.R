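# Flux variability analysis over community models and the net maximal
# production capability (NMPC) of exchanged metabolites.

#' Flux variability analysis
#'
#' For each listed reaction, solves the two LPs minimizing and maximizing
#' its flux subject to stoichiometric steady state, reaction bounds,
#' coupling constraints and the community biomass window. Results are
#' independent of the reaction ordering; a solver failure on one reaction
#' is recorded in the status columns and the run continues.
#'
#' @param model a `community_model`.
#' @param reactions character vector of reaction ids (default: all
#'   boundary exchange reactions).
#' @param biomass_window optional override of the model's biomass window.
#' @return A data.frame with columns `reaction`, `min`, `max`,
#'   `status_min`, `status_max`, of class `fva_result`.
#' @export
fva <- function(model, reactions = NULL, biomass_window = NULL) {
  stopifnot(inherits(model, "community_model"))
  if (!is.null(biomass_window)) {
    model$rxns$lb[model$rxns$id == "communityBiomass"] <- biomass_window[1]
    model$rxns$ub[model$rxns$id == "communityBiomass"] <- biomass_window[2]
    model$env <- new.env(parent = emptyenv())
  }
  if (is.null(reactions))
    reactions <- model$rxns$id[model$rxns$type %in%
                                 c("exchange_diet", "exchange_fecal")]
  bad <- setdiff(reactions, model$rxns$id)
  if (length(bad))
    stop("unknown reaction(s): ", paste(bad, collapse = ", "))
  inst <- community_lp(model)
  n <- nrow(model$rxns)
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                    status_min = NA_character_, status_max = NA_character_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(reactions)) {
    obj <- as.numeric(model$rxns$id == reactions[k])
    lo <- lp_optimize(inst, obj, maximize = FALSE)
    hi <- lp_optimize(inst, obj, maximize = TRUE)
    out$status_min[k] <- lo$status
    out$status_max[k] <- hi$status
    if (lo$status == "optimal") out$min[k] <- lo$objective
    if (hi$status == "optimal") out$max[k] <- hi$objective
  }
  class(out) <- c("fva_result", "data.frame")
  out
}

#' Net maximal production capability of one metabolite
#'
#' The NMPC is the absolute value of the sum of two FVA solutions: the
#' maximal secretion flux into the fecal compartment (`max EX_<met>_fe`,
#' non-negative) and the maximal dietary uptake flux (`min EX_<met>_d`,
#' non-positive by the secretion-positive sign convention). A metabolite
#' that can only pass through unchanged therefore has NMPC 0, and the
#' NMPC measures net community production. Values below `snap_tol` are
#' snapped to 0 to suppress solver noise in the zero class.
#'
#' @param model a `community_model`.
#' @param metabolite metabolite id. If the metabolite has no fecal
#'   exchange route in this community, the NMPC is 0.
#' @param full also compute the two complementary LPs (minimal fecal
#'   secretion, maximal dietary inflow) and attach all four as an
#'   attribute.
#' @param snap_tol zero-snapping tolerance (default 1e-6).
#' @return A non-negative scalar (mmol/day).
#' @export
compute_nmpc <- function(model, metabolite, full = FALSE,
                         snap_tol = 1e-6) {
  fe <- paste0("EX_", metabolite, "_fe")
  dd <- paste0("EX_", metabolite, "_d")
  if (!fe %in% model$rxns$id) return(0)
  inst <- community_lp(model)
  obj_fe <- as.numeric(model$rxns$id == fe)
  obj_d <- as.numeric(model$rxns$id == dd)
  hi <- lp_optimize(inst, obj_fe, maximize = TRUE)
  lo <- lp_optimize(inst, obj_d, maximize = FALSE)
  if (hi$status != "optimal" || lo$status != "optimal")
    stop("NMPC LPs for ", metabolite, " on sample ", model$sample_id,
         " did not solve: ", hi$status, " / ", lo$status)
  val <- abs(hi$objective + lo$objective)
  if (val < snap_tol) val <- 0
  if (full) {
    lo_fe <- lp_optimize(inst, obj_fe, maximize = FALSE)
    hi_d <- lp_optimize(inst, obj_d, maximize = TRUE)
    attr(val, "fva") <- c(fe_min = lo_fe$objective, fe_max = hi$objective,
                          d_min = lo$objective, d_max = hi_d$objective)
  }
  val
}

#' NMPC matrix over samples and metabolites
#'
#' Fills a samples x metabolites matrix by [compute_nmpc()]; per-sample
#' computations are independent, so the result does not depend on sample
#' or metabolite order. An infeasible sample is flagged and its row left
#' missing; the run continues.
#'
#' @param models named list of `community_model` objects sharing a diet.
#' @param metabolites character vector of metabolite ids (default: all
#'   metabolites with a fecal exchange in the first model).
#' @return An `nmpc_matrix`: list with `values` (samples x metabolites,
#'   mmol/day), `diet`, `provenance` (biomass window, coupling factor)
#'   and `failed` (character vector of failed sample ids).
#' @export
compute_nmpc_matrix <- function(models, metabolites = NULL) {
  stopifnot(length(models) >= 1)
  diets <- unique(vapply(models, function(m) m$diet$name, ""))
  if (length(diets) != 1)
    stop("all models must share a diet; found: ",
         paste(diets, collapse = ", "))
  if (is.null(metabolites)) {
    r1 <- models[[1]]$rxns
    metabolites <- setdiff(r1$met[r1$type == "exchange_fecal"],
                           c("h2o", "biomass"))
  }
  ids <- vapply(models, function(m) m$sample_id, "")
  vals <- matrix(NA_real_, length(models), length(metabolites),
                 dimnames = list(ids, metabolites))
  failed <- character(0)
  for (i in seq_along(models)) {
    row <- tryCatch(
      vapply(metabolites, function(met) compute_nmpc(models[[i]], met), 0),
      error = function(e) NULL)
    if (is.null(row)) failed <- c(failed, ids[i]) else vals[i, ] <- row
  }
  structure(
    list(values = vals, diet = models[[1]]$diet$name,
         provenance = list(
           biomass_window = models[[1]]$biomass_window,
           coupling_factor = models[[1]]$coupling_factor),
         failed = failed),
    class = "nmpc_matrix")
}

#' @export
print.nmpc_matrix <- function(x, ...) {
  cat("<nmpc_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " metabolites, diet ", x$diet,
      if (length(x$failed)) paste0(" (", length(x$failed), " failed)"),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.nmpc_matrix <- function(x, ...) x$values

#' Write / read an NMPC matrix as TSV with a JSON provenance sidecar
#'
#' @param nmpc an `nmpc_matrix`.
#' @param path TSV path; the sidecar is written to `<path>.json`.
#' @export
write_nmpc_matrix <- function(nmpc, path) {
  df <- data.frame(sample_id = rownames(nmpc$values), nmpc$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(diet = nmpc$diet, provenance = nmpc$provenance,
         failed = nmpc$failed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nmpc_matrix
#' @export
read_nmpc_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$sample_id
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(diet = NA, provenance = list(), failed = character(0))
  structure(list(values = vals, diet = meta$diet,
                 provenance = meta$provenance,
                 failed = meta$failed %||% character(0)),
            class = "nmpc_matrix")
}
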