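# Pan-taxon model construction: merge strain models of one taxon by
# reaction union, then mitigate futile cycles introduced by the merge.

#' Merge strain models into a pan-taxon model
#'
#' The pan model's reaction set is the union of the strains' reactions;
#' for reactions shared between strains the widest bounds are taken.
#' Strains must agree on the stoichiometry of a shared reaction id.
#'
#' After the union, futile cycles that the merge may have created are
#' mitigated: with all exchange bounds closed, flux variability analysis
#' identifies internal reactions that can still carry flux (a
#' thermodynamically impossible loop); reversible members of such loops
#' are made irreversible one at a time, preferring the forward direction
#' when a strain's default bounds carry it, until no loop flux remains.
#' Every bound change is recorded in the model's provenance log
#' (`attr(, "provenance")`).
#'
#' @param strains non-empty list of `taxon_model` objects sharing a
#'   metabolite namespace.
#' @param taxon label for the merged model.
#' @return A `taxon_model` with a `provenance` attribute (character
#'   vector, one entry per bound change).
#' @export
build_pan_model <- function(strains, taxon) {
  if (length(strains) == 0) stop("empty strain list")
  stopifnot(all(vapply(strains, inherits, TRUE, "taxon_model")))
  rxns <- list()
  for (s in strains) {
    for (id in names(s$rxns)) {
      r <- s$rxns[[id]]
      if (is.null(rxns[[id]])) {
        rxns[[id]] <- r
      } else {
        prev <- rxns[[id]]
        same <- identical(sort(names(prev$stoich)), sort(names(r$stoich))) &&
          all(abs(prev$stoich[names(r$stoich)] - r$stoich) < 1e-12)
        if (!same)
          stop("conflicting stoichiometry for reaction id '", id,
               "' across strains of ", taxon)
        rxns[[id]]$lb <- min(prev$lb, r$lb)
        rxns[[id]]$ub <- max(prev$ub, r$ub)
      }
    }
  }
  pan <- structure(
    list(taxon = taxon, rxns = rxns,
         biomass = strains[[1]]$biomass,
         exchanges = unique(unlist(lapply(strains, `[[`, "exchanges"))),
         spec = strains[[1]]$spec),
    class = "taxon_model")
  .mitigate_futile_cycles(pan, strains)
}

# Closed-exchange FVA ranges for the internal reactions of a taxon model.
.closed_exchange_ranges <- function(model, internal) {
  S <- taxon_smatrix(model)
  lb <- vapply(model$rxns, `[[`, 0, "lb")
  ub <- vapply(model$rxns, `[[`, 0, "ub")
  lb[model$exchanges] <- 0
  ub[model$exchanges] <- 0
  inst <- lp_instance(S, rep("=", nrow(S)), rep(0, nrow(S)), lb = lb, ub = ub)
  out <- matrix(0, length(internal), 2,
                dimnames = list(internal, c("min", "max")))
  for (id in internal) {
    obj <- as.numeric(names(model$rxns) == id)
    out[id, "min"] <- lp_optimize(inst, obj, maximize = FALSE)$objective
    out[id, "max"] <- lp_optimize(inst, obj, maximize = TRUE)$objective
  }
  out
}

.mitigate_futile_cycles <- function(pan, strains, tol = 1e-6,
                                    max_pass = 100) {
  internal <- setdiff(names(pan$rxns), c(pan$exchanges, pan$biomass))
  log <- character(0)
  for (pass in seq_len(max_pass)) {
    if (!length(internal)) break
    rng <- .closed_exchange_ranges(pan, internal)
    loop <- internal[rng[, "max"] > tol | rng[, "min"] < -tol]
    if (!length(loop)) break
    rev_loop <- loop[vapply(loop, function(id) pan$rxns[[id]]$lb < 0, TRUE)]
    if (!length(rev_loop)) {
      log <- c(log, paste0("unresolved loop over irreversible reactions: ",
                           paste(loop, collapse = ", ")))
      break
    }
    id <- sort(rev_loop)[1]
    # direction carried by at least one strain's default bounds
    fwd_ok <- any(vapply(strains, function(s)
      !is.null(s$rxns[[id]]) && s$rxns[[id]]$ub > 0, TRUE))
    bwd_ok <- any(vapply(strains, function(s)
      !is.null(s$rxns[[id]]) && s$rxns[[id]]$lb < 0, TRUE))
    try_dirs <- c(if (fwd_ok) "forward", if (bwd_ok) "backward")
    if (!length(try_dirs)) try_dirs <- "forward"
    fixed <- FALSE
    for (dir in try_dirs) {
      cand <- pan
      if (dir == "forward") cand$rxns[[id]]$lb <- 0
      else cand$rxns[[id]]$ub <- 0
      r2 <- .closed_exchange_ranges(cand, id)
      if (r2[1, "max"] <= tol && r2[1, "min"] >= -tol) {
        pan <- cand
        log <- c(log, paste0("futile-cycle mitigation: restricted ", id,
                             " to ", dir, " direction"))
        fixed <- TRUE
        break
      }
    }
    if (!fixed) {
      # restriction alone does not kill the loop; take the first allowed
      # direction anyway and keep iterating on the remaining members
      dir <- try_dirs[1]
      if (dir == "forward") pan$rxns[[id]]$lb <- 0
      else pan$rxns[[id]]$ub <- 0
      log <- c(log, paste0("futile-cycle mitigation: restricted ", id,
                           " to ", dir, " direction (loop persists)"))
    }
  }
  attr(pan, "provenance") <- log
  pan
}
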