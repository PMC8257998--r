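# Taxa-level resolution of metabolite exchange at a production optimum:
# which taxa secrete and which consume each metabolite when community
# production of a target is maximized, and the crossfeeding edges implied.

#' Maximize production of a target and attribute fluxes to taxa
#'
#' Maximizes fecal secretion of the target metabolite under the biomass
#' window, then fixes the objective at its optimum and minimizes the sum
#' of absolute fluxes (parsimonious secondary objective) to obtain a
#' deterministic, reproducible flux pattern among alternate optima.
#' Per-taxon secretion and uptake are read from the taxon-lumen (IEX)
#' reactions.
#'
#' @param model a `community_model`.
#' @param target metabolite id with a fecal exchange route.
#' @param fix_tol slack allowed when pinning the objective at its optimum.
#' @return A `flux_breakdown`: list with `target`, `objective` (maximal
#'   fecal secretion, mmol/day), `fluxes` (data.frame taxon x metabolite
#'   with `secretion`, `uptake`), and `lumen` (per-metabolite diet inflow
#'   and fecal outflow, for the lumen steady-state invariant).
#' @export
maximize_and_attribute <- function(model, target, fix_tol = 1e-8) {
  stopifnot(inherits(model, "community_model"))
  fe <- paste0("EX_", target, "_fe")
  if (!fe %in% model$rxns$id)
    stop("no fecal exchange route for '", target, "' in this community")
  rx <- model$rxns
  if (any(!is.finite(rx$ub)))
    stop("unbounded reaction bounds; diet bounds must be finite")

  # Extended LP [v, t]: steady state + coupling on v, |v| <= t for
  # reversible reactions (irreversible ones contribute v directly to the
  # parsimony objective). Solved as a warm-started sequence: maximize
  # community biomass with the window's lower bound relaxed, re-impose
  # the window, maximize the target, pin it at its optimum, then
  # minimize total absolute flux.
  n <- nrow(rx)
  lb <- rx$lb; ub <- rx$ub
  rev_idx <- which(lb < 0)
  nr <- length(rev_idx)
  S <- model$S
  nm <- nrow(S)
  blocks <- list(cbind(as.matrix(S), matrix(0, nm, nr)))
  dirs <- rep("=", nm)
  if (!is.null(model$coupling)) {
    blocks <- c(blocks, list(cbind(as.matrix(model$coupling),
                                   matrix(0, nrow(model$coupling), nr))))
    dirs <- c(dirs, rep("<=", nrow(model$coupling)))
  }
  if (nr) {
    P <- matrix(0, nr, n + nr)          #  v - t <= 0
    M <- matrix(0, nr, n + nr)          # -v - t <= 0
    P[cbind(seq_len(nr), rev_idx)] <- 1
    M[cbind(seq_len(nr), rev_idx)] <- -1
    P[cbind(seq_len(nr), n + seq_len(nr))] <- -1
    M[cbind(seq_len(nr), n + seq_len(nr))] <- -1
    blocks <- c(blocks, list(P, M))
    dirs <- c(dirs, rep("<=", 2 * nr))
  }
  A <- do.call(rbind, blocks)
  jb <- match("communityBiomass", rx$id)
  jt <- match(fe, rx$id)
  b_lo <- lb[jb]
  lb[jb] <- 0
  inst <- lp_instance(A, dirs, rep(0, nrow(A)),
                      lb = c(lb, rep(0, nr)),
                      ub = c(ub, rep(10000, nr)))
  sel <- function(j) as.numeric(seq_len(n + nr) == j)
  fb <- lp_optimize(inst, sel(jb), maximize = TRUE)
  if (fb$status != "optimal" || fb$objective < b_lo - 1e-9)
    stop("community infeasible under its biomass window for ", target)
  lp_set_bound(inst, jb, b_lo, ub[jb])
  top <- lp_optimize(inst, sel(jt), maximize = TRUE)
  if (top$status != "optimal")
    stop("maximization of ", target, " failed: ", top$status)
  lp_set_bound(inst, jt, max(0, top$objective - fix_tol), ub[jt])
  cost <- c(ifelse(lb >= 0, 1, 0), rep(1, nr))
  cost[jb] <- 0                        # the biomass drain is not penalized
  fit <- lp_optimize(inst, cost, maximize = FALSE)
  if (fit$status != "optimal")
    stop("parsimonious refit for ", target, " failed: ", fit$status)
  v <- setNames(fit$x[seq_len(n)], rx$id)

  iex <- rx$type == "iex"
  fluxes <- data.frame(
    taxon = rx$taxon[iex], metabolite = rx$met[iex],
    secretion = pmax(v[iex], 0), uptake = pmax(-v[iex], 0),
    row.names = NULL, stringsAsFactors = FALSE)
  lum_met <- rx$met[rx$type == "diet_transport"]
  lumen <- data.frame(
    metabolite = lum_met,
    diet_in = v[paste0("DUt_", lum_met)],
    fecal_out = v[paste0("UFEt_", lum_met)],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(sample_id = model$sample_id, target = target,
                 objective = top$objective, fluxes = fluxes,
                 lumen = lumen),
            class = "flux_breakdown")
}

#' @export
print.flux_breakdown <- function(x, ...) {
  cat("<flux_breakdown> sample ", x$sample_id, ", target ", x$target,
      ": max fecal secretion ", round(x$objective, 4), " mmol/day\n",
      sep = "")
  act <- x$fluxes[x$fluxes$secretion > 1e-6 | x$fluxes$uptake > 1e-6, ]
  print(utils::head(act[order(-pmax(act$secretion, act$uptake)), ], 10),
        row.names = FALSE)
  invisible(x)
}

#' Detect crossfeeding edges in a flux breakdown
#'
#' A crossfeeding edge exists for a metabolite secreted by one taxon and
#' taken up by a *different* taxon, both at or above the threshold `tau`
#' (default 5 mmol/day, focusing on the largest contributors). Edges are
#' sorted by `min(secretion, uptake)` descending.
#'
#' @param breakdown a `flux_breakdown`.
#' @param tau flux threshold in mmol/day.
#' @return A data.frame with columns `metabolite`, `donor`, `receiver`,
#'   `donor_secretion`, `receiver_uptake`, `tau` (possibly 0 rows).
#' @export
detect_crossfeeding <- function(breakdown, tau = 5) {
  stopifnot(inherits(breakdown, "flux_breakdown"))
  fl <- breakdown$fluxes
  out <- list()
  for (met in unique(fl$metabolite)) {
    sub <- fl[fl$metabolite == met, ]
    donors <- sub[sub$secretion >= tau, ]
    recvs <- sub[sub$uptake >= tau, ]
    if (!nrow(donors) || !nrow(recvs)) next
    for (i in seq_len(nrow(donors))) for (j in seq_len(nrow(recvs))) {
      if (donors$taxon[i] == recvs$taxon[j]) next
      out[[length(out) + 1]] <- data.frame(
        metabolite = met, donor = donors$taxon[i],
        receiver = recvs$taxon[j],
        donor_secretion = donors$secretion[i],
        receiver_uptake = recvs$uptake[j],
        tau = tau, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(metabolite = character(), donor = character(),
                      receiver = character(), donor_secretion = numeric(),
                      receiver_uptake = numeric(), tau = numeric(),
                      stringsAsFactors = FALSE))
  edges <- do.call(rbind, out)
  edges[order(-pmin(edges$donor_secretion, edges$receiver_uptake)), ,
        drop = FALSE]
}

#' Compare flux breakdowns between sample groups
#'
#' For each (taxon, metabolite) pair, computes group means of secretion
#' and uptake and a two-sided rank-sum p-value on the net flux
#' (secretion minus uptake) across the groups' samples. Taxa are ranked
#' by the sum of absolute uptake and secretion rates across groups, and
#' the top `top_k` per metabolite are flagged (the figure convention).
#'
#' @param groups named list (>= 2 entries) of lists of `flux_breakdown`
#'   objects for the same target.
#' @param top_k taxa retained per metabolite in the ranking (default 5).
#' @return A data.frame with per-group mean secretion/uptake columns,
#'   `p_value`, `total_flux` (ranking key), and `top` (logical).
#' @export
compare_breakdowns <- function(groups, top_k = 5) {
  stopifnot(length(groups) >= 2, !is.null(names(groups)))
  empty <- names(groups)[!vapply(groups, length, 1L) > 0]
  if (length(empty))
    stop("group(s) with no breakdowns: ", paste(empty, collapse = ", "))
  long <- list()
  for (g in names(groups)) {
    for (b in groups[[g]]) {
      d <- b$fluxes
      d$group <- g
      d$sample_id <- b$sample_id
      long[[length(long) + 1]] <- d
    }
  }
  long <- do.call(rbind, long)
  long$net <- long$secretion - long$uptake
  key <- interaction(long$taxon, long$metabolite, drop = TRUE)
  rows <- list()
  for (k in levels(key)) {
    sub <- long[key == k, ]
    means <- lapply(names(groups), function(g) {
      s <- sub[sub$group == g, ]
      c(secretion = mean(s$secretion), uptake = mean(s$uptake))
    })
    p <- if (length(groups) == 2) {
      x <- sub$net[sub$group == names(groups)[1]]
      y <- sub$net[sub$group == names(groups)[2]]
      if (length(x) && length(y)) ranksum(x, y) else NA_real_
    } else NA_real_
    row <- data.frame(taxon = sub$taxon[1], metabolite = sub$metabolite[1],
                      stringsAsFactors = FALSE)
    for (i in seq_along(groups)) {
      row[[paste0("secretion_", names(groups)[i])]] <- means[[i]]["secretion"]
      row[[paste0("uptake_", names(groups)[i])]] <- means[[i]]["uptake"]
    }
    row$p_value <- p
    row$total_flux <- sum(vapply(means, function(m) sum(abs(m)), 0))
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$top <- FALSE
  for (met in unique(out$metabolite)) {
    idx <- which(out$metabolite == met)
    keep <- idx[order(-out$total_flux[idx])][seq_len(min(top_k, length(idx)))]
    out$top[keep] <- TRUE
  }
  out[order(out$metabolite, -out$total_flux), ]
}

#' Write a flux breakdown or crossfeeding edges as TSV
#'
#' Breakdowns are written long-format (`sample`, `taxon`, `metabolite`,
#' `secretion`, `uptake`); edge data.frames are written as-is.
#'
#' @param x a `flux_breakdown` or a crossfeeding edge data.frame.
#' @param path file path.
#' @export
write_breakdown <- function(x, path) {
  df <- if (inherits(x, "flux_breakdown"))
    data.frame(sample = x$sample_id, x$fluxes, stringsAsFactors = FALSE)
  else x
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
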