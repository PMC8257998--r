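# Direct generator of synthetic capability (NMPC) matrices with planted
# cluster structure and designed differential metabolites. This is the
# statistical test-bed for the clustering + differential-production layer:
# unlike the LP route, the ground truth (which metabolites differ, and by
# how much) is known exactly.

#' Generate a synthetic NMPC matrix with planted effects
#'
#' Draws per-sample NMPC values around archetype-specific means with
#' multiplicative log-normal noise. Ten metabolites are planted as
#' differential between the first (high-gout) and second (low-gout)
#' archetype with designed effect sizes that pass the screen's magnitude
#' filters (mean > 10 mmol/day in one group, relative difference >= 0.10);
#' the remaining metabolites have identical means (nulls), including two
#' all-zero and one below-floor metabolite that the screen must not flag.
#' The third archetype has a distinct profile (elevated succinate and
#' acetate) so that three clusters are recoverable.
#'
#' @param archetypes list of [community_archetype()] objects (defaults;
#'   only names, sizes and gout probabilities are used).
#' @param n_per_archetype samples per archetype (default 26/44/8).
#' @param sigma log-normal noise scale on the natural-log scale
#'   (default 0.2, i.e. ~20% multiplicative scatter).
#' @param seed integer RNG seed.
#' @return List with `nmpc` (an `nmpc_matrix`), `phenotype`, `archetype`
#'   (ground truth), and `planted` (metabolite ids designed differential
#'   between archetypes 1 and 2).
#' @export
gen_nmpc_matrix <- function(archetypes = default_archetypes(),
                            n_per_archetype = c(26, 44, 8),
                            sigma = 0.2, seed = 1) {
  stopifnot(length(archetypes) == 3,
            length(n_per_archetype) == 3, sigma >= 0)
  #              arch1 (high gout)  arch2 (low gout)  arch3 (prevotella)
  profile <- rbind(
    ala_L  = c(60,  30,  30),
    ala_D  = c(50,  25,  25),
    h2     = c(160, 100, 100),
    ibut   = c(24,  12,  12),
    isoval = c(30,  15,  15),
    but    = c(25,  60,  15),
    lac_L  = c(35,  70,  35),
    cys_L  = c(12,  20,  12),
    met_L  = c(11,  18,  11),
    h2s    = c(12,  25,  12),
    glc    = c(20,  20,  35),
    ac     = c(80,  80, 120),
    succ   = c(40,  40,  90),
    for.   = c(70,  70,  70),
    co2    = c(90,  90,  90),
    nh3    = c(20,  20,  20),
    lac_D  = c(70,  70,  70),
    pyr    = c(75,  75,  75),
    ser_L  = c(28,  28,  28),
    val_L  = c(5,   5,   5),
    so4    = c(0,   0,   0),
    fiber  = c(0,   0,   0))
  rownames(profile)[rownames(profile) == "for."] <- "for"
  planted <- c("ala_L", "ala_D", "h2", "ibut", "isoval",
               "but", "lac_L", "cys_L", "met_L", "h2s")
  old <- .seed_rng(seed)
  on.exit(.restore_rng(old))
  n_tot <- sum(n_per_archetype)
  ids <- sprintf("S%03d", seq_len(n_tot))
  vals <- matrix(0, n_tot, nrow(profile),
                 dimnames = list(ids, rownames(profile)))
  phenotype <- character(n_tot)
  arch <- character(n_tot)
  row <- 0L
  for (k in 1:3) {
    a <- archetypes[[k]]
    for (i in seq_len(n_per_archetype[k])) {
      row <- row + 1L
      mu <- profile[, k]
      noise <- exp(stats::rnorm(length(mu), 0, sigma))
      vals[row, ] <- ifelse(mu > 0, mu * noise, 0)
      phenotype[row] <- if (runif(1) < a$gout_probability) "gouty"
                        else "healthy"
      arch[row] <- a$name
    }
  }
  nm <- structure(
    list(values = vals, diet = "synthetic",
         provenance = list(generator = "gen_nmpc_matrix", sigma = sigma,
                           seed = seed),
         failed = character(0)),
    class = "nmpc_matrix")
  list(nmpc = nm,
       phenotype = setNames(phenotype, ids),
       archetype = setNames(arch, ids),
       planted = planted)
}
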