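# Independent brute-force oracles and shared fixtures. These never call
# the code paths they are used to check.

# Exhaustive vertex enumeration for  min/max c'v  s.t.  S v = 0,
# lb <= v <= ub, with S of full row rank. Every basic solution fixes
# n - nrow(S) variables at a bound and solves for the rest.
enum_lp_extrema <- function(obj, S, lb, ub) {
  n <- ncol(S)
  m <- nrow(S)
  free <- n - m
  lo <- Inf
  hi <- -Inf
  for (cols in utils::combn(n, free, simplify = FALSE)) {
    Bcols <- setdiff(seq_len(n), cols)
    SB <- S[, Bcols, drop = FALSE]
    if (abs(det(SB)) < 1e-10) next
    grid <- expand.grid(rep(list(c(1, 2)), free))
    for (g in seq_len(nrow(grid))) {
      vF <- ifelse(unlist(grid[g, ]) == 1, lb[cols], ub[cols])
      if (any(!is.finite(vF))) next
      rhs <- -S[, cols, drop = FALSE] %*% vF
      vB <- solve(SB, rhs)
      v <- numeric(n)
      v[cols] <- vF
      v[Bcols] <- vB
      if (all(v >= lb - 1e-8) && all(v <= ub + 1e-8)) {
        z <- sum(obj * v)
        lo <- min(lo, z)
        hi <- max(hi, z)
      }
    }
  }
  c(min = lo, max = hi)
}

# Two-sided exact Wilcoxon rank-sum p by full enumeration (tie-free input).
ranksum_oracle <- function(x, y) {
  n <- length(x)
  all_r <- rank(c(x, y))
  W <- sum(all_r[seq_len(n)])
  mu <- n * (length(x) + length(y) + 1) / 2
  combs <- utils::combn(length(x) + length(y), n)
  Ws <- apply(combs, 2, function(ix) sum(all_r[ix]))
  mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  p0 <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# Step-up Benjamini-Hochberg by hand.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Wrap a raw stoichiometric network (no coupling) as a community_model so
# fva()/compute_nmpc() can run on hand-built toy networks. A zero-flux
# dummy community biomass column satisfies the model contract.
raw_community <- function(S, lb, ub, types = NULL, mets = NA) {
  S <- cbind(S, communityBiomass = 0)
  lb <- c(lb, 0); ub <- c(ub, 0)
  n <- ncol(S)
  rxns <- data.frame(
    id = colnames(S), taxon = NA_character_,
    type = c(if (is.null(types)) rep("internal", n - 1) else types,
             "community_biomass"),
    met = c(if (length(mets) == 1 && is.na(mets)) rep(NA_character_, n - 1)
            else mets, NA),
    lb = lb, ub = ub, stringsAsFactors = FALSE)
  structure(
    list(sample_id = "raw", taxa = character(0), abundances = numeric(0),
         diet = structure(list(name = "raw", bounds = numeric(0)),
                          class = "diet_spec"),
         biomass_window = c(0, 0), coupling_factor = NA,
         rxns = rxns, S = Matrix::Matrix(S, sparse = TRUE), coupling = NULL,
         env = new.env(parent = emptyenv())),
    class = "community_model")
}

# A 6-reaction branched toy network used for FVA oracle equivalence:
# A taken from outside, split to B and C, an interconversion B <-> C,
# and two capped exports.
toy_branched_network <- function(exa = -5, exb = 10, exc = 8) {
  S <- matrix(0, 3, 6,
              dimnames = list(c("A", "B", "C"),
                              c("EX_A", "rAB", "rAC", "rBC", "EX_B", "EX_C")))
  S["A", "EX_A"] <- -1
  S["A", "rAB"] <- -1; S["B", "rAB"] <- 1
  S["A", "rAC"] <- -1; S["C", "rAC"] <- 1
  S["B", "rBC"] <- -1; S["C", "rBC"] <- 1
  S["B", "EX_B"] <- -1
  S["C", "EX_C"] <- -1
  list(S = S,
       lb = c(exa, 0, 0, -10, 0, 0),
       ub = c(0, 10, 10, 10, exb, exc))
}

# Two-taxon crossfeeding fixture: an acetate producer (Bacteroides-like)
# beside the acetate-requiring butyrate producer (Faecalibacterium-like),
# and the same community with the producer replaced by a non-producer.
crossfeeding_fixture <- function() {
  specs <- default_taxon_specs()
  pans <- lapply(specs[c("Bacteroides", "Faecalibacterium",
                         "Subdoligranulum")], gen_taxon_model)
  diet <- gen_diet("EUD")
  list(
    with_producer = build_community_model(
      pans, c(Bacteroides = 0.5, Faecalibacterium = 0.5), diet,
      sample_id = "with_producer"),
    without_producer = build_community_model(
      pans, c(Subdoligranulum = 0.5, Faecalibacterium = 0.5), diet,
      sample_id = "without_producer"))
}

# The worked single-taxon lactate community: glucose bound 10, one
# conversion glc -> 2 D-lactate, biomass drain 0.1 glc per unit.
lactate_toy_community <- function(glc_bound = 10,
                                  biomass_window = c(0.4, 1)) {
  toy <- gen_taxon_model(taxon_spec("toy", "homolactic_D", "glc"))
  diet <- structure(list(name = "toy_diet",
                         bounds = c(glc = glc_bound)),
                    class = "diet_spec")
  build_community_model(list(toy = toy), c(toy = 1), diet,
                        biomass_window = biomass_window,
                        sample_id = "toy")
}
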