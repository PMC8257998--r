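# Pan-model merging and community model construction.

# hand-built strain with arbitrary reactions (no balance checking needed
# at this level)
mini_strain <- function(taxon, rxns) {
  structure(list(taxon = taxon, rxns = rxns, biomass = "BIOMASS",
                 exchanges = grep("^EX_", names(rxns), value = TRUE),
                 spec = NULL),
            class = "taxon_model")
}

test_that("pan model takes the reaction union with widest bounds", {
  r <- function(st, lb = 0, ub = 10) list(stoich = st, lb = lb, ub = ub)
  s1 <- mini_strain("t", list(
    r1 = r(c(A = -1, B = 1)), r2 = r(c(B = -1, C = 1), lb = -5),
    EX_A = r(c(A = -1), lb = -10), EX_C = r(c(C = -1)),
    BIOMASS = r(c(C = -0.1, biomass = 1)), EX_biomass = r(c(biomass = -1))))
  s2 <- mini_strain("t", list(
    r2 = r(c(B = -1, C = 1), lb = 0, ub = 20), r3 = r(c(C = -1, D = 1)),
    EX_A = r(c(A = -1), lb = -10), EX_C = r(c(C = -1)),
    BIOMASS = r(c(C = -0.1, biomass = 1)), EX_biomass = r(c(biomass = -1))))
  pan <- build_pan_model(list(s1, s2), "t")
  expect_true(all(c("r1", "r2", "r3") %in% names(pan$rxns)))
  expect_equal(pan$rxns$r2$lb, -5)      # widest bounds
  expect_equal(pan$rxns$r2$ub, 20)
})

test_that("pan model of a single strain is identical to that strain", {
  strain <- gen_taxon_model(default_taxon_specs()$Bacteroides)
  pan <- build_pan_model(list(strain), "Bacteroides")
  attr(pan, "provenance") <- NULL
  expect_identical(pan, strain)
})

test_that("conflicting stoichiometry for a shared reaction id errors", {
  r <- function(st) list(stoich = st, lb = 0, ub = 10)
  s1 <- mini_strain("t", list(r1 = r(c(A = -1, B = 1)),
                              BIOMASS = r(c(A = -0.1, biomass = 1))))
  s2 <- mini_strain("t", list(r1 = r(c(A = -1, B = 2)),
                              BIOMASS = r(c(A = -0.1, biomass = 1))))
  expect_error(build_pan_model(list(s1, s2), "t"),
               "conflicting stoichiometry.*r1")
})

test_that("futile cycle from merging is silenced by the loop pass", {
  r <- function(st, lb = 0, ub = 10) list(stoich = st, lb = lb, ub = ub)
  # two parallel A <-> B reactions, each reversible in its own strain:
  # the union admits a thermodynamically impossible loop
  s1 <- mini_strain("t", list(
    r_f = r(c(A = -1, B = 1), lb = -10),
    EX_A = r(c(A = -1), lb = -10), EX_B = r(c(B = -1)),
    BIOMASS = r(c(B = -0.1, biomass = 1)), EX_biomass = r(c(biomass = -1))))
  s2 <- mini_strain("t", list(
    r_b = r(c(A = -1, B = 1), lb = -10),
    EX_A = r(c(A = -1), lb = -10), EX_B = r(c(B = -1)),
    BIOMASS = r(c(B = -0.1, biomass = 1)), EX_biomass = r(c(biomass = -1))))
  pan <- build_pan_model(list(s1, s2), "t")
  rng <- gutflux:::.closed_exchange_ranges(pan, c("r_f", "r_b"))
  expect_true(all(abs(rng) < 1e-6))     # no flux with exchanges closed
  expect_true(length(attr(pan, "provenance")) >= 1)
  expect_match(attr(pan, "provenance")[1], "futile-cycle")
  # the merged model still interconverts A and B when fed
  fb <- taxon_fba(pan, c(A = 5), objective = "EX_B")
  expect_gt(fb$objective, 4.9)
})

test_that("worked single-taxon community reproduces the hand LP", {
  cm <- lactate_toy_community()
  # biomass at its window floor 0.4 consumes 0.04 glc; the rest of the
  # 10 glc/day makes 2 lactate each: 2 * (10 - 0.1*0.4) = 19.92
  r <- fva(cm, "EX_lac_D_fe")
  expect_equal(r$max, 19.92, tolerance = 1e-6)
  expect_equal(compute_nmpc(cm, "lac_D"), 19.92, tolerance = 1e-6)
})

test_that("two identical taxa at half abundance behave like one", {
  toy <- gen_taxon_model(taxon_spec("toy", "homolactic_D", "glc"))
  diet <- structure(list(name = "d", bounds = c(glc = 10)),
                    class = "diet_spec")
  cm <- build_community_model(list(a = toy, b = toy), c(a = 0.5, b = 0.5),
                              diet)
  expect_equal(compute_nmpc(cm, "lac_D"), 19.92, tolerance = 1e-6)
})

test_that("zero-abundance taxa are omitted from the community", {
  toy <- gen_taxon_model(taxon_spec("toy", "homolactic_D", "glc"))
  diet <- structure(list(name = "d", bounds = c(glc = 10)),
                    class = "diet_spec")
  cm <- build_community_model(list(a = toy, b = toy), c(a = 1, b = 0), diet)
  expect_equal(cm$taxa, "a")
  expect_false(any(grepl("__b$", cm$rxns$id)))
})

test_that("a starved community cannot meet the biomass window", {
  toy <- gen_taxon_model(taxon_spec("toy", "homolactic_D", "glc"))
  diet <- structure(list(name = "starve", bounds = c(glc = 0)),
                    class = "diet_spec")
  expect_error(build_community_model(list(toy = toy), c(toy = 1), diet),
               "infeasible")
})

test_that("elemental mass balances across diet, feces and biomass", {
  cm <- lactate_toy_community()
  inst <- community_lp(cm)
  r <- lp_optimize(inst, as.numeric(cm$rxns$id == "EX_lac_D_fe"),
                   maximize = TRUE)
  v <- setNames(r$x, cm$rxns$id)
  uni <- metabolite_universe()
  comp <- parse_formula(uni$formula)
  names(comp) <- uni$id
  bio <- sum(v[grep("^BIOMASS__", names(v))]) * 0.1   # glc per biomass unit
  for (el in c("C", "H", "O")) {
    inflow <- outflow <- 0
    for (i in which(cm$rxns$type == "exchange_diet")) {
      f <- comp[[cm$rxns$met[i]]]
      if (el %in% names(f)) inflow <- inflow - unname(v[i]) * f[[el]]
    }
    for (i in which(cm$rxns$type == "exchange_fecal")) {
      f <- comp[[cm$rxns$met[i]]]
      if (el %in% names(f)) outflow <- outflow + unname(v[i]) * f[[el]]
    }
    biomass_el <- bio * comp[["glc"]][[el]]
    expect_equal(inflow, outflow + biomass_el, tolerance = 1e-6,
                 label = paste("element", el))
  }
})

test_that("enlarging a diet bound never shrinks maximal secretion", {
  toy <- gen_taxon_model(taxon_spec("toy", "homolactic_D", "glc"))
  prev <- -Inf
  for (g in c(2, 5, 10, 20)) {
    diet <- structure(list(name = "d", bounds = c(glc = g)),
                      class = "diet_spec")
    cm <- build_community_model(list(toy = toy), c(toy = 1), diet)
    cur <- compute_nmpc(cm, "lac_D")
    expect_gte(cur, prev - 1e-9)
    prev <- cur
  }
})

test_that("coupling constraints only restrict the feasible region", {
  specs <- default_taxon_specs()
  pans <- lapply(specs[c("Bacteroides", "Faecalibacterium")],
                 gen_taxon_model)
  ab <- c(Bacteroides = 0.7, Faecalibacterium = 0.3)
  diet <- gen_diet("EUD")
  with_c <- build_community_model(pans, ab, diet, coupling = TRUE)
  no_c <- build_community_model(pans, ab, diet, coupling = FALSE)
  for (met in c("but", "ac", "h2s"))
    expect_gte(compute_nmpc(no_c, met) - compute_nmpc(with_c, met), -1e-6)
})
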