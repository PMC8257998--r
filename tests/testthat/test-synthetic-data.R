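# Generators: taxon models, strain variants, abundance tables, diets.

test_that("every reaction template is elementally balanced", {
  all_caps <- names(capability_registry())
  spec <- taxon_spec("omnibus", all_caps,
                     c("fiber", "glc", "cys_L", "ser_L", "so4", "nh3",
                       "val_L", "leu_L", "ala_L", "ala_D", "ac", "h2",
                       "lac_D", "lac_L"))
  expect_silent(m <- gen_taxon_model(spec))
  expect_true(check_balance(m))
})

test_that("an unbalanced reaction is reported with reaction and element", {
  m <- gen_taxon_model(taxon_spec("toy", "homolactic_D", "glc"))
  m$rxns$HEX_LACD$stoich["lac_D"] <- 3        # break the carbon balance
  expect_error(check_balance(m), "HEX_LACD.*element C")
})

test_that("minimal single-capability spec yields the minimal model", {
  m <- gen_taxon_model(taxon_spec("toy", "homolactic_D", "glc"))
  internal <- setdiff(names(m$rxns), c(m$exchanges, m$biomass))
  expect_equal(internal, "HEX_LACD")          # one internal conversion
  expect_true(all(c("EX_glc", "EX_lac_D") %in% m$exchanges))
  expect_equal(m$biomass, "BIOMASS")
  # uptake allowed only for the preference
  expect_lt(m$rxns$EX_glc$lb, 0)
  expect_equal(m$rxns$EX_lac_D$lb, 0)
})

test_that("the Bacteroides-like model has the designed secretion profile", {
  mb <- gen_taxon_model(default_taxon_specs()$Bacteroides)
  diet <- c(fiber = 10, glc = 10, cys_L = 10, nh3 = 10)
  for (met in c("ac", "succ", "lac_D", "for", "h2", "h2s"))
    expect_gt(taxon_fba(mb, diet, objective = paste0("EX_", met))$objective,
              1, label = paste("secretion of", met))
  expect_false(any(c("HEX_BUT", "BUT_AC") %in% names(mb$rxns)))
})

test_that("Faecalibacterium-like butyrate requires external acetate", {
  mf <- gen_taxon_model(default_taxon_specs()$Faecalibacterium)
  closed <- taxon_fba(mf, c(glc = 10), objective = "EX_but")
  open <- taxon_fba(mf, c(glc = 10, ac = 10), objective = "EX_but")
  expect_equal(closed$objective, 0, tolerance = 1e-9)
  expect_gt(open$objective, 1)
})

test_that("all roster taxa grow under their preferred diets", {
  for (spec in default_taxon_specs()) {
    m <- gen_taxon_model(spec)
    diet <- setNames(rep(10, length(spec$uptake_preferences)),
                     spec$uptake_preferences)
    fb <- taxon_fba(m, diet)
    expect_equal(fb$status, "optimal", label = spec$name)
    expect_gt(fb$objective, 1e-6, label = paste(spec$name, "biomass"))
  }
})

test_that("strain variants: identity, reproducibility, feasibility, union", {
  mb <- gen_taxon_model(default_taxon_specs()$Bacteroides)
  # n = 1, deletion 0 -> identical to parent (modulo the name)
  v0 <- gen_strain_variants(mb, 1, 0, seed = 1)[[1]]
  expect_identical(v0$rxns, mb$rxns)
  # fixed seed -> identical reaction subsets on rerun
  v1 <- gen_strain_variants(mb, 3, 0.2, seed = 7)
  v2 <- gen_strain_variants(mb, 3, 0.2, seed = 7)
  expect_identical(lapply(v1, function(x) names(x$rxns)),
                   lapply(v2, function(x) names(x$rxns)))
  # every variant retains biomass feasibility
  pref <- setNames(rep(10, length(mb$spec$uptake_preferences)),
                   mb$spec$uptake_preferences)
  for (v in gen_strain_variants(mb, 5, 0.25, seed = 3))
    expect_gt(taxon_fba(v, pref)$objective, 1e-6)
  # with enough variants the union of reactions recovers the parent
  many <- gen_strain_variants(mb, 12, 0.15, seed = 11)
  expect_setequal(unique(unlist(lapply(many, function(x) names(x$rxns)))),
                  names(mb$rxns))
})

test_that("abundance generator: determinism, counts, degenerate Dirichlet", {
  t1 <- gen_abundance_table(seed = 5)
  t2 <- gen_abundance_table(seed = 5)
  expect_identical(t1, t2)
  expect_equal(nrow(t1$reads), 78)            # 26 + 44 + 8
  expect_equal(unname(table(t1$archetype)[unique(t1$archetype)]),
               c(26L, 44L, 8L), ignore_attr = TRUE)
  expect_true(all(t1$phenotype %in% c("gouty", "healthy")))
  expect_true(all(t1$modeled_fraction >= 0.94 & t1$modeled_fraction <= 1))
  # concentration -> infinity: compositions collapse onto the means
  tight <- default_archetypes(concentration = 1e7)[1]
  t3 <- gen_abundance_table(tight, 5, c(1, 1), seed = 1)
  fr <- t3$reads / rowSums(t3$reads)
  expect_equal(colMeans(fr), tight[[1]]$mean_abundances, tolerance = 5e-3)
  expect_error(gen_abundance_table(list(), integer(0)), "empty archetype")
})

test_that("abundance preprocessing: split, bins, filter, normalization", {
  reads <- matrix(c(10, 4, 2, 3, 5,
                    20, 8, 2, 3, 5), 2, byrow = TRUE,
                  dimnames = list(c("s1", "s2"),
                                  c("Escherichia/Shigella", "Bacteroides",
                                    "Lachnobacterium", "Faecalibacterium",
                                    "Lachnospiraceae_unclassified")))
  tab <- structure(list(
    reads = reads,
    phenotype = c(s1 = "gouty", s2 = "healthy"),
    modeled_fraction = c(s1 = 0.89, s2 = 0.90),
    archetype = NULL), class = "abundance_table")
  prep <- prepare_abundances(
    tab,
    modeled_taxa = c("Escherichia", "Shigella", "Bacteroides",
                     "Faecalibacterium", "Lachnospiraceae_unclassified"),
    family_bins = list(Lachnospiraceae_unclassified = "Lachnobacterium"))
  # 0.89 dropped, 0.90 retained (inclusive threshold)
  expect_equal(rownames(prep$reads), "s2")
  expect_equal(attr(prep, "n_dropped"), 1)
  # combined reads split equally
  expect_equal(unname(prep$reads["s2", c("Escherichia", "Shigella")]),
               c(10, 10))
  # family bin absorbed the unmodelable genus
  expect_equal(unname(prep$reads["s2", "Lachnospiraceae_unclassified"]),
               5 + 2)
  expect_equal(unname(rowSums(prep$fractions)), 1, tolerance = 1e-9)
  expect_error(prepare_abundances(tab, min_modeled_fraction = 0.99),
               "below the modeled-fraction filter")
})

test_that("plain normalization matches hand arithmetic", {
  tab <- structure(list(
    reads = matrix(c(2, 3, 5), 1,
                   dimnames = list("s1", c("A", "B", "C"))),
    phenotype = c(s1 = "gouty"),
    modeled_fraction = c(s1 = 1),
    archetype = NULL), class = "abundance_table")
  prep <- prepare_abundances(tab)
  expect_equal(unname(prep$fractions["s1", ]), c(0.2, 0.3, 0.5))
})

test_that("diet presets: schema, cysteine ratio, scaling", {
  eud <- gen_diet("EUD")
  expect_true(all(is.finite(eud$bounds)) && all(eud$bounds > 0))
  hfd <- gen_diet("HFD")
  expect_equal(hfd$bounds[["cys_L"]] / eud$bounds[["cys_L"]], 1.84)
  expect_gt(hfd$bounds[["fiber"]], eud$bounds[["fiber"]])
  hpd <- gen_diet("HPD")
  expect_equal(hpd$bounds[["val_L"]] / eud$bounds[["val_L"]], 2.5)
  expect_true(all(gen_diet("EUD", scale = 0)$bounds == 0))
  expect_error(gen_diet("FODMAP"))
})

test_that("synthetic NMPC matrix is deterministic with planted structure", {
  g1 <- gen_nmpc_matrix(seed = 3)
  g2 <- gen_nmpc_matrix(seed = 3)
  expect_identical(g1, g2)
  X <- g1$nmpc$values
  expect_equal(dim(X), c(78, 22))
  expect_true(all(X >= 0))
  i1 <- g1$archetype == "bacteroides_dominated"
  i2 <- g1$archetype == "faecalibacterium_elevated"
  expect_gt(mean(X[i1, "ala_L"]), mean(X[i2, "ala_L"]))
  expect_gt(mean(X[i2, "but"]), mean(X[i1, "but"]))
})
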