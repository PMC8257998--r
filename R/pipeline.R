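# End-to-end synthetic study: generate a cohort, build per-sample
# community models, compute the NMPC capability matrix, cluster, and
# screen for differential production.

#' Run the full community modeling pipeline on a synthetic cohort
#'
#' Generates taxon models (optionally via strain variants merged into pan
#' models), a synthetic abundance table with phenotype labels, builds one
#' community model per retained sample under the chosen diet, computes
#' the NMPC matrix by flux variability analysis, clusters samples by
#' capability (k-means++), tests cluster-phenotype association, and runs
#' the differential-production screen between the high- and low-gout
#' clusters.
#'
#' Every random step derives from `seed`; a rerun with the same arguments
#' reproduces all outputs bit-identically.
#'
#' @param seed integer master seed.
#' @param diet a `diet_spec` (default the EU-average preset).
#' @param archetypes,n_per_archetype cohort design (defaults 26/44/8
#'   samples from the three archetypes).
#' @param modeled_fraction_range per-sample modeled-fraction interval.
#' @param n_strains strain variants per taxon merged into each pan model
#'   (1 skips variant generation and uses the parent model).
#' @param deletion_fraction reaction-deletion fraction for the variants.
#' @param k number of capability clusters (default 3).
#' @param kmeans_replicates k-means++ replicates (default 1000).
#' @param min_cluster_size smallest cluster eligible as the high/low gout
#'   cluster (default 10; lower it for reduced cohorts).
#' @param metabolites NMPC metabolite set (default: all exchangeable).
#' @param out_dir if non-NULL, TSV outputs (abundances, NMPC matrix,
#'   cluster assignments, differential screen) are written here.
#' @return List with `abundances`, `pan_models`, `models`, `nmpc`,
#'   `clusters`, `gout_clusters`, `associations`, `differential`.
#' @export
run_pipeline <- function(seed = 1,
                         diet = gen_diet("EUD"),
                         archetypes = default_archetypes(),
                         n_per_archetype = c(26, 44, 8),
                         modeled_fraction_range = c(0.94, 1),
                         n_strains = 1,
                         deletion_fraction = 0.15,
                         k = 3,
                         kmeans_replicates = 1000,
                         min_cluster_size = 10,
                         metabolites = NULL,
                         out_dir = NULL) {
  specs <- default_taxon_specs()
  pan_models <- list()
  for (t in names(specs)) {
    parent <- gen_taxon_model(specs[[t]])
    pan_models[[t]] <- if (n_strains > 1) {
      strains <- gen_strain_variants(parent, n_strains, deletion_fraction,
                                     seed = seed + match(t, names(specs)))
      build_pan_model(strains, t)
    } else parent
  }

  tab <- gen_abundance_table(archetypes, n_per_archetype,
                             modeled_fraction_range, seed = seed)
  prep <- prepare_abundances(tab, modeled_taxa = names(pan_models))

  models <- vector("list", nrow(prep$fractions))
  names(models) <- rownames(prep$fractions)
  for (s in rownames(prep$fractions))
    models[[s]] <- build_community_model(
      pan_models, prep$fractions[s, ], diet, sample_id = s)

  nmpc <- compute_nmpc_matrix(models, metabolites = metabolites)

  clusters <- kmeans_cluster(nmpc$values, k = k,
                             replicates = kmeans_replicates,
                             seed = seed, phenotype = prep$phenotype)
  gout <- select_gout_clusters(clusters, min_size = min_cluster_size)
  assoc <- list(
    high_vs_low = cluster_phenotype_association(clusters, gout$high,
                                                reference = gout$low),
    high_vs_all = cluster_phenotype_association(clusters, gout$high,
                                                reference = "all"))
  grp <- ifelse(clusters$assignments == gout$high, "high",
                ifelse(clusters$assignments == gout$low, "low", NA))
  keep <- !is.na(grp)
  diff <- differential_metabolites(
    nmpc$values[keep, , drop = FALSE],
    setNames(grp[keep], names(clusters$assignments)[keep]))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_abundance_table(prep, file.path(out_dir, "abundances.tsv"))
    write_nmpc_matrix(nmpc, file.path(out_dir, "nmpc.tsv"))
    write.table(
      data.frame(sample_id = names(clusters$assignments),
                 cluster = clusters$assignments,
                 phenotype = prep$phenotype[names(clusters$assignments)]),
      file.path(out_dir, "clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(diff), file.path(out_dir, "differential.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(abundances = prep, pan_models = pan_models, models = models,
       nmpc = nmpc, clusters = clusters, gout_clusters = gout,
       associations = assoc, differential = diff)
}
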