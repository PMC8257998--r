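# Synthetic 16S-style abundance tables: community archetypes, Dirichlet-
# multinomial read sampling, phenotype labels, and the preprocessing that
# turns raw reads into normalized modeled-taxon abundances.

#' Define a community archetype
#'
#' An archetype is a compositional template for one sample cluster:
#' expected taxon fractions, a Dirichlet concentration controlling how
#' tightly samples scatter around them, and the probability that a sample
#' from this archetype carries the gouty phenotype.
#'
#' @param name archetype label.
#' @param mean_abundances named numeric vector of expected taxon fractions
#'   (must sum to 1).
#' @param concentration positive Dirichlet concentration scalar; larger is
#'   tighter around the mean.
#' @param gout_probability probability in `[0, 1]` that a sample is
#'   labeled `"gouty"`.
#' @return A `community_archetype` object.
#' @export
community_archetype <- function(name, mean_abundances, concentration,
                                gout_probability) {
  stopifnot(abs(sum(mean_abundances) - 1) < 1e-6,
            concentration > 0,
            gout_probability >= 0, gout_probability <= 1)
  structure(list(name = name, mean_abundances = mean_abundances,
                 concentration = concentration,
                 gout_probability = gout_probability),
            class = "community_archetype")
}

#' Default archetypes of the synthetic study
#'
#' Three archetypes emulating the observed capability clusters: a
#' *Bacteroides*-dominated, predominantly gouty group (mean *Bacteroides*
#' fraction 0.75, gout probability 22/26); a *Faecalibacterium*-elevated,
#' predominantly healthy group (*Faecalibacterium* 0.15, gout probability
#' 11/44); and a small *Prevotella*-elevated group (*Prevotella* 0.45,
#' gout probability 6/8).
#'
#' @param concentration Dirichlet concentration (default 150: moderate
#'   within-cluster compositional scatter, small enough that capability
#'   differences between archetypes dominate it, emulating the robust
#'   sample clustering observed for real communities).
#' @return Named list of three [community_archetype()] objects.
#' @export
default_archetypes <- function(concentration = 150) {
  list(
    bacteroides_dominated = community_archetype(
      "bacteroides_dominated",
      c(Bacteroides = 0.75, Faecalibacterium = 0.03, Prevotella = 0.01,
        Roseburia = 0.02, Coprococcus = 0.01, Subdoligranulum = 0.01,
        Lachnospiraceae_unclassified = 0.03, Escherichia = 0.08,
        Shigella = 0.04, Desulfovibrio = 0.02),
      concentration, 22 / 26),
    faecalibacterium_elevated = community_archetype(
      "faecalibacterium_elevated",
      c(Bacteroides = 0.30, Faecalibacterium = 0.15, Prevotella = 0.05,
        Roseburia = 0.10, Coprococcus = 0.06, Subdoligranulum = 0.06,
        Lachnospiraceae_unclassified = 0.13, Escherichia = 0.04,
        Shigella = 0.02, Desulfovibrio = 0.09),
      concentration, 11 / 44),
    prevotella_elevated = community_archetype(
      "prevotella_elevated",
      c(Bacteroides = 0.20, Faecalibacterium = 0.06, Prevotella = 0.45,
        Roseburia = 0.04, Coprococcus = 0.03, Subdoligranulum = 0.02,
        Lachnospiraceae_unclassified = 0.08, Escherichia = 0.06,
        Shigella = 0.03, Desulfovibrio = 0.03),
      concentration, 6 / 8))
}

#' Generate a synthetic abundance table
#'
#' Samples taxon read counts per archetype from a Dirichlet-multinomial
#' model, draws a phenotype label per sample from the archetype's gout
#' probability, and a modeled fraction (the share of total reads covered
#' by modeled taxa) uniformly from `modeled_fraction_range`. The default
#' sizes 26/44/8 mirror the study's three capability clusters.
#'
#' @param archetypes list of [community_archetype()] objects.
#' @param n_per_archetype integer vector, samples per archetype.
#' @param modeled_fraction_range length-2 interval within `[0, 1]`.
#' @param seed integer RNG seed.
#' @param total_reads expected 16S read depth per sample.
#' @return An `abundance_table`: list with `reads` (samples x taxa integer
#'   matrix), `phenotype`, `modeled_fraction`, and `archetype` (the
#'   ground-truth generating archetype per sample).
#' @export
gen_abundance_table <- function(archetypes = default_archetypes(),
                                n_per_archetype = c(26, 44, 8),
                                modeled_fraction_range = c(0.94, 1),
                                seed = 1, total_reads = 50000) {
  if (length(archetypes) == 0) stop("empty archetype list")
  stopifnot(length(archetypes) == length(n_per_archetype),
            all(modeled_fraction_range >= 0),
            all(modeled_fraction_range <= 1))
  taxa <- names(archetypes[[1]]$mean_abundances)
  old <- .seed_rng(seed)
  on.exit(.restore_rng(old))
  n_tot <- sum(n_per_archetype)
  reads <- matrix(0L, n_tot, length(taxa),
                  dimnames = list(sprintf("S%03d", seq_len(n_tot)), taxa))
  phenotype <- character(n_tot)
  arch <- character(n_tot)
  row <- 0L
  for (k in seq_along(archetypes)) {
    a <- archetypes[[k]]
    stopifnot(identical(names(a$mean_abundances), taxa))
    for (i in seq_len(n_per_archetype[k])) {
      row <- row + 1L
      g <- rgamma(length(taxa), shape = a$concentration * a$mean_abundances)
      if (sum(g) <= 0) g <- a$mean_abundances
      p <- g / sum(g)
      reads[row, ] <- as.integer(rmultinom(1, total_reads, p))
      phenotype[row] <- if (runif(1) < a$gout_probability) "gouty" else "healthy"
      arch[row] <- a$name
    }
  }
  mf <- runif(n_tot, modeled_fraction_range[1], modeled_fraction_range[2])
  structure(list(
    reads = reads,
    phenotype = setNames(phenotype, rownames(reads)),
    modeled_fraction = setNames(mf, rownames(reads)),
    archetype = setNames(arch, rownames(reads))),
    class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> ", nrow(x$reads), " samples x ", ncol(x$reads),
      " taxa (", sum(x$phenotype == "gouty"), " gouty / ",
      sum(x$phenotype == "healthy"), " healthy)\n", sep = "")
  invisible(x)
}

#' Prepare abundances for community modeling
#'
#' Applies the preprocessing used before model construction: combined
#' `Escherichia/Shigella` read columns are split equally between the two
#' genera; reads of unmodelable genera are absorbed into configured family
#' bins; samples whose modeled fraction is below `min_modeled_fraction`
#' are dropped; and the remaining rows are renormalized over the modeled
#' taxa to sum to one.
#'
#' @param table an `abundance_table`.
#' @param modeled_taxa character vector of taxa with pan models (defaults
#'   to all columns after splitting).
#' @param family_bins named list mapping a family-bin column to the
#'   unmodelable genus columns it absorbs, e.g.
#'   `list(Lachnospiraceae_unclassified = c("Lachnobacterium"))`.
#' @param min_modeled_fraction retention threshold on the per-sample
#'   modeled fraction (default 0.9; samples at exactly the threshold are
#'   retained).
#' @return An `abundance_table` with an added `fractions` matrix (rows sum
#'   to 1 over `modeled_taxa`), subset to retained samples. Attributes
#'   `n_dropped` and `coverage_mean` record the filter outcome.
#' @export
prepare_abundances <- function(table, modeled_taxa = NULL,
                               family_bins = NULL,
                               min_modeled_fraction = 0.9) {
  stopifnot(inherits(table, "abundance_table"))
  reads <- table$reads
  comb <- grep("/", colnames(reads), value = TRUE)
  for (cc in comb) {
    parts <- strsplit(cc, "/", fixed = TRUE)[[1]]
    half <- reads[, cc] / 2
    for (p in parts)
      reads <- cbind(reads, setNames(data.frame(half), p))[, , drop = FALSE]
    reads <- as.matrix(as.data.frame(reads))
    colnames(reads)[(ncol(reads) - length(parts) + 1):ncol(reads)] <- parts
    reads <- reads[, colnames(reads) != cc, drop = FALSE]
  }
  for (bin in names(family_bins)) {
    src <- intersect(family_bins[[bin]], colnames(reads))
    if (!length(src)) next
    if (!bin %in% colnames(reads)) {
      reads <- cbind(reads, 0)
      colnames(reads)[ncol(reads)] <- bin
    }
    reads[, bin] <- reads[, bin] + rowSums(reads[, src, drop = FALSE])
    reads <- reads[, !colnames(reads) %in% src, drop = FALSE]
  }
  if (is.null(modeled_taxa)) modeled_taxa <- colnames(reads)
  missing <- setdiff(modeled_taxa, colnames(reads))
  if (length(missing))
    stop("modeled taxa absent from table: ", paste(missing, collapse = ", "))
  keep <- table$modeled_fraction >= min_modeled_fraction
  if (!any(keep)) stop("all samples fall below the modeled-fraction filter")
  reads <- reads[keep, modeled_taxa, drop = FALSE]
  fr <- reads / rowSums(reads)
  out <- table
  out$reads <- reads
  out$fractions <- fr
  out$phenotype <- table$phenotype[keep]
  out$modeled_fraction <- table$modeled_fraction[keep]
  out$archetype <- table$archetype[keep]
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "coverage_mean") <- mean(table$modeled_fraction)
  out
}

#' Write / read an abundance table as TSV
#'
#' First column `sample_id`, one column per taxon (raw reads), then
#' `phenotype` and `modeled_fraction` (and `archetype` when ground truth
#' is recorded).
#'
#' @param table an `abundance_table`.
#' @param path file path.
#' @export
write_abundance_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table$reads), table$reads,
                   phenotype = table$phenotype,
                   modeled_fraction = table$modeled_fraction,
                   check.names = FALSE)
  if (!is.null(table$archetype)) df$archetype <- table$archetype
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_table
#' @export
read_abundance_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- intersect(c("phenotype", "modeled_fraction", "archetype"),
                    names(df))
  taxa <- setdiff(names(df), c("sample_id", meta))
  reads <- as.matrix(df[, taxa, drop = FALSE])
  rownames(reads) <- df$sample_id
  structure(list(
    reads = reads,
    phenotype = setNames(df$phenotype, df$sample_id),
    modeled_fraction = setNames(df$modeled_fraction, df$sample_id),
    archetype = if ("archetype" %in% meta)
      setNames(df$archetype, df$sample_id) else NULL),
    class = "abundance_table")
}
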