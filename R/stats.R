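# Statistical layer: capability-matrix clustering, cluster-phenotype
# association, differential-production screening, and multi-diet
# comparison.

#' k-means clustering with k-means++ initialization and replicates
#'
#' Runs `replicates` k-means fits (squared Euclidean distance, Lloyd
#' iterations via [stats::kmeans()]) from independent k-means++ seedings
#' and keeps the solution with the lowest total within-cluster sum of
#' squares. Cluster ids are relabeled by descending cluster size so
#' results are reproducible despite the arbitrariness of k-means labels.
#'
#' @param X numeric matrix, samples in rows; no missing values.
#' @param k number of clusters (>= 2).
#' @param replicates number of replicate runs (default 1000).
#' @param seed integer RNG seed.
#' @param phenotype optional named phenotype vector (`"gouty"`/
#'   `"healthy"`) used to fill the per-cluster contingency counts.
#' @return A `cluster_result`: list with `assignments` (named integer),
#'   `k`, `centroids`, `tot_withinss`, and `phenotype_counts` (k x 2
#'   matrix) when phenotypes are supplied.
#' @export
kmeans_cluster <- function(X, k, replicates = 1000, seed = 1,
                           phenotype = NULL) {
  X <- as.matrix(X)
  stopifnot(k >= 2, replicates >= 1, !anyNA(X))
  if (k > nrow(X)) stop("k exceeds the number of samples")
  old <- .seed_rng(seed)
  on.exit(.restore_rng(old))
  best <- NULL
  for (r in seq_len(replicates)) {
    centers <- .kmeanspp_init(X, k)
    fit <- suppressWarnings(
      stats::kmeans(X, centers = centers, iter.max = 100,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss - 1e-12)
      best <- fit
  }
  # relabel by descending cluster size (ties: by first occurrence)
  sizes <- tabulate(best$cluster, k)
  ord <- order(-sizes, seq_len(k))
  relab <- match(seq_len(k), ord)
  assignments <- setNames(relab[best$cluster], rownames(X))
  centroids <- best$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  counts <- NULL
  if (!is.null(phenotype)) {
    phenotype <- phenotype[names(assignments)]
    counts <- t(vapply(seq_len(k), function(cl)
      c(gouty = sum(phenotype[assignments == cl] == "gouty"),
        healthy = sum(phenotype[assignments == cl] == "healthy")),
      c(gouty = 0, healthy = 0)))
  }
  structure(list(assignments = assignments, k = k, centroids = centroids,
                 tot_withinss = best$tot.withinss,
                 phenotype_counts = counts),
            class = "cluster_result")
}

# k-means++ seeding: first center uniform, then D^2-weighted.
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- X[sample.int(n, 1, prob = probs), ]
    dj <- rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  # ensure distinct centers (duplicate rows would crash kmeans)
  if (anyDuplicated(centers))
    centers <- centers + matrix(stats::rnorm(length(centers), 0, 1e-8),
                                k, ncol(X))
  centers
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> k = ", x$k, ", sizes ",
      paste(tabulate(x$assignments, x$k), collapse = "/"),
      ", total within-SS ", signif(x$tot_withinss, 6), "\n", sep = "")
  if (!is.null(x$phenotype_counts)) {
    cat("  phenotype counts per cluster:\n")
    print(x$phenotype_counts)
  }
  invisible(x)
}

#' Select the number of clusters by the silhouette criterion
#'
#' For each candidate k, clusters with [kmeans_cluster()] and scores the
#' partition by the mean silhouette width computed with the L1
#' (sum-of-absolute-differences) distance. Returns the k with the highest
#' mean silhouette; ties go to the smallest k.
#'
#' @param X numeric matrix, samples in rows.
#' @param k_range integer vector of candidate k (within `[2, n-1]`).
#' @param replicates k-means replicates per candidate (default 100).
#' @param seed integer RNG seed.
#' @return The selected k (integer), with the per-k mean silhouettes as
#'   attribute `silhouette`.
#' @export
select_k <- function(X, k_range = 2:6, replicates = 100, seed = 1) {
  X <- as.matrix(X)
  stopifnot(all(k_range >= 2), all(k_range <= nrow(X) - 1))
  if (all(apply(X, 2, function(col) diff(range(col)) == 0)))
    stop("degenerate matrix: all rows identical")
  D <- stats::dist(X, method = "manhattan")
  sil <- vapply(k_range, function(k) {
    cl <- kmeans_cluster(X, k, replicates = replicates, seed = seed)
    mean(cluster::silhouette(cl$assignments, D)[, "sil_width"])
  }, 0)
  k <- k_range[which.max(sil)]   # which.max takes the first (smallest) tie
  structure(as.integer(k), silhouette = setNames(sil, k_range))
}

#' Principal component projection
#'
#' Column-centered PCA (no scaling), as applied directly to normalized
#' abundances and NMPC matrices for visualization.
#'
#' @param X numeric matrix, samples in rows.
#' @param n_components number of components to return.
#' @return List with `scores` (samples x components), `loadings`, and
#'   `explained` (variance fractions, non-increasing, summing to <= 1).
#' @export
pca_project <- function(X, n_components = 2) {
  X <- as.matrix(X)
  if (all(abs(sweep(X, 2, colMeans(X))) < 1e-12))
    stop("constant matrix: no variance to decompose")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(p$x))
  ev <- p$sdev^2
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       loadings = p$rotation[, seq_len(n_components), drop = FALSE],
       explained = (ev / sum(ev))[seq_len(n_components)])
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided exact test: the p-value sums hypergeometric probabilities of
#' all tables with the observed margins whose point probability does not
#' exceed the observed table's. A table with a zero margin returns p = 1
#' with a `degenerate` flag.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return An `association_result`: list with `table`, `odds_ratio`
#'   (conditional MLE), `p_value`, `degenerate`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(abs(table - round(table)) < 1e-9))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(structure(list(table = table, odds_ratio = NA_real_,
                          p_value = 1, degenerate = TRUE),
                     class = "association_result"))
  ft <- stats::fisher.test(table)
  structure(list(table = table, odds_ratio = unname(ft$estimate),
                 p_value = ft$p.value, degenerate = FALSE),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("<association_result> odds ratio ", signif(x$odds_ratio, 4),
      ", two-sided Fisher p = ", signif(x$p_value, 4),
      if (x$degenerate) " (degenerate table)", "\n", sep = "")
  invisible(x)
}

#' Cluster-phenotype association
#'
#' Tests whether one cluster is enriched for a phenotype relative to a
#' reference group, via Fisher's exact test on the 2x2 table of
#' phenotype counts. The reference is either another cluster, or the
#' entire sample set (the cluster's own samples included, `reference =
#' "all"`), or the complement of the cluster (`reference =
#' "complement"`).
#'
#' @param clusters a `cluster_result` with phenotype counts.
#' @param cluster cluster id whose enrichment is tested.
#' @param reference a cluster id, `"all"`, or `"complement"`.
#' @param phenotype which phenotype the first table column counts
#'   (default `"gouty"`).
#' @return An `association_result` (see [fisher_exact_2x2()]).
#' @export
cluster_phenotype_association <- function(clusters, cluster,
                                          reference = "all",
                                          phenotype = c("gouty", "healthy")) {
  stopifnot(inherits(clusters, "cluster_result"),
            !is.null(clusters$phenotype_counts))
  phenotype <- match.arg(phenotype)
  cnt <- clusters$phenotype_counts
  if (phenotype == "healthy") cnt <- cnt[, c("healthy", "gouty")]
  top <- cnt[cluster, ]
  bot <- if (identical(reference, "all")) colSums(cnt)
         else if (identical(reference, "complement")) colSums(cnt) - top
         else cnt[reference, ]
  fisher_exact_2x2(rbind(top, bot))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when both samples are small (`min(n) <= 10`) and
#' tie-free; otherwise the normal approximation with tie and continuity
#' corrections. Identical constant samples give p = 1.
#'
#' @param x,y numeric vectors (non-empty).
#' @return Two-sided p-value.
#' @export
ranksum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1) return(1)
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 10 && !has_ties
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH q-values: monotone in the p-value ranks and capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs preserved).
#' @return Vector of q-values, `q >= p` elementwise.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Proportionality coefficient for compositional association
#'
#' `rho_p = 2 cov(log x, log y) / (var(log x) + var(log y))`, a
#' normalization-robust association measure for relative-abundance data;
#' 1 iff `log y = log x + c`, -1 for log-antiproportionality. Zeros are
#' replaced by a pseudocount (default half the smallest nonzero value
#' across both vectors).
#'
#' @param x,y non-negative numeric vectors of equal length >= 3.
#' @param pseudocount replacement for zeros; `NULL` for the default rule.
#' @return `rho_p` in `[-1, 1]`; `NA` with a warning if either
#'   log-transformed vector has zero variance.
#' @export
proportionality <- function(x, y, pseudocount = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(x >= 0), all(y >= 0))
  if (is.null(pseudocount)) {
    nz <- c(x[x > 0], y[y > 0])
    if (!length(nz)) stop("all values are zero")
    pseudocount <- min(nz) / 2
  }
  lx <- log(ifelse(x == 0, pseudocount, x))
  ly <- log(ifelse(y == 0, pseudocount, y))
  vx <- stats::var(lx); vy <- stats::var(ly)
  if (vx == 0 || vy == 0) {
    warning("zero variance after log transform; rho_p undefined")
    return(NA_real_)
  }
  2 * stats::cov(lx, ly) / (vx + vy)
}

#' Differential-production screen between two sample groups
#'
#' Per metabolite: a two-sided rank-sum test across the two groups,
#' BH-FDR correction over all tested metabolites, and the magnitude
#' filters of the screen: a metabolite is flagged differential iff
#' `q < fdr_alpha`, its mean NMPC exceeds `floor` (mmol/day) in at least
#' one group, and the relative mean difference (denominator: the larger
#' mean) is at least `rel_diff`. Metabolites that are all-zero in both
#' groups are reported untested.
#'
#' @param nmpc an `nmpc_matrix` or a plain samples x metabolites matrix.
#' @param groups named vector (sample -> group label) with exactly two
#'   distinct labels among the matrix rows.
#' @param fdr_alpha FDR threshold (default 0.05).
#' @param floor production floor in mmol/day (default 10).
#' @param rel_diff minimum relative mean difference (default 0.10).
#' @return A `differential_result` data.frame: `metabolite`, per-group
#'   means, `p_value`, `q_value`, `passes_magnitude`, `differential`,
#'   `tested`.
#' @export
differential_metabolites <- function(nmpc, groups, fdr_alpha = 0.05,
                                     floor = 10, rel_diff = 0.10) {
  X <- if (inherits(nmpc, "nmpc_matrix")) nmpc$values else as.matrix(nmpc)
  groups <- groups[rownames(X)]
  if (anyNA(groups)) stop("groups must cover all samples in the matrix")
  labs <- unique(groups)
  if (length(labs) != 2) stop("exactly two groups are required")
  i1 <- groups == labs[1]; i2 <- groups == labs[2]
  res <- data.frame(metabolite = colnames(X),
                    mean1 = colMeans(X[i1, , drop = FALSE]),
                    mean2 = colMeans(X[i2, , drop = FALSE]),
                    p_value = NA_real_, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(res)[2:3] <- paste0("mean_", labs)
  res$tested <- !(res[[2]] == 0 & res[[3]] == 0)
  for (j in which(res$tested))
    res$p_value[j] <- ranksum(X[i1, j], X[i2, j])
  res$q_value <- NA_real_
  res$q_value[res$tested] <- bh_fdr(res$p_value[res$tested])
  m1 <- res[[2]]; m2 <- res[[3]]
  bigger <- pmax(m1, m2)
  res$passes_magnitude <- bigger > floor &
    ifelse(bigger > 0, abs(m1 - m2) / bigger, 0) >= rel_diff
  res$differential <- res$tested & !is.na(res$q_value) &
    res$q_value < fdr_alpha & res$passes_magnitude
  attr(res, "params") <- list(fdr_alpha = fdr_alpha, floor = floor,
                              rel_diff = rel_diff, groups = labs)
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Pick the high- and low-gout clusters
#'
#' Among clusters with at least `min_size` samples, returns the cluster
#' with the highest gouty fraction (`high`) and the lowest (`low`);
#' smaller clusters are excluded from the comparison.
#'
#' @param clusters a `cluster_result` with phenotype counts.
#' @param min_size minimum cluster size (default 10).
#' @return List with `high` and `low` cluster ids and the gouty
#'   `fractions` per eligible cluster.
#' @export
select_gout_clusters <- function(clusters, min_size = 10) {
  stopifnot(inherits(clusters, "cluster_result"),
            !is.null(clusters$phenotype_counts))
  cnt <- clusters$phenotype_counts
  sizes <- rowSums(cnt)
  ok <- which(sizes >= min_size)
  if (length(ok) < 2)
    stop("fewer than two clusters reach the minimum size ", min_size)
  frac <- cnt[ok, "gouty"] / sizes[ok]
  list(high = ok[which.max(frac)], low = ok[which.min(frac)],
       fractions = setNames(frac, ok))
}

#' Rand index between two partitions
#'
#' Fraction of sample pairs on whose co-membership the two partitions
#' agree.
#'
#' @param a,b cluster assignments over the same samples.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    sa <- a[i] == a[(i + 1):n]
    sb <- b[i] == b[(i + 1):n]
    agree <- agree + sum(sa == sb)
  }
  agree / (n * (n - 1) / 2)
}

#' Compare clusterings and production across diets
#'
#' Measures pairwise cluster-membership concordance (Rand index over
#' sample pairs) between the clusterings obtained under different diets,
#' and screens each metabolite for differential production between the
#' matched (high-gout or low-gout) clusters of two diets with a rank-sum
#' test and BH correction.
#'
#' @param nmpc_by_diet named list of `nmpc_matrix` objects over the same
#'   retained samples.
#' @param clusterings named list of `cluster_result` objects, same names.
#' @param which_cluster `"high"` or `"low"`: which matched gout cluster
#'   to compare across diets (requires phenotype counts).
#' @param fdr_alpha FDR threshold for the cross-diet screen.
#' @return List with `agreement` (diet-pair Rand index matrix) and
#'   `cross_diet` (per-metabolite data.frame per diet pair).
#' @export
compare_diets <- function(nmpc_by_diet, clusterings,
                          which_cluster = c("high", "low"),
                          fdr_alpha = 0.05) {
  stopifnot(identical(names(nmpc_by_diet), names(clusterings)),
            length(nmpc_by_diet) >= 2)
  which_cluster <- match.arg(which_cluster)
  diets <- names(nmpc_by_diet)
  samp <- lapply(clusterings, function(cl) sort(names(cl$assignments)))
  if (!all(vapply(samp, identical, TRUE, samp[[1]])))
    stop("clusterings cover different sample sets")
  nd <- length(diets)
  agreement <- matrix(1, nd, nd, dimnames = list(diets, diets))
  for (i in seq_len(nd - 1)) for (j in (i + 1):nd) {
    a <- clusterings[[i]]$assignments[samp[[1]]]
    b <- clusterings[[j]]$assignments[samp[[1]]]
    agreement[i, j] <- agreement[j, i] <- rand_index(a, b)
  }
  cross <- list()
  for (i in seq_len(nd - 1)) for (j in (i + 1):nd) {
    gi <- select_gout_clusters(clusterings[[i]])[[which_cluster]]
    gj <- select_gout_clusters(clusterings[[j]])[[which_cluster]]
    si <- names(clusterings[[i]]$assignments)[
      clusterings[[i]]$assignments == gi]
    sj <- names(clusterings[[j]]$assignments)[
      clusterings[[j]]$assignments == gj]
    Xi <- nmpc_by_diet[[i]]$values
    Xj <- nmpc_by_diet[[j]]$values
    mets <- intersect(colnames(Xi), colnames(Xj))
    p <- vapply(mets, function(met) {
      x <- Xi[si, met]; y <- Xj[sj, met]
      if (all(x == 0) && all(y == 0)) NA_real_ else ranksum(x, y)
    }, 0)
    q <- rep(NA_real_, length(p))
    q[!is.na(p)] <- bh_fdr(p[!is.na(p)])
    cross[[paste(diets[i], diets[j], sep = "_vs_")]] <-
      data.frame(metabolite = mets, p_value = p, q_value = q,
                 flagged = !is.na(q) & q < fdr_alpha,
                 row.names = NULL, stringsAsFactors = FALSE)
  }
  list(agreement = agreement, cross_diet = cross)
}
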