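# Clustering, association, correlation and differential-production
# statistics against oracles and hand computations.

test_that("k-means separates well-separated 1-D blobs and keeps duplicates together", {
  X <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  rownames(X) <- paste0("s", 1:4)
  cl <- kmeans_cluster(X, 2, replicates = 20, seed = 1)
  expect_equal(cl$assignments[["s1"]], cl$assignments[["s2"]])
  expect_equal(cl$assignments[["s3"]], cl$assignments[["s4"]])
  expect_false(cl$assignments[["s1"]] == cl$assignments[["s3"]])

  Xd <- rbind(X, s5 = 0.1, s6 = 10.1)
  cld <- kmeans_cluster(Xd, 2, replicates = 20, seed = 2)
  expect_equal(cld$assignments[["s2"]], cld$assignments[["s5"]])
  expect_equal(cld$assignments[["s4"]], cld$assignments[["s6"]])
})

test_that("clusters are relabeled by descending size", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(10, 30), 5))
  rownames(X) <- paste0("s", 1:25)
  cl <- kmeans_cluster(X, 2, replicates = 20, seed = 3)
  expect_equal(unname(tabulate(cl$assignments, 2)), c(20, 5))
})

test_that("k-means objective: replicates only improve, Lloyd never worsens", {
  set.seed(9)
  X <- matrix(rnorm(120), 30)
  rownames(X) <- paste0("s", 1:30)
  best <- kmeans_cluster(X, 3, replicates = 50, seed = 4)$tot_withinss
  singles <- vapply(1:10, function(s)
    kmeans_cluster(X, 3, replicates = 1, seed = s)$tot_withinss, 0)
  expect_true(all(best <= singles + 1e-9))
  # Lloyd iterations are monotone in the objective from a fixed start
  init <- X[c(1, 2, 3), ]
  w1 <- suppressWarnings(stats::kmeans(X, init, iter.max = 1,
                                       algorithm = "Lloyd"))$tot.withinss
  w9 <- suppressWarnings(stats::kmeans(X, init, iter.max = 50,
                                       algorithm = "Lloyd"))$tot.withinss
  expect_lte(w9, w1 + 1e-9)
})

test_that("silhouette-based k selection finds planted blob counts", {
  set.seed(5)
  three <- rbind(matrix(rnorm(60, 0, 0.5), 20),
                 matrix(rnorm(60, 10, 0.5), 20),
                 matrix(rnorm(60, 20, 0.5), 20))
  rownames(three) <- paste0("s", 1:60)
  expect_equal(as.integer(select_k(three, 2:5, replicates = 20, seed = 1)),
               3L)
  two <- three[1:40, ]
  expect_equal(as.integer(select_k(two, 2:5, replicates = 20, seed = 1)),
               2L)
  # a perfect partition scores higher than a shuffled one
  D <- stats::dist(three, method = "manhattan")
  truth <- rep(1:3, each = 20)
  rnd <- sample(truth)
  sil_true <- mean(cluster::silhouette(truth, D)[, "sil_width"])
  sil_rnd <- mean(cluster::silhouette(rnd, D)[, "sil_width"])
  expect_gt(sil_true, sil_rnd)
  expect_error(select_k(matrix(1, 5, 2), 2:3), "degenerate")
})

test_that("PCA projection: rank-1 variance, orthogonality, isometry at full rank", {
  u <- rnorm(10); w <- rnorm(4)
  rank1 <- outer(u, w)
  p1 <- pca_project(rank1, 2)
  expect_equal(p1$explained[1], 1, tolerance = 1e-9)
  set.seed(6)
  X <- matrix(rnorm(50), 10)
  p <- pca_project(X, 5)
  expect_equal(crossprod(p$loadings), diag(5), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-12)
  # distances preserved when all components are kept
  expect_equal(as.matrix(dist(p$scores)), as.matrix(dist(X)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(pca_project(matrix(2, 4, 3)), "constant")
})

test_that("Fisher exact test reproduces the study's contingency results", {
  # Bacteroides-dominated (22/26 gouty) vs Faecalibacterium-elevated
  # (11/44 gouty): printed as p < 1e-5
  high_low <- fisher_exact_2x2(rbind(c(22, 4), c(11, 33)))
  expect_lt(high_low$p_value, 1e-5)
  # Faecalibacterium-elevated healthy (33/44) vs Prevotella-elevated
  # (2/8): printed as p = 0.011
  low_prev <- fisher_exact_2x2(rbind(c(33, 11), c(2, 6)))
  expect_equal(round(low_prev$p_value, 3), 0.011)
  expect_equal(fisher_exact_2x2(rbind(c(1, 1), c(1, 1)))$p_value, 1)
  degen <- fisher_exact_2x2(rbind(c(0, 0), c(3, 5)))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
})

test_that("Fisher p matches hypergeometric enumeration on small tables", {
  set.seed(11)
  for (i in 1:30) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_value, fisher_oracle(tab),
                 tolerance = 1e-9, label = paste(tab, collapse = ","))
  }
})

test_that("cluster-phenotype association supports all reference modes", {
  cl <- structure(list(
    assignments = setNames(rep(1:3, c(26, 44, 8)), paste0("s", 1:78)),
    k = 3, centroids = NULL, tot_withinss = 0,
    phenotype_counts = rbind(c(gouty = 22, healthy = 4),
                             c(gouty = 11, healthy = 33),
                             c(gouty = 6, healthy = 2))),
    class = "cluster_result")
  vs_low <- cluster_phenotype_association(cl, 1, reference = 2)
  expect_lt(vs_low$p_value, 1e-5)
  vs_all <- cluster_phenotype_association(cl, 1, reference = "all")
  expect_equal(round(vs_all$p_value, 3), 0.002)
  vs_all_h <- cluster_phenotype_association(cl, 2, reference = "all",
                                            phenotype = "healthy")
  expect_equal(round(vs_all_h$p_value, 3), 0.008)
  vs_comp <- cluster_phenotype_association(cl, 1, reference = "complement")
  expect_lt(vs_comp$p_value, vs_all$p_value)   # sharper contrast
})

test_that("rank-sum test: exact enumeration, ties, identical samples", {
  # all three x below all three y: only 2 of the 20 assignments are as
  # extreme, exact p = 0.1
  expect_equal(ranksum(1:3, 4:6), 0.1, tolerance = 1e-9)
  expect_equal(ranksum(c(2, 2, 2), c(2, 2, 2)), 1)
  set.seed(12)
  for (i in 1:25) {
    nx <- sample(3:7, 1); ny <- sample(3:7, 1)
    x <- round(rnorm(nx), 6); y <- round(rnorm(ny, 0.5), 6)
    expect_equal(ranksum(x, y), ranksum_oracle(x, y), tolerance = 1e-9)
  }
  # exact and normal approximation agree on moderate samples
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10, 1)
    exact <- ranksum(x, y)
    approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("BH adjustment matches the hand-rolled step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
  }
})

test_that("proportionality coefficient: exact cases and direct formula", {
  x <- c(1, 2, 5, 9, 3)
  expect_equal(proportionality(x, 3 * x), 1)
  expect_equal(proportionality(x, 1 / x), -1)
  set.seed(15)
  for (i in 1:10) {
    a <- rlnorm(8); b <- rlnorm(8)
    direct <- 2 * cov(log(a), log(b)) / (var(log(a)) + var(log(b)))
    expect_equal(proportionality(a, b), direct, tolerance = 1e-12)
  }
  # zeros replaced by half the smallest nonzero value across both vectors
  z <- c(0, 1, 2, 4)
  expect_equal(proportionality(z, z), 1)
  expect_equal(proportionality(z, 2 * z, pseudocount = 0.5),
               proportionality(c(0.5, 1, 2, 4), c(0.5, 2, 4, 8)))
  expect_warning(out <- proportionality(rep(2, 4), c(1, 2, 3, 4)),
                 "zero variance")
  expect_true(is.na(out))
})

test_that("differential screen applies FDR and both magnitude filters", {
  set.seed(16)
  n1 <- 15; n2 <- 15
  mk <- function(m1, m2, sd = 0.02) c(rnorm(n1, m1, sd), rnorm(n2, m2, sd))
  X <- cbind(
    strong = mk(100, 50),       # passes everything
    small_rel = mk(12, 11.5),   # relative difference 4% < 10%
    below_floor = mk(8, 2),     # max mean below 10 mmol/day
    null = mk(40, 40, 2),       # no real difference
    silent = rep(0, n1 + n2))   # untested
  rownames(X) <- paste0("s", seq_len(n1 + n2))
  groups <- setNames(rep(c("high", "low"), c(n1, n2)), rownames(X))
  res <- differential_metabolites(X, groups)
  get <- function(met) res[res$metabolite == met, ]
  expect_true(get("strong")$differential)
  expect_false(get("small_rel")$differential)
  expect_true(get("small_rel")$q_value < 0.05)   # fails only on magnitude
  expect_false(get("below_floor")$differential)
  expect_false(get("null")$differential)
  expect_false(get("silent")$tested)
  expect_true(all(res$q_value >= res$p_value, na.rm = TRUE))
})

test_that("high/low gout cluster selection respects the minimum size", {
  cl <- structure(list(
    assignments = setNames(rep(1:3, c(26, 44, 8)), paste0("s", 1:78)),
    k = 3, centroids = NULL, tot_withinss = 0,
    phenotype_counts = rbind(c(gouty = 22, healthy = 4),
                             c(gouty = 11, healthy = 33),
                             c(gouty = 6, healthy = 2))),
    class = "cluster_result")
  sel <- select_gout_clusters(cl)
  expect_equal(unname(sel$high), 1L)   # 22/26 = 0.85
  expect_equal(unname(sel$low), 2L)    # 11/44 = 0.25
  expect_false(3 %in% names(sel$fractions))  # 8 samples < 10 excluded
})

test_that("diet comparison: identical clusterings agree, planted shift flagged", {
  g <- gen_nmpc_matrix(seed = 21)
  cl <- kmeans_cluster(g$nmpc$values, 3, replicates = 50, seed = 1,
                       phenotype = g$phenotype)
  # a second diet: same capabilities plus tiny noise -> same clustering
  set.seed(22)
  X2 <- g$nmpc$values * exp(matrix(rnorm(length(g$nmpc$values), 0, 0.01),
                                   nrow(g$nmpc$values)))
  nm2 <- g$nmpc; nm2$values <- X2
  cl2 <- kmeans_cluster(X2, 3, replicates = 50, seed = 1,
                        phenotype = g$phenotype)
  out <- compare_diets(list(EUD = g$nmpc, HPD = nm2),
                       list(EUD = cl, HPD = cl2))
  expect_equal(out$agreement["EUD", "HPD"], 1)
  # a third diet with one metabolite strongly shifted in every sample
  X3 <- g$nmpc$values
  X3[, "succ"] <- X3[, "succ"] * 3
  nm3 <- g$nmpc; nm3$values <- X3
  cl3 <- kmeans_cluster(X3, 3, replicates = 50, seed = 1,
                        phenotype = g$phenotype)
  out3 <- compare_diets(list(EUD = g$nmpc, HFD = nm3),
                        list(EUD = cl, HFD = cl3))
  cross <- out3$cross_diet$EUD_vs_HFD
  expect_true(cross$flagged[cross$metabolite == "succ"])
})

test_that("Rand index: identical, independent and shifted partitions", {
  a <- rep(1:3, each = 10)
  expect_equal(rand_index(a, a), 1)
  expect_equal(rand_index(a, (a %% 3) + 1), 1)   # relabeling is irrelevant
  b <- rep(1, 30)
  expect_lt(rand_index(a, b), 0.5)
})
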