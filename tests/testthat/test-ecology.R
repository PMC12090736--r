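test_that("Bray-Curtis follows the sum formula and its bounds", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 3, 0)), 1)   # disjoint
  expect_equal(bray_curtis(c(2, 2), c(1, 3)), 0.25)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(-1, 1), c(1, 1)), "non-negative")
})

test_that("the pairwise formula agrees with vegan's distance matrix", {
  set.seed(31)
  m <- matrix(rlnorm(60), nrow = 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  d <- distance_matrix(phf_abundance(m), "bray_curtis")
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(d[i, j], bray_curtis(m[, i], m[, j]), tolerance = 1e-12)
  }
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
})

test_that("unifrac is zero on identical samples and bounded by one", {
  set.seed(17)
  tree <- ape::rtree(5, rooted = TRUE)
  x <- setNames(c(1, 2, 0, 4, 0.5), tree$tip.label)
  expect_equal(unifrac(tree, x, x, weighted = FALSE), 0)
  expect_equal(unifrac(tree, x, x, weighted = TRUE), 0)
  y <- setNames(c(0, 1, 3, 0, 2), tree$tip.label)
  for (w in c(TRUE, FALSE)) {
    d <- unifrac(tree, x, y, weighted = w)
    expect_gte(d, 0)
    expect_lte(d, 1)
  }
})

test_that("unweighted unifrac on a star tree is presence Jaccard", {
  # equal-length star: unique branch fraction reduces to Jaccard distance
  tree <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1):0;")
  x <- c(A = 2, B = 1, C = 3, D = 0, E = 0)
  y <- c(A = 0, B = 5, C = 1, D = 4, E = 0)
  inter <- 2  # B, C
  union <- 4  # A, B, C, D
  expect_equal(unifrac(tree, x, y, weighted = FALSE), 1 - inter / union)
})

test_that("weighted unifrac hits 1 on disjoint root subtrees", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  x <- c(A = 2, B = 3, C = 0, D = 0)
  y <- c(A = 0, B = 0, C = 1, D = 4)
  expect_equal(unifrac(tree, x, y, weighted = TRUE), 1)
  expect_equal(unifrac(tree, x, y, weighted = FALSE), 1)
})

test_that("both unifrac variants match the branch-enumeration oracle", {
  set.seed(41)
  for (i in 1:100) {
    case <- random_unifrac_case()
    for (w in c(TRUE, FALSE)) {
      expect_equal(unifrac(case$tree, case$x, case$y, weighted = w),
                   oracle_unifrac(case$tree, case$x, case$y, weighted = w),
                   tolerance = 1e-10)
    }
  }
  tree <- ape::rtree(4, rooted = TRUE)
  bad <- c(nope = 1)
  expect_error(unifrac(tree, bad, bad), "tree tip")
})

test_that("the distance matrix routes equal values to every pair", {
  set.seed(43)
  tree <- ape::rtree(8, rooted = TRUE)
  m <- matrix(rlnorm(8 * 5), nrow = 8,
              dimnames = list(tree$tip.label, paste0("s", 1:5)))
  t <- phf_abundance(m)
  for (metric in c("unifrac_unweighted", "unifrac_weighted")) {
    d <- distance_matrix(t, metric, tree = tree)
    expect_true(isSymmetric(d))
    expect_true(all(diag(d) == 0))
    w <- metric == "unifrac_weighted"
    for (i in 1:4) for (j in (i + 1):5) {
      expect_equal(d[i, j], unifrac(tree, m[, i], m[, j], weighted = w),
                   tolerance = 1e-12)
    }
  }
  expect_error(distance_matrix(t, "unifrac_weighted"), "tree")
})

test_that("unifrac agrees with phyloseq on a random table", {
  set.seed(47)
  tree <- ape::rtree(10, rooted = TRUE)
  m <- matrix(rpois(10 * 4, 20) + 1, nrow = 10,
              dimnames = list(tree$tip.label, paste0("s", 1:4)))
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(m, taxa_are_rows = TRUE),
    phyloseq::phy_tree(tree))
  ours_w <- distance_matrix(phf_abundance(m), "unifrac_weighted",
                            tree = tree)
  theirs_w <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                          normalized = TRUE))
  expect_equal(ours_w[colnames(theirs_w), colnames(theirs_w)], theirs_w,
               tolerance = 1e-8, ignore_attr = TRUE)
  ours_u <- distance_matrix(phf_abundance(m), "unifrac_unweighted",
                            tree = tree)
  theirs_u <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  expect_equal(ours_u[colnames(theirs_u), colnames(theirs_u)], theirs_u,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("reference trees prune to one deterministic tip per family", {
  tree <- ape::read.tree(
    text = "(((g1:1,g2:1):1,(g3:1,g4:1):1):1,(g5:1,g6:1):2);")
  fams <- c(g1 = "FamA", g2 = "FamA", g3 = "FamB", g4 = "", g5 = "FamC",
            g6 = "FamA")
  pruned <- prune_tree_to_families(tree, fams)
  expect_setequal(pruned$tip.label, c("FamA", "FamB", "FamC"))
  # FamA's representative is g1 (first in preorder), so FamA sits sister
  # to FamB, not inside the (g5, g6) clade
  pair <- ape::getMRCA(pruned, c("FamA", "FamB"))
  expect_gt(pair, ape::getMRCA(pruned, c("FamA", "FamC")))
  # repeated calls are identical, and the pruned tree feeds unifrac
  expect_identical(ape::write.tree(pruned),
                   ape::write.tree(prune_tree_to_families(tree, fams)))
  x <- c(FamA = 1, FamB = 2, FamC = 0.5)
  expect_equal(unifrac(pruned, x, x, weighted = TRUE), 0)
})

test_that("pairs partition exactly into inter and intra sets", {
  m <- matrix(rlnorm(4 * 4), nrow = 4,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:4)))
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     individual_id = c("A", "A", "B", "B"))
  d <- distance_matrix(phf_abundance(m), "bray_curtis")
  parts <- partition_distances(d, meta)
  expect_length(parts$intra, 2)
  expect_length(parts$inter, 4)
  # single individual: no inter pairs, and conservation n(n-1)/2
  meta1 <- data.frame(sample_id = paste0("s", 1:4), individual_id = "A")
  parts1 <- partition_distances(d, meta1)
  expect_length(parts1$inter, 0)
  expect_equal(length(parts1$intra) + length(parts1$inter), 4 * 3 / 2)
})

test_that("stability is one minus consecutive-sample distance", {
  # planted distances, including a gap in time: consecutive in collection
  # order, not calendar
  samples <- c("t1", "t2", "t4")
  d <- matrix(0, 3, 3, dimnames = list(samples, samples))
  d["t1", "t2"] <- d["t2", "t1"] <- 0.25
  d["t2", "t4"] <- d["t4", "t2"] <- 0.4
  d["t1", "t4"] <- d["t4", "t1"] <- 0.9
  meta <- data.frame(sample_id = samples, individual_id = "A",
                     time_index = c(1L, 2L, 4L))
  st <- stability_series(d, meta)
  expect_equal(st$from_sample, c("t1", "t2"))
  expect_equal(st$to_sample, c("t2", "t4"))
  expect_equal(st$stability, c(0.75, 0.6))

  # identical consecutive samples give stability exactly 1
  m <- matrix(c(1, 2, 1, 2), nrow = 2,
              dimnames = list(c("f1", "f2"), c("a", "b")))
  db <- distance_matrix(phf_abundance(m), "bray_curtis")
  stb <- stability_series(db, data.frame(sample_id = c("a", "b"),
                                         individual_id = "X",
                                         time_index = 1:2))
  expect_equal(stb$stability, 1)

  # individuals with fewer than two samples contribute nothing
  lone <- stability_series(d, data.frame(sample_id = samples,
                                         individual_id = c("A", "B", "C"),
                                         time_index = 1L))
  expect_equal(nrow(lone), 0)
  expect_error(
    stability_series(d, data.frame(sample_id = samples,
                                   individual_id = "A",
                                   time_index = c(1L, 1L, 2L))),
    "duplicate time_index")
})

test_that("matched-metric comparison degenerates and orders correctly", {
  v <- runif(15)
  same <- list(a = v, b = v, c = v)
  res <- compare_metrics_matched(same)
  expect_equal(res$friedman$statistic, 0)
  expect_gte(res$friedman$p_value, 0.99)
  expect_true(all(res$pairwise$p_value == 1))
  expect_true(all(res$pairwise$p_adjusted <= 1))

  # strictly ordered matched triples: every post-hoc test is significant
  set.seed(53)
  base <- runif(20, 0.3, 0.7)
  ordered <- list(low = base - 0.2, mid = base, high = base + 0.2)
  res2 <- compare_metrics_matched(ordered)
  expect_lt(res2$friedman$p_value, 0.001)
  expect_true(all(res2$pairwise$p_adjusted < 0.05))
  expect_lt(res2$pairwise$median_diff[res2$pairwise$group_a == "low" &
                                        res2$pairwise$group_b == "high"], 0)
  expect_error(compare_metrics_matched(list(a = 1:3, b = 1:4)),
               "not matched")
})

test_that("PHF-host correlations recover planted monotone structure", {
  n <- 60
  x <- seq_len(n) / n
  phf_m <- rbind(FamA = x, FamB = rev(x), FamC = rep(0.5, n))
  colnames(phf_m) <- paste0("s", 1:n)
  host_m <- rbind(HostA = x^2, HostB = x, HostC = rep(1, n))
  colnames(host_m) <- paste0("s", 1:n)
  map <- data.frame(name_a = c("FamA", "FamB", "FamC"),
                    name_b = c("HostA", "HostB", "HostC"),
                    fraction_mapping = c(0.9, 0.9, 0.9))
  res <- correlate_phf_host(phf_abundance(phf_m), phf_abundance(host_m),
                            map)
  expect_equal(res$rho[res$phf == "FamA"], 1)      # monotone increasing
  expect_equal(res$rho[res$phf == "FamB"], -1)
  expect_true(res$excluded[res$phf == "FamC"])     # constant: undefined
  expect_true(res$significant[res$phf == "FamA"])

  # below-threshold mappings drop the pair entirely
  weak_map <- within(map, fraction_mapping <- 0.4)
  expect_equal(nrow(correlate_phf_host(phf_abundance(phf_m),
                                       phf_abundance(host_m), weak_map)),
               0)
})

test_that("spearman estimates recover planted correlations at n = 200", {
  set.seed(59)
  n <- 200
  for (rho_true in c(0.1, 0.6, 0.9)) {
    x <- rnorm(n)
    y <- rho_true * x + sqrt(1 - rho_true^2) * rnorm(n)
    phf_m <- matrix(exp(x), nrow = 1,
                    dimnames = list("FamA", paste0("s", 1:n)))
    host_m <- matrix(exp(y), nrow = 1,
                     dimnames = list("HostA", paste0("s", 1:n)))
    map <- data.frame(name_a = "FamA", name_b = "HostA",
                      fraction_mapping = 1)
    res <- correlate_phf_host(phf_abundance(phf_m), phf_abundance(host_m),
                              map)
    expect_lt(abs(res$rho - rho_true), 0.1)
  }
})
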