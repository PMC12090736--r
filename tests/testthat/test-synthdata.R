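small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_individuals = 4, samples_per_individual = 6, n_families = 20,
         votus_per_family_per_individual = 3, seed = 101),
    list(...))
  do.call(cohort_config, args)
}

test_that("the same seed reproduces the cohort exactly", {
  a <- generate_cohort(small_cfg())
  b <- generate_cohort(small_cfg())
  expect_identical(a$prediction, b$prediction)
  expect_identical(a$linkage, b$linkage)
  expect_identical(a$abundance$values, b$abundance$values)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  c <- generate_cohort(small_cfg(seed = 202))
  expect_false(identical(a$abundance$values, c$abundance$values))
})

test_that("a noiseless cohort recovers 100% concordance everywhere", {
  cfg <- small_cfg(p_predicted = 1,
                   pred_error = c(phylum = 0, class = 0, order = 0,
                                  family = 0, genus = 0),
                   multi_prediction_rate = 0, hic_multi_host_rate = 0)
  co <- generate_cohort(cfg)
  rep <- concordance_report(co$prediction, co$linkage)
  expect_true(all(rep$percent == 100))
  expect_equal(attr(rep, "n_contigs_both"), nrow(co$abundance$values))
})

test_that("generated lineages stay population-consistent across ranks", {
  co <- generate_cohort(small_cfg(pred_error = c(phylum = 0.1,
                                                 class = 0.15,
                                                 order = 0.2,
                                                 family = 0.25,
                                                 genus = 0.5)))
  all_lin <- rbind(co$prediction[lineage_ranks()],
                   co$linkage[lineage_ranks()],
                   co$truth$lineages[lineage_ranks()])
  # every name at a rank must imply a unique parent name: equality at a
  # deeper rank then forces equality at every shallower rank
  ranks <- lineage_ranks()
  for (k in 2:length(ranks)) {
    pairs <- unique(all_lin[nzchar(all_lin[[ranks[k]]]),
                            c(ranks[k - 1], ranks[k])])
    expect_false(any(duplicated(pairs[[ranks[k]]])))
  }
})

test_that("empirical prediction error converges to the configured rates", {
  cfg <- cohort_config(n_families = 74, multi_prediction_rate = 0,
                       hic_multi_host_rate = 0, p_predicted = 1,
                       seed = 303)
  withr::with_seed(7001, {
    sim <- simulate_host_assignments(5000, cfg)
  })
  best <- assign_phf(sim$prediction)
  truth_fam <- sim$truth$family[match(best$contig_id,
                                      sim$truth$contig_id)]
  fam_err <- mean(best$phf != truth_fam)
  expect_lt(abs(fam_err - cfg$pred_error[["family"]]), 0.02)
  # genus-level error via the concordance machinery (Hi-C is error-free)
  rep <- concordance_report(sim$prediction, sim$linkage)
  genus_err <- 1 - concordance_percent(rep, "genus", "strict") / 100
  expect_lt(abs(genus_err - cfg$pred_error[["genus"]]), 0.02)
})

test_that("AR(1) fluctuations carry the configured persistence", {
  withr::with_seed(61, {
    x <- simulate_ar1(2000, persistence = 0.7, sigma = 1)
  })
  emp <- cor(x[-1], x[-length(x)])
  expect_lt(abs(emp - 0.7), 0.1)
  expect_lt(abs(sd(x) - 1), 0.15)
  withr::with_seed(62, {
    flat <- simulate_ar1(500, persistence = 0, sigma = 0.5)
  })
  expect_lt(abs(cor(flat[-1], flat[-length(flat)])), 0.15)
})

test_that("private vOTU pools push contig distances above PHF distances", {
  cfg <- small_cfg(shared_votu_fraction = 0.05, n_individuals = 6,
                   samples_per_individual = 3)
  co <- generate_cohort(cfg)
  rel <- to_relative_abundance(co$abundance)
  assign <- assign_phf(co$prediction, feature_ids(rel))
  phl <- drop_unknown(agglomerate_phf(rel, assign))
  d_contig <- distance_matrix(rel, "bray_curtis")
  d_phf <- distance_matrix(phl, "bray_curtis")
  meta <- rel$sample_meta
  inter_contig <- mean(partition_distances(d_contig, meta)$inter)
  inter_phf <- mean(partition_distances(d_phf, meta)$inter)
  expect_gt(inter_contig - inter_phf, 0.1)
})

test_that("infeasible configurations are rejected up front", {
  expect_error(cohort_config(n_individuals = 1, shared_votu_fraction = 0.5),
               "at least 2 individuals")
  expect_error(cohort_config(pred_error = c(phylum = 0.5, class = 0.1,
                                            order = 0.1, family = 0.1,
                                            genus = 0.1)),
               "non-increasing")
  expect_error(cohort_config(ar_persistence = 1), "ar_persistence")
  expect_error(cohort_config(p_predicted = 1.2), "p_predicted")
  expect_error(cohort_config(genera_per_family = 1), "genera per family")
})

test_that("planting controls which features cross 50% prevalence", {
  cfg <- cohort_config(n_individuals = 9, samples_per_individual = 4,
                       n_families = 30, seed = 71)
  planted <- plant_prevalence(cfg, 7)
  prev <- prevalence(planted$abundance)
  expect_setequal(prevalent_features(prev), planted$planted)

  none <- plant_prevalence(cfg, 0)
  expect_length(prevalent_features(prevalence(none$abundance)), 0)

  all_in <- plant_prevalence(cfg, 30)
  expect_length(prevalent_features(prevalence(all_in$abundance)), 30)
})
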