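# Synthetic longitudinal virome cohorts with ground truth. The generator
# reproduces the statistical structure the PHF analyses assume: host
# family abundance profiles shared across individuals, vOTU pools that are
# mostly individual-private, autocorrelated within-individual dynamics,
# and host predictions corrupted at configurable per-rank error rates
# against an error-free proximity-ligation reference.

#' Cohort generator configuration
#'
#' Builds and validates the parameter set for [generate_cohort()]. The
#' defaults describe a longitudinal human gut virome cohort: 10
#' individuals sampled 14 times each (140 samples), 74 host families,
#' 86.3% of contigs receiving a host prediction, per-rank prediction
#' error rates descending from genus (0.33) to phylum (0.02) that mirror
#' the concordance profile of host-prediction tools against Hi-C, a 20%
#' multi-prediction rate (about 1.28 predictions per predicted contig)
#' and a 2% multi-host Hi-C rate. Desk-scale choices (vOTUs per family,
#' sequencing depth model) are documented in the methods vignette.
#'
#' Prediction error rates must be non-increasing from genus up to phylum:
#' a wrong family implies a wrong genus, so the corruption model is
#' nested.
#'
#' @param n_individuals number of individuals.
#' @param samples_per_individual longitudinal samples per individual.
#' @param n_families number of host (bacterial) families.
#' @param genera_per_family genera within each family (>= 2 allows
#'   genus-level corruption).
#' @param votus_per_family_per_individual vOTUs per family in each
#'   individual's pool.
#' @param shared_votu_fraction fraction of each family's vOTUs drawn from
#'   a cohort-shared pool; the rest are private to the individual.
#' @param family_profile_concentration Dirichlet concentration tying
#'   individual family profiles to the cohort profile (larger = more
#'   alike).
#' @param ar_persistence lag-1 autocorrelation of within-individual
#'   log-abundance dynamics, in `[0, 1)`.
#' @param lognormal_sigma stationary standard deviation of those
#'   log-abundance fluctuations.
#' @param p_predicted fraction of contigs given any host prediction.
#' @param pred_error named per-rank error rates (phylum..genus) for the
#'   most confident prediction.
#' @param extra_pred_error per-rank error rates for additional, less
#'   confident predictions.
#' @param multi_prediction_rate probability a predicted contig gets more
#'   than one prediction.
#' @param multi_prediction_lambda Poisson mean for predictions beyond the
#'   second, given multiple.
#' @param hic_error per-rank error rates of the top Hi-C hit (0 = treat
#'   Hi-C as the experimental reference).
#' @param hic_multi_host_rate probability a contig gets more than one
#'   Hi-C-linked host.
#' @param hic_multi_host_lambda Poisson mean for Hi-C hosts beyond the
#'   second, given multiple.
#' @param depth_mean,depth_dispersion negative-binomial read-count model:
#'   expected reads per sample and NB size parameter.
#' @param dysbiosis_rate per-sample probability of the dysbiotic state.
#' @param diagnosis_probs named probabilities over diagnosis groups.
#' @param seed integer seed; the same seed gives byte-identical cohorts.
#' @return a validated `phf_cohort_config` list.
#' @export
cohort_config <- function(n_individuals = 10,
                          samples_per_individual = 14,
                          n_families = 74,
                          genera_per_family = 3,
                          votus_per_family_per_individual = 4,
                          shared_votu_fraction = 0.25,
                          family_profile_concentration = 50,
                          ar_persistence = 0.7,
                          lognormal_sigma = 1,
                          p_predicted = 0.863,
                          pred_error = c(phylum = 0.02, class = 0.03,
                                         order = 0.04, family = 0.07,
                                         genus = 0.33),
                          extra_pred_error = NULL,
                          multi_prediction_rate = 0.2,
                          multi_prediction_lambda = 0.3,
                          hic_error = c(phylum = 0, class = 0, order = 0,
                                        family = 0, genus = 0),
                          hic_multi_host_rate = 0.02,
                          hic_multi_host_lambda = 0.2,
                          depth_mean = 5e4,
                          depth_dispersion = 10,
                          dysbiosis_rate = 0.25,
                          diagnosis_probs = c(nonIBD = 27, CD = 65,
                                              UC = 38) / 130,
                          seed = 1) {
  cfg <- list(n_individuals = n_individuals,
              samples_per_individual = samples_per_individual,
              n_families = n_families,
              genera_per_family = genera_per_family,
              votus_per_family_per_individual = votus_per_family_per_individual,
              shared_votu_fraction = shared_votu_fraction,
              family_profile_concentration = family_profile_concentration,
              ar_persistence = ar_persistence,
              lognormal_sigma = lognormal_sigma,
              p_predicted = p_predicted,
              pred_error = normalize_rates(pred_error, "pred_error"),
              extra_pred_error = if (is.null(extra_pred_error)) {
                normalize_rates(pmin(2 * normalize_rates(pred_error,
                                                         "pred_error"),
                                     0.9), "extra_pred_error")
              } else normalize_rates(extra_pred_error, "extra_pred_error"),
              multi_prediction_rate = multi_prediction_rate,
              multi_prediction_lambda = multi_prediction_lambda,
              hic_error = normalize_rates(hic_error, "hic_error"),
              hic_multi_host_rate = hic_multi_host_rate,
              hic_multi_host_lambda = hic_multi_host_lambda,
              depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              dysbiosis_rate = dysbiosis_rate,
              diagnosis_probs = diagnosis_probs,
              seed = seed)
  props <- c(shared_votu_fraction = shared_votu_fraction,
             p_predicted = p_predicted,
             multi_prediction_rate = multi_prediction_rate,
             hic_multi_host_rate = hic_multi_host_rate,
             dysbiosis_rate = dysbiosis_rate)
  bad <- names(props)[props < 0 | props > 1]
  if (length(bad)) {
    stop("proportion(s) outside [0, 1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (ar_persistence < 0 || ar_persistence >= 1) {
    stop("ar_persistence must lie in [0, 1)", call. = FALSE)
  }
  if (n_individuals < 1 || samples_per_individual < 1 || n_families < 2) {
    stop("need >= 1 individual, >= 1 sample each, >= 2 families",
         call. = FALSE)
  }
  if (n_individuals < 2 && shared_votu_fraction > 0) {
    stop("a shared vOTU fraction needs at least 2 individuals",
         call. = FALSE)
  }
  if (genera_per_family < 2 && cfg$pred_error[["genus"]] > 0) {
    stop("genus-level error needs >= 2 genera per family", call. = FALSE)
  }
  class(cfg) <- "phf_cohort_config"
  cfg
}

# per-rank rate vector in comparison-rank order; must be non-increasing
# from genus (deepest) up to phylum so the nested corruption model is
# well defined
normalize_rates <- function(rates, what) {
  if (is.null(names(rates))) {
    if (length(rates) != length(COMPARISON_RANKS)) {
      stop(what, " must be named or have ", length(COMPARISON_RANKS),
           " entries", call. = FALSE)
    }
    names(rates) <- COMPARISON_RANKS
  }
  missing <- setdiff(COMPARISON_RANKS, names(rates))
  if (length(missing)) {
    stop(what, " is missing rank(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rates <- rates[COMPARISON_RANKS]
  if (any(rates < 0 | rates > 1)) {
    stop(what, " rates must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(rates)) {
    stop(what, " rates must be non-increasing from genus to phylum",
         call. = FALSE)
  }
  rates
}

# balanced synthetic host taxonomy: one row per genus, names unique across
# the whole taxonomy so a name determines its full ancestry (this is what
# makes lineages population-consistent: equal at rank r implies equal at
# every shallower rank)
make_taxonomy <- function(n_families, genera_per_family) {
  n_orders <- max(1L, min(16L, n_families %/% 2L))
  n_classes <- max(1L, min(8L, n_orders %/% 2L))
  n_phyla <- max(1L, min(4L, n_classes %/% 2L))
  fam_order <- rep_len(seq_len(n_orders), n_families)
  ord_class <- rep_len(seq_len(n_classes), n_orders)
  cls_phy <- rep_len(seq_len(n_phyla), n_classes)
  fam <- sprintf("Family_%03d", seq_len(n_families))
  rows <- list()
  for (f in seq_len(n_families)) {
    o <- fam_order[[f]]
    cl <- ord_class[[o]]
    ph <- cls_phy[[cl]]
    for (g in seq_len(genera_per_family)) {
      genus <- sprintf("Genus_%03d_%d", f, g)
      rows[[length(rows) + 1L]] <- data.frame(
        domain = "Bacteria",
        phylum = sprintf("Phylum_%02d", ph),
        class = sprintf("Class_%02d", cl),
        order = sprintf("Order_%02d", o),
        family = fam[[f]],
        genus = genus,
        species = paste0(genus, "_sp"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# nested corruption: draw the shallowest wrong rank (marginal error at
# rank r equals rates[r] when rates are non-increasing towards phylum),
# then swap in a sibling taxon's sub-lineage from that rank down
corrupt_lineage <- function(true_row, taxonomy, rates) {
  u <- stats::runif(1)
  wrong_rank <- NA_character_
  for (r in COMPARISON_RANKS) {          # shallowest first
    if (u < rates[[r]]) { wrong_rank <- r; break }
  }
  if (is.na(wrong_rank)) return(true_row)
  depth <- match(wrong_rank, PHF_RANKS)
  above <- PHF_RANKS[seq_len(depth - 1L)]
  same_above <- rep(TRUE, nrow(taxonomy))
  for (r in above) same_above <- same_above & taxonomy[[r]] == true_row[[r]]
  cand <- which(same_above & taxonomy[[wrong_rank]] != true_row[[wrong_rank]])
  if (length(cand) == 0L) {
    stop("taxonomy too small to corrupt at rank '", wrong_rank,
         "': no sibling taxon available; increase n_families or ",
         "genera_per_family", call. = FALSE)
  }
  alt <- taxonomy[cand[sample.int(length(cand), 1L)], , drop = FALSE]
  out <- true_row
  swap <- PHF_RANKS[depth:length(PHF_RANKS)]
  out[swap] <- alt[swap]
  attr(out, "corruption_depth") <- depth
  out
}

#' Simulate host predictions and Hi-C links for a set of contigs
#'
#' The assignment half of [generate_cohort()], exposed on its own for
#' concordance studies: each contig has a true host lineage; the top Hi-C
#' hit and the most confident prediction are independently corrupted at
#' the configured per-rank error rates, extra predictions and multi-host
#' links are added at the configured rates, and confidence scores
#' decrease with corruption depth so only their ordering is meaningful.
#'
#' @param n_contigs number of contigs.
#' @param cfg a [cohort_config()]; only the taxonomy and assignment
#'   parameters are used.
#' @param true_lineages optional lineage frame of true hosts (one row per
#'   contig); drawn uniformly from the synthetic taxonomy when `NULL`.
#' @param contig_ids optional contig ids.
#' @return list with `prediction` (prediction table), `linkage` (linkage
#'   table), and `truth` (lineage frame with `contig_id`).
#' @export
simulate_host_assignments <- function(n_contigs, cfg,
                                      true_lineages = NULL,
                                      contig_ids = NULL) {
  stopifnot(inherits(cfg, "phf_cohort_config"))
  taxonomy <- make_taxonomy(cfg$n_families, cfg$genera_per_family)
  if (is.null(contig_ids)) {
    contig_ids <- sprintf("votu_%05d", seq_len(n_contigs))
  }
  if (is.null(true_lineages)) {
    true_lineages <- taxonomy[sample(nrow(taxonomy), n_contigs,
                                     replace = TRUE), , drop = FALSE]
    rownames(true_lineages) <- NULL
  }
  pred_rows <- list()
  link_rows <- list()
  for (i in seq_len(n_contigs)) {
    truth <- true_lineages[i, , drop = FALSE]
    # Hi-C: top hit plus occasional extra hosts
    top_hic <- corrupt_lineage(truth, taxonomy, cfg$hic_error)
    hic <- cbind(data.frame(contig_id = contig_ids[[i]],
                            stringsAsFactors = FALSE),
                 top_hic, link_rank = 1L)
    if (stats::runif(1) < cfg$hic_multi_host_rate) {
      n_extra <- 1L + stats::rpois(1, cfg$hic_multi_host_lambda)
      others <- taxonomy[taxonomy$genus != top_hic$genus, , drop = FALSE]
      extra <- others[sample(nrow(others), min(n_extra, nrow(others))), ,
                      drop = FALSE]
      extra_df <- cbind(data.frame(contig_id = contig_ids[[i]],
                                   stringsAsFactors = FALSE),
                        extra, link_rank = 1L + seq_len(nrow(extra)))
      hic <- rbind(hic, extra_df)
    }
    link_rows[[length(link_rows) + 1L]] <- hic
    # predictions for the predicted fraction only
    if (stats::runif(1) >= cfg$p_predicted) next
    primary <- corrupt_lineage(truth, taxonomy, cfg$pred_error)
    depth1 <- attr(primary, "corruption_depth") %||% (length(PHF_RANKS) + 1L)
    conf1 <- 100 * (1 - 0.05 * (length(PHF_RANKS) + 1L - depth1)) +
      stats::runif(1, -2, 2)
    preds <- cbind(data.frame(contig_id = contig_ids[[i]],
                              stringsAsFactors = FALSE),
                   primary, confidence = min(100, max(0, conf1)))
    if (stats::runif(1) < cfg$multi_prediction_rate) {
      n_extra <- 1L + stats::rpois(1, cfg$multi_prediction_lambda)
      for (k in seq_len(n_extra)) {
        extra <- corrupt_lineage(truth, taxonomy, cfg$extra_pred_error)
        depth_k <- attr(extra, "corruption_depth") %||%
          (length(PHF_RANKS) + 1L)
        conf_k <- 100 * (1 - 0.05 * (length(PHF_RANKS) + 1L - depth_k)) -
          8 * k + stats::runif(1, -2, 2)
        preds <- rbind(preds,
                       cbind(data.frame(contig_id = contig_ids[[i]],
                                        stringsAsFactors = FALSE),
                             extra,
                             confidence = min(100, max(0, conf_k))))
      }
    }
    pred_rows[[length(pred_rows) + 1L]] <- preds
  }
  empty_tab <- function(extra_col, extra_val) {
    out <- cbind(data.frame(contig_id = character(0),
                            stringsAsFactors = FALSE),
                 empty_lineage_frame(0))
    out[[extra_col]] <- extra_val
    out
  }
  prediction <- if (length(pred_rows)) do.call(rbind, pred_rows)
                else empty_tab("confidence", numeric(0))
  linkage <- if (length(link_rows)) do.call(rbind, link_rows)
             else empty_tab("link_rank", integer(0))
  rownames(prediction) <- rownames(linkage) <- NULL
  truth <- cbind(data.frame(contig_id = contig_ids,
                            stringsAsFactors = FALSE), true_lineages)
  rownames(truth) <- NULL
  list(prediction = prediction, linkage = linkage, truth = truth)
}

#' First-order autoregressive log-abundance fluctuations
#'
#' Stationary AR(1) series with marginal standard deviation `sigma` and
#' lag-1 autocorrelation `persistence`; the within-individual temporal
#' model of [generate_cohort()].
#'
#' @param n series length.
#' @param persistence lag-1 autocorrelation in `[0, 1)`.
#' @param sigma stationary standard deviation.
#' @return numeric vector of length `n`.
#' @export
simulate_ar1 <- function(n, persistence, sigma) {
  stopifnot(n >= 1, persistence >= 0, persistence < 1, sigma >= 0)
  x <- numeric(n)
  x[1L] <- stats::rnorm(1, 0, sigma)
  if (n > 1L) {
    innov_sd <- sigma * sqrt(1 - persistence^2)
    for (t in 2:n) {
      x[t] <- persistence * x[t - 1L] + stats::rnorm(1, 0, innov_sd)
    }
  }
  x
}

#' Generate a synthetic longitudinal virome cohort
#'
#' Produces every table the pipeline consumes, plus ground truth, from one
#' seed:
#' * a cohort-level host-family profile is drawn once, and each
#'   individual's family profile from a Dirichlet centred on it, so
#'   individuals resemble each other at the family level;
#' * each individual's vOTUs are mostly private (a `shared_votu_fraction`
#'   of each family's pool is cohort-shared), so contig-level overlap
#'   between individuals is low;
#' * within-individual dynamics follow a stationary AR(1) process on log
#'   abundances ([simulate_ar1()]), and read counts are drawn
#'   negative-binomially under the depth model (zeros are real zeros);
#' * host predictions and Hi-C links are derived from the true lineages
#'   with the configured per-rank corruption
#'   ([simulate_host_assignments()]);
#' * a random rooted tree with positive branch lengths is drawn over the
#'   host families.
#'
#' The same seed yields a byte-identical cohort.
#'
#' @param cfg a [cohort_config()].
#' @return a `phf_cohort` list: `prediction`, `linkage`, `abundance` (raw
#'   counts with feature and sample metadata), `tree` (family-level
#'   `phylo`), and `truth` (contig lineages, per-individual family
#'   profiles, the config).
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "phf_cohort_config"))
  withr::with_seed(cfg$seed, generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  taxonomy <- make_taxonomy(cfg$n_families, cfg$genera_per_family)
  fams <- unique(taxonomy$family)
  nf <- length(fams)
  inds <- sprintf("I%02d", seq_len(cfg$n_individuals))
  tt <- cfg$samples_per_individual

  # cohort-level family profile and per-individual Dirichlet draws
  base <- rgamma_dirichlet(rep(1, nf))
  profiles <- t(vapply(inds, function(i)
    rgamma_dirichlet(cfg$family_profile_concentration * nf * base + 1e-3),
    numeric(nf)))
  dimnames(profiles) <- list(inds, fams)

  # vOTU pools: per family, a shared slice plus per-individual private
  # contigs
  k <- cfg$votus_per_family_per_individual
  n_shared <- round(cfg$shared_votu_fraction * k)
  pool <- list()        # per individual: character vector of contig ids
  contig_family <- character(0)
  shared_ids <- list()
  for (f in seq_len(nf)) {
    sid <- if (n_shared > 0) sprintf("votu_shared_%03d_%02d", f,
                                     seq_len(n_shared)) else character(0)
    shared_ids[[f]] <- sid
    contig_family[sid] <- fams[[f]]
  }
  for (i in inds) {
    ids <- character(0)
    for (f in seq_len(nf)) {
      priv <- if (k - n_shared > 0) {
        sprintf("votu_%s_%03d_%02d", i, f, seq_len(k - n_shared))
      } else character(0)
      contig_family[priv] <- fams[[f]]
      ids <- c(ids, shared_ids[[f]], priv)
    }
    pool[[i]] <- ids
  }
  contigs <- names(contig_family)
  nc <- length(contigs)

  # true genus within the contig's family
  gidx <- vapply(contig_family, function(f) {
    rows <- which(taxonomy$family == f)
    rows[sample.int(length(rows), 1L)]
  }, integer(1))
  true_lineages <- taxonomy[gidx, , drop = FALSE]
  rownames(true_lineages) <- NULL

  # per-individual, per-contig expected abundance with AR(1) dynamics
  sample_ids <- as.vector(vapply(inds, function(i)
    sprintf("%s_T%02d", i, seq_len(tt)), character(tt)))
  expected <- matrix(0, nrow = nc, ncol = length(sample_ids),
                     dimnames = list(contigs, sample_ids))
  contig_w <- stats::setNames(stats::rlnorm(nc, 0, 1), contigs)
  fam_of <- contig_family
  for (i in inds) {
    cols <- sprintf("%s_T%02d", i, seq_len(tt))
    for (cid in pool[[i]]) {
      x <- simulate_ar1(tt, cfg$ar_persistence, cfg$lognormal_sigma)
      expected[cid, cols] <- profiles[i, fam_of[[cid]]] / k *
        contig_w[[cid]] * exp(x)
    }
  }
  # negative-binomial counts under the depth model
  p <- sweep(expected, 2, colSums(expected), "/")
  counts <- matrix(stats::rnbinom(length(p),
                                  mu = as.vector(p) * cfg$depth_mean,
                                  size = cfg$depth_dispersion),
                   nrow = nc, dimnames = dimnames(p))
  # guard against the (rare) all-zero sample: give its most expected
  # feature a single read so compositions stay defined
  zero <- which(colSums(counts) == 0)
  for (j in zero) counts[which.max(p[, j]), j] <- 1

  # feature metadata
  len <- pmax(1500, round(stats::rlnorm(nc, log(10000), 0.6)))
  prophage <- stats::runif(nc) < 0.234
  amg <- stats::rpois(nc, len / 1e6 * ifelse(prophage, 18.5, 12.3))
  feature_meta <- data.frame(feature_id = contigs, length_bp = len,
                             prophage = prophage, amg_count = amg,
                             completeness = round(stats::runif(nc, 50, 100),
                                                  1),
                             stringsAsFactors = FALSE)
  diagnosis <- stats::setNames(
    sample(names(cfg$diagnosis_probs), cfg$n_individuals, replace = TRUE,
           prob = cfg$diagnosis_probs), inds)
  sample_meta <- data.frame(
    sample_id = sample_ids,
    individual_id = rep(inds, each = tt),
    time_index = rep(seq_len(tt), times = cfg$n_individuals),
    diagnosis = diagnosis[rep(inds, each = tt)],
    dysbiotic = stats::runif(length(sample_ids)) < cfg$dysbiosis_rate,
    stringsAsFactors = FALSE)
  rownames(sample_meta) <- NULL
  abundance <- phf_abundance(counts, feature_meta, sample_meta)

  assignments <- simulate_host_assignments(nc, cfg,
                                           true_lineages = true_lineages,
                                           contig_ids = contigs)
  tree <- ape::rtree(nf, tip.label = sample(fams), rooted = TRUE)

  truth <- list(lineages = assignments$truth,
                contig_family = contig_family,
                family_profiles = profiles,
                config = cfg)
  structure(list(prediction = assignments$prediction,
                 linkage = assignments$linkage,
                 abundance = abundance,
                 tree = tree,
                 truth = truth),
            class = "phf_cohort")
}

rgamma_dirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' @export
print.phf_cohort <- function(x, ...) {
  cat("phf_cohort: ", nrow(x$abundance$values), " contigs, ",
      ncol(x$abundance$values), " samples, ",
      length(unique(x$truth$contig_family)), " host families\n", sep = "")
  cat("  predictions: ", nrow(x$prediction), " rows over ",
      length(unique(x$prediction$contig_id)), " contigs\n", sep = "")
  cat("  Hi-C links: ", nrow(x$linkage), " rows over ",
      length(unique(x$linkage$contig_id)), " contigs\n", sep = "")
  invisible(x)
}

#' Plant an exact number of prevalent features
#'
#' Builds a PHF-level abundance table in which exactly `k_prevalent` of
#' `cfg$n_families` features occur in strictly more than half of the
#' individuals (in all samples of their chosen individuals), and every
#' other feature in at most half. Ground truth for testing the prevalence
#' logic.
#'
#' @param cfg a [cohort_config()] (uses `n_individuals`,
#'   `samples_per_individual`, `n_families`, `seed`).
#' @param k_prevalent how many features to plant above 50% prevalence.
#' @return list with `abundance` (a PHF-level [phf_abundance()]) and
#'   `planted` (the planted feature ids).
#' @export
plant_prevalence <- function(cfg, k_prevalent) {
  stopifnot(inherits(cfg, "phf_cohort_config"),
            k_prevalent >= 0, k_prevalent <= cfg$n_families)
  withr::with_seed(cfg$seed + 1L, {
    n <- cfg$n_individuals
    tt <- cfg$samples_per_individual
    fams <- sprintf("Family_%03d", seq_len(cfg$n_families))
    planted <- fams[seq_len(k_prevalent)]
    inds <- sprintf("I%02d", seq_len(n))
    sample_ids <- as.vector(vapply(inds, function(i)
      sprintf("%s_T%02d", i, seq_len(tt)), character(tt)))
    m <- matrix(0, nrow = length(fams), ncol = length(sample_ids),
                dimnames = list(fams, sample_ids))
    half <- n %/% 2L
    for (f in fams) {
      pos_range <- if (f %in% planted) (half + 1L):n else 0:half
      n_pos <- pos_range[sample.int(length(pos_range), 1L)]
      if (n_pos == 0L) next
      chosen <- sample(inds, n_pos)
      cols <- as.vector(vapply(chosen, function(i)
        sprintf("%s_T%02d", i, seq_len(tt)), character(tt)))
      m[f, cols] <- stats::rlnorm(length(cols), 0, 1)
    }
    sample_meta <- data.frame(sample_id = sample_ids,
                              individual_id = rep(inds, each = tt),
                              time_index = rep(seq_len(tt), times = n),
                              stringsAsFactors = FALSE)
    list(abundance = phf_abundance(m, sample_meta = sample_meta),
         planted = planted)
  })
}
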