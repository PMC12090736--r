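# Ecological distances (Bray-Curtis via vegan; UniFrac computed from
# branch proportions), inter/intra-individual partitioning, longitudinal
# stability, and the matched-metric statistical comparisons.

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`, bounded in `[0, 1]`. Both vectors must use
#' the same feature order; two all-zero vectors have no defined
#' dissimilarity.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return dissimilarity in `[0, 1]`.
#' @export
#' @examples
#' bray_curtis(c(2, 2), c(1, 3))  # 2/8 = 0.25
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  tot <- sum(x) + sum(y)
  if (tot <= 0) stop("both vectors are all-zero", call. = FALSE)
  sum(abs(x - y)) / tot
}

# mass of each sample under each edge of the tree: edges x samples matrix,
# rows aligned to tree$edge. Computed once per table, then any pairwise
# UniFrac is a weighted column comparison.
edge_masses <- function(tree, values) {
  tips <- tree$tip.label
  missing <- setdiff(rownames(values), tips)
  if (length(missing)) {
    stop("feature(s) without a tree tip: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  ntip <- length(tips)
  nnode <- tree$Nnode
  nmass <- matrix(0, nrow = ntip + nnode, ncol = ncol(values))
  nmass[match(rownames(values), tips), ] <- values
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L]
    child <- po$edge[e, 2L]
    nmass[parent, ] <- nmass[parent, ] + nmass[child, ]
  }
  # back in the original edge order
  nmass[tree$edge[, 2L], , drop = FALSE]
}

#' UniFrac distance between two samples
#'
#' Phylogenetic beta-diversity over a rooted host tree. Unweighted UniFrac
#' is the fraction of branch length leading to taxa found in exactly one
#' of the two samples, out of the branch length leading to taxa found in
#' either. Weighted UniFrac (the normalized variant) is
#' `sum(L_b * |p_b(x) - p_b(y)|) / sum(L_b * (p_b(x) + p_b(y)))`, where
#' `p_b` is the proportion of a sample's total abundance descending from
#' branch `b`. Both lie in `[0, 1]`.
#'
#' @param tree rooted `phylo` tree with non-negative branch lengths whose
#'   tips cover the feature names.
#' @param x,y named non-negative abundance vectors (names are tree tips;
#'   tips absent from a vector count as zero).
#' @param weighted compute the abundance-weighted variant.
#' @return distance in `[0, 1]`.
#' @export
unifrac <- function(tree, x, y, weighted = FALSE) {
  validate_host_tree(tree)
  if (is.null(names(x)) || is.null(names(y))) {
    stop("abundance vectors must be named by tree tip", call. = FALSE)
  }
  if (sum(x) <= 0 || sum(y) <= 0) {
    stop("each sample needs positive total abundance", call. = FALSE)
  }
  feats <- union(names(x), names(y))
  m <- matrix(0, nrow = length(feats), ncol = 2,
              dimnames = list(feats, c("x", "y")))
  m[names(x), 1L] <- x
  m[names(y), 2L] <- y
  em <- edge_masses(tree, m)
  L <- tree$edge.length
  if (weighted) {
    px <- em[, 1L] / sum(x)
    py <- em[, 2L] / sum(y)
    sum(L * abs(px - py)) / sum(L * (px + py))
  } else {
    inx <- em[, 1L] > 0
    iny <- em[, 2L] > 0
    denom <- sum(L[inx | iny])
    if (denom <= 0) stop("no branch length under either sample",
                         call. = FALSE)
    sum(L[xor(inx, iny)]) / denom
  }
}

#' Prune a reference host tree to one tip per family
#'
#' Family-agglomerated tables are scored against a genome-level reference
#' tree by collapsing the tree to one representative tip per host family:
#' the first tip encountered in a deterministic preorder (cladewise)
#' traversal whose family annotation matches, relabelled with the family
#' name. Callers with a purpose-built family-level tree can skip this and
#' pass that tree directly.
#'
#' @param tree rooted `phylo` reference tree.
#' @param tip_families named character vector mapping tip labels to family
#'   names; tips with no (or empty) family are never chosen.
#' @return a `phylo` tree whose tips are family names.
#' @export
prune_tree_to_families <- function(tree, tip_families) {
  validate_host_tree(tree)
  if (is.null(names(tip_families))) {
    stop("tip_families must be named by tip label", call. = FALSE)
  }
  po <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  tip_seq <- po$edge[po$edge[, 2L] <= ntip, 2L]
  tips_in_order <- tree$tip.label[tip_seq]
  fams <- tip_families[tips_in_order]
  ok <- !is.na(fams) & nzchar(fams)
  reps <- tips_in_order[ok][!duplicated(fams[ok])]
  if (length(reps) < 2L) {
    stop("fewer than two families have a representative tip",
         call. = FALSE)
  }
  pruned <- ape::keep.tip(tree, reps)
  pruned$tip.label <- unname(tip_families[pruned$tip.label])
  pruned
}

#' All pairwise sample distances
#'
#' Builds the full symmetric sample-by-sample distance matrix under one
#' metric. Bray-Curtis goes through [vegan::vegdist()]; the UniFrac
#' metrics reuse one branch-mass computation across all pairs. Distances
#' are intended for relative abundances ([to_relative_abundance()]), with
#' the unknown-host fraction dropped first for PHF-level tables
#' ([drop_unknown()]).
#'
#' @param t a [phf_abundance()] object.
#' @param metric `"bray_curtis"`, `"unifrac_unweighted"`, or
#'   `"unifrac_weighted"`.
#' @param tree rooted host tree; required for the UniFrac metrics, whose
#'   tips must cover the feature ids.
#' @return symmetric numeric matrix with zero diagonal and a `"metric"`
#'   attribute.
#' @export
distance_matrix <- function(t, metric = c("bray_curtis",
                                          "unifrac_unweighted",
                                          "unifrac_weighted"),
                            tree = NULL) {
  stopifnot(inherits(t, "phf_abundance"))
  metric <- match.arg(metric)
  v <- t$values
  n <- ncol(v)
  if (metric == "bray_curtis") {
    d <- as.matrix(vegan::vegdist(t(v), method = "bray"))
  } else {
    if (is.null(tree)) stop("UniFrac needs a host tree", call. = FALSE)
    validate_host_tree(tree)
    totals <- colSums(v)
    if (any(totals <= 0)) {
      stop("sample(s) with zero total abundance", call. = FALSE)
    }
    em <- edge_masses(tree, v)
    L <- tree$edge.length
    d <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
    if (metric == "unifrac_weighted") {
      p <- sweep(em, 2, totals, "/")
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          val <- sum(L * abs(p[, i] - p[, j])) /
            sum(L * (p[, i] + p[, j]))
          d[i, j] <- d[j, i] <- val
        }
      }
    } else {
      pres <- em > 0
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          either <- pres[, i] | pres[, j]
          val <- sum(L[xor(pres[, i], pres[, j])]) / sum(L[either])
          d[i, j] <- d[j, i] <- val
        }
      }
    }
  }
  attr(d, "metric") <- metric
  d
}

#' Split pairwise distances into inter- and intra-individual sets
#'
#' Each unordered sample pair is counted once: pairs within one individual
#' are intra-individual, all others inter-individual.
#'
#' @param d symmetric distance matrix from [distance_matrix()].
#' @param sample_meta data.frame with `sample_id` and `individual_id`
#'   covering the matrix's samples.
#' @return list with numeric vectors `inter` and `intra` (named
#'   `"s1|s2"`).
#' @export
partition_distances <- function(d, sample_meta) {
  ids <- colnames(d)
  ind <- sample_meta$individual_id[match(ids, sample_meta$sample_id)]
  if (any(is.na(ind))) {
    stop("sample(s) missing from metadata: ",
         paste(utils::head(ids[is.na(ind)], 5), collapse = ", "),
         call. = FALSE)
  }
  n <- length(ids)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  vals <- d[pairs]
  nm <- paste(ids[pairs[, 1L]], ids[pairs[, 2L]], sep = "|")
  same <- ind[pairs[, 1L]] == ind[pairs[, 2L]]
  list(inter = stats::setNames(vals[!same], nm[!same]),
       intra = stats::setNames(vals[same], nm[same]))
}

#' Longitudinal virome stability per individual
#'
#' Stability is `1 - distance` between consecutively collected samples of
#' the same individual, consecutive in collection order (`time_index`),
#' not calendar spacing — an individual sampled at times 1, 2, 4
#' contributes the pairs (1,2) and (2,4). Individuals with fewer than two
#' samples contribute nothing.
#'
#' @param d symmetric distance matrix over the samples.
#' @param sample_meta data.frame with `sample_id`, `individual_id`,
#'   `time_index` (unique within an individual).
#' @return data.frame with columns `individual_id`, `from_sample`,
#'   `to_sample`, `from_time`, `to_time`, `distance`, `stability`.
#' @export
stability_series <- function(d, sample_meta) {
  need <- c("sample_id", "individual_id", "time_index")
  stopifnot(all(need %in% names(sample_meta)))
  meta <- sample_meta[sample_meta$sample_id %in% colnames(d), , drop = FALSE]
  out <- list()
  for (ind in unique(meta$individual_id)) {
    rows <- meta[meta$individual_id == ind, , drop = FALSE]
    if (anyDuplicated(rows$time_index)) {
      stop("duplicate time_index for individual ", ind, call. = FALSE)
    }
    rows <- rows[order(rows$time_index), , drop = FALSE]
    if (nrow(rows) < 2L) next
    from <- rows$sample_id[-nrow(rows)]
    to <- rows$sample_id[-1L]
    dist <- d[cbind(from, to)]
    out[[length(out) + 1L]] <- data.frame(
      individual_id = ind, from_sample = from, to_sample = to,
      from_time = rows$time_index[-nrow(rows)],
      to_time = rows$time_index[-1L],
      distance = dist, stability = 1 - dist,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(individual_id = character(0),
                      from_sample = character(0), to_sample = character(0),
                      from_time = numeric(0), to_time = numeric(0),
                      distance = numeric(0), stability = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Compare matched distance sets across metrics
#'
#' Tests whether matched distance values (the same sample pairs measured
#' under different metrics/levels, e.g. contig-level Bray-Curtis vs
#' PHF-level Bray-Curtis vs PHF-level weighted UniFrac) differ: a
#' Friedman test across all groups, then pairwise Wilcoxon signed-rank
#' tests with Bonferroni correction (each p multiplied by the number of
#' pairwise tests performed, capped at 1). Median paired differences give
#' the effect direction. Pairs where every difference is zero get p = 1.
#'
#' @param value_sets named list of `>= 2` numeric vectors of equal length,
#'   matched elementwise.
#' @param alternative passed to [stats::wilcox.test()]; default
#'   two-sided.
#' @return list with `friedman` (`statistic`, `df`, `p_value`; `NULL`
#'   when only two groups) and `pairwise` (data.frame `group_a`,
#'   `group_b`, `median_diff`, `p_value`, `p_adjusted`).
#' @export
compare_metrics_matched <- function(value_sets, alternative = "two.sided") {
  stopifnot(is.list(value_sets), length(value_sets) >= 2L,
            !is.null(names(value_sets)))
  lens <- lengths(value_sets)
  if (length(unique(lens)) != 1L) {
    stop("value sets are not matched: lengths ",
         paste(lens, collapse = ", "), call. = FALSE)
  }
  m <- do.call(cbind, value_sets)
  friedman <- NULL
  if (length(value_sets) >= 3L) {
    ft <- stats::friedman.test(m)
    stat <- unname(ft$statistic)
    pv <- ft$p.value
    if (is.nan(stat)) {           # all ranks tied in every block
      stat <- 0
      pv <- 1
    }
    friedman <- list(statistic = stat, df = unname(ft$parameter),
                     p_value = pv)
  }
  combos <- utils::combn(names(value_sets), 2, simplify = FALSE)
  n_tests <- length(combos)
  pw <- lapply(combos, function(pair) {
    a <- value_sets[[pair[1L]]]
    b <- value_sets[[pair[2L]]]
    diffs <- a - b
    p <- if (all(diffs == 0)) 1 else {
      suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                          alternative = alternative)$p.value)
    }
    data.frame(group_a = pair[1L], group_b = pair[2L],
               median_diff = stats::median(diffs), p_value = p,
               stringsAsFactors = FALSE)
  })
  pairwise <- do.call(rbind, pw)
  pairwise$p_adjusted <- pmin(1, pairwise$p_value * n_tests)
  list(friedman = friedman, pairwise = pairwise)
}

#' Correlate PHF abundances with their bacterial host families
#'
#' Pairs each PHF (named in the prediction namespace, e.g. GTDB) with its
#' bacterial family in the profiling namespace (e.g. NCBI) through a
#' fraction-mapping table at the given threshold, then computes Spearman's
#' rank correlation of their relative abundances across shared samples.
#' p-values are Benjamini-Hochberg adjusted across all tested pairs;
#' constant vectors have no defined rank correlation and are flagged
#' `excluded`.
#'
#' @param phf_abund PHF-level [phf_abundance()] (features = family names
#'   in the source namespace).
#' @param host_abund bacterial family [phf_abundance()] (features = family
#'   names in the target namespace).
#' @param map namespace mapping table ([read_namespace_map()]).
#' @param threshold fraction-mapping acceptance threshold (default 0.6).
#' @param alpha adjusted-p significance cutoff (default 0.05).
#' @return data.frame with `phf`, `host_family`, `n_samples`, `rho`,
#'   `p_value`, `p_adjusted`, `significant`, `excluded`.
#' @export
correlate_phf_host <- function(phf_abund, host_abund, map, threshold = 0.6,
                               alpha = 0.05) {
  stopifnot(inherits(phf_abund, "phf_abundance"),
            inherits(host_abund, "phf_abundance"))
  shared <- intersect(sample_ids(phf_abund), sample_ids(host_abund))
  if (length(shared) < 3L) {
    stop("need at least 3 shared samples", call. = FALSE)
  }
  rows <- list()
  for (fam in feature_ids(phf_abund)) {
    target <- map_name(map, fam, threshold = threshold)
    if (is.na(target) || !target %in% feature_ids(host_abund)) next
    x <- phf_abund$values[fam, shared]
    y <- host_abund$values[target, shared]
    constant <- stats::sd(x) == 0 || stats::sd(y) == 0
    if (constant) {
      rows[[length(rows) + 1L]] <- data.frame(
        phf = fam, host_family = target, n_samples = length(shared),
        rho = NA_real_, p_value = NA_real_, excluded = TRUE,
        stringsAsFactors = FALSE)
    } else {
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                             exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        phf = fam, host_family = target, n_samples = length(shared),
        rho = unname(ct$estimate), p_value = ct$p.value, excluded = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(phf = character(0), host_family = character(0),
                      n_samples = integer(0), rho = numeric(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      significant = logical(0), excluded = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  tested <- !out$excluded
  out$p_adjusted[tested] <- stats::p.adjust(out$p_value[tested],
                                            method = "BH")
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted <= alpha
  out
}
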