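# vOTU -> PHF transformations: best-prediction selection, family-level
# agglomeration, the sample filters, presence calling, dereplication,
# prevalence and AMG density summaries.

#' Assign one predicted host family per contig
#'
#' When a contig has more than one predicted host, the most confident
#' prediction is kept (maximum confidence; ties broken by the
#' lexicographically smallest serialized lineage, so the result is
#' deterministic). Contigs in `contigs` absent from the prediction table —
#' or whose best prediction carries no family name — get `"Unknown"`.
#'
#' @param pred prediction table ([read_prediction_table()] shape).
#' @param contigs contig ids to assign; defaults to those in `pred`.
#' @return a `phf_assignment` data.frame: `contig_id`, `phf` (family name
#'   or `"Unknown"`), `confidence` (`NA` for unknowns).
#' @export
assign_phf <- function(pred, contigs = NULL) {
  if (is.null(contigs)) contigs <- unique(pred$contig_id)
  contigs <- as.character(contigs)
  best <- order_predictions(pred)
  best <- best[!duplicated(best$contig_id), , drop = FALSE]
  idx <- match(contigs, best$contig_id)
  fam <- best$family[idx]
  conf <- best$confidence[idx]
  unknown <- is.na(fam) | !nzchar(fam)
  fam[unknown] <- "Unknown"
  conf[unknown] <- NA_real_
  out <- data.frame(contig_id = contigs, phf = fam, confidence = conf,
                    stringsAsFactors = FALSE)
  class(out) <- c("phf_assignment", "data.frame")
  out
}

assignment_lookup <- function(assign, ids) {
  fam <- assign$phf[match(ids, assign$contig_id)]
  fam[is.na(fam)] <- "Unknown"
  fam
}

#' Convert counts to relative abundance
#'
#' Divides every sample (column) by its total so columns sum to 1. A
#' zero-sum sample has no defined composition and is an error.
#'
#' @param t a [phf_abundance()] object.
#' @return a [phf_abundance()] object of per-sample proportions.
#' @export
to_relative_abundance <- function(t) {
  stopifnot(inherits(t, "phf_abundance"))
  totals <- colSums(t$values)
  zero <- colnames(t$values)[totals <= 0]
  if (length(zero)) {
    stop("sample(s) with zero total abundance: ",
         paste(utils::head(zero, 5), collapse = ", "), call. = FALSE)
  }
  out <- t
  out$values <- sweep(t$values, 2, totals, "/")
  out
}

#' Filter samples by their unknown-host community fraction
#'
#' Retains samples where the summed relative abundance of features with no
#' assigned host family is strictly below `max_unknown` (default 30%).
#' Comparing samples dominated by unassigned contigs against well-resolved
#' ones would bias community comparisons, so such samples are dropped
#' before PHF-level analysis.
#'
#' @param t a relative-abundance [phf_abundance()] object (column sums 1).
#' @param assign a `phf_assignment` from [assign_phf()].
#' @param max_unknown strict upper bound on the unknown fraction.
#' @return filtered [phf_abundance()]; empty (with a warning) if no sample
#'   passes.
#' @export
filter_unknown_fraction <- function(t, assign, max_unknown = 0.30) {
  stopifnot(inherits(t, "phf_abundance"))
  fam <- assignment_lookup(assign, feature_ids(t))
  unknown_mass <- colSums(t$values[fam == "Unknown", , drop = FALSE])
  keep <- unknown_mass < max_unknown
  if (!any(keep)) {
    warning("no samples pass the unknown-host fraction filter",
            call. = FALSE)
  }
  t[, keep]
}

#' Agglomerate features to predicted host families
#'
#' Sums abundances over all features sharing a predicted host family,
#' yielding one feature per distinct PHF (including `"Unknown"` when
#' present). Per-sample totals are conserved exactly, and applying the
#' operation twice is a no-op. Output features are ordered alphabetically.
#' The agglomerated feature metadata carries the family name as both
#' `feature_id` and `phf`, the number of member features, and (when input
#' lengths are available) the summed member length.
#'
#' @param t a [phf_abundance()] object (counts or relative abundance).
#' @param assign a `phf_assignment`; features absent from it are treated
#'   as `"Unknown"`.
#' @return a PHF-level [phf_abundance()] object.
#' @export
agglomerate_phf <- function(t, assign) {
  stopifnot(inherits(t, "phf_abundance"))
  fam <- assignment_lookup(assign, feature_ids(t))
  v <- rowsum(t$values, group = fam, reorder = TRUE)
  fmeta <- data.frame(feature_id = rownames(v), phf = rownames(v),
                      n_members = as.integer(table(fam)[rownames(v)]),
                      stringsAsFactors = FALSE)
  if ("length_bp" %in% names(t$feature_meta)) {
    fmeta$length_bp <- as.numeric(
      rowsum(as.numeric(t$feature_meta$length_bp), group = fam,
             reorder = TRUE))
  }
  phf_abundance(v, fmeta, t$sample_meta)
}

#' Drop the unknown-host fraction of a table
#'
#' Removes features assigned `"Unknown"` (or, at PHF level, the
#' `"Unknown"` pseudo-family) before distance or prevalence analysis,
#' optionally renormalizing the remaining composition to sum to 1 per
#' sample. The unknown fraction participates in [to_relative_abundance()]
#' and [filter_unknown_fraction()], but community comparisons are made on
#' the assigned fraction.
#'
#' @param t a [phf_abundance()] object.
#' @param assign optional `phf_assignment`; if `NULL`, features whose id
#'   (or `phf` metadata) equals `"Unknown"` are dropped.
#' @param renormalize rescale each sample to sum to 1 after dropping.
#' @return a [phf_abundance()] object.
#' @export
drop_unknown <- function(t, assign = NULL, renormalize = TRUE) {
  stopifnot(inherits(t, "phf_abundance"))
  fam <- if (!is.null(assign)) {
    assignment_lookup(assign, feature_ids(t))
  } else if ("phf" %in% names(t$feature_meta)) {
    t$feature_meta$phf
  } else {
    feature_ids(t)
  }
  out <- t[fam != "Unknown", ]
  if (renormalize) out <- to_relative_abundance(out)
  out
}

#' Call vOTU presence from breadth of coverage
#'
#' Length-dependent breadth thresholds: a feature is present in a sample
#' when mapped reads cover at least 50% of contigs shorter than 5 kb, 30%
#' of contigs of 5 kb up to (excluding) 20 kb, or 10% of contigs of 20 kb
#' and longer.
#'
#' @param breadth numeric matrix of breadth-of-coverage proportions
#'   (features x samples), values in `[0, 1]`.
#' @param lengths named vector of feature lengths in bp covering every row
#'   of `breadth`.
#' @return logical matrix of the same shape.
#' @export
call_presence <- function(breadth, lengths) {
  stopifnot(is.matrix(breadth))
  if (any(breadth < 0 | breadth > 1, na.rm = TRUE)) {
    stop("breadth of coverage must lie in [0, 1]", call. = FALSE)
  }
  len <- lengths[rownames(breadth)]
  if (any(is.na(len))) {
    stop("missing length for feature(s): ",
         paste(utils::head(rownames(breadth)[is.na(len)], 5),
               collapse = ", "), call. = FALSE)
  }
  if (any(len <= 0)) stop("feature lengths must be positive", call. = FALSE)
  thr <- ifelse(len < 5000, 0.50, ifelse(len < 20000, 0.30, 0.10))
  breadth >= thr
}

#' Good's coverage of one sample
#'
#' `1 - f1/N`, where `f1` is the number of features observed exactly once
#' and `N` the total count: the estimated probability that one more read
#' belongs to an already-seen feature.
#'
#' @param counts non-negative integer count vector for one sample.
#' @return proportion in `[0, 1]`.
#' @export
#' @examples
#' goods_coverage(c(1, 4, 5))  # 1 - 1/10 = 0.9
goods_coverage <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- sum(counts)
  if (n <= 0) stop("total count is zero", call. = FALSE)
  1 - sum(counts == 1) / n
}

#' Drop samples with low length-normalized viral read counts
#'
#' A sample's depth is the sum over features of
#' `normalizer(reads, length_bp)`; with the default reads-per-kilobase
#' normalizer, `reads * 1000 / length_bp`. Samples strictly below
#' `min_count` (default 1,500) are dropped.
#'
#' @param t a raw-count [phf_abundance()] whose feature metadata has
#'   `length_bp`.
#' @param min_count minimum normalized depth to retain a sample.
#' @param normalizer `function(reads, length_bp)` returning per-feature
#'   normalized counts; the definition of "length-normalized" is
#'   convention, so it is pluggable.
#' @return filtered [phf_abundance()].
#' @export
filter_low_depth <- function(t, min_count = 1500,
                             normalizer = function(reads, length_bp)
                               reads * 1000 / length_bp) {
  stopifnot(inherits(t, "phf_abundance"))
  if (!"length_bp" %in% names(t$feature_meta)) {
    stop("feature metadata must carry length_bp", call. = FALSE)
  }
  len <- as.numeric(t$feature_meta$length_bp)
  norm <- colSums(normalizer(t$values, len))
  t[, norm >= min_count]
}

#' Filter features on a metadata column
#'
#' One-line metadata filter, e.g. keep contigs at least 50% complete:
#' `filter_feature_meta(t, "completeness", min = 50)`.
#'
#' @param t a [phf_abundance()] object.
#' @param column feature-metadata column name.
#' @param min inclusive lower bound on the column.
#' @return filtered [phf_abundance()].
#' @export
filter_feature_meta <- function(t, column, min) {
  stopifnot(inherits(t, "phf_abundance"))
  if (!column %in% names(t$feature_meta)) {
    stop("no feature-metadata column '", column, "'", call. = FALSE)
  }
  t[!is.na(t$feature_meta[[column]]) & t$feature_meta[[column]] >= min, ]
}

#' Greedy dereplication of contigs into vOTUs
#'
#' Clusters contigs from pairwise ANI / alignment-fraction hits using the
#' standard greedy longest-first rule: contigs are visited in order of
#' decreasing length (ties by id); each unassigned contig becomes a
#' cluster representative, and every later contig linked to it with
#' `ani >= min_ani` and `af >= min_af` joins that cluster. Membership is
#' only ever granted against representatives, so a chain a-b, b-c with a-c
#' failing yields clusters `{a, b}` and `{c}` when `a` is longest.
#'
#' @param hits data.frame with columns `query_id`, `target_id`, `ani`,
#'   `af` (both percentages); treated as symmetric.
#' @param lengths named numeric vector of contig lengths covering every id
#'   in `hits` and `ids`.
#' @param min_ani,min_af inclusive thresholds (defaults 95 and 85: 95%
#'   average nucleotide identity over 85% alignment fraction of the
#'   shorter sequence).
#' @param ids contigs to cluster; defaults to `names(lengths)`.
#' @return named character vector mapping each contig to its cluster
#'   representative (the vOTU id).
#' @export
dereplicate <- function(hits, lengths, min_ani = 95, min_af = 85,
                        ids = names(lengths)) {
  stopifnot(is.data.frame(hits),
            all(c("query_id", "target_id", "ani", "af") %in% names(hits)))
  if (is.null(names(lengths))) {
    stop("lengths must be a named vector", call. = FALSE)
  }
  unknown <- setdiff(unique(c(hits$query_id, hits$target_id)), names(lengths))
  if (length(unknown)) {
    stop("hit(s) reference unknown contig(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  pass <- hits[hits$ani >= min_ani & hits$af >= min_af, , drop = FALSE]
  # symmetrize the passing links
  edge <- unique(rbind(data.frame(a = pass$query_id, b = pass$target_id,
                                  stringsAsFactors = FALSE),
                       data.frame(a = pass$target_id, b = pass$query_id,
                                  stringsAsFactors = FALSE)))
  edge <- edge[edge$a != edge$b, , drop = FALSE]
  ids <- ids[order(-lengths[ids], ids)]
  rep_of <- stats::setNames(rep(NA_character_, length(ids)), ids)
  links <- split(edge$b, edge$a)
  for (id in ids) {
    if (!is.na(rep_of[[id]])) next
    rep_of[[id]] <- id
    linked <- links[[id]]
    if (!is.null(linked)) {
      joinable <- linked[linked %in% ids & is.na(rep_of[linked])]
      rep_of[joinable] <- id
    }
  }
  rep_of
}

#' Feature prevalence across individuals
#'
#' A feature is present in an individual when present in at least one of
#' that individual's samples; prevalence is the fraction of individuals
#' with the feature. On an abundance table, presence means a value `> 0`
#' (use [call_presence()] first for breadth-based calls).
#'
#' @param x a [phf_abundance()] object, or a logical/numeric matrix
#'   (features x samples) together with `individuals`.
#' @param individuals individual id per column; taken from sample metadata
#'   for a `phf_abundance`.
#' @return named numeric vector of prevalences in `[0, 1]`.
#' @export
prevalence <- function(x, individuals = NULL) {
  if (inherits(x, "phf_abundance")) {
    individuals <- x$sample_meta$individual_id
    x <- x$values
  }
  stopifnot(is.matrix(x), !is.null(individuals),
            length(individuals) == ncol(x))
  present <- x > 0
  by_ind <- vapply(split(seq_len(ncol(x)), individuals),
                   function(cols) rowSums(present[, cols, drop = FALSE]) > 0,
                   logical(nrow(x)))
  if (is.null(dim(by_ind))) by_ind <- matrix(by_ind, nrow = 1)
  stats::setNames(rowMeans(by_ind), rownames(x))
}

#' @rdname prevalence
#' @param prev prevalence vector from `prevalence()`.
#' @param cutoff strict prevalence cutoff; "prevalent" means `> 0.5`.
#' @return `prevalent_features()`: character vector of feature ids with
#'   prevalence strictly above `cutoff`.
#' @export
prevalent_features <- function(prev, cutoff = 0.5) {
  names(prev)[prev > cutoff]
}

#' Community mass carried by prevalent features
#'
#' Per sample, the summed relative abundance of a set of (prevalent)
#' features, plus the cohort mean: how much of the community the widely
#' shared features account for.
#'
#' @param t a relative-abundance [phf_abundance()] object.
#' @param prevalent character vector of feature ids.
#' @return list with `per_sample` (named numeric) and `mean`.
#' @export
prevalent_mass <- function(t, prevalent) {
  stopifnot(inherits(t, "phf_abundance"))
  mass <- colSums(t$values[feature_ids(t) %in% prevalent, , drop = FALSE])
  list(per_sample = mass, mean = mean(mass))
}

#' AMG density per group
#'
#' Auxiliary metabolic genes per megabase of assembled sequence:
#' `sum(amg_count) / (sum(length_bp) / 1e6)` within each group (e.g.
#' prophage vs non-prophage vOTUs, or PHFs).
#'
#' @param amg_count AMG counts per feature.
#' @param length_bp feature lengths in bp.
#' @param group group label per feature.
#' @return named numeric vector, AMGs per Mb per group.
#' @export
#' @examples
#' amg_density(c(4, 20), c(5e5, 1.5e6), c("g", "g"))  # 24 / 2 Mb = 12
amg_density <- function(amg_count, length_bp, group) {
  stopifnot(length(amg_count) == length(length_bp),
            length(amg_count) == length(group))
  mb <- tapply(as.numeric(length_bp), group, sum) / 1e6
  if (any(mb <= 0)) {
    stop("group(s) with zero total length: ",
         paste(names(mb)[mb <= 0], collapse = ", "), call. = FALSE)
  }
  amg <- tapply(as.numeric(amg_count), group, sum)
  stats::setNames(as.numeric(amg / mb), names(mb))
}

#' Individuals with samples in both dysbiosis states
#'
#' For paired differential-abundance designs: keeps individuals with at
#' least one dysbiotic and one non-dysbiotic sample.
#'
#' @param sample_meta data.frame with `individual_id` and a logical
#'   `dysbiotic` column.
#' @return character vector of individual ids.
#' @export
select_paired_individuals <- function(sample_meta) {
  stopifnot(all(c("individual_id", "dysbiotic") %in% names(sample_meta)))
  states <- split(sample_meta$dysbiotic, sample_meta$individual_id)
  ok <- vapply(states, function(s) {
    s <- s[!is.na(s)]
    any(s) && any(!s)
  }, logical(1))
  names(states)[ok]
}
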