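# Per-rank, three-mode concordance between computationally predicted hosts
# and Hi-C proximity-ligation host assignments. The denominator is the set
# of contigs with hosts from both evidence sources; a missing name at a
# rank counts as discordant there (optionally dropped via drop_unranked).

CONCORDANCE_MODES <- c("strict", "top_vs_any", "any_vs_any")

#' Matching stringencies for host concordance
#'
#' The three rules for calling a contig's predicted and Hi-C hosts
#' concordant at a rank, from most to least stringent:
#' \describe{
#'   \item{strict}{the most confident prediction matches the top-ranked
#'     Hi-C hit.}
#'   \item{top_vs_any}{the most confident prediction matches any Hi-C hit.}
#'   \item{any_vs_any}{any prediction matches any Hi-C hit.}
#' }
#' @return character vector of mode names.
#' @export
concordance_modes <- function() CONCORDANCE_MODES

#' Contigs with hosts from both evidence sources
#'
#' The concordance denominator: contigs present in both the prediction and
#' the linkage table. An empty intersection is allowed but warned about
#' (the report then has `n_total = 0` and undefined percents).
#'
#' @param pred prediction table ([read_prediction_table()] shape).
#' @param link linkage table ([read_linkage_table()] shape).
#' @return character vector of contig ids.
#' @export
intersect_contigs <- function(pred, link) {
  both <- intersect(unique(pred$contig_id), unique(link$contig_id))
  if (length(both) == 0L) {
    warning("no contigs shared between prediction and linkage tables",
            call. = FALSE)
  }
  both
}

# order predictions by confidence descending, ties by lexicographically
# smallest serialized lineage (deterministic "most confident" selection);
# Hi-C rows by link_rank ascending
order_predictions <- function(pred) {
  pred[order(pred$contig_id, -pred$confidence, serialize_lineage(pred)), ,
       drop = FALSE]
}

order_linkages <- function(link) {
  link[order(link$contig_id, link$link_rank), , drop = FALSE]
}

#' Is one contig's host pairing concordant?
#'
#' Applies one matching stringency at one rank to a single contig's
#' ordered host lists. `pred_lineages` must be ordered by confidence
#' descending and `hic_lineages` by link rank (1 = strongest), as
#' [concordance_report()] arranges them.
#'
#' @param pred_lineages lineage frame of predicted hosts, most confident
#'   first.
#' @param hic_lineages lineage frame of Hi-C hosts, top hit first.
#' @param rank rank at which to compare (see [lineage_ranks()]).
#' @param mode one of [concordance_modes()].
#' @return single logical.
#' @export
is_concordant <- function(pred_lineages, hic_lineages, rank,
                          mode = c("strict", "top_vs_any", "any_vs_any")) {
  mode <- match.arg(mode)
  pred_lineages <- as_lineage_frame(pred_lineages)
  hic_lineages <- as_lineage_frame(hic_lineages)
  if (nrow(pred_lineages) == 0L || nrow(hic_lineages) == 0L) {
    stop("is_concordant requires non-empty host lists", call. = FALSE)
  }
  switch(mode,
    strict = names_match_at(pred_lineages[1L, , drop = FALSE],
                            hic_lineages[1L, , drop = FALSE], rank),
    top_vs_any = any(names_match_at(pred_lineages[1L, , drop = FALSE],
                                    hic_lineages, rank)),
    any_vs_any = {
      p <- pred_lineages[[rank]]
      h <- hic_lineages[[rank]]
      any(p[nzchar(p)] %in% h[nzchar(h)])
    })
}

#' Per-rank, per-mode host-prediction concordance report
#'
#' For every rank from phylum to genus and every matching stringency,
#' counts the contigs (among those with hosts from both sources) whose
#' predicted and Hi-C hosts agree, and reports
#' `percent = 100 * n_concordant / n_total`. "Most confident prediction"
#' is the maximum confidence score, ties broken by the lexicographically
#' smallest serialized lineage; "top Hi-C hit" is `link_rank == 1`.
#'
#' By default a contig whose Hi-C hosts all lack a name at a rank counts
#' as discordant at that rank (the denominator stays the total contig
#' count at every rank); `drop_unranked = TRUE` instead removes such
#' contigs from that rank's denominator.
#'
#' @param pred prediction table.
#' @param link linkage table.
#' @param drop_unranked drop contigs with no named Hi-C host at a rank
#'   from that rank's denominator instead of counting them discordant.
#' @return a `phf_concordance` object: a data.frame with columns `rank`,
#'   `mode`, `n_concordant`, `n_total`, `percent`, plus attributes
#'   `n_contigs_predicted`, `n_contigs_linked`, `n_contigs_both`.
#' @export
concordance_report <- function(pred, link, drop_unranked = FALSE) {
  contigs <- intersect_contigs(pred, link)
  p <- order_predictions(pred[pred$contig_id %in% contigs, , drop = FALSE])
  h <- order_linkages(link[link$contig_id %in% contigs, , drop = FALSE])
  p_top <- p[!duplicated(p$contig_id), , drop = FALSE]
  h_top <- h[!duplicated(h$contig_id), , drop = FALSE]  # lowest link_rank
  h_top <- h_top[match(p_top$contig_id, h_top$contig_id), , drop = FALSE]

  rows <- list()
  for (rank in COMPARISON_RANKS) {
    denom_ids <- contigs
    if (drop_unranked) {
      named <- tapply(nzchar(h[[rank]]), h$contig_id, any)
      denom_ids <- names(named)[named]
    }
    n_total <- length(denom_ids)
    # strict: top vs top, vectorized over contigs
    strict_ok <- p_top$contig_id[names_match_at(p_top, h_top, rank)]
    # top_vs_any: join top predictions with all Hi-C names at this rank
    hic_names <- h[nzchar(h[[rank]]), c("contig_id", rank)]
    top_named <- p_top[nzchar(p_top[[rank]]), c("contig_id", rank)]
    tva_ok <- unique(merge(top_named, hic_names,
                           by = c("contig_id", rank))$contig_id)
    # any_vs_any: join all prediction names with all Hi-C names
    all_named <- p[nzchar(p[[rank]]), c("contig_id", rank)]
    ava_ok <- unique(merge(all_named, hic_names,
                           by = c("contig_id", rank))$contig_id)
    counts <- c(strict = length(intersect(strict_ok, denom_ids)),
                top_vs_any = length(intersect(tva_ok, denom_ids)),
                any_vs_any = length(intersect(ava_ok, denom_ids)))
    for (mode in CONCORDANCE_MODES) {
      rows[[length(rows) + 1L]] <- data.frame(
        rank = rank, mode = mode,
        n_concordant = unname(counts[[mode]]), n_total = n_total,
        percent = if (n_total > 0) 100 * counts[[mode]] / n_total
                  else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_contigs_predicted") <- length(unique(pred$contig_id))
  attr(out, "n_contigs_linked") <- length(unique(link$contig_id))
  attr(out, "n_contigs_both") <- length(contigs)
  class(out) <- c("phf_concordance", "data.frame")
  out
}

#' @export
print.phf_concordance <- function(x, ...) {
  cat("Host-prediction concordance over ", attr(x, "n_contigs_both"),
      " contigs (", attr(x, "n_contigs_predicted"), " predicted, ",
      attr(x, "n_contigs_linked"), " Hi-C linked)\n", sep = "")
  df <- as.data.frame(x)
  df$percent <- ifelse(is.na(df$percent), "NA",
                       formatC(df$percent, format = "f", digits = 1))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Extract one concordance percentage
#'
#' Convenience accessor for a single (rank, mode) cell of a
#' [concordance_report()].
#'
#' @param report a `phf_concordance` object.
#' @param rank,mode the cell to extract.
#' @return percentage in `[0, 100]` (or `NA` if the denominator was 0).
#' @export
concordance_percent <- function(report, rank, mode) {
  row <- report$rank == rank & report$mode == mode
  if (!any(row)) stop("no such rank/mode in report", call. = FALSE)
  report$percent[row]
}
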