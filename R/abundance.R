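# feature x sample abundance container: a numeric matrix plus feature and
# sample metadata kept in matrix order. Deliberately lightweight (no S4);
# the matrix is always accessible as t$values.

#' Construct a feature-by-sample abundance table
#'
#' The central container of the pipeline: a non-negative numeric matrix
#' (features in rows, samples in columns) plus per-feature metadata
#' (typically `length_bp`, `phf`, `prophage`, `amg_count`) and per-sample
#' metadata (`individual_id`, `time_index`, optionally `diagnosis`,
#' `dysbiotic`). Metadata rows are aligned to matrix order; supplying
#' metadata for a different id set is an error, never a silent reorder.
#'
#' @param values numeric matrix with rownames (feature ids) and colnames
#'   (sample ids); all values must be `>= 0` and finite.
#' @param feature_meta data.frame with a `feature_id` column covering
#'   exactly the rownames of `values`. Defaults to ids only.
#' @param sample_meta data.frame with a `sample_id` column covering exactly
#'   the colnames of `values`, plus `individual_id`. `time_index` must be
#'   unique within an individual when present.
#' @return an object of class `phf_abundance`: a list with elements
#'   `values`, `feature_meta`, `sample_meta`.
#' @export
phf_abundance <- function(values, feature_meta = NULL, sample_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have feature rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicated feature id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicated sample id(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("abundance values must be finite and non-negative", call. = FALSE)
  }
  if (is.null(feature_meta)) {
    feature_meta <- data.frame(feature_id = rownames(values),
                               stringsAsFactors = FALSE)
  }
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = colnames(values),
                              individual_id = colnames(values),
                              stringsAsFactors = FALSE)
  }
  feature_meta <- align_meta(feature_meta, "feature_id", rownames(values),
                             "feature")
  sample_meta <- align_meta(sample_meta, "sample_id", colnames(values),
                            "sample")
  if (!"individual_id" %in% names(sample_meta)) {
    stop("sample_meta must have an individual_id column", call. = FALSE)
  }
  if (any(is.na(sample_meta$individual_id))) {
    stop("every sample needs a non-missing individual_id", call. = FALSE)
  }
  if ("time_index" %in% names(sample_meta) &&
      !all(is.na(sample_meta$time_index))) {
    key <- split(sample_meta$time_index, sample_meta$individual_id)
    dup <- names(key)[vapply(key, function(v) anyDuplicated(v[!is.na(v)]) > 0,
                             logical(1))]
    if (length(dup)) {
      stop("duplicate time_index within individual(s): ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(values = values, feature_meta = feature_meta,
                 sample_meta = sample_meta),
            class = "phf_abundance")
}

align_meta <- function(meta, id_col, ids, what) {
  if (!is.data.frame(meta) || !id_col %in% names(meta)) {
    stop(what, " metadata must be a data.frame with a ", id_col,
         " column", call. = FALSE)
  }
  meta[[id_col]] <- as.character(meta[[id_col]])
  if (anyDuplicated(meta[[id_col]])) {
    stop("duplicated ", id_col, " in ", what, " metadata", call. = FALSE)
  }
  missing <- setdiff(ids, meta[[id_col]])
  extra <- setdiff(meta[[id_col]], ids)
  if (length(missing) || length(extra)) {
    stop(what, " metadata does not match the matrix: ",
         if (length(missing)) paste0("missing [",
           paste(utils::head(missing, 5), collapse = ", "), "]") else "",
         if (length(missing) && length(extra)) "; " else "",
         if (length(extra)) paste0("extraneous [",
           paste(utils::head(extra, 5), collapse = ", "), "]") else "",
         call. = FALSE)
  }
  out <- meta[match(ids, meta[[id_col]]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.phf_abundance <- function(x, ...) {
  cat("phf_abundance: ", nrow(x$values), " features x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  individuals: ", length(unique(x$sample_meta$individual_id)),
      "\n", sep = "")
  cat("  feature metadata: ",
      paste(setdiff(names(x$feature_meta), "feature_id"), collapse = ", "),
      "\n", sep = "")
  cat("  sample metadata: ",
      paste(setdiff(names(x$sample_meta), "sample_id"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Subset an abundance table
#'
#' `t[i, j]` subsets features (`i`) and samples (`j`) with any of the usual
#' index types, keeping metadata aligned.
#'
#' @param x a [phf_abundance()] object.
#' @param i,j feature / sample indices (integer, logical, or character ids).
#' @param ... ignored.
#' @export
`[.phf_abundance` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  phf_abundance(v,
                x$feature_meta[match(rownames(v), x$feature_meta$feature_id), ,
                               drop = FALSE],
                x$sample_meta[match(colnames(v), x$sample_meta$sample_id), ,
                              drop = FALSE])
}

#' @export
dim.phf_abundance <- function(x) dim(x$values)

#' Feature and sample ids of an abundance table
#' @param t a [phf_abundance()] object.
#' @return character vector of ids.
#' @export
feature_ids <- function(t) rownames(t$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(t) colnames(t$values)
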