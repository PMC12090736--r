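# Readers/writers for every table the pipeline touches. TSV is the
# canonical dialect; CSV is accepted (by extension or an explicit sep).
# "NA"/"" mean missing in metadata columns and are illegal in the numeric
# matrix. Readers preserve file order; they never reorder rows silently.

read_table_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  utils::read.delim(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""), quote = "\"",
                    fileEncoding = "UTF-8")
}

write_table_auto <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
}

# extract a lineage frame from a table that carries either one lineage
# string column or seven per-rank columns; the two dialects parse to
# identical lineages
table_lineages <- function(raw, lineage_col, dialect, path) {
  if (!is.null(lineage_col) && lineage_col %in% names(raw)) {
    return(parse_lineage(raw[[lineage_col]], dialect = dialect))
  }
  if (all(PHF_RANKS %in% names(raw))) {
    lin <- raw[PHF_RANKS]
    for (r in PHF_RANKS) {
      v <- as.character(lin[[r]])
      v[is.na(v)] <- ""
      # per-rank columns may still carry prefixes; strip them
      lin[[r]] <- sub(paste0("^", RANK_PREFIXES[[r]]), "", trimws(v))
    }
    return(lin)
  }
  stop("table ", path, " has neither a '", lineage_col,
       "' column nor per-rank columns (",
       paste(PHF_RANKS, collapse = ", "), ")", call. = FALSE)
}

#' Read a host-prediction table
#'
#' Reads per-contig host predictions (the shape of iPHoP genus-level
#' output): contig id, host lineage, and a confidence score in
#' `[0, 100]`. Multiple rows per contig are allowed (one per predicted
#' host). The lineage may be a single semicolon-delimited column or seven
#' per-rank columns; upstream exports vary in column naming, so the roles
#' are mapped through `columns` rather than hard-coded.
#'
#' @param path delimited text file with a header.
#' @param columns named list with roles `contig` (default `"contig_id"`),
#'   `lineage` (default `"host_lineage"`), `confidence` (default
#'   `"confidence"`).
#' @param dialect lineage string dialect, see [parse_lineage()].
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return data.frame with columns `contig_id`, the seven rank columns,
#'   and `confidence`.
#' @export
read_prediction_table <- function(path,
                                  columns = list(contig = "contig_id",
                                                 lineage = "host_lineage",
                                                 confidence = "confidence"),
                                  dialect = "auto", sep = NULL) {
  raw <- read_table_auto(path, sep)
  ccol <- columns$contig %||% "contig_id"
  if (!ccol %in% names(raw)) {
    stop("prediction table ", path, " is missing column '", ccol, "'",
         call. = FALSE)
  }
  scol <- columns$confidence %||% "confidence"
  if (!scol %in% names(raw)) {
    stop("prediction table ", path, " is missing column '", scol, "'",
         call. = FALSE)
  }
  conf <- suppressWarnings(as.numeric(raw[[scol]]))
  bad <- which(is.na(conf))
  if (length(bad)) {
    stop("non-numeric confidence in ", path, " at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  contig <- as.character(raw[[ccol]])
  if (any(is.na(contig) | !nzchar(contig))) {
    stop("empty contig id in ", path, call. = FALSE)
  }
  out <- cbind(data.frame(contig_id = contig, stringsAsFactors = FALSE),
               table_lineages(raw, columns$lineage %||% "host_lineage",
                              dialect, path))
  out$confidence <- conf
  out
}

#' Write a host-prediction table
#'
#' @param pred prediction table as returned by [read_prediction_table()].
#' @param path output path (TSV).
#' @param dialect lineage serialization dialect.
#' @export
write_prediction_table <- function(pred, path, dialect = "prefixed") {
  write_table_auto(data.frame(contig_id = pred$contig_id,
                              host_lineage = serialize_lineage(pred, dialect),
                              confidence = pred$confidence,
                              stringsAsFactors = FALSE), path)
  invisible(path)
}

#' Read a Hi-C phage-host linkage table
#'
#' Reads proximity-ligation linkage records: contig id, linked host
#' lineage, and a link rank (1 = strongest). If the file instead carries a
#' linkage `strength` column, ranks are derived per contig by descending
#' strength, breaking ties by the lexicographically smallest serialized
#' lineage so ordering is deterministic. `link_rank` must be unique within
#' a contig.
#'
#' @param path delimited text file with a header.
#' @param columns named list with roles `contig`, `lineage`, `link_rank`,
#'   `strength`.
#' @param dialect,sep see [read_prediction_table()].
#' @return data.frame with `contig_id`, rank columns, `link_rank`.
#' @export
read_linkage_table <- function(path,
                               columns = list(contig = "contig_id",
                                              lineage = "host_lineage",
                                              link_rank = "link_rank",
                                              strength = "strength"),
                               dialect = "auto", sep = NULL) {
  raw <- read_table_auto(path, sep)
  ccol <- columns$contig %||% "contig_id"
  if (!ccol %in% names(raw)) {
    stop("linkage table ", path, " is missing column '", ccol, "'",
         call. = FALSE)
  }
  contig <- as.character(raw[[ccol]])
  if (any(is.na(contig) | !nzchar(contig))) {
    stop("empty contig id in ", path, call. = FALSE)
  }
  lin <- table_lineages(raw, columns$lineage %||% "host_lineage", dialect,
                        path)
  rcol <- columns$link_rank %||% "link_rank"
  stcol <- columns$strength %||% "strength"
  if (rcol %in% names(raw)) {
    lr <- suppressWarnings(as.integer(raw[[rcol]]))
    if (any(is.na(lr) | lr < 1L)) {
      stop("link_rank must be a positive integer in ", path, call. = FALSE)
    }
  } else if (stcol %in% names(raw)) {
    strength <- suppressWarnings(as.numeric(raw[[stcol]]))
    if (any(is.na(strength))) {
      stop("non-numeric linkage strength in ", path, call. = FALSE)
    }
    ser <- serialize_lineage(lin)
    lr <- integer(length(contig))
    for (ct in unique(contig)) {
      idx <- which(contig == ct)
      lr[idx] <- order(order(-strength[idx], ser[idx]))
    }
  } else {
    stop("linkage table ", path, " needs a '", rcol, "' or '", stcol,
         "' column", call. = FALSE)
  }
  out <- cbind(data.frame(contig_id = contig, stringsAsFactors = FALSE), lin)
  out$link_rank <- as.integer(lr)
  dup <- tapply(out$link_rank, out$contig_id,
                function(v) anyDuplicated(v) > 0)
  if (any(dup)) {
    stop("duplicate link_rank within contig(s): ",
         paste(utils::head(names(dup)[dup], 5), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @rdname write_prediction_table
#' @param link linkage table as returned by [read_linkage_table()].
#' @export
write_linkage_table <- function(link, path, dialect = "prefixed") {
  write_table_auto(data.frame(contig_id = link$contig_id,
                              host_lineage = serialize_lineage(link, dialect),
                              link_rank = link$link_rank,
                              stringsAsFactors = FALSE), path)
  invisible(path)
}

#' Read an abundance table from its three files
#'
#' The on-disk form of a [phf_abundance()] object is three delimited
#' files: the numeric matrix (first column = feature id, remaining columns
#' = samples), the feature metadata, and the sample metadata. Matrix
#' values must all be numeric; missing values are illegal there, while in
#' metadata `"NA"`/empty means missing.
#'
#' @param path_matrix,path_feature_meta,path_sample_meta file paths.
#' @param sep field separator; inferred from extension when `NULL`.
#' @return a [phf_abundance()] object.
#' @export
read_abundance <- function(path_matrix, path_feature_meta = NULL,
                           path_sample_meta = NULL, sep = NULL) {
  raw <- read_table_auto(path_matrix, sep)
  if (ncol(raw) < 2L) {
    stop("abundance matrix ", path_matrix,
         " needs a feature id column plus at least one sample",
         call. = FALSE)
  }
  ids <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  if (any(is.na(m))) {
    stop("non-numeric or missing values in abundance matrix ", path_matrix,
         call. = FALSE)
  }
  rownames(m) <- ids
  fmeta <- if (!is.null(path_feature_meta)) {
    read_table_auto(path_feature_meta, sep)
  }
  smeta <- if (!is.null(path_sample_meta)) {
    read_table_auto(path_sample_meta, sep)
  }
  phf_abundance(m, fmeta, smeta)
}

#' Write an abundance table to three files
#'
#' Values are formatted with 15 significant digits, so a write/read
#' round-trip reproduces the object up to that precision.
#'
#' @param t a [phf_abundance()] object.
#' @param path_matrix,path_feature_meta,path_sample_meta output paths.
#' @export
write_abundance <- function(t, path_matrix, path_feature_meta,
                            path_sample_meta) {
  stopifnot(inherits(t, "phf_abundance"))
  m <- as.data.frame(apply(t$values, 2, function(col)
    format(col, digits = 15, trim = TRUE, scientific = FALSE)),
    optional = TRUE, stringsAsFactors = FALSE)
  colnames(m) <- colnames(t$values)
  df <- cbind(data.frame(feature_id = rownames(t$values),
                         stringsAsFactors = FALSE), m)
  write_table_auto(df, path_matrix)
  write_table_auto(t$feature_meta, path_feature_meta)
  write_table_auto(t$sample_meta, path_sample_meta)
  invisible(path_matrix)
}

#' Read and validate a rooted host tree
#'
#' Reads a Newick tree over host taxa (e.g. the GTDB bacterial genome
#' tree, or a family-level tree) and validates what the downstream UniFrac
#' computations assume: rooted, unique tip labels, and non-negative branch
#' lengths.
#'
#' @param path Newick file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_host_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick tree: ", path,
                          call. = FALSE)
  validate_host_tree(tree)
  tree
}

validate_host_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("expected a phylo tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("tree tip labels are not unique", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch length(s)", call. = FALSE)
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  invisible(tree)
}

#' @rdname read_host_tree
#' @param tree a `phylo` object.
#' @export
write_host_tree <- function(tree, path) {
  validate_host_tree(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
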