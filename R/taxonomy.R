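# Lineage representation: a data.frame with one character column per rank,
# "" meaning unassigned. Rank prefixes ("d__", "p__", ...) are stripped at
# parse time; all downstream comparisons are on bare names.

PHF_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")
RANK_PREFIXES <- c(domain = "d__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__",
                   species = "s__")
# concordance is only reported for these, as resolution below genus is not
# expected from host-prediction tools
COMPARISON_RANKS <- c("phylum", "class", "order", "family", "genus")

#' Taxonomic ranks used by the package
#'
#' The seven canonical ranks from domain (shallowest) to species (deepest),
#' in order. Host-prediction concordance is reported for phylum through
#' genus only; species is carried in the data model.
#'
#' @param comparison if `TRUE`, return only the ranks at which concordance
#'   is scored (phylum through genus).
#' @return character vector of rank names, shallowest first.
#' @export
#' @examples
#' lineage_ranks()
#' lineage_ranks(comparison = TRUE)
lineage_ranks <- function(comparison = FALSE) {
  if (comparison) COMPARISON_RANKS else PHF_RANKS
}

rank_depth <- function(rank) match(match.arg(rank, PHF_RANKS), PHF_RANKS)

empty_lineage_frame <- function(n) {
  out <- as.data.frame(matrix("", nrow = n, ncol = length(PHF_RANKS)),
                       stringsAsFactors = FALSE)
  names(out) <- PHF_RANKS
  out
}

#' Parse taxonomic lineage strings
#'
#' Parses semicolon-delimited lineage strings into a lineage frame (one
#' character column per rank, domain through species). Two dialects are
#' supported: `"prefixed"` (GTDB style, `"d__Bacteria;p__Bacteroidota;..."`)
#' and `"bare"` (names in rank order, `"Bacteria;Bacteroidota;..."`).
#' `"auto"` detects the dialect per string from the `__` rank markers.
#' Prefixes are stripped, whitespace trimmed, and empty segments stored as
#' empty names; ranks are never silently reordered (out-of-order prefixes
#' are an error). `NA` or empty input yields an all-empty row, which is not
#' a valid lineage (see [is_valid_lineage()]).
#'
#' @param x character vector of lineage strings.
#' @param dialect `"auto"`, `"prefixed"`, or `"bare"`.
#' @return data.frame with columns `domain`, `phylum`, `class`, `order`,
#'   `family`, `genus`, `species`; one row per element of `x`.
#' @seealso [serialize_lineage()] for the inverse.
#' @export
#' @examples
#' parse_lineage("d__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Bacteroidaceae;g__Bacteroides")$family
parse_lineage <- function(x, dialect = c("auto", "prefixed", "bare")) {
  dialect <- match.arg(dialect)
  x <- as.character(x)
  out <- empty_lineage_frame(length(x))
  if (length(x) == 0L) return(out)
  for (i in seq_along(x)) {
    s <- x[[i]]
    if (is.na(s) || !nzchar(trimws(s))) next
    tokens <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    d <- dialect
    if (d == "auto") {
      d <- if (any(grepl("^[a-z]__", tokens))) "prefixed" else "bare"
    }
    if (d == "prefixed") {
      tok_ranks <- integer(length(tokens))
      for (j in seq_along(tokens)) {
        tok <- tokens[[j]]
        if (!nzchar(tok)) { tok_ranks[[j]] <- NA_integer_; next }
        pref <- substr(tok, 1L, 3L)
        r <- match(pref, RANK_PREFIXES)
        if (is.na(r)) {
          stop("cannot parse lineage token '", tok, "' in '", s,
               "': expected a rank prefix like 'f__'", call. = FALSE)
        }
        tok_ranks[[j]] <- r
        out[i, r] <- trimws(substr(tok, 4L, nchar(tok)))
      }
      kept <- tok_ranks[!is.na(tok_ranks)]
      if (is.unsorted(kept, strictly = TRUE)) {
        stop("rank prefixes out of order in lineage '", s, "'",
             call. = FALSE)
      }
    } else {
      if (length(tokens) > length(PHF_RANKS)) {
        stop("lineage '", s, "' has ", length(tokens),
             " segments; at most ", length(PHF_RANKS), " ranks supported",
             call. = FALSE)
      }
      for (j in seq_along(tokens)) out[i, j] <- tokens[[j]]
    }
  }
  out
}

#' Serialize a lineage frame back to strings
#'
#' Inverse of [parse_lineage()]: `parse_lineage(serialize_lineage(lin))`
#' reproduces `lin` exactly. The prefixed dialect always emits all seven
#' ranks (empty names as bare prefixes, e.g. `"g__"`), so serialization is
#' lossless.
#'
#' @param lin lineage frame as returned by [parse_lineage()].
#' @param dialect `"prefixed"` (default) or `"bare"`.
#' @return character vector, one lineage string per row.
#' @export
serialize_lineage <- function(lin, dialect = c("prefixed", "bare")) {
  dialect <- match.arg(dialect)
  lin <- as_lineage_frame(lin)
  if (nrow(lin) == 0L) return(character(0))
  cols <- lapply(PHF_RANKS, function(r) as.character(lin[[r]]))
  if (dialect == "prefixed") {
    cols <- Map(function(pref, v) paste0(pref, v), RANK_PREFIXES, cols)
  }
  do.call(paste, c(cols, sep = ";"))
}

# coerce/validate anything carrying the seven rank columns
as_lineage_frame <- function(x) {
  if (!is.data.frame(x)) stop("expected a lineage data.frame", call. = FALSE)
  missing <- setdiff(PHF_RANKS, names(x))
  if (length(missing)) {
    stop("lineage frame is missing rank column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- x[PHF_RANKS]
  for (r in PHF_RANKS) {
    v <- as.character(out[[r]])
    v[is.na(v)] <- ""
    out[[r]] <- v
  }
  out
}

#' Is a lineage valid?
#'
#' A lineage is valid when at least its domain name is non-empty.
#'
#' @param lin lineage frame.
#' @return logical vector, one per row.
#' @export
is_valid_lineage <- function(lin) {
  nzchar(as_lineage_frame(lin)$domain)
}

#' Compare two lineages at one rank
#'
#' `TRUE` iff both names at `rank` are non-empty and exactly equal
#' (case-sensitive). A missing name at the rank can never be concordant:
#' empty-vs-anything is `FALSE`. No fuzzy matching is done — taxonomy names
#' are a controlled vocabulary and approximate matching would fabricate
#' concordance.
#'
#' Both arguments are lineage frames; rows are compared elementwise, with
#' the usual recycling of a single row against many.
#'
#' @param a,b lineage frames ([parse_lineage()]).
#' @param rank one of `lineage_ranks()`.
#' @return logical vector.
#' @export
names_match_at <- function(a, b, rank) {
  rank <- match.arg(rank, PHF_RANKS)
  na <- as_lineage_frame(a)[[rank]]
  nb <- as_lineage_frame(b)[[rank]]
  if (length(na) != length(nb)) {
    if (length(na) == 1L) na <- rep(na, length(nb))
    else if (length(nb) == 1L) nb <- rep(nb, length(na))
    else stop("lineage frames have incompatible row counts (", length(na),
              " vs ", length(nb), ")", call. = FALSE)
  }
  nzchar(na) & nzchar(nb) & na == nb
}

#' Look up a name in a taxonomy namespace map
#'
#' Maps a taxon name from one taxonomy namespace to another (e.g. GTDB to
#' NCBI) through a fraction-mapping table: each record states what
#' proportion of the source taxon maps onto the target name. The mapped
#' name with the highest `fraction_mapping` at or above `threshold` is
#' returned; if no record passes, `NA` (absence is a valid result). Ties on
#' the fraction are broken by the lexicographically smallest target name so
#' lookups are deterministic.
#'
#' @param map data.frame with columns `name_a`, `name_b`,
#'   `fraction_mapping` (in `[0, 1]`) and optionally `rank`; see
#'   [read_namespace_map()].
#' @param name source-namespace name to look up.
#' @param rank optional rank filter, applied only if `map` has a `rank`
#'   column.
#' @param threshold minimum fraction mapping; default 0.6.
#' @return mapped name, or `NA_character_` if nothing passes.
#' @export
#' @examples
#' m <- data.frame(name_a = c("X", "X"), name_b = c("Y", "Z"),
#'                 fraction_mapping = c(0.7, 0.8))
#' map_name(m, "X")  # "Z": highest passing fraction
map_name <- function(map, name, rank = NULL, threshold = 0.6) {
  stopifnot(is.data.frame(map),
            all(c("name_a", "name_b", "fraction_mapping") %in% names(map)))
  if (threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  hits <- map[map$name_a == name & map$fraction_mapping >= threshold, ,
              drop = FALSE]
  if (!is.null(rank) && "rank" %in% names(map)) {
    hits <- hits[hits$rank == rank, , drop = FALSE]
  }
  if (nrow(hits) == 0L) return(NA_character_)
  hits <- hits[order(-hits$fraction_mapping, hits$name_b), , drop = FALSE]
  hits$name_b[[1L]]
}

#' Read a namespace mapping table
#'
#' Reads a delimited table of (source name, target name, fraction mapping)
#' records, e.g. an NCBI-GTDB mapping export. The fraction must lie in
#' `[0, 1]`.
#'
#' @param path file path (TSV canonical; CSV accepted by extension).
#' @param columns named list mapping the roles `name_a`, `name_b`,
#'   `fraction_mapping` (and optionally `rank`) to column names in the file.
#' @return data.frame with columns `name_a`, `name_b`, `fraction_mapping`
#'   and, when present, `rank`.
#' @export
read_namespace_map <- function(path,
                               columns = list(name_a = "name_a",
                                              name_b = "name_b",
                                              fraction_mapping = "fraction_mapping")) {
  raw <- read_table_auto(path)
  need <- c("name_a", "name_b", "fraction_mapping")
  for (role in need) {
    col <- columns[[role]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("namespace map ", path, " is missing column '",
           if (is.null(col)) role else col, "'", call. = FALSE)
    }
  }
  out <- data.frame(name_a = as.character(raw[[columns$name_a]]),
                    name_b = as.character(raw[[columns$name_b]]),
                    fraction_mapping = as.numeric(raw[[columns$fraction_mapping]]),
                    stringsAsFactors = FALSE)
  if (!is.null(columns$rank) && columns$rank %in% names(raw)) {
    out$rank <- as.character(raw[[columns$rank]])
  }
  bad <- which(is.na(out$fraction_mapping) | out$fraction_mapping < 0 |
                 out$fraction_mapping > 1)
  if (length(bad)) {
    stop("fraction_mapping outside [0, 1] at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out
}
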