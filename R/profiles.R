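#' ORF relative-abundance profiles
#'
#' An `abundance_profile` holds, for one metagenomic data set, the relative
#' abundance of every ORF of a reference phage in hits per megabase of
#' sequence data (hits/Mb): the number of valid homology-search hits assigned
#' to the ORF divided by the data set size in Mb. A `profile_matrix` stacks
#' profiles over a shared ORF universe (rows = data sets, columns = ORFs)
#' and carries per-data-set metadata (habitat group, size, and, for simulated
#' pollution, source and strength labels).
#'
#' @param abundance Named non-negative numeric vector, one entry per ORF.
#' @param dataset_id Data set identifier.
#' @param meta Optional named list or one-row data.frame of metadata
#'   (`habitat_group`, `total_bp`, `assembled`, ...).
#' @return An `abundance_profile` object.
#' @export
abundance_profile <- function(abundance, dataset_id, meta = list()) {
  if (is.null(names(abundance)) || anyDuplicated(names(abundance))) {
    stop("abundance must be a named vector with unique ORF ids")
  }
  if (any(!is.finite(abundance)) || any(abundance < 0)) {
    stop("abundances must be finite and non-negative")
  }
  structure(
    list(dataset_id = as.character(dataset_id),
         abundance = abundance,
         meta = as.list(meta)),
    class = "abundance_profile"
  )
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat("abundance_profile:", x$dataset_id, "\n")
  cat(sprintf("  %d ORFs, %d with hits, cumulative %.4g hits/Mb\n",
              length(x$abundance), sum(x$abundance > 0),
              sum(x$abundance)))
  invisible(x)
}

#' Construct a profile matrix
#'
#' @param x Numeric matrix, rows = data sets (rownames = dataset ids),
#'   columns = ORF ids, values in hits/Mb.
#' @param meta `data.frame` with one row per data set (column `dataset_id`
#'   matching rownames of `x`); may carry `habitat_group`, `total_bp`,
#'   `source_label`, `strength`, and similar per-data-set annotation.
#' @return A `profile_matrix`: the numeric matrix with the metadata attached
#'   as attribute `"meta"`.
#' @export
profile_matrix <- function(x, meta = NULL) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("profile matrix needs dataset rownames and ORF colnames")
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("abundances must be finite and non-negative")
  }
  if (is.null(meta)) {
    meta <- data.frame(dataset_id = rownames(x), stringsAsFactors = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"dataset_id" %in% names(meta)) {
    stop("meta must have a dataset_id column")
  }
  if (!identical(as.character(meta$dataset_id), rownames(x))) {
    idx <- match(rownames(x), meta$dataset_id)
    if (anyNA(idx)) {
      stop("meta is missing rows for some data sets")
    }
    meta <- meta[idx, , drop = FALSE]
  }
  rownames(meta) <- NULL
  structure(x, meta = meta, class = c("profile_matrix", "matrix", "array"))
}

#' @export
print.profile_matrix <- function(x, ...) {
  meta <- profile_meta(x)
  cat(sprintf("profile_matrix: %d data sets x %d ORFs\n", nrow(x), ncol(x)))
  if ("habitat_group" %in% names(meta)) {
    tab <- table(meta$habitat_group)
    cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Metadata of a profile matrix
#' @param x A `profile_matrix`.
#' @return The per-data-set metadata `data.frame`.
#' @export
profile_meta <- function(x) {
  attr(x, "meta")
}

#' Stack abundance profiles into a profile matrix
#'
#' All profiles must share the same ORF universe (same ORF ids, any order;
#' they are aligned to the first profile's order).
#'
#' @param profiles List of `abundance_profile` objects.
#' @return A `profile_matrix`.
#' @export
bind_profiles <- function(profiles) {
  if (length(profiles) == 0L) {
    stop("need at least one profile")
  }
  universe <- names(profiles[[1L]]$abundance)
  rows <- lapply(profiles, function(p) {
    if (!setequal(names(p$abundance), universe)) {
      stop("profiles do not share an ORF universe")
    }
    p$abundance[universe]
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(profiles, function(p) p$dataset_id, character(1))
  colnames(m) <- universe
  meta_rows <- lapply(profiles, function(p) {
    fields <- p$meta[setdiff(names(p$meta), "dataset_id")]
    c(list(dataset_id = p$dataset_id), fields)
  })
  all_names <- unique(unlist(lapply(meta_rows, names)))
  meta <- do.call(rbind, lapply(meta_rows, function(r) {
    r[setdiff(all_names, names(r))] <- NA
    as.data.frame(r[all_names], stringsAsFactors = FALSE)
  }))
  profile_matrix(m, meta)
}

#' Compute a per-ORF relative-abundance profile from a hit table
#'
#' Valid hits (see [is_valid_hit()]) are counted per ORF and divided by the
#' data set size in megabases, giving hits/Mb. Multiple alignments between
#' the same (query, ORF) pair are first collapsed to the single best one
#' (lowest e-value, ties broken by higher bit score), so duplicated
#' alignments never inflate a count. A query validly hitting several distinct
#' ORFs contributes one count to each of them; pass `best_orf_only = TRUE`
#' to credit only the query's single best ORF instead.
#'
#' @param hits A `hit_table` from [read_hit_table()].
#' @param query_lengths Named lengths of the query sequences (reads for
#'   `"read_query"` tables, ORF proteins for `"orf_query"` tables).
#' @param orf_ids Character vector: the ORF universe of the reference phage.
#'   Hits to ORFs outside this universe are an error (they indicate a mixed
#'   reference).
#' @param meta Named list or one-row data.frame with at least `dataset_id`
#'   and `total_bp` (> 0); `habitat_group` and `assembled` are carried along.
#' @param best_orf_only Credit each query to only its best ORF (default
#'   `FALSE`).
#' @param min_identity,min_coverage,max_evalue Passed to [is_valid_hit()].
#' @return An `abundance_profile` over `orf_ids` (absent ORFs are exactly 0).
#' @export
compute_profile <- function(hits, query_lengths, orf_ids, meta,
                            best_orf_only = FALSE,
                            min_identity = 35, min_coverage = 0.5,
                            max_evalue = 1e-5) {
  meta <- as.list(meta)
  if (is.null(meta$total_bp) || !is.finite(meta$total_bp) || meta$total_bp <= 0) {
    stop("meta$total_bp must be a positive number of base pairs")
  }
  if (is.null(meta$dataset_id)) {
    stop("meta$dataset_id is required")
  }
  orientation <- attr(hits, "orientation")
  if (is.null(orientation)) {
    stop("hits must carry an orientation (use read_hit_table())")
  }
  orf_col <- if (orientation == "read_query") "subject_id" else "query_id"
  counts <- stats::setNames(numeric(length(orf_ids)), orf_ids)

  if (nrow(hits) > 0L) {
    unknown <- setdiff(unique(hits[[orf_col]]), orf_ids)
    if (length(unknown) > 0L) {
      stop("hit table references ORF(s) outside the declared universe: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
    # collapse to best alignment per (query, ORF): lowest e-value, then
    # highest bit score
    ord <- order(hits$query_id, hits[[orf_col]], hits$evalue, -hits$bit_score)
    h <- hits[ord, , drop = FALSE]
    keep <- !duplicated(paste(h$query_id, h[[orf_col]], sep = "\r"))
    h <- h[keep, , drop = FALSE]
    valid <- is_valid_hit(h, query_lengths,
                          min_identity = min_identity,
                          min_coverage = min_coverage,
                          max_evalue = max_evalue)
    h <- h[valid, , drop = FALSE]
    if (best_orf_only && nrow(h) > 0L) {
      ord2 <- order(h$query_id, h$evalue, -h$bit_score)
      h <- h[ord2, , drop = FALSE]
      h <- h[!duplicated(h$query_id), , drop = FALSE]
    }
    if (nrow(h) > 0L) {
      tab <- table(factor(h[[orf_col]], levels = orf_ids))
      counts[] <- as.numeric(tab)
    }
  }
  abundance <- counts / (meta$total_bp / 1e6)
  abundance_profile(abundance, meta$dataset_id, meta)
}

#' Cumulative relative abundance
#'
#' Sum of per-ORF hits/Mb values over a subset of ORFs (or all ORFs). For a
#' `profile_matrix` the sum is returned per data set.
#'
#' @param x An `abundance_profile` or `profile_matrix`.
#' @param orf_subset Optional character vector of ORF ids (or an
#'   [orf_subset()] object); must lie within the ORF universe.
#' @return Numeric: cumulative hits/Mb (vector for a matrix input).
#' @export
cumulative_abundance <- function(x, orf_subset = NULL) {
  if (inherits(x, "abundance_profile")) {
    v <- x$abundance
  } else {
    v <- as.matrix(x)
  }
  universe <- if (is.matrix(v)) colnames(v) else names(v)
  ids <- subset_ids(orf_subset)
  if (is.null(ids)) {
    ids <- universe
  } else {
    missing <- setdiff(ids, universe)
    if (length(missing) > 0L) {
      stop("subset ORF(s) not in profile universe: ",
           paste(missing, collapse = ", "))
    }
  }
  if (is.matrix(v)) {
    rowSums(v[, ids, drop = FALSE])
  } else {
    sum(v[ids])
  }
}

#' Drop data sets with too few detected ORFs
#'
#' Retains only the data sets whose profiles have at least `min_distinct`
#' strictly positive ORF abundances, the stringency filter applied before
#' ordination (default: at least two distinct ORFs detected).
#'
#' @param x A `profile_matrix`.
#' @param min_distinct Minimum number of distinct ORFs with hits (default 2).
#' @return The filtered `profile_matrix`, row order preserved.
#' @export
filter_min_orf_representation <- function(x, min_distinct = 2) {
  stopifnot(inherits(x, "profile_matrix"), min_distinct >= 0)
  keep <- rowSums(unclass(x) > 0) >= min_distinct
  profile_matrix(unclass(x)[keep, , drop = FALSE],
                 profile_meta(x)[keep, , drop = FALSE])
}

#' Write / read a profile matrix as CSV
#'
#' The CSV has one row per data set, a leading `dataset_id` column and one
#' column per ORF (hits/Mb). Metadata travels in a companion CSV (see
#' [read_metadata()]) or via the `meta` argument.
#'
#' @param x A `profile_matrix`.
#' @param path Output/input CSV path.
#' @param meta Optional metadata `data.frame` to attach on reading.
#' @return `write_profile_matrix()` returns `path` invisibly;
#'   `read_profile_matrix()` returns a `profile_matrix`.
#' @export
write_profile_matrix <- function(x, path) {
  df <- data.frame(dataset_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(path, meta = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "dataset_id") {
    stop("first column of a profile CSV must be dataset_id")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$dataset_id
  profile_matrix(m, meta)
}

#' ORF subsets
#'
#' A named set of ORF identifiers used for cumulative-abundance scoring.
#' Numeric ids are expanded to `ORF_<n>` to match profile column names.
#' [subset1_orfs()] and [subset2_orfs()] return the two published
#' human-gut-affiliated subsets of the *Bacteroides* phage B124-14 genome:
#' subset 1 (ORFs 5, 16, 18, 20, 21, 22, 23, 25, 34, 36, 43, 44, 59, 61, 67)
#' has significantly elevated relative abundance in human gut viromes over
#' environmental viromes; subset 2 (ORFs 16, 34, 56) is elevated over all
#' other virome groups.
#'
#' @param name Subset label.
#' @param ids Character ORF ids or integers.
#' @return An `orf_subset` object.
#' @export
orf_subset <- function(name, ids) {
  if (is.numeric(ids)) {
    ids <- orf_id(ids)
  }
  ids <- unique(as.character(ids))
  if (length(ids) == 0L) {
    stop("an ORF subset cannot be empty")
  }
  structure(list(name = name, orf_ids = ids), class = "orf_subset")
}

#' @rdname orf_subset
#' @export
subset1_orfs <- function() {
  orf_subset("subset1", c(5, 16, 18, 20, 21, 22, 23, 25, 34, 36, 43, 44, 59, 61, 67))
}

#' @rdname orf_subset
#' @export
subset2_orfs <- function() {
  orf_subset("subset2", c(16, 34, 56))
}

#' @rdname orf_subset
#' @param n Integer ORF numbers.
#' @export
orf_id <- function(n) {
  paste0("ORF_", as.integer(n))
}

subset_ids <- function(s) {
  if (is.null(s)) return(NULL)
  if (inherits(s, "orf_subset")) return(s$orf_ids)
  if (is.numeric(s)) return(orf_id(s))
  as.character(s)
}
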