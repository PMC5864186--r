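#' Read a 12-column tabular homology-search hit table
#'
#' Reads the tab-separated 12-column alignment format produced by sequence
#' similarity search tools (query id, subject id, percent identity, alignment
#' length, mismatches, gap opens, query start/end, subject start/end, e-value,
#' bit score). Lines starting with `#` are skipped.
#'
#' The `orientation` argument records which side of the alignment is the
#' phage ORF: for viral data sets raw reads are searched against translated
#' ORFs (`"read_query"`, ORF is the subject), whereas whole-community data
#' sets are searched with the ORF protein as query (`"orf_query"`). Hit
#' validity is always assessed on the query side, whichever that is.
#'
#' @param path Path to the hit table. An empty file yields a zero-row table.
#' @param orientation `"read_query"` or `"orf_query"`.
#' @return A `data.frame` of class `hit_table` with one row per alignment and
#'   columns `query_id`, `subject_id`, `percent_identity`, `alignment_length`,
#'   `mismatches`, `gap_opens`, `query_start`, `query_end`, `subject_start`,
#'   `subject_end`, `evalue`, `bit_score`; the orientation is kept in
#'   `attr(, "orientation")`.
#' @seealso [compute_profile()], [is_valid_hit()]
#' @export
read_hit_table <- function(path, orientation = c("read_query", "orf_query")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop("hit table not found: ", path)
  }
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) {
    return(hit_table(empty_hit_df(), orientation))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 12L)) {
    bad <- which(ncols != 12L)[1L]
    stop(sprintf("malformed hit table row at line %d: expected 12 columns, found %d",
                 line_no[bad], ncols[bad]))
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  suppressWarnings(vals <- matrix(as.numeric(m[, 3:12]), ncol = 10L))
  if (anyNA(vals)) {
    bad <- which(apply(vals, 1L, anyNA))[1L]
    stop(sprintf("malformed hit table row at line %d: non-numeric value in a numeric column",
                 line_no[bad]))
  }
  df <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    percent_identity = vals[, 1L], alignment_length = vals[, 2L],
    mismatches = vals[, 3L], gap_opens = vals[, 4L],
    query_start = vals[, 5L], query_end = vals[, 6L],
    subject_start = vals[, 7L], subject_end = vals[, 8L],
    evalue = vals[, 9L], bit_score = vals[, 10L],
    stringsAsFactors = FALSE
  )
  hit_table(df, orientation)
}

hit_table <- function(df, orientation) {
  structure(df, class = c("hit_table", "data.frame"), orientation = orientation)
}

empty_hit_df <- function() {
  data.frame(
    query_id = character(), subject_id = character(),
    percent_identity = numeric(), alignment_length = numeric(),
    mismatches = numeric(), gap_opens = numeric(),
    query_start = numeric(), query_end = numeric(),
    subject_start = numeric(), subject_end = numeric(),
    evalue = numeric(), bit_score = numeric(),
    stringsAsFactors = FALSE
  )
}

#' Test hits against the validity filter
#'
#' A hit is valid when it has at least 35 percent identity, covers at least
#' half of the query sequence, and has an e-value of at most 1e-5. All three
#' comparisons are inclusive at the boundary. Query coverage is
#' `(query_end - query_start + 1) / query_length` with 1-based inclusive
#' coordinates.
#'
#' @param hits A `hit_table` (or data.frame with the same columns).
#' @param query_lengths Named numeric vector of query sequence lengths in
#'   residues (or bases), e.g. from [read_length_table()]. Every query id in
#'   `hits` must be present.
#' @param min_identity,min_coverage,max_evalue Filter thresholds; defaults are
#'   the published criteria (35, 0.5, 1e-5).
#' @return Logical vector, one element per hit row.
#' @export
is_valid_hit <- function(hits, query_lengths,
                         min_identity = 35, min_coverage = 0.5,
                         max_evalue = 1e-5) {
  if (nrow(hits) == 0L) {
    return(logical(0))
  }
  qlen <- query_lengths[hits$query_id]
  if (anyNA(qlen)) {
    missing <- unique(hits$query_id[is.na(qlen)])
    stop("no length entry for query id(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ..." else "")
  }
  if (any(qlen <= 0)) {
    stop("query lengths must be positive")
  }
  coverage <- (hits$query_end - hits$query_start + 1) / as.numeric(qlen)
  hits$percent_identity >= min_identity &
    coverage >= min_coverage &
    hits$evalue <= max_evalue
}

#' Read sequence lengths from a FASTA file or a two-column TSV
#'
#' FASTA input (detected by a leading `>` or a `.fa/.fasta/.faa/.fna`
#' extension) is read with \pkg{Biostrings}; otherwise the file is parsed as
#' tab-separated `id<TAB>length` with no header.
#'
#' @param path Path to the lengths file.
#' @return Named numeric vector of lengths.
#' @export
read_length_table <- function(path) {
  if (!file.exists(path)) {
    stop("length table not found: ", path)
  }
  first <- readLines(path, n = 1L)
  is_fasta <- grepl("\\.(fa|fasta|faa|fna)$", path, ignore.case = TRUE) ||
    (length(first) == 1L && startsWith(first, ">"))
  if (is_fasta) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA lengths requires the Biostrings package")
    }
    out <- Biostrings::fasta.seqlengths(path)
    # keep only the first whitespace-delimited token of each header
    names(out) <- sub("\\s.*$", "", names(out))
    return(out)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("id", "length"),
                          colClasses = c("character", "numeric"))
  if (anyDuplicated(df$id)) {
    stop("duplicate ids in length table: ", path)
  }
  stats::setNames(df$length, df$id)
}

#' Read a metagenome metadata table
#'
#' CSV with header `dataset_id,habitat_group,total_bp,assembled`. `total_bp`
#' is the total amount of sequence in the data set in base pairs and is the
#' denominator of the hits/Mb normalisation; it must be positive.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with one row per data set.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("dataset_id", "habitat_group", "total_bp")
  if (!all(required %in% names(df))) {
    stop("metadata must have columns ", paste(required, collapse = ", "))
  }
  if (!"assembled" %in% names(df)) {
    df$assembled <- FALSE
  }
  df$assembled <- as.logical(df$assembled)
  if (anyDuplicated(df$dataset_id)) {
    stop("dataset_id values must be unique")
  }
  if (any(!is.finite(df$total_bp)) || any(df$total_bp <= 0)) {
    stop("total_bp must be positive for every data set")
  }
  df
}
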