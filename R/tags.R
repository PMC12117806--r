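#' Extract reference-free sequence tags from a trimmed read file
#'
#' A tag is the first \code{tag_length} bases of a read, keyed by exact
#' sequence.  Reads shorter than \code{min_read_length} are dropped outright;
#' reads of at least \code{min_read_length} but shorter than
#' \code{tag_length} contribute to the sample's total read count (they are
#' legitimate trimmed reads) but not to any tag.
#'
#' @param file path to a FASTQ file (plain or gzip), already demultiplexed
#'   and quality/adapter trimmed.
#' @param tag_length tag width in bases (default 65).
#' @param min_read_length minimum surviving read length (default 40).
#' @return list with \code{counts} (named integer vector, tag sequence ->
#'   count), \code{total_reads} (reads of length >= \code{min_read_length}),
#'   \code{n_below_min} (dropped short reads) and \code{n_subtag} (reads
#'   counted in the total but too short to yield a tag).
#' @export
extract_tags <- function(file, tag_length = 65L, min_read_length = 40L) {
  reads <- tryCatch(
    Biostrings::readDNAStringSet(file, format = "fastq"),
    error = function(e)
      stop("failed to parse FASTQ file '", file, "': ",
           conditionMessage(e), call. = FALSE))
  w <- Biostrings::width(reads)
  n_below <- sum(w < min_read_length)
  keep <- w >= min_read_length
  reads <- reads[keep]
  w <- w[keep]
  taggable <- w >= tag_length
  counts <- integer(0)
  if (any(taggable)) {
    tags <- as.character(Biostrings::subseq(reads[taggable], 1L, tag_length))
    tab <- table(tags)
    counts <- stats::setNames(as.integer(tab), names(tab))
  }
  list(counts = counts,
       total_reads = length(reads),
       n_below_min = n_below,
       n_subtag = sum(!taggable))
}

#' Assemble per-sample tag counts into a tag-count matrix
#'
#' @param extracts named list of \code{\link{extract_tags}} results (names
#'   are sample ids).
#' @param tag_ids optional tag universe defining the columns; defaults to
#'   the union of observed tags in first-seen order.
#' @return integer matrix (samples x tags) with attribute \code{total_reads}.
#' @export
tag_count_matrix <- function(extracts, tag_ids = NULL) {
  if (is.null(names(extracts)))
    stop("'extracts' must be a named list (sample ids)")
  if (is.null(tag_ids))
    tag_ids <- unique(unlist(lapply(extracts, function(x) names(x$counts)),
                             use.names = FALSE))
  m <- matrix(0L, length(extracts), length(tag_ids),
              dimnames = list(names(extracts), tag_ids))
  for (i in seq_along(extracts)) {
    ci <- extracts[[i]]$counts
    ci <- ci[names(ci) %in% tag_ids]
    m[i, names(ci)] <- ci
  }
  attr(m, "total_reads") <- vapply(extracts, `[[`, numeric(1), "total_reads")
  m
}

#' Discard low-depth samples
#'
#' Samples whose total read count is strictly below \code{min_reads} are
#' removed (a sample with exactly \code{min_reads} reads is retained).
#'
#' @param counts tag-count matrix (samples x tags).
#' @param min_reads QC threshold (default 100000 reads).
#' @param total_reads per-sample totals; defaults to the matrix's
#'   \code{total_reads} attribute, else to row sums.
#' @return list with \code{counts} (retained samples, \code{total_reads}
#'   attribute subset accordingly) and \code{report} (data.frame of
#'   sample_id, total_reads, status).
#' @export
sample_qc <- function(counts, min_reads = 100000, total_reads = NULL) {
  if (is.null(total_reads)) total_reads <- attr(counts, "total_reads")
  if (is.null(total_reads)) total_reads <- rowSums(counts)
  stopifnot(length(total_reads) == nrow(counts))
  keep <- total_reads >= min_reads
  if (!any(keep))
    stop("all samples fall below the read-count threshold (", min_reads, ")")
  report <- data.frame(sample_id = rownames(counts),
                       total_reads = as.numeric(total_reads),
                       status = ifelse(keep, "retained", "discarded"),
                       stringsAsFactors = FALSE)
  out <- counts[keep, , drop = FALSE]
  attr(out, "total_reads") <- total_reads[keep]
  list(counts = out, report = report)
}

#' Filter tags by presence in a reference sample set
#'
#' A tag is retained if it has at least one read in at least
#' \code{presence_threshold} of the reference samples (inclusive
#' comparison).  For forward prediction the reference set is the training
#' samples; for cross-validation it is all samples.  All samples keep only
#' the retained tag columns, so validation-sample columns may be all zero.
#'
#' @param counts tag-count matrix (samples x tags).
#' @param reference_samples sample ids defining presence; defaults to all.
#' @param presence_threshold required presence fraction (default 0.25).
#' @return the filtered tag-count matrix.
#' @export
filter_tags <- function(counts, reference_samples = rownames(counts),
                        presence_threshold = 0.25) {
  if (length(reference_samples) == 0L)
    stop("'reference_samples' must be non-empty")
  if (!all(reference_samples %in% rownames(counts)))
    stop("'reference_samples' must be a subset of the sample ids")
  pres <- colMeans(counts[reference_samples, , drop = FALSE] >= 1L)
  out <- counts[, pres >= presence_threshold, drop = FALSE]
  attr(out, "total_reads") <- attr(counts, "total_reads")
  out
}
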