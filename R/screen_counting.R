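#' Count screen reads into a construct count matrix
#'
#' Each read is assigned by locating the first direct-repeat anchor
#' (exact, or up to `anchor_max_mismatch` substitutions), extracting the
#' following spacer-length window and matching it exactly against the
#' position-1 spacer dictionary of the library. Optionally every array
#' position is verified (`verify_all = TRUE`, for reads covering the
#' whole amplicon). Reads failing any step are counted as unassigned, so
#' assigned + unassigned = total for every sample.
#'
#' @param fastq_paths named character vector: sample id -> FASTQ path
#'   (gzip allowed).
#' @param library a `LibraryTable` (position-1 spacers must be unique
#'   across constructs; collisions are fatal).
#' @param sample_meta optional data.frame with rownames or a `sample_id`
#'   column giving condition/replicate/timepoint per sample.
#' @param anchor direct-repeat anchor sequence.
#' @param anchor_max_mismatch mismatches tolerated when locating the
#'   anchor (0 or 1).
#' @param verify_all require every array position to match its spacer.
#' @param spacer_len spacer length extracted after each anchor.
#' @return a `ScreenCounts` object: `counts` (constructs x samples
#'   integer matrix), `samples` (metadata data.frame), `unassigned`
#'   (per-sample integer).
#' @export
count_reads <- function(fastq_paths, library, sample_meta = NULL,
                        anchor = DEFAULT_DR, anchor_max_mismatch = 0L,
                        verify_all = FALSE, spacer_len = 23L) {
  constructs <- library$constructs
  sp1 <- constructs$spacer1
  if (anyDuplicated(sp1)) {
    stop("position-1 spacers are not unique across constructs; ",
         "cannot identify constructs")
  }
  dict <- setNames(seq_along(sp1), sp1)
  samples <- names(fastq_paths)
  if (is.null(samples)) samples <- paste0("S", seq_along(fastq_paths))
  counts <- matrix(0L, nrow = nrow(constructs), ncol = length(samples),
                   dimnames = list(constructs$construct_id, samples))
  unassigned <- setNames(integer(length(samples)), samples)

  for (si in seq_along(samples)) {
    reads <- Biostrings::readDNAStringSet(fastq_paths[[si]], format = "fastq")
    total <- length(reads)
    if (!total) next
    hit <- Biostrings::vmatchPattern(anchor, reads,
                                     max.mismatch = anchor_max_mismatch)
    first <- vapply(Biostrings::startIndex(hit), function(s)
      if (length(s)) min(s) else NA_integer_, integer(1))
    rs <- unname(as.character(reads))
    sp_start <- first + nchar(anchor)
    ok <- !is.na(first) & sp_start + spacer_len - 1L <= nchar(rs)
    idx <- rep(NA_integer_, total)
    idx[ok] <- dict[substr(rs[ok], sp_start[ok], sp_start[ok] + spacer_len - 1L)]
    if (verify_all) {
      for (r in which(!is.na(idx))) {
        expect <- unlist(constructs[idx[r], paste0("spacer", 1:4)])
        expect <- expect[!is.na(expect) & nzchar(expect)]
        unit <- paste0(anchor, expect)
        want <- paste0(unit, collapse = "")
        got <- substr(rs[r], first[r], first[r] + nchar(want) - 1L)
        if (!identical(got, want)) idx[r] <- NA_integer_
      }
    }
    tab <- table(idx[!is.na(idx)])
    counts[as.integer(names(tab)), si] <- as.integer(tab)
    unassigned[si] <- total - sum(!is.na(idx))
    if (total >= 100 && sum(is.na(first)) / total > 0.95) {
      warning("anchor '", anchor, "' not found in >95% of reads for sample ",
              samples[si], "; check the direct-repeat/vector dialect")
    }
  }
  new_screen_counts(counts, sample_meta, unassigned)
}

new_screen_counts <- function(counts, sample_meta = NULL,
                              unassigned = NULL) {
  storage.mode(counts) <- "integer"
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = colnames(counts))
  }
  if (is.null(unassigned)) {
    unassigned <- setNames(integer(ncol(counts)), colnames(counts))
  }
  structure(list(counts = counts, samples = sample_meta,
                 unassigned = unassigned),
            class = "ScreenCounts")
}

#' @export
print.ScreenCounts <- function(x, ...) {
  cat("ScreenCounts:", nrow(x$counts), "constructs x", ncol(x$counts),
      "samples; total assigned", sum(x$counts), "\n")
  invisible(x)
}

#' Normalise counts to log2 counts-per-million
#'
#' `log2((count + pseudocount) / (library_size + 2 * pseudocount) * 1e6)`
#' with `library_size` the column sum. The pseudocount (default 0.5)
#' keeps zero counts finite; depth normalisation is plain CPM.
#'
#' @param counts a `ScreenCounts` or a non-negative integer matrix.
#' @param pseudocount continuity correction added to each count.
#' @return a `LogCpm` object: `values` matrix, `pseudocount`,
#'   `lib_sizes`, and the sample metadata.
#' @export
normalize_log_cpm <- function(counts, pseudocount = 0.5) {
  samples <- NULL
  if (inherits(counts, "ScreenCounts")) {
    samples <- counts$samples
    counts <- counts$counts
  }
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("zero-depth sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  values <- log2(t(t(counts + pseudocount) / (lib + 2 * pseudocount)) * 1e6)
  structure(list(values = values, pseudocount = pseudocount,
                 lib_sizes = lib, samples = samples),
            class = "LogCpm")
}
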