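# Mismatch-tolerant off-target search.
#
# A 23-mer with at most 3 mismatches must match one of four disjoint
# pieces (widths 6, 6, 6, 5) exactly (pigeonhole), so exact seed lookups
# over an integer-coded genome followed by Hamming verification find every
# site. Brute force is the independent oracle in the test suite.

seed_pieces <- function(len) {
  # Disjoint pieces covering the pattern; one more piece than the
  # mismatch budget (3) so at least one piece is exact.
  stopifnot(len >= 8)
  w <- len %/% 4
  starts <- c(1, w + 1, 2 * w + 1, 3 * w + 1)
  widths <- c(w, w, w, len - 3 * w)
  data.frame(start = starts, width = widths)
}

# Rolling first-char-most-significant base-4 codes for windows of width w.
window_codes <- function(code, w) {
  L <- length(code)
  if (L < w) return(integer(0))
  n <- L - w + 1L
  cw <- numeric(n)
  for (j in 0:(w - 1)) cw <- cw * 4 + code[(1 + j):(n + j)]
  cw
}

seed_table <- function(cw) {
  ok <- which(!is.na(cw))
  ord <- ok[order(cw[ok])]
  list(pos = ord, sorted = cw[ord])
}

seed_lookup <- function(tab, value) {
  # binary search for the run of `value` in tab$sorted (findInterval
  # re-validates its inputs on every call, which dominates at this scale)
  x <- tab$sorted
  n <- length(x)
  if (!n) return(integer(0))
  lo <- 1L; hi <- n + 1L
  while (lo < hi) {  # first index with x >= value
    mid <- (lo + hi) %/% 2L
    if (x[mid] < value) lo <- mid + 1L else hi <- mid
  }
  i1 <- lo
  if (i1 > n || x[i1] != value) return(integer(0))
  hi <- n + 1L
  while (lo < hi) {  # first index with x > value
    mid <- (lo + hi) %/% 2L
    if (x[mid] <= value) lo <- mid + 1L else hi <- mid
  }
  tab$pos[i1:(lo - 1L)]
}

#' Build an off-target search index over a genome model
#'
#' Precomputes integer-coded contig sequences and exact-seed lookup tables
#' used by [count_cds_offtargets()] and the non-targeting-control
#' validator. Build once per genome and pass to the design functions.
#'
#' @param model a `GenomeModel`.
#' @param spacer_len spacer length the index will be queried with.
#' @return an `OfftargetIndex` object.
#' @export
build_offtarget_index <- function(model, spacer_len = 23L) {
  pieces <- seed_pieces(spacer_len)
  widths <- unique(pieces$width)
  contigs <- lapply(names(model$contigs), function(nm) {
    code <- encode_dna(as.character(model$contigs[[nm]]))
    tabs <- lapply(widths, function(w) seed_table(window_codes(code, w)))
    names(tabs) <- as.character(widths)
    list(code = code, tabs = tabs)
  })
  names(contigs) <- names(model$contigs)

  parts <- lapply(model$genes, function(g) {
    cds <- IRanges::reduce(do.call(c, c(list(IRanges::IRanges()),
      lapply(g$transcripts, function(t) t$cds))))
    if (!length(cds)) return(NULL)
    data.frame(contig = g$contig, start = IRanges::start(cds),
               end = IRanges::end(cds), gene_id = g$gene_id)
  })
  parts <- do.call(rbind, parts)
  cds_gr <- if (is.null(parts)) GenomicRanges::GRanges() else {
    gr <- GenomicRanges::GRanges(parts$contig,
                                 IRanges::IRanges(parts$start, parts$end))
    gr$gene_id <- parts$gene_id
    gr
  }
  structure(list(contigs = contigs, cds = cds_gr, spacer_len = spacer_len,
                 pieces = pieces), class = "OfftargetIndex")
}

# All genomic sites matching `pattern_codes` with <= max_mm mismatches on
# the forward strand of one contig. Returns start positions + mismatch count.
seeded_hits_one <- function(contig_entry, pieces, pattern_codes, max_mm) {
  code <- contig_entry$code
  L <- length(code)
  len <- length(pattern_codes)
  if (L < len) return(data.frame(start = integer(0), mm = integer(0)))
  cand <- integer(0)
  for (i in seq_len(nrow(pieces))) {
    o <- pieces$start[i]; w <- pieces$width[i]
    pc <- pattern_codes[o:(o + w - 1)]
    if (anyNA(pc)) next
    v <- 0
    for (x in pc) v <- v * 4 + x
    hits <- seed_lookup(contig_entry$tabs[[as.character(w)]], v)
    cand <- c(cand, hits - (o - 1L))
  }
  cand <- unique(cand)
  cand <- cand[cand >= 1L & cand <= L - len + 1L]
  if (!length(cand)) return(data.frame(start = integer(0), mm = integer(0)))
  mm <- integer(length(cand))
  for (k in seq_len(len)) {
    xx <- code[cand + k - 1L]
    mm <- mm + (is.na(xx) | xx != pattern_codes[k])
  }
  keep <- mm <= max_mm
  data.frame(start = cand[keep], mm = mm[keep])
}

# Genomic sites matching `spacer` (protospacer sense) at <= max_mm
# mismatches on either strand, optionally requiring an adjacent exact
# TTTV-style PAM. Orientation "+" means the protospacer lies on the
# forward strand (PAM immediately 5', i.e. left); "-" means the reverse
# strand (PAM bases immediately right of the matched window).
offtarget_sites <- function(index, spacer, max_mm = 3L, require_pam = TRUE) {
  len <- nchar(spacer)
  stopifnot(len == index$spacer_len)
  pats <- list(`+` = encode_dna(spacer), `-` = encode_dna(revcomp(spacer)))
  out <- list()
  for (contig in names(index$contigs)) {
    entry <- index$contigs[[contig]]
    code <- entry$code
    L <- length(code)
    for (ori in c("+", "-")) {
      h <- seeded_hits_one(entry, index$pieces, pats[[ori]], max_mm)
      if (!nrow(h)) next
      if (require_pam) {
        if (ori == "+") {
          p <- h$start
          ok <- p >= 5L
          p0 <- pmax(p, 5L)
          pam_ok <- code[p0 - 4L] %in% 3L & code[p0 - 3L] %in% 3L &
            code[p0 - 2L] %in% 3L & code[p0 - 1L] %in% c(0L, 1L, 2L)
          ok <- ok & pam_ok
        } else {
          e <- h$start + len - 1L
          ok <- e + 4L <= L
          e0 <- pmin(e, L - 4L)
          pam_ok <- code[e0 + 1L] %in% c(1L, 2L, 3L) & code[e0 + 2L] %in% 0L &
            code[e0 + 3L] %in% 0L & code[e0 + 4L] %in% 0L
          ok <- ok & pam_ok
        }
        h <- h[ok, , drop = FALSE]
      }
      if (nrow(h)) {
        out[[length(out) + 1L]] <- data.frame(
          contig = contig, start = h$start, end = h$start + len - 1L,
          orientation = ori, mismatches = h$mm)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), orientation = character(0),
                      mismatches = integer(0)))
  }
  do.call(rbind, out)
}

#' Count coding-sequence off-targets of spacer candidates
#'
#' For each candidate, counts genomic sites on either strand where an
#' exact PAM match is immediately adjacent to a match of the spacer with
#' at most `max_mismatches` substitutions, and the protospacer window
#' overlaps the CDS of a gene other than the candidate's own. The
#' intended on-target site is excluded.
#'
#' @param candidates candidate table from [enumerate_spacers()].
#' @param model a `GenomeModel` (ignored when `index` is supplied).
#' @param max_mismatches mismatch budget (default 3).
#' @param index optional prebuilt [build_offtarget_index()] result.
#' @return the candidate table with `offtarget_count` filled in.
#' @export
count_cds_offtargets <- function(candidates, model = NULL, max_mismatches = 3L,
                                 index = NULL) {
  if (is.null(index)) index <- build_offtarget_index(model)
  if (!nrow(candidates)) {
    candidates$offtarget_count <- integer(0)
    return(candidates)
  }
  all_sites <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    sites <- offtarget_sites(index, candidates$spacer_seq[i],
                             max_mm = max_mismatches, require_pam = TRUE)
    if (!nrow(sites)) next
    own <- sites$contig == candidates$contig[i] &
      sites$start == candidates$spacer_start[i] &
      sites$orientation == candidates$strand[i]
    sites <- sites[!own, , drop = FALSE]
    if (nrow(sites)) {
      sites$cand <- i
      all_sites[[i]] <- sites
    }
  }
  n <- integer(nrow(candidates))
  all_sites <- do.call(rbind, all_sites)
  if (!is.null(all_sites) && nrow(all_sites)) {
    q <- GenomicRanges::GRanges(all_sites$contig,
                                IRanges::IRanges(all_sites$start,
                                                 all_sites$end))
    hits <- GenomicRanges::findOverlaps(q, index$cds)
    qh <- S4Vectors::queryHits(hits)
    other <- index$cds$gene_id[S4Vectors::subjectHits(hits)] !=
      candidates$gene_id[all_sites$cand[qh]]
    counted <- unique(qh[other])
    if (length(counted)) {
      tab <- table(all_sites$cand[counted])
      n[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  candidates$offtarget_count <- n
  candidates
}

# Number of genomic matches of a spacer at <= max_mm mismatches on either
# strand, PAM-agnostic. Used to validate non-targeting controls.
genome_match_count <- function(index, spacer, max_mm = 3L) {
  nrow(offtarget_sites(index, spacer, max_mm = max_mm, require_pam = FALSE))
}
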