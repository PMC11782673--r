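#' Constraints on spacer arrangement within dual pairs and quad arrays
#'
#' Distances are end-to-start gaps between protospacer genomic intervals
#' (within a pair/array: to avoid competition for nuclease occupancy) and
#' between the spanned regions of the two pairs of a dual design (to avoid
#' large unintended deletions). The region spanned by a pair's or array's
#' outermost protospacers must not overlap annotated non-coding elements.
#'
#' @param min_intra_pair_gap minimum gap (nt) between spacers of one
#'   pair/array.
#' @param min_inter_pair_gap minimum gap (nt) between the spanned regions
#'   of a gene's two pairs.
#' @param require_exon_diversity soft preference for spreading spacers
#'   across distinct exons when possible.
#' @param avoid_ncrna_overlap hard exclusion of spans overlapping
#'   non-coding elements.
#' @param max_candidates_considered selection is solved exhaustively over
#'   the top-ranked candidates up to this count.
#' @return a `PairConstraints` list.
#' @export
pair_constraints <- function(min_intra_pair_gap = 25L,
                             min_inter_pair_gap = 50L,
                             require_exon_diversity = TRUE,
                             avoid_ncrna_overlap = TRUE,
                             max_candidates_considered = 50L) {
  stopifnot(min_intra_pair_gap >= 0, min_inter_pair_gap >= 0)
  structure(list(min_intra_pair_gap = as.integer(min_intra_pair_gap),
                 min_inter_pair_gap = as.integer(min_inter_pair_gap),
                 require_exon_diversity = isTRUE(require_exon_diversity),
                 avoid_ncrna_overlap = isTRUE(avoid_ncrna_overlap),
                 max_candidates_considered = as.integer(max_candidates_considered)),
            class = "PairConstraints")
}

#' Rank filtered spacer candidates for selection
#'
#' Total order: fewer CDS off-targets; then Pfam-domain overlap; then cut
#' site within the first 85% of the spliced CDS; then higher on-target
#' score; then genomic position ascending with "+" before "-" as the final
#' deterministic tie-break. Only candidates passing the hard filters are
#' retained. A `priority` column (larger = better) is added for use as a
#' selection objective.
#'
#' @param candidates candidate table with `offtarget_count` populated.
#' @param cds_frac_cutoff prioritisation cutoff on the spliced-CDS
#'   fraction (default 0.85).
#' @return the passing candidates, ordered, with `priority` added.
#' @export
rank_candidates <- function(candidates, cds_frac_cutoff = 0.85) {
  cand <- candidates[candidates$pass, , drop = FALSE]
  if (!nrow(cand)) {
    cand$priority <- integer(0)
    return(cand)
  }
  early <- !is.na(cand$cds_frac) & cand$cds_frac <= cds_frac_cutoff
  ord <- order(cand$offtarget_count, -as.integer(cand$in_pfam),
               -as.integer(early), -cand$on_target_score,
               cand$spacer_start, cand$strand)
  cand <- cand[ord, , drop = FALSE]
  cand$priority <- rev(seq_len(nrow(cand)))
  rownames(cand) <- NULL
  cand
}

# end-to-start gap in nt between two 1-based closed intervals (negative
# when they overlap or abut)
interval_gap <- function(s1, e1, s2, e2) {
  pmax(s2 - e1, s1 - e2) - 1L
}

#' Select two constraint-satisfying spacer pairs for a gene
#'
#' Chooses 4 spacers arranged as 2 pairs maximising summed rank priority
#' subject to: >= `min_intra_pair_gap` nt between the protospacer
#' intervals within each pair; >= `min_inter_pair_gap` nt between the two
#' pairs' spanned regions; no pair span overlapping a non-coding element.
#' Exon diversity is a soft lexicographic bonus among assignments of equal
#' priority. The search is exhaustive over the top
#' `max_candidates_considered` ranked candidates (branch-and-bound with a
#' proof-preserving bound, so the result equals the full-enumeration
#' optimum). Genes without a feasible 4-spacer assignment fall back to the
#' best single feasible pair (`status = "partial"`) or `"none"`.
#'
#' @param ranked output of [rank_candidates()] for one gene.
#' @param constraints a [pair_constraints()].
#' @param model a `GenomeModel` (for non-coding intervals).
#' @return list with `status` ("full", "partial", "none") and `pairs`, a
#'   list of candidate-table subsets (2 rows each) ordered by position.
#' @export
build_dual_pairs <- function(ranked, constraints = pair_constraints(),
                             model = NULL) {
  K <- min(nrow(ranked), constraints$max_candidates_considered)
  cand <- ranked[seq_len(K), , drop = FALSE]
  if (K < 2) return(list(status = "none", pairs = list()))
  ncrna <- if (!is.null(model)) model$ncrna else GenomicRanges::GRanges()

  idx <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  gap <- interval_gap(cand$spacer_start[i], cand$spacer_end[i],
                      cand$spacer_start[j], cand$spacer_end[j])
  span_s <- pmin(cand$spacer_start[i], cand$spacer_start[j])
  span_e <- pmax(cand$spacer_end[i], cand$spacer_end[j])
  ok <- gap >= constraints$min_intra_pair_gap
  if (constraints$avoid_ncrna_overlap && length(ncrna) && any(ok)) {
    ov <- overlaps_intervals(cand$contig[1], span_s, span_e, ncrna)
    ok <- ok & !ov
  }
  if (!any(ok)) return(list(status = "none", pairs = list()))
  pairs <- data.frame(i = i[ok], j = j[ok],
                      score = cand$priority[i[ok]] + cand$priority[j[ok]],
                      span_s = span_s[ok], span_e = span_e[ok])
  pairs <- pairs[order(-pairs$score, pairs$i, pairs$j), , drop = FALSE]
  np <- nrow(pairs)

  exon_bonus <- function(rows) {
    ex <- cand$exon_index[rows]
    length(unique(ex[!is.na(ex)]))
  }
  best_obj <- -Inf
  best <- NULL
  for (a in seq_len(np)) {
    # bound: no later pair can beat the incumbent
    if (10 * (pairs$score[a] + pairs$score[a]) + 4 <= best_obj) break
    comp <- seq_len(np) > a &
      pairs$i != pairs$i[a] & pairs$i != pairs$j[a] &
      pairs$j != pairs$i[a] & pairs$j != pairs$j[a] &
      interval_gap(pairs$span_s[a], pairs$span_e[a],
                   pairs$span_s, pairs$span_e) >= constraints$min_inter_pair_gap
    if (!any(comp)) next
    bscore <- max(pairs$score[comp])
    for (b in which(comp & pairs$score == bscore)) {
      rows <- c(pairs$i[a], pairs$j[a], pairs$i[b], pairs$j[b])
      bonus <- if (constraints$require_exon_diversity) exon_bonus(rows) else 0
      obj <- 10 * (pairs$score[a] + bscore) + bonus
      if (obj > best_obj) {
        best_obj <- obj
        best <- list(a = a, b = b)
      }
    }
  }
  if (is.null(best)) {
    # no compatible second pair: emit the single best feasible pair
    p <- pairs[1, ]
    return(list(status = "partial",
                pairs = list(cand[c(p$i, p$j), , drop = FALSE])))
  }
  pa <- pairs[best$a, ]; pb <- pairs[best$b, ]
  plist <- list(cand[c(pa$i, pa$j), , drop = FALSE],
                cand[c(pb$i, pb$j), , drop = FALSE])
  ord <- order(vapply(plist, function(p) min(p$spacer_start), numeric(1)))
  list(status = "full", pairs = plist[ord])
}

#' Select quad arrays covering a gene's isoforms
#'
#' Picks 4 spacers (position-ordered, adjacent protospacer gaps >=
#' `min_intra_pair_gap` nt, span clear of non-coding elements) maximising
#' first the number of CDS-bearing isoforms cut by all four spacers, then
#' summed rank priority. When no single array covers every isoform,
#' additional arrays are emitted for the remaining isoforms until all are
#' covered or no feasible array remains.
#'
#' @param ranked ranked candidates for the gene, carrying an
#'   `isoform_hits` list-column (transcript ids whose CDS contains each
#'   candidate's cut site); [enumerate_spacers_all_isoforms()] provides it.
#' @param constraints a [pair_constraints()].
#' @param model a `GenomeModel`.
#' @return list with `status` ("full", "partial", "none") and `quads`, a
#'   list of 4-row candidate subsets; `covered`, the isoform ids covered.
#' @export
build_quad_arrays <- function(ranked, constraints = pair_constraints(),
                              model = NULL) {
  K <- min(nrow(ranked), constraints$max_candidates_considered)
  cand <- ranked[seq_len(K), , drop = FALSE]
  all_iso <- sort(unique(unlist(cand$isoform_hits)))
  if (K < 4 || !length(all_iso)) {
    return(list(status = if (K < 4) "partial" else "none",
                quads = list(), covered = character(0)))
  }
  ncrna <- if (!is.null(model)) model$ncrna else GenomicRanges::GRanges()
  ord <- order(cand$spacer_start)
  cand <- cand[ord, , drop = FALSE]

  quads <- list()
  remaining <- all_iso
  while (length(remaining)) {
    pick <- best_quad_for(cand, remaining, constraints, ncrna)
    if (is.null(pick)) break
    quads[[length(quads) + 1L]] <- cand[pick$rows, , drop = FALSE]
    remaining <- setdiff(remaining, pick$covered)
  }
  covered <- setdiff(all_iso, remaining)
  status <- if (!length(quads)) "none"
  else if (length(remaining)) "partial" else "full"
  list(status = status, quads = quads, covered = covered)
}

# Best feasible quad among candidates, maximising (#isoforms of `iso_set`
# cut by all 4 spacers, summed priority). Candidates must be
# position-sorted. Returns NULL when no quad cuts any remaining isoform.
best_quad_for <- function(cand, iso_set, constraints, ncrna) {
  K <- nrow(cand)
  hits <- lapply(cand$isoform_hits, intersect, iso_set)
  best <- NULL
  best_key <- c(-1, -Inf)
  for (sub in subsets_by_size(iso_set)) {
    # candidates cutting every isoform in `sub`
    pool <- which(vapply(hits, function(h) all(sub %in% h), logical(1)))
    if (length(pool) < 4) next
    if (best_key[1] > length(sub)) break
    rows <- max_priority_chain(cand, pool, 4L, constraints$min_intra_pair_gap,
                               ncrna, constraints$avoid_ncrna_overlap)
    if (is.null(rows)) next
    key <- c(length(sub), sum(cand$priority[rows]))
    if (key[1] > best_key[1] || (key[1] == best_key[1] && key[2] > best_key[2])) {
      best_key <- key
      best <- list(rows = rows, covered = sub)
    }
  }
  best
}

# all non-empty subsets ordered by decreasing size (|set| is small)
subsets_by_size <- function(set) {
  n <- length(set)
  subs <- unlist(lapply(seq(n, 1), function(k)
    utils::combn(set, k, simplify = FALSE)), recursive = FALSE)
  subs
}

# Maximum-priority chain of m candidates from `pool` (position-sorted
# indices into cand) with adjacent gaps >= min_gap and span clear of
# ncRNA. Dynamic programme per chain start so the span constraint stays
# exact. Returns row indices or NULL.
max_priority_chain <- function(cand, pool, m, min_gap, ncrna, avoid_ncrna) {
  n <- length(pool)
  if (n < m) return(NULL)
  s <- cand$spacer_start[pool]; e <- cand$spacer_end[pool]
  pr <- cand$priority[pool]
  contig <- cand$contig[1]
  check_span <- avoid_ncrna && length(ncrna)
  best_total <- -Inf; best_rows <- NULL
  for (f in seq_len(n - m + 1)) {
    # dp[j, k]: best priority of a k-chain starting at f, ending at j
    dp <- matrix(-Inf, n, m)
    back <- matrix(NA_integer_, n, m)
    dp[f, 1] <- pr[f]
    for (k in 2:m) {
      if (f + k - 1 > n) break
      for (j in seq(f + k - 1, n)) {
        prev <- which(dp[, k - 1] > -Inf & s[j] - e[seq_len(n)] - 1L >= min_gap)
        prev <- prev[prev < j]
        if (!length(prev)) next
        pbest <- prev[which.max(dp[prev, k - 1])]
        dp[j, k] <- dp[pbest, k - 1] + pr[j]
        back[j, k] <- pbest
      }
      if (all(dp[, k] == -Inf)) break
    }
    ends <- which(dp[, m] > -Inf)
    if (!length(ends)) next
    if (check_span) {
      ok <- !overlaps_intervals(contig, rep(s[f], length(ends)), e[ends], ncrna)
      ends <- ends[ok]
      if (!length(ends)) next
    }
    jbest <- ends[which.max(dp[ends, m])]
    if (dp[jbest, m] > best_total) {
      chain <- integer(m); chain[m] <- jbest
      for (k in seq(m, 2)) chain[k - 1] <- back[chain[k], k]
      best_total <- dp[jbest, m]
      best_rows <- pool[chain]
    }
  }
  best_rows
}

#' Generate non-targeting control constructs
#'
#' Emits `n` constructs (2 spacers each in DUAL mode, 4 in QUAD) whose
#' spacers pass every hard filter and have zero genomic matches at up to
#' `max_mismatches` substitutions on either strand, PAM-agnostic.
#' Reproducible for a fixed seed.
#'
#' @param n number of constructs.
#' @param model a `GenomeModel` the controls must avoid.
#' @param mode "DUAL" or "QUAD".
#' @param config a [filter_config()].
#' @param seed RNG seed.
#' @param max_mismatches mismatch budget for the genome-avoidance check.
#' @param index optional prebuilt [build_offtarget_index()].
#' @param max_attempts attempt budget before giving up.
#' @return data.frame with columns `construct_id`, `kind`, `spacer1..4`.
#' @export
generate_ntcs <- function(n, model, mode = c("DUAL", "QUAD"),
                          config = filter_config(), seed = 1L,
                          max_mismatches = 3L, index = NULL,
                          max_attempts = 60L * n) {
  mode <- match.arg(toupper(mode[1]), c("DUAL", "QUAD"))
  per <- if (mode == "DUAL") 2L else 4L
  need <- n * per
  if (n == 0) return(ntc_frame(character(0), mode, per))
  if (is.null(index)) index <- build_offtarget_index(model, config$spacer_len)
  set.seed(seed)
  found <- character(0)
  attempts <- 0L
  while (length(found) < need && attempts < max_attempts) {
    batch <- min(4L * need, max_attempts - attempts)
    sp <- random_dna(batch, config$spacer_len)
    attempts <- attempts + batch
    flags <- apply_filters(data.frame(spacer_seq = sp), config)
    sp <- unique(sp[flags$pass])
    sp <- setdiff(sp, found)
    for (s in sp) {
      if (length(found) >= need) break
      if (genome_match_count(index, s, max_mismatches) == 0L) {
        found <- c(found, s)
      }
    }
  }
  if (length(found) < need) {
    stop("could not find ", need, " valid NTC spacers within attempt budget; ",
         "achieved ", length(found))
  }
  ntc_frame(found[seq_len(need)], mode, per)
}

ntc_frame <- function(spacers, mode, per) {
  n <- length(spacers) %/% per
  mat <- matrix(spacers, ncol = per, byrow = TRUE)
  df <- data.frame(
    construct_id = sprintf("NTC_%04d", seq_len(n)),
    kind = rep(paste0("NTC_", mode), n),
    gene_id = rep("NTC", n))
  for (k in 1:4) {
    df[[paste0("spacer", k)]] <- if (k <= per) mat[, k] else rep(NA_character_, n)
  }
  df
}

#' Assemble a pre-crRNA expression cassette and cloning oligos
#'
#' Each spacer is preceded by its direct repeat:
#' `cassette = DR1 + spacer1 + DR2 + spacer2 + ...`. The sense oligo
#' prepends the 5'-TCCC overhang to the cassette; the antisense oligo
#' prepends 5'-AAAC to the reverse complement. Restriction sites are
#' re-checked on the assembled oligos and reported via `re_flagged`.
#'
#' @param spacers character vector of spacer sequences (>= 1).
#' @param drs direct repeats, one per spacer (a single DR is recycled).
#' @param overhangs length-2 character vector: sense and antisense 5'
#'   overhangs.
#' @param restriction_sites sites re-checked on the assembled oligos.
#' @return list with `cassette_seq`, `sense_oligo`, `antisense_oligo`,
#'   `drs`, `re_flagged`.
#' @export
assemble_cassette <- function(spacers, drs = DEFAULT_DR,
                              overhangs = c(sense = "TCCC", antisense = "AAAC"),
                              restriction_sites = c("GAATTC", "GGTACC")) {
  spacers <- spacers[!is.na(spacers) & nzchar(spacers)]
  if (!length(spacers)) stop("cannot assemble a cassette with no spacers")
  drs <- rep_len(drs, length(spacers))
  cassette <- paste0(paste0(drs, spacers), collapse = "")
  sense <- paste0(overhangs[[1]], cassette)
  antisense <- paste0(overhangs[[2]], revcomp(cassette))
  flagged <- any(contains_site_either_strand(c(sense, antisense),
                                             restriction_sites))
  list(cassette_seq = cassette, sense_oligo = sense,
       antisense_oligo = antisense, drs = drs, re_flagged = flagged)
}

LIBRARY_COLUMNS <- c("construct_id", "kind", "gene_id",
                     paste0("spacer", 1:4), "cassette_seq",
                     "sense_oligo", "antisense_oligo", "re_flagged")

#' Write a library table to TSV
#'
#' One row per construct; lossless round-trip with [read_library()].
#' Duplicate construct ids are fatal.
#'
#' @param table a `LibraryTable` (see [design_dual_library()]) or a bare
#'   construct data.frame.
#' @param path output TSV path.
#' @param report_path optional TSV path for the per-gene design report.
#' @return invisibly, `path`.
#' @export
write_library <- function(table, path, report_path = NULL) {
  constructs <- if (inherits(table, "LibraryTable")) table$constructs else table
  if (anyDuplicated(constructs$construct_id)) {
    stop("duplicate construct_id in library table")
  }
  cols <- intersect(LIBRARY_COLUMNS, names(constructs))
  write.table(constructs[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(report_path) && inherits(table, "LibraryTable")) {
    write.table(table$design_report, report_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a library table written by [write_library()]
#' @param path TSV path.
#' @return a `LibraryTable` with the constructs table.
#' @export
read_library <- function(path) {
  constructs <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(constructs)) {
    constructs$re_flagged <- as.logical(constructs$re_flagged)
  } else {
    constructs$re_flagged <- logical(0)
  }
  if (anyDuplicated(constructs$construct_id)) {
    stop("duplicate construct_id in library file")
  }
  structure(list(constructs = constructs,
                 design_report = data.frame()),
            class = "LibraryTable")
}

#' @export
print.LibraryTable <- function(x, ...) {
  k <- table(x$constructs$kind)
  cat("LibraryTable:", nrow(x$constructs), "constructs (",
      paste(names(k), k, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}
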