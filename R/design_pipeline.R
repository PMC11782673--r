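#' Enumerate candidates over every CDS-bearing isoform of a gene
#'
#' Like [enumerate_spacers()] but pools PAM sites across all transcripts
#' (quad arrays must be able to target isoforms outside the canonical
#' CDS). Candidates are deduplicated by (position, strand) and carry an
#' `isoform_hits` list-column: the transcript ids whose CDS contains the
#' candidate's cut position.
#'
#' @inheritParams enumerate_spacers
#' @return candidate data.frame with `isoform_hits`.
#' @export
enumerate_spacers_all_isoforms <- function(model, gene,
                                           config = filter_config(),
                                           scorer = score_on_target) {
  txs <- Filter(function(t) length(t$cds) > 0, gene$transcripts)
  if (!length(txs)) {
    out <- enumerate_spacers(model, gene, config, scorer)
    out$isoform_hits <- list()
    return(out)
  }
  parts <- lapply(names(txs), function(tid) {
    g2 <- gene
    g2$canonical_transcript_id <- tid
    enumerate_spacers(model, g2, config, scorer)
  })
  cand <- do.call(rbind, parts)
  cand <- cand[!duplicated(cand[c("spacer_start", "strand")]), , drop = FALSE]
  cand <- cand[order(cand$spacer_start, cand$strand), , drop = FALSE]
  canon <- gene$canonical_transcript_id
  if (!is.na(canon) && !is.null(txs[[canon]])) {
    # report cds_frac/exon_index in the canonical frame where defined
    fr <- cds_fraction(txs[[canon]], cand$cut_pos)
    use <- !is.na(fr)
    cand$cds_frac[use] <- fr[use]
    cand$transcript_id[use] <- canon
  }
  cand$isoform_hits <- lapply(cand$cut_pos, function(p) {
    names(txs)[vapply(txs, function(t) !is.na(cds_fraction(t, p)), logical(1))]
  })
  rownames(cand) <- NULL
  cand
}

design_report_row <- function(gene_id, status, n_candidates, note = "") {
  data.frame(gene_id = gene_id, status = status,
             n_candidates = n_candidates, note = note)
}

#' Design a dual (2 x 2-spacer) pre-crRNA library over a genome
#'
#' For every gene: enumerate filtered candidates over the canonical CDS,
#' count CDS off-targets, rank, and select two constraint-satisfying
#' pairs ([build_dual_pairs()]). Adds `n_ntc` non-targeting pairs, then
#' assembles every construct's direct-repeat cassette and cloning oligos.
#' Deterministic for fixed inputs and seed.
#'
#' @param model a `GenomeModel`.
#' @param config a [filter_config()].
#' @param constraints a [pair_constraints()].
#' @param n_ntc number of non-targeting control pairs (default 500).
#' @param seed RNG seed (non-targeting controls are the only random step).
#' @param max_mismatches off-target mismatch budget.
#' @param drs direct repeat(s) for cassette assembly.
#' @param scorer on-target scorer passed to [enumerate_spacers()].
#' @return a `LibraryTable`: `constructs` data.frame plus a per-gene
#'   `design_report` (status fully_designed / partial / non_designable).
#' @export
design_dual_library <- function(model, config = filter_config(),
                                constraints = pair_constraints(),
                                n_ntc = 500L, seed = 1L,
                                max_mismatches = 3L, drs = DEFAULT_DR,
                                scorer = score_on_target) {
  index <- build_offtarget_index(model, config$spacer_len)
  constructs <- list()
  report <- list()
  for (g in model$genes) {
    cand <- enumerate_spacers(model, g, config, scorer)
    cand <- cand[cand$pass, , drop = FALSE]
    if (!nrow(cand)) {
      report[[g$gene_id]] <- design_report_row(g$gene_id, "non_designable", 0L)
      next
    }
    cand <- count_cds_offtargets(cand, max_mismatches = max_mismatches,
                                 index = index)
    ranked <- rank_candidates(cand)
    sel <- build_dual_pairs(ranked, constraints, model)
    if (sel$status == "none") {
      report[[g$gene_id]] <- design_report_row(g$gene_id, "non_designable",
                                               nrow(ranked),
                                               "no feasible pair")
      next
    }
    status <- if (sel$status == "full") "fully_designed" else "partial"
    report[[g$gene_id]] <- design_report_row(g$gene_id, status, nrow(ranked))
    for (pi in seq_along(sel$pairs)) {
      p <- sel$pairs[[pi]]
      constructs[[length(constructs) + 1L]] <- data.frame(
        construct_id = paste0(g$gene_id, "_pair", pi),
        kind = "DUAL", gene_id = g$gene_id,
        spacer1 = p$spacer_seq[1], spacer2 = p$spacer_seq[2],
        spacer3 = NA_character_, spacer4 = NA_character_,
        contig = p$contig[1],
        spacer_starts = paste(p$spacer_start, collapse = ","),
        spacer_ends = paste(p$spacer_end, collapse = ","))
    }
  }
  ntc <- generate_ntcs(n_ntc, model, "DUAL", config, seed = seed,
                       index = index)
  finish_library(constructs, ntc, report, drs, config)
}

#' Design a quad (4-spacer array) pre-crRNA library over a genome
#'
#' One four-spacer array per gene targeting all CDS-bearing isoforms when
#' a feasible non-coding-free region exists; otherwise the primary array
#' covers the maximal isoform set and additional arrays are emitted for
#' the remaining isoforms ([build_quad_arrays()]). Non-targeting controls
#' are quad arrays.
#'
#' @inheritParams design_dual_library
#' @return a `LibraryTable`.
#' @export
design_quad_library <- function(model, config = filter_config(),
                                constraints = pair_constraints(),
                                n_ntc = 500L, seed = 1L,
                                max_mismatches = 3L, drs = DEFAULT_DR,
                                scorer = score_on_target) {
  index <- build_offtarget_index(model, config$spacer_len)
  constructs <- list()
  report <- list()
  for (g in model$genes) {
    cand <- enumerate_spacers_all_isoforms(model, g, config, scorer)
    cand <- cand[cand$pass, , drop = FALSE]
    if (!nrow(cand)) {
      report[[g$gene_id]] <- design_report_row(g$gene_id, "non_designable", 0L)
      next
    }
    cand <- count_cds_offtargets(cand, max_mismatches = max_mismatches,
                                 index = index)
    ranked <- rank_candidates(cand)
    sel <- build_quad_arrays(ranked, constraints, model)
    if (!length(sel$quads)) {
      report[[g$gene_id]] <- design_report_row(g$gene_id, "non_designable",
                                               nrow(ranked),
                                               "no feasible quad")
      next
    }
    status <- if (sel$status == "full") "fully_designed" else "partial"
    report[[g$gene_id]] <- design_report_row(
      g$gene_id, status, nrow(ranked),
      paste0("isoforms_covered=", length(sel$covered)))
    for (qi in seq_along(sel$quads)) {
      q <- sel$quads[[qi]]
      constructs[[length(constructs) + 1L]] <- data.frame(
        construct_id = paste0(g$gene_id, "_quad", qi),
        kind = "QUAD", gene_id = g$gene_id,
        spacer1 = q$spacer_seq[1], spacer2 = q$spacer_seq[2],
        spacer3 = q$spacer_seq[3], spacer4 = q$spacer_seq[4],
        contig = q$contig[1],
        spacer_starts = paste(q$spacer_start, collapse = ","),
        spacer_ends = paste(q$spacer_end, collapse = ","))
    }
  }
  ntc <- generate_ntcs(n_ntc, model, "QUAD", config, seed = seed,
                       index = index)
  finish_library(constructs, ntc, report, drs, config)
}

finish_library <- function(constructs, ntc, report, drs, config) {
  constructs <- if (length(constructs)) do.call(rbind, constructs) else NULL
  if (!is.null(constructs) && nrow(ntc)) {
    for (col in setdiff(names(constructs), names(ntc))) ntc[[col]] <- NA
    for (col in setdiff(names(ntc), names(constructs))) constructs[[col]] <- NA
    ntc <- ntc[names(constructs)]
  }
  all_constructs <- rbind(constructs, ntc)
  if (is.null(all_constructs) || !nrow(all_constructs)) {
    stop("library design produced no constructs")
  }
  asm <- lapply(seq_len(nrow(all_constructs)), function(i) {
    sp <- unlist(all_constructs[i, paste0("spacer", 1:4)])
    assemble_cassette(sp, drs = drs,
                      restriction_sites = config$restriction_sites)
  })
  all_constructs$cassette_seq <- vapply(asm, `[[`, "", "cassette_seq")
  all_constructs$sense_oligo <- vapply(asm, `[[`, "", "sense_oligo")
  all_constructs$antisense_oligo <- vapply(asm, `[[`, "", "antisense_oligo")
  all_constructs$re_flagged <- vapply(asm, `[[`, logical(1), "re_flagged")
  rownames(all_constructs) <- NULL
  design_report <- if (length(report)) {
    do.call(rbind, c(report, list(make.row.names = FALSE)))
  } else data.frame()
  structure(list(constructs = all_constructs, design_report = design_report),
            class = "LibraryTable")
}
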