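#' Direct repeat recognised by Cas12a during pre-crRNA maturation
#' @export
DEFAULT_DR <- "TAATTTCTACTCTTGTAGAT"

#' Hard-filter configuration for spacer candidates
#'
#' Defaults follow the dual-library design rules: GC strictly between 20
#' and 80 percent, no poly-T stretch (>= 4 consecutive T, a Pol III
#' terminator), no EcoRI (GAATTC) or KpnI (GGTACC) recognition site in the
#' cloning context, 23-nt spacers at TTTV PAMs.
#'
#' @param gc_min_pct,gc_max_pct strict GC bounds in percent.
#' @param poly_t_min_run minimum run of T that disqualifies a spacer.
#' @param restriction_sites recognition sites checked on both strands of
#'   the assembled cloning context.
#' @param spacer_len spacer length in nt.
#' @param pam_patterns IUPAC PAM patterns (read on the protospacer strand,
#'   immediately 5' of the protospacer).
#' @return a `FilterConfig` list.
#' @export
filter_config <- function(gc_min_pct = 20, gc_max_pct = 80,
                          poly_t_min_run = 4L,
                          restriction_sites = c(EcoRI = "GAATTC",
                                                KpnI = "GGTACC"),
                          spacer_len = 23L, pam_patterns = "TTTV") {
  stopifnot(gc_min_pct >= 0, gc_min_pct < gc_max_pct, gc_max_pct <= 100,
            poly_t_min_run >= 1, spacer_len >= 8)
  structure(list(gc_min_pct = gc_min_pct, gc_max_pct = gc_max_pct,
                 poly_t_min_run = as.integer(poly_t_min_run),
                 restriction_sites = restriction_sites,
                 spacer_len = as.integer(spacer_len),
                 pam_patterns = pam_patterns),
            class = "FilterConfig")
}

# Cut-site offset within the protospacer: Cas12a cuts ~18 nt distal to the
# PAM (0-based from the PAM-proximal end); used to test the 85%-CDS rule.
CUT_OFFSET <- 18L

#' Scan a sequence for Cas12a spacer candidates
#'
#' Enumerates every PAM match on both strands whose full-length
#' protospacer fits inside the sequence. Coordinates are reported in the
#' frame of the supplied sequence (shift with `offset` to express them on
#' a larger contig). `spacer_seq` reads 5' to 3' on the protospacer
#' strand, starting adjacent to the PAM.
#'
#' @param seq a DNA string (character or `DNAString`).
#' @param config a [filter_config()].
#' @param contig contig name recorded in the output.
#' @param offset added to all reported coordinates.
#' @return data.frame of candidate sites ordered by position then strand.
#' @export
scan_spacers <- function(seq, config = filter_config(), contig = "seq",
                         offset = 0L) {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  s <- as.character(seq)
  L <- nchar(s)
  sl <- config$spacer_len
  frames <- list(empty_scan_frame())
  for (pam in config$pam_patterns) {
    pw <- nchar(pam)
    if (L < pw + sl) next
    # plus strand: PAM then protospacer to its right
    p <- Biostrings::start(Biostrings::matchPattern(pam, seq, fixed = FALSE))
    p <- p[p + pw - 1L + sl <= L]
    if (length(p)) {
      frames[[length(frames) + 1L]] <- data.frame(
        contig = contig, strand = "+",
        pam_start = p + offset,
        pam_seq = substring(s, p, p + pw - 1L),
        spacer_start = p + pw + offset,
        spacer_end = p + pw + sl - 1L + offset,
        spacer_seq = substring(s, p + pw, p + pw + sl - 1L),
        cut_pos = p + pw + CUT_OFFSET + offset)
    }
    # minus strand: genome carries revcomp(PAM); protospacer to its left
    q <- Biostrings::start(Biostrings::matchPattern(revcomp(pam), seq,
                                                    fixed = FALSE))
    q <- q[q > sl]
    if (length(q)) {
      frames[[length(frames) + 1L]] <- data.frame(
        contig = contig, strand = "-",
        pam_start = q + offset,
        pam_seq = revcomp(substring(s, q, q + pw - 1L)),
        spacer_start = q - sl + offset,
        spacer_end = q - 1L + offset,
        spacer_seq = revcomp(substring(s, q - sl, q - 1L)),
        cut_pos = q - 1L - CUT_OFFSET + offset)
    }
  }
  out <- do.call(rbind, frames)
  out <- out[order(out$spacer_start, out$strand), , drop = FALSE]
  out <- out[!duplicated(out[c("spacer_start", "strand")]), , drop = FALSE]
  rownames(out) <- NULL
  out$gc_percent <- gc_percent(out$spacer_seq)
  out
}

empty_scan_frame <- function() {
  data.frame(contig = character(0), strand = character(0),
             pam_start = integer(0), pam_seq = character(0),
             spacer_start = integer(0), spacer_end = integer(0),
             spacer_seq = character(0), cut_pos = integer(0))
}

FILTER_FLAGS <- c("POLY_T", "GC_LOW", "GC_HIGH", "RESTRICTION_SITE",
                  "AMBIGUOUS_BASE")

#' Apply hard sequence filters to spacer candidates
#'
#' Sets `filter_flags` (comma-separated subset of POLY_T, GC_LOW, GC_HIGH,
#' RESTRICTION_SITE, AMBIGUOUS_BASE) and `pass` (no flags). GC bounds are
#' strict inequalities. Restriction sites are searched on both strands of
#' the spacer in its cloning context (direct repeat + spacer); the fully
#' assembled oligo is re-checked at cassette assembly.
#'
#' @param candidates data.frame with a `spacer_seq` column.
#' @param config a [filter_config()].
#' @param dr direct-repeat context used for the restriction-site scan.
#' @return `candidates` with flag columns set (idempotent).
#' @export
apply_filters <- function(candidates, config = filter_config(),
                          dr = DEFAULT_DR) {
  sp <- candidates$spacer_seq
  if (is.null(candidates$gc_percent)) candidates$gc_percent <- gc_percent(sp)
  gc <- candidates$gc_percent
  flag <- list(
    POLY_T = has_base_run(sp, "T", config$poly_t_min_run),
    GC_LOW = gc < config$gc_min_pct,
    GC_HIGH = gc > config$gc_max_pct,
    RESTRICTION_SITE = contains_site_either_strand(paste0(dr, sp),
                                                   config$restriction_sites),
    AMBIGUOUS_BASE = grepl("[^ACGT]", sp)
  )
  mat <- do.call(cbind, flag)
  candidates$filter_flags <- apply(mat, 1, function(r)
    paste(FILTER_FLAGS[r], collapse = ","))
  candidates$pass <- !apply(mat, 1, any)
  candidates
}

#' Enumerate filtered spacer candidates over a gene's canonical CDS
#'
#' One candidate per PAM match (both strands) whose predicted cut position
#' lies within the canonical transcript's CDS. Populates the spliced-CDS
#' fraction of the cut site, the exon index (transcription order), Pfam
#' overlap of the protospacer, hard-filter flags and the on-target score.
#' Off-target counts are filled in by [count_cds_offtargets()].
#'
#' @param model a `GenomeModel`.
#' @param gene a `GeneModel` from `model`.
#' @param config a [filter_config()].
#' @param scorer on-target scorer, `function(spacer_seq, pam_seq)`;
#'   defaults to [score_on_target()].
#' @return data.frame of candidates ordered by position then strand;
#'   zero rows for non-designable genes.
#' @export
enumerate_spacers <- function(model, gene, config = filter_config(),
                              scorer = score_on_target) {
  empty <- scan_spacers("", config)
  empty$gene_id <- character(0); empty$transcript_id <- character(0)
  empty$cds_frac <- numeric(0); empty$exon_index <- integer(0)
  empty$in_pfam <- logical(0); empty$filter_flags <- character(0)
  empty$pass <- logical(0); empty$on_target_score <- numeric(0)
  empty$offtarget_count <- integer(0)
  tid <- gene$canonical_transcript_id
  if (is.na(tid)) return(empty)
  tx <- gene$transcripts[[tid]]
  if (!length(tx$cds)) return(empty)
  contig_seq <- model$contigs[[gene$contig]]
  margin <- config$spacer_len + 4L
  lo <- max(1L, min(IRanges::start(tx$exons)) - margin)
  hi <- min(length(contig_seq), max(IRanges::end(tx$exons)) + margin)
  cand <- scan_spacers(contig_seq[lo:hi], config, contig = gene$contig,
                       offset = lo - 1L)
  if (!nrow(cand)) return(empty)
  in_cds <- !is.na(cds_fraction(tx, cand$cut_pos))
  cand <- cand[in_cds, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand$gene_id <- gene$gene_id
  cand$transcript_id <- tid
  cand$cds_frac <- cds_fraction(tx, cand$cut_pos)
  cand$exon_index <- exon_index_of(tx, cand$cut_pos)
  cand$in_pfam <- overlaps_intervals(gene$contig, cand$spacer_start,
                                     cand$spacer_end, model$pfam)
  cand <- apply_filters(cand, config)
  cand$on_target_score <- mapply(scorer, cand$spacer_seq, cand$pam_seq,
                                 USE.NAMES = FALSE)
  cand$offtarget_count <- NA_integer_
  rownames(cand) <- NULL
  cand
}

# Exon index (in transcription order) containing each position; NA outside.
exon_index_of <- function(tx, pos) {
  ex <- tx$exons
  st <- IRanges::start(ex); en <- IRanges::end(ex)
  idx <- vapply(pos, function(p) {
    i <- which(p >= st & p <= en)[1]
    if (is.na(i)) NA_integer_ else i
  }, integer(1))
  if (tx$strand == "-") idx <- length(ex) + 1L - idx
  idx
}

#' Surrogate on-target activity score
#'
#' A fixed, documented logistic stand-in for gradient-boosting activity
#' predictors whose weights are not redistributable. Combines PAM
#' canonicalness (exact TTTV), GC distance from 50%, and penalties for
#' homopolymer runs. Deterministic, in \[0, 1\]; a canonical PAM never
#' scores below the same spacer behind a non-canonical PAM. Any scorer
#' with the same signature can be plugged into [enumerate_spacers()].
#'
#' @param spacer_seq spacer sequence(s).
#' @param pam_seq matching PAM sequence(s) (protospacer-strand).
#' @param context_seq optional PAM+protospacer context; when supplied it
#'   must be at least 4 + spacer length nt and overrides the other
#'   arguments (first 4 nt = PAM, rest = spacer).
#' @return numeric score(s) in \[0, 1\].
#' @export
score_on_target <- function(spacer_seq, pam_seq = "TTTT",
                            context_seq = NULL) {
  if (!is.null(context_seq)) {
    if (any(nchar(context_seq) < 4 + nchar(spacer_seq[1])))
      stop("context_seq too short: need PAM + protospacer")
    pam_seq <- substr(context_seq, 1, 4)
    spacer_seq <- substr(context_seq, 5, nchar(context_seq))
  }
  canonical <- grepl("^TTT[ACG]$", pam_seq)
  gc <- gc_percent(spacer_seq)
  run <- pmax(max_base_run(spacer_seq, "A"), max_base_run(spacer_seq, "C"),
              max_base_run(spacer_seq, "G"), max_base_run(spacer_seq, "T"))
  z <- 0.8 + 1.2 * canonical - 0.05 * abs(gc - 50) - 0.4 * pmax(0, run - 3)
  stats::plogis(z)
}
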