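#' Configuration for the synthetic mini-genome simulator
#'
#' The generator plants, in every gene's CDS, regularly spaced canonical
#' TTTV PAM sites followed by filter-clean 23-mers, so designability is
#' guaranteed by construction; the background sequence is uniform random
#' and contributes additional (possibly filter-failing) candidates. A
#' stated fraction of genes carry a planted non-coding element inside
#' their CDS span (so naive spacer pairs are rejected) and a fraction are
#' multi-isoform (one exon skipped in the second isoform).
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range (min, max).
#' @param cds_length CDS length range in nt; must accommodate
#'   `min_design_sites` planted sites at `site_spacing`.
#' @param frac_multi_isoform fraction of (multi-exon) genes given a
#'   second isoform.
#' @param frac_ncrna_genes fraction of genes with a planted non-coding
#'   element inside the CDS span.
#' @param n_ncrna_intergenic additional intergenic non-coding elements.
#' @param frac_pfam_genes fraction of genes with a Pfam interval.
#' @param site_spacing genomic spacing of planted PAM sites (nt); 80 nt
#'   leaves >= 25 nt between adjacent protospacers and >= 50 nt between
#'   pair spans.
#' @param min_design_sites minimum planted sites per gene.
#' @param intergenic_gap intergenic spacer length (nt).
#' @param seed RNG seed; fixed seed implies byte-identical outputs.
#' @return a `SimGenomeConfig` list.
#' @export
sim_genome_config <- function(n_genes = 20L, exons_per_gene = c(1L, 3L),
                              cds_length = c(700L, 1200L),
                              frac_multi_isoform = 0.25,
                              frac_ncrna_genes = 0.15,
                              n_ncrna_intergenic = 5L,
                              frac_pfam_genes = 0.5,
                              site_spacing = 80L, min_design_sites = 6L,
                              intergenic_gap = 300L, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "SimGenomeConfig")
  if (cds_length[1] < min_design_sites * site_spacing %/% 2) {
    stop("infeasible config: CDS too short for the requested PAM site density")
  }
  cfg
}

# lazily refilled pool of 23-mers guaranteed to pass every hard filter in
# their DR context (batch generation keeps the filter scan vectorised)
planted_spacer_pool <- function(config = filter_config(), batch = 500L) {
  pool <- character(0)
  function() {
    while (!length(pool)) {
      s <- vapply(seq_len(batch), function(i)
        paste(sample(c("A", "C", "G", "T"), 23, replace = TRUE,
                     prob = c(0.28, 0.22, 0.22, 0.28)), collapse = ""),
        character(1))
      f <- apply_filters(data.frame(spacer_seq = s), config)
      pool <<- s[f$pass]
    }
    out <- pool[1]
    pool <<- pool[-1]
    out
  }
}

# one exon's sequence with planted PAM+spacer units; returns sequence and
# local PAM offsets
planted_exon <- function(len, spacing, draw_spacer) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  k <- max(1L, (len - 34L) %/% spacing)
  pam_at <- 4L + (seq_len(k) - 1L) * spacing
  pam_at <- pam_at[pam_at + 26L <= len]
  for (p in pam_at) {
    unit <- paste0("TTT", sample(c("A", "C", "G"), 1), draw_spacer())
    chars[p:(p + 26L)] <- strsplit(unit, "")[[1]]
  }
  list(seq = paste(chars, collapse = ""), pam_at = pam_at)
}

#' Simulate a designable mini-genome
#'
#' Generates a `GenomeModel` (and optionally its FASTA/GFF3/BED files)
#' with planted spacer sites, non-coding elements, Pfam intervals and
#' multi-isoform genes, plus a truth record of everything planted.
#' A pure function of (config); identical configs give identical output.
#'
#' @param config a [sim_genome_config()].
#' @param outdir optional directory; when given, FASTA, GFF3 and BED
#'   files are written there and their paths returned.
#' @return list: `model` (a `GenomeModel`), `truth` (per-gene
#'   data.frame), `files` (named paths or NULL).
#' @export
simulate_genome <- function(config = sim_genome_config(), outdir = NULL) {
  set.seed(config$seed)
  draw_spacer <- planted_spacer_pool(filter_config())
  contig_parts <- character(0)
  offset <- 0L
  genes <- list()
  truth <- list()
  ncrna <- list()
  pfam <- list()

  add_gap <- function(len) {
    contig_parts[[length(contig_parts) + 1L]] <<- paste(
      sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    offset <<- offset + len
  }

  for (gi in seq_len(config$n_genes)) {
    gid <- sprintf("G%04d", gi)
    add_gap(config$intergenic_gap)
    n_ex <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1)
    cds_len <- sample(seq(config$cds_length[1], config$cds_length[2]), 1)
    ex_lens <- rep(cds_len %/% n_ex, n_ex)
    ex_lens[n_ex] <- cds_len - sum(ex_lens[-n_ex])
    strand <- sample(c("+", "-"), 1)
    has_nc <- runif(1) < config$frac_ncrna_genes
    multi <- n_ex >= 2 && runif(1) < config$frac_multi_isoform
    has_pf <- runif(1) < config$frac_pfam_genes

    # build the gene block in plus-strand orientation, then flip if needed
    block <- character(0)
    local_len <- 0L
    ex_local <- matrix(0L, n_ex, 2)  # local start/end of each exon
    nc_local <- NULL
    for (e in seq_len(n_ex)) {
      if (e > 1) {
        ilen <- sample(120:250, 1)
        if (has_nc && is.null(nc_local) && e == 2) {
          # non-coding element in the middle of the first intron
          nc_local <- c(local_len + ilen %/% 2 - 30L,
                        local_len + ilen %/% 2 + 30L)
        }
        block[[length(block) + 1L]] <- paste(
          sample(c("A", "C", "G", "T"), ilen, replace = TRUE), collapse = "")
        local_len <- local_len + ilen
      }
      pe <- planted_exon(ex_lens[e], config$site_spacing, draw_spacer)
      if (has_nc && is.null(nc_local) && n_ex == 1 && length(pe$pam_at) >= 4) {
        # single-exon gene: element in the gap between planted sites 3 and 4
        g0 <- local_len + pe$pam_at[3] + 27L + 8L
        nc_local <- c(g0, g0 + 30L)
      }
      ex_local[e, ] <- c(local_len + 1L, local_len + ex_lens[e])
      block[[length(block) + 1L]] <- pe$seq
      local_len <- local_len + ex_lens[e]
    }
    block <- paste(block, collapse = "")
    if (strand == "-") {
      block <- revcomp(block)
      ex_local <- cbind(local_len - ex_local[, 2] + 1L,
                        local_len - ex_local[, 1] + 1L)
      ex_local <- ex_local[rev(seq_len(n_ex)), , drop = FALSE]
      if (!is.null(nc_local)) {
        nc_local <- c(local_len - nc_local[2] + 1L, local_len - nc_local[1] + 1L)
      }
    }
    ex <- IRanges::IRanges(offset + ex_local[, 1], offset + ex_local[, 2])
    t1 <- new_transcript_model(paste0(gid, ".t1"), "chr1", strand, ex, ex,
                               canonical_tag = runif(1) < 0.5)
    txs <- setNames(list(t1), t1$transcript_id)
    if (multi) {
      drop <- sample(seq_len(n_ex), 1)
      ex2 <- ex[-drop]
      t2 <- new_transcript_model(paste0(gid, ".t2"), "chr1", strand, ex2, ex2)
      txs[[t2$transcript_id]] <- t2
    }
    gene <- structure(list(gene_id = gid, contig = "chr1", strand = strand,
                           transcripts = txs,
                           canonical_transcript_id = NA_character_),
                      class = "GeneModel")
    gene$canonical_transcript_id <- select_canonical_transcript(gene)
    genes[[gid]] <- gene
    if (!is.null(nc_local)) {
      ncrna[[length(ncrna) + 1L]] <- c(offset + nc_local[1], offset + nc_local[2])
    }
    if (has_pf) {
      fe <- ex_local[1, ]
      pfam[[length(pfam) + 1L]] <- list(
        start = offset + fe[1], end = offset + fe[1] + (fe[2] - fe[1]) %/% 2,
        id = sprintf("PF%05d", gi))
    }
    contig_parts[[length(contig_parts) + 1L]] <- block
    offset <- offset + local_len
    truth[[gid]] <- data.frame(
      gene_id = gid, strand = strand, n_exons = n_ex, cds_length = cds_len,
      multi_isoform = multi, has_ncrna = !is.null(nc_local),
      in_pfam = has_pf)
  }
  add_gap(config$intergenic_gap)
  for (i in seq_len(config$n_ncrna_intergenic)) {
    # drop intergenic elements in the terminal gap
    s <- offset - config$intergenic_gap + 10L + (i - 1L) * 50L
    if (s + 30L < offset) ncrna[[length(ncrna) + 1L]] <- c(s, s + 30L)
  }

  contig <- Biostrings::DNAStringSet(paste(contig_parts, collapse = ""))
  names(contig) <- "chr1"
  ncrna_gr <- if (length(ncrna)) {
    m <- do.call(rbind, ncrna)
    BiocGenerics::sort(BiocGenerics::unique(GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(m[, 1], m[, 2]))))
  } else GenomicRanges::GRanges()
  pfam_gr <- if (length(pfam)) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
      vapply(pfam, `[[`, numeric(1), "start"),
      vapply(pfam, `[[`, numeric(1), "end")))
    gr$domain_id <- vapply(pfam, `[[`, "", "id")
    gr
  } else GenomicRanges::GRanges()

  model <- validate_genome_model(structure(list(
    contigs = contig, genes = genes, ncrna = ncrna_gr, pfam = pfam_gr
  ), class = "GenomeModel"))

  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- c(fasta = file.path(outdir, "genome.fa"),
               gff = file.path(outdir, "genome.gff3"),
               pfam = file.path(outdir, "pfam.bed"),
               ncrna = file.path(outdir, "ncrna.bed"))
    write_genome(model, files["fasta"], files["gff"], files["pfam"],
                 files["ncrna"])
  }
  list(model = model, truth = do.call(rbind, c(truth,
         list(make.row.names = FALSE))), files = files)
}

#' Configuration for the screen count simulator
#'
#' @param coverage mean reads per construct (default 300, the target
#'   screening coverage).
#' @param n_replicates replicates per condition (default 6).
#' @param dispersion negative-binomial dispersion
#'   (`var = mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param abundance_sdlog log-normal SD of baseline construct abundance.
#' @return a `SimScreenConfig` list.
#' @export
sim_screen_config <- function(coverage = 300, n_replicates = 6L,
                              dispersion = 0.05, abundance_sdlog = 0.25) {
  stopifnot(coverage > 0, dispersion >= 0)
  structure(as.list(environment()), class = "SimScreenConfig")
}

#' Simulate screen counts with planted effects
#'
#' Counts are negative binomial with mean proportional to a baseline
#' log-normal construct abundance scaled per condition by
#' `2^(planted logFC)` and renormalised (selection redistributes reads).
#' Non-targeting controls always have logFC 0. The truth record gives
#' every construct's planted logFC per condition.
#'
#' @param library a `LibraryTable`.
#' @param conditions named list: condition -> named numeric of planted
#'   gene-level logFCs (constructs of unlisted genes get 0). The first
#'   condition is conventionally the input/reference.
#' @param config a [sim_screen_config()].
#' @param seed RNG seed.
#' @return list: `counts` (a `ScreenCounts` whose samples carry condition
#'   and replicate), `truth` (construct x condition logFC data.frame).
#' @export
simulate_screen_counts <- function(library,
                                   conditions = list(input = NULL,
                                                     treated = NULL),
                                   config = sim_screen_config(), seed = 1L) {
  set.seed(seed)
  constructs <- library$constructs
  n <- nrow(constructs)
  base <- exp(rnorm(n, 0, config$abundance_sdlog))
  base <- base / sum(base)
  sample_ids <- character(0)
  meta <- list()
  cols <- list()
  truth_lfc <- matrix(0, n, length(conditions),
                      dimnames = list(constructs$construct_id,
                                      names(conditions)))
  for (cond in names(conditions)) {
    eff <- conditions[[cond]]
    lfc <- rep(0, n)
    if (length(eff)) {
      hit <- constructs$gene_id %in% names(eff)
      lfc[hit] <- unname(eff[constructs$gene_id[hit]])
    }
    truth_lfc[, cond] <- lfc
    ab <- base * 2^lfc
    ab <- ab / sum(ab)
    mu <- config$coverage * n * ab
    for (r in seq_len(config$n_replicates)) {
      cnt <- if (config$dispersion > 0) {
        rnbinom(n, mu = mu, size = 1 / config$dispersion)
      } else {
        stats::rpois(n, mu)
      }
      sid <- paste0(cond, "_r", r)
      sample_ids <- c(sample_ids, sid)
      meta[[sid]] <- data.frame(sample_id = sid, condition = cond,
                                replicate = r)
      cols[[sid]] <- cnt
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- constructs$construct_id
  sc <- new_screen_counts(counts,
                          do.call(rbind, c(meta, list(make.row.names = FALSE))))
  list(counts = sc, truth = as.data.frame(truth_lfc))
}

# fixed synthetic vector context 5' of the cassette (ends like an hU6
# transcription start so the first direct repeat follows immediately)
SIM_VECTOR_PREFIX <- "GACGAAACACCGTGCTCAGT"

#' Simulate pre-crRNA array amplicon reads
#'
#' Each read is the synthetic vector prefix plus the construct's cassette,
#' padded with vector sequence to an amplicon length drawn uniformly in
#' \[250, 350\] nt, truncated to `read_length`, with independent per-base
#' substitution errors. Truth maps each read id to its construct.
#'
#' @param library a `LibraryTable`.
#' @param abundances construct sampling probabilities (must sum to 1
#'   within 1e-6), in library order or named by construct id.
#' @param n_reads number of reads.
#' @param error_rate per-base substitution probability.
#' @param read_length read length in nt.
#' @param seed RNG seed.
#' @param path FASTQ output path.
#' @return list: `path`, `truth` (data.frame read_id, construct_id).
#' @export
simulate_array_reads <- function(library, abundances, n_reads,
                                 error_rate = 0, read_length = 100L,
                                 seed = 1L, path = tempfile(fileext = ".fastq")) {
  constructs <- library$constructs
  if (!is.null(names(abundances))) {
    abundances <- abundances[constructs$construct_id]
  }
  if (length(abundances) != nrow(constructs)) {
    stop("abundances must have one entry per construct")
  }
  if (abs(sum(abundances) - 1) > 1e-6) {
    stop("abundances must sum to 1 (tolerance 1e-6)")
  }
  set.seed(seed)
  if (n_reads == 0) {
    file.create(path)
    return(list(path = path,
                truth = data.frame(read_id = character(0),
                                   construct_id = character(0))))
  }
  pick <- sample.int(nrow(constructs), n_reads, replace = TRUE,
                     prob = abundances)
  amp_len <- sample(250:350, n_reads, replace = TRUE)
  pad <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  templates <- paste0(SIM_VECTOR_PREFIX, constructs$cassette_seq[pick], pad)
  reads <- substr(templates, 1L, pmin(read_length, amp_len))
  if (error_rate > 0) {
    reads <- vapply(reads, function(r) {
      ch <- strsplit(r, "")[[1]]
      err <- runif(length(ch)) < error_rate
      if (any(err)) {
        ch[err] <- vapply(ch[err], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      }
      paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  ids <- sprintf("read%06d", seq_len(n_reads))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n",
                    strrep("I", nchar(reads))), con)
  list(path = path,
       truth = data.frame(read_id = ids,
                          construct_id = constructs$construct_id[pick]))
}
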