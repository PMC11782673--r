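#' @import methods
NULL

NCRNA_GFF_TYPES <- c("miRNA", "tRNA", "lncRNA", "rRNA", "snRNA", "snoRNA")

#' Read a genome model from FASTA + GFF3 (+ optional BED tracks)
#'
#' Ingests a genome sequence and its annotation into a validated object
#' model used by the library designer. Non-coding RNA features present in
#' the GFF3 (types miRNA, tRNA, lncRNA, rRNA, snRNA, snoRNA) are merged
#' with the optional ncRNA BED track; Pfam domain intervals come from the
#' optional Pfam BED track. All internal coordinates are 1-based closed
#' (IRanges convention); GFF3 is taken as-is and BED is converted on import.
#'
#' @param fasta_path path to a genome FASTA file.
#' @param gff_path path to a GFF3 annotation (Ensembl dialect:
#'   gene/mRNA/exon/CDS features linked by `Parent` attributes).
#' @param pfam_bed_path optional BED file of Pfam domain intervals
#'   (name column = domain id).
#' @param ncrna_bed_path optional BED file of non-coding elements.
#' @return a `GenomeModel`: list with `contigs` (DNAStringSet), `genes`
#'   (named list of gene models), `ncrna` and `pfam` (GRanges).
#' @export
read_genome <- function(fasta_path, gff_path, pfam_bed_path = NULL,
                        ncrna_bed_path = NULL) {
  contigs <- Biostrings::readDNAStringSet(fasta_path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  bad <- grepl("[^ACGTN]", as.character(contigs))
  if (any(bad)) {
    stop("contig(s) contain characters other than A/C/G/T/N: ",
         paste(names(contigs)[bad], collapse = ", "))
  }

  gff <- rtracklayer::import(gff_path, format = "gff3")
  feat_contig <- as.character(GenomicRanges::seqnames(gff))
  unknown <- setdiff(unique(feat_contig), names(contigs))
  if (length(unknown)) {
    stop("GFF3 features reference contig(s) absent from the FASTA: ",
         paste(unknown, collapse = ", "))
  }

  type <- as.character(gff$type)
  ids <- as.character(gff$ID %||% rep(NA_character_, length(gff)))
  parents <- gff$Parent
  parent1 <- vapply(seq_along(gff), function(i) {
    p <- parents[[i]]
    if (length(p)) as.character(p[1]) else NA_character_
  }, character(1))

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript")
  genes <- list()
  tx_by_gene <- split(which(is_tx), parent1[is_tx])

  # map transcript id -> exon / CDS rows
  child_rows <- which(type %in% c("exon", "CDS"))
  rows_by_parent <- split(child_rows, parent1[child_rows])

  tag_col <- intersect(c("tag", "Tag"), names(S4Vectors::mcols(gff)))

  for (gi in which(is_gene)) {
    gid <- ids[gi]
    gstrand <- as.character(GenomicRanges::strand(gff)[gi])
    gcontig <- feat_contig[gi]
    txs <- list()
    for (ti in tx_by_gene[[gid]] %||% integer(0)) {
      tid <- ids[ti]
      rows <- rows_by_parent[[tid]] %||% integer(0)
      ex_rows <- rows[type[rows] == "exon"]
      cds_rows <- rows[type[rows] == "CDS"]
      exons <- IRanges::IRanges(GenomicRanges::start(gff)[ex_rows],
                                GenomicRanges::end(gff)[ex_rows])
      exons <- BiocGenerics::sort(exons)
      cds <- IRanges::IRanges(GenomicRanges::start(gff)[cds_rows],
                              GenomicRanges::end(gff)[cds_rows])
      cds <- BiocGenerics::sort(cds)
      if (length(exons) > 1 &&
          any(IRanges::start(exons)[-1] <= IRanges::end(exons)[-length(exons)])) {
        stop("transcript ", tid, " has overlapping exons")
      }
      if (length(cds) && length(exons)) {
        cov <- IRanges::countOverlaps(cds, exons, type = "within")
        if (any(cov == 0)) {
          stop("CDS segment outside exons for transcript ", tid)
        }
      }
      tag <- FALSE
      if (length(tag_col)) {
        tv <- S4Vectors::mcols(gff)[[tag_col[1]]][ti]
        tv <- unlist(tv)
        tag <- any(grepl("canonical", tv, ignore.case = TRUE), na.rm = TRUE)
      }
      txs[[tid]] <- new_transcript_model(tid, gcontig, gstrand, exons, cds, tag)
    }
    gene <- structure(list(
      gene_id = gid, contig = gcontig, strand = gstrand,
      transcripts = txs, canonical_transcript_id = NA_character_
    ), class = "GeneModel")
    gene$canonical_transcript_id <- select_canonical_transcript(gene)
    genes[[gid]] <- gene
  }

  ncrna <- gff[type %in% NCRNA_GFF_TYPES]
  ncrna <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(ncrna),
    IRanges::IRanges(GenomicRanges::start(ncrna), GenomicRanges::end(ncrna)))
  if (!is.null(ncrna_bed_path)) {
    bed <- rtracklayer::import(ncrna_bed_path, format = "bed")
    extra <- setdiff(unique(as.character(GenomicRanges::seqnames(bed))),
                     names(contigs))
    if (length(extra)) stop("ncRNA BED references unknown contig(s): ",
                            paste(extra, collapse = ", "))
    ncrna <- c(ncrna, GenomicRanges::granges(bed))
  }
  ncrna <- BiocGenerics::sort(BiocGenerics::unique(ncrna))

  pfam <- GenomicRanges::GRanges()
  if (!is.null(pfam_bed_path)) {
    bed <- rtracklayer::import(pfam_bed_path, format = "bed")
    pfam <- GenomicRanges::granges(bed)
    pfam$domain_id <- as.character(bed$name %||% rep(NA_character_, length(bed)))
    pfam <- BiocGenerics::sort(pfam)
  }

  validate_genome_model(structure(list(
    contigs = contigs, genes = genes, ncrna = ncrna, pfam = pfam
  ), class = "GenomeModel"))
}

new_transcript_model <- function(transcript_id, contig, strand, exons, cds,
                                 canonical_tag = FALSE) {
  structure(list(
    transcript_id = transcript_id, contig = contig, strand = strand,
    exons = exons, cds = cds, cds_length = sum(IRanges::width(cds)),
    canonical_tag = canonical_tag
  ), class = "TranscriptModel")
}

validate_genome_model <- function(model) {
  lens <- setNames(Biostrings::width(model$contigs), names(model$contigs))
  chk <- function(contig, ir, what) {
    if (!length(ir)) return(invisible())
    if (any(IRanges::start(ir) < 1) || any(IRanges::end(ir) > lens[[contig]])) {
      stop(what, " interval outside contig ", contig)
    }
  }
  for (g in model$genes) {
    for (tx in g$transcripts) {
      chk(g$contig, tx$exons, paste0("exon (", tx$transcript_id, ")"))
      chk(g$contig, tx$cds, paste0("CDS (", tx$transcript_id, ")"))
      stopifnot(tx$cds_length == sum(IRanges::width(tx$cds)))
    }
  }
  model
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat("GenomeModel:", length(x$contigs), "contig(s),",
      length(x$genes), "gene(s),", length(x$ncrna), "ncRNA interval(s),",
      length(x$pfam), "Pfam interval(s)\n")
  invisible(x)
}

#' Select the canonical transcript of a gene
#'
#' Returns the transcript carrying an annotation tag containing
#' "canonical" (case-insensitive) when one exists; otherwise the
#' transcript with the longest CDS, with ties broken by lexicographically
#' smallest transcript id. Genes with no CDS-bearing transcript are
#' non-designable and yield `NA`.
#'
#' @param gene a `GeneModel`.
#' @return a transcript id, or `NA_character_` for a non-designable gene.
#' @export
select_canonical_transcript <- function(gene) {
  txs <- gene$transcripts
  if (!length(txs)) return(NA_character_)
  tagged <- names(txs)[vapply(txs, function(t) isTRUE(t$canonical_tag), logical(1))]
  if (length(tagged)) return(sort(tagged)[1])
  cds_len <- vapply(txs, function(t) t$cds_length, numeric(1))
  if (all(cds_len == 0)) return(NA_character_)
  cand <- names(txs)[cds_len == max(cds_len)]
  sort(cand)[1]
}

#' Spliced-CDS fraction of a genomic position
#'
#' Maps a genomic position to its fractional position along the spliced
#' coding sequence of a transcript: `(1 + spliced CDS offset) / cds_length`,
#' where the offset respects the transcript's strand. Positions outside the
#' CDS yield `NA` (undefined).
#'
#' @param transcript a `TranscriptModel`.
#' @param genomic_pos integer vector of genomic positions (1-based).
#' @return numeric vector of fractions in (0, 1], `NA` outside the CDS.
#' @export
cds_fraction <- function(transcript, genomic_pos) {
  cds <- transcript$cds
  if (!length(cds)) return(rep(NA_real_, length(genomic_pos)))
  st <- IRanges::start(cds); en <- IRanges::end(cds); w <- IRanges::width(cds)
  vapply(genomic_pos, function(pos) {
    seg <- which(pos >= st & pos <= en)[1]
    if (is.na(seg)) return(NA_real_)
    if (transcript$strand == "+") {
      offset <- if (seg > 1) sum(w[seq_len(seg - 1)]) else 0L
      offset <- offset + (pos - st[seg])
    } else {
      offset <- if (seg < length(cds)) sum(w[seq(seg + 1, length(cds))]) else 0L
      offset <- offset + (en[seg] - pos)
    }
    (1 + offset) / transcript$cds_length
  }, numeric(1))
}

#' Spliced CDS sequence of a transcript
#'
#' Concatenates the CDS segments in transcription order; minus-strand
#' transcripts are reverse-complemented.
#'
#' @param model a `GenomeModel`.
#' @param transcript a `TranscriptModel` belonging to `model`.
#' @return a single DNA string.
#' @export
spliced_cds_seq <- function(model, transcript) {
  seqs <- as.character(Biostrings::extractAt(
    model$contigs[[transcript$contig]], transcript$cds))
  s <- paste(seqs, collapse = "")
  if (transcript$strand == "-") s <- revcomp(s)
  s
}

#' Write a genome model back to FASTA + GFF3 (+ BED tracks)
#'
#' Inverse of [read_genome()]; writing then re-reading yields an identical
#' model (round-trip property).
#'
#' @param model a `GenomeModel`.
#' @param fasta_path,gff_path output paths.
#' @param pfam_bed_path,ncrna_bed_path optional BED output paths.
#' @return invisibly, the model.
#' @export
write_genome <- function(model, fasta_path, gff_path, pfam_bed_path = NULL,
                         ncrna_bed_path = NULL) {
  Biostrings::writeXStringSet(model$contigs, fasta_path)
  con <- file(gff_path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  line <- function(contig, type, start, end, strand, attrs) {
    paste(contig, "cas12ascreen", type, start, end, ".", strand, ".",
          attrs, sep = "\t")
  }
  for (g in model$genes) {
    gspan <- range(unlist(lapply(g$transcripts, function(t)
      c(IRanges::start(t$exons), IRanges::end(t$exons)))))
    writeLines(line(g$contig, "gene", gspan[1], gspan[2], g$strand,
                    paste0("ID=", g$gene_id)), con)
    for (tx in g$transcripts) {
      tspan <- c(min(IRanges::start(tx$exons)), max(IRanges::end(tx$exons)))
      attrs <- paste0("ID=", tx$transcript_id, ";Parent=", g$gene_id)
      if (isTRUE(tx$canonical_tag)) attrs <- paste0(attrs, ";tag=Ensembl_canonical")
      writeLines(line(g$contig, "mRNA", tspan[1], tspan[2], g$strand, attrs), con)
      for (i in seq_along(tx$exons)) {
        writeLines(line(g$contig, "exon", IRanges::start(tx$exons)[i],
                        IRanges::end(tx$exons)[i], g$strand,
                        paste0("ID=", tx$transcript_id, ":exon", i,
                               ";Parent=", tx$transcript_id)), con)
      }
      for (i in seq_along(tx$cds)) {
        writeLines(line(g$contig, "CDS", IRanges::start(tx$cds)[i],
                        IRanges::end(tx$cds)[i], g$strand,
                        paste0("ID=", tx$transcript_id, ":cds", i,
                               ";Parent=", tx$transcript_id)), con)
      }
    }
  }
  if (!is.null(ncrna_bed_path)) write_bed(model$ncrna, ncrna_bed_path)
  if (!is.null(pfam_bed_path)) {
    write_bed(model$pfam, pfam_bed_path,
              names = model$pfam$domain_id %||% NULL)
  }
  invisible(model)
}

# BED is 0-based half-open; internal coordinates are 1-based closed.
write_bed <- function(gr, path, names = NULL) {
  if (!length(gr)) {
    file.create(path)
    return(invisible())
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(names)) names else ".",
    score = 0L,
    strand = "."
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

# TRUE for each (start, end) interval on `contig` overlapping `gr`.
overlaps_intervals <- function(contig, start, end, gr) {
  if (!length(gr) || !length(start)) return(rep(FALSE, length(start)))
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end))
  IRanges::overlapsAny(q, gr)
}
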