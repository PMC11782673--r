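# In-code fixture builders: tiny genomes written as FASTA/GFF3/BED text
# and re-read through the public API.

write_fixture_genome <- function(contigs, gff_lines, dir = tempfile("fix"),
                                 pfam = NULL, ncrna = NULL) {
  dir.create(dir)
  fa <- file.path(dir, "genome.fa")
  writeLines(unlist(lapply(names(contigs), function(nm)
    c(paste0(">", nm), contigs[[nm]]))), fa)
  gff <- file.path(dir, "genes.gff3")
  writeLines(c("##gff-version 3", gff_lines), gff)
  paths <- list(fasta = fa, gff = gff, pfam = NULL, ncrna = NULL)
  write_bed_df <- function(df, path) {
    writeLines(apply(df, 1, paste, collapse = "\t"), path)
    path
  }
  if (!is.null(pfam)) {
    paths$pfam <- write_bed_df(pfam, file.path(dir, "pfam.bed"))
  }
  if (!is.null(ncrna)) {
    paths$ncrna <- write_bed_df(ncrna, file.path(dir, "ncrna.bed"))
  }
  paths
}

gff_feature <- function(contig, type, start, end, strand, id,
                        parent = NULL, extra = NULL) {
  attrs <- paste0("ID=", id)
  if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
  if (!is.null(extra)) attrs <- paste0(attrs, ";", extra)
  paste(contig, "test", type, start, end, ".", strand, ".", attrs,
        sep = "\t")
}

# two-gene fixture: geneA (+, 2 exons, CDS inset in exons) and geneB
# (-, single exon, exon == CDS). Coordinates chosen by hand.
two_gene_fixture <- function(seed = 42) {
  set.seed(seed)
  contig <- random_seq(600)
  lines <- c(
    gff_feature("chr1", "gene", 51, 260, "+", "geneA"),
    gff_feature("chr1", "mRNA", 51, 260, "+", "geneA.t1", "geneA"),
    gff_feature("chr1", "exon", 51, 150, "+", "geneA.t1.e1", "geneA.t1"),
    gff_feature("chr1", "exon", 201, 260, "+", "geneA.t1.e2", "geneA.t1"),
    gff_feature("chr1", "CDS", 61, 150, "+", "geneA.t1.c1", "geneA.t1"),
    gff_feature("chr1", "CDS", 201, 250, "+", "geneA.t1.c2", "geneA.t1"),
    gff_feature("chr1", "gene", 351, 470, "-", "geneB"),
    gff_feature("chr1", "mRNA", 351, 470, "-", "geneB.t1", "geneB"),
    gff_feature("chr1", "exon", 351, 470, "-", "geneB.t1.e1", "geneB.t1"),
    gff_feature("chr1", "CDS", 351, 470, "-", "geneB.t1.c1", "geneB.t1")
  )
  list(contig = contig,
       paths = write_fixture_genome(list(chr1 = contig), lines))
}

# a GenomeModel built from explicit single-exon gene coordinates placed
# on supplied contig strings (exon == CDS)
model_from_genes <- function(contigs, genes) {
  lines <- unlist(lapply(genes, function(g) {
    tid <- paste0(g$id, ".t1")
    c(gff_feature(g$contig, "gene", g$start, g$end, g$strand, g$id),
      gff_feature(g$contig, "mRNA", g$start, g$end, g$strand, tid, g$id),
      gff_feature(g$contig, "exon", g$start, g$end, g$strand,
                  paste0(tid, ".e1"), tid),
      gff_feature(g$contig, "CDS", g$start, g$end, g$strand,
                  paste0(tid, ".c1"), tid))
  }))
  paths <- write_fixture_genome(contigs, lines)
  read_genome(paths$fasta, paths$gff)
}

# synthetic ranked candidate table for selection tests (positions and
# priorities chosen directly; no genome needed unless ncRNA matters)
toy_candidates <- function(starts, priority = rev(seq_along(starts)),
                           exon_index = rep(1L, length(starts)),
                           contig = "chr1", width = 23L) {
  data.frame(
    contig = contig, strand = "+", pam_start = starts - 4L,
    pam_seq = "TTTA", spacer_start = starts,
    spacer_end = starts + width - 1L,
    spacer_seq = strrep("A", width), cut_pos = starts + 18L,
    gc_percent = 50, gene_id = "G", transcript_id = "G.t1",
    cds_frac = 0.5, exon_index = exon_index, in_pfam = FALSE,
    filter_flags = "", pass = TRUE, on_target_score = 0.5,
    offtarget_count = 0L, priority = priority)
}

# full-enumeration oracle for dual-pair selection: all 4-subsets x all 3
# pairings, feasibility by linear scan, objective (priority sum, exon
# diversity)
oracle_best_dual <- function(cand, min_intra = 25, min_inter = 50,
                             ncrna = NULL) {
  n <- nrow(cand)
  gap <- function(i, j) {
    max(cand$spacer_start[j] - cand$spacer_end[i],
        cand$spacer_start[i] - cand$spacer_end[j]) - 1
  }
  span <- function(i, j) c(min(cand$spacer_start[c(i, j)]),
                           max(cand$spacer_end[c(i, j)]))
  span_clear <- function(sp) {
    if (is.null(ncrna)) return(TRUE)
    !any(sp[1] <= ncrna$end & ncrna$start <= sp[2])
  }
  pair_ok <- function(i, j) gap(i, j) >= min_intra && span_clear(span(i, j))
  best <- NULL
  best_key <- c(-Inf, -Inf)
  if (n < 4) return(NULL)
  for (sub in utils::combn(n, 4, simplify = FALSE)) {
    for (split in list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))) {
      p1 <- sub[split[1:2]]; p2 <- sub[split[3:4]]
      if (!pair_ok(p1[1], p1[2]) || !pair_ok(p2[1], p2[2])) next
      s1 <- span(p1[1], p1[2]); s2 <- span(p2[1], p2[2])
      inter_gap <- max(s2[1] - s1[2], s1[1] - s2[2]) - 1
      if (inter_gap < min_inter) next
      key <- c(sum(cand$priority[sub]),
               length(unique(cand$exon_index[sub])))
      if (key[1] > best_key[1] ||
          (key[1] == best_key[1] && key[2] > best_key[2])) {
        best_key <- key
        best <- list(pairs = list(sort(p1), sort(p2)), key = key)
      }
    }
  }
  best
}
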