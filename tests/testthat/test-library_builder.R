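test_that("rank_candidates applies the full key order", {
  base <- toy_candidates(c(100, 200))
  base$priority <- NULL
  a <- base; a$offtarget_count <- c(0L, 2L)
  r <- rank_candidates(a)
  expect_equal(r$offtarget_count, c(0L, 2L))

  b <- base; b$in_pfam <- c(FALSE, TRUE)
  expect_equal(rank_candidates(b)$in_pfam, c(TRUE, FALSE))

  c3 <- base; c3$cds_frac <- c(0.95, 0.40)
  expect_equal(rank_candidates(c3)$cds_frac, c(0.40, 0.95))

  d <- base; d$on_target_score <- c(0.2, 0.9)
  expect_equal(rank_candidates(d)$on_target_score, c(0.9, 0.2))

  # fully tied: genomic position breaks the tie
  expect_equal(rank_candidates(base)$spacer_start, c(100, 200))
  # off-target count outranks Pfam (primary key first)
  e <- base; e$offtarget_count <- c(0L, 2L); e$in_pfam <- c(FALSE, TRUE)
  expect_equal(rank_candidates(e)$offtarget_count, c(0L, 2L))
  # failing candidates are dropped
  f <- base; f$pass <- c(TRUE, FALSE)
  expect_equal(nrow(rank_candidates(f)), 1)
})

test_that("build_dual_pairs enforces gaps and ncRNA avoidance", {
  # two candidates 10 nt apart can never form a pair; with only four
  # candidates and interleaved spans, no second disjoint pair exists
  cand <- toy_candidates(c(100, 133, 300, 400))  # gap(1,2) = 133-122-1 = 10
  sel <- build_dual_pairs(cand)
  expect_equal(sel$status, "partial")
  for (p in sel$pairs) {
    expect_false(all(c(100, 133) %in% p$spacer_start))
  }

  # only one constraint-satisfying assignment exists -> that assignment
  cand2 <- toy_candidates(c(100, 150, 300, 350))
  sel2 <- build_dual_pairs(cand2)
  expect_equal(sel2$status, "full")
  expect_equal(sort(sel2$pairs[[1]]$spacer_start), c(100, 150))
  expect_equal(sort(sel2$pairs[[2]]$spacer_start), c(300, 350))

  # a pair spanning a planted non-coding element is rejected; the
  # next-best feasible configuration is chosen instead
  model <- list(ncrna = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(260, 290)))
  cand3 <- toy_candidates(c(100, 150, 230, 320, 600, 700),
                          priority = c(10, 9, 8, 7, 2, 1))
  sel3 <- build_dual_pairs(cand3, model = model)
  expect_equal(sel3$status, "full")
  for (p in sel3$pairs) {
    span <- c(min(p$spacer_start), max(p$spacer_end))
    expect_false(span[1] <= 290 && 260 <= span[2])
  }
  # the top-priority pairing (230, 320) straddles the element, so 230 and
  # 320 cannot be in the same pair
  for (p in sel3$pairs) expect_false(all(c(230, 320) %in% p$spacer_start))

  # fewer than 4 feasible spacers -> partial
  expect_equal(build_dual_pairs(toy_candidates(c(100, 150, 300)))$status,
               "partial")
  expect_equal(build_dual_pairs(toy_candidates(c(100)))$status, "none")
})

test_that("pair selection equals the full-enumeration optimum (<=12)", {
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- sample(6:12, 1)
    starts <- sort(sample(seq(1, 2000, by = 10), n))
    prio <- sample(100, n)
    exi <- sample(1:3, n, replace = TRUE)
    cand <- toy_candidates(starts, priority = prio, exon_index = exi)
    # random ncRNA interval half the time
    ncr <- NULL
    model <- NULL
    if (s %% 2 == 0) {
      a <- sample(1500, 1)
      ncr <- data.frame(start = a, end = a + 80)
      model <- list(ncrna = GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(a, a + 80)))
    }
    sel <- build_dual_pairs(cand, model = model)
    ora <- oracle_best_dual(cand, ncrna = ncr)
    if (is.null(ora)) {
      expect_true(sel$status %in% c("partial", "none"))
    } else {
      expect_equal(sel$status, "full")
      got_prio <- sum(vapply(sel$pairs, function(p) sum(p$priority),
                             numeric(1)))
      got_ex <- length(unique(unlist(lapply(sel$pairs,
                                            function(p) p$exon_index))))
      expect_equal(got_prio, ora$key[1])
      expect_equal(got_ex, ora$key[2])
    }
  }
})

test_that("quad arrays cover isoforms under spacing and ncRNA rules", {
  # single isoform, >= 4 feasible spacers -> exactly one quad
  cand <- toy_candidates(seq(100, 700, by = 100))
  cand$isoform_hits <- rep(list("t1"), nrow(cand))
  sel <- build_quad_arrays(cand)
  expect_equal(sel$status, "full")
  expect_length(sel$quads, 1)
  q <- sel$quads[[1]]
  expect_equal(nrow(q), 4)
  gaps <- q$spacer_start[-1] - q$spacer_end[-4] - 1
  expect_true(all(gaps >= 25))

  # 3 feasible spacers -> no quad, partial status
  cand3 <- toy_candidates(c(100, 200, 300))
  cand3$isoform_hits <- rep(list("t1"), 3)
  sel3 <- build_quad_arrays(cand3)
  expect_equal(sel3$status, "partial")
  expect_length(sel3$quads, 0)

  # two isoforms with no common ncRNA-free region -> two quads whose
  # union covers both (verified by brute-force coverage over all quads)
  starts <- c(seq(100, 400, by = 100), seq(1000, 1300, by = 100))
  cand2 <- toy_candidates(starts, priority = rev(seq_along(starts)))
  cand2$isoform_hits <- c(rep(list("t1"), 4), rep(list("t2"), 4))
  model <- list(ncrna = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(600, 800)))
  sel2 <- build_quad_arrays(cand2, model = model)
  expect_equal(sel2$status, "full")
  expect_length(sel2$quads, 2)
  expect_setequal(sel2$covered, c("t1", "t2"))
  for (q in sel2$quads) {
    span <- c(min(q$spacer_start), max(q$spacer_end))
    expect_false(span[1] <= 800 && 600 <= span[2])
  }
})

test_that("NTC generation: count, determinism, zero genome matches", {
  sim <- simulate_genome(sim_genome_config(n_genes = 5, seed = 14))
  ntc <- generate_ntcs(25, sim$model, "DUAL", seed = 42)
  expect_equal(nrow(ntc), 25)
  sp <- c(ntc$spacer1, ntc$spacer2)
  expect_length(unique(sp), 50)
  expect_true(all(is.na(ntc$spacer3)))

  # same seed -> byte-identical output
  ntc2 <- generate_ntcs(25, sim$model, "DUAL", seed = 42)
  expect_identical(ntc, ntc2)

  # every NTC spacer: zero matches at <=3 mismatches, exhaustive scan
  contigs <- as.list(as.character(sim$model$contigs))
  for (s in sp[1:8]) {
    expect_equal(nrow(oracle_hamming_sites(contigs, s, 3)), 0)
  }
  idx <- build_offtarget_index(sim$model)
  for (s in sp) {
    expect_equal(cas12ascreen:::genome_match_count(idx, s, 3), 0)
  }

  # quad mode emits 4 spacers per construct
  ntcq <- generate_ntcs(3, sim$model, "QUAD", seed = 1, index = idx)
  expect_false(anyNA(ntcq$spacer4))
})

test_that("cassette assembly follows the DR/overhang layout", {
  s1 <- "GCAGCAGCAGGCAGCAGCAGGCA"
  a <- assemble_cassette(s1)
  expect_equal(a$cassette_seq, paste0("TAATTTCTACTCTTGTAGAT", s1))
  expect_equal(a$sense_oligo, paste0("TCCC", "TAATTTCTACTCTTGTAGAT", s1))
  expect_equal(a$antisense_oligo,
               paste0("AAAC", oracle_revcomp(paste0("TAATTTCTACTCTTGTAGAT", s1))))

  # dual cassette length = 2 * (20 + 23) = 86 with the default DR
  s2 <- "ACGGACGGACGGACGGACGGACG"
  d <- assemble_cassette(c(s1, s2))
  expect_equal(nchar(d$cassette_seq), 86)
  expect_equal(substr(d$sense_oligo, 1, 4), "TCCC")
  expect_equal(substr(d$antisense_oligo, 1, 4), "AAAC")

  expect_error(assemble_cassette(character(0)), "no spacers")
  expect_error(assemble_cassette(NA_character_), "no spacers")

  # a spacer that creates an EcoRI site in the assembled oligo is flagged
  bad <- paste0("GAATTC", strrep("A", 8), strrep("G", 9))
  expect_true(assemble_cassette(bad)$re_flagged)
  expect_false(a$re_flagged)
})

test_that("library TSV round-trips losslessly", {
  sim <- simulate_genome(sim_genome_config(n_genes = 4, seed = 15))
  lib <- design_dual_library(sim$model, n_ntc = 2, seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_library(lib, path)
  back <- read_library(path)
  cols <- intersect(cas12ascreen:::LIBRARY_COLUMNS, names(lib$constructs))
  a <- lib$constructs[cols]
  b <- back$constructs[cols]
  a$spacer3 <- as.character(a$spacer3); a$spacer4 <- as.character(a$spacer4)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(b, a)

  # duplicate ids are fatal on write and on read
  dup <- lib$constructs[c(1, 1), ]
  expect_error(write_library(dup, tempfile()), "duplicate")

  # empty table -> header-only file, re-read as empty
  empty <- lib$constructs[0, ]
  p2 <- tempfile(fileext = ".tsv")
  write_library(empty, p2)
  expect_equal(nrow(read_library(p2)$constructs), 0)
})

test_that("quad library designs cover isoforms end-to-end", {
  sim <- simulate_genome(sim_genome_config(
    n_genes = 10, frac_multi_isoform = 0.6, exons_per_gene = c(2, 3),
    seed = 23))
  lib <- design_quad_library(sim$model, n_ntc = 3, seed = 6)
  quads <- lib$constructs[lib$constructs$kind == "QUAD", ]
  expect_gt(nrow(quads), 0)
  expect_false(anyNA(quads[paste0("spacer", 1:4)]))
  nc_s <- GenomicRanges::start(sim$model$ncrna)
  nc_e <- GenomicRanges::end(sim$model$ncrna)
  for (i in seq_len(nrow(quads))) {
    s <- as.integer(strsplit(quads$spacer_starts[i], ",")[[1]])
    e <- as.integer(strsplit(quads$spacer_ends[i], ",")[[1]])
    o <- order(s); s <- s[o]; e <- e[o]
    expect_true(all(s[-1] - e[-4] - 1 >= 25))
    expect_false(any(s[1] <= nc_e & nc_s <= e[4]))
  }
  # a primary array per designed gene; extra arrays only for genes whose
  # isoforms could not be covered by one array
  expect_true(all(table(quads$gene_id) >= 1))
  full <- lib$design_report$gene_id[
    lib$design_report$status == "fully_designed"]
  expect_gt(length(full), 5)
})

test_that("dual library designs satisfy constraints and are deterministic", {
  sim <- simulate_genome(sim_genome_config(n_genes = 12, seed = 16))
  lib1 <- design_dual_library(sim$model, n_ntc = 5, seed = 7)
  lib2 <- design_dual_library(sim$model, n_ntc = 5, seed = 7)
  p1 <- tempfile(); p2 <- tempfile()
  write_library(lib1, p1); write_library(lib2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_true(all(table(lib1$constructs$gene_id[
    lib1$constructs$kind == "DUAL"]) <= 2))
})
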