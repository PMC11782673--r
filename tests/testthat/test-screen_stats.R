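# direct NB log-CPM simulator for statistics tests (independent of the
# library/design machinery)
nb_logcpm <- function(n_constructs, n_per_group, lfc = rep(0, n_constructs),
                      mu0 = 300, dispersion = 0.05, seed = 1) {
  set.seed(seed)
  groups <- rep(c("trt", "ctl"), each = n_per_group)
  mu <- outer(mu0 * 2^(lfc / 2), ifelse(groups == "trt", 1, 1))
  mu[, groups == "trt"] <- mu0 * 2^(lfc)
  mu[, groups == "ctl"] <- mu0
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = n_constructs,
                   dimnames = list(sprintf("c%05d", seq_len(n_constructs)),
                                   paste0("s", seq_along(groups))))
  list(lcpm = normalize_log_cpm(counts), groups = groups)
}

test_that("construct fits recover null and planted log-fold changes", {
  sim <- nb_logcpm(1000, 6, seed = 2)
  fit <- fit_construct_models(sim$lcpm, sim$groups, c("trt", "ctl"))
  expect_lt(abs(mean(fit$logFC)), 0.05)
  expect_true(all(fit$df == 10))

  # planted 4-fold enrichment in a sparse subset (dense effects would
  # shift the CPM denominator and attenuate every logFC)
  lfc <- c(rep(2, 20), rep(0, 1980))
  sim2 <- nb_logcpm(2000, 6, lfc = lfc, seed = 3)
  fit2 <- fit_construct_models(sim2$lcpm, sim2$groups, c("trt", "ctl"))
  expect_lt(abs(mean(fit2$logFC[1:20]) - 2), 0.1)

  # constant-value construct: zero residual variance, flagged degenerate
  m <- matrix(100L, 12, 12, dimnames = list(paste0("k", 1:12), NULL))
  fitc <- fit_construct_models(normalize_log_cpm(m), sim$groups,
                               c("trt", "ctl"), weights = FALSE)
  expect_true(all(fitc$degenerate))
  expect_true(all(fitc$s2 == 0))

  # fewer than 2 replicates per group is fatal, naming the comparison
  expect_error(
    fit_construct_models(sim$lcpm, c("trt", rep("ctl", 11)),
                         c("trt", "ctl")),
    "trt vs ctl")
})

test_that("weighted fits downweight the noisy end of the trend", {
  set.seed(8)
  lfc <- rep(0, 2000)
  sim <- nb_logcpm(2000, 6, lfc = lfc, dispersion = 0.1, seed = 8)
  f_w <- fit_construct_models(sim$lcpm, sim$groups, c("trt", "ctl"),
                              weights = TRUE)
  f_u <- fit_construct_models(sim$lcpm, sim$groups, c("trt", "ctl"),
                              weights = FALSE)
  # weighting must not distort the average effect under the null
  expect_lt(abs(mean(f_w$logFC)), 0.05)
  expect_gt(stats::cor(f_w$logFC, f_u$logFC), 0.95)
})

test_that("empirical-Bayes moderation: limits, recovery, limma oracle", {
  # all residual variances identical -> d0 infinite, s2_post == s0^2
  st <- data.frame(construct_id = paste0("c", 1:50), logFC = 0,
                   s2 = 0.25, df = 10L, se_unit = sqrt(1 / 3),
                   avg_logcpm = 8, degenerate = FALSE)
  mod <- moderate_variances(st)
  prior <- attr(mod, "prior")
  expect_true(is.infinite(prior$d0))
  expect_equal(mod$s2_post, rep(0.25, 50), tolerance = 1e-8)

  # parameter recovery: scaled inverse-chi-square prior d0=4, s0^2=0.25
  set.seed(4)
  n <- 5000; d0 <- 4; s0_2 <- 0.25; d <- 10
  sigma2 <- s0_2 * d0 / stats::rchisq(n, d0)
  s2 <- sigma2 * stats::rchisq(n, d) / d
  st2 <- data.frame(construct_id = paste0("c", 1:n), logFC = 0, s2 = s2,
                    df = d, se_unit = 1, avg_logcpm = 8, degenerate = FALSE)
  mod2 <- moderate_variances(st2)
  pr <- attr(mod2, "prior")
  expect_gte(pr$d0, 3); expect_lte(pr$d0, 5)
  expect_lt(abs(pr$s0_2 - s0_2) / s0_2, 0.2)

  # independent oracle: limma's squeezeVar on the same inputs
  sq <- limma::squeezeVar(s2, df = d)
  expect_lt(abs(pr$d0 - sq$df.prior) / sq$df.prior, 0.05)
  expect_lt(abs(pr$s0_2 - sq$var.prior) / sq$var.prior, 0.05)
  expect_equal(mod2$s2_post, sq$var.post, tolerance = 0.01)

  # posterior variances lie between each s2 and the prior scale
  expect_true(all(mod2$s2_post >= pmin(mod2$s2, pr$s0_2) - 1e-12))
  expect_true(all(mod2$s2_post <= pmax(mod2$s2, pr$s0_2) + 1e-12))

  # too few constructs is a precondition failure
  expect_error(moderate_variances(st[1, ]), "insufficient")
})

test_that("gene aggregation rewards consistency and is calibrated", {
  mk <- function(t_by_gene) {
    genes <- rep(names(t_by_gene), lengths(t_by_gene))
    data.frame(construct_id = paste0("c", seq_along(genes)),
               gene_id = genes, logFC = unlist(t_by_gene),
               moderated_t = unlist(t_by_gene), degenerate = FALSE)
  }
  res <- aggregate_genes(mk(list(gA = c(3, 3), gB = c(3, -3))))
  expect_lt(res$p_value[res$gene_id == "gA"],
            res$p_value[res$gene_id == "gB"])
  expect_equal(res$direction[res$gene_id == "gA"], "up")

  # single-construct gene in normal mode: p is the two-sided normal p
  res1 <- aggregate_genes(mk(list(gC = 1.7)))
  expect_equal(res1$p_value, 2 * pnorm(-1.7))

  # pure null: gene p-values are uniform (KS statistic < 0.05, 2000 genes)
  set.seed(5)
  tnull <- replicate(2000, rnorm(2), simplify = FALSE)
  names(tnull) <- paste0("g", 1:2000)
  resn <- aggregate_genes(mk(tnull))
  ks <- suppressWarnings(stats::ks.test(resn$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)

  # NTC empirical null reproduces the normal-mode answer approximately
  set.seed(6)
  genes <- c(rep("gA", 2), rep("NTC", 400))
  stats_df <- data.frame(construct_id = paste0("c", seq_along(genes)),
                         gene_id = genes,
                         logFC = c(2, 2, rnorm(400)),
                         moderated_t = c(2, 2, rnorm(400)),
                         degenerate = FALSE)
  res_ntc <- aggregate_genes(stats_df, null_mode = "NTC", seed = 9)
  expect_equal(nrow(res_ntc), 1)  # NTCs never appear as genes
  expect_lt(abs(res_ntc$p_value - 2 * pnorm(-2 * sqrt(2))), 0.02)
})

test_that("planted resistance genes rank at the top by q-value", {
  # 50 planted genes (construct logFC +2) among 2000, 2 constructs each:
  # all of them must land in the top 100 by q-value, across seeds
  for (s in 1:3) {
    n_genes <- 2000
    n <- 2 * n_genes
    gene_ids <- rep(sprintf("g%04d", 1:n_genes), each = 2)
    lfc <- ifelse(gene_ids %in% sprintf("g%04d", 1:50), 2, 0)
    sim <- nb_logcpm(n, 6, lfc = lfc, seed = 300 + s)
    gm <- setNames(gene_ids, sprintf("c%05d", 1:n))
    fit <- fit_construct_models(sim$lcpm, sim$groups, c("trt", "ctl"),
                                gene_map = gm)
    res <- aggregate_genes(moderate_variances(fit))
    top100 <- res$gene_id[order(res$q_value, res$p_value)][1:100]
    expect_gte(length(intersect(top100, sprintf("g%04d", 1:50))), 48)
  }
})

test_that("BH q-values: hand example, permutation equivariance, oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(numeric(0)), numeric(0))

  set.seed(10)
  p <- runif(500)^2
  q <- bh_fdr(p)
  expect_equal(q, stats::p.adjust(p, "BH"))  # independent oracle
  perm <- sample(500)
  expect_equal(bh_fdr(p[perm]), q[perm])
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("hypergeometric enrichment matches closed forms", {
  universe <- paste0("g", 1:20)
  sets <- list(hit5 = universe[1:5], other = universe[6:10])
  res <- hypergeometric_enrichment(universe[1:5], sets, universe)
  expect_equal(res$p_value[1], 1 / choose(20, 5))
  expect_equal(res$overlap, c(5L, 0L))

  # empty hit list: p = 1 everywhere; set == universe: p = 1
  expect_true(all(hypergeometric_enrichment(character(0), sets,
                                            universe)$p_value == 1))
  expect_equal(hypergeometric_enrichment(universe[1:3],
                                         list(all = universe),
                                         universe)$p_value, 1)
  expect_error(hypergeometric_enrichment("g1", sets, character(0)),
               "empty universe")
})

test_that("depletion QC separates planted essential genes", {
  set.seed(11)
  res <- data.frame(
    gene_id = paste0("g", 1:1000),
    mean_logFC = c(rnorm(500, -2, 0.7), rnorm(500, 0, 0.7)))
  ess <- paste0("g", 1:500); non <- paste0("g", 501:1000)
  qc <- depletion_qc(res, ess, non)
  expect_gt(qc$separation_probability, 0.9)
  expect_lt(qc$median_logFC_essential, qc$median_logFC_nonessential)

  # identical distributions: separation ~ 0.5 (n = 500 per class)
  res0 <- data.frame(gene_id = paste0("g", 1:1000),
                     mean_logFC = rnorm(1000))
  qc0 <- depletion_qc(res0, ess, non)
  expect_lt(abs(qc0$separation_probability - 0.5), 0.05)

  expect_error(depletion_qc(res, paste0("x", 1:5), non), "essential")
})

test_that("top abundant constructs report genes with deterministic ties", {
  counts <- matrix(c(900L, 50L, 30L, 10L, 10L, 5L), 6, 1,
                   dimnames = list(paste0("G", 1:6, "_pair1"), "s1"))
  lib <- list(constructs = data.frame(
    construct_id = rownames(counts),
    gene_id = c(paste0("gene", 1:5), "NTC")))
  top <- top_abundant_genes(counts, lib, k = 4)
  expect_equal(top$s1[1], "gene1")
  expect_length(top$s1, 4)
  # tie at rank 4 (both 10): lexicographically smaller construct id wins
  expect_equal(top$s1[4], "gene4")
  # k larger than the library: clamped, no error
  expect_length(top_abundant_genes(counts, lib, k = 99)$s1, 6)
})

test_that("4-way export joins, classifies and drops with warning", {
  rx <- data.frame(gene_id = paste0("g", 1:10), mean_logFC = 1:10 / 10)
  ry <- data.frame(gene_id = paste0("g", 2:11), mean_logFC = -(2:11) / 10)
  expect_warning(
    fw <- export_four_way(rx, ry, hit_genes = "g3",
                          essential_ids = c("g4", "g3"),
                          nonessential_ids = "g5"),
    "missing")
  expect_equal(nrow(fw), 9)  # intersection size
  expect_equal(fw$class[fw$gene_id == "g3"], "hit")  # hit outranks essential
  expect_equal(fw$class[fw$gene_id == "g4"], "essential")
  expect_equal(fw$class[fw$gene_id == "g5"], "non-essential")
  expect_equal(fw$class[fw$gene_id == "g6"], "other")
  expect_equal(fw$logFC_x[fw$gene_id == "g2"], 0.2)
  expect_equal(fw$logFC_y[fw$gene_id == "g2"], -0.2)

  # empty essential list: nothing classed essential
  fw2 <- suppressWarnings(export_four_way(rx, ry))
  expect_false(any(fw2$class %in% c("essential", "non-essential", "hit")))
})
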