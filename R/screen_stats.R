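#' Per-construct differential abundance by weighted least squares
#'
#' Fits an ordinary least-squares two-group model to each construct's
#' log-CPM values. With `weights = TRUE`, observation weights follow the
#' mean-variance trend: the square root of each construct's residual SD
#' is regressed on its average log-CPM by lowess, per-observation SDs are
#' predicted from the fitted (group-mean) values, and the weight is the
#' predicted variance inverse. `weights = FALSE` gives unweighted OLS.
#'
#' @param lcpm a `LogCpm` object (or bare matrix) from
#'   [normalize_log_cpm()].
#' @param groups character/factor of group labels, one per sample
#'   (column).
#' @param contrast length-2 character: log-fold-change is
#'   `contrast[1] - contrast[2]` (e.g. treatment vs input).
#' @param gene_map named vector construct_id -> gene_id (optional; taken
#'   from a `LibraryTable` via [gene_map_of()]).
#' @param weights use variance-trend observation weights.
#' @return a `ConstructStats` data.frame: per-construct `logFC`,
#'   residual variance `s2`, residual df `df`, unit standard error
#'   `se_unit`, `avg_logcpm`, `degenerate` flag.
#' @export
fit_construct_models <- function(lcpm, groups, contrast, gene_map = NULL,
                                 weights = TRUE) {
  values <- if (inherits(lcpm, "LogCpm")) lcpm$values else lcpm
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(values), length(contrast) == 2)
  use <- groups %in% contrast
  y <- values[, use, drop = FALSE]
  g <- groups[use]
  nA <- sum(g == contrast[1]); nB <- sum(g == contrast[2])
  if (nA < 2 || nB < 2) {
    stop("comparison ", contrast[1], " vs ", contrast[2],
         " needs >=2 replicates per group (got ", nA, " and ", nB, ")")
  }
  inA <- g == contrast[1]

  fit_once <- function(w) {
    swA <- rowSums(w[, inA, drop = FALSE])
    swB <- rowSums(w[, !inA, drop = FALSE])
    mA <- rowSums((w * y)[, inA, drop = FALSE]) / swA
    mB <- rowSums((w * y)[, !inA, drop = FALSE]) / swB
    fitted <- matrix(mB, nrow(y), ncol(y))
    fitted[, inA] <- mA
    res <- y - fitted
    s2 <- rowSums(w * res^2) / (ncol(y) - 2)
    list(mA = mA, mB = mB, fitted = fitted, s2 = s2,
         se_unit = sqrt(1 / swA + 1 / swB))
  }

  w <- matrix(1, nrow(y), ncol(y))
  f <- fit_once(w)
  if (weights) {
    avg <- rowMeans(y)
    sq_sd <- sqrt(sqrt(pmax(f$s2, 0)))
    lo <- lowess(avg, sq_sd, f = 0.5)
    pred <- approx(lo$x, lo$y, xout = f$fitted, rule = 2)$y
    pred <- pmax(pred, 1e-4)
    w <- matrix(pred^-4, nrow(y), ncol(y))
    f <- fit_once(w)
  }
  out <- data.frame(
    construct_id = rownames(y) %||% as.character(seq_len(nrow(y))),
    logFC = f$mA - f$mB,
    s2 = f$s2,
    df = ncol(y) - 2L,
    se_unit = f$se_unit,
    avg_logcpm = rowMeans(y),
    degenerate = f$s2 <= 0 | apply(y, 1, function(r) all(r == r[1]))
  )
  if (!is.null(gene_map)) out$gene_id <- unname(gene_map[out$construct_id])
  attr(out, "contrast") <- contrast
  class(out) <- c("ConstructStats", class(out))
  out
}

#' Construct-to-gene map of a library table
#' @param library a `LibraryTable`.
#' @return named character vector construct_id -> gene_id.
#' @export
gene_map_of <- function(library) {
  setNames(library$constructs$gene_id, library$constructs$construct_id)
}

# Newton inversion of the trigamma function (for the prior df estimate).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

#' Empirical-Bayes moderation of construct variances
#'
#' Assumes residual variances follow a scaled inverse-chi-square prior
#' with df `d0` and scale `s0^2`, estimated by the method of moments on
#' `e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)`. Posterior variances
#' shrink each `s2_g` toward `s0^2`:
#' `s2_post = (d0 s0^2 + d_g s2_g) / (d0 + d_g)`. Moderated t statistics
#' use `d0 + d_g` degrees of freedom; the moderated F is `t^2` for this
#' single-contrast design. When the observed variances carry no excess
#' spread, `d0` is infinite and every posterior variance equals `s0^2`.
#' Degenerate constructs are excluded from moderation and assigned p = 1.
#'
#' @param stats a `ConstructStats` from [fit_construct_models()].
#' @return `stats` with `s2_post`, `moderated_t`, `moderated_F`,
#'   `p_value`, `df_total` added; the prior is in `attr(, "prior")`
#'   (fields `d0`, `s0_2`).
#' @export
moderate_variances <- function(stats) {
  ok <- !stats$degenerate & stats$df > 0 & stats$s2 > 0
  if (sum(ok) < 10) {
    stop("insufficient constructs for empirical-Bayes moderation (need >=10 ",
         "with positive residual df, got ", sum(ok), ")")
  }
  d <- stats$df[ok]
  z <- log(stats$s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- var(e) * (length(e) - 1) / length(e) - mean(trigamma(d / 2))
  if (var(z) < 1e-15) {
    # no spread at all: the documented limit shrinks every variance to
    # the common observed value
    evar <- -Inf
    e <- z
  }
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(mean(e))
  }
  prior <- list(d0 = d0, s0_2 = s0_2)

  s2_post <- if (is.infinite(d0)) rep(s0_2, nrow(stats)) else {
    (d0 * s0_2 + stats$df * stats$s2) / (d0 + stats$df)
  }
  stats$s2_post <- s2_post
  stats$df_total <- d0 + stats$df
  stats$moderated_t <- stats$logFC / (sqrt(s2_post) * stats$se_unit)
  stats$moderated_t[stats$degenerate] <- 0
  stats$moderated_F <- stats$moderated_t^2
  stats$p_value <- 2 * pt(-abs(stats$moderated_t), df = stats$df_total)
  stats$p_value[stats$degenerate] <- 1
  attr(stats, "prior") <- prior
  stats
}

#' Benjamini-Hochberg step-up q-values
#'
#' Classic step-up procedure with cumulative-minimum enforcement;
#' monotone in sorted-p order and equivariant under input permutation.
#'
#' @param p_values p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  m <- length(p_values)
  if (!m) return(numeric(0))
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(p_values[o] * m / (m:1)))
  q[ro]
}

#' Aggregate construct statistics to gene level
#'
#' The gene statistic is the mean moderated t over the gene's constructs,
#' so constructs that agree in direction reinforce each other while
#' opposed constructs cancel (the consistency behaviour of rotation-based
#' gene-set tests, here in closed form). Two-sided p-values come from
#' either a normal null with variance `1/n_constructs` (`"normal"`) or an
#' empirical null of random pseudo-genes assembled from non-targeting
#' control constructs (`"NTC"`). Benjamini-Hochberg q-values are attached.
#'
#' @param stats moderated `ConstructStats` carrying `gene_id`.
#' @param null_mode "normal" or "NTC".
#' @param ntc_label gene label identifying non-targeting constructs.
#' @param n_null pseudo-genes drawn per gene size in NTC mode.
#' @param seed RNG seed for the NTC resampling null.
#' @return a `GeneResults` data.frame: `gene_id`, `n_constructs`,
#'   `mean_logFC`, `stat`, `p_value`, `q_value`, `direction`.
#' @export
aggregate_genes <- function(stats, null_mode = c("normal", "NTC"),
                            ntc_label = "NTC", n_null = 10000L, seed = 1L) {
  null_mode <- match.arg(null_mode)
  if (is.null(stats$gene_id)) stop("stats must carry gene_id")
  is_ntc <- stats$gene_id == ntc_label
  tgt <- stats[!is_ntc, , drop = FALSE]
  if (!nrow(tgt)) stop("no targeting constructs to aggregate")
  sp <- split(seq_len(nrow(tgt)), tgt$gene_id)
  gene_id <- names(sp)
  n_constructs <- lengths(sp)
  mean_t <- vapply(sp, function(i) mean(tgt$moderated_t[i]), numeric(1))
  mean_lfc <- vapply(sp, function(i) mean(tgt$logFC[i]), numeric(1))

  if (null_mode == "normal") {
    p <- 2 * pnorm(-abs(mean_t) * sqrt(n_constructs))
  } else {
    ntc_t <- stats$moderated_t[is_ntc & !stats$degenerate]
    if (length(ntc_t) < 10) {
      stop("NTC null requires >=10 non-targeting constructs (label '",
           ntc_label, "')")
    }
    set.seed(seed)
    p <- numeric(length(sp))
    for (sz in unique(n_constructs)) {
      null_means <- rowMeans(matrix(
        sample(ntc_t, n_null * sz, replace = TRUE), n_null, sz))
      which_sz <- n_constructs == sz
      p[which_sz] <- vapply(mean_t[which_sz], function(tt)
        (1 + sum(abs(null_means) >= abs(tt))) / (n_null + 1), numeric(1))
    }
  }
  res <- data.frame(gene_id = gene_id, n_constructs = as.integer(n_constructs),
                    mean_logFC = mean_lfc, stat = mean_t,
                    p_value = p, q_value = bh_fdr(p),
                    direction = ifelse(mean_t >= 0, "up", "down"))
  rownames(res) <- NULL
  class(res) <- c("GeneResults", class(res))
  res
}

#' Hypergeometric over-representation of gene sets among hits
#'
#' Upper-tail hypergeometric p for an overlap at least as large as
#' observed, per set, with Benjamini-Hochberg q-values across sets.
#' Hit lists are typically selected with a log-fold-change threshold
#' (enrichment logFC > 0; depletion logFC < -5; growth advantage
#' logFC > 0.5) and an FDR cutoff.
#'
#' @param hit_genes character vector of hit gene ids (subset of
#'   `universe`).
#' @param gene_sets named list of character vectors.
#' @param universe character vector of all tested genes.
#' @return data.frame: set, set size (in universe), overlap, p, q.
#' @export
hypergeometric_enrichment <- function(hit_genes, gene_sets, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  hits <- intersect(unique(hit_genes), universe)
  res <- data.frame(
    set = names(gene_sets),
    set_size = NA_integer_, overlap = NA_integer_, p_value = NA_real_)
  for (i in seq_along(gene_sets)) {
    s <- intersect(unique(gene_sets[[i]]), universe)
    k <- length(intersect(hits, s))
    res$set_size[i] <- length(s)
    res$overlap[i] <- k
    res$p_value[i] <- phyper(k - 1, length(s), length(universe) - length(s),
                             length(hits), lower.tail = FALSE)
  }
  res$q_value <- bh_fdr(res$p_value)
  res
}

#' Essential-gene depletion diagnostics
#'
#' Summarises separation between known essential and non-essential genes
#' for a depletion comparison: per-class median log-fold change, and the
#' Mann-Whitney probability that a random essential gene falls below a
#' random non-essential gene.
#'
#' @param gene_results a `GeneResults` table with `mean_logFC`.
#' @param essential_ids,nonessential_ids gene id vectors.
#' @return list: `median_logFC_essential`, `median_logFC_nonessential`,
#'   `separation_probability`, class sizes.
#' @export
depletion_qc <- function(gene_results, essential_ids, nonessential_ids) {
  ess <- gene_results$mean_logFC[gene_results$gene_id %in% essential_ids]
  non <- gene_results$mean_logFC[gene_results$gene_id %in% nonessential_ids]
  if (!length(ess)) stop("essential gene list does not intersect results")
  if (!length(non)) stop("non-essential gene list does not intersect results")
  r <- rank(c(ess, non))
  # P(essential < nonessential), ties counted half
  auc <- (sum(r[seq_along(ess)]) - length(ess) * (length(ess) + 1) / 2) /
    (length(ess) * length(non))
  list(median_logFC_essential = median(ess),
       median_logFC_nonessential = median(non),
       separation_probability = 1 - auc,
       n_essential = length(ess), n_nonessential = length(non))
}

#' Genes of the most abundant constructs per sample
#'
#' Reports the genes targeted by the `k` highest-count constructs in each
#' sample (in vivo hit calling); ties are broken by lexicographically
#' smaller construct id, non-targeting constructs report as their label.
#'
#' @param counts a `ScreenCounts` or count matrix.
#' @param library a `LibraryTable`.
#' @param k number of constructs per sample (default 4; clamped to the
#'   library size).
#' @return named list: sample -> character vector of gene ids in rank
#'   order.
#' @export
top_abundant_genes <- function(counts, library, k = 4L) {
  mat <- if (inherits(counts, "ScreenCounts")) counts$counts else counts
  gm <- gene_map_of(library)
  lapply(setNames(seq_len(ncol(mat)), colnames(mat)), function(si) {
    o <- order(-mat[, si], rownames(mat))
    top <- head(o, min(k, nrow(mat)))
    unname(gm[rownames(mat)[top]])
  })
}

#' Two-comparison gene table for 4-way plotting
#'
#' Joins two gene-level result tables on their common genes and labels
#' each gene hit / essential / non-essential / other (in that precedence).
#' Genes present in only one comparison are dropped with a warning.
#'
#' @param res_x,res_y `GeneResults` for the x- and y-axis comparisons.
#' @param hit_genes,essential_ids,nonessential_ids classification lists.
#' @return data.frame: `gene_id`, `logFC_x`, `logFC_y`, `class`.
#' @export
export_four_way <- function(res_x, res_y, hit_genes = character(0),
                            essential_ids = character(0),
                            nonessential_ids = character(0)) {
  common <- intersect(res_x$gene_id, res_y$gene_id)
  dropped <- setdiff(union(res_x$gene_id, res_y$gene_id), common)
  if (length(dropped)) {
    warning(length(dropped), " gene(s) missing from one comparison; dropped")
  }
  x <- res_x[match(common, res_x$gene_id), ]
  y <- res_y[match(common, res_y$gene_id), ]
  cls <- rep("other", length(common))
  cls[common %in% nonessential_ids] <- "non-essential"
  cls[common %in% essential_ids] <- "essential"
  cls[common %in% hit_genes] <- "hit"
  data.frame(gene_id = common, logFC_x = x$mean_logFC, logFC_y = y$mean_logFC,
             class = cls)
}
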