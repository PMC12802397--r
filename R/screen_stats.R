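#' Normalize a count matrix to counts per million
#'
#' Adds a pseudocount to every cell and scales each sample column to
#' 1e6, giving per-element frequencies comparable across sequencing
#' depths.  The pseudocount keeps downstream log-ratios finite for
#' elements that dropped to zero in one bin.
#'
#' @param counts a [count_matrix()].
#' @param pseudocount value added to every count before scaling
#'   (default 1).
#' @return A `normalized_matrix`: list with `freq` (elements x samples,
#'   columns summing to 1e6), `pseudocount`, `manifest_name`,
#'   `element_id`.
#' @export
normalize_counts <- function(counts, pseudocount = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  raw <- counts$counts
  zero_cols <- colSums(raw) == 0
  if (any(zero_cols))
    stopf("all-zero count column(s): %s",
          paste(colnames(raw)[zero_cols], collapse = ", "))
  shifted <- raw + pseudocount
  freq <- sweep(shifted, 2, colSums(shifted), "/") * 1e6
  structure(list(freq = freq, pseudocount = pseudocount,
                 manifest_name = counts$manifest_name,
                 element_id = counts$element_id),
            class = "normalized_matrix")
}

#' Per-sgRNA log2 enrichment between sorted bins or timepoints
#'
#' For the FACS arm the ratio is non-responder bin over responder bin
#' (`low_bin / high_bin`), so that sgRNAs depleted from the responder
#' (high red/green) tail — knockdowns that suppress the response, i.e.
#' positive regulators — receive positive log2FC.  For the survival arm
#' the ratio is `endpoint / day0`.  When the two roles have matching
#' replicate numbers, log2 ratios are computed per replicate pair and
#' averaged; otherwise frequencies are averaged within role first.
#'
#' @param norm a [normalize_counts()] result.
#' @param sheet a [sample_sheet()].
#' @param screen_id screen to extract.
#' @param arm `"facs"` or `"survival"`.
#' @param manifest the `library_manifest` (provides gene/category columns).
#' @return An `sgrna_stats` data frame: `element_id`, `gene`, `category`,
#'   `log2fc`.
#' @export
sgrna_log2fc <- function(norm, sheet, screen_id, arm = c("facs", "survival"),
                         manifest) {
  stopifnot(inherits(norm, "normalized_matrix"), inherits(sheet, "sample_sheet"),
            inherits(manifest, "library_manifest"))
  arm <- match.arg(arm)
  roles <- if (arm == "facs") c(num = "low_bin", den = "high_bin")
           else c(num = "endpoint", den = "day0")
  sub <- sheet[sheet$screen_id == screen_id & sheet$arm == arm, , drop = FALSE]
  if (nrow(sub) == 0) stopf("no samples for screen '%s', arm '%s'", screen_id, arm)
  num_s <- sub[sub$role == roles["num"], , drop = FALSE]
  den_s <- sub[sub$role == roles["den"], , drop = FALSE]
  if (nrow(num_s) == 0 || nrow(den_s) == 0)
    stopf("screen '%s' arm '%s' is missing role %s", screen_id, arm,
          if (nrow(num_s) == 0) roles["num"] else roles["den"])
  missing_cols <- setdiff(c(num_s$sample_id, den_s$sample_id), colnames(norm$freq))
  if (length(missing_cols) > 0)
    stopf("samples absent from the count matrix: %s",
          paste(missing_cols, collapse = ", "))
  paired <- setequal(num_s$replicate, den_s$replicate) &&
    !anyDuplicated(num_s$replicate) && !anyDuplicated(den_s$replicate)
  if (paired) {
    reps <- sort(num_s$replicate)
    l2 <- sapply(reps, function(r) {
      log2(norm$freq[, num_s$sample_id[num_s$replicate == r]] /
             norm$freq[, den_s$sample_id[den_s$replicate == r]])
    })
    log2fc <- rowMeans(as.matrix(l2))
  } else {
    num_f <- rowMeans(norm$freq[, num_s$sample_id, drop = FALSE])
    den_f <- rowMeans(norm$freq[, den_s$sample_id, drop = FALSE])
    log2fc <- log2(num_f / den_f)
  }
  structure(data.frame(element_id = norm$element_id,
                       gene = manifest$gene,
                       category = manifest$category,
                       log2fc = unname(log2fc),
                       stringsAsFactors = FALSE),
            screen_id = screen_id, arm = arm,
            class = c("sgrna_stats", "data.frame"))
}

# Vectorized two-sided rank-sum (Mann-Whitney) p-values of groups of size n
# against a common pool.  `u` is the Mann-Whitney U of each group vs the
# pool; exact null distribution (pwilcox) when no ties and the table is
# small, normal approximation with tie correction and continuity correction
# otherwise.  Verified against stats::wilcox.test in the test suite.
rank_sum_p <- function(u, n, m, tied, pool_ties = 0) {
  p <- numeric(length(u))
  exact_ok <- !tied & (n * m <= 1e5) & (u == round(u))
  if (any(exact_ok)) {
    ue <- u[exact_ok]
    lower <- stats::pwilcox(ue, n, m)
    upper <- stats::pwilcox(ue - 1, n, m, lower.tail = FALSE)
    p[exact_ok] <- pmin(1, 2 * pmin(lower, upper))
  }
  if (any(!exact_ok)) {
    ua <- u[!exact_ok]
    ties_a <- if (length(pool_ties) > 1) pool_ties[!exact_ok] else pool_ties
    mu <- n * m / 2
    N <- n + m
    sigma2 <- (n * m / 12) * ((N + 1) - ties_a / (N * (N - 1)))
    z <- (ua - mu - sign(ua - mu) * 0.5) / sqrt(sigma2)
    p[!exact_ok] <- pmin(1, 2 * stats::pnorm(-abs(z)))
  }
  p
}

# U statistics of several groups against a sorted pool via findInterval;
# returns U counting 0.5 per tie.  groups: matrix n_groups x group_size of
# values.
group_u_stats <- function(groups, pool_sorted) {
  lt <- matrix(findInterval(groups, pool_sorted, left.open = TRUE),
               nrow = nrow(groups))
  le <- matrix(findInterval(groups, pool_sorted), nrow = nrow(groups))
  tie_count <- rowSums(le - lt)
  u <- rowSums(lt) + 0.5 * tie_count
  list(u = u, tie_count = tie_count, tied = tie_count > 0)
}

#' Gene-level screen statistics with a quasi-gene empirical FDR
#'
#' Aggregates per-sgRNA log2 fold changes to genes, tests each gene's
#' sgRNA set against the pooled non-targeting-control (NTC) sgRNAs with a
#' two-sided rank-sum test, and calibrates an empirical false discovery
#' rate on "quasi-genes": pseudo-genes assembled by resampling NTC sgRNAs
#' (without replacement within a draw, with replacement across draws) in
#' groups of the modal per-gene sgRNA count and scored exactly like real
#' genes.  The phenotype score is `effect * -log10(p)`; the FDR at
#' threshold t is the quasi-gene tail fraction over the real-gene tail
#' fraction (per sign direction), with an add-one correction in the null
#' tail count for finite-sample conservativeness, capped at 1 and made
#' monotone so that a larger |phenotype score| never has a larger FDR.
#'
#' @param sg an [sgrna_log2fc()] result.
#' @param aggregation `"mean_all"` (mean of all sgRNA log2FCs) or
#'   `"mean_top_k"` (mean of the `k` largest by |log2FC|).
#' @param k top-k size for `mean_top_k`.
#' @param n_quasi number of quasi-genes (default 10x the real gene count).
#' @param seed integer seed for quasi-gene resampling.
#' @param strong_fdr,weak_fdr hit-classification thresholds, passed to
#'   [classify_hits()].
#' @return A `gene_stats` data frame (`gene`, `n_sgrnas`, `effect`,
#'   `p_value`, `phenotype_score`, `fdr`, `hit_class`) with the scored
#'   quasi-gene table in `attr(, "quasi")`.
#' @export
gene_stats <- function(sg, aggregation = c("mean_all", "mean_top_k"), k = 3L,
                       n_quasi = NULL, seed = 1L,
                       strong_fdr = 0.05, weak_fdr = 0.1) {
  stopifnot(inherits(sg, "sgrna_stats"))
  aggregation <- match.arg(aggregation)
  ntc_vals <- sg$log2fc[sg$category == "non_targeting"]
  if (length(ntc_vals) == 0)
    stopf("no non-targeting controls in the library; the empirical null cannot be built")
  targ <- sg[sg$category == "targeting", , drop = FALSE]
  split_vals <- split(targ$log2fc, targ$gene)
  sizes <- lengths(split_vals)
  if (any(sizes < 2))
    stopf("gene(s) with fewer than 2 sgRNAs: %s",
          paste(utils::head(names(split_vals)[sizes < 2], 5), collapse = ", "))
  genes <- names(split_vals)
  n_genes <- length(genes)
  ntc_center <- stats::median(ntc_vals)

  agg_fun <- function(x) {
    if (aggregation == "mean_top_k") x <- x[order(-abs(x))][seq_len(min(k, length(x)))]
    mean(x)
  }
  effect <- vapply(split_vals, agg_fun, numeric(1)) - ntc_center

  pool_sorted <- sort(ntc_vals)
  m <- length(ntc_vals)
  pool_tie_tab <- table(ntc_vals)
  # p-values per distinct group size (exact null reused within a size)
  p_value <- numeric(n_genes)
  for (sz in unique(sizes)) {
    idx <- which(sizes == sz)
    gm <- matrix(unlist(split_vals[idx], use.names = FALSE),
                 nrow = length(idx), byrow = TRUE)
    us <- group_u_stats(gm, pool_sorted)
    ties_term <- tie_correction(gm, ntc_vals, us$tied)
    p_value[idx] <- rank_sum_p(us$u, sz, m, us$tied, ties_term)
  }
  phenotype_score <- effect * (-log10(p_value))

  # quasi-genes: modal per-gene size, sampled from the NTC pool
  s_modal <- as.integer(names(which.max(table(sizes))))
  n_quasi <- n_quasi %||% (10L * n_genes)
  quasi <- with_seed(seed, {
    draw <- replicate(n_quasi, sample.int(m, s_modal))   # s_modal x n_quasi
    qm <- matrix(ntc_vals[draw], nrow = n_quasi, byrow = TRUE)
    q_effect <- (if (aggregation == "mean_top_k")
      apply(qm, 1, agg_fun) else rowMeans(qm)) - ntc_center
    # test each quasi-gene against the pool minus its own members; its U
    # against the full pool minus the within-group U gives exactly that
    us <- group_u_stats(qm, pool_sorted)
    u_excl <- us$u - self_u(qm)
    # ordered equal pairs within the group (incl. self-pairs); external
    # ties exist iff the full-pool tie count exceeds them
    within_eq <- apply(qm, 1, function(x) sum(outer(x, x, "==")))
    tied <- (us$tie_count - within_eq) > 0
    ties_term <- numeric(n_quasi)
    for (i in which(tied)) {
      tt <- table(c(qm[i, ], ntc_vals[-draw[, i]]))
      ties_term[i] <- sum(tt^3 - tt)
    }
    q_p <- rank_sum_p(u_excl, s_modal, m - s_modal, tied, ties_term)
    data.frame(quasi_gene = sprintf("ntcq_%05d", seq_len(n_quasi)),
               effect = q_effect, p_value = q_p,
               phenotype_score = q_effect * (-log10(q_p)),
               stringsAsFactors = FALSE)
  })

  fdr <- empirical_fdr(phenotype_score, quasi$phenotype_score)

  out <- data.frame(gene = genes,
                    n_sgrnas = as.integer(sizes),
                    effect = unname(effect),
                    p_value = p_value,
                    phenotype_score = phenotype_score,
                    fdr = fdr,
                    stringsAsFactors = FALSE)
  out <- structure(out, class = c("gene_stats", "data.frame"),
                   quasi = quasi, seed = seed,
                   screen_id = attr(sg, "screen_id"), arm = attr(sg, "arm"),
                   n_ntc = m, quasi_size = s_modal)
  classify_hits(out, strong_fdr = strong_fdr, weak_fdr = weak_fdr)
}

# U of each row-group against itself (subtracted when a quasi-gene's
# members are part of the pool): sum over ordered pairs of [x_i > x_j] +
# 0.5 [x_i == x_j], including the 0.5 per self-pair.
self_u <- function(gm) {
  s <- ncol(gm)
  apply(gm, 1, function(x) {
    sum(outer(x, x, ">")) + 0.5 * sum(outer(x, x, "=="))
  })
}

# tie-correction term sum(t^3 - t) of the combined group+pool sample, per
# group; only needed for groups flagged tied (0 otherwise)
tie_correction <- function(gm, pool, tied) {
  if (!any(tied)) return(0)
  terms <- numeric(nrow(gm))
  for (i in which(tied)) {
    tt <- table(c(gm[i, ], pool))
    terms[i] <- sum(tt^3 - tt)
  }
  terms
}

#' Empirical FDR from quasi-gene phenotype scores
#'
#' For each real score t the raw FDR is the (add-one-corrected) fraction
#' of quasi-gene scores at least as extreme, over the fraction of real
#' scores at least as extreme, evaluated separately for the positive and
#' negative directions and capped at 1.  The returned values are
#' monotonized q-values: each gene gets the minimum raw FDR over all
#' thresholds no more extreme than its own, so FDR is non-increasing in
#' |phenotype score| within a direction.
#'
#' @param real numeric vector of real-gene phenotype scores.
#' @param quasi numeric vector of quasi-gene phenotype scores.
#' @return FDR vector aligned with `real`.
#' @export
empirical_fdr <- function(real, quasi) {
  n_real <- length(real)
  n_quasi <- length(quasi)
  stopifnot(n_real > 0, n_quasi > 0)
  scale <- n_real / n_quasi
  fdr <- rep(NA_real_, n_real)
  for (dir in c(1, -1)) {
    side <- if (dir == 1) real >= 0 else real < 0
    if (!any(side)) next
    t_vals <- real[side] * dir
    q_vals <- quasi * dir
    r_vals <- real * dir
    # tail counts at each gene's own score (>= t in the signed direction)
    n_q_tail <- n_quasi - findInterval(t_vals - 1e-12, sort(q_vals))
    n_r_tail <- n_real - findInterval(t_vals - 1e-12, sort(r_vals))
    raw <- pmin(1, (n_q_tail * scale + 1) / pmax(n_r_tail, 1))
    # q-value: min raw FDR over own and all less extreme thresholds
    ord <- order(t_vals)            # ascending extremeness
    q <- raw
    q[ord] <- cummin(raw[ord])
    fdr[side] <- q
  }
  pmin(fdr, 1)
}

#' Classify hits from the FDR
#'
#' Strong hits have `fdr < strong_fdr`, weak hits `fdr < weak_fdr`;
#' direction follows the sign of the effect (positive regulators are genes
#' whose knockdown suppressed the response).
#'
#' @param g a `gene_stats` table with an `fdr` column.
#' @param strong_fdr,weak_fdr FDR thresholds.
#' @return `g` with a `hit_class` column in
#'   `{strong_positive_regulator, weak_positive_regulator,
#'     strong_negative_regulator, weak_negative_regulator, none}`.
#' @export
classify_hits <- function(g, strong_fdr = 0.05, weak_fdr = 0.1) {
  stopifnot(all(c("fdr", "effect") %in% names(g)))
  strength <- ifelse(g$fdr < strong_fdr, "strong",
                     ifelse(g$fdr < weak_fdr, "weak", "none"))
  direction <- ifelse(g$effect >= 0, "positive_regulator", "negative_regulator")
  g$hit_class <- ifelse(strength == "none", "none",
                        paste(strength, direction, sep = "_"))
  g
}

#' Rank genes by phenotype score
#'
#' Descending by phenotype score with a stable lexicographic tie-break on
#' the gene symbol.
#'
#' @param g a `gene_stats` table.
#' @param top_n optionally keep only the first `top_n` rows.
#' @return The reordered table with a `rank` column.
#' @export
rank_by_phenotype <- function(g, top_n = NULL) {
  stopifnot("phenotype_score" %in% names(g))
  ord <- order(-g$phenotype_score, g$gene)
  out <- g[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out
}

#' Write a gene-stats table as TSV
#'
#' @param g a `gene_stats` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_stats <- function(g, path) {
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full hit-calling pipeline on a counted screen
#'
#' Convenience wrapper: normalize, per-sgRNA log2FC, gene statistics.
#'
#' @param counts a [count_matrix()].
#' @param sheet a [sample_sheet()].
#' @param manifest a `library_manifest`.
#' @param screen_id screen to analyze.
#' @param arm `"facs"` or `"survival"`.
#' @param pseudocount passed to [normalize_counts()].
#' @param ... passed to [gene_stats()].
#' @return A `gene_stats` table.
#' @export
call_screen <- function(counts, sheet, manifest, screen_id = "sim",
                        arm = "facs", pseudocount = 1, ...) {
  norm <- normalize_counts(counts, pseudocount = pseudocount)
  sg <- sgrna_log2fc(norm, sheet, screen_id, arm = arm, manifest = manifest)
  gene_stats(sg, ...)
}
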