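#' Pair two screens on their common genes
#'
#' @param a,b `gene_stats` tables.
#' @param labels length-2 character vector of screen labels.
#' @return A `screen_pair`: list with the two tables restricted to the
#'   gene intersection (same order) and the labels.
#' @export
screen_pair <- function(a, b, labels = c("screen_a", "screen_b")) {
  common <- intersect(a$gene, b$gene)
  if (length(common) < 3)
    stopf("need at least 3 shared genes, found %d", length(common))
  structure(list(a = a[match(common, a$gene), , drop = FALSE],
                 b = b[match(common, b$gene), , drop = FALSE],
                 labels = labels),
            class = "screen_pair")
}

#' Pearson correlation of phenotype scores between two screens
#'
#' @param pair a [screen_pair()].
#' @return List with `r`, `n` and the two-sided `p_value`.
#' @export
phenotype_correlation <- function(pair) {
  stopifnot(inherits(pair, "screen_pair"))
  x <- pair$a$phenotype_score
  y <- pair$b$phenotype_score
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("phenotype scores have zero variance; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x), p_value = ct$p.value)
}

#' Recall of a reference gene set at a phenotype-score threshold
#'
#' Recall is the fraction of reference genes present in the screen whose
#' phenotype score is at least the threshold.  A sweep over a score grid
#' is returned alongside the point estimate.
#'
#' @param g a `gene_stats` table.
#' @param reference_set character vector of gene symbols (e.g. common
#'   essential genes for a survival screen).
#' @param threshold phenotype-score cutoff.
#' @param grid score grid for the sweep (default: 101 points spanning the
#'   observed scores).
#' @return List with `recall`, `threshold`, `n_reference` (reference genes
#'   in the screen) and `sweep` (data frame `threshold`, `recall`).
#' @export
recall_at_threshold <- function(g, reference_set, threshold = 1, grid = NULL) {
  in_screen <- intersect(reference_set, g$gene)
  if (length(in_screen) == 0)
    stopf("no reference genes are present in the screen")
  scores <- g$phenotype_score[match(in_screen, g$gene)]
  recall_at <- function(t) mean(scores >= t)
  if (is.null(grid))
    grid <- seq(min(g$phenotype_score), max(g$phenotype_score), length.out = 101)
  list(recall = recall_at(threshold),
       threshold = threshold,
       n_reference = length(in_screen),
       sweep = data.frame(threshold = grid,
                          recall = vapply(grid, recall_at, numeric(1))))
}

#' Hit status of one screen's top genes across screens
#'
#' Takes the `top_n` genes of the first screen by phenotype score and
#' tabulates their score and hit class in both screens.
#'
#' @param pair a [screen_pair()].
#' @param top_n number of top genes from the first screen.
#' @return Data frame with one row per top gene: scores and hit classes in
#'   each screen, plus `shared` (hit in both).
#' @export
hitset_overlap <- function(pair, top_n = 30L) {
  stopifnot(inherits(pair, "screen_pair"))
  if (top_n > nrow(pair$a)) stopf("top_n exceeds the shared gene count")
  if (top_n == 0)
    return(data.frame(gene = character(0), score_a = numeric(0),
                      class_a = character(0), score_b = numeric(0),
                      class_b = character(0), shared = logical(0)))
  top <- rank_by_phenotype(pair$a, top_n = top_n)$gene
  ia <- match(top, pair$a$gene)
  ib <- match(top, pair$b$gene)
  data.frame(gene = top,
             score_a = pair$a$phenotype_score[ia],
             class_a = pair$a$hit_class[ia],
             score_b = pair$b$phenotype_score[ib],
             class_b = pair$b$hit_class[ib],
             shared = pair$a$hit_class[ia] != "none" &
               pair$b$hit_class[ib] != "none",
             stringsAsFactors = FALSE)
}

#' Gene-set over-representation for a hit list
#'
#' Upper-tail hypergeometric test of each set against the screen universe
#' (the genes the library targets), with Benjamini-Hochberg adjustment
#' across sets and fold enrichment `(k/n) / (K/N)`.
#'
#' @param hits character vector of hit genes (must be within `universe`).
#' @param sets named list of character vectors, or a data frame with
#'   columns `set_name` and `gene`.
#' @param universe character vector of all testable genes.
#' @return Data frame per set: `set_name`, `k` (hits in set), `K` (set
#'   size in universe), `n` (hits), `N` (universe), `fold`, `p_value`
#'   (P(X >= k)), `q_value` (BH).
#' @export
geneset_enrichment <- function(hits, sets, universe) {
  if (is.data.frame(sets)) {
    stopifnot(all(c("set_name", "gene") %in% names(sets)))
    sets <- split(sets$gene, sets$set_name)
  }
  hits <- unique(hits)
  universe <- unique(universe)
  stray_hits <- setdiff(hits, universe)
  if (length(stray_hits) > 0)
    stopf("hit gene(s) outside the universe: %s",
          paste(utils::head(stray_hits, 5), collapse = ", "))
  stray <- lapply(sets, setdiff, y = universe)
  offenders <- names(stray)[lengths(stray) > 0]
  if (length(offenders) > 0)
    stopf("gene set(s) contain genes outside the universe: %s",
          paste(offenders, collapse = ", "))
  N <- length(universe)
  n <- length(hits)
  res <- lapply(names(sets), function(nm) {
    set <- unique(sets[[nm]])
    K <- length(set)
    k <- length(intersect(set, hits))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
    data.frame(set_name = nm, k = k, K = K, n = n, N = N,
               fold = fold, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}

#' Read a gene-set TSV (columns `set_name`, `gene`)
#'
#' @param path path to the TSV.
#' @return Named list of gene vectors.
#' @export
load_gene_sets <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  stopifnot(all(c("set_name", "gene") %in% names(df)))
  split(df$gene, df$set_name)
}
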