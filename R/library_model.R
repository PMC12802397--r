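#' sgRNA library manifests
#'
#' A library manifest is a data frame with one row per library element and
#' columns `element_id`, `gene`, `protospacer` and `category`.  Non-targeting
#' controls carry the reserved gene token `"NTC"` and category
#' `"non_targeting"`; all other elements are `"targeting"`.  Protospacers are
#' nucleotide strings over A/C/G/T with one fixed length per manifest
#' (typically 19 or 20 nt for CRISPRi-v2-style libraries).
#'
#' @param elements data frame with columns `element_id`, `gene`,
#'   `protospacer` and optionally `category` (derived from `gene` when
#'   absent).
#' @param name library name stored with the manifest.
#' @return A validated `library_manifest` (a data frame).
#' @examples
#' m <- library_manifest(data.frame(
#'   element_id = c("A_1", "A_2", "ctl_1"),
#'   gene = c("A", "A", "NTC"),
#'   protospacer = c("ACGTACGTACGTACGTACG", "TGCATGCATGCATGCATGC",
#'                   "AAAACCCCGGGGTTTTACG")))
#' composition_summary(m)$n_total
#' @export
library_manifest <- function(elements, name = "library") {
  required <- c("element_id", "gene", "protospacer")
  missing_cols <- setdiff(required, names(elements))
  if (length(missing_cols) > 0)
    stopf("manifest is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  m <- as.data.frame(elements, stringsAsFactors = FALSE)
  m$element_id <- as.character(m$element_id)
  m$gene <- as.character(m$gene)
  m$protospacer <- toupper(as.character(m$protospacer))
  if (!"category" %in% names(m)) {
    m$category <- ifelse(m$gene == "NTC", "non_targeting", "targeting")
  }
  m$category <- as.character(m$category)
  validate_manifest(m)
  rownames(m) <- NULL
  structure(m[, c("element_id", "gene", "protospacer", "category")],
            name = name,
            class = c("library_manifest", "data.frame"))
}

validate_manifest <- function(m) {
  if (nrow(m) == 0) stopf("manifest has no elements")
  dup_id <- duplicated(m$element_id)
  if (any(dup_id))
    stopf("duplicate element_id at row(s) %s: %s",
          paste(which(dup_id), collapse = ", "),
          paste(unique(m$element_id[dup_id]), collapse = ", "))
  dup_ps <- duplicated(m$protospacer)
  if (any(dup_ps))
    stopf("duplicate protospacer at row(s) %s: %s",
          paste(which(dup_ps), collapse = ", "),
          paste(unique(m$protospacer[dup_ps]), collapse = ", "))
  lens <- unique(nchar(m$protospacer))
  if (length(lens) != 1)
    stopf("mixed protospacer lengths in one manifest: %s",
          paste(sort(lens), collapse = ", "))
  bad_chr <- grepl("[^ACGT]", m$protospacer)
  if (any(bad_chr))
    stopf("protospacer with non-ACGT characters at row(s) %s",
          paste(which(bad_chr), collapse = ", "))
  bad_cat <- (m$category == "non_targeting") != (m$gene == "NTC")
  if (any(bad_cat))
    stopf("category/gene mismatch at row(s) %s (category is non_targeting iff gene is NTC)",
          paste(which(bad_cat), collapse = ", "))
  ok_cat <- m$category %in% c("targeting", "non_targeting")
  if (!all(ok_cat))
    stopf("unknown category at row(s) %s", paste(which(!ok_cat), collapse = ", "))
  invisible(m)
}

#' Read a library manifest from a tab-delimited file
#'
#' Expects a headered TSV with columns `element_id`, `gene`, `protospacer`
#' and optionally `category`.  All manifest invariants (unique IDs, unique
#' protospacers, one protospacer length, NTC/category consistency) are
#' enforced at load; row order is preserved.
#'
#' @param path path to the TSV file.
#' @param name library name; defaults to the file name without extension.
#' @return A `library_manifest`.
#' @export
load_manifest <- function(path, name = NULL) {
  if (!file.exists(path)) stopf("manifest file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  library_manifest(df, name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a library manifest as TSV
#'
#' @param m a `library_manifest`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path) {
  stopifnot(inherits(m, "library_manifest"))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize library composition
#'
#' Totals of targeting and non-targeting elements, number of targeted genes,
#' NTC fraction, and the per-gene element-count histogram.
#'
#' @param m a `library_manifest`.
#' @return A list with `n_total`, `n_targeting`, `n_ntc`, `n_genes`,
#'   `ntc_fraction`, and `per_gene_hist` (a table: elements-per-gene value
#'   -> number of genes).
#' @export
composition_summary <- function(m) {
  stopifnot(inherits(m, "library_manifest"))
  if (nrow(m) == 0) stopf("cannot summarize an empty manifest")
  targeting <- m[m$category == "targeting", , drop = FALSE]
  per_gene <- table(targeting$gene)
  out <- list(
    name = attr(m, "name"),
    n_total = nrow(m),
    n_targeting = nrow(targeting),
    n_ntc = sum(m$category == "non_targeting"),
    n_genes = length(per_gene),
    ntc_fraction = sum(m$category == "non_targeting") / nrow(m),
    per_gene_hist = table(as.integer(per_gene))
  )
  stopifnot(out$n_total == out$n_targeting + out$n_ntc)
  class(out) <- "library_composition"
  out
}

#' @export
print.library_composition <- function(x, ...) {
  cat(sprintf("Library '%s': %d elements (%d targeting, %d NTC; %.2f%% NTC)\n",
              x$name, x$n_total, x$n_targeting, x$n_ntc, 100 * x$ntc_fraction))
  cat(sprintf("Targeted genes: %d\n", x$n_genes))
  cat("Elements per gene:\n")
  print(x$per_gene_hist)
  invisible(x)
}

#' Construct a synthetic manifest
#'
#' Builds a manifest with `n_genes` genes named `g0001`, `g0002`, ... each
#' carrying `sgrnas_per_gene` elements, plus `n_ntc` non-targeting controls.
#' Protospacers are deterministic unique sequences (base-4 index encoding),
#' so two calls with the same arguments give identical manifests.  Intended
#' for simulation and tests.
#'
#' @param n_genes number of targeting genes.
#' @param sgrnas_per_gene elements per gene (may be a vector of length
#'   `n_genes` for unequal designs).
#' @param n_ntc number of non-targeting controls.
#' @param protospacer_length protospacer length in nt (19 or 20 typical).
#' @param name library name.
#' @return A `library_manifest`.
#' @export
make_manifest <- function(n_genes, sgrnas_per_gene = 5L, n_ntc = 0L,
                          protospacer_length = 19L, name = "synthetic") {
  per_gene <- rep_len(as.integer(sgrnas_per_gene), n_genes)
  genes <- sprintf("g%04d", seq_len(n_genes))
  gene_col <- rep(genes, per_gene)
  idx_within <- unlist(lapply(per_gene, seq_len), use.names = FALSE)
  ids <- c(paste0(gene_col, "_sg", idx_within),
           if (n_ntc > 0) sprintf("NTC_sg%d", seq_len(n_ntc)))
  gene_col <- c(gene_col, rep("NTC", n_ntc))
  n_total <- length(ids)
  if (n_total > 4^protospacer_length)
    stopf("protospacer length %d cannot encode %d unique elements",
          protospacer_length, n_total)
  library_manifest(data.frame(
    element_id = ids,
    gene = gene_col,
    protospacer = index_protospacer(seq_len(n_total) - 1L, protospacer_length),
    stringsAsFactors = FALSE), name = name)
}

#' Sample sheets
#'
#' A sample sheet pairs sequenced samples with their screen, arm and role.
#' The `facs` arm compares sorted response bins and needs at least one
#' `high_bin` (responder tail) and one `low_bin` (non-responder tail) sample
#' per screen; the `survival` (dropout) arm compares `day0` against
#' `endpoint`.
#'
#' @param records data frame with columns `sample_id`, `screen_id`, `arm`,
#'   `role`, and optionally `stimulus`, `replicate`, `fastq_path`,
#'   `counts_path`.
#' @return A validated `sample_sheet` (a data frame).
#' @export
sample_sheet <- function(records) {
  required <- c("sample_id", "screen_id", "arm", "role")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0)
    stopf("sample sheet is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  s <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"stimulus" %in% names(s)) s$stimulus <- NA_character_
  if (!"replicate" %in% names(s)) s$replicate <- 1L
  s$replicate <- as.integer(s$replicate)
  if (anyDuplicated(s$sample_id))
    stopf("duplicate sample_id: %s",
          paste(unique(s$sample_id[duplicated(s$sample_id)]), collapse = ", "))
  bad_arm <- !s$arm %in% c("facs", "survival")
  if (any(bad_arm))
    stopf("unknown arm '%s' (expected facs or survival)",
          paste(unique(s$arm[bad_arm]), collapse = ", "))
  bad_role <- !s$role %in% c("high_bin", "low_bin", "day0", "endpoint")
  if (any(bad_role))
    stopf("unknown role '%s'", paste(unique(s$role[bad_role]), collapse = ", "))
  for (sc in unique(s$screen_id)) {
    sub <- s[s$screen_id == sc, , drop = FALSE]
    for (a in unique(sub$arm)) {
      roles <- sub$role[sub$arm == a]
      if (a == "facs" && !(any(roles == "high_bin") && any(roles == "low_bin")))
        stopf("facs screen '%s' needs at least one high_bin and one low_bin sample", sc)
      if (a == "survival" && !(any(roles == "day0") && any(roles == "endpoint")))
        stopf("survival screen '%s' needs day0 and endpoint samples", sc)
    }
  }
  rownames(s) <- NULL
  structure(s, class = c("sample_sheet", "data.frame"))
}

#' Read a sample sheet from CSV
#'
#' @param path path to a headered CSV with the columns described in
#'   [sample_sheet()].
#' @param manifest optional `library_manifest`; recorded for provenance.
#' @return A `sample_sheet`.
#' @export
load_sample_sheet <- function(path, manifest = NULL) {
  if (!file.exists(path)) stopf("sample sheet not found: %s", path)
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        check.names = FALSE)
  s <- sample_sheet(df)
  if (!is.null(manifest)) attr(s, "manifest_name") <- attr(manifest, "name")
  s
}
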