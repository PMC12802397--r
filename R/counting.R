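#' Count matrices
#'
#' An elements x samples integer count matrix tied to a library manifest:
#' rows follow manifest order (zero-filled where an element was never
#' seen), and per-sample unmapped-read counts are carried so that
#' mapped + unmapped equals the reads that went in.
#'
#' @param counts integer matrix with rownames = element_ids (manifest
#'   order) and colnames = sample_ids.
#' @param manifest the `library_manifest` the rows refer to.
#' @param unmapped named integer vector of unmapped reads per sample.
#' @param policy matching policy recorded for provenance.
#' @return A `count_matrix`.
#' @export
count_matrix <- function(counts, manifest, unmapped = NULL, policy = "exact") {
  stopifnot(inherits(manifest, "library_manifest"))
  counts <- as.matrix(counts)
  if (!identical(rownames(counts), manifest$element_id))
    stopf("count rows must match the manifest element order")
  if (any(counts < 0)) stopf("negative counts")
  if (is.null(unmapped)) unmapped <- setNames(integer(ncol(counts)), colnames(counts))
  structure(list(counts = counts,
                 manifest_name = attr(manifest, "name"),
                 element_id = manifest$element_id,
                 unmapped = unmapped,
                 policy = policy),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d elements x %d samples (library '%s', policy %s)\n",
              nrow(x$counts), ncol(x$counts), x$manifest_name, x$policy))
  cat("per-sample mapped / unmapped:\n")
  print(rbind(mapped = colSums(x$counts), unmapped = x$unmapped))
  invisible(x)
}

# build the one-mismatch lookup: for every protospacer, all Hamming-1
# variants; variants shared by >= 2 elements are flagged ambiguous
mismatch_table <- function(protospacers) {
  L <- nchar(protospacers[1])
  n <- length(protospacers)
  keys <- vector("list", 3L * L)
  bases <- c("A", "C", "G", "T")
  slot <- 0L
  for (pos in seq_len(L)) {
    orig <- substr(protospacers, pos, pos)
    for (b in bases) {
      variant <- protospacers
      substr(variant, pos, pos) <- b
      keep <- orig != b
      slot <- slot + 1L
      keys[[slot]] <- cbind(variant[keep], which(keep))
    }
  }
  all_keys <- do.call(rbind, keys)
  variant <- all_keys[, 1]
  elem <- as.integer(all_keys[, 2])
  # a variant equal to another element's exact protospacer can never win
  # (the distance-0 match takes precedence), drop those entries
  clash <- match(variant, protospacers)
  drop <- !is.na(clash)
  variant <- variant[!drop]
  elem <- elem[!drop]
  dup <- duplicated(variant) | duplicated(variant, fromLast = TRUE)
  list(variant = variant, elem = elem, ambiguous = dup)
}

read_fastq_seqs <- function(path) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stopf("unreadable FASTQ '%s': %s", path, conditionMessage(e)))
  toupper(as.character(seqs))
}

# scan candidate offsets on the first reads and return the one with the
# most exact protospacer matches
detect_offset <- function(reads, protospacers, n_scan = 1000L) {
  reads <- utils::head(reads, n_scan)
  L <- nchar(protospacers[1])
  max_off <- min(nchar(reads)) - L + 1L
  if (max_off < 1L) stopf("reads shorter than the protospacer length")
  hits <- vapply(seq_len(max_off), function(off) {
    sum(substr(reads, off, off + L - 1L) %in% protospacers)
  }, integer(1))
  which.max(hits)
}

#' Count protospacer reads for one sample
#'
#' Extracts the fixed-offset protospacer from each read and assigns it to a
#' library element.  Under the `exact` policy the extracted sequence must
#' equal a protospacer; under `one_mismatch` a read also counts when it has
#' a unique best match at Hamming distance 1 (reads within distance 1 of
#' two or more library protospacers are left unmapped).
#'
#' @param fastq path to a FASTQ file (plain or gzip).
#' @param manifest a `library_manifest`.
#' @param sample_id column name for the resulting counts.
#' @param offset 1-based protospacer offset within the read; `NULL`
#'   auto-detects by scanning the first 1000 reads for the offset with the
#'   most exact matches.
#' @param policy `"exact"` or `"one_mismatch"`.
#' @return A one-column `count_matrix` (with `unmapped` and total-read
#'   provenance).
#' @export
count_sample <- function(fastq, manifest, sample_id = NULL, offset = NULL,
                         policy = c("exact", "one_mismatch")) {
  stopifnot(inherits(manifest, "library_manifest"))
  policy <- match.arg(policy)
  sample_id <- sample_id %||% sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq))
  reads <- read_fastq_seqs(fastq)
  ps <- manifest$protospacer
  L <- nchar(ps[1])
  n_elem <- nrow(manifest)
  counts <- matrix(0L, nrow = n_elem, ncol = 1,
                   dimnames = list(manifest$element_id, sample_id))
  if (length(reads) == 0) {
    warnf("no reads in '%s'; returning an empty column", fastq)
    return(count_matrix(counts, manifest,
                        unmapped = setNames(0L, sample_id), policy = policy))
  }
  if (is.null(offset)) offset <- detect_offset(reads, ps)
  if (offset + L - 1L > min(nchar(reads)))
    stopf("offset %d + protospacer length %d exceeds read length %d",
          offset, L, min(nchar(reads)))
  extracted <- substr(reads, offset, offset + L - 1L)
  hit <- match(extracted, ps)
  if (policy == "one_mismatch" && anyNA(hit)) {
    tab <- mismatch_table(ps)
    miss <- which(is.na(hit))
    vi <- match(extracted[miss], tab$variant)
    ok <- !is.na(vi) & !tab$ambiguous[pmax(vi, 1L)]
    hit[miss[ok]] <- tab$elem[vi[ok]]
  }
  mapped <- hit[!is.na(hit)]
  tallied <- tabulate(mapped, nbins = n_elem)
  counts[, 1] <- tallied
  unmapped <- length(reads) - length(mapped)
  out <- count_matrix(counts, manifest,
                      unmapped = setNames(as.integer(unmapped), sample_id),
                      policy = policy)
  attr(out, "offset") <- offset
  out
}

#' Merge single-sample count columns into one matrix
#'
#' @param ... `count_matrix` objects produced against the same manifest.
#' @param sheet optional `sample_sheet`; when given, columns are reordered
#'   to follow it.
#' @return A merged `count_matrix`.
#' @export
merge_columns <- function(..., sheet = NULL) {
  cols <- list(...)
  if (length(cols) == 1 && is.list(cols[[1]]) && !inherits(cols[[1]], "count_matrix"))
    cols <- cols[[1]]
  stopifnot(length(cols) >= 1)
  lapply(cols, function(x) stopifnot(inherits(x, "count_matrix")))
  ref <- cols[[1]]
  for (x in cols[-1]) {
    if (!identical(x$manifest_name, ref$manifest_name) ||
        !identical(x$element_id, ref$element_id))
      stopf("cannot merge columns counted against different manifests ('%s' vs '%s')",
            x$manifest_name, ref$manifest_name)
  }
  counts <- do.call(cbind, lapply(cols, `[[`, "counts"))
  unmapped <- do.call(c, lapply(cols, `[[`, "unmapped"))
  if (!is.null(sheet)) {
    ord <- intersect(sheet$sample_id, colnames(counts))
    counts <- counts[, ord, drop = FALSE]
    unmapped <- unmapped[ord]
  }
  out <- ref
  out$counts <- counts
  out$unmapped <- unmapped
  out
}

#' Write / read a count matrix as TSV
#'
#' The TSV has an `element_id` first column and one column per sample.
#'
#' @param x a `count_matrix`.
#' @param path file path.
#' @return `path` (write) or a `count_matrix` (read), invisibly for write.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(element_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @param manifest the `library_manifest` the counts refer to.
#' @export
read_counts <- function(path, manifest) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (names(df)[1] != "element_id") stopf("first column must be element_id")
  idx <- match(manifest$element_id, df$element_id)
  if (anyNA(idx)) stopf("counts file is missing %d manifest elements", sum(is.na(idx)))
  counts <- as.matrix(df[idx, -1, drop = FALSE])
  rownames(counts) <- manifest$element_id
  storage.mode(counts) <- "integer"
  count_matrix(counts, manifest, policy = "loaded")
}
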