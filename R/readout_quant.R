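#' Gate the tails of the red/green ratio distribution
#'
#' Emulates the sorter: events are ranked by red/green ratio and the top
#' and bottom `q` fractions are kept as the high (responder) and low
#' (non-responder) bins.  Bin sizes are `floor(q * n)` when ratios at the
#' boundary are distinct; a tied group spanning a cut is kept together and
#' excluded from the bin (a sorter cutting at a threshold cannot split
#' identical ratios), so with all ratios equal both bins are empty.
#'
#' @param events data frame with `red` and `green` columns (plus anything
#'   else, carried through).
#' @param q tail fraction in (0, 0.5).
#' @return List with `high`, `low` (row subsets of `events`), `hi_cut`,
#'   `lo_cut` and `n_dropped` (events with green <= 0).
#' @export
gate_tails <- function(events, q = 0.35) {
  if (q <= 0 || q >= 0.5) stopf("q must lie in (0, 0.5); bins would overlap")
  keep <- events$green > 0
  events <- events[keep, , drop = FALSE]
  n <- nrow(events)
  if (n < 1 / q) stopf("too few events (%d) for tail fraction %g", n, q)
  ratio <- events$red / events$green
  v <- sort(ratio)
  k <- floor(q * n)
  if (k == 0) {
    warnf("tail fraction %g of %d events is empty", q, n)
    empty <- events[0, , drop = FALSE]
    return(list(high = empty, low = empty, hi_cut = NA_real_,
                lo_cut = NA_real_, n_dropped = sum(!keep)))
  }
  lo_cut <- v[k]
  low_sel <- if (k < n && v[k + 1] == lo_cut) ratio < lo_cut else ratio <= lo_cut
  hi_cut <- v[n - k + 1]
  high_sel <- if (n - k >= 1 && v[n - k] == hi_cut) ratio > hi_cut else ratio >= hi_cut
  if (!any(low_sel) || !any(high_sel))
    warnf("tied ratios at the cut left a bin empty (no separable tails)")
  list(high = events[high_sel, , drop = FALSE],
       low = events[low_sel, , drop = FALSE],
       hi_cut = hi_cut, lo_cut = lo_cut, n_dropped = sum(!keep))
}

#' Integrated calcium activity from flow events
#'
#' Per-sample median red/green ratio ("integrated calcium activity"),
#' summarized per condition as mean +/- SEM over samples and expressed
#' relative to a reference condition's mean.
#'
#' @param events data frame with `sample_id`, `condition`, `green`, `red`.
#' @param reference_condition condition whose mean defines relative
#'   activity 1.
#' @return List with `samples` (sample_id, condition, median_ratio,
#'   n_events, n_dropped) and `conditions` (condition, mean, sem,
#'   n_samples, relative).
#' @export
integrated_activity <- function(events, reference_condition) {
  stopifnot(all(c("sample_id", "condition", "green", "red") %in% names(events)))
  if (!reference_condition %in% events$condition)
    stopf("reference condition '%s' has no samples", reference_condition)
  dropped <- events$green <= 0
  kept <- events[!dropped, , drop = FALSE]
  empty <- setdiff(unique(events$sample_id), unique(kept$sample_id))
  if (length(empty) > 0)
    stopf("sample(s) with no retained events: %s", paste(empty, collapse = ", "))
  med <- tapply(kept$red / kept$green, kept$sample_id, stats::median)
  cond <- tapply(kept$condition, kept$sample_id, function(x) x[1])
  n_ev <- tapply(kept$sample_id, kept$sample_id, length)
  n_drop <- tapply(dropped, events$sample_id, sum)
  samples <- data.frame(sample_id = names(med),
                        condition = as.character(cond[names(med)]),
                        median_ratio = as.numeric(med),
                        n_events = as.integer(n_ev[names(med)]),
                        n_dropped = as.integer(n_drop[names(med)]),
                        stringsAsFactors = FALSE)
  agg_mean <- tapply(samples$median_ratio, samples$condition, mean)
  agg_sem <- tapply(samples$median_ratio, samples$condition, sem)
  agg_n <- tapply(samples$median_ratio, samples$condition, length)
  conditions <- data.frame(condition = names(agg_mean),
                           mean = as.numeric(agg_mean),
                           sem = as.numeric(agg_sem),
                           n_samples = as.integer(agg_n),
                           stringsAsFactors = FALSE)
  ref_mean <- conditions$mean[conditions$condition == reference_condition]
  conditions$relative <- conditions$mean / ref_mean
  rownames(samples) <- rownames(conditions) <- NULL
  list(samples = samples, conditions = conditions,
       reference_condition = reference_condition)
}

#' dF/F0 traces and peak extraction
#'
#' For each cell, `F0` is the mean fluorescence over the baseline window,
#' `dF/F0(t) = (F(t) - F0)/F0`, and the peak is the maximum over the
#' post-stimulation window (stimulation frame to the end of the trace
#' unless narrowed).  Before peak-picking the dF/F0 series is lightly
#' smoothed with a centered `smooth_frames`-point moving average (partial
#' windows at the trace edges); taking the maximum of a raw noisy trace
#' overestimates the peak, and a short moving average removes most of
#' that bias while leaving any transient at least `smooth_frames` wide
#' untouched.  Set `smooth_frames = 1` for the raw maximum.  Cells with
#' `F0 <= 0` are excluded with a reason.
#'
#' @param traces an `imaging_traces` object from [simulate_traces()], or a
#'   list with `traces` (data frame `cell_id`, `frame`, `F`),
#'   `stim_frame` and `baseline_window`.
#' @param peak_window optional `c(from, to)` frames for the peak search;
#'   default stimulation frame to trace end.
#' @param smooth_frames odd moving-average width for peak extraction
#'   (default 5).
#' @return List with `dff` (long data frame `cell_id`, `frame`, `dff`;
#'   unsmoothed), `peaks` (`cell_id`, `f0`, `peak_dff`) and `excluded`.
#' @export
dff_traces <- function(traces, peak_window = NULL, smooth_frames = 5L) {
  if (smooth_frames < 1 || smooth_frames %% 2 == 0)
    stopf("smooth_frames must be a positive odd integer")
  tr <- traces$traces
  stim <- traces$stim_frame
  bw <- traces$baseline_window
  if (bw[2] >= stim) stopf("baseline window must precede the stimulation frame")
  f0 <- tapply(tr$F[tr$frame >= bw[1] & tr$frame <= bw[2]],
               tr$cell_id[tr$frame >= bw[1] & tr$frame <= bw[2]], mean)
  bad <- names(f0)[!is.finite(f0) | f0 <= 0]
  excluded <- data.frame(cell_id = bad,
                         reason = rep("non-positive baseline F0", length(bad)),
                         stringsAsFactors = FALSE)
  keep <- !(tr$cell_id %in% bad)
  tr <- tr[keep, , drop = FALSE]
  dff <- (tr$F - as.numeric(f0[tr$cell_id])) / as.numeric(f0[tr$cell_id])
  out_dff <- data.frame(cell_id = tr$cell_id, frame = tr$frame, dff = dff,
                        stringsAsFactors = FALSE)
  pw <- peak_window %||% c(stim, max(tr$frame))
  # centered moving average with partial windows at the edges
  smooth_vec <- function(x) {
    if (smooth_frames == 1L) return(x)
    h <- (smooth_frames - 1L) %/% 2L
    cs <- cumsum(c(0, x))
    n <- length(x)
    from <- pmax(seq_len(n) - h, 1L)
    to <- pmin(seq_len(n) + h, n)
    (cs[to + 1L] - cs[from]) / (to - from + 1L)
  }
  by_cell <- split(seq_len(nrow(out_dff)), out_dff$cell_id)
  peaks_v <- vapply(by_cell, function(ix) {
    ix <- ix[order(out_dff$frame[ix])]
    sm <- smooth_vec(out_dff$dff[ix])
    fr <- out_dff$frame[ix]
    max(sm[fr >= pw[1] & fr <= pw[2]])
  }, numeric(1))
  peaks <- data.frame(cell_id = names(peaks_v),
                      f0 = as.numeric(f0[names(peaks_v)]),
                      peak_dff = as.numeric(peaks_v),
                      stringsAsFactors = FALSE)
  rownames(peaks) <- NULL
  list(dff = out_dff, peaks = peaks, excluded = excluded)
}

#' Stimulus response normalized to a reference stimulus
#'
#' Per-cell ratio of the peak dF/F0 for stimulus A over the reference
#' stimulus B (e.g. tryptone over KCl), with cells lacking a positive
#' reference response excluded.
#'
#' @param peaks_a,peaks_b data frames (`cell_id`, `peak_dff`) for the two
#'   stimuli, paired by `cell_id`.
#' @return Data frame `cell_id`, `peak_a`, `peak_b`, `normalized`.
#' @export
normalized_response <- function(peaks_a, peaks_b) {
  common <- intersect(peaks_a$cell_id, peaks_b$cell_id)
  a <- peaks_a$peak_dff[match(common, peaks_a$cell_id)]
  b <- peaks_b$peak_dff[match(common, peaks_b$cell_id)]
  keep <- b > 0
  data.frame(cell_id = common[keep], peak_a = a[keep], peak_b = b[keep],
             normalized = a[keep] / b[keep], stringsAsFactors = FALSE)
}

#' Percent change between paired pre/post measurements
#'
#' @param pre,post paired numeric vectors.
#' @return `(post - pre) / pre * 100`.
#' @export
percent_change <- function(pre, post) (post - pre) / pre * 100

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `r(x) = bottom + (top - bottom) / (1 +
#' (ec50/x)^hill)` with EC50 parameterized on the log scale, from five
#' deterministic EC50 starts spanning the dose range (Hill starts at
#' +/-1).  The best converged fit by SSE is returned; non-convergence and
#' a negative Hill slope (non-monotone/inverted data) are flagged, not
#' hidden.
#'
#' @param dose,response numeric vectors (>= 4 distinct doses, dose > 0).
#' @param fix_hill optional fixed Hill slope.
#' @param bottom_floor lower bound for `bottom` (0 for fluorescence or
#'   secretion data; `-Inf` to disable).
#' @return A `dose_response_fit` list: `bottom`, `top`, `ec50`, `hill`,
#'   `sse`, `converged`, `negative_hill`, and `fitted(x)` closure.
#' @export
fit_4pl <- function(dose, response, fix_hill = NULL, bottom_floor = 0) {
  stopifnot(length(dose) == length(response), all(dose > 0))
  if (length(unique(dose)) < 4) stopf("need at least 4 distinct doses")
  df <- data.frame(x = dose, y = response)
  rng <- range(response)
  starts_le <- stats::quantile(log(unique(dose)), c(0.1, 0.3, 0.5, 0.7, 0.9),
                               names = FALSE)
  lower <- c(bottom = bottom_floor, top = bottom_floor, log_ec50 = -Inf, hill = -Inf)
  best <- NULL
  for (le in starts_le) {
    for (h0 in if (is.null(fix_hill)) c(1, -1) else fix_hill) {
      start <- list(bottom = max(rng[1], bottom_floor),
                    top = max(rng[2], bottom_floor + 1e-6),
                    log_ec50 = le, hill = h0)
      if (!is.null(fix_hill)) {
        form <- y ~ bottom + (top - bottom) / (1 + exp(fix_hill * (log_ec50 - log(x))))
        start$hill <- NULL
        lw <- lower[c("bottom", "top", "log_ec50")]
      } else {
        form <- y ~ bottom + (top - bottom) / (1 + exp(hill * (log_ec50 - log(x))))
        lw <- lower
      }
      fit <- tryCatch(
        minpack.lm::nlsLM(form, data = df, start = start, lower = lw,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best))
    return(structure(list(bottom = NA_real_, top = NA_real_, ec50 = NA_real_,
                          hill = fix_hill %||% NA_real_, sse = NA_real_,
                          converged = FALSE, negative_hill = NA),
                     class = "dose_response_fit"))
  cf <- stats::coef(best$fit)
  hill <- if (is.null(fix_hill)) unname(cf["hill"]) else fix_hill
  out <- list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
              ec50 = exp(unname(cf["log_ec50"])), hill = hill,
              sse = best$sse,
              converged = best$fit$convInfo$isConv %||% TRUE,
              negative_hill = hill < 0)
  out$fitted <- function(x) four_pl(x, out$bottom, out$top, out$ec50, out$hill)
  structure(out, class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("4PL fit: bottom %.4g, top %.4g, EC50 %.4g, hill %.3g (SSE %.3g%s)\n",
              x$bottom, x$top, x$ec50, x$hill, x$sse,
              if (isTRUE(x$negative_hill)) "; WARNING: negative hill slope" else ""))
  invisible(x)
}

#' Relative expression and knockdown by the ddCt method
#'
#' `dCt = Ct_target - Ct_reference` per condition (technical replicates
#' averaged; a replicate SD above 0.5 cycles is flagged), `ddCt =
#' dCt_condition - dCt_control`, relative expression `2^-ddCt`, knockdown
#' `(1 - relative) * 100` percent.
#'
#' @param ct data frame with columns `condition`, `gene`, `ct` (one row
#'   per technical replicate).
#' @param target target gene symbol.
#' @param reference reference (housekeeping) gene, default `"Gapdh"`.
#' @param control control condition label (e.g. the NTC sgRNA sample).
#' @return Data frame per condition: `dct`, `ddct`,
#'   `relative_expression`, `knockdown_pct`, `flag_high_sd`.
#' @export
ddct_knockdown <- function(ct, target, reference = "Gapdh", control) {
  stopifnot(all(c("condition", "gene", "ct") %in% names(ct)))
  if (!reference %in% ct$gene)
    stopf("reference gene '%s' not present in the Ct table", reference)
  if (!target %in% ct$gene) stopf("target gene '%s' not in the Ct table", target)
  if (!control %in% ct$condition) stopf("control condition '%s' missing", control)
  conds <- unique(ct$condition)
  get_ct <- function(cond, gene) {
    x <- ct$ct[ct$condition == cond & ct$gene == gene]
    if (length(x) == 0)
      stopf("no Ct values for gene '%s' in condition '%s'", gene, cond)
    c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0)
  }
  rows <- lapply(conds, function(cond) {
    tg <- get_ct(cond, target)
    rf <- get_ct(cond, reference)
    data.frame(condition = cond, dct = tg["mean"] - rf["mean"],
               flag_high_sd = tg["sd"] > 0.5 || rf["sd"] > 0.5,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dct_control <- out$dct[out$condition == control]
  out$ddct <- out$dct - dct_control
  out$relative_expression <- 2^(-out$ddct)
  out$knockdown_pct <- (1 - out$relative_expression) * 100
  rownames(out) <- NULL
  out
}

#' Relative secretion fold changes
#'
#' Expresses each well's measured hormone concentration as a fold change
#' over the mean of the reference-condition wells, with per-condition
#' mean +/- SEM over wells.
#'
#' @param wells data frame with `condition` and `value` columns.
#' @param reference_condition reference condition label.
#' @return List with `wells` (input plus `fold`) and `conditions`
#'   (`condition`, `mean_fold`, `sem`, `n_wells`).
#' @export
relative_secretion <- function(wells, reference_condition) {
  stopifnot(all(c("condition", "value") %in% names(wells)))
  ref <- wells$value[wells$condition == reference_condition]
  if (length(ref) < 1) stopf("no wells for reference condition '%s'",
                             reference_condition)
  if (mean(ref) <= 0) stopf("reference mean must be positive")
  wells$fold <- wells$value / mean(ref)
  mean_fold <- tapply(wells$fold, wells$condition, mean)
  sem_fold <- tapply(wells$fold, wells$condition, sem)
  n_wells <- tapply(wells$fold, wells$condition, length)
  conditions <- data.frame(condition = names(mean_fold),
                           mean_fold = as.numeric(mean_fold),
                           sem = as.numeric(sem_fold),
                           n_wells = as.integer(n_wells),
                           stringsAsFactors = FALSE)
  rownames(conditions) <- NULL
  list(wells = wells, conditions = conditions,
       reference_condition = reference_condition)
}
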