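#' Simulation configuration for a sorted CRISPRi screen
#'
#' Captures the experimental conditions of a sort-based activity screen:
#' low-MOI single-integration infection at a given per-element coverage,
#' a stimulus-induced responder state whose odds are modulated by gene
#' knockdown, top/bottom tail sorting on the (log) red/green ratio, a
#' parallel dropout arm run for a number of population doublings, and
#' sequencing with optional overdispersion.
#'
#' Per-sgRNA knockdown efficacy is drawn uniformly on `kd_range`; it scales
#' the planted gene effect on the log-odds scale, so an efficacy of 0 leaves
#' a cell wild-type and 1 applies the full effect.  Gene effects are odds
#' multipliers on the responder state (`< 1`: knockdown suppresses the
#' response, the screen's positive regulators; `> 1`: negative regulators).
#' Fitness is a per-doubling growth multiplier relative to neutral cells.
#'
#' @param seed integer seed; all randomness in [simulate_screen()] flows
#'   from it.
#' @param moi multiplicity of infection in `[0.05, 1]`; used as a
#'   single-integration multiplicity filter (cells with more than one
#'   integration are discarded), reported in the provenance record.
#' @param coverage cells per library element after selection.
#' @param doublings population doublings of the dropout arm (>= 6).
#' @param base_responder_fraction probability that a wild-type cell enters
#'   the photoconverted (responder) state under stimulus.
#' @param gate_quantile sorted tail fraction in (0, 0.5); 0.35 reproduces
#'   top/bottom-35% sorting.
#' @param reads_per_sample sequencing depth per sample; default
#'   `1000 * n_elements` (1000x depth).
#' @param dispersion count overdispersion; 0 gives multinomial reads,
#'   `> 0` a gamma-mixed multinomial (negative-binomial-like).
#' @param kd_range range of the uniform per-sgRNA knockdown efficacy.
#' @param ratio_mu means of the per-cell log red/green ratio for the
#'   non-responder and responder components.
#' @param ratio_sd common sd of the log-ratio components.
#' @param effects named numeric vector of per-gene responder-odds
#'   multipliers (genes absent from the vector are neutral, multiplier 1).
#' @param fitness named numeric vector of per-gene per-doubling growth
#'   multipliers (absent genes have fitness 1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       moi = 0.4,
                       coverage = 1000,
                       doublings = 6L,
                       base_responder_fraction = 0.3,
                       gate_quantile = 0.35,
                       reads_per_sample = NULL,
                       dispersion = 0,
                       kd_range = c(0.5, 1),
                       ratio_mu = c(non_responder = 0, responder = 1),
                       ratio_sd = 0.5,
                       effects = NULL,
                       fitness = NULL) {
  if (gate_quantile <= 0 || gate_quantile >= 0.5)
    stopf("gate_quantile must lie in (0, 0.5), got %g", gate_quantile)
  if (moi < 0.05 || moi > 1)
    stopf("moi must lie in [0.05, 1], got %g", moi)
  if (base_responder_fraction < 0 || base_responder_fraction > 1)
    stopf("base_responder_fraction must be a probability")
  if (doublings < 6) stopf("doublings must be >= 6, got %d", doublings)
  if (dispersion < 0) stopf("dispersion must be >= 0")
  stopifnot(length(kd_range) == 2, kd_range[1] >= 0, kd_range[2] <= 1,
            kd_range[1] <= kd_range[2])
  structure(list(seed = as.integer(seed), moi = moi, coverage = coverage,
                 doublings = as.integer(doublings),
                 base_responder_fraction = base_responder_fraction,
                 gate_quantile = gate_quantile,
                 reads_per_sample = reads_per_sample,
                 dispersion = dispersion, kd_range = kd_range,
                 ratio_mu = ratio_mu, ratio_sd = ratio_sd,
                 effects = effects, fitness = fitness),
            class = "sim_config")
}

# solve for the log-ratio cut c with mixture tail mass `target` above (upper)
# or below (lower) the cut, given responder weight w.
mixture_cut <- function(w, mu, sd, target, side = c("upper", "lower")) {
  side <- match.arg(side)
  f <- function(c) {
    if (side == "upper")
      w * stats::pnorm(c, mu[2], sd, lower.tail = FALSE) +
        (1 - w) * stats::pnorm(c, mu[1], sd, lower.tail = FALSE) - target
    else
      w * stats::pnorm(c, mu[2], sd) + (1 - w) * stats::pnorm(c, mu[1], sd) - target
  }
  lo <- min(mu) - 10 * sd
  hi <- max(mu) + 10 * sd
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# gamma-mixed multinomial read sampling; dispersion 0 -> plain multinomial
sample_reads <- function(abundance, depth, dispersion) {
  if (all(abundance <= 0)) return(integer(length(abundance)))
  w <- abundance
  if (dispersion > 0) {
    shape <- 1 / dispersion
    w <- w * stats::rgamma(length(w), shape = shape, rate = shape)
  }
  as.integer(stats::rmultinom(1, size = depth, prob = w))
}

#' Simulate a sorted CRISPRi screen with planted effects
#'
#' Generates count matrices for the FACS arm (high and low sorted bins) and
#' the survival (dropout) arm (day 0 and endpoint), together with the
#' planted ground truth.  Cells carrying an sgRNA against gene *g* with
#' knockdown efficacy *e* become responders with probability
#' `plogis(qlogis(base) + e * log(odds_multiplier[g]))`; per-cell log
#' red/green ratios are a two-component Gaussian mixture, and the sorter
#' cuts the top and bottom `gate_quantile` of the pooled ratio
#' distribution.  In the default aggregate mode each element's cell mass is
#' split binomially between responder states and bins, which preserves the
#' sampling distribution at a fraction of the per-cell cost; `mode =
#' "percell"` simulates every cell explicitly and is intended for
#' small-instance validation.
#'
#' @param manifest a `library_manifest`.
#' @param cfg a [sim_config()].
#' @param mode `"aggregate"` (default) or `"percell"`.
#' @return A `sim_output` list: `counts` (a [count_matrix()]), `sheet`
#'   (a [sample_sheet()]), `truth` (per-gene effect class, odds multiplier,
#'   fitness; per-sgRNA kd efficacy and responder probability), and
#'   `provenance` (config echo, gate cuts, single-integration fraction).
#' @export
simulate_screen <- function(manifest, cfg, mode = c("aggregate", "percell")) {
  stopifnot(inherits(manifest, "library_manifest"), inherits(cfg, "sim_config"))
  mode <- match.arg(mode)
  n_elem <- nrow(manifest)
  depth <- cfg$reads_per_sample %||% (1000L * n_elem)
  if (depth < n_elem)
    warnf("reads_per_sample (%d) is below 1x element coverage (%d)", depth, n_elem)

  genes <- unique(manifest$gene[manifest$category == "targeting"])
  odds_mult <- setNames(rep(1, length(genes)), genes)
  if (!is.null(cfg$effects)) {
    unknown <- setdiff(names(cfg$effects), genes)
    if (length(unknown) > 0)
      stopf("effects for genes not in manifest: %s",
            paste(utils::head(unknown, 5), collapse = ", "))
    odds_mult[names(cfg$effects)] <- cfg$effects
  }
  fitness <- setNames(rep(1, length(genes)), genes)
  if (!is.null(cfg$fitness)) {
    unknown <- setdiff(names(cfg$fitness), genes)
    if (length(unknown) > 0)
      stopf("fitness for genes not in manifest: %s",
            paste(utils::head(unknown, 5), collapse = ", "))
    fitness[names(cfg$fitness)] <- cfg$fitness
  }

  with_seed(cfg$seed, {
    is_ntc <- manifest$category == "non_targeting"
    kd <- stats::runif(n_elem, cfg$kd_range[1], cfg$kd_range[2])
    kd[is_ntc] <- 0
    elem_mult <- rep(1, n_elem)
    elem_fit <- rep(1, n_elem)
    idx <- !is_ntc
    elem_mult[idx] <- odds_mult[manifest$gene[idx]]
    elem_fit[idx] <- fitness[manifest$gene[idx]]

    base <- cfg$base_responder_fraction
    # kd efficacy scales the planted effect on the log-odds scale; NTCs and
    # neutral genes stay exactly at the base rate
    log_odds <- log(base / (1 - base)) + kd * log(elem_mult)
    p_resp <- ifelse(elem_mult == 0 & kd > 0, 0, stats::plogis(log_odds))
    p_resp[is_ntc] <- base

    # representation after infection + selection; MOI enters as the
    # single-integration fraction of infected cells (Poisson filter)
    single_frac <- stats::dpois(1, cfg$moi) / (1 - stats::dpois(0, cfg$moi))
    total_cells <- round(cfg$coverage * n_elem)
    cells <- as.integer(stats::rmultinom(1, total_cells, rep(1, n_elem)))

    mu <- cfg$ratio_mu
    sdv <- cfg$ratio_sd
    q <- cfg$gate_quantile

    if (mode == "aggregate") {
      responders <- stats::rbinom(n_elem, cells, p_resp)
      non_resp <- cells - responders
      w <- sum(responders) / sum(cells)
      hi_cut <- mixture_cut(w, mu, sdv, q, "upper")
      lo_cut <- mixture_cut(w, mu, sdv, q, "lower")
      p_r_hi <- stats::pnorm(hi_cut, mu[2], sdv, lower.tail = FALSE)
      p_n_hi <- stats::pnorm(hi_cut, mu[1], sdv, lower.tail = FALSE)
      p_r_lo <- stats::pnorm(lo_cut, mu[2], sdv)
      p_n_lo <- stats::pnorm(lo_cut, mu[1], sdv)
      high_cells <- stats::rbinom(n_elem, responders, p_r_hi) +
        stats::rbinom(n_elem, non_resp, p_n_hi)
      low_cells <- stats::rbinom(n_elem, responders, p_r_lo) +
        stats::rbinom(n_elem, non_resp, p_n_lo)
    } else {
      elem_of_cell <- rep.int(seq_len(n_elem), cells)
      resp_cell <- stats::rbinom(length(elem_of_cell), 1L,
                                 p_resp[elem_of_cell]) == 1L
      ratio <- stats::rnorm(length(elem_of_cell),
                            ifelse(resp_cell, mu[2], mu[1]), sdv)
      hi_cut <- stats::quantile(ratio, 1 - q, type = 1, names = FALSE)
      lo_cut <- stats::quantile(ratio, q, type = 1, names = FALSE)
      high_cells <- tabulate(elem_of_cell[ratio >= hi_cut], nbins = n_elem)
      low_cells <- tabulate(elem_of_cell[ratio <= lo_cut], nbins = n_elem)
      w <- mean(resp_cell)
    }

    # dropout arm: endpoint abundance scales with fitness^doublings
    # (neutral growth cancels in the relative abundances)
    day0_cells <- cells
    endpoint_ab <- cells * elem_fit^cfg$doublings

    counts <- cbind(
      facs_high = sample_reads(high_cells, depth, cfg$dispersion),
      facs_low = sample_reads(low_cells, depth, cfg$dispersion),
      day0 = sample_reads(day0_cells, depth, cfg$dispersion),
      endpoint = sample_reads(endpoint_ab, depth, cfg$dispersion))
    rownames(counts) <- manifest$element_id

    sheet <- sample_sheet(data.frame(
      sample_id = colnames(counts),
      screen_id = "sim",
      arm = c("facs", "facs", "survival", "survival"),
      role = c("high_bin", "low_bin", "day0", "endpoint"),
      stimulus = "simulated",
      replicate = 1L,
      stringsAsFactors = FALSE))

    effect_class <- ifelse(odds_mult < 1, "positive_regulator",
                           ifelse(odds_mult > 1, "negative_regulator", "neutral"))
    truth <- list(
      genes = data.frame(gene = genes,
                         effect_class = effect_class,
                         odds_multiplier = unname(odds_mult),
                         fitness = unname(fitness),
                         stringsAsFactors = FALSE),
      sgrnas = data.frame(element_id = manifest$element_id,
                          gene = manifest$gene,
                          kd_efficacy = kd,
                          responder_prob = p_resp,
                          stringsAsFactors = FALSE))

    structure(list(
      counts = count_matrix(counts, manifest,
                            unmapped = setNames(integer(4), colnames(counts)),
                            policy = "simulated"),
      sheet = sheet,
      truth = truth,
      provenance = list(config = cfg, mode = mode,
                        responder_fraction = w,
                        hi_cut = hi_cut, lo_cut = lo_cut,
                        single_integration_fraction = single_frac,
                        reads_per_sample = depth)),
      class = "sim_output")
  })
}

#' Simulate per-cell flow cytometry events
#'
#' Draws a two-component log-normal mixture over the red/green ratio: a
#' responder (photoconverted, high-ratio) and a non-responder component.
#' Green intensities are log-normal around `green_mu`; red is green times
#' the component ratio.  Component membership is retained as hidden truth.
#'
#' @param n_cells number of events.
#' @param responder_fraction probability an event is a responder.
#' @param ratio_params list with `mu_responder`, `mu_non_responder`
#'   (log-ratio means) and `sd` (common log-ratio sd).
#' @param green_mu,green_sd log-scale parameters of the green intensity.
#' @param sample_id,condition labels attached to every event.
#' @param seed integer seed.
#' @return A data frame with `sample_id`, `condition`, `green`, `red` and
#'   the hidden `truth_responder` flag.
#' @export
simulate_flow_events <- function(n_cells, responder_fraction,
                                 ratio_params = list(mu_responder = 1,
                                                     mu_non_responder = 0,
                                                     sd = 0.5),
                                 green_mu = log(1000), green_sd = 0.4,
                                 sample_id = "s1", condition = "stim",
                                 seed = 1L) {
  stopifnot(n_cells >= 1, responder_fraction >= 0, responder_fraction <= 1)
  with_seed(seed, {
    resp <- stats::runif(n_cells) < responder_fraction
    log_ratio <- stats::rnorm(n_cells,
                              ifelse(resp, ratio_params$mu_responder,
                                     ratio_params$mu_non_responder),
                              ratio_params$sd)
    green <- exp(stats::rnorm(n_cells, green_mu, green_sd))
    data.frame(sample_id = sample_id, condition = condition,
               green = green, red = green * exp(log_ratio),
               truth_responder = resp, stringsAsFactors = FALSE)
  })
}

#' Simulate calcium-imaging fluorescence traces
#'
#' Each cell's trace is a flat baseline followed by a stimulus transient
#' and white noise: dF/F0 steps to `peak_dff` at the stimulation frame,
#' holds it for `plateau_frames` (calcium transients have a finite-width
#' peak), then decays exponentially with time constant `decay_tau`.
#'
#' @param n_cells number of cells.
#' @param peak_dff true peak dF/F0 (scalar or per-cell vector).
#' @param onset_frame stimulation frame (baseline is frames
#'   `1:(onset_frame-1)`).
#' @param decay_tau decay time constant in frames (> 0).
#' @param noise_sd white-noise sd on the dF/F0 scale.
#' @param plateau_frames frames the transient stays at its peak before
#'   decaying.
#' @param n_frames trace length.
#' @param f0 baseline fluorescence (arbitrary units).
#' @param seed integer seed.
#' @return An `imaging_traces` list: `traces` (long data frame `cell_id`,
#'   `frame`, `F`), `stim_frame`, `baseline_window`, and `truth` (per-cell
#'   true peaks).
#' @export
simulate_traces <- function(n_cells, peak_dff, onset_frame = 20L,
                            decay_tau = 30, noise_sd = 0.05,
                            plateau_frames = 5L, n_frames = 100L,
                            f0 = 100, seed = 1L) {
  if (decay_tau <= 0) stopf("decay_tau must be > 0")
  if (plateau_frames < 1) stopf("plateau_frames must be >= 1")
  peak <- rep_len(peak_dff, n_cells)
  with_seed(seed, {
    frames <- seq_len(n_frames)
    decay_from <- onset_frame + plateau_frames - 1L
    shape <- ifelse(frames < onset_frame, 0,
                    ifelse(frames <= decay_from, 1,
                           exp(-(frames - decay_from) / decay_tau)))
    dff <- outer(peak, shape)                       # cells x frames
    dff <- dff + stats::rnorm(length(dff), 0, noise_sd)
    traces <- data.frame(
      cell_id = rep(sprintf("c%04d", seq_len(n_cells)), each = n_frames),
      frame = rep(frames, times = n_cells),
      F = as.vector(t(f0 * (1 + dff))),
      stringsAsFactors = FALSE)
    structure(list(traces = traces,
                   stim_frame = as.integer(onset_frame),
                   baseline_window = c(1L, as.integer(onset_frame) - 1L),
                   truth = data.frame(cell_id = sprintf("c%04d", seq_len(n_cells)),
                                      peak_dff = peak,
                                      stringsAsFactors = FALSE)),
              class = "imaging_traces")
  })
}

#' Simulate dose-response measurements from a 4PL curve
#'
#' @param doses positive dose vector.
#' @param bottom,top,ec50,hill true four-parameter logistic parameters.
#' @param noise_sd additive Gaussian noise sd (response units).
#' @param n_reps replicate measurements per dose.
#' @param seed integer seed.
#' @return Data frame with `dose` and `response`.
#' @export
simulate_dose_response <- function(doses, bottom = 0, top = 1, ec50 = 1,
                                   hill = 1, noise_sd = 0, n_reps = 1L,
                                   seed = 1L) {
  stopifnot(all(doses > 0), ec50 > 0)
  d <- rep(doses, each = n_reps)
  with_seed(seed, {
    r <- four_pl(d, bottom, top, ec50, hill) +
      stats::rnorm(length(d), 0, noise_sd)
    data.frame(dose = d, response = r)
  })
}

#' Write a count column as a synthetic FASTQ file
#'
#' Emits one read per sequenced fragment: a fixed-length read with the
#' element's protospacer embedded at `offset` (1-based) inside random
#' flanking sequence, constant quality.  Used to exercise the counting
#' module end to end.
#'
#' @param counts named integer vector (element_id -> reads).
#' @param manifest the `library_manifest` the counts refer to.
#' @param path output FASTQ path (plain text).
#' @param read_length total read length.
#' @param offset 1-based position of the protospacer within the read.
#' @param error_rate per-read probability of a single random substitution
#'   inside the protospacer (models sequencing error).
#' @param seed integer seed.
#' @return `path`, invisibly.
#' @export
write_screen_fastq <- function(counts, manifest, path, read_length = 50L,
                               offset = 11L, error_rate = 0, seed = 1L) {
  stopifnot(inherits(manifest, "library_manifest"))
  ps_len <- nchar(manifest$protospacer[1])
  if (offset + ps_len - 1L > read_length)
    stopf("offset %d + protospacer length %d exceeds read length %d",
          offset, ps_len, read_length)
  counts <- counts[counts > 0]
  idx <- match(names(counts), manifest$element_id)
  if (anyNA(idx)) stopf("counts contain element_ids not in the manifest")
  with_seed(seed, {
    n_reads <- sum(counts)
    elem <- rep.int(idx, counts)
    elem <- sample(elem)                        # shuffle read order
    bases <- c("A", "C", "G", "T")
    left <- offset - 1L
    right <- read_length - left - ps_len
    rand_seq <- function(n, len) {
      if (len == 0L) return(rep("", n))
      m <- matrix(sample(bases, n * len, replace = TRUE), nrow = len)
      apply(m, 2, paste, collapse = "")
    }
    ps <- manifest$protospacer[elem]
    if (error_rate > 0) {
      hit <- which(stats::runif(n_reads) < error_rate)
      if (length(hit) > 0) {
        pos <- sample.int(ps_len, length(hit), replace = TRUE)
        sub <- sample(bases, length(hit), replace = TRUE)
        substr(ps[hit], pos, pos) <- sub
      }
    }
    reads <- paste0(rand_seq(n_reads, left), ps, rand_seq(n_reads, right))
    qual <- strrep("I", read_length)
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(paste0("@read", seq_len(n_reads), "\n", reads, "\n+\n", qual), con)
  })
  invisible(path)
}

# 4PL mean function shared by the simulator and the fitter
four_pl <- function(x, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / x)^hill)
}
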