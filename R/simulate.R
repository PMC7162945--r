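#' Phase distributions for the synthetic generator
#'
#' Diel transcriptomes concentrate peak times around the light/dark
#' transitions, so the default phase law is a two-component wrapped-normal
#' mixture centred at dawn (ZT0) and at the dusk-side peak (ZT12), with a
#' 60/40 dawn/dusk split and a 1-h spread: field-grown material shows peak
#' -time histograms whose two modal 2-h bins (at dawn and near dusk) hold
#' roughly two thirds of all rhythmic transcripts, which this law
#' reproduces.  `phase_law_uniform()` draws phases uniformly over the cycle
#' instead.
#'
#' @param centers component centres, hours ZT.
#' @param sd per-component wrapped-normal spread, hours.
#' @param weights mixing weights (normalised internally).
#' @return an object of class `phase_law`.
#' @export
phase_law_mixture <- function(centers = c(0, 12), sd = c(1, 1),
                              weights = c(0.6, 0.4)) {
  stopifnot(length(centers) == length(sd), length(centers) == length(weights),
            all(sd >= 0), all(weights > 0))
  structure(list(kind = "mixture", centers = centers, sd = sd,
                 weights = weights / sum(weights)), class = "phase_law")
}

#' @rdname phase_law_mixture
#' @export
phase_law_uniform <- function() {
  structure(list(kind = "uniform"), class = "phase_law")
}

# Draw n phases in [0, period) from a phase law (uses the current RNG stream).
sample_phases <- function(law, n, period_h = 24) {
  if (n == 0) return(numeric(0))
  if (law$kind == "uniform") return(stats::runif(n, 0, period_h))
  comp <- sample.int(length(law$weights), n, replace = TRUE, prob = law$weights)
  (law$centers[comp] + stats::rnorm(n, 0, law$sd[comp])) %% period_h
}

#' Simulate a single diel expression time series
#'
#' The waveform is a cosine peaking at `phase_zt` with additive i.i.d.
#' Gaussian noise on the normalised-log scale:
#' `value(t) = baseline + amplitude * cos(2*pi*(t - phase_zt)/period) + N(0, noise_sd)`.
#' An optional sawtooth waveform (linear rise to the peak, linear fall) is
#' available for robustness experiments.
#'
#' @param design a [diel_design()].
#' @param baseline additive offset (normalised-log units).
#' @param amplitude cosine amplitude (>= 0); half the peak-to-trough range.
#' @param phase_zt peak time, hours ZT.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed optional integer seed for reproducibility.
#' @param waveform `"cosine"` (default) or `"sawtooth"`.
#' @return numeric vector, one value per sample time.
#' @examples
#' d <- diel_design()
#' s <- simulate_series(d, amplitude = 1, phase_zt = 4, noise_sd = 0)
#' d$sample_times_zt[which.max(s)]  # 4
#' @export
simulate_series <- function(design, baseline = 0, amplitude = 1, phase_zt = 0,
                            noise_sd = 0, seed = NULL,
                            waveform = c("cosine", "sawtooth")) {
  waveform <- match.arg(waveform)
  if (amplitude < 0) rhythmod_stop("simulate", "amplitude must be >= 0")
  if (noise_sd < 0) rhythmod_stop("simulate", "noise_sd must be >= 0")
  t <- design$sample_times_zt
  shape <- switch(waveform,
    cosine = cos(2 * pi * (t - phase_zt) / design$period_h),
    sawtooth = {
      x <- ((t - phase_zt) / design$period_h) %% 1  # 0 at peak
      1 - 2 * pmin(x, 1 - x) * 2                    # triangle wave in [-1, 1]
    }
  )
  with_seed(seed, baseline + amplitude * shape + stats::rnorm(length(t), 0, noise_sd))
}

# Core organ simulator shared by the single- and multi-organ front ends.
# `phases` is a named vector of planted peak times for the rhythmic ids.
.simulate_organ <- function(design, organ, ids, expressed, rhythmic, phases,
                            amplitude_range, noise_sd, dropout_rate,
                            bg_detect_rate, n_replicates) {
  n <- length(ids)
  t <- design$sample_times_zt
  amplitude <- rep(0, n)
  amplitude[rhythmic] <- stats::runif(sum(rhythmic), amplitude_range[1],
                                      amplitude_range[2])
  baseline <- rep(0, n)
  signal <- matrix(0, n, length(t), dimnames = list(ids, zt_labels(design)))
  if (any(rhythmic)) {
    ph <- phases[ids[rhythmic]]
    signal[rhythmic, ] <- baseline[rhythmic] + amplitude[rhythmic] *
      cos(outer(ph, t, function(p, tt) 2 * pi * (tt - p) / design$period_h))
  }
  replicates <- lapply(seq_len(n_replicates), function(r) {
    signal + matrix(stats::rnorm(n * length(t), 0, noise_sd), n, length(t))
  })
  values <- Reduce(`+`, replicates) / n_replicates
  p_det <- ifelse(expressed, 1 - dropout_rate, bg_detect_rate)
  detected <- matrix(stats::rbinom(n * length(t), 1, rep(p_det, length(t))),
                     n, length(t), dimnames = dimnames(signal))
  truth <- data.frame(
    transcript_id = ids, organ = organ, expressed = expressed,
    rhythmic = rhythmic,
    true_phase_zt = ifelse(rhythmic, unname(phases[ids]), NA_real_),
    amplitude = amplitude, noise_sd = noise_sd, baseline = baseline,
    stringsAsFactors = FALSE
  )
  list(
    matrix = expression_matrix(organ, values, detected, design),
    truth = truth,
    replicates = replicates
  )
}

#' Simulate one organ's diel expression dataset with known ground truth
#'
#' Plants exactly `round(n_transcripts * rhythmic_fraction)` rhythmic
#' transcripts (cosine waveforms with phases drawn from `phase_law`); the
#' remaining transcripts are pure noise.  Two independent replicate series per
#' time point are drawn by default, mirroring duplicate hybridisations, and
#' averaged into the returned expression matrix.  Detection dropout sets each
#' mask cell to 0 independently with probability `dropout_rate`.
#'
#' @param design a [diel_design()].
#' @param n_transcripts number of transcripts (> 0).
#' @param rhythmic_fraction proportion of transcripts that are rhythmic.
#' @param phase_law a [phase_law_mixture()] or [phase_law_uniform()].
#' @param amplitude_range range of planted cosine amplitudes (uniform draw).
#' @param noise_sd per-replicate Gaussian noise SD (normalised-log units).
#' @param dropout_rate per-cell probability that an expressed transcript's
#'   detection flag is 0.
#' @param n_replicates replicate series per time point (averaged; 1 or 2).
#' @param organ organ label.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return list with `matrix` (an `expression_matrix`), `truth` (ground-truth
#'   data frame) and `replicates` (list of per-replicate value matrices).
#' @export
simulate_organ_dataset <- function(design = diel_design(),
                                   n_transcripts = 12000,
                                   rhythmic_fraction = 0.3,
                                   phase_law = phase_law_mixture(),
                                   amplitude_range = c(0.5, 2),
                                   noise_sd = 0.25,
                                   dropout_rate = 0.1,
                                   n_replicates = 2,
                                   organ = "L1",
                                   seed = NULL) {
  if (n_transcripts <= 0) rhythmod_stop("simulate", "n_transcripts must be > 0")
  if (rhythmic_fraction < 0 || rhythmic_fraction > 1) {
    rhythmod_stop("simulate", "rhythmic_fraction must be in [0, 1]")
  }
  if (dropout_rate < 0 || dropout_rate > 1) {
    rhythmod_stop("simulate", "dropout_rate must be in [0, 1]")
  }
  with_seed(seed, {
    ids <- sprintf("t%05d", seq_len(n_transcripts))
    n_rhythmic <- round(n_transcripts * rhythmic_fraction)
    rhythmic <- rep(FALSE, n_transcripts)
    rhythmic[sample.int(n_transcripts, n_rhythmic)] <- TRUE
    phases <- stats::setNames(rep(NA_real_, n_transcripts), ids)
    phases[rhythmic] <- sample_phases(phase_law, n_rhythmic, design$period_h)
    .simulate_organ(design, organ, ids, expressed = rep(TRUE, n_transcripts),
                    rhythmic = rhythmic, phases = phases,
                    amplitude_range = amplitude_range, noise_sd = noise_sd,
                    dropout_rate = dropout_rate, bg_detect_rate = 0.2,
                    n_replicates = n_replicates)
  })
}

#' Cross-organ sharing specification for the multi-organ simulator
#'
#' Controls how much of the transcriptome is shared between organs: the first
#' `n_shared` universe transcripts are expressed in every organ, of which
#' `n_rhythmic_shared` are rhythmic in every organ with a common base phase;
#' `phase_shift_h` plants a per-organ phase shift on that shared rhythmic
#' pool.  Each organ tops up its rhythmic quota from its organ-specific pool.
#'
#' @param n_shared transcripts expressed in all organs.
#' @param n_rhythmic_shared shared transcripts rhythmic in all organs.
#' @param phase_shift_h named per-organ phase shifts, hours (default 0).
#' @return a `sharing_spec` list.
#' @export
sharing_spec <- function(n_shared, n_rhythmic_shared, phase_shift_h = NULL) {
  structure(list(n_shared = n_shared, n_rhythmic_shared = n_rhythmic_shared,
                 phase_shift_h = phase_shift_h), class = "sharing_spec")
}

#' Simulate a multi-organ diel dataset with planted cross-organ structure
#'
#' @param design a [diel_design()].
#' @param organ_specs named list (one entry per organ, >= 2 organs) of
#'   parameter lists accepted by [simulate_organ_dataset()]
#'   (`n_transcripts`, `rhythmic_fraction`, `amplitude_range`, `noise_sd`,
#'   `dropout_rate`, `n_replicates`, `phase_law`).
#' @param sharing a [sharing_spec()].
#' @param seed integer seed; per-organ sub-streams are derived from it.
#' @return list with one element per organ (each as returned by
#'   [simulate_organ_dataset()], with per-organ `truth`), plus attribute
#'   `universe` (all transcript ids).
#' @export
simulate_multi_organ <- function(design = diel_design(), organ_specs, sharing,
                                 seed = NULL) {
  if (length(organ_specs) < 2) {
    rhythmod_stop("simulate", "need at least 2 organs")
  }
  organs <- names(organ_specs)
  if (is.null(organs) || any(organs == "")) {
    rhythmod_stop("simulate", "organ_specs must be a named list")
  }
  defaults <- list(n_transcripts = 12000, rhythmic_fraction = 0.3,
                   phase_law = phase_law_mixture(),
                   amplitude_range = c(0.5, 2), noise_sd = 0.25,
                   dropout_rate = 0.1, n_replicates = 2)
  specs <- lapply(organ_specs, function(s) utils::modifyList(defaults, s))
  n_per_organ <- vapply(specs, `[[`, numeric(1), "n_transcripts")
  n_rhy <- round(n_per_organ *
                 vapply(specs, `[[`, numeric(1), "rhythmic_fraction"))
  if (sharing$n_shared > min(n_per_organ)) {
    rhythmod_stop("simulate", "n_shared exceeds an organ's transcript total")
  }
  if (sharing$n_rhythmic_shared > sharing$n_shared ||
      any(sharing$n_rhythmic_shared > n_rhy)) {
    rhythmod_stop("simulate", "n_rhythmic_shared inconsistent with pool sizes")
  }
  shifts <- stats::setNames(rep(0, length(organs)), organs)
  if (!is.null(sharing$phase_shift_h)) {
    shifts[names(sharing$phase_shift_h)] <- sharing$phase_shift_h
  }

  # universe: shared block first, then one organ-specific block per organ
  shared_ids <- sprintf("t%05d", seq_len(sharing$n_shared))
  own_ids <- list()
  offset <- sharing$n_shared
  for (org in organs) {
    n_own <- n_per_organ[[org]] - sharing$n_shared
    own_ids[[org]] <- if (n_own > 0) sprintf("t%05d", offset + seq_len(n_own))
                      else character(0)
    offset <- offset + n_own
  }
  universe <- c(shared_ids, unlist(own_ids, use.names = FALSE))

  with_seed(seed, {
    shared_rhythmic <- sample(shared_ids, sharing$n_rhythmic_shared)
    base_phase <- stats::setNames(
      sample_phases(specs[[1]]$phase_law, sharing$n_rhythmic_shared,
                    design$period_h),
      shared_rhythmic
    )
    out <- list()
    for (i in seq_along(organs)) {
      org <- organs[i]
      spec <- specs[[org]]
      expressed <- universe %in% c(shared_ids, own_ids[[org]])
      n_extra <- n_rhy[[org]] - sharing$n_rhythmic_shared
      if (n_extra > length(own_ids[[org]])) {
        rhythmod_stop("simulate", sprintf(
          "organ %s needs %d organ-specific rhythmic transcripts but has only %d specific ids",
          org, n_extra, length(own_ids[[org]])))
      }
      extra_rhythmic <- if (n_extra > 0) sample(own_ids[[org]], n_extra)
                        else character(0)
      rhythmic_ids <- c(shared_rhythmic, extra_rhythmic)
      phases <- stats::setNames(rep(NA_real_, length(universe)), universe)
      phases[shared_rhythmic] <- (base_phase + shifts[[org]]) %% design$period_h
      phases[extra_rhythmic] <- sample_phases(spec$phase_law, n_extra,
                                              design$period_h)
      res <- with_seed(
        derive_seed(if (is.null(seed)) 0L else seed, i),
        .simulate_organ(design, org, universe,
                        expressed = expressed,
                        rhythmic = universe %in% rhythmic_ids,
                        phases = phases,
                        amplitude_range = spec$amplitude_range,
                        noise_sd = spec$noise_sd,
                        dropout_rate = spec$dropout_rate,
                        bg_detect_rate = 0.2,
                        n_replicates = spec$n_replicates)
      )
      out[[org]] <- res
    }
    attr(out, "universe") <- universe
    out
  })
}

#' Simulate a transcript-to-category annotation with planted enrichment
#'
#' Assigns one functional category per transcript.  Category draws are
#' weighted so that for rhythmic transcripts the odds of landing in category
#' `c` are multiplied by `odds[c]`, planting an over-representation (odds > 1)
#' or under-representation (odds < 1) of that category among the rhythmic
#' set; `odds = 1` everywhere plants no association.
#'
#' @param ids all transcript ids.
#' @param rhythmic_ids subset of `ids` carrying the planted association.
#' @param categories non-empty character vector of category labels.
#' @param odds named numeric vector of rhythmicity odds multipliers per
#'   category (default 1 for all).
#' @param prop_annotated proportion of transcripts that receive a category at
#'   all; the rest are labelled `"unannotated"`.
#' @param seed integer seed.
#' @return data frame with columns `transcript_id`, `category`; every id
#'   appears exactly once.
#' @export
simulate_annotation <- function(ids, rhythmic_ids = character(0), categories,
                                odds = NULL, prop_annotated = 0.8,
                                seed = NULL) {
  if (length(categories) == 0) {
    rhythmod_stop("simulate", "categories must be non-empty")
  }
  if (!all(rhythmic_ids %in% ids)) {
    rhythmod_stop("simulate", "rhythmic_ids contains unknown transcript ids")
  }
  w <- stats::setNames(rep(1, length(categories)), categories)
  if (!is.null(odds)) {
    if (!all(names(odds) %in% categories)) {
      rhythmod_stop("simulate", "odds names must be categories")
    }
  }
  with_seed(seed, {
    cat_of <- character(length(ids))
    annotated <- stats::runif(length(ids)) < prop_annotated
    is_rhy <- ids %in% rhythmic_ids
    for (i in seq_along(ids)) {
      if (!annotated[i]) {
        cat_of[i] <- "unannotated"
      } else {
        wi <- w
        if (is_rhy[i] && !is.null(odds)) wi[names(odds)] <- wi[names(odds)] * odds
        cat_of[i] <- sample(categories, 1, prob = wi)
      }
    }
    data.frame(transcript_id = ids, category = cat_of, stringsAsFactors = FALSE)
  })
}
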