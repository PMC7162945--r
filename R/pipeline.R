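#' Signed circular phase difference
#'
#' Wraps `phase_b - phase_a` into `(-period/2, period/2]` hours.
#'
#' @param phase_a,phase_b phases in hours.
#' @param period_h cycle length.
#' @return signed difference in hours.
#' @export
circular_phase_diff <- function(phase_a, phase_b, period_h = 24) {
  x <- (phase_b - phase_a) %% period_h
  ifelse(x > period_h / 2, x - period_h, x)
}

# unsigned circular distance in [0, period/2]
circular_distance <- function(a, b, period_h = 24) {
  abs(circular_phase_diff(a, b, period_h))
}

#' Circular median of phases
#'
#' The member phase minimising the summed circular distance to all phases;
#' ties resolved toward the earliest phase.
#'
#' @param phases phases in `[0, period)`.
#' @param period_h cycle length.
#' @return one phase value.
#' @export
circular_median <- function(phases, period_h = 24) {
  stopifnot(length(phases) > 0)
  cand <- sort(unique(phases))
  cost <- vapply(cand,
                 function(c) sum(circular_distance(phases, c, period_h)),
                 numeric(1))
  cand[which(cost <= min(cost) + 1e-9)][1]
}

#' Pipeline configuration
#'
#' Houses the decision thresholds of the inference: modules with a
#' Bonferroni-adjusted JTK P strictly below `p_adjusted_max` (default 0.75)
#' are rhythmic; members whose Spearman correlation with their module
#' representative falls below `member_min_spearman` (default 0.3) are
#' filtered out as noisy; module phases are harmonised by clustering all
#' organs' representatives and cutting at `dendrogram_cut`; phase
#' relations between organs use a `phase_tolerance_h` (default 2 h) window.
#'
#' @param p_adjusted_max rhythmicity threshold on the adjusted P (strict <).
#' @param member_min_spearman member retention threshold (>= rule).
#' @param phase_tolerance_h tolerance for "same phase", hours.
#' @param dendrogram_cut dissimilarity cut height for the phase dendrogram.
#' @param min_detected_timepoints expression-call threshold (default 8).
#' @param network a [network_config()].
#' @param jtk a [jtk_config()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(p_adjusted_max = 0.75, member_min_spearman = 0.3,
                            phase_tolerance_h = 2, dendrogram_cut = 0.25,
                            min_detected_timepoints = 8,
                            network = network_config(), jtk = jtk_config()) {
  if (p_adjusted_max <= 0 || p_adjusted_max > 1) {
    rhythmod_stop("pipeline", "p_adjusted_max must be in (0, 1]")
  }
  if (member_min_spearman < -1 || member_min_spearman > 1) {
    rhythmod_stop("pipeline", "member_min_spearman must be in [-1, 1]")
  }
  if (phase_tolerance_h < 0) {
    rhythmod_stop("pipeline", "phase_tolerance_h must be >= 0")
  }
  structure(list(p_adjusted_max = p_adjusted_max,
                 member_min_spearman = member_min_spearman,
                 phase_tolerance_h = phase_tolerance_h,
                 dendrogram_cut = dendrogram_cut,
                 min_detected_timepoints = min_detected_timepoints,
                 network = network, jtk = jtk),
            class = "pipeline_config")
}

#' Flag rhythmic modules from their JTK results
#'
#' A module is rhythmic when its representative's adjusted P is strictly
#' below the threshold (`p = 0.75` itself is not rhythmic).
#'
#' @param jtk_results data frame from [jtk_batch()] on the representatives.
#' @param p_adjusted_max threshold (default 0.75).
#' @return the input with a logical `rhythmic` column appended.
#' @export
call_rhythmic_modules <- function(jtk_results, p_adjusted_max = 0.75) {
  if (anyNA(jtk_results$p_adjusted)) {
    rhythmod_stop("pipeline", "missing JTK result for a module")
  }
  jtk_results$rhythmic <- jtk_results$p_adjusted < p_adjusted_max
  jtk_results
}

#' Filter noisy module members
#'
#' Retains members whose Spearman rank correlation with the module
#' representative is at least `min_spearman` (the >= 0.3 rule); constant
#' members, for which the correlation is undefined, are dropped with a
#' message.
#'
#' @param zmembers Z-scored member series (members x time points).
#' @param representative the module representative series.
#' @param min_spearman retention threshold.
#' @return character vector of retained member ids.
#' @export
filter_noisy_members <- function(zmembers, representative, min_spearman = 0.3) {
  keep <- character(0)
  for (id in rownames(zmembers)) {
    x <- zmembers[id, ]
    if (stats::sd(x) == 0 || stats::sd(representative) == 0) {
      message(sprintf("dropping constant member %s (Spearman undefined)", id))
      next
    }
    if (stats::cor(x, representative, method = "spearman") >= min_spearman) {
      keep <- c(keep, id)
    }
  }
  keep
}

#' Harmonise module phases against a cross-organ dendrogram
#'
#' Average-linkage clustering of all organs' module representatives on
#' `1 - Pearson` dissimilarity, cut at `cut_height`; modules that cluster
#' together are considered to share a phase and all receive the cluster
#' consensus phase, the circular median of the member JTK phases (ties
#' toward the earliest phase).
#'
#' @param representatives matrix of representatives (module x time), rownames
#'   unique across organs.
#' @param phases named vector of JTK phases for the same modules.
#' @param cut_height dissimilarity cut height.
#' @param period_h cycle length.
#' @return named vector of corrected phases.
#' @export
correct_phases_by_dendrogram <- function(representatives, phases,
                                         cut_height = 0.25, period_h = 24) {
  ids <- rownames(representatives)
  stopifnot(length(ids) >= 1, all(ids %in% names(phases)))
  phases <- phases[ids]
  if (length(ids) == 1) return(phases)
  d <- 1 - stats::cor(t(representatives))
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(tree, h = cut_height)
  corrected <- phases
  for (k in unique(cl)) {
    in_k <- ids[cl == k]
    corrected[in_k] <- circular_median(phases[in_k], period_h)
  }
  corrected
}

#' Classify the phase relation between two organs
#'
#' The signed circular difference `d = wrap(phase_b - phase_a)` decides the
#' class: `|d| <= tolerance` is `same`, `d > tolerance` is `delayed` (organ B
#' peaks later), `d < -tolerance` is `advanced`.
#'
#' @param phase_a,phase_b phases in `[0, period)`.
#' @param tolerance_h tolerance in hours (default 2).
#' @param period_h cycle length.
#' @return `"same"`, `"delayed"` or `"advanced"` (vectorised).
#' @export
classify_phase_relation <- function(phase_a, phase_b, tolerance_h = 2,
                                    period_h = 24) {
  d <- circular_phase_diff(phase_a, phase_b, period_h)
  ifelse(abs(d) <= tolerance_h + 1e-9, "same",
         ifelse(d > 0, "delayed", "advanced"))
}

#' Per-transcript rhythm calls
#'
#' A transcript is rhythmic when it is a retained member of a rhythmic
#' module; its phase is the module's corrected phase, its phase bin the 2-h
#' ZT bin containing that phase, and it is a day-peaking transcript when the
#' phase falls before dusk (`phase < photoperiod_h`).
#'
#' @param expressed_ids expressed transcript ids.
#' @param membership data frame `transcript_id`, `module_id`, `sign` of
#'   retained members of final modules.
#' @param module_info data frame with `module_id`, `rhythmic`, `phase_zt`.
#' @param design a [diel_design()].
#' @param organ organ label.
#' @return data frame of class-less rhythm calls: `transcript_id`, `organ`,
#'   `expressed`, `rhythmic`, `module_id`, `sign`, `phase_zt`, `phase_bin`,
#'   `day_peak`.
#' @export
assign_transcript_calls <- function(expressed_ids, membership, module_info,
                                    design, organ = "organ") {
  if (anyDuplicated(membership$transcript_id)) {
    rhythmod_stop("pipeline", "a transcript belongs to two modules")
  }
  idx <- match(membership$module_id, module_info$module_id)
  mem <- data.frame(
    transcript_id = membership$transcript_id,
    module_id = membership$module_id,
    sign = membership$sign,
    mod_rhythmic = module_info$rhythmic[idx],
    mod_phase = module_info$phase_zt[idx],
    stringsAsFactors = FALSE
  )
  calls <- data.frame(transcript_id = expressed_ids, organ = organ,
                      expressed = TRUE, stringsAsFactors = FALSE)
  j <- match(calls$transcript_id, mem$transcript_id)
  calls$module_id <- mem$module_id[j]
  calls$sign <- mem$sign[j]
  calls$rhythmic <- !is.na(j) & mem$mod_rhythmic[j]
  calls$rhythmic[is.na(calls$rhythmic)] <- FALSE
  calls$phase_zt <- ifelse(calls$rhythmic, mem$mod_phase[j], NA_real_)
  calls$phase_bin <- ifelse(
    calls$rhythmic,
    sprintf("ZT%02d", 2 * (floor(calls$phase_zt / 2) %% (design$period_h / 2))),
    NA_character_
  )
  calls$day_peak <- ifelse(calls$rhythmic,
                           calls$phase_zt < design$photoperiod_h, NA)
  calls
}

#' Run the full rhythm-detection pipeline
#'
#' Executes the stages in order: expression call, Z-scoring, network and
#' module construction (including sign splitting, merging and the adjacency
#' threshold), JTK on module representatives, the rhythmic-module call, the
#' member Spearman filter, cross-organ dendrogram phase correction, and
#' per-transcript calls.  Deterministic given inputs and config.
#'
#' @param organs named list of [expression_matrix()] objects (one per organ).
#' @param config a [pipeline_config()].
#' @return object of class `rhythm_analysis`: list with `calls` (one data
#'   frame per organ), `modules` (per-organ module tables), `jtk` (module
#'   JTK results incl. corrected phases), `design`, `config`, `summary`.
#' @export
run_full_pipeline <- function(organs, config = pipeline_config()) {
  if (length(organs) == 0) rhythmod_stop("pipeline", "no input organs")
  if (is.null(names(organs)) || any(names(organs) == "")) {
    rhythmod_stop("pipeline", "organs must be a named list")
  }
  design <- organs[[1]]$design
  times <- design$sample_times_zt
  per_organ <- list()
  for (org in names(organs)) {
    mat <- organs[[org]]
    expressed <- call_expressed(mat, config$min_detected_timepoints)
    if (length(expressed) < 2) {
      rhythmod_stop("pipeline", sprintf("organ %s: fewer than 2 expressed transcripts", org))
    }
    z <- zscore_matrix(mat$values[expressed, , drop = FALSE])
    mods <- build_modules(z, config$network, organ = org)
    per_organ[[org]] <- list(expressed = expressed, z = z, modules = mods)
  }

  # JTK on all module representatives, organ-qualified module ids
  rep_list <- lapply(names(per_organ), function(org) {
    r <- per_organ[[org]]$modules$representatives
    if (nrow(r) > 0) rownames(r) <- paste0(org, ".", rownames(r))
    r
  })
  all_reps <- do.call(rbind, rep_list)
  if (is.null(all_reps) || nrow(all_reps) == 0) {
    # nothing clustered anywhere (e.g. pure noise): all calls non-rhythmic
    jtk_res <- data.frame(series_id = character(0), period = numeric(0),
                          phase_zt = numeric(0), tau = numeric(0),
                          p_exact = numeric(0), p_adjusted = numeric(0),
                          degenerate = logical(0), rhythmic = logical(0),
                          phase_corrected = numeric(0),
                          stringsAsFactors = FALSE)
  } else {
    jtk_res <- jtk_batch(all_reps, times, config$jtk)
    jtk_res <- call_rhythmic_modules(jtk_res, config$p_adjusted_max)

    # dendrogram phase correction across organs
    phases <- stats::setNames(jtk_res$phase_zt, jtk_res$series_id)
    ok <- !is.na(phases)
    corrected <- phases
    if (any(ok)) {
      corrected[ok] <- correct_phases_by_dendrogram(
        all_reps[ok, , drop = FALSE], phases[ok],
        config$dendrogram_cut, design$period_h)
    }
    jtk_res$phase_corrected <- unname(corrected[jtk_res$series_id])
  }

  calls <- list()
  module_tables <- list()
  for (org in names(per_organ)) {
    po <- per_organ[[org]]
    mods <- po$modules
    qualified <- if (nrow(mods$representatives) > 0) {
      paste0(org, ".", rownames(mods$representatives))
    } else character(0)
    info <- data.frame(
      module_id = rownames(mods$representatives),
      rhythmic = jtk_res$rhythmic[match(qualified, jtk_res$series_id)],
      phase_zt = jtk_res$phase_corrected[match(qualified, jtk_res$series_id)],
      stringsAsFactors = FALSE
    )
    # Spearman member filter against each module representative
    membership <- mods$membership
    retained <- logical(nrow(membership))
    for (mid in unique(membership$module_id)) {
      rows <- which(membership$module_id == mid)
      ids <- membership$transcript_id[rows]
      kept <- filter_noisy_members(po$z[ids, , drop = FALSE],
                                   mods$representatives[mid, ],
                                   config$member_min_spearman)
      retained[rows] <- ids %in% kept
    }
    membership$retained <- retained
    module_tables[[org]] <- membership
    calls[[org]] <- assign_transcript_calls(
      po$expressed, membership[membership$retained, , drop = FALSE],
      info, design, organ = org)
  }

  summary <- lapply(names(calls), function(org) {
    cl <- calls[[org]]
    rhythmic <- sum(cl$rhythmic)
    list(organ = org,
         n_expressed = nrow(cl),
         n_rhythmic = rhythmic,
         pct_rhythmic = percent(rhythmic, max(nrow(cl), 1)),
         pct_day_peak = if (rhythmic > 0)
           percent(sum(cl$day_peak, na.rm = TRUE), rhythmic) else NA_real_)
  })
  names(summary) <- names(calls)

  structure(list(calls = calls, modules = module_tables, jtk = jtk_res,
                 design = design, config = config, summary = summary),
            class = "rhythm_analysis")
}

#' @export
print.rhythm_analysis <- function(x, ...) {
  cat("rhythm_analysis\n")
  for (s in x$summary) {
    cat(sprintf("  %s: %d expressed, %d rhythmic (%.1f%%)\n",
                s$organ, s$n_expressed, s$n_rhythmic, s$pct_rhythmic))
  }
  invisible(x)
}
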