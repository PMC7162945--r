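#' Write an expression matrix (and mask) as TSV
#'
#' Tab-separated, UTF-8, '.' decimal; first column `transcript_id`, remaining
#' columns labelled by ZT time ("ZT-2", "ZT00", ..., "ZT24").  The detection
#' mask is written to a parallel 0/1 TSV with the same layout.
#'
#' @param mat an [expression_matrix()].
#' @param values_path output path for the values.
#' @param mask_path output path for the mask (optional).
#' @return invisibly, the paths written.
#' @export
write_expression_tsv <- function(mat, values_path, mask_path = NULL) {
  write_table_tsv(mat$values, values_path)
  if (!is.null(mask_path)) write_table_tsv(mat$detected, mask_path)
  invisible(c(values_path, mask_path))
}

# matrix -> TSV with a transcript_id first column; numbers via format() to
# keep full precision and byte-stable output
write_table_tsv <- function(m, path) {
  df <- data.frame(transcript_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an expression matrix (and mask) from TSV
#'
#' @param values_path TSV of values (layout of [write_expression_tsv()]).
#' @param mask_path TSV of the 0/1 detection mask; when absent, an
#'   all-detected mask is assumed with a warning.
#' @param organ organ label for the result.
#' @param design a [diel_design()]; when `NULL`, the sample times are
#'   recovered from the ZT column labels (default dawn/dusk clocks).
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(values_path, mask_path = NULL, organ = "organ",
                                design = NULL) {
  values <- read_matrix_tsv(values_path)
  if (is.null(design)) {
    times <- as.numeric(sub("^ZT", "", colnames(values)))
    if (anyNA(times)) {
      rhythmod_stop("io", "column headers must be ZT labels (e.g. ZT00)")
    }
    design <- diel_design(
      n_timepoints = length(times),
      interval_h = if (length(times) > 1) times[2] - times[1] else 2,
      start_offset_h = times[1]
    )
  }
  if (is.null(mask_path)) {
    warning("no detection mask supplied; assuming all time points detected")
    detected <- matrix(1, nrow(values), ncol(values), dimnames = dimnames(values))
  } else {
    detected <- read_matrix_tsv(mask_path)
    if (!identical(rownames(detected), rownames(values))) {
      rhythmod_stop("io", "mask transcript ids do not match the values")
    }
  }
  expression_matrix(organ, values, detected, design)
}

read_matrix_tsv <- function(path) {
  if (!file.exists(path)) rhythmod_stop("io", sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "transcript_id") {
    rhythmod_stop("io", "first column must be transcript_id")
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    rhythmod_stop("io", sprintf("duplicate transcript id: %s",
                                ids[duplicated(ids)][1]))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) rhythmod_stop("io", "non-numeric cells in table")
  rownames(m) <- ids
  m
}

#' Default run configuration
#'
#' All analysis constants in one nested list: the sampling design, the
#' expression call (8 of 14 detected time points), the network stage
#' (beta 18, merge at 0.25, adjacency threshold 0.175), the JTK grid
#' (24-h period, 2-h lags), the pipeline thresholds (adjusted P < 0.75,
#' Spearman >= 0.3, +/- 2 h phase tolerance) and the enrichment alpha
#' (0.05/0.95 rule).
#'
#' @return nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "rhythmod_out",
    design = list(n_timepoints = 14L, interval_h = 2, start_offset_h = -2,
                  dawn_clock = "5:45", dusk_clock = "19:00", period_h = 24),
    expression = list(min_detected_timepoints = 8L),
    network = list(beta = 18, merge_dissim_max = 0.25, adjacency_min = 0.175,
                   adjacency_filter = "module", min_module_size = 10L,
                   cut_height = 0.93, linkage = "average", use_tom = TRUE),
    jtk = list(periods_h = 24, lag_step_h = NULL),
    pipeline = list(p_adjusted_max = 0.75, member_min_spearman = 0.3,
                    phase_tolerance_h = 2, dendrogram_cut = 0.25),
    enrichment = list(alpha = 0.05),
    simulate = list(organs = c("L1", "I1", "I5"), n_transcripts = 1000L,
                    rhythmic_fraction = 0.3, amplitude_min = 0.5,
                    amplitude_max = 2, noise_sd = 0.25, dropout_rate = 0.1,
                    n_replicates = 2L, shared_fraction = 0.75,
                    shared_rhythmic_fraction = 0.5)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML document, fills absent keys with the defaults of
#' [default_run_config()], rejects unknown keys, and validates every
#' threshold by constructing the corresponding config objects.
#'
#' @param path YAML file; an empty file yields all defaults.
#' @return list with the merged `config`, the `design`, and a validated
#'   [pipeline_config()] as `pipeline`.
#' @export
load_config <- function(path) {
  defaults <- default_run_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  check_keys <- function(u, d, prefix = "") {
    unknown <- setdiff(names(u), names(d))
    if (length(unknown) > 0) {
      rhythmod_stop("config", sprintf("unknown key: %s%s", prefix, unknown[1]))
    }
    for (k in names(u)) {
      if (is.list(d[[k]]) && !is.null(names(d[[k]])) && is.list(u[[k]])) {
        check_keys(u[[k]], d[[k]], paste0(prefix, k, "."))
      }
    }
  }
  check_keys(user, defaults)
  cfg <- utils::modifyList(defaults, user)
  design <- do.call(diel_design, cfg$design)
  net <- do.call(network_config, cfg$network)
  jtk <- jtk_config(periods_h = unlist(cfg$jtk$periods_h),
                    lag_step_h = cfg$jtk$lag_step_h)
  pipe <- pipeline_config(
    p_adjusted_max = cfg$pipeline$p_adjusted_max,
    member_min_spearman = cfg$pipeline$member_min_spearman,
    phase_tolerance_h = cfg$pipeline$phase_tolerance_h,
    dendrogram_cut = cfg$pipeline$dendrogram_cut,
    min_detected_timepoints = cfg$expression$min_detected_timepoints,
    network = net, jtk = jtk
  )
  if (cfg$enrichment$alpha <= 0 || cfg$enrichment$alpha >= 0.5) {
    rhythmod_stop("config", "enrichment alpha must be in (0, 0.5)")
  }
  list(config = cfg, design = design, pipeline = pipe)
}

#' Write per-organ rhythm calls and module tables
#'
#' @param analysis a `rhythm_analysis` from [run_full_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_analysis_tsv <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (org in names(analysis$calls)) {
    f <- file.path(dir, sprintf("calls_%s.tsv", org))
    utils::write.table(analysis$calls[[org]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    files <- c(files, f)
    f <- file.path(dir, sprintf("modules_%s.tsv", org))
    utils::write.table(analysis$modules[[org]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    files <- c(files, f)
  }
  f <- file.path(dir, "modules_jtk.tsv")
  utils::write.table(analysis$jtk, f, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  files <- c(files, f)
  f <- file.path(dir, "summary.json")
  jsonlite::write_json(analysis$summary, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}
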