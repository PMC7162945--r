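#' Weighted coexpression network configuration
#'
#' Defaults follow the analysis the package implements: soft-threshold power
#' `beta = 18`, module merging at representative dissimilarity <= 0.25, and a
#' 0.175 adjacency threshold for final modules.  The tree is cut at a static
#' height on the topological-overlap dissimilarity scale; `cut_height` and
#' `min_module_size` have no published values and their defaults were
#' calibrated on synthetic data (see the package vignette).
#'
#' @param beta soft-threshold power (>= 1).
#' @param merge_dissim_max merge modules whose representative dissimilarity
#'   (1 - Pearson) is at or below this value.
#' @param adjacency_min adjacency threshold for final modules.
#' @param adjacency_filter how the adjacency threshold is applied:
#'   `"module"` keeps a module when its mean intramodular adjacency reaches
#'   the threshold (default), `"member"` prunes individual members whose mean
#'   adjacency to their co-members is below it, `"none"` disables the filter.
#' @param min_module_size clusters smaller than this are left unassigned.
#' @param cut_height static cut height on the clustering dissimilarity.
#' @param linkage hierarchical clustering linkage method.
#' @param use_tom cluster on topological-overlap dissimilarity (default) or
#'   directly on `1 - adjacency`.
#' @return a `network_config` list.
#' @export
network_config <- function(beta = 18, merge_dissim_max = 0.25,
                           adjacency_min = 0.175,
                           adjacency_filter = c("module", "member", "none"),
                           min_module_size = 10, cut_height = 0.93,
                           linkage = "average", use_tom = TRUE) {
  adjacency_filter <- match.arg(adjacency_filter)
  if (beta < 1) rhythmod_stop("network", "beta must be >= 1")
  for (v in c(merge_dissim_max, adjacency_min)) {
    if (v < 0 || v > 1) rhythmod_stop("network", "thresholds must be in [0, 1]")
  }
  structure(list(beta = beta, merge_dissim_max = merge_dissim_max,
                 adjacency_min = adjacency_min,
                 adjacency_filter = adjacency_filter,
                 min_module_size = min_module_size, cut_height = cut_height,
                 linkage = linkage, use_tom = use_tom),
            class = "network_config")
}

#' Pearson correlation matrix of expression series
#'
#' @param values transcripts x time points matrix (>= 2 rows, no constant
#'   rows).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(values) {
  if (nrow(values) < 2) rhythmod_stop("network", "need at least 2 transcripts")
  sds <- apply(values, 1, stats::sd)
  if (any(!is.finite(sds) | sds == 0)) {
    rhythmod_stop("network", sprintf(
      "constant series have no correlation: %s",
      paste(utils::head(rownames(values)[!is.finite(sds) | sds == 0], 5),
            collapse = ", ")))
  }
  r <- stats::cor(t(values))
  diag(r) <- 1
  r
}

#' Soft-thresholded (unsigned) network adjacency
#'
#' `a_ij = |r_ij|^beta` with a zero diagonal.  The unsigned form keeps
#' anti-correlated transcripts adjacent; they are separated later by sign
#' splitting.
#'
#' @param corr correlation matrix with entries in `[-1, 1]`.
#' @param beta soft-threshold power.
#' @return adjacency matrix in `[0, 1]`, zero diagonal.
#' @export
soft_adjacency <- function(corr, beta = 18) {
  if (any(abs(corr) > 1 + 1e-8)) {
    rhythmod_stop("network", "correlations must be in [-1, 1]")
  }
  a <- abs(corr)^beta
  diag(a) <- 0
  a
}

#' Topological overlap dissimilarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu`; returns `1 - TOM` with a zero diagonal.  Transcripts
#' sharing network neighbourhoods get low dissimilarity even when their
#' direct adjacency is modest.
#'
#' @param adjacency symmetric adjacency matrix, zero diagonal, entries >= 0.
#' @return dissimilarity matrix in `[0, 1]`.
#' @export
topological_overlap <- function(adjacency) {
  if (any(adjacency < 0)) rhythmod_stop("network", "adjacency must be >= 0")
  k <- rowSums(adjacency)
  num <- adjacency %*% adjacency + adjacency
  denom <- outer(k, k, pmin) + 1 - adjacency
  d <- 1 - num / denom
  d <- pmin(pmax(d, 0), 1)
  diag(d) <- 0
  dimnames(d) <- dimnames(adjacency)
  d
}

#' Initial modules by static-height hierarchical clustering
#'
#' Average-linkage clustering of the dissimilarity matrix cut at a fixed
#' height; clusters smaller than `min_module_size` go to the unassigned pool
#' (module 0).
#'
#' @param dissimilarity square dissimilarity matrix.
#' @param cut_height static cut height.
#' @param min_module_size minimum cluster size.
#' @param linkage linkage method for [stats::hclust()].
#' @return list with `assignment` (named integer vector; 0 = unassigned) and
#'   `tree` (the `hclust` object).
#' @export
hierarchical_modules <- function(dissimilarity, cut_height = 0.93,
                                 min_module_size = 10, linkage = "average") {
  n <- nrow(dissimilarity)
  if (is.null(n) || n == 0) rhythmod_stop("network", "empty dissimilarity")
  ids <- rownames(dissimilarity)
  if (n == 1) {
    assignment <- stats::setNames(0L, ids)
    if (min_module_size <= 1) assignment[] <- 1L
    return(list(assignment = assignment, tree = NULL))
  }
  tree <- stats::hclust(stats::as.dist(dissimilarity), method = linkage)
  cl <- stats::cutree(tree, h = cut_height)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  assignment <- integer(n)
  for (i in seq_along(keep)) assignment[cl == keep[i]] <- i
  # stable module numbering: decreasing size, ties by first member
  if (length(keep)) {
    ord <- order(-as.integer(sizes[as.character(keep)]), match(keep, keep))
    relabel <- integer(length(keep))
    relabel[ord] <- seq_along(keep)
    assignment[assignment > 0] <- relabel[assignment[assignment > 0]]
  }
  list(assignment = stats::setNames(assignment, ids), tree = tree)
}

#' Split a module's members by correlation sign
#'
#' Unsigned networks group positively and negatively correlated series
#' together; this separates them.  The seed member is the one most strongly
#' correlated (in absolute value) with the module mean series; members with
#' non-negative correlation to the seed form the plus group, the rest the
#' minus group.  Empty groups are dropped.
#'
#' @param zmembers Z-scored member series (members x time points).
#' @return named list of member-id vectors (`plus`, and `minus` if any).
#' @export
split_by_sign <- function(zmembers) {
  if (nrow(zmembers) == 0) rhythmod_stop("network", "empty module")
  if (nrow(zmembers) == 1) return(list(plus = rownames(zmembers)))
  center <- colMeans(zmembers)
  if (stats::sd(center) == 0) {
    # perfectly balanced anti-phase module: seed on the first member instead
    seed <- 1L
  } else {
    seed <- which.max(abs(apply(zmembers, 1, stats::cor, y = center)))
  }
  r <- apply(zmembers, 1, stats::cor, y = zmembers[seed, ])
  out <- list(plus = rownames(zmembers)[r >= 0],
              minus = rownames(zmembers)[r < 0])
  out[vapply(out, length, integer(1)) > 0]
}

#' Module representative (typical) series
#'
#' Pointwise median of the Z-scored member series.
#'
#' @param zmembers Z-scored member series (members x time points).
#' @return numeric vector of length `ncol(zmembers)`.
#' @export
module_representative <- function(zmembers) {
  if (nrow(zmembers) == 0) rhythmod_stop("network", "empty module")
  apply(zmembers, 2, stats::median)
}

#' Merge modules with similar representatives
#'
#' Representative dissimilarity is `1 - Pearson(rep_i, rep_j)`.  The closest
#' pair at or below `merge_dissim_max` is merged first (ties broken by
#' lexicographic module id), the combined representative is recomputed from
#' the pooled members, and the loop repeats until no pair is close enough.
#'
#' @param members named list of member-id vectors, one per module.
#' @param zmat Z-scored expression matrix containing all members.
#' @param merge_dissim_max merge threshold on `1 - Pearson`.
#' @return list with updated `members` and `representatives` (matrix, one row
#'   per surviving module).
#' @export
merge_close_modules <- function(members, zmat, merge_dissim_max = 0.25) {
  reps <- t(vapply(members,
                   function(m) module_representative(zmat[m, , drop = FALSE]),
                   numeric(ncol(zmat))))
  repeat {
    if (length(members) < 2) break
    d <- 1 - stats::cor(t(reps))
    diag(d) <- Inf
    if (min(d) > merge_dissim_max) break
    idx <- which(d == min(d), arr.ind = TRUE)
    # ties: lexicographically smallest (id_i, id_j) pair
    pairs <- cbind(rownames(d)[idx[, 1]], colnames(d)[idx[, 2]])
    pairs <- t(apply(pairs, 1, sort))
    pick <- order(pairs[, 1], pairs[, 2])[1]
    i <- pairs[pick, 1]; j <- pairs[pick, 2]
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- NULL
    reps <- reps[setdiff(rownames(reps), j), , drop = FALSE]
    reps[i, ] <- module_representative(zmat[members[[i]], , drop = FALSE])
  }
  list(members = members, representatives = reps)
}

#' Apply the adjacency threshold to candidate modules
#'
#' Final modules must be supported by the weighted network itself, not only
#' by the clustering: with `mode = "module"` a module is eligible when its
#' mean intramodular adjacency reaches `adjacency_min`; with
#' `mode = "member"` each member must have mean adjacency to its co-members
#' of at least `adjacency_min` (boundary value retained) and emptied modules
#' are dropped.
#'
#' @param members named list of member-id vectors.
#' @param adjacency adjacency matrix covering all members.
#' @param adjacency_min threshold in `[0, 1]`.
#' @param mode `"module"`, `"member"`, or `"none"`.
#' @return named list of member-id vectors for the surviving modules.
#' @export
apply_adjacency_threshold <- function(members, adjacency,
                                      adjacency_min = 0.175,
                                      mode = c("module", "member", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(members)
  out <- list()
  for (id in names(members)) {
    m <- members[[id]]
    a <- adjacency[m, m, drop = FALSE]
    if (mode == "module") {
      mean_a <- if (length(m) < 2) 0 else sum(a) / (length(m) * (length(m) - 1))
      if (mean_a >= adjacency_min) out[[id]] <- m
    } else {
      if (length(m) < 2) next
      mean_to_rest <- rowSums(a) / (length(m) - 1)
      kept <- m[mean_to_rest >= adjacency_min]
      if (length(kept) > 0) out[[id]] <- kept
    }
  }
  out
}

#' Build final coexpression modules from Z-scored expression
#'
#' Runs the whole module stage: correlation, soft adjacency, topological
#' overlap, static-cut average-linkage clustering, sign splitting,
#' representative computation, merging of close modules, and the adjacency
#' threshold.
#'
#' @param zmat Z-scored expression matrix (transcripts x time points).
#' @param config a [network_config()].
#' @param organ organ label stored in the output.
#' @return object of class `coexpression_modules`: list with `membership`
#'   (data frame: `transcript_id`, `module_id`, `sign`), `representatives`
#'   (module x time matrix), `unassigned` (ids in no final module), `organ`,
#'   `config`.
#' @export
build_modules <- function(zmat, config = network_config(), organ = "organ") {
  corr <- correlation_matrix(zmat)
  adj <- soft_adjacency(corr, config$beta)
  diss <- if (config$use_tom) topological_overlap(adj) else {
    d <- 1 - adj; diag(d) <- 0; d
  }
  hm <- hierarchical_modules(diss, config$cut_height, config$min_module_size,
                             config$linkage)
  assignment <- hm$assignment
  members <- list()
  sign_of <- character(0)
  for (k in setdiff(sort(unique(assignment)), 0L)) {
    ids <- names(assignment)[assignment == k]
    groups <- split_by_sign(zmat[ids, , drop = FALSE])
    for (g in names(groups)) {
      sgn <- if (g == "plus") "+" else "-"
      mid <- sprintf("M%02d%s", k, sgn)
      members[[mid]] <- groups[[g]]
      sign_of[mid] <- sgn
    }
  }
  if (length(members) > 0) {
    merged <- merge_close_modules(members, zmat, config$merge_dissim_max)
    members <- apply_adjacency_threshold(merged$members, adj,
                                         config$adjacency_min,
                                         config$adjacency_filter)
  }
  membership <- if (length(members) == 0) {
    data.frame(transcript_id = character(0), module_id = character(0),
               sign = character(0), stringsAsFactors = FALSE)
  } else {
    data.frame(
      transcript_id = unlist(members, use.names = FALSE),
      module_id = rep(names(members), lengths(members)),
      sign = rep(unname(sign_of[names(members)]), lengths(members)),
      stringsAsFactors = FALSE
    )
  }
  reps <- if (length(members) == 0) {
    matrix(numeric(0), 0, ncol(zmat), dimnames = list(NULL, colnames(zmat)))
  } else {
    t(vapply(members,
             function(m) module_representative(zmat[m, , drop = FALSE]),
             numeric(ncol(zmat))))
  }
  structure(list(
    membership = membership,
    representatives = reps,
    unassigned = setdiff(rownames(zmat), membership$transcript_id),
    organ = organ,
    config = config
  ), class = "coexpression_modules")
}

#' @export
print.coexpression_modules <- function(x, ...) {
  cat(sprintf("coexpression_modules: organ %s, %d modules, %d assigned / %d transcripts\n",
              x$organ, nrow(x$representatives), nrow(x$membership),
              nrow(x$membership) + length(x$unassigned)))
  invisible(x)
}
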