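d <- diel_design()

test_that("correlation matrix is a proper correlation matrix", {
  set.seed(1)
  x <- rnorm(14)
  m <- rbind(a = x, b = -x, c = rnorm(14))
  r <- correlation_matrix(m)
  expect_equal(r["a", "a"], 1)
  expect_equal(r["a", "b"], -1)
  expect_equal(r, t(r))
  # random rows: symmetric, PSD up to tolerance, |r| < 1 off-diagonal
  g <- matrix(rnorm(30 * 14), 30, 14, dimnames = list(sprintf("g%d", 1:30), NULL))
  rg <- correlation_matrix(g)
  expect_true(min(eigen(rg, symmetric = TRUE, only.values = TRUE)$values) > -1e-8)
  expect_true(all(abs(rg[upper.tri(rg)]) < 1))
  expect_error(correlation_matrix(rbind(a = rep(1, 14), b = rnorm(14))),
               "constant")
  expect_error(correlation_matrix(m[1, , drop = FALSE]), "2 transcripts")
})

test_that("soft adjacency is |r|^beta with zero diagonal, monotone in |r|", {
  r <- matrix(c(1, 0.9, 0, 0.9, 1, -0.5, 0, -0.5, 1), 3)
  a <- soft_adjacency(r, 18)
  expect_equal(diag(a), rep(0, 3))
  expect_equal(a[1, 2], 0.9^18)
  expect_equal(a[1, 2], 0.1500946, tolerance = 1e-6)
  expect_equal(a[2, 3], 0.5^18)
  expect_equal(a[1, 3], 0)
  rr <- seq(0, 1, by = 0.05)
  aa <- abs(rr)^18
  expect_true(all(diff(aa) >= 0))
  expect_true(all(aa >= 0 & aa <= 1))
  expect_error(soft_adjacency(matrix(2, 2, 2), 18), "\\[-1, 1\\]")
})

test_that("topological overlap matches the worked 3-node case and its bounds", {
  a <- matrix(0.5, 3, 3); diag(a) <- 0
  dd <- topological_overlap(a)
  # TOM12 = (0.25 + 0.5)/(1 + 1 - 0.5) = 0.5 -> dissimilarity 0.5
  expect_equal(dd[1, 2], 0.5)
  # identical rows with direct adjacency 1 -> dissimilarity 0
  b <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(topological_overlap(b)[1, 2], 0)
  # empty network -> dissimilarity 1 off-diagonal
  z <- matrix(0, 3, 3)
  expect_true(all(topological_overlap(z)[upper.tri(z)] == 1))
  # random adjacency: symmetric, in [0,1], zero diagonal
  set.seed(2)
  r <- abs(cor(matrix(rnorm(20 * 14), 14)))^6
  diag(r) <- 0
  td <- topological_overlap(r)
  expect_equal(td, t(td))
  expect_true(all(td >= 0 & td <= 1))
  expect_equal(diag(td), rep(0, 20))
  expect_error(topological_overlap(matrix(-0.1, 2, 2)), ">= 0")
})

test_that("static-cut clustering recovers planted blocks and pools small clusters", {
  set.seed(3)
  t <- d$sample_times_zt
  block <- function(ph, n) {
    t(vapply(seq_len(n), function(i) {
      cos(2 * pi * (t - ph) / 24) + rnorm(14, 0, 0.2)
    }, numeric(14)))
  }
  m <- rbind(block(0, 15), block(8, 15))
  rownames(m) <- sprintf("g%02d", 1:30)
  z <- zscore_matrix(m)
  diss <- topological_overlap(soft_adjacency(correlation_matrix(z), 18))
  hm <- hierarchical_modules(diss, cut_height = 0.93, min_module_size = 10)
  truth <- rep(1:2, each = 15)
  found <- hm$assignment
  expect_equal(length(unique(found[found > 0])), 2)
  expect_gte(adjusted_rand_index(truth, found), 0.8)
  # all-identical series cluster into one module
  same <- matrix(rep(cos(2 * pi * t / 24), each = 12), 12, 14, byrow = FALSE)
  same <- same + matrix(rnorm(12 * 14, 0, 1e-6), 12, 14)
  rownames(same) <- sprintf("s%02d", 1:12)
  zs <- zscore_matrix(same)
  ds <- topological_overlap(soft_adjacency(correlation_matrix(zs), 18))
  one <- hierarchical_modules(ds, 0.93, 10)$assignment
  expect_equal(unname(one), rep(1L, 12))
  # fewer series than the minimum size -> all unassigned
  few <- hierarchical_modules(ds[1:4, 1:4], 0.93, 10)$assignment
  expect_equal(unname(few), rep(0L, 4))
  expect_error(hierarchical_modules(matrix(0, 0, 0)), "empty")
})

test_that("sign splitting separates anti-correlated members", {
  set.seed(4)
  x <- zscore_series(cos(2 * pi * (d$sample_times_zt) / 24))
  m <- rbind(a = x, b = -x)
  g <- split_by_sign(m)
  expect_equal(length(g), 2)
  expect_equal(unname(sort(unlist(lapply(g, length)))), c(1L, 1L))
  # all positively correlated -> a single plus group
  pos <- rbind(a = x, b = x + rnorm(14, 0, 0.05), c = x + rnorm(14, 0, 0.05))
  expect_equal(names(split_by_sign(pos)), "plus")
  # planted anti-phase halves are recovered exactly
  half1 <- t(replicate(8, x + rnorm(14, 0, 0.1)))
  half2 <- t(replicate(8, -x + rnorm(14, 0, 0.1)))
  mm <- rbind(half1, half2)
  rownames(mm) <- sprintf("g%02d", 1:16)
  gg <- split_by_sign(mm)
  split_sets <- lapply(gg, sort)
  expect_true(setequal(split_sets[[1]], sprintf("g%02d", 1:8)) ||
                setequal(split_sets[[1]], sprintf("g%02d", 9:16)))
})

test_that("module representative is the pointwise median", {
  m <- rbind(a = c(1, 5, 3), b = c(2, 4, 9), c = c(0, 6, 6))
  expect_equal(module_representative(m), c(1, 5, 6))
  expect_equal(module_representative(m[1, , drop = FALSE]), c(1, 5, 3))
  # symmetric noise around a cosine: representative close to the truth
  set.seed(5)
  truth <- zscore_series(cos(2 * pi * d$sample_times_zt / 24))
  members <- t(replicate(51, truth + rnorm(14, 0, 0.3)))
  rownames(members) <- sprintf("m%02d", 1:51)
  rep_series <- module_representative(members)
  expect_lt(sqrt(mean((rep_series - truth)^2)), 0.15)
})

test_that("module merging pools close representatives and recomputes", {
  set.seed(6)
  t <- d$sample_times_zt
  x <- cos(2 * pi * t / 24)
  z <- rbind(
    a1 = zscore_series(x + rnorm(14, 0, 0.02)),
    a2 = zscore_series(x + rnorm(14, 0, 0.02)),
    b1 = zscore_series(-x + rnorm(14, 0, 0.02))
  )
  # identical representatives merge; anti-correlated do not
  merged <- merge_close_modules(list(A = "a1", B = "a2", C = "b1"), z, 0.25)
  expect_equal(sort(names(merged$members)), c("A", "C"))
  expect_true(setequal(merged$members$A, c("a1", "a2")))
  # transitive merging via recomputation: three mutually close modules -> one
  y <- cos(2 * pi * (t - 1) / 24)
  w <- cos(2 * pi * (t - 2) / 24)
  z3 <- rbind(a = zscore_series(x), b = zscore_series(y), c = zscore_series(w))
  m3 <- merge_close_modules(list(A = "a", B = "b", C = "c"), z3, 0.25)
  expect_equal(length(m3$members), 1)
})

test_that("the adjacency threshold gates modules and members as configured", {
  a <- matrix(1, 4, 4); diag(a) <- 0
  rownames(a) <- colnames(a) <- c("w", "x", "y", "z")
  # clique at adjacency 1: everything kept in both modes
  expect_equal(apply_adjacency_threshold(list(M = c("w", "x", "y")), a, 0.175,
                                         "member")$M, c("w", "x", "y"))
  expect_equal(apply_adjacency_threshold(list(M = c("w", "x", "y")), a, 0.175,
                                         "module")$M, c("w", "x", "y"))
  # isolated member pruned in member mode; boundary value retained (>= rule)
  a2 <- a; a2["z", ] <- 0; a2[, "z"] <- 0
  expect_equal(apply_adjacency_threshold(list(M = c("w", "x", "z")), a2, 0.175,
                                         "member")$M, c("w", "x"))
  a3 <- matrix(0.175, 3, 3); diag(a3) <- 0
  rownames(a3) <- colnames(a3) <- c("w", "x", "y")
  expect_equal(apply_adjacency_threshold(list(M = c("w", "x", "y")), a3, 0.175,
                                         "member")$M, c("w", "x", "y"))
  # module mode drops a weak module entirely
  weak <- matrix(0.01, 3, 3); diag(weak) <- 0
  rownames(weak) <- colnames(weak) <- c("w", "x", "y")
  expect_equal(length(apply_adjacency_threshold(list(M = c("w", "x", "y")),
                                                weak, 0.175, "module")), 0)
})

test_that("final modules partition rhythmic transcripts against planted truth", {
  set.seed(7)
  t <- d$sample_times_zt
  phases <- c(0, 6, 12)
  m <- do.call(rbind, lapply(seq_along(phases), function(k) {
    t(replicate(20, cos(2 * pi * (t - phases[k]) / 24) + rnorm(14, 0, 0.2)))
  }))
  rownames(m) <- sprintf("g%02d", 1:60)
  z <- zscore_matrix(m)
  mods <- build_modules(z, network_config(), organ = "L1")
  truth <- rep(1:3, each = 20)
  names(truth) <- rownames(m)
  found <- match(mods$membership$module_id,
                 unique(mods$membership$module_id))
  names(found) <- mods$membership$transcript_id
  common <- intersect(names(truth), names(found))
  expect_gte(length(common), 54)  # at least 90% of members assigned
  expect_gte(adjusted_rand_index(truth[common], found[common]), 0.8)
  # every transcript sits in at most one (module, sign)
  expect_equal(anyDuplicated(mods$membership$transcript_id), 0L)
})
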