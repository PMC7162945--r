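d <- diel_design()

test_that("noise-free series follow the cosine contract", {
  expect_equal(simulate_series(d, baseline = 2, amplitude = 0, noise_sd = 0),
               rep(2, 14))
  s <- simulate_series(d, amplitude = 1, phase_zt = 4, noise_sd = 0)
  expect_equal(d$sample_times_zt[which.max(s)], 4)
  # peak lands on the sample nearest the planted phase, for any phase
  for (ph in c(0, 3, 7.9, 13, 23.4)) {
    s <- simulate_series(d, amplitude = 1, phase_zt = ph, noise_sd = 0)
    t_in_cycle <- d$sample_times_zt %% 24
    nearest <- which.min(pmin(abs(t_in_cycle - ph), 24 - abs(t_in_cycle - ph)))
    expect_equal(s[which.max(s)], s[nearest])
  }
  expect_error(simulate_series(d, noise_sd = -1), "noise_sd")
  expect_error(simulate_series(d, amplitude = -1), "amplitude")
})

test_that("a fixed seed reproduces series and datasets bit for bit", {
  expect_identical(simulate_series(d, noise_sd = 0.5, seed = 3),
                   simulate_series(d, noise_sd = 0.5, seed = 3))
  a <- simulate_organ_dataset(d, n_transcripts = 50, seed = 9)
  b <- simulate_organ_dataset(d, n_transcripts = 50, seed = 9)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$matrix$detected, b$matrix$detected)
  expect_identical(a$truth, b$truth)
})

test_that("planted rhythmic counts are exact and dropout matches its rate", {
  zero <- simulate_organ_dataset(d, n_transcripts = 100, rhythmic_fraction = 0,
                                 seed = 1)
  expect_equal(sum(zero$truth$rhythmic), 0)
  ds <- simulate_organ_dataset(d, n_transcripts = 1000,
                               rhythmic_fraction = 0.3, seed = 2)
  expect_equal(sum(ds$truth$rhythmic), 300)
  expect_true(all(ds$truth$expressed[ds$truth$rhythmic]))
  expect_true(all(is.na(ds$truth$true_phase_zt[!ds$truth$rhythmic])))
  # detection density ~ Binomial(n_cells, 1 - dropout), within 3 SD
  half <- simulate_organ_dataset(d, n_transcripts = 1000, dropout_rate = 0.5,
                                 seed = 3)
  n_cells <- length(half$matrix$detected)
  expect_lt(abs(mean(half$matrix$detected) - 0.5),
            3 * sqrt(0.25 / n_cells))
  expect_error(simulate_organ_dataset(d, n_transcripts = 0), "n_transcripts")
})

test_that("multi-organ sharing plants common phases and exact shifts", {
  spec <- list(n_transcripts = 60, rhythmic_fraction = 0.5, noise_sd = 0.1)
  data <- simulate_multi_organ(d, list(A = spec, B = spec),
                               sharing_spec(60, 30), seed = 4)
  shared_rhy <- intersect(
    data$A$truth$transcript_id[data$A$truth$rhythmic],
    data$B$truth$transcript_id[data$B$truth$rhythmic])
  expect_equal(length(shared_rhy), 30)
  ia <- match(shared_rhy, data$A$truth$transcript_id)
  ib <- match(shared_rhy, data$B$truth$transcript_id)
  expect_equal(data$A$truth$true_phase_zt[ia], data$B$truth$true_phase_zt[ib])
  # full sharing -> identical expressed sets
  expect_identical(data$A$truth$expressed, data$B$truth$expressed)

  shifted <- simulate_multi_organ(
    d, list(A = spec, B = spec),
    sharing_spec(60, 30, phase_shift_h = c(B = 2)), seed = 4)
  ja <- match(shared_rhy, shifted$A$truth$transcript_id)
  jb <- match(shared_rhy, shifted$B$truth$transcript_id)
  dphi <- (shifted$B$truth$true_phase_zt[jb] -
             shifted$A$truth$true_phase_zt[ja]) %% 24
  expect_equal(dphi, rep(2, length(dphi)))
})

test_that("inconsistent sharing pools are rejected", {
  spec <- list(n_transcripts = 50, rhythmic_fraction = 0.2)
  expect_error(simulate_multi_organ(d, list(A = spec, B = spec),
                                    sharing_spec(60, 5), seed = 1),
               "n_shared")
  expect_error(simulate_multi_organ(d, list(A = spec, B = spec),
                                    sharing_spec(50, 20), seed = 1),
               "n_rhythmic_shared")
  expect_error(simulate_multi_organ(d, list(A = spec), sharing_spec(10, 2)),
               "2 organs")
})

test_that("annotation generator validates inputs and plants enrichment", {
  ids <- sprintf("t%05d", 1:400)
  expect_error(simulate_annotation(ids, categories = character(0)),
               "non-empty")
  expect_error(simulate_annotation(ids, rhythmic_ids = "missing",
                                   categories = "X"), "unknown")
  ann <- simulate_annotation(ids, rhythmic_ids = ids[1:120],
                             categories = c("X", "Y", "Z"),
                             odds = c(X = 12), prop_annotated = 1, seed = 8)
  expect_equal(sort(ann$transcript_id), sort(ids))
  expect_equal(anyDuplicated(ann$transcript_id), 0L)
  # planted association detected by the enrichment stage on the truth sets
  res <- enrich_categories(ids[1:120], ids, ann)
  expect_equal(res$call[res$category == "X"], "over")
  # flat odds -> no systematic call
  flat <- simulate_annotation(ids, rhythmic_ids = ids[1:120],
                              categories = c("X", "Y", "Z"),
                              prop_annotated = 1, seed = 8)
  res_flat <- enrich_categories(ids[1:120], ids, flat)
  expect_true(all(res_flat$p_over > 1e-4))
})
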