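test_that("GFP matches a direct per-frame loop and handles edge cases", {
  set.seed(1)
  m <- matrix(rnorm(5 * 40), 5)
  rec <- recording(m, 100)
  g <- gfp(rec)
  # brute-force oracle: population SD across channels after average reference
  for (t in c(1, 7, 40)) {
    v <- m[, t] - mean(m[, t])
    expect_equal(g[t], sqrt(mean((v - mean(v))^2)), tolerance = 1e-12)
  }
  flat <- recording(matrix(rep(c(1, 1), 10), 2), 10)
  expect_equal(gfp(flat), rep(0, 10))
  pm <- recording(matrix(rep(c(1, -1), 10), 2), 10)
  expect_equal(gfp(pm), rep(1, 10))
  expect_error(gfp(recording(matrix(rnorm(10), 1), 10)), "2 channels")
})

test_that("GFP peak picking: strict maxima thinned by separation", {
  expect_identical(find_gfp_peaks(1:10), integer(0))
  bump <- c(0, 1, 2, 3, 2, 1, 0)
  expect_identical(find_gfp_peaks(bump), 4L)
  two <- c(0, 2, 1, 3, 0, 0, 0, 0)         # peaks at 2 and 4, separation 2
  expect_identical(find_gfp_peaks(two, min_separation = 5), 4L)
  expect_identical(sort(find_gfp_peaks(two, min_separation = 1)), c(2L, 4L))
  expect_error(find_gfp_peaks(c(1, 2)), "too short")
})

test_that("modified k-means recovers orthogonal ground-truth maps", {
  topo <- test_topographies(19, 4)
  set.seed(2)
  amps <- rnorm(400, 0, 1) + sign(rnorm(400)) * 0.5
  states <- rep(1:4, each = 100)
  maps <- topo[, states] * rep(amps, each = 19)
  model <- cluster_topographies(maps, k = 4, n_restarts = 20, seed = 1)
  cors <- abs(stats::cor(model$prototypes, topo))
  # every ground-truth map matched by exactly one prototype, |cor| >= 0.99
  expect_equal(sort(apply(cors, 2, max)), rep(1, 4), tolerance = 0.01)
  expect_equal(sort(apply(cors, 2, which.max)), 1:4)
  # polarity invariance: flipping all map signs leaves prototypes unchanged up to sign
  model2 <- cluster_topographies(-maps, k = 4, n_restarts = 20, seed = 1)
  cc <- abs(stats::cor(model$prototypes, model2$prototypes))
  expect_equal(unname(sort(apply(cc, 2, max))), rep(1, 4), tolerance = 1e-6)
  expect_error(cluster_topographies(maps[, 1:3], k = 4), "at least k")
})

test_that("GEV is non-decreasing over iterations and k = 1 returns the common map", {
  topo <- test_topographies(10, 3, seed = 5)
  set.seed(3)
  maps <- topo[, sample(1:3, 200, TRUE)] * rep(rnorm(200), each = 10) +
    matrix(rnorm(2000, 0, 0.1), 10)
  model <- cluster_topographies(maps, k = 3, n_restarts = 10, seed = 2)
  expect_true(all(diff(model$gev_trace) >= -1e-12))
  expect_true(model$gev > 0 && model$gev <= 1)
  same <- topo[, 1] %o% rep(2, 20)
  m1 <- cluster_topographies(same, k = 1, n_restarts = 3, seed = 1)
  expect_equal(abs(sum(m1$prototypes[, 1] * topo[, 1])), 1, tolerance = 1e-9)
})

test_that("template maps control letter assignment", {
  topo <- test_topographies(19, 4)
  set.seed(4)
  maps <- topo[, rep(1:4, 50)] * rep(rnorm(200) + 2, each = 19)
  model <- cluster_topographies(maps, k = 4, n_restarts = 10, seed = 1,
                                templates = topo)
  cors <- abs(stats::cor(model$prototypes, topo))
  expect_equal(unname(diag(cors)), rep(1, 4), tolerance = 0.01)
  expect_error(cluster_topographies(maps, k = 4, templates = topo[, 1:2]),
               "channels x k")
})

test_that("back-fitting is polarity-invariant and validates channels", {
  topo <- test_topographies(12, 4)
  model <- list(prototypes = `colnames<-`(topo, LETTERS[1:4]))
  class(model) <- "microstate_model"
  recB <- recording(topo[, 2] %o% rnorm(30, 3), 100)
  expect_true(all(backfit(recB, model) == "B"))
  recC <- recording(-(topo[, 3] %o% rep(2, 30)), 100)
  expect_true(all(backfit(recC, model) == "C"))
  bad <- recording(matrix(rnorm(50), 5), 100)
  expect_error(backfit(bad, model), "channel mismatch")
})

test_that("run-length statistics match hand counts", {
  lab <- rep(rep(c("A", "B"), each = 10), 10)     # alternating 10-sample runs
  st <- microstate_stats(lab, fs = 100)
  expect_equal(st$duration_ms, c(100, 100))
  expect_equal(st$occurrence_per_s, c(5, 5))
  expect_equal(st$coverage, c(0.5, 0.5))
  one <- microstate_stats(rep("C", 250), fs = 250)
  expect_equal(one$coverage, 1)
  expect_equal(one$occurrence_per_s, 1)           # one instance over 1 s
  set.seed(5)
  rnd <- microstate_stats(sample(LETTERS[1:4], 1000, TRUE), fs = 100)
  expect_equal(sum(rnd$coverage), 1, tolerance = 1e-12)
  expect_error(microstate_stats(character(0), 100), "empty")
})

test_that("statistics are invariant under class permutation", {
  set.seed(6)
  lab <- sample(LETTERS[1:4], 500, TRUE)
  st <- microstate_stats(lab, 100)
  perm <- c(A = "D", B = "C", C = "A", D = "B")
  st2 <- microstate_stats(unname(perm[lab]), 100)
  for (cl in names(perm)) {
    expect_equal(st2[st2$class == perm[[cl]], -1],
                 st[st$class == cl, -1], ignore_attr = TRUE)
  }
})

test_that("full pipeline recovers labels and dwell time on synthetic EEG", {
  topo <- test_topographies(19, 4)
  sim <- gen_microstate_eeg(microstate_spec(topo, mean_dwell = 100, fs = 250,
                                            duration = 40, snr = 5, seed = 8))
  res <- microstate_pipeline(sim$eeg, k = 4, n_restarts = 15, seed = 1,
                             min_peak_separation = 2)
  expect_gte(label_agreement(res$labels, sim$states), 0.99)
  expect_equal(sum(res$stats$coverage), 1, tolerance = 1e-12)
  true_dwell <- mean(rle(sim$states)$lengths) / 250 * 1000
  est_dwell <- sum(res$stats$duration_ms * res$stats$occurrence_per_s) /
    sum(res$stats$occurrence_per_s)
  expect_lt(abs(est_dwell - true_dwell) / true_dwell, 0.10)
})
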