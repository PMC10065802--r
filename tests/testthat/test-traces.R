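test_that("domain validation names the offending field", {
  expect_error(synthesize_trace(domain_spec("g", 90, 80)), "edges")
  expect_error(synthesize_trace(domain_spec("g", 10, 20, amplitude = 0)),
               "amplitude")
  expect_error(synthesize_trace(domain_spec("g", 10, 20,
                                            edge_sharpness = 0)),
               "edge_sharpness")
  expect_error(synthesize_trace(domain_spec("g", 10, 20), n_points = 5),
               "n_points")
})

test_that("the generator produces the designed profile", {
  dom <- domain_spec("wg", 80, 95, amplitude = 10, edge_sharpness = 1,
                     baseline = 1)
  tr <- synthesize_trace(dom, n_points = 301, noise_sd = 0)
  at <- function(p) tr$intensity[which.min(abs(tr$position - p))]
  # Plateau versus baseline.
  expect_gt(at(87.5), at(70))
  # Plateau height ~ baseline + amplitude (logistic tails only).
  expect_equal(max(tr$intensity), 11, tolerance = 1e-2)
  # Far from the domain the signal sits at baseline.
  expect_equal(at(10), 1, tolerance = 1e-6)
  # Intensities never dip below zero even with heavy noise.
  noisy <- synthesize_trace(domain_spec("g", 40, 60, amplitude = 1),
                            noise_sd = 5, seed = 7)
  expect_true(all(noisy$intensity >= 0))
})

test_that("traces are reproducible per seed and leave the RNG alone", {
  dom <- domain_spec("cad", 70, 85)
  a <- synthesize_trace(dom, noise_sd = 0.5, seed = 11)
  b <- synthesize_trace(dom, noise_sd = 0.5, seed = 11)
  d <- synthesize_trace(dom, noise_sd = 0.5, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$intensity, d$intensity))
  withr::with_seed(99, {
    before <- .Random.seed
    synthesize_trace(dom, noise_sd = 1, seed = 5)
    expect_identical(before, .Random.seed)
  })
})

test_that("min-max normalisation is correct, flagged, and idempotent", {
  tr <- new_trace_for_test(c(2, 4, 6))
  norm <- normalize_trace(tr)
  expect_equal(norm$intensity, c(0, 0.5, 1))
  expect_true(is_normalized(norm))
  # Constant series collapse to zero with a degeneracy flag.
  flat <- new_trace_for_test(c(3, 3, 3))
  nflat <- normalize_trace(flat)
  expect_equal(nflat$intensity, c(0, 0, 0))
  expect_identical(degenerate_genes(nflat), "g")
  # Idempotence.
  expect_equal(normalize_trace(norm)$intensity, norm$intensity)
})

test_that("windowing keeps the stated interval and rejects empty windows", {
  tr <- synthesize_trace(domain_spec("cad", 70, 85), n_points = 201)
  w <- window_trace(tr)  # defaults: the 67.5-97.5 %EL posterior window
  expect_true(all(w$position >= 67.5 & w$position <= 97.5))
  expect_identical(window_trace(tr, 0, 100)$intensity, tr$intensity)
  expect_error(window_trace(tr, 97.5, 67.5), "empty")
  expect_error(window_trace(tr, 101, 102), "no sampled positions")
})

test_that("window-then-normalise differs from normalise-then-window when extrema leave the window", {
  # Domain peak anterior of the window: windowing first rescales the
  # in-window remnant to [0, 1]; normalising first leaves it compressed.
  dom <- domain_spec("cad", 40, 72, edge_sharpness = 1)
  tr <- synthesize_trace(dom, n_points = 401, noise_sd = 0)
  wn <- normalize_trace(window_trace(tr))
  nw <- window_trace(normalize_trace(tr))
  expect_equal(max(wn$intensity), 1)
  expect_lt(max(nw$intensity), 1)
  # With the extrema (effectively) inside the window the two orders
  # agree up to the logistic tail mass outside it.
  dom2 <- domain_spec("wg", 80, 90)
  tr2 <- synthesize_trace(dom2, n_points = 401, noise_sd = 0)
  expect_equal(normalize_trace(window_trace(tr2))$intensity,
               window_trace(normalize_trace(tr2))$intensity,
               tolerance = 1e-4)
})

test_that("boundary calling finds half-max crossings at the edges", {
  tr <- normalize_trace(synthesize_trace(
    domain_spec("wg", 80, 95, edge_sharpness = 0.5), n_points = 301,
    noise_sd = 0))
  b <- boundary_positions(tr, "wg")
  expect_identical(b$direction, c("rising", "falling"))
  expect_lt(b$position[1], b$position[2])
  expect_equal(b$position[b$direction == "falling"], 95, tolerance = 0.1)
  expect_equal(b$position[b$direction == "rising"], 80, tolerance = 0.1)
  # A flat trace has no crossings.
  flat <- normalize_trace(new_trace_for_test(c(3, 3, 3)))
  expect_identical(nrow(boundary_positions(flat, "g")), 0L)
  expect_error(boundary_positions(tr, "nope"), "nope")
  expect_error(boundary_positions(synthesize_trace(
    domain_spec("wg", 80, 95)), "wg"), "normalised")
})

test_that("boundary shifts are signed, antisymmetric, and NA when undefined", {
  ref <- normalize_trace(synthesize_trace(domain_spec("cad", 70, 85),
                                          noise_sd = 0))
  expect_equal(boundary_shift(ref, ref, "cad", "falling"), 0)
  mut <- normalize_trace(synthesize_trace(domain_spec("cad", 70, 83),
                                          noise_sd = 0))
  expect_equal(boundary_shift(ref, mut, "cad", "falling"), -2,
               tolerance = 0.05)
  expect_equal(boundary_shift(mut, ref, "cad", "falling"),
               -boundary_shift(ref, mut, "cad", "falling"),
               tolerance = 1e-9)
  # Reference without the crossing -> undefined.
  flat <- normalize_trace(synthesize_trace(
    domain_spec("cad", 1, 99, edge_sharpness = 0.5), n_points = 301))
  w_ref <- window_trace(ref, 70, 80)
  w_flat <- window_trace(flat, 70, 80)
  expect_true(is.na(boundary_shift(w_flat, w_ref, "cad", "falling")))
  # Mismatched windows are an error.
  expect_error(boundary_shift(ref, window_trace(mut, 60, 90), "cad"),
               "window")
})

test_that("boundary estimates recover the generating edges under noise", {
  # Noise at 5% of amplitude, 100 seeds; at least 95% of boundary
  # estimates within 0.5% egg length of the generating parameters.
  dom <- domain_spec("cad", 75, 90, amplitude = 10, edge_sharpness = 1)
  errs <- unlist(lapply(1:100, function(s) {
    tr <- synthesize_trace(dom, n_points = 301, noise_sd = 0.5, seed = s)
    tr <- normalize_trace(window_trace(tr))
    b <- boundary_positions(tr, "cad")
    c(b$position[b$direction == "rising"][1] - 75,
      utils::tail(b$position[b$direction == "falling"], 1) - 90)
  }))
  expect_identical(length(errs), 200L)
  expect_gte(mean(abs(errs) <= 0.5), 0.95)
})
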