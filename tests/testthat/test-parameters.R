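test_that("duration, occurrence and coverage match hand-computed values", {
  # one 2 s epoch at 500 Hz: class A in runs of 30 and 20 samples
  labs <- c(rep(1, 30), rep(2, 100), rep(1, 20), rep(4, 850))
  p <- compute_parameters(make_labels(labs))
  expect_equal(p$duration_ms[p$class == "A"], 50)            # (60 + 40) / 2 ms
  expect_equal(p$occurrence_per_s[p$class == "A"], 1)        # 2 runs / 2 s
  expect_equal(p$coverage_pct[p$class == "A"], 5)            # 50 / 1000
  # 5 class-A runs in 2 s -> 2.5 /s
  labs2 <- rep(c(rep(1, 20), rep(2, 180)), 5)
  p2 <- compute_parameters(make_labels(labs2))
  expect_equal(p2$occurrence_per_s[p2$class == "A"], 2.5)
  # 300 of 1000 samples in class D -> 30%
  labs3 <- c(rep(4, 300), rep(1, 700))
  p3 <- compute_parameters(make_labels(labs3))
  expect_equal(p3$coverage_pct[p3$class == "D"], 30)
})

test_that("absent classes report NA duration and zero occurrence/coverage", {
  p <- compute_parameters(make_labels(rep(c(1, 2), each = 500)))
  expect_true(is.na(p$duration_ms[p$class == "C"]))
  expect_equal(p$occurrence_per_s[p$class == "C"], 0)
  expect_equal(p$coverage_pct[p$class == "C"], 0)
})

test_that("occurrence x duration = coverage holds exactly and coverages sum to 100", {
  set.seed(1)
  for (r in 1:5) {
    labs <- sample(1:4, 4000, TRUE)
    p <- compute_parameters(make_labels(labs, epoch_length = 1000))
    expect_equal(sum(p$coverage_pct), 100, tolerance = 1e-9)
    ok <- !is.na(p$duration_ms)
    expect_equal(p$occurrence_per_s[ok] * p$duration_ms[ok] / 1000,
                 p$coverage_pct[ok] / 100, tolerance = 1e-9)
  }
})

test_that("epoch-truncated runs can be excluded from duration and occurrence", {
  # two epochs; class 1 runs: (10 | interior 20 | 30-truncated), epoch2: all class 2
  labs <- c(rep(1, 10), rep(2, 500), rep(1, 20), rep(2, 440), rep(1, 30),
            rep(2, 1000))
  series <- make_labels(labs, epoch_length = 1000)
  inc <- compute_parameters(series, exclude_truncated = FALSE)
  exc <- compute_parameters(series, exclude_truncated = TRUE)
  expect_equal(inc$duration_ms[1], mean(c(10, 20, 30)) * 2)
  expect_equal(exc$duration_ms[1], 20 * 2)       # only the interior run remains
  expect_equal(inc$occurrence_per_s[1], 3 / 4)
  expect_equal(exc$occurrence_per_s[1], 1 / 4)
  expect_equal(inc$coverage_pct, exc$coverage_pct)
})

test_that("runs and transitions never span epoch boundaries", {
  # class 1 ends epoch 1 and starts epoch 2: two runs, no 1->1 or cross transition
  labs <- c(rep(2, 900), rep(1, 100), rep(1, 100), rep(3, 900))
  series <- make_labels(labs, epoch_length = 1000)
  p <- compute_parameters(series)
  expect_equal(p$occurrence_per_s[1], 2 / 4)
  tr <- compute_transitions(series)
  expect_equal(tr$percent[tr$from == "B" & tr$to == "A"], 50)
  expect_equal(tr$percent[tr$from == "A" & tr$to == "C"], 50)
  expect_equal(sum(tr$percent), 100, tolerance = 1e-9)
})

test_that("transition percentages match hand-computed values and sum to 100", {
  # run sequence A, B, A, C -> three transitions at 33.33% each
  labs <- c(rep(1, 10), rep(2, 10), rep(1, 10), rep(3, 10))
  tr <- compute_transitions(make_labels(labs, epoch_length = 40))
  expect_equal(tr$percent[tr$from == "A" & tr$to == "B"], 100 / 3, tolerance = 1e-9)
  expect_equal(tr$percent[tr$from == "B" & tr$to == "A"], 100 / 3, tolerance = 1e-9)
  expect_equal(tr$percent[tr$from == "A" & tr$to == "C"], 100 / 3, tolerance = 1e-9)
  expect_equal(sum(tr$percent), 100, tolerance = 1e-9)
  # alternating A,B: both directions about 50%
  labs2 <- rep(c(rep(1, 10), rep(2, 10)), 25)
  tr2 <- compute_transitions(make_labels(labs2, epoch_length = 500))
  expect_equal(tr2$percent[tr2$from == "A" & tr2$to == "B"], 50, tolerance = 2)
  expect_equal(tr2$percent[tr2$from == "B" & tr2$to == "A"], 50, tolerance = 2)
  expect_error(compute_transitions(make_labels(rep(1, 100))), "no transitions")
})

test_that("long draws from the reference chain recover the planted transition table", {
  sp <- preset_dynamics("mwoa")
  labs <- sample_state_sequence(sp, 1200, 500, seed = 13)
  tr <- compute_transitions(make_labels(labs, epoch_length = 600000))
  # planted joint percentages: stationary weight x embedded transition, x100
  J <- sp$segment_weights * sp$embedded_transitions
  J <- J / sum(J) * 100
  want <- as.vector(t(J))[as.vector(t(diag(4) == 0))]
  expect_equal(tr$percent, want, tolerance = 0.5 / 9)   # within 0.5 points
})

test_that("parameters are invariant to polarity flips and channel permutation", {
  mon <- tiny_montage()
  tpl <- canonical_templates(mon)
  labs <- sample_state_sequence(uniform_dynamics(60), 8, 500, seed = 3)
  rec <- render_eeg(labs, tpl, fs = 500, snr = 5, seed = 3, montage = mon)
  ep <- epoch_recording(rec, 2)
  base <- compute_parameters(backfit(ep, tpl))
  # global sign flip
  rec2 <- rec; rec2$data <- -rec2$data
  p2 <- compute_parameters(backfit(epoch_recording(rec2, 2), tpl))
  expect_equal(p2, base)
  # consistent channel permutation of data and maps
  set.seed(4); perm <- sample(12)
  rec3 <- rec; rec3$data <- rec$data[perm, ]
  rec3$montage <- ms_montage(mon$name[perm], mon$x[perm], mon$y[perm])
  p3 <- compute_parameters(backfit(epoch_recording(rec3, 2), tpl[, perm]))
  expect_equal(p3, base)
})
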