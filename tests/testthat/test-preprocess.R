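make_sine_rec <- function(freq, fs = 500, secs = 4, mon = tiny_montage()) {
  t <- seq_len(fs * secs) / fs
  base <- sin(2 * pi * freq * t)
  X <- outer(seq_len(nrow(mon)) - mean(seq_len(nrow(mon))), base)
  ms_recording(X, fs = fs, montage = mon)
}

test_that("in-band sinusoids pass the microstate band almost unchanged", {
  rec <- make_sine_rec(10)
  out <- filter_recording(rec, 2, 20)
  mid <- 500:1500                      # avoid filter edge transients
  ratio <- sd(out$data[1, mid]) / sd(rec$data[1, mid])
  expect_equal(ratio, 1, tolerance = 0.05)
})

test_that("the 50 Hz notch removes mains-frequency content", {
  rec <- make_sine_rec(50)
  out <- filter_recording(rec, 0.5, 70, notch = 50)
  mid <- 500:1500
  expect_lt(sd(out$data[1, mid]) / sd(rec$data[1, mid]), 0.05)
})

test_that("filtering is linear and validates the band", {
  mon <- tiny_montage()
  z <- ms_recording(matrix(0, 12, 1000), 500, mon)
  expect_equal(max(abs(filter_recording(z, 2, 20)$data)), 0)
  expect_error(filter_recording(z, 2, 300), "Nyquist")
  expect_error(filter_recording(z, 20, 2), "band_lo")
})

test_that("filtering commutes with channel permutation", {
  mon <- tiny_montage()
  set.seed(1)
  X <- matrix(rnorm(12 * 1000), 12)
  perm <- sample(12)
  a <- filter_recording(ms_recording(X, 500, mon), 2, 20)$data[perm, ]
  b <- filter_recording(ms_recording(X[perm, ], 500,
        ms_montage(mon$name[perm], mon$x[perm], mon$y[perm])), 2, 20)$data
  expect_equal(unname(a), unname(b), tolerance = 1e-12)
})

test_that("downsampling halves the length and preserves in-band content", {
  mon <- tiny_montage()
  t <- seq_len(240 * 1000) / 1000
  X <- outer(rep(1, 12), sin(2 * pi * 10 * t)) * (1:12)
  rec <- ms_recording(X, fs = 1000, montage = mon,
                      truth_labels = rep(1:4, each = 60000))
  out <- resample_recording(rec, 500)
  expect_equal(ncol(out$data), 120000)
  expect_equal(out$fs, 500)
  expect_length(out$truth_labels, 120000)
  # dominant frequency unchanged
  sp <- Mod(stats::fft(out$data[5, ]))[2:60000]
  fpeak <- which.max(sp) * 500 / 120000
  expect_equal(fpeak, 10, tolerance = 0.01)
  # identity and error branches
  expect_identical(resample_recording(rec, 1000), rec)
  expect_error(resample_recording(out, 1000), "upsampling")
})

test_that("epoching yields average-referenced epochs of the right shape", {
  mon <- tiny_montage()
  set.seed(2)
  rec <- ms_recording(matrix(rnorm(12 * 120000), 12), 500, mon)
  ep <- epoch_recording(rec, 2, 60)
  expect_equal(dim(ep$epochs), c(60L, 12L, 1000L))
  m <- apply(ep$epochs, c(1, 3), mean)
  expect_lt(max(abs(m)), 1e-10)
  expect_error(epoch_recording(rec, 2, 200), "available")
})

test_that("a common offset on all channels is rejected by the average reference", {
  mon <- tiny_montage()
  set.seed(3)
  X <- matrix(rnorm(12 * 2000), 12)
  a <- epoch_recording(ms_recording(X, 500, mon), 2)
  b <- epoch_recording(ms_recording(X + 7.5, 500, mon), 2)
  expect_equal(a$epochs, b$epochs, tolerance = 1e-12)
})

test_that("average referencing is idempotent and epochs concatenate to the referenced signal", {
  mon <- tiny_montage()
  set.seed(4)
  X <- matrix(rnorm(12 * 4000), 12)
  ref <- sweep(X, 2, colMeans(X))
  ep1 <- epoch_recording(ms_recording(X, 500, mon), 2)
  ep2 <- epoch_recording(ms_recording(ref, 500, mon), 2)
  expect_equal(ep1$epochs, ep2$epochs, tolerance = 1e-12)
  # concatenating epochs reproduces the referenced signal exactly
  recon <- do.call(cbind, lapply(1:4, function(e) ep1$epochs[e, , ]))
  expect_equal(recon, unname(ref), tolerance = 1e-12)
})

test_that("the artifact hook flags only epochs above threshold", {
  mon <- tiny_montage()
  X <- matrix(rnorm(12 * 3000), 12)
  X[3, 1500] <- 100
  ep <- epoch_recording(ms_recording(X, 500, mon), 2)
  expect_identical(flag_epochs(ep), integer(0))
  expect_identical(flag_epochs(ep, threshold = 50), 2L)
})
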