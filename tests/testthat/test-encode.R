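test_that("segmentation yields non-overlapping 250 ms records", {
  rec10 <- tiny_recording(hold = 10)
  segs <- segment_recording(rec10)
  expect_equal(nrow(segs), 40)            # 10 000 ms / 250 ms
  expect_equal(dim(segs$samples[[1]]), c(16, 500))
  expect_equal(segs$gesture_id[1], rec10$gesture_id)
  # non-overlapping: segments tile the recording exactly
  expect_identical(segs$samples[[2]], rec10$samples[, 501:1000])

  rec250 <- tiny_recording(hold = 0.25)
  one <- segment_recording(rec250)
  expect_equal(nrow(one), 1)
  expect_equal(ncol(one$samples[[1]]), 500)

  rec240 <- tiny_recording(hold = 0.24)
  expect_warning(none <- segment_recording(rec240), "shorter")
  expect_equal(nrow(none), 0)
})

test_that("STFT framing gives 4 frames x 129 bins and matches a direct DFT", {
  x <- sin(2 * pi * 80 * (1:500) / 2000) + 0.3 * sin(2 * pi * 310 * (1:500) / 2000)
  m <- stft_frames(x)
  expect_equal(dim(m), c(4, 129))

  # independent oracle: explicit DFT sums on each Hann-tapered 200-sample
  # frame, zero-padded to 256 points
  n_win <- 200; hop <- 100; nfft <- 256
  taper <- 0.5 * (1 - cos(2 * pi * (0:(n_win - 1)) / (n_win - 1)))
  for (f in 1:4) {
    frame <- x[((f - 1) * hop + 1):((f - 1) * hop + n_win)] * taper
    for (k in c(0, 7, 64, 128)) {
      dft_k <- sum(frame * exp(-2i * pi * k * (0:(n_win - 1)) / nfft))
      expect_equal(m[f, k + 1], Mod(dft_k), tolerance = 1e-9)
    }
  }

  expect_equal(stft_frames(numeric(500)), matrix(0, 4, 129))
  expect_error(stft_frames(numeric(300)), "expected 500")
  expect_error(stft_frames(x, s = stft_spec(nfft = 128)), ">=")
})

test_that("grayscale normalization maps to [0,1] with a degenerate-range rule", {
  expect_equal(to_grayscale(matrix(c(0, 2, 1, 4), 2)),
               matrix(c(0, 0.5, 0.25, 1), 2))
  expect_equal(to_grayscale(matrix(3, 2, 2)), matrix(0, 2, 2))
  set.seed(2)
  g <- to_grayscale(matrix(rnorm(30), 5))
  expect_equal(range(g), c(0, 1))
  expect_error(to_grayscale(matrix(c(1, Inf), 1)), "non-finite")
})

test_that("the auxiliary channel is the pointwise cross-channel maximum", {
  seg <- matrix(rnorm(8 * 500), 8)
  aug <- augment_max_channel(seg)
  expect_equal(dim(aug), c(9, 500))
  expect_identical(aug[1:8, ], seg)
  expect_true(all(aug[9, ] >= apply(seg, 2, max) - 1e-15))
  expect_equal(nrow(augment_max_channel(matrix(0, 16, 10))), 17)

  consts <- matrix(rep(1:8, 10), 8)
  expect_equal(augment_max_channel(consts)[9, ], rep(8, 10))
  expect_error(augment_max_channel(matrix(0, 9, 10)), "8 or 16")
})

test_that("encoder image sizes match their contracts", {
  seg16 <- tiny_recording(hold = 0.25)$samples
  seg8 <- seg16[seq(1, 15, 2), ]

  expect_equal(dim(encode_time_domain(seg16)$pixels), c(16, 250))
  expect_equal(dim(encode_time_domain(seg8)$pixels), c(8, 250))
  expect_equal(dim(encode_spectrogram(seg8)$pixels), c(32, 129))
  expect_equal(dim(encode_spectrogram(seg16)$pixels), c(64, 129))
  expect_equal(dim(encode_spectrogram(augment_max_channel(seg8))$pixels),
               c(36, 129))
  e17 <- encode_spectrogram(augment_max_channel(seg16))
  expect_equal(dim(e17$pixels), c(68, 129))
  expect_equal(e17$encoder, "enhanced_spectrogram")
  expect_equal(e17$n_channels_source, 17L)
  expect_equal(encode_spectrogram(seg16)$encoder, "spectrogram")

  expect_true(all(encode_spectrogram(seg16)$pixels >= 0 &
                    encode_spectrogram(seg16)$pixels <= 1))
  # constant segment maps to an all-zero time-domain image
  expect_equal(encode_time_domain(matrix(5, 8, 500))$pixels,
               matrix(0, 8, 250))
  expect_error(encode_time_domain(seg16[, 1:499]), "even")
})

test_that("channel permutation permutes 4-row spectrogram blocks identically", {
  seg <- tiny_recording(hold = 0.25)$samples
  perm <- c(3, 1, 2, seq(4, 16))
  img <- encode_spectrogram(seg)$pixels
  img_p <- encode_spectrogram(seg[perm, ])$pixels
  # to_grayscale is a global min-max, identical for both stacks
  for (c in seq_along(perm)) {
    expect_equal(img_p[(4 * (c - 1) + 1):(4 * c), ],
                 img[(4 * (perm[c] - 1) + 1):(4 * perm[c]), ])
  }
})

test_that("encoding is deterministic and dataset encoding carries labels", {
  seg <- tiny_recording(hold = 0.25)$samples
  expect_identical(encode_spectrogram(seg)$pixels,
                   encode_spectrogram(seg)$pixels)

  d <- simulate_dataset(gesture_profiles()[1:3, ],
                        tiny_sim_config(hold = 0.5, subjects = 1, reps = 2))
  imgs <- encode_dataset(d, "spectrogram", n_channels = 8)
  expect_equal(nrow(imgs), 3 * 2 * 2)     # 3 gestures x 2 reps x 2 segments
  expect_equal(dim(imgs$image[[1]]$pixels), c(32, 129))
  expect_setequal(unique(purrr::map_int(imgs$image, "label")), c(0L, 1L, 2L))
})
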