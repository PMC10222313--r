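test_that("default gesture profiles are ten distinct 16-channel patterns", {
  prof <- gesture_profiles()
  expect_equal(nrow(prof), 10)
  expect_equal(prof$gesture_id, 0:9)
  expect_setequal(
    prof$name,
    c("Power Grip", "OK Hand", "Thumb Up", "Thumb Down", "Scissorhands",
      "Palm Up", "Palm Down", "Palm Outward", "Palm to the left",
      "Palm to the right")
  )
  for (a in prof$activation) {
    expect_length(a, 16)
    expect_true(all(is.finite(a)) && all(a >= 0) && any(a > 0))
  }
  # spatial separability: pairwise cosine similarity below 0.95
  A <- do.call(rbind, prof$activation)
  G <- A %*% t(A)
  cos_sim <- G / sqrt(outer(diag(G), diag(G)))
  diag(cos_sim) <- 0
  expect_lt(max(cos_sim), 0.95)
})

test_that("recording length, shape and determinism follow the config", {
  cfg <- tiny_sim_config(hold = 10)
  rec <- simulate_recording(gesture_profiles()[1, ], cfg, 1, 1)
  expect_s3_class(rec, "emg_recording")
  expect_equal(dim(rec$samples), c(16, 20000))  # 2000 sps x 10 s
  expect_true(all(is.finite(rec$samples)))

  rec2 <- simulate_recording(gesture_profiles()[1, ], cfg, 1, 1)
  expect_identical(rec$samples, rec2$samples)
  rec3 <- simulate_recording(gesture_profiles()[1, ], cfg, 1, 2)
  expect_false(identical(rec$samples, rec3$samples))

  cfg8 <- tiny_sim_config(n_channels = 8)
  expect_equal(nrow(simulate_recording(gesture_profiles()[1, ],
                                       cfg8, 1, 1)$samples), 8)
})

test_that("zero activation and zero noise leave only the DC offset", {
  prof <- list(gesture_id = 0, name = "null", activation = rep(0, 16))
  cfg <- tiny_sim_config(hold = 0.5, powerline_amp = 0, noise_rms = 0,
                         dc_offset = 0.7)
  rec <- simulate_recording(prof, cfg, 1, 1)
  expect_equal(rec$samples, matrix(0.7, 16, 1000))
})

test_that("powerline contamination peaks at the 50 Hz bin", {
  rec <- tiny_recording(hold = 2, powerline_amp = 0.8)
  for (ch in c(1, 9)) {
    pg <- periodogram(rec$samples[ch, ], rec$fs)
    bin50 <- which.min(abs(pg$freq - 50))
    neighbours <- pg$power[setdiff(seq(bin50 - 10, bin50 + 10), bin50)]
    expect_gt(pg$power[bin50], stats::median(neighbours))
    # local maximum at the bin nearest 50 Hz
    expect_equal(which.max(pg$power[(bin50 - 5):(bin50 + 5)]), 6)
  }
})

test_that("EMG carrier power is confined to the configured band", {
  rec <- tiny_recording(hold = 2, powerline_amp = 0, dc_offset = 0,
                        noise_rms = 0)
  pg <- periodogram(rec$samples[1, ], rec$fs)
  in_band <- pg$freq >= 20 & pg$freq <= 450
  expect_gt(sum(pg$power[in_band]) / sum(pg$power), 0.9)
})

test_that("doubling activation doubles the clean signal RMS", {
  base <- gesture_profiles()[1, ]
  doubled <- base
  doubled$activation[[1]] <- 2 * base$activation[[1]]
  cfg <- tiny_sim_config(powerline_amp = 0, dc_offset = 0, noise_rms = 0,
                         hold = 0.5)
  r1 <- simulate_recording(base, cfg, 1, 1)
  r2 <- simulate_recording(doubled, cfg, 1, 1)
  expect_equal(2 * rms(r1$samples[1, ]), rms(r2$samples[1, ]))
})

test_that("invalid configs and gestures are rejected", {
  expect_error(sim_config(n_channels = 12), "8 or 16")
  expect_error(sim_config(emg_band = c(100, 20)), "low < high")
  expect_error(sim_config(emg_band = c(20, 1500)), "low < high")
  expect_error(sim_config(noise_rms = -1), ">= 0")
  prof <- list(gesture_id = 11, name = "bad", activation = rep(1, 16))
  expect_error(simulate_recording(prof, tiny_sim_config(), 1, 1), "0..9")
})

test_that("dataset generation is balanced, complete and reproducible", {
  prof <- gesture_profiles()
  cfg <- tiny_sim_config(hold = 0.25, subjects = 2, reps = 3)
  d <- simulate_dataset(prof, cfg)
  expect_equal(nrow(d), 2 * 10 * 3)
  expect_true(all(table(d$gesture_id) == 6))  # uniform class histogram

  d2 <- simulate_dataset(prof, cfg)
  expect_identical(
    purrr::map(d$recording, "samples"),
    purrr::map(d2$recording, "samples")
  )

  dup <- prof[c(1, 1, 2), ]
  expect_error(simulate_dataset(dup, cfg), "duplicate")
  expect_error(simulate_dataset(prof[1, ], cfg), "at least 2")
})

test_that("subject jitter is fixed per subject and varies across subjects", {
  cfg <- tiny_sim_config(hold = 0.25, powerline_amp = 0, noise_rms = 0,
                         dc_offset = 0)
  prof <- gesture_profiles()[1, ]
  r_s1a <- simulate_recording(prof, cfg, 1, 1, seed = 7)
  r_s1b <- simulate_recording(prof, cfg, 1, 1, seed = 7)
  r_s2 <- simulate_recording(prof, cfg, 2, 1, seed = 7)
  expect_identical(r_s1a$samples, r_s1b$samples)
  # same recording seed, different subject: only activation scaling differs,
  # so per-channel signals are proportional but not equal
  expect_false(identical(r_s1a$samples, r_s2$samples))
  ratio <- r_s2$samples[1, ] / r_s1a$samples[1, ]
  ratio <- ratio[is.finite(ratio)]  # the envelope endpoint is exactly zero
  expect_lt(stats::sd(ratio), 1e-8)
})
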