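# preprocess module: filter frequency responses against RMS oracles,
# rejection statistics, PCA retention, ICA cleaning, surface Laplacian.

test_that("notch filter removes the mains line and spares the passband", {
  x60 <- sinusoid(60)
  y60 <- notch_filter(x60, fs = 256)
  expect_lt(mid_rms(y60[1, ]), 0.1 * mid_rms(x60[1, ]))

  x10 <- sinusoid(10)
  y10 <- notch_filter(x10, fs = 256)
  expect_equal(mid_rms(y10[1, ]), mid_rms(x10[1, ]), tolerance = 0.1)

  z <- notch_filter(matrix(0, 1, 1024), fs = 256)
  expect_equal(max(abs(z)), 0)
  expect_error(notch_filter(x60, filter_spec(notch_freq = 200), fs = 256),
               "Nyquist")
})

test_that("band-pass keeps 1-29 Hz and rejects DC and 45 Hz", {
  dc <- matrix(1, 1, 3072)
  ydc <- bandpass_filter(dc, fs = 256)
  expect_lt(mid_rms(ydc[1, ]), 0.01)

  x45 <- sinusoid(45)
  y45 <- bandpass_filter(x45, fs = 256)
  expect_lt(mid_rms(y45[1, ]), 0.1 * mid_rms(x45[1, ]))

  x10 <- sinusoid(10)
  y10 <- bandpass_filter(x10, fs = 256)
  expect_equal(mid_rms(y10[1, ]), mid_rms(x10[1, ]), tolerance = 0.1)
  expect_error(filter_spec(bandpass = c(10, 5)), "edge")
})

test_that("filtering is linear", {
  withr::with_seed(1, {
    x <- matrix(rnorm(2048), 1)
    y <- matrix(rnorm(2048), 1)
  })
  for (f in list(function(m) bandpass_filter(m, fs = 256),
                 function(m) notch_filter(m, fs = 256))) {
    lhs <- f(2 * x - 3 * y)
    rhs <- 2 * f(x) - 3 * f(y)
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})

test_that("reject_trials flags amplitude and kurtosis outliers", {
  base <- lapply(1:12, function(i) {
    e <- simulate_trial("SOG", "STOP", quiet_params(noise_sd = 5),
                        seed = 300 + i, trial_id = sprintf("T%03d", i))
    e
  })
  spiky <- base
  spiky[[4]]$signal[3, 100] <- 200 # single 200 uV spike
  rep1 <- reject_trials(spiky)
  expect_true("T004" %in% rep1$rejected$trial_id)
  expect_equal(rep1$rejected$reason[rep1$rejected$trial_id == "T004"],
               "amplitude")

  # identical clean trials: nothing rejected
  same <- lapply(1:6, function(i) {
    e <- base[[1]]
    e$trial_id <- sprintf("S%03d", i)
    e
  })
  rep2 <- reject_trials(same)
  expect_equal(nrow(rep2$rejected), 0)
  expect_length(rep2$kept_ids, 6)

  # heavy-tailed trial among Gaussian ones -> kurtosis (amplitudes kept
  # under the 150 uV limit so only the shape statistic can fire)
  heavy <- withr::with_seed(5, lapply(1:12, function(i) {
    x <- if (i == 2) {
      pmax(pmin(10 * stats::rt(32 * 3072, df = 2), 140), -140)
    } else rnorm(32 * 3072, sd = 10)
    as_epoch(matrix(x, 32), trial_id = sprintf("T%03d", i))
  }))
  rep3 <- reject_trials(heavy)
  expect_true("T002" %in% rep3$rejected$trial_id)
  expect_equal(rep3$rejected$reason[rep3$rejected$trial_id == "T002"],
               "kurtosis")
  expect_error(reject_trials(list()), "empty")
})

test_that("rejection is permutation-equivariant", {
  sess <- lapply(1:10, function(i)
    simulate_trial("FCO", "STOP", quiet_params(), seed = 400 + i,
                   trial_id = sprintf("T%03d", i)))
  sess[[7]]$signal[1, 50] <- 400
  r1 <- reject_trials(sess)
  perm <- withr::with_seed(2, sample(10))
  r2 <- reject_trials(sess[perm])
  expect_setequal(r1$kept_ids, r2$kept_ids)
  expect_setequal(r1$rejected$trial_id, r2$rejected$trial_id)
})

test_that("PCA retains the minimal component count for the threshold", {
  # rank-1 data: all channels identical
  withr::with_seed(3, {
    base <- rnorm(1000)
    rank1 <- matrix(rep(base, 4), 4, byrow = TRUE)
  })
  f1 <- pca_fit_project(list(rank1), threshold = 0.95)
  expect_equal(f1$model$retained_count, 1)

  # known eigenvalues via uncorrelated rows with variances 9 and 1
  withr::with_seed(4, {
    x <- rbind(3 * rnorm(20000), rnorm(20000), 0.01 * rnorm(20000))
  })
  f2 <- pca_fit_project(list(x), threshold = 0.9)
  ev <- eigen(stats::cov(t(x)))$values # brute-force oracle
  k_oracle <- which(cumsum(ev) / sum(ev) >= 0.9)[1]
  expect_equal(f2$model$retained_count, k_oracle)

  # threshold 1 on full-rank data retains all channels
  withr::with_seed(5, full <- matrix(rnorm(4 * 500), 4))
  f3 <- pca_fit_project(list(full), threshold = 1)
  expect_equal(f3$model$retained_count, 4)
  expect_error(pca_fit_project(list(full), threshold = 0), "threshold")

  # retained variance equals the sum of retained eigenvalues
  v_reduced <- sum(apply(f2$epochs[[1]], 1, stats::var))
  expect_equal(v_reduced, sum(ev[seq_len(k_oracle)]), tolerance = 1e-6)
})

test_that("ICA removes a synthetic blink and passes clean data through", {
  withr::with_seed(6, {
    n <- 4000
    src <- rbind(rnorm(n), sin(2 * pi * 10 * (1:n) / 256) + 0.1 * rnorm(n),
                 rnorm(n))
    blink <- numeric(n)
    at <- seq(200, n - 200, by = 700)
    for (a in at) blink[a + 0:76] <- smrfes:::blink_template(256)
    mix <- matrix(rnorm(16), 4, 4)[, 1:3]
    x <- mix %*% src
    x[1, ] <- x[1, ] + 8 * blink # frontal channel carries the artifact
    rownames(x) <- c("AFz", "F3", "C3", "CP3")
  })
  res <- ica_clean(list(x), template = blink)
  expect_s3_class(res$model, "ica_model")
  expect_true(any(res$model$component_flags == "artifact"))
  expect_lt(abs(stats::cor(res$epochs[[1]]["AFz", ], blink)), 0.2)
  # mixing o unmixing ~ identity on the retained subspace
  mu <- res$model$unmixing %*% res$model$mixing
  expect_equal(mu, diag(nrow(mu)), tolerance = 1e-6)

  # nothing flagged -> pass-through
  clean <- withr::with_seed(7, matrix(rnorm(3 * 3000), 3))
  rownames(clean) <- c("AFz", "C3", "CP3")
  res2 <- ica_clean(list(clean), template = withr::with_seed(8, rnorm(3000)))
  expect_equal(res2$epochs[[1]], clean, tolerance = 1e-6)

  expect_error(ica_clean(list(x), template = blink, online = TRUE),
               "offline only")
})

test_that("surface Laplacian sharpens focal sources", {
  labs <- c("C3", "C5", "C1", "FC3", "CP3")
  montage <- list(C3 = c("C5", "C1", "FC3", "CP3"))
  # spatially uniform signal -> ~0 on channels with neighbors
  u <- matrix(1, 5, 100)
  rownames(u) <- labs
  lu <- surface_laplacian(u, montage, segments = "all")
  expect_equal(max(abs(lu["C3", ])), 0)

  # focal source on C3
  withr::with_seed(9, f <- matrix(0, 5, 100))
  f[1, ] <- sin(2 * pi * 10 * (1:100) / 256)
  rownames(f) <- labs
  lf <- surface_laplacian(f, montage, segments = "all")
  expect_gt(max(abs(lf["C3", ])), 0.5 * max(abs(f["C3", ])))
  # direct arithmetic oracle
  expect_equal(lf["C3", ],
               f["C3", ] - colMeans(f[c("C5", "C1", "FC3", "CP3"), ]))
  # channels without neighbors pass through
  expect_equal(lf["C5", ], f["C5", ])
})

test_that("Laplacian on trial epochs touches only reference+MI by default", {
  e <- simulate_trial("SOG", "STOP", quiet_params(), seed = 31)
  le <- surface_laplacian(e, default_montage())
  fs <- 256
  rest_idx <- 1:(2.5 * fs)
  mi_idx <- (5 * fs + 1):(8 * fs)
  expect_equal(le$signal[, rest_idx], e$signal[, rest_idx])
  expect_false(isTRUE(all.equal(le$signal[, mi_idx], e$signal[, mi_idx])))
})
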