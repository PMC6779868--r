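test_that("histogram text files round-trip through write/read", {
  s <- quick_sim("2/5", seed = 11)
  path <- file.path(withr::local_tempdir(), "s1.txt")
  write_histogram(s$histogram, path)
  h2 <- read_histogram(path)
  expect_equal(h2$channels, s$histogram$channels)
  expect_equal(h2$counts, s$histogram$counts)
  expect_equal(h2$sample_id, s$histogram$sample_id)
  expect_equal(sum(h2$counts), sum(s$histogram$counts))
})

test_that("malformed histogram files are rejected with the offending line", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.txt")
  writeLines(c("channel\tcount", "1\t10", "2\toops"), bad)
  expect_error(read_histogram(bad), "line 3")
  neg <- file.path(dir, "neg.txt")
  writeLines(c("1 10", "2 -5"), neg)
  expect_error(read_histogram(neg), "negative count")
  empty <- file.path(dir, "empty.txt")
  writeLines(character(0), empty)
  expect_error(read_histogram(empty), "empty")
  expect_error(read_histogram(file.path(dir, "nothere.txt")), "not found")
})

test_that("peak detection recovers simulated peak positions and CVs", {
  s <- quick_sim("2/5", seed = 21)
  pk <- detect_peaks(s$histogram)
  truth <- s$truth[s$truth$role %in% c("embryo_G1", "endosperm_G1"), ]
  for (i in seq_len(nrow(truth))) {
    j <- which.min(abs(pk$mean_fluorescence - truth$position[i]))
    expect_lt(abs(pk$mean_fluorescence[j] / truth$position[i] - 1), 0.02)
  }
  # CV estimate on an isolated Gaussian is within 20% of configured
  s1 <- simulate_histogram(seed_sim("2/3", g2 = FALSE, endosperm_frac = 0,
                                    debris_frac = 0, cv = 3),
                           rng_seed = 5)
  pk1 <- detect_peaks(s1$histogram)
  expect_equal(nrow(pk1), 1L)
  expect_lt(abs(pk1$cv_percent / 3 - 1), 0.2)
})

test_that("flat and empty-signal histograms raise NoPeaksDetected", {
  flat <- fcss_histogram(1:200, rep(10L, 200))
  expect_warning(expect_error(detect_peaks(flat), class = "fcss_no_peaks"),
                 "particles")
})

test_that("histograms below the particle gate warn but still run", {
  s <- simulate_histogram(seed_sim("2/3", total_particles = 800),
                          rng_seed = 3)
  expect_warning(detect_peaks(s$histogram), "particles")
})

test_that("roles are assigned by dominance and quotient geometry", {
  # sexual geometry: dominant embryo at 100, endosperm at 150
  s <- quick_sim("2/3", seed = 31)
  seed <- assign_roles(detect_peaks(s$histogram), s$histogram)
  expect_equal(seed$embryo$role, "embryo_G1")
  expect_lt(abs(seed$embryo$mean_fluorescence / 100 - 1), 0.02)
  expect_false(seed$used_second_peak)
  expect_lt(abs(seed$quotient / 1.5 - 1), 0.03)
  expect_true(seed$endosperm_percent > 0 && seed$endosperm_percent < 100)
})

test_that("endopolyploid seeds trigger the second-peak halving rule", {
  s <- simulate_histogram(seed_sim("2/3", endopolyploid = TRUE),
                          rng_seed = 41)
  seed <- assign_roles(detect_peaks(s$histogram), s$histogram)
  expect_true(seed$used_second_peak)
  # replicate peak at 300 halved to an effective endosperm mean near 150
  expect_lt(abs(seed$endosperm_effective_mean / 150 - 1), 0.03)
  expect_lt(abs(seed$quotient / 1.5 - 1), 0.03)
  expect_match(paste(seed$notes, collapse = " "), "second-peak")
})

test_that("a lone embryo peak yields a no-endosperm measurement", {
  s <- simulate_histogram(seed_sim("2/3", endosperm_frac = 0, g2 = FALSE),
                          rng_seed = 51)
  seed <- assign_roles(detect_peaks(s$histogram), s$histogram)
  expect_true(seed$no_endosperm)
  expect_true(is.na(seed$quotient))
})

test_that("role assignment recovers the generating roles on simulated seeds", {
  labels <- c("2/3", "2/4", "2/5", "2/6")
  n <- 1000L
  ok <- logical(n)
  for (i in seq_len(n)) {
    s <- simulate_histogram(seed_sim(labels[(i %% 4L) + 1L], cv = 3),
                            rng_seed = 10000L + i)
    seed <- assign_roles(detect_peaks(s$histogram), s$histogram)
    t_emb <- s$truth$position[s$truth$role == "embryo_G1"]
    t_end <- s$truth$position[s$truth$role == "endosperm_G1"]
    ok[i] <- !seed$no_endosperm &&
      abs(seed$embryo$mean_fluorescence / t_emb - 1) < 0.03 &&
      abs(seed$endosperm_effective_mean / t_end - 1) < 0.03
  }
  expect_gte(mean(ok), 0.99)
})

test_that("endosperm percentage follows the nuclei-count ratio", {
  expect_equal(endosperm_percentage(500, 500), 50)
  expect_equal(endosperm_percentage(1000, 500), 100 * 500 / 1500)
  expect_equal(endosperm_percentage(123, 0), 0)
  # scale invariance in the counts
  expect_equal(endosperm_percentage(700, 300),
               endosperm_percentage(7000, 3000))
  expect_error(endosperm_percentage(0, 0), "undefined")
})

test_that("quotients are invariant to rescaling of the fluorescence axis", {
  s <- quick_sim("2/5", seed = 61)
  h <- s$histogram
  h2 <- fcss_histogram(h$channels * 3.7, h$counts, sample_id = h$sample_id)
  q1 <- assign_roles(detect_peaks(h), h)$quotient
  q2 <- assign_roles(detect_peaks(h2), h2)$quotient
  expect_equal(q1, q2, tolerance = 1e-10)
})

test_that("internal-standard genome sizes follow the fluorescence ratio", {
  expect_equal(relative_genome_size(500, 500, 9.09), 9.09)
  expect_equal(relative_genome_size(800, 400, 3.38), 6.76)
  expect_error(relative_genome_size(100, 200), "standard")

  # mother plants with a genome-size/standard ratio in [2.7, 3] keep it
  # through simulation, measurement and conversion
  std <- list(species = "Pisum sativum", two_c_pg = 9.09, position = 120)
  for (i in 1:5) {
    ratio <- 2.7 + 0.3 * (i - 1) / 4
    s <- simulate_histogram(
      seed_sim("2/3", embryo_position = ratio * std$position,
               standard = std, n_channels = 2048L),
      rng_seed = 70 + i)
    params <- peak_params(standard_window = c(100, 140))
    seed <- assign_roles(detect_peaks(s$histogram, params), s$histogram,
                         params)
    est_ratio <- seed$embryo_relative_gs / std$two_c_pg
    expect_lt(abs(est_ratio / ratio - 1), 0.02)
    expect_gte(est_ratio, 2.7 * 0.98)
    expect_lte(est_ratio, 3.0 * 1.02)
  }
})
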