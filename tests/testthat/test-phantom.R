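test_that("biphasic waveform hits its peaks and integrates to zero", {
  for (np in c(12L, 21L)) {
    w <- biphasic_waveform(np, 40, 2.90, -5.03)
    t <- attr(w, "times")
    expect_equal(max(w), 2.90)
    expect_equal(min(w), -5.03)
    expect_lt(abs(tpmsense:::trapz(t, w)), 1e-9 * diff(range(t)))
  }
  expect_error(biphasic_waveform(10, 40, -1, -5), "peak_sys")
})

test_that("painted velocities reproduce the prescribed waveforms exactly", {
  spec <- small_spec(n_phases = 2, radial_waveform = c(3, -5),
                     longitudinal_waveform = c(1, -2))
  truth <- generate_ground_truth(spec)
  myo <- truth$myocardium_mask
  model <- segment_model(truth$center)
  field <- structure(list(v = truth$velocity, venc = spec$venc,
                          background_fit = NULL), class = "tpm_velocity_field")
  proj <- project_velocities(field, model)
  expect_identical(mean(proj$radial[, , 1][myo]), 3)
  expect_identical(mean(proj$radial[, , 2][myo]), -5)
  expect_identical(mean(proj$longitudinal[, , 1][myo]), 1)
  expect_identical(mean(proj$longitudinal[, , 2][myo]), -2)
  # zero velocity on static tissue, disjoint masks
  expect_true(all(truth$velocity[, , , 1][rep(truth$static_mask, 3)] == 0))
  expect_false(any(truth$static_mask & truth$myocardium_mask))
})

test_that("zero waveforms give identically zero velocity maps", {
  spec <- small_spec(radial_waveform = rep(0, 12),
                     longitudinal_waveform = rep(0, 12))
  truth <- generate_ground_truth(spec)
  expect_true(all(truth$velocity == 0))
})

test_that("waveforms at or beyond the VENC are rejected unless wrap is allowed", {
  spec <- small_spec(radial_waveform = c(rep(0, 11), 31),
                     longitudinal_waveform = rep(0, 12))
  expect_error(generate_ground_truth(spec), "wrap")
  expect_s3_class(generate_ground_truth(spec, allow_wrap = TRUE),
                  "tpm_ground_truth")
})

test_that("coil sensitivities are deterministic, smooth and cover the object", {
  s1 <- simulate_sensitivities(8, 64, seed = 11)
  s2 <- simulate_sensitivities(8, 64, seed = 11)
  expect_identical(unclass(s1), unclass(s2))
  s3 <- simulate_sensitivities(8, 64, seed = 12)
  expect_false(identical(unclass(s1), unclass(s3)))
  # coverage floor over the imaged object
  truth <- generate_ground_truth(phantom_spec())
  maxmag <- apply(Mod(unclass(s1)), c(1, 2), max)
  expect_gt(min(maxmag[truth$intensity > 0.1]), 0.1)
  # degenerate uniform body coil
  u <- simulate_sensitivities(1, 16, uniform = TRUE)
  expect_true(all(u == 1 + 0i))
  expect_error(simulate_sensitivities(2, 16, uniform = TRUE), "n_coils = 1")
})

test_that("zero velocity and zero background phase give four identical encodings", {
  spec <- small_spec(radial_waveform = rep(0, 12),
                     longitudinal_waveform = rep(0, 12),
                     background_phase_plane = c(0, 0, 0),
                     velocity_offset_planes = matrix(0, 3, 3))
  truth <- generate_ground_truth(spec)
  sens <- simulate_sensitivities(2, 32, seed = 3)
  enc <- encode_images(truth, sens)
  for (e in 2:4)
    expect_equal(enc$data[, , , e, ], enc$data[, , , 1L, ], tolerance = 1e-15)
})

test_that("encoding phases follow the balanced four-point pattern", {
  # uniform in-plane velocity equal to the VENC along x
  spec <- small_spec(background_phase_plane = c(0, 0, 0),
                     velocity_offset_planes = matrix(0, 3, 3))
  truth <- generate_ground_truth(spec)
  g <- spec$grid_size
  truth$velocity[] <- 0
  truth$velocity[, , 1L, ] <- spec$venc   # v = (venc, 0, 0) everywhere
  sens <- simulate_sensitivities(1, g, uniform = TRUE)
  enc <- encode_images(truth, sens)
  ph <- sapply(1:4, function(e) Arg(enc$data[16, 16, 1, e, 1] /
                                      truth$intensity[16, 16]))
  expect_equal(ph, c(-pi / 2, pi / 2, pi / 2, -pi / 2), tolerance = 1e-12)
})

test_that("hadamard decode inverts the encoder for random sub-VENC velocities", {
  spec <- small_spec(background_phase_plane = c(0.4, 0.02, -0.03),
                     velocity_offset_planes = matrix(0, 3, 3))
  truth <- generate_ground_truth(spec)
  g <- spec$grid_size
  set.seed(42)
  for (rep in 1:10) {
    v <- runif(3, -0.45, 0.45) * spec$venc   # inside the unambiguous region
    for (k in 1:3) truth$velocity[, , k, ] <- v[k]
    sens <- simulate_sensitivities(1, g, uniform = TRUE)
    enc <- encode_images(truth, sens)
    dec <- hadamard_decode(enc$data[, , 1, , , drop = TRUE], venc = spec$venc)
    for (k in 1:3)
      expect_lt(max(abs(dec$v[, , k, ] - v[k])), 1e-10)
  }
})

test_that("k-space sampling keeps ceiling(rows / R) lines and pads when needed", {
  img <- structure(list(data = array(1 + 0i, c(168, 8, 2, 4, 1)),
                        domain = "image", sampling = NULL, venc = 30,
                        sense_factor = 1L, noise_sigma = 0, seed = NULL),
                   class = "tpm_encoded")
  k2 <- sample_kspace(img, 2)
  expect_identical(dim(k2$data)[1L], 84L)
  ch <- small_chain()
  for (R in 1:4) {
    k <- sample_kspace(ch$images, R)
    expect_identical(dim(k$data)[1L], as.integer(ceiling(32 / R)))
    expect_identical(k$sampling$rows, seq.int(1L, k$sampling$nrow_padded, by = R))
  }
  expect_error(sample_kspace(ch$images, 5), "underdetermined")
  expect_warning(sample_kspace(ch$images, 5, allow_underdetermined = TRUE),
                 "underdetermined")
})

test_that("noise is reproducible under a seed and absent at sigma zero", {
  ch <- small_chain()
  a <- sample_kspace(ch$images, 2, noise_sigma = 1, seed = 5)
  b <- sample_kspace(ch$images, 2, noise_sigma = 1, seed = 5)
  expect_identical(a$data, b$data)
  d <- sample_kspace(ch$images, 2, noise_sigma = 1, seed = 6)
  expect_false(identical(a$data, d$data))
  expect_error(sample_kspace(ch$images, 2, noise_sigma = 1), "seed")
  quiet1 <- sample_kspace(ch$images, 2, noise_sigma = 0, seed = 5)
  quiet2 <- sample_kspace(ch$images, 2, noise_sigma = 0)
  expect_identical(quiet1$data, quiet2$data)
})
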