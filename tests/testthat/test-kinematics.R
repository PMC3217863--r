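field_from <- function(varr, venc = 30) {
  structure(list(v = varr, venc = venc, background_fit = NULL),
            class = "tpm_velocity_field")
}

test_that("projection separates radial and longitudinal motion", {
  g <- 33L
  model <- segment_model(c(17, 17))
  rows <- matrix(seq_len(g), g, g)
  cols <- matrix(seq_len(g), g, g, byrow = TRUE)
  d <- sqrt((rows - 17)^2 + (cols - 17)^2)
  ux <- (17 - cols) / d; uy <- (17 - rows) / d
  v <- array(0, c(g, g, 3, 1))
  v[, , 1, 1] <- 3 * ux
  v[, , 2, 1] <- 3 * uy
  proj <- project_velocities(field_from(v), model)
  off <- d > 0
  expect_true(all(abs(proj$radial[, , 1][off] - 3) < 1e-12))
  expect_true(is.na(proj$radial[17, 17, 1]))   # centre has no radial direction
  expect_true(all(proj$longitudinal == 0))
  # purely through-plane motion toward the apex
  v2 <- array(0, c(g, g, 3, 1)); v2[, , 3, 1] <- 6.08
  proj2 <- project_velocities(field_from(v2), model)
  expect_true(all(proj2$longitudinal == 6.08))
  expect_true(all(abs(proj2$radial[, , 1][off]) < 1e-12))
  # rotating (tangential) field has no radial component
  v3 <- array(0, c(g, g, 3, 1))
  v3[, , 1, 1] <- -uy; v3[, , 2, 1] <- ux
  proj3 <- project_velocities(field_from(v3), model)
  expect_true(all(abs(proj3$radial[, , 1][off]) < 1e-12))
})

test_that("segment partition covers the annulus in six balanced ordered sectors", {
  g <- 201L
  ctr <- c(101, 101)
  rows <- matrix(seq_len(g), g, g)
  cols <- matrix(seq_len(g), g, g, byrow = TRUE)
  d <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
  mask <- d >= 60 & d <= 90
  model <- segment_model(ctr, reference_angle = 0)
  labels <- partition_segments(mask, model)
  # a partition: every mask pixel labelled exactly once
  expect_identical(sum(!is.na(labels)), sum(mask))
  counts <- table(labels[mask])
  expect_lt(diff(range(counts)) / mean(counts), 0.02)
  # pixel at polar angle 30 degrees lies in the first (anteroseptal) sector
  r0 <- round(ctr[1] - 70 * sin(pi / 6)); c0 <- round(ctr[2] + 70 * cos(pi / 6))
  expect_identical(labels[r0, c0], "anteroseptal")
  # rotating the reference by 60 degrees permutes labels cyclically
  rot <- partition_segments(mask, segment_model(ctr, reference_angle = pi / 3))
  expect_identical(unname(rot[r0, c0]), "anterior")
  perm <- table(labels[mask], rot[mask])
  for (i in seq_along(SEGMENT_LABELS)) {
    from <- SEGMENT_LABELS[i]
    to <- SEGMENT_LABELS[(i - 2) %% 6 + 1]   # shift by -1 in label order
    expect_gt(perm[from, to], 0.95 * sum(labels[mask] == from))
  }
  expect_error(partition_segments(matrix(FALSE, 4, 4), model), "empty")
})

test_that("spline resampling reproduces knots and cubic polynomials", {
  t <- seq(0, 800, by = 40)
  vals <- sin(t / 130) * 3
  cv <- spline_resample(velocity_curve(t, vals), dt = 0.5)
  at_knots <- cv$dense_values[match(t, cv$dense_times)]
  expect_equal(at_knots, vals, tolerance = 1e-12)
  # natural splines are exact on data from a straight line
  lin <- spline_resample(velocity_curve(t, 0.5 + 0.002 * t), dt = 0.25)
  expect_equal(lin$dense_values, 0.5 + 0.002 * lin$dense_times,
               tolerance = 1e-9)
  # a cubic restricted to the interior where natural boundary conditions hold
  cub <- function(x) (x - 400)^3 / 1e6
  cv3 <- spline_resample(velocity_curve(t, cub(t)), dt = 1)
  interior <- cv3$dense_times > 200 & cv3$dense_times < 600
  expect_lt(max(abs(cv3$dense_values[interior] - cub(cv3$dense_times[interior]))),
            0.02 * max(abs(cub(t))))
  # degenerate grids flag themselves
  wide <- spline_resample(velocity_curve(c(0, 40), c(1, 2)), dt = 100)
  expect_identical(wide$dense_times, c(0, 40))
  expect_match(attr(wide, "degenerate"), "span")
  few <- spline_resample(velocity_curve(c(0, 40, 80), c(1, 2, 0)), dt = 1)
  expect_match(attr(few, "degenerate"), "linear")
  expect_error(spline_resample(velocity_curve(t, vals), dt = 0), "dt")
})

test_that("extracted region curves are means, shifted and densely resampled", {
  g <- 32L
  mask <- matrix(FALSE, g, g)
  mask[10:22, 10:22] <- TRUE
  model <- segment_model(c(16.5, 16.5))
  labels <- partition_segments(mask, model)
  n_ph <- 6L
  v <- array(0, c(g, g, 3, n_ph))
  # paint distinct constant values in two sectors at one phase
  sel_a <- !is.na(labels) & labels == "anteroseptal"
  sel_b <- !is.na(labels) & labels == "inferior"
  for (ph in seq_len(n_ph)) {
    vz <- matrix(0, g, g)
    vz[sel_a] <- 2 * ph
    vz[sel_b] <- -3 * ph
    v[, , 3, ph] <- vz
  }
  proj <- project_velocities(field_from(v), model)
  times <- (seq_len(n_ph) - 1) * 40
  cs <- extract_curves(proj, mask, times, labels, dt = 1)
  # pre-shift segment means are the painted values: undo the recorded shift
  cur <- cs$anteroseptal.longitudinal
  expect_equal(cur$values + attr(cur, "shift"), 2 * seq_len(n_ph),
               tolerance = 1e-12)
  cur <- cs$inferior.longitudinal
  expect_equal(cur$values + attr(cur, "shift"), -3 * seq_len(n_ph),
               tolerance = 1e-12)
  # constant fields collapse to zero after the shift
  v5 <- array(5, c(g, g, 3, n_ph))
  cs5 <- extract_curves(project_velocities(field_from(v5), model),
                        mask, times, dt = 1)
  expect_true(all(abs(cs5$global.longitudinal$values) < 1e-12))
  # empty regions warn and are skipped
  empty_labels <- labels
  empty_labels[empty_labels == "anterior"] <- "anterolateral"
  attr(empty_labels, "levels") <- SEGMENT_LABELS
  expect_warning(extract_curves(proj, mask, times, empty_labels, dt = 1),
                 "empty")
})
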