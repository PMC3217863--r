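# Shared fixtures: a small noiseless phantom chain, memoised so several
# test files can reuse the same simulated acquisition.

small_spec <- function(noise_sigma = 0, n_phases = 12, ...) {
  phantom_spec(grid_size = 32, endo_radius = 10, epi_radius = 16,
               n_phases = n_phases, n_coils = 4, noise_sigma = noise_sigma,
               seed = 7L, ...)
}

.fixtures <- new.env(parent = emptyenv())

small_chain <- function() {
  if (is.null(.fixtures$chain)) {
    spec <- small_spec()
    truth <- generate_ground_truth(spec)
    sens <- simulate_sensitivities(spec$n_coils, spec$grid_size, seed = 7L)
    images <- encode_images(truth, sens)
    .fixtures$chain <- list(spec = spec, truth = truth, sens = sens,
                            images = images)
  }
  .fixtures$chain
}

# decoded, background-corrected velocity field at a given R (noiseless)
small_field <- function(R = 1L) {
  key <- paste0("field_R", R)
  if (is.null(.fixtures[[key]])) {
    ch <- small_chain()
    k <- sample_kspace(ch$images, R)
    un <- sense_unfold(k, ch$sens)
    .fixtures[[key]] <- correct_background(hadamard_decode(un),
                                           ch$truth$static_mask)
  }
  .fixtures[[key]]
}

make_curve <- function(values, times = NULL, dt = 0.5, ...) {
  times <- times %||% seq(0, by = 40, length.out = length(values))
  spline_resample(velocity_curve(times, values, ...), dt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
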