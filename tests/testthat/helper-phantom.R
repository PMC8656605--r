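# Shared fixtures: small phantoms built in code at test time.

# plain-array Dice, independent of the package's dice()
dice_raw <- function(a, b) {
  a <- a > 0; b <- b > 0
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

# a small default phantom reused across tests
tiny_phantom <- function(seed = 1L, noise_sigma = 0) {
  generate_phantom(phantom_spec(
    grid_shape = c(48L, 48L, 20L), spacing = c(1, 1, 2.4),
    wp_semi_axes = c(18, 14, 18), cg_semi_axes = c(11, 8, 11),
    lesions = list(list(center = c(13, 0, 2), semi_axes = c(4, 4, 4),
                        adc = 0.8e-3, is_cspca = TRUE)),
    noise_sigma = noise_sigma, psa = 10, seed = seed))
}

# random probability grid on a given shape
random_prob_grid <- function(shape = c(12L, 10L, 4L), seed = 1L,
                             spacing = c(1, 1, 1)) {
  set.seed(seed)
  voxel_grid(array(stats::runif(prod(shape)), shape), spacing,
             kind = "probability")
}
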