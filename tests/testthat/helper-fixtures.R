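# Shared fixtures, all built in code at test time.

# a small asymmetric 3-channel pixel array (values distinguish every pixel)
asym_pixels <- function(nr = 5, nc = 7) {
  array(seq_len(nr * nc * 3) * 11 %% 60000, c(nr, nc, 3))
}

# uniform dose plane
uniform_plane <- function(value = 10, n = 21, spacing = 1) {
  dose_plane(matrix(value, n, n), spacing_mm = spacing)
}

# pair of slightly different smooth planes for gamma property tests
random_pair <- function(seed, n = 32, spacing = 1.5) {
  ref <- make_random_field_plane(n, spacing, d_max_gy = 10, seed = seed)
  ev <- ref
  set.seed(seed + 10000)
  ev$dose_gy <- ev$dose_gy * (1 + 0.02 * sin(seq_len(n) / 3)) +
    0.1 * make_random_field_plane(n, spacing, d_max_gy = 1,
                                  seed = seed + 20000)$dose_gy
  list(ref = ref, ev = ev)
}

# noiseless small film model with low-dose-friendly response
test_model <- function(...) film_model(...)
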