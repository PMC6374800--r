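# Shared fixtures, generated once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Noiseless left-to-right phantom and its preprocessed form.
noiseless_phantom <- function() {
  cached("noiseless", generate_phantom(phantom_params(seed = 11, noise_sigma = 0)))
}

noiseless_pre <- function() {
  cached("noiseless_pre", preprocess(noiseless_phantom()$image))
}

# Default (noisy) phantom segmented end to end.
default_phantom <- function() {
  cached("default_ph", generate_phantom(phantom_params(seed = 42)))
}

default_segmentation <- function() {
  cached("default_seg", segment_image(default_phantom()$image))
}

# Map a seed set / x0 from the standardized frame back to the phantom's
# canonical frame for comparison with stored truth.
seeds_in_canonical <- function(ss, pre, ph) {
  phantom_to_canonical(std_to_orig(ss$seeds, pre$transform), ph)
}

x0_in_canonical <- function(x0, pre, ph) {
  phantom_to_canonical(std_to_orig(cbind(1, x0), pre$transform), ph)[2]
}
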