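# Shared fixtures: small phantoms and a deterministic toy model, built in
# code at test time.

small_phantom_spec <- function(...) {
  phantom_spec(slice_count_range = c(60, 90), in_plane_size = c(32, 32), ...)
}

# one cached small subject for tests that only need any valid volume
small_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(small_phantom_spec(), 101)
    cache
  }
})

tiny_scorer <- function(input_size = c(16, 16), head_width = 8, seed = 5) {
  scorer_init(scorer_config("tiny2conv", head_width = head_width,
                            input_size = input_size), seed = seed)
}

# strictly increasing synthetic score curve over t slices
linear_curve <- function(t, from = 0, to = 100) seq(from, to, length.out = t)
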