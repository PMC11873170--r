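# Shared tiny fixtures, built once per test run.

local({
  env <- topenv(environment())
  assign("tiny_scene", synth_scene(image_size = 48L, seed = 101L), envir = env)
})

# memoized small dataset so several test files can share it
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_dataset(6L, tiny_scene)
    cache
  }
})

micro_scene <- function(seed = 9L) synth_scene(image_size = 32L, seed = seed)
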