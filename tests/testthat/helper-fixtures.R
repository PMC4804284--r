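# Small in-code fixtures shared across test files.

# a corrected stack wrapping given channel matrices
corrected_stack <- function(nuclear, structural = nuclear, marker = NULL,
                            image_id = "fix") {
  channel_stack(nuclear = nuclear, structural = structural, marker = marker,
                image_id = image_id, corrected = TRUE)
}

# a nucleus record from explicit 0-based pixel coordinates
make_nucleus <- function(pixels, id = 1L, image_id = "fix") {
  list(nucleus_id = id, image_id = image_id, pixels = pixels,
       area = nrow(pixels), centroid = c(row = mean(pixels[, 1]),
                                         col = mean(pixels[, 2])))
}

# compact scene spec for fast multi-image tests; ... overrides defaults
small_scene_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(height = 224, width = 224, n_target_nuclei = 8,
         n_other_nuclei = 18, min_center_separation = 24, seed = seed),
    list(...))
  do.call(scene_spec, args)
}

# cache expensive shared fixtures across test files within one run
.fixture_env <- new.env(parent = emptyenv())
fixture_cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}
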