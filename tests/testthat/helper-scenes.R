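# Shared synthetic scenes. Unit tests use a half-resolution camera
# (540 x 960, ~4 mm/px) to stay fast; full-resolution sequences are reserved
# for the end-to-end acceptance checks.

test_scene_spec <- function(...) {
  scene_spec(image_width = 540, image_height = 960, ...)
}

test_profile <- function(family = "constant", range_m = 0.35,
                         duration_s = 0.5, fps = 120,
                         rest_before_s = 0.2, rest_after_s = 0.2) {
  motion_profile(family, range_m, duration_s, fps,
                 rest_before_s = rest_before_s, rest_after_s = rest_after_s)
}

# one cached default rendered scene, reused by detection/tracking tests
default_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- render_scene(test_scene_spec(camera_tilt_deg = 8),
                             test_profile())
    cache
  }
})

run_test_pipeline <- function(scene, load = NULL, ...) {
  run_pipeline(scene, pipeline_config(scene$geometry, load = load,
                                      focal_px = scene$spec$focal_px, ...))
}
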