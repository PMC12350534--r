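# shared fixtures: built once per test run

rand_tf <- function(trans_range_mm = 100) {
  q <- rnorm(4)
  rigid_transform(depthreg:::quaternion_to_rotation(q / sqrt(sum(q^2))),
                  runif(3, -trans_range_mm, trans_range_mm))
}

small_rot_tf <- function(sigma_rad = 0.3, sigma_mm = 60) {
  rigid_transform(depthreg:::axis_angle_to_rotation(rnorm(3, 0, sigma_rad)),
                  runif(3, -sigma_mm, sigma_mm))
}

# one default phantom scene, reused across files (generation is cheap but
# registration fixtures benefit from identity)
test_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom_head(seed = 1,
                                                        point_spacing_mm = 2.5)
    cache
  }
})

zero_preset <- function(range_max = 2000) {
  camera_noise_preset("zero-noise", 0, range_min_mm = 50,
                      range_max_mm = range_max)
}

default_intrinsics <- function() {
  camera_intrinsics(800, 800, 640, 360, width = 1280, height = 720)
}

trans_err_mm <- function(a, b) sqrt(sum((a$t - b$t)^2))
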