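# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# small anatomy shared across tests (deterministic given the seed)
small_anatomy <- function() {
  if (is.null(fixture_env$anatomy)) {
    cfg <- synth_config(n_patients = 12, n_subjects = 3, n_timepoints = 40,
                        seed = 424242L)
    fixture_env$anatomy_cfg <- cfg
    fixture_env$anatomy <- make_anatomy(cfg)
  }
  list(cfg = fixture_env$anatomy_cfg, anatomy = fixture_env$anatomy)
}

random_volume <- function(dims = c(6, 5, 4), affine = diag(4)) {
  volume3d(array(rnorm(prod(dims)), dims), affine)
}

random_affine <- function() {
  repeat {
    m <- diag(4)
    m[1:3, 1:3] <- matrix(rnorm(9, sd = 0.4), 3) + diag(3)
    m[1:3, 4] <- rnorm(3, sd = 10)
    if (abs(det(m[1:3, 1:3])) > 0.1) return(m)
  }
}
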