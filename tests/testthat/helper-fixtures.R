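# shared fixtures, built once per test session

# compact phantom: 3 disks, mild curvature, fits a small grid
tiny_spec <- function(...) {
  defaults <- list(grid_shape = c(28L, 36L, 80L), n_disks = 3L,
                   cobb_like_angle_deg = 20,
                   disk_semi_axes_mm = c(ap = 8, lr = 9, si = 4))
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

tiny_phantom <- function() fixture("tiny_phantom", function()
  make_spine_phantom(tiny_spec()))

tiny_model <- function() fixture("tiny_model", function()
  train_knn(make_training_regions(tiny_spec(), n_per_class = 15, seed = 3),
            k = 5))
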