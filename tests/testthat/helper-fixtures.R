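# Shared fixtures. Heavy objects are built lazily and cached for the session.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(make)()
  .fixtures[[name]]
}

grid512 <- function() fixture("grid512", function() pupil_grid(512))
grid256 <- function() fixture("grid256", function() pupil_grid(256))
grid64 <- function() fixture("grid64", function() pupil_grid(64))

# dense 1-D reflectance dip oracle, independent of the image estimators
dense_dip <- function(stack, lo = stack$ns + 0.01, hi = stack$na,
                      step = 2e-6) {
  b <- seq(lo, hi, by = step)
  b[which.min(reflectance_spectrum(stack, b))]
}

# the desk-scale study model: 128 px quadrants, 200 training pairs,
# 32 channels, 10 epochs (instance-normalized variant with a step-decay
# schedule; see the methods vignette); trained once per test session
scaled_model <- function() fixture("scaled_model", function() {
  ds <- generate_dataset(223, seed = 77, size_px = 256)  # 200 train + 23 val
  cfg <- can_config(input_size = 128, base_channels = 32,
                    learning_rate = c(rep(2e-3, 6), rep(5e-4, 3), 2e-4),
                    epochs = 10, batch_size = 1, norm = "instance",
                    seed = 78)
  train_can(build_can(cfg), ds)
})
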