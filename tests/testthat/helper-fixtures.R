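# Shared fixtures: small domains and rasters built in code.

square_domain <- function(side = 100) study_domain(width = side, height = side)

# two-class raster split at x = split: class 1 (forest) left, class 2 right
split_raster <- function(domain, split, cell = 1,
                         labels = c("forest", "water")) {
  r <- uniform_raster(domain, cell_size = cell, class_labels = labels,
                      reference = "forest")
  cc <- raster_cell_centers(r)
  r$codes <- matrix(ifelse(cc$x < split, 1L, 2L), r$nx, r$ny)
  r
}

five_class_props <- c(artificial = 0.05, agricultural = 0.10, forest = 0.60,
                      wetland = 0.20, water = 0.05)

true_weights_E <- c(artificial = 0.10, agricultural = 0.10, forest = 1,
                    wetland = 0.50, water = 0.05)

# straight-line trajectories object: one agent per row of (x0, y0, heading),
# n_steps equal steps of length step_len each
straight_trajectories <- function(x0, y0, heading, step_len = 1,
                                  n_steps = 6, group_size = 1,
                                  steps_per_day = 6) {
  n <- length(x0)
  tt <- 0:n_steps
  X <- outer(tt * step_len, cos(heading)) + rep(x0, each = n_steps + 1)
  Y <- outer(tt * step_len, sin(heading)) + rep(y0, each = n_steps + 1)
  structure(list(x = X, y = Y, t_days = tt / steps_per_day,
                 id = seq_len(n),
                 group_size = rep_len(group_size, n),
                 heading_final = heading),
            class = "trajectories")
}
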