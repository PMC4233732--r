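# Shared fixtures: meshes, toy strands, and memoised default-model runs.

# Axis-aligned cube surface mesh with consistent outward winding.
cube_mesh <- function(edge = 10, shift = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(c(0, edge), c(0, edge), c(0, edge)))
  v <- sweep(v, 2, shift, `+`)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
    c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
    c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  list(vertices = v, faces = f)
}

# Latitude/longitude sphere mesh, consistently wound outward.
uv_sphere_mesh <- function(r = 5, n_stack = 32, n_ring = 48) {
  v <- matrix(c(0, 0, r), 1, 3)
  for (i in seq_len(n_stack - 1)) {
    th <- pi * i / n_stack
    for (j in seq_len(n_ring) - 1) {
      ph <- 2 * pi * j / n_ring
      v <- rbind(v, r * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)))
    }
  }
  v <- rbind(v, c(0, 0, -r))
  idx <- function(i, j) 1 + (i - 1) * n_ring + (j %% n_ring) + 1
  f <- NULL
  for (j in seq_len(n_ring) - 1) f <- rbind(f, c(1, idx(1, j), idx(1, j + 1)))
  for (i in seq_len(n_stack - 2)) {
    for (j in seq_len(n_ring) - 1) {
      a <- idx(i, j); b <- idx(i, j + 1)
      cc <- idx(i + 1, j); d <- idx(i + 1, j + 1)
      f <- rbind(f, c(a, cc, d), c(a, d, b))
    }
  }
  bot <- nrow(v)
  for (j in seq_len(n_ring) - 1) {
    f <- rbind(f, c(bot, idx(n_stack - 1, j + 1), idx(n_stack - 1, j)))
  }
  list(vertices = v, faces = f)
}

# Minimal model stub carrying just the fields strand/pose functions use.
toy_model_stub <- function(condyle_halfwidth = 14) {
  list(
    condyle_right = c(0, -condyle_halfwidth, 0),
    condyle_left = c(0, condyle_halfwidth, 0),
    fossa_normal_right = c(0, 0, -1),
    fossa_normal_left = c(0, 0, -1)
  )
}

toy_strand <- function(path, frames, share = 10) {
  structure(list(
    muscle = "superficial_masseter", side = "right", index_within = 1L,
    path = path, frames = frames, max_force_share = share,
    rest_length = masticate:::polyline_length(path), is_closer = TRUE
  ), class = "muscle_strand")
}

# Memoised default model and mode runs (shared across test files).
.sim_cache <- new.env(parent = emptyenv())

default_model <- function() {
  if (is.null(.sim_cache$model)) .sim_cache$model <- build_jaw_model()
  .sim_cache$model
}

default_sim <- function(mode) {
  key <- paste0("sim_", mode)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- run_mode(mode, model = default_model())
  }
  .sim_cache[[key]]
}
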