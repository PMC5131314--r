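# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small demo scene (follicles + vessels + egg nest), with noise and blur
demo_build <- function() cached("demo", function() build_phantom(demo_phantom_spec(seed = 7)))

demo_measured <- function() {
  cached("demo_measured", function() measure_stack(demo_build()$stack))
}

# single noiseless spherical-shell follicle: outer d = 1 mm, wall 100 um
shell_build <- function() {
  cached("shell", function() {
    spec <- phantom_spec(
      c(80L, 300L, 300L),
      list(follicle_phantom(c(640, 600, 600), c(500, 500, 500),
                            theca_thickness_base = 100,
                            gap_width = 15, granulosa_width = 25)),
      seed = 5L
    )
    build_phantom(spec, blur = FALSE, noise = FALSE)
  })
}

shell_masks <- function() {
  cached("shell_masks", function() {
    b <- shell_build()
    lv <- ingest_manual_masks(b$truth$labels, b$stack)
    extract_shell_masks(b$stack, lv, 1L)
  })
}

# brute-force oracles ---------------------------------------------------

# all-pairs nearest squared distance (physical units), same arithmetic as
# the optimized search but a plain double loop
brute_nearest_sq <- function(outer, inner, dy, dx) {
  apply(outer, 1, function(p) {
    min((dy * (p[1] - inner[, 1]))^2 + (dx * (p[2] - inner[, 2]))^2)
  })
}

# per-pixel loop MIP
brute_mip <- function(v, axis) {
  d <- dim(v)
  rest <- setdiff(1:3, axis)
  out <- matrix(-Inf, d[rest[1]], d[rest[2]])
  for (k in seq_len(d[axis])) {
    sl <- switch(axis, v[k, , ], v[, k, ], v[, , k])
    out <- pmax(out, sl)
  }
  out
}

rand_stack <- function(shape = c(6, 10, 8), seed = 1, spacing = c(16, 4, 4)) {
  set.seed(seed)
  image_stack(array(runif(prod(shape)), shape), spacing)
}
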