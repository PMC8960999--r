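# Shared fixtures, built once per test run.

# canonical phantom: zero jitter, zero angular dispersion (deterministic paths)
canonical_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_phantom(
        phantom_config(jitter_sd = c(0, 0, 0), dispersion_deg = 0), seed = 1)
    cache
  }
})

# canonical phantom with the default 8-degree dispersion
dispersed_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_phantom(phantom_config(jitter_sd = c(0, 0, 0)), seed = 1)
    cache
  }
})

# a cached left-DTCp reconstruction on the dispersed phantom
cached_dtcp <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(99)
      cache <<- track_pathway(dispersed_phantom(), "L", tracking_params())
    }
    cache
  }
})

# uniform single-population field: direction `dir` everywhere
uniform_field <- function(dims = c(21L, 21L, 21L), dir = c(0, 0, 1),
                          frac = 0.5, disp = 0, voxel_size = 1) {
  grid <- volume_grid(dims, voxel_size = voxel_size)
  dir <- dir / sqrt(sum(dir^2))
  dirs <- array(0, c(dims, 3L, 1L))
  for (a in 1:3) dirs[, , , a, 1] <- dir[a]
  fibre_field(grid, dirs,
              array(frac, c(dims, 1L)), array(disp, c(dims, 1L)))
}

# axis-aligned box mask in voxel index space (1-based inclusive ranges)
voxel_box <- function(dims, i = NULL, j = NULL, k = NULL) {
  m <- array(FALSE, dims)
  i <- i %||% c(1L, dims[1]); j <- j %||% c(1L, dims[2])
  k <- k %||% c(1L, dims[3])
  m[i[1]:i[2], j[1]:j[2], k[1]:k[2]] <- TRUE
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force 26-connected component labelling oracle (O(n^2) union-find)
brute_components <- function(roi) {
  coords <- arrayInd(which(roi), dim(roi))
  n <- nrow(coords)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      if (all(abs(coords[a, ] - coords[b, ]) <= 1)) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}
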