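# Small deterministic fixtures used across the tests.

# a unit tetrahedron as an indexed mesh
tetrahedron_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  triangle_mesh(v, f)
}

# write a binary STL facet soup by hand (no package code involved)
write_binary_stl_soup <- function(facets, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(length(facets)), con, size = 4, endian = "little")
  for (fc in facets) {
    writeBin(as.numeric(c(0, 0, 0, t(fc))), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}

# a quick random small arch shared by several tests
small_arch <- local({
  cache <- new.env()
  function(target_faces = 300, seed = 2) {
    key <- paste(target_faces, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_arch(arch_params(target_faces = target_faces,
                                                seed = seed))
    cache[[key]]
  }
})

# tiny network configuration that keeps unit tests fast
tiny_config <- function(seed = 11L, ...) {
  network_config(K_small = 2L, K_large = 6L, mgfl_dims = c(8L, 12L),
                 head_dims = c(10L, 8L), C = 15L, dropout = 0, seed = seed,
                 ...)
}

random_unit_normals <- function(n, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * 3), n, 3)
  x / sqrt(rowSums(x^2))
}
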