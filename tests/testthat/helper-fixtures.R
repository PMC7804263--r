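# Shared fixtures, all generated in code.

# small scene for fast end-to-end unit tests (not the acceptance scene)
small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- generate_scene_truth(shape = c(96, 96), pixel_size = 0.25,
                                    seed = 7, n_patches = 10)
      cache <<- list(
        truth = truth,
        ortho = render_orthomosaic(truth, optics_params(), seed = 8),
        ortho0 = render_orthomosaic(truth,
                                    optics_params(texture_sd = 0,
                                                  sensor_noise_sd = 0),
                                    seed = 8),
        dsm0 = generate_dsm(truth, 0, seed = 9))
    }
    cache
  }
})

# tiny community matrix with a planted 2-group structure
toy_community <- function(n_per_group = 3, seed = 1) {
  set.seed(seed)
  g1 <- matrix(rep(c(60, 30, 10, 0), each = n_per_group), n_per_group) +
    matrix(runif(n_per_group * 4, 0, 2), n_per_group)
  g2 <- matrix(rep(c(0, 10, 30, 60), each = n_per_group), n_per_group) +
    matrix(runif(n_per_group * 4, 0, 2), n_per_group)
  m <- rbind(g1, g2)
  m <- 100 * sweep(m, 1, rowSums(m), "/")
  rownames(m) <- paste0("u", seq_len(nrow(m)))
  colnames(m) <- paste0("t", seq_len(ncol(m)))
  community_matrix(m, transform = "pruned_standardized")
}

# brute-force Bray-Curtis similarity (independent oracle)
bray_oracle <- function(m) {
  n <- nrow(m)
  s <- matrix(100, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k) next
    num <- 0
    den <- 0
    for (i in seq_len(ncol(m))) {
      num <- num + min(m[j, i], m[k, i])
      den <- den + m[j, i] + m[k, i]
    }
    s[j, k] <- if (den > 0) 100 * 2 * num / den else 0
  }
  dimnames(s) <- list(rownames(m), rownames(m))
  s
}
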