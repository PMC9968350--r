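# shared builders for small synthetic fixtures; everything is generated in
# code at test time

small_grid <- function(shape = c(16L, 16L, 16L), vs = 2, kind = "full_cube") {
  gen_brain_grid(toy_brain_spec(shape, vs, kind))
}

# constant-value effect-size map on a grid (for hand-checkable combination)
const_map <- function(g, var_g, grid, study_id = "s") {
  V <- sum(grid$mask)
  structure(list(g = rep(g, V), var_g = rep(var_g, V), grid = grid,
                 study_id = study_id),
            class = "effect_size_map")
}

# a meta_result built directly from a z vector (for clustering tests)
meta_from_z <- function(z, grid) {
  V <- sum(grid$mask)
  stopifnot(length(z) == V)
  structure(list(g = z, se = rep(1, V), z = z, p = z_to_p(z),
                 tau2 = rep(0, V), Q = rep(0, V), I2 = rep(0, V),
                 grid = grid, k = 2L),
            class = "meta_result")
}

# default truth with two planted clusters inside a centred mask
demo_truth <- function(n_genes = 60L, n_true = 10L, target_r = 0.6,
                       lambda = 15) {
  synthetic_truth(sprintf("g%04d", seq_len(n_true)), target_r,
                  pooled_effect = c(0.8, -0.8),
                  cluster_centers_mm = rbind(c(-6, 0, 0), c(6, 2, 2)),
                  autocorr_length_mm = lambda)
}

# a smooth target map on a grid (deterministic given seed)
smooth_target <- function(grid, seed = 7) {
  set.seed(seed)
  assets <- gen_annotation_assets(c("a", "b"), n_sets = 1, edge_density = 0.5,
                                  n_terms = 1, grid = grid, seed = seed)
  assets$term_maps[[1]]
}
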