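# Shared fixtures: tiny configs and hand-built volumes.

tiny_config <- function(...) {
  sim_config(grid_shape = c(32, 32, 32), voxel_size_mm = 2, ...)
}

# volume on an identity-scaled centered grid
toy_volume <- function(data, voxel = 2) {
  gm_volume(data, sim_affine(dim(data), voxel))
}

# deterministic small cohort for design/GLM tests
toy_cohort <- function(n = 12, seed = 42) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    group = rep(c("patient", "control"), length.out = n),
    age = round(runif(n, 60, 85), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    icv_mm3 = round(rnorm(n, 1.4e6, 1e5)))
}

# complete 30-row score record for one subject from a 6x5 matrix
records_from_matrix <- function(m, subject = "S1") {
  stopifnot(identical(dim(m), c(6L, 5L)))
  data.frame(subject_id = subject,
             cue = rep(1:6, times = 5), period = rep(1:5, each = 6),
             score = as.vector(m))
}

# independent connected-components oracle over the voxel adjacency graph
igraph_components <- function(supra_array, connectivity = 18) {
  d <- dim(supra_array)
  idx <- which(supra_array)
  id_of <- array(0L, dim = d)
  id_of[idx] <- seq_along(idx)
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  nz <- rowSums(offs != 0)
  offs <- offs[nz >= 1 & nz <= ifelse(connectivity == 18, 2, 3) &
                 nz >= ifelse(connectivity == 6, 1, 1), , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(offs != 0) == 1, , drop = FALSE]
  ai <- arrayInd(idx, d)
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(ai, 2, as.numeric(offs[r, ]), `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    tgt <- id_of[lin]
    src <- seq_along(idx)[ok]
    keep <- tgt > 0
    edges[[r]] <- cbind(src[keep], tgt[keep])
  }
  e <- do.call(rbind, edges)
  if (is.null(e) || nrow(e) == 0) {
    out <- array(0L, dim = d)
    out[idx] <- seq_along(idx)
    return(out)
  }
  g <- igraph::graph_from_edgelist(unique(t(apply(e, 1, sort))),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  out <- array(0L, dim = d)
  out[idx] <- memb
  out
}
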