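# Shared oracles and fixtures for the test suite. Growth runs are expensive,
# so the sensitivity-grid runs are computed once per session (memoised) at a
# coarse desk resolution and shared across test files.

# Closed-form interface pressure of a thermally expanded solid sphere
# (E1, nu1, stress-free strain a) inside a shell R1..R2 (E2, nu2):
# continuity of radial displacement at the interface.
lame_interface_pressure <- function(a, E1, nu1, E2, nu2, R1, R2) {
  C <- ((1 - 2 * nu2) * R1^3 + (1 + nu2) * R2^3 / 2) / (R2^3 - R1^3)
  a / ((1 - 2 * nu1) / E1 + C / E2)
}

# Independent 1-D bilateral front oracle: element centroids x in (0, w) of a
# strip flanked by bone at x <= 0 and x >= w; the front advances at `rate`
# from both margins. Returns the time at which the last element converts.
front_closure_time <- function(centroids, w, rate) {
  max(pmin(centroids, w - centroids)) / rate
}

# Independent strain of an affine displacement on a single tetrahedron:
# fit u = c + G x by solving the 4x4 system, then symmetrise G.
affine_strain_oracle <- function(X, U) {
  A <- cbind(1, X)
  G <- t(solve(A, U))[, 2:4]   # du_i/dx_j
  (G + t(G)) / 2
}

# Numerical-Hessian element stiffness oracle for a single linear tetrahedron:
# second derivatives of the exact elastic energy of the affine displacement
# field (constant strain) by central differences.
tet_stiffness_oracle <- function(X, E, nu, h = 1e-6) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  V <- abs(det(cbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ]))) / 6
  energy <- function(uvec) {
    U <- matrix(uvec, 4, 3, byrow = TRUE)
    eps <- affine_strain_oracle(X, U)
    V * (lam / 2 * sum(diag(eps))^2 + mu * sum(eps * eps))
  }
  K <- matrix(0, 12, 12)
  for (i in 1:12) for (j in i:12) {
    ei <- numeric(12); ei[i] <- h
    ej <- numeric(12); ej[j] <- h
    K[i, j] <- K[j, i] <-
      (energy(ei + ej) - energy(ei - ej) - energy(ej - ei) +
         energy(-ei - ej)) / (4 * h^2)
  }
  K
}

# A single positively oriented tetrahedron mesh with the given region label.
single_tet_mesh <- function(region = "solid", edge = 1) {
  nodes <- rbind(c(0, 0, 0), c(edge, 0, 0), c(0, edge, 0), c(0, 0, edge))
  labeled_mesh(nodes, matrix(1:4, 1), region)
}

# 1-D slab fixture: bone | suture | bone along x, fine in x only.
slab_mesh <- function(w = 4, bone = 6, nx_sut = 8, nx_bone = 3) {
  hx_s <- w / nx_sut
  hx_b <- bone / nx_bone
  xs <- c(seq(-bone, 0, by = hx_b), seq(hx_s, w, by = hx_s),
          seq(w + hx_b, w + bone, by = hx_b))
  # build as a box then relabel by centroid
  m <- box_mesh(c(2 * bone + w, 4, 4), c(length(xs) - 1, 2, 2),
                origin = c(-bone, 0, 0))
  # snap x-planes to the graded grid
  xi <- sort(unique(round(m$nodes[, 1], 9)))
  m$nodes[, 1] <- xs[match(round(m$nodes[, 1], 9), xi)]
  cen <- element_centroids(m)
  m$region <- ifelse(cen[, 1] > 0 & cen[, 1] < w, "coronal", "frontal")
  m
}

# ---- memoised coarse growth runs of the builtin sensitivity grid ----------

.run_cache <- new.env(parent = emptyenv())

# coarse desk resolution used throughout the suite
test_configs <- function() {
  builtin_configs(mesh_size = 16, n_brain_layers = 2L, n_sub = 3L, seed = 0L)
}

cached_run <- function(name) {
  if (!is.null(.run_cache[[name]])) return(.run_cache[[name]])
  cfg <- test_configs()[[name]]
  if (is.null(cfg)) stop("unknown builtin config: ", name)
  bundle <- suppressWarnings(run_experiment(cfg))
  .run_cache[[name]] <- bundle
  bundle
}

all_builtin_names <- function() names(test_configs())
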