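# Linear-elastic core: assembly, thermal-analogy loading, strains,
# constraints, and the penalty contact solver on small fixtures.

test_that("patch test: affine boundary data reproduces the affine field", {
  mats <- material_card()
  Aff <- matrix(c(0.01, 0.002, 0.001, 0.003, -0.004, 0.002,
                  0.001, 0.005, -0.002), 3, 3)
  for (order in 1:2) {
    m <- box_mesh(c(2, 1, 1), c(3, 2, 2))
    if (order == 2) m <- as_tet10(m)
    uex <- m$nodes %*% t(Aff)
    on_bnd <- m$nodes[, 1] %in% c(0, 2) | m$nodes[, 2] %in% c(0, 1) |
      m$nodes[, 3] %in% c(0, 1)
    asm <- fe_assemble(m, mats)
    fd <- calvaria:::.node_dofs(which(on_bnd))
    u <- calvaria:::.solve_dirichlet(asm$K, asm$f, fd,
                                     as.vector(t(uex[on_bnd, ])))
    err <- max(abs(matrix(u, ncol = 3, byrow = TRUE) - uex)) / max(abs(uex))
    expect_lt(err, 1e-8)
  }
})

test_that("stiffness has translational and rotational zero-energy modes", {
  m <- box_mesh(c(1, 2, 1), c(2, 2, 2))
  asm <- fe_assemble(m, material_card())
  n <- nrow(m$nodes)
  tr <- rep(c(1, 0, 0), n)
  rot <- as.vector(t(cbind(-m$nodes[, 2], m$nodes[, 1], 0)))
  scale <- max(abs(asm$K))
  expect_lt(max(abs(asm$K %*% tr)) / scale, 1e-10)
  expect_lt(max(abs(asm$K %*% rot)) / scale, 1e-10)
})

test_that("assembled element stiffness matches the numerical-Hessian oracle", {
  set.seed(42)
  for (k in 1:3) {
    X <- matrix(rnorm(12), 4, 3)
    # keep positive volume and decent shape
    if (det(cbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ])) < 0.05)
      X[4, ] <- X[4, ] + c(0, 0, 2)
    m <- labeled_mesh(X, matrix(1:4, 1), "solid")
    E <- 3000; nu <- 0.3
    asm <- fe_assemble(m, material_card(bone = c(E, nu)))
    Kor <- tet_stiffness_oracle(X, E, nu)
    expect_equal(as.matrix(asm$K), Kor, tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
})

test_that("zero growth strain gives zero displacement", {
  m <- box_mesh(c(1, 1, 1), c(2, 2, 2))
  st <- solve_increment(m, material_card(), 0, constraints = integer(0))
  expect_lt(max(abs(st$u)), 1e-10)
})

test_that("free growth of a solid equals uniform expansion exactly", {
  m <- box_mesh(c(2, 1, 1), c(3, 2, 2), region = "brain_block")
  alpha <- 0.05
  st <- solve_increment(m, material_card(), alpha, constraints = integer(0))
  sr <- compute_strains(m, st$u)
  expect_equal(range(sr$eh), c(alpha, alpha), tolerance = 1e-7)
})

test_that("uniaxial bar: tip strain t/E, energy equals half external work", {
  E <- 100; nu <- 0.3; t_ap <- 2
  m <- box_mesh(c(10, 2, 2), c(5, 2, 2), region = "brain_bar")
  asm <- fe_assemble(m, material_card(brain = c(E, nu)))
  left <- which(m$nodes[, 1] == 0)
  # x-dof fixed on the left face; minimal transverse anchors
  fd <- c(3 * (left - 1) + 1,
          calvaria:::.node_dofs(which(m$nodes[, 1] == 0 & m$nodes[, 2] == 0 &
                                        m$nodes[, 3] == 0))[2:3],
          (3 * (which(m$nodes[, 1] == 0 & m$nodes[, 2] == 2 &
                        m$nodes[, 3] == 0) - 1) + 3))
  # consistent nodal loads on the right face from its triangulation
  f <- numeric(3 * nrow(m$nodes))
  bf <- boundary_faces(m)
  on_right <- matrix(m$nodes[t(bf), 1] == 10, ncol = 3, byrow = TRUE)
  tris <- bf[rowSums(on_right) == 3, , drop = FALSE]
  for (r in seq_len(nrow(tris))) {
    p <- m$nodes[tris[r, ], ]
    area <- 0.5 * sqrt(sum(calvaria:::.cross3(p[2, ] - p[1, ],
                                              p[3, ] - p[1, ])^2))
    f[3 * (tris[r, ] - 1) + 1] <- f[3 * (tris[r, ] - 1) + 1] +
      t_ap * area / 3
  }
  u <- calvaria:::.solve_dirichlet(asm$K, f, fd)
  sr <- compute_strains(m, u)
  expect_equal(unname(range(sr$eps[, "xx"])), rep(t_ap / E, 2),
               tolerance = 1e-8)
  # energy consistency: strain energy = half the external work
  W_ext <- sum(f * u)
  W_int <- as.numeric(u %*% (asm$K %*% u))
  expect_equal(W_int, W_ext, tolerance = 1e-6)
})

test_that("hydrostatic strain equals the affine-fit oracle on one tet", {
  set.seed(7)
  m <- single_tet_mesh()
  U <- matrix(rnorm(12, sd = 0.01), 4, 3)
  sr <- compute_strains(m, as.vector(t(U)))
  eps_or <- affine_strain_oracle(m$nodes, U)
  expect_equal(sr$eh, sum(diag(eps_or)) / 3, tolerance = 1e-6)
  expect_equal(unname(sr$eps[1, c("xx", "yy", "zz")]),
               unname(diag(eps_or)), tolerance = 1e-9)
})

test_that("missing material labels are reported by name", {
  m <- single_tet_mesh(region = "mystery_tissue")
  mats <- material_card()
  # unknown labels fall back to bone class; force a real failure instead
  mats$bone <- NULL
  expect_error(fe_assemble(m, mats), "bone|material")
})

test_that("open gap transmits no contact pressure", {
  bs <- ball_shell_mesh(40, 45, n_theta = 9, n_phi = 12, n_radial = 2)
  bs$region[bs$region == "core"] <- "brain_core"
  # shrink the ball to open a uniform 2 mm gap
  ball_nodes <- seq_len(max(bs$contact$slave_nodes))
  bs$nodes[ball_nodes, ] <- bs$nodes[ball_nodes, ] * (38 / 40)
  st <- solve_increment(bs, material_card(), 0.001,
                        constraints = integer(0), contact = contact_spec())
  expect_true(all(st$contact$pressure == 0))
})

test_that("frictionless expansion leaves tangential tractions near zero", {
  bs <- ball_shell_mesh(40, 44, n_theta = 13, n_phi = 16, n_radial = 3)
  bs$region[bs$region == "core"] <- "brain_core"
  st <- solve_increment(bs, material_card(brain = c(100, 0.3)),
                        ifelse(region_class(bs$region) == "brain", 0.01, 0),
                        constraints = integer(0),
                        contact = contact_spec(friction = 0))
  expect_lt(max(st$contact$tangential), 0.02 * mean(st$contact$pressure))
})

test_that("contact pressure map equals stiffness times penetration", {
  bs <- ball_shell_mesh(40, 44, n_theta = 9, n_phi = 12, n_radial = 2)
  bs$region[bs$region == "core"] <- "brain_core"
  st <- solve_increment(bs, material_card(brain = c(100, 0.3)),
                        ifelse(region_class(bs$region) == "brain", 0.01, 0),
                        constraints = integer(0), contact = contact_spec())
  act <- st$contact$pressure > 0
  expect_true(any(act))
  # smooth unilateral law: pressure is the law value at the penetration
  law <- calvaria:::.contact_law(st$contact$penetration,
                                 st$contact$kn_pair, st$contact$law_width)
  expect_equal(st$contact$pressure[act], law$p[act], tolerance = 1e-9)
  fp <- extract_contact_pressure(st, bs)
  expect_equal(nrow(fp), nrow(bs$contact$slave_tris))
  expect_true(all(fp$pressure >= 0))
  expect_error(extract_contact_pressure(list(contact = NULL), bs),
               "unsolved|no contact")
})

test_that("mesh refinement changes the sphere-in-shell solution by little", {
  mats <- material_card(brain = c(100, 0.3))
  sol <- function(nt, np, nr) {
    bs <- ball_shell_mesh(50, 55, n_theta = nt, n_phi = np, n_radial = nr)
    bs$region[bs$region == "core"] <- "brain_core"
    st <- solve_increment(bs, mats,
                          ifelse(region_class(bs$region) == "brain", 0.01, 0),
                          constraints = integer(0), contact = contact_spec())
    mean(st$contact$pressure)
  }
  p1 <- sol(13, 16, 3)
  p2 <- sol(17, 24, 4)
  expect_lt(abs(p2 - p1) / p2, 0.05)
})
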