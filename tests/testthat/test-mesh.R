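# Mesh container, structured builders and geometric utilities.

test_that("structured box mesh has exact volume and conforming faces", {
  m <- box_mesh(c(2, 3, 4), c(3, 2, 2))
  expect_equal(sum(tet_volumes(m)), 24, tolerance = 1e-12)
  expect_silent(check_conforming(m))
  expect_true(all(tet_volumes(m) > 0))
})

test_that("ball-in-shell mesh is conforming with near-analytic volumes", {
  bs <- ball_shell_mesh(50, 55, n_theta = 25, n_phi = 32, n_radial = 4)
  expect_silent(check_conforming(bs))
  v_core <- sum(tet_volumes(bs)[bs$region == "core"])
  v_shell <- sum(tet_volumes(bs)[bs$region == "shell"])
  # polyhedral approximation underestimates slightly at this resolution
  expect_equal(v_core, 4 / 3 * pi * 50^3, tolerance = 0.02)
  expect_equal(v_shell, 4 / 3 * pi * (55^3 - 50^3), tolerance = 0.02)
})

test_that("mesh scaling multiplies volumes by s^3", {
  for (s in c(0.5, 2)) {
    a <- ball_shell_mesh(30, 33, n_theta = 9, n_phi = 12, n_radial = 2)
    b <- ball_shell_mesh(30 * s, 33 * s, n_theta = 9, n_phi = 12,
                         n_radial = 2)
    expect_equal(sum(tet_volumes(b)) / sum(tet_volumes(a)), s^3,
                 tolerance = 1e-9)
  }
})

test_that("mirror symmetry of structured meshes is tight", {
  bs <- ball_shell_mesh(40, 44, n_theta = 13, n_phi = 16, n_radial = 3)
  expect_lt(mirror_symmetry_error(bs), 1e-4)
})

test_that("labeled_mesh validates its inputs", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_error(labeled_mesh(nodes, matrix(c(1, 2, 3, 5), 1), "a"),
               "outside")
  expect_error(labeled_mesh(nodes, matrix(1:4, 1), c("a", "b")))
})

test_that("boundary extraction finds exactly the outer faces of a box", {
  m <- box_mesh(c(1, 1, 1), c(2, 2, 2))
  bf <- boundary_faces(m)
  # each cube face: 4 cells x 2 triangles
  expect_equal(nrow(bf), 6 * 4 * 2)
})
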