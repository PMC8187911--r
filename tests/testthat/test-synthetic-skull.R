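# Parametric skull generator: volumes, labels, craniotomies, landmarks.

coarse_params <- function(...) {
  skull_params(mesh_size = 16, n_brain_layers = 2L, ...)
}

test_that("generated skull hits the target intracranial volume", {
  m <- generate_calvaria(coarse_params())
  expect_equal(icv_volume(m), 659, tolerance = 0.01)
  expect_silent(check_conforming(m))
  # spread of required labels
  expect_true(all(c("frontal", "parietal_L", "parietal_R", "occipital",
                    "temporal_L", "temporal_R", "craniofacial",
                    "metopic", "coronal", "lambdoid", "squamosal",
                    "anterior_fontanelle", "reinserted_bone") %in% m$region))
  expect_true(any(startsWith(m$region, "craniotomy")))
  expect_true(all(c("brain_frontal", "brain_parietal", "brain_temporal",
                    "brain_occipital", "cerebellum") %in% m$region))
  expect_false("csf" %in% m$region)   # CSF-absent default
  expect_true(all(c("foramen_magnum_ring", "nasion") %in%
                    names(m$node_sets)))
})

test_that("a CSF layer appears only when requested", {
  m <- generate_calvaria(coarse_params(csf_thickness = 2.5))
  expect_true("csf" %in% m$region)
  # the CSF belongs to the ICV: brain + csf still matches the target
  expect_equal(icv_volume(m), 659, tolerance = 0.01)
})

test_that("mirror symmetry of the generated skull is within mesh_size/10", {
  p <- coarse_params()
  m <- generate_calvaria(p)
  expect_lt(mirror_symmetry_error(m), p$mesh_size / 10)
})

test_that("parameter validation rejects degenerate inputs", {
  expect_error(skull_params(icv_target_volume = -1), "positive")
  expect_error(skull_params(csf_thickness = 5), "0, 3")
  expect_error(craniotomy_spec(parietal_cut_width = 50), "30, 40")
  expect_error(craniotomy_spec(kerf_gap = 0), "positive")
  # kerf too wide for the parietal span: error names the achievable maximum
  expect_error(generate_calvaria(coarse_params(
    craniotomy_spec = craniotomy_spec(kerf_gap = 35))), "maximum")
})

test_that("craniotomies relabel without changing geometry", {
  p <- coarse_params(craniotomy_spec = NULL)
  m0 <- generate_calvaria(p)
  expect_false(any(startsWith(m0$region, "craniotomy")))
  expect_true(any(m0$region == "sagittal_fused"))
  v0 <- sum(tet_volumes(m0))
  bone0 <- sum(tet_volumes(m0)[region_class(m0$region) == "bone"])
  m1 <- apply_craniotomies(m0, craniotomy_spec())
  # volume bookkeeping: total conserved exactly, bone down, craniotomy up
  expect_equal(sum(tet_volumes(m1)), v0, tolerance = 1e-12)
  bone1 <- sum(tet_volumes(m1)[region_class(m1$region) == "bone"])
  cran1 <- sum(tet_volumes(m1)[region_class(m1$region) == "craniotomy"])
  expect_lt(bone1, bone0)
  expect_gt(cran1, 0)
  # pattern: kerf gaps on both sides plus reinserted bone
  expect_true(any(m1$region == "craniotomy_strip_L"))
  expect_true(any(m1$region == "craniotomy_strip_R"))
  expect_true(any(m1$region == "reinserted_bone"))
  expect_true(all(c("craniotomy_kerf_anterior", "craniotomy_kerf_middle",
                    "craniotomy_kerf_posterior") %in% m1$region))
})

test_that("landmarks sit symmetrically and are all placed", {
  m <- generate_calvaria(coarse_params())
  lm <- m$landmarks
  expect_setequal(names(lm), c("glabella", "opisthocranion", "euryon_L",
                               "euryon_R", "bregma", "basion"))
  expect_equal(abs(m$nodes[lm["euryon_L"], 2]),
               abs(m$nodes[lm["euryon_R"], 2]),
               tolerance = coarse_params()$mesh_size / 10)
  expect_gt(m$nodes[lm["glabella"], 1], 0)
  expect_lt(m$nodes[lm["opisthocranion"], 1], 0)
})

test_that("landmarks on a sphere give equal length and width", {
  bs <- ball_shell_mesh(40, 44, n_theta = 17, n_phi = 24, n_radial = 2)
  bs <- place_landmarks(bs)
  r <- measure(bs)
  expect_equal(r$length, 2 * 44, tolerance = 0.01)
  expect_equal(r$width, 2 * 44, tolerance = 0.01)
  expect_equal(r$cephalic_index, 100, tolerance = 0.01)
})

test_that("generation is deterministic for a fixed seed", {
  m1 <- generate_calvaria(coarse_params(seed = 3L, jitter = 0.2))
  m2 <- generate_calvaria(coarse_params(seed = 3L, jitter = 0.2))
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$region, m2$region)
})
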