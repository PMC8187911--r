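# Growth schedule, volume-age mapping, and the two formation algorithms.

test_that("equal-ratio schedule matches the closed-form expansion", {
  s <- build_schedule(659, 1245, 6)
  ratio <- (1245 / 659)^(1 / 6)
  expect_equal(s$alpha, rep(ratio^(1 / 3) - 1, 6), tolerance = 1e-12)
  total_linear <- prod(1 + s$alpha) - 1
  expect_equal(total_linear, (1245 / 659)^(1 / 3) - 1, tolerance = 1e-12)
  # about 24% of linear growth over the six years
  expect_equal(total_linear, 0.236, tolerance = 5e-3)
  expect_equal(prod(1 + s$alpha)^3, 1245 / 659, tolerance = 1e-9)
})

test_that("volume x8 over one interval means linear strain 1", {
  s <- build_schedule(100, 800, 1)
  expect_equal(s$alpha, 1, tolerance = 1e-12)
})

test_that("degenerate schedules are rejected", {
  expect_error(build_schedule(659, 659, 6), "v_pre < v_follow")
  expect_error(build_schedule(659, 100, 6), "v_pre < v_follow")
  bad <- data.frame(volume_ml = c(659, 600, 1245), age_months = c(4, 10, 76))
  expect_error(build_schedule(659, 1245, 6, curve = bad), "increasing")
})

test_that("schedule end ages follow the volume-age curve", {
  s <- build_schedule()
  expect_equal(s$start_age, 4)
  expect_equal(s$end_age, 76)
  expect_true(all(diff(s$ages) > 0))
})

test_that("formation rule validates and resolves per-region rates", {
  r <- formation_rule(rates = c(suture = 0.2, metopic = 0.6))
  expect_equal(unname(r$rates["craniotomy"]), 0.8)   # class default kept
  rates <- calvaria:::.formation_rates(
    c("metopic", "coronal", "craniotomy_kerf_middle", "frontal"), r)
  expect_equal(rates, c(0.6, 0.2, 0.8, 0))
  expect_error(formation_rule(rates = c(suture = -1)), ">= 0")
  expect_error(formation_rule(strain_window = c(1, 0)), "low <= high")
})

test_that("single formation step converts by distance and strain gate", {
  m <- slab_mesh(w = 4, bone = 6, nx_sut = 8)
  rule <- formation_rule(rates = c(suture = 0.5, craniotomy = 0.8))
  cen <- element_centroids(m)
  # everything in window: only elements within rate*months of the margins
  eh <- rep(0.1, nrow(m$elems))
  m1 <- gradual_formation_step(m, eh, rule, months = 1)
  conv <- m1$ossified
  d_margin <- pmin(pmax(cen[, 1], 0), pmax(4 - cen[, 1], 0))
  in_sut <- m$region == "coronal"
  expect_true(all(conv[in_sut & d_margin <= 0.5 - 1e-9]))
  expect_false(any(conv[in_sut & d_margin > 0.5 + 1e-9]))
  expect_false(any(conv[!in_sut]))
  # strain outside the window blocks conversion regardless of distance
  eh_hot <- rep(0.9, nrow(m$elems))
  m2 <- gradual_formation_step(m, eh_hot, rule, months = 1)
  expect_false(any(m2$ossified))
  # a null window plus any nonzero strain converts nothing
  rule0 <- formation_rule(rates = c(suture = 0.5), strain_window = c(0, 0))
  m3 <- gradual_formation_step(m, eh, rule0, months = 100)
  expect_false(any(m3$ossified))
})

test_that("ossification is monotone under repeated stepping", {
  m <- slab_mesh(w = 4, bone = 6, nx_sut = 8)
  rule <- formation_rule(rates = c(suture = 0.3))
  eh <- rep(0.05, nrow(m$elems))
  prev <- 0L
  for (k in 1:6) {
    m <- gradual_formation_step(m, eh, rule, months = 1)
    expect_gte(sum(m$ossified), prev)
    prev <- sum(m$ossified)
  }
})

test_that("slab closure time matches the bilateral 1-D front oracle", {
  w <- 4; rate <- 0.25
  m <- slab_mesh(w = w, bone = 6, nx_sut = 8)
  rule <- formation_rule(rates = c(suture = rate))
  eh <- rep(0.1, nrow(m$elems))
  front0 <- calvaria:::.formation_front(m)
  rate_el <- calvaria:::.formation_rates(m$region, rule)
  cen <- element_centroids(m)
  in_sut <- m$region == "coronal"
  t_or <- front_closure_time(cen[in_sut, 1], w, rate)
  dt <- 0.25
  closure <- NA
  for (t in seq(dt, 20, by = dt)) {
    m <- gradual_formation_step(m, eh, rule, NULL, front_faces = front0,
                                radius = rate_el * t)
    if (all(m$ossified[in_sut])) { closure <- t; break }
  }
  expect_false(is.na(closure))
  expect_equal(closure, t_or, tolerance = dt / t_or + 1e-9)
})

test_that("bulk ramp runs from baseline to bone stiffness", {
  mats <- material_card()
  rule <- formation_rule(scenario = "bulk")
  m1 <- bulk_formation_step(mats, rule, 1, 6)
  expect_equal(m1$suture[1], 30)        # first interval at baseline
  m6 <- bulk_formation_step(mats, rule, 6, 6)
  expect_equal(m6$suture[1], 3000)      # final interval at bone stiffness
  # geometric in between, verified against the closed form
  prev <- 0
  for (k in 1:6) {
    mk <- bulk_formation_step(mats, rule, k, 6)
    expect_equal(mk$suture[1], 30 * 100^((k - 1) / 5), tolerance = 1e-9)
    expect_gte(mk$suture[1], prev)
    prev <- mk$suture[1]
  }
  expect_error(bulk_formation_step(mats, formation_rule(
    scenario = "bulk", bulk_ramp = list(suture = c(30, 3000))), 1, 6),
    "shorter")
})

test_that("unconstrained growth reproduces the cube-law volume ratio", {
  m <- box_mesh(c(20, 15, 12), c(2, 2, 2), region = "brain_block")
  v0 <- sum(tet_volumes(m))
  run <- grow_calvaria(m, schedule = build_schedule(659, 1245, 6),
                       rule = formation_rule(rates = c(suture = 0,
                                                       craniotomy = 0)),
                       contact = NULL, constraints = integer(0),
                       n_sub = 1, verbose = FALSE)
  v1 <- sum(tet_volumes(run$mesh))
  expect_equal(v1 / v0, 1245 / 659, tolerance = 1e-6)
})
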