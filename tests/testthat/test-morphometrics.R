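# Craniometric measures, volumes, patency, pressure statistics and
# cross-sections.

test_that("cephalic index is width over length times 100", {
  expect_equal(cephalic_index(100, 100), 100)
  expect_equal(cephalic_index(80, 100), 80)
  # half-away-from-zero rounding to two decimals
  expect_equal(cephalic_index(79.165, 100), 79.17)
})

test_that("measure reports distances between the placed landmarks", {
  bs <- ball_shell_mesh(40, 44, n_theta = 17, n_phi = 24, n_radial = 2)
  bs <- place_landmarks(bs)
  r <- measure(bs, age = 10)
  expect_s3_class(r, "morphometrics_report")
  expect_equal(r$age, 10)
  bs$landmarks <- bs$landmarks[-1]
  expect_error(measure(bs), "glabella")
})

test_that("icv_volume matches closed forms and is rotation invariant", {
  m <- single_tet_mesh(region = "brain_tet")
  expect_equal(icv_volume(m), (1 / 6) / 1000, tolerance = 1e-12)
  bs <- ball_shell_mesh(10, 11, n_theta = 25, n_phi = 32, n_radial = 4)
  bs$region[bs$region == "core"] <- "brain_core"
  expect_equal(icv_volume(bs) * 1000, 4 / 3 * pi * 1000, tolerance = 0.02)
  # rigid rotation leaves the volume unchanged
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  bs2 <- bs; bs2$nodes <- bs$nodes %*% t(R)
  expect_equal(icv_volume(bs2), icv_volume(bs), tolerance = 1e-12)
  m$region <- "shell"
  expect_error(icv_volume(m), "ICV")
})

test_that("lobe volumes add up to the intracranial volume", {
  m <- generate_calvaria(skull_params(mesh_size = 16, n_brain_layers = 2L))
  v <- tet_volumes(m)
  lobes <- startsWith(m$region, "brain") | m$region == "cerebellum"
  expect_equal(sum(v[lobes]) / 1000, icv_volume(m), tolerance = 1e-12)
})

test_that("patency is monotone and closure ages are first-zero ages", {
  region <- c("coronal", "coronal", "metopic", "frontal")
  snaps <- list(
    list(age = 4, ossified = c(FALSE, FALSE, FALSE, FALSE)),
    list(age = 12, ossified = c(TRUE, FALSE, FALSE, FALSE)),
    list(age = 24, ossified = c(TRUE, TRUE, FALSE, FALSE))
  )
  pat <- patency(list(region = region, snapshots = snaps))
  expect_true(all(unlist(tapply(pat$fraction_open, pat$region, diff)) <= 0))
  ca <- closure_ages(pat)
  expect_equal(unname(ca["coronal"]), 24)
  expect_true(is.na(ca["metopic"]))
  # inconsistent element counts are rejected
  snaps_bad <- c(snaps, list(list(age = 36, ossified = c(TRUE, TRUE))))
  expect_error(patency(list(region = region, snapshots = snaps_bad)),
               "inconsistent")
})

test_that("per-lobe pressure statistics match direct enumeration", {
  bs <- ball_shell_mesh(30, 33, n_theta = 9, n_phi = 12, n_radial = 2)
  # make two fake lobes out of the ball
  cen <- element_centroids(bs)
  core <- bs$region == "core"
  bs$region[core & cen[, 1] >= 0] <- "brain_frontal"
  bs$region[core & cen[, 1] < 0] <- "brain_occipital"
  ns <- length(bs$contact$slave_nodes)
  set.seed(1)
  pressures <- round(runif(ns, 0, 10), 3)
  pressures[sample(ns, 20)] <- 0
  state <- structure(list(contact = list(pressure = pressures)),
                     class = "sim_state")
  rep_ <- pressure_report(state, bs)
  expect_true(all(rep_$min <= rep_$mean & rep_$mean <= rep_$max))
  expect_true(all(rep_$min >= 0))
  # enumeration oracle: recompute the face pressures directly
  pn <- numeric(nrow(bs$nodes))
  pn[bs$contact$slave_nodes] <- pressures
  st <- bs$contact$slave_tris
  fp <- (pn[st[, 1]] + pn[st[, 2]] + pn[st[, 3]]) / 3
  # the exported face map equals the enumeration
  fmap <- extract_contact_pressure(state, bs)
  expect_equal(fmap$pressure, fp, tolerance = 1e-12)
  # faces clearly on the +x side belong to the frontal lobe: their
  # pressures must lie inside that lobe's reported range
  fc_x <- (bs$nodes[st[, 1], 1] + bs$nodes[st[, 2], 1] +
             bs$nodes[st[, 3], 1]) / 3
  fr <- rep_[rep_$lobe == "brain_frontal", ]
  sel <- fc_x > 1
  expect_true(all(fp[sel] >= fr$min - 1e-12 & fp[sel] <= fr$max + 1e-12))
  expect_equal(max(fp), max(rep_$max), tolerance = 1e-12)
  expect_equal(min(fp), min(rep_$min), tolerance = 1e-12)
})

test_that("uniform pressure collapses min, max and mean per lobe", {
  bs <- ball_shell_mesh(30, 33, n_theta = 9, n_phi = 12, n_radial = 2)
  bs$region[bs$region == "core"] <- "brain_parietal"
  ns <- length(bs$contact$slave_nodes)
  state <- structure(list(contact = list(pressure = rep(2.5, ns))),
                     class = "sim_state")
  rep_ <- pressure_report(state, bs)
  expect_equal(rep_$min, 2.5, tolerance = 1e-12)
  expect_equal(rep_$max, 2.5, tolerance = 1e-12)
  expect_equal(rep_$mean, 2.5, tolerance = 1e-12)
})

test_that("cross-sections recover analytic outlines", {
  bs <- ball_shell_mesh(30, 33, n_theta = 25, n_phi = 32, n_radial = 2)
  # label the core intracranial so the outer skull surface is selected
  bs$region[bs$region == "core"] <- "brain_core"
  out <- cross_section(bs, "midsagittal")
  expect_gt(nrow(out), 10)
  expect_equal(outline_length(out), 2 * pi * 33, tolerance = 0.02)
  # in-plane rotation leaves the outline length unchanged
  th <- 0.4
  R <- rbind(c(cos(th), 0, -sin(th)), c(0, 1, 0), c(sin(th), 0, cos(th)))
  bs2 <- bs; bs2$nodes <- bs$nodes %*% t(R)
  out2 <- cross_section(bs2, "midsagittal")
  expect_equal(outline_length(out2), outline_length(out), tolerance = 0.02)
  # a plane outside the bounding box is flagged empty
  expect_message(out3 <- cross_section(bs, "axial", offset = 100),
                 "does not intersect")
  expect_equal(nrow(out3), 0)
})
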