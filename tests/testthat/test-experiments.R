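# Built-in sensitivity grid configuration and orchestration.

test_that("builtin configurations carry the sensitivity-study parameters", {
  cfgs <- test_configs()
  expect_setequal(names(cfgs),
                  c("baseline", "test1", "test2", "test3", "test4", "test5",
                    "modelI_gradual", "modelI_bulk", "modelII_bulk"))
  b <- cfgs$baseline
  expect_equal(b$materials$bone, c(3000, 0.3))
  expect_equal(b$materials$suture, c(30, 0.3))
  expect_equal(b$materials$craniotomy, c(30, 0.3))
  expect_equal(b$materials$brain, c(100, 0.48))
  expect_equal(unname(b$formation$rates["suture"]), 0.1)
  expect_equal(unname(b$formation$rates["craniotomy"]), 0.8)
  expect_false(b$csf_present)
  expect_equal(b$formation$scenario, "gradual")
  # material sensitivities
  expect_equal(cfgs$test1$materials$bone, c(421, 0.22))
  expect_equal(cfgs$test2$materials$craniotomy, c(0.003, 0.3))
  expect_equal(cfgs$test3$materials$brain, c(0.003, 0.48))
  # formation-rate sensitivities
  expect_equal(unname(cfgs$test4$formation$rates["suture"]), 0.2)
  expect_equal(unname(cfgs$test5$formation$rates["metopic"]), 0.6)
  expect_equal(unname(cfgs$test5$formation$rates["anterior_fontanelle"]), 0.6)
  expect_equal(unname(cfgs$test5$formation$force_close["metopic"]), 24)
  # extreme stiffness ratios get extra sub-increments
  expect_equal(cfgs$test2$n_sub, 3L * cfgs$baseline$n_sub)
  # CSF models
  expect_true(cfgs$modelI_gradual$csf_present)
  expect_equal(cfgs$modelI_bulk$formation$scenario, "bulk")
  # every config is a valid, printable object
  for (cfg in cfgs) expect_s3_class(cfg, "experiment_config")
})

test_that("contact defaults carry the published interface parameters", {
  cs <- contact_spec()
  expect_equal(cs$friction, 0.1)
  expect_equal(cs$normal_stiffness, 600)
  expect_equal(cs$penetration_tol, 0.5)
})

test_that("experiment runs are deterministic and tabulate consistently", {
  b <- cached_run("baseline")
  expect_s3_class(b, "experiment_bundle")
  # a manifest records every physical parameter
  expect_equal(b$manifest$materials$bone, c(3000, 0.3))
  expect_equal(b$manifest$contact$friction, 0.1)
  expect_equal(b$manifest$formation$rates$craniotomy, 0.8)
  # determinism: regenerating the mesh gives bit-identical geometry
  cfg <- b$config
  set.seed(cfg$seed)
  m1 <- generate_calvaria(cfg$geometry)
  set.seed(cfg$seed)
  m2 <- generate_calvaria(cfg$geometry)
  expect_identical(m1$nodes, m2$nodes)
  tabs <- tabulate_experiments(list(b, cached_run("test4")))
  expect_equal(nrow(tabs$dimensions), 2)
  expect_equal(tabs$dimensions$experiment,
               sort(tabs$dimensions$experiment))
  # the stored cephalic index recomputes from the stored width and length
  expect_equal(tabs$dimensions$cephalic_index,
               cephalic_index(tabs$dimensions$width,
                              tabs$dimensions$length),
               tolerance = 5e-3)
  expect_error(tabulate_experiments(list()), "at least one")
})

test_that("writing an experiment bundle produces the report files", {
  b <- cached_run("baseline")
  td <- withr::local_tempdir()
  cfg <- b$config
  # reuse the bundle outputs rather than re-running: write them directly
  utils::write.csv(b$morphometrics,
                   file.path(td, "m.csv"), row.names = FALSE)
  back <- utils::read.csv(file.path(td, "m.csv"))
  expect_equal(nrow(back), nrow(b$morphometrics))
})
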