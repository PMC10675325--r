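test_that("zero enzyme and zero burst give a fully inert disc", {
  truth <- simulate_kinetics(
    list(well_condition("A", 0)),
    disc_spec(burst_frac = 0), duration = 20, step = 0.5, seed = 1
  )
  expect_true(all(truth$radius[, "A"] == 2))
  expect_true(all(truth$cum_pva[, "A"] == 0))
  expect_true(all(truth$cum_gel[, "A"] == 0))
  expect_true(is.na(truth$t_complete["A"]))
})

test_that("linear erosion follows the closed-form geometry", {
  # erode_coeff * enzyme_conc = 0.2 mm/h on a 2 mm disc
  truth <- simulate_kinetics(
    list(well_condition("A", 100, erode_coeff = 0.002)),
    disc_spec(), duration = 20, step = 0.5, seed = 1
  )
  expect_equal(unname(truth$t_complete["A"]), 10)
  i5 <- which(truth$times == 5)
  expect_equal(unname(truth$area_mm2[i5, "A"] / truth$area_mm2[1, "A"]),
               0.25)
})

test_that("pure burst release matches the exponential closed form", {
  truth <- simulate_kinetics(
    list(well_condition("A", 0)),
    disc_spec(pva_load = 100, burst_frac = 1, burst_tau = 1),
    duration = 2, step = 0.25, seed = 1
  )
  i1 <- which(truth$times == 1)
  expect_equal(unname(truth$cum_pva[i1, "A"]), 100 * (1 - exp(-1)),
               tolerance = 1e-12)
})

test_that("kinetics invariants hold across random conditions", {
  wells <- withr::with_seed(99, lapply(1:6, function(i)
    well_condition(paste0("W", i), enzyme_conc = runif(1, 0, 250),
                   erode_coeff = runif(1, 1e-4, 3e-3),
                   disintegrate_frac = runif(1, 0, 0.5),
                   disintegrate_prob = sample(c(0, 0.3), 1))))
  disc <- disc_spec(pva_load = 500, burst_frac = 0.4)
  truth <- simulate_kinetics(wells, disc, duration = 18, step = 0.25,
                             seed = 31)
  # radius non-increasing, area = pi r^2, mass conservation, release bounds
  expect_true(all(apply(truth$radius, 2, function(r) all(diff(r) <= 0))))
  expect_equal(truth$area_mm2, pi * truth$radius^2)
  expect_equal(truth$cum_gel + truth$mass,
               matrix(truth$mass[1, ], nrow(truth$mass), ncol(truth$mass),
                      byrow = TRUE), ignore_attr = TRUE)
  expect_true(all(apply(truth$cum_pva, 2, function(x) all(diff(x) >= 0))))
  expect_true(all(truth$cum_pva <= disc$pva_load + 1e-9))
})

test_that("higher enzyme concentration degrades pointwise faster", {
  mk <- function(conc) well_condition(paste0("c", conc), conc)
  truth <- simulate_kinetics(lapply(c(50, 100, 200), mk), disc_spec(),
                             duration = 20, step = 0.5, seed = 1)
  expect_true(all(truth$radius[, "c100"] <= truth$radius[, "c50"]))
  expect_true(all(truth$radius[, "c200"] <= truth$radius[, "c100"]))
  tc <- truth$t_complete
  expect_true(tc["c200"] <= tc["c100"])
})

test_that("disintegration zeroes the radius once, after the area gate", {
  w <- well_condition("A", 100, disintegrate_frac = 0.5,
                      disintegrate_prob = 1)
  truth <- simulate_kinetics(list(w), disc_spec(), duration = 20,
                             step = 0.25, seed = 5)
  td <- truth$t_disintegrate["A"]
  expect_false(is.na(td))
  # with prob 1 the event fires at the first step whose linear-law area
  # fraction is below the gate; before it the radius follows the linear law
  linear <- pmax(0, 2 - (100 / 600) * truth$times)
  before <- truth$times < td
  expect_equal(truth$radius[before, "A"], linear[before])
  expect_true((linear[truth$times == td] / 2)^2 < 0.5)
  expect_true(all(truth$radius[truth$times >= td, "A"] == 0))
  # deterministic given the seed
  truth2 <- simulate_kinetics(list(w), disc_spec(), duration = 20,
                              step = 0.25, seed = 5)
  expect_identical(truth$radius, truth2$radius)
})

test_that("invalid durations and steps are rejected", {
  w <- list(well_condition("A", 0))
  expect_error(simulate_kinetics(w, disc_spec(), duration = 0, step = 1),
               "duration")
  expect_error(simulate_kinetics(w, disc_spec(), duration = 10, step = -1),
               "step")
})

test_that("noiseless rendering draws exactly the rasterized circle", {
  sc <- render_single_disc(r_px = 30)
  fr <- sc$frames[[1]]
  disc_px <- sum(fr$pixels[, , 1] == 200 & fr$pixels[, , 2] == 30 &
                   fr$pixels[, , 3] == 40)
  expect_equal(disc_px, oracle_circle_count(dim(fr$pixels)[1],
                                            dim(fr$pixels)[2],
                                            sc$center["x"], sc$center["y"],
                                            30))
})

test_that("a fully degraded truth renders no disc pixels", {
  truth <- simulate_kinetics(list(well_condition("A", 100,
                                                 erode_coeff = 1)),
                             disc_spec(), duration = 5, step = 1, seed = 1)
  expect_true(all(truth$radius[-1, "A"] == 0))
  layout <- well_layout(data.frame(well_id = "A", cx_px = 40, cy_px = 40,
                                   r_px = 30))
  cfg <- render_config(px_per_mm = 10, frame_interval = 60, noise_sd = 0,
                       debris_rate = 0)
  out <- render_frames(truth, layout, cfg)
  last <- out$frames[[length(out$frames)]]
  expect_equal(sum(last$pixels[, , 1] == 200 & last$pixels[, , 2] == 30 &
                     last$pixels[, , 3] == 40), 0)
})

test_that("rendering is bit-identical for a repeated seed", {
  a <- render_single_disc(r_px = 12, noise_sd = 6, debris_rate = 3, seed = 11)
  b <- render_single_disc(r_px = 12, noise_sd = 6, debris_rate = 3, seed = 11)
  for (k in seq_along(a$frames))
    expect_identical(a$frames[[k]]$pixels, b$frames[[k]]$pixels)
})

test_that("a disc larger than its well is rejected", {
  truth <- simulate_kinetics(list(well_condition("A", 0)), disc_spec(),
                             duration = 1, step = 1, seed = 1)
  layout <- well_layout(data.frame(well_id = "A", cx_px = 40, cy_px = 40,
                                   r_px = 15))
  cfg <- render_config(px_per_mm = 10, frame_interval = 60)
  expect_error(render_frames(truth, layout, cfg), "exceeds well radius")
})

test_that("frames and manifest round-trip through disk", {
  sc_dir <- withr::local_tempdir()
  truth <- simulate_kinetics(list(well_condition("A", 100)), disc_spec(),
                             duration = 2, step = 0.5, seed = 3)
  layout <- well_layout(data.frame(well_id = "A", cx_px = 40, cy_px = 40,
                                   r_px = 35))
  cfg <- render_config(px_per_mm = 10, frame_interval = 30, noise_sd = 4,
                       debris_rate = 1, seed = 3)
  mem <- render_frames(truth, layout, cfg)
  render_frames(truth, layout, cfg, dir = sc_dir)
  back <- read_frame_sequence(sc_dir)
  expect_equal(length(back), nrow(mem$manifest))
  for (k in seq_along(back)) {
    expect_identical(back[[k]]$pixels, mem$frames[[k]]$pixels)
    expect_equal(back[[k]]$time, mem$manifest$time_min[k])
  }
})
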