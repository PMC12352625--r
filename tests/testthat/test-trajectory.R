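fixed_water_traj <- function(n_frames, dist) {
  gp <- make_porphyrin(porphyrin_spec(fe_water = dist))
  t <- Trajectory(gp$structure,
                  frames = rep(list(coords(gp$structure$models[[1]])),
                               n_frames))
  fe <- which(gp$structure$models[[1]]$element == "FE")
  list(t = t, fe = fe, topo = gp$structure)
}

test_that("a fixed water at 2.5 A gives occupancy 1, mean 2.5, sd 0", {
  x <- fixed_water_traj(100, 2.5)
  pr <- water_residence(x$t, x$fe)
  expect_equal(pr$occupancy, 1.0)
  expect_equal(pr$mean, 2.5, tolerance = 1e-9)
  expect_equal(pr$sd, 0)
  expect_equal(sum(pr$histogram$counts), 100)
})

test_that("a waterless trajectory has occupancy 0 and absent statistics", {
  gp <- make_porphyrin(porphyrin_spec(fe_water = NA))
  t <- Trajectory(gp$structure)
  fe <- which(gp$structure$models[[1]]$element == "FE")
  pr <- water_residence(t, fe)
  expect_equal(pr$occupancy, 0)
  expect_true(is.na(pr$mean))
  expect_error(water_residence(Trajectory(gp$structure,
                                          frames = list(coords(
                                            gp$structure$models[[1]]))[0]),
                               fe))
})

test_that("Gaussian Fe-water statistics are recovered on synthetic frames", {
  gp <- make_porphyrin(porphyrin_spec(fe_water = 3.3))
  mt <- make_trajectory(trajectory_spec(n_frames = 2000,
                                        fe_water_distribution =
                                          list(c(1, 3.3, 0.1)),
                                        seed = 21),
                        gp$structure)
  pr <- water_residence(mt$trajectory, mt$truth$fe)
  expect_lt(abs(pr$mean - 3.3), 3 * 0.1 / sqrt(2000) + 0.01)
  expect_lt(abs(pr$sd - 0.1) / 0.1, 0.10)
  # per-frame minima equal the generator's drawn distances exactly
  expect_equal(pr$per_frame_min_dist, mt$truth$distances,
               tolerance = 1e-9)
})

test_that("contributing-frames vs all-frames residence statistics differ", {
  gp <- make_porphyrin(porphyrin_spec(fe_water = 3.3))
  mt <- make_trajectory(trajectory_spec(n_frames = 500,
                                        fe_water_distribution =
                                          list(c(0.5, 2.7, 0.1),
                                               c(0.5, 4.5, 0.1)),
                                        seed = 22),
                        gp$structure)
  pr_c <- water_residence(mt$trajectory, mt$truth$fe)
  pr_a <- water_residence(mt$trajectory, mt$truth$fe, all_frames = TRUE)
  expect_lt(pr_c$occupancy, 1)
  expect_lt(pr_c$mean, pr_a$mean)       # far component excluded
  expect_equal(sum(pr_c$histogram$counts),
               sum(pr_c$per_frame_min_dist <= pr_c$cutoff))
})

test_that("hbond occupancy: trivial satisfied/violated cases and criteria error", {
  # donor-acceptor at 2.8 A every frame, heavy-only criteria
  m <- new_atom_table(3)
  m$serial <- 1:3; m$name <- c("O", "H1", "ND")
  m$resname <- c("HOH", "HOH", "HEC"); m$chain <- "A"
  m$resseq <- c(1L, 1L, 2L); m$element <- c("O", "H", "N")
  m$occupancy <- 1
  m$x <- c(0, 0.96, 2.8); m$y <- 0; m$z <- 0
  s <- Structure(list(m), "synthetic", "hb")
  t <- Trajectory(s, frames = rep(list(coords(m)), 10))
  expect_equal(hbond_occupancy(t, donor = 1, acceptor = 3), 1.0)
  # with hydrogens: D-H...A angle is 180 deg here (H between D and A)
  expect_equal(hbond_occupancy(t, donor = 1, acceptor = 3, hydrogens = 2,
                               criteria = hbond_criteria(mode =
                                                         "with_hydrogens")),
               1.0)
  # move H perpendicular: angle at H becomes ~90 deg -> never satisfied
  m2 <- m; m2$x[2] <- 0; m2$y[2] <- 0.96
  t2 <- Trajectory(Structure(list(m2), "synthetic", "hb2"),
                   frames = rep(list(coords(m2)), 10))
  expect_equal(hbond_occupancy(t2, donor = 1, acceptor = 3, hydrogens = 2,
                               criteria = hbond_criteria(mode =
                                                         "with_hydrogens")),
               0.0)
  expect_error(hbond_occupancy(t, donor = 1, acceptor = 3,
                               criteria = hbond_criteria(mode =
                                                         "with_hydrogens")),
               "hydrogen")
})

test_that("hbond occupancy equals exhaustive per-frame counting", {
  gp <- make_porphyrin(porphyrin_spec(fe_water = 3.3))
  mt <- make_trajectory(trajectory_spec(n_frames = 300,
                                        hbond_satisfied_fraction = 0.4,
                                        seed = 23),
                        gp$structure)
  crit <- hbond_criteria()
  occ <- hbond_occupancy(mt$trajectory, mt$truth$water_o,
                         mt$truth$acceptor, criteria = crit)
  brute <- mean(vapply(mt$trajectory$frames, function(f)
    sqrt(sum((f[mt$truth$water_o, ] - f[mt$truth$acceptor, ])^2)) <=
      crit$da_max, logical(1)))
  expect_equal(occ, brute)
  expect_equal(occ, 0.4)                     # constructed count is exact
  expect_gte(occ, 0); expect_lte(occ, 1)
})

test_that("distance_series: closed forms and Gaussian recovery", {
  x <- fixed_water_traj(5, 3.0)
  wo <- which(x$topo$models[[1]]$resname == "HOH")
  ds <- distance_series(x$t, x$fe, wo)
  expect_equal(ds$mean, 3.0, tolerance = 1e-9)
  expect_equal(ds$sd, 0)
  # two-frame series at 2 and 4 A: mean 3, sample sd sqrt(2)
  f1 <- coords(x$topo$models[[1]]); f2 <- f1
  fe_z <- f1[x$fe, 3]
  f1[wo, ] <- f1[x$fe, ] + c(0, 0, 2)
  f2[wo, ] <- f2[x$fe, ] + c(0, 0, 4)
  t2 <- Trajectory(x$topo, frames = list(f1, f2))
  ds2 <- distance_series(t2, x$fe, wo)
  expect_equal(ds2$mean, 3.0, tolerance = 1e-12)
  expect_equal(ds2$sd, sqrt(2), tolerance = 1e-12)
  # recovery at n = 1500 from a (2.7, 0.2) component
  gp <- make_porphyrin(porphyrin_spec(fe_water = 2.7))
  mt <- make_trajectory(trajectory_spec(n_frames = 1500,
                                        fe_water_distribution =
                                          list(c(1, 2.7, 0.2)),
                                        seed = 24),
                        gp$structure)
  ds3 <- distance_series(mt$trajectory, mt$truth$fe, mt$truth$water_o)
  expect_lt(abs(ds3$mean - 2.7), 3 * 0.2 / sqrt(1500))
})

test_that("statistics are invariant under per-frame rigid motion", {
  gp <- make_porphyrin(porphyrin_spec(fe_water = 3.0))
  mt <- make_trajectory(trajectory_spec(n_frames = 50, seed = 25),
                        gp$structure)
  set.seed(99)
  moved <- lapply(mt$trajectory$frames, function(f) {
    R <- random_rotation()
    sweep(f %*% t(R), 2, rnorm(3, sd = 20), `+`)
  })
  t2 <- Trajectory(gp$structure, frames = moved)
  pr0 <- water_residence(mt$trajectory, mt$truth$fe)
  pr1 <- water_residence(t2, mt$truth$fe)
  expect_equal(pr1$per_frame_min_dist, pr0$per_frame_min_dist,
               tolerance = 1e-9)
  occ0 <- hbond_occupancy(mt$trajectory, mt$truth$water_o,
                          mt$truth$acceptor)
  occ1 <- hbond_occupancy(t2, mt$truth$water_o, mt$truth$acceptor)
  expect_equal(occ1, occ0)
})

test_that("mode detection: unimodal, bimodal, degenerate and flat inputs", {
  gp <- make_porphyrin(porphyrin_spec(fe_water = 3.3))
  uni <- make_trajectory(trajectory_spec(n_frames = 2000,
                                         fe_water_distribution =
                                           list(c(1, 3.3, 0.1)),
                                         seed = 26), gp$structure)
  pr <- water_residence(uni$trajectory, uni$truth$fe)
  expect_length(pr$modes, 1)
  expect_lt(abs(pr$modes - 3.3), 0.06)

  bi <- make_trajectory(trajectory_spec(n_frames = 4000,
                                        fe_water_distribution =
                                          list(c(0.5, 2.6, 0.1),
                                               c(0.5, 2.9, 0.1)),
                                        seed = 27), gp$structure)
  prb <- water_residence(bi$trajectory, bi$truth$fe)
  expect_length(prb$modes, 2)
  expect_lt(abs(prb$modes[1] - 2.6), 0.06)
  expect_lt(abs(prb$modes[2] - 2.9), 0.06)

  # separation 0.05 A at sigma 0.1 collapses to one mode
  near <- make_trajectory(trajectory_spec(n_frames = 4000,
                                          fe_water_distribution =
                                            list(c(0.5, 2.60, 0.1),
                                                 c(0.5, 2.65, 0.1)),
                                          seed = 28), gp$structure)
  prn <- water_residence(near$trajectory, near$truth$fe)
  expect_length(prn$modes, 1)

  expect_equal(detect_modes(list(mids = 2.5, counts = 7)), 2.5)
  flat <- list(mids = seq(2, 3, by = 0.05),
               counts = rep(4, 21))
  expect_equal(detect_modes(flat), sum(flat$mids * flat$counts) /
                 sum(flat$counts))
  expect_error(detect_modes(list(mids = numeric(0), counts = integer(0))),
               "empty")
})
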