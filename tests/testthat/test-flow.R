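test_that("Starling source vanishes at equilibrium and matches the table
           arithmetic at zero pressure", {
  dm <- c(4, 4, 4)
  g <- build_grid(rep(8, 3), rep(2, 3), region = array(1L, dm))
  props <- cedsim:::expand_tissue_properties(g)
  sv0 <- array(2.0e4, dim = dm)
  phi <- array(1, dim = dm)

  p_eq <- 4610 - 0.82 * (3440 - 1110)  # tumor Starling equilibrium, 2699.4 Pa
  expect_equal(p_eq, 2699.4)
  f0 <- starling_source(array(p_eq, dim = dm), phi, sv0, props)
  expect_lt(max(abs(f0)), 1e-18)

  # direct arithmetic from the tumor property table at p = 0
  f1 <- starling_source(array(0, dim = dm), phi, sv0, props)
  expect_equal(f1[1], 1.1e-12 * 2.0e4 * p_eq)
  expect_equal(f1[1], 5.94e-5, tolerance = 1e-3)

  expect_true(all(starling_source(array(0, dim = dm), phi * 0, sv0,
                                  props) == 0))
})

test_that("no sources and no exchange give identically zero pressure", {
  tis <- uniform_tissue(n = 8, h_mm = 2)
  props <- cedsim:::expand_tissue_properties(tis$grid)
  props$L_BL[] <- 0
  fl <- solve_flow(tis, props = props)
  expect_lt(max(abs(fl$p)), 1e-12)
  expect_lt(max(abs(fl$qx)), 1e-25)
})

test_that("infusion pressure follows the Darcy point-source solution", {
  n <- 32; h <- 1.5
  tis <- uniform_tissue(n = n, h_mm = h)
  props <- cedsim:::expand_tissue_properties(tis$grid)
  props$L_BL[] <- 0
  tip <- c(n / 2, n / 2, n / 2)
  cth <- catheter_spec(tis$grid, tip, block_shaft = FALSE)
  Q <- 5e-11; mu <- 7.8e-4; kap <- 6.4e-14
  K <- Q * mu / (4 * pi * kap)
  tipc <- (tip - 0.5) * h
  pb <- function(x, y, z) {
    K / (sqrt((x - tipc[1])^2 + (y - tipc[2])^2 + (z - tipc[3])^2) * 1e-3)
  }
  fl <- solve_flow(tis, catheter = cth, Q_in_m3s = Q, props = props,
                   p_boundary = pb, tol = 1e-10)
  expect_lt(fl$balance$rel_error, 1e-6)

  d <- distance_map(tis$grid, cth)
  band <- d >= 2 * h & d <= n * h / 4
  num <- distance_course(fl$p, d, band, bin_mm = h)
  ana <- distance_course(K / (d * 1e-3), d, band, bin_mm = h)
  rel <- abs(num$value - ana$value) / ana$value
  expect_lt(max(rel, na.rm = TRUE), 0.05)

  # worked value: ~9.7 Pa at r = 5 mm
  shell5 <- abs(d - 5) < 0.5 & band
  expect_equal(mean(fl$p[shell5]), 9.7, tolerance = 0.05)

  # linearity: doubling the infusion rate doubles the field
  fl2 <- solve_flow(tis, catheter = cth, Q_in_m3s = 2 * Q, props = props,
                    p_boundary = function(x, y, z) 2 * pb(x, y, z),
                    tol = 1e-10)
  expect_equal(fl2$p[band], 2 * fl$p[band], tolerance = 1e-6)
})

test_that("refinement improves the point-source accuracy", {
  run <- function(n, h) {
    tis <- uniform_tissue(n = n, h_mm = h)
    props <- cedsim:::expand_tissue_properties(tis$grid)
    props$L_BL[] <- 0
    tip <- c(n / 2, n / 2, n / 2)
    cth <- catheter_spec(tis$grid, tip, block_shaft = FALSE)
    Q <- 5e-11; K <- Q * 7.8e-4 / (4 * pi * 6.4e-14)
    tipc <- (tip - 0.5) * h
    pb <- function(x, y, z) {
      K / (sqrt((x - tipc[1])^2 + (y - tipc[2])^2 + (z - tipc[3])^2) * 1e-3)
    }
    fl <- solve_flow(tis, catheter = cth, Q_in_m3s = Q, props = props,
                     p_boundary = pb, tol = 1e-10)
    d <- distance_map(tis$grid, cth)
    sel <- d >= 6 & d <= 12   # fixed physical band (mm)
    max(abs(fl$p[sel] - K / (d[sel] * 1e-3)) / (K / (d[sel] * 1e-3)))
  }
  e_coarse <- run(16, 3)
  e_fine <- run(32, 1.5)
  expect_lt(e_fine, e_coarse)
  expect_lt(e_fine, 0.02)
})

test_that("a large all-tumor domain plateaus at the Starling equilibrium", {
  n <- 40
  tis <- uniform_tissue(n = n, h_mm = 20)  # 800 mm box
  fl <- solve_flow(tis, tol = 1e-10)
  ctr <- fl$p[n / 2, n / 2, n / 2]
  expect_equal(ctr, 2699.4, tolerance = 0.01)
  # pressure falls towards the Dirichlet outer boundary
  expect_lt(fl$p[1, n / 2, n / 2], 0.5 * ctr)
})

test_that("discrete fluid balance closes with exchange and infusion", {
  ph <- generate_tissue_maps(small_phantom_spec())
  tis <- ph$tissue
  site <- select_infusion_site(tis)
  cth <- catheter_spec(tis$grid, site)
  fl <- solve_flow(tis, catheter = cth, Q_in_m3s = 5e-11, tol = 1e-10)
  expect_lt(fl$balance$rel_error, 1e-6)
  # infusion raises the tip pressure above the no-infusion solution
  f0 <- solve_flow(tis, catheter = cth, Q_in_m3s = 0, tol = 1e-10)
  expect_gt(fl$p[cth$tip_linear], f0$p[cth$tip_linear])
  # blocked and exterior cells carry no flow
  expect_true(all(fl$p[cth$blocked] == 0))
})
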