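test_that("1-D closed form reproduces the printed equilibrium points", {
  eq <- equilibrium1D(1)
  v <- fractions(eq)
  expect_equal(unname(v[c("z1", "z3")]), c(0.125, 0.125))
  expect_equal(v[["y2"]], 0.25)
  expect_equal(fractions(eq, aggregated = TRUE)[["z2"]], 0.25)
  expect_equal(eq@s, 1)

  eq3 <- equilibrium1D(3)
  expect_equal(eq3@fractions@z[1], 81 / 200)  # 0.405
  expect_equal(eq3@fractions@z[3], 1 / 200)   # 0.005
  expect_equal(eq3@s, 81)
})

test_that("1-D closed form obeys the equilibrium symmetry and limits", {
  for (h in c(0.4, 0.9, 1.7, 2.5)) {
    fr <- equilibrium1D(h)@fractions
    expect_equal(fr@z[1], fr@z[6])
    expect_equal(fr@z[2], fr@z[5])
    expect_equal(fr@z[3], fr@z[4])
    expect_equal(fr@y[1], fr@y[3])
    expect_equal(fr@x, c(0.5, 0.5))
    expect_true(all(c(fr@y, fr@z) <= 0.5 + 1e-15))
    expect_equal(fr@z[1] / fr@z[3], h^4, tolerance = 1e-9)  # s = z1/z3
  }
  # h -> 0: alternation dominates
  lo <- equilibrium1D(1e-4)@fractions
  expect_equal(lo@z[3], 0.5, tolerance = 1e-3)
  expect_equal(lo@z[1], 0, tolerance = 1e-8)
  expect_equal(lo@y[2], 0.5, tolerance = 1e-3)
  # h -> infinity: like-domains dominate, but some unlike pairs persist
  hi <- equilibrium1D(100)@fractions
  expect_equal(hi@z[1], 0.5, tolerance = 1e-3)
  expect_equal(hi@z[3], 0, tolerance = 1e-8)
  expect_gt(hi@y[2], 0)
  expect_error(equilibrium1D(-1), "> 0")
})

test_that("1-D closed form is a stationary point of the free energy", {
  # central-difference feasible-direction gradient of the 1-D functional
  for (h in c(0.5, 1, 2, 3)) {
    fr0 <- equilibrium1D(h)@fractions
    eps <- 4 * log(h)
    gAt <- function(z1, z3) {
      z2 <- (0.5 - z1 - z3) / 2
      fr <- new("ConfigurationFractions", x = c(0.5, 0.5),
                y = c(z1 + z2, z2 + z3, z1 + z2),
                w = c(z1 + z3, 2 * z2, z1 + z3),
                z = c(z1, z2, z3, z3, z2, z1),
                nWindows = NA_real_, dims = 1L)
      reducedFreeEnergy(fr, thermoParams(eps = eps), dims = 1L)@gReduced
    }
    ## analytic feasible-direction gradient at the closed form, via the
    ## stationarity relations: both components vanish identically
    z1 <- fr0@z[1]; z2 <- fr0@z[2]; z3 <- fr0@z[3]
    y1 <- z1 + z2; y2 <- z2 + z3
    g1 <- -eps - 2 * log(y1 / y2) + 4 * log(z1 / z2)
    g3 <- +eps + 2 * log(y1 / y2) + 4 * log(z3 / z2)
    expect_lt(abs(g1), 1e-8)
    expect_lt(abs(g3), 1e-8)
    ## and the numerical central difference agrees
    d <- 1e-7
    expect_lt(abs((gAt(z1 + d, z3) - gAt(z1 - d, z3)) / (2 * d)), 1e-5)
    expect_lt(abs((gAt(z1, z3 + d) - gAt(z1, z3 - d)) / (2 * d)), 1e-5)
  }
})

test_that("direct minimization of the 1-D functional recovers the closed form", {
  # independent route: optim on the reduced (z1, z3) parameterization of
  # the package-evaluated 1-D free energy
  for (h in seq(0.3, 3, length.out = 13)) {
    eps <- 4 * log(h)
    obj <- function(p) {
      z1 <- plogis(p[1]) / 2; z3 <- plogis(p[2]) / 2
      z2 <- (0.5 - z1 - z3) / 2
      if (z2 <= 0) return(1e6)
      fr <- new("ConfigurationFractions", x = c(0.5, 0.5),
                y = c(z1 + z2, z2 + z3, z1 + z2),
                w = c(z1 + z3, 2 * z2, z1 + z3),
                z = c(z1, z2, z3, z3, z2, z1),
                nWindows = NA_real_, dims = 1L)
      reducedFreeEnergy(fr, thermoParams(eps = eps), dims = 1L)@gReduced
    }
    fit <- optim(c(-1.1, -1.1), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 5000))
    zHat <- c(plogis(fit$par[1]) / 2, plogis(fit$par[2]) / 2)
    fr0 <- equilibrium1D(h)@fractions
    expect_equal(zHat[1], fr0@z[1], tolerance = 1e-6)
    expect_equal(zHat[2], fr0@z[3], tolerance = 1e-6)
  }
})

test_that("stationarity relations hold with a single scalar q at lambda = 0", {
  for (h in c(0.6, 1, 1.8, 2.7)) {
    fr <- equilibrium1D(h)@fractions
    eps <- 4 * log(h)
    y <- fr@y; z <- fr@z
    q <- y[1] / z[1]
    expect_equal(z[2] * q, sqrt(y[1] * y[2]) * exp(-eps / 4), tolerance = 1e-10)
    expect_equal(z[3] * q, y[2] * exp(-eps / 2), tolerance = 1e-10)
    expect_equal(z[4] * q, y[2] * exp(-eps / 2), tolerance = 1e-10)
    expect_equal(z[5] * q, sqrt(y[2] * y[3]) * exp(-eps / 4), tolerance = 1e-10)
    expect_equal(z[6] * q, y[3], tolerance = 1e-10)
  }
})

test_that("2-D analytic z3 matches its printed values and branch algebra", {
  expect_equal(as.numeric(equilibrium2DZ3(1)), 0.125)
  expect_equal(as.numeric(equilibrium2DZ3(sqrt(3))), 0)
  expect_equal(as.numeric(equilibrium2DZ3(1 / sqrt(3))), 0.5)
  expect_equal(as.numeric(equilibrium2DZ3(1.2)),
               (1.2^2 - 3) * (1.2^2 + 1) / (8 * (1.2^4 - 6 * 1.2^2 + 1)),
               tolerance = 1e-15)
  expect_equal(round(as.numeric(equilibrium2DZ3(1.2)), 4), 0.0855)
  # divergence guards at h^2 = 3 +/- 2 sqrt(2)
  expect_error(equilibrium2DZ3(sqrt(2) - 1), "singularity")
  expect_error(equilibrium2DZ3(sqrt(2) + 1), "singularity")
  out <- equilibrium2DZ3(2)
  expect_equal(attr(out, "branch"), "outside")
  expect_equal(attr(equilibrium2DZ3(1), "branch"), "valid")
})

test_that("2-D numerical minimizer agrees with the analytic z3 on the branch", {
  for (h in c(0.62, 0.8, 1, 1.25, 1.55)) {
    sol <- equilibrium2DNumeric(h)
    expect_lt(sol@gradNorm, 1e-9)
    expect_equal(sol@fractions@z[3], as.numeric(equilibrium2DZ3(h)),
                 tolerance = 1e-7)
    expect_length(sol@flags, 0)
  }
  # uniform solution at h = 1
  s1 <- equilibrium2DNumeric(1)
  expect_equal(s1@fractions@z, rep(0.125, 6), tolerance = 1e-9)
  expect_equal(s1@fractions@y[2], 0.25, tolerance = 1e-9)
  expect_error(equilibrium2DNumeric(2), "branch")
})

test_that("the swapped 2-D solution minimizes the functional equally", {
  sol <- equilibrium2DNumeric(1.3)
  swapped <- swapStates(sol@fractions)
  g <- reducedFreeEnergy(swapped, thermoParams(h = 1.3), dims = 2L)
  expect_equal(g@gReduced, sol@gReduced, tolerance = 1e-12)
})

test_that("equilibrium curves tabulate closed forms with monotone structure", {
  tab <- equilibriumCurve(0.5, 2, steps = 7, dims = 1)
  expect_equal(nrow(tab), 7)
  expect_true(all(c("h", "x1", "y2", "z1", "z3", "g_reduced", "flags")
                  %in% names(tab)))
  row1 <- tab[tab$h == 1, ]
  expect_equal(row1$z1, 0.125)
  expect_equal(row1$z3, 0.125)
  # z3 strictly decreasing, z1 strictly increasing in h
  expect_true(all(diff(tab$z3) < 0))
  expect_true(all(diff(tab$z1) > 0))

  tab2 <- equilibriumCurve(0.6, 1.7, steps = 5, dims = 2)
  inb <- tab2$flags == ""
  expect_true(all(vapply(tab2$h[inb], function(h) {
    abs(tab2$z3[tab2$h == h] - as.numeric(equilibrium2DZ3(h))) < 1e-7
  }, logical(1))))
  expect_error(equilibriumCurve(2, 1, 5), "hMin < hMax")
  expect_error(equilibriumCurve(0.5, 2, 1), "at least 2")
})
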