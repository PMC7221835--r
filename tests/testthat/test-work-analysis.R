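# Work integration and pathway ranking: closed-form integrands, a dense-grid
# quadrature oracle, unit round trips, aggregation and the ranking rule.

# force record along +x with positions x and force profile f(x) (pN)
rec_along_x <- function(x, f) {
  n <- length(x)
  force_record(t_ps = seq_along(x), anchor = cbind(x, 0, 0),
               com = cbind(x, 0, 0), force_pN = cbind(f, 0, 0))
}

test_that("work integral matches closed forms on constant and linear profiles", {
  x <- seq(0, 5, by = 0.5)
  expect_equal(integrate_work(rec_along_x(x, rep(10, length(x)))), 50)
  expect_equal(integrate_work(rec_along_x(x, rep(0, length(x)))), 0)
  # trapezoid is exact for a linear integrand: int_0^5 2x dx = 25
  x <- seq(0, 5, by = 0.01)
  expect_equal(integrate_work(rec_along_x(x, 2 * x)), 25, tolerance = 1e-12)
})

test_that("work on smooth random profiles matches a dense-grid quadrature oracle", {
  set.seed(42)
  for (rep in 1:5) {
    a <- runif(3, -2, 2); b <- runif(3, 0.2, 1.5)
    f <- function(x) a[1] * sin(b[1] * x) + a[2] * cos(b[2] * x) +
      a[3] * exp(-b[3] * x / 5) + 3
    coarse <- seq(0, 8, length.out = 60)
    dense <- seq(0, 8, length.out = 20001)
    oracle <- sum((f(dense)[-1] + f(dense)[-length(dense)]) / 2 * diff(dense))
    w <- integrate_work(rec_along_x(coarse, f(coarse)))
    expect_lt(abs(w - oracle) / abs(oracle), 1e-3)
  }
})

test_that("work integrates the full 3-vector against the COM path", {
  # circular path with tangential force: W = F * arc length
  th <- seq(0, pi, length.out = 2001)
  com <- cbind(cos(th), sin(th), 0)
  tangent <- cbind(-sin(th), cos(th), 0)
  rec <- force_record(seq_along(th), anchor = com, com = com,
                      force_pN = 10 * tangent)
  expect_equal(integrate_work(rec), 10 * pi, tolerance = 1e-4)
})

test_that("work is additive over any interior split point", {
  set.seed(7)
  x <- cumsum(runif(40, 0.1, 0.5))
  rec <- rec_along_x(x, rnorm(40, 5, 2))
  total <- integrate_work(rec)
  for (cut in c(2, 17, 39)) {
    w1 <- integrate_work(rec[1:cut, ])
    w2 <- integrate_work(rec[cut:40, ])
    expect_equal(w1 + w2, total, tolerance = 1e-12)
  }
})

test_that("unit round trip pN*A <-> kcal/mol is the identity", {
  w <- 123.456
  expect_equal(kcal_to_pn(pn_to_kcal(w)), w, tolerance = 1e-14)
  x <- seq(0, 5, 0.5)
  rec <- rec_along_x(x, rep(69.479, length(x)))
  expect_equal(integrate_work(rec, "kcal_mol"), 5, tolerance = 1e-12)
})

test_that("degenerate and malformed records are rejected", {
  x <- seq(0, 5, 0.5)
  rec <- rec_along_x(x, rep(1, length(x)))
  expect_error(integrate_work(rec[1, ]), "2 samples")
  bad <- rec; bad$t_ps <- rev(bad$t_ps)
  expect_error(integrate_work(bad), "increasing")
  expect_error(max_force(rec[0, ]), "empty")
})

test_that("max_force is the maximum vector magnitude", {
  rec <- force_record(1:2, anchor = matrix(0, 2, 3), com = matrix(0, 2, 3),
                      force_pN = rbind(c(3, 4, 0), c(1, 0, 0)))
  expect_equal(max_force(rec), 5)
  zero <- force_record(1:3, matrix(0, 3, 3), matrix(0, 3, 3), matrix(0, 3, 3))
  expect_equal(max_force(zero), 0)
  # monotone ramp: the last sample wins
  x <- seq(0, 5, 0.5)
  ramp <- rec_along_x(x, 2 * x)
  expect_equal(max_force(ramp), 10)
})

test_that("aggregation gives mean/SD, flags single repeats, ignores order", {
  mk_prof <- function(w, fmax, dir = "A") {
    x <- c(0, 1)
    p <- work_profile(rec_along_x(x, rep(kcal_to_pn(w), 2)), dir)
    p$fmax_pN <- fmax
    p
  }
  profs <- list(mk_prof(10, 100), mk_prof(20, 120), mk_prof(30, 80))
  agg <- aggregate_direction(profs)
  expect_equal(agg$mean_W_kcal, 20)
  expect_equal(agg$sd_W_kcal, 10)
  expect_false(agg$sd_degenerate)

  one <- aggregate_direction(profs[2])
  expect_equal(one$mean_W_kcal, 20)
  expect_equal(one$sd_W_kcal, 0)
  expect_true(one$sd_degenerate)

  perm <- aggregate_direction(profs[c(3, 1, 2)])
  expect_equal(perm, agg)

  mixed <- list(mk_prof(1, 1, "A"), mk_prof(2, 2, "B"))
  expect_error(aggregate_direction(mixed), "mixed direction")
})

test_that("ranking sorts by mean work and breaks ties by max force", {
  tab <- data.frame(direction = c("A", "B", "C"), n_repeats = 3,
                    mean_W_kcal = c(10, 20, 30), sd_W_kcal = c(1, 1, 1),
                    mean_Fmax_pN = c(5, 5, 5), sd_Fmax_pN = 0,
                    sd_degenerate = FALSE)
  rk <- rank_pathways(tab)
  expect_identical(rk$order, c("A", "B", "C"))
  expect_identical(rk$winner, "A")
  expect_false(rk$runner_up_equivalent)

  # A and B within one SD; B has the lower max force -> B first, flagged
  tab2 <- data.frame(direction = c("A", "B", "C"), n_repeats = 3,
                     mean_W_kcal = c(10, 11, 30), sd_W_kcal = c(2, 2, 1),
                     mean_Fmax_pN = c(50, 40, 5), sd_Fmax_pN = 0,
                     sd_degenerate = FALSE)
  rk2 <- rank_pathways(tab2)
  expect_identical(rk2$order, c("B", "A", "C"))
  expect_true(rk2$runner_up_equivalent)
})
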