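test_that("target attainment percentages are computed and partitioned correctly", {
  w <- target_window()
  expect_equal(w$lower, 5); expect_equal(w$upper, 15)
  p <- probability_of_target(rep(10, 50), w)
  expect_equal(unname(p), c(0, 100, 0))
  p <- probability_of_target(rep(20, 50), w)
  expect_equal(unname(p), c(0, 0, 100))
  p <- probability_of_target(c(1, 5, 10, 15, 30), w)
  expect_equal(unname(p), c(20, 60, 20))   # window bounds inclusive
  expect_equal(sum(p), 100)
  expect_error(probability_of_target(numeric(0), w), "empty")
})

test_that("simulated trough distributions follow the lognormal clearance model", {
  spec <- published_model()
  expect_equal(simulate_trough_distribution(spec, 10, 0, n = 100, seed = 1),
               rep(0, 100))
  tr <- simulate_trough_distribution(spec, 10, 0.07, n = 20000, seed = 2)
  # lognormal-median property: sample median ~ the eta = 0 closed form
  p0 <- structural_params(typical_clearance(spec, 10),
                          typical_volume(spec, 10), spec$ka)
  det_trough <- steady_state_trough(p0, dose_regimen(0.07 * 10 / 2, 12))
  expect_equal(median(tr), det_trough, tolerance = 0.02)
  expect_identical(tr[1:100],
                   simulate_trough_distribution(spec, 10, 0.07, n = 100,
                                                seed = 2)[1:100])
})

test_that("the PTA grid is seed-reproducible, complete and internally consistent", {
  spec <- published_model()
  grid <- simulation_grid(n_virtual = 300, seed = 5)
  pta <- pta_grid(spec, grid)
  expect_equal(nrow(pta), 7 * 10)
  expect_equal(pta$p_below + pta$p_in + pta$p_above, rep(100, nrow(pta)))
  expect_identical(as.data.frame(pta_grid(spec, grid)), as.data.frame(pta))
  # default dimensions follow the study design
  g0 <- simulation_grid()
  expect_equal(g0$weights, c(5, 10, 20, 30, 40, 50, 60))
  expect_equal(g0$doses, seq(0.01, 0.10, by = 0.01))
  expect_equal(g0$n_virtual, 1000)

  # a restricted grid reproduces the same cells
  sub <- pta_grid(spec, simulation_grid(weights = 20, doses = 0.05,
                                        n_virtual = 300, seed = 5))
  full_cell <- pta[pta$weight == 20 & pta$dose == 0.05, ]
  expect_equal(as.data.frame(sub), as.data.frame(full_cell),
               ignore_attr = TRUE)

  # exceedance is monotone non-decreasing in dose at fixed weight
  for (w in unique(pta$weight)) {
    sub <- pta[pta$weight == w, ]
    expect_true(all(diff(sub$p_above[order(sub$dose)]) >= 0))
  }
})

test_that("simulated troughs vary with weight as the allometric model dictates", {
  spec <- published_model()
  # per-kg dosing with exponent-0.75 clearance: trough rises with weight
  med <- vapply(c(5, 10, 20, 40, 60), function(w) {
    median(simulate_trough_distribution(spec, w, 0.05, n = 4000,
                                        seed = 11))
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("Monte Carlo attainment matches the closed-form probability", {
  spec <- published_model()
  for (cell in list(c(5, 0.07), c(20, 0.05), c(60, 0.04))) {
    tr <- simulate_trough_distribution(spec, cell[1], cell[2], n = 20000,
                                       seed = 21)
    mc <- probability_of_target(tr)[["in_window"]] / 100
    cf <- sirodose:::closed_form_p_in(spec, cell[1], cell[2],
                                      target_window())
    expect_equal(mc, cf, tolerance = 0.02)
  }
})

test_that("dose recommendation picks per-weight optima and merges bands", {
  # constructed PTA table with a known optimum pattern and a tie
  spec <- published_model()
  pta <- pta_grid(spec, simulation_grid(weights = c(5, 10),
                                        doses = c(0.05, 0.07),
                                        n_virtual = 500, seed = 9))
  # single-candidate grid: that dose is recommended everywhere
  one <- pta[pta$dose == 0.07, ]
  attributes(one)[c("spec", "window", "grid")] <-
    attributes(pta)[c("spec", "window", "grid")]
  class(one) <- class(pta)
  rec1 <- recommend_dose(one)
  expect_equal(nrow(rec1), 1)
  expect_equal(rec1$dose, 0.07)
  expect_equal(c(rec1$weight_lo, rec1$weight_hi), c(5, 10))

  # a tie in p_in resolves to the lower dose
  fake <- data.frame(weight = rep(c(10, 20), each = 2),
                     dose = rep(c(0.04, 0.06), 2),
                     p_below = 0, p_in = c(80, 80, 90, 70),
                     p_above = c(20, 20, 10, 30))
  attr(fake, "spec") <- spec
  attr(fake, "window") <- target_window()
  class(fake) <- c("pta_result", "data.frame")
  rec2 <- recommend_dose(fake)
  expect_equal(rec2$dose[1], 0.04)
})

test_that("band boundaries fall at the closed-form crossover weight", {
  spec <- published_model()
  pta <- pta_grid(spec, simulation_grid(weights = c(10, 20, 30, 40),
                                        doses = c(0.04, 0.05, 0.06, 0.07),
                                        n_virtual = 2000, seed = 31))
  rec <- recommend_dose(pta)
  expect_true(nrow(rec) >= 2)
  expect_equal(rec$weight_lo[1], 10)
  expect_equal(rec$weight_hi[nrow(rec)], 40)
  # bands are ordered, non-overlapping, and contiguous
  expect_true(all(diff(rec$weight_lo) > 0))
  expect_equal(rec$weight_lo[-1], rec$weight_hi[-nrow(rec)])
  # boundaries sit where the adjacent doses attain equally (to 0.1 kg)
  for (b in seq_len(nrow(rec) - 1)) {
    w_star <- rec$weight_hi[b]
    d1 <- rec$dose[b]; d2 <- rec$dose[b + 1]
    f <- function(w) sirodose:::closed_form_p_in(spec, w, d1,
                                                 target_window()) -
      sirodose:::closed_form_p_in(spec, w, d2, target_window())
    expect_lt(abs(f(w_star)), abs(f(w_star - 0.2)))
    expect_lt(abs(f(w_star)), abs(f(w_star + 0.2)))
  }
})
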