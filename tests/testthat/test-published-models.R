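# Double-entry transcription of the five published equations, keyed
# "(x,y,z)|ipe" -> coefficient; entered independently of the JSON fixtures.
published_coefficients <- list(
  `1B7` = c(intercept = 7.89,
            "(2,11,4)|any" = -13.99, "(-1,8,2)|any" = -6.96,
            "(0,-2,9)|any" = -2.04, "(1,13,1)|any" = 22.68,
            "(1,-1,9)|any" = 12.16, "(1,2,2)|ar" = 1.84,
            "(1,11,-2)|any" = 19.60),
  `1B9` = c(intercept = 8.19,
            "(2,11,4)|any" = -18.84, "(0,-2,-1)|any" = -6.13,
            "(0,1,-2)|any" = 8.45, "(0,11,5)|any" = -8.71,
            "(-1,8,2)|any" = -7.54, "(1,6,-2)|np" = -20.98,
            "(1,13,1)|any" = 15.96, "(1,2,0)|any" = 3.93,
            "(0,0,-2)|any" = 1.61),
  `2B7` = c(intercept = 7.70,
            "(-1,9,4)|any" = 2.47, "(0,10,4)|any" = -10.58,
            "(0,7,-2)|any" = 8.22, "(-1,-2,11)|any" = -5.27,
            "(0,5,-3)|any" = -35.20, "(0,2,2)|ar" = 21.70,
            "(0,-1,9)|ar" = 0.84),
  `2B8` = c(intercept = 8.34,
            "(-3,9,4)|any" = -6.52, "(0,10,4)|any" = -9.04,
            "(0,2,-1)|any" = -7.64, "(-1,-2,11)|any" = -5.08,
            "(0,1,-2)|any" = -9.03, "(-3,8,5)|any" = 5.37,
            "(0,5,-3)|any" = -26.15, "(0,2,2)|ar" = 23.89),
  `2B9` = c(intercept = 6.66,
            "(-1,12,6)|any" = -30.48, "(1,3,6)|hba" = 10.92,
            "(0,11,3)|p-" = 16.70, "(0,12,-1)|any" = -15.21,
            "(0,10,-2)|any" = 14.18, "(0,0,-2)|any" = 0.57,
            "(-1,-2,11)|any" = -4.01, "(0,2,2)|ar" = 18.23,
            "(2,5,0)|any" = -25.70)
)

test_that("encoded equations byte-match an independent transcription", {
  sizes <- c(`1B7` = 7L, `1B9` = 9L, `2B7` = 7L, `2B8` = 8L, `2B9` = 9L)
  for (nm in names(published_coefficients)) {
    m <- load_published_model(nm)
    ref <- published_coefficients[[nm]]
    expect_equal(length(m$coefficients), unname(sizes[nm]))
    expect_identical(m$intercept, unname(ref["intercept"]))
    expect_setequal(m$keys, setdiff(names(ref), "intercept"))
    expect_identical(stats::setNames(m$coefficients, m$keys)[setdiff(names(ref), "intercept")],
                     ref[setdiff(names(ref), "intercept")])
    expect_equal(m$grid_size, 1.0)
    expect_equal(m$alignment, as.integer(substr(nm, 1, 1)))
  }
})

test_that("zero occupancy predicts the printed intercepts", {
  empty <- stats::setNames(numeric(0), character(0))
  expect_equal(predict(load_published_model("1B9"), empty), 8.19)
  expect_equal(predict(load_published_model("1B7"), empty), 7.89)
  expect_equal(predict(load_published_model("2B9"), empty), 6.66)
  expect_equal(predict(load_published_model("2B7"), empty), 7.70)
  expect_equal(predict(load_published_model("2B8"), empty), 8.34)
})

test_that("prediction is the linear form over matching occupancy keys", {
  m <- load_published_model("1B9")
  occ <- c("(1,13,1)|any" = 0.1)
  expect_equal(predict(m, occ), 8.19 + 15.96 * 0.1)
  # unknown keys ignored, missing keys treated as zero
  occ2 <- c("(1,13,1)|any" = 0.1, "(9,9,9)|any" = 5)
  expect_equal(predict(m, occ2), 8.19 + 15.96 * 0.1)
  expect_error(predict(m, c("(1,13,1)|any" = -0.1)), "non-negative")
  # linearity on random occupancy vectors over the model's own keys
  set.seed(31)
  u <- stats::setNames(runif(9), m$keys)
  v <- stats::setNames(runif(9), m$keys)
  a <- 0.3; b <- 1.7
  lhs <- predict(m, a * u + b * v)
  rhs <- a * (predict(m, u) - m$intercept) +
    b * (predict(m, v) - m$intercept) + m$intercept
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("matrix prediction matches vector prediction row-wise", {
  m <- load_published_model("2B9")
  set.seed(32)
  M <- matrix(runif(3 * 9), 3, dimnames = list(NULL, m$keys))
  got <- predict(m, M)
  for (i in 1:3) expect_equal(got[i], predict(m, M[i, ]))
})

test_that("residual convention is calculated minus experimental", {
  expect_equal(potency_residual(9.84, 9.70), 0.14)
  expect_equal(potency_residual(8.11, 9.52), -1.41)
  expect_equal(potency_residual(5, 5), 0)
  # every published table row obeys it within print rounding
  for (nm in c("1B9", "2B9")) {
    rt <- load_residual_table(nm)
    expect_true(all(abs(potency_residual(rt$pic50_calc, rt$pic50_exp) -
                          rt$residual) <= 0.005 + 1e-12))
  }
})

test_that("bioactive selection maximizes potency inside the energy window", {
  m <- load_published_model("1B9")
  # two conformers: the out-of-window one predicts higher potency but must
  # not be chosen
  occ <- rbind(c(0.0), c(1.0))
  colnames(occ) <- "(1,13,1)|any"
  ens <- list(energies = c(0, 12))
  class(ens) <- "conformer_ensemble"
  sel <- select_bioactive(ens, occ, m)
  expect_equal(sel$index, 1L)
  # single conformer
  sel1 <- select_bioactive(list(energies = 0), occ[1, , drop = FALSE], m)
  expect_equal(sel1$index, 1L)
  # 20-conformer ensemble vs brute-force oracle
  set.seed(33)
  occ20 <- matrix(runif(20 * 9), 20, dimnames = list(NULL, m$keys))
  en20 <- c(0, runif(19, 0, 15))
  sel20 <- select_bioactive(list(energies = en20), occ20, m)
  window <- which(en20 <= min(en20) + 10)
  preds <- vapply(window, function(k) predict(m, occ20[k, ]), numeric(1))
  expect_equal(sel20$index, window[which.max(preds)])
  expect_equal(sel20$predicted, max(preds))
  # ties break to the lower energy
  occ_tie <- matrix(0.2, 2, 1, dimnames = list(NULL, "(1,13,1)|any"))
  sel_tie <- select_bioactive(list(energies = c(3, 1)), occ_tie, m)
  expect_equal(sel_tie$index, 2L)
})
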