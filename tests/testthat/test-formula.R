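test_that("formula strings parse to element counts", {
  expect_equal(parseFormula("C5H9NO4"), c(C = 5L, H = 9L, N = 1L, O = 4L))
  expect_equal(parseFormula("H2O"), c(H = 2L, O = 1L))
  expect_equal(parseFormula("CH4N2O"), c(C = 1L, H = 4L, N = 2L, O = 1L))
  # repeated symbols accumulate
  expect_equal(parseFormula("CH3COOH")[["C"]], 2L)
  expect_equal(parseFormula("CH3COOH")[["O"]], 2L)
  # two-letter symbols are not split
  expect_equal(parseFormula("NaCl"), c(Na = 1L, Cl = 1L))
})

test_that("invalid formulas raise typed errors", {
  expect_error(parseFormula("C10H12R2"), class = "unsupported_formula")
  expect_error(parseFormula("C6H5(OH)"), class = "unsupported_formula")
  expect_error(parseFormula("C2H3O2-"), class = "unsupported_formula")
  err <- tryCatch(parseFormula("C5Qq2"), error = identity)
  expect_s3_class(err, "formula_parse_error")
  expect_match(conditionMessage(err), "Qq")
  expect_error(parseFormula(""), "non-empty")
  expect_error(parseFormula("C0H4"), class = "formula_parse_error")
})

test_that("parse and format are inverse on Hill-ordered formulas", {
  pool <- metabolitePool()
  for (f in pool$formula)
    expect_identical(formatFormula(parseFormula(f)), f)
  # non-Hill input is canonicalized, then stable
  expect_identical(formatFormula(parseFormula("O4C5NH9")), "C5H9NO4")
  expect_identical(formatFormula(parseFormula("ClNa")), "ClNa")
})

test_that("monoisotopic masses agree with an independent table summation", {
  expect_identical(monoisotopicMass("C"), 12)
  expect_equal(monoisotopicMass("C5H9NO4"), 147.05316, tolerance = 1e-7)
  expect_equal(monoisotopicMass("H2O"), 18.010565, tolerance = 1e-7)
  pool <- metabolitePool()
  for (f in pool$formula)
    expect_equal(monoisotopicMass(f), oracleMass(f), tolerance = 1e-9)
})

test_that("monoisotopic mass is additive over formula union", {
  set.seed(11)
  pool <- metabolitePool()$formula
  for (i in 1:50) {
    f1 <- parseFormula(sample(pool, 1))
    f2 <- parseFormula(sample(pool, 1))
    joint <- tapply(c(f1, f2),
                    factor(c(names(f1), names(f2))), sum)
    expect_equal(monoisotopicMass(joint),
                 monoisotopicMass(f1) + monoisotopicMass(f2),
                 tolerance = 1e-12)
  }
})

test_that("ppm error is signed, zero at identity, antisymmetric", {
  expect_identical(ppmError(148.06044, 148.06044), 0)
  expect_equal(ppmError(100.0005, 100.0000), 5.0, tolerance = 1e-9)
  # the reported glutamate ion sits ~5.7 ppm below theory
  expect_equal(ppmError(148.0596, 148.06044), -5.67, tolerance = 0.01)
  set.seed(3)
  x <- runif(100, 50, 1000)
  y <- x * (1 + runif(100, -1e-5, 1e-5))
  expect_equal(ppmError(x, y) / ppmError(y, x), -x / y, tolerance = 1e-9)
})
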