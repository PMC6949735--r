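test_that("Tanimoto drug-likeness follows the continuous form", {
  expect_equal(tanimoto_dl(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(tanimoto_dl(c(1, 0), c(0, 1)), 0)
  # direct arithmetic: 4 / (5 + 5 - 4)
  expect_equal(tanimoto_dl(c(1, 2), c(2, 1)), 4 / 6)

  expect_error(tanimoto_dl(c(1, 2), c(1, 2, 3)), "dimension")
  expect_error(tanimoto_dl(c(0, 0), c(0, 0)), "denominator")
})

test_that("Tanimoto score is symmetric, 1 on the diagonal, and not scale-invariant", {
  set.seed(42)
  for (i in 1:25) {
    d <- sample(2:8, 1)
    x <- rnorm(d); y <- rnorm(d)
    expect_equal(tanimoto_dl(x, y), tanimoto_dl(y, x))
    expect_equal(tanimoto_dl(x, x), 1)
  }
  # the continuous form is documented NOT to be scale-invariant
  x <- c(1, 2); y <- c(2, 1)
  expect_false(isTRUE(all.equal(tanimoto_dl(2 * x, y), tanimoto_dl(x, y))))
})

test_that("half-life predictor evaluates the published coefficients", {
  m <- hl_model_default()
  d0 <- setNames(as.list(numeric(8)), names(m$coef))
  expect_equal(predict_hl(d0, m), 13.310)
  d1 <- d0; d1$DDr09 <- 1
  expect_equal(predict_hl(d1, m), 13.310 + 0.053)
  expect_equal(m$metadata$r2, 0.65)
  expect_equal(m$metadata$n_training, 126)

  # missing descriptor is named
  expect_error(predict_hl(d0[-3], m), names(m$coef)[3])
})

test_that("half-life predictor is affine and matches a dot-product oracle", {
  m <- hl_model_default()
  set.seed(7)
  for (i in 1:50) {
    a <- setNames(as.list(rnorm(8, 0, 3)), names(m$coef))
    b <- setNames(as.list(rnorm(8, 0, 3)), names(m$coef))
    expect_equal(predict_hl(a, m), hl_oracle(a, m), tolerance = 1e-9)
    ab <- setNames(Map(`+`, a, b), names(m$coef))
    expect_equal(predict_hl(a, m) + predict_hl(b, m) - m$intercept,
                 predict_hl(ab, m), tolerance = 1e-9)
  }
})

test_that("screen applies inclusive bounds and records every failed criterion", {
  t1 <- table1_fixture()
  rep <- screen(t1)
  # berberine passes all three, quercetin fails only on half-life
  expect_true(rep$report$pass[t1$ingredient_id == "mol05"])
  expect_equal(rep$report$failed[t1$ingredient_id == "mol01"], "HL")
  # multiple violations are all listed
  expect_equal(rep$report$failed[t1$ingredient_id == "mol02"], "DL,HL")

  # boundary values are included, just-outside values are not
  edge <- data.frame(ingredient_id = c("lo", "hi", "out"),
                     name = NA, ob = c(30, 100, 29.99),
                     dl = c(0.18, 1, 0.18), hl = c(4, 8, 8.01),
                     stringsAsFactors = FALSE)
  er <- screen(edge)
  expect_equal(er$report$pass, c(TRUE, TRUE, FALSE))
  expect_equal(er$report$failed[3], "OB,HL")
})

test_that("screen report partitions the input and missing values fail as missing", {
  t1 <- table1_fixture()
  rep <- screen(t1)
  expect_equal(rep$n_pass + rep$n_fail, rep$n_total)
  expect_equal(sort(c(rep$pass$ingredient_id, rep$fail$ingredient_id)),
               sort(t1$ingredient_id))
  expect_true(all(rep$report$pass == !nzchar(rep$report$failed)))

  x <- data.frame(ingredient_id = "m1", name = NA, ob = NA_real_,
                  dl = 0.5, hl = 5, stringsAsFactors = FALSE)
  xr <- screen(x)
  expect_false(xr$report$pass)
  expect_equal(xr$report$failed, "OB:missing")
})

test_that("relaxing any threshold never shrinks the pass set", {
  set.seed(11)
  cat_df <- data.frame(ingredient_id = sprintf("m%03d", 1:200), name = NA,
                       ob = runif(200, 0, 60), dl = runif(200),
                       hl = runif(200, 0, 12), stringsAsFactors = FALSE)
  base <- screening_criteria()
  base_pass <- screen(cat_df, base)$pass$ingredient_id
  relaxed <- list(
    screening_criteria(ob_min = 20),
    screening_criteria(dl_min = 0.1),
    screening_criteria(hl_min = 2),
    screening_criteria(hl_max = 10),
    screening_criteria(ob_min = 0, dl_min = 0, hl_min = 0, hl_max = Inf)
  )
  for (cr in relaxed) {
    expect_true(all(base_pass %in% screen(cat_df, cr)$pass$ingredient_id))
  }
})

test_that("retention rate rounds half-up to two decimals", {
  expect_equal(retention_rate(41, 382), 10.73)
  expect_equal(retention_rate(0, 10), 0)
  expect_equal(retention_rate(382, 382), 100)
  # half-up, not banker's: 81/800 = 10.125% must round to 10.13 (an exact
  # binary fraction, so the tie is genuine)
  expect_equal(retention_rate(81, 800), 10.13)
  expect_error(retention_rate(1, 0), "positive")
  expect_error(retention_rate(5, 4))
})

test_that("packaged default criteria match the stated thresholds", {
  cr <- criteria_default()
  expect_equal(cr$ob_min, 30)
  expect_equal(cr$dl_min, 0.18)
  expect_equal(cr$hl_min, 4)
  expect_equal(cr$hl_max, 8)
})
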