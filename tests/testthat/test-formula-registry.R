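test_that("registry holds 42 stable entries with published cut-offs", {
  reg <- btt_formulae()
  expect_length(reg, 42)
  expect_equal(names(reg), names(btt_formulae()))  # stable order

  sl <- reg$shine_lal
  expect_equal(sl$expression, "mcv^2 * mch / 100")
  expect_equal(sl$cutoff, 1530)
  expect_equal(sl$comparator, "<")

  scs <- reg$scs_btt
  expect_equal(scs$cutoff, 24.99)
  expect_equal(scs$comparator, "<")

  expect_equal(sum(vapply(reg, function(f) f$kind, "") == "composite"), 2)
})

test_that("evaluation matches hand arithmetic on the printed coefficients", {
  rec <- data.frame(hb = 15, hct = 40, mcv = 80, mch = 27, mchc = 33,
                    rbc = 5, rdw = 14)
  expect_equal(evaluate_formula("scs_btt", rec), 25.5223, tolerance = 1e-12)
  expect_equal(evaluate_formula("mentzer",
                                transform(rec, mcv = 65, rbc = 6.5)), 10)
  expect_equal(evaluate_formula("bordbar", rec), 0)   # |80-MCV| vanishes
})

test_that("classification follows the printed comparison strictness", {
  rec <- data.frame(hb = 12, hct = 36, mcv = 65, mch = 22, mchc = 31,
                    rbc = 5, rdw = 15)
  # mentzer value 13 exactly: bare '<' classifies the boundary negative
  rec$mcv <- 65; rec$rbc <- 5  # 65/5 = 13
  expect_false(classify_record("mentzer", rec))
  rec$rbc <- 6.5               # 10 < 13
  expect_true(classify_record("mentzer", rec))
  # scs 25.5223 vs < 24.99 is negative
  rec2 <- data.frame(hb = 15, hct = 40, mcv = 80, mch = 27, mchc = 33,
                     rbc = 5, rdw = 14)
  expect_false(classify_record("scs_btt", rec2))
  # cruise boundary: '>= 42.63' is inclusive
  env <- data.frame(hb = 12, hct = 36, mcv = 80, mch = 27, mchc = 33,
                    rbc = 5, rdw = 14)
  v <- evaluate_formula("cruise", env)
  env$rdw <- env$rdw + (42.63 - v) / 0.523   # push value onto the boundary
  expect_equal(evaluate_formula("cruise", env), 42.63, tolerance = 1e-9)
  expect_true(classify_record("cruise", env))
})

test_that("every simple formula agrees with its naive oracle on fuzzed records", {
  reg <- btt_formulae()
  set.seed(11)
  recs <- data.frame(hb = runif(60, 6, 17), hct = runif(60, 20, 52),
                     mcv = runif(60, 52, 110), mch = runif(60, 14, 36),
                     mchc = runif(60, 26, 37), rbc = runif(60, 3, 7),
                     rdw = runif(60, 11, 24))
  for (spec in reg) {
    if (spec$kind != "simple") next
    got <- evaluate_formula(spec, recs)
    want <- naive_formula_values(spec$formula_id, recs)
    expect_equal(got, want, tolerance = 1e-12, label = spec$formula_id)
    calls <- classify_record(spec, recs)
    naive_calls <- switch(spec$comparator,
                          "<" = want < spec$cutoff, "<=" = want <= spec$cutoff,
                          ">" = want > spec$cutoff, ">=" = want >= spec$cutoff)
    expect_equal(calls, naive_calls, label = paste(spec$formula_id, "calls"))
  }
})

test_that("below-threshold formulae flip classification at most once in MCV", {
  # Shine & Lal is strictly increasing in MCV with MCH fixed
  mcvs <- seq(50, 120, by = 0.5)
  recs <- data.frame(hb = 12, hct = 36, mcv = mcvs, mch = 24, mchc = 32,
                     rbc = 5, rdw = 14)
  calls <- classify_record("shine_lal", recs)
  expect_lte(sum(diff(calls) != 0), 1)
  expect_true(calls[1])          # microcytic end is BTT-like
  expect_false(calls[length(calls)])
})

test_that("composite formulae vote over configured members", {
  reg <- btt_formulae()
  expect_error(evaluate_composite("janel_11t", make_cohort_df(2), reg),
               "set_composite_members")
  members <- c("mentzer", "shine_lal", "ehsani", "sirdah", "green_king",
               "sb", "ef", "kerman_2", "sehgal", "jayabose_rdwi", "kerman_1")
  reg <- set_composite_members(reg, "janel_11t", members)
  # strongly carrier-like record: every member fires
  pos <- data.frame(hb = 11, hct = 33, mcv = 58, mch = 18, mchc = 30,
                    rbc = 5.9, rdw = 16)
  expect_equal(evaluate_composite("janel_11t", pos, reg), 11L)
  expect_true(classify_record("janel_11t", pos, reg))
  # clearly normal record: no member fires
  neg <- data.frame(hb = 14.5, hct = 43, mcv = 92, mch = 30, mchc = 33,
                    rbc = 4.4, rdw = 12.5)
  expect_equal(evaluate_composite("janel_11t", neg, reg), 0L)
  expect_false(classify_record("janel_11t", neg, reg))
  # vote threshold >= 8 is inclusive
  votes <- evaluate_composite("janel_11t", pos, reg)
  expect_true(votes >= 8)
  expect_error(set_composite_members(reg, "mentzer", members), "not a composite")
  expect_error(set_composite_members(reg, "index26", c("nope")), "unknown member")
})

test_that("registry exports and re-imports losslessly", {
  reg <- btt_formulae()
  reg <- set_composite_members(reg, "janel_11t",
                               c("mentzer", "shine_lal", "ehsani"))
  path <- tempfile(fileext = ".csv")
  write_formula_registry(reg, path)
  back <- read_formula_registry(path)
  expect_equal(names(back), names(reg))
  for (id in names(reg)) {
    expect_equal(back[[id]]$expression, reg[[id]]$expression, label = id)
    expect_equal(back[[id]]$cutoff, reg[[id]]$cutoff, label = id)
    expect_equal(back[[id]]$comparator, reg[[id]]$comparator, label = id)
  }
  expect_equal(back$janel_11t$members, reg$janel_11t$members)
})

test_that("zero denominators raise an error naming the formula", {
  rec <- data.frame(hb = 12, hct = 36, mcv = 80, mch = 27, mchc = 33,
                    rbc = 1e-300, rdw = 14)
  rec$rbc <- 0  # slipped past validation
  expect_error(evaluate_formula("mentzer", rec), "mentzer")
})
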