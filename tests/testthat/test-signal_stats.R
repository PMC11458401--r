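# Disproportionality statistics: frozen worked examples, oracle
# equivalence, null behaviour, monotonicity, threshold logic, ranking.

test_that("worked example (10, 90, 100, 9900) reproduces the closed forms", {
  r <- ror_score(10, 90, 100, 9900)
  expect_equal(r$estimate, 11.0)
  expect_equal(r$lower, 5.559515, tolerance = 1e-6)
  expect_equal(r$upper, 21.76449, tolerance = 1e-6)

  p <- prr_score(10, 90, 100, 9900)
  expect_equal(p$estimate, 10.0)

  expect_equal(chi2_score(10, 90, 100, 9900, yates = FALSE), 74.44717,
               tolerance = 1e-6)
  expect_equal(chi2_score(10, 90, 100, 9900, yates = TRUE), 66.32694,
               tolerance = 1e-6)

  e <- ebgm_score(10, 90, 100, 9900)
  expect_equal(e$ebgm, 10 * 10100 / (100 * 110))

  # frozen from the brute-force oracle (strong shrinkage at a = 10)
  ic <- bcpnn_score(10, 90, 100, 9900)
  expect_equal(ic$ic, 2.382489, tolerance = 1e-6)
  expect_lt(ic$ic025, ic$ic)
})

test_that("independence tables give ROR = PRR = EBGM = 1 and IC near 0", {
  r <- ror_score(10, 90, 90, 810)
  p <- prr_score(10, 90, 90, 810)
  e <- ebgm_score(10, 90, 90, 810)
  expect_equal(r$estimate, 1)
  expect_equal(p$estimate, 1)
  expect_equal(e$ebgm, 1)
  expect_equal(chi2_score(10, 90, 90, 810, yates = FALSE), 0)
  expect_lt(abs(bcpnn_score(10, 90, 90, 810)$ic), 0.05)
})

test_that("zero cells raise a named error without correction and are Haldane-corrected with it", {
  expect_error(ror_score(3, 0, 5, 100), "'b'",
               class = "faersignal_undefined_score")
  r <- ror_score(3, 0, 5, 100, correction = "haldane")
  expect_equal(r$estimate, (3.5 * 100.5) / (0.5 * 5.5))
  # correction applies only to tables that contain a zero
  r2 <- ror_score(c(3, 10), c(0, 90), c(5, 100), c(100, 9900),
                  correction = "haldane")
  expect_equal(r2$estimate[2], 11.0)
})

test_that("the BCPNN priors regularize degenerate tables", {
  ic <- bcpnn_score(1, 0, 0, 0)
  expect_true(is.finite(ic$ic))
  expect_true(is.finite(ic$ic025))
  expect_lt(ic$ic025, ic$ic)
})

test_that("IC approaches log2(EBGM) as counts grow (shrinkage vanishes)", {
  small <- bcpnn_score(10, 90, 100, 9900)$ic
  big <- bcpnn_score(1000, 9000, 10000, 990000)$ic
  lim <- log2(ebgm_score(10, 90, 100, 9900)$ebgm)
  expect_lt(abs(big - lim), 0.02)
  expect_lt(abs(big - lim), abs(small - lim))
})

test_that("all five statistics match the brute-force oracle on random tables", {
  tabs <- random_tables(200, seed = 2024)
  r <- ror_score(tabs$a, tabs$b, tabs$c, tabs$d)
  p <- prr_score(tabs$a, tabs$b, tabs$c, tabs$d)
  x0 <- chi2_score(tabs$a, tabs$b, tabs$c, tabs$d, yates = FALSE)
  x1 <- chi2_score(tabs$a, tabs$b, tabs$c, tabs$d, yates = TRUE)
  ic <- bcpnn_score(tabs$a, tabs$b, tabs$c, tabs$d)
  e <- ebgm_score(tabs$a, tabs$b, tabs$c, tabs$d)
  o <- lapply(seq_len(nrow(tabs)), function(i) {
    oracle_one(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
  })
  pull <- function(f) vapply(o, `[[`, 0, f)
  expect_lt(max_rel_err(r$estimate, pull("ror")), 1e-9)
  expect_lt(max_rel_err(r$lower, pull("ror_lo")), 1e-9)
  expect_lt(max_rel_err(p$estimate, pull("prr")), 1e-9)
  expect_lt(max_rel_err(x0, pull("chi2_plain")), 1e-9)
  expect_lt(max_rel_err(x1, pull("chi2_yates")), 1e-9)
  expect_lt(max(abs(ic$ic - pull("ic"))), 1e-9)
  expect_lt(max(abs(ic$ic025 - pull("ic025"))), 1e-9)
  expect_lt(max_rel_err(e$ebgm, pull("ebgm")), 1e-9)
  expect_lt(max_rel_err(e$ebgm05, pull("ebgm05")), 1e-9)
})

test_that("the chi-square agrees with stats::chisq.test on both corrections", {
  tabs <- random_tables(50, seed = 77)
  for (i in seq_len(nrow(tabs))) {
    m <- matrix(c(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]), 2, byrow = TRUE)
    ref0 <- suppressWarnings(stats::chisq.test(m, correct = FALSE))$statistic
    ref1 <- suppressWarnings(stats::chisq.test(m, correct = TRUE))$statistic
    expect_equal(chi2_score(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i],
                            yates = FALSE), unname(ref0), tolerance = 1e-8)
    expect_equal(chi2_score(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i],
                            yates = TRUE), unname(ref1), tolerance = 1e-8)
  }
})

test_that("each statistic is strictly increasing in a with margins held fixed", {
  a <- 10:40
  b <- 100 - a
  c <- 110 - a
  d <- 9890 + a
  r <- ror_score(a, b, c, d)$estimate
  p <- prr_score(a, b, c, d)$estimate
  ic <- bcpnn_score(a, b, c, d)$ic
  e <- ebgm_score(a, b, c, d)$ebgm
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(p) > 0))
  expect_true(all(diff(ic) > 0))
  expect_true(all(diff(e) > 0))

  # decisions are monotone: no flag flips from pass to fail as a grows
  tabs <- tibble::tibble(event_id = sprintf("E%02d", seq_along(a)),
                         level = "PT", a = a, b = b, c = c, d = d)
  sc <- score_all(tabs)
  sc <- sc[order(sc$a), ]
  for (flag in c("pass_ror", "pass_prr", "pass_bcpnn", "pass_ebgm")) {
    expect_true(all(diff(as.integer(sc[[flag]])) >= 0))
  }
})

test_that("ROR intervals achieve nominal coverage on Poisson null tables", {
  tabs <- withr::with_seed(4242, tibble::tibble(
    a = stats::rpois(10000, 20), b = stats::rpois(10000, 2000),
    c = stats::rpois(10000, 200), d = stats::rpois(10000, 20000)
  ))
  tabs <- tabs[tabs$a > 0 & tabs$b > 0 & tabs$c > 0 & tabs$d > 0, ]
  r <- ror_score(tabs$a, tabs$b, tabs$c, tabs$d)
  coverage <- mean(r$lower <= 1 & r$upper >= 1)
  expect_gt(coverage, 0.93)
  expect_lt(coverage, 0.97)
})

test_that("threshold decisions follow the published rules at the boundaries", {
  eps <- 1e-9
  grid <- tibble::tibble(
    a = c(2, 3, 3, 3, 3, 3, 3, 3, 3),
    ror_low = c(2, 2, 1 - eps, 1 + eps, 2, 2, 2, 2, 2),
    prr_low = c(2, 2, 2, 2, 1 - eps, 2, 2, 2, 2),
    ic025 = c(1, 1, 1, 1, 1, -eps, eps, 1, 1),
    ebgm05 = c(3, 3, 3, 3, 3, 3, 3, 2 - eps, 2 + eps)
  )
  out <- decide(grid)
  expect_equal(out$pass_ror,
               c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(out$pass_prr[5], FALSE)
  expect_equal(out$pass_bcpnn, c(rep(TRUE, 5), FALSE, TRUE, TRUE, TRUE))
  expect_equal(out$pass_ebgm, c(rep(TRUE, 7), FALSE, TRUE))
  expect_equal(out$pass_all,
               out$pass_ror & out$pass_prr & out$pass_bcpnn & out$pass_ebgm)
})

test_that("score_all ranks by EBGM descending with lexicographic tie-breaks", {
  tabs <- tibble::tibble(
    event_id = c("ZETA", "ALPHA", "MID"),
    level = "PT",
    a = c(20, 20, 10), b = c(80, 80, 90),
    c = c(50, 50, 100), d = c(9850, 9850, 9800)
  )
  sc <- score_all(tabs)
  # ZETA and ALPHA share identical cells, hence identical ebgm
  expect_equal(sc$event_id[1:2], c("ALPHA", "ZETA"))
  expect_true(all(diff(sc$ebgm) <= 0))
})
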