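# Disproportionality statistics on the 2x2 four-grid (a, b, c, d):
#
#   ROR  = ad / bc                        (reporting odds ratio)
#   PRR  = [a/(a+b)] / [c/(c+d)]          (proportional reporting ratio)
#   chi2 = Pearson chi-square, optional Yates continuity correction
#   IC   = BCPNN information component, log2 of observed over expected
#          under independent Beta priors on the marginal reporting
#          probabilities (Bate et al. style), with IC025 = E(IC) - 2*SD
#   EBGM = a*N / ((a+b)(a+c)), the observed-over-expected (relative
#          reporting ratio) form, with EBGM05 the lower limit of a
#          Woolf-type 95% interval
#
# All score functions are vectorized over the four cell arguments.

# Validate cells and return them as doubles (integer cells would
# overflow in products like (a+b)(c+d)(a+c)(b+d)).
check_cells <- function(a, b, c, d) {
  n <- length(a)
  if (!all(lengths(list(b, c, d)) == n)) {
    abort("a, b, c, d must have equal length", class = "faersignal_stat_error")
  }
  if (any(is.na(c(a, b, c, d))) || any(c(a, b, c, d) < 0)) {
    abort("cells must be non-negative and non-missing",
          class = "faersignal_stat_error")
  }
  list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
       d = as.numeric(d))
}

# Haldane-Anscombe: add 0.5 to every cell of tables containing any zero.
haldane <- function(a, b, c, d) {
  z <- a == 0 | b == 0 | c == 0 | d == 0
  list(a = a + 0.5 * z, b = b + 0.5 * z, c = c + 0.5 * z, d = d + 0.5 * z)
}

name_zero_cell <- function(a, b, c, d) {
  cells <- cbind(a = a == 0, b = b == 0, c = c == 0, d = d == 0)
  idx <- which(rowSums(cells) > 0)[1]
  cell <- colnames(cells)[which(cells[idx, ])[1]]
  abort(sprintf("zero cell '%s' in table %d makes the score undefined; use correction = \"haldane\"",
                cell, idx),
        class = "faersignal_undefined_score")
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = ad/bc`, with the Woolf interval
#' `exp(ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param a,b,c,d cells of the 2x2 table(s); vectors are accepted.
#' @param correction `"none"` (zero cells raise an error naming the
#'   cell) or `"haldane"` (0.5 added to every cell of tables containing
#'   a zero).
#' @return Tibble with columns `estimate`, `lower`, `upper`.
#' @examples
#' ror_score(10, 90, 100, 9900) # 11.0 (5.56, 21.76)
#' @export
ror_score <- function(a, b, c, d, correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  cl <- check_cells(a, b, c, d)
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  if (correction == "haldane") {
    h <- haldane(a, b, c, d)
    a <- h$a; b <- h$b; c <- h$c; d <- h$d
  } else if (any(a == 0 | b == 0 | c == 0 | d == 0)) {
    name_zero_cell(a, b, c, d)
  }
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble::tibble(
    estimate = est,
    lower = exp(log(est) - 1.96 * se),
    upper = exp(log(est) + 1.96 * se)
  )
}

#' Proportional reporting ratio with 95% confidence interval
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`, with interval
#' `exp(ln PRR +/- 1.96 * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#'
#' @inheritParams ror_score
#' @return Tibble with columns `estimate`, `lower`, `upper`.
#' @examples
#' prr_score(10, 90, 100, 9900) # 10.0
#' @export
prr_score <- function(a, b, c, d, correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  cl <- check_cells(a, b, c, d)
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  if (correction == "haldane") {
    h <- haldane(a, b, c, d)
    a <- h$a; b <- h$b; c <- h$c; d <- h$d
  } else if (any(a == 0 | c == 0)) {
    name_zero_cell(a, b, c, d)
  }
  est <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  tibble::tibble(
    estimate = est,
    lower = exp(log(est) - 1.96 * se),
    upper = exp(log(est) + 1.96 * se)
  )
}

#' Pearson chi-square for the 2x2 table
#'
#' With `yates = TRUE` (default) the Yates continuity correction is
#' applied: `chi2 = N * (|ad - bc| - N/2)^2 / [(a+b)(c+d)(a+c)(b+d)]`,
#' where the `N/2` reduction is floored at zero. Tables with a zero
#' margin return 0 with a warning.
#'
#' @inheritParams ror_score
#' @param yates apply the continuity correction (default `TRUE`).
#' @return Numeric vector of chi-square statistics.
#' @examples
#' chi2_score(10, 90, 100, 9900, yates = FALSE) # 74.45
#' chi2_score(10, 90, 100, 9900)                # 66.33
#' @export
chi2_score <- function(a, b, c, d, yates = TRUE) {
  cl <- check_cells(a, b, c, d)
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  bad <- denom == 0
  if (any(bad)) warn("zero margin: chi-square set to 0 for affected table(s)")
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(dev - n / 2, 0)
  out <- ifelse(bad, 0, n * dev^2 / ifelse(bad, 1, denom))
  as.numeric(out)
}

#' BCPNN priors
#'
#' Hyperparameters of the Bayesian confidence propagation neural network
#' information component. The defaults are the canonical choices
#' (`alpha1 = beta1 = gamma11 = 1`, `alpha = beta = 2`), under which the
#' posterior expectation of IC shrinks toward 0. The joint prior
#' parameter `gamma` is derived, not stored:
#' `gamma = gamma11 * (N+alpha)(N+beta) / ((a+b+alpha1)(a+c+beta1))`.
#'
#' @param alpha1,beta1,gamma11,alpha,beta strictly positive reals.
#' @return A `bcpnn_priors` list.
#' @export
bcpnn_priors <- function(alpha1 = 1, beta1 = 1, gamma11 = 1,
                         alpha = 2, beta = 2) {
  vals <- c(alpha1 = alpha1, beta1 = beta1, gamma11 = gamma11,
            alpha = alpha, beta = beta)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all BCPNN prior parameters must be strictly positive",
          class = "faersignal_config_error")
  }
  structure(as.list(vals), class = "bcpnn_priors")
}

#' BCPNN information component with IC025
#'
#' Posterior expectation and variance of the information component
#' `IC = log2 p(x,y) / (p(x) p(y))`:
#'
#' `E(IC) = log2 [(a + g11)(N + al)(N + be)] / [(N + g)(a+b+a1)(a+c+b1)]`
#'
#' `V(IC) = (1/ln^2 2) * [ (N - a + g - g11) / ((a + g11)(1 + N + g))`
#' `  + (N - (a+b) + al - a1) / ((a+b+a1)(1 + N + al))`
#' `  + (N - (a+c) + be - b1) / ((a+c+b1)(1 + N + be)) ]`
#'
#' with `g` the derived joint prior parameter (see [bcpnn_priors()]).
#' The reported lower bound is `IC025 = E(IC) - 2 * sqrt(V(IC))`, the
#' "minus two standard deviations" convention, not a posterior quantile.
#' The priors regularize degenerate tables, so every input yields a
#' finite score.
#'
#' @inheritParams ror_score
#' @param priors a [bcpnn_priors()] object.
#' @return Tibble with columns `ic`, `ic_var`, `ic025` (in bits).
#' @export
bcpnn_score <- function(a, b, c, d, priors = bcpnn_priors()) {
  stopifnot(inherits(priors, "bcpnn_priors"))
  cl <- check_cells(a, b, c, d)
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  n <- a + b + c + d
  a1 <- priors$alpha1; b1 <- priors$beta1; g11 <- priors$gamma11
  al <- priors$alpha;  be <- priors$beta
  g <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  ic <- log2((a + g11) * (n + al) * (n + be) /
               ((n + g) * (a + b + a1) * (a + c + b1)))
  vic <- ((n - a + g - g11) / ((a + g11) * (1 + n + g)) +
            (n - (a + b) + al - a1) / ((a + b + a1) * (1 + n + al)) +
            (n - (a + c) + be - b1) / ((a + c + b1) * (1 + n + be))) / log(2)^2
  tibble::tibble(ic = ic, ic_var = vic, ic025 = ic - 2 * sqrt(vic))
}

#' Empirical Bayes geometric mean (observed/expected form) with EBGM05
#'
#' `EBGM = a * N / ((a+b)(a+c))` — the ratio of the observed count to
#' the count expected under independence of drug and event — with
#' `EBGM05 = exp(ln EBGM - 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))` as the
#' lower limit of the 95% interval. This closed form is not the full
#' gamma-Poisson mixture shrinker; no hyperparameters are estimated.
#' Zero cells are Haldane-corrected for the standard error only; the
#' point estimate always uses the raw cells. `a = 0` yields
#' `ebgm = ebgm05 = 0`.
#'
#' @inheritParams ror_score
#' @return Tibble with columns `ebgm`, `ebgm05`.
#' @examples
#' ebgm_score(10, 90, 100, 9900) # 9.1818
#' @export
ebgm_score <- function(a, b, c, d) {
  cl <- check_cells(a, b, c, d)
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  n <- a + b + c + d
  if (any((a + b) == 0 | (a + c) == 0)) {
    abort("zero margin (a+b or a+c): EBGM undefined",
          class = "faersignal_undefined_score")
  }
  est <- a * n / ((a + b) * (a + c))
  h <- haldane(a, b, c, d)
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)
  lo <- exp(log(est) - 1.96 * se)
  zero <- a == 0
  tibble::tibble(ebgm = ifelse(zero, 0, est),
                 ebgm05 = ifelse(zero, 0, lo))
}

#' Signal thresholds
#'
#' The conventional decision rules: ROR and PRR require at least
#' `min_a` target reports of the event and a 95% CI lower limit above
#' 1; BCPNN requires `IC025 > 0`; EBGM requires `EBGM05 > 2`. A pair is
#' a consensus signal (`pass_all`) when all four rules fire.
#'
#' @param min_a minimum `a` for the ROR/PRR rules (default 3).
#' @param ror_ci_low_gt,prr_ci_low_gt CI lower-limit cutoffs (default 1).
#' @param ic025_gt IC025 cutoff (default 0).
#' @param ebgm05_gt EBGM05 cutoff (default 2).
#' @return A `signal_thresholds` list.
#' @export
signal_thresholds <- function(min_a = 3L, ror_ci_low_gt = 1,
                              prr_ci_low_gt = 1, ic025_gt = 0,
                              ebgm05_gt = 2) {
  stopifnot_scalar_count(min_a, "min_a")
  if (min_a < 1) {
    abort("'min_a' must be >= 1", class = "faersignal_config_error")
  }
  structure(
    list(min_a = as.integer(min_a), ror_ci_low_gt = ror_ci_low_gt,
         prr_ci_low_gt = prr_ci_low_gt, ic025_gt = ic025_gt,
         ebgm05_gt = ebgm05_gt),
    class = "signal_thresholds"
  )
}

#' Apply the four signal-decision rules
#'
#' @param scores data frame with columns `a`, `ror_low`, `prr_low`,
#'   `ic025`, `ebgm05` (as produced by [score_all()]).
#' @param th a [signal_thresholds()] object.
#' @return `scores` with logical columns `pass_ror`, `pass_prr`,
#'   `pass_bcpnn`, `pass_ebgm`, `pass_all` added; missing scores never
#'   pass.
#' @export
decide <- function(scores, th = signal_thresholds()) {
  stopifnot(inherits(th, "signal_thresholds"))
  need <- c("a", "ror_low", "prr_low", "ic025", "ebgm05")
  missing <- setdiff(need, names(scores))
  if (length(missing) > 0) {
    abort(paste0("decide(): missing score column(s): ",
                 paste(missing, collapse = ", ")),
          class = "faersignal_stat_error")
  }
  pass <- function(x) !is.na(x) & x
  scores$pass_ror <- pass(scores$a >= th$min_a &
                            scores$ror_low > th$ror_ci_low_gt)
  scores$pass_prr <- pass(scores$a >= th$min_a &
                            scores$prr_low > th$prr_ci_low_gt)
  scores$pass_bcpnn <- pass(scores$ic025 > th$ic025_gt)
  scores$pass_ebgm <- pass(scores$ebgm05 > th$ebgm05_gt)
  scores$pass_all <- scores$pass_ror & scores$pass_prr &
    scores$pass_bcpnn & scores$pass_ebgm
  scores
}

#' Score every contingency table and rank by EBGM
#'
#' Computes ROR, PRR, chi-square, IC and EBGM (with intervals) for each
#' table, applies the threshold rules, and returns one row per
#' drug-event pair in deterministic order: EBGM descending, ties broken
#' by `event_id`. The Haldane correction is used automatically for
#' tables with zero cells (raw cells are always reported alongside).
#'
#' @param tables tibble of contingency tables from [build_pt_tables()]
#'   or [build_soc_tables()].
#' @param priors a [bcpnn_priors()] object.
#' @param thresholds a [signal_thresholds()] object.
#' @param yates use the continuity-corrected chi-square (default `TRUE`).
#' @return Tibble with columns `event_id`, `level`, `a`, `b`, `c`, `d`,
#'   `ror`, `ror_low`, `ror_high`, `prr`, `prr_low`, `prr_high`,
#'   `chi2`, `ic`, `ic025`, `ebgm`, `ebgm05` and the five `pass_*`
#'   flags.
#' @export
score_all <- function(tables, priors = bcpnn_priors(),
                      thresholds = signal_thresholds(), yates = TRUE) {
  need <- c("event_id", "level", "a", "b", "c", "d")
  if (!all(need %in% names(tables))) {
    abort("'tables' must have columns event_id, level, a, b, c, d",
          class = "faersignal_stat_error")
  }
  if (nrow(tables) == 0) {
    return(tibble::tibble(
      event_id = character(), level = character(), a = integer(),
      b = integer(), c = integer(), d = integer(), ror = double(),
      ror_low = double(), ror_high = double(), prr = double(),
      prr_low = double(), prr_high = double(), chi2 = double(),
      ic = double(), ic025 = double(), ebgm = double(), ebgm05 = double(),
      pass_ror = logical(), pass_prr = logical(), pass_bcpnn = logical(),
      pass_ebgm = logical(), pass_all = logical()
    ))
  }
  a <- tables$a; b <- tables$b; c <- tables$c; d <- tables$d
  s_ror <- ror_score(a, b, c, d, correction = "haldane")
  s_prr <- prr_score(a, b, c, d, correction = "haldane")
  s_chi <- suppressWarnings(chi2_score(a, b, c, d, yates = yates))
  s_ic <- bcpnn_score(a, b, c, d, priors = priors)
  s_eb <- ebgm_score(a, b, c, d)
  out <- tibble::tibble(
    event_id = tables$event_id, level = tables$level,
    a = a, b = b, c = c, d = d,
    ror = s_ror$estimate, ror_low = s_ror$lower, ror_high = s_ror$upper,
    prr = s_prr$estimate, prr_low = s_prr$lower, prr_high = s_prr$upper,
    chi2 = s_chi,
    ic = s_ic$ic, ic025 = s_ic$ic025,
    ebgm = s_eb$ebgm, ebgm05 = s_eb$ebgm05
  )
  out <- decide(out, thresholds)
  dplyr::arrange(out, dplyr::desc(.data$ebgm), .data$event_id)
}
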