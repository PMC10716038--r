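#' Fit a signed two-component titration
#'
#' For fusion-protein titrations in which two binding sites pull the
#' normalized response in opposite directions: one site contributes a
#' positive amplitude, the other a negative one. Two protocols are offered.
#'
#' `mode = "piecewise"` reproduces the split-fit protocol used for such
#' curves: points at or below `split_conc` are fitted with a single
#' positive-amplitude site (optionally clamping the plateau to
#' `fixed_max_response`, e.g. the plateau fitted on a reference curve where
#' only that site binds), and points above `split_conc` are fitted with a
#' single negative-amplitude site on top of a free baseline. The protocol is
#' simple but systematically biased because each segment ignores the other
#' component's tail.
#'
#' `mode = "simultaneous"` fits the full two-component sum
#' `R(c) = R0 + A_pos * c/(c + Kd_pos) + A_neg * c/(c + Kd_neg)` with
#' `A_pos > 0 > A_neg` enforced by log-parameterized magnitudes; on
#' noiseless data this recovers the generating parameters essentially
#' exactly.
#'
#' @param curve a [titration_curve()].
#' @param mode `"piecewise"` or `"simultaneous"`.
#' @param split_conc concentration splitting the two regimes (uM).
#' @param fixed_max_response optional plateau value clamped in the
#'   low-concentration (positive) segment of the piecewise protocol.
#' @return a `tern_fit` with `kd_pos`, `kd_neg`, `a_pos`, `a_neg`.
#' @export
fit_two_site_signed <- function(curve,
                                mode = c("piecewise", "simultaneous"),
                                split_conc = 5,
                                fixed_max_response = NULL) {
  stopifnot(inherits(curve, "titration_curve"))
  mode <- match.arg(mode)
  if (mode == "piecewise") {
    .fit_two_site_piecewise(curve, split_conc, fixed_max_response)
  } else {
    .fit_two_site_simultaneous(curve, split_conc, fixed_max_response)
  }
}

.fit_two_site_piecewise <- function(curve, split_conc, fixed_max_response) {
  lo <- curve[curve$conc <= split_conc, , drop = FALSE]
  hi <- curve[curve$conc > split_conc, , drop = FALSE]
  if (length(unique(lo$conc)) < 4L || length(unique(hi$conc)) < 4L) {
    stop("piecewise protocol needs >= 4 distinct concentrations on each ",
         "side of split_conc", call. = FALSE)
  }
  flags <- character(0)

  # low segment: rising one-site component
  if (is.null(fixed_max_response)) {
    flo <- fit_one_site(titration_curve(lo$conc, lo$response))
    kd_pos <- flo$kd; a_pos <- flo$a; r0 <- flo$r0
    lo_rss <- flo$rss; lo_ok <- flo$converged; kd_pos_se <- flo$kd_se
    if (is.finite(a_pos) && a_pos <= 0) {
      flags <- c(flags, "positive_amplitude_violation")
    }
  } else {
    resid_lo <- function(p) {
      lo$response - (p[1] + (fixed_max_response - p[1]) *
                       theta_one_site(lo$conc, exp(p[2])))
    }
    lkd0 <- stats::median(log(lo$conc[lo$conc > 0]))
    flo <- .lm_fit(c(r0 = min(lo$response), lkd = lkd0), resid_lo,
                   lower = c(-Inf, .LKD_LO), upper = c(Inf, .LKD_HI))
    r0 <- flo$par[["r0"]]; kd_pos <- exp(flo$par[["lkd"]])
    a_pos <- fixed_max_response - r0
    lo_rss <- flo$rss; lo_ok <- flo$info %in% 1:3
    kd_pos_se <- kd_pos * flo$se[["lkd"]]
    if (a_pos <= 0) flags <- c(flags, "positive_amplitude_violation")
  }

  # high segment: falling one-site component; its plateau is the clamped
  # maximum response when one was supplied, otherwise a free baseline
  lkd0 <- stats::median(log(hi$conc))
  amp0 <- max(abs(diff(range(hi$response))), 1e-3)
  if (is.null(fixed_max_response)) {
    resid_hi <- function(p) {
      hi$response - (p[1] - exp(p[2]) * theta_one_site(hi$conc, exp(p[3])))
    }
    fhi <- .lm_fit(c(cc = max(hi$response), lamp = log(amp0), lkd = lkd0),
                   resid_hi, lower = c(-Inf, -Inf, .LKD_LO),
                   upper = c(Inf, Inf, .LKD_HI))
  } else {
    resid_hi <- function(p) {
      hi$response - (fixed_max_response -
                       exp(p[1]) * theta_one_site(hi$conc, exp(p[2])))
    }
    fhi <- .lm_fit(c(lamp = log(amp0), lkd = lkd0), resid_hi,
                   lower = c(-Inf, .LKD_LO), upper = c(Inf, .LKD_HI))
  }
  kd_neg <- exp(fhi$par[["lkd"]])
  a_neg <- -exp(fhi$par[["lamp"]])
  if (is.finite(fhi$se[["lamp"]]) && fhi$se[["lamp"]] > 3 ||
      is.finite(fhi$se[["lkd"]]) && fhi$se[["lkd"]] > 3) {
    flags <- c(flags, "negative_component_unresolved")
  }
  converged <- length(flags) == 0 && isTRUE(lo_ok) && fhi$info %in% 1:3
  est <- c(kd_pos = unname(kd_pos), kd_neg = unname(kd_neg),
           a_pos = unname(a_pos), a_neg = unname(a_neg))
  .new_fit_result("two_site_piecewise", estimates = est,
                  se = c(kd_pos = unname(kd_pos_se),
                         kd_neg = unname(kd_neg * fhi$se[["lkd"]]),
                         a_pos = NA_real_,
                         a_neg = unname(abs(a_neg) * fhi$se[["lamp"]])),
                  cov = NULL,
                  rss = lo_rss + fhi$rss,
                  sigma = NA_real_, converged = converged, flags = flags,
                  extra = list(kd_pos = unname(kd_pos),
                               kd_neg = unname(kd_neg),
                               a_pos = unname(a_pos), a_neg = unname(a_neg),
                               split_conc = split_conc))
}

.fit_two_site_simultaneous <- function(curve, split_conc,
                                       fixed_max_response) {
  conc <- curve$conc; resp <- curve$response
  resid_fn <- function(p) {
    resp - (p[1] + exp(p[2]) * theta_one_site(conc, exp(p[4])) -
              exp(p[3]) * theta_one_site(conc, exp(p[5])))
  }
  # start from the piecewise protocol when possible, else crude heuristics
  start <- tryCatch({
    pw <- .fit_two_site_piecewise(curve, split_conc, fixed_max_response)
    c(r0 = 0, lap = log(max(pw$a_pos, 1e-3)),
      lan = log(max(abs(pw$a_neg), 1e-3)),
      lkp = log(pw$kd_pos), lkn = log(pw$kd_neg))
  }, error = function(e) {
    rng <- range(resp)
    c(r0 = resp[which.min(conc)], lap = log(max(diff(rng), 1e-3)),
      lan = log(max(diff(rng), 1e-3)),
      lkp = stats::quantile(log(conc[conc > 0]), 0.25, names = FALSE),
      lkn = stats::quantile(log(conc[conc > 0]), 0.75, names = FALSE))
  })
  f <- .lm_fit(start, resid_fn,
               lower = c(-Inf, -Inf, -Inf, .LKD_LO, .LKD_LO),
               upper = c(Inf, Inf, Inf, .LKD_HI, .LKD_HI))
  kd_pos <- exp(f$par[["lkp"]]); kd_neg <- exp(f$par[["lkn"]])
  a_pos <- exp(f$par[["lap"]]); a_neg <- -exp(f$par[["lan"]])
  flags <- character(0)
  if ((is.finite(f$se[["lkn"]]) && f$se[["lkn"]] > 3) ||
      !is.finite(f$se[["lkn"]]) || abs(a_neg) < 2 * f$sigma + 1e-12) {
    flags <- c(flags, "negative_component_unresolved")
  }
  if ((is.finite(f$se[["lkp"]]) && f$se[["lkp"]] > 3) ||
      a_pos < 2 * f$sigma + 1e-12) {
    flags <- c(flags, "positive_component_unresolved")
  }
  est <- c(kd_pos = unname(kd_pos), kd_neg = unname(kd_neg),
           a_pos = unname(a_pos), a_neg = unname(a_neg),
           r0 = unname(f$par[["r0"]]))
  .new_fit_result("two_site_simultaneous", estimates = est,
                  se = c(kd_pos = unname(kd_pos * f$se[["lkp"]]),
                         kd_neg = unname(kd_neg * f$se[["lkn"]]),
                         a_pos = unname(a_pos * f$se[["lap"]]),
                         a_neg = unname(abs(a_neg) * f$se[["lan"]]),
                         r0 = unname(f$se[["r0"]])),
                  cov = f$cov, rss = f$rss, sigma = f$sigma,
                  converged = f$info %in% 1:3 && length(flags) == 0,
                  flags = flags,
                  extra = list(kd_pos = unname(kd_pos),
                               kd_neg = unname(kd_neg),
                               a_pos = unname(a_pos), a_neg = unname(a_neg)))
}

#' Fit a fixed-asymptote dose-response (displacement) curve
#'
#' Four-parameter logistic with the top and bottom asymptotes frozen to the
#' values measured on positive/negative controls (carried by the curve
#' object):
#' `MFI(c) = bottom + (top - bottom) / (1 + (c / IC50)^h)`.
#' The IC50 is log-parameterized; the Hill slope is free by default or can
#' be fixed at 1. A curve that never descends appreciably below the top
#' asymptote within the measured range is refused (flagged, no IC50).
#'
#' @param curve a [dose_response_curve()].
#' @param hill `"free"` or `"fixed"` (at 1).
#' @return a `tern_fit` with `ic50` (uM) and `hill`.
#' @export
fit_dose_response <- function(curve, hill = c("free", "fixed")) {
  stopifnot(inherits(curve, "dose_response_curve"))
  hill <- match.arg(hill)
  top <- attr(curve, "top"); bottom <- attr(curve, "bottom")
  conc <- curve$conc; mfi <- curve$mfi
  span <- top - bottom
  drop_frac <- (top - (if (span > 0) min(mfi) else max(mfi))) / span
  if (drop_frac < 0.1) {
    return(.new_fit_result("dose_response",
                           estimates = c(ic50 = NA, hill = NA),
                           se = c(NA, NA), cov = NULL, rss = NA, sigma = NA,
                           converged = FALSE,
                           flags = "no_descent_from_top",
                           extra = list(ic50 = NA_real_, hill = NA_real_)))
  }
  model <- function(lic50, h) {
    bottom + span / (1 + (conc / exp(lic50))^h)
  }
  mid <- bottom + span / 2
  lic0 <- log(conc[which.min(abs(mfi - mid))])
  if (!is.finite(lic0)) lic0 <- stats::median(log(conc[conc > 0]))
  if (hill == "free") {
    f <- .lm_fit(c(lic50 = lic0, lh = 0),
                 function(p) mfi - model(p[1], exp(p[2])),
                 lower = c(log(1e-6), log(0.2)),
                 upper = c(log(1e4), log(5)))
    ic50 <- exp(f$par[["lic50"]]); h <- exp(f$par[["lh"]])
    se <- c(ic50 = unname(ic50 * f$se[["lic50"]]),
            hill = unname(h * f$se[["lh"]]))
  } else {
    f <- .lm_fit(c(lic50 = lic0),
                 function(p) mfi - model(p[1], 1),
                 lower = log(1e-6), upper = log(1e4))
    ic50 <- exp(f$par[["lic50"]]); h <- 1
    se <- c(ic50 = unname(ic50 * f$se[["lic50"]]), hill = NA_real_)
  }
  .new_fit_result("dose_response",
                  estimates = c(ic50 = unname(ic50), hill = unname(h)),
                  se = se, cov = f$cov, rss = f$rss, sigma = f$sigma,
                  converged = f$info %in% 1:3, flags = character(0),
                  extra = list(ic50 = unname(ic50), hill = unname(h),
                               top = top, bottom = bottom))
}
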