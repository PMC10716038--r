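#' Titration curve container
#'
#' Concentration series of a titrant with (possibly signed) normalized
#' responses and replicate structure, as produced by equilibrium titration
#' readouts such as thermophoresis.
#'
#' @param conc titrant concentrations (uM, >= 0; may repeat across
#'   replicates).
#' @param response normalized responses (arbitrary units, signed).
#' @param replicate replicate identifiers.
#' @param labeled_total total of the labeled species (uM), if known.
#' @return data frame of class `titration_curve` with attribute
#'   `labeled_total`.
#' @export
titration_curve <- function(conc, response, replicate = 1L,
                            labeled_total = NA_real_) {
  if (length(conc) != length(response)) {
    stop("'conc' and 'response' must have equal length", call. = FALSE)
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentrations must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(response))) {
    stop("responses must be finite", call. = FALSE)
  }
  if (length(unique(conc)) < 4L) {
    stop("need at least 4 distinct concentrations", call. = FALSE)
  }
  df <- data.frame(conc = conc, response = response,
                   replicate = rep_len(replicate, length(conc)))
  attr(df, "labeled_total") <- labeled_total
  class(df) <- c("titration_curve", "data.frame")
  df
}

#' Dose-response curve container for displacement assays
#'
#' Competitor concentration series with mean fluorescence intensities and
#' the top/bottom asymptotes measured on positive/negative controls (which
#' the fitting protocol holds fixed).
#'
#' @param conc competitor concentrations (uM).
#' @param mfi mean fluorescence intensities.
#' @param top,bottom fixed asymptotes (`top != bottom`).
#' @param replicate replicate identifiers.
#' @return data frame of class `dose_response_curve` with attributes `top`
#'   and `bottom`.
#' @export
dose_response_curve <- function(conc, mfi, top, bottom, replicate = 1L) {
  if (length(conc) != length(mfi)) {
    stop("'conc' and 'mfi' must have equal length", call. = FALSE)
  }
  if (!is.finite(top) || !is.finite(bottom) || top == bottom) {
    stop("'top' and 'bottom' must be finite and different", call. = FALSE)
  }
  if (length(unique(conc)) < 4L) {
    stop("need at least 4 distinct concentrations", call. = FALSE)
  }
  df <- data.frame(conc = conc, mfi = mfi,
                   replicate = rep_len(replicate, length(conc)))
  attr(df, "top") <- top
  attr(df, "bottom") <- bottom
  class(df) <- c("dose_response_curve", "data.frame")
  df
}

# one-site bound fraction; exact two-total quadratic when depletion is on
theta_one_site <- function(conc, kd, labeled_total = NULL) {
  if (is.null(labeled_total)) {
    conc / (conc + kd)
  } else {
    s <- labeled_total + conc + kd
    b <- (s - sqrt(pmax(s^2 - 4 * labeled_total * conc, 0))) / 2
    b / labeled_total
  }
}

# Levenberg-Marquardt wrapper with covariance from J'J
.lm_fit <- function(par, fn, lower = NULL, upper = NULL) {
  ctl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                    ptol = 1e-15, gtol = 0)
  out <- if (is.null(lower)) {
    minpack.lm::nls.lm(par = par, fn = fn, control = ctl)
  } else {
    minpack.lm::nls.lm(par = par, fn = fn, lower = lower, upper = upper,
                       control = ctl)
  }
  p <- out$par
  rss <- out$deviance
  nres <- length(fn(p))
  dof <- max(nres - length(p), 1L)
  sigma <- sqrt(rss / dof)
  cov <- tryCatch({
    h <- out$hessian
    if (is.null(h) || any(!is.finite(h)) || rcond(h) < 1e-14) NULL
    else sigma^2 * chol2inv(chol(h))
  }, error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, length(p)) else sqrt(pmax(diag(cov), 0))
  names(se) <- names(p)
  # an essentially perfect fit can have an ill-scaled J'J; the covariance is
  # meaningless there and its failure must not mask convergence
  list(par = p, se = se, cov = cov, rss = rss, sigma = sigma,
       info = out$info, message = out$message,
       ok = out$info %in% c(1L, 2L, 3L) &&
         (!is.null(cov) || sigma < 1e-10))
}

.new_fit_result <- function(mode, estimates, se, cov, rss, sigma, converged,
                            flags = character(0), extra = list()) {
  structure(c(list(mode = mode, estimates = estimates, se = se, cov = cov,
                   rss = rss, sigma = sigma, converged = converged,
                   flags = flags), extra),
            class = "tern_fit")
}

#' @export
print.tern_fit <- function(x, ...) {
  cat("<tern_fit> mode:", x$mode,
      if (!x$converged) " (NOT converged)", "\n")
  est <- data.frame(estimate = signif(x$estimates, 5),
                    se = signif(x$se, 3))
  print(est)
  cat("RSS:", format(x$rss, digits = 5), "\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# log-Kd bounds shared by all binding fits (uM)
.LKD_LO <- log(1e-4)
.LKD_HI <- log(1e5)

# candidate log-Kd start: concentration nearest the half-saturation response
.lkd_start_candidates <- function(conc, resp) {
  cpos <- conc[conc > 0]
  qs <- stats::quantile(log(cpos), c(0.15, 0.35, 0.5, 0.65, 0.85),
                        names = FALSE)
  unique(pmin(pmax(qs, .LKD_LO + 1), .LKD_HI - 1))
}

#' Fit a one-site binding isotherm
#'
#' Model `R(c) = R0 + A * theta(c)` where `theta` is `c/(c + Kd)`
#' (depletion off) or the exact quadratic bound fraction for the labeled and
#' titrant totals (depletion on). Kd is log-parameterized with bounds
#' `[1e-4, 1e5]` uM; unweighted least squares over all points, pooling
#' replicates.
#'
#' @param curve a [titration_curve()].
#' @param depletion account for labeled-species depletion via the exact
#'   two-total solution (requires a finite `labeled_total` on the curve).
#' @return a `tern_fit` with entries `kd`, `kd_se`, `r0`, `a` in addition to
#'   the common fields; a Kd pinned at its bound or an unresolved amplitude
#'   flags the fit as not converged.
#' @export
fit_one_site <- function(curve, depletion = FALSE) {
  stopifnot(inherits(curve, "titration_curve"))
  conc <- curve$conc; resp <- curve$response
  lt <- if (depletion) {
    v <- attr(curve, "labeled_total")
    if (!is.finite(v)) stop("depletion fit needs a labeled_total",
                            call. = FALSE)
    v
  } else NULL
  if (stats::sd(resp) < 1e-14) {
    return(.new_fit_result("one_site",
                           estimates = c(r0 = mean(resp), a = 0, kd = NA),
                           se = c(NA, NA, NA), cov = NULL, rss = 0, sigma = 0,
                           converged = FALSE,
                           flags = "constant_response_kd_unidentifiable",
                           extra = list(kd = NA_real_, kd_se = NA_real_)))
  }

  resid_fn <- function(p) {
    resp - (p[1] + p[2] * theta_one_site(conc, exp(p[3]), lt))
  }
  r0_0 <- mean(resp[conc <= stats::quantile(conc, 0.15)])
  a_0 <- mean(resp[conc >= stats::quantile(conc, 0.9)]) - r0_0
  best <- NULL
  for (lkd0 in .lkd_start_candidates(conc, resp)) {
    f <- tryCatch(.lm_fit(c(r0 = r0_0, a = a_0, lkd = lkd0), resid_fn,
                          lower = c(-Inf, -Inf, .LKD_LO),
                          upper = c(Inf, Inf, .LKD_HI)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$rss < best$rss)) best <- f
  }
  if (is.null(best)) {
    return(.new_fit_result("one_site", estimates = c(r0 = NA, a = NA, kd = NA),
                           se = rep(NA_real_, 3), cov = NULL, rss = NA,
                           sigma = NA, converged = FALSE,
                           flags = "optimizer_failure",
                           extra = list(kd = NA_real_, kd_se = NA_real_)))
  }
  kd <- exp(best$par[["lkd"]])
  flags <- character(0)
  at_bound <- best$par[["lkd"]] <= .LKD_LO + 1e-6 ||
    best$par[["lkd"]] >= .LKD_HI - 1e-6
  if (at_bound) flags <- c(flags, "kd_at_bound")
  unresolved <- is.finite(best$se[["lkd"]]) && best$se[["lkd"]] > 3
  if (unresolved) flags <- c(flags, "kd_poorly_determined")
  converged <- best$ok && !at_bound && !unresolved
  est <- c(r0 = unname(best$par[["r0"]]), a = unname(best$par[["a"]]),
           kd = unname(kd))
  kd_se <- kd * best$se[["lkd"]]
  .new_fit_result("one_site", estimates = est,
                  se = c(r0 = unname(best$se[["r0"]]),
                         a = unname(best$se[["a"]]), kd = unname(kd_se)),
                  cov = best$cov, rss = best$rss, sigma = best$sigma,
                  converged = converged, flags = flags,
                  extra = list(kd = unname(kd), kd_se = unname(kd_se),
                               r0 = unname(best$par[["r0"]]),
                               a = unname(best$par[["a"]]),
                               depletion = depletion))
}

#' Globally fit several titration curves with a shared Kd
#'
#' One shared log-Kd; per-curve baseline and amplitude as nuisance
#' parameters (amplitudes may differ in sign between curves). With a single
#' curve this reduces to [fit_one_site()].
#'
#' @param curves list of [titration_curve()] objects.
#' @param depletion as in [fit_one_site()] (applied per curve).
#' @return a `tern_fit`; `kd` is the shared constant, `per_curve` holds the
#'   nuisance estimates.
#' @export
fit_global <- function(curves, depletion = FALSE) {
  if (inherits(curves, "titration_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "titration_curve")))
  m <- length(curves)
  conc <- lapply(curves, `[[`, "conc")
  resp <- lapply(curves, `[[`, "response")
  lts <- if (depletion) {
    lapply(curves, function(cv) {
      v <- attr(cv, "labeled_total")
      if (!is.finite(v)) stop("depletion fit needs labeled_total",
                              call. = FALSE)
      v
    })
  } else vector("list", m)

  # parameters: lkd, then (r0_i, a_i) pairs
  resid_fn <- function(p) {
    kd <- exp(p[1])
    unlist(lapply(seq_len(m), function(i) {
      resp[[i]] - (p[2 * i] + p[2 * i + 1] *
                     theta_one_site(conc[[i]], kd, lts[[i]]))
    }))
  }
  starts <- lapply(curves, function(cv) {
    f <- fit_one_site(cv, depletion = depletion)
    if (is.finite(f$kd)) c(log(f$kd), f$r0, f$a)
    else c(stats::median(log(cv$conc[cv$conc > 0])), mean(cv$response),
           diff(range(cv$response)))
  })
  lkd0 <- stats::median(vapply(starts, `[[`, numeric(1), 1L))
  p0 <- c(lkd = lkd0,
          unlist(lapply(starts, function(s) s[2:3])))
  names(p0) <- c("lkd", paste0(rep(c("r0_", "a_"), m),
                               rep(seq_len(m), each = 2)))
  lower <- c(.LKD_LO, rep(-Inf, 2 * m))
  upper <- c(.LKD_HI, rep(Inf, 2 * m))
  f <- .lm_fit(p0, resid_fn, lower = lower, upper = upper)
  kd <- exp(f$par[["lkd"]])
  at_bound <- f$par[["lkd"]] <= .LKD_LO + 1e-6 ||
    f$par[["lkd"]] >= .LKD_HI - 1e-6
  per_curve <- data.frame(
    curve = seq_len(m),
    r0 = f$par[seq(2, 2 * m, by = 2)],
    a = f$par[seq(3, 2 * m + 1, by = 2)]
  )
  est <- c(kd = unname(kd))
  .new_fit_result("global_one_site", estimates = est,
                  se = c(kd = unname(kd * f$se[["lkd"]])),
                  cov = f$cov, rss = f$rss, sigma = f$sigma,
                  converged = f$ok && !at_bound,
                  flags = if (at_bound) "kd_at_bound" else character(0),
                  extra = list(kd = unname(kd),
                               kd_se = unname(kd * f$se[["lkd"]]),
                               per_curve = per_curve, depletion = depletion))
}
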