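#' A dissociation constant with uncertainty
#'
#' @param value dissociation constant (uM, > 0).
#' @param sd standard deviation across replicates (uM, >= 0).
#' @param n replicate count; 0 means unknown.
#' @param label free-text provenance label.
#' @return object of class `measured_kd`.
#' @export
#' @examples
#' measured_kd(108, 12, label = "THD1 vs beta3-CT")
measured_kd <- function(value, sd = 0, n = 0L, label = "") {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0) {
    stop("Kd value must be a single finite number > 0", call. = FALSE)
  }
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0) {
    stop("Kd sd must be a single finite number >= 0", call. = FALSE)
  }
  if (n < 0 || n != round(n)) stop("'n' must be a count", call. = FALSE)
  structure(list(value = unname(value), sd = unname(sd), n = as.integer(n),
                 label = label),
            class = "measured_kd")
}

as_measured_kd <- function(x) {
  if (inherits(x, "measured_kd")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(measured_kd(x))
  if (is.numeric(x) && length(x) == 2L) return(measured_kd(x[1], x[2]))
  stop("cannot interpret input as a measured Kd", call. = FALSE)
}

#' Association constant of a measured Kd
#'
#' `Ka = 1/Kd` (uM^-1); a derived view, never stored.
#' @param x a [measured_kd()].
#' @export
ka <- function(x) 1 / as_measured_kd(x)$value

#' @export
print.measured_kd <- function(x, ...) {
  cat(sprintf("Kd = %s +/- %s uM", signif(x$value, 4), signif(x$sd, 4)))
  if (x$n > 0) cat("  (n =", x$n, ")")
  if (nzchar(x$label)) cat("  [", x$label, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' The four step constants of a thermodynamic binding cycle
#'
#' `kd_T` and `kd_K` are the adaptors' constants for the free tail; the
#' starred constants are for the tail pre-occupied by the other adaptor.
#'
#' @param kd_T,kd_K,kd_T_star,kd_K_star [measured_kd()] objects or numerics
#'   (`c(value, sd)` also accepted).
#' @param label free-text identifier of the square.
#' @return object of class `energy_square`.
#' @export
#' @examples
#' sq <- energy_square(c(108, 12), c(9, 2), c(102, 40), c(54, 27))
#' cycle_product(sq)
energy_square <- function(kd_T, kd_K, kd_T_star, kd_K_star, label = "") {
  structure(list(
    kd_T = as_measured_kd(kd_T), kd_K = as_measured_kd(kd_K),
    kd_T_star = as_measured_kd(kd_T_star),
    kd_K_star = as_measured_kd(kd_K_star),
    label = label
  ), class = "energy_square")
}

#' @export
print.energy_square <- function(x, ...) {
  cat("<energy_square>", if (nzchar(x$label)) x$label, "\n")
  for (f in c("kd_T", "kd_K", "kd_T_star", "kd_K_star")) {
    cat(sprintf("  %-10s %s +/- %s uM\n", f,
                signif(x[[f]]$value, 4), signif(x[[f]]$sd, 4)))
  }
  invisible(x)
}

#' Cycle product statistic of an energy square
#'
#' At equilibrium, microscopic reversibility demands that the product of the
#' association and dissociation constants around the cycle equals 1; in Kd
#' form, `Q = (Kd_T* x Kd_K) / (Kd_T x Kd_K*)`. A `Q` deviating from 1
#' signals that the four measured constants are not the step constants of a
#' single four-state cycle (extra states, allostery, or direct
#' adaptor-adaptor binding). Uncertainty is propagated to first order by
#' adding relative errors in quadrature:
#' `sigma_Q = Q * sqrt(sum((sd_i / value_i)^2))`.
#'
#' @param square an [energy_square()].
#' @return list with `Q` and `sigma_Q`.
#' @seealso [consistency_verdict()], [cycle_product_mc()]
#' @export
cycle_product <- function(square) {
  stopifnot(inherits(square, "energy_square"))
  v <- vapply(square[c("kd_T", "kd_K", "kd_T_star", "kd_K_star")],
              function(k) k$value, numeric(1))
  s <- vapply(square[c("kd_T", "kd_K", "kd_T_star", "kd_K_star")],
              function(k) k$sd, numeric(1))
  Q <- (v[["kd_T_star"]] * v[["kd_K"]]) / (v[["kd_T"]] * v[["kd_K_star"]])
  list(Q = Q, sigma_Q = Q * sqrt(sum((s / v)^2)))
}

#' Monte Carlo propagation of the cycle product uncertainty
#'
#' Cross-check of the first-order quadrature in [cycle_product()]: draws each
#' constant from a normal truncated to positive values and returns the mean
#' and standard deviation of the resulting Q sample.
#'
#' @param square an [energy_square()].
#' @param n number of draws.
#' @param seed optional seed (local; the global RNG stream is restored).
#' @return list with `Q_mean`, `Q_sd` (plain standard deviation) and
#'   `Q_sd_robust` (half the central 68.3% interquantile width). When a
#'   denominator constant carries a large relative error the ratio
#'   distribution is heavy-tailed and the plain standard deviation is
#'   dominated by rare near-zero denominators; the robust spread is the
#'   meaningful comparison to the first-order `sigma_Q` in that regime.
#' @export
cycle_product_mc <- function(square, n = 1e5, seed = NULL) {
  stopifnot(inherits(square, "energy_square"))
  draws <- with_preserved_seed(seed, {
    d <- lapply(square[c("kd_T", "kd_K", "kd_T_star", "kd_K_star")],
                function(k) rnorm_pos(n, k$value, k$sd))
    (d$kd_T_star * d$kd_K) / (d$kd_T * d$kd_K_star)
  })
  list(Q_mean = mean(draws), Q_sd = stats::sd(draws),
       Q_sd_robust = unname(diff(stats::quantile(
         draws, c(0.15865, 0.84135))) / 2))
}

# normal draws truncated to > 0 by redrawing
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Microscopic-reversibility verdict for an energy square
#'
#' Scores `z = |Q - 1| / sigma_Q` and declares the square inconsistent with
#' a single four-state cycle when `z` exceeds the threshold (default 2).
#' `sigma_Q = 0` with `Q != 1` yields an infinite `z`, flagged explicitly.
#' The result also carries the per-edge binding-mode classifications from
#' [classify_pair()].
#'
#' @param square an [energy_square()].
#' @param z_threshold verdict threshold on `z`.
#' @return object of class `cycle_test_result`: `Q`, `sigma_Q`, `z`,
#'   `verdict` (`"consistent"` or `"inconsistent"`), `z_threshold`,
#'   `edges` (talin and kindlin mode classifications), `flags`.
#' @export
#' @examples
#' consistency_verdict(energy_square(c(108, 12), c(9, 2), c(102, 40), c(54, 27)))
consistency_verdict <- function(square, z_threshold = 2) {
  cp <- cycle_product(square)
  flags <- character(0)
  if (cp$sigma_Q == 0) {
    z <- if (cp$Q == 1) 0 else Inf
    if (is.infinite(z)) flags <- "zero_uncertainty_nonunit_Q"
  } else {
    z <- abs(cp$Q - 1) / cp$sigma_Q
  }
  structure(list(
    Q = cp$Q, sigma_Q = cp$sigma_Q, z = z,
    verdict = if (z > z_threshold) "inconsistent" else "consistent",
    z_threshold = z_threshold,
    edges = list(
      talin = classify_pair(square$kd_T, square$kd_T_star, z_threshold),
      kindlin = classify_pair(square$kd_K, square$kd_K_star, z_threshold)
    ),
    flags = flags, label = square$label
  ), class = "cycle_test_result")
}

#' @export
print.cycle_test_result <- function(x, ...) {
  cat(sprintf("<cycle_test_result>%s\n  Q = %.4g +/- %.4g   z = %.3g  -> %s\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              x$Q, x$sigma_Q, x$z, x$verdict))
  cat("  talin edge:   ", x$edges$talin, "\n")
  cat("  kindlin edge: ", x$edges$kindlin, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Classify a free-tail vs occupied-tail Kd pair
#'
#' Two-sample z statistic on log(Kd), with each relative uncertainty
#' `sd/value` serving as the log-scale standard deviation. `|z|` below the
#' threshold means the occupancy of the other adaptor leaves the constant
#' unchanged (independent binding); a significantly larger starred constant
#' means competition; a significantly smaller one, mutual reinforcement.
#'
#' @param kd constant for the free tail ([measured_kd()] or numeric).
#' @param kd_star constant for the occupied tail.
#' @param z_threshold significance threshold.
#' @return `"independent"`, `"competitive"` or `"reinforced"`, with the
#'   signed z statistic attached as attribute `"z"`.
#' @export
#' @examples
#' classify_pair(c(9, 2), c(54, 27))    # competitive
#' classify_pair(c(108, 12), c(102, 40)) # independent
classify_pair <- function(kd, kd_star, z_threshold = 2) {
  a <- as_measured_kd(kd); b <- as_measured_kd(kd_star)
  se <- sqrt((a$sd / a$value)^2 + (b$sd / b$value)^2)
  dlog <- log(b$value) - log(a$value)
  z <- if (se == 0) {
    if (dlog == 0) 0 else sign(dlog) * Inf
  } else {
    dlog / se
  }
  mode <- if (abs(z) <= z_threshold) "independent"
  else if (z > 0) "competitive" else "reinforced"
  structure(mode, z = z)
}

#' Ratio of two dissociation constants with propagated uncertainty
#'
#' @param kd_a,kd_b [measured_kd()] objects or numerics; the ratio reported
#'   is `kd_a / kd_b` with relative errors added in quadrature.
#' @return list with `ratio` and `sd`.
#' @export
#' @examples
#' fold_change(c(470, 140), c(25, 3)) # ~18.8-fold
fold_change <- function(kd_a, kd_b) {
  a <- as_measured_kd(kd_a); b <- as_measured_kd(kd_b)
  r <- a$value / b$value
  list(ratio = r, sd = r * sqrt((a$sd / a$value)^2 + (b$sd / b$value)^2))
}

#' Round a value +/- sd pair for reporting
#'
#' Keeps two significant digits of the value (at least one decimal place)
#' and renders the sd at the same number of decimals, rounding half up. Raw
#' values should always be retained alongside.
#'
#' @param value,sd numbers to round.
#' @param digits optional explicit number of decimals.
#' @return numeric vector `c(value, sd)` rounded.
#' @export
round_pm <- function(value, sd, digits = NULL) {
  if (is.null(digits)) {
    digits <- max(1L, 1L - floor(log10(abs(value))))
  }
  half_up <- function(x, d) floor(x * 10^d + 0.5 + 1e-12) / 10^d
  c(value = half_up(value, digits), sd = half_up(sd, digits))
}

# run code under a temporary seed, restoring the caller's RNG state;
# relies on lazy evaluation: `expr` is forced only after set.seed()
with_preserved_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
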