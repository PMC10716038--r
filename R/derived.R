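#' Derive the four step dissociation constants of an energy square
#'
#' Reads the binary and ternary formation constants for one tail conformer
#' and returns the step constants Kd_T (T for the free tail), Kd_K, Kd_T*
#' (T for the K-occupied tail) and Kd_K* (K for the T-occupied tail). Since
#' the network stores overall formation constants, the product statistic of
#' the derived square is exactly 1 -- microscopic reversibility holds by
#' construction, and this accessor is a read-only view.
#'
#' @param network an [eq_network()] with roles T, K, I.
#' @param conformer tail species name to read; required when the tail is a
#'   conformer group (e.g. `"I_in"`), ignored otherwise.
#' @return an [energy_square()] with zero uncertainties.
#' @export
derived_step_kds <- function(network, conformer = NULL) {
  stopifnot(inherits(network, "eq_network"))
  r <- network$roles
  if (is.null(r) || is.null(r$T) || is.null(r$K) || is.null(r$I)) {
    stop("network lacks T/K/I role tags", call. = FALSE)
  }
  tail_sp <- r$I
  if (tail_sp %in% names(network$conformers)) {
    states <- network$conformers[[tail_sp]]$states
    if (is.null(conformer)) {
      stop("tail is a conformer group; pick one of: ",
           paste(states, collapse = ", "), call. = FALSE)
    }
    if (!conformer %in% states) {
      stop("'", conformer, "' is not a tail conformer", call. = FALSE)
    }
    tail_sp <- conformer
  }
  comp2 <- function(a, b) { v <- c(1, 1); names(v) <- c(a, b); v }
  i_TI <- .find_complex(network, comp2(r$T, tail_sp))
  i_KI <- .find_complex(network, comp2(r$K, tail_sp))
  v3 <- c(1, 1, 1); names(v3) <- c(r$T, r$K, tail_sp)
  i_TIK <- .find_complex(network, v3)
  if (is.na(i_TI) || is.na(i_KI) || is.na(i_TIK)) {
    stop("network must contain the TI, KI and TIK complexes of one tail ",
         "conformer", call. = FALSE)
  }
  lb <- network$log_beta
  energy_square(
    kd_T = exp(-lb[i_TI]),
    kd_K = exp(-lb[i_KI]),
    kd_T_star = exp(lb[i_KI] - lb[i_TIK]),
    kd_K_star = exp(lb[i_TI] - lb[i_TIK]),
    label = paste0("derived:", tail_sp)
  )
}

#' Serial-dilution concentration grid
#'
#' @param top highest titrant concentration (uM).
#' @param n number of points.
#' @param dilution dilution factor between consecutive points.
#' @return increasing numeric vector of length `n`.
#' @export
titration_grid <- function(top, n = 16L, dilution = 2) {
  stopifnot(top > 0, n >= 2, dilution > 1)
  sort(top / dilution^(seq_len(n) - 1L))
}

#' Simulate an occupancy titration
#'
#' Holds the labeled species at a fixed, small total and sweeps the total
#' concentration of a titrant over a grid, recording at each point the
#' fraction of the labeled species in a selected bound class (for example
#' "any T-containing complex"). This is the noiseless forward model of an
#' equilibrium titration readout.
#'
#' @param network an [eq_network()].
#' @param labeled monomer observed (the fluorescent/isotope-labeled species).
#' @param titrant monomer whose total is swept; must differ from `labeled`.
#' @param grid strictly increasing non-negative totals for the titrant (uM).
#' @param readout monomer name or complex names defining the scored bound
#'   class; defaults to any complex containing the titrant.
#' @param labeled_total optional override of the labeled species total (uM).
#' @return a [titration_curve()] whose response is the bound fraction.
#' @export
occupancy_titration <- function(network, labeled, titrant, grid,
                                readout = titrant, labeled_total = NULL) {
  stopifnot(inherits(network, "eq_network"))
  if (identical(labeled, titrant)) {
    stop("titrant must differ from the labeled species", call. = FALSE)
  }
  if (!all(c(labeled, titrant) %in% names(network$totals))) {
    stop("unknown monomer in 'labeled'/'titrant'", call. = FALSE)
  }
  if (any(grid < 0) || any(diff(grid) <= 0)) {
    stop("'grid' must be strictly increasing and non-negative", call. = FALSE)
  }
  if (!is.null(labeled_total)) {
    network <- set_totals(network, stats::setNames(labeled_total, labeled))
  }
  resp <- vapply(grid, function(g) {
    st <- solve_equilibrium(network,
                            totals = stats::setNames(g, titrant))
    bound_fraction(st, labeled, readout)
  }, numeric(1))
  titration_curve(conc = grid, response = resp,
                  labeled_total = network$totals[[labeled]])
}

# pooled binary dissociation constant of an adaptor for the (possibly
# two-state) tail: (sum of conformer weights) / (sum of weight * beta)
.binary_kd <- function(network, adaptor, tail = network$roles$I) {
  sp <- network$species
  tail_states <- sp$species[sp$monomer == tail]
  w <- exp(sp$log_w[sp$monomer == tail])
  betas <- vapply(tail_states, function(s) {
    v <- c(1, 1); names(v) <- c(adaptor, s)
    i <- .find_complex(network, v)
    if (is.na(i)) 0 else exp(network$log_beta[i])
  }, numeric(1))
  if (sum(w * betas) == 0) {
    stop("no binary complex of '", adaptor, "' with the tail", call. = FALSE)
  }
  sum(w) / sum(w * betas)
}

#' Operational apparent dissociation constant
#'
#' Mirrors how a near-saturation competition experiment reports affinity:
#' simulate an occupancy titration of `titrant` (optionally with a competitor
#' held at a fixed total concentration), then fit a one-site isotherm against
#' the *total* titrant concentration and report the fitted midpoint. The
#' result is an operational quantity -- with a competitor present, or with a
#' direct titrant-competitor interaction in the network, it need not equal
#' any single step constant of the network.
#'
#' @inheritParams occupancy_titration
#' @param competitor optional competitor monomer name.
#' @param competitor_total its fixed total (uM); default 4x its pooled binary
#'   Kd for the tail, emulating near-saturation conditions.
#' @param grid titrant totals; default 16-point 2-fold dilution series from
#'   `top`.
#' @param top top titrant concentration for the default grid; default 200x
#'   the titrant's pooled binary Kd so that even strongly shifted midpoints
#'   stay inside the grid.
#' @param labeled_total total of the labeled species (uM); the default
#'   0.1 uM keeps it trace-level relative to uM-scale constants.
#' @return object of class `apparent_kd`: list with `value` (uM), `rss`,
#'   `converged`, `readout`, `competitor`, `fit` (the underlying
#'   [fit_one_site()] result) and `curve`.
#' @export
apparent_kd <- function(network, titrant, labeled = network$roles$I,
                        readout = titrant,
                        competitor = NULL, competitor_total = NULL,
                        grid = NULL, top = NULL, labeled_total = 0.1) {
  stopifnot(inherits(network, "eq_network"))
  network <- set_totals(network, stats::setNames(labeled_total, labeled))
  if (!is.null(competitor)) {
    if (identical(competitor, titrant)) {
      stop("competitor must differ from the titrant", call. = FALSE)
    }
    if (is.null(competitor_total)) {
      competitor_total <- 4 * .binary_kd(network, competitor)
    }
    network <- set_totals(network,
                          stats::setNames(competitor_total, competitor))
  }
  if (is.null(grid)) {
    if (is.null(top)) top <- 200 * .binary_kd(network, titrant)
    grid <- titration_grid(top, n = 16L)
  }
  curve <- occupancy_titration(network, labeled = labeled, titrant = titrant,
                               grid = grid, readout = readout)
  fit <- fit_one_site(curve)
  structure(list(
    value = if (fit$converged) fit$kd else NA_real_,
    rss = fit$rss, converged = fit$converged,
    readout = readout,
    competitor = if (is.null(competitor)) NULL else
      list(name = competitor, total = competitor_total),
    fit = fit, curve = curve
  ), class = "apparent_kd")
}

#' @export
print.apparent_kd <- function(x, ...) {
  cat("<apparent_kd>  Kd,app = ", signif(x$value, 4), " uM",
      if (!x$converged) "  (fit did not converge)", "\n", sep = "")
  if (!is.null(x$competitor)) {
    cat("  competitor: ", x$competitor$name, " at ",
        signif(x$competitor$total, 4), " uM\n", sep = "")
  }
  invisible(x)
}
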