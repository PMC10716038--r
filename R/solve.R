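#' Solve a mass-action equilibrium network for species concentrations
#'
#' Finds the free concentration of every species such that (i) each complex
#' obeys its overall formation constant exactly and (ii) mass is conserved
#' for every monomer. The solver runs a damped Newton iteration on the log
#' free concentrations of the conservation equations, which keeps all
#' concentrations positive and handles formation constants spanning many
#' orders of magnitude. The initial guess assigns half of each total to the
#' free pool. The method is deterministic; failure to converge within the
#' iteration budget is a loud error carrying the worst residual.
#'
#' @param network an [eq_network()].
#' @param totals optional named numeric vector overriding monomer totals (uM).
#' @param tol convergence tolerance on `|log(computed total / target total)|`.
#' @param maxit iteration budget.
#' @return an object of class `eq_state`: list with `free` (named species
#'   concentrations, uM), `bound` (named complex concentrations, uM) and
#'   `max_conservation_residual` (worst relative mass-balance error).
#' @export
#' @examples
#' net <- simple_cycle(108, 9, 1, totals = c(T = 50, K = 50, I = 0.1))
#' st <- solve_equilibrium(net)
#' st$bound
solve_equilibrium <- function(network, totals = NULL, tol = 1e-11,
                              maxit = 200L) {
  stopifnot(inherits(network, "eq_network"))
  if (!is.null(totals)) network <- set_totals(network, totals)
  tot <- network$totals
  mon <- names(tot)
  sp <- network$species
  par_idx <- match(sp$monomer, mon)
  wsum <- as.vector(tapply(exp(sp$log_w), factor(sp$monomer, levels = mon), sum))

  act <- tot > 0
  # complexes are active only if every constituent monomer is present
  if (nrow(network$S)) {
    cx_act <- apply(network$S, 1L, function(r) all(tot[r > 0] > 0))
  } else {
    cx_act <- logical(0)
  }

  free <- numeric(nrow(sp)); names(free) <- sp$species
  bound <- numeric(nrow(network$N)); names(bound) <- rownames(network$N)

  if (any(act)) {
    am <- which(act)
    nm <- length(am)
    Na <- network$N[cx_act, , drop = FALSE]
    Sa <- network$S[cx_act, am, drop = FALSE]
    lba <- network$log_beta[cx_act]
    sp_par <- match(sp$monomer, mon[am]) # NA for species of absent monomers

    eval_at <- function(x) {
      logf <- sp$log_w + x[sp_par]
      logf[is.na(logf)] <- -Inf
      logc <- if (nrow(Na)) {
        lba + as.vector(Na %*% ifelse(is.finite(logf), logf, -1e6))
      } else numeric(0)
      conc <- exp(logc)
      u <- exp(x)
      tot_hat <- wsum[am] * u +
        (if (nrow(Sa)) as.vector(t(Sa) %*% conc) else 0)
      list(conc = conc, u = u, tot_hat = tot_hat,
           F = log(tot_hat) - log(tot[am]))
    }
    jac_at <- function(ev) {
      A <- if (nrow(Sa)) t(Sa) %*% (Sa * ev$conc) else matrix(0, nm, nm)
      (diag(wsum[am] * ev$u, nrow = nm) + A) / ev$tot_hat
    }
    newton_polish <- function(x, steps = 30L) {
      ev <- eval_at(x)
      for (i in seq_len(steps)) {
        if (max(abs(ev$F)) <= tol) break
        step <- tryCatch(solve(jac_at(ev), -ev$F), error = function(e) NULL)
        if (is.null(step)) break
        step <- pmin(pmax(step, -2), 2)
        x_new <- x + step
        ev_new <- eval_at(x_new)
        if (!all(is.finite(ev_new$F)) ||
            max(abs(ev_new$F)) >= max(abs(ev$F))) break
        x <- x_new; ev <- ev_new
      }
      list(x = x, ev = ev, obj = max(abs(ev$F)))
    }

    # Levenberg-Marquardt (damped Newton) on the log conservation residuals,
    # tried from several free-fraction starting points, then a plain Newton
    # polish down to the target tolerance
    starts <- lapply(c(0.5, 0.99, 1e-6), function(fr) {
      log(fr * tot[am] / wsum[am])
    })
    best <- NULL
    for (x0 in starts) {
      lmfit <- tryCatch(minpack.lm::nls.lm(
        par = x0,
        fn = function(x) eval_at(x)$F,
        jac = function(x) jac_at(eval_at(x)),
        control = minpack.lm::nls.lm.control(
          maxiter = maxit, ftol = 1e-15, ptol = 1e-15, gtol = 0)),
        error = function(e) NULL)
      if (is.null(lmfit)) next
      pol <- newton_polish(lmfit$par)
      if (is.null(best) || pol$obj < best$obj) best <- pol
      if (best$obj <= tol) break
    }
    if (is.null(best) || best$obj > tol) {
      stop(sprintf(paste0(
        "equilibrium solver failed to converge ",
        "(worst relative conservation residual %.3g)"),
        if (is.null(best)) Inf else best$obj), call. = FALSE)
    }
    logf <- sp$log_w + best$x[sp_par]
    free[!is.na(logf)] <- exp(logf[!is.na(logf)])
    bound[cx_act] <- best$ev$conc
  }

  # residual on the original scale, over monomers with mass present
  res <- 0
  if (any(act)) {
    got <- as.vector(t(network$S[, act, drop = FALSE]) %*% bound) +
      as.vector(tapply(free, factor(sp$monomer, levels = mon), sum))[act]
    res <- max(abs(got - tot[act]) / tot[act])
  }

  structure(list(free = free, bound = bound,
                 max_conservation_residual = res,
                 network = network),
            class = "eq_state")
}

#' @export
print.eq_state <- function(x, ...) {
  cat("<eq_state>  max conservation residual: ",
      format(x$max_conservation_residual, digits = 3), "\n", sep = "")
  cat("free (uM):\n"); print(signif(x$free, 6))
  if (length(x$bound)) { cat("bound (uM):\n"); print(signif(x$bound, 6)) }
  invisible(x)
}

#' Fraction of a labeled monomer found in a given bound class
#'
#' @param state an `eq_state` from [solve_equilibrium()].
#' @param labeled monomer whose occupancy is scored.
#' @param readout either a monomer name (score all complexes containing both
#'   `labeled` and this monomer) or a character vector of complex names.
#' @return fraction of the labeled monomer's total in the selected class.
#' @export
bound_fraction <- function(state, labeled, readout) {
  net <- state$network
  tot <- net$totals[labeled]
  if (is.na(tot)) stop("unknown monomer '", labeled, "'", call. = FALSE)
  if (tot == 0) return(0)
  S <- net$S
  if (all(readout %in% rownames(S)) && !all(readout %in% colnames(S))) {
    sel <- rownames(S) %in% readout & S[, labeled] > 0
  } else {
    if (length(readout) != 1L || !(readout %in% colnames(S))) {
      stop("'readout' must be a monomer name or complex names", call. = FALSE)
    }
    sel <- S[, labeled] > 0 & S[, readout] > 0
  }
  unname(sum(state$bound[sel] * S[sel, labeled]) / tot)
}
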