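#' Define a coupled mass-action equilibrium network
#'
#' A network consists of monomeric species with total concentrations,
#' optional conformer groups (a monomer partitioned into two conformational
#' states related by an isomerization constant), and complexes defined by
#' *overall* formation constants from the free components. Because every
#' complex is parameterized by its overall formation constant, the product of
#' derived step constants around any reaction cycle equals 1 by construction:
#' thermodynamic consistency is structural, not something to be checked.
#'
#' All concentrations and dissociation constants are in micromolar (uM); the
#' formation constant of an n-mer has units uM^-(n-1) and is stored
#' internally on a log scale.
#'
#' @param monomers named numeric vector of total concentrations (uM, >= 0).
#' @param complexes named list; each element is `list(comp = c(T = 1, I = 1),
#'   beta = 1/108)` where `comp` counts free components (monomer or conformer
#'   names) and `beta` is the overall formation constant
#'   `[complex] / prod([free components])`. `log_beta` may be given instead
#'   of `beta`.
#' @param conformers named list keyed by monomer name; each element is
#'   `list(states = c("I_in", "I_act"), L = 0.01)` where
#'   `L = [second state]/[first state]` among the free species at
#'   equilibrium (dimensionless, > 0).
#' @param roles optional named list tagging which monomer plays which part
#'   (e.g. `list(T = "T", K = "K", I = "I")`); used by [derived_step_kds()]
#'   and the titration helpers.
#' @return an object of class `eq_network`.
#' @seealso [simple_cycle()], [two_state_tail()], [solve_equilibrium()]
#' @export
#' @examples
#' net <- eq_network(
#'   monomers = c(T = 9, I = 0.2),
#'   complexes = list(TI = list(comp = c(T = 1, I = 1), beta = 1 / 9))
#' )
#' solve_equilibrium(net)
eq_network <- function(monomers, complexes = list(), conformers = list(),
                       roles = NULL) {
  if (is.null(names(monomers)) || any(names(monomers) == "") ||
      anyDuplicated(names(monomers))) {
    stop("'monomers' must be a uniquely named numeric vector", call. = FALSE)
  }
  if (!is.numeric(monomers) || any(!is.finite(monomers)) || any(monomers < 0)) {
    stop("monomer totals must be finite and >= 0", call. = FALSE)
  }
  mon <- names(monomers)

  # species table: each monomer contributes itself or its conformer states
  sp_name <- character(0); sp_mon <- character(0); sp_logw <- numeric(0)
  for (m in mon) {
    cg <- conformers[[m]]
    if (is.null(cg)) {
      sp_name <- c(sp_name, m); sp_mon <- c(sp_mon, m); sp_logw <- c(sp_logw, 0)
    } else {
      if (!is.list(cg) || length(cg$states) != 2L ||
          !is.numeric(cg$L) || length(cg$L) != 1L) {
        stop("conformer group for '", m,
             "' must be list(states = <2 names>, L = <number>)", call. = FALSE)
      }
      if (!is.finite(cg$L) || cg$L <= 0) {
        stop("isomerization constant L must be finite and > 0", call. = FALSE)
      }
      sp_name <- c(sp_name, cg$states)
      sp_mon <- c(sp_mon, m, m)
      sp_logw <- c(sp_logw, 0, log(cg$L))
    }
  }
  if (length(setdiff(names(conformers), mon))) {
    stop("conformer groups reference unknown monomers: ",
         paste(setdiff(names(conformers), mon), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sp_name)) {
    stop("species names must be unique across monomers and conformers",
         call. = FALSE)
  }

  ncx <- length(complexes)
  if (ncx && (is.null(names(complexes)) || any(names(complexes) == "") ||
              anyDuplicated(names(complexes)))) {
    stop("'complexes' must be a uniquely named list", call. = FALSE)
  }
  N <- matrix(0, nrow = ncx, ncol = length(sp_name),
              dimnames = list(names(complexes), sp_name))
  log_beta <- numeric(ncx)
  names(log_beta) <- names(complexes)
  for (j in seq_len(ncx)) {
    cx <- complexes[[j]]
    comp <- cx$comp
    if (is.null(comp) || is.null(names(comp)) ||
        !all(names(comp) %in% sp_name)) {
      stop("complex '", names(complexes)[j],
           "' references undeclared species", call. = FALSE)
    }
    if (any(comp <= 0) || any(comp != round(comp))) {
      stop("complex stoichiometries must be positive integers", call. = FALSE)
    }
    if (sum(comp) < 2) {
      stop("complex '", names(complexes)[j],
           "' must contain at least two components", call. = FALSE)
    }
    N[j, names(comp)] <- comp
    lb <- cx$log_beta
    if (is.null(lb)) {
      if (is.null(cx$beta) || !is.finite(cx$beta) || cx$beta <= 0) {
        stop("complex '", names(complexes)[j],
             "' needs a finite formation constant beta > 0", call. = FALSE)
      }
      lb <- log(cx$beta)
    }
    if (!is.finite(lb)) {
      stop("complex '", names(complexes)[j],
           "' has a non-finite log formation constant", call. = FALSE)
    }
    log_beta[j] <- lb
  }

  # species -> monomer aggregation
  M <- matrix(0, nrow = length(sp_name), ncol = length(mon),
              dimnames = list(sp_name, mon))
  M[cbind(seq_along(sp_name), match(sp_mon, mon))] <- 1
  S <- N %*% M # complexes x monomers stoichiometry

  structure(list(
    totals = monomers,
    species = data.frame(species = sp_name, monomer = sp_mon,
                         log_w = sp_logw, stringsAsFactors = FALSE),
    N = N, S = S, log_beta = log_beta,
    conformers = conformers, roles = roles
  ), class = "eq_network")
}

#' @export
print.eq_network <- function(x, ...) {
  cat("<eq_network> ", length(x$totals), " monomers, ",
      nrow(x$N), " complexes\n", sep = "")
  cat("totals (uM): ",
      paste(names(x$totals), signif(x$totals, 4), sep = "=", collapse = ", "),
      "\n", sep = "")
  if (length(x$conformers)) {
    for (m in names(x$conformers)) {
      cg <- x$conformers[[m]]
      cat("conformers of ", m, ": ", paste(cg$states, collapse = " <-> "),
          "  L=", signif(cg$L, 4), "\n", sep = "")
    }
  }
  if (nrow(x$N)) {
    for (j in seq_len(nrow(x$N))) {
      comp <- x$N[j, x$N[j, ] > 0]
      cat("  ", rownames(x$N)[j], ": ",
          paste(names(comp), comp, sep = "x", collapse = " + "),
          "  beta=", signif(exp(x$log_beta[j]), 6), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Return a copy of a network with modified total concentrations
#'
#' @param network an [eq_network()].
#' @param totals named numeric vector of totals to override (uM, >= 0).
#' @return the modified `eq_network`.
#' @export
set_totals <- function(network, totals) {
  stopifnot(inherits(network, "eq_network"))
  if (length(totals)) {
    if (is.null(names(totals)) || !all(names(totals) %in% names(network$totals))) {
      stop("'totals' must be named after declared monomers", call. = FALSE)
    }
    if (any(!is.finite(totals)) || any(totals < 0)) {
      stop("totals must be finite and >= 0", call. = FALSE)
    }
    network$totals[names(totals)] <- totals
  }
  network
}

# locate a complex index by its aggregate composition over species names;
# returns NA if absent
.find_complex <- function(network, comp) {
  N <- network$N
  if (!all(names(comp) %in% colnames(N))) return(NA_integer_)
  target <- numeric(ncol(N)); names(target) <- colnames(N)
  target[names(comp)] <- comp
  hit <- which(apply(N, 1L, function(r) all(r == target)))
  if (length(hit)) hit[1L] else NA_integer_
}
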