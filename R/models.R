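#' The simple ternary-complex cycle ("energy square") network
#'
#' Two adaptors T and K bind one tail I with dissociation constants `kd_T`
#' and `kd_K`; the ternary complex TIK forms with overall formation constant
#' `1/(kd_T * kd_K * alpha)`. The coupling factor `alpha` measures how the
#' presence of one adaptor changes the step constant of the other:
#' `alpha = 1` is independent binding, `alpha > 1` competition, `alpha < 1`
#' mutual reinforcement.
#'
#' @param kd_T,kd_K dissociation constants for the free tail (uM, > 0).
#' @param alpha dimensionless coupling factor (> 0).
#' @param totals named totals for T, K, I (uM); defaults to an unloaded
#'   network with 0.1 uM tail.
#' @return an [eq_network()] with monomers T, K, I and complexes TI, KI, TIK.
#' @export
#' @examples
#' derived_step_kds(simple_cycle(108, 9, 6)) # step constants (108, 9, 648, 54)
simple_cycle <- function(kd_T, kd_K, alpha,
                         totals = c(T = 0, K = 0, I = 0.1)) {
  .check_pos(kd_T = kd_T, kd_K = kd_K, alpha = alpha)
  eq_network(
    monomers = totals,
    complexes = list(
      TI  = list(comp = c(T = 1, I = 1), log_beta = -log(kd_T)),
      KI  = list(comp = c(K = 1, I = 1), log_beta = -log(kd_K)),
      TIK = list(comp = c(T = 1, K = 1, I = 1),
                 log_beta = -(log(kd_T) + log(kd_K) + log(alpha)))
    ),
    roles = list(T = "T", K = "K", I = "I")
  )
}

#' Ternary cycle extended by a direct adaptor-adaptor contact
#'
#' Adds a binary T-K complex in solution (`kd_TK`) and lets the direct
#' contact stabilize the ternary complex by the factor `chi` (> 1 means the
#' T-K contact makes the ternary complex more stable than the tail
#' interactions alone would).
#'
#' @inheritParams simple_cycle
#' @param kd_TK dissociation constant of the binary T-K complex (uM, > 0).
#' @param chi dimensionless ternary stabilization from the direct contact.
#' @return an [eq_network()].
#' @export
adapter_contact_cycle <- function(kd_T, kd_K, alpha, kd_TK, chi,
                                  totals = c(T = 0, K = 0, I = 0.1)) {
  .check_pos(kd_T = kd_T, kd_K = kd_K, alpha = alpha,
             kd_TK = kd_TK, chi = chi)
  eq_network(
    monomers = totals,
    complexes = list(
      TI  = list(comp = c(T = 1, I = 1), log_beta = -log(kd_T)),
      KI  = list(comp = c(K = 1, I = 1), log_beta = -log(kd_K)),
      TK  = list(comp = c(T = 1, K = 1), log_beta = -log(kd_TK)),
      TIK = list(comp = c(T = 1, K = 1, I = 1),
                 log_beta = log(chi) - (log(kd_T) + log(kd_K) + log(alpha)))
    ),
    roles = list(T = "T", K = "K", I = "I")
  )
}

#' Two-conformer ("inactive"/"active") tail model
#'
#' The tail monomer I is split into conformers `I_in` (inactive: low talin
#' affinity) and `I_act` (active: high talin affinity, low kindlin affinity)
#' related by the isomerization constant `L = [I_act]/[I_in]` among the free
#' species. Each conformer carries its own binary and ternary formation
#' constants; observable occupancies sum over the conformers. An optional
#' direct T-K contact (`kd_TK`, `chi`) can be layered on top, which is the
#' configuration that reproduces the unidirectional competition seen in
#' apparent-affinity measurements (see the package vignette).
#'
#' @param L isomerization constant `[active]/[inactive]` of the free tail.
#' @param kd_T_inactive,kd_T_active talin step constants per conformer (uM).
#' @param kd_K_inactive,kd_K_active kindlin step constants per conformer (uM).
#' @param alpha_inactive,alpha_active per-conformer coupling factors.
#' @param kd_TK optional direct T-K contact dissociation constant (uM);
#'   `NULL` omits the contact.
#' @param chi ternary stabilization by the direct contact (used only with
#'   `kd_TK`).
#' @param totals named totals for T, K, I (uM).
#' @return an [eq_network()] whose tail is a two-state conformer group.
#' @export
two_state_tail <- function(L, kd_T_inactive, kd_T_active,
                           kd_K_inactive, kd_K_active,
                           alpha_inactive, alpha_active,
                           kd_TK = NULL, chi = 1,
                           totals = c(T = 0, K = 0, I = 0.1)) {
  .check_pos(L = L,
             kd_T_inactive = kd_T_inactive, kd_T_active = kd_T_active,
             kd_K_inactive = kd_K_inactive, kd_K_active = kd_K_active,
             alpha_inactive = alpha_inactive, alpha_active = alpha_active,
             chi = chi)
  lchi <- 0
  cxs <- list(
    TI_in  = list(comp = c(T = 1, I_in = 1),  log_beta = -log(kd_T_inactive)),
    TI_act = list(comp = c(T = 1, I_act = 1), log_beta = -log(kd_T_active)),
    KI_in  = list(comp = c(K = 1, I_in = 1),  log_beta = -log(kd_K_inactive)),
    KI_act = list(comp = c(K = 1, I_act = 1), log_beta = -log(kd_K_active))
  )
  if (!is.null(kd_TK)) {
    .check_pos(kd_TK = kd_TK)
    cxs$TK <- list(comp = c(T = 1, K = 1), log_beta = -log(kd_TK))
    lchi <- log(chi)
  }
  cxs$TIK_in <- list(
    comp = c(T = 1, K = 1, I_in = 1),
    log_beta = lchi - (log(kd_T_inactive) + log(kd_K_inactive) +
                         log(alpha_inactive)))
  cxs$TIK_act <- list(
    comp = c(T = 1, K = 1, I_act = 1),
    log_beta = lchi - (log(kd_T_active) + log(kd_K_active) +
                         log(alpha_active)))
  eq_network(
    monomers = totals,
    complexes = cxs,
    conformers = list(I = list(states = c("I_in", "I_act"), L = L)),
    roles = list(T = "T", K = "K", I = "I",
                 tail_states = c("I_in", "I_act"))
  )
}

#' Frozen reference parameterization reproducing the asymmetric competition
#'
#' A two-state tail combined with a direct T-K contact, with parameters fixed
#' once from a coarse search so that the *operational* apparent affinities
#' (titration plus one-site fit against total titrant, competitor held at the
#' concentrations used in near-saturation experiments) show the asymmetric
#' pattern: kindlin's apparent Kd rises severalfold in the presence of
#' saturating talin while talin's apparent Kd is essentially unchanged in the
#' presence of saturating kindlin. Pure tail allostery cannot produce this
#' pattern (detailed balance forces equal fold-changes at matched relative
#' saturation); the direct contact plus the tenfold difference in absolute
#' competitor concentrations does.
#'
#' @return `asymmetry_reference_model()` returns an [eq_network()];
#'   `asymmetry_reference_params()` returns the frozen parameter list with
#'   entries `model` (arguments to [two_state_tail()]), `talin_saturation`
#'   and `kindlin_saturation` (the fixed competitor totals, uM, chosen as
#'   the near-saturation concentrations used experimentally: talin at a few
#'   hundred micromolar, kindlin a tenfold lower absolute concentration at a
#'   comparable multiple of its own Kd).
#' @seealso [two_state_tail()], [apparent_kd()]
#' @export
asymmetry_reference_model <- function() {
  do.call(two_state_tail, asymmetry_reference_params()$model)
}

#' @rdname asymmetry_reference_model
#' @export
asymmetry_reference_params <- function() {
  list(
    model = list(L = 0.001,
                 kd_T_inactive = 110, kd_T_active = 2,
                 kd_K_inactive = 9,   kd_K_active = 90,
                 alpha_inactive = 10, alpha_active = 1,
                 kd_TK = 50, chi = 16),
    talin_saturation = 400,
    kindlin_saturation = 36
  )
}

.check_pos <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("'", nm, "' must be a single finite value > 0", call. = FALSE)
    }
  }
  invisible(TRUE)
}
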