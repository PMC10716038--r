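# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms from the package code paths.

# closed-form one-site complex concentration with ligand depletion:
# [TI] from the quadratic for T + I <-> TI with Kd
oracle_binary_complex <- function(kd, t_tot, i_tot) {
  s <- t_tot + i_tot + kd
  (s - sqrt(s^2 - 4 * t_tot * i_tot)) / 2
}

# nested-bisection solve of the simple three-monomer ternary cycle
# (complexes TI, KI, TIK with overall formation constants b_ti, b_ki, b_tik);
# returns free concentrations of T, K, I
oracle_ternary_free <- function(t_tot, k_tot, i_tot, b_ti, b_ki, b_tik,
                                iter = 200L) {
  f_i <- function(ft, fk) i_tot / (1 + b_ti * ft + b_ki * fk + b_tik * ft * fk)
  inner_fk <- function(ft) {
    g <- function(fk) {
      fi <- f_i(ft, fk)
      fk * (1 + b_ki * fi + b_tik * ft * fi) - k_tot
    }
    lo <- 0; hi <- k_tot
    for (j in seq_len(iter)) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  h <- function(ft) {
    fk <- inner_fk(ft)
    fi <- f_i(ft, fk)
    ft * (1 + b_ti * fi + b_tik * fk * fi) - t_tot
  }
  lo <- 0; hi <- t_tot
  for (j in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (h(mid) > 0) hi <- mid else lo <- mid
  }
  ft <- (lo + hi) / 2
  fk <- inner_fk(ft)
  c(T = ft, K = fk, I = f_i(ft, fk))
}

# literal re-implementation of the robust CSP threshold rule
# (RMS sigma, iterative 3-sigma exclusion, significance at 2 sigma)
oracle_csp_threshold <- function(v) {
  rms <- function(x) sqrt(mean(x^2))
  keep <- rep(TRUE, length(v))
  repeat {
    sigma <- rms(v[keep])
    keep_new <- v <= 3 * sigma
    if (identical(keep_new, keep) || !any(keep_new)) break
    keep <- keep_new
  }
  2 * sigma
}

# random valid small network for property sweeps (2 or 3 monomers,
# all pairwise complexes plus the ternary for 3 monomers)
random_network <- function() {
  nm <- sample(2:3, 1)
  mons <- c("A", "B", "C")[seq_len(nm)]
  totals <- stats::setNames(10^stats::runif(nm, -2, 2.3), mons)
  cxs <- list()
  pairs <- utils::combn(mons, 2, simplify = FALSE)
  for (p in pairs) {
    v <- c(1, 1); names(v) <- p
    cxs[[paste(p, collapse = "")]] <-
      list(comp = v, log_beta = stats::runif(1, -3, 3) * log(10))
  }
  if (nm == 3) {
    v <- c(A = 1, B = 1, C = 1)
    cxs$ABC <- list(comp = v, log_beta = stats::runif(1, -3, 3) * log(10))
  }
  eq_network(totals, cxs)
}

# synthetic paired-peak table with prescribed CSP magnitudes (all in the
# proton dimension) and intensity ratios
make_paired <- function(residues, csp_values, ratios = 1,
                        aa = "A", ref_int = 1) {
  lab <- paste0(rep_len(aa, length(residues)), residues, "N-H")
  ref <- peak_table(residue = residues, aa = rep_len(aa, length(residues)),
                    w1 = 8 + seq_along(residues) * 0.01,
                    w2 = 110 + seq_along(residues) * 0.1,
                    intensity = rep_len(ref_int, length(residues)),
                    assignment = lab)
  tit <- peak_table(residue = residues, aa = rep_len(aa, length(residues)),
                    w1 = ref$w1 + csp_values,
                    w2 = ref$w2,
                    intensity = ref$intensity * rep_len(ratios,
                                                        length(residues)),
                    assignment = lab)
  match_peaks(ref, tit)
}
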