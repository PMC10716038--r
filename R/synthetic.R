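#' Integrin beta1 tail sequence (author numbering 758-798)
#'
#' One-letter residue codes of the beta1 cytoplasmic tail used as the
#' default sequence for simulated peak tables; the membrane-proximal NPxY
#' motif (talin site) ends at Y783 and the membrane-distal NPKY motif
#' (kindlin site) at Y795.
#'
#' @return named character vector; names are residue numbers.
#' @export
beta1_ct_sequence <- function() {
  s <- strsplit("HDRREFAKFEKEKMNAKWDTGENPIYKSAVTTVVNPKYEGK", "")[[1]]
  names(s) <- as.character(758:798)
  s
}

#' Ground-truth record of a simulated dataset
#'
#' Every generator returns its inputs (parameters, design, noise model and
#' seed) bundled as a record; [regenerate()] re-runs the generator from the
#' record and must reproduce the dataset bit-identically.
#'
#' @param generator generator name.
#' @param params list of generator arguments.
#' @return object of class `ground_truth_record`.
#' @export
ground_truth_record <- function(generator, params) {
  structure(list(generator = generator, params = params),
            class = "ground_truth_record")
}

#' Re-run a generator from its ground-truth record
#'
#' @param record a [ground_truth_record()].
#' @return the regenerated dataset (same structure as the original call).
#' @export
regenerate <- function(record) {
  stopifnot(inherits(record, "ground_truth_record"))
  fn <- switch(record$generator,
               gen_titration = gen_titration,
               gen_dose_response = gen_dose_response,
               gen_square_measurements = gen_square_measurements,
               gen_peak_tables = gen_peak_tables,
               stop("unknown generator '", record$generator, "'",
                    call. = FALSE))
  do.call(fn, record$params)
}

#' Serialize a ground-truth record to JSON
#'
#' Networks are expanded to their serializable form; the JSON sidecar is
#' written next to generated datasets so any of them can be regenerated.
#'
#' @param record a [ground_truth_record()].
#' @param path output path.
#' @export
write_ground_truth <- function(record, path) {
  p <- record$params
  if (!is.null(p$network)) p$network <- .network_to_list(p$network)
  jsonlite::write_json(list(generator = record$generator, params = p),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Simulate thermophoresis-style titration curves
#'
#' Forward model of a signed titration readout: at each grid point the
#' network is solved, the bound fraction of the labeled species in each
#' scored class is computed, and the response is the signed-amplitude sum
#' over classes plus a baseline and Gaussian noise. Opposite signs for two
#' classes reproduce the opposing response trends of a fusion construct
#' whose two sites pull the readout in different directions.
#'
#' @param network an [eq_network()].
#' @param titrant monomer whose total is swept.
#' @param grid strictly increasing titrant totals (uM).
#' @param amplitudes named numeric: response amplitude per readout class
#'   (names are monomer names; each class is "any complex containing the
#'   labeled species and this monomer"). A ternary complex containing both
#'   adaptors contributes to both classes.
#' @param labeled labeled monomer; defaults to the network's tail role.
#' @param baseline additive baseline.
#' @param noise_sd Gaussian noise standard deviation on the response.
#' @param replicates number of replicate curves.
#' @param seed RNG seed (stored in the record; global RNG state restored).
#' @param labeled_total labeled-species total (uM).
#' @return list with `curve` (a [titration_curve()] pooling the replicates)
#'   and `record` (a [ground_truth_record()]).
#' @export
gen_titration <- function(network, titrant, grid,
                          amplitudes = stats::setNames(1, titrant),
                          labeled = network$roles$I,
                          baseline = 0, noise_sd = 0, replicates = 1L,
                          seed = 1L, labeled_total = 0.1) {
  stopifnot(inherits(network, "eq_network"))
  record <- ground_truth_record("gen_titration", list(
    network = network, titrant = titrant, grid = grid,
    amplitudes = amplitudes, labeled = labeled, baseline = baseline,
    noise_sd = noise_sd, replicates = replicates, seed = seed,
    labeled_total = labeled_total))
  network <- set_totals(network, stats::setNames(labeled_total, labeled))
  clean <- rep(baseline, length(grid))
  for (cls in names(amplitudes)) {
    frac <- occupancy_titration(network, labeled = labeled,
                                titrant = titrant, grid = grid,
                                readout = cls)$response
    clean <- clean + amplitudes[[cls]] * frac
  }
  resp <- with_preserved_seed(seed, {
    as.vector(vapply(seq_len(replicates), function(r) {
      clean + stats::rnorm(length(grid), 0, noise_sd)
    }, numeric(length(grid))))
  })
  curve <- titration_curve(
    conc = rep(grid, times = replicates), response = resp,
    replicate = rep(seq_len(replicates), each = length(grid)),
    labeled_total = labeled_total)
  list(curve = curve, record = record)
}

#' Simulate a fixed-asymptote dose-response displacement curve
#'
#' @param top,bottom fixed asymptotes.
#' @param ic50 midpoint (uM).
#' @param hill Hill slope.
#' @param grid competitor concentrations (uM).
#' @param noise_sd noise scale: absolute (Gaussian) or relative (lognormal).
#' @param noise_model `"gaussian"` additive, or `"lognormal"` multiplicative
#'   (positive, right-skewed, as flow-cytometry intensities are).
#' @param replicates number of replicates.
#' @param seed RNG seed.
#' @return list with `curve` (a [dose_response_curve()]) and `record`.
#' @export
gen_dose_response <- function(top, bottom, ic50, hill, grid,
                              noise_sd = 0,
                              noise_model = c("gaussian", "lognormal"),
                              replicates = 1L, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (any(grid < 0) || any(diff(grid) <= 0)) {
    stop("'grid' must be strictly increasing and non-negative", call. = FALSE)
  }
  record <- ground_truth_record("gen_dose_response", list(
    top = top, bottom = bottom, ic50 = ic50, hill = hill, grid = grid,
    noise_sd = noise_sd, noise_model = noise_model,
    replicates = replicates, seed = seed))
  clean <- bottom + (top - bottom) / (1 + (grid / ic50)^hill)
  mfi <- with_preserved_seed(seed, {
    as.vector(vapply(seq_len(replicates), function(r) {
      if (noise_model == "gaussian") {
        clean + stats::rnorm(length(grid), 0, noise_sd)
      } else {
        clean * stats::rlnorm(length(grid), 0, noise_sd)
      }
    }, numeric(length(grid))))
  })
  curve <- dose_response_curve(
    conc = rep(grid, times = replicates), mfi = mfi, top = top,
    bottom = bottom, replicate = rep(seq_len(replicates), each = length(grid)))
  list(curve = curve, record = record)
}

#' Simulate noisy energy-square measurements from a true network
#'
#' Derives the (exactly consistent) step constants of the network and
#' perturbs each by multiplicative Gaussian noise truncated positive; the
#' reported uncertainty of each constant is `value * relative_noise`, so the
#' simulated squares calibrate the type-I error of the cycle verdict.
#'
#' @param true_network an [eq_network()] containing TI/KI/TIK.
#' @param relative_noise relative measurement error (e.g. 0.1).
#' @param n number of squares.
#' @param seed RNG seed.
#' @param conformer passed to [derived_step_kds()] for two-state tails.
#' @return list with `squares` (list of [energy_square()]) and `record`.
#' @export
gen_square_measurements <- function(true_network, relative_noise, n,
                                    seed = 1L, conformer = NULL) {
  stopifnot(n >= 1)
  record <- ground_truth_record("gen_square_measurements", list(
    true_network = true_network, relative_noise = relative_noise, n = n,
    seed = seed, conformer = conformer))
  sq <- derived_step_kds(true_network, conformer = conformer)
  truth <- vapply(sq[c("kd_T", "kd_K", "kd_T_star", "kd_K_star")],
                  function(k) k$value, numeric(1))
  vals <- with_preserved_seed(seed, {
    m <- matrix(stats::rnorm(4L * n, 1, relative_noise), ncol = 4L)
    bad <- which(m <= 0)
    while (length(bad)) {
      m[bad] <- stats::rnorm(length(bad), 1, relative_noise)
      bad <- bad[m[bad] <= 0]
    }
    sweep(m, 2L, truth, `*`)
  })
  squares <- lapply(seq_len(n), function(i) {
    energy_square(
      kd_T = measured_kd(vals[i, 1], vals[i, 1] * relative_noise),
      kd_K = measured_kd(vals[i, 2], vals[i, 2] * relative_noise),
      kd_T_star = measured_kd(vals[i, 3], vals[i, 3] * relative_noise),
      kd_K_star = measured_kd(vals[i, 4], vals[i, 4] * relative_noise),
      label = paste0("sim_", i))
  })
  list(squares = squares, record = record)
}

#' Simulate fast-exchange reference and titrated peak tables
#'
#' Builds an amide peak table for a tail sequence, then a titrated table in
#' which residues inside annotated binding-site regions shift by
#' `occupancy * max_csp` (split between the proton and nitrogen dimensions
#' at a fixed ratio, fast exchange) and are attenuated by complex formation:
#' `I = I_ref * (1 - gamma * mass-weighted bound fraction)`, floored at 0,
#' where each complex is weighted by its molecular mass relative to the
#' largest complex. An optional ternary-specific broadening attenuates a
#' further region only by the ternary complex fraction (phenomenological
#' stand-in for inter-motif residues broadened beyond detection).
#'
#' @param network an [eq_network()] with roles T, K, I.
#' @param totals named totals applied before solving (uM).
#' @param site_map list of sites: each `list(region = c(start, end),
#'   class = <monomer>)`.
#' @param max_csp maximal CSP at full occupancy (ppm).
#' @param gamma attenuation coefficient in `[0, 1]`.
#' @param noise_sd Gaussian noise on shifts (ppm) and relative noise on
#'   intensities.
#' @param seed RNG seed.
#' @param sequence named residue vector, as [beta1_ct_sequence()].
#' @param masses molecular masses (kDa) per monomer for the attenuation
#'   weights.
#' @param hn_ratio nitrogen:proton split of the generated CSP.
#' @param ternary_broadening optional `list(region = c(start, end),
#'   gamma = <coef>)`.
#' @return list with `reference`, `titrated` (both [peak_table()]) and
#'   `record`.
#' @export
gen_peak_tables <- function(network, totals, site_map,
                            max_csp = 0.2, gamma = 0.8, noise_sd = 0,
                            seed = 1L, sequence = beta1_ct_sequence(),
                            masses = c(T = 50, K = 53, I = 5),
                            hn_ratio = 5, ternary_broadening = NULL) {
  stopifnot(inherits(network, "eq_network"))
  res_no <- as.integer(names(sequence))
  for (s in site_map) {
    if (!all(s$region >= min(res_no) & s$region <= max(res_no))) {
      stop("site region outside the sequence", call. = FALSE)
    }
    if (!s$class %in% names(network$totals)) {
      stop("site class '", s$class, "' is not a network monomer",
           call. = FALSE)
    }
  }
  record <- ground_truth_record("gen_peak_tables", list(
    network = network, totals = totals, site_map = site_map,
    max_csp = max_csp, gamma = gamma, noise_sd = noise_sd, seed = seed,
    sequence = sequence, masses = masses, hn_ratio = hn_ratio,
    ternary_broadening = ternary_broadening))

  st <- solve_equilibrium(network, totals = totals)
  tail_m <- network$roles$I
  S <- network$S
  tail_total <- network$totals
  tail_total[names(totals)] <- totals
  tot_I <- tail_total[[tail_m]]
  cx_mass <- as.vector(S %*% masses[colnames(S)])
  wmass <- cx_mass / max(cx_mass)

  # per adaptor class: plain and mass-weighted bound fractions of the tail
  frac <- function(cls, weighted) {
    sel <- S[, tail_m] > 0 & S[, cls] > 0
    w <- if (weighted) wmass[sel] else 1
    sum(st$bound[sel] * S[sel, tail_m] * w) / tot_I
  }
  tern_sel <- S[, tail_m] > 0 &
    rowSums(S[, setdiff(colnames(S), tail_m), drop = FALSE] > 0) >= 2
  tern_frac <- sum(st$bound[tern_sel] * S[tern_sel, tail_m]) / tot_I

  n <- length(res_no)
  base <- with_preserved_seed(seed, {
    list(h = stats::runif(n, 7.8, 8.6),
         nn = stats::runif(n, 105, 125),
         int = stats::runif(n, 0.8, 1.2),
         h_noise = stats::rnorm(n, 0, noise_sd),
         n_noise = stats::rnorm(n, 0, noise_sd),
         i_noise = stats::rnorm(n, 0, noise_sd))
  })
  reference <- peak_table(
    residue = res_no, aa = unname(sequence),
    w1 = base$h, w2 = base$nn, intensity = base$int,
    assignment = paste0(unname(sequence), res_no, "N-H"))

  dh <- numeric(n); dn <- numeric(n); att <- numeric(n)
  split_h <- 1 / sqrt(1 + hn_ratio^2 / 6) # so that csp(dh, dn) = max_csp
  for (s in site_map) {
    in_reg <- res_no >= s$region[1] & res_no <= s$region[2]
    occ <- frac(s$class, weighted = FALSE)
    dh[in_reg] <- dh[in_reg] + occ * max_csp * split_h
    dn[in_reg] <- dn[in_reg] + occ * max_csp * split_h * hn_ratio
    att[in_reg] <- pmin(att[in_reg] + gamma * frac(s$class, weighted = TRUE), 1)
  }
  if (!is.null(ternary_broadening)) {
    in_reg <- res_no >= ternary_broadening$region[1] &
      res_no <= ternary_broadening$region[2]
    att[in_reg] <- pmin(att[in_reg] + ternary_broadening$gamma * tern_frac, 1)
  }
  titrated <- peak_table(
    residue = res_no, aa = unname(sequence),
    w1 = base$h + dh + base$h_noise,
    w2 = base$nn + dn + base$n_noise,
    intensity = pmax(base$int * (1 - att) * (1 + base$i_noise), 0),
    assignment = paste0(unname(sequence), res_no, "N-H"))

  list(reference = reference, titrated = titrated, record = record)
}
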