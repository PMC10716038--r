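#' Read and write titration CSV files
#'
#' Columns `conc_uM`, `response`, `replicate` and optionally
#' `labeled_total_uM` (constant per file).
#'
#' @param path file path.
#' @return a [titration_curve()].
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("conc_uM", "response")
  if (!all(need %in% names(df))) {
    stop("titration CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  titration_curve(
    conc = df$conc_uM, response = df$response,
    replicate = if ("replicate" %in% names(df)) df$replicate else 1L,
    labeled_total = if ("labeled_total_uM" %in% names(df))
      df$labeled_total_uM[1] else NA_real_)
}

#' @rdname read_titration_csv
#' @param curve a [titration_curve()].
#' @export
write_titration_csv <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  df <- data.frame(conc_uM = curve$conc, response = curve$response,
                   replicate = curve$replicate)
  lt <- attr(curve, "labeled_total")
  if (is.finite(lt)) df$labeled_total_uM <- lt
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write dose-response CSV files with an asymptote sidecar
#'
#' The CSV holds `conc_uM`, `mfi`, `replicate`; the fixed top/bottom
#' asymptotes live in a YAML sidecar (default `<path>.yml`) with keys `top`
#' and `bottom`, mirroring how control values are recorded separately from
#' the titration itself.
#'
#' @param path CSV path.
#' @param sidecar sidecar path; defaults to `<path>.yml`.
#' @return a [dose_response_curve()].
#' @export
read_dose_response_csv <- function(path, sidecar = paste0(path, ".yml")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("conc_uM", "mfi") %in% names(df))) {
    stop("dose-response CSV needs columns conc_uM, mfi", call. = FALSE)
  }
  side <- yaml::read_yaml(sidecar)
  if (is.null(side$top) || is.null(side$bottom)) {
    stop("sidecar must define 'top' and 'bottom'", call. = FALSE)
  }
  dose_response_curve(
    conc = df$conc_uM, mfi = df$mfi, top = side$top, bottom = side$bottom,
    replicate = if ("replicate" %in% names(df)) df$replicate else 1L)
}

#' @rdname read_dose_response_csv
#' @param curve a [dose_response_curve()].
#' @export
write_dose_response_csv <- function(curve, path,
                                    sidecar = paste0(path, ".yml")) {
  stopifnot(inherits(curve, "dose_response_curve"))
  utils::write.csv(data.frame(conc_uM = curve$conc, mfi = curve$mfi,
                              replicate = curve$replicate),
                   path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(top = attr(curve, "top"),
                        bottom = attr(curve, "bottom")), sidecar)
  invisible(path)
}

#' Read and write energy-square tables
#'
#' CSV columns: `label`, `kd_T`, `sd_T`, `kd_K`, `sd_K`, `kd_T_star`,
#' `sd_T_star`, `kd_K_star`, `sd_K_star`, `units` (always `uM`).
#'
#' @param path file path.
#' @return list of [energy_square()] objects.
#' @export
read_squares_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "kd_T", "sd_T", "kd_K", "sd_K",
            "kd_T_star", "sd_T_star", "kd_K_star", "sd_K_star")
  if (!all(need %in% names(df))) {
    stop("squares CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(df)) stop("squares CSV contains no rows", call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    energy_square(
      kd_T = measured_kd(df$kd_T[i], df$sd_T[i]),
      kd_K = measured_kd(df$kd_K[i], df$sd_K[i]),
      kd_T_star = measured_kd(df$kd_T_star[i], df$sd_T_star[i]),
      kd_K_star = measured_kd(df$kd_K_star[i], df$sd_K_star[i]),
      label = df$label[i])
  })
}

#' @rdname read_squares_csv
#' @param squares list of [energy_square()] objects.
#' @export
write_squares_csv <- function(squares, path) {
  df <- do.call(rbind, lapply(squares, function(sq) {
    data.frame(label = sq$label,
               kd_T = sq$kd_T$value, sd_T = sq$kd_T$sd,
               kd_K = sq$kd_K$value, sd_K = sq$kd_K$sd,
               kd_T_star = sq$kd_T_star$value, sd_T_star = sq$kd_T_star$sd,
               kd_K_star = sq$kd_K_star$value, sd_K_star = sq$kd_K_star$sd,
               units = "uM")
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write peak lists
#'
#' Two dialects round-trip: a Sparky-export-like TSV with columns
#' `Assignment`, `w1`, `w2`, `Height` (assignments such as `"G778N-H"`) and
#' a plain CSV with columns `residue`, `aa`, `shift1`, `shift2`,
#' `intensity`.
#'
#' @param path file path.
#' @param dims shift-dimension labels for the resulting [peak_table()].
#' @return a [peak_table()].
#' @export
read_peaks_tsv <- function(path, dims = c("H", "N")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("Assignment", "w1", "w2", "Height") %in% names(df))) {
    stop("peak TSV needs columns Assignment, w1, w2, Height", call. = FALSE)
  }
  m <- regmatches(df$Assignment,
                  regexec("^([A-Z])([0-9]+)", df$Assignment))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("unparseable assignment(s): ",
         paste(utils::head(df$Assignment[bad], 3), collapse = ", "),
         call. = FALSE)
  }
  peak_table(
    residue = vapply(m, function(x) as.integer(x[3]), integer(1)),
    aa = vapply(m, `[`, character(1), 2L),
    w1 = df$w1, w2 = df$w2, intensity = df$Height,
    assignment = df$Assignment, dims = dims)
}

#' @rdname read_peaks_tsv
#' @param table a [peak_table()].
#' @export
write_peaks_tsv <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  assn <- ifelse(is.na(table$assignment) | !nzchar(table$assignment),
                 paste0(table$aa, table$residue, "N-H"), table$assignment)
  df <- data.frame(Assignment = assn, w1 = table$w1, w2 = table$w2,
                   Height = table$intensity)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_peaks_tsv
#' @export
read_peaks_csv <- function(path, dims = c("H", "N")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue", "aa", "shift1", "shift2", "intensity")
  if (!all(need %in% names(df))) {
    stop("peak CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  peak_table(residue = df$residue, aa = df$aa, w1 = df$shift1,
             w2 = df$shift2, intensity = df$intensity,
             assignment = if ("assignment" %in% names(df)) df$assignment
             else NA_character_, dims = dims)
}

#' @rdname read_peaks_tsv
#' @export
write_peaks_csv <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  df <- data.frame(residue = table$residue, aa = table$aa,
                   shift1 = table$w1, shift2 = table$w2,
                   intensity = table$intensity,
                   assignment = table$assignment)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# serializable form of a network
.network_to_list <- function(network) {
  cx <- lapply(seq_len(nrow(network$N)), function(j) {
    comp <- network$N[j, network$N[j, ] > 0, drop = TRUE]
    list(comp = as.list(comp), log_beta = unname(network$log_beta[j]))
  })
  names(cx) <- rownames(network$N)
  list(monomers = as.list(network$totals),
       conformers = network$conformers,
       complexes = cx,
       roles = network$roles)
}

.network_from_list <- function(x) {
  cxs <- lapply(x$complexes, function(c) {
    list(comp = unlist(c$comp), log_beta = c$log_beta)
  })
  conf <- lapply(x$conformers, function(cg) {
    list(states = unlist(cg$states), L = cg$L)
  })
  roles <- x$roles
  if (!is.null(roles$tail_states)) {
    roles$tail_states <- unlist(roles$tail_states)
  }
  eq_network(monomers = unlist(x$monomers), complexes = cxs,
             conformers = conf, roles = roles)
}

#' Serialize an equilibrium network to YAML or JSON
#'
#' Round-trips are lossless: monomers, totals, conformer groups, complexes
#' (as log formation constants at full precision) and role tags are all
#' preserved.
#'
#' @param network an [eq_network()].
#' @param path output path.
#' @export
write_network_yaml <- function(network, path) {
  yaml::write_yaml(.network_to_list(network), path,
                   precision = 15L)
  invisible(path)
}

#' @rdname write_network_yaml
#' @export
read_network_yaml <- function(path) {
  .network_from_list(yaml::read_yaml(path))
}

#' @rdname write_network_yaml
#' @export
write_network_json <- function(network, path) {
  jsonlite::write_json(.network_to_list(network), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_network_yaml
#' @export
read_network_json <- function(path) {
  .network_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' Energy-square consistency report
#'
#' Applies [consistency_verdict()] to each square and tabulates the cycle
#' statistic, its uncertainty, the z score, the verdict and the per-edge
#' binding-mode classifications.
#'
#' @param squares list of [energy_square()] objects, or a squares CSV path.
#' @param z_threshold verdict threshold.
#' @return data frame of class `cycle_report`.
#' @export
cycle_report <- function(squares, z_threshold = 2) {
  if (is.character(squares)) squares <- read_squares_csv(squares)
  rows <- lapply(squares, function(sq) {
    v <- consistency_verdict(sq, z_threshold = z_threshold)
    data.frame(label = sq$label, Q = v$Q, sigma_Q = v$sigma_Q, z = v$z,
               verdict = v$verdict,
               talin_mode = as.character(v$edges$talin),
               kindlin_mode = as.character(v$edges$kindlin),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cycle_report", "data.frame")
  out
}

#' Write a cycle report as JSON and plain text
#'
#' Both renderings carry exactly the same numbers (full double precision in
#' the JSON, 15 significant digits in the text).
#'
#' @param report a [cycle_report()].
#' @param json_path,text_path output paths (either may be `NULL`).
#' @export
write_cycle_report <- function(report, json_path = NULL, text_path = NULL) {
  stopifnot(inherits(report, "cycle_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, digits = NA, dataframe = "rows")
  }
  if (!is.null(text_path)) {
    lines <- c("cycle consistency report",
               vapply(seq_len(nrow(report)), function(i) {
                 sprintf("%s: Q=%.15g sigma=%.15g z=%.15g %s (talin %s, kindlin %s)",
                         report$label[i], report$Q[i], report$sigma_Q[i],
                         report$z[i], report$verdict[i],
                         report$talin_mode[i], report$kindlin_mode[i])
               }, character(1)))
    writeLines(lines, text_path)
  }
  invisible(report)
}

#' Bundled reference dissociation constants and energy squares
#'
#' The package ships two small plain-text tables of previously reported
#' equilibrium constants for talin-head (THD1, THD2) and kindlin-2 binding
#' to integrin beta-tails, including the four energy squares used throughout
#' the documentation: wild-type THD1/KIND2 with the beta3 tail, the
#' contact-breaking substitutions THD1-K402E and KIND2-Y13A, and the
#' decoupled beta1-spacer tail.
#'
#' @param which `"squares"` or `"kds"`.
#' @return for `"squares"` a list of [energy_square()]s; for `"kds"` a data
#'   frame.
#' @export
reference_constants <- function(which = c("squares", "kds")) {
  which <- match.arg(which)
  if (which == "squares") {
    read_squares_csv(system.file("extdata", "energy_squares.csv",
                                 package = "ternabind", mustWork = TRUE))
  } else {
    utils::read.csv(system.file("extdata", "measured_kds.csv",
                                package = "ternabind", mustWork = TRUE),
                    stringsAsFactors = FALSE)
  }
}
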