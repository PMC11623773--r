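#' Pharmacokinetic parameters for the steady-state detectability bound
#'
#' Parameters of the constant-infusion model of circulating DNA: a rare
#' cell population of `n_cells` cells dies at a constant rate over
#' `duration` minutes, each dying diploid cell releasing `genome_mass` pg
#' of DNA, of which a fraction `d` reaches plasma cfDNA. At steady state
#' the plasma concentration is `C = d * k0 * t_half / (ln(2) * Vd)` with
#' infusion rate `k0 = n_cells * genome_mass / duration`.
#'
#' Defaults are the standard-man / literature values: plasma volume 3.0 L,
#' steady-state cfDNA half-life 114 min, 6.46 pg per diploid genome,
#' ~500,000 lower motor neurons, total plasma cfDNA 297 pg/ul, and
#' plasma-availability fraction `d` between 3% (megakaryocytes,
#' endothelium) and 0.003% (erythrocyte progenitors) — 3% being the
#' optimistic bound used for motor neurons.
#'
#' @param d Fraction of released DNA reaching plasma cfDNA (dimensionless).
#' @param t_half Steady-state cfDNA half-life, minutes.
#' @param vd Plasma volume (volume of distribution), litres.
#' @param n_cells Number of cells in the dying population.
#' @param genome_mass DNA mass per dying diploid cell, pg.
#' @param duration Period over which the cells die, minutes (default 24 h).
#' @param total_cfdna Expected total plasma cfDNA concentration, pg/ul.
#' @return An object of class `pk_params`.
#' @export
pk_params <- function(d = 0.03, t_half = 114, vd = 3.0, n_cells = 5e5,
                      genome_mass = 6.46, duration = 1440,
                      total_cfdna = 297) {
  vals <- c(d = d, t_half = t_half, vd = vd, n_cells = n_cells,
            genome_mass = genome_mass, duration = duration,
            total_cfdna = total_cfdna)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all pharmacokinetic parameters must be strictly positive; got ",
         paste(names(vals)[!is.finite(vals) | vals <= 0], collapse = ", "))
  }
  if (d > 1) stop("d is a fraction and must satisfy 0 < d <= 1")
  structure(as.list(vals), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Steady-state infusion model parameters\n")
  cat(sprintf("  d = %g, t_half = %g min, Vd = %g L\n", x$d, x$t_half, x$vd))
  cat(sprintf("  %g cells x %g pg dying over %g min; total cfDNA %g pg/ul\n",
              x$n_cells, x$genome_mass, x$duration, x$total_cfdna))
  invisible(x)
}

#' Steady-state concentration and cfDNA fraction of the dying population
#'
#' Closed form: `k0 = n_cells * genome_mass / duration` (pg/min),
#' `C = d * k0 * t_half / (ln(2) * Vd)` with `Vd` converted to microlitres,
#' and `fraction = C / total_cfdna`.
#'
#' @param params A [pk_params()].
#' @return An object of class `pk_result`: list with `k0` (pg/min),
#'   `concentration` (pg/ul), `fraction` (of total cfDNA) and `percent`.
#' @examples
#' steady_state_concentration(pk_params())  # all 500,000 MN over 24 h
#' @export
steady_state_concentration <- function(params = pk_params()) {
  stopifnot(inherits(params, "pk_params"))
  k0 <- params$n_cells * params$genome_mass / params$duration
  vd_ul <- params$vd * 1e6
  C <- params$d * k0 * params$t_half / (log(2) * vd_ul)
  fraction <- C / params$total_cfdna
  structure(list(k0 = k0, concentration = C, fraction = fraction,
                 percent = 100 * fraction, params = params),
            class = "pk_result")
}

#' @export
print.pk_result <- function(x, ...) {
  cat("Steady-state result\n")
  cat(sprintf("  infusion rate k0 = %.4g pg/min\n", x$k0))
  cat(sprintf("  concentration C = %.4g pg/ul\n", x$concentration))
  cat(sprintf("  fraction of total cfDNA = %.4g (%.4g%%)\n",
              x$fraction, x$percent))
  invisible(x)
}

#' Cell-death rate required to reach a target cfDNA fraction
#'
#' Inverts the closed form:
#' `k0 = target_fraction * total_cfdna * ln(2) * Vd / (d * t_half)`,
#' then divides by the per-cell DNA mass for a rate in cells per minute,
#' and reports how long the whole population of `n_cells` would last at
#' that rate.
#'
#' @param target_fraction Target fraction of total cfDNA, in `(0, 1]`.
#' @param params A [pk_params()].
#' @return An object of class `pk_rate`: list with `k0` (pg/min),
#'   `cells_per_min`, and `minutes_to_deplete` (time for all `n_cells` to
#'   die at that rate).
#' @examples
#' required_death_rate(0.01)  # 1% of plasma cfDNA
#' @export
required_death_rate <- function(target_fraction, params = pk_params()) {
  stopifnot(inherits(params, "pk_params"))
  if (!(is.numeric(target_fraction) && target_fraction > 0 &&
        target_fraction <= 1)) {
    stop("target_fraction must be in (0, 1]")
  }
  vd_ul <- params$vd * 1e6
  k0 <- target_fraction * params$total_cfdna * log(2) * vd_ul /
    (params$d * params$t_half)
  cells_per_min <- k0 / params$genome_mass
  structure(list(k0 = k0, cells_per_min = cells_per_min,
                 minutes_to_deplete = params$n_cells / cells_per_min,
                 target_fraction = target_fraction, params = params),
            class = "pk_rate")
}

#' @export
print.pk_rate <- function(x, ...) {
  cat(sprintf("To reach %.4g%% of plasma cfDNA:\n", 100 * x$target_fraction))
  cat(sprintf("  death rate %.4g cells/min (all %g cells in %.3g minutes)\n",
              x$cells_per_min, x$params$n_cells, x$minutes_to_deplete))
  invisible(x)
}

#' Detectability grid over disease durations and availability fractions
#'
#' One steady-state cfDNA fraction per (duration, d) combination; the
#' default `d` endpoints are 3% and 0.003%, the observed extremes of the
#' plasma-availability fraction across cell types.
#'
#' @param durations Disease durations in minutes (default 1-5 years).
#' @param d_values Availability fractions (default `c(0.03, 3e-5)`).
#' @param params A [pk_params()]; `duration` and `d` are overridden cell
#'   by cell.
#' @return data.frame with columns `duration`, `d`, `concentration`,
#'   `fraction`, `percent`.
#' @export
scenario_grid <- function(durations = (1:5) * 525960,
                          d_values = c(0.03, 3e-5),
                          params = pk_params()) {
  if (length(durations) == 0 || length(d_values) == 0) {
    stop("durations and d_values must be non-empty")
  }
  grid <- expand.grid(duration = durations, d = d_values,
                      KEEP.OUT.ATTRS = FALSE)
  res <- mapply(function(dur, dd) {
    p <- params; p$duration <- dur; p$d <- dd
    r <- steady_state_concentration(p)
    c(r$concentration, r$fraction)
  }, grid$duration, grid$d)
  grid$concentration <- res[1, ]
  grid$fraction <- res[2, ]
  grid$percent <- 100 * grid$fraction
  grid
}
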