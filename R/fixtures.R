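# Registry of published parameter sets for the rule-of-mixtures model.
# Every number is stored verbatim as printed in its source table/caption,
# together with its printed unit; conversion to a single working stress unit
# happens in as_material_params() and can be logged with verbose = TRUE.
# `c_Jm3` values (1 J/m^3 = 1 Pa) come from the pseudo-elastic fits and only
# enter the energy; the softened stress law does not involve c.

fixture_registry <- function() {
  row <- function(name, label, mu, mu_unit, N, A1, A2, A_unit, b, C, C_unit,
                  f_percent, stress_kind, lambda_protocol,
                  pe = NULL, c_Jm3 = 0, table = "") {
    list(name = name, label = label,
         printed = list(mu = mu, mu_unit = mu_unit, N = N,
                        A1 = A1, A2 = A2, A_unit = A_unit,
                        b = b, C = C, C_unit = C_unit,
                        f_percent = f_percent, c_Jm3 = c_Jm3),
         pe = pe, stress_kind = stress_kind,
         lambda_protocol = lambda_protocol, source = table)
  }
  pe_set <- function(m1, r1, r2, gamma) list(m1 = m1, r1 = r1, r2 = r2,
                                             gamma = gamma)
  list(
    row("vaginal_longitudinal", "Vaginal tissue (longitudinal axis)",
        0.085, "MPa", 3.25, -6.5, 70, "MPa", 1.3, 0.7, "MPa", 0.2,
        "cauchy", 1.6, pe_set(1.8, 1.0001, 0.1, 0.3), -0.0284,
        "published fit, soft-tissue set"),
    row("vaginal_transverse", "Vaginal tissue (transverse axis)",
        0.085, "MPa", 3.25, -6.5, 3.93, "MPa", 1.3, 0.7, "MPa", 0.2,
        "cauchy", 1.6, pe_set(1.8, 1.0001, 0.1, 0.3), -0.0284,
        "published fit, soft-tissue set"),
    row("male_mouse_skin", "Male mouse skin",
        0.95, "MPa", 1.082, 0, 30, "MPa", 2.8, 0.98, "MPa", 9.0,
        "cauchy", 1.25, pe_set(0.0525, 1.00001, 0.55, 0.55), 0.0994,
        "published fit, soft-tissue set"),
    row("female_mouse_skin", "Female mouse skin",
        0.77, "MPa", 1.18, 0, 20, "MPa", 2.55, 1.2, "MPa", 9.0,
        "cauchy", 1.35, pe_set(0.05, 1.001, 0.04, 0.55), 0.7741,
        "published fit, soft-tissue set"),
    row("pgc25_suture", "PGC25 suture material",
        100, "MPa", 2.35, 0, 1300, "MPa", 0.95, 0.008, "MPa", 10,
        "engineering", 1.5, pe_set(1.65, 1.1, 0.6, 1), -27.5616,
        "published fit, suture set"),
    row("polypropylene_suture", "Polypropylene suture material",
        300, "MPa", 50.5, -7500, -2100, "MPa", 0.6, 0.0024, "MPa", 1.35,
        "engineering", 2.0, pe_set(0.85, 1.0001, 0.35, 0.975), -78.5996,
        "published fit, suture set"),
    row("csm_trachea", "Circumferential mucosa and submucosa membrane (CSM)",
        5, "kPa", 1.029, 0, 2500, "MPa", 1.3, 2.1, "kPa", 0.8,
        "cauchy", 1.15, NULL, 0, "published fit, tracheal set"),
    row("asm_trachea", "Axial mucosa and submucosa membrane (ASM)",
        5, "kPa", 1.029, 0, 15, "MPa", 1.3, 2.1, "kPa", 0.8,
        "cauchy", 1.15, NULL, 0, "published fit, tracheal set"),
    row("cam_trachea", "Circumferential adventitial membrane (CAM)",
        10, "kPa", 1.045, 0, 35000, "MPa", 1, 3.4, "kPa", 0.6,
        "cauchy", 1.215, NULL, 0, "published fit, tracheal set"),
    row("aam_trachea", "Axial adventitial membrane (AAM)",
        10, "kPa", 1.045, 0, 1.5, "MPa", 1, 3.4, "kPa", 0.6,
        "cauchy", 1.215, NULL, 0, "published fit, tracheal set"),
    row("frontal_tension", "Frontal lobe (sagittal direction: tension)",
        2.6, "kPa", 1.065, -150, -3000, "kPa", 2.7, 4.6, "kPa", 1,
        "engineering", 1.15, pe_set(0.095, 1.001, 0.8, 0.1), -0.8263,
        "published fit, brain set"),
    row("frontal_compression", "Frontal lobe (sagittal direction: compression)",
        2.6, "kPa", 1.065, -150, -3000, "kPa", 2.5, 0.6, "kPa", 1,
        "engineering", 0.85, pe_set(0.095, 1.001, 0.8, 0.1), -0.8263,
        "published fit, brain set"),
    row("occipital_tension", "Occipital lobe (frontal direction: tension)",
        2.65, "kPa", 2.5, -350, 650, "kPa", 2.7, 3.8, "kPa", 0.93,
        "engineering", 1.3, pe_set(0.006, 2.5, 1.8, 0.1), -0.0205,
        "published fit, brain set"),
    row("occipital_compression", "Occipital lobe (frontal direction: compression)",
        2.65, "kPa", 2.5, -350, 650, "kPa", 2.7, 3.8, "kPa", 0.93,
        "engineering", 0.7, pe_set(0.006, 2.5, 1.8, 0.1), -0.0205,
        "published fit, brain set"),
    {
      r <- row("rubber", "Vulcanized natural rubber (energy-split validation)",
               0.475, "MPa", 28.13, 0, 0.0001, "MPa", NA, NA, "MPa", 25,
               "engineering", 6, NULL, -0.1880,
               "published fit, energy-split rubber set")
      r
    })
}

#' Names of the packaged material parameter sets
#'
#' @return character vector of fixture names usable with
#'   [material_fixture()].
#' @export
fixture_names <- function() {
  vapply(fixture_registry(), `[[`, "", "name")
}

#' Load a packaged material parameter set
#'
#' Returns one of the packaged literature parameter sets (14 tissue/material
#' rows plus the rubber energy-split set), carrying both the verbatim printed
#' values with their printed units and a converted [material_params()] block
#' in a single working stress unit (the unit of \code{mu}). Conversions
#' applied at load: fiber constants printed in MPa are rescaled to kPa where
#' \code{mu} is in kPa; the energy constant \code{c} printed in J/m^3 (= Pa)
#' is rescaled to the working unit; the fiber fraction column, printed in
#' percent, is divided by 100.
#'
#' @param name fixture name, see [fixture_names()].
#' @param f_as_fraction if TRUE, read the printed fiber-fraction number as a
#'   fraction rather than a percentage (relevant only for the vaginal-tissue
#'   sets, whose printed 0.2 is ambiguous; the percent reading is default).
#' @param verbose log unit conversions via [message()].
#' @return an object of class \code{"material_fixture"} with fields
#'   \code{name}, \code{label}, \code{printed} (verbatim values),
#'   \code{params} (converted [material_params()]), \code{stress_kind} and
#'   \code{lambda_protocol}.
#' @export
#' @examples
#' fx <- material_fixture("male_mouse_skin")
#' fx$params$iso$mu  # 0.95 MPa
material_fixture <- function(name, f_as_fraction = FALSE, verbose = FALSE) {
  reg <- fixture_registry()
  nm <- vapply(reg, `[[`, "", "name")
  if (!name %in% nm)
    stop_domain(sprintf("unknown fixture '%s'; available: %s",
                        name, paste(nm, collapse = ", ")))
  fx <- reg[[match(name, nm)]]
  fx$params <- as_material_params(fx, f_as_fraction = f_as_fraction,
                                  verbose = verbose)
  class(fx) <- "material_fixture"
  fx
}

# convert a registry entry's printed values into one working stress unit
as_material_params <- function(fx, f_as_fraction = FALSE, verbose = FALSE) {
  p <- fx$printed
  unit <- p$mu_unit
  scale_A <- if (p$A_unit == unit) 1
             else if (p$A_unit == "MPa" && unit == "kPa") 1e3
             else if (p$A_unit == "kPa" && unit == "MPa") 1e-3
             else stop_domain("unsupported unit pair")
  if (verbose && scale_A != 1)
    message(sprintf("fixture %s: A1/A2 converted %s -> %s (x%g)",
                    fx$name, p$A_unit, unit, scale_A))
  scale_c <- switch(unit, MPa = 1e-6, kPa = 1e-3,
                    stop_domain("unsupported stress unit"))
  if (verbose && p$c_Jm3 != 0)
    message(sprintf("fixture %s: c = %g J/m^3 converted to %g %s",
                    fx$name, p$c_Jm3, p$c_Jm3 * scale_c, unit))
  f <- if (f_as_fraction) p$f_percent else p$f_percent / 100
  if (f < 0 || f > 1) stop_domain("fiber fraction outside [0, 1] after reading")
  soft <- if (is.finite(p$b) && is.finite(p$C))
    softening_params(b = p$b, C = p$C / p$mu, n = 1) else NULL
  # note: the printed C column carries stress units; the residual term enters
  # the stress as (mu*C/2)*grad, so the dimensionless model constant is C/mu.
  pe <- if (!is.null(fx$pe))
    pseudoelastic_params(fx$pe$m1, fx$pe$r1, fx$pe$r2, fx$pe$gamma) else NULL
  material_params(
    iso = isotropic_params(mu = p$mu, N = p$N, c = p$c_Jm3 * scale_c),
    fib = fiber_params(f = f, A1 = p$A1 * scale_A, A2 = p$A2 * scale_A),
    soft = soft, pe = pe, unit = unit)
}

#' Overview table of all packaged parameter sets
#'
#' @return a data frame with one row per fixture, printed values and units.
#' @export
fixture_table <- function() {
  reg <- fixture_registry()
  do.call(rbind, lapply(reg, function(fx) {
    p <- fx$printed
    data.frame(name = fx$name, label = fx$label,
               mu = p$mu, unit = p$mu_unit, N = p$N,
               A1 = p$A1, A2 = p$A2, A_unit = p$A_unit,
               b = p$b, C = p$C, f_percent = p$f_percent,
               c_Jm3 = p$c_Jm3,
               has_pe = !is.null(fx$pe),
               stress_kind = fx$stress_kind,
               lambda_protocol = fx$lambda_protocol,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.material_fixture <- function(x, ...) {
  cat(sprintf("Material fixture '%s': %s\n", x$name, x$label))
  cat(sprintf("  source: %s; %s stress; protocol stretch %.4g\n",
              x$source, x$stress_kind, x$lambda_protocol))
  print(x$params)
  invisible(x)
}
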