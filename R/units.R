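#' Binding constants for the single-site free hormone equilibrium
#'
#' Bundles the affinity constants of vitamin D binding protein (VDBP) and
#' albumin for 25-hydroxyvitamin D together with the molecular weights needed
#' to convert clinical mass concentrations to molar concentrations. The
#' affinity constants are the conventional values used with the Bikle
#' equilibrium equation. Molecular weights are not fixed by any assay standard;
#' the defaults are the values conventionally paired with these affinity
#' constants and may be overridden.
#'
#' @param ka_dbp Affinity constant of VDBP for 25(OH)D, in M^-1.
#' @param ka_alb Affinity constant of albumin for 25(OH)D, in M^-1.
#' @param mw_25ohd Molecular weight of 25(OH)D, g/mol.
#' @param mw_vdbp Molecular weight of VDBP, g/mol.
#' @param mw_albumin Molecular weight of albumin, g/mol.
#'
#' @return An object of class `binding_constants`.
#' @examples
#' binding_constants()
#' binding_constants(mw_vdbp = 52000) # alternative VDBP molecular weight
#' @export
binding_constants <- function(ka_dbp = 8.00e8,
                              ka_alb = 6.00e5,
                              mw_25ohd = 400.64,
                              mw_vdbp = 58000,
                              mw_albumin = 66430) {
  for (nm in c("ka_dbp", "ka_alb", "mw_25ohd", "mw_vdbp", "mw_albumin")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive finite number", nm),
           call. = FALSE)
    }
  }
  if (ka_dbp <= ka_alb) {
    stop("`ka_dbp` must exceed `ka_alb`: VDBP is the high-affinity carrier",
         call. = FALSE)
  }
  structure(
    list(ka_dbp = ka_dbp, ka_alb = ka_alb, mw_25ohd = mw_25ohd,
         mw_vdbp = mw_vdbp, mw_albumin = mw_albumin),
    class = "binding_constants"
  )
}

#' @export
print.binding_constants <- function(x, ...) {
  cat("Binding constants for free 25(OH)D equilibrium\n")
  cat(sprintf("  Ka (VDBP):    %.3g M^-1\n", x$ka_dbp))
  cat(sprintf("  Ka (albumin): %.3g M^-1\n", x$ka_alb))
  cat(sprintf("  MW 25(OH)D:   %.5g g/mol\n", x$mw_25ohd))
  cat(sprintf("  MW VDBP:      %.5g g/mol\n", x$mw_vdbp))
  cat(sprintf("  MW albumin:   %.5g g/mol\n", x$mw_albumin))
  invisible(x)
}

# Analyte registry: one native clinical unit per analyte, with the factor that
# takes the native unit to g/L and the field of `binding_constants` holding the
# molecular weight.
.analytes <- list(
  "25(OH)D-total" = list(unit = "ng/mL", to_g_l = 1e-6, mw = "mw_25ohd"),
  "25(OH)D3"      = list(unit = "ng/mL", to_g_l = 1e-6, mw = "mw_25ohd"),
  "25(OH)D2"      = list(unit = "ng/mL", to_g_l = 1e-6, mw = "mw_25ohd"),
  "VDBP"          = list(unit = "ug/mL", to_g_l = 1e-3, mw = "mw_vdbp"),
  "albumin"       = list(unit = "g/dL",  to_g_l = 10,   mw = "mw_albumin")
)

#' Analytes with registered native clinical units
#'
#' @return Data frame of analyte names and their native unit.
#' @examples
#' analyte_units()
#' @export
analyte_units <- function() {
  data.frame(
    analyte = names(.analytes),
    native_unit = vapply(.analytes, `[[`, character(1), "unit"),
    row.names = NULL
  )
}

.analyte_entry <- function(analyte) {
  entry <- .analytes[[analyte]]
  if (is.null(entry)) {
    stop(sprintf("unknown analyte '%s'; known analytes: %s", analyte,
                 paste(names(.analytes), collapse = ", ")), call. = FALSE)
  }
  entry
}

#' Convert a clinical mass concentration to molar
#'
#' Concentrations arrive in each analyte's native clinical unit (ng/mL for
#' vitamin D metabolites, ug/mL for VDBP, g/dL for albumin), are rescaled to
#' g/L and divided by the molecular weight. The molar scale is what the
#' binding-equilibrium affinity constants act on.
#'
#' @param value Concentration(s) in the analyte's native unit; non-negative.
#' @param analyte One of `analyte_units()$analyte`.
#' @param constants A [binding_constants()] object supplying molecular weights.
#'
#' @return Concentration(s) in mol/L.
#' @examples
#' to_molar(4.3, "albumin")            # ~6.47e-4 M
#' to_molar(253.3, "VDBP")             # ~4.37e-6 M
#' @export
to_molar <- function(value, analyte, constants = binding_constants()) {
  entry <- .analyte_entry(analyte)
  stopifnot(inherits(constants, "binding_constants"))
  if (any(!is.na(value) & value < 0)) {
    stop(sprintf("negative concentration for %s", analyte), call. = FALSE)
  }
  value * entry$to_g_l / constants[[entry$mw]]
}

#' Convert a molar concentration back to the analyte's native clinical unit
#'
#' Exact inverse of [to_molar()].
#'
#' @inheritParams to_molar
#' @param value Concentration(s) in mol/L; non-negative.
#' @return Concentration(s) in the analyte's native unit.
#' @examples
#' from_molar(to_molar(4.3, "albumin"), "albumin") # 4.3
#' @export
from_molar <- function(value, analyte, constants = binding_constants()) {
  entry <- .analyte_entry(analyte)
  stopifnot(inherits(constants, "binding_constants"))
  if (any(!is.na(value) & value < 0)) {
    stop(sprintf("negative concentration for %s", analyte), call. = FALSE)
  }
  value * constants[[entry$mw]] / entry$to_g_l
}
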