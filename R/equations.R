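#' Construct a free 25(OH)D estimating equation specification
#'
#' An estimating equation is a linear model on (possibly log-transformed)
#' biomarkers: an intercept, main-effect terms, optional pairwise interaction
#' terms between the log-transformed variables, and optional additive offsets
#' by Gc diplotype. Estimates are on the pg/mL scale. All logarithms are
#' natural logarithms.
#'
#' @param name Identifier for the equation.
#' @param intercept Intercept, pg/mL scale.
#' @param terms Data frame (or list coercible to one) with columns `variable`,
#'   `transform` (`"identity"` or `"log"`) and `coefficient`.
#' @param interactions Optional data frame with columns `var_a`, `var_b`,
#'   `coefficient`; both variables enter as natural logs.
#' @param phenotype_offsets Optional named numeric vector covering all six
#'   diplotypes of [gc_diplotypes()], reference Gc1f/Gc1f offset 0.
#'
#' @return An object of class `free25d_equation`.
#' @seealso [eq1_spec()], [eq2_spec()], [eq3_spec()], [evaluate_equation()]
#' @export
equation_spec <- function(name, intercept, terms, interactions = NULL,
                          phenotype_offsets = NULL) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  stopifnot(all(c("variable", "transform", "coefficient") %in% names(terms)))
  if (!all(terms$transform %in% c("identity", "log"))) {
    stop("term transforms must be 'identity' or 'log'", call. = FALSE)
  }
  known <- c(.cohort_schema$variable, "total_25ohd")
  bad <- setdiff(terms$variable, known)
  if (length(bad)) {
    stop(sprintf("unknown variable(s) in equation terms: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(interactions)) {
    interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
    stopifnot(all(c("var_a", "var_b", "coefficient") %in% names(interactions)))
    bad <- setdiff(c(interactions$var_a, interactions$var_b), known)
    if (length(bad)) {
      stop(sprintf("unknown variable(s) in interactions: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (!is.null(phenotype_offsets)) {
    if (!setequal(names(phenotype_offsets), gc_diplotypes())) {
      stop("phenotype_offsets must cover exactly the six Gc diplotypes",
           call. = FALSE)
    }
    if (phenotype_offsets[["Gc1f/Gc1f"]] != 0) {
      stop("the reference diplotype Gc1f/Gc1f must have offset 0",
           call. = FALSE)
    }
    phenotype_offsets <- phenotype_offsets[gc_diplotypes()]
  }
  required <- unique(c(terms$variable,
                       if (!is.null(interactions)) c(interactions$var_a,
                                                     interactions$var_b),
                       if (!is.null(phenotype_offsets)) "phenotype"))
  structure(
    list(name = name, intercept = intercept, terms = terms,
         interactions = interactions, phenotype_offsets = phenotype_offsets,
         required = required),
    class = "free25d_equation"
  )
}

#' @export
print.free25d_equation <- function(x, ...) {
  cat(sprintf("Free 25(OH)D estimating equation '%s'\n", x$name))
  cat(sprintf("  intercept: %g\n", x$intercept))
  for (i in seq_len(nrow(x$terms))) {
    tr <- x$terms$transform[i]
    v <- if (tr == "log") sprintf("log[%s]", x$terms$variable[i]) else
      x$terms$variable[i]
    cat(sprintf("  %+g x %s\n", x$terms$coefficient[i], v))
  }
  if (!is.null(x$interactions)) {
    for (i in seq_len(nrow(x$interactions))) {
      cat(sprintf("  %+g x log[%s] x log[%s]\n",
                  x$interactions$coefficient[i],
                  x$interactions$var_a[i], x$interactions$var_b[i]))
    }
  }
  if (!is.null(x$phenotype_offsets)) {
    cat("  Gc diplotype offsets:\n")
    for (p in names(x$phenotype_offsets)) {
      cat(sprintf("    %-10s %+g\n", p, x$phenotype_offsets[[p]]))
    }
  }
  invisible(x)
}

#' Published free 25(OH)D estimating equations
#'
#' The three equations as published: Eq. (1) uses albumin plus log-transformed
#' 25(OH)D3, 25(OH)D2, VDBP, 1,25(OH)2D3 and 24,25(OH)2D3 with a
#' log[25(OH)D3] x log[24,25(OH)2D3] interaction; Eq. (2) adds additive Gc
#' diplotype offsets; Eq. (3) uses only biomarkers available in a typical
#' clinical laboratory (albumin, 25(OH)D3, iPTH, 1,25(OH)2D3). Input units:
#' albumin g/dL, 25(OH)D3 and 25(OH)D2 and 24,25(OH)2D3 ng/mL, VDBP ug/mL,
#' 1,25(OH)2D3 and iPTH pg/mL. Output is pg/mL.
#'
#' @return A `free25d_equation` object.
#' @name shipped_equations
NULL

#' @rdname shipped_equations
#' @export
eq1_spec <- function() {
  equation_spec(
    name = "eq1", intercept = 12.202,
    terms = data.frame(
      variable = c("albumin", "d25_3", "d25_2", "vdbp", "d1_25_3", "d24_25_3"),
      transform = c("identity", rep("log", 5)),
      coefficient = c(0.359, 0.844, 0.145, -1.522, -0.851, -1.906)
    ),
    interactions = data.frame(var_a = "d25_3", var_b = "d24_25_3",
                              coefficient = 0.943)
  )
}

#' @rdname shipped_equations
#' @export
eq2_spec <- function() {
  equation_spec(
    name = "eq2", intercept = 12.779,
    terms = data.frame(
      variable = c("albumin", "d25_3", "vdbp", "d25_2", "d1_25_3", "d24_25_3"),
      transform = c("identity", rep("log", 5)),
      coefficient = c(0.348, 0.748, -1.566, 0.149, -0.833, -1.826)
    ),
    interactions = data.frame(var_a = "d25_3", var_b = "d24_25_3",
                              coefficient = 0.935),
    phenotype_offsets = c(
      "Gc1f/Gc1f" = 0, "Gc1f/Gc1s" = 0.019716, "Gc1s/Gc1s" = 0.002741,
      "Gc2/Gc1f" = -0.394562, "Gc2/Gc1s" = -0.1283514, "Gc2/Gc2" = -0.1381116
    )
  )
}

#' @rdname shipped_equations
#' @export
eq3_spec <- function() {
  equation_spec(
    name = "eq3", intercept = 3.098,
    terms = data.frame(
      variable = c("albumin", "d25_3", "ipth", "d1_25_3"),
      transform = c("identity", "log", "log", "log"),
      coefficient = c(0.275, 2.370, -0.467, -1.194)
    )
  )
}

#' Evaluate an estimating equation on participant data
#'
#' Computes intercept + sum of coefficient x transform(value) + sum of
#' coefficient x log(a) x log(b) + diplotype offset, per participant.
#' Logarithms are natural. Estimates can be negative at extreme inputs; raw
#' values are returned (with a warning) rather than clipped, so that agreement
#' statistics remain faithful — use [floor_estimates()] for presentation.
#'
#' @param spec A [equation_spec()] object.
#' @param data A cohort data frame ([read_cohort()], [generate_cohort()]), or
#'   any data frame supplying the required variables by schema column name or
#'   bare variable name.
#' @return Numeric vector of estimated free 25(OH)D, pg/mL.
#' @examples
#' medians <- data.frame(albumin = 4.3, d25_3 = 20.3, d25_2 = 0.33,
#'                       vdbp = 253.3, d1_25_3 = 40.2, d24_25_3 = 1.7)
#' evaluate_equation(eq1_spec(), medians)
#' @export
evaluate_equation <- function(spec, data) {
  stopifnot(inherits(spec, "free25d_equation"))
  n <- nrow(data)
  out <- rep(spec$intercept, n)
  log_of <- function(variable) {
    v <- get_variable(data, variable)
    if (any(!is.na(v) & v <= 0)) {
      stop(sprintf("non-positive value(s) of '%s' under log transform",
                   variable), call. = FALSE)
    }
    log(v)
  }
  for (i in seq_len(nrow(spec$terms))) {
    v <- spec$terms$variable[i]
    x <- if (spec$terms$transform[i] == "log") log_of(v) else
      get_variable(data, v)
    out <- out + spec$terms$coefficient[i] * x
  }
  if (!is.null(spec$interactions)) {
    for (i in seq_len(nrow(spec$interactions))) {
      out <- out + spec$interactions$coefficient[i] *
        log_of(spec$interactions$var_a[i]) * log_of(spec$interactions$var_b[i])
    }
  }
  if (!is.null(spec$phenotype_offsets)) {
    ph <- normalize_phenotype(as.character(get_variable(data, "phenotype")))
    if (anyNA(ph)) {
      stop("phenotype is required (equation carries diplotype offsets) but is missing",
           call. = FALSE)
    }
    out <- out + unname(spec$phenotype_offsets[ph])
  }
  neg <- which(!is.na(out) & out < 0)
  if (length(neg)) {
    warning(sprintf("%d estimate(s) are negative; see floor_estimates()",
                    length(neg)), call. = FALSE)
    attr(out, "flagged_negative") <- neg
  }
  out
}

#' Floor estimates for clinical presentation
#'
#' @param x Numeric estimates, pg/mL.
#' @param floor Lower bound, pg/mL.
#' @return `pmax(x, floor)` with flags dropped.
#' @export
floor_estimates <- function(x, floor = 0.1) {
  pmax(as.numeric(x), floor)
}

#' @rdname shipped_equations
#' @param data A cohort data frame; see [evaluate_equation()].
#' @export
estimate_eq1 <- function(data) evaluate_equation(eq1_spec(), data)

#' @rdname shipped_equations
#' @export
estimate_eq2 <- function(data) evaluate_equation(eq2_spec(), data)

#' @rdname shipped_equations
#' @export
estimate_eq3 <- function(data) evaluate_equation(eq3_spec(), data)

#' Bikle single-site binding-equilibrium estimate of free 25(OH)D
#'
#' Free fraction = 1 / (1 + Ka1 [VDBP] + Ka2 [albumin]) with molar carrier
#' concentrations; free 25(OH)D = total 25(OH)D x free fraction. Total
#' 25(OH)D is the D3 + D2 sum (D2 taken as 0 when absent). The estimate is
#' strictly decreasing in both carrier concentrations and equals total
#' 25(OH)D when both are zero.
#'
#' @param data Cohort data frame supplying `d25_3` (ng/mL), `vdbp` (ug/mL) and
#'   `albumin` (g/dL); `d25_2` (ng/mL) optional.
#' @param constants [binding_constants()].
#' @return Estimated free 25(OH)D, pg/mL.
#' @examples
#' estimate_bikle(data.frame(albumin = 4.3, d25_3 = 20.3, d25_2 = 0.33,
#'                           vdbp = 253.3))
#' @export
estimate_bikle <- function(data, constants = binding_constants()) {
  d3 <- get_variable(data, "d25_3")
  d2 <- if (has_variable(data, "d25_2")) get_variable(data, "d25_2") else 0
  d2[is.na(d2)] <- 0
  vdbp <- get_variable(data, "vdbp")
  alb <- get_variable(data, "albumin")
  if (any(!is.na(d3) & d3 < 0) || any(d2 < 0) ||
      any(!is.na(vdbp) & vdbp < 0) || any(!is.na(alb) & alb < 0)) {
    stop("Bikle estimate requires non-negative concentrations", call. = FALSE)
  }
  total_ng_ml <- d3 + d2
  denom <- 1 + constants$ka_dbp * to_molar(vdbp, "VDBP", constants) +
    constants$ka_alb * to_molar(alb, "albumin", constants)
  # ng/mL -> pg/mL
  1000 * total_ng_ml / denom
}

#' Vitamin D metabolite ratio (VMR)
#'
#' 100 x 24,25(OH)2D3 / 25(OH)D3, both in ng/mL: a scale-invariant marker of
#' vitamin D catabolism.
#'
#' @param d24_25_3 24,25(OH)2D3, ng/mL; non-negative.
#' @param d25_3 25(OH)D3, ng/mL; strictly positive.
#' @return Dimensionless ratio x 100.
#' @examples
#' vmr(1.7, 20.3)
#' @export
vmr <- function(d24_25_3, d25_3) {
  if (any(!is.na(d25_3) & d25_3 <= 0)) {
    stop("25(OH)D3 must be strictly positive to form the VMR", call. = FALSE)
  }
  if (any(!is.na(d24_25_3) & d24_25_3 < 0)) {
    stop("24,25(OH)2D3 must be non-negative", call. = FALSE)
  }
  100 * d24_25_3 / d25_3
}
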