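# Cohort table schema. Units are embedded in column names so that unit errors
# surface at parse time rather than as silently wrong estimates — the main
# failure mode for free-vitamin-D calculators.

.cohort_schema <- data.frame(
  variable = c("albumin", "d25_3", "d25_2", "vdbp", "d1_25_3", "d24_25_3",
               "ipth", "ifgf23", "calcium", "phosphate", "egfr", "age", "bmi",
               "sex", "race", "season", "site", "diabetes", "phenotype",
               "measured_free"),
  column = c("albumin_g_dl", "d25_3_ng_ml", "d25_2_ng_ml", "vdbp_ug_ml",
             "d1_25_3_pg_ml", "d24_25_3_ng_ml", "ipth_pg_ml", "ifgf23_pg_ml",
             "calcium_mg_dl", "phosphate_mg_dl", "egfr_ml_min_173",
             "age_years", "bmi_kg_m2", "sex", "race", "season", "site",
             "diabetes", "phenotype", "free25ohd_pg_ml"),
  kind = c(rep("numeric", 13), "factor", "factor", "factor", "factor",
           "numeric", "phenotype", "numeric"),
  stringsAsFactors = FALSE
)

.factor_levels <- list(
  sex = c("female", "male"),
  race = c("white", "black"),
  season = c("winter", "spring", "summer", "fall"),
  site = c("memphis", "pittsburgh")
)

#' Cohort table column schema
#'
#' Maps the short variable names used by equation specifications to the
#' unit-bearing column names of the cohort CSV.
#'
#' @return Data frame with columns `variable`, `column` and `kind`.
#' @examples
#' cohort_schema()
#' @export
cohort_schema <- function() .cohort_schema

# Fetch a model variable from a cohort data frame, accepting either the
# canonical unit-bearing column name or the bare variable name. total_25ohd is
# derived as the D2 + D3 sum (D2 taken as 0 when absent).
get_variable <- function(data, variable) {
  if (variable == "total_25ohd") {
    d3 <- get_variable(data, "d25_3")
    d2 <- tryCatch(get_variable(data, "d25_2"), error = function(e) NULL)
    if (is.null(d2)) d2 <- 0
    d2[is.na(d2)] <- 0
    return(d3 + d2)
  }
  col <- .cohort_schema$column[match(variable, .cohort_schema$variable)]
  if (!is.na(col) && col %in% names(data)) return(data[[col]])
  if (variable %in% names(data)) return(data[[variable]])
  stop(sprintf("required variable '%s' (column '%s') is missing from the data",
               variable, ifelse(is.na(col), variable, col)), call. = FALSE)
}

has_variable <- function(data, variable) {
  !inherits(tryCatch(get_variable(data, variable), error = identity), "error")
}
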