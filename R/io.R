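# Cohort CSV reading/writing and equation-spec serialization.
#
# The cohort format is RFC-4180 CSV, UTF-8, "." decimal, one row per
# participant, with unit-bearing canonical headers (see cohort_schema()).
# Lines starting with '#' are provenance comments. Missing values are empty
# fields; "NA" is accepted on read, never written.

#' Read a cohort CSV
#'
#' Headers are matched to the canonical schema case-insensitively and
#' canonicalized; unknown columns are kept with a warning. Gc diplotype
#' strings are normalized to the canonical labels. Zero or missing 25(OH)D2
#' values are replaced by the detection floor (a warning reports how many),
#' since the estimating equations log-transform it.
#'
#' @param path Path to a CSV file.
#' @param d25_2_floor Detection floor for 25(OH)D2, ng/mL; default 0.2. Set
#'   `NULL` to disable substitution.
#' @return Cohort data frame with attribute `provenance` (any `#` header
#'   comments found).
#' @export
read_cohort <- function(path, d25_2_floor = 0.2) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  comments <- head_lines[startsWith(head_lines, "#")]
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = FALSE)
  # canonicalize headers case-insensitively
  canon <- .cohort_schema$column
  idx <- match(tolower(names(df)), tolower(canon))
  known <- !is.na(idx)
  names(df)[known] <- canon[idx[known]]
  if (any(!known)) {
    warning(sprintf("unrecognized column(s) kept as-is: %s",
                    paste(names(df)[!known], collapse = ", ")), call. = FALSE)
  }
  # numeric validation with row-level reporting
  num_cols <- intersect(.cohort_schema$column[.cohort_schema$kind == "numeric"],
                        names(df))
  for (col in num_cols) {
    if (is.numeric(df[[col]])) next
    raw <- df[[col]]
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(parsed))
    if (length(bad)) {
      stop(sprintf(
        "column '%s': %d unparseable numeric value(s), e.g. data row(s) %s",
        col, length(bad),
        paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- parsed
  }
  if ("phenotype" %in% names(df)) {
    df$phenotype <- normalize_phenotype(df$phenotype)
  }
  if (!is.null(d25_2_floor) && "d25_2_ng_ml" %in% names(df)) {
    low <- is.na(df$d25_2_ng_ml) | df$d25_2_ng_ml < d25_2_floor
    if (any(low)) {
      warning(sprintf(
        "%d 25(OH)D2 value(s) below/missing the %.2g ng/mL detection floor were floored",
        sum(low), d25_2_floor), call. = FALSE)
      df$d25_2_ng_ml[low] <- d25_2_floor
    }
  }
  attr(df, "provenance") <- comments
  df
}

#' Write a cohort CSV
#'
#' Columns are emitted in canonical schema order (extra columns after), with
#' provenance and seed echoed as `#` comment lines.
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  prov <- attr(cohort, "provenance")
  seed <- attr(cohort, "seed")
  ord <- c(intersect(.cohort_schema$column, names(cohort)),
           setdiff(names(cohort), .cohort_schema$column))
  cohort <- cohort[, ord, drop = FALSE]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (is.null(prov)) prov <- "# freevitd cohort"
  prov <- ifelse(startsWith(prov, "#"), prov, paste("#", prov))
  writeLines(prov, con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  utils::write.csv(cohort, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Serialize an estimating equation to JSON text
#'
#' The format is lossless: intercept, terms with transforms, interaction
#' pairs, and Gc diplotype offsets round-trip exactly through
#' [parse_equation()]. Shipped files for the three published equations and
#' the Bikle binding constants live under
#' `system.file("extdata", "equations", package = "freevitd")`.
#'
#' @param spec A [equation_spec()].
#' @return A JSON string (class `json`).
#' @export
serialize_equation <- function(spec) {
  stopifnot(inherits(spec, "free25d_equation"))
  obj <- list(
    name = spec$name,
    intercept = spec$intercept,
    terms = spec$terms
  )
  if (!is.null(spec$interactions)) obj$interactions <- spec$interactions
  if (!is.null(spec$phenotype_offsets)) {
    obj$phenotype_offsets <- as.list(spec$phenotype_offsets)
  }
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Parse an estimating equation from JSON text or file
#'
#' @param text JSON string, or path to a JSON file.
#' @return A [equation_spec()].
#' @export
parse_equation <- function(text) {
  obj <- if (length(text) == 1L && file.exists(text)) {
    jsonlite::fromJSON(text)
  } else {
    jsonlite::fromJSON(paste(text, collapse = "\n"))
  }
  offsets <- NULL
  if (!is.null(obj$phenotype_offsets)) {
    offsets <- unlist(obj$phenotype_offsets)
  }
  equation_spec(
    name = obj$name, intercept = obj$intercept,
    terms = obj$terms,
    interactions = obj$interactions,
    phenotype_offsets = offsets
  )
}

#' Load a shipped equation by name
#'
#' @param name One of `"eq1"`, `"eq2"`, `"eq3"`.
#' @return A [equation_spec()] parsed from the shipped file.
#' @export
load_shipped_equation <- function(name = c("eq1", "eq2", "eq3")) {
  name <- match.arg(name)
  parse_equation(system.file("extdata", "equations",
                             paste0(name, ".json"), package = "freevitd",
                             mustWork = TRUE))
}
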