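# Equation development: cohort splitting, log-transformed OLS, forward
# selection under the adjusted-R2 improvement rule, and pairwise interaction
# search.

# Variables entered as natural logs (right-skewed biomarkers); everything else
# enters untransformed.
.log_variables <- c("d25_3", "d25_2", "vdbp", "d1_25_3", "d24_25_3",
                    "ipth", "ifgf23", "total_25ohd")

# Categorical variables enter selection as all-in-or-all-out indicator blocks,
# counted by their number of indicator columns in the adjusted R2.
.block_levels <- list(
  phenotype = NULL, # filled from gc_diplotypes() at call time
  season = c("winter", "spring", "summer", "fall"),
  site = c("memphis", "pittsburgh"),
  sex = c("female", "male"),
  race = c("white", "black")
)

.default_candidates <- c("total_25ohd", "d24_25_3", "d1_25_3", "vdbp",
                         "phenotype", "age", "sex", "race", "bmi", "season",
                         "site", "diabetes", "egfr", "calcium", "phosphate",
                         "ipth", "ifgf23")

.clinical_candidates <- c("d25_3", "albumin", "ipth", "d1_25_3", "calcium",
                          "phosphate", "egfr", "d25_2")

#' Configuration for equation development
#'
#' @param forced Variables forced into the model before selection.
#' @param candidates Ordered candidate variables for forward selection. The
#'   default is the full evaluated list: total 25(OH)D, 24,25(OH)2D3,
#'   1,25(OH)2D3, VDBP, VDBP phenotype, age, sex, race, BMI, season, site,
#'   diabetes, eGFR, calcium, phosphate, iPTH and iFGF-23. `total_25ohd` is
#'   dropped automatically when 25(OH)D3 or 25(OH)D2 is forced, to avoid
#'   engineered collinearity.
#' @param retention_threshold Minimum adjusted-R2 improvement for a candidate
#'   (or interaction) to be retained; default 0.02.
#' @param split_fraction Development-set fraction of the cohort; default 2/3.
#' @param seed Integer seed governing the split.
#' @param dev_n Optional explicit development-set size overriding
#'   `round(split_fraction * n)`.
#' @param prescreen If `TRUE`, candidates are re-ordered by univariable
#'   adjusted R2 against the response before selection (affects tie-breaking
#'   order only, never eligibility).
#' @return A list of class `free25d_model_config`.
#' @export
model_config <- function(forced = character(),
                         candidates = .default_candidates,
                         retention_threshold = 0.02,
                         split_fraction = 2 / 3,
                         seed = 1L,
                         dev_n = NULL,
                         prescreen = FALSE) {
  stopifnot(retention_threshold > 0,
            split_fraction > 0, split_fraction < 1,
            is.numeric(seed), length(seed) == 1L)
  if (any(c("d25_3", "d25_2") %in% forced)) {
    candidates <- setdiff(candidates, "total_25ohd")
  }
  candidates <- setdiff(candidates, forced)
  structure(
    list(forced = forced, candidates = candidates,
         retention_threshold = retention_threshold,
         split_fraction = split_fraction, seed = as.integer(seed),
         dev_n = dev_n, prescreen = isTRUE(prescreen)),
    class = "free25d_model_config"
  )
}

#' Split a cohort into development and validation sets
#'
#' Random, disjoint, exhaustive partition; the development set has
#' `round(fraction * n)` rows unless `dev_n` fixes its size explicitly (used
#' to reproduce a published split whose size does not equal the rounded
#' fraction). Identical seeds give identical membership.
#'
#' @param cohort Data frame of participants.
#' @param fraction Development fraction, in (0, 1); default 2/3.
#' @param seed Integer seed.
#' @param dev_n Optional explicit development-set size.
#' @return List with elements `development` and `validation`.
#' @examples
#' s <- split_cohort(data.frame(x = 1:10), seed = 1)
#' nrow(s$development) # 7
#' @export
split_cohort <- function(cohort, fraction = 2 / 3, seed = 1L, dev_n = NULL) {
  n <- nrow(cohort)
  if (is.null(n) || n < 3L) {
    stop("cohort must have at least 3 rows to split", call. = FALSE)
  }
  stopifnot(fraction > 0, fraction < 1)
  size <- if (is.null(dev_n)) round(fraction * n) else as.integer(dev_n)
  if (size < 1L || size >= n) {
    stop("development-set size must leave at least one validation row",
         call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(n, size))
  list(development = cohort[sort(idx), , drop = FALSE],
       validation = cohort[setdiff(seq_len(n), idx), , drop = FALSE])
}

# Transformed value of a continuous model variable.
transform_variable <- function(data, variable) {
  v <- get_variable(data, variable)
  if (variable %in% .log_variables) {
    if (any(!is.na(v) & v <= 0)) {
      stop(sprintf("non-positive value(s) of '%s' under log transform",
                   variable), call. = FALSE)
    }
    log(v)
  } else if (variable == "diabetes") {
    as.numeric(v)
  } else {
    as.numeric(v)
  }
}

# Expand one model term into its design column(s). Categorical blocks become
# indicator columns against the first (reference) level.
term_columns <- function(data, variable) {
  if (variable == "phenotype") {
    ph <- normalize_phenotype(as.character(get_variable(data, "phenotype")))
    levs <- gc_diplotypes()
    cols <- sapply(levs[-1], function(l) as.numeric(ph == l))
    colnames(cols) <- paste0("phenotype=", levs[-1])
    return(cols)
  }
  if (variable %in% names(.block_levels) && variable != "phenotype") {
    levs <- .block_levels[[variable]]
    v <- tolower(as.character(get_variable(data, variable)))
    bad <- setdiff(unique(v[!is.na(v)]), levs)
    if (length(bad)) {
      stop(sprintf("unknown level(s) of '%s': %s", variable,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    cols <- sapply(levs[-1], function(l) as.numeric(v == l))
    cols <- matrix(cols, nrow = length(v),
                   dimnames = list(NULL, paste0(variable, "=", levs[-1])))
    return(cols)
  }
  x <- transform_variable(data, variable)
  nm <- if (variable %in% .log_variables) paste0("log_", variable) else variable
  matrix(x, ncol = 1, dimnames = list(NULL, nm))
}

# Design matrix for a set of main-effect terms plus log-log interaction pairs.
build_design <- function(data, terms, interactions = NULL) {
  mats <- lapply(terms, function(v) term_columns(data, v))
  if (!is.null(interactions) && nrow(interactions)) {
    for (i in seq_len(nrow(interactions))) {
      a <- interactions$var_a[i]; b <- interactions$var_b[i]
      col <- transform_variable(data, a) * transform_variable(data, b)
      mats <- c(mats, list(matrix(col, ncol = 1,
                                  dimnames = list(NULL,
                                                  paste0("log_", a, ":log_",
                                                         b)))))
    }
  }
  if (!length(mats)) {
    return(matrix(numeric(nrow(data) * 0), nrow = nrow(data)))
  }
  do.call(cbind, mats)
}

#' Ordinary least-squares fit on a design matrix
#'
#' Thin wrapper around [stats::lm()] exposing the quantities the development
#' pipeline needs: coefficients with standard errors, adjusted R-squared
#' (counting every design column as a predictor), RMSE of residuals, and
#' fitted values. The design must be full rank; a rank-deficient design fails
#' with the names of the collinear columns.
#'
#' @param response Numeric response vector.
#' @param design Numeric matrix of transformed predictors (no intercept
#'   column; one is added).
#' @return List of class `free25d_ols` with elements `coefficients`, `se`,
#'   `adj_r2`, `r2`, `rmse`, `fitted`, `residuals`, `n`, `p`.
#' @export
fit_ols <- function(response, design) {
  design <- as.matrix(design)
  n <- length(response)
  p <- ncol(design)
  if (nrow(design) != n) {
    stop("response and design have different numbers of rows", call. = FALSE)
  }
  if (n <= p + 1L) {
    stop("need more observations than predictors + 1", call. = FALSE)
  }
  df <- data.frame(.y = response, design, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop(sprintf("singular design: collinear column(s) %s",
                 paste(names(co)[is.na(co)], collapse = ", ")), call. = FALSE)
  }
  # noiseless designs are legitimate here (validation of exact recovery);
  # muffle summary.lm's perfect-fit warning only
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  # lm backticks non-syntactic design column names; restore the raw names
  strip <- function(x) gsub("^`|`$", "", x)
  names(co) <- strip(names(co))
  se <- sm$coefficients[, "Std. Error"]
  names(se) <- strip(names(se))
  list(
    coefficients = co,
    se = se,
    adj_r2 = adjusted_r2(response, stats::fitted(fit), p),
    r2 = sm$r.squared,
    rmse = sqrt(mean(stats::residuals(fit)^2)),
    fitted = unname(stats::fitted(fit)),
    residuals = unname(stats::residuals(fit)),
    n = n, p = p
  ) |> structure(class = "free25d_ols")
}

adj_r2_for <- function(data, response, terms, interactions = NULL) {
  X <- build_design(data, terms, interactions)
  if (ncol(X) == 0L) return(list(adj_r2 = 0, ok = TRUE))
  fit <- tryCatch(fit_ols(response, X), error = identity)
  if (inherits(fit, "error")) return(list(adj_r2 = NA_real_, ok = FALSE,
                                          message = conditionMessage(fit)))
  list(adj_r2 = fit$adj_r2, ok = TRUE)
}

new_trace_row <- function(step, candidate, before, after, retained) {
  data.frame(step = step, candidate = unname(candidate),
             adj_r2_before = unname(before), adj_r2_after = unname(after),
             improvement = unname(after - before), retained = retained,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Forward selection under the adjusted-R2 improvement rule
#'
#' Starts from the model containing the forced variables (an intercept-only
#' model when none are forced). At each step, every remaining candidate is
#' evaluated by refitting the model with that candidate added; the candidate
#' with the largest adjusted-R2 improvement is retained if the improvement
#' meets `retention_threshold`, and selection stops when no candidate
#' qualifies. Categorical variables enter as complete indicator blocks. Ties
#' are broken by candidate order; zero-variance candidates are skipped with a
#' warning. Every evaluation is recorded in the trace.
#'
#' @param data Development-set data frame containing the response.
#' @param config A [model_config()].
#' @param response Name of the response variable; default `"measured_free"`.
#' @return List of class `free25d_selection` with elements `steps` (the
#'   trace), `forced`, `retained`, `adj_r2_forced`, `adj_r2_final`.
#' @export
forward_select <- function(data, config, response = "measured_free") {
  stopifnot(inherits(config, "free25d_model_config"))
  y <- get_variable(data, response)
  if (anyNA(y)) stop("response contains missing values", call. = FALSE)
  base <- if (length(config$forced)) {
    fit <- adj_r2_for(data, y, config$forced)
    if (!fit$ok) stop("forced model could not be fitted: ", fit$message,
                      call. = FALSE)
    fit$adj_r2
  } else 0
  candidates <- config$candidates
  # drop degenerate candidates up front
  keep <- vapply(candidates, function(v) {
    X <- tryCatch(term_columns(data, v), error = identity)
    if (inherits(X, "error")) return(FALSE)
    any(apply(X, 2, stats::var, na.rm = TRUE) > 0)
  }, logical(1))
  if (any(!keep)) {
    warning(sprintf("skipping zero-variance candidate(s): %s",
                    paste(candidates[!keep], collapse = ", ")), call. = FALSE)
    candidates <- candidates[keep]
  }
  if (config$prescreen && length(candidates)) {
    uni <- vapply(candidates, function(v) {
      r <- adj_r2_for(data, y, v)
      if (r$ok) r$adj_r2 else -Inf
    }, numeric(1))
    candidates <- candidates[order(-uni)]
  }
  retained <- character()
  steps <- NULL
  current <- base
  step <- 0L
  repeat {
    if (!length(candidates)) break
    step <- step + 1L
    after <- vapply(candidates, function(v) {
      r <- adj_r2_for(data, y, c(config$forced, retained, v))
      if (r$ok) r$adj_r2 else NA_real_
    }, numeric(1))
    rows <- new_trace_row(step, candidates, current, after, FALSE)
    imp <- after - current
    best <- which(!is.na(imp) & imp == max(imp, na.rm = TRUE))[1]
    if (!is.na(imp[best]) && imp[best] >= config$retention_threshold) {
      rows$retained[best] <- TRUE
      retained <- c(retained, candidates[best])
      current <- after[best]
      candidates <- candidates[-best]
      steps <- rbind(steps, rows)
    } else {
      steps <- rbind(steps, rows)
      break
    }
  }
  structure(
    list(steps = steps, forced = config$forced, retained = retained,
         adj_r2_forced = base, adj_r2_final = current, response = response),
    class = "free25d_selection"
  )
}

#' @export
print.free25d_selection <- function(x, ...) {
  cat("Forward selection trace\n")
  cat(sprintf("  forced: %s\n",
              if (length(x$forced)) paste(x$forced, collapse = ", ")
              else "(none)"))
  cat(sprintf("  retained: %s\n",
              if (length(x$retained)) paste(x$retained, collapse = ", ")
              else "(none)"))
  if (!is.null(x$interactions_retained)) {
    cat(sprintf("  interactions: %s\n",
                if (nrow(x$interactions_retained))
                  paste(paste0(x$interactions_retained$var_a, "x",
                               x$interactions_retained$var_b),
                        collapse = ", ")
                else "(none)"))
  }
  cat(sprintf("  adjusted R2: %.4f (forced) -> %.4f (final)\n",
              x$adj_r2_forced, x$adj_r2_final))
  invisible(x)
}

#' Pairwise interaction search among retained variables
#'
#' Forms the products of the (log-transformed) values of every unordered pair
#' of distinct continuous variables in the forced-plus-retained set, evaluates
#' each by the same adjusted-R2 improvement rule, and greedily adds qualifying
#' products in decreasing-improvement order. Categorical blocks do not form
#' products.
#'
#' @param data Development-set data frame.
#' @param selection A `free25d_selection` from [forward_select()].
#' @param config The same [model_config()].
#' @return The selection object extended with `interactions_retained` (a data
#'   frame of pairs and coefficients to be refit) and additional trace rows.
#' @export
interaction_search <- function(data, selection, config) {
  stopifnot(inherits(selection, "free25d_selection"))
  y <- get_variable(data, selection$response)
  vars <- c(selection$forced, selection$retained)
  cont <- setdiff(vars, names(.block_levels))
  cont <- setdiff(cont, "diabetes")
  pairs <- if (length(cont) >= 2) utils::combn(cont, 2, simplify = FALSE)
           else list()
  retained_int <- data.frame(var_a = character(), var_b = character(),
                             stringsAsFactors = FALSE)
  current <- selection$adj_r2_final
  steps <- selection$steps
  step <- if (is.null(steps)) 0L else max(steps$step)
  repeat {
    if (!length(pairs)) break
    step <- step + 1L
    after <- vapply(pairs, function(p) {
      ints <- rbind(retained_int, data.frame(var_a = p[1], var_b = p[2]))
      r <- adj_r2_for(data, y, vars, ints)
      if (r$ok) r$adj_r2 else NA_real_
    }, numeric(1))
    labels <- vapply(pairs, function(p) paste0("log_", p[1], ":log_", p[2]),
                     character(1))
    rows <- new_trace_row(step, labels, current, after, FALSE)
    imp <- after - current
    best <- which(!is.na(imp) & imp == max(imp, na.rm = TRUE))[1]
    if (!is.na(imp[best]) && imp[best] >= config$retention_threshold) {
      rows$retained[best] <- TRUE
      retained_int <- rbind(retained_int,
                            data.frame(var_a = pairs[[best]][1],
                                       var_b = pairs[[best]][2],
                                       stringsAsFactors = FALSE))
      current <- after[best]
      pairs <- pairs[-best]
      steps <- rbind(steps, rows)
    } else {
      steps <- rbind(steps, rows)
      break
    }
  }
  selection$steps <- steps
  selection$interactions_retained <- retained_int
  selection$adj_r2_final <- current
  selection
}

# Build a free25d_equation from a final fitted model. Categorical blocks other
# than phenotype cannot be represented in the printed-equation format.
spec_from_fit <- function(name, fit, terms, interactions) {
  other_blocks <- intersect(terms, setdiff(names(.block_levels), "phenotype"))
  if (length(other_blocks)) {
    stop(sprintf(paste("retained categorical variable(s) %s cannot be encoded",
                       "in the printed-equation format (only Gc diplotype",
                       "offsets are supported)"),
                 paste(other_blocks, collapse = ", ")), call. = FALSE)
  }
  co <- fit$coefficients
  cont <- setdiff(terms, "phenotype")
  term_df <- data.frame(
    variable = cont,
    transform = ifelse(cont %in% .log_variables, "log", "identity"),
    coefficient = vapply(cont, function(v) {
      nm <- if (v %in% .log_variables) paste0("log_", v) else v
      unname(co[[nm]])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  int_df <- NULL
  if (!is.null(interactions) && nrow(interactions)) {
    int_df <- interactions
    int_df$coefficient <- vapply(seq_len(nrow(int_df)), function(i) {
      unname(co[[paste0("log_", int_df$var_a[i], ":log_", int_df$var_b[i])]])
    }, numeric(1))
  }
  offsets <- NULL
  if ("phenotype" %in% terms) {
    levs <- gc_diplotypes()
    offsets <- stats::setNames(c(0, vapply(levs[-1], function(l) {
      unname(co[[paste0("phenotype=", l)]])
    }, numeric(1))), levs)
  }
  spec <- equation_spec(name, unname(co[["(Intercept)"]]), term_df, int_df,
                        offsets)
  spec
}

#' Develop and internally validate a free 25(OH)D estimating equation
#'
#' Runs the complete published procedure on a cohort with measured free
#' 25(OH)D: random two-thirds / one-third split, forced-variable model,
#' forward selection under the adjusted-R2 rule, pairwise interaction search,
#' final refit on the development set, and validation of the fitted equation
#' on the held-out set.
#'
#' Modes: `"eq1"` forces albumin, 25(OH)D3, 25(OH)D2 and VDBP; `"eq2"` forces
#' those plus Gc diplotype; `"eq3"` forces nothing but restricts candidates to
#' biomarkers available in a typical clinical laboratory (25(OH)D3, albumin,
#' iPTH, 1,25(OH)2D3, calcium, phosphate, eGFR, 25(OH)D2).
#'
#' @param cohort Cohort data frame with a measured free 25(OH)D column.
#' @param config A [model_config()]; its `forced`/`candidates` are overridden
#'   by `mode` unless `mode = "custom"`.
#' @param mode One of `"eq1"`, `"eq2"`, `"eq3"`, `"custom"`.
#' @return List of class `free25d_development` with elements `spec` (the
#'   fitted [equation_spec()]), `selection` (the trace), `fit` (development
#'   fit), `dev_rmse`, `val_rmse`, `validation` (a [validate_estimates()]
#'   report on the held-out set), and `split` sizes.
#' @export
develop_equation <- function(cohort, config = model_config(),
                             mode = c("eq1", "eq2", "eq3", "custom")) {
  mode <- match.arg(mode)
  if (!has_variable(cohort, "measured_free")) {
    stop("cohort must contain measured free 25(OH)D for equation development",
         call. = FALSE)
  }
  if (mode == "eq1") {
    config <- model_config(forced = c("albumin", "d25_3", "d25_2", "vdbp"),
                           candidates = .default_candidates,
                           retention_threshold = config$retention_threshold,
                           split_fraction = config$split_fraction,
                           seed = config$seed, dev_n = config$dev_n,
                           prescreen = config$prescreen)
  } else if (mode == "eq2") {
    config <- model_config(forced = c("albumin", "d25_3", "d25_2", "vdbp",
                                      "phenotype"),
                           candidates = .default_candidates,
                           retention_threshold = config$retention_threshold,
                           split_fraction = config$split_fraction,
                           seed = config$seed, dev_n = config$dev_n,
                           prescreen = config$prescreen)
  } else if (mode == "eq3") {
    config <- model_config(forced = character(),
                           candidates = .clinical_candidates,
                           retention_threshold = config$retention_threshold,
                           split_fraction = config$split_fraction,
                           seed = config$seed, dev_n = config$dev_n,
                           prescreen = config$prescreen)
  }
  halves <- split_cohort(cohort, config$split_fraction, config$seed,
                         config$dev_n)
  dev <- halves$development
  val <- halves$validation
  sel <- forward_select(dev, config)
  sel <- interaction_search(dev, sel, config)
  terms <- c(sel$forced, sel$retained)
  y_dev <- get_variable(dev, "measured_free")
  fit <- fit_ols(y_dev, build_design(dev, terms, sel$interactions_retained))
  spec <- spec_from_fit(paste0("developed_", mode), fit, terms,
                        sel$interactions_retained)
  est_val <- evaluate_equation(spec, val)
  y_val <- get_variable(val, "measured_free")
  report <- validate_estimates(as.numeric(est_val), y_val)
  structure(
    list(spec = spec, selection = sel, fit = fit,
         dev_rmse = fit$rmse, val_rmse = rmse(as.numeric(est_val), y_val),
         validation = report,
         split = c(development = nrow(dev), validation = nrow(val)),
         config = config),
    class = "free25d_development"
  )
}

#' @export
print.free25d_development <- function(x, ...) {
  cat(sprintf("Developed equation (n_dev = %d, n_val = %d)\n",
              x$split[["development"]], x$split[["validation"]]))
  print(x$spec)
  cat(sprintf("RMSE: %.3f (development), %.3f (validation)\n",
              x$dev_rmse, x$val_rmse))
  cat("Held-out validation report:\n")
  print(x$validation)
  invisible(x)
}
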