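test_that("cohort splitting is a seeded, disjoint, exhaustive partition", {
  cohort <- data.frame(id = 1:370, x = rnorm(370))
  s <- split_cohort(cohort, seed = 9)
  expect_equal(nrow(s$development), 247) # round(2/3 * 370)
  expect_equal(nrow(s$validation), 123)
  expect_setequal(c(s$development$id, s$validation$id), cohort$id)
  expect_length(intersect(s$development$id, s$validation$id), 0)
  s2 <- split_cohort(cohort, seed = 9)
  expect_identical(s$development$id, s2$development$id)
  s3 <- split_cohort(cohort, seed = 10)
  expect_false(identical(s$development$id, s3$development$id))
  # explicit override reproduces the published 244/126 sizes
  s4 <- split_cohort(cohort, seed = 9, dev_n = 244)
  expect_equal(nrow(s4$development), 244)
  expect_equal(nrow(s4$validation), 126)
  expect_error(split_cohort(cohort[1:2, ]), "at least 3")
})

test_that("fit_ols recovers a noiseless linear model exactly", {
  set.seed(5)
  X <- cbind(a = rnorm(50), b = runif(50))
  y <- 2 - 1.5 * X[, "a"] + 0.75 * X[, "b"]
  fit <- fit_ols(y, X)
  expect_equal(unname(fit$coefficients), c(2, -1.5, 0.75), tolerance = 1e-9)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
  expect_equal(fit$rmse, 0, tolerance = 1e-9)
})

test_that("fit_ols reproduces the 3-point hand example and ignores row order", {
  X <- matrix(c(1, 2, 4), dimnames = list(NULL, "x"))
  fit <- fit_ols(c(1, 2, 3), X)
  expect_equal(unname(fit$coefficients), c(0.5, 0.642857142857),
               tolerance = 1e-9)
  expect_equal(fit$adj_r2, 0.928571, tolerance = 1e-5)
  set.seed(6)
  X2 <- cbind(u = rnorm(30), v = rnorm(30))
  y2 <- 1 + X2 %*% c(0.4, -0.2) + rnorm(30, 0, 0.3)
  p <- sample(30)
  expect_equal(fit_ols(y2, X2)$coefficients,
               fit_ols(y2[p], X2[p, ])$coefficients, tolerance = 1e-10)
})

test_that("fit_ols agrees with a normal-equations oracle on random designs", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    p <- sample(1:6, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("c", seq_len(p))))
    y <- rnorm(n)
    fit <- fit_ols(y, X)
    oracle <- ols_oracle(y, X)
    expect_equal(unname(fit$coefficients), oracle$coefficients,
                 tolerance = 1e-8)
    expect_equal(fit$fitted, oracle$fitted, tolerance = 1e-8)
  }
})

test_that("rank-deficient designs fail naming the collinear column", {
  set.seed(9)
  a <- rnorm(30)
  X <- cbind(a = a, b = 2 * a)
  expect_error(fit_ols(rnorm(30), X), "singular design.*b")
})

test_that("forward selection keeps a real predictor and rejects pure noise", {
  set.seed(12)
  n <- 2000
  d <- data.frame(
    x1 = exp(rnorm(n, 1, 0.6)),
    x2 = rnorm(n),
    stringsAsFactors = FALSE
  )
  d$measured_free <- 2 * log(d$x1) + rnorm(n, 0, 0.5)
  # register x1 as a log variable by aliasing onto schema names
  d$d25_3_ng_ml <- d$x1
  d$age_years <- d$x2
  cfg <- model_config(forced = character(), candidates = c("d25_3", "age"))
  sel <- forward_select(d, cfg)
  expect_identical(sel$retained, "d25_3")
  expect_true(all(sel$steps$improvement[sel$steps$retained] >= 0.02))
  # adjusted R2 non-decreasing over retained steps
  expect_gte(sel$adj_r2_final, sel$adj_r2_forced)
})

test_that("a threshold above any attainable improvement keeps only the forced model", {
  co <- generate_cohort(generator_config(n = 400, seed = 14))
  cfg <- model_config(forced = c("albumin", "d25_3"),
                      candidates = c("d1_25_3", "age"),
                      retention_threshold = 0.99)
  sel <- forward_select(co, cfg)
  expect_length(sel$retained, 0)
  expect_equal(sel$adj_r2_final, sel$adj_r2_forced)
})

test_that("zero-variance candidates are skipped with a warning", {
  co <- generate_cohort(generator_config(n = 300, seed = 15))
  co$calcium_mg_dl <- 8.9
  cfg <- model_config(forced = "d25_3", candidates = c("calcium", "d1_25_3"))
  expect_warning(sel <- forward_select(co, cfg), "calcium")
  expect_false("calcium" %in% sel$retained)
})

test_that("selection is deterministic given cohort and config", {
  co <- generate_cohort(generator_config(n = 500, seed = 16))
  cfg <- model_config(forced = c("albumin", "d25_3", "d25_2", "vdbp"))
  s1 <- forward_select(co, cfg)
  s2 <- forward_select(co, cfg)
  expect_identical(s1$steps, s2$steps)
  expect_identical(s1$retained, s2$retained)
})

test_that("interaction search retains a strong log-log interaction and no spurious one", {
  set.seed(17)
  n <- 1000
  d <- data.frame(d25_3_ng_ml = exp(rnorm(n, 3, 0.6)),
                  d24_25_3_ng_ml = exp(rnorm(n, 0.5, 0.6)))
  base <- 1 + 0.9 * log(d$d25_3_ng_ml) - 0.5 * log(d$d24_25_3_ng_ml)
  cfg <- model_config(forced = c("d25_3", "d24_25_3"),
                      candidates = character())
  # with a true interaction
  d$measured_free <- base + 0.8 * log(d$d25_3_ng_ml) * log(d$d24_25_3_ng_ml) +
    rnorm(n, 0, 0.5)
  sel <- interaction_search(d, forward_select(d, cfg), cfg)
  expect_equal(nrow(sel$interactions_retained), 1)
  expect_setequal(unlist(sel$interactions_retained[1, c("var_a", "var_b")]),
                  c("d25_3", "d24_25_3"))
  # self-products never appear among evaluated pairs
  int_rows <- sel$steps[grepl(":", sel$steps$candidate), ]
  pairs <- strsplit(sub("^log_", "", int_rows$candidate), ":log_")
  expect_true(all(vapply(pairs, function(p) p[1] != p[2], logical(1))))
  # without a true interaction
  d$measured_free <- base + rnorm(n, 0, 0.5)
  sel0 <- interaction_search(d, forward_select(d, cfg), cfg)
  expect_equal(nrow(sel0$interactions_retained), 0)
})

test_that("development on a noiseless cohort recovers the generating equation exactly", {
  cfg <- generator_config(n = 800, seed = 18, noise_sd = 0)
  co <- generate_cohort(cfg)
  res <- develop_equation(co, model_config(seed = 18), mode = "eq2")
  expect_equal(res$fit$adj_r2, 1, tolerance = 1e-9)
  expect_equal(res$dev_rmse, 0, tolerance = 1e-8)
  truth <- eq2_spec()
  got <- res$spec$terms$coefficient[match(truth$terms$variable,
                                          res$spec$terms$variable)]
  expect_equal(got, truth$terms$coefficient, tolerance = 1e-6)
  expect_equal(res$spec$intercept, truth$intercept, tolerance = 1e-5)
  expect_equal(res$spec$phenotype_offsets, truth$phenotype_offsets,
               tolerance = 1e-6)
  expect_equal(res$validation$p30[1], 1)
})

test_that("dev and validation RMSE stay close for a well-specified model", {
  co <- generate_cohort(generator_config(n = 370, seed = 19))
  res <- develop_equation(co, model_config(seed = 19), mode = "eq2")
  expect_lt(abs(res$dev_rmse - res$val_rmse), 0.35)
  expect_gte(res$selection$adj_r2_final, res$selection$adj_r2_forced)
})

test_that("coefficient bias shrinks as the cohort grows", {
  truth <- eq2_spec()
  err_at <- function(n) {
    co <- generate_cohort(generator_config(n = n, seed = 20))
    y <- co$free25ohd_pg_ml
    X <- freevitd:::build_design(
      co, c("albumin", "d25_3", "vdbp", "d25_2", "d1_25_3", "d24_25_3",
            "phenotype"),
      data.frame(var_a = "d25_3", var_b = "d24_25_3"))
    fit <- fit_ols(y, X)
    mean(abs(fit$coefficients[c("albumin", "log_d25_3", "log_vdbp")] -
               c(0.348, 0.748, -1.566)))
  }
  expect_lt(err_at(5000), err_at(500))
})
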