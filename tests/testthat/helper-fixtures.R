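# Shared fixtures. The cohort-median record mirrors the published overall
# medians: albumin 4.3 g/dL, 25(OH)D3 20.3 ng/mL, 25(OH)D2 0.33 ng/mL,
# VDBP 253.3 ug/mL, 1,25(OH)2D3 40.2 pg/mL, 24,25(OH)2D3 1.7 ng/mL,
# iPTH 34 pg/mL (midpoint of the middle-quartile medians).
median_record <- function(phenotype = "Gc1f/Gc1f") {
  data.frame(albumin = 4.3, d25_3 = 20.3, d25_2 = 0.33, vdbp = 253.3,
             d1_25_3 = 40.2, d24_25_3 = 1.7, ipth = 34,
             phenotype = phenotype, stringsAsFactors = FALSE)
}

# Brute-force normal-equations OLS, independent of the lm-based fit_ols path.
ols_oracle <- function(y, X) {
  Xi <- cbind(1, as.matrix(X))
  beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  fitted <- as.numeric(Xi %*% beta)
  list(coefficients = as.numeric(beta), fitted = fitted)
}
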