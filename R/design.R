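# Design-matrix construction shared by the three relationship models.
#
# Covariates are referred to by column name and rescaled to the units used
# throughout: percentage columns (pct_*) enter per 10 percentage points,
# count columns (n_*) per 10 persons, and centre_type becomes a REG
# indicator (reference REC). Any other numeric column enters unscaled,
# which is how generic extra covariates (e.g. country-of-origin shares)
# are supported.

scale_covariate <- function(name, x) {
  if (startsWith(name, "pct_") || startsWith(name, "n_")) x / 10 else x
}

build_design <- function(data, covariates) {
  n <- nrow(data)
  cols <- list("(Intercept)" = rep(1, n))
  for (v in covariates) {
    if (identical(v, "1")) next
    if (!v %in% names(data)) stop("missing covariate column: ", v)
    if (v == "centre_type") {
      ct <- as.character(data[[v]])
      bad <- setdiff(unique(ct), c("REC", "REG"))
      if (length(bad))
        stop("centre_type must be REC or REG; found: ",
             paste(bad, collapse = ", "))
      cols[["centre_typeREG"]] <- as.numeric(ct == "REG")
    } else {
      x <- data[[v]]
      if (!is.numeric(x)) stop("covariate '", v, "' is not numeric")
      if (anyNA(x)) stop("covariate '", v, "' contains missing values")
      cols[[v]] <- scale_covariate(v, x)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

# Build a design matrix directly from coefficient names (used when a
# parameter set, not a covariate list, defines the model — e.g. when
# simulating from generating truth or predicting from a stored fit).
design_from_coef <- function(coefs, data) {
  n <- nrow(data)
  cols <- lapply(names(coefs), function(nm) {
    if (nm == "(Intercept)") return(rep(1, n))
    if (nm == "centre_typeREG") {
      if (!"centre_type" %in% names(data))
        stop("missing covariate column: centre_type")
      return(as.numeric(as.character(data$centre_type) == "REG"))
    }
    if (!nm %in% names(data)) stop("missing covariate column: ", nm)
    scale_covariate(nm, data[[nm]])
  })
  X <- do.call(cbind, cols)
  colnames(X) <- names(coefs)
  X
}

linear_predictor <- function(coefs, data) {
  as.vector(design_from_coef(coefs, data) %*% coefs)
}

# Align a coefficient vector with the columns of a design matrix built from
# the same covariate list (names must agree exactly).
align_coef <- function(beta, X) {
  if (is.null(names(beta))) {
    if (length(beta) != ncol(X)) stop("coefficient length mismatch")
    return(beta)
  }
  miss <- setdiff(colnames(X), names(beta))
  if (length(miss))
    stop("coefficients missing for: ", paste(miss, collapse = ", "))
  beta[colnames(X)]
}
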