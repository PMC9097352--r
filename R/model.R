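#' @title L1-penalized logistic prediction model
#' @description
#' The risk model is a logistic regression with an L1 (lasso) penalty,
#' which shrinks weak coefficients exactly to zero and so performs variable
#' selection: the features with nonzero coefficients are the "retained"
#' predictors. The penalty weight `lambda` is chosen by tenfold
#' cross-validation (stratified on the outcome) to minimize held-out
#' binomial deviance. Predictors are standardized internally; coefficients
#' are reported on the original feature scale, so an age coefficient reads
#' "per year of age".
#' @name model
NULL

#' Fit the lasso logistic model with cross-validated shrinkage
#'
#' @param X Numeric feature matrix (no missing values), columns named.
#' @param y Binary 0/1 outcome vector, `length(y) == nrow(X)`.
#' @param lambda_grid Optional decreasing vector of penalty weights. The
#'   default is a 100-point log-spaced grid from `lambda_max` (the smallest
#'   penalty that zeroes every slope) down to `lambda_max * 1e-4`. A single
#'   value skips cross-validation and fits at that penalty exactly.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param rule `"min"` (default) selects the deviance-minimizing lambda;
#'   `"1se"` the largest lambda within one standard error of it.
#' @return An object of class `mci_lasso_fit`: `intercept`, `coefficients`
#'   (named, original scale; exact zeros = not retained),
#'   `lambda_selected`, `lambda_grid`, `cv_trace` (tibble `lambda`,
#'   `mean_deviance`, `se_deviance`), `feature_names`, `seed`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
#' y <- rbinom(100, 1, plogis(X[, 1]))
#' fit <- fit_lasso_logistic(X, y, seed = 1)
#' retained_features(fit)
#' @export
fit_lasso_logistic <- function(X, y, lambda_grid = NULL, folds = 10L,
                               seed = 1L, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(X), !anyNA(X), length(y) == nrow(X),
            all(y %in% c(0, 1)), nrow(X) >= folds)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  feature_names <- colnames(X)
  if (ncol(X) == 1L) {
    # the backend requires >= 2 columns; a zero column is inert (its
    # coefficient is identically 0) and is stripped from the result
    X <- cbind(X, `..pad..` = 0)
  }
  const <- apply(X, 2, function(col) length(unique(col)) == 1L)
  const <- const & colnames(X) != "..pad.."
  if (any(const)) {
    warning("constant feature column(s), coefficient forced to 0: ",
            paste(colnames(X)[const], collapse = ", "))
  }

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  if (!is.null(lambda_grid) && length(lambda_grid) == 1L) {
    # fixed penalty, no CV; coefficients extracted exactly at the value
    fit <- glmnet::glmnet(X, y, family = "binomial", standardize = TRUE,
                          thresh = 1e-12)
    cf <- as.matrix(coef(fit, s = lambda_grid, exact = TRUE, x = X, y = y,
                         family = "binomial", standardize = TRUE,
                         thresh = 1e-12))
    cv_trace <- tibble::tibble(lambda = numeric(0), mean_deviance = numeric(0),
                               se_deviance = numeric(0))
    lambda_sel <- lambda_grid
    grid <- lambda_grid
  } else {
    foldid <- stratified_folds(y, folds)
    cv <- glmnet::cv.glmnet(X, y, family = "binomial",
                            type.measure = "deviance", foldid = foldid,
                            lambda = lambda_grid, standardize = TRUE,
                            lambda.min.ratio = 1e-4, nlambda = 100L,
                            thresh = 1e-10)
    lambda_sel <- if (rule == "min") cv$lambda.min else cv$lambda.1se
    cf <- as.matrix(coef(cv$glmnet.fit, s = lambda_sel))
    cv_trace <- tibble::tibble(lambda = cv$lambda, mean_deviance = cv$cvm,
                               se_deviance = cv$cvsd)
    grid <- cv$lambda
  }

  beta <- setNames(as.numeric(cf[-1, 1]), colnames(X))[feature_names]
  structure(list(intercept = as.numeric(cf[1, 1]),
                 coefficients = beta,
                 lambda_selected = lambda_sel,
                 lambda_grid = grid,
                 cv_trace = cv_trace,
                 feature_names = feature_names,
                 seed = seed,
                 rule = rule),
            class = "mci_lasso_fit")
}

# outcome-stratified fold labels; depends on the caller's RNG state
stratified_folds <- function(y, folds) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  foldid
}

#' Features retained (nonzero coefficient) by a fitted model
#' @param m An `mci_lasso_fit`.
#' @return Character vector of feature names.
#' @export
retained_features <- function(m) {
  stopifnot(inherits(m, "mci_lasso_fit"))
  names(m$coefficients)[m$coefficients != 0]
}

#' @export
print.mci_lasso_fit <- function(x, ...) {
  cat("<mci_lasso_fit> lambda =", signif(x$lambda_selected, 4), "(", x$rule,
      "rule ) -", length(retained_features(x)), "of",
      length(x$coefficients), "features retained\n")
  invisible(x)
}

#' Predicted MCI probabilities
#'
#' Inverse-logit of the fitted linear predictor. The feature columns of `X`
#' must exactly match the model's schema (order-insensitive); missing or
#' extra columns are a hard error.
#'
#' @param m An `mci_lasso_fit`.
#' @param X Numeric feature matrix with named columns.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_probability <- function(m, X) {
  stopifnot(inherits(m, "mci_lasso_fit"), is.matrix(X))
  missing_cols <- setdiff(m$feature_names, colnames(X))
  extra_cols <- setdiff(colnames(X), m$feature_names)
  if (length(missing_cols) || length(extra_cols)) {
    stop("feature schema mismatch; missing: [",
         paste(missing_cols, collapse = ", "), "], extra: [",
         paste(extra_cols, collapse = ", "), "]")
  }
  eta <- m$intercept + as.numeric(X[, m$feature_names, drop = FALSE] %*%
                                    m$coefficients)
  plogis(eta)
}

#' Contribution of one feature to the linear predictor
#'
#' The product `coefficient * value` on the original feature scale — e.g.
#' with an age coefficient of 0.023 per year, a 70-year-old contributes
#' 0.023 * 70 = 1.61 to the log-odds.
#'
#' @param m An `mci_lasso_fit`.
#' @param feature Feature name.
#' @param value Feature value.
#' @return The contribution (log-odds scale).
#' @export
coefficient_contribution <- function(m, feature, value) {
  stopifnot(inherits(m, "mci_lasso_fit"))
  if (!feature %in% names(m$coefficients)) stop("unknown feature: ", feature)
  unname(m$coefficients[feature] * value)
}

#' Serialize / restore a fitted model as flat YAML
#'
#' Human-readable round trip of the schema, coefficients, selected penalty
#' and seed.
#'
#' @param m An `mci_lasso_fit`.
#' @param path File path.
#' @return `read_model()` returns the restored `mci_lasso_fit`.
#' @export
write_model <- function(m, path) {
  stopifnot(inherits(m, "mci_lasso_fit"))
  yaml::write_yaml(list(
    intercept = m$intercept,
    lambda_selected = m$lambda_selected,
    rule = m$rule,
    seed = m$seed,
    coefficients = as.list(m$coefficients)), path,
    precision = 17L)  # full double precision so models round-trip
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  raw <- yaml::read_yaml(path)
  beta <- unlist(raw$coefficients)
  structure(list(intercept = raw$intercept,
                 coefficients = beta,
                 lambda_selected = raw$lambda_selected,
                 lambda_grid = raw$lambda_selected,
                 cv_trace = tibble::tibble(lambda = numeric(0),
                                           mean_deviance = numeric(0),
                                           se_deviance = numeric(0)),
                 feature_names = names(beta),
                 seed = raw$seed,
                 rule = raw$rule),
            class = "mci_lasso_fit")
}
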