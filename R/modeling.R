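#' Radscore: the linear radiomics signature combination
#'
#' Radscore = beta0 + sum_i beta_i x_i over the selected signature features,
#' with x_i standardized by the training statistics stored in the model. The
#' coefficients are the LASSO coefficients at `lambda_min` and beta0 is the
#' LASSO intercept (the training label mean under 0/1 coding).
#'
#' @param fit a `lasso_fit` from [lasso_select()].
#' @return A `radscore_model`: `beta0`, `betas`, `feature_names`, `center`,
#'   `scale`.
#' @export
radscore_model <- function(fit) {
  stopifnot(inherits(fit, "lasso_fit"))
  sel <- fit$selected_names
  if (length(sel) == 0L) stop("the LASSO selected no features; no signature to score")
  structure(
    list(beta0 = fit$intercept, betas = fit$beta[sel], feature_names = sel,
         center = fit$center[sel], scale = fit$scale[sel]),
    class = "radscore_model"
  )
}

#' @param model a `radscore_model`.
#' @param features data frame containing every signature feature.
#' @return `radscore()`: numeric vector, one score per row.
#' @rdname radscore_model
#' @export
radscore <- function(model, features) {
  missing <- setdiff(model$feature_names, colnames(features))
  if (length(missing) > 0L)
    stop("missing signature feature(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(features[, model$feature_names, drop = FALSE])
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  as.numeric(model$beta0 + Xs %*% model$betas)
}

# ordinal severity coding for Child-Pugh stage
child_pugh_ordinal <- function(x) {
  out <- match(as.character(x), c("A", "B", "C"))
  if (anyNA(out)) stop("Child-Pugh stage must be A, B or C")
  out
}

.check_separation <- function(glm_fit, kind) {
  separated <- !glm_fit$converged || any(abs(stats::coef(glm_fit)) > 15) ||
    any(fitted(glm_fit) > 1 - 1e-8) || any(fitted(glm_fit) < 1e-8)
  if (separated) {
    warning(kind, " model shows (quasi-)separation; coefficients are unstable ",
            "but evaluation proceeds on the fitted scores")
  }
  separated
}

#' Fit the radiomics-only (R) logistic model
#'
#' Unpenalized maximum-likelihood logistic regression of class on the
#' signature features (standardized by the signature's training statistics).
#' Perfect separation is flagged with a warning, never silently ignored:
#' small synthetic cohorts can separate.
#'
#' @param features training feature data frame.
#' @param labels training class labels.
#' @param signature a `radscore_model` defining the features and their
#'   standardization.
#' @param positive_class label treated as the event (default `"CHE"`).
#' @return A `fitted_classifier` of kind `"R"`.
#' @export
fit_r_model <- function(features, labels, signature, positive_class = "CHE") {
  y <- as.numeric(as.character(labels) == positive_class)
  if (length(unique(y)) != 2L) stop("both classes must be present")
  if (length(y) < 10L) stop("need at least 10 training subjects")
  X <- as.matrix(features[, signature$feature_names, drop = FALSE])
  Xs <- sweep(sweep(X, 2, signature$center), 2, signature$scale, "/")
  df <- data.frame(y = y, Xs)
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
  structure(
    list(kind = "R", glm = fit, signature = signature,
         predictors = signature$feature_names,
         coefficients = stats::coef(fit),
         separation = .check_separation(fit, "R"),
         positive_class = positive_class, n = length(y)),
    class = "fitted_classifier"
  )
}

#' Fit the radiomics + clinical (R-C) logistic model
#'
#' Multivariable logistic regression on exactly Radscore, venous blood
#' ammonia (NH3) and Child-Pugh stage (encoded ordinal 1/2/3).
#'
#' @param features training feature data frame.
#' @param clinical training clinical data frame with `nh3` and `child_pugh`.
#' @inheritParams fit_r_model
#' @return A `fitted_classifier` of kind `"R-C"`.
#' @export
fit_rc_model <- function(features, clinical, labels, signature,
                         positive_class = "CHE") {
  y <- as.numeric(as.character(labels) == positive_class)
  if (length(unique(y)) != 2L) stop("both classes must be present")
  if (length(y) < 10L) stop("need at least 10 training subjects")
  df <- data.frame(
    y = y,
    radscore = radscore(signature, features),
    nh3 = clinical$nh3,
    child_pugh = child_pugh_ordinal(clinical$child_pugh)
  )
  fit <- stats::glm(y ~ radscore + nh3 + child_pugh, data = df,
                    family = stats::binomial())
  structure(
    list(kind = "R-C", glm = fit, signature = signature,
         predictors = c("radscore", "nh3", "child_pugh"),
         coefficients = stats::coef(fit),
         separation = .check_separation(fit, "R-C"),
         positive_class = positive_class, n = length(y)),
    class = "fitted_classifier"
  )
}

#' Predicted event probabilities from a fitted classifier
#'
#' @param object a `fitted_classifier`.
#' @param features feature data frame (R and R-C models).
#' @param clinical clinical data frame (R-C model only).
#' @param ... unused.
#' @return Numeric vector of predicted probabilities of the positive class.
#' @export
predict_prob <- function(object, features, clinical = NULL, ...) {
  stopifnot(inherits(object, "fitted_classifier"))
  sig <- object$signature
  if (object$kind == "R") {
    X <- as.matrix(features[, sig$feature_names, drop = FALSE])
    Xs <- sweep(sweep(X, 2, sig$center), 2, sig$scale, "/")
    nd <- as.data.frame(Xs)
  } else {
    if (is.null(clinical)) stop("the R-C model needs the clinical table")
    nd <- data.frame(
      radscore = radscore(sig, features),
      nh3 = clinical$nh3,
      child_pugh = child_pugh_ordinal(clinical$child_pugh)
    )
  }
  as.numeric(stats::predict(object$glm, newdata = nd, type = "response"))
}
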