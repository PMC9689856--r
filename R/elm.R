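#' Train an extreme learning machine classifier
#'
#' Single-hidden-layer network with seeded random input weights and biases;
#' the hidden layer is `H = act(X W + b)` and the output weights `beta` solve
#' the ridge-regularized least squares `(H'H + ridge I) beta = H'T` against
#' one-hot class targets `T`. Only `beta` is learned, which makes training a
#' single linear solve.
#'
#' @param x `N x D` numeric feature matrix.
#' @param y class labels (any atomic type); at least two distinct values.
#' @param hidden_units hidden layer width (default 500).
#' @param ridge ridge regularization strength.
#' @param activation `"sigmoid"` (default), `"tanh"` or `"relu"`.
#' @param seed RNG seed for the random input weights.
#' @return an object of class `elm_model`.
#' @export
elm_train <- function(x, y, hidden_units = 500, ridge = 1e-6,
                      activation = c("sigmoid", "tanh", "relu"), seed = 1) {
  activation <- match.arg(activation)
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite features", call. = FALSE)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  stopifnot(hidden_units >= 1, nrow(x) == length(y))
  D <- ncol(x)
  with_seed(seed, {
    W <- matrix(runif(D * hidden_units, -1, 1), D, hidden_units)
    b <- runif(hidden_units, -1, 1)
  })
  H <- elm_hidden(x, W, b, activation)
  Tm <- onehot(match(y, classes), length(classes))  # C x N
  A <- crossprod(H) + diag(ridge, hidden_units)
  beta <- solve(A, crossprod(H, t(Tm)))
  model <- structure(list(W = W, b = b, beta = beta, classes = classes,
                          activation = activation, ridge = ridge,
                          hidden_units = hidden_units, d = D),
                     class = "elm_model")
  model$train_error <- mean(elm_predict(model, x) != y)
  model
}

elm_hidden <- function(x, W, b, activation) {
  Z <- x %*% W
  Z <- sweep(Z, 2, b, "+")
  switch(activation,
         sigmoid = 1 / (1 + exp(-Z)),
         tanh = tanh(Z),
         relu = pmax(Z, 0))
}

#' Predict classes with a trained ELM
#'
#' Argmax over the class scores `H beta`; deterministic.
#'
#' @param model an [elm_train()] model.
#' @param x `N x D` feature matrix with the training dimensionality.
#' @return vector of predicted labels from the model's class list.
#' @export
elm_predict <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$d)
    stop(sprintf("feature dimension %d does not match model (%d)",
                 ncol(x), model$d), call. = FALSE)
  H <- elm_hidden(x, model$W, model$b, model$activation)
  S <- H %*% model$beta
  model$classes[max.col(S, ties.method = "first")]
}

#' Serialize an ELM model to a JSON string
#'
#' A portable text bundle (weights plus metadata) that [elm_from_json()]
#' restores exactly.
#'
#' @param model an [elm_train()] model.
#' @return a JSON character string.
#' @export
elm_to_json <- function(model) {
  stopifnot(inherits(model, "elm_model"))
  as.character(jsonlite::toJSON(list(
    W = model$W, b = model$b, beta = model$beta,
    classes = model$classes, activation = model$activation,
    ridge = model$ridge, hidden_units = model$hidden_units, d = model$d,
    train_error = model$train_error), digits = NA))
}

#' Restore an ELM model from its JSON bundle
#' @param json a string produced by [elm_to_json()].
#' @return an `elm_model`.
#' @export
elm_from_json <- function(json) {
  o <- jsonlite::fromJSON(json)
  structure(list(W = as.matrix(o$W), b = as.numeric(o$b),
                 beta = as.matrix(o$beta), classes = o$classes,
                 activation = o$activation, ridge = o$ridge,
                 hidden_units = o$hidden_units, d = o$d,
                 train_error = o$train_error),
            class = "elm_model")
}

#' Classification metrics from true and predicted labels
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param classes class list; rows/columns of the confusion matrix. Defaults
#'   to the sorted union of the labels.
#' @return list with `accuracy`, `confusion` (rows = true classes), and
#'   `recall` (per-class).
#' @export
evaluate_predictions <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred))
    stop("label vectors differ in length", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  if (!all(y_true %in% classes) || !all(y_pred %in% classes))
    stop("label outside the class list", call. = FALSE)
  cm <- table(factor(y_true, levels = classes),
              factor(y_pred, levels = classes))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("true", "predicted")
  rs <- rowSums(cm)
  recall <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  list(accuracy = sum(diag(cm)) / length(y_true), confusion = cm,
       recall = recall)
}
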