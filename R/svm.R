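# Soft-margin SVM (linear / RBF) -------------------------------------------
#
# The decision function is f(x) = sign(sum_i alpha_i y_i K(x_i, x) + b).
# The RBF kernel is parameterised by its radius g, K(x, x') =
# exp(-||x - x'||^2 / (2 g^2)); a solver working with exp(-gamma d^2)
# therefore receives gamma = 1 / (2 g^2). Features are standardised
# (zero mean, unit variance, fitted on the training data only) before
# kernel evaluation because relative band powers (percent) and movement
# power (device units, ~10^2) live on incompatible scales for an RBF
# distance; the transform is stored inside the model.

#' Evaluate a kernel function
#'
#' Linear kernel: dot product. RBF kernel:
#' `exp(-||x - x'||^2 / (2 g^2))`, with `g` the kernel radius.
#'
#' @param kind `"linear"` or `"rbf"`.
#' @param x,xp numeric vectors of equal length.
#' @param g RBF radius (> 0); ignored for the linear kernel.
#' @return Scalar kernel value.
#' @export
kernel_eval <- function(kind = c("linear", "rbf"), x, xp, g = 1) {
  kind <- match.arg(kind)
  if (length(x) != length(xp))
    stop("kernel contract error: dimension mismatch (", length(x), " vs ",
         length(xp), ")", call. = FALSE)
  if (kind == "linear") return(sum(x * xp))
  if (g <= 0) stop("kernel contract error: g must be > 0 for rbf", call. = FALSE)
  exp(-sum((x - xp)^2) / (2 * g^2))
}

#' Train a soft-margin SVM
#'
#' Fits a binary C-SVM with the requested kernel by a deterministic SMO
#' solver (maximal-violating-pair selection, tolerance `tol`, no
#' randomisation). Labels must be -1 (alert) / +1 (slightly drowsy) and
#' both classes must be present.
#'
#' @param x numeric feature matrix (rows = windows).
#' @param y integer labels in `{-1, +1}`.
#' @param kernel `"linear"` or `"rbf"`.
#' @param C soft-margin penalty (> 0).
#' @param g RBF radius (> 0).
#' @param scale standardise features on the training data (default `TRUE`).
#' @param tol SMO KKT tolerance (default 1e-3).
#' @param max_iter SMO iteration cap.
#' @return A `ddd_svm` model: kernel, `C`, `g`, scaling parameters, support
#'   vectors, coefficients `alpha_i y_i` and bias `b`.
#' @export
train_svm <- function(x, y, kernel = c("linear", "rbf"), C = 1, g = 1,
                      scale = TRUE, tol = 1e-3, max_iter = 200000L) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (length(y) != nrow(x))
    stop("training error: ", nrow(x), " rows but ", length(y), " labels",
         call. = FALSE)
  if (!all(y %in% c(-1L, 1L)))
    stop("training error: labels must be -1/+1", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("training error: both classes must be present", call. = FALSE)
  if (C <= 0) stop("training error: C must be > 0", call. = FALSE)
  if (kernel == "rbf" && g <= 0)
    stop("training error: g must be > 0 for rbf", call. = FALSE)

  if (scale) {
    center <- colMeans(x)
    sc <- apply(x, 2, sd)
    sc[sc == 0 | is.na(sc)] <- 1
  } else {
    center <- rep(0, ncol(x))
    sc <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, center), 2, sc, "/")

  gamma <- if (kernel == "rbf") 1 / (2 * g^2) else 0
  fit <- smo_cpp(xs, y, if (kernel == "linear") 0L else 1L, gamma, C, tol,
                 as.integer(max_iter))
  keep <- fit$alpha > 1e-12
  structure(list(kernel = kernel, C = C, g = g, gamma = gamma,
                 center = center, scale = sc,
                 sv = xs[keep, , drop = FALSE],
                 coef = fit$alpha[keep] * y[keep],
                 b = fit$b, n_sv = sum(keep),
                 iterations = fit$iterations, converged = fit$converged,
                 feature_names = colnames(x)),
            class = "ddd_svm")
}

#' @export
print.ddd_svm <- function(x, ...) {
  cat(sprintf("<ddd_svm %s kernel, C = %g%s, %d support vectors, b = %.4g>\n",
              x$kernel, x$C,
              if (x$kernel == "rbf") sprintf(", g = %g", x$g) else "",
              x$n_sv, x$b))
  invisible(x)
}

#' Decision values and class predictions
#'
#' Evaluates `sum_i alpha_i y_i K(sv_i, x) + b` on (internally rescaled)
#' inputs. A decision value of exactly 0 maps to +1 — in a safety
#' application the tie goes to the drowsy class.
#'
#' @param object a `ddd_svm` model.
#' @param newdata numeric matrix (or vector for one window) of raw,
#'   unscaled features.
#' @param type `"class"` for -1/+1 labels, `"decision"` for decision values.
#' @param ... unused.
#' @return Integer labels or numeric decision values.
#' @export
predict.ddd_svm <- function(object, newdata,
                            type = c("class", "decision"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center))
    stop("prediction contract error: expected ", length(object$center),
         " features, got ", ncol(newdata), call. = FALSE)
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  K <- if (object$kernel == "linear") {
    xs %*% t(object$sv)
  } else {
    d2 <- outer(rowSums(xs^2), rowSums(object$sv^2), "+") -
      2 * xs %*% t(object$sv)
    exp(-object$gamma * pmax(d2, 0))
  }
  dec <- drop(K %*% object$coef) + object$b
  if (type == "decision") return(dec)
  ifelse(dec >= 0, 1L, -1L)
}

# Model persistence ----------------------------------------------------------

#' Write / read an SVM model as structured JSON text
#'
#' Serialises everything needed for bit-reproducible prediction: kernel,
#' `C`, `g`, scaling parameters, support-vector matrix, coefficients and
#' bias, at full floating-point precision.
#'
#' @param model a `ddd_svm`.
#' @param path JSON file path.
#' @return `write_model` invisibly returns `path`; `read_model` the model.
#' @export
write_model <- function(model, path) {
  obj <- unclass(model)
  obj$sv <- unname(as.matrix(obj$sv))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       always_decimal = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$sv <- matrix(as.numeric(obj$sv), nrow = obj$n_sv)
  obj$coef <- as.numeric(obj$coef)
  obj$center <- as.numeric(obj$center)
  obj$scale <- as.numeric(obj$scale)
  structure(obj, class = "ddd_svm")
}
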