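#' Train the linear margin classifier
#'
#' Fits an L2-regularized hinge-loss linear SVM by dual coordinate descent on
#' the sparse design matrix — the solver family used for large sparse text
#' problems where kernel-based quadratic programming is impractical. The bias
#' is handled by augmenting each sample with a constant feature (and is
#' therefore regularized, the convention of sparse linear-SVM solvers). The
#' fit is deterministic for fixed inputs and `seed`.
#'
#' @param X sparse design matrix (`dgCMatrix`, rows = records).
#' @param y labels: logical, or numeric +1/-1. Both classes must be present.
#' @param c_param regularization constant C (> 0); larger C fits harder.
#' @param tol convergence tolerance on the largest projected dual gradient.
#' @param max_epochs maximum passes over the data.
#' @param seed integer seed for the coordinate-shuffling PRNG.
#' @return object of class `"linear_model"` with `weights` (named by design
#'   columns), `bias`, and `c_param`.
#' @export
train_linear_svm <- function(X, y, c_param = 1, tol = 0.05, max_epochs = 300,
                             seed = 1L) {
  stop_if_not(nrow(X) > 0, "empty design matrix")
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  y <- as.numeric(y)
  stop_if_not(all(y %in% c(-1, 1)), "labels must be logical or +1/-1")
  stop_if_not(length(y) == nrow(X), "X rows and y length differ")
  stop_if_not(length(unique(y)) == 2, "both classes must be present in y")
  stop_if_not(is.numeric(c_param) && length(c_param) == 1 && c_param > 0,
              "c_param must be a positive number")
  Xt <- Matrix::t(methods::as(X, "CsparseMatrix"))
  Xaug <- methods::as(rbind(Xt, rep(1, ncol(Xt))), "CsparseMatrix")
  fit <- svm_dcd(Xaug, y, as.numeric(c_param), as.numeric(tol),
                 as.integer(max_epochs), as.integer(seed))
  p <- nrow(Xt)
  w <- fit$w
  structure(list(weights = stats::setNames(w[seq_len(p)], colnames(X)),
                 bias = w[p + 1L], c_param = c_param,
                 epochs = fit$epochs, converged = fit$max_pg < tol),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("<linear_model> %d weights, bias %.4f, C=%g (%d epochs%s)\n",
              length(x$weights), x$bias, x$c_param, x$epochs,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Signed margin distances
#'
#' The raw linear score `w'x + b` per record: positive means the model places
#' the record on the Humans side, magnitude reflects confidence. These margins
#' are the input to the probability calibration step.
#'
#' @param model a [train_linear_svm()] fit.
#' @param X design matrix with the same columns the model was trained on.
#' @return numeric vector of signed margins, one per row.
#' @export
margin_scores <- function(model, X) {
  stop_if_not(ncol(X) == length(model$weights),
              "design matrix has ", ncol(X), " columns but model expects ",
              length(model$weights))
  if (!is.null(colnames(X)) && !is.null(names(model$weights))) {
    stop_if_not(identical(colnames(X), names(model$weights)),
                "design matrix columns are not aligned with model weights")
  }
  as.numeric(X %*% model$weights) + model$bias
}
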