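MODEL_FORMAT_VERSION <- 1L

new_model <- function(mode, support_seqs, dual_coefs, bias, dp, kp, hyper,
                      meta = list()) {
  structure(list(mode = mode, support_seqs = support_seqs,
                 dual_coefs = dual_coefs, bias = bias,
                 dp = dp, kp = kp, hyper = hyper, meta = meta),
            class = "editscan_model")
}

#' Train the binary editing-site classifier
#'
#' Fits a soft-margin maximal-margin classifier on the precomputed string
#' kernel over positive (editing) and negative (background) contexts, via
#' sequential minimal optimization. Only support sequences and their dual
#' coefficients are retained.
#'
#' @param pos,neg character vectors of `L1`-mer contexts (positive /
#'   negative class). Both must be non-empty.
#' @param dp [dist_params()].
#' @param kp [kernel_params()].
#' @param C soft-margin cost (> 0). The upstream work reports no value;
#'   the default is 1.
#' @param tol SMO stopping tolerance on the maximal KKT violation.
#' @param max_iter iteration cap; exceeding it is an error (diagnostics in
#'   the message), not a silent approximation.
#' @param kernel optional precomputed Gram matrix over `c(pos, neg)`
#'   (rows/cols in that order); skips kernel construction.
#' @return an `editscan_model` of mode `"binary"`.
#' @export
train_binary <- function(pos, neg, dp = dist_params(), kp = kernel_params(),
                         C = 1, tol = 1e-3, max_iter = 1e6L,
                         kernel = NULL) {
  if (!length(pos) || !length(neg))
    stop("both classes must be non-empty", call. = FALSE)
  if (!is.numeric(C) || C <= 0) stop("C must be > 0", call. = FALSE)
  dp <- as_dist_params(dp); kp <- as_kernel_params(kp)
  x <- toupper(c(as.character(pos), as.character(neg)))
  check_lengths(x, dp$L1)
  y <- c(rep(1L, length(pos)), rep(-1L, length(neg)))
  K <- if (is.null(kernel))
    kernel_matrix(x, dp = dp, kp = kp, check_psd = TRUE) else kernel
  stopifnot(nrow(K) == length(x), ncol(K) == length(x))
  n <- length(x)
  fit <- .smo_solve_cpp(K, y, rep(-1, n), rep(as.numeric(C), n),
                        rep(0, n), tol, as.integer(max_iter))
  if (!fit$converged)
    stop(sprintf(
      "SMO did not converge within %d iterations (n = %d, C = %g)",
      as.integer(max_iter), n, C), call. = FALSE)
  coefs <- fit$alpha * y
  sv <- which(abs(coefs) > 1e-12)
  new_model("binary", x[sv], coefs[sv], fit$bias, dp, kp,
            hyper = list(C = as.numeric(C)),
            meta = list(n_pos = length(pos), n_neg = length(neg),
                        iterations = fit$iterations,
                        trained = format(Sys.time(), tz = "UTC")))
}

#' Train the one-class editing-site model
#'
#' Fits the nu-parameterized one-class maximal-margin model on positive
#' contexts only: the decision boundary separates the training mass from
#' the origin in kernel space. `nu` is an upper bound on the fraction of
#' training errors (points scored negative) and a lower bound on the
#' fraction of support vectors. Predictions are `+1` (editing event) or
#' `-1` (non-editing event).
#'
#' @param pos character vector of `L1`-mer positive contexts.
#' @param nu in (0, 1); default 0.1, the operating point of the two-stage
#'   genome scan.
#' @inheritParams train_binary
#' @return an `editscan_model` of mode `"one-class"`.
#' @export
train_one_class <- function(pos, dp = dist_params(), kp = kernel_params(),
                            nu = 0.1, tol = 1e-4, max_iter = 1e6L,
                            kernel = NULL) {
  if (!length(pos)) stop("positive set must be non-empty", call. = FALSE)
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0 || nu >= 1)
    stop("nu must be in (0, 1)", call. = FALSE)
  dp <- as_dist_params(dp); kp <- as_kernel_params(kp)
  x <- toupper(as.character(pos))
  check_lengths(x, dp$L1)
  n <- length(x)
  K <- if (is.null(kernel))
    kernel_matrix(x, dp = dp, kp = kp) else kernel
  stopifnot(nrow(K) == n, ncol(K) == n)
  up <- 1 / (nu * n)
  # feasible start as in LIBSVM: the first floor(nu*n) points at the upper
  # bound, the remainder fraction on the next point, sum(alpha) = 1
  a0 <- numeric(n)
  nfull <- floor(nu * n)
  if (nfull > 0) a0[seq_len(nfull)] <- up
  if (nfull < n) a0[nfull + 1L] <- (nu * n - nfull) * up
  fit <- .smo_solve_cpp(K, rep(1L, n), rep(0, n), rep(up, n), a0, tol,
                        as.integer(max_iter))
  if (!fit$converged)
    stop(sprintf(
      "SMO did not converge within %d iterations (n = %d, nu = %g)",
      as.integer(max_iter), n, nu), call. = FALSE)
  sv <- which(fit$alpha > 1e-12)
  new_model("one-class", x[sv], fit$alpha[sv], fit$bias, dp, kp,
            hyper = list(nu = as.numeric(nu)),
            meta = list(n_pos = n, iterations = fit$iterations,
                        trained = format(Sys.time(), tz = "UTC")))
}

#' Predict editing labels for context sequences
#'
#' The decision value is the kernel expansion
#' `f(x) = sum_i coef_i * K(x, sv_i) + bias`; the label is `+1` (editing
#' event) iff `f(x) > 0`, with the tie at exactly zero called `-1`
#' (conservative).
#'
#' @param object an `editscan_model`.
#' @param newdata character vector of `L1`-mer contexts.
#' @param ... unused.
#' @return data.frame with columns `seq`, `decision_value`, `label`
#'   (integer `+1` / `-1`).
#' @export
predict.editscan_model <- function(object, newdata, ...) {
  x <- toupper(as.character(newdata))
  bad <- which(nchar(x) != object$dp$L1)
  if (length(bad))
    stop(sprintf("input %d has length %d, expected L1 = %d",
                 bad[1L], nchar(x[bad[1L]]), object$dp$L1), call. = FALSE)
  K <- kernel_matrix(x, object$support_seqs, dp = object$dp, kp = object$kp)
  dv <- as.numeric(K %*% object$dual_coefs + object$bias)
  data.frame(seq = x, decision_value = dv,
             label = ifelse(dv > 0, 1L, -1L), stringsAsFactors = FALSE)
}

#' @export
print.editscan_model <- function(x, ...) {
  cat(sprintf("editscan %s model: %d support sequences (L1 = %d)\n",
              x$mode, length(x$support_seqs), x$dp$L1))
  cat(sprintf("  distance: w = %g, L1 = %d, L2 = %d; kernel gamma = %g\n",
              x$dp$w, x$dp$L1, x$dp$L2, x$kp$gamma))
  hp <- if (x$mode == "binary") sprintf("C = %g", x$hyper$C)
        else sprintf("nu = %g", x$hyper$nu)
  cat(sprintf("  hyperparameters: %s; bias = %.6g\n", hp, x$bias))
  invisible(x)
}

#' Save / load a trained model
#'
#' Models are stored as versioned, self-describing JSON (support sequences,
#' dual coefficients at full precision, bias, distance and kernel
#' parameters, hyperparameters, provenance). A load after a save reproduces
#' predictions bit-for-bit.
#'
#' @param model an `editscan_model`.
#' @param path file path.
#' @return `save_model`: `path`, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "editscan_model"))
  obj <- list(format = "editscan_model",
              format_version = MODEL_FORMAT_VERSION,
              mode = model$mode,
              support_seqs = model$support_seqs,
              # decimal copies are for human eyes; the hex floats are
              # authoritative and restore coefficients bit-for-bit
              dual_coefs = model$dual_coefs,
              dual_coefs_hex = sprintf("%a", model$dual_coefs),
              bias = model$bias,
              bias_hex = sprintf("%a", model$bias),
              dp = unclass(model$dp), kp = unclass(model$kp),
              hyper = model$hyper, meta = model$meta)
  json <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e)
                    stop("corrupt model file: ", conditionMessage(e),
                         call. = FALSE))
  if (!identical(obj$format, "editscan_model"))
    stop("not an editscan model file", call. = FALSE)
  if (!identical(as.integer(obj$format_version), MODEL_FORMAT_VERSION))
    stop("unsupported model format version: ", obj$format_version,
         call. = FALSE)
  need <- c("mode", "support_seqs", "dual_coefs", "bias", "dp", "kp", "hyper")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("corrupt model file: missing fields ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(obj$support_seqs) != length(obj$dual_coefs))
    stop("corrupt model file: coefficient/support length mismatch",
         call. = FALSE)
  coefs <- if (!is.null(obj$dual_coefs_hex))
    as.numeric(obj$dual_coefs_hex) else as.numeric(obj$dual_coefs)
  bias <- if (!is.null(obj$bias_hex))
    as.numeric(obj$bias_hex) else as.numeric(obj$bias)
  if (any(is.na(coefs)) || is.na(bias))
    stop("corrupt model file: unparseable coefficients", call. = FALSE)
  new_model(obj$mode, as.character(obj$support_seqs),
            coefs, bias,
            dist_params(obj$dp$w, obj$dp$L1, obj$dp$L2),
            kernel_params(obj$kp$gamma), obj$hyper, obj$meta)
}
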