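#' Combined string-distance parameters
#'
#' The combined distance weighs a length-normalized Levenshtein (edit)
#' distance computed on the full `L1`-mer context against a length-normalized
#' Hamming distance computed on the centered inner `L2`-mer:
#' `D = w * D_edit/L1 + (1 - w) * D_ham/L2`. At `w = 0` only the Hamming
#' term contributes; at `w = 1` only the edit term.
#'
#' @param w weight of the edit-distance term, in `[0, 1]`.
#' @param L1 odd context length for the edit distance (default 41,
#'   i.e. 20 nt flanks).
#' @param L2 odd inner window length for the Hamming distance, `L2 <= L1`
#'   (default 31). The `L2 > L1` case is rejected, not guessed.
#' @return an object of class `dist_params`.
#' @examples
#' dist_params(w = 0.2)
#' @export
dist_params <- function(w = 0.2, L1 = 41L, L2 = 31L) {
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1)
    stop("w must be a single number in [0, 1]", call. = FALSE)
  L1 <- as.integer(L1); L2 <- as.integer(L2)
  if (is.na(L1) || L1 < 1L || L1 %% 2L == 0L)
    stop("L1 must be a positive odd integer", call. = FALSE)
  if (is.na(L2) || L2 < 1L || L2 %% 2L == 0L)
    stop("L2 must be a positive odd integer", call. = FALSE)
  if (L2 > L1)
    stop("L2 must not exceed L1 (nested-window form)", call. = FALSE)
  structure(list(w = as.numeric(w), L1 = L1, L2 = L2),
            class = "dist_params")
}

#' String-kernel parameters
#'
#' @param gamma positive kernel width of `K(a, b) = exp(-gamma * D^2)`;
#'   default 0.1.
#' @return an object of class `kernel_params`.
#' @export
kernel_params <- function(gamma = 0.1) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma <= 0)
    stop("gamma must be a single positive number", call. = FALSE)
  structure(list(gamma = as.numeric(gamma)), class = "kernel_params")
}

#' @export
print.dist_params <- function(x, ...) {
  cat(sprintf("combined string distance: w = %g, L1 = %d, L2 = %d\n",
              x$w, x$L1, x$L2))
  invisible(x)
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("string kernel: gamma = %g\n", x$gamma))
  invisible(x)
}

as_dist_params <- function(dp) {
  if (inherits(dp, "dist_params")) return(dp)
  if (is.list(dp)) return(dist_params(dp$w, dp$L1, dp$L2))
  stop("expected dist_params", call. = FALSE)
}

as_kernel_params <- function(kp) {
  if (inherits(kp, "kernel_params")) return(kp)
  if (is.list(kp)) return(kernel_params(kp$gamma))
  stop("expected kernel_params", call. = FALSE)
}
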