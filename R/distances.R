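#' Levenshtein (edit) distance
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions (unit costs) transforming `a` into `b`. Case-insensitive;
#' arguments are recycled to the longer length.
#'
#' @param a,b character vectors.
#' @return integer vector of distances.
#' @examples
#' edit_distance("kitten", "sitting")  # 3
#' @export
edit_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(toupper(as.character(a)), n)
  b <- rep_len(toupper(as.character(b)), n)
  .lev_cpp(a, b)
}

#' Hamming distance
#'
#' Number of mismatching positions between equal-length strings
#' (substitutions only). `N` differs from everything, including another
#' `N` — assembly gaps never count as matches.
#'
#' @param a,b character vectors of equal-length strings.
#' @return integer vector of distances.
#' @export
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(toupper(as.character(a)), n)
  b <- rep_len(toupper(as.character(b)), n)
  .hamming_cpp(a, b)
}

# centered L2-mer of an L1-mer
inner_window <- function(x, L1, L2) {
  off <- (L1 - L2) %/% 2L
  substr(x, off + 1L, off + L2)
}

check_lengths <- function(x, L1, what = "sequence") {
  bad <- which(nchar(x) != L1)
  if (length(bad))
    stop(sprintf("%s %d has length %d, expected L1 = %d",
                 what, bad[1L], nchar(x[bad[1L]]), L1), call. = FALSE)
  invisible(TRUE)
}

#' Combined string distance
#'
#' `D = w * D_edit(a, b) / L1 + (1 - w) * D_ham(inner(a), inner(b)) / L2`,
#' where the edit term is the Levenshtein distance over the full `L1`-mers
#' and the Hamming term is computed on the centered inner `L2`-mers. Both
#' terms are normalized by their window length, so `D` lies in `[0, 1]`.
#'
#' @param a,b character vectors of `L1`-mers (recycled).
#' @param dp [dist_params()].
#' @return numeric vector of distances in `[0, 1]`.
#' @examples
#' combined_distance("AAAAA", "AATAA", dist_params(w = 0.5, L1 = 5, L2 = 3))
#' @export
combined_distance <- function(a, b, dp = dist_params()) {
  dp <- as_dist_params(dp)
  n <- max(length(a), length(b))
  a <- rep_len(toupper(as.character(a)), n)
  b <- rep_len(toupper(as.character(b)), n)
  check_lengths(a, dp$L1); check_lengths(b, dp$L1)
  de <- as.numeric(.lev_cpp(a, b))
  dh <- as.numeric(.hamming_cpp(inner_window(a, dp$L1, dp$L2),
                                inner_window(b, dp$L1, dp$L2)))
  dp$w * de / dp$L1 + (1 - dp$w) * dh / dp$L2
}

#' String-kernel value
#'
#' `K(a, b) = exp(-gamma * D(a, b)^2)` with `D` the combined distance.
#' Takes values in `(0, 1]`, equal to 1 iff `D = 0`, and strictly
#' decreasing in `D`.
#'
#' @inheritParams combined_distance
#' @param kp [kernel_params()].
#' @return numeric vector of kernel values.
#' @export
kernel_value <- function(a, b, dp = dist_params(), kp = kernel_params()) {
  kp <- as_kernel_params(kp)
  d <- combined_distance(a, b, dp)
  exp(-kp$gamma * d^2)
}

#' Component distance matrices
#'
#' Returns the two length-normalized component matrices of the combined
#' distance — `edit` (`D_edit / L1` over full windows) and `hamming`
#' (`D_ham / L2` over inner windows) — so that sweeps over the weight `w`
#' can recombine them without recomputing string distances:
#' `D = w * edit + (1 - w) * hamming`.
#'
#' @param X,Y character vectors of `L1`-mers; `Y = NULL` means `Y = X`
#'   (symmetric fast path).
#' @param dp [dist_params()] (its `w` is ignored here).
#' @return list with numeric matrices `edit` and `hamming`.
#' @export
distance_components <- function(X, Y = NULL, dp = dist_params()) {
  dp <- as_dist_params(dp)
  X <- toupper(as.character(X))
  check_lengths(X, dp$L1)
  symmetric <- is.null(Y)
  Y <- if (symmetric) X else toupper(as.character(Y))
  check_lengths(Y, dp$L1)
  E <- .edit_matrix_cpp(X, Y, symmetric) / dp$L1
  H <- .hamming_matrix_cpp(inner_window(X, dp$L1, dp$L2),
                           inner_window(Y, dp$L1, dp$L2),
                           symmetric) / dp$L2
  list(edit = E, hamming = H)
}

#' Kernel matrix
#'
#' Builds the `|X| x |Y|` matrix of string-kernel values. When `Y` is
#' omitted the symmetric Gram matrix of `X` is built, exploiting symmetry
#' and with a unit diagonal. The kernel over this non-Euclidean distance is
#' not guaranteed positive semi-definite; the matrix is returned as-is
#' (the solver copes), and a warning is emitted if strong indefiniteness
#' is detected on a small Gram matrix (most-negative eigenvalue of a
#' sampled submatrix below `-1e-6`).
#'
#' @inheritParams distance_components
#' @param kp [kernel_params()].
#' @param check_psd check a sampled submatrix for strong indefiniteness
#'   (symmetric case only).
#' @return numeric matrix of kernel values in `(0, 1]`.
#' @export
kernel_matrix <- function(X, Y = NULL, dp = dist_params(),
                          kp = kernel_params(), check_psd = FALSE) {
  dp <- as_dist_params(dp); kp <- as_kernel_params(kp)
  comp <- distance_components(X, Y, dp)
  D <- dp$w * comp$edit + (1 - dp$w) * comp$hamming
  K <- exp(-kp$gamma * D^2)
  if (check_psd && is.null(Y)) {
    idx <- seq_len(min(nrow(K), 200L))
    ev <- min(eigen(K[idx, idx], symmetric = TRUE,
                    only.values = TRUE)$values)
    if (ev < -1e-6)
      warning(sprintf(
        "string kernel Gram matrix is strongly indefinite (min eigenvalue %.3g)",
        ev), call. = FALSE)
  }
  K
}

# kernel matrix from precomputed component matrices (w-sweep fast path)
kernel_from_components <- function(comp, w, gamma) {
  D <- w * comp$edit + (1 - w) * comp$hamming
  exp(-gamma * D^2)
}

#' Dump a kernel matrix as TSV
#'
#' Debugging helper: writes the matrix with row/column indices.
#' @param K numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kernel_tsv <- function(K, path) {
  write.table(format(K, digits = 10), path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}
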