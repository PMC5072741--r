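#' Confusion-matrix performance criteria
#'
#' Computes the six criteria used throughout: sensitivity `Sn = TP/P`,
#' specificity `Sp = TN/N`, accuracy `Acc = (TP+TN)/(P+N)`, positive
#' predictive value `PPV = TP/(TP+FP)`, Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt(P*N*(TP+FP)*(TN+FN))`, and the geometric
#' mean `Gmean = sqrt(Sn * Sp)`. MCC and G-mean weigh performance on both
#' classes, which is what makes them informative on imbalanced data.
#'
#' `PPV` is `NaN` (with `ppv_undefined = TRUE`) when no positive calls were
#' made; `MCC` is 0 when its denominator vanishes.
#'
#' @param TP,FP,TN,FN confusion counts; alternatively pass a list or
#'   one-row data.frame with those fields as `TP`.
#' @return object of class `metrics_report`: the counts, `P`, `N`, and the
#'   six criteria.
#' @examples
#' compute_metrics(TP = 1332, FP = 1234, TN = 3301, FN = 627)
#' @export
compute_metrics <- function(TP, FP = NULL, TN = NULL, FN = NULL) {
  if (is.list(TP)) {
    cc <- TP
    TP <- cc$TP; FP <- cc$FP; TN <- cc$TN; FN <- cc$FN
  }
  cnt <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(is.na(cnt)) || any(cnt < 0))
    stop("confusion counts must be non-negative", call. = FALSE)
  P <- TP + FN; N <- TN + FP
  if (P < 1 || N < 1)
    stop("both P (= TP + FN) and N (= TN + FP) must be >= 1", call. = FALSE)
  Sn <- TP / P; Sp <- TN / N
  Acc <- (TP + TN) / (P + N)
  ppv_undefined <- (TP + FP) == 0
  PPV <- if (ppv_undefined) NaN else TP / (TP + FP)
  denom <- sqrt(P) * sqrt(N) * sqrt(TP + FP) * sqrt(TN + FN)
  MCC <- if (denom == 0) 0 else (TP * TN - FP * FN) / denom
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN, P = P, N = N,
                 Sn = Sn, Sp = Sp, Acc = Acc, PPV = PPV, MCC = MCC,
                 Gmean = gmean(Sn, Sp), ppv_undefined = ppv_undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d  (P = %d, N = %d)\n",
              x$TP, x$FP, x$TN, x$FN, x$P, x$N))
  cat(sprintf(
    "Sn %.3f  Sp %.3f  Acc %.3f  PPV %s  MCC %.3f  Gmean %.3f\n",
    x$Sn, x$Sp, x$Acc,
    if (x$ppv_undefined) "NaN" else sprintf("%.3f", x$PPV),
    x$MCC, x$Gmean))
  invisible(x)
}

metrics_row <- function(m) {
  data.frame(TP = m$TP, FP = m$FP, TN = m$TN, FN = m$FN,
             Sn = m$Sn, Sp = m$Sp, Acc = m$Acc, PPV = m$PPV,
             MCC = m$MCC, Gmean = m$Gmean)
}

#' Geometric mean of sensitivity and specificity
#'
#' @param Sn,Sp values in `[0, 1]`.
#' @return `sqrt(Sn * Sp)`.
#' @examples
#' gmean(0.680, 0.728)  # 0.704
#' @export
gmean <- function(Sn, Sp) {
  if (any(Sn < 0 | Sn > 1 | Sp < 0 | Sp > 1, na.rm = TRUE))
    stop("Sn and Sp must lie in [0, 1]", call. = FALSE)
  sqrt(Sn * Sp)
}

#' Oversample a minority class to a target size
#'
#' Cyclic duplication: as many whole copies of the input as fit, then a
#' seeded random remainder drawn without replacement. The achieved fold
#' factor (`target_size / length(minority)`) is attached as attribute
#' `"fold"`. With fly-sized classes (1959 positives against 4535
#' negatives) this is the 2.31-fold oversampling of the imbalanced
#' training protocol; mouse (8059 vs 15475) gives 1.92-fold.
#'
#' @param minority vector (any type) of minority-class items.
#' @param target_size desired output length, `>= length(minority)`.
#' @param seed integer seed for the remainder draw.
#' @return vector of length `target_size`.
#' @export
oversample_to_balance <- function(minority, target_size, seed = 1L) {
  n <- length(minority)
  if (n == 0L) stop("minority set is empty", call. = FALSE)
  target_size <- as.integer(target_size)
  if (target_size < n)
    stop("target_size must be >= the minority size", call. = FALSE)
  whole <- target_size %/% n
  rem <- target_size %% n
  out <- rep(minority, whole)
  if (rem > 0L) {
    old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
    out <- c(out, minority[sample.int(n, rem)])
  }
  attr(out, "fold") <- target_size / n
  out
}

# stratified seeded fold assignment
assign_folds <- function(n_pos, n_neg, nfolds, seed) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  c(sample(rep_len(seq_len(nfolds), n_pos)),
    sample(rep_len(seq_len(nfolds), n_neg)))
}

# CV engine over a precomputed Gram matrix; y in {+1,-1}, positives first.
cv_kernel <- function(K, y, nfolds, C, seed, oversample, tol = 1e-3,
                      max_iter = 1e6L) {
  n <- length(y)
  fold <- assign_folds(sum(y == 1L), sum(y == -1L), nfolds, seed)
  dv <- numeric(n)
  per_fold <- vector("list", nfolds)
  for (f in seq_len(nfolds)) {
    test <- which(fold == f)
    train <- which(fold != f)
    tr_pos <- train[y[train] == 1L]
    tr_neg <- train[y[train] == -1L]
    if (oversample && length(tr_pos) < length(tr_neg))
      tr_pos <- oversample_to_balance(tr_pos, length(tr_neg),
                                      seed = seed + f)
    tr <- c(tr_pos, tr_neg)
    ytr <- y[tr]
    m <- length(tr)
    fit <- .smo_solve_cpp(K[tr, tr, drop = FALSE], ytr, rep(-1, m),
                          rep(as.numeric(C), m), rep(0, m), tol,
                          as.integer(max_iter))
    if (!fit$converged)
      stop(sprintf("SMO did not converge in CV fold %d", f), call. = FALSE)
    coefs <- fit$alpha * ytr
    dv[test] <- as.numeric(K[test, tr, drop = FALSE] %*% coefs + fit$bias)
    pred <- ifelse(dv[test] > 0, 1L, -1L)
    per_fold[[f]] <- compute_metrics(
      TP = sum(pred == 1L & y[test] == 1L),
      FP = sum(pred == 1L & y[test] == -1L),
      TN = sum(pred == -1L & y[test] == -1L),
      FN = sum(pred == -1L & y[test] == 1L))
  }
  pred <- ifelse(dv > 0, 1L, -1L)
  pooled <- compute_metrics(TP = sum(pred == 1L & y == 1L),
                            FP = sum(pred == 1L & y == -1L),
                            TN = sum(pred == -1L & y == -1L),
                            FN = sum(pred == -1L & y == 1L))
  fold_tab <- cbind(fold = seq_len(nfolds),
                    do.call(rbind, lapply(per_fold, metrics_row)))
  list(per_fold = fold_tab, pooled = pooled,
       decisions = data.frame(index = seq_len(n), truth = y, fold = fold,
                              decision_value = dv))
}

#' Stratified N-fold cross-validation of the binary classifier
#'
#' Folds are stratified by class and seeded. When `oversample` is set,
#' positives are duplicated only inside each training fold, up to that
#' fold's negative training count; held-out evaluation always uses the
#' original, unduplicated instances, so pooled counts refer to
#' `length(pos) + length(neg)` evaluations. Pooled metrics are computed
#' from the summed confusion counts.
#'
#' @param pos,neg character vectors of `L1`-mer contexts.
#' @param nfolds number of folds (>= 2); both classes must have at least
#'   `nfolds` members.
#' @param dp,kp distance / kernel parameters.
#' @param C soft-margin cost.
#' @param seed fold-assignment (and oversampling-remainder) seed.
#' @param oversample duplicate training-fold positives to balance classes.
#' @return list with `per_fold` (data.frame of per-fold metrics), `pooled`
#'   (a `metrics_report`), and `decisions` (per-instance held-out decision
#'   values with truth labels).
#' @export
cross_validate <- function(pos, neg, nfolds = 5L, dp = dist_params(),
                           kp = kernel_params(), C = 1, seed = 1L,
                           oversample = TRUE) {
  nfolds <- as.integer(nfolds)
  if (nfolds < 2L) stop("nfolds must be >= 2", call. = FALSE)
  if (length(pos) < nfolds || length(neg) < nfolds)
    stop("each class needs at least nfolds members", call. = FALSE)
  dp <- as_dist_params(dp); kp <- as_kernel_params(kp)
  x <- toupper(c(as.character(pos), as.character(neg)))
  check_lengths(x, dp$L1)
  y <- c(rep(1L, length(pos)), rep(-1L, length(neg)))
  K <- kernel_matrix(x, dp = dp, kp = kp)
  cv_kernel(K, y, nfolds, C, seed, oversample)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the decision values (tied values share one
#' threshold step); AUC by the trapezoidal rule, which equals the
#' Mann-Whitney concordance probability with ties counted half.
#'
#' @param decision_values numeric scores, larger = more positive.
#' @param truth_labels class labels: `+1`/`-1`, logical, or a two-level
#'   factor-like vector where the larger value is the positive class.
#' @return list with `auc` and `points` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(decision_values, truth_labels) {
  y <- normalize_truth(truth_labels)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in truth_labels", call. = FALSE)
  stopifnot(length(decision_values) == length(y))
  o <- order(decision_values, decreasing = TRUE)
  dv <- decision_values[o]; yy <- y[o]
  grp <- cumsum(!duplicated(dv))          # tie groups share a step
  tp <- tapply(yy == 1L, grp, sum)
  fp <- tapply(yy == -1L, grp, sum)
  P <- sum(yy == 1L); N <- sum(yy == -1L)
  tpr <- c(0, cumsum(tp) / P)
  fpr <- c(0, cumsum(fp) / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc,
       points = data.frame(threshold = c(Inf, dv[!duplicated(dv)]),
                           fpr = fpr, tpr = tpr))
}

normalize_truth <- function(truth) {
  if (is.logical(truth)) return(ifelse(truth, 1L, -1L))
  u <- sort(unique(truth))
  if (length(u) > 2L) stop("truth_labels must be binary", call. = FALSE)
  if (all(u %in% c(-1L, 1L))) return(as.integer(truth))
  ifelse(truth == u[length(u)], 1L, -1L)
}

#' Cross-validated sweep over the distance weight w
#'
#' The two component matrices of the combined distance (normalized edit and
#' Hamming) are computed once and recombined for every grid value, so the
#' sweep costs one string-distance pass regardless of grid size.
#'
#' @inheritParams cross_validate
#' @param w_grid numeric vector of weights in `[0, 1]`.
#' @param dp_base [dist_params()] supplying `L1`/`L2` (its `w` is ignored).
#' @return data.frame: one row per grid value with pooled CV metrics and
#'   AUC.
#' @export
sweep_w <- function(pos, neg, w_grid = seq(0, 1, by = 0.1),
                    dp_base = dist_params(), kp = kernel_params(),
                    nfolds = 5L, C = 1, seed = 1L, oversample = TRUE) {
  dp_base <- as_dist_params(dp_base); kp <- as_kernel_params(kp)
  if (any(w_grid < 0 | w_grid > 1))
    stop("w_grid values must lie in [0, 1]", call. = FALSE)
  x <- toupper(c(as.character(pos), as.character(neg)))
  check_lengths(x, dp_base$L1)
  y <- c(rep(1L, length(pos)), rep(-1L, length(neg)))
  comp <- distance_components(x, dp = dp_base)
  out <- lapply(w_grid, function(w) {
    K <- kernel_from_components(comp, w, kp$gamma)
    cv <- cv_kernel(K, y, as.integer(nfolds), C, seed, oversample)
    roc <- roc_auc(cv$decisions$decision_value, cv$decisions$truth)
    cbind(w = w, metrics_row(cv$pooled), AUC = roc$auc)
  })
  do.call(rbind, out)
}

#' Cross-validated sweep over context lengths
#'
#' Re-extracts contexts at each length and cross-validates each pure
#' distance: `edit` (`w = 1`) and `hamming` (`w = 0`, Hamming over the full
#' window, `L2 = L1`). Emits one row per (length, distance).
#'
#' @param genome genome as in [extract_context()].
#' @param pos_sites,neg_sites site data.frames (`chrom`, `pos`, `strand`).
#' @param lengths odd context lengths to evaluate.
#' @inheritParams cross_validate
#' @return data.frame with columns `length`, `distance`, `n_pos`, `n_neg`
#'   and pooled CV metrics.
#' @export
sweep_length <- function(genome, pos_sites, neg_sites,
                         lengths = c(11L, 21L, 31L, 41L, 51L),
                         kp = kernel_params(), nfolds = 5L, C = 1,
                         seed = 1L, oversample = TRUE) {
  lengths <- as.integer(lengths)
  if (any(lengths %% 2L == 0L))
    stop("context lengths must be odd", call. = FALSE)
  genome <- as_genome(genome)
  out <- list()
  for (L in lengths) {
    flank <- (L - 1L) %/% 2L
    pos <- suppressMessages(extract_contexts(genome, pos_sites, flank))$seq
    neg <- suppressMessages(extract_contexts(genome, neg_sites, flank))$seq
    for (dist in c("edit", "hamming")) {
      w <- if (dist == "edit") 1 else 0
      cv <- cross_validate(pos, neg, nfolds = nfolds,
                           dp = dist_params(w = w, L1 = L, L2 = L),
                           kp = kp, C = C, seed = seed,
                           oversample = oversample)
      out[[length(out) + 1L]] <-
        cbind(length = L, distance = dist, n_pos = length(pos),
              n_neg = length(neg), metrics_row(cv$pooled))
    }
  }
  do.call(rbind, out)
}

#' Write a metrics or sweep table as TSV
#'
#' @param x data.frame (e.g. from [sweep_w()]) or a `metrics_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(x, path) {
  if (inherits(x, "metrics_report")) x <- metrics_row(x)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
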