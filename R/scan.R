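#' Enumerate adenine-centered candidate windows
#'
#' Every forward-strand `A` yields a `+` candidate; every forward-strand
#' `T` yields a `-` candidate whose context is the reverse complement of
#' the forward window (the edited adenine sits at the center of its own
#' strand). Positions closer than `(L1 - 1) / 2` to a contig edge are
#' skipped and counted in attribute `"skipped"`.
#'
#' @param genome genome as in [extract_context()].
#' @param L1 odd context length.
#' @return data.frame `chrom`, `pos` (1-based center), `strand`, `seq`,
#'   with attribute `"skipped"`.
#' @export
enumerate_candidates <- function(genome, L1 = 41L) {
  L1 <- as.integer(L1)
  if (L1 %% 2L == 0L) stop("L1 must be odd", call. = FALSE)
  genome <- as_genome(genome)
  rows <- list()
  skipped <- 0L
  for (chrom in names(genome)) {
    r <- .enumerate_candidates_cpp(genome[[chrom]], L1)
    skipped <- skipped + r$skipped
    if (!length(r$pos)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, pos = r$pos,
      strand = ifelse(r$strand == 1L, "+", "-"),
      seq = r$context, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), strand = character(),
               seq = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Mismatch-tolerant seed search
#'
#' Finds every adenine-centered genome window (both strand orientations)
#' within `max_mismatch` substitutions — no indels — of some seed context.
#' Exact search (`max_mismatch = 0`) uses a hash index over the seeds;
#' mismatch search is an early-exit scan. Hits at the same
#' `(chrom, pos, strand)` from several seeds are merged keeping the
#' lowest-mismatch seed (ties broken by seed input order). The mismatch
#' budget applies to the flanks: the central base always matches by
#' construction (only `A`/`T`-centered windows are considered against
#' adenine-centered seeds).
#'
#' @param seeds character vector of equal, odd-length adenine-centered
#'   contexts.
#' @param genome genome as in [extract_context()].
#' @param max_mismatch allowed substitutions, 0..3.
#' @return data.frame `chrom`, `pos`, `strand`, `seq` (the strand-resolved
#'   context), `seed_id` (index into `seeds`), `mismatches`, ordered by
#'   (chrom, pos, strand).
#' @export
seed_match <- function(seeds, genome, max_mismatch = 0L) {
  max_mismatch <- as.integer(max_mismatch)
  if (is.na(max_mismatch) || max_mismatch < 0L || max_mismatch > 3L)
    stop("max_mismatch must be between 0 and 3", call. = FALSE)
  seeds <- toupper(as.character(seeds))
  if (!length(seeds)) stop("no seeds given", call. = FALSE)
  if (length(unique(nchar(seeds))) != 1L)
    stop("seeds must all have the same length", call. = FALSE)
  genome <- as_genome(genome)
  rows <- list()
  for (chrom in names(genome)) {
    r <- .seed_scan_cpp(genome[[chrom]], seeds, max_mismatch)
    if (!length(r$pos)) next
    strand <- ifelse(r$strand == 1L, "+", "-")
    flank <- (nchar(seeds[1L]) - 1L) %/% 2L
    ctx <- substring(genome[[chrom]], r$pos - flank, r$pos + flank)
    ctx[strand == "-"] <- revcomp(ctx[strand == "-"])
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, pos = r$pos, strand = strand, seq = ctx,
      seed_id = r$seed_id, mismatches = r$mismatches,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), strand = character(),
               seq = character(), seed_id = integer(),
               mismatches = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-stage putative-site caller
#'
#' Stage 1 applies the one-class model (trained on positives only,
#' typically `nu = 0.1`) to remove the most unlikely candidates; stage 2
#' applies the binary classifier to the survivors. Candidates with a
#' stage-2 label of `+1` are the putative editing sites. Binary fields are
#' populated only for stage-1 survivors. Stage-wise counts are reported
#' via `message()`.
#'
#' @param candidates data.frame with at least a `seq` column of `L1`-mers
#'   (e.g. from [enumerate_candidates()] or [seed_match()]).
#' @param oneclass_model,binary_model trained [editscan
#'   models][train_binary()]; they must share distance and kernel
#'   parameters.
#' @return `candidates` with columns added: `oneclass_pass` (logical),
#'   `binary_label` (`+1`/`-1`, `NA` for stage-1 rejects),
#'   `decision_value` (stage-2 value, `NA` for stage-1 rejects).
#' @export
two_stage_scan <- function(candidates, oneclass_model, binary_model) {
  stopifnot(inherits(oneclass_model, "editscan_model"),
            inherits(binary_model, "editscan_model"))
  if (oneclass_model$mode != "one-class" || binary_model$mode != "binary")
    stop("need a one-class model and a binary model, in that order",
         call. = FALSE)
  if (!identical(unclass(oneclass_model$dp), unclass(binary_model$dp)) ||
      !identical(unclass(oneclass_model$kp), unclass(binary_model$kp)))
    stop("models disagree on distance/kernel parameters", call. = FALSE)
  out <- candidates
  n <- nrow(out)
  out$oneclass_pass <- logical(n)
  out$binary_label <- rep(NA_integer_, n)
  out$decision_value <- rep(NA_real_, n)
  if (n == 0L) {
    message("two_stage_scan: 0 candidates")
    return(out)
  }
  p1 <- predict(oneclass_model, out$seq)
  out$oneclass_pass <- p1$label == 1L
  surv <- which(out$oneclass_pass)
  if (length(surv)) {
    p2 <- predict(binary_model, out$seq[surv])
    out$binary_label[surv] <- p2$label
    out$decision_value[surv] <- p2$decision_value
  }
  message(sprintf(
    "two_stage_scan: %d candidates -> %d one-class survivors -> %d putative editing sites",
    n, length(surv), sum(out$binary_label == 1L, na.rm = TRUE)))
  out
}

#' Write scan hits
#'
#' `tsv` carries every column; `bed` is BED6 with 0-based half-open
#' coordinates and the stage-2 decision value rescaled to an integer score
#' in `[0, 1000]` (`NA` decision values score 0). Rows are ordered by
#' (chrom, pos, strand).
#'
#' @param hits data.frame from [two_stage_scan()] or [seed_match()].
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  hits <- hits[order(hits$chrom, hits$pos, hits$strand), , drop = FALSE]
  if (format == "tsv") {
    write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    dv <- if ("decision_value" %in% names(hits)) hits$decision_value
          else rep(NA_real_, nrow(hits))
    score <- integer(nrow(hits))
    ok <- !is.na(dv)
    if (any(ok)) {
      rng <- range(dv[ok])
      score[ok] <- if (diff(rng) == 0) 500L else
        as.integer(round(1000 * (dv[ok] - rng[1L]) / diff(rng)))
    }
    bed <- data.frame(chrom = hits$chrom, start = hits$pos - 1L,
                      end = hits$pos,
                      name = sprintf("hit_%d", seq_len(nrow(hits))),
                      score = score, strand = hits$strand,
                      stringsAsFactors = FALSE)
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
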