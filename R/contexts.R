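#' Extract an adenine-centered editing-sequence context
#'
#' Returns the `(2 * flank + 1)`-mer genomic window centered on a site. For
#' minus-strand sites the reverse complement of the forward-strand window is
#' returned, so the central base is the edited adenine on its own strand
#' (a forward-strand `T` at the sampled position). T-to-C discrepancies are
#' thereby treated as A-to-I events on the opposite strand.
#'
#' @param genome named character vector or `DNAStringSet` of contigs.
#' @param chrom,pos,strand site coordinate: contig name, 1-based position,
#'   `"+"` or `"-"`. Alternatively pass a one-row data.frame as `chrom`.
#' @param flank flank length in nt on each side (>= 1); the context length
#'   is `2 * flank + 1`.
#' @return uppercase context string of length `2 * flank + 1`, center `A`.
#' @examples
#' extract_context(c(c1 = "CCCACCC"), "c1", 4, "+", flank = 2)  # "CCACC"
#' @export
extract_context <- function(genome, chrom, pos, strand = "+", flank = 20L) {
  genome <- as_genome(genome)
  if (is.data.frame(chrom)) {
    s <- validate_sites(chrom)
    if (nrow(s) != 1L) stop("pass one site at a time", call. = FALSE)
    pos <- s$pos; strand <- s$strand; chrom <- s$chrom
  }
  flank <- as.integer(flank)
  if (is.na(flank) || flank < 1L) stop("flank must be >= 1", call. = FALSE)
  if (!chrom %in% names(genome))
    stop("unknown contig: ", chrom, call. = FALSE)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'", call. = FALSE)
  L <- nchar(genome[[chrom]])
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L || pos > L)
    stop(sprintf("position %d outside contig %s (length %d)", pos, chrom, L),
         call. = FALSE)
  if (pos - flank < 1L || pos + flank > L)
    stop(sprintf(
      "window [%d, %d] at %s:%d(%s) crosses the contig boundary",
      pos - flank, pos + flank, chrom, pos, strand), call. = FALSE)
  ctx <- substr(genome[[chrom]], pos - flank, pos + flank)
  if (strand == "-") ctx <- revcomp(ctx)
  center <- substr(ctx, flank + 1L, flank + 1L)
  if (center != "A")
    stop(sprintf("not adenine-centered: %s:%d(%s) has center '%s'",
                 chrom, pos, strand, center), call. = FALSE)
  n_frac <- lengths(regmatches(ctx, gregexpr("N", ctx))) / nchar(ctx)
  if (n_frac > 0.2)
    stop(sprintf("context at %s:%d(%s) is >20%% N", chrom, pos, strand),
         call. = FALSE)
  ctx
}

#' Extract contexts for a table of sites
#'
#' Vectorized [extract_context()]. Sites whose window crosses a contig
#' boundary, is not adenine-centered, or is more than 20% `N` are either
#' dropped (`on_error = "drop"`, the default, with a message) or raise the
#' first error (`on_error = "stop"`).
#'
#' @param genome genome as in [extract_context()].
#' @param sites data.frame with `chrom`, `pos`, `strand` (and optionally
#'   `label`).
#' @param flank flank length.
#' @param on_error `"drop"` or `"stop"`.
#' @return `sites` with a `seq` column added (dropped rows removed).
#' @export
extract_contexts <- function(genome, sites, flank = 20L,
                             on_error = c("drop", "stop")) {
  on_error <- match.arg(on_error)
  genome <- as_genome(genome)
  sites <- validate_sites(sites)
  n <- nrow(sites)
  seqs <- character(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      extract_context(genome, sites$chrom[i], sites$pos[i],
                      sites$strand[i], flank),
      error = function(e) if (on_error == "stop") stop(e) else NA_character_)
    ok[i] <- !is.na(res)
    if (ok[i]) seqs[i] <- res
  }
  if (any(!ok))
    message(sum(!ok), " of ", n, " sites dropped during context extraction")
  out <- sites[ok, , drop = FALSE]
  out$seq <- seqs[ok]
  rownames(out) <- NULL
  out
}

#' Sample background (negative) sites from a genome
#'
#' Draws one independent Bernoulli trial per genomic position per strand at
#' the given per-nucleotide rate, keeps the adenine-centered draws (forward
#' `A` for `+`, forward `T` for `-`), extracts their contexts, and discards
#' any whose sequence exactly matches a positive (excluded) context. The
#' draw is deterministic given `seed`.
#'
#' @param genome genome as in [extract_context()].
#' @param rate per-nucleotide sampling probability, in (0, 1); the default
#'   1e-4 mirrors the density of known human editing events per sequenced
#'   base.
#' @param flank flank length for the extracted contexts.
#' @param exclude character vector of context sequences to exclude (the
#'   positive set).
#' @param seed integer seed; the caller's RNG state is restored on exit.
#' @return data.frame with `chrom`, `pos`, `strand`, `seq`, `label`
#'   (`"negative"`).
#' @export
sample_negative_sites <- function(genome, rate = 1e-4, flank = 20L,
                                  exclude = character(), seed = 1L) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate <= 0 || rate >= 1)
    stop("rate must be in (0, 1)", call. = FALSE)
  genome <- as_genome(genome)
  if (sum(nchar(genome)) == 0L) stop("empty genome", call. = FALSE)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  rows <- list()
  for (chrom in names(genome)) {
    L <- nchar(genome[[chrom]])
    for (strand in c("+", "-")) {
      hit <- which(runif(L) < rate)
      if (!length(hit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, pos = hit, strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), seq = character(),
                      label = character(), stringsAsFactors = FALSE))
  cand <- do.call(rbind, rows)
  # keep adenine-centered draws: forward A on '+', forward T on '-'
  base <- substr_vec(genome, cand$chrom, cand$pos)
  keep <- (cand$strand == "+" & base == "A") |
          (cand$strand == "-" & base == "T")
  cand <- cand[keep, , drop = FALSE]
  out <- suppressMessages(extract_contexts(genome, cand, flank))
  out <- out[!out$seq %in% exclude, , drop = FALSE]
  out$label <- rep("negative", nrow(out))
  rownames(out) <- NULL
  out
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

substr_vec <- function(genome, chrom, pos) {
  vapply(seq_along(chrom),
         function(i) substr(genome[[chrom[i]]], pos[i], pos[i]),
         character(1))
}

#' Greedy identity-based redundancy filter
#'
#' Clusters equal-length sequences in input order: a sequence joins the
#' first existing representative whose identity (exact-position matches /
#' length; `N` matches nothing, itself included; maximum over the forward
#' and reverse-complement orientations when `both_strands`) is strictly
#' greater than `identity_threshold`, otherwise it founds a new cluster.
#' This reproduces the CD-HIT-EST threshold semantics (redundant when
#' identity > 0.8 with another sequence) without its alignment heuristics.
#'
#' @param seqs character vector of equal-length sequences.
#' @param identity_threshold fraction in (0, 1]; default 0.8.
#' @param both_strands compare both `+/+` and `+/-` orientations
#'   (default `TRUE`, CD-HIT-EST default behaviour here).
#' @return list with `representatives` (in founding order), `cluster`
#'   (integer id per input sequence, numbered by founding order), and
#'   `representative_index` (index into `seqs` per cluster).
#' @export
redundancy_filter <- function(seqs, identity_threshold = 0.8,
                              both_strands = TRUE) {
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]", call. = FALSE)
  seqs <- toupper(as.character(seqs))
  if (!length(seqs))
    return(list(representatives = character(), cluster = integer(),
                representative_index = integer()))
  rep_idx <- .greedy_cluster_cpp(seqs, identity_threshold, both_strands)
  reps <- unique(rep_idx)
  list(representatives = seqs[reps],
       cluster = match(rep_idx, reps),
       representative_index = reps)
}

#' Count cross-set similar sequences
#'
#' Counts members of `setA` similar (identity strictly above the threshold,
#' best orientation when `both_strands`) to at least one member of `setB`.
#' `setA` is not clustered internally.
#'
#' @param setA,setB character vectors of equal-length sequences.
#' @inheritParams redundancy_filter
#' @return integer count; the per-member logical vector is attached as
#'   attribute `"similar"`.
#' @export
cross_set_similarity <- function(setA, setB, identity_threshold = 0.8,
                                 both_strands = TRUE) {
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]", call. = FALSE)
  sim <- .cross_similar_cpp(toupper(as.character(setA)),
                            toupper(as.character(setB)),
                            identity_threshold, both_strands)
  structure(sum(sim), similar = sim)
}
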