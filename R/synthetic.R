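#' Motif model for planted editing sites
#'
#' The sequence signal around true editing sites in real genomes is
#' unknown; the synthetic benchmark stands in for it with the simplest
#' learnable model: a fixed adenine-centered consensus whose non-central
#' positions are independently mutated with probability
#' `per_position_mutation_prob` when an instance is planted. The central
#' `A` is always preserved.
#'
#' @param length odd motif length (the context length `L1`).
#' @param consensus optional consensus string (center must be `A`); drawn
#'   uniformly at random from `seed` when omitted.
#' @param per_position_mutation_prob per-position mutation probability in
#'   `[0, 1)`; 0.05 gives a strong signal, 0.75 erases it (a random base
#'   equals the consensus 25% of the time anyway).
#' @param seed seed for drawing a consensus when none is given.
#' @return object of class `motif_model`.
#' @export
motif_model <- function(length = 41L, consensus = NULL,
                        per_position_mutation_prob = 0.05, seed = 1L) {
  length <- as.integer(length)
  if (length %% 2L == 0L || length < 3L)
    stop("motif length must be odd and >= 3", call. = FALSE)
  p <- per_position_mutation_prob
  if (!is.numeric(p) || p < 0 || p >= 1)
    stop("per_position_mutation_prob must be in [0, 1)", call. = FALSE)
  center <- (length + 1L) %/% 2L
  if (is.null(consensus)) {
    old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
    b <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    b[center] <- "A"
    consensus <- paste(b, collapse = "")
  } else {
    consensus <- toupper(consensus)
    if (nchar(consensus) != length)
      stop("consensus length disagrees with `length`", call. = FALSE)
    if (substr(consensus, center, center) != "A")
      stop("consensus center must be 'A'", call. = FALSE)
  }
  structure(list(length = length, consensus = consensus,
                 per_position_mutation_prob = p),
            class = "motif_model")
}

#' Generate an i.i.d. random genome
#'
#' @param length total genome length in nt.
#' @param base_composition named probabilities for `A`, `C`, `G`, `T`
#'   (must sum to 1 within 1e-9).
#' @param n_contigs number of equally sized contigs (named `chr1`,
#'   `chr2`, ...).
#' @param seed integer seed; output is deterministic given it.
#' @return named character vector of contigs.
#' @export
generate_genome <- function(length = 100000L,
                            base_composition = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                            n_contigs = 1L, seed = 1L) {
  length <- as.integer(length)
  if (length < 1L) stop("genome length must be >= 1", call. = FALSE)
  bc <- base_composition[c("A", "C", "G", "T")]
  if (any(is.na(bc)) || any(bc < 0) || abs(sum(bc) - 1) > 1e-9)
    stop("base_composition must be named A/C/G/T probabilities summing to 1",
         call. = FALSE)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  sizes <- rep(length %/% n_contigs, n_contigs)
  sizes[n_contigs] <- sizes[n_contigs] + length %% n_contigs
  g <- vapply(sizes, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = bc),
          collapse = ""), character(1))
  names(g) <- paste0("chr", seq_len(n_contigs))
  g
}

#' Plant motif instances (editing sites) into a genome
#'
#' Draws `n_sites` non-overlapping windows, each on a uniformly random
#' strand, replaces the genomic window with a mutated motif instance
#' (center `A` preserved on its own strand; minus-strand plants are
#' written reverse-complemented onto the forward strand), and returns the
#' modified genome plus the truth site list in genomic order.
#'
#' @param genome genome as in [extract_context()].
#' @param motif a [motif_model()].
#' @param n_sites number of sites to plant.
#' @param seed integer seed.
#' @return list with `genome` (modified) and `sites` (data.frame `chrom`,
#'   `pos`, `strand`, `seq` — the planted context on its own strand,
#'   `label = "positive"`).
#' @export
plant_sites <- function(genome, motif, n_sites, seed = 1L) {
  stopifnot(inherits(motif, "motif_model"))
  genome <- as_genome(genome)
  L <- motif$length
  flank <- (L - 1L) %/% 2L
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  # candidate centers per contig, kept non-overlapping greedily
  avail <- lapply(genome, function(s) {
    n <- nchar(s)
    if (n < L) integer() else seq.int(flank + 1L, n - flank)
  })
  total <- sum(lengths(avail))
  if (total < n_sites * L)
    stop("genome too small to place the requested sites without overlap",
         call. = FALSE)
  placed <- list()
  occupied <- lapply(genome, function(s) logical(nchar(s)))
  tries <- 0L
  while (length(placed) < n_sites) {
    if ((tries <- tries + 1L) > 50L * n_sites)
      stop("could not place sites without overlap; genome too crowded",
           call. = FALSE)
    chrom <- sample(names(genome), 1L,
                    prob = pmax(lengths(avail), 1e-9))
    cand <- avail[[chrom]]
    if (!length(cand)) next
    pos <- cand[sample.int(length(cand), 1L)]
    win <- seq.int(pos - flank, pos + flank)
    if (any(occupied[[chrom]][win])) next
    occupied[[chrom]][win] <- TRUE
    strand <- sample(c("+", "-"), 1L)
    inst <- mutate_consensus(motif)
    fwd <- if (strand == "+") inst else revcomp(inst)
    substr(genome[[chrom]], pos - flank, pos + flank) <- fwd
    placed[[length(placed) + 1L]] <- data.frame(
      chrom = chrom, pos = pos, strand = strand, seq = inst,
      label = "positive", stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, placed)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  list(genome = genome, sites = sites)
}

# one mutated instance of the consensus; center A is never touched
mutate_consensus <- function(motif) {
  b <- strsplit(motif$consensus, "")[[1L]]
  center <- (motif$length + 1L) %/% 2L
  hit <- which(runif(motif$length) < motif$per_position_mutation_prob)
  hit <- setdiff(hit, center)
  for (i in hit)
    b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  paste(b, collapse = "")
}

#' Build a complete synthetic benchmark
#'
#' Composes [generate_genome()], [plant_sites()], [extract_contexts()] and
#' [sample_negative_sites()] into a ready train/test bundle: a genome with
#' planted motif-carrying editing sites, the positive contexts, and
#' background negatives sampled at the stated per-nucleotide rate. Fully
#' deterministic given the single `seed` (internal seeds are derived from
#' it).
#'
#' @param genome_length genome size in nt (default 200 kb — desk scale).
#' @param n_sites planted positive sites (default 150).
#' @param motif a [motif_model()]; default strong signal
#'   (`per_position_mutation_prob = 0.05`) at `L1 = 41`.
#' @param rate negative per-nucleotide sampling rate (default 1e-4; at the
#'   default genome size this yields far fewer negatives than a real
#'   genome would — raise it for balanced desk-scale sets).
#' @param base_composition genome base composition.
#' @param seed master seed.
#' @return list with `genome`, `pos` (positive context data.frame),
#'   `neg` (negative context data.frame), `motif`, and `config`.
#' @export
make_benchmark <- function(genome_length = 200000L, n_sites = 150L,
                           motif = motif_model(41L), rate = 2e-3,
                           base_composition = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25),
                           seed = 1L) {
  seed <- as.integer(seed)
  flank <- (motif$length - 1L) %/% 2L
  g0 <- generate_genome(genome_length, base_composition, seed = seed)
  pl <- plant_sites(g0, motif, n_sites, seed = seed + 1L)
  pos <- suppressMessages(
    extract_contexts(pl$genome, pl$sites[c("chrom", "pos", "strand")],
                     flank))
  pos$label <- "positive"
  neg <- sample_negative_sites(pl$genome, rate = rate, flank = flank,
                               exclude = pos$seq, seed = seed + 2L)
  list(genome = pl$genome, pos = pos, neg = neg, motif = motif,
       config = list(genome_length = genome_length, n_sites = n_sites,
                     rate = rate, base_composition = base_composition,
                     seed = seed))
}
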