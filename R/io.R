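#' Load a genome from FASTA
#'
#' Reads a (possibly multi-record, line-wrapped) FASTA file and returns the
#' genome as a named uppercase character vector, one element per contig.
#' Record names are truncated at the first whitespace, matching common
#' chromosome-naming practice.
#'
#' @param path path to a `.fa` / `.fasta` file.
#' @return named character vector of uppercase contig sequences.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(ss))
  names(g) <- sub("\\s.*$", "", names(ss))
  g
}

#' Write a genome to FASTA
#'
#' @param genome named character vector (or `DNAStringSet`) of contigs.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  genome <- as_genome(genome)
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# Normalize a genome argument: named uppercase character vector.
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    g <- toupper(as.character(genome))
    names(g) <- sub("\\s.*$", "", names(genome))
    return(g)
  }
  if (is.character(genome)) {
    if (is.null(names(genome)) || any(names(genome) == ""))
      stop("genome contigs must be named", call. = FALSE)
    return(toupper(genome))
  }
  stop("genome must be a named character vector or DNAStringSet",
       call. = FALSE)
}

#' Read a site list
#'
#' Sites are 1-based, strand-aware genomic coordinates of (putative) editing
#' adenines, in a TSV with columns `chrom`, `pos`, `strand` and an optional
#' `label` column; lines starting with `#` are comments. A header line is
#' detected automatically.
#'
#' @param path TSV path.
#' @return data.frame with columns `chrom` (character), `pos` (integer,
#'   1-based), `strand` (`"+"`/`"-"`), and `label` if present.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("site file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  first <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  header <- suppressWarnings(is.na(as.integer(first[2L])))
  df <- read.delim(text = paste(lines, collapse = "\n"),
                   header = header, stringsAsFactors = FALSE)
  if (!header) {
    nm <- c("chrom", "pos", "strand", "label")[seq_len(ncol(df))]
    names(df) <- nm
  }
  validate_sites(df)
}

validate_sites <- function(df) {
  need <- c("chrom", "pos", "strand")
  if (!all(need %in% names(df)))
    stop("site table needs columns chrom, pos, strand", call. = FALSE)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  if (any(is.na(df$pos)) || any(df$pos < 1L))
    stop("site pos must be integers >= 1 (1-based)", call. = FALSE)
  df$strand <- as.character(df$strand)
  if (!all(df$strand %in% c("+", "-")))
    stop("site strand must be '+' or '-'", call. = FALSE)
  df
}

#' Write a site list as TSV
#'
#' @param sites data.frame with `chrom`, `pos`, `strand` and optionally
#'   `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  sites <- validate_sites(sites)
  keep <- intersect(c("chrom", "pos", "strand", "seq", "label"),
                    names(sites))
  write.table(sites[keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write sites as BED6
#'
#' Coordinates are converted from the 1-based site convention to BED's
#' 0-based half-open intervals (`pos - 1`, `pos`).
#'
#' @param sites data.frame with `chrom`, `pos`, `strand`; optional `name`
#'   and `score` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  sites <- validate_sites(sites)
  name <- if ("name" %in% names(sites)) sites$name else
    sprintf("site_%d", seq_len(nrow(sites)))
  score <- if ("score" %in% names(sites)) sites$score else 0L
  bed <- data.frame(chrom = sites$chrom, start = sites$pos - 1L,
                    end = sites$pos, name = name, score = score,
                    strand = sites$strand, stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read context sequences (seeds)
#'
#' Accepts plain FASTA or one-sequence-per-line text; returns uppercase
#' sequences.
#'
#' @param path input path.
#' @return character vector of sequences.
#' @export
read_seeds <- function(path) {
  if (!file.exists(path)) stop("seed file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && startsWith(trimws(lines[1L]), ">")) {
    g <- read_genome(path)
    return(unname(g))
  }
  toupper(trimws(lines))
}

#' Reverse complement
#'
#' @param x character vector of DNA strings (`A`,`C`,`G`,`T`; anything else
#'   becomes `N`).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) .revcomp_cpp(toupper(as.character(x)))
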