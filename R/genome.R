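#' Genome container
#'
#' A genome is an ordered set of named chromosome sequences over
#' \{A,C,G,T,N\}, stored uppercase, addressed with 0-based half-open
#' coordinates.
#'
#' @param sequences named character vector or list of DNA sequences.
#' @param assembly_tag short label for the assembly (e.g. `"WS260"`); used to
#'   guard against mixing indexes built on different genomes.
#' @return an object of class `"Genome"`.
#' @export
#' @examples
#' g <- Genome(c(I = "ACGTACGT", II = "GGGGCCCC"), assembly_tag = "toy")
#' chrom_lengths(g)
Genome <- function(sequences, assembly_tag = "custom") {
  sequences <- unlist(sequences)
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("all chromosome sequences must be named", call. = FALSE)
  if (anyDuplicated(names(sequences)))
    stop("chromosome names must be unique", call. = FALSE)
  sequences <- toupper(sequences)
  assert_dna(sequences, what = "chromosome sequence")
  structure(list(sequences = sequences,
                 assembly_tag = as.character(assembly_tag)),
            class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("Genome <%s>: %d chromosome(s), %s bp total\n",
              x$assembly_tag, length(x$sequences),
              format(sum(nchar(x$sequences)), big.mark = ",")))
  for (nm in names(x$sequences))
    cat(sprintf("  %s  %s bp\n", nm,
                format(nchar(x$sequences[[nm]]), big.mark = ",")))
  invisible(x)
}

#' @rdname Genome
#' @param genome a `Genome`.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "Genome"))
  setNames(nchar(genome$sequences), names(genome$sequences))
}

#' Extract genome sequence on a 0-based half-open interval
#'
#' @param genome a [Genome()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bounds, `0 <= start <= end <= length`.
#' @return character scalar.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "Genome"))
  if (!chrom %in% names(genome$sequences))
    stop(sprintf("unknown chromosome '%s'", chrom), call. = FALSE)
  len <- nchar(genome$sequences[[chrom]])
  if (!is_count(start) || !is.numeric(end) || start > end || end > len)
    stop(sprintf("interval [%s, %s) out of bounds for %s (length %d)",
                 format(start), format(end), chrom, len), call. = FALSE)
  seq_slice(genome$sequences[[chrom]], start, end)
}

#' Genomic interval (0-based half-open)
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bounds with `end > start`
#'   (`end == start` is allowed only for point insertions).
#' @param strand one of `"+"`, `"-"`, `"."`.
#' @return an object of class `"GenomicInterval"` (a small list).
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  if (!is_count(start) || !is.numeric(end) || end < start)
    stop("invalid interval bounds", call. = FALSE)
  if (!strand %in% c("+", "-", "."))
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  structure(list(chrom = as.character(chrom), start = as.integer(start),
                 end = as.integer(end), strand = strand),
            class = "GenomicInterval")
}

#' @export
print.GenomicInterval <- function(x, ...) {
  cat(sprintf("GenomicInterval %s:[%d, %d) %s\n",
              x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

check_interval <- function(genome, interval) {
  stopifnot(inherits(interval, "GenomicInterval"))
  lens <- chrom_lengths(genome)
  if (!interval$chrom %in% names(lens))
    stop(sprintf("unknown chromosome '%s'", interval$chrom), call. = FALSE)
  if (interval$end > lens[[interval$chrom]])
    stop(sprintf("interval end %d beyond %s length %d",
                 interval$end, interval$chrom, lens[[interval$chrom]]),
         call. = FALSE)
  invisible(interval)
}

#' Read a FASTA file into a Genome
#'
#' Residues are uppercased on read (soft-masked input is accepted, not
#' excluded). Characters outside \{A,C,G,T,N\} are rejected with an error
#' naming the offending line.
#'
#' @param path FASTA file, optionally line-wrapped.
#' @param assembly_tag assembly label to attach, see [Genome()].
#' @return a [Genome()].
#' @export
read_fasta <- function(path, assembly_tag = basename(path)) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) | seq_along(lines) < length(lines)
  names_ <- character(0)
  seqs <- character(0)
  cur <- NULL
  cur_chunks <- character(0)
  cur_line <- NA_integer_
  flush <- function() {
    if (is.null(cur)) return()
    s <- paste(cur_chunks, collapse = "")
    if (nchar(s) == 0L)
      stop(sprintf("FASTA format error: empty sequence for record '%s' (line %d)",
                   cur, cur_line), call. = FALSE)
    names_[[length(names_) + 1L]] <<- cur
    seqs[[length(seqs) + 1L]] <<- s
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^>", ln)) {
      nm <- sub("^>\\s*", "", ln)
      nm <- sub("\\s.*$", "", nm)
      if (nchar(nm) == 0L)
        stop(sprintf("FASTA format error: malformed header at line %d", i),
             call. = FALSE)
      flush()
      cur <- nm
      cur_chunks <- character(0)
      cur_line <- i
    } else if (grepl("^\\s*$", ln)) {
      next
    } else {
      if (is.null(cur))
        stop(sprintf("FASTA format error: sequence before any header at line %d", i),
             call. = FALSE)
      s <- toupper(gsub("\\s", "", ln))
      if (!grepl("^[ACGTN]*$", s))
        stop(sprintf("FASTA format error: invalid residue at line %d (only A,C,G,T,N allowed)", i),
             call. = FALSE)
      cur_chunks[[length(cur_chunks) + 1L]] <- s
    }
  }
  if (is.null(cur))
    stop("FASTA format error: no records found", call. = FALSE)
  flush()
  Genome(setNames(seqs, names_), assembly_tag = assembly_tag)
}

#' Write sequences as FASTA
#'
#' @param x a [Genome()] or a named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  seqs <- if (inherits(x, "Genome")) x$sequences else unlist(x)
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}
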