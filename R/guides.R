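#' Guide filter configuration
#'
#' Defaults encode the production filter cascade: GC content within
#' \[20%, 80%\] (bounds inclusive), no poly-T tract of length five or more on
#' the protospacer, a 12-mer-plus-PAM seed unique in the genome, and a unique
#' genome placement when allowing an edit distance of three. The GG-3'-end
#' flag and the folding energy are annotations, not filters, unless
#' `mfe_min` is set by the user.
#'
#' @param gc_min,gc_max inclusive GC-fraction bounds.
#' @param polyt_len minimum poly-T run length that disqualifies a guide.
#' @param seed_len number of PAM-proximal protospacer bases in the seed.
#' @param pam PAM pattern; only `"NGG"` (SpCas9) is supported.
#' @param max_edits Levenshtein distance allowed in the off-target scan.
#' @param guide_len protospacer length.
#' @param mfe_min optional folding-energy floor in kcal/mol; guides folding
#'   below it are excluded when the constraint is applied.
#' @return a list of class `"FilterConfig"`.
#' @export
filter_config <- function(gc_min = 0.20, gc_max = 0.80, polyt_len = 5L,
                          seed_len = 12L, pam = "NGG", max_edits = 3L,
                          guide_len = 20L, mfe_min = NULL) {
  stopifnot(gc_min >= 0, gc_min < gc_max, gc_max <= 1,
            is_count(polyt_len, 1L), is_count(seed_len, 1L),
            seed_len <= guide_len, is_count(max_edits), is_count(guide_len, 1L))
  if (!identical(pam, "NGG"))
    stop("only the SpCas9 'NGG' PAM is supported", call. = FALSE)
  structure(list(gc_min = gc_min, gc_max = gc_max,
                 polyt_len = as.integer(polyt_len),
                 seed_len = as.integer(seed_len), pam = pam,
                 max_edits = as.integer(max_edits),
                 guide_len = as.integer(guide_len), mfe_min = mfe_min),
            class = "FilterConfig")
}

#' GC fraction of a DNA sequence
#'
#' @param seq character vector of sequences over \{A,C,G,T\}.
#' @return numeric vector, `(#G + #C) / length`.
#' @export
#' @examples
#' gc_fraction("GGGGGGGGGGAAAAAAAAAA")  # 0.5
gc_fraction <- function(seq) {
  assert_dna(seq, "protospacer", allow_n = FALSE)
  n <- nchar(seq)
  if (any(n == 0L)) stop("empty sequence has no GC fraction", call. = FALSE)
  gc <- nchar(gsub("[AT]", "", seq))
  gc / n
}

#' Poly-T tract detection
#'
#' `TRUE` when the sequence contains `k` or more consecutive `T`s. Applied to
#' the protospacer in guide orientation (a run of Ts in the transcribed guide
#' acts as a Pol III terminator).
#'
#' @param seq character vector over \{A,C,G,T\}.
#' @param k minimum run length.
#' @return logical vector.
#' @export
has_polyt <- function(seq, k = 5L) {
  assert_dna(seq, "protospacer", allow_n = FALSE)
  stopifnot(is_count(k, 1L))
  grepl(strrep("T", k), seq, fixed = TRUE)
}

#' GG at the guide 3' end
#'
#' Annotation only (GG-ending guides tend to cut more efficiently); it never
#' changes the pass/fail status of a candidate.
#'
#' @param protospacer character vector of 20-mers.
#' @return logical vector.
#' @export
gg_end <- function(protospacer) {
  if (any(nchar(protospacer) != 20L))
    stop("protospacer must be 20 bases", call. = FALSE)
  substr(protospacer, 19L, 20L) == "GG"
}

#' Enumerate all Cas9 guide candidates in a genome
#'
#' Every position on either strand where an `NGG` PAM follows a full 20-mer
#' protospacer yields one candidate. Candidates whose 23-mer site contains
#' `N` are dropped. The cut position is 3 bp 5' of the PAM (blunt,
#' strand-aware), reported as the 0-based coordinate of the base immediately
#' 3' of the cut on the forward strand.
#'
#' @param genome a [Genome()].
#' @param config a [filter_config()].
#' @param region optional [genomic_interval()]: bound the scan to the region
#'   (padded by one site length so edge-overlapping candidates are kept).
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `protospacer`, `pam`, `cut_pos`, sorted by (chromosome order, start,
#'   strand `+` before `-`).
#' @export
enumerate_candidates <- function(genome, config = filter_config(),
                                 region = NULL) {
  stopifnot(inherits(genome, "Genome"))
  gl <- config$guide_len
  site_len <- gl + 3L
  out <- vector("list", length(genome$sequences))
  chroms <- names(genome$sequences)
  for (ci in seq_along(chroms)) {
    chrom <- chroms[[ci]]
    s <- genome$sequences[[chrom]]
    off <- 0L
    if (!is.null(region)) {
      if (region$chrom != chrom) next
      lo <- max(0L, region$start - site_len)
      hi <- min(nchar(s), region$end + site_len)
      s <- seq_slice(s, lo, hi)
      off <- lo
    }
    n <- nchar(s)
    if (n < site_len) next
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    gg <- which(ch[-n] == "G" & ch[-1L] == "G")       # i: first G of "GG"
    cc <- which(ch[-n] == "C" & ch[-1L] == "C")       # i: first C of "CC"
    # forward: PAM N at q = i - 1, protospacer [q-gl, q-1] (1-based)
    q <- gg - 1L
    q <- q[q >= gl + 1L & q + 2L <= n]
    fwd <- NULL
    if (length(q)) {
      fwd <- data.frame(
        chrom = chrom, start = off + q - gl - 1L, end = off + q + 2L,
        strand = "+",
        protospacer = substring(s, q - gl, q - 1L),
        pam = substring(s, q, q + 2L),
        stringsAsFactors = FALSE)
      fwd$cut_pos <- fwd$start + gl - 3L
    }
    # reverse: site begins with "CCN" at i; protospacer revcomp of [i+3, i+gl+2]
    i <- cc[cc + site_len - 1L <= n]
    rev <- NULL
    if (length(i)) {
      rev <- data.frame(
        chrom = chrom, start = off + i - 1L, end = off + i + site_len - 1L,
        strand = "-",
        protospacer = revcomp(substring(s, i + 3L, i + site_len - 1L)),
        pam = revcomp(substring(s, i, i + 2L)),
        stringsAsFactors = FALSE)
      rev$cut_pos <- rev$start + 6L
    }
    cand <- rbind(fwd, rev)
    if (is.null(cand) || nrow(cand) == 0L) next
    site23 <- paste0(cand$protospacer, cand$pam)
    cand <- cand[!grepl("N", site23, fixed = TRUE), , drop = FALSE]
    out[[ci]] <- cand
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      protospacer = character(0), pam = character(0),
                      cut_pos = integer(0), stringsAsFactors = FALSE))
  res <- res[order(match(res$chrom, chroms), res$start,
                   match(res$strand, c("+", "-"))), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Seed uniqueness index
#'
#' Indexes every occurrence, on both strands, of the 15-position seed context
#' `[12 bases][N][G][G]` (12 PAM-proximal protospacer bases followed by the
#' PAM, whose first base is a wildcard -- 14 informative bases). Used to
#' eliminate guides whose seed occurs more than once in the genome.
#'
#' @param genome a [Genome()].
#' @param config a [filter_config()].
#' @return an object of class `"SeedIndex"`.
#' @export
build_seed_index <- function(genome, config = filter_config()) {
  stopifnot(inherits(genome, "Genome"))
  sl <- config$seed_len
  keys <- character(0)
  for (chrom in names(genome$sequences)) {
    s <- genome$sequences[[chrom]]
    n <- nchar(s)
    if (n < sl + 3L) next
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    gg <- which(ch[-n] == "G" & ch[-1L] == "G")
    cc <- which(ch[-n] == "C" & ch[-1L] == "C")
    # forward GG at (i, i+1): seed 12-mer at [i - sl - 1, i - 2]
    i <- gg[gg >= sl + 2L]
    if (length(i)) keys <- c(keys, substring(s, i - sl - 1L, i - 2L))
    # reverse CC at (i, i+1): seed context revcomp of [i + 3, i + sl + 2]
    i <- cc[cc + sl + 2L <= n]
    if (length(i)) keys <- c(keys, revcomp(substring(s, i + 3L, i + sl + 2L)))
  }
  keys <- keys[!grepl("N", keys, fixed = TRUE)]
  counts <- table(keys)
  env <- new.env(parent = emptyenv(), size = max(1L, length(counts)))
  for (k in seq_along(counts))
    assign(names(counts)[k], as.integer(counts[[k]]), envir = env)
  structure(list(counts = env, seed_len = sl,
                 assembly_tag = genome$assembly_tag),
            class = "SeedIndex")
}

#' @rdname build_seed_index
#' @param index a `SeedIndex`.
#' @param candidates candidate data.frame from [enumerate_candidates()], or a
#'   character vector of protospacers.
#' @param genome the genome the candidates came from; its `assembly_tag` must
#'   match the one the index was built on.
#' @return integer vector of genome-wide seed occurrence counts (>= 1 for
#'   candidates extracted from the indexed genome).
#' @export
seed_count <- function(index, candidates, genome = NULL) {
  stopifnot(inherits(index, "SeedIndex"))
  if (!is.null(genome) && !identical(genome$assembly_tag, index$assembly_tag))
    stop(sprintf("seed index built on '%s' but genome is '%s'",
                 index$assembly_tag, genome$assembly_tag), call. = FALSE)
  proto <- if (is.data.frame(candidates)) candidates$protospacer
           else candidates
  sl <- index$seed_len
  keys <- substr(proto, nchar(proto) - sl + 1L, nchar(proto))
  vapply(keys, function(k) {
    v <- get0(k, envir = index$counts, ifnotfound = 0L)
    v
  }, integer(1), USE.NAMES = FALSE)
}

# number of distinct sites given qualifying alignment end positions:
# runs of end positions separated by gaps <= max_edits collapse to one site
collapse_end_positions <- function(ends, max_edits) {
  if (length(ends) == 0L) return(0L)
  sum(diff(sort(ends)) > max_edits) + 1L
}

#' Genome-wide off-target placement count
#'
#' Counts the genomic sites, on either strand, whose local alignment to the
#' guide-plus-PAM 23-mer has Levenshtein distance at most `max_edits`
#' (substitutions and indels; the PAM `N` matches any base for free). The
#' on-target site counts once, so a specific guide returns 1; guides with a
#' count above 1 map to multiple locations and are eliminated by the cascade.
#' The scan is full-sensitivity (every offset of every chromosome, both
#' strands).
#'
#' @param genome a [Genome()].
#' @param candidates candidate data.frame from [enumerate_candidates()], or a
#'   character vector of 23-mer `protospacer + PAM` strings.
#' @param config a [filter_config()].
#' @return integer vector of site counts, one per candidate.
#' @export
genome_hits <- function(genome, candidates, config = filter_config()) {
  stopifnot(inherits(genome, "Genome"))
  sites <- if (is.data.frame(candidates))
    paste0(candidates$protospacer, candidates$pam) else candidates
  gl <- config$guide_len
  patterns <- sites
  substr(patterns, gl + 1L, gl + 1L) <- "N"   # PAM N is a wildcard
  texts <- character(0)
  for (chrom in names(genome$sequences)) {
    s <- genome$sequences[[chrom]]
    texts <- c(texts, s, revcomp(s))
  }
  vapply(patterns, function(p) {
    total <- 0L
    for (tx in texts) {
      ends <- .edit_end_positions(tx, p, config$max_edits)
      total <- total + collapse_end_positions(ends, config$max_edits)
    }
    total
  }, integer(1), USE.NAMES = FALSE)
}

#' Annotate guide cut sites with the targeted gene feature
#'
#' Labels each cut position with the highest-priority overlapping feature
#' (`CDS` > UTRs > `exon` > `intron` > `ncRNA` > `intergenic`).
#'
#' @param candidates data.frame with columns `chrom` and `cut_pos`.
#' @param features a [FeatureSet()].
#' @return the input data.frame with `feature` and `gene` columns added.
#' @export
annotate_cut <- function(candidates, features) {
  ann <- lapply(seq_len(nrow(candidates)), function(i)
    annotate_position(features, candidates$chrom[i], candidates$cut_pos[i]))
  candidates$feature <- vapply(ann, `[[`, character(1), "label")
  candidates$gene <- vapply(ann, `[[`, character(1), "public_name")
  candidates
}

#' Design guide RNAs for a target region
#'
#' Enumerates candidates whose cut site falls inside `target`, computes every
#' cascade metric and annotation, and sets the `passes` flag:
#' `gc_min <= GC <= gc_max`, no poly-T tract, `seed_count == 1` and
#' `genome_hits == 1`. Optional user constraints (`require_gg`,
#' `config$mfe_min`) subset the returned table on top of the cascade.
#'
#' @param genome a [Genome()].
#' @param features a [FeatureSet()] or `NULL` (features then reported as
#'   `intergenic`).
#' @param target a [genomic_interval()] or query string for [resolve_query()].
#' @param config a [filter_config()].
#' @param require_gg keep only guides ending in GG.
#' @param seed_index optional precomputed [build_seed_index()] for `genome`.
#' @return guide table data.frame with columns `chrom`, `start`, `end`,
#'   `strand`, `protospacer`, `pam`, `gc`, `polyT`, `gg_end`, `seed_count`,
#'   `genome_hits`, `mfe`, `cut_pos`, `feature`, `passes`, deterministically
#'   ordered.
#' @export
design_guides <- function(genome, features, target, config = filter_config(),
                          require_gg = FALSE, seed_index = NULL) {
  if (is.character(target))
    target <- resolve_query(features, genome, target)
  check_interval(genome, target)
  cand <- enumerate_candidates(genome, config, region = target)
  cand <- cand[cand$cut_pos >= target$start & cand$cut_pos < target$end, ,
               drop = FALSE]
  if (nrow(cand) == 0L) {
    empty <- cand
    for (col in c("gc", "mfe")) empty[[col]] <- numeric(0)
    for (col in c("polyT", "gg_end", "passes")) empty[[col]] <- logical(0)
    for (col in c("seed_count", "genome_hits")) empty[[col]] <- integer(0)
    empty$feature <- character(0)
    return(empty[guide_table_columns])
  }
  if (is.null(seed_index)) seed_index <- build_seed_index(genome, config)
  cand$gc <- gc_fraction(cand$protospacer)
  cand$polyT <- has_polyt(cand$protospacer, config$polyt_len)
  cand$gg_end <- gg_end(cand$protospacer)
  cand$seed_count <- seed_count(seed_index, cand, genome)
  cand$genome_hits <- genome_hits(genome, cand, config)
  cand$mfe <- vapply(cand$protospacer, fold_mfe, numeric(1), USE.NAMES = FALSE)
  if (is.null(features)) {
    cand$feature <- "intergenic"
    cand$gene <- NA_character_
  } else {
    cand <- annotate_cut(cand, features)
  }
  cand$passes <- cand$gc >= config$gc_min & cand$gc <= config$gc_max &
    !cand$polyT & cand$seed_count == 1L & cand$genome_hits == 1L
  if (require_gg) cand <- cand[cand$gg_end, , drop = FALSE]
  if (!is.null(config$mfe_min))
    cand <- cand[cand$mfe >= config$mfe_min, , drop = FALSE]
  rownames(cand) <- NULL
  cand[guide_table_columns]
}

guide_table_columns <- c("chrom", "start", "end", "strand", "protospacer",
                         "pam", "gc", "polyT", "gg_end", "seed_count",
                         "genome_hits", "mfe", "cut_pos", "feature", "passes")

#' Write or read a guide table as TSV
#'
#' @param guides guide table from [design_guides()].
#' @param path file path.
#' @return `path` (write) or the guide table (read).
#' @export
write_guide_table <- function(guides, path) {
  write.table(guides[intersect(guide_table_columns, names(guides))], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_guide_table
#' @export
read_guide_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Export guides as BED6
#'
#' 0-based half-open BED with `name = protospacer_PAM`, `score = 0` and the
#' guide strand.
#'
#' @param guides guide table with columns `chrom`, `start`, `end`, `strand`,
#'   `protospacer`, `pam`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(guides, path) {
  bed <- data.frame(chrom = guides$chrom, start = guides$start,
                    end = guides$end,
                    name = if (nrow(guides))
                      paste0(guides$protospacer, "_", guides$pam)
                    else character(0),
                    score = rep(0L, nrow(guides)), strand = guides$strand,
                    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
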