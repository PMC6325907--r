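#' Gene feature set
#'
#' Container for gene models: a gene table and a typed feature interval table
#' (`CDS`, `exon`, `intron`, `five_prime_UTR`, `three_prime_UTR`, `ncRNA`).
#' All coordinates are 0-based half-open. Gene lookup by name or ID is
#' case-insensitive.
#'
#' @param genes data.frame with columns `gene_id`, `public_name`, `chrom`,
#'   `start`, `end`, `strand`.
#' @param features data.frame with columns `gene_id`, `type`, `chrom`,
#'   `start`, `end`, `strand`.
#' @return an object of class `"FeatureSet"`.
#' @export
FeatureSet <- function(genes, features) {
  need_g <- c("gene_id", "public_name", "chrom", "start", "end", "strand")
  need_f <- c("gene_id", "type", "chrom", "start", "end", "strand")
  stopifnot(all(need_g %in% names(genes)), all(need_f %in% names(features)))
  ok_types <- c("CDS", "exon", "intron", "five_prime_UTR", "three_prime_UTR",
                "ncRNA")
  bad <- setdiff(unique(features$type), ok_types)
  if (length(bad))
    stop("unknown feature type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(genes = genes[need_g], features = features[need_f]),
            class = "FeatureSet")
}

#' @export
print.FeatureSet <- function(x, ...) {
  cat(sprintf("FeatureSet: %d gene(s), %d feature interval(s)\n",
              nrow(x$genes), nrow(x$features)))
  invisible(x)
}

first_or_na <- function(x) {
  vapply(x, function(v) if (length(v)) as.character(v[[1]]) else NA_character_,
         character(1))
}

#' Read gene models from GFF3
#'
#' Parsing is delegated to [rtracklayer::import()]; the three-level
#' gene/transcript/child hierarchy is flattened into a [FeatureSet()] with
#' per-gene unions of each feature type. Introns are derived per transcript
#' as the gaps between its exons. 1-based closed GFF coordinates are
#' converted to 0-based half-open. Child features whose parent cannot be
#' resolved trigger a warning and are skipped.
#'
#' @param path GFF3 file.
#' @return a [FeatureSet()].
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,        # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    id = if ("ID" %in% names(md)) as.character(md$ID) else NA_character_,
    name = if ("Name" %in% names(md)) as.character(md$Name) else NA_character_,
    parent = if ("Parent" %in% names(md)) first_or_na(md$Parent)
             else NA_character_,
    stringsAsFactors = FALSE)
  df$strand[!df$strand %in% c("+", "-")] <- "."

  tx_types <- c("mRNA", "transcript", "ncRNA", "tRNA", "rRNA", "snoRNA",
                "snRNA", "miRNA", "pre_miRNA", "lincRNA", "pseudogenic_transcript")
  child_types <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")

  gene_rows <- df[df$type == "gene", , drop = FALSE]
  if (nrow(gene_rows) == 0L)
    stop("GFF3 contains no gene records", call. = FALSE)
  genes <- data.frame(
    gene_id = gene_rows$id,
    public_name = ifelse(is.na(gene_rows$name), gene_rows$id, gene_rows$name),
    chrom = gene_rows$chrom, start = gene_rows$start, end = gene_rows$end,
    strand = gene_rows$strand, stringsAsFactors = FALSE)

  tx_rows <- df[df$type %in% tx_types, , drop = FALSE]
  tx2gene <- setNames(tx_rows$parent, tx_rows$id)
  orphan_tx <- !is.na(tx2gene) & !tx2gene %in% genes$gene_id
  orphan_tx <- orphan_tx | is.na(tx2gene)
  if (any(orphan_tx)) {
    warning(sprintf("skipping %d transcript(s) without a known parent gene",
                    sum(orphan_tx)), call. = FALSE)
    tx2gene <- tx2gene[!orphan_tx]
  }
  tx_coding <- setNames(tx_rows$type %in% c("mRNA", "transcript"), tx_rows$id)

  ch <- df[df$type %in% child_types, , drop = FALSE]
  known_parent <- ch$parent %in% names(tx2gene) | ch$parent %in% genes$gene_id
  if (any(!known_parent)) {
    warning(sprintf("skipping %d feature(s) without a known parent",
                    sum(!known_parent)), call. = FALSE)
    ch <- ch[known_parent, , drop = FALSE]
  }
  ch$gene_id <- ifelse(ch$parent %in% names(tx2gene),
                       unname(tx2gene[ch$parent]), ch$parent)
  # exons of non-coding transcripts become ncRNA intervals
  noncoding_parent <- ch$parent %in% names(tx_coding) & !tx_coding[ch$parent]
  ch$ftype <- ch$type
  ch$ftype[ch$type == "exon" & noncoding_parent] <- "ncRNA"

  feats <- data.frame(gene_id = ch$gene_id, type = ch$ftype, chrom = ch$chrom,
                      start = ch$start, end = ch$end, strand = ch$strand,
                      stringsAsFactors = FALSE)

  # introns: gaps between exons, per transcript
  ex <- ch[ch$type == "exon", , drop = FALSE]
  if (nrow(ex)) {
    by_tx <- split(ex, ex$parent)
    intr <- lapply(by_tx, function(e) {
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) < 2L) return(NULL)
      data.frame(gene_id = e$gene_id[1L], type = "intron",
                 chrom = e$chrom[1L],
                 start = e$end[-nrow(e)], end = e$start[-1L],
                 strand = e$strand[1L], stringsAsFactors = FALSE)
    })
    intr <- do.call(rbind, intr)
    if (!is.null(intr) && nrow(intr))
      feats <- rbind(feats, intr[intr$end > intr$start, , drop = FALSE])
  }

  # union intervals per (gene, type)
  feats <- reduce_features(feats)
  FeatureSet(genes, feats)
}

# merge overlapping intervals within (gene_id, type, chrom, strand)
reduce_features <- function(feats) {
  if (nrow(feats) == 0L) return(feats)
  key <- paste(feats$gene_id, feats$type, feats$chrom, feats$strand,
               sep = "\r")
  parts <- lapply(split(seq_len(nrow(feats)), key), function(idx) {
    f <- feats[idx, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(f$start + 1L, f$end))
    data.frame(gene_id = f$gene_id[1L], type = f$type[1L], chrom = f$chrom[1L],
               start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
               strand = f$strand[1L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$gene_id, out$type, out$start), , drop = FALSE]
}

#' Write a FeatureSet as GFF3
#'
#' Emits gene, mRNA, exon, CDS and UTR records (one synthetic transcript per
#' gene); introns are left implicit as exon gaps, matching what [read_gff3()]
#' derives.
#'
#' @param features a [FeatureSet()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  stopifnot(inherits(features, "FeatureSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- features$genes
  f <- features$features
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    line <- function(type, start, end, id, parent = NULL, name = NULL) {
      attrs <- paste0("ID=", id)
      if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
      if (!is.null(name)) attrs <- paste0(attrs, ";Name=", name)
      sprintf("%s\tcrisprworm\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom[i], type, start + 1L, end, g$strand[i], attrs)
    }
    writeLines(line("gene", g$start[i], g$end[i], gid, name = g$public_name[i]),
               con)
    tid <- paste0(gid, ".t1")
    fi <- f[f$gene_id == gid & f$type != "intron", , drop = FALSE]
    is_nc <- nrow(fi) > 0L && all(fi$type == "ncRNA")
    writeLines(line(if (is_nc) "ncRNA" else "mRNA", g$start[i], g$end[i], tid,
                    parent = gid), con)
    k <- 0L
    for (j in seq_len(nrow(fi))) {
      k <- k + 1L
      type <- if (fi$type[j] == "ncRNA") "exon" else fi$type[j]
      writeLines(line(type, fi$start[j], fi$end[j],
                      paste0(tid, ".", type, k), parent = tid), con)
    }
  }
  invisible(path)
}

#' Resolve a user target query to a genomic interval
#'
#' Accepts either a `chrom:start-end` string in the 1-based inclusive browser
#' dialect, or a gene name / gene ID (case-insensitive).
#'
#' @param features a [FeatureSet()] (may be `NULL` for pure interval queries).
#' @param genome a [Genome()].
#' @param query query string.
#' @return a [genomic_interval()]; for gene queries, the gene's span and
#'   strand.
#' @export
#' @examples
#' g <- Genome(c(I = strrep("ACGT", 100)))
#' resolve_query(NULL, g, "I:101-200")
resolve_query <- function(features, genome, query) {
  stopifnot(is.character(query), length(query) == 1L)
  m <- regmatches(query, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", query))[[1]]
  if (length(m) == 4L) {
    chrom <- m[2]
    s1 <- as.numeric(gsub(",", "", m[3]))
    e1 <- as.numeric(gsub(",", "", m[4]))
    lens <- chrom_lengths(genome)
    if (!chrom %in% names(lens))
      stop(sprintf("unknown chromosome '%s' in interval query", chrom),
           call. = FALSE)
    if (s1 < 1 || e1 < s1)
      stop(sprintf("malformed interval '%s': need 1 <= start <= end", query),
           call. = FALSE)
    if (e1 > lens[[chrom]])
      stop(sprintf("interval '%s' out of bounds (chromosome length %d)",
                   query, lens[[chrom]]), call. = FALSE)
    return(genomic_interval(chrom, s1 - 1, e1))
  }
  if (grepl(":", query, fixed = TRUE))
    stop(sprintf("malformed interval query '%s' (expected chrom:start-end)",
                 query), call. = FALSE)
  if (is.null(features))
    stop("gene-name query requires gene models", call. = FALSE)
  g <- features$genes
  hit <- which(tolower(g$public_name) == tolower(query) |
               tolower(g$gene_id) == tolower(query))
  if (length(hit) == 0L)
    stop(sprintf("unknown gene '%s'", query), call. = FALSE)
  i <- hit[[1]]
  genomic_interval(g$chrom[i], g$start[i], g$end[i], g$strand[i])
}

# Highest-priority feature label at a single 0-based position.
# Priority: CDS > UTRs > exon > intron > ncRNA > intergenic.
feature_priority <- c(CDS = 1L, five_prime_UTR = 2L, three_prime_UTR = 2L,
                      exon = 3L, intron = 4L, ncRNA = 5L)

annotate_position <- function(features, chrom, pos) {
  f <- features$features
  ov <- f$chrom == chrom & f$start <= pos & pos < f$end
  if (!any(ov))
    return(list(label = "intergenic", gene_id = NA_character_,
                public_name = NA_character_))
  f <- f[ov, , drop = FALSE]
  pr <- feature_priority[f$type]
  i <- which.min(pr)
  gid <- f$gene_id[i]
  gi <- match(gid, features$genes$gene_id)
  list(label = f$type[i], gene_id = gid,
       public_name = if (is.na(gi)) NA_character_
                     else features$genes$public_name[gi])
}
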