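# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: enumeration walks every 23-mer window, seed counting uses
# regex lookahead, off-target counting uses utils::adist over every window
# length, folding enumerates every nested structure, and PCR matching uses
# Biostrings::matchPattern.

oracle_enumerate <- function(genome) {
  out <- list()
  for (chrom in names(genome$sequences)) {
    s <- genome$sequences[[chrom]]
    n <- nchar(s)
    if (n < 23L) next
    for (st in 0:(n - 23L)) {
      w <- substr(s, st + 1L, st + 23L)
      if (grepl("N", w, fixed = TRUE)) next
      if (substr(w, 22L, 23L) == "GG")
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = st, end = st + 23L, strand = "+",
          protospacer = substr(w, 1L, 20L), pam = substr(w, 21L, 23L),
          stringsAsFactors = FALSE)
      if (substr(w, 1L, 2L) == "CC") {
        rc <- crisprworm::revcomp(w)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = st, end = st + 23L, strand = "-",
          protospacer = substr(rc, 1L, 20L), pam = substr(rc, 21L, 23L),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  res <- res[order(match(res$chrom, names(genome$sequences)), res$start,
                   match(res$strand, c("+", "-"))), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# overlapping occurrences of [seed12][any][G][G] on both strands
oracle_seed_count <- function(genome, protospacer) {
  seed <- substr(protospacer, 9L, 20L)
  pat <- paste0("(?=", seed, ".GG)")
  total <- 0L
  for (chrom in names(genome$sequences)) {
    for (s in c(genome$sequences[[chrom]],
                crisprworm::revcomp(genome$sequences[[chrom]]))) {
      m <- gregexpr(pat, s, perl = TRUE)[[1]]
      total <- total + sum(m > 0L)
    }
  }
  total
}

# per-end-position minimum semi-global Levenshtein distance via adist,
# over all window lengths; PAM N expanded to its four substitutions
oracle_hit_ends <- function(text, pattern23, k) {
  n <- nchar(text)
  m <- nchar(pattern23)
  pats <- vapply(c("A", "C", "G", "T"), function(b) {
    p <- pattern23
    substr(p, 21L, 21L) <- b
    p
  }, character(1))
  ends_min <- rep(Inf, n)
  for (L in max(1L, m - k):(m + k)) {
    if (L > n) next
    starts <- seq_len(n - L + 1L)
    wins <- substring(text, starts, starts + L - 1L)
    d <- do.call(pmin, lapply(pats, function(p) drop(utils::adist(p, wins))))
    ends <- starts + L - 1L
    ends_min[ends] <- pmin(ends_min[ends], d)
  }
  which(ends_min <= k)
}

oracle_genome_hits <- function(genome, protospacer, pam, k) {
  pattern <- paste0(protospacer, pam)
  substr(pattern, 21L, 21L) <- "N"
  total <- 0L
  for (chrom in names(genome$sequences)) {
    for (s in c(genome$sequences[[chrom]],
                crisprworm::revcomp(genome$sequences[[chrom]]))) {
      ends <- oracle_hit_ends(s, pattern, k)
      if (length(ends))
        total <- total + sum(diff(sort(ends)) > k) + 1L
    }
  }
  total
}

# exhaustive enumeration of nested structures (pairs >= 4 apart) and their
# energies under the shipped table
oracle_structures <- function(i, j, canp) {
  if (j - i < 4L) return(list(list()))
  out <- oracle_structures(i + 1L, j, canp)
  for (k in (i + 4L):j) {
    if (canp[i, k]) {
      left <- oracle_structures(i + 1L, k - 1L, canp)
      right <- if (k + 1L <= j) oracle_structures(k + 1L, j, canp)
               else list(list())
      for (L in left) for (R in right)
        out[[length(out) + 1L]] <- c(list(c(i, k)), L, R)
    }
  }
  out
}

oracle_mfe <- function(seq) {
  b <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(b)
  st <- crisprworm:::.stack_table
  hp <- crisprworm:::.hairpin_penalty
  ok <- rownames(st)
  canp <- outer(seq_len(n), seq_len(n), function(i, j)
    paste0(b[i], b[j]) %in% ok & j - i >= 4L)
  if (n < 5L || !any(canp)) return(0)
  energy <- function(pairs) {
    if (!length(pairs)) return(0)
    pm <- do.call(rbind, pairs)
    e <- 0
    for (r in seq_len(nrow(pm))) {
      i <- pm[r, 1L]; j <- pm[r, 2L]
      if (any(pm[, 1L] == i + 1L & pm[, 2L] == j - 1L))
        e <- e + st[paste0(b[i], b[j]), paste0(b[i + 1L], b[j - 1L])]
      if (!any(pm[, 1L] > i & pm[, 2L] < j))
        e <- e + hp
    }
    e
  }
  structs <- oracle_structures(1L, n, canp)
  min(0, min(vapply(structs, energy, numeric(1))))
}

# brute-force PCR products via Biostrings matching
oracle_pcr <- function(template, fwd, rev, max_product) {
  hits <- function(primer, subject) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(primer),
                                  Biostrings::DNAString(subject))
    Biostrings::start(m) - 1L
  }
  one <- function(tmpl, strand) {
    fs <- hits(fwd, tmpl)
    rs <- hits(crisprworm::revcomp(rev), tmpl)
    out <- list()
    for (f in fs) for (r in rs) {
      if (r >= f + nchar(fwd) && r + nchar(rev) - f <= max_product)
        out[[length(out) + 1L]] <- data.frame(
          start = f, end = r + nchar(rev), size = r + nchar(rev) - f,
          strand = strand, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  plus <- one(template, "+")
  n <- nchar(template)
  minus <- one(crisprworm::revcomp(template), "-")
  if (!is.null(minus) && nrow(minus)) {
    sp <- n - minus$end
    minus$end <- n - minus$start
    minus$start <- sp
  }
  res <- rbind(plus, minus)
  if (is.null(res))
    return(data.frame(start = integer(0), end = integer(0),
                      size = integer(0), strand = character(0)))
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# independent per-row re-evaluation of the cohort filter
oracle_filter_kept <- function(table, focal, th) {
  obs <- table$observations
  key <- function(c, p) paste(c, p)
  cand <- obs[obs$strain == focal & obs$genotype != "ref", , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    k <- key(cand$chrom[i], cand$pos[i])
    p <- obs[obs$strain == table$parental_strain &
               key(obs$chrom, obs$pos) == k, , drop = FALSE]
    pd <- if (nrow(p)) p$depth[1] else 0L
    pa <- if (nrow(p)) p$ref_agreement[1] else 0
    sib <- obs[obs$strain %in% setdiff(table$edited_strains, focal) &
                 key(obs$chrom, obs$pos) == k & obs$depth > 0L, ,
               drop = FALSE]
    keep[i] <- pd >= th$min_parental_depth &&
      pa >= th$min_parental_agreement &&
      (nrow(sib) == 0L ||
         all(sib$ref_agreement >= th$min_sibling_agreement))
  }
  cand[keep, , drop = FALSE]
}

random_seq <- function(n, seed, gc = 0.5) {
  withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
}
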