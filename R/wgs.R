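#' Filtering thresholds for sequencing quality control
#'
#' Defaults encode the cohort filter: candidate sites are eliminated when the
#' parental strain has read depth strictly below 10 or reference agreement
#' strictly below 98%, and kept only when every sibling strain agrees with
#' the reference for at least 95% of its reads. Boundary values (depth 10,
#' 0.98, 0.95) pass. CNV windows are 1 kb wide (step 500 bp by default) and
#' segments are called at `|log2 ratio| >= 0.58` (about 1.5-fold).
#'
#' @param min_parental_depth minimum parental read depth.
#' @param min_parental_agreement minimum parental reference-agreement
#'   fraction.
#' @param min_sibling_agreement minimum sibling reference-agreement fraction.
#' @param cnv_window CNV window width, bases.
#' @param cnv_step CNV window step, bases.
#' @param cnv_log2_cutoff absolute log2-ratio cutoff for segment calling.
#' @param cnv_pseudo pseudo-count added to median-normalised window counts.
#' @return a list of class `"FilterThresholds"`.
#' @export
filter_thresholds <- function(min_parental_depth = 10L,
                              min_parental_agreement = 0.98,
                              min_sibling_agreement = 0.95,
                              cnv_window = 1000L, cnv_step = 500L,
                              cnv_log2_cutoff = 0.58, cnv_pseudo = 0.01) {
  stopifnot(is_count(min_parental_depth),
            min_parental_agreement >= 0, min_parental_agreement <= 1,
            min_sibling_agreement >= 0, min_sibling_agreement <= 1,
            is_count(cnv_window, 1L), is_count(cnv_step, 1L),
            cnv_log2_cutoff >= 0, cnv_pseudo > 0)
  structure(list(min_parental_depth = as.integer(min_parental_depth),
                 min_parental_agreement = min_parental_agreement,
                 min_sibling_agreement = min_sibling_agreement,
                 cnv_window = as.integer(cnv_window),
                 cnv_step = as.integer(cnv_step),
                 cnv_log2_cutoff = cnv_log2_cutoff,
                 cnv_pseudo = cnv_pseudo),
            class = "FilterThresholds")
}

#' Cohort variant table
#'
#' Per-site, per-strain observations for one parental strain and a set of
#' edited sibling strains derived from it.
#'
#' @param parental_strain parental strain name.
#' @param edited_strains character vector of edited strain names.
#' @param observations data.frame with columns `strain`, `chrom`, `pos`
#'   (0-based), `ref`, `alt` (`NA` when the strain matches the reference),
#'   `depth`, `ref_agreement`, `genotype` (`hom`, `het` or `ref`). A site
#'   missing for a strain is treated as depth 0.
#' @return a list of class `"CohortVariantTable"`.
#' @export
cohort_variant_table <- function(parental_strain, edited_strains,
                                 observations) {
  need <- c("strain", "chrom", "pos", "ref", "alt", "depth", "ref_agreement",
            "genotype")
  stopifnot(all(need %in% names(observations)))
  if (parental_strain %in% edited_strains)
    stop("the parental strain cannot also be an edited strain", call. = FALSE)
  ra <- observations$ref_agreement
  if (any(!is.na(ra) & (ra < 0 | ra > 1)))
    stop("ref_agreement must be within [0, 1]", call. = FALSE)
  structure(list(parental_strain = parental_strain,
                 edited_strains = edited_strains,
                 observations = observations[need]),
            class = "CohortVariantTable")
}

site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

#' Filter candidate off-target variants against parent and siblings
#'
#' A focal-strain variant is kept when the parental strain covers the site
#' with at least `min_parental_depth` reads and at least
#' `min_parental_agreement` reference agreement (so sites already variant or
#' poorly covered in the parental population are eliminated), and every other
#' edited strain agrees with the reference for at least
#' `min_sibling_agreement` of its reads (eliminating shared artifacts, e.g.
#' PCR errors near A/T homopolymers). Siblings with zero depth at a site are
#' treated as agreeing. Variants inside the engineered target interval are
#' not off-target candidates and are reported separately.
#'
#' @param table a [cohort_variant_table()].
#' @param focal_strain the edited strain being screened.
#' @param thresholds a [filter_thresholds()].
#' @param target_interval optional [genomic_interval()] of the engineered
#'   edit.
#' @return list with data.frames `kept`, `on_target`, and `dropped` (with a
#'   `reason` column: `parental_depth`, `parental_agreement`, or
#'   `sibling_agreement`).
#' @export
filter_variants <- function(table, focal_strain,
                            thresholds = filter_thresholds(),
                            target_interval = NULL) {
  stopifnot(inherits(table, "CohortVariantTable"))
  if (!focal_strain %in% table$edited_strains)
    stop(sprintf("unknown focal strain '%s'", focal_strain), call. = FALSE)
  obs <- table$observations
  cand <- obs[obs$strain == focal_strain & obs$genotype != "ref", ,
              drop = FALSE]
  parent <- obs[obs$strain == table$parental_strain, , drop = FALSE]
  pk <- site_key(parent$chrom, parent$pos)
  sibs <- setdiff(table$edited_strains, focal_strain)
  reason <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    key <- site_key(cand$chrom[i], cand$pos[i])
    pi <- match(key, pk)
    p_depth <- if (is.na(pi)) 0L else parent$depth[pi]
    p_agree <- if (is.na(pi)) NA_real_ else parent$ref_agreement[pi]
    if (p_depth < thresholds$min_parental_depth) {
      reason[i] <- "parental_depth"
    } else if (is.na(p_agree) ||
               p_agree < thresholds$min_parental_agreement) {
      reason[i] <- "parental_agreement"
    } else {
      srows <- obs[obs$strain %in% sibs &
                     site_key(obs$chrom, obs$pos) == key, , drop = FALSE]
      covered <- srows[srows$depth > 0L, , drop = FALSE]
      if (nrow(covered) &&
          any(covered$ref_agreement < thresholds$min_sibling_agreement))
        reason[i] <- "sibling_agreement"
    }
  }
  on_target <- rep(FALSE, nrow(cand))
  if (!is.null(target_interval))
    on_target <- cand$chrom == target_interval$chrom &
      cand$pos >= target_interval$start & cand$pos < target_interval$end
  kept <- cand[reason == "" & !on_target, , drop = FALSE]
  dropped <- cand[reason != "" & !on_target, , drop = FALSE]
  dropped$reason <- reason[reason != "" & !on_target]
  rownames(kept) <- rownames(dropped) <- NULL
  ot <- cand[on_target, , drop = FALSE]
  rownames(ot) <- NULL
  list(kept = kept, on_target = ot, dropped = dropped)
}

#' Annotate variants with the overlapped gene feature
#'
#' Uses the same priority scheme as the guide cut-site annotation
#' ([annotate_cut()]).
#'
#' @param variants data.frame with columns `chrom`, `pos` (0-based).
#' @param features a [FeatureSet()].
#' @return the input with `feature` and `gene` columns added.
#' @export
annotate_variants <- function(variants, features) {
  ann <- lapply(seq_len(nrow(variants)), function(i)
    annotate_position(features, variants$chrom[i], variants$pos[i]))
  variants$feature <- vapply(ann, `[[`, character(1), "label")
  variants$gene <- vapply(ann, `[[`, character(1), "public_name")
  variants
}

#' Tile a genome into fixed-width windows
#'
#' @param genome a [Genome()].
#' @param window window width, bases.
#' @param step window step, bases (sliding when `step < window`).
#' @return data.frame `chrom`, `start`, `end`; incomplete terminal windows
#'   are dropped so every window has the full width.
#' @export
make_windows <- function(genome, window = 1000L, step = window) {
  lens <- chrom_lengths(genome)
  out <- lapply(names(lens), function(chrom) {
    if (lens[[chrom]] < window) return(NULL)
    starts <- seq.int(0L, lens[[chrom]] - window, by = step)
    data.frame(chrom = chrom, start = starts, end = starts + window,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Copy-number profile of a strain against its parent
#'
#' Window counts from both strains are normalised by their genome-wide
#' medians (so library size cancels) and compared as
#' `log2((s/median_s + eps) / (p/median_p + eps))` with a small pseudo-count
#' `eps` guarding empty windows. A clean homozygous duplication therefore
#' sits near +1, a homozygous deletion near a strongly negative value, and
#' scaling either strain's counts by a constant leaves the profile
#' unchanged.
#'
#' @param windows_strain,windows_parent data.frames with columns `chrom`,
#'   `start`, `end`, `count` on identical window grids.
#' @param thresholds a [filter_thresholds()].
#' @return data.frame `chrom`, `start`, `end`, `count_strain`,
#'   `count_parent`, `log2_ratio`.
#' @export
cnv_profile <- function(windows_strain, windows_parent,
                        thresholds = filter_thresholds()) {
  key_s <- paste(windows_strain$chrom, windows_strain$start,
                 windows_strain$end)
  key_p <- paste(windows_parent$chrom, windows_parent$start,
                 windows_parent$end)
  if (!identical(sort(key_s), sort(key_p)))
    stop("strain and parent window grids differ", call. = FALSE)
  windows_parent <- windows_parent[match(key_s, key_p), , drop = FALSE]
  med_s <- median(windows_strain$count)
  med_p <- median(windows_parent$count)
  if (med_p <= 0)
    stop("parent has zero median coverage; cannot form copy-number ratios",
         call. = FALSE)
  if (med_s <= 0)
    stop("strain has zero median coverage; cannot form copy-number ratios",
         call. = FALSE)
  eps <- thresholds$cnv_pseudo
  data.frame(chrom = windows_strain$chrom, start = windows_strain$start,
             end = windows_strain$end,
             count_strain = windows_strain$count,
             count_parent = windows_parent$count,
             log2_ratio = log2((windows_strain$count / med_s + eps) /
                                 (windows_parent$count / med_p + eps)),
             stringsAsFactors = FALSE)
}

#' Call copy-number segments from a profile
#'
#' Segments are maximal runs of consecutive windows whose absolute log2
#' ratio meets the cutoff with a consistent direction, merged across at most
#' `max_gap` intervening sub-threshold window(s).
#'
#' @param profile data.frame from [cnv_profile()].
#' @param thresholds a [filter_thresholds()].
#' @param max_gap sub-threshold windows tolerated inside a segment.
#' @return data.frame `chrom`, `start`, `end`, `n_windows` (qualifying
#'   windows), `mean_log2`, `direction` (`"gain"` or `"loss"`).
#' @export
call_cnv_segments <- function(profile, thresholds = filter_thresholds(),
                              max_gap = 1L) {
  cutoff <- thresholds$cnv_log2_cutoff
  out <- list()
  for (chrom in unique(profile$chrom)) {
    p <- profile[profile$chrom == chrom, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    state <- sign(p$log2_ratio) * (abs(p$log2_ratio) >= cutoff)
    i <- 1L
    while (i <= nrow(p)) {
      if (state[i] == 0) { i <- i + 1L; next }
      dir <- state[i]
      j <- i
      gap <- 0L
      last_hit <- i
      while (j < nrow(p)) {
        nxt <- state[j + 1L]
        if (nxt == dir) {
          j <- j + 1L; last_hit <- j; gap <- 0L
        } else if (nxt == 0 && gap < max_gap) {
          j <- j + 1L; gap <- gap + 1L
        } else break
      }
      idx <- i:last_hit
      hit <- idx[state[idx] == dir]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = p$start[i], end = p$end[last_hit],
        n_windows = length(hit), mean_log2 = mean(p$log2_ratio[hit]),
        direction = if (dir > 0) "gain" else "loss",
        stringsAsFactors = FALSE)
      i <- last_hit + 1L
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      mean_log2 = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read and write site-observation and window-count tables
#'
#' Site tables are VCF-like TSVs with columns `strain`, `chrom`, `pos`,
#' `ref`, `alt`, `depth`, `ref_agreement`, `genotype` (unset `alt` written
#' as `"."`). Window-count tables are bedGraph-like TSVs with columns
#' `chrom`, `start`, `end`, `count`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_site_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if ("alt" %in% names(df)) df$alt[df$alt == "."] <- NA_character_
  df
}

#' @rdname read_site_table
#' @param observations site-observation data.frame.
#' @export
write_site_table <- function(observations, path) {
  obs <- observations
  obs$alt[is.na(obs$alt)] <- "."
  write.table(obs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_site_table
#' @export
read_window_counts <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_site_table
#' @param windows window-count data.frame.
#' @export
write_window_counts <- function(windows, path) {
  write.table(windows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
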