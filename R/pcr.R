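#' Primer pair
#'
#' @param forward,reverse primer sequences over \{A,C,G,T\}, length >= 15,
#'   written 5' to 3' on opposite strands (standard PCR orientation).
#' @param expected_size expected product size in bp, or `NULL`.
#' @return an object of class `"PrimerPair"`.
#' @export
primer_pair <- function(forward, reverse, expected_size = NULL) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  assert_dna(c(forward, reverse), "primer", allow_n = FALSE)
  if (nchar(forward) < 15L || nchar(reverse) < 15L)
    stop("primers must be at least 15 bases", call. = FALSE)
  structure(list(forward = forward, reverse = reverse,
                 expected_size = expected_size), class = "PrimerPair")
}

#' In-silico PCR with exact primer matching
#'
#' Reports a product for every placement where the forward primer matches
#' one strand exactly and the reverse primer matches the other strand
#' downstream, with non-overlapping primer binding sites and product size at
#' most `max_product`. Both template strands are considered. No mismatch or
#' thermodynamic model is applied: the physical assays this emulates are
#' presence/size calls on a gel.
#'
#' @param template template sequence (character scalar).
#' @param pair a [primer_pair()].
#' @param max_product largest product size to report, bp.
#' @return data.frame with columns `start`, `end` (0-based half-open product
#'   span on the given template), `size`, `strand` (`"+"` if the forward
#'   primer sits on the template strand as given).
#' @export
insilico_pcr <- function(template, pair, max_product = 10000L) {
  stopifnot(inherits(pair, "PrimerPair"))
  template <- toupper(template)
  assert_dna(template, "template")
  plus <- pcr_one_orientation(template, pair$forward, pair$reverse,
                              max_product)
  plus$strand <- rep("+", nrow(plus))
  n <- nchar(template)
  minus <- pcr_one_orientation(revcomp(template), pair$forward, pair$reverse,
                               max_product)
  if (nrow(minus)) {
    sp <- n - minus$end
    minus$end <- n - minus$start
    minus$start <- sp
  }
  minus$strand <- rep("-", nrow(minus))
  out <- rbind(plus, minus)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

pcr_one_orientation <- function(template, fwd, rev, max_product) {
  f_starts <- exact_matches(template, fwd)
  r_starts <- exact_matches(template, revcomp(rev))
  flen <- nchar(fwd); rlen <- nchar(rev)
  out <- list()
  for (f in f_starts) {
    rs <- r_starts[r_starts >= f + flen &
                     r_starts + rlen - f <= max_product]
    if (length(rs))
      out[[length(out) + 1L]] <- data.frame(start = f, end = rs + rlen,
                                            size = rs + rlen - f)
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      size = integer(0)))
  do.call(rbind, out)
}

#' Classify an edited strain from the four-reaction PCR panel
#'
#' Implements the quality-control decision table: a failed wild-type control
#' on N2 invalidates the assay; a wild-type product from the mutant template
#' means the gene is not null (`GENE_PARTIALLY_INTACT`); otherwise two
#' correct junction products mean a `PRECISE_EDIT` and anything else an
#' `IMPRECISE_EDIT` (a mutant, probably with a rearrangement). Missing and
#' wrong-size junction products are treated identically
#' (`incorrect_or_absent`).
#'
#' @param left_junction,right_junction `"correct"` or `"incorrect_or_absent"`.
#' @param wt_on_mutant `"product"` or `"no_product"` for the wild-type assay
#'   on the mutant template.
#' @param wt_on_n2 `"correct"` or `"failed"` for the wild-type assay on N2.
#' @return character vector over `PRECISE_EDIT`, `IMPRECISE_EDIT`,
#'   `GENE_PARTIALLY_INTACT`, `ASSAY_INVALID` (vectorised over panels).
#' @export
#' @examples
#' classify_mutant("correct", "correct", "no_product", "correct")
classify_mutant <- function(left_junction, right_junction, wt_on_mutant,
                            wt_on_n2) {
  n <- length(left_junction)
  stopifnot(length(right_junction) == n, length(wt_on_mutant) == n,
            length(wt_on_n2) == n)
  chk <- function(x, ok, what) {
    if (!all(x %in% ok))
      stop(sprintf("%s must be one of: %s", what,
                   paste(ok, collapse = ", ")), call. = FALSE)
  }
  chk(left_junction, c("correct", "incorrect_or_absent"), "left_junction")
  chk(right_junction, c("correct", "incorrect_or_absent"), "right_junction")
  chk(wt_on_mutant, c("product", "no_product"), "wt_on_mutant")
  chk(wt_on_n2, c("correct", "failed"), "wt_on_n2")
  out <- character(n)
  out[] <- "IMPRECISE_EDIT"
  out[left_junction == "correct" & right_junction == "correct"] <-
    "PRECISE_EDIT"
  out[wt_on_mutant == "product"] <- "GENE_PARTIALLY_INTACT"
  out[wt_on_n2 == "failed"] <- "ASSAY_INVALID"
  out
}

mutant_classes <- c("PRECISE_EDIT", "IMPRECISE_EDIT", "GENE_PARTIALLY_INTACT")

#' Summarise mutant classes per gene target
#'
#' For each gene, the proportion of its (valid) strains in each class; the
#' report is the unweighted mean of those per-gene proportions across genes
#' -- not the pooled per-strain proportion, so every gene target counts
#' equally regardless of how many strains it produced. `ASSAY_INVALID`
#' records are excluded and counted; genes left with no valid strain are
#' excluded with a warning.
#'
#' @param records data.frame with columns `gene_id`, `strain_id`, `class`.
#' @return list with `class_means` (data.frame `class`, `mean_proportion`),
#'   `per_gene` (one row per gene and class), `n_invalid`, `genes_excluded`.
#' @export
summarize_classes <- function(records) {
  stopifnot(all(c("gene_id", "strain_id", "class") %in% names(records)))
  inv <- records$class == "ASSAY_INVALID"
  n_invalid <- sum(inv)
  rec <- records[!inv, , drop = FALSE]
  bad <- setdiff(unique(rec$class), mutant_classes)
  if (length(bad))
    stop("unknown class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  all_genes <- unique(records$gene_id)
  kept_genes <- unique(rec$gene_id)
  excluded <- setdiff(all_genes, kept_genes)
  if (length(excluded))
    warning(sprintf("%d gene(s) with no valid strain excluded: %s",
                    length(excluded), paste(excluded, collapse = ", ")),
            call. = FALSE)
  per_gene <- do.call(rbind, lapply(kept_genes, function(g) {
    cls <- rec$class[rec$gene_id == g]
    data.frame(gene_id = g, class = mutant_classes,
               n_strains = length(cls),
               proportion = vapply(mutant_classes,
                                   function(k) mean(cls == k), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  means <- vapply(mutant_classes, function(k)
    mean(per_gene$proportion[per_gene$class == k]), numeric(1))
  list(class_means = data.frame(class = mutant_classes,
                                mean_proportion = unname(means),
                                stringsAsFactors = FALSE),
       per_gene = per_gene, n_invalid = n_invalid,
       genes_excluded = excluded)
}

#' Score a junction assay from in-silico PCR products
#'
#' `"correct"` when exactly the expected-size product is present (within
#' `tol` bp), `"incorrect_or_absent"` otherwise.
#'
#' @param products data.frame from [insilico_pcr()].
#' @param expected_size expected product size, bp.
#' @param tol size tolerance, bp.
#' @return `"correct"` or `"incorrect_or_absent"`.
#' @export
call_junction <- function(products, expected_size, tol = 0L) {
  if (nrow(products) && any(abs(products$size - expected_size) <= tol))
    "correct" else "incorrect_or_absent"
}

#' Run the four-reaction QC panel in silico
#'
#' Applies the left-junction, right-junction and wild-type primer pairs to a
#' mutant template and the wild-type pair to the N2 (unedited) template,
#' then scores the panel fields for [classify_mutant()]. Expected junction
#' sizes are taken from each pair's `expected_size` (typically measured on
#' the precisely edited reference with [insilico_pcr()]).
#'
#' @param mutant_seq,n2_seq template sequences (edited and wild-type).
#' @param left_pair,right_pair,wt_pair [primer_pair()]s; the junction pairs
#'   must carry `expected_size`; the wild-type pair's `expected_size` is used
#'   to validate the N2 control.
#' @param max_product passed to [insilico_pcr()].
#' @param tol junction size tolerance, bp.
#' @return list with the four panel fields plus `class`.
#' @export
run_qc_panel <- function(mutant_seq, n2_seq, left_pair, right_pair, wt_pair,
                         max_product = 10000L, tol = 0L) {
  stopifnot(!is.null(left_pair$expected_size),
            !is.null(right_pair$expected_size))
  left <- call_junction(insilico_pcr(mutant_seq, left_pair, max_product),
                        left_pair$expected_size, tol)
  right <- call_junction(insilico_pcr(mutant_seq, right_pair, max_product),
                         right_pair$expected_size, tol)
  wt_mut <- if (nrow(insilico_pcr(mutant_seq, wt_pair, max_product)))
    "product" else "no_product"
  n2 <- insilico_pcr(n2_seq, wt_pair, max_product)
  wt_n2 <- if (is.null(wt_pair$expected_size)) {
    if (nrow(n2)) "correct" else "failed"
  } else {
    if (nrow(n2) && any(abs(n2$size - wt_pair$expected_size) <= tol))
      "correct" else "failed"
  }
  list(left_junction = left, right_junction = right, wt_on_mutant = wt_mut,
       wt_on_n2 = wt_n2,
       class = classify_mutant(left, right, wt_mut, wt_n2))
}

#' Read or write QC panel tables
#'
#' Panel TSV columns: `strain`, `gene`, `left`, `right`, `wt_mutant`,
#' `wt_n2`; [classify_panels()] adds a `class` column.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_panel_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "gene", "left", "right", "wt_mutant", "wt_n2")
  if (!all(need %in% names(df)))
    stop("panel table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_panel_table
#' @param panels panel data.frame as from [read_panel_table()].
#' @export
classify_panels <- function(panels) {
  panels$class <- classify_mutant(panels$left, panels$right,
                                  panels$wt_mutant, panels$wt_n2)
  panels
}
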