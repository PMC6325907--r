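#' Deletion plan
#'
#' Pairs a target interval with the guide(s) that cut it. With two guides the
#' deleted interval runs from the left cut to the right cut; with a single
#' guide the caller supplies the target interval explicitly and the cut must
#' fall inside or immediately adjacent to it.
#'
#' @param guides guide table rows (1 or 2 guides) from [design_guides()], or
#'   `NULL`.
#' @param target a [genomic_interval()]; required for single-guide or
#'   guide-free plans.
#' @param cassette_id label of the selection cassette to integrate.
#' @return an object of class `"DeletionPlan"`.
#' @export
deletion_plan <- function(guides = NULL, target = NULL,
                          cassette_id = "dual-marker") {
  if (!is.null(guides) && nrow(guides) == 2L) {
    cuts <- sort(guides$cut_pos)
    if (length(unique(guides$chrom)) != 1L)
      stop("the two guides must cut the same chromosome", call. = FALSE)
    target <- genomic_interval(guides$chrom[1], cuts[1], cuts[2])
  }
  if (is.null(target))
    stop("single-guide plans require an explicit target interval",
         call. = FALSE)
  stopifnot(inherits(target, "GenomicInterval"))
  if (!is.null(guides) && nrow(guides) == 1L) {
    if (guides$chrom != target$chrom ||
        guides$cut_pos < target$start - 1L ||
        guides$cut_pos > target$end + 1L)
      stop("guide cut site must lie within or adjacent to the target",
           call. = FALSE)
  }
  structure(list(target = target, guides = guides, cassette_id = cassette_id),
            class = "DeletionPlan")
}

#' Design homology arms for an HDR repair template
#'
#' Copies `genomic_arm_len` bases immediately flanking the deletion interval
#' from the + strand (regardless of gene orientation) and attaches the
#' assembly-overlap adapters: the left arm carries the first `adapter_len`
#' bases of the cassette appended, the right arm carries the last
#' `adapter_len` bases prepended, so each synthesized fragment is
#' `genomic_arm_len + adapter_len` bases (500 bp with the defaults, the
#' gBlock specification). Arms shorter than 400 bp of genomic homology emit
#' a warning: editing efficiency drops markedly below that length when
#' integrating a multi-kb cassette.
#'
#' @param genome a [Genome()].
#' @param target deletion interval ([genomic_interval()]).
#' @param genomic_arm_len genomic homology per arm, bases.
#' @param adapter_len assembly-overlap adapter length, bases.
#' @param cassette cassette sequence used to derive the adapters; `NULL`
#'   leaves the adapters empty.
#' @return an object of class `"RepairTemplate"` with elements `left_arm`,
#'   `right_arm` (genomic parts), `left_adapter`, `right_adapter`,
#'   `left_gblock`, `right_gblock`, `genomic_arm_len`, `adapter_len`,
#'   `target`.
#' @export
design_homology_arms <- function(genome, target, genomic_arm_len = 450L,
                                 adapter_len = 50L, cassette = NULL) {
  check_interval(genome, target)
  stopifnot(is_count(genomic_arm_len, 1L), is_count(adapter_len, 0L))
  len <- chrom_lengths(genome)[[target$chrom]]
  left_avail <- target$start
  right_avail <- len - target$end
  if (left_avail < genomic_arm_len || right_avail < genomic_arm_len) {
    short <- min(left_avail, right_avail)
    stop(sprintf(
      "insufficient flanking sequence for %d bp arms: only %d bp available on the %s side",
      genomic_arm_len, short,
      if (left_avail < right_avail) "left" else "right"), call. = FALSE)
  }
  if (genomic_arm_len < 400L)
    warning(sprintf(
      "homology arms of %d bp are below the ~400 bp needed for efficient cassette integration; expect reduced editing efficiency",
      genomic_arm_len), call. = FALSE)
  left <- genome_seq(genome, target$chrom, target$start - genomic_arm_len,
                     target$start)
  right <- genome_seq(genome, target$chrom, target$end,
                      target$end + genomic_arm_len)
  la <- ra <- ""
  if (!is.null(cassette) && adapter_len > 0L) {
    assert_dna(cassette, "cassette")
    if (nchar(cassette) < adapter_len)
      stop("cassette shorter than the adapter length", call. = FALSE)
    la <- substr(cassette, 1L, adapter_len)
    ra <- substr(cassette, nchar(cassette) - adapter_len + 1L,
                 nchar(cassette))
  }
  structure(list(left_arm = left, right_arm = right,
                 left_adapter = la, right_adapter = ra,
                 left_gblock = paste0(left, la),
                 right_gblock = paste0(ra, right),
                 genomic_arm_len = as.integer(genomic_arm_len),
                 adapter_len = if (nzchar(la)) as.integer(adapter_len) else 0L,
                 target = target),
            class = "RepairTemplate")
}

#' @export
print.RepairTemplate <- function(x, ...) {
  cat(sprintf(
    "RepairTemplate: %d bp genomic arms + %d bp adapters around %s:[%d, %d)\n",
    x$genomic_arm_len, x$adapter_len, x$target$chrom, x$target$start,
    x$target$end))
  invisible(x)
}

#' Assemble the full repair template
#'
#' Joins left arm, cassette and right arm into one molecule, merging the
#' adapter overlaps once (the Gibson-style assembly product). The template's
#' adapters must match the cassette's terminal sequences.
#'
#' @param template a [design_homology_arms()] result.
#' @param cassette cassette sequence.
#' @return assembled sequence, `left_arm + cassette + right_arm`.
#' @export
assemble_template <- function(template, cassette) {
  stopifnot(inherits(template, "RepairTemplate"))
  assert_dna(cassette, "cassette")
  al <- template$adapter_len
  if (al > 0L) {
    if (!identical(template$left_adapter, substr(cassette, 1L, al)) ||
        !identical(template$right_adapter,
                   substr(cassette, nchar(cassette) - al + 1L,
                          nchar(cassette))))
      stop("adapters do not match the cassette terminal sequences",
           call. = FALSE)
  }
  paste0(template$left_arm, cassette, template$right_arm)
}

#' Model the HDR-edited genome
#'
#' Replaces the target interval with the cassette on its chromosome; every
#' other chromosome, and every base outside the interval, is untouched. The
#' chromosome length changes by `nchar(cassette) - width(target)`.
#'
#' @param genome a [Genome()].
#' @param target deletion interval.
#' @param cassette replacement sequence (may be `""` for a pure deletion).
#' @return the edited [Genome()], with `assembly_tag` suffixed `"+edit"`.
#' @export
apply_hdr_edit <- function(genome, target, cassette = "") {
  check_interval(genome, target)
  assert_dna(cassette, "cassette")
  s <- genome$sequences[[target$chrom]]
  edited <- paste0(seq_slice(s, 0L, target$start), toupper(cassette),
                   seq_slice(s, target$end, nchar(s)))
  seqs <- genome$sequences
  seqs[[target$chrom]] <- edited
  Genome(seqs, assembly_tag = paste0(genome$assembly_tag, "+edit"))
}

#' Write a repair template as FASTA
#'
#' Three records (`left_arm`, `cassette`, `right_arm`, each including the
#' adapter overlaps where applicable) plus an optional single-record
#' assembled template.
#'
#' @param template a [design_homology_arms()] result.
#' @param cassette cassette sequence.
#' @param path output FASTA for the parts.
#' @param assembled_path optional output FASTA for the assembled molecule.
#' @return `path`, invisibly.
#' @export
write_template_fasta <- function(template, cassette, path,
                                 assembled_path = NULL) {
  write_fasta(c(left_arm = template$left_gblock, cassette = cassette,
                right_arm = template$right_gblock), path)
  if (!is.null(assembled_path))
    write_fasta(c(assembled_template = assemble_template(template, cassette)),
                assembled_path)
  invisible(path)
}
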