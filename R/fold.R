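# Guide self-folding: minimum free energy of a nested RNA secondary
# structure under a compact nearest-neighbour model. The energy of a
# structure is the sum of stack free energies for directly stacked pairs
# plus a flat penalty per hairpin loop; unpaired bases, bulges, interior
# and multibranch loops are free. Allowed pairs: Watson-Crick and G.U.
# This is deliberately a simplified folding model -- enough to flag guides
# with strong self-structure -- and is exactly the objective the dynamic
# programme optimises (verified by exhaustive enumeration in the tests);
# no parity with full loop-based folding packages is claimed.

# stack free energies, kcal/mol at 37C; rows: outer pair (i,j),
# cols: inner pair (i+1, j-1). Watson-Crick block from the standard
# nearest-neighbour set; wobble-containing stacks flattened.
rna_pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")

.build_stack_table <- function() {
  E <- matrix(NA_real_, 6, 6, dimnames = list(rna_pairs, rna_pairs))
  wc <- function(p1, p2, v) {
    E[p1, p2] <<- v
    flip <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
    E[flip(p2), flip(p1)] <<- v     # strand-reading symmetry
  }
  wc("AU", "AU", -0.93); wc("AU", "UA", -1.10); wc("UA", "AU", -1.33)
  wc("CG", "UA", -2.08); wc("CG", "AU", -2.11); wc("GC", "UA", -2.24)
  wc("GC", "AU", -2.35); wc("CG", "GC", -2.36); wc("GC", "GC", -3.26)
  wc("GC", "CG", -3.42)
  wobble <- grepl("GU|UG", rna_pairs)
  for (a in seq_len(6)) for (b in seq_len(6)) {
    nw <- wobble[a] + wobble[b]
    if (nw == 1L) E[a, b] <- -1.2
    if (nw == 2L) E[a, b] <- -0.4
  }
  E
}

.stack_table <- .build_stack_table()
.hairpin_penalty <- 5.0
.min_hairpin <- 3L   # unpaired bases enclosed by an innermost pair

pair_code <- function(a, b) {
  p <- paste0(a, b)
  ifelse(p %in% rna_pairs, p, NA_character_)
}

#' Minimum folding free energy of a guide RNA
#'
#' Computes the optimum over all nested secondary structures of the sum of
#' nearest-neighbour stack energies plus a flat hairpin-loop penalty, with
#' hairpin loops of at least three unpaired bases and free unpaired bases.
#' The result is capped at 0 (the open chain), so values are always
#' `<= 0` kcal/mol; strongly negative values flag self-folding guides.
#' DNA input is transliterated T to U internally.
#'
#' @param seq a single sequence over \{A,C,G,T,U\} (case-insensitive).
#' @return folding free energy in kcal/mol (`<= 0`).
#' @export
#' @examples
#' fold_mfe(strrep("A", 20))        # 0: nothing can pair
#' fold_mfe("GGGGGAAAACCCCC") < 0   # a stable hairpin
fold_mfe <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("Tt", "Uu", toupper(seq))
  if (!grepl("^[ACGU]+$", s))
    stop("sequence must be over A,C,G,T/U", call. = FALSE)
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(b)
  if (n < .min_hairpin + 2L) return(0)
  INF <- Inf
  V <- matrix(INF, n, n)    # min energy with (i,j) paired
  Wp <- matrix(INF, n, n)   # min energy of a structure with >= 1 pair in [i,j]
  W <- function(i, j) if (i > j) 0 else min(0, Wp[i, j])
  for (len in (.min_hairpin + 1L):(n - 1L)) {
    for (i in seq_len(n - len)) {
      j <- i + len
      pc <- pair_code(b[i], b[j])
      if (!is.na(pc)) {
        e <- .hairpin_penalty
        inner <- pair_code(b[i + 1L], b[j - 1L])
        if (!is.na(inner) && V[i + 1L, j - 1L] < INF)
          e <- min(e, .stack_table[pc, inner] + V[i + 1L, j - 1L])
        if (j - 1L >= i + 1L && Wp[i + 1L, j - 1L] < INF)
          e <- min(e, Wp[i + 1L, j - 1L])
        V[i, j] <- e
      }
      # Wp[i,j]: leftmost paired base a = i, partner b; or a > i
      best <- if (i + 1L <= j) Wp[i + 1L, j] else INF
      bs <- seq.int(i + .min_hairpin + 1L, j)
      for (bb in bs) {
        if (V[i, bb] < INF) {
          cand <- V[i, bb] + W(bb + 1L, j)
          if (cand < best) best <- cand
        }
      }
      Wp[i, j] <- best
    }
  }
  min(0, Wp[1L, n])
}
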