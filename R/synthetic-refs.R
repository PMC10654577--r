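#' Toy V/J/C reference segments
#'
#' A closed, seeded reference set for the internal annotator and the read
#' simulator: per locus (TRA, TRB by default) 4 V segments (200-300 nt,
#' ending in the conserved Cys codon TGT), 3 J segments (50 nt, beginning
#' with a TTT/TTC-GG-x Phe-Gly motif) and 2 C segments (150 nt). Each V
#' segment additionally carries a 5' UTR/leader (250-300 nt, role `UTR`)
#' emulating the upstream sequence captured by template switching, which
#' brings simulated transcripts to roughly the 800 nt scale of real
#' target-enriched TCR cDNA.
#'
#' The set shipped at `inst/extdata/toy_tcr_refs.fasta` is
#' `toy_references(seed = 42)`.
#'
#' @param seed Integer seed; the same seed always yields the same set.
#' @param n_v,n_j,n_c Segments per role and locus.
#' @param loci Character vector of locus names.
#' @return A reference tibble (see [read_segment_fasta()]).
#' @export
toy_references <- function(seed = 42, n_v = 4, n_j = 3, n_c = 2,
                           loci = c("TRA", "TRB")) {
  with_seed(seed, {
    rows <- list()
    for (locus in loci) {
      for (i in seq_len(n_v)) {
        len <- sample(200:300, 1)
        seq <- paste0(random_dna(1, len - 3), "TGT")
        utr <- random_dna(1, sample(250:300, 1))
        vid <- sprintf("%sV%d", locus, i)
        rows[[length(rows) + 1]] <- tibble(
          segment_id = vid, locus = locus, role = "V", seq = seq,
          cys_offset = len - 3L, motif_offset = NA_integer_,
          utr_of = NA_character_
        )
        rows[[length(rows) + 1]] <- tibble(
          segment_id = paste0(vid, "-UTR"), locus = locus, role = "UTR",
          seq = utr, cys_offset = NA_integer_, motif_offset = NA_integer_,
          utr_of = vid
        )
      }
      for (i in seq_len(n_j)) {
        motif <- paste0(sample(c("TTT", "TTC"), 1), "GG", sample(c("A", "C", "G", "T"), 1))
        rows[[length(rows) + 1]] <- tibble(
          segment_id = sprintf("%sJ%d", locus, i), locus = locus, role = "J",
          seq = paste0(motif, random_dna(1, 44)),
          cys_offset = NA_integer_, motif_offset = 0L, utr_of = NA_character_
        )
      }
      for (i in seq_len(n_c)) {
        rows[[length(rows) + 1]] <- tibble(
          segment_id = sprintf("%sC%d", locus, i), locus = locus, role = "C",
          seq = random_dna(1, 150),
          cys_offset = NA_integer_, motif_offset = NA_integer_,
          utr_of = NA_character_
        )
      }
    }
    bind_rows(rows)
  })
}

# The 61 sense codons (no stop codons), used to build CDR3 junctions whose
# translation is free of '*' and 'X'.
sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(
    as.vector(outer(bases, bases, paste0)), bases, paste0
  ))
  setdiff(all, c("TAA", "TAG", "TGA"))
}
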