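#' Consensus-correction benchmark on simulated nanopore-like reads
#'
#' Runs the error-correction half of the pipeline under controlled
#' conditions: a repertoire of planted clones is simulated with ~800 nt
#' transcripts at the long-read error rate (default 4.74% per base,
#' substitutions + indels), reads are emitted, reoriented and trimmed,
#' annotated, grouped by (V, C), clustered and consensus-corrected, and
#' the per-read error rate against the constant-segment references is
#' measured before and after correction.
#'
#' @param n_clones Number of planted clones (default 100).
#' @param reads_per_clone Length-2 range of total reads per clone
#'   (default 20-60).
#' @param n_spots Lattice size for the simulated tissue (default 256).
#' @param error_rates Error-channel rates (default the 4.74% mix).
#' @param seed Integer seed.
#' @return A list: `pre` and `post` (`error_report`s), `n_reads`,
#'   `n_clusters`, `bundle`, and `corrected`.
#' @export
correction_benchmark <- function(n_clones = 100, reads_per_clone = c(20, 60),
                                 n_spots = 256,
                                 error_rates = c(sub = 0.0260, ins = 0.0095, del = 0.0119),
                                 seed) {
  refs <- toy_references()
  bundle <- simulate_repertoire(
    n_spots = n_spots, n_clones = n_clones,
    error_rates = error_rates, refs = refs, seed = seed
  )
  em <- emit_reads(bundle, reads_per_clone = reads_per_clone)
  inserts <- orient_and_split(em$reads)
  annotations <- annotate_inserts(inserts, refs)
  pre <- measure_error(
    tibble(read_id = inserts$insert_id, seq = inserts$seq), refs
  )
  corrected <- correct_partitions(inserts, annotations)
  post <- measure_error(corrected[, c("read_id", "seq")], refs)
  list(
    pre = pre, post = post,
    n_reads = nrow(em$reads),
    n_clusters = length(unique(paste(corrected$partition, corrected$cluster))),
    bundle = bundle, corrected = corrected
  )
}
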