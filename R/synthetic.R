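#' Simulate a ground-truthed spatial TCR repertoire
#'
#' Places spots on a hexagonal lattice (unit spacing), plants clones with
#' either a locally *expanded* spatial pattern (a contiguous, lattice-
#' connected patch of spots) or a *dispersed* one (spots sampled uniformly),
#' and assigns every occupied (clone, spot) pair a planted UMI count. Clone
#' transcripts are built from the toy reference set as
#' 5'UTR + V + CDR3-tail + J + C; planted CDR3 amino-acid sequences are
#' pairwise at Levenshtein distance >= 2 so clonotype recovery is
#' unambiguous. Deterministic given `seed`.
#'
#' @param n_spots Number of lattice spots (>= 9).
#' @param n_clones Number of planted clones (0 allowed).
#' @param pattern_mix Named numeric fractions for `expanded` and `dispersed`;
#'   must sum to 1.
#' @param spots_per_clone Integer vector of candidate per-clone spot counts.
#' @param umis_per_spot Mean planted UMIs per occupied spot (each spot gets
#'   `1 + rpois(umis_per_spot - 1)`).
#' @param error_rates Named numeric vector `sub`, `ins`, `del`, each in
#'   `[0, 0.5)`; defaults reproduce a 4.74% mean per-base error channel with
#'   an R9-like substitution/insertion/deletion mix.
#' @param refs Segment reference tibble; defaults to [toy_references()].
#' @param seed Integer seed (required).
#' @return A `truth_bundle` list: `clones` (one row per clone with truth
#'   transcript, CDR3 and pattern), `planted` (clone_id, barcode, n_umis),
#'   `spot_table`, `whitelist`, `error_rates`, `refs`, `seed`.
#' @export
simulate_repertoire <- function(n_spots = 100, n_clones = 20,
                                pattern_mix = c(expanded = 0.5, dispersed = 0.5),
                                spots_per_clone = 3:8,
                                umis_per_spot = 2,
                                error_rates = c(sub = 0.0260, ins = 0.0095, del = 0.0119),
                                refs = toy_references(),
                                seed) {
  if (missing(seed)) abort("simulate_repertoire() needs an explicit seed")
  if (n_spots < 9) abort("n_spots must be >= 9", class = "clonospace_config_error")
  if (abs(sum(pattern_mix) - 1) > 1e-8) {
    abort("pattern_mix fractions must sum to 1", class = "clonospace_config_error")
  }
  if (!all(c("sub", "ins", "del") %in% names(error_rates)) ||
    any(error_rates < 0) || any(error_rates >= 0.5)) {
    abort("error_rates must name sub/ins/del, each in [0, 0.5)",
      class = "clonospace_config_error"
    )
  }
  with_seed(seed, {
    spot_table <- hex_lattice(n_spots)
    if (n_clones == 0) {
      clones <- tibble(
        clone_id = character(), locus = character(), v_call = character(),
        j_call = character(), c_call = character(), cdr3_nt = character(),
        cdr3_aa = character(), pattern = character(), transcript = character()
      )
      planted <- tibble(clone_id = character(), barcode = character(), n_umis = integer())
    } else {
      clones <- plant_clones(n_clones, pattern_mix, refs)
      planted <- plant_spots(clones, spot_table, spots_per_clone, umis_per_spot)
    }
    structure(
      list(
        clones = clones, planted = planted, spot_table = spot_table,
        whitelist = spot_table$barcode, error_rates = error_rates,
        refs = refs, seed = seed
      ),
      class = "truth_bundle"
    )
  })
}

hex_lattice <- function(n_spots) {
  ncol <- ceiling(sqrt(n_spots))
  nrow <- ceiling(n_spots / ncol)
  grid <- expand.grid(col = seq_len(ncol), row = seq_len(nrow))[seq_len(n_spots), ]
  tibble(
    barcode = random_dna(n_spots, 16),
    x = grid$col + 0.5 * (grid$row %% 2),
    y = grid$row * sqrt(3) / 2,
    in_tissue = TRUE,
    n_cells = 1L + rpois(n_spots, 4),
    total_umis = as.integer(round((1L + rpois(n_spots, 4)) *
      rlnorm(n_spots, log(1200), 0.3)))
  )
}

plant_clones <- function(n_clones, pattern_mix, refs) {
  codons <- sense_codons()
  vs <- refs[refs$role == "V", ]
  js <- refs[refs$role == "J", ]
  cs <- refs[refs$role == "C", ]
  utrs <- refs[refs$role == "UTR", ]
  n_exp <- round(n_clones * pattern_mix[["expanded"]])
  patterns <- sample(c(
    rep("expanded", n_exp),
    rep("dispersed", n_clones - n_exp)
  ))
  loci <- sample(c("TRA", "TRB"), n_clones, replace = TRUE, prob = c(0.4, 0.6))
  cdr3_aa_seen <- character(0)
  rows <- vector("list", n_clones)
  for (i in seq_len(n_clones)) {
    locus <- loci[i]
    v <- vs[vs$locus == locus, ][sample(sum(vs$locus == locus), 1), ]
    j <- js[js$locus == locus, ][sample(sum(js$locus == locus), 1), ]
    cc <- cs[cs$locus == locus, ][sample(sum(cs$locus == locus), 1), ]
    utr <- utrs$seq[utrs$utr_of == v$segment_id]
    repeat {
      n_aa <- sample(5:20, 1) # CDR3 of 15-60 nt: inside the default 5-30 aa
      # repertoire filter, so planted clones are recoverable by construction
      tail_nt <- paste(sample(codons, n_aa - 1, replace = TRUE), collapse = "")
      cdr3_nt <- paste0("TGT", tail_nt)
      cdr3_aa <- translate_nt(cdr3_nt)
      if (length(cdr3_aa_seen) == 0 ||
        min(lev_cross_cpp(cdr3_aa, cdr3_aa_seen)) >= 2) {
        break
      }
    }
    cdr3_aa_seen <- c(cdr3_aa_seen, cdr3_aa)
    rows[[i]] <- tibble(
      clone_id = sprintf("clone%03d", i), locus = locus,
      v_call = v$segment_id, j_call = j$segment_id, c_call = cc$segment_id,
      cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa, pattern = patterns[i],
      transcript = paste0(utr, v$seq, substr(cdr3_nt, 4, nchar(cdr3_nt)), j$seq, cc$seq)
    )
  }
  bind_rows(rows)
}

plant_spots <- function(clones, spot_table, spots_per_clone, umis_per_spot) {
  n_spots <- nrow(spot_table)
  adj <- lattice_neighbors(spot_table)
  rows <- vector("list", nrow(clones))
  for (i in seq_len(nrow(clones))) {
    k <- min(sample(spots_per_clone, 1), n_spots)
    idx <- if (clones$pattern[i] == "expanded") {
      grow_patch(adj, k)
    } else {
      sample(n_spots, k)
    }
    rows[[i]] <- tibble(
      clone_id = clones$clone_id[i],
      barcode = spot_table$barcode[idx],
      n_umis = 1L + rpois(length(idx), max(umis_per_spot - 1, 0))
    )
  }
  bind_rows(rows)
}

# Hex-lattice adjacency: spots within 1.05 lattice units.
lattice_neighbors <- function(spot_table) {
  d <- as.matrix(stats::dist(cbind(spot_table$x, spot_table$y)))
  lapply(seq_len(nrow(d)), function(i) which(d[i, ] > 0 & d[i, ] < 1.05))
}

# Breadth-first contiguous patch of k spots from a random seed spot.
grow_patch <- function(adj, k) {
  start <- sample(length(adj), 1)
  patch <- start
  frontier <- setdiff(adj[[start]], patch)
  while (length(patch) < k && length(frontier) > 0) {
    nxt <- if (length(frontier) == 1) frontier else sample(frontier, 1)
    patch <- c(patch, nxt)
    frontier <- setdiff(unique(c(frontier, adj[[nxt]])), patch)
  }
  patch
}

#' Emit structured noisy reads from a truth bundle
#'
#' Each read is `R1-adapter + barcode + UMI + transcript + revcomp(TSO)`,
#' corrupted by the bundle's position-independent substitution/insertion/
#' deletion channel; about half the reads are emitted reverse-complemented.
#' Quality strings are a constant Phred+33 fill.
#'
#' @param bundle A `truth_bundle` from [simulate_repertoire()].
#' @param mean_reads_per_umi Mean reads per planted UMI (each UMI gets
#'   `1 + rpois(mean_reads_per_umi - 1)` reads).
#' @param reads_per_clone Optional length-2 integer range; when given, each
#'   clone's total read count is drawn uniformly from it and allocated over
#'   its planted UMIs (each UMI keeps at least one read).
#' @param seed Seed for the read-level randomness; defaults to
#'   `bundle$seed + 1`.
#' @param qual_char Constant quality character (default `-`, Phred 12).
#' @return A list with `reads` (tibble `read_id`, `seq`, `qual`) and `truth`
#'   (tibble `read_id`, `clone_id`, `barcode`, `umi`, `strand`, `n_errors`).
#' @export
emit_reads <- function(bundle, mean_reads_per_umi = 2, reads_per_clone = NULL,
                       seed = bundle$seed + 1, qual_char = "-") {
  stopifnot(inherits(bundle, "truth_bundle"))
  er <- bundle$error_rates
  with_seed(seed, {
    planted <- bundle$planted
    if (nrow(planted) == 0) {
      return(list(
        reads = tibble(read_id = character(), seq = character(), qual = character()),
        truth = tibble(
          read_id = character(), clone_id = character(), barcode = character(),
          umi = character(), strand = character(), n_errors = integer()
        )
      ))
    }
    # one row per planted UMI
    umi_tbl <- planted[rep(seq_len(nrow(planted)), planted$n_umis), c("clone_id", "barcode")]
    umi_tbl$umi <- random_dna(nrow(umi_tbl), 12)
    if (is.null(reads_per_clone)) {
      umi_tbl$n_reads <- 1L + rpois(nrow(umi_tbl), max(mean_reads_per_umi - 1, 0))
    } else {
      umi_tbl <- umi_tbl |>
        group_by(.data$clone_id) |>
        mutate(n_reads = allocate_reads(
          dplyr::n(),
          sample(seq(reads_per_clone[1], reads_per_clone[2]), 1)
        )) |>
        ungroup()
    }
    read_tbl <- umi_tbl[rep(seq_len(nrow(umi_tbl)), umi_tbl$n_reads), c("clone_id", "barcode", "umi")]
    n <- nrow(read_tbl)
    read_tbl$read_id <- sprintf("read%07d", seq_len(n))
    tx <- setNames(bundle$clones$transcript, bundle$clones$clone_id)
    fwd <- paste0(
      r1_adapter(), read_tbl$barcode, read_tbl$umi,
      tx[read_tbl$clone_id], revcomp(tso_sequence())
    )
    corrupted <- corrupt_seqs(fwd, er[["sub"]], er[["ins"]], er[["del"]])
    strand <- ifelse(runif(n) < 0.5, "fwd", "rev")
    seqs <- corrupted$seq
    seqs[strand == "rev"] <- revcomp(seqs[strand == "rev"])
    list(
      reads = tibble(
        read_id = read_tbl$read_id, seq = seqs,
        qual = strrep(qual_char, nchar(seqs))
      ),
      truth = tibble(
        read_id = read_tbl$read_id, clone_id = read_tbl$clone_id,
        barcode = read_tbl$barcode, umi = read_tbl$umi, strand = strand,
        n_errors = corrupted$n_errors
      )
    )
  })
}

# >= 1 read per UMI, remainder multinomial.
allocate_reads <- function(n_umis, total) {
  total <- max(total, n_umis)
  extra <- stats::rmultinom(1, total - n_umis, rep(1 / n_umis, n_umis))[, 1]
  as.integer(1L + extra)
}

#' Apply a position-independent error channel
#'
#' Per base: deletion with probability `del`; otherwise substitution to one
#' of the three other bases with probability `sub`; an insertion of a
#' uniform random base occurs before each base (and after the last) with
#' probability `ins`.
#'
#' @param seqs Character vector of sequences.
#' @param sub,ins,del Per-base event probabilities.
#' @return A list with `seq` (corrupted sequences) and `n_errors`
#'   (integer count of events per sequence).
#' @export
corrupt_seqs <- function(seqs, sub, ins, del) {
  bases <- c("A", "C", "G", "T")
  out <- character(length(seqs))
  nerr <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    L <- length(ch)
    del_hit <- runif(L) < del
    sub_hit <- !del_hit & runif(L) < sub
    if (any(sub_hit)) {
      ch[sub_hit] <- vapply(
        ch[sub_hit],
        function(b) sample(setdiff(bases, b), 1), character(1),
        USE.NAMES = FALSE
      )
    }
    ins_hit <- runif(L + 1) < ins
    n_ins <- sum(ins_hit)
    if (n_ins > 0) {
      pieces <- character(L + 1)
      pieces[ins_hit] <- sample(bases, n_ins, replace = TRUE)
      kept <- c(ifelse(del_hit, "", ch), "")
      out[i] <- paste0(paste0(pieces, kept), collapse = "")
    } else {
      out[i] <- paste(ch[!del_hit], collapse = "")
    }
    nerr[i] <- sum(del_hit) + sum(sub_hit) + n_ins
  }
  list(seq = out, n_errors = nerr)
}
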