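#' Simulation configuration
#'
#' Bundles the knobs of the synthetic repertoire generator. Defaults emulate
#' the study's library chemistry: 500-1,000 bp sheared gDNA fragments, a 6N
#' UMI in the adapter, 2 x 300 paired-end sequencing, junctional trimming
#' that makes the three reading-frame offsets equiprobable, and error-free
#' base calls (quality Phred 35) so trimming behaviour can be tested
#' independently of assignment.
#'
#' @param n_molecules number of rearranged molecules to draw.
#' @param fragment_len_range sonication range in bp (gDNA).
#' @param umi_len UMI length; fixed at 6 by the library chemistry.
#' @param pcr_dup_rate probability that a molecule is re-sampled by PCR; each
#'   molecule yields `1 + Geometric(1 - rate)` identical reads, so the
#'   expected read count is `n / (1 - rate)`.
#' @param cross_prime_rate probability that a Jk primer amplifies a
#'   neighbouring Jk's product (the read then carries the wrong primer but
#'   the correct upstream Jk sequence).
#' @param seq_error_rate per-base substitution rate at read emission.
#' @param nmd_survival survival probability of a non-productive transcript in
#'   RNA libraries (nonsense-mediated decay).
#' @param read_len sequenced read length per mate.
#' @param v_trim_max junctional trimming: V-side loss uniform on
#'   `0:v_trim_max`. The default 2 makes frame offsets equiprobable.
#' @param j_trim_max J-side junctional loss, uniform on `0:j_trim_max`.
#' @param n_insert_max non-templated junctional insertion, uniform length on
#'   `0:n_insert_max`.
#' @param stop_injection_rate probability of planting a premature stop codon
#'   in the V portion of a molecule (off by default).
#' @param primer_set Jk PCR primer set used for gDNA libraries.
#' @param seed integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_molecules = 10000L,
                       fragment_len_range = c(500L, 1000L),
                       umi_len = 6L,
                       pcr_dup_rate = 0,
                       cross_prime_rate = 0,
                       seq_error_rate = 0,
                       nmd_survival = 0.1,
                       read_len = 300L,
                       v_trim_max = 2L,
                       j_trim_max = 0L,
                       n_insert_max = 0L,
                       stop_injection_rate = 0,
                       primer_set = c("primary", "alternate"),
                       seed = 1L) {
  primer_set <- match.arg(primer_set)
  probs <- c(pcr_dup_rate, cross_prime_rate, seq_error_rate, nmd_survival,
             stop_injection_rate)
  abort_if(any(probs < 0 | probs > 1), "rates must lie in [0, 1]")
  abort_if(umi_len != 6L, "the library chemistry uses a 6N UMI")
  abort_if(any(fragment_len_range <= 0) ||
             fragment_len_range[1] > fragment_len_range[2],
           "fragment_len_range must be a positive increasing pair")
  structure(list(
    n_molecules = as.integer(n_molecules),
    fragment_len_range = as.integer(fragment_len_range),
    umi_len = 6L, pcr_dup_rate = pcr_dup_rate,
    cross_prime_rate = cross_prime_rate, seq_error_rate = seq_error_rate,
    nmd_survival = nmd_survival, read_len = as.integer(read_len),
    v_trim_max = as.integer(v_trim_max), j_trim_max = as.integer(j_trim_max),
    n_insert_max = as.integer(n_insert_max),
    stop_injection_rate = stop_injection_rate,
    primer_set = primer_set, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate the ground-truth rearranged repertoire
#'
#' Draws `n_molecules` rearranged molecules from a per-gene x per-Jk
#' frequency matrix and realises each junction: the V-side trimming offset is
#' uniform over `0:v_trim_max` so the three reading-frame classes are
#' equiprobable under the defaults, and a molecule is productive iff its net
#' junctional offset preserves frame and no stop codon was injected.
#'
#' @param ref a `kappa_ref`.
#' @param config a [sim_config()].
#' @param freq optional genes x Jk frequency matrix (rownames = Vk names,
#'   colnames = Jk names); normalised to sum to 1. Defaults to log-normal
#'   per-gene weights crossed with Jk usage `c(0.4, 0.2, 0.2, 0.2)`,
#'   mirroring the observed dominance of Jk1.
#' @param promoter_strength optional positive per-gene multiplier applied
#'   only in RNA simulation (default all 1).
#' @param planted_effect coefficient linking the designated synthetic
#'   coverage track to log-frequency (consumed by
#'   [simulate_signal_tracks()]).
#' @return A list of class `kappa_truth` with elements `freq`,
#'   `promoter_strength`, `molecules` (one row per molecule with its junction
#'   realisation and productivity flag) and `planted_effect`.
#' @export
simulate_repertoire <- function(ref, config, freq = NULL,
                                promoter_strength = NULL,
                                planted_effect = 1) {
  set.seed(config$seed)
  genes <- ref$v_genes$name
  jks <- ref$j_genes$name
  if (is.null(freq)) {
    gw <- stats::rlnorm(length(genes), 0, 1)
    jw <- c(0.4, 0.2, 0.2, 0.2)
    freq <- outer(gw / sum(gw), jw)
    dimnames(freq) <- list(genes, jks)
  }
  abort_if(!all(rownames(freq) %in% genes) || !all(colnames(freq) %in% jks),
           "freq dimnames must match the reference gene names")
  abort_if(sum(freq) <= 0, "degenerate frequency matrix: all zero")
  freq <- freq / sum(freq)
  if (is.null(promoter_strength)) {
    promoter_strength <- stats::setNames(rep(1, length(genes)), genes)
  }
  abort_if(any(promoter_strength <= 0), "promoter_strength must be positive")

  n <- config$n_molecules
  cell <- sample.int(length(freq), n, replace = TRUE, prob = as.vector(freq))
  gi <- (cell - 1L) %% nrow(freq) + 1L
  ji <- (cell - 1L) %/% nrow(freq) + 1L

  v_trim <- sample.int(config$v_trim_max + 1L, n, replace = TRUE) - 1L
  j_trim <- if (config$j_trim_max > 0) {
    sample.int(config$j_trim_max + 1L, n, replace = TRUE) - 1L
  } else rep(0L, n)
  ins_len <- if (config$n_insert_max > 0) {
    sample.int(config$n_insert_max + 1L, n, replace = TRUE) - 1L
  } else rep(0L, n)
  ins_seq <- ifelse(ins_len > 0, vapply(ins_len, function(l) {
    if (l > 0) paste(sample(DNA_BASES, l, replace = TRUE), collapse = "") else ""
  }, character(1)), "")
  offset <- (ins_len - v_trim - j_trim) %% 3L
  stop_injected <- stats::runif(n) < config$stop_injection_rate

  molecules <- tibble::tibble(
    molecule_id = seq_len(n),
    v_gene = rownames(freq)[gi],
    jk = colnames(freq)[ji],
    v_trim = v_trim, j_trim = j_trim,
    insert_len = ins_len, insert_seq = ins_seq,
    frame_offset = offset,
    stop_injected = stop_injected,
    productive = offset == 0L & !stop_injected,
    umi = random_umi(n)
  )
  structure(list(freq = freq, promoter_strength = promoter_strength,
                 molecules = molecules, planted_effect = planted_effect,
                 config = config),
            class = "kappa_truth")
}

# The V-segment retained in each molecule (V-sense, after junctional trim),
# with optional planted stop codon.
molecule_v_segment <- function(truth, ref) {
  vs <- v_sequences(ref)
  m <- truth$molecules
  seqs <- substr(vs[m$v_gene], 1L, nchar(vs[m$v_gene]) - m$v_trim)
  if (any(m$stop_injected)) {
    idx <- which(m$stop_injected)
    for (i in idx) {
      # overwrite an interior in-frame codon with TAA
      pos <- 3L * (nchar(seqs[i]) %/% 6L) + 1L
      substr(seqs[i], pos, pos + 2L) <- "TAA"
    }
  }
  unname(seqs)
}

read_names <- function(m, dup_index) {
  paste0("mol|", m$molecule_id, "|", m$v_gene, "|", m$jk, "|",
         ifelse(m$productive, "P", "NP"), "|dup", dup_index)
}

#' Parse ground-truth labels out of simulated read names
#'
#' Read names carry `(molecule id, Vk gene, Jk gene, productivity)` so that
#' oracle tests can score the pipeline without sidecar files. The pipeline
#' itself never consumes these labels.
#'
#' @param read_id character vector of simulated read names.
#' @return Tibble with `molecule_id`, `true_v`, `true_jk`, `true_productive`.
#' @export
parse_truth_labels <- function(read_id) {
  parts <- stringr::str_split_fixed(read_id, stringr::fixed("|"), 6)
  tibble::tibble(
    molecule_id = as.integer(parts[, 2]),
    true_v = parts[, 3],
    true_jk = parts[, 4],
    true_productive = parts[, 5] == "P"
  )
}

apply_seq_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- stats::rbinom(1L, n, rate)
    if (k == 0) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

pcr_expand <- function(n, rate) {
  if (rate <= 0) return(rep(1L, n))
  1L + stats::rgeom(n, prob = 1 - rate)
}

emit_pairs <- function(amplicon, umi, m, config) {
  copies <- pcr_expand(nrow(m), config$pcr_dup_rate)
  idx <- rep(seq_len(nrow(m)), copies)
  dup_i <- sequence(copies)
  full <- paste0(umi, amplicon)[idx]
  rl <- config$read_len
  seq1 <- substr(full, 1L, rl)
  seq2 <- revcomp(substr(full, pmax(1L, nchar(full) - rl + 1L), nchar(full)))
  seq1 <- apply_seq_errors(seq1, config$seq_error_rate)
  seq2 <- apply_seq_errors(seq2, config$seq_error_rate)
  tibble::tibble(
    read_id = read_names(m[idx, ], dup_i),
    seq1 = seq1, qual1 = phred_string(nchar(seq1)),
    seq2 = seq2, qual2 = phred_string(nchar(seq2)),
    clipped = nchar(full) < rl
  )
}

#' Simulate a gDNA (VDJ-seq style) repertoire library
#'
#' Each rearranged molecule is sheared (fragment length uniform over the
#' sonication range; the fragment always spans the junction and the Jk
#' primer), ligated to a 6N-UMI adapter at the shear end and amplified from a
#' Jk primer. The amplicon runs from the shear point inside the Vk gene to
#' the primer; the shear point is uniform over the positions that leave at
#' least `min_v_cov` bp of V sequence in the amplicon. Cross-primed molecules
#' carry the wrong Jk primer but the correct upstream Jk exon sequence. PCR
#' duplicates re-emit the identical (UMI, shear start) read.
#'
#' @param truth a `kappa_truth` from [simulate_repertoire()].
#' @param ref the `kappa_ref` used to build the truth.
#' @param config the [sim_config()].
#' @param dir if non-`NULL`, write `R1.fastq.gz`/`R2.fastq.gz` there.
#' @param min_v_cov minimum V bases retained in the amplicon.
#' @return Tibble of read pairs (`read_id`, `seq1`, `qual1`, `seq2`, `qual2`,
#'   `clipped`), with attributes `chemistry = "gdna"`, `primer_set`, and
#'   `files` when written. Read ids encode ground truth for oracle tests.
#' @export
simulate_gdna_library <- function(truth, ref, config, dir = NULL,
                                  min_v_cov = 150L) {
  force(truth)  # arguments may carry their own RNG use; settle them first
  set.seed(config$seed + 1L)
  m <- truth$molecules
  vseg <- molecule_v_segment(truth, ref)
  jx <- j_sequences(ref)
  primers <- j_primers(ref, config$primer_set)
  po <- if (config$primer_set == "primary") {
    ref$j_genes$primer_offset_primary[1]
  } else ref$j_genes$primer_offset_alternate[1]

  # shear start (1-based within the V-sense segment), uniform over the span
  # that keeps >= min_v_cov V bases
  span <- pmax(1L, nchar(vseg) - min_v_cov + 1L)
  v_start <- 1L + floor(stats::runif(nrow(m)) * span)
  v_part <- substr(vseg, v_start, nchar(vseg))

  # cross-priming: the annealed primer belongs to another Jk
  primer_jk <- m$jk
  crossed <- stats::runif(nrow(m)) < config$cross_prime_rate
  if (any(crossed)) {
    others <- vapply(m$jk[crossed], function(j) {
      sample(setdiff(names(jx), j), 1L)
    }, character(1))
    primer_jk[crossed] <- others
  }
  upstream <- substr(jx[m$jk], 1L + m$j_trim, po - 1L)
  amplicon <- paste0(v_part, m$insert_seq, upstream, primers[primer_jk])

  m2 <- dplyr::mutate(m, v_start = v_start, primer_jk = primer_jk)
  reads <- emit_pairs(amplicon, m$umi, m2, config)
  attr(reads, "chemistry") <- "gdna"
  attr(reads, "primer_set") <- config$primer_set
  if (!is.null(dir)) attr(reads, "files") <- write_fastq_pair(reads, dir)
  reads
}

#' Simulate a 5' RACE RNA repertoire library
#'
#' Transcripts are sampled from the ground-truth molecules with weight
#' `promoter_strength[gene] * (1 if productive else nmd_survival)`,
#' emulating promoter-strength bias and nonsense-mediated decay. Each
#' transcript covers the full-length V region, carries a fresh 6N UMI in the
#' 5' bridge adapter, and extends through the Jk exon into constant-region
#' sequence.
#'
#' @inheritParams simulate_gdna_library
#' @param n_transcripts number of transcript molecules to sample (default:
#'   `config$n_molecules`).
#' @return Tibble of read pairs as in [simulate_gdna_library()], with
#'   attribute `chemistry = "rna"`.
#' @export
simulate_rna_library <- function(truth, ref, config, dir = NULL,
                                 n_transcripts = NULL) {
  force(truth)
  set.seed(config$seed + 2L)
  m <- truth$molecules
  w <- truth$promoter_strength[m$v_gene] *
    ifelse(m$productive, 1, config$nmd_survival)
  abort_if(sum(w) <= 0, "no transcript survives: all weights zero")
  n_tr <- n_transcripts %||% config$n_molecules
  pick <- sample.int(nrow(m), n_tr, replace = TRUE, prob = w)

  vseg <- molecule_v_segment(truth, ref)
  jx <- j_sequences(ref)
  j <- ref$j_genes
  const_seq <- stats::setNames(vapply(seq_len(nrow(j)), function(i) {
    subseq0(ref$genome[[j$chrom[i]]], j$end[i], j$end[i] + 60L)
  }, character(1)), j$name)

  mt <- m[pick, ]
  transcript <- paste0(vseg[pick], mt$insert_seq,
                       substr(jx[mt$jk], 1L + mt$j_trim, nchar(jx[mt$jk])),
                       const_seq[mt$jk])
  umi <- random_umi(n_tr)
  reads <- emit_pairs(transcript, umi, mt, config)
  attr(reads, "chemistry") <- "rna"
  if (!is.null(dir)) attr(reads, "files") <- write_fastq_pair(reads, dir)
  reads
}

#' Molecule-level junction table for productivity analysis
#'
#' Reconstructs, for every simulated molecule, the junction-bearing sequence
#' (retained V segment, insertions, retained Jk exon) together with the
#' coordinates [call_productive()] consumes, so productivity can be called
#' on the exact molecule population without read-level processing.
#'
#' @param truth a `kappa_truth`.
#' @param ref the `kappa_ref` used to build it.
#' @return Tibble with one row per molecule: `v_gene`, `v_start`, `v_end`,
#'   `jk`, `j_trim`, `insert_len`, `seq`, `j_read_start`.
#' @export
junction_calls <- function(truth, ref) {
  m <- truth$molecules
  vseg <- molecule_v_segment(truth, ref)
  jx <- j_sequences(ref)
  v_len <- stats::setNames(nchar(v_sequences(ref)), ref$v_genes$name)
  jpart <- substr(jx[m$jk], 1L + m$j_trim, nchar(jx[m$jk]))
  tibble::tibble(
    molecule_id = m$molecule_id,
    v_gene = m$v_gene,
    v_start = 1L,
    v_end = unname(v_len[m$v_gene]) - m$v_trim,
    jk = m$jk,
    j_trim = m$j_trim,
    insert_len = m$insert_len,
    seq = paste0(vseg, m$insert_seq, jpart),
    j_read_start = nchar(vseg) + m$insert_len + 1L
  )
}
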