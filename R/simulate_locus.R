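#' Simulate a ground-truthed Igk-like locus
#'
#' Builds a single-chromosome genome slice laid out like the mouse Igk locus:
#' Vk genes spaced along the left of the slice (most Jk-proximal gene closest
#' to the Jk cluster), the four functional Jk genes at the right end on the
#' plus strand. Each Vk gene carries a leader exon + intron, a stop-free
#' in-frame coding region and an RSS; a configurable fraction of genes are
#' inversional (minus strand), mirroring the real locus where over half of
#' the Vk genes oppose the Jk--Ck cluster. Optionally, pairs of genes share
#' an identical 3'-most 150 bp of coding sequence, reproducing the three
#' ambiguous pairs of the real annotation; each member gets a discriminating
#' upstream tag registered in the pair table.
#'
#' @param n_v number of Vk genes.
#' @param v_len coding length in bp (multiple of 3).
#' @param n_pairs number of 3'-identical gene pairs to plant.
#' @param frac_inversional fraction of genes in inversional orientation.
#' @param frac_pseudogene fraction annotated as pseudogenes.
#' @param spacing distance in bp between consecutive gene slots; the default
#'   leaves room for non-overlapping 2.5 kb flanking feature windows.
#' @param seed integer RNG seed.
#' @return A validated `kappa_ref`.
#' @export
simulate_locus <- function(n_v = 20L, v_len = 294L, n_pairs = 0L,
                           frac_inversional = 0.55, frac_pseudogene = 0.2,
                           spacing = 9000L, seed = 1L) {
  abort_if(v_len %% 3L != 0L, "v_len must be a multiple of 3")
  abort_if(2L * n_pairs > n_v, "too many identical pairs for n_v")
  abort_if(spacing < 3200L + 165L + v_len + 28L + 3100L,
           "spacing too small for non-overlapping feature windows")
  set.seed(seed)

  leader_len <- 45L   # leader exon
  intron_len <- 120L
  rss_len <- 28L      # heptamer-spacer-nonamer footprint
  # room upstream of leader 1: must exceed the 500 bp promoter pad plus the
  # 2.5 kb upstream feature window so no gene's windows cross its slot
  pre_leader <- 3200L

  chrom <- "chrIgk"
  genome_parts <- character(0)
  pos <- 0L
  rows <- list()

  orient <- ifelse(stats::runif(n_v) < frac_inversional, "inversional", "deletional")
  func <- sample(c("functional", "ORF", "pseudogene"), n_v, replace = TRUE,
                 prob = c(1 - frac_pseudogene - 0.05, 0.05, frac_pseudogene))
  # RSS quality: functional genes tend to carry better (higher) RIC scores.
  ric <- round(stats::rnorm(n_v, mean = ifelse(func == "pseudogene", -38, -28), sd = 4), 2)

  # Pair members are consecutive distal-side genes; the second member's coding
  # 3' 150 bp is copied from the first.
  pair_first <- if (n_pairs > 0) seq.int(n_v - 2L * n_pairs + 1L, by = 2L,
                                         length.out = n_pairs) else integer(0)

  coding_seqs <- character(n_v)
  for (i in seq_len(n_v)) {
    coding_seqs[i] <- random_orf(v_len %/% 3L)
    if ((i - 1L) %in% pair_first) {
      donor <- coding_seqs[i - 1L]
      coding_seqs[i] <- paste0(substr(coding_seqs[i], 1L, v_len - 150L),
                               substr(donor, v_len - 149L, v_len))
    }
  }

  # Genes are emitted distal -> proximal left to right; gene 1 (most proximal)
  # sits immediately left of the Jk cluster.
  for (i in rev(seq_len(n_v))) {
    slot_start <- pos
    slot_end <- pos + spacing
    gap <- spacing - (pre_leader + leader_len + intron_len + v_len + rss_len)
    # V-sense layout within the slot: [pre_leader][leader][intron][coding][rss][gap]
    v_sense <- paste0(random_dna(pre_leader),
                      random_dna(leader_len), random_dna(intron_len),
                      coding_seqs[i], random_dna(rss_len), random_dna(gap))
    if (orient[i] == "deletional") {
      slot_seq <- v_sense
      leader_start <- slot_start + pre_leader
      leader_end <- leader_start + leader_len + intron_len
      leader1_start <- leader_start
      cstart <- leader_end
      cend <- cstart + v_len
      rss_start <- cend
      rss_end <- rss_start + rss_len
    } else {
      # Minus strand: the V-sense layout appears reverse-complemented, so
      # genomically the slot reads [gap][rss][coding][intron+leader][pre_leader].
      slot_seq <- revcomp(v_sense)
      rss_start <- slot_start + gap
      rss_end <- rss_start + rss_len
      cstart <- rss_end
      cend <- cstart + v_len
      leader_start <- cend
      leader_end <- leader_start + leader_len + intron_len
      leader1_start <- leader_end  # 5'-most leader base lies rightmost
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      chrom = chrom, start = cstart, end = cend,
      name = paste0("Vk", ((i - 1L) %% 18L) + 1L, "-", i),
      family = ((i - 1L) %% 18L) + 1L,
      orientation = orient[i], functionality = func[i], ric_score = ric[i],
      leader1_start = leader1_start, leader_start = leader_start,
      leader_end = leader_end, rss_start = rss_start, rss_end = rss_end
    )
    genome_parts <- c(genome_parts, slot_seq)
    pos <- pos + spacing
  }

  # Jk cluster: four exons on the plus strand, with primer sites inside and
  # downstream of each exon (primary offset 24, alternate offset 34).
  j_exon_len <- 39L
  j_gap <- 350L
  j_rows <- list()
  pos <- pos + 2000L
  genome_parts <- c(genome_parts, random_dna(2000L))
  for (k in c(1L, 2L, 4L, 5L)) {
    exon <- random_orf(j_exon_len %/% 3L)
    j_rows[[length(j_rows) + 1L]] <- tibble::tibble(
      chrom = chrom, start = pos, end = pos + j_exon_len,
      name = paste0("Jk", k),
      primer_offset_primary = 24L, primer_offset_alternate = 34L
    )
    genome_parts <- c(genome_parts, exon, random_dna(j_gap - j_exon_len))
    pos <- pos + j_gap
  }
  genome_parts <- c(genome_parts, random_dna(500L))

  genome <- stats::setNames(paste(genome_parts, collapse = ""), chrom)
  v_genes <- dplyr::bind_rows(rev(rows))  # order Jk-proximal -> distal
  j_genes <- dplyr::bind_rows(j_rows)

  pairs <- NULL
  if (n_pairs > 0) {
    vs_tmp <- v_genes
    ref_tmp <- structure(list(genome = genome, v_genes = vs_tmp,
                              j_genes = j_genes, pairs = NULL),
                         class = "kappa_ref")
    vseq <- v_sequences(ref_tmp)
    pairs <- purrr::map_dfr(pair_first, function(a) {
      na <- v_genes$name[a]
      nb <- v_genes$name[a + 1L]
      # tags sit in the upstream unique region, at a depth most sheared
      # fragments still cover
      tibble::tibble(member_a = na, member_b = nb,
                     tag_a = substr(vseq[[na]], 61L, 90L),
                     tag_b = substr(vseq[[nb]], 61L, 90L))
    })
  }

  assign_halves(kappa_ref(genome, v_genes, j_genes, pairs))
}
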