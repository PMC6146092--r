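# Repertoire statistics: counts, frequency views, Jk usage, active-gene
# classification, gDNA/RNA and genotype ratio analyses, locus-half bias.

#' Tabulate deduplicated calls into per-sample counts
#'
#' @param calls deduplicated VJCall tibble; rows without both a V and a J
#'   assignment are dropped.
#' @return Tibble with `sample_id`, `v_gene`, `jk`, `n`.
#' @export
repertoire_counts <- function(calls) {
  if (!"sample_id" %in% names(calls)) calls$sample_id <- NA_character_
  calls |>
    dplyr::filter(!is.na(.data$v_gene), !is.na(.data$jk)) |>
    dplyr::count(.data$sample_id, .data$v_gene, .data$jk, name = "n") |>
    dplyr::mutate(n = as.numeric(.data$n))
}

restrict_view <- function(counts, view) {
  if (identical(view, "all")) return(counts)
  abort_if(!view %in% counts$jk, paste0("no reads for view ", view))
  counts[counts$jk == view, ]
}

#' Per-gene rearrangement frequencies
#'
#' Pooled-replicate frequency of each Vk gene: the summed count over all
#' samples divided by the summed total, within a repertoire view (`"all"`
#' for VkJkALL, or one Jk name for e.g. the VkJk1 repertoire). Per-replicate
#' vectors are returned instead when `per_replicate = TRUE`.
#'
#' @param counts tibble from [repertoire_counts()] (possibly reallocated).
#' @param view `"all"` or a Jk gene name.
#' @param per_replicate return one frequency vector per sample.
#' @return Tibble with `v_gene`, `n`, `freq` (and `sample_id` if per
#'   replicate).
#' @export
repertoire_frequencies <- function(counts, view = "all",
                                   per_replicate = FALSE) {
  counts <- restrict_view(counts, view)
  grp <- if (per_replicate) c("sample_id", "v_gene") else "v_gene"
  out <- counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  if (per_replicate) {
    out <- out |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(freq = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
    abort_if(any(!is.finite(out$freq)), "a sample has zero total reads")
  } else {
    tot <- sum(out$n)
    abort_if(tot <= 0, "zero total reads")
    out$freq <- out$n / tot
  }
  out
}

#' Global Jk usage
#'
#' Percentage of rearrangements using each Jk gene, per sample and pooled.
#'
#' @param counts tibble from [repertoire_counts()].
#' @return Tibble with `sample_id` (`"pooled"` row included), `jk`, `n`,
#'   `pct`.
#' @export
jk_usage <- function(counts) {
  per <- counts |>
    dplyr::group_by(.data$sample_id, .data$jk) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop_last") |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  pooled <- counts |>
    dplyr::group_by(.data$jk) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(sample_id = "pooled", pct = 100 * .data$n / sum(.data$n))
  dplyr::bind_rows(per, pooled)
}

#' Per-gene Jk usage profiles
#'
#' The Jk distribution of each Vk gene, restricted to genes with at least
#' `min_reads` reads in every sample (the per-gene profile is unstable
#' below that depth).
#'
#' @param counts tibble from [repertoire_counts()].
#' @param min_reads minimum per-sample read count for a gene to be profiled.
#' @return Tibble with `v_gene`, `jk`, `n`, `pct` (pooled across samples).
#' @export
jk_usage_per_gene <- function(counts, min_reads = 5) {
  n_samples <- length(unique(counts$sample_id))
  eligible <- counts |>
    dplyr::group_by(.data$sample_id, .data$v_gene) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::group_by(.data$v_gene) |>
    dplyr::summarise(ok = dplyr::n() == n_samples && all(.data$n >= min_reads),
                     .groups = "drop") |>
    dplyr::filter(.data$ok)
  counts |>
    dplyr::filter(.data$v_gene %in% eligible$v_gene) |>
    dplyr::group_by(.data$v_gene, .data$jk) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop_last") |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Correlation matrix between per-Jk repertoires
#'
#' Pearson correlations, across Vk genes, between the frequency vectors of
#' the individual Jk repertoires (genes absent from a repertoire count as
#' frequency 0).
#'
#' @param counts tibble from [repertoire_counts()].
#' @return Jk x Jk correlation matrix.
#' @export
jk_repertoire_correlations <- function(counts) {
  wide <- counts |>
    dplyr::group_by(.data$jk, .data$v_gene) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::group_by(.data$jk) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "jk", values_from = "freq",
                       values_fill = 0)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$v_gene
  stats::cor(m)
}

#' Classify Vk genes as active or inactive
#'
#' In the deeply sequenced pre-B mode a gene is active iff its pooled count
#' reaches `threshold_per_million` reads per million pooled reads. In the
#' shallow pro-B mode the cut-off is an absolute `min_reads` (1 read by
#' default).
#'
#' @param counts tibble from [repertoire_counts()] (all replicates pooled).
#' @param mode `"preB"` (reads-per-million threshold) or `"proB"` (absolute).
#' @param threshold_per_million reads-per-million threshold for pre-B mode.
#' @param min_reads absolute cut-off for pro-B mode.
#' @param genes optional character vector of the full gene universe, so that
#'   genes with zero reads appear as inactive rows.
#' @return Tibble with `v_gene`, `n`, `active` (logical).
#' @export
classify_active <- function(counts, mode = c("preB", "proB"),
                            threshold_per_million = 15, min_reads = 1,
                            genes = NULL) {
  mode <- match.arg(mode)
  per_gene <- counts |>
    dplyr::group_by(.data$v_gene) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  if (!is.null(genes)) {
    per_gene <- tibble::tibble(v_gene = genes) |>
      dplyr::left_join(per_gene, by = "v_gene") |>
      dplyr::mutate(n = tidyr::replace_na(.data$n, 0))
  }
  total <- sum(per_gene$n)
  cut <- if (mode == "preB") threshold_per_million * total / 1e6 else min_reads
  dplyr::mutate(per_gene, active = .data$n >= cut)
}

# Align two count tables replicate-by-replicate. Default pairing matches the
# sorted sample ids positionally.
replicate_pairing <- function(counts_a, counts_b, pairing = NULL) {
  if (is.null(pairing)) {
    sa <- sort(unique(counts_a$sample_id))
    sb <- sort(unique(counts_b$sample_id))
    abort_if(length(sa) != length(sb),
             "tables have different replicate counts; supply a pairing")
    pairing <- tibble::tibble(sample_a = sa, sample_b = sb)
  }
  abort_if(!all(pairing$sample_a %in% counts_a$sample_id) ||
             !all(pairing$sample_b %in% counts_b$sample_id),
           "pairing names samples absent from the tables")
  pairing
}

#' Flag genes divergent between two repertoires
#'
#' Per-gene, per-replicate frequency ratios between two paired repertoire
#' tables (e.g. gDNA vs RNA from the same sorted cells). A gene is flagged
#' divergent in one direction iff the arithmetic mean of its replicate
#' ratios is at least `min_fold_avg` and every individual replicate ratio is
#' at least `min_fold_each` in that same direction. Genes lacking reads in
#' any replicate of either table are excluded, as are pseudogenes when
#' `functional_only` is set.
#'
#' @param counts_a,counts_b tibbles from [repertoire_counts()].
#' @param ref a `kappa_ref` (needed for `functional_only`).
#' @param pairing optional tibble (`sample_a`, `sample_b`) aligning
#'   replicates; defaults to positional matching of sorted sample ids.
#' @param min_fold_avg threshold on the mean replicate ratio.
#' @param min_fold_each threshold on every individual replicate ratio.
#' @param functional_only drop pseudogenes before testing.
#' @param view repertoire view passed to the per-replicate frequencies.
#' @return Tibble with `v_gene`, `mean_ratio_ab`, `mean_ratio_ba`,
#'   `flag` (`"A"`, `"B"` or `NA`); per-replicate ratios in the
#'   `replicate_ratios` attribute.
#' @export
ratio_analysis <- function(counts_a, counts_b, ref = NULL, pairing = NULL,
                           min_fold_avg = 2, min_fold_each = 1.5,
                           functional_only = FALSE, view = "all") {
  pairing <- replicate_pairing(counts_a, counts_b, pairing)
  fa <- repertoire_frequencies(restrict_view(counts_a, view), "all",
                               per_replicate = TRUE)
  fb <- repertoire_frequencies(restrict_view(counts_b, view), "all",
                               per_replicate = TRUE)
  if (functional_only) {
    abort_if(is.null(ref), "functional_only requires the locus reference")
    keep <- ref$v_genes$name[ref$v_genes$functionality != "pseudogene"]
    fa <- fa[fa$v_gene %in% keep, ]
    fb <- fb[fb$v_gene %in% keep, ]
  }
  n_rep <- nrow(pairing)
  merged <- purrr::map_dfr(seq_len(n_rep), function(i) {
    a <- fa[fa$sample_id == pairing$sample_a[i], c("v_gene", "freq")]
    b <- fb[fb$sample_id == pairing$sample_b[i], c("v_gene", "freq")]
    dplyr::inner_join(a, b, by = "v_gene", suffix = c("_a", "_b")) |>
      dplyr::mutate(replicate = i)
  })
  # only genes with reads in every replicate of both tables
  complete_genes <- merged |>
    dplyr::filter(.data$freq_a > 0, .data$freq_b > 0) |>
    dplyr::count(.data$v_gene) |>
    dplyr::filter(.data$n == n_rep)
  merged <- merged |>
    dplyr::filter(.data$v_gene %in% complete_genes$v_gene) |>
    dplyr::mutate(ratio_ab = .data$freq_a / .data$freq_b,
                  ratio_ba = .data$freq_b / .data$freq_a)
  out <- merged |>
    dplyr::group_by(.data$v_gene) |>
    dplyr::summarise(
      mean_ratio_ab = mean(.data$ratio_ab),
      mean_ratio_ba = mean(.data$ratio_ba),
      all_ab = all(.data$ratio_ab >= min_fold_each),
      all_ba = all(.data$ratio_ba >= min_fold_each),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      flag = dplyr::case_when(
        .data$mean_ratio_ab >= min_fold_avg & .data$all_ab ~ "A",
        .data$mean_ratio_ba >= min_fold_avg & .data$all_ba ~ "B",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::select(-"all_ab", -"all_ba")
  attr(out, "replicate_ratios") <- merged
  out
}

#' Frequency ratios with zero replacement
#'
#' Computes per-gene frequency ratios between two repertoires, replacing a
#' zero frequency by the frequency equivalent of a single read (1/total of
#' that repertoire) so a ratio can still be formed; such ratios are flagged
#' as an underrepresentation of the actual difference. Genes at zero in both
#' repertoires are skipped.
#'
#' @param freq_a,freq_b tibbles with `v_gene` and `freq` covering the same
#'   gene universe (missing genes count as frequency 0).
#' @param total_a,total_b total read counts behind each frequency vector.
#' @return Tibble with `v_gene`, `freq_a`, `freq_b`, `ratio_ab`,
#'   `replaced` (`"a"`, `"b"` or `NA`), `underrepresented` (logical).
#' @export
pseudo_count_ratio <- function(freq_a, freq_b, total_a, total_b) {
  abort_if(total_a <= 0 || total_b <= 0, "totals must be positive")
  genes <- union(freq_a$v_gene, freq_b$v_gene)
  a <- stats::setNames(rep(0, length(genes)), genes)
  a[freq_a$v_gene] <- freq_a$freq
  b <- stats::setNames(rep(0, length(genes)), genes)
  b[freq_b$v_gene] <- freq_b$freq
  both_zero <- a == 0 & b == 0
  genes <- genes[!both_zero]
  a <- a[!both_zero]
  b <- b[!both_zero]
  replaced <- dplyr::case_when(a == 0 ~ "a", b == 0 ~ "b",
                               TRUE ~ NA_character_)
  a2 <- ifelse(a == 0, 1 / total_a, a)
  b2 <- ifelse(b == 0, 1 / total_b, b)
  tibble::tibble(
    v_gene = genes, freq_a = unname(a), freq_b = unname(b),
    ratio_ab = unname(a2 / b2),
    replaced = replaced,
    underrepresented = !is.na(replaced)
  )
}

#' Proximal/distal locus-half frequency split
#'
#' Sums each sample's rearrangement frequency over the Jk-proximal and
#' Jk-distal halves of the locus.
#'
#' @param counts tibble from [repertoire_counts()].
#' @param ref a `kappa_ref` with halves assigned.
#' @param view repertoire view (`"all"` or a Jk name).
#' @return Tibble with `sample_id`, `proximal`, `distal` (summing to 1).
#' @export
half_bias <- function(counts, ref, view = "all") {
  abort_if(any(is.na(ref$v_genes$half)), "assign_halves() first")
  halves <- stats::setNames(ref$v_genes$half, ref$v_genes$name)
  restrict_view(counts, view) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::mutate(half = unname(halves[.data$v_gene])) |>
    dplyr::summarise(
      proximal = sum(.data$freq[.data$half == "proximal"]),
      distal = sum(.data$freq[.data$half == "distal"]),
      .groups = "drop"
    )
}

#' Paired comparison of distal-half usage between two repertoires
#'
#' @param bias_a,bias_b tibbles from [half_bias()].
#' @param pairing optional replicate pairing as in [ratio_analysis()].
#' @return Tibble with one row per replicate pair and the distal-half
#'   frequency difference (a minus b).
#' @export
half_bias_paired <- function(bias_a, bias_b, pairing = NULL) {
  if (is.null(pairing)) {
    sa <- sort(bias_a$sample_id)
    sb <- sort(bias_b$sample_id)
    abort_if(length(sa) != length(sb), "unequal replicate counts")
    pairing <- tibble::tibble(sample_a = sa, sample_b = sb)
  }
  purrr::map_dfr(seq_len(nrow(pairing)), function(i) {
    da <- bias_a$distal[bias_a$sample_id == pairing$sample_a[i]]
    db <- bias_b$distal[bias_b$sample_id == pairing$sample_b[i]]
    tibble::tibble(sample_a = pairing$sample_a[i],
                   sample_b = pairing$sample_b[i],
                   distal_a = da, distal_b = db,
                   distal_diff = da - db)
  })
}
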