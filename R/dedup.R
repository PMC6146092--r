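# PCR-duplicate collapse and reallocation of counts between 3'-identical
# Vk gene pairs.

#' Collapse PCR duplicates
#'
#' Reads sharing the same dedup key are presumed to originate from the same
#' molecule and are counted once (the first occurrence in stable input order
#' is retained). The key is the 6N adapter UMI for both chemistries, plus
#' the V read start position for gDNA, whose shear points are random; the
#' assigned (V gene, Jk) pair is always part of the key so molecules from
#' different genes never collapse.
#'
#' @param calls VJCall tibble from one sample (columns `umi`, `v_gene`,
#'   `jk`, and `v_start` for gDNA).
#' @param chemistry `"gdna"` or `"rna"`; defaults to the calls' `chemistry`
#'   column when present.
#' @return The deduplicated calls tibble.
#' @export
dedup_calls <- function(calls, chemistry = NULL) {
  if (is.null(chemistry)) {
    abort_if(!"chemistry" %in% names(calls),
             "chemistry must be given or present as a column")
    chem <- unique(calls$chemistry)
    abort_if(length(chem) != 1, "mixed chemistries in one batch")
    chemistry <- chem
  }
  abort_if(!chemistry %in% c("gdna", "rna"), "unknown chemistry")
  key_cols <- c("v_gene", "jk", "umi")
  if (chemistry == "gdna") key_cols <- c(key_cols, "v_start")
  if ("sample_id" %in% names(calls)) key_cols <- c("sample_id", key_cols)
  dplyr::distinct(calls, dplyr::across(dplyr::all_of(key_cols)),
                  .keep_all = TRUE)
}

#' Count discriminating-tag hits for identical-pair reads
#'
#' For each registered 3'-identical pair, reads assigned to either member
#' whose sequence is long enough to reach the discriminating upstream region
#' are searched for each member's tag string.
#'
#' @param calls deduplicated VJCall tibble with a `seq` column.
#' @param ref a `kappa_ref` with a pair registry.
#' @return Tibble with one row per (sample, pair): `member_a`, `member_b`,
#'   `hits_a`, `hits_b`.
#' @export
count_tag_hits <- function(calls, ref) {
  abort_if(is.null(ref$pairs) || nrow(ref$pairs) == 0,
           "reference has no identical-pair registry")
  abort_if(!"seq" %in% names(calls), "calls must retain the read sequence")
  if (!"sample_id" %in% names(calls)) calls$sample_id <- NA_character_
  purrr::map_dfr(seq_len(nrow(ref$pairs)), function(i) {
    p <- ref$pairs[i, ]
    sub <- calls[calls$v_gene %in% c(p$member_a, p$member_b) &
                   !is.na(calls$v_gene), ]
    sub |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(
        member_a = p$member_a, member_b = p$member_b,
        hits_a = sum(grepl(p$tag_a, .data$seq, fixed = TRUE)),
        hits_b = sum(grepl(p$tag_b, .data$seq, fixed = TRUE)),
        .groups = "drop"
      )
  })
}

#' Reallocate counts between 3'-identical Vk gene pairs
#'
#' Reads covering only the shared 3' 150 bp of an identical pair are
#' assigned to one member arbitrarily, so the pooled pair total is reliable
#' but its split is not. Among reads long enough to cover each member's
#' discriminating upstream tag, the tag-hit ratio a:b re-divides the pooled
#' total: `n_a' = T * a/(a+b)`, `n_b' = T * b/(a+b)`. Fractional counts are
#' kept (rounding happens only at report time) and the pair total is
#' conserved exactly. A pair with no tag-covering reads is left unadjusted
#' with a warning.
#'
#' @param counts tibble with `sample_id`, `v_gene`, `jk`, `n` (e.g. from
#'   [repertoire_counts()]).
#' @param tag_hits tibble from [count_tag_hits()] (per sample:
#'   `member_a`, `member_b`, `hits_a`, `hits_b`).
#' @return `counts` with pair members' `n` re-divided; an `audit` attribute
#'   records (pair, total, hits, adjusted counts) per sample.
#' @export
reallocate_identical_pairs <- function(counts, tag_hits) {
  if (!"sample_id" %in% names(counts)) counts$sample_id <- NA_character_
  if (!"sample_id" %in% names(tag_hits)) tag_hits$sample_id <- NA_character_
  audit <- list()
  for (i in seq_len(nrow(tag_hits))) {
    h <- tag_hits[i, ]
    sel <- counts$sample_id %in% h$sample_id &
      counts$v_gene %in% c(h$member_a, h$member_b)
    pair_rows <- counts[sel, ]
    tot_a <- sum(pair_rows$n[pair_rows$v_gene == h$member_a])
    tot_b <- sum(pair_rows$n[pair_rows$v_gene == h$member_b])
    tot <- tot_a + tot_b
    if (h$hits_a + h$hits_b == 0 || tot == 0) {
      rlang::warn(paste0("no tag-covering reads for pair ", h$member_a, "/",
                         h$member_b, "; left unadjusted"))
      new_a <- tot_a
      new_b <- tot_b
    } else {
      new_a <- tot * h$hits_a / (h$hits_a + h$hits_b)
      new_b <- tot * h$hits_b / (h$hits_a + h$hits_b)
      # Re-divide the pooled total; each member keeps its own Jk profile, and
      # a member with no reads of its own inherits the pair's pooled profile.
      rescale <- function(member, old_tot, new_tot) {
        if (old_tot > 0) {
          rows <- pair_rows[pair_rows$v_gene == member, ]
          rows$n <- rows$n * new_tot / old_tot
        } else {
          rows <- dplyr::summarise(
            dplyr::group_by(pair_rows, .data$sample_id, .data$jk),
            n = sum(.data$n), .groups = "drop"
          )
          rows$v_gene <- member
          rows$n <- new_tot * rows$n / sum(rows$n)
        }
        rows
      }
      counts <- dplyr::bind_rows(
        counts[!sel, ],
        rescale(h$member_a, tot_a, new_a),
        rescale(h$member_b, tot_b, new_b)
      )
    }
    audit[[i]] <- tibble::tibble(
      sample_id = h$sample_id, member_a = h$member_a, member_b = h$member_b,
      total = tot, hits_a = h$hits_a, hits_b = h$hits_b,
      adjusted_a = new_a, adjusted_b = new_b
    )
  }
  attr(counts, "audit") <- dplyr::bind_rows(audit)
  counts
}
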