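# Read preparation: 3' quality trimming with paired discard, and
# overlap-consensus merging of mate pairs.

# Length of the trailing run of bases with quality <= floor.
trailing_low_run <- function(qual, floor = 20L) {
  vapply(qual, function(q) {
    ints <- rev(utf8ToInt(q)) - 33L
    low <- ints <= floor
    if (!any(!low)) return(length(ints))
    which.min(low) - 1L
  }, integer(1), USE.NAMES = FALSE)
}

#' Quality-trim read pairs, discarding pairs trimmed too hard
#'
#' Removes the trailing run of 3' bases whose quality is at or below
#' `phred_floor` from each mate ("Phred > 20" read strictly: a base survives
#' only if its quality exceeds the floor). If either mate would lose more
#' than `max_trim` bases the whole pair is discarded.
#'
#' @param reads read-pair tibble (`read_id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @param max_trim maximum bases trimmable from a single mate.
#' @param phred_floor quality floor; bases with Phred <= floor are trimmed.
#' @return The surviving pairs, trimmed; discarded pairs are recorded in the
#'   `discards` attribute with a reason code.
#' @export
trim_filter <- function(reads, max_trim = 50L, phred_floor = 20L) {
  t1 <- trailing_low_run(reads$qual1, phred_floor)
  t2 <- trailing_low_run(reads$qual2, phred_floor)
  drop <- t1 > max_trim | t2 > max_trim
  kept <- reads[!drop, ]
  k1 <- t1[!drop]
  k2 <- t2[!drop]
  kept$seq1 <- substr(kept$seq1, 1L, nchar(kept$seq1) - k1)
  kept$qual1 <- substr(kept$qual1, 1L, nchar(kept$qual1) - k1)
  kept$seq2 <- substr(kept$seq2, 1L, nchar(kept$seq2) - k2)
  kept$qual2 <- substr(kept$qual2, 1L, nchar(kept$qual2) - k2)
  attr(kept, "discards") <- tibble::tibble(
    read_id = reads$read_id[drop],
    reason = "trimmed_over_max"
  )
  kept
}

# Find the best overlap between seq1 and the reverse-complemented mate.
# Returns list(ov, mism) or NULL. Seed-and-extend: exact 16-mer seed of rc2
# against seq1, with a full scan fallback for error-laden overlaps.
find_overlap <- function(s1, rc2, min_overlap, max_mismatch_frac) {
  l1 <- nchar(s1)
  l2 <- nchar(rc2)
  best <- NULL
  consider <- function(p, best) {
    ov <- l1 - p + 1L
    if (ov < min_overlap || ov > l2) return(best)
    a <- utf8ToInt(substr(s1, p, l1))
    b <- utf8ToInt(substr(rc2, 1L, ov))
    mism <- sum(a != b)
    if (mism / ov > max_mismatch_frac) return(best)
    if (is.null(best) || mism / ov < best$mism / best$ov ||
        (mism / ov == best$mism / best$ov && ov > best$ov)) {
      return(list(ov = ov, mism = mism, p = p))
    }
    best
  }
  seed_len <- min(16L, l2)
  seed <- substr(rc2, 1L, seed_len)
  hits <- gregexpr(seed, s1, fixed = TRUE)[[1]]
  if (hits[1] != -1L) {
    for (p in as.integer(hits)) best <- consider(p, best)
  }
  if (is.null(best)) {
    for (p in seq.int(max(1L, l1 - l2 + 1L), max(1L, l1 - min_overlap + 1L))) {
      best <- consider(p, best)
    }
  }
  best
}

#' Merge mate pairs by overlap consensus
#'
#' Reverse-complements mate 2, locates the overlap with mate 1
#' (seed-and-extend with a scan fallback), and merges when the overlap
#' reaches `min_overlap` bases with a mismatch fraction at most
#' `max_mismatch_frac`. At a mismatching column the base with the higher
#' quality wins; merged quality takes the per-column maximum. Unmerged pairs
#' are dropped from the output and recorded in the `discards` attribute.
#'
#' @param reads trimmed read-pair tibble.
#' @param min_overlap minimum acceptable overlap length in bp.
#' @param max_mismatch_frac maximum mismatch fraction in the overlap.
#' @return Tibble with `read_id`, `seq`, `qual`, `overlap_len`.
#' @export
merge_pairs <- function(reads, min_overlap = 20L, max_mismatch_frac = 0.1) {
  n <- nrow(reads)
  rc2 <- revcomp(reads$seq2)
  rq2 <- vapply(reads$qual2, function(q) {
    intToUtf8(rev(utf8ToInt(q)))
  }, character(1), USE.NAMES = FALSE)

  out_seq <- character(n)
  out_qual <- character(n)
  out_ov <- integer(n)
  merged <- logical(n)
  for (i in seq_len(n)) {
    hit <- find_overlap(reads$seq1[i], rc2[i], min_overlap, max_mismatch_frac)
    if (is.null(hit)) next
    l1 <- nchar(reads$seq1[i])
    l2 <- nchar(rc2[i])
    ov <- hit$ov
    p <- hit$p
    if (hit$mism == 0L) {
      seq_ov <- substr(reads$seq1[i], p, l1)
      q1 <- utf8ToInt(substr(reads$qual1[i], p, l1))
      q2 <- utf8ToInt(substr(rq2[i], 1L, ov))
      qual_ov <- intToUtf8(pmax(q1, q2))
    } else {
      a <- utf8ToInt(substr(reads$seq1[i], p, l1))
      b <- utf8ToInt(substr(rc2[i], 1L, ov))
      q1 <- utf8ToInt(substr(reads$qual1[i], p, l1))
      q2 <- utf8ToInt(substr(rq2[i], 1L, ov))
      take2 <- a != b & q2 > q1
      cons <- ifelse(take2, b, a)
      seq_ov <- intToUtf8(cons)
      qual_ov <- intToUtf8(pmax(q1, q2))
    }
    out_seq[i] <- paste0(substr(reads$seq1[i], 1L, p - 1L), seq_ov,
                         substr(rc2[i], ov + 1L, l2))
    out_qual[i] <- paste0(substr(reads$qual1[i], 1L, p - 1L), qual_ov,
                          substr(rq2[i], ov + 1L, l2))
    out_ov[i] <- ov
    merged[i] <- TRUE
  }
  res <- tibble::tibble(
    read_id = reads$read_id[merged],
    seq = out_seq[merged],
    qual = out_qual[merged],
    overlap_len = out_ov[merged]
  )
  attr(res, "discards") <- tibble::tibble(
    read_id = reads$read_id[!merged], reason = "unmerged"
  )
  res
}

#' Extract the 6N UMI from merged reads
#'
#' Both library chemistries place the 6 random adapter nucleotides at the 5'
#' end of the merged read (gDNA: shear-end adapter; RNA: 3' end of the 5'
#' bridge adapter), so extraction strips the leading 6 bases.
#'
#' @param merged tibble from [merge_pairs()].
#' @param umi_len UMI length (6 by chemistry).
#' @return The tibble with a `umi` column and the UMI removed from `seq`.
#' @export
extract_umi <- function(merged, umi_len = 6L) {
  merged$umi <- substr(merged$seq, 1L, umi_len)
  merged$seq <- substr(merged$seq, umi_len + 1L, nchar(merged$seq))
  merged$qual <- substr(merged$qual, umi_len + 1L, nchar(merged$qual))
  merged
}

#' Prepare raw read pairs for V/J calling
#'
#' Convenience wrapper chaining [trim_filter()], [merge_pairs()] and
#' [extract_umi()].
#'
#' @inheritParams trim_filter
#' @inheritParams merge_pairs
#' @return Tibble with `read_id`, `umi`, `seq`, `qual`.
#' @export
prep_reads <- function(reads, max_trim = 50L, phred_floor = 20L,
                       min_overlap = 20L, max_mismatch_frac = 0.1) {
  reads |>
    trim_filter(max_trim = max_trim, phred_floor = phred_floor) |>
    merge_pairs(min_overlap = min_overlap,
                max_mismatch_frac = max_mismatch_frac) |>
    extract_umi()
}
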