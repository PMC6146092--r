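# V/J assignment: anchored seed-and-extend alignment of merged reads against
# the Vk references, Jk re-assignment from the sequence upstream of the PCR
# primer, frame-based productivity calling, and orientation classification.

# k-mer index over the V-sense references. `first` lookups go through
# base::match (hashed); k-mers occurring in more than one place (the shared
# 3' 150 bp of identical pairs) get an explicit multi-candidate list.
build_v_index <- function(ref, k = 20L) {
  vs <- v_sequences(ref)
  lens <- nchar(vs)
  gene <- rep(seq_along(vs), times = pmax(0L, lens - k + 1L))
  pos <- unlist(lapply(lens, function(l) seq_len(max(0L, l - k + 1L))),
                use.names = FALSE)
  starts <- pos
  kmers <- substring(vs[gene], starts, starts + k - 1L)
  dup <- kmers %in% kmers[duplicated(kmers)]
  multi <- NULL
  if (any(dup)) {
    multi <- split(data.frame(gene = gene[dup], pos = pos[dup]), kmers[dup])
  }
  list(k = k, kmers = kmers, gene = gene, pos = pos,
       multi = multi, v_seqs = vs, v_int = lapply(vs, utf8ToInt),
       names = names(vs))
}

# Evaluate one candidate placement: read position x maps to V position x + d.
# Leading/trailing mismatch runs are excluded from the aligned span; identity
# is matches over aligned columns.
eval_candidate <- function(read_int, v_int, d) {
  lr <- length(read_int)
  lv <- length(v_int)
  x1 <- max(1L, 1L - d)
  x2 <- min(lr, lv - d)
  if (x2 < x1) return(NULL)
  m <- read_int[x1:x2] == v_int[(x1 + d):(x2 + d)]
  if (!any(m)) return(NULL)
  a1 <- x1 + which.max(m) - 1L
  a2 <- x1 + length(m) - which.max(rev(m))
  span <- a2 - a1 + 1L
  matches <- sum(m[(a1 - x1 + 1L):(a2 - x1 + 1L)])
  list(identity = 100 * matches / span, len = span,
       v_start = a1 + d, v_end = a2 + d, read_end = a2)
}

#' Assign merged reads to Vk genes
#'
#' Anchored seed-and-extend alignment: an exact k-mer seed from the read is
#' looked up in an index of all V-sense references (several seed offsets are
#' tried so isolated mismatches cannot mask a gene), the implied placement is
#' extended over the full read/reference overlap, and leading/trailing
#' mismatch runs are excluded from the aligned span. A gene is assigned only
#' if the aligned V length reaches `min_len` (150 bp) and identity reaches
#' `min_identity` (95%). Reads whose best and runner-up candidates tie on
#' identity and length (notably reads confined to the shared 3' 150 bp of an
#' identical pair) are assigned to the lexicographically first gene and
#' flagged ambiguous for later reallocation.
#'
#' @param reads tibble with `read_id` and `seq` (merged, UMI removed).
#' @param ref a `kappa_ref`.
#' @param min_len minimum aligned V length in bp.
#' @param min_identity minimum percent identity over aligned columns.
#' @param k seed length.
#' @return `reads` with columns `v_gene`, `identity_pct`, `v_aligned_len`,
#'   `v_start`, `v_end`, `v_read_end`, `ambiguous_v`.
#' @export
assign_v <- function(reads, ref, min_len = 150L, min_identity = 95, k = 20L) {
  idx <- build_v_index(ref, k)
  n <- nrow(reads)
  seqs <- reads$seq

  v_gene <- rep(NA_character_, n)
  identity_pct <- rep(NA_real_, n)
  v_aligned_len <- rep(NA_integer_, n)
  v_start <- rep(NA_integer_, n)
  v_end <- rep(NA_integer_, n)
  v_read_end <- rep(NA_integer_, n)
  ambiguous <- rep(FALSE, n)

  # seed lookup at staggered offsets until a hit
  hit_pos <- rep(NA_integer_, n)
  seed_off <- rep(NA_integer_, n)
  for (off in seq(1L, 101L, by = 10L)) {
    todo <- which(is.na(hit_pos) & nchar(seqs) >= off + k - 1L)
    if (length(todo) == 0) break
    sd <- substr(seqs[todo], off, off + k - 1L)
    mm <- match(sd, idx$kmers)
    got <- !is.na(mm)
    hit_pos[todo[got]] <- mm[got]
    seed_off[todo[got]] <- off
  }

  for (i in which(!is.na(hit_pos))) {
    ri <- utf8ToInt(seqs[i])
    h <- hit_pos[i]
    seed_kmer <- idx$kmers[h]
    cands <- if (!is.null(idx$multi) && !is.null(idx$multi[[seed_kmer]])) {
      idx$multi[[seed_kmer]]
    } else {
      data.frame(gene = idx$gene[h], pos = idx$pos[h])
    }
    best <- NULL
    best_name <- NA_character_
    tie <- FALSE
    for (ci in seq_len(nrow(cands))) {
      g <- cands$gene[ci]
      d <- cands$pos[ci] - seed_off[i]
      ev <- eval_candidate(ri, idx$v_int[[g]], d)
      if (is.null(ev)) next
      if (is.null(best)) {
        best <- ev; best_name <- idx$names[g]; tie <- FALSE
      } else if (ev$identity > best$identity ||
                 (ev$identity == best$identity && ev$len > best$len)) {
        best <- ev; best_name <- idx$names[g]; tie <- FALSE
      } else if (ev$identity == best$identity && ev$len == best$len &&
                 idx$names[g] != best_name) {
        tie <- TRUE
        if (idx$names[g] < best_name) {
          best <- ev; best_name <- idx$names[g]
        }
      }
    }
    if (is.null(best)) next
    if (best$len >= min_len && best$identity >= min_identity) {
      v_gene[i] <- best_name
      identity_pct[i] <- best$identity
      v_aligned_len[i] <- best$len
      v_start[i] <- best$v_start
      v_end[i] <- best$v_end
      v_read_end[i] <- best$read_end
      ambiguous[i] <- tie
    }
  }
  dplyr::mutate(reads, v_gene = v_gene, identity_pct = identity_pct,
                v_aligned_len = v_aligned_len, v_start = v_start,
                v_end = v_end, v_read_end = v_read_end,
                ambiguous_v = ambiguous)
}

# Score a read's upstream-of-primer segment against each Jk exon allowing a
# junctional loss of up to `max_shift` exon-proximal bases. Returns the best
# (jk, shift, frac, j_read_start).
score_j_upstream <- function(seq_int, p_pr, exon_ints, po, max_shift,
                             min_frac = 0.9) {
  best <- NULL
  for (jn in names(exon_ints)) {
    ex <- exon_ints[[jn]]
    for (s in 0:max_shift) {
      L <- po - 1L - s
      if (L < 8L || p_pr - L < 1L) next
      seg <- seq_int[(p_pr - L):(p_pr - 1L)]
      frac <- mean(seg == ex[(1L + s):(po - 1L)])
      if (frac < min_frac) next
      if (is.null(best) || frac > best$frac) {
        best <- list(jk = jn, shift = s, frac = frac, j_read_start = p_pr - L)
      }
    }
  }
  best
}

#' Re-assign gDNA reads to their proper Jk gene
#'
#' Jk PCR primers can cross-amplify a neighbouring Jk's product, so the
#' primer found at the read 3' end is not trusted. The sequence upstream of
#' the primer is compared against every Jk exon, excluding the most
#' Vk-proximal exon nucleotides (1 for the primary primer set, 6 for the
#' alternate set) which junction formation may have removed; the
#' best-matching exon wins. Reads matching no exon are left `unassigned-J`.
#'
#' Identical upstream+primer suffixes are evaluated once and the result
#' broadcast, which makes the scan cheap on deduplicated-scale inputs.
#'
#' @param calls tibble with `seq` (merged, UMI removed).
#' @param ref a `kappa_ref`.
#' @param primer_set `"primary"` or `"alternate"`.
#' @param primer_len primer length in bp.
#' @return `calls` with columns `jk` (NA when unassigned), `j_trim`,
#'   `j_read_start` (read position of the first retained exon base).
#' @export
reassign_j <- function(calls, ref, primer_set = c("primary", "alternate"),
                       primer_len = 20L) {
  primer_set <- match.arg(primer_set)
  primers <- j_primers(ref, primer_set, primer_len)
  po <- if (primer_set == "primary") {
    ref$j_genes$primer_offset_primary[1]
  } else ref$j_genes$primer_offset_alternate[1]
  excl <- junction_exclusion_nt(primer_set)
  exon_ints <- lapply(j_sequences(ref), utf8ToInt)

  suffix_w <- po - 1L + primer_len
  keys <- substr(calls$seq, pmax(1L, nchar(calls$seq) - suffix_w + 1L),
                 nchar(calls$seq))
  uk <- unique(keys)
  res <- lapply(uk, function(key) {
    kl <- nchar(key)
    p_end <- vapply(primers, function(pr) {
      if (endsWith(key, pr)) kl else -1L
    }, integer(1))
    if (all(p_end < 0)) {
      # primer not flush with the read end (e.g. clipped read): search for it
      for (pr in primers) {
        hit <- regexpr(pr, key, fixed = TRUE)
        if (hit > 0) {
          p_end <- rep(-1L, length(primers))
          p_end[1] <- as.integer(hit) + primer_len - 1L
          break
        }
      }
    }
    if (all(p_end < 0)) {
      return(list(jk = NA_character_, j_trim = NA_integer_,
                  j_read_start = NA_integer_))
    }
    pe <- max(p_end)
    p_pr <- pe - primer_len + 1L
    best <- score_j_upstream(utf8ToInt(key), p_pr, exon_ints, po, excl)
    if (is.null(best)) {
      return(list(jk = NA_character_, j_trim = NA_integer_,
                  j_read_start = NA_integer_))
    }
    list(jk = best$jk, j_trim = best$shift,
         j_read_start = best$j_read_start - kl)  # offset from read end
  })
  names(res) <- uk
  picked <- res[keys]
  calls$jk <- vapply(picked, `[[`, character(1), "jk")
  calls$j_trim <- vapply(picked, `[[`, integer(1), "j_trim")
  rel <- vapply(picked, `[[`, integer(1), "j_read_start")
  calls$j_read_start <- ifelse(is.na(rel), NA_integer_,
                               nchar(calls$seq) + rel)
  calls
}

#' Locate the Jk segment in RNA (5' RACE) reads
#'
#' RNA reads contain the full Jk exon followed by constant-region sequence;
#' the exon core (from base 8 on) is located exactly and the junction-side
#' loss (up to 7 bases) resolved by extending the match leftwards.
#'
#' @param calls tibble with `seq`.
#' @param ref a `kappa_ref`.
#' @return `calls` with `jk`, `j_trim`, `j_read_start`.
#' @export
assign_j_rna <- function(calls, ref) {
  exons <- j_sequences(ref)
  cores <- substr(exons, 8L, nchar(exons))
  jk <- rep(NA_character_, nrow(calls))
  j_trim <- rep(NA_integer_, nrow(calls))
  j_read_start <- rep(NA_integer_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    s <- calls$seq[i]
    for (jn in names(exons)) {
      pos <- regexpr(cores[[jn]], s, fixed = TRUE)
      if (pos < 0) next
      found <- FALSE
      for (sh in 0:7) {
        lead <- 7L - sh
        if (pos - lead < 1L) next
        if (lead == 0L ||
            substr(s, pos - lead, pos - 1L) ==
              substr(exons[[jn]], 1L + sh, 7L)) {
          jk[i] <- jn
          j_trim[i] <- sh
          j_read_start[i] <- as.integer(pos) - lead
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }
  dplyr::mutate(calls, jk = jk, j_trim = j_trim, j_read_start = j_read_start)
}

#' Call productivity of V-J junctions
#'
#' A rearrangement is productive iff the V reading frame is preserved into
#' the Jk frame across the junction (net junctional offset, V-side loss plus
#' J-side loss minus insertions, divisible by 3) and no in-frame stop codon
#' occurs within the sequenced region. Calls lacking a V or J assignment, or
#' whose junction cannot be resolved, are `indeterminate`.
#'
#' @param calls tibble with `v_gene`, `v_end` (last aligned V base, V
#'   coordinates), `jk`, `j_trim`, and either `v_read_end` + `j_read_start` +
#'   `seq` (pipeline output) or an explicit `insert_len` column.
#' @param ref a `kappa_ref`.
#' @return `calls` with a `productive` column
#'   (`productive`/`non-productive`/`indeterminate`).
#' @export
call_productive <- function(calls, ref) {
  v_len <- stats::setNames(nchar(v_sequences(ref)), ref$v_genes$name)
  exon_len <- stats::setNames(nchar(j_sequences(ref)), ref$j_genes$name)

  if (!"insert_len" %in% names(calls)) {
    calls$insert_len <- calls$j_read_start - calls$v_read_end - 1L
  }
  ok <- !is.na(calls$v_gene) & !is.na(calls$jk) & !is.na(calls$insert_len)
  delta <- rep(NA_integer_, nrow(calls))
  delta[ok] <- (v_len[calls$v_gene[ok]] - calls$v_end[ok]) +
    calls$j_trim[ok] - calls$insert_len[ok]
  in_frame <- !is.na(delta) & delta %% 3L == 0L

  has_stop <- rep(FALSE, nrow(calls))
  if ("seq" %in% names(calls)) {
    scan_idx <- which(ok & in_frame)
    for (i in scan_idx) {
      vs <- if ("v_start" %in% names(calls) && !is.na(calls$v_start[i])) {
        calls$v_start[i]
      } else 1L
      f <- (vs - 1L) %% 3L
      from <- ((3L - f) %% 3L) + 1L
      to <- nchar(calls$seq[i])
      if ("j_read_start" %in% names(calls) && !is.na(calls$j_read_start[i])) {
        to <- min(to, calls$j_read_start[i] +
                    (exon_len[calls$jk[i]] - calls$j_trim[i]) - 1L)
      }
      has_stop[i] <- has_inframe_stop(substr(calls$seq[i], 1L, to), from)
    }
  }
  calls$productive <- dplyr::case_when(
    !ok ~ "indeterminate",
    in_frame & !has_stop ~ "productive",
    TRUE ~ "non-productive"
  )
  calls
}

#' Classify rearrangement orientation
#'
#' Copies the deletional/inversional class of the assigned Vk gene onto each
#' call; unassigned reads get `NA`.
#'
#' @param calls tibble with `v_gene`.
#' @param ref a `kappa_ref`.
#' @return `calls` with an `orientation_class` column.
#' @export
classify_orientation <- function(calls, ref) {
  map <- stats::setNames(ref$v_genes$orientation, ref$v_genes$name)
  dplyr::mutate(calls, orientation_class = unname(map[.data$v_gene]))
}

#' Full V/J calling on prepared reads
#'
#' Chains [assign_v()], Jk assignment ([reassign_j()] for gDNA chemistry,
#' [assign_j_rna()] for RNA), [call_productive()] and
#' [classify_orientation()].
#'
#' @param prepped tibble from [prep_reads()] (`read_id`, `umi`, `seq`).
#' @param ref a `kappa_ref`.
#' @param chemistry `"gdna"` or `"rna"`.
#' @param primer_set Jk primer set (gDNA only).
#' @param sample_id optional sample label attached to every call.
#' @return VJCall tibble: one row per read with assignment, junction and
#'   productivity columns.
#' @export
call_vj <- function(prepped, ref, chemistry = c("gdna", "rna"),
                    primer_set = c("primary", "alternate"),
                    sample_id = NA_character_) {
  chemistry <- match.arg(chemistry)
  primer_set <- match.arg(primer_set)
  calls <- assign_v(prepped, ref)
  calls <- if (chemistry == "gdna") {
    reassign_j(calls, ref, primer_set)
  } else {
    assign_j_rna(calls, ref)
  }
  calls <- call_productive(calls, ref)
  calls <- classify_orientation(calls, ref)
  calls$chemistry <- chemistry
  calls$sample_id <- sample_id
  dplyr::select(calls, dplyr::any_of(c(
    "read_id", "sample_id", "chemistry", "umi", "v_gene", "identity_pct",
    "v_aligned_len", "v_start", "v_end", "ambiguous_v", "jk", "j_trim",
    "insert_len", "productive", "orientation_class", "seq"
  )))
}
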