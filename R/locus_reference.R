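#' Annotated Igk locus reference
#'
#' A `kappa_ref` bundles the genome slice spanning the Igk locus with the
#' Vk/Jk gene annotation and the registry of 3'-identical Vk gene pairs.
#' All coordinates are 0-based half-open on the plus strand of the slice,
#' which is oriented so that the Jk--Ck cluster is transcribed left to right
#' at the right-hand end; `deletional` Vk genes are therefore plus-strand
#' (transcribed toward Jk) and `inversional` genes minus-strand.
#'
#' @param genome named character vector of chromosome sequences.
#' @param v_genes tibble of Vk gene annotation (see [load_locus_reference()]).
#' @param j_genes tibble of Jk gene annotation.
#' @param pairs tibble registry of 3'-identical Vk pairs with per-member
#'   discriminating upstream tag sequences, or `NULL`.
#'
#' @return An object of class `kappa_ref`.
#' @export
kappa_ref <- function(genome, v_genes, j_genes, pairs = NULL) {
  v_genes <- tibble::as_tibble(v_genes)
  j_genes <- tibble::as_tibble(j_genes)
  need_v <- c("chrom", "start", "end", "name", "family", "orientation",
              "functionality", "ric_score", "leader1_start",
              "leader_start", "leader_end", "rss_start", "rss_end")
  need_j <- c("chrom", "start", "end", "name",
              "primer_offset_primary", "primer_offset_alternate")
  miss <- setdiff(need_v, names(v_genes))
  abort_if(length(miss) > 0,
           paste0("V annotation is missing fields: ", paste(miss, collapse = ", ")))
  miss <- setdiff(need_j, names(j_genes))
  abort_if(length(miss) > 0,
           paste0("J annotation is missing fields: ", paste(miss, collapse = ", ")))
  if (!is.null(pairs)) pairs <- tibble::as_tibble(pairs)

  ref <- structure(
    list(genome = genome, v_genes = v_genes, j_genes = j_genes, pairs = pairs),
    class = "kappa_ref"
  )
  ref$v_genes$distance_to_jk1 <- compute_distance_to_jk1(ref)
  if (!"half" %in% names(ref$v_genes)) ref$v_genes$half <- NA_character_
  validate_kappa_ref(ref)
  ref
}

compute_distance_to_jk1 <- function(ref) {
  jk1 <- ref$j_genes[which.min(ref$j_genes$start), ]
  pmax(0L, as.integer(jk1$start) - as.integer(ref$v_genes$end))
}

validate_kappa_ref <- function(ref) {
  v <- ref$v_genes
  j <- ref$j_genes
  abort_if(anyDuplicated(c(v$name, j$name)) > 0, "gene names must be unique")
  abort_if(!all(v$functionality %in% c("functional", "ORF", "pseudogene")),
           "functionality must be functional, ORF or pseudogene")
  abort_if(!all(v$orientation %in% c("deletional", "inversional")),
           "orientation must be deletional or inversional")
  abort_if(!all(is.finite(v$ric_score)), "ric_score must be finite")
  abort_if(nrow(j) != 4L, "exactly four functional Jk genes expected")
  for (chrom in unique(c(v$chrom, j$chrom))) {
    abort_if(!chrom %in% names(ref$genome),
             paste0("chromosome absent from genome: ", chrom))
    len <- nchar(ref$genome[[chrom]])
    vv <- v[v$chrom == chrom, ]
    abort_if(any(vv$start < 0 | vv$end > len | vv$start >= vv$end),
             "V gene interval outside genome slice")
  }
  # leader 1 must lie upstream of the coding region in the gene's own
  # orientation: left of it for plus-strand (deletional), right for minus.
  plus <- v$orientation == "deletional"
  abort_if(any(v$leader1_start[plus] >= v$start[plus]) ||
             any(v$leader1_start[!plus] < v$end[!plus]),
           "leader 1 start must be upstream of the coding region")
  if (!is.null(ref$pairs) && nrow(ref$pairs) > 0) validate_pairs(ref)
  invisible(ref)
}

# Each registered pair must be literally identical over the 3'-most 150 bp of
# the V-sense coding sequence, and each member's discriminating tag must occur
# in that member's sequence only.
validate_pairs <- function(ref) {
  vs <- v_sequences(ref)
  for (i in seq_len(nrow(ref$pairs))) {
    p <- ref$pairs[i, ]
    abort_if(!all(c(p$member_a, p$member_b) %in% names(vs)),
             paste0("identical-pair member not in annotation: ",
                    p$member_a, "/", p$member_b))
    tail_a <- substr(vs[[p$member_a]], nchar(vs[[p$member_a]]) - 149L,
                     nchar(vs[[p$member_a]]))
    tail_b <- substr(vs[[p$member_b]], nchar(vs[[p$member_b]]) - 149L,
                     nchar(vs[[p$member_b]]))
    abort_if(!identical(tail_a, tail_b),
             paste0("pair ", p$member_a, "/", p$member_b,
                    " differs over the 3'-most 150 bp"))
    abort_if(identical(p$tag_a, p$tag_b),
             paste0("pair ", p$member_a, "/", p$member_b,
                    " has equal discriminating tags"))
    hit_aa <- grepl(p$tag_a, vs[[p$member_a]], fixed = TRUE)
    hit_ab <- grepl(p$tag_a, vs[[p$member_b]], fixed = TRUE)
    hit_bb <- grepl(p$tag_b, vs[[p$member_b]], fixed = TRUE)
    hit_ba <- grepl(p$tag_b, vs[[p$member_a]], fixed = TRUE)
    abort_if(!(hit_aa && !hit_ab && hit_bb && !hit_ba),
             paste0("discriminating tags for ", p$member_a, "/", p$member_b,
                    " must each occur in exactly one member"))
  }
  invisible(ref)
}

#' V-sense coding sequences of all Vk genes
#'
#' Extracts each Vk coding region from the genome slice, reverse-complemented
#' for inversional genes so every returned sequence reads 5' to 3' in the
#' gene's own transcriptional orientation.
#'
#' @param ref a `kappa_ref`.
#' @return Named character vector, one sequence per Vk gene.
#' @export
v_sequences <- function(ref) {
  v <- ref$v_genes
  out <- vapply(seq_len(nrow(v)), function(i) {
    s <- subseq0(ref$genome[[v$chrom[i]]], v$start[i], v$end[i])
    if (v$orientation[i] == "inversional") s <- revcomp(s) else s
  }, character(1))
  stats::setNames(out, v$name)
}

#' Jk exon sequences (plus strand)
#' @param ref a `kappa_ref`.
#' @return Named character vector of exon sequences.
#' @export
j_sequences <- function(ref) {
  j <- ref$j_genes
  stats::setNames(
    vapply(seq_len(nrow(j)), function(i) {
      subseq0(ref$genome[[j$chrom[i]]], j$start[i], j$end[i])
    }, character(1)),
    j$name
  )
}

# Jk primer sequences for a primer set: the primer occupies `primer_len` bases
# starting at the (1-based) primer offset within the exon and may run past the
# exon end into downstream genomic sequence.
j_primers <- function(ref, primer_set = c("primary", "alternate"),
                      primer_len = 20L) {
  primer_set <- match.arg(primer_set)
  j <- ref$j_genes
  off <- if (primer_set == "primary") j$primer_offset_primary else j$primer_offset_alternate
  stats::setNames(
    vapply(seq_len(nrow(j)), function(i) {
      subseq0(ref$genome[[j$chrom[i]]],
              j$start[i] + off[i] - 1L,
              j$start[i] + off[i] - 1L + primer_len)
    }, character(1)),
    j$name
  )
}

#' Junction-exclusion width of a Jk primer set
#'
#' When re-assigning gDNA reads to their proper Jk gene from the sequence
#' upstream of the PCR primer, the most Vk-proximal exon nucleotides are
#' excluded from the comparison because junction formation may have removed
#' them: 1 nt for the primary primer set, 6 nt for the alternate set placed
#' further downstream.
#'
#' @param primer_set `"primary"` or `"alternate"`.
#' @return Integer exclusion width.
#' @export
junction_exclusion_nt <- function(primer_set = c("primary", "alternate")) {
  primer_set <- match.arg(primer_set)
  if (primer_set == "primary") 1L else 6L
}

#' Load an Igk locus reference from FASTA + annotation
#'
#' The annotation is a headered BED-like TSV: the first three columns are
#' `chrom`, `start`, `end` (0-based half-open), plus `name`, `type` (`V`/`J`)
#' and the named extra columns required for each gene type (`family`,
#' `orientation`, `functionality`, `ric_score`, `leader1_start`,
#' `leader_start`, `leader_end`, `rss_start`, `rss_end` for V rows;
#' `primer_offset_primary`, `primer_offset_alternate` for J rows). An optional
#' pairs TSV (`member_a`, `member_b`, `tag_a`, `tag_b`) registers 3'-identical
#' Vk gene pairs; the registry is verified against the genome on load.
#'
#' @param genome_fasta path to the locus FASTA.
#' @param annotation path to the annotation TSV.
#' @param pairs optional path to the identical-pair registry TSV.
#' @return A validated `kappa_ref`.
#' @export
load_locus_reference <- function(genome_fasta, annotation, pairs = NULL) {
  gen <- Biostrings::readDNAStringSet(genome_fasta)
  genome <- stats::setNames(as.character(gen), names(gen))
  ann <- readr::read_tsv(annotation, show_col_types = FALSE, progress = FALSE)
  abort_if(!"type" %in% names(ann), "annotation must carry a 'type' column (V/J)")
  int_cols <- intersect(c("start", "end", "family", "leader1_start",
                          "leader_start", "leader_end", "rss_start",
                          "rss_end", "distance_to_jk1",
                          "primer_offset_primary", "primer_offset_alternate"),
                        names(ann))
  ann[int_cols] <- lapply(ann[int_cols], as.integer)
  v <- ann[ann$type == "V", setdiff(names(ann), c("type", "primer_offset_primary",
                                                  "primer_offset_alternate"))]
  j <- ann[ann$type == "J", c("chrom", "start", "end", "name",
                              "primer_offset_primary", "primer_offset_alternate")]
  pr <- if (!is.null(pairs)) readr::read_tsv(pairs, show_col_types = FALSE,
                                             progress = FALSE) else NULL
  kappa_ref(genome, v, j, pr)
}

#' Write a locus reference back to disk
#'
#' Emits the FASTA, the annotation TSV and (if present) the pair registry in
#' the same layout [load_locus_reference()] reads, so that a load/write cycle
#' round-trips field for field.
#'
#' @param ref a `kappa_ref`.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_locus_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "locus.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$genome), fa)
  v <- dplyr::mutate(ref$v_genes, type = "V")
  j <- dplyr::mutate(ref$j_genes, type = "J")
  ann <- dplyr::bind_rows(v, j)
  lead <- c("chrom", "start", "end", "name", "type")
  ann <- ann[, c(lead, setdiff(names(ann), lead))]
  annp <- file.path(dir, "annotation.tsv")
  readr::write_tsv(ann, annp, progress = FALSE)
  pp <- NULL
  if (!is.null(ref$pairs)) {
    pp <- file.path(dir, "pairs.tsv")
    readr::write_tsv(ref$pairs, pp, progress = FALSE)
  }
  invisible(list(fasta = fa, annotation = annp, pairs = pp))
}

#' Apply curated locus corrections
#'
#' Applies an override table to a loaded reference. Each row names a gene, a
#' field and a replacement value; supported fields are `orientation`,
#' `functionality`, `rss_start` and `rss_end`. This is how the curated
#' C57BL/6 fixes are injected: the flipped orientation of Vk8-23-1, the
#' corrected Vk4-60 RSS interval, and the reclassification of Vk8-18, Vk1-35,
#' Vk14-126 and Vk1-131 as non-pseudogenes.
#'
#' @param ref a `kappa_ref`.
#' @param overrides tibble/data.frame with columns `name`, `field`, `value`.
#'   An empty table leaves the reference unchanged.
#' @return The corrected `kappa_ref`.
#' @export
apply_corrections <- function(ref, overrides) {
  overrides <- tibble::as_tibble(overrides)
  if (nrow(overrides) == 0) return(ref)
  need <- c("name", "field", "value")
  abort_if(!all(need %in% names(overrides)),
           "overrides need columns name, field, value")
  v <- ref$v_genes
  for (i in seq_len(nrow(overrides))) {
    o <- overrides[i, ]
    idx <- which(v$name == o$name)
    abort_if(length(idx) == 0, paste0("override names unknown gene: ", o$name))
    field <- o$field
    abort_if(!field %in% c("orientation", "functionality", "rss_start", "rss_end"),
             paste0("unsupported override field: ", field))
    val <- if (field %in% c("rss_start", "rss_end")) as.integer(o$value) else o$value
    v[[field]][idx] <- val
  }
  ref$v_genes <- v
  validate_kappa_ref(ref)
  ref
}

#' Default curated corrections for the C57BL/6 Igk annotation
#'
#' Orientation flip for Vk8-23-1 and IMGT-based reclassification of four
#' genes as non-pseudogenes. The corrected Vk4-60 RSS coordinates are
#' annotation-specific and must be supplied by the user alongside these rows.
#'
#' @param current_orientation the raw annotation's orientation for Vk8-23-1,
#'   which the correction flips.
#' @return Override tibble suitable for [apply_corrections()].
#' @export
igk_default_overrides <- function(current_orientation = "deletional") {
  flipped <- if (current_orientation == "deletional") "inversional" else "deletional"
  tibble::tibble(
    name = c("Vk8-23-1", "Vk8-18", "Vk1-35", "Vk14-126", "Vk1-131"),
    field = c("orientation", rep("functionality", 4)),
    value = c(flipped, rep("functional", 4))
  )
}

#' Label each Vk gene as proximal- or distal-half
#'
#' The locus is divided at the midpoint of the genomic span between the most
#' Jk-proximal and the most Jk-distal Vk gene. For the real mouse annotation
#' (recognised by the presence of both Vk13-76 and Vk4-77) the division is
#' pinned between those two genes, matching the distance-based split.
#'
#' @param ref a `kappa_ref`.
#' @return The reference with `half` filled in (`proximal`/`distal`).
#' @export
assign_halves <- function(ref) {
  v <- dplyr::arrange(ref$v_genes, .data$distance_to_jk1)
  if (all(c("Vk13-76", "Vk4-77") %in% v$name)) {
    cut <- which(v$name == "Vk13-76")
    v$half <- ifelse(seq_len(nrow(v)) <= cut, "proximal", "distal")
  } else {
    mid <- (min(v$distance_to_jk1) + max(v$distance_to_jk1)) / 2
    v$half <- ifelse(v$distance_to_jk1 <= mid, "proximal", "distal")
  }
  ref$v_genes <- v[match(ref$v_genes$name, v$name), ]
  ref
}

#' @export
print.kappa_ref <- function(x, ...) {
  cat("<kappa_ref> Igk locus reference\n")
  cat("  chromosomes:", paste(names(x$genome), collapse = ", "),
      sprintf("(%s bp)\n", format(sum(nchar(x$genome)), big.mark = ",")))
  cat("  Vk genes:", nrow(x$v_genes),
      sprintf("(%d deletional / %d inversional)\n",
              sum(x$v_genes$orientation == "deletional"),
              sum(x$v_genes$orientation == "inversional")))
  cat("  Jk genes:", paste(x$j_genes$name, collapse = ", "), "\n")
  if (!is.null(x$pairs) && nrow(x$pairs) > 0)
    cat("  3'-identical pairs:", nrow(x$pairs), "\n")
  invisible(x)
}
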