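# Feature windows around each Vk gene and window-based quantification of
# coverage tracks (bedGraph + declared total-tag count).

#' Four analysis windows per Vk gene
#'
#' For every gene, in its own transcriptional orientation: the promoter
#' window (500 bp upstream of the leader-1 start plus the leader exon and
#' its intron), the RSS window (coding region plus 500 bp downstream), the
#' upstream window (2.5 kb immediately upstream of the promoter window) and
#' the downstream window (2.5 kb immediately downstream of the RSS window).
#' Windows are non-overlapping by construction; inversional genes get the
#' mirror-image layout.
#'
#' @param ref a `kappa_ref`.
#' @param promoter_pad bp upstream of leader 1 in the promoter window.
#' @param rss_pad bp downstream of the coding region in the RSS window.
#' @param flank_len length of the upstream/downstream windows.
#' @return Tibble with `v_gene`, `window`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
build_windows <- function(ref, promoter_pad = 500L, rss_pad = 500L,
                          flank_len = 2500L) {
  v <- ref$v_genes
  abort_if(any(is.na(v$leader1_start)) || any(is.na(v$leader_start)),
           paste0("missing leader annotation for: ",
                  paste(v$name[is.na(v$leader1_start)], collapse = ", ")))
  purrr::map_dfr(seq_len(nrow(v)), function(i) {
    g <- v[i, ]
    if (g$orientation == "deletional") {  # plus strand
      prom <- c(g$leader1_start - promoter_pad, g$leader_end)
      rss <- c(g$start, g$end + rss_pad)
      up <- c(prom[1] - flank_len, prom[1])
      down <- c(rss[2], rss[2] + flank_len)
    } else {                              # minus strand, mirrored
      prom <- c(g$leader_start, g$leader1_start + promoter_pad)
      rss <- c(g$start - rss_pad, g$end)
      up <- c(prom[2], prom[2] + flank_len)
      down <- c(rss[1] - flank_len, rss[1])
    }
    tibble::tibble(
      v_gene = g$name,
      window = c("promoter", "rss", "upstream", "downstream"),
      chrom = g$chrom,
      start = c(prom[1], rss[1], up[1], down[1]),
      end = c(prom[2], rss[2], up[2], down[2])
    )
  })
}

#' Read / write bedGraph coverage tracks
#'
#' Plain four-column bedGraph (`chrom`, `start`, `end`, `value`); `track`
#' and comment lines are ignored on read.
#'
#' @param path file path (plain or gzipped).
#' @return Tibble with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^(track|#|browser)", lines) & nzchar(lines)]
  readr::read_tsv(I(lines), col_names = c("chrom", "start", "end", "value"),
                  col_types = "ciid", progress = FALSE)
}

#' @rdname read_bedgraph
#' @param track tibble with `chrom`, `start`, `end`, `value`.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(track, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Quantify a coverage track over gene windows
#'
#' Window signal is the coverage-weighted overlap (sum over track intervals
#' of value x overlapping bp), normalised to a sequencing depth of 10
#' million tags: `signal = raw * 1e7 / total_tags`. Windows outside the
#' track span score 0.
#'
#' @param track tibble with `chrom`, `start`, `end`, `value` (or a bedGraph
#'   path).
#' @param windows tibble from [build_windows()].
#' @param total_tags total mapped tags behind the track.
#' @return `windows` with a `signal` column.
#' @export
quantify_track <- function(track, windows, total_tags) {
  abort_if(total_tags <= 0, "total_tags must be positive")
  if (is.character(track)) track <- read_bedgraph(track)
  windows$signal <- 0
  for (chrom in unique(windows$chrom)) {
    wi <- which(windows$chrom == chrom)
    tr <- track[track$chrom == chrom & track$value != 0, ]
    if (nrow(tr) == 0) next
    w_rng <- IRanges::IRanges(start = windows$start[wi] + 1L,
                              end = windows$end[wi])
    t_rng <- IRanges::IRanges(start = tr$start + 1L, end = tr$end)
    ov <- IRanges::findOverlaps(w_rng, t_rng)
    if (length(ov) == 0) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    ov_w <- IRanges::width(IRanges::pintersect(w_rng[qh], t_rng[sh]))
    sig <- tapply(ov_w * tr$value[sh], qh, sum)
    windows$signal[wi[as.integer(names(sig))]] <- as.numeric(sig)
  }
  windows$signal <- windows$signal * 1e7 / total_tags
  windows
}

#' Assemble the gene x feature matrix
#'
#' Quantifies every manifest track over the four windows of every Vk gene
#' and binds the two genetic features (RSS RIC score and distance to Jk1).
#' Feature columns are named `<track>.<window>`. In `"preB"` stage mode all
#' tracks enter the matrix (a pre-B response is modelled with both pre-B and
#' pro-B features); `"proB"` mode keeps pro-B tracks only. A `mask` drops
#' named feature columns, allowing a reduced published feature set to be
#' reproduced exactly.
#'
#' @param ref a `kappa_ref`.
#' @param tracks named list of track tibbles (or bedGraph paths); names must
#'   match the manifest.
#' @param manifest tibble with `name`, `stage` (`"preB"`/`"proB"`),
#'   `total_tags` (and optionally `assay`).
#' @param stage_mode `"preB"` or `"proB"`.
#' @param mask character vector of feature columns to drop.
#' @return Tibble with `v_gene` followed by numeric feature columns; no
#'   missing values.
#' @export
assemble_feature_matrix <- function(ref, tracks, manifest,
                                    stage_mode = c("preB", "proB"),
                                    mask = NULL) {
  stage_mode <- match.arg(stage_mode)
  abort_if(!all(c("name", "stage", "total_tags") %in% names(manifest)),
           "manifest needs columns name, stage, total_tags")
  abort_if(!all(manifest$name %in% names(tracks)),
           "manifest names tracks that were not provided")
  use <- if (stage_mode == "proB") manifest[manifest$stage == "proB", ] else manifest
  abort_if(nrow(use) == 0, "no tracks left for this stage mode")
  windows <- build_windows(ref)
  feat <- purrr::map_dfc(seq_len(nrow(use)), function(i) {
    q <- quantify_track(tracks[[use$name[i]]], windows, use$total_tags[i])
    wide <- tidyr::pivot_wider(q[, c("v_gene", "window", "signal")],
                               names_from = "window", values_from = "signal")
    out <- wide[match(ref$v_genes$name, wide$v_gene), -1]
    names(out) <- paste0(use$name[i], ".", names(out))
    out
  })
  res <- dplyr::bind_cols(
    tibble::tibble(v_gene = ref$v_genes$name),
    feat,
    tibble::tibble(ric_score = ref$v_genes$ric_score,
                   distance_to_jk1 = as.numeric(ref$v_genes$distance_to_jk1))
  )
  if (!is.null(mask)) res <- res[, setdiff(names(res), mask)]
  abort_if(anyNA(res), "feature matrix contains missing values")
  res
}

#' Simulate planted-effect coverage tracks
#'
#' Emits `n_tracks` synthetic coverage tracks over the gene windows. One
#' designated track carries a planted log-linear effect in its RSS window:
#' `log(freq) = a + b * signal + noise` over genes with nonzero truth
#' frequency, with `b` taken from the truth's `planted_effect`. All other
#' windows and all remaining tracks are independent noise, so the planted
#' track's RSS-window feature is the only genuinely predictive column.
#'
#' @param ref a `kappa_ref`.
#' @param truth a `kappa_truth` (for the per-gene frequencies).
#' @param config a [sim_config()] (seed source).
#' @param n_tracks number of tracks (half labelled pre-B, half pro-B).
#' @param designated name of the planted track.
#' @param noise_sd noise standard deviation on the planted linear relation.
#' @param total_tags declared tag total per track.
#' @param dir if non-`NULL`, write bedGraph files there.
#' @return List with `tracks` (named list of tibbles), `manifest`,
#'   `designated`, and `planted_feature` (the `<track>.rss` column name).
#' @export
simulate_signal_tracks <- function(ref, truth, config, n_tracks = 34L,
                                   designated = "planted", noise_sd = 0.1,
                                   total_tags = 1e7, dir = NULL) {
  force(truth)
  set.seed(config$seed + 3L)
  windows <- build_windows(ref)
  b <- truth$planted_effect

  names_all <- c(designated,
                 sprintf("noise%02d", seq_len(max(0L, n_tracks - 1L))))
  tracks <- stats::setNames(vector("list", n_tracks), names_all)
  for (tn in names_all) {
    tr <- windows
    tr$value <- stats::rlnorm(nrow(tr), meanlog = 0, sdlog = 0.5)
    if (tn == designated && b != 0) {
      rss <- tr$window == "rss"
      f <- rowSums(truth$freq)[tr$v_gene[rss]]
      active <- f > 0
      sig <- rep(NA_real_, sum(rss))
      sig[active] <- (log(f[active]) - mean(log(f[active]))) / b +
        stats::rnorm(sum(active), 0, noise_sd)
      # shift to positive coverage; inactive genes sit at baseline
      base <- if (any(active)) min(sig[active]) else 0
      sig <- sig - base + 0.5
      sig[!active] <- 0.25
      tr$value[rss] <- sig
    }
    # store per-bp coverage such that the quantified window signal equals
    # value (windows scale by width and depth normalisation)
    tr$value <- tr$value / (tr$end - tr$start) / (1e7 / total_tags)
    tracks[[tn]] <- tr[, c("chrom", "start", "end", "value")]
  }
  manifest <- tibble::tibble(
    name = names_all,
    stage = rep_len(c("preB", "proB"), n_tracks),
    assay = "chip",
    total_tags = total_tags
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    manifest$path <- file.path(dir, paste0(manifest$name, ".bedGraph"))
    purrr::walk2(tracks, manifest$path, write_bedgraph)
  }
  list(tracks = tracks, manifest = manifest, designated = designated,
       planted_feature = paste0(designated, ".rss"))
}
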