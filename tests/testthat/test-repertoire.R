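# Frequency views, Jk usage, active classification, ratio analyses,
# locus-half bias.

toy_counts <- function() {
  tibble::tibble(
    sample_id = rep(c("r1", "r2", "r3"), each = 2),
    v_gene = rep(c("g", "h"), 3),
    jk = "Jk1",
    n = c(10, 90, 20, 80, 70, 30)
  )
}

test_that("pooled frequencies are summed counts over summed totals", {
  counts <- toy_counts()
  f <- repertoire_frequencies(counts)
  expect_equal(f$freq[f$v_gene == "g"], 100 / 300)
  # single gene with all reads
  one <- tibble::tibble(sample_id = "s", v_gene = "g", jk = "Jk1", n = 10)
  expect_equal(repertoire_frequencies(one)$freq, 1)
  # frequency views sum to one
  sc <- small_calls()
  counts2 <- repertoire_counts(dedup_calls(sc$calls))
  expect_equal(sum(repertoire_frequencies(counts2)$freq), 1)
  expect_equal(sum(repertoire_frequencies(counts2, view = "Jk1")$freq), 1)
  # VkJkALL frequency equals the sum of per-Jk contributions
  all_f <- repertoire_frequencies(counts2)
  by_jk <- counts2 |>
    dplyr::group_by(v_gene) |>
    dplyr::summarise(n = sum(n))
  expect_equal(all_f$n, by_jk$n[match(all_f$v_gene, by_jk$v_gene)])
  expect_error(repertoire_frequencies(dplyr::mutate(counts, n = 0)), "zero")
})

test_that("estimated frequencies sit within binomial error of the truth", {
  sc <- small_calls()
  counts <- repertoire_counts(dedup_calls(sc$calls))
  est <- repertoire_frequencies(counts)
  true_f <- rowSums(sc$truth$freq)
  n <- sc$cfg$n_molecules
  for (g in names(true_f)) {
    fhat <- est$freq[est$v_gene == g]
    if (length(fhat) == 0) fhat <- 0
    se <- sqrt(true_f[[g]] * (1 - true_f[[g]]) / n)
    expect_lt(abs(fhat - true_f[[g]]), 4 * se + 2 / n)
  }
})

test_that("Jk usage recovers the planted weights and respects the 5-read rule", {
  ref <- tiny_ref()
  w <- c(0.5, 0.2, 0.2, 0.1)
  freq <- outer(rep(1, 6), w)
  dimnames(freq) <- list(ref$v_genes$name, ref$j_genes$name)
  cfg <- sim_config(n_molecules = 30000, seed = 31)
  truth <- simulate_repertoire(ref, cfg, freq = freq)
  counts <- truth$molecules |>
    dplyr::count(v_gene, jk, name = "n") |>
    dplyr::mutate(sample_id = "s1", n = as.numeric(n))
  u <- jk_usage(counts)
  pooled <- u[u$sample_id == "pooled", ]
  expect_lt(max(abs(pooled$pct[match(ref$j_genes$name, pooled$jk)] / 100 - w)),
            0.01)

  # per-gene profile: a gene with reads only to Jk1 is (100, 0, 0, 0)
  counts2 <- tibble::tibble(
    sample_id = "s1", v_gene = c("g", "g", "h"), jk = c("Jk1", "Jk1", "Jk2"),
    n = c(5, 3, 7)
  )
  prof <- jk_usage_per_gene(counts2, min_reads = 5)
  expect_equal(prof$pct[prof$v_gene == "g"], 100)
  # gene below 5 reads in one replicate is excluded
  counts3 <- dplyr::bind_rows(
    counts2,
    tibble::tibble(sample_id = "s2", v_gene = c("g", "h"),
                   jk = "Jk1", n = c(4, 9))
  )
  prof3 <- jk_usage_per_gene(counts3, min_reads = 5)
  expect_false("g" %in% prof3$v_gene)
  expect_true("h" %in% prof3$v_gene)
})

test_that("per-Jk repertoire correlations behave on constructed cases", {
  # identical per-gene weights for Jk4 and Jk5: r -> 1
  counts <- tibble::tibble(
    sample_id = "s",
    v_gene = rep(c("a", "b", "c"), times = 4),
    jk = rep(c("Jk1", "Jk2", "Jk4", "Jk5"), each = 3),
    n = c(5, 1, 4, 2, 2, 6, 10, 20, 70, 10, 20, 70)
  )
  m <- jk_repertoire_correlations(counts)
  expect_equal(dim(m), c(4L, 4L))
  expect_equal(m["Jk4", "Jk5"], 1)
  expect_equal(diag(m), setNames(rep(1, 4), colnames(m)))
  # orthogonal two-gene toy vectors: r = -1
  counts2 <- tibble::tibble(
    sample_id = "s", v_gene = c("a", "b"), jk = c("Jk1", "Jk2"), n = c(1, 1)
  )
  m2 <- jk_repertoire_correlations(counts2)
  expect_equal(m2["Jk1", "Jk2"], -1)
})

test_that("active-gene thresholds sit exactly at the documented boundaries", {
  mk <- function(n_g) tibble::tibble(
    sample_id = "s", v_gene = c("g", "filler"), jk = "Jk1",
    n = c(n_g, 1e6 - n_g)
  )
  act15 <- classify_active(mk(15), mode = "preB")
  expect_true(act15$active[act15$v_gene == "g"])
  act14 <- classify_active(mk(14), mode = "preB")
  expect_false(act14$active[act14$v_gene == "g"])

  # pro-B absolute rule: 1 read is active, 0 reads inactive
  pro <- classify_active(
    tibble::tibble(sample_id = "s", v_gene = "g", jk = "Jk1", n = 1),
    mode = "proB", genes = c("g", "zero")
  )
  expect_true(pro$active[pro$v_gene == "g"])
  expect_false(pro$active[pro$v_gene == "zero"])

  # monotone: raising the threshold never activates a gene
  set.seed(1)
  counts <- tibble::tibble(sample_id = "s", v_gene = letters[1:20],
                           jk = "Jk1", n = rpois(20, 50))
  for (th in c(5, 50, 500, 5000)) {
    lo <- classify_active(counts, "preB", threshold_per_million = th)
    hi <- classify_active(counts, "preB", threshold_per_million = th * 2)
    expect_true(all(lo$active | !hi$active))
  }

  # genes with zero planted frequency are inactive at any positive threshold
  sc <- small_calls()
  zero_genes <- names(which(rowSums(sc$truth$freq) == 0))
  cls <- classify_active(repertoire_counts(dedup_calls(sc$calls)), "proB",
                         genes = sc$ref$v_genes$name)
  expect_true(all(!cls$active[cls$v_gene %in% zero_genes]))
})

test_that("divergence flags need both the mean and every-replicate rule", {
  genes <- c("steady", "partial", "up", "filler")
  mk_counts <- function(freqs, sample) {
    # filler tops each replicate up to 1000 reads so that frequency ratios
    # equal count ratios across the two tables
    tibble::tibble(sample_id = sample, v_gene = genes, jk = "Jk1",
                   n = c(freqs, 1000 - sum(freqs)))
  }
  # 'partial' has replicate ratios (2.5, 2.1, 1.4): mean passes, one
  # replicate fails the 1.5-fold rule
  base <- c(100, 100, 100)
  a <- dplyr::bind_rows(
    mk_counts(c(100, 250, 300), "r1"),
    mk_counts(c(100, 210, 300), "r2"),
    mk_counts(c(100, 140, 300), "r3")
  )
  b <- dplyr::bind_rows(
    mk_counts(base, "r1"), mk_counts(base, "r2"), mk_counts(base, "r3")
  )
  out <- ratio_analysis(a, b)
  expect_true(is.na(out$flag[out$v_gene == "partial"]))
  expect_equal(out$flag[out$v_gene == "up"], "A")

  # identical tables flag nothing
  none <- ratio_analysis(a, a)
  expect_true(all(is.na(none$flag)))

  # direction symmetry: swapping tables swaps flags exactly
  sw <- ratio_analysis(b, a)
  expect_equal(sw$flag[sw$v_gene == "up"], "B")
  merged <- dplyr::inner_join(out, sw, by = "v_gene", suffix = c("", ".sw"))
  expect_true(all(
    (is.na(merged$flag) & is.na(merged$flag.sw)) |
      (merged$flag == "A" & merged$flag.sw == "B") |
      (merged$flag == "B" & merged$flag.sw == "A"),
    na.rm = TRUE
  ))
})

test_that("a planted strong promoter is flagged RNA-high", {
  ref <- simulate_locus(n_v = 10, seed = 2)
  u <- matrix(1, 10, 4, dimnames = list(ref$v_genes$name, ref$j_genes$name))
  ps <- stats::setNames(rep(1, 10), ref$v_genes$name)
  strong <- ref$v_genes$name[5]
  ps[strong] <- 3
  cfg <- sim_config(n_molecules = 30000, seed = 33, nmd_survival = 1)
  truth <- simulate_repertoire(ref, cfg, freq = u, promoter_strength = ps)
  # three replicate RNA/gDNA library pairs from the same truth
  gd <- list()
  rn <- list()
  for (i in 1:3) {
    cfg_i <- sim_config(n_molecules = 10000, seed = 33 + i, nmd_survival = 1)
    gd[[i]] <- parse_truth_labels(
      simulate_gdna_library(truth, ref, cfg_i)$read_id
    ) |>
      dplyr::count(v_gene = true_v, jk = true_jk, name = "n") |>
      dplyr::mutate(sample_id = paste0("g", i), n = as.numeric(n))
    rn[[i]] <- parse_truth_labels(
      simulate_rna_library(truth, ref, cfg_i, n_transcripts = 10000)$read_id
    ) |>
      dplyr::count(v_gene = true_v, jk = true_jk, name = "n") |>
      dplyr::mutate(sample_id = paste0("r", i), n = as.numeric(n))
  }
  out <- ratio_analysis(dplyr::bind_rows(rn), dplyr::bind_rows(gd), ref)
  expect_equal(out$flag[out$v_gene == strong], "A")  # RNA-high
  expect_true(all(is.na(out$flag[out$v_gene != strong])))
})

test_that("zero frequencies are replaced by one-read equivalents in ratios", {
  fa <- tibble::tibble(v_gene = c("g", "h", "z"), freq = c(0.02, 0.01, 0))
  fb <- tibble::tibble(v_gene = c("g", "h", "z"), freq = c(0.01, 0, 0.005))
  out <- pseudo_count_ratio(fa, fb, total_a = 1e4, total_b = 1e4)
  expect_equal(out$ratio_ab[out$v_gene == "g"], 2)          # no replacement
  expect_equal(out$ratio_ab[out$v_gene == "h"], 0.01 / 1e-4)  # denom 1/total
  expect_equal(out$replaced[out$v_gene == "h"], "b")
  expect_true(out$underrepresented[out$v_gene == "h"])
  expect_false(out$underrepresented[out$v_gene == "g"])
  # both-zero genes are skipped
  fa2 <- dplyr::bind_rows(fa, tibble::tibble(v_gene = "dead", freq = 0))
  fb2 <- dplyr::bind_rows(fb, tibble::tibble(v_gene = "dead", freq = 0))
  out2 <- pseudo_count_ratio(fa2, fb2, 1e4, 1e4)
  expect_false("dead" %in% out2$v_gene)
})

test_that("locus-half sums conserve total frequency and recover planted bias", {
  ref <- assign_halves(simulate_locus(n_v = 10, seed = 2))
  prox <- ref$v_genes$name[ref$v_genes$half == "proximal"]
  dist <- ref$v_genes$name[ref$v_genes$half == "distal"]

  # all reads proximal
  c1 <- tibble::tibble(sample_id = "s", v_gene = prox[1], jk = "Jk1", n = 10)
  hb1 <- half_bias(c1, ref)
  expect_equal(hb1$proximal, 1)
  expect_equal(hb1$distal, 0)

  # planted distal shares 0.55 vs 0.40: difference ~0.15
  mk <- function(d_share, sample, n_tot = 20000, seed = 1) {
    set.seed(seed)
    gene_w <- c(stats::setNames(rep((1 - d_share) / length(prox),
                                    length(prox)), prox),
                stats::setNames(rep(d_share / length(dist),
                                    length(dist)), dist))
    draws <- sample(names(gene_w), n_tot, TRUE, prob = gene_w)
    tibble::tibble(sample_id = sample, v_gene = draws, jk = "Jk1") |>
      dplyr::count(sample_id, v_gene, jk, name = "n") |>
      dplyr::mutate(n = as.numeric(n))
  }
  ca <- dplyr::bind_rows(mk(0.55, "p1", seed = 41), mk(0.55, "p2", seed = 42))
  cb <- dplyr::bind_rows(mk(0.40, "q1", seed = 43), mk(0.40, "q2", seed = 44))
  ba <- half_bias(ca, ref)
  bb <- half_bias(cb, ref)
  expect_equal(ba$proximal + ba$distal, rep(1, 2))
  paired <- half_bias_paired(ba, bb)
  expect_lt(max(abs(paired$distal_diff - 0.15)), 0.02)
})
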