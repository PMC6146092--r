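# Ground-truthed read simulation: sampling, junction frames, duplication,
# cross-priming, reproducibility, label fidelity.

test_that("molecule draws follow the frequency matrix", {
  ref <- simulate_locus(n_v = 10, seed = 2)
  cfg <- sim_config(n_molecules = 50000, seed = 5)
  truth <- simulate_repertoire(ref, cfg)  # default log-normal weights
  shares <- prop.table(table(truth$molecules$v_gene))
  expected <- rowSums(truth$freq)
  expect_lt(max(abs(shares[names(expected)] - expected)), 0.01)

  # uniform case: each gene ~10%
  u <- matrix(1, 10, 4, dimnames = list(ref$v_genes$name, ref$j_genes$name))
  tu <- simulate_repertoire(ref, cfg, freq = u)
  su <- prop.table(table(tu$molecules$v_gene))
  expect_lt(max(abs(su - 0.1)), 0.01)

  # point mass: every molecule from the one allowed gene
  pm <- matrix(0, 10, 4, dimnames = dimnames(u))
  pm[3, 2] <- 1
  tp <- simulate_repertoire(ref, cfg, freq = pm)
  expect_true(all(tp$molecules$v_gene == ref$v_genes$name[3]))
  expect_true(all(tp$molecules$jk == ref$j_genes$name[2]))

  # degenerate matrix errors
  z <- matrix(0, 10, 4, dimnames = dimnames(u))
  expect_error(simulate_repertoire(ref, cfg, freq = z), "degenerate")
})

test_that("uniform junction offsets give one third productive molecules", {
  ref <- tiny_ref()
  cfg <- sim_config(n_molecules = 100000, seed = 5)
  truth <- simulate_repertoire(ref, cfg)
  prod_frac <- mean(truth$molecules$productive)
  expect_lt(abs(prod_frac - 1 / 3), 0.01)
  # conservation: every molecule accounted for
  expect_equal(nrow(truth$molecules), cfg$n_molecules)
})

test_that("PCR duplication and cross-priming hit their configured rates", {
  ref <- tiny_ref()
  cfg0 <- sim_config(n_molecules = 5000, seed = 6, pcr_dup_rate = 0)
  truth <- simulate_repertoire(ref, cfg0)
  reads0 <- simulate_gdna_library(truth, ref, cfg0)
  expect_equal(nrow(reads0), 5000L)

  cfg5 <- sim_config(n_molecules = 10000, seed = 6, pcr_dup_rate = 0.5)
  truth5 <- simulate_repertoire(ref, cfg5)
  reads5 <- simulate_gdna_library(truth5, ref, cfg5)
  # geometric resampling: expected reads n / (1 - 0.5) = 2n
  expect_lt(abs(nrow(reads5) / 20000 - 1), 0.05)
  # duplicate groups share UMI and shear start: dedup keys collapse exactly
  # to the per-molecule keys
  labs <- parse_truth_labels(reads5$read_id)
  expect_equal(length(unique(labs$molecule_id)), 10000L)

  cfgx <- sim_config(n_molecules = 5000, seed = 6, cross_prime_rate = 0.2)
  truthx <- simulate_repertoire(ref, cfgx)
  readsx <- simulate_gdna_library(truthx, ref, cfgx)
  primers <- kappaseq:::j_primers(ref, "primary")
  labsx <- parse_truth_labels(readsx$read_id)
  # primer at the read 3' end (mate 2 is primer-anchored)
  suffix <- kappaseq:::revcomp(substr(readsx$seq2, 1, 20))
  primer_jk <- names(primers)[match(suffix, primers)]
  crossed <- primer_jk != labsx$true_jk
  expect_lt(abs(mean(crossed) - 0.2), 0.02)
})

test_that("identical seeds give byte-identical FASTQ output", {
  ref <- tiny_ref()
  cfg <- sim_config(n_molecules = 300, seed = 12, pcr_dup_rate = 0.2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  t1 <- simulate_repertoire(ref, cfg)
  f1 <- attr(simulate_gdna_library(t1, ref, cfg, dir = d1), "files")
  t2 <- simulate_repertoire(ref, cfg)
  f2 <- attr(simulate_gdna_library(t2, ref, cfg, dir = d2), "files")
  r1 <- read_fastq_pair(f1$r1, f1$r2)
  r2 <- read_fastq_pair(f2$r1, f2$r2)
  expect_identical(r1, r2)
  # FASTQ round-trip preserves the in-memory reads
  mem <- simulate_gdna_library(simulate_repertoire(ref, cfg), ref, cfg)
  expect_identical(r1$seq1, mem$seq1)
  expect_identical(r1$qual2, mem$qual2)
})

test_that("RNA libraries reflect promoter strength and NMD", {
  ref <- simulate_locus(n_v = 10, seed = 2)
  u <- matrix(1, 10, 4, dimnames = list(ref$v_genes$name, ref$j_genes$name))

  # promoter strength 3 for one gene among 10 equal genes, NMD off:
  # RNA share of that gene -> 3 / (9 + 3)
  ps <- stats::setNames(rep(1, 10), ref$v_genes$name)
  ps[4] <- 3
  cfg <- sim_config(n_molecules = 40000, seed = 9, nmd_survival = 1)
  truth <- simulate_repertoire(ref, cfg, freq = u, promoter_strength = ps)
  rna <- simulate_rna_library(truth, ref, cfg)
  labs <- parse_truth_labels(rna$read_id)
  share <- mean(labs$true_v == ref$v_genes$name[4])
  expect_lt(abs(share - 3 / 12), 0.015)

  # equal strengths, nmd_survival = 1: RNA gene shares track gDNA shares
  truth2 <- simulate_repertoire(ref, cfg, freq = u)
  rna2 <- simulate_rna_library(truth2, ref, cfg)
  labs2 <- parse_truth_labels(rna2$read_id)
  expect_lt(max(abs(prop.table(table(labs2$true_v)) - 0.1)), 0.015)

  # nmd_survival = 0: every RNA read is productive
  cfg0 <- sim_config(n_molecules = 5000, seed = 9, nmd_survival = 0)
  truth0 <- simulate_repertoire(ref, cfg0, freq = u)
  rna0 <- simulate_rna_library(truth0, ref, cfg0)
  labs0 <- parse_truth_labels(rna0$read_id)
  expect_true(all(labs0$true_productive))
})

test_that("read names carry faithful ground-truth labels", {
  sc <- small_calls()
  labs <- parse_truth_labels(sc$reads$read_id)
  m <- sc$truth$molecules
  expect_identical(labs$true_v, m$v_gene[labs$molecule_id])
  expect_identical(labs$true_jk, m$jk[labs$molecule_id])
  expect_identical(labs$true_productive, m$productive[labs$molecule_id])
})

test_that("planted-effect tracks correlate with frequency; noise tracks do not", {
  ref <- simulate_locus(n_v = 30, seed = 4)
  cfg <- sim_config(n_molecules = 1000, seed = 4)
  truth <- simulate_repertoire(ref, cfg, planted_effect = 1)
  sig <- simulate_signal_tracks(ref, truth, cfg, n_tracks = 34,
                                noise_sd = 1e-6)
  expect_length(sig$tracks, 34L)
  fm <- assemble_feature_matrix(ref, sig$tracks, sig$manifest, "preB")
  f <- rowSums(truth$freq)[fm$v_gene]
  # near-zero noise: rank correlation of the planted RSS feature -> 1
  expect_gt(cor(fm[[sig$planted_feature]], log(f), method = "spearman"),
            0.999)
  # b = 0 leaves the designated track indistinguishable from noise
  truth0 <- simulate_repertoire(ref, cfg, planted_effect = 0)
  sig0 <- simulate_signal_tracks(ref, truth0, cfg, n_tracks = 10)
  fm0 <- assemble_feature_matrix(ref, sig0$tracks, sig0$manifest, "preB")
  expect_lt(abs(cor(fm0[[sig0$planted_feature]], log(f))), 0.5)
})
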