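test_that("loop consensus matching accepts AGNN and rejects others", {
  # stem of 12 perfect pairs around each candidate loop
  arm <- "GCATCGATCGAT"
  mk <- function(loop) paste0(arm, loop, revcomp(arm))
  agtt <- find_hairpins(mk("AGTT"))
  expect_equal(nrow(agtt), 1L)
  expect_equal(agtt$loop_seq, "AGTT")
  expect_equal(agtt$loop_start, 12L)
  expect_equal(agtt$stem_len, 12L)
  expect_equal(nrow(find_hairpins(mk("CGAA"))), 0L)
  expect_equal(nrow(find_hairpins(strrep("A", 100L))), 0L)
})

test_that("planted hairpin with wobbles is recovered exactly", {
  set.seed(7)
  # stem 12 with two G.T wobbles: arm5 G positions pair with T in arm3
  arm5 <- "GGATCCGATCAT"
  arm3c <- strsplit(revcomp(arm5), "")[[1]]
  a3 <- arm3c
  a3[12 - 1 + 1] <- "T"   # pairs arm5[1] = G
  a3[12 - 2 + 1] <- "T"   # pairs arm5[2] = G
  hp <- paste0(arm5, "AGAA", paste(a3, collapse = ""))
  seq <- paste0(random_dna(16), hp, random_dna(16))
  found <- find_hairpins(seq)
  planted <- oracle_hairpins(seq)
  expect_equal(found, planted, ignore_attr = TRUE)
  expect_true(any(found$loop_start == 16 + 12 & found$stem_len >= 12 &
                    found$n_wobble >= 2))
})

test_that("scanner equals the brute-force enumerator on random input", {
  set.seed(42)
  params <- hairpin_params()
  for (i in 1:300) {
    n <- sample(20:80, 1)
    s <- random_dna(n)
    expect_equal(find_hairpins(s, params), oracle_hairpins(s, params),
                 ignore_attr = TRUE)
  }
  # and with a permissive parameterization (wobble off, mismatch allowed)
  params2 <- hairpin_params(min_stem = 5, allow_wobble = FALSE,
                            max_mismatch = 1)
  for (i in 1:200) {
    s <- random_dna(sample(20:80, 1))
    expect_equal(find_hairpins(s, params2), oracle_hairpins(s, params2),
                 ignore_attr = TRUE)
  }
})

test_that("N never appears inside a reported hairpin", {
  arm <- "GCATCGATCGAT"
  seq <- paste0(arm, "AGTT", revcomp(arm))
  seqN <- paste0(substr(seq, 1, 3), "N", substr(seq, 5, nchar(seq)))
  found <- find_hairpins(seqN)
  # stem truncated before the N: 12 - 4 positions remain
  expect_true(all(found$arm5_start > 3))
})

test_that("predict_rcs places candidates at the configured distance", {
  set.seed(11)
  cfg <- sim_config(seed = 3L, n_cd_ext = 3L, n_cd_noext = 1L,
                    n_haca_capped = 1L, n_haca_ext = 1L,
                    n_polycistron = 0L)
  sim <- gen_genome_and_genes(cfg)
  truth <- sim$truth
  for (i in which(truth$has_rcs)) {
    gene <- sim$genes[sim$genes$gene_id == truth$gene_id[i], ]
    rcs <- predict_rcs(gene, sim$genome)
    expect_equal(nrow(rcs), 1L)
    expect_equal(rcs$loop_start_t, truth$loop_start_t[i])
    expect_equal(rcs$cleave_up_t, truth$loop_start_t[i] - 14L)
    expect_equal(rcs$cleave_up_g, truth$cleave_up_g[i])
    expect_true(rcs$within_extension)
  }
  # a gene without a 5' extension yields an empty, flagged result
  noext <- sim$genes[sim$genes$gene_id ==
                       truth$gene_id[truth$ext5_len == 0][1], ]
  r0 <- predict_rcs(noext, sim$genome)
  expect_equal(nrow(r0), 0L)
  expect_equal(attr(r0, "reason"), "no 5' extension")
  expect_error(predict_rcs(transform(noext, chrom = "chrX"), sim$genome),
               "unknown chromosome")
})

test_that("predictions mirror under reverse-complementation", {
  cfg <- sim_config(seed = 5L, n_cd_ext = 4L, n_cd_noext = 0L,
                    n_haca_capped = 0L, n_haca_ext = 2L,
                    n_polycistron = 1L)
  sim <- gen_genome_and_genes(cfg)
  fwd <- predict_rcs_all(sim$genes, sim$genome)
  mir <- mirror_dataset(sim$genome, sim$genes)
  rev <- predict_rcs_all(mir$genes, mir$genome)
  rev <- rev[match(fwd$rcs_id, rev$rcs_id), ]
  n <- nchar(sim$genome[["chrS"]])
  expect_equal(rev$loop_gstart, n - fwd$loop_gend)
  expect_equal(rev$loop_gend, n - fwd$loop_gstart)
  expect_equal(rev$cleave_up_g, n - 1L - fwd$cleave_up_g)
  expect_equal(rev$loop_start_t, fwd$loop_start_t)
  expect_equal(rev$stem_len, fwd$stem_len)
})

test_that("shuffled extensions carry no hairpins beyond chance", {
  set.seed(19)
  cfg <- sim_config(seed = 23L, n_cd_ext = 10L, n_cd_noext = 0L,
                    n_haca_capped = 0L, n_haca_ext = 5L,
                    n_polycistron = 0L)
  sim <- gen_genome_and_genes(cfg)
  truth <- sim$truth
  n_shuffle_hits <- 0L
  for (i in which(truth$has_rcs)) {
    gene <- sim$genes[sim$genes$gene_id == truth$gene_id[i], ]
    ext <- transcript_seq(sim$genome, gene, 0L, ext5_len(gene))
    for (r in 1:3) {
      n_shuffle_hits <- n_shuffle_hits +
        nrow(find_hairpins(dinuc_shuffle(ext)))
    }
  }
  # 45 dinucleotide-preserving shuffles of planted extensions: the AGNN
  # hairpin signal must not survive shuffling
  expect_lte(n_shuffle_hits, 1L)
})
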