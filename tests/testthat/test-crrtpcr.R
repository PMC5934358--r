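clone_fixture <- local({
  cfg <- sim_config(seed = 31L, n_cd_ext = 2L, n_cd_noext = 0L,
                    n_haca_capped = 0L, n_haca_ext = 0L,
                    n_polycistron = 0L)
  sim <- gen_genome_and_genes(cfg)
  gid <- sim$truth$gene_id[1]
  list(cfg = cfg, sim = sim, gid = gid,
       gene = sim$genes[sim$genes$gene_id == gid, ])
})

# rotate a string by k (move first k chars to the end)
rotate <- function(s, k) {
  paste0(substr(s, k + 1L, nchar(s)), substr(s, 1L, k))
}

test_that("hand-built clones are parsed to their exact calls", {
  fx <- clone_fixture
  txs <- transcript_seq(fx$sim$genome, fx$gene)
  mstart <- ext5_len(fx$gene); mend <- mature_end_t(fx$gene)

  # exact circular permutation of the mature sequence
  mature <- substr(txs, mstart + 1L, mend)
  canon <- canonicalize_junction(txs, mstart, mend, 0L, prefer = mstart)
  call <- parse_clone(rotate(mature, 30L), "c1", fx$gene, fx$sim$genome)
  expect_equal(call$status, "ok")
  expect_equal(call$five_offset, canon$s - mstart)
  expect_equal(call$ext3_len, canon$e - mend)
  expect_equal(call$tailA_len, 0L)

  # mature + 6 templated nt + 5 non-templated A's
  mol <- paste0(substr(txs, mstart + 1L, mend + 6L), strrep("A", 5L))
  canon <- canonicalize_junction(txs, mstart, mend + 6L, 5L, prefer = mstart)
  call <- parse_clone(rotate(mol, 40L), "c2", fx$gene, fx$sim$genome)
  expect_equal(call$status, "ok")
  expect_equal(call$ext3_len, canon$e - mend)
  expect_equal(call$tailA_len, canon$tail)
  expect_equal(call$five_offset, canon$s - mstart)
  # molecule length is conserved by canonicalization
  expect_equal((canon$e - canon$s) + canon$tail, (mend + 6L - mstart) + 5L)
  expect_false(call$mature_3prime)

  # 5'-extended by 20 nt
  mol <- substr(txs, mstart - 20L + 1L, mend)
  canon <- canonicalize_junction(txs, mstart - 20L, mend, 0L, prefer = mstart)
  call <- parse_clone(rotate(mol, 50L), "c3", fx$gene, fx$sim$genome)
  expect_equal(call$five_offset, canon$s - mstart)
  expect_lte(call$five_offset, -19L)   # canonical form may shift by ties

  # garbage read is rejected, not force-called
  expect_equal(parse_clone(random_dna(80L), "c4", fx$gene,
                           fx$sim$genome)$status, "unmappable")
})

test_that("tail assignment is maximal-templated-first and deterministic", {
  # build a transcript where the templated extension ends in genomic A's;
  # the bases flanking the planted region are fixed non-A so the canonical
  # absorption stops exactly at the A run
  set.seed(83)
  genome <- c(chrT = paste0(random_dna(19), "C",
                            "ACGTACGTACGTACGTACGTACGTACGTACGT",  # mature 32
                            "GCAAA",                             # ext + A run
                            "G", random_dna(19)))
  gene <- make_gene(tss = 5L, mature_start = 20L, mature_end = 52L,
                    terminator_end = 77L, chrom = "chrT")
  txs <- transcript_seq(genome, gene)
  mstart <- 15L; mend <- 47L
  # molecule: mature + "GC" + "AAAAA" where the genome continues with AAA
  mol <- paste0(substr(txs, mstart + 1L, mend + 2L), strrep("A", 5L))
  call <- parse_clone(rotate(mol, 16L), "t1", gene, genome)
  expect_equal(call$status, "ok")
  # three genomic A's absorbed as templated: ext3 = 5, tail = 2
  expect_equal(call$ext3_len, 5L)
  expect_equal(call$tailA_len, 2L)
  # invariant under the rotation point
  for (k in c(17L, 25L, 40L)) {
    again <- parse_clone(rotate(mol, k), "t2", gene, genome)
    expect_equal(again$ext3_len, 5L)
    expect_equal(again$tailA_len, 2L)
  }
})

test_that("generated cohorts are recovered exactly when error-free", {
  fx <- clone_fixture
  for (cond in c("wt", "mutant", "wt_precursor")) {
    gc <- gen_clones(fx$cfg, fx$sim, cond, gene_id = fx$gid)
    calls <- parse_clones(gc$clones, fx$gene, fx$sim$genome)
    expect_true(all(calls$status == "ok"))
    expect_equal(calls$five_offset, gc$truth$five_offset)
    expect_equal(calls$ext3_len, gc$truth$ext3_len)
    expect_equal(calls$tailA_len, gc$truth$tailA_len)
  }
})

test_that("reconstruction identity holds for error-free clones", {
  fx <- clone_fixture
  txs <- transcript_seq(fx$sim$genome, fx$gene)
  mstart <- ext5_len(fx$gene); mend <- mature_end_t(fx$gene)
  gc <- gen_clones(fx$cfg, fx$sim, "mutant", gene_id = fx$gid)
  calls <- parse_clones(gc$clones, fx$gene, fx$sim$genome)
  for (i in seq_len(nrow(calls))) {
    s <- mstart + calls$five_offset[i]
    e <- mend + calls$ext3_len[i]
    mol <- paste0(substr(txs, s + 1L, e), strrep("A", calls$tailA_len[i]))
    read <- gc$clones[[calls$clone_id[i]]]
    rotations <- vapply(0:(nchar(mol) - 1L), function(k) rotate(mol, k),
                        "")
    expect_true(read %in% rotations)
  }
})

test_that("clone summaries recover the planted 5'/3' association", {
  fx <- clone_fixture
  gc <- gen_clones(fx$cfg, fx$sim, "mutant", gene_id = fx$gid)
  calls <- parse_clones(gc$clones, fx$gene, fx$sim$genome)
  smry <- summarize_clones(calls)
  ct <- smry$crosstab
  # 5'-extended clones carry unprocessed oligoadenylated 3' ends;
  # 5'-mature clones carry mature 3' ends
  expect_equal(unname(ct["five_extended", "three_extended"]),
               fx$cfg$n_clones_ext)
  expect_equal(unname(ct["five_mature", "three_mature"]),
               fx$cfg$n_clones_mature)
  expect_equal(unname(ct["five_extended", "three_mature"]), 0L)
  expect_equal(unname(ct["five_mature", "three_extended"]), 0L)

  wt <- gen_clones(fx$cfg, fx$sim, "wt", gene_id = fx$gid)
  wt_calls <- parse_clones(wt$clones, fx$gene, fx$sim$genome)
  expect_equal(summarize_clones(wt_calls)$mature_fraction, 1.0)

  pre <- gen_clones(fx$cfg, fx$sim, "wt_precursor", gene_id = fx$gid)
  pre_calls <- parse_clones(pre$clones, fx$gene, fx$sim$genome)
  expect_true(all(pre_calls$ext3_len >= 2L))
})
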