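test_that("the generator is a pure function of its seed", {
  cfg <- sim_config(seed = 9L, n_cd_ext = 3L, n_cd_noext = 1L,
                    n_haca_capped = 2L, n_haca_ext = 1L,
                    n_polycistron = 1L)
  a <- gen_genome_and_genes(cfg)
  b <- gen_genome_and_genes(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(as.data.frame(a$genes), as.data.frame(b$genes))
  expect_identical(a$truth, b$truth)
  expect_identical(gen_netseq(cfg, a)$counts, gen_netseq(cfg, b)$counts)
  expect_identical(gen_rnaseq(cfg, a, "mutant")$counts,
                   gen_rnaseq(cfg, b, "mutant")$counts)
  expect_identical(gen_clones(cfg, a, "mutant")$clones,
                   gen_clones(cfg, b, "mutant")$clones)
  expect_identical(gen_qpcr(cfg)$table$ct, gen_qpcr(cfg)$table$ct)
})

test_that("category counts, invariants and planted structure all hold", {
  cfg <- sim_config(seed = 13L)
  sim <- gen_genome_and_genes(cfg)
  expect_equal(nrow(sim$genes),
               cfg$n_cd_ext + cfg$n_cd_noext + cfg$n_haca_capped +
                 cfg$n_haca_ext + 2L * cfg$n_polycistron)
  expect_s3_class(sim$genes, "sno_genes")   # invariants ran at build
  tab <- table(sim$truth$category)
  expect_equal(as.vector(tab[c("cd_ext", "cd_noext", "haca_capped",
                               "haca_ext")]),
               c(cfg$n_cd_ext, cfg$n_cd_noext, cfg$n_haca_capped,
                 cfg$n_haca_ext))
  # extension-bearing genes carry exactly one planted hairpin; planted
  # stems are inside the configured range
  with_ext <- sim$truth[sim$truth$ext5_len > 0, ]
  expect_true(all(with_ext$has_rcs))
  expect_true(all(with_ext$stem_len >= cfg$stem_range[1] &
                    with_ext$stem_len <= cfg$stem_range[2]))
  # H/ACA genes never get a mutant 3' extension
  expect_true(all(is.na(sim$truth$ext3_mut[sim$truth$class == "HACA"])))
  expect_true(all(!sim$truth$rd_3prime[sim$truth$class == "HACA"]))
})

test_that("empty configuration still emits a genome", {
  cfg <- sim_config(seed = 2L, n_cd_ext = 0L, n_cd_noext = 0L,
                    n_haca_capped = 0L, n_haca_ext = 0L,
                    n_polycistron = 0L)
  sim <- gen_genome_and_genes(cfg)
  expect_equal(nrow(sim$genes), 0L)
  expect_gt(nchar(sim$genome[[1]]), 0L)
})

test_that("NET-seq pileups sit at planted sites on the gene strand", {
  cfg <- sim_config(seed = 17L, n_cd_ext = 4L, n_cd_noext = 2L,
                    n_haca_capped = 2L, n_haca_ext = 2L,
                    n_polycistron = 1L)
  sim <- gen_genome_and_genes(cfg)
  net <- gen_netseq(cfg, sim)
  truth <- sim$truth
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    g <- sim$genes[sim$genes$gene_id == tr$gene_id, ]
    if (tr$has_rcs) {
      v <- track_values(net, g$chrom, g$strand, tr$cleave_up_g,
                        tr$cleave_up_g + 1L)
      expect_gte(v, cfg$netseq_peak)
      anti <- if (g$strand == "+") "-" else "+"
      va <- track_values(net, g$chrom, anti, tr$cleave_up_g,
                         tr$cleave_up_g + 1L)
      expect_lt(va, cfg$netseq_peak)
    } else {
      # no pileup anywhere upstream of genes without 5' extensions
      up <- tx_values(net, g, 0L, ext5_len(g) + 1L)
      expect_lt(max(up), cfg$netseq_peak)
    }
  }
  # peak height 0 gives a background-only track
  cfg0 <- sim_config(seed = 17L, n_cd_ext = 4L, n_cd_noext = 2L,
                     n_haca_capped = 2L, n_haca_ext = 2L,
                     n_polycistron = 1L, netseq_peak = 0)
  net0 <- gen_netseq(cfg0, sim)
  expect_lt(max(unlist(net0$counts)), 10)
})

test_that("simulate_dataset writes the full byte-stable file set", {
  cfg <- sim_config(seed = 21L, n_cd_ext = 3L, n_cd_noext = 1L,
                    n_haca_capped = 2L, n_haca_ext = 1L,
                    n_polycistron = 1L, n_clones_wt = 4L,
                    n_clones_ext = 5L, n_clones_mature = 2L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  files <- list.files(d1)
  expect_true(all(c("genome.fa", "genes.tsv", "netseq.plus.bedgraph",
                    "rnaseq.wt.plus.bedgraph", "clones.mut.fa",
                    "qpcr.csv", "truth.json") %in% files))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  # the written files feed the reading path back to identical objects
  genome <- read_genome(file.path(d1, "genome.fa"))
  genes <- read_genes(file.path(d1, "genes.tsv"))
  sim <- gen_genome_and_genes(cfg)
  expect_identical(genome, sim$genome)
  expect_identical(as.data.frame(genes), as.data.frame(sim$genes))
  net <- load_bedgraph_pair(file.path(d1, "netseq.plus.bedgraph"),
                            file.path(d1, "netseq.minus.bedgraph"),
                            "netseq_3prime_ends",
                            seqlens = nchar(genome))
  expect_equal(net$counts, gen_netseq(cfg, sim)$counts)
})
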