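# shared small cohort for the signal tests
local_sim <- local({
  cfg <- sim_config(seed = 77L, n_cd_ext = 6L, n_cd_noext = 2L,
                    n_haca_capped = 4L, n_haca_ext = 3L,
                    n_polycistron = 1L)
  sim <- gen_genome_and_genes(cfg)
  list(cfg = cfg, sim = sim,
       netseq = gen_netseq(cfg, sim),
       wt = gen_rnaseq(cfg, sim, "WT"),
       mut = gen_rnaseq(cfg, sim, "mutant"))
})

test_that("5' extension detection needs a sustained mutant excess", {
  sim <- local_sim$sim
  ext_gene <- sim$genes[sim$genes$gene_id ==
                          sim$truth$gene_id[sim$truth$category ==
                                              "cd_ext"][1], ]
  # identical tracks: nothing to detect
  same <- detect_five_prime_extension(ext_gene, local_sim$wt,
                                      local_sim$wt)
  expect_false(same$extended_in_mut)
  # planted precursor coverage: full extension detected
  hit <- detect_five_prime_extension(ext_gene, local_sim$wt,
                                     local_sim$mut)
  expect_true(hit$extended_in_mut)
  expect_equal(hit$est_extension_len, ext5_len(ext_gene))
  # no annotated extension: flagged reason
  noext <- sim$genes[sim$genes$gene_id ==
                       sim$truth$gene_id[sim$truth$ext5_len == 0][1], ]
  r <- detect_five_prime_extension(noext, local_sim$wt, local_sim$mut)
  expect_false(r$extended_in_mut)
  expect_match(r$reason, "no 5' extension")
  # a 5-nt blip does not satisfy min_len = 10
  g5 <- make_gene(tss = 0L, mature_start = 40L, mature_end = 90L,
                  terminator_end = 100L, chrom = "chrZ")
  wt5 <- new_track(c(chrZ = 100L), "coverage")
  mut5 <- new_track(c(chrZ = 100L), "coverage")
  wt5$counts[["chrZ:+"]][41:90] <- 10
  mut5$counts[["chrZ:+"]][41:90] <- 10
  mut5$counts[["chrZ:+"]][10:14] <- 50
  expect_false(detect_five_prime_extension(g5, wt5, mut5)$extended_in_mut)
})

test_that("co-localization calls planted peaks and rejects flat signal", {
  sim <- local_sim$sim
  rcs <- predict_rcs_all(sim$genes, sim$genome)
  coloc <- colocalize_rcs_all(rcs, sim$genes, local_sim$netseq)
  expect_true(all(coloc$is_colocalized))
  expect_true(all(coloc$peak_offset == -14L))

  # all-zero track
  zero <- new_track(c(chrS = nchar(sim$genome[["chrS"]])),
                    "netseq_3prime_ends")
  c0 <- colocalize_rcs_all(rcs, sim$genes, zero)
  expect_false(any(c0$is_colocalized))
  expect_true(all(c0$enrichment == 0))

  # uniform track: peak equals background, enrichment ~ 1
  unif <- zero
  for (k in names(unif$counts)) unif$counts[[k]][] <- 5
  cu <- colocalize_rcs_all(rcs, sim$genes, unif)
  expect_true(all(abs(cu$enrichment - 1) < 1e-9))
  expect_false(any(cu$is_colocalized))
})

test_that("calls are invariant under library scaling (scale up)", {
  sim <- local_sim$sim
  rcs <- predict_rcs_all(sim$genes, sim$genome)
  before <- colocalize_rcs_all(rcs, sim$genes, local_sim$netseq)
  after <- colocalize_rcs_all(rcs, sim$genes,
                              track_scale(local_sim$netseq, 3))
  expect_equal(after$is_colocalized, before$is_colocalized)
  expect_equal(after$peak_t, before$peak_t)

  nf <- metagene_3prime(sim$genes, local_sim$wt, local_sim$mut)$norm_factor
  calls_a <- classify_three_prime_all(sim$genes, local_sim$wt,
                                      local_sim$mut, norm_factor = nf)
  calls_b <- classify_three_prime_all(sim$genes,
                                      track_scale(local_sim$wt, 3),
                                      track_scale(local_sim$mut, 3),
                                      norm_factor = nf)
  expect_equal(calls_b$extended, calls_a$extended)
})

test_that("loop-anchored metagene is a delta at the planted offset", {
  sim <- local_sim$sim
  truth <- sim$truth
  one <- truth[truth$category == "cd_ext", ][1, ]
  gene <- sim$genes[sim$genes$gene_id == one$gene_id, ]
  rcs <- predict_rcs(gene, sim$genome)
  clean <- new_track(c(chrS = nchar(sim$genome[["chrS"]])),
                     "netseq_3prime_ends")
  key <- paste0(gene$chrom, ":", gene$strand)
  clean$counts[[key]][one$cleave_up_g + 1L] <- 50
  mg <- metagene_5prime(rcs, sim$genes, clean)
  expect_s3_class(mg, "metagene_profile")
  hit <- which(mg$mean$sense > 0)
  expect_equal(mg$offsets[hit], -14L)
  expect_true(all(mg$mean$antisense == 0))

  # averaging identity: two identical rows equal each row
  rcs2 <- rbind(rcs, rcs)
  mg2 <- metagene_5prime(rcs2, sim$genes, clean)
  expect_equal(mg2$mean$sense, mg$mean$sense)
})

test_that("3' metagene computes the normalization factor from data", {
  sim <- local_sim$sim
  rd <- sim$genes[!is.na(sim$genes$polycistron_id) |
                    (sim$genes$class == "CD" &
                       sim$truth$ext5_len > 0), , drop = FALSE]
  # identical conditions: factor 1, identical profiles
  mg_same <- metagene_3prime(rd, local_sim$wt, local_sim$wt)
  expect_equal(mg_same$norm_factor, 1.0)
  expect_equal(mg_same$mean$wt, mg_same$mean$mut)

  # a global 1/1.73 scaling is recovered as a factor of 1.73 exactly
  mg_scaled <- metagene_3prime(rd, local_sim$wt,
                               track_scale(local_sim$wt, 1 / 1.73))
  expect_equal(mg_scaled$norm_factor, 1.73, tolerance = 1e-12)
  expect_equal(mg_scaled$mean$mut, mg_scaled$mean$wt)

  # planted mutant: normalized excess only at positive offsets
  mg <- metagene_3prime(rd, local_sim$wt, local_sim$mut)
  pos <- mg$offsets >= 1 & mg$offsets <= 10
  neg <- mg$offsets <= 0 & mg$offsets >= -6
  expect_gt(mean(mg$mean$mut[pos] - mg$mean$wt[pos]), 50)
  expect_lt(max(abs(mg$mean$mut[neg] / mg$mean$wt[neg] - 1)), 0.1)

  # normalization idempotence: re-deriving the factor after applying it
  mg_idem <- metagene_3prime(rd, local_sim$wt,
                             track_scale(local_sim$mut, mg$norm_factor))
  expect_equal(mg_idem$norm_factor, 1.0, tolerance = 1e-9)

  # exclusions are honored
  mg_ex <- metagene_3prime(rd, local_sim$wt, local_sim$mut,
                           exclude = rd$gene_id[1])
  expect_equal(mg_ex$n_genes, nrow(rd) - 1L)

  # zero mutant signal in the reference window is an error
  zero <- new_track(c(chrS = nchar(sim$genome[["chrS"]])), "coverage")
  expect_error(metagene_3prime(rd, local_sim$wt, zero),
               "normalization undefined")
})

test_that("3' classification separates planted truth from controls", {
  sim <- local_sim$sim
  nf <- 1.73
  calls <- classify_three_prime_all(sim$genes, local_sim$wt,
                                    local_sim$mut, norm_factor = nf)
  truth <- sim$truth[match(calls$gene_id, sim$truth$gene_id), ]
  expect_equal(calls$extended, truth$rd_3prime)

  # wt vs wt: nothing called
  none <- classify_three_prime_all(sim$genes, local_sim$wt,
                                   local_sim$wt, norm_factor = 1)
  expect_false(any(none$extended))

  # an extension present equally in both conditions fails the ratio test
  g <- make_gene(tss = 0L, mature_start = 0L, mature_end = 60L,
                 terminator_end = 100L, chrom = "chrZ")
  both <- new_track(c(chrZ = 100L), "coverage")
  both$counts[["chrZ:+"]][1:75] <- 100
  same <- classify_three_prime_extension(g, both, both, norm_factor = 1)
  expect_false(same$extended)
})
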