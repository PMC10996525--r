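test_that("noncoding flanks are the 50 kb windows minus all CDS", {
  # free-standing gene: symmetric full-length flanks
  fl <- extract_noncoding_flanks(list(start = 100000L, end = 101000L),
                                 NULL, 1e6)
  expect_equal(fl, data.frame(start = c(50000L, 101000L),
                              end = c(100000L, 151000L)))
  expect_equal(sum(fl$end - fl$start), 100000)

  # gene at the chromosome start: left flank empty
  fl0 <- extract_noncoding_flanks(list(start = 0L, end = 500L), NULL, 1e6)
  expect_equal(nrow(fl0), 1)
  expect_lte(sum(fl0$end - fl0$start), 50000)

  # neighbouring CDS abutting the focal gene truncates the left flank
  cds <- data.frame(start = 99000L, end = 100000L)
  fl2 <- extract_noncoding_flanks(list(start = 100000L, end = 101000L),
                                  cds, 1e6)
  expect_equal(fl2$end[1], 99000L)
  expect_equal(sum(fl2$end - fl2$start), 99000)
})

test_that("flank extraction matches the per-base oracle on random instances", {
  set.seed(401)
  for (i in 1:60) {
    inst <- random_instance()
    gi <- sample(nrow(inst$genes), 1)
    got <- extract_noncoding_flanks(inst$genes[gi, ], inst$cds, inst$L,
                                    inst$flank_len)
    want <- bf_flank_positions(inst$genes$start[gi], inst$genes$end[gi],
                               inst$cds, inst$L, inst$flank_len)
    expect_equal(bf_positions(got$start, got$end, inst$L), want,
                 info = paste("instance", i))
  }
})

test_that("overlap resolution keeps the higher-scoring record intact", {
  r2 <- data.frame(chrom = "c1", start = c(10L, 20L), end = c(30L, 40L),
                   family_name = c("hi", "lo"), score = c(250, 100),
                   strand = "+", te_class = "LINE")
  out <- resolve_repeat_overlaps(r2)
  expect_equal(out$family_name, "hi")
  expect_equal(out$start, 10L)

  # non-overlapping input unchanged
  r3 <- data.frame(chrom = "c1", start = c(0L, 50L), end = c(10L, 60L),
                   family_name = c("a", "b"), score = c(1, 2), strand = "+",
                   te_class = "DNA")
  expect_equal(resolve_repeat_overlaps(r3), r3)

  # chain A > B > C with A and C disjoint: B falls, A and C survive
  rc <- data.frame(chrom = "c1", start = c(0L, 8L, 16L), end = c(10L, 18L, 26L),
                   family_name = c("A", "B", "C"), score = c(3, 2, 1),
                   strand = "+", te_class = "LTR")
  expect_equal(resolve_repeat_overlaps(rc)$family_name, c("A", "C"))
})

test_that("resolution matches the greedy oracle on random instances", {
  set.seed(402)
  for (i in 1:80) {
    inst <- random_instance()
    if (nrow(inst$rep) == 0) next
    got <- resolve_repeat_overlaps(inst$rep)
    want <- bf_resolve(inst$rep)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("instance", i))
  }
})

test_that("TE density counts covered flank positions, clipped to flanks", {
  fl <- data.frame(start = 0L, end = 100L)
  rep <- data.frame(chrom = "c1", start = c(10L, 50L), end = c(20L, 80L),
                    family_name = "f", score = 1, strand = "+",
                    te_class = c("LINE", "DNA"))
  d <- compute_te_density(fl, rep)
  expect_equal(d$te_covered_len, 40)
  expect_equal(d$density, 0.4)

  expect_equal(compute_te_density(fl, rep[0, ])$density, 0)

  clip <- data.frame(chrom = "c1", start = 90L, end = 200L,
                     family_name = "f", score = 1, strand = "+",
                     te_class = "LTR")
  expect_equal(compute_te_density(fl, clip)$te_covered_len, 10)

  # unresolved (overlapping) repeats are refused
  bad <- data.frame(chrom = "c1", start = c(0L, 5L), end = c(10L, 15L),
                    family_name = "f", score = 1, strand = "+",
                    te_class = "LINE")
  expect_error(compute_te_density(fl, bad), "resolve_repeat_overlaps")
  expect_error(compute_te_density(fl, rep, te_classes = "Simple"), "excluded")
})

test_that("percentile calls use linear interpolation and call ties upward", {
  prof10 <- data.frame(gene_id = sprintf("g%02d", 1:10),
                       noncoding_len = 100L, eligible = TRUE,
                       density_ALL = (1:10) / 100)
  calls <- call_compartmentalized(prof10, "ALL", 90)
  expect_equal(calls$called_gene_ids, "g10")
  expect_equal(calls$cutoff_value, 0.091)

  prof100 <- data.frame(gene_id = sprintf("g%03d", 1:100),
                        noncoding_len = 100L, eligible = TRUE,
                        density_ALL = (1:100) / 1000)
  expect_length(call_compartmentalized(prof100, "ALL", 95)$called_gene_ids, 5)

  tied <- data.frame(gene_id = sprintf("g%02d", 1:12), noncoding_len = 100L,
                     eligible = TRUE, density_ALL = 0.3)
  expect_warning(ct <- call_compartmentalized(tied, "ALL", 90), "degenerate")
  expect_length(ct$called_gene_ids, 12)

  few <- prof10[1:9, ]
  expect_error(call_compartmentalized(few, "ALL", 90), "fewer than 10")
})

test_that("ineligible genes are excluded from the density distribution", {
  prof <- data.frame(gene_id = sprintf("g%02d", 1:12),
                     noncoding_len = c(rep(100L, 10), 0L, 0L),
                     eligible = c(rep(TRUE, 10), FALSE, FALSE),
                     density_ALL = c((1:10) / 10, NA, NA))
  calls <- call_compartmentalized(prof, "ALL", 90)
  expect_false(any(c("g11", "g12") %in%
                     c(calls$called_gene_ids, calls$background_gene_ids)))
})

test_that("per-class covers partition the total TE cover", {
  fx <- planted_species()
  prof <- fx$profiles
  expect_equal(prof$cov_ALL,
               prof$cov_LINE + prof$cov_SINE + prof$cov_LTR + prof$cov_DNA +
                 prof$cov_Other)
  expect_true(all(prof$density_ALL[prof$eligible] >=
                    pmax(prof$density_LINE, prof$density_SINE,
                         prof$density_LTR, prof$density_DNA)[prof$eligible]))
})

test_that("vectorized profiles agree with per-gene extraction and coverage", {
  set.seed(403)
  inst <- random_instance()
  chroms <- chromosome_spec("c1", inst$L)
  genes <- data.frame(gene_id = paste0("g", seq_len(nrow(inst$genes))),
                      chrom = "c1", start = inst$genes$start,
                      end = inst$genes$end, strand = "+")
  # genes may overlap in the random instance; keep a non-overlapping subset
  keep <- c(TRUE, if (nrow(genes) > 1) genes$start[-1] >= cummax(genes$end[-nrow(genes)]) else NULL)
  genes <- genes[keep, ]
  cds <- inst$cds[inst$cds$gene_id %in% genes$gene_id, ]
  if (is.null(cds)) cds <- genes[0, c("gene_id", "chrom", "start", "end")]
  ann <- genome_annotation(chroms, genes, cds)
  rep <- resolve_repeat_overlaps(inst$rep)
  prof <- flank_profiles(ann, rep, inst$flank_len)
  for (i in seq_len(nrow(genes))) {
    fl <- extract_noncoding_flanks(genes[i, ], cds, inst$L, inst$flank_len)
    d <- compute_te_density(fl, rep)
    expect_equal(prof$noncoding_len[i], d$noncoding_len)
    expect_equal(prof$cov_ALL[i], d$te_covered_len)
  }
})
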