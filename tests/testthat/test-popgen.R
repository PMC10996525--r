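sv_row <- function(start, end, vtype = "TE_SV_INS", sample = "s1",
                   te_coverage = 0.9) {
  data.frame(chrom = "chr1", start = start, end = end, vtype = vtype,
             sample = sample, length = end - start,
             te_coverage = te_coverage, stringsAsFactors = FALSE)
}

test_that("SV merging is single-linkage on both breakpoints within 500 bp", {
  two <- rbind(sv_row(1000, 1400, sample = "s1"),
               sv_row(1300, 1700, sample = "s2"))
  m <- merge_sv_calls(two, 500, n_samples = 10)
  expect_equal(nrow(m), 1)
  expect_equal(m$alt_count, 2L)
  expect_equal(m$pos, 1000)          # leftmost representative

  # insertion vs deletion at the same spot never merge
  mixed <- rbind(sv_row(1000, 1400, "TE_SV_INS"),
                 sv_row(1000, 1400, "TE_SV_DEL", sample = "s2"))
  expect_equal(nrow(merge_sv_calls(mixed, 500, 10)), 2)

  # A-B and B-C within 500 but A-C at 900: one single-linkage cluster
  chain <- rbind(sv_row(1000, 2000, sample = "s1"),
                 sv_row(1450, 2450, sample = "s2"),
                 sv_row(1900, 2900, sample = "s3"))
  mc <- merge_sv_calls(chain, 500, 10)
  expect_equal(nrow(mc), 1)
  expect_equal(mc$alt_count, 3L)
})

test_that("SV merging matches the exhaustive clustering oracle", {
  set.seed(701)
  for (i in 1:40) {
    n <- sample(2:12, 1)
    st <- sample(0:5000, n, replace = TRUE)
    en <- st + sample(c(100, 300, 700), n, replace = TRUE)
    svs <- sv_row(st, en, sample = paste0("s", seq_len(n)))
    m <- merge_sv_calls(svs, 500, n_samples = n)
    comp <- cluster_oracle(st, en, 500)
    expect_equal(nrow(m), length(unique(comp)), info = paste("instance", i))
    expect_equal(sort(m$alt_count), sort(as.integer(table(comp))),
                 info = paste("instance", i))
  }
})

test_that("TE-SV filter keeps length > 50 and coverage >= 0.5, literally", {
  svs <- data.frame(
    variant_id = paste0("v", 1:5), chrom = "chr1", pos = 1:5,
    vtype = "TE_SV_INS",
    length = c(49L, 50L, 51L, 200L, 200L),
    te_coverage = c(0.9, 0.9, 0.5, 0.49, 0.5),
    alt_count = 1L, n_samples = 4L, stringsAsFactors = FALSE)
  kept <- filter_te_svs(svs)
  expect_equal(kept$variant_id, c("v3", "v5"))
  # ambiguous-sequence calls drop before filtering; missing coverage is fatal
  svs$ambiguous <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(filter_te_svs(svs)$variant_id, "v5")
  svs$ambiguous <- NULL
  svs$te_coverage[2] <- NA
  expect_error(filter_te_svs(svs), "te_coverage missing")
})

test_that("the bundled 20-record VCF filters to exactly the known survivors", {
  vcf <- system.file("extdata", "toy_sv.vcf", package = "tecompart")
  v <- read_variants(vcf)
  expect_equal(nrow(v), 20)
  kept <- filter_te_svs(v)
  expect_equal(nrow(kept), 11)
  expect_true(all(kept$length > 50 & kept$te_coverage >= 0.5))
})

test_that("variants are assigned to flank/CDS with called-group priority", {
  flanks <- data.frame(gene_id = c("gCalled", "gOther"), chrom = "chr1",
                       start = c(100L, 350L), end = c(400L, 600L))
  cds <- data.frame(gene_id = c("gCalled", "gOther"), chrom = "chr1",
                    start = c(1000L, 2000L), end = c(1200L, 2200L))
  calls <- make_calls("gCalled", "gOther")
  v <- data.frame(
    variant_id = c("sv_in_called", "sv_in_both", "snv_other", "sv_nowhere"),
    chrom = "chr1", pos = c(150L, 380L, 2100L, 5000L),
    vtype = c("TE_SV_INS", "TE_SV_DEL", "SNV_SYN", "TE_SV_INS"),
    length = 100L, te_coverage = 0.9, alt_count = 1L, n_samples = 4L,
    stringsAsFactors = FALSE)
  a <- assign_variants(v, flanks, cds, calls)
  expect_equal(nrow(a), 3)                        # unassigned dropped
  expect_false("sv_nowhere" %in% a$variant_id)
  expect_equal(a$group[a$variant_id == "sv_in_called"], "called")
  expect_equal(a$group[a$variant_id == "sv_in_both"], "called")  # priority
  expect_equal(a$context[a$variant_id == "snv_other"], "cds")
  expect_equal(a$group[a$variant_id == "snv_other"], "other")
  # partition: each retained variant in exactly one cell
  expect_equal(anyDuplicated(a$variant_id), 0)
})

test_that("folded spectra bin minor-allele counts and drop monomorphics", {
  a <- folded_afs(c(1L, 3L, 2L), 4)
  expect_equal(unname(a$bins), c(2L, 1L))
  expect_equal(a$n_variants, 3)
  e <- folded_afs(integer(0), 10)
  expect_equal(sum(e$bins), 0)
  expect_equal(unname(folded_afs(25L, 50)$bins[25]), 1L)   # n/2 boundary
  expect_message(m <- folded_afs(c(0L, 5L, 10L), 10), "monomorphic")
  expect_equal(m$n_variants, 1)
  # folding an already-folded count vector changes nothing
  set.seed(702)
  ac <- simulate_alt_counts(500, 50)
  expect_equal(folded_afs(pmin(ac, 50L - ac), 50)$bins, folded_afs(ac, 50)$bins)
})

test_that("AFS chi-square pools the tail, conserves counts, matches chisq.test", {
  x <- folded_afs(c(1L, 3L, 2L, 10L, 25L), 50)
  same <- compare_afs_chi2(x, x)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  set.seed(703)
  a <- folded_afs(simulate_alt_counts(2000, 8), 8)
  b <- folded_afs(simulate_alt_counts(2000, 8, 0.4), 8)
  got <- compare_afs_chi2(a, b)
  # all expected counts >= 5 here, so no pooling: plain chisq must agree
  ref <- suppressWarnings(chisq.test(rbind(a$bins, b$bins), correct = FALSE))
  expect_equal(got$chi2, unname(ref$statistic))
  expect_equal(got$p, unname(ref$p.value))
  expect_equal(got$df, unname(ref$parameter))

  # sparse tails pool from the top; totals are conserved
  set.seed(704)
  c1 <- folded_afs(simulate_alt_counts(60, 50), 50)
  c2 <- folded_afs(simulate_alt_counts(60, 50), 50)
  pooled <- compare_afs_chi2(c1, c2)
  expect_lt(pooled$k_pooled, 25)
  expect_error(compare_afs_chi2(folded_afs(integer(0), 50), c2),
               "at least one variant")
  expect_error(compare_afs_chi2(c1, folded_afs(simulate_alt_counts(10, 8), 8)),
               "different sample counts")
})

test_that("skew confined to called flanks raises the called-group minor frequency", {
  fx <- planted_species()
  calls <- call_compartmentalized(fx$profiles, "ALL", 95, "sim")
  pop <- simulate_population(fx$sim, fx$cfg)
  flanks <- noncoding_flank_table(fx$sim$ann, fx$cfg$flank_len)
  assigned <- assign_variants(pop, flanks, fx$sim$ann$cds, calls)
  te <- assigned[assigned$context == "flank", ]
  maf <- pmin(te$alt_count, te$n_samples - te$alt_count) / te$n_samples
  expect_gt(mean(maf[te$group == "called"]), mean(maf[te$group == "other"]))
})
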