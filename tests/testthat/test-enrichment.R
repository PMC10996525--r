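test_that("two-sided Fisher p matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(2, 0, 0, 2)$p, 1 / 3)
  # a zero margin leaves a single attainable table
  expect_equal(fisher_exact_2x2(0, 0, 3, 5)$p, 1)
  expect_equal(fisher_exact_2x2(4, 0, 6, 0)$p, 1)
  # transposition symmetry
  expect_equal(fisher_exact_2x2(3, 1, 2, 4)$p, fisher_exact_2x2(3, 2, 1, 4)$p)
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
  set.seed(501)
  for (i in 1:25) {
    tb <- as.integer(sample(0:8, 4, replace = TRUE))
    if (sum(tb) == 0) next
    expect_equal(fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])$p,
                 fisher_enum(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
  }
})

test_that("BH q-values equal the step-up formula and preserve order", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(502)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_direct(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    # permutation equivariance
    o <- sample(length(p))
    expect_equal(bh_fdr(p[o]), q[o])
  }
  expect_false(is.unsorted(bh_fdr(sort(runif(15)))))
})

toy_go_world <- function() {
  # 20 genes; term T1 on g1..g3 + g10 (three of them called), T2 everywhere
  genes <- sprintf("g%02d", 1:20)
  go <- rbind(data.frame(gene_id = genes[c(1:3, 10)], term = "T1"),
              data.frame(gene_id = genes, term = "T2"))
  calls <- make_calls(genes[1:5], genes[6:20])
  list(genes = genes, go = go, calls = calls)
}

test_that("GO enrichment reports both directions with BH over terms", {
  w <- toy_go_world()
  rec <- go_enrichment(w$calls, w$go)
  expect_setequal(rec$term_id, c("T1", "T2"))
  t1 <- rec[rec$term_id == "T1", ]
  expect_equal(t1$study_hits, 3)
  expect_equal(t1$study_n, 5)
  expect_equal(t1$pop_hits, 4)
  expect_equal(t1$pop_n, 20)
  expect_equal(t1$fold, (3 / 5) / (4 / 20))
  expect_equal(t1$direction, "enriched")
  # a term carried by every gene is uninformative
  t2 <- rec[rec$term_id == "T2", ]
  expect_equal(t2$fold, 1)
  expect_equal(t2$p, 1)
  expect_equal(rec$q, bh_fdr(rec$p))   # BH is permutation-equivariant
})

test_that("GO enrichment enforces the test-set and annotation-quality floors", {
  w <- toy_go_world()
  # only 3 annotated called genes -> no test, reasoned empty result
  small <- make_calls(c("g01", "g02", "g03", "g18"), sprintf("g%02d", 4:17))
  go3 <- w$go[w$go$gene_id != "g18", ]
  res <- go_enrichment(small, go3)
  expect_equal(nrow(res), 0)
  expect_match(attr(res, "reason"), "minimum test-set size")
  # species with sparse annotation refused outright
  sparse <- data.frame(gene_id = c("g01", "g02"), term = "T1")
  expect_error(go_enrichment(w$calls, sparse), "refused")
})

test_that("planted GO term is recovered with the smallest q", {
  fx <- planted_species()
  calls <- call_compartmentalized(fx$profiles, "ALL", 95, "sim")
  rec <- go_enrichment(calls, fx$sim$go_map)
  expect_equal(rec$term_id[1], fx$sim$truth$planted_go_term)
  expect_lt(rec$q[1], 0.05)
  expect_equal(rec$direction[1], "enriched")
})

test_that("95th-percentile fallback fires only when no term passes FDR", {
  fx <- planted_species()
  res <- go_enrichment_with_fallback(fx$profiles, fx$sim$go_map, "ALL")
  expect_equal(res$percentile_used, 90)   # strong plant already passes at 90
  # scrambled annotations never pass, so the fallback must fire
  set.seed(503)
  shuffled <- fx$sim$go_map
  shuffled$gene_id <- sample(shuffled$gene_id)
  res2 <- go_enrichment_with_fallback(fx$profiles, shuffled, "ALL")
  expect_equal(res2$percentile_used, 95)
})

test_that("multigene fold is the ratio of multigene-family fractions", {
  fam <- data.frame(
    gene_id = sprintf("g%02d", 1:20),
    family_id = c(rep("BIG", 10), paste0("S", 1:10)))
  calls <- make_calls(sprintf("g%02d", c(1:8, 11, 12)),
                      sprintf("g%02d", c(9, 10, 13:20)))
  mg <- multigene_fold(calls, fam, size_threshold = 10)
  expect_equal(mg$fold, (8 / 10) / (2 / 10))
  # identical composition
  calls2 <- make_calls(sprintf("g%02d", c(1:5, 11:15)),
                       sprintf("g%02d", c(6:10, 16:20)))
  expect_equal(multigene_fold(calls2, fam)$fold, 1)
  # empty background refused; zero background fraction -> Inf sentinel
  expect_error(multigene_fold(make_calls("g01", character(0)), fam),
               "empty background")
  callsb <- make_calls(sprintf("g%02d", 1:4), sprintf("g%02d", 11:14))
  expect_equal(multigene_fold(callsb, fam)$fold, Inf)
})

test_that("TE-class profile comparison is null for identical call sets", {
  fx <- planted_species()
  calls <- call_compartmentalized(fx$profiles, "ALL", 95, "sim")
  by_sp <- list(sim = list(LINE = calls, SINE = calls))
  res <- compare_te_class_profiles(by_sp, list(sim = fx$sim$go_map))
  expect_equal(res$records$p, rep(1, nrow(res$records)))
  expect_equal(res$summary$fraction_significant, 0)
  expect_error(compare_te_class_profiles(list(sim = list(LINE = calls)),
                                         list(sim = fx$sim$go_map)),
               "two TE classes")
})

test_that("term frequencies aggregate significant enrichment across species", {
  r1 <- data.frame(term_id = c("T1", "T2"), study_hits = 1, study_n = 5,
                   pop_hits = 2, pop_n = 10, fold = c(3, 0.5),
                   p = c(0.001, 0.2), q = c(0.01, 0.4),
                   direction = c("enriched", "purified"))
  r2 <- data.frame(term_id = "T1", study_hits = 1, study_n = 5,
                   pop_hits = 2, pop_n = 10, fold = 2, p = 0.2, q = 0.6,
                   direction = "enriched")
  agg <- aggregate_term_frequencies(list(a = r1, b = r2))
  expect_equal(agg$n_species_tested[agg$term_id == "T1"], 2L)
  expect_equal(agg$n_species_enriched[agg$term_id == "T1"], 1L)
  # purified or non-significant terms never count as enriched
  expect_equal(agg$n_species_enriched[agg$term_id == "T2"], 0L)
  expect_false("T9" %in% agg$term_id)
})
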