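# GO enrichment / purification of compartment calls, multigene-family
# fold enrichment, TE-class profile comparison, and cross-species term
# aggregation. GO terms are flat labels: no DAG propagation.

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Thin wrapper around [stats::fisher.test()] exposing the contingency
#' counts directly: `a` study hits, `b` study misses, `c` background
#' hits, `d` background misses.
#'
#' @param a,b,c,d non-negative integer counts, total >= 1.
#' @return list with `odds_ratio` (conditional MLE) and `p` (two-sided).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) < 1) stop("empty table")
  ft <- fisher.test(matrix(counts, 2, 2, byrow = TRUE))
  list(odds_ratio = unname(ft$estimate),
       p = min(1, max(0, ft$p.value)))   # guard float fuzz past 1
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Wrapper around [stats::p.adjust()] (method "BH"); order of the input
#' vector is preserved.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Per-species GO annotation quality
#'
#' Species with under 20% of genes GO-annotated are excluded from
#' enrichment testing.
#'
#' @param gene_ids all gene ids of the species.
#' @param go_map gene-to-term table (see [read_go_map()]).
#' @param min_fraction minimum annotated fraction (default 0.20).
#' @return list with n_genes, n_annotated, fraction_annotated, passes.
#' @export
species_go_quality <- function(gene_ids, go_map, min_fraction = 0.20) {
  n <- length(gene_ids)
  n_ann <- length(intersect(gene_ids, unique(go_map$gene_id)))
  frac <- if (n > 0) n_ann / n else 0
  list(n_genes = n, n_annotated = n_ann, fraction_annotated = frac,
       passes = frac >= min_fraction)
}

empty_enrichment <- function(reason) {
  structure(data.frame(term_id = character(), study_hits = integer(),
                       study_n = integer(), pop_hits = integer(),
                       pop_n = integer(), fold = numeric(), p = numeric(),
                       q = numeric(), direction = character(),
                       stringsAsFactors = FALSE),
            reason = reason)
}

#' GO enrichment and purification of a compartment call set
#'
#' One two-sided Fisher test per GO term: called, GO-annotated genes
#' (study) against all GO-annotated eligible genes (population), with BH
#' correction over terms. Both directions are reported: fold > 1 terms as
#' "enriched", fold < 1 as "purified". Species with under
#' `min_annotation_fraction` of genes annotated are refused; a study set
#' smaller than `min_study` annotated genes yields an empty result with a
#' `reason` attribute.
#'
#' @param calls a [call_compartmentalized()] result.
#' @param go_map gene-to-term table.
#' @param min_study minimum annotated called genes to test (default 4).
#' @param min_annotation_fraction species-quality floor (default 0.20).
#' @return data.frame of enrichment records (one row per term with at
#'   least one population hit), sorted by q then p.
#' @export
go_enrichment <- function(calls, go_map, min_study = 4,
                          min_annotation_fraction = 0.20) {
  universe <- c(calls$called_gene_ids, calls$background_gene_ids)
  qual <- species_go_quality(universe, go_map, min_annotation_fraction)
  if (!qual$passes)
    stop(sprintf("species refused: only %.1f%% of genes GO-annotated (need %.0f%%)",
                 100 * qual$fraction_annotated, 100 * min_annotation_fraction))
  gm <- go_map[go_map$gene_id %in% universe, , drop = FALSE]
  annotated <- unique(gm$gene_id)
  study <- intersect(calls$called_gene_ids, annotated)
  pop_n <- length(annotated)
  study_n <- length(study)
  if (study_n < min_study)
    return(empty_enrichment(sprintf(
      "only %d annotated called genes; minimum test-set size is %d",
      study_n, min_study)))
  by_term <- split(gm$gene_id, gm$term)
  terms <- names(by_term)
  study_hits <- vapply(by_term, function(g) sum(unique(g) %in% study), integer(1))
  pop_hits <- vapply(by_term, function(g) length(intersect(g, annotated)), integer(1))
  keep <- pop_hits >= 1
  terms <- terms[keep]; study_hits <- study_hits[keep]; pop_hits <- pop_hits[keep]
  p <- vapply(seq_along(terms), function(i)
    fisher_exact_2x2(study_hits[i], study_n - study_hits[i],
                     pop_hits[i] - study_hits[i],
                     (pop_n - study_n) - (pop_hits[i] - study_hits[i]))$p,
    numeric(1))
  fold <- (study_hits / study_n) / (pop_hits / pop_n)
  out <- data.frame(term_id = terms, study_hits = study_hits,
                    study_n = study_n, pop_hits = pop_hits, pop_n = pop_n,
                    fold = fold, p = p, q = bh_fdr(p),
                    direction = ifelse(fold >= 1, "enriched", "purified"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$q, out$p, out$term_id), , drop = FALSE]
}

#' GO enrichment with the 95th-percentile fallback
#'
#' Tests calls at the 90th percentile; if no term reaches `q < alpha`,
#' recomputes the call set at the 95th percentile and retests.
#'
#' @param profiles data.frame from [flank_profiles()].
#' @param go_map gene-to-term table.
#' @param te_class TE class for the call ("ALL" by default).
#' @param alpha FDR threshold triggering the fallback (default 0.05).
#' @param species_id label carried into the call set.
#' @param ... passed on to [go_enrichment()].
#' @return list with `records`, `calls`, `percentile_used`.
#' @export
go_enrichment_with_fallback <- function(profiles, go_map, te_class = "ALL",
                                        alpha = 0.05,
                                        species_id = NA_character_, ...) {
  calls90 <- call_compartmentalized(profiles, te_class, 90, species_id)
  rec <- go_enrichment(calls90, go_map, ...)
  if (nrow(rec) > 0 && any(rec$q < alpha))
    return(list(records = rec, calls = calls90, percentile_used = 90))
  calls95 <- call_compartmentalized(profiles, te_class, 95, species_id)
  list(records = go_enrichment(calls95, go_map, ...), calls = calls95,
       percentile_used = 95)
}

#' Top nominally-significant terms for species failing FDR
#'
#' Optional rescue report: the most enriched terms with unadjusted
#' p < `alpha` for species where no term survives FDR correction.
#'
#' @param records a [go_enrichment()] result.
#' @param n_top number of terms to report (default 5).
#' @param alpha nominal p-value threshold (default 0.05).
#' @return subset of `records` (possibly empty), enriched direction only.
#' @export
top_nominal_terms <- function(records, n_top = 5, alpha = 0.05) {
  cand <- records[records$p < alpha & records$direction == "enriched", , drop = FALSE]
  head(cand[order(cand$p), , drop = FALSE], n_top)
}

#' Multigene-family fold enrichment of a call set
#'
#' Ratio of the fraction of called genes belonging to families at or
#' above `size_threshold` members to the same fraction among background
#' genes. Returns `Inf` when the background fraction is zero but the
#' called fraction is positive.
#'
#' @param calls a [call_compartmentalized()] result.
#' @param family_map gene-to-family table (see [read_family_map()]).
#' @param size_threshold minimum family size counted as multigene
#'   (default 10).
#' @return list with fold, frac_called, frac_background, n_called,
#'   n_background.
#' @export
multigene_fold <- function(calls, family_map, size_threshold = 10) {
  if (length(calls$called_gene_ids) == 0) stop("empty call set")
  if (length(calls$background_gene_ids) == 0) stop("empty background set")
  sizes <- table(family_map$family_id)
  multi_fams <- names(sizes)[sizes >= size_threshold]
  gene_multi <- setNames(family_map$family_id %in% multi_fams, family_map$gene_id)
  fc <- mean(gene_multi[calls$called_gene_ids], na.rm = TRUE)
  fb <- mean(gene_multi[calls$background_gene_ids], na.rm = TRUE)
  fold <- if (fb == 0) { if (fc > 0) Inf else NaN } else fc / fb
  list(fold = fold, frac_called = fc, frac_background = fb,
       n_called = length(calls$called_gene_ids),
       n_background = length(calls$background_gene_ids))
}

#' Compare GO profiles of compartment calls between TE classes
#'
#' For each GO term and each pair of TE classes, builds a 2x2 table of
#' called genes with/without the term in class A vs class B, pooled
#' across species, and applies a two-sided Fisher test with BH
#' correction over terms within each class pair.
#'
#' @param calls_by_species named list: species -> named list of
#'   [call_compartmentalized()] results keyed by TE class.
#' @param go_maps named list: species -> gene-to-term table.
#' @param alpha q-value threshold for `fraction_significant`.
#' @return list with `records` (per class pair and term) and `summary`
#'   (per class pair: n_terms, n_significant, fraction_significant).
#' @export
compare_te_class_profiles <- function(calls_by_species, go_maps, alpha = 0.05) {
  classes <- sort(unique(unlist(lapply(calls_by_species, names))))
  if (length(classes) < 2) stop("need calls for at least two TE classes")
  # per class: pooled counts of called genes with/without each term
  term_hits <- function(cl) {
    tot <- 0L
    hits <- list()
    for (sp in names(calls_by_species)) {
      calls <- calls_by_species[[sp]][[cl]]
      if (is.null(calls)) next
      gm <- go_maps[[sp]]
      called <- intersect(calls$called_gene_ids, unique(gm$gene_id))
      tot <- tot + length(called)
      if (!length(called)) next
      tab <- table(unique(gm[gm$gene_id %in% called, c("gene_id", "term")])$term)
      hits[[sp]] <- setNames(as.integer(tab), names(tab))
    }
    flat <- do.call(c, unname(hits))
    counts <- if (length(flat)) tapply(flat, names(flat), sum) else NULL
    list(total = tot, counts = counts)
  }
  per_class <- lapply(setNames(classes, classes), term_hits)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  rec_rows <- list()
  sum_rows <- list()
  for (pr in pairs) {
    A <- per_class[[pr[1]]]; B <- per_class[[pr[2]]]
    if (A$total == 0 || B$total == 0) {
      warning("no called, annotated genes for pair ", pr[1], "/", pr[2])
      next
    }
    terms <- sort(union(names(A$counts), names(B$counts)))
    if (!length(terms)) next
    a <- ifelse(terms %in% names(A$counts), A$counts[terms], 0L)
    c_ <- ifelse(terms %in% names(B$counts), B$counts[terms], 0L)
    p <- vapply(seq_along(terms), function(i)
      fisher_exact_2x2(a[i], A$total - a[i], c_[i], B$total - c_[i])$p,
      numeric(1))
    q <- bh_fdr(p)
    rec_rows[[paste(pr, collapse = "-")]] <- data.frame(
      class_a = pr[1], class_b = pr[2], term_id = terms,
      hits_a = as.integer(a), n_a = A$total,
      hits_b = as.integer(c_), n_b = B$total,
      p = p, q = q, stringsAsFactors = FALSE, row.names = NULL)
    sum_rows[[paste(pr, collapse = "-")]] <- data.frame(
      class_a = pr[1], class_b = pr[2], n_terms = length(terms),
      n_significant = sum(q < alpha),
      fraction_significant = mean(q < alpha),
      stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, rec_rows), summary = do.call(rbind, sum_rows))
}

#' Aggregate enrichment frequencies across species
#'
#' Counts, for every GO term, in how many species it was tested and in
#' how many it was significantly enriched (q < alpha, direction
#' "enriched").
#'
#' @param records_by_species named list of [go_enrichment()] results.
#' @param alpha q-value threshold (default 0.05).
#' @return data.frame with term_id, n_species_enriched, n_species_tested,
#'   frequency.
#' @export
aggregate_term_frequencies <- function(records_by_species, alpha = 0.05) {
  if (!length(records_by_species)) stop("need at least one species")
  tested <- unlist(lapply(records_by_species, function(r) unique(r$term_id)))
  enr <- unlist(lapply(records_by_species, function(r)
    r$term_id[r$q < alpha & r$direction == "enriched"]))
  terms <- sort(unique(tested))
  n_tested <- as.integer(table(factor(tested, levels = terms)))
  n_enr <- as.integer(table(factor(enr, levels = terms)))
  data.frame(term_id = terms, n_species_enriched = n_enr,
             n_species_tested = n_tested,
             frequency = ifelse(n_tested > 0, n_enr / n_tested, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}
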