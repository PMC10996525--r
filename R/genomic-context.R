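# Chromosomal-position, GC and recombination context of compartment
# calls, with cross-species trend tests.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Subtelomeric enrichment/depletion permutation test for one chromosome
#'
#' A gene is subtelomeric iff its midpoint lies in the first or last
#' `terminal_frac` of the chromosome. The observed proportion of called
#' genes that are subtelomeric is compared with a null built by
#' resampling `|called|` genes without replacement from the chromosome's
#' genes `n_perm` times. The two-sided p doubles the smaller tail, with a
#' +1 pseudocount in numerator and denominator, capped at 1.
#'
#' @param positions gene midpoints (bp) on the chromosome.
#' @param chrom_len chromosome length (bp).
#' @param is_called logical vector parallel to `positions`.
#' @param terminal_frac terminal fraction per end (default 0.10).
#' @param n_perm number of permutations (default 1000).
#' @param alpha significance level used to label the direction.
#' @param seed optional seed (restores the RNG state afterwards).
#' @return list with n_genes, n_called, observed_prop, expected_prop,
#'   p, direction ("enriched", "depleted" or "ns").
#' @export
subtelomere_permutation_test <- function(positions, chrom_len, is_called,
                                         terminal_frac = 0.10, n_perm = 1000,
                                         alpha = 0.05, seed = NULL) {
  stopifnot(length(positions) == length(is_called))
  n_called <- sum(is_called)
  if (n_called == 0) {
    warning("no called genes on chromosome; test skipped")
    return(NULL)
  }
  subtel <- positions < terminal_frac * chrom_len |
            positions >= (1 - terminal_frac) * chrom_len
  obs <- mean(subtel[is_called])
  null_props <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      mean(subtel[sample.int(length(positions), n_called)]), numeric(1))
  })
  lo <- (1 + sum(null_props <= obs)) / (n_perm + 1)
  hi <- (1 + sum(null_props >= obs)) / (n_perm + 1)
  p <- min(1, 2 * min(lo, hi))
  expected <- mean(subtel)
  direction <- if (p >= alpha) "ns" else if (obs > expected) "enriched" else "depleted"
  list(n_genes = length(positions), n_called = n_called,
       observed_prop = obs, expected_prop = expected, p = p,
       direction = direction)
}

#' Subtelomere test across all chromosomes of a species
#'
#' @param ann a [genome_annotation()].
#' @param calls a [call_compartmentalized()] result.
#' @param ... passed to [subtelomere_permutation_test()].
#' @param seed optional seed; chromosome i uses `seed + i`.
#' @return data.frame with one row per testable chromosome.
#' @export
subtelomere_scan <- function(ann, calls, ..., seed = NULL) {
  genes <- ann$genes
  rows <- list()
  for (i in seq_len(nrow(ann$chroms))) {
    chr <- ann$chroms$name[i]
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (!nrow(g)) next
    res <- subtelomere_permutation_test(
      (g$start + g$end) / 2, ann$chroms$length[i],
      g$gene_id %in% calls$called_gene_ids, ...,
      seed = if (is.null(seed)) NULL else seed + i)
    if (is.null(res)) next
    rows[[chr]] <- data.frame(chrom = chr, n_genes = res$n_genes,
                              n_called = res$n_called,
                              observed_prop = res$observed_prop,
                              expected_prop = res$expected_prop,
                              p = res$p, direction = res$direction,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), n_genes = integer(),
                      n_called = integer(), observed_prop = numeric(),
                      expected_prop = numeric(), p = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare a per-gene quantitative context between called and background
#'
#' Two-sided Wilcoxon rank-sum comparison of a per-gene value (GC
#' content, recombination rate) between called and background genes. The
#' sign is that of (median called - median background). Fully tied
#' (constant) input returns sign 0 and p 1.
#'
#' @param values_called,values_background numeric vectors (>= 4 each).
#' @return list with median_called, median_background, p, sign (+1, -1
#'   or 0).
#' @export
context_group_comparison <- function(values_called, values_background) {
  if (length(values_called) < 4 || length(values_background) < 4)
    stop("need at least 4 values per group")
  mc <- median(values_called)
  mb <- median(values_background)
  all_equal <- length(unique(c(values_called, values_background))) == 1
  p <- if (all_equal) 1 else
    suppressWarnings(wilcox.test(values_called, values_background,
                                 alternative = "two.sided")$p.value)
  list(median_called = mc, median_background = mb, p = p,
       sign = sign(mc - mb))
}

#' Exact two-sided cross-species binomial test on direction signs
#'
#' Tests whether "+" outcomes depart from Binomial(n, 0.5). Zero signs
#' are dropped; the two-sided p sums the probabilities of all outcomes no
#' more likely than the observed count (the [stats::binom.test()]
#' construction).
#'
#' @param signs vector of +1 / -1 (0s are dropped).
#' @return list with n_positive, n, p.
#' @export
cross_species_binomial <- function(signs) {
  s <- signs[signs != 0]
  if (!length(s)) stop("no non-zero signs: cross-species test undefined")
  k <- sum(s > 0)
  list(n_positive = k, n = length(s),
       p = binom.test(k, length(s), 0.5, alternative = "two.sided")$p.value)
}

#' bp-weighted mean of a bedGraph track over a set of intervals
#'
#' Used to attach a recombination rate or GC value to a gene region (the
#' gene span plus its noncoding flanks): the mean of track values
#' weighted by the overlap width with each track interval.
#'
#' @param track data.frame from [read_bedgraph()] (chrom, start, end,
#'   value).
#' @param intervals data.frame with chrom, start, end.
#' @return weighted mean value (NA when there is no overlap).
#' @export
track_mean_over_intervals <- function(track, intervals) {
  tot_w <- 0
  tot_v <- 0
  for (chr in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == chr, , drop = FALSE]
    tr <- track[track$chrom == chr, , drop = FALSE]
    if (!nrow(tr) || !nrow(iv)) next
    h <- IRanges::findOverlaps(ir(iv$start, iv$end), ir(tr$start, tr$end))
    if (!length(h)) next
    w <- IRanges::width(IRanges::pintersect(
      ir(iv$start, iv$end)[S4Vectors::queryHits(h)],
      ir(tr$start, tr$end)[S4Vectors::subjectHits(h)]))
    tot_w <- tot_w + sum(w)
    tot_v <- tot_v + sum(w * tr$value[S4Vectors::subjectHits(h)])
  }
  if (tot_w == 0) NA_real_ else tot_v / tot_w
}

#' Per-gene context values and called/background comparison
#'
#' Attaches a bp-weighted track value to every gene (gene span plus
#' noncoding flanks) and compares called vs background with
#' [context_group_comparison()].
#'
#' @param ann a [genome_annotation()].
#' @param calls a [call_compartmentalized()] result.
#' @param track data.frame from [read_bedgraph()].
#' @param flank_len flank window included in each gene's region (bp).
#' @return list as from [context_group_comparison()], plus n_called and
#'   n_background.
#' @export
gene_context_comparison <- function(ann, calls, track, flank_len = 50000L) {
  flanks <- noncoding_flank_table(ann, flank_len)
  genes <- ann$genes
  vals <- vapply(seq_len(nrow(genes)), function(i) {
    iv <- rbind(data.frame(chrom = genes$chrom[i], start = genes$start[i],
                           end = genes$end[i], stringsAsFactors = FALSE),
                flanks[flanks$gene_id == genes$gene_id[i],
                       c("chrom", "start", "end")])
    track_mean_over_intervals(track, iv)
  }, numeric(1))
  names(vals) <- genes$gene_id
  vc <- vals[calls$called_gene_ids]
  vb <- vals[calls$background_gene_ids]
  vc <- vc[!is.na(vc)]; vb <- vb[!is.na(vb)]
  res <- context_group_comparison(vc, vb)
  c(res, list(n_called = length(vc), n_background = length(vb)))
}
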