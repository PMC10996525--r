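# The core statistic: TE density of the noncoding flanking regions of
# each gene, and percentile-based compartmentalization calls. Interval
# arithmetic goes through IRanges; densities are per gene and per TE
# class. Flanks of adjacent genes may overlap each other — each gene is
# scored independently, as per-gene coverage implies.

ir <- function(start, end) IRanges::IRanges(start = start + 1L, width = end - start)

ir_to_df <- function(x) {
  data.frame(start = IRanges::start(x) - 1L,
             end = IRanges::end(x), stringsAsFactors = FALSE)
}

#' Noncoding flanking intervals of one gene
#'
#' Takes the windows of `flank_len` bp immediately up- and downstream of
#' the gene span (truncated at the chromosome ends) and subtracts every
#' CDS interval on the chromosome — the focal gene's and its neighbours'
#' alike. Introns and UTRs of neighbouring genes remain; only CDS is
#' removed.
#'
#' @param gene one-row data.frame (or list) with `start`, `end` (0-based
#'   half-open).
#' @param cds data.frame of CDS intervals on the same chromosome with
#'   columns `start`, `end`.
#' @param chrom_len chromosome length in bp.
#' @param flank_len flank window size in bp (default 50 kb).
#' @return data.frame of disjoint sorted intervals (`start`, `end`).
#' @export
extract_noncoding_flanks <- function(gene, cds, chrom_len, flank_len = 50000L) {
  stopifnot(flank_len > 0, gene$start < gene$end, gene$end <= chrom_len)
  left <- c(max(0L, gene$start - flank_len), gene$start)
  right <- c(gene$end, min(chrom_len, gene$end + flank_len))
  wins <- rbind(left, right)
  wins <- wins[wins[, 1] < wins[, 2], , drop = FALSE]
  if (nrow(wins) == 0) return(data.frame(start = integer(), end = integer()))
  w <- ir(wins[, 1], wins[, 2])
  if (!is.null(cds) && nrow(cds) > 0) {
    res <- IRanges::setdiff(w, IRanges::reduce(ir(cds$start, cds$end)))
  } else {
    res <- IRanges::reduce(w)
  }
  ir_to_df(BiocGenerics::sort(res))
}

#' Resolve overlapping repeat annotations by score
#'
#' Greedy resolution in the style of RM2Bed's `higher_score` rule:
#' records are ranked by descending score (ties: leftmost start, then
#' longer record) and a record is kept only if it overlaps no
#' already-kept record. Survivors are kept intact; losers are dropped
#' whole. The output is pairwise non-overlapping within each chromosome.
#'
#' @param repeats repeat data.frame (see [read_repeats()]).
#' @return the surviving subset, sorted by (chrom, start).
#' @export
resolve_repeat_overlaps <- function(repeats) {
  if (nrow(repeats) < 2) return(repeats)
  keep <- logical(nrow(repeats))
  for (chr in unique(repeats$chrom)) {
    idx <- which(repeats$chrom == chr)
    r <- repeats[idx, ]
    ord <- order(-r$score, r$start, -(r$end - r$start))
    rng <- ir(r$start, r$end)
    hits <- IRanges::findOverlaps(rng, rng)
    adj <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    kept <- logical(length(idx))
    for (i in ord) {
      nb <- adj[[as.character(i)]]
      if (!any(kept[nb[nb != i]])) kept[i] <- TRUE
    }
    keep[idx] <- kept
  }
  out <- repeats[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

stop_if_unresolved <- function(repeats) {
  for (chr in unique(repeats$chrom)) {
    r <- repeats[repeats$chrom == chr, ]
    red <- IRanges::reduce(ir(r$start, r$end))
    if (sum(IRanges::width(red)) != sum(r$end - r$start))
      stop("repeat annotations overlap; run resolve_repeat_overlaps() first")
  }
  invisible(TRUE)
}

#' TE coverage and density of a set of flank intervals
#'
#' Density is the proportion of nucleotide positions in the flank
#' intervals covered by a repeat of one of the requested classes.
#' Repeats must already be non-overlapping (see
#' [resolve_repeat_overlaps()]); overlapping input is a hard error.
#' Simple repeats are never counted as TE sequence.
#'
#' @param flanks data.frame of disjoint intervals (`start`, `end`) on one
#'   chromosome.
#' @param repeats resolved repeat data.frame restricted to the same
#'   chromosome.
#' @param te_classes classes to count (default the four TE classes plus
#'   "Other"; "Simple" is refused).
#' @return list with `noncoding_len`, `te_covered_len`, `density`.
#' @export
compute_te_density <- function(flanks, repeats,
                               te_classes = c(TE_CLASSES, "Other")) {
  if ("Simple" %in% te_classes)
    stop("simple repeats are excluded from TE density")
  stop_if_unresolved(repeats)
  noncoding_len <- sum(flanks$end - flanks$start)
  r <- repeats[repeats$te_class %in% te_classes, , drop = FALSE]
  covered <- 0L
  if (nrow(r) > 0 && nrow(flanks) > 0) {
    inter <- IRanges::intersect(ir(flanks$start, flanks$end), ir(r$start, r$end))
    covered <- sum(IRanges::width(inter))
  }
  list(noncoding_len = noncoding_len, te_covered_len = covered,
       density = if (noncoding_len > 0) covered / noncoding_len else NA_real_)
}

#' Per-gene flank TE density profiles
#'
#' Computes, for every gene, the noncoding flank intervals and the TE
#' coverage and density per TE class (LINE, SINE, LTR, DNA, Other) plus
#' their union ("ALL"). Genes whose flanks are entirely coding (noncoding
#' length 0) are flagged ineligible.
#'
#' @param ann a [genome_annotation()].
#' @param repeats resolved repeat data.frame.
#' @param flank_len flank window size in bp (default 50 kb).
#' @return data.frame with one row per gene: gene_id, chrom,
#'   noncoding_len, eligible, and cov_/density_ columns per class.
#' @export
flank_profiles <- function(ann, repeats, flank_len = 50000L) {
  stop_if_unresolved(repeats)
  classes <- c(TE_CLASSES, "Other")
  genes <- ann$genes
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    noncoding_len = 0L, stringsAsFactors = FALSE)
  cov <- matrix(0L, nrow(genes), length(classes) + 1L,
                dimnames = list(NULL, c(classes, "ALL")))
  for (chr in unique(genes$chrom)) {
    gi <- which(genes$chrom == chr)
    chrom_len <- ann$chroms$length[match(chr, ann$chroms$name)]
    cds_chr <- ann$cds[ann$cds$chrom == chr, , drop = FALSE]
    cds_union <- IRanges::reduce(ir(cds_chr$start, cds_chr$end))
    # flank windows for all genes on the chromosome, tagged by gene index
    g <- genes[gi, ]
    w_start <- c(pmax(0L, g$start - flank_len), g$end)
    w_end <- c(g$start, pmin(chrom_len, g$end + flank_len))
    tag <- c(gi, gi)
    ok <- w_start < w_end
    w_start <- w_start[ok]; w_end <- w_end[ok]; tag <- tag[ok]
    if (!length(tag)) next
    wins <- ir(w_start, w_end)
    # subtract the genome-wide CDS union by intersecting with its gaps
    gaps <- IRanges::gaps(cds_union, start = 1L, end = chrom_len)
    hits <- IRanges::findOverlaps(wins, gaps)
    qh <- S4Vectors::queryHits(hits)
    pieces <- IRanges::pintersect(wins[qh], gaps[S4Vectors::subjectHits(hits)])
    ptag <- tag[qh]
    nc <- tapply(IRanges::width(pieces), ptag, sum)
    out$noncoding_len[as.integer(names(nc))] <- as.integer(nc)
    # coverage per class over the flank pieces
    r_chr <- repeats[repeats$chrom == chr, , drop = FALSE]
    for (cl in classes) {
      r <- r_chr[r_chr$te_class == cl, , drop = FALSE]
      if (nrow(r) == 0 || length(pieces) == 0) next
      rh <- IRanges::findOverlaps(pieces, ir(r$start, r$end))
      if (length(rh) == 0) next
      wdt <- IRanges::width(IRanges::pintersect(
        pieces[S4Vectors::queryHits(rh)],
        ir(r$start, r$end)[S4Vectors::subjectHits(rh)]))
      cc <- tapply(wdt, ptag[S4Vectors::queryHits(rh)], sum)
      cov[as.integer(names(cc)), cl] <- cov[as.integer(names(cc)), cl] + as.integer(cc)
    }
  }
  # resolved repeats are pairwise disjoint, so the class covers partition
  # the total TE cover
  cov[, "ALL"] <- rowSums(cov[, classes, drop = FALSE])
  out$eligible <- out$noncoding_len > 0
  for (cl in c(classes, "ALL")) {
    out[[paste0("cov_", cl)]] <- cov[, cl]
    out[[paste0("density_", cl)]] <- ifelse(out$eligible,
                                            cov[, cl] / out$noncoding_len, NA_real_)
  }
  out
}

#' Call TE-compartmentalized genes at a density percentile
#'
#' The cutoff is the linear-interpolation percentile (type 7) of the
#' density distribution over eligible genes, computed independently per
#' species and per TE class; every gene at or above the cutoff is called.
#' Ties at the cutoff are all called, so a degenerate (constant) density
#' distribution calls every gene (a warning is emitted).
#'
#' @param profiles data.frame from [flank_profiles()].
#' @param te_class one of "ALL", "LINE", "SINE", "LTR", "DNA".
#' @param percentile percentile threshold, typically 90 or 95.
#' @param species_id optional species label carried through.
#' @return object of class `compartment_calls`: list with species_id,
#'   te_class, percentile, cutoff_value, called_gene_ids,
#'   background_gene_ids, densities (named, eligible genes only).
#' @export
call_compartmentalized <- function(profiles, te_class = "ALL",
                                   percentile = 90, species_id = NA_character_) {
  col <- paste0("density_", te_class)
  if (!col %in% names(profiles)) stop("unknown TE class: ", te_class)
  elig <- profiles[profiles$eligible, , drop = FALSE]
  if (nrow(elig) < 10)
    stop("fewer than 10 density-eligible genes; species unusable")
  d <- setNames(elig[[col]], elig$gene_id)
  cutoff <- quantile(d, percentile / 100, type = 7, names = FALSE)
  if (max(d) == min(d))
    warning("degenerate density distribution: all eligible genes called")
  called <- names(d)[d >= cutoff]
  structure(list(species_id = species_id, te_class = te_class,
                 percentile = percentile, cutoff_value = cutoff,
                 called_gene_ids = called,
                 background_gene_ids = setdiff(names(d), called),
                 densities = d),
            class = "compartment_calls")
}

#' @export
print.compartment_calls <- function(x, ...) {
  cat(sprintf("compartment_calls [%s, class %s, tau=%d]: %d called / %d eligible (cutoff %.4g)\n",
              x$species_id, x$te_class, as.integer(x$percentile),
              length(x$called_gene_ids),
              length(x$called_gene_ids) + length(x$background_gene_ids),
              x$cutoff_value))
  invisible(x)
}

#' Long table of noncoding flank intervals for every gene
#'
#' Convenience view used by the population-genetic stage (variant-to-gene
#' assignment) and the simulator.
#'
#' @param ann a [genome_annotation()].
#' @param flank_len flank window size in bp.
#' @return data.frame with columns gene_id, chrom, start, end.
#' @export
noncoding_flank_table <- function(ann, flank_len = 50000L) {
  genes <- ann$genes
  res <- vector("list", nrow(genes))
  for (chr in unique(genes$chrom)) {
    gi <- which(genes$chrom == chr)
    chrom_len <- ann$chroms$length[match(chr, ann$chroms$name)]
    cds_chr <- ann$cds[ann$cds$chrom == chr, , drop = FALSE]
    for (i in gi) {
      fl <- extract_noncoding_flanks(genes[i, ], cds_chr, chrom_len, flank_len)
      if (nrow(fl))
        res[[i]] <- data.frame(gene_id = genes$gene_id[i], chrom = chr,
                               start = fl$start, end = fl$end,
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(gene_id = character(), chrom = character(),
                                      start = integer(), end = integer())
  rownames(out) <- NULL
  out
}
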