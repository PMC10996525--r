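# TE-associated structural-variant filtering and merging, assignment of
# population variants to gene compartments, and the folded
# allele-frequency spectrum comparison between TE-compartmentalized and
# other genes.

#' Merge redundant per-sample SV calls by breakpoint vicinity
#'
#' Single-linkage clustering of same-chromosome, same-type SV calls whose
#' start and end breakpoints are each within `max_dist` bp. One
#' representative per cluster survives (leftmost start, ties broken by
#' the longer call); its `alt_count` is the number of distinct samples
#' contributing a member.
#'
#' @param svs data.frame of per-sample calls with columns chrom, start,
#'   end, vtype, sample and optionally length, te_coverage.
#' @param max_dist breakpoint vicinity in bp (default 500).
#' @param n_samples total haploid genomes in the population (for the
#'   merged records' `n_samples` field).
#' @return data.frame of merged variant records (variant_id, chrom, pos,
#'   vtype, length, te_coverage, alt_count, n_samples).
#' @export
merge_sv_calls <- function(svs, max_dist = 500, n_samples = NULL) {
  if (nrow(svs) == 0) return(empty_variant_table())
  if (is.null(n_samples)) n_samples <- length(unique(svs$sample))
  if (is.null(svs$length)) svs$length <- svs$end - svs$start
  groups <- split(seq_len(nrow(svs)), list(svs$chrom, svs$vtype), drop = TRUE)
  reps <- list()
  for (idx in groups) {
    r <- svs[idx, , drop = FALSE]
    n <- nrow(r)
    # union-find over pairs with both breakpoints within max_dist
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    if (n > 1) {
      ord <- order(r$start)
      for (a in seq_len(n - 1)) {
        for (b in (a + 1):n) {
          i <- ord[a]; j <- ord[b]
          if (r$start[j] - r$start[i] > max_dist) break
          if (abs(r$end[i] - r$end[j]) <= max_dist) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
          }
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (cl in split(seq_len(n), comp)) {
      m <- r[cl, , drop = FALSE]
      best <- order(m$start, -(m$length))[1]
      reps[[length(reps) + 1L]] <- data.frame(
        chrom = m$chrom[best], pos = m$start[best], vtype = m$vtype[best],
        length = m$length[best],
        te_coverage = if (is.null(m$te_coverage)) NA_real_ else m$te_coverage[best],
        alt_count = length(unique(m$sample)),
        n_samples = n_samples, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, reps)
  out <- out[order(out$chrom, out$pos, out$vtype), , drop = FALSE]
  out <- cbind(variant_id = sprintf("msv%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter structural variants for TE association
#'
#' Keeps SVs strictly longer than `min_len` bp whose sequence is covered
#' by a TE for at least `min_te_cov` of its length. Records flagged
#' ambiguous (logical column `ambiguous`) are dropped first.
#'
#' @param svs variant data.frame (TE_SV_* records; `length` and
#'   `te_coverage` populated).
#' @param min_len strict minimum length (default 50: "> 50 bp").
#' @param min_te_cov inclusive minimum TE coverage (default 0.5).
#' @return the surviving subset.
#' @export
filter_te_svs <- function(svs, min_len = 50, min_te_cov = 0.5) {
  if (!is.null(svs$ambiguous)) svs <- svs[!svs$ambiguous, , drop = FALSE]
  if (nrow(svs) == 0) return(svs)
  if (any(is.na(svs$te_coverage)))
    stop("te_coverage missing for ", sum(is.na(svs$te_coverage)), " SV(s)")
  out <- svs[svs$length > min_len & svs$te_coverage >= min_te_cov, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign variants to compartment groups and genomic contexts
#'
#' TE structural variants are assigned to a gene iff their position falls
#' in its noncoding flank; SNVs iff their position falls in a CDS. A
#' variant hitting genes of both groups is assigned to the called group
#' (stated priority). Variants hitting no gene are dropped.
#'
#' @param variants variant data.frame (see [read_variants()]).
#' @param flanks long flank table from [noncoding_flank_table()].
#' @param cds CDS table (gene_id, chrom, start, end).
#' @param calls a [call_compartmentalized()] result.
#' @return data.frame with variant_id, vtype, alt_count, n_samples,
#'   group ("called"/"other"), context ("flank"/"cds").
#' @export
assign_variants <- function(variants, flanks, cds, calls) {
  called_set <- calls$called_gene_ids
  assign_one <- function(v, tab, context) {
    hits <- tab$gene_id[tab$chrom == v$chrom & tab$start <= v$pos & v$pos < tab$end]
    if (!length(hits)) return(NULL)
    grp <- if (any(hits %in% called_set)) "called" else "other"
    data.frame(variant_id = v$variant_id, vtype = v$vtype,
               alt_count = v$alt_count, n_samples = v$n_samples,
               group = grp, context = context, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (v$vtype %in% c("TE_SV_INS", "TE_SV_DEL"))
      assign_one(v, flanks, "flank")
    else if (v$vtype %in% c("SNV_SYN", "SNV_NONSYN"))
      assign_one(v, cds, "cds")
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variant_id = character(), vtype = character(),
                      alt_count = integer(), n_samples = integer(),
                      group = character(), context = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Folded allele-frequency spectrum
#'
#' Bins biallelic variants by minor-allele count `min(alt, n - alt)` into
#' bins 1..floor(n/2). Monomorphic records (alt_count 0 or n) are
#' excluded (a message reports how many).
#'
#' @param variants data.frame with `alt_count` (and `n_samples`), or an
#'   integer vector of alt counts.
#' @param n_samples haploid sample count.
#' @return object of class `folded_afs`: list with n_samples, bins
#'   (named integer vector 1..floor(n/2)), n_variants.
#' @export
folded_afs <- function(variants, n_samples) {
  ac <- if (is.data.frame(variants)) variants$alt_count else as.integer(variants)
  if (any(ac < 0 | ac > n_samples)) stop("alt_count outside 0..n_samples")
  mono <- ac == 0 | ac == n_samples
  if (any(mono)) message(sum(mono), " monomorphic record(s) excluded")
  ac <- ac[!mono]
  k <- floor(n_samples / 2)
  minor <- pmin(ac, n_samples - ac)
  bins <- as.integer(table(factor(minor, levels = seq_len(k))))
  structure(list(n_samples = as.integer(n_samples),
                 bins = setNames(bins, seq_len(k)),
                 n_variants = length(ac)),
            class = "folded_afs")
}

#' @export
print.folded_afs <- function(x, ...) {
  cat(sprintf("folded_afs: n=%d haploid samples, %d variants, %d bins\n",
              x$n_samples, x$n_variants, length(x$bins)))
  invisible(x)
}

#' Chi-square comparison of two folded spectra
#'
#' 2xK contingency test on the binned counts. Adjacent high-frequency
#' bins are pooled from the top of the spectrum until every expected
#' cell is at least 5 (or only two bins remain); all-zero columns
#' contribute nothing. The statistic is the usual sum of
#' (observed - expected)^2 / expected with df = K_pooled - 1 (columns
#' with a positive total).
#'
#' @param afs_a,afs_b [folded_afs()] objects with equal `n_samples`.
#' @return list with chi2, df, p, k_pooled.
#' @export
compare_afs_chi2 <- function(afs_a, afs_b) {
  stopifnot(inherits(afs_a, "folded_afs"), inherits(afs_b, "folded_afs"))
  if (afs_a$n_samples != afs_b$n_samples)
    stop("spectra have different sample counts")
  if (afs_a$n_variants < 1 || afs_b$n_variants < 1)
    stop("both spectra must contain at least one variant")
  m <- rbind(a = afs_a$bins, b = afs_b$bins)
  expected <- function(m) outer(rowSums(m), colSums(m)) / sum(m)
  while (ncol(m) > 2 && any(expected(m) < 5)) {
    k <- ncol(m)
    m[, k - 1] <- m[, k - 1] + m[, k]
    m <- m[, -k, drop = FALSE]
  }
  if (ncol(m) < 2) stop("fewer than 2 bins after pooling; test undefined")
  pos <- colSums(m) > 0
  if (sum(pos) < 2) stop("fewer than 2 populated bins; test undefined")
  mm <- m[, pos, drop = FALSE]
  E <- expected(mm)
  chi2 <- sum((mm - E)^2 / E)
  df <- ncol(mm) - 1
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       k_pooled = ncol(mm))
}

#' Folded spectra and tests per compartment group
#'
#' Builds the folded AFS for TE variants in flanks and for synonymous and
#' nonsynonymous SNVs in CDS, separately for called and other genes, and
#' compares called vs other within each variant category.
#'
#' @param assigned output of [assign_variants()].
#' @param n_samples haploid sample count.
#' @return list with `spectra` (nested: category -> group -> folded_afs)
#'   and `tests` (data.frame: category, chi2, df, p).
#' @export
afs_by_group <- function(assigned, n_samples) {
  cats <- list(te_flank = assigned$vtype %in% c("TE_SV_INS", "TE_SV_DEL") &
                            assigned$context == "flank",
               snv_syn = assigned$vtype == "SNV_SYN",
               snv_nonsyn = assigned$vtype == "SNV_NONSYN")
  spectra <- list()
  tests <- list()
  for (cat in names(cats)) {
    sub <- assigned[cats[[cat]], , drop = FALSE]
    spectra[[cat]] <- list(
      called = folded_afs(sub[sub$group == "called", ], n_samples),
      other = folded_afs(sub[sub$group == "other", ], n_samples))
    tst <- tryCatch(
      compare_afs_chi2(spectra[[cat]]$called, spectra[[cat]]$other),
      error = function(e) NULL)
    if (!is.null(tst))
      tests[[cat]] <- data.frame(category = cat, chi2 = tst$chi2,
                                 df = tst$df, p = tst$p,
                                 stringsAsFactors = FALSE)
  }
  out_tests <- do.call(rbind, tests)
  if (is.null(out_tests))
    out_tests <- data.frame(category = character(), chi2 = numeric(),
                            df = integer(), p = numeric(),
                            stringsAsFactors = FALSE)
  rownames(out_tests) <- NULL
  list(spectra = spectra, tests = out_tests)
}
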