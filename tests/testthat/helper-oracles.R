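# Independent brute-force oracles. All interval oracles work on per-base
# boolean arrays over a small chromosome; statistical oracles enumerate
# directly. None of them share code with the implementation.

# positions (0-based) covered by a set of intervals
bf_positions <- function(start, end, L) {
  v <- logical(L)
  for (i in seq_along(start)) {
    if (start[i] < end[i]) {
      a <- max(0L, start[i]); b <- min(L, end[i])
      if (a < b) v[(a + 1):b] <- TRUE
    }
  }
  v
}

# noncoding flank positions of a gene: flank windows minus all CDS
bf_flank_positions <- function(gene_start, gene_end, cds, L, flank_len) {
  fl <- logical(L)
  a <- max(0L, gene_start - flank_len)
  if (a < gene_start) fl[(a + 1):gene_start] <- TRUE
  b <- min(L, gene_end + flank_len)
  if (gene_end < b) fl[(gene_end + 1):b] <- TRUE
  if (!is.null(cds) && nrow(cds) > 0)
    fl <- fl & !bf_positions(cds$start, cds$end, L)
  fl
}

# greedy score resolution, written independently (O(n^2) scan)
bf_resolve <- function(rep) {
  ord <- order(-rep$score, rep$start, -(rep$end - rep$start))
  kept <- integer(0)
  for (i in ord) {
    ov <- any(rep$chrom[kept] == rep$chrom[i] &
                rep$start[kept] < rep$end[i] & rep$start[i] < rep$end[kept])
    if (!ov) kept <- c(kept, i)
  }
  out <- rep[sort(kept), , drop = FALSE]
  out[order(out$chrom, out$start), , drop = FALSE]
}

# intervals -> per-base cover on one chromosome, restricted to a class set
bf_class_cover <- function(rep, classes, L) {
  r <- rep[rep$te_class %in% classes, , drop = FALSE]
  bf_positions(r$start, r$end, L)
}

# two-sided Fisher p by exhaustive hypergeometric enumeration
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  xs <- max(0, k - n_):min(k, m)
  probs <- dhyper(xs, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# BH by direct evaluation of q_(j) = min_{l >= j} p_(l) * m / l
bh_direct <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (j in seq_len(m))
    q_sorted[j] <- min(1, min(p[o][j:m] * m / (j:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# exact two-sided binomial p by direct summation
binom_enum <- function(k, n, pr = 0.5) {
  probs <- dbinom(0:n, n, pr)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# exhaustive single-linkage clustering of SV calls: grow components by
# repeated pairwise expansion until fixed point
cluster_oracle <- function(start, end, max_dist) {
  n <- length(start)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          abs(start[i] - start[j]) <= max_dist &&
          abs(end[i] - end[j]) <= max_dist) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# random small instance for the interval/density oracle sweep
random_instance <- function() {
  L <- sample(2000:10000, 1)
  n_g <- sample(1:5, 1)
  g_start <- sort(sample(0:(L - 60), n_g))
  g_end <- pmin(L, g_start + sample(30:500, n_g, replace = TRUE))
  cds <- do.call(rbind, lapply(seq_len(n_g), function(i) {
    k <- sample(0:2, 1)
    if (k == 0) return(NULL)
    w <- g_end[i] - g_start[i]
    s <- sort(sample(0:(w - 1), k))
    e <- pmin(w, s + sample(5:60, k, replace = TRUE))
    keep <- c(TRUE, if (k > 1) s[-1] >= e[-k] else NULL)   # non-overlapping
    data.frame(gene_id = paste0("g", i), chrom = "c1",
               start = g_start[i] + s[keep], end = g_start[i] + e[keep])
  }))
  n_r <- sample(0:25, 1)
  rep <- if (n_r == 0)
    data.frame(chrom = character(), start = integer(), end = integer(),
               family_name = character(), score = numeric(),
               strand = character(), te_class = character())
  else {
    rs <- sample(0:(L - 20), n_r, replace = TRUE)
    data.frame(chrom = "c1", start = rs,
               end = pmin(L, rs + sample(10:400, n_r, replace = TRUE)),
               family_name = "f", score = sample(1:500, n_r, replace = TRUE),
               strand = "+",
               te_class = sample(c("LINE", "SINE", "LTR", "DNA", "Other", "Simple"),
                                 n_r, replace = TRUE))
  }
  list(L = L, genes = data.frame(start = g_start, end = g_end),
       cds = cds, rep = rep[order(rep$chrom, rep$start), , drop = FALSE],
       flank_len = sample(c(200L, 1000L, 5000L, 50000L), 1))
}

# build a compartment-calls-shaped object directly (for stages that only
# need the called/background partition)
make_calls <- function(called, background, te_class = "ALL", percentile = 90) {
  structure(list(species_id = "toy", te_class = te_class,
                 percentile = percentile, cutoff_value = NA_real_,
                 called_gene_ids = called, background_gene_ids = background,
                 densities = NULL),
            class = "compartment_calls")
}
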