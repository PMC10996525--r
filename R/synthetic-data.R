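# Synthetic species generator. No nucleotide sequence is simulated —
# only annotation geometry: chromosomes, genes with CDS structure,
# classed TE intervals with controllable flank coverage, GO and family
# tables, polymorphic variants and per-site selection posteriors, each
# with a plantable signal and recorded ground truth.

#' Simulation configuration
#'
#' Defaults describe one synthetic species at a scale where every
#' downstream statistic is well populated: 1,000 genes on 5 chromosomes of
#' 40 Mb (mean gene spacing 200 kb, so 50 kb flanks of neighbouring genes
#' rarely overlap), ~5% of genes in "labile" families whose flanks carry
#' 10x the background TE coverage, a GO term planted on labile families,
#' and a 50-genome haploid population.
#'
#' `frac_labile` is the target fraction of *genes* that belong to labile
#' families; labile families are drawn size-weighted until that quota is
#' met, which simultaneously plants the multigene-family enrichment of
#' the called set.
#'
#' @param seed integer seed; all generator functions derive their streams
#'   from it (see Details in the package vignette).
#' @param n_chroms,chrom_length,n_genes,gene_length genome geometry (bp).
#' @param n_families number of gene families; `family_exponent` is the
#'   truncated power-law exponent for family sizes.
#' @param frac_labile target fraction of genes in labile families.
#' @param te_rate_background,te_rate_labile expected TE bp per flank bp.
#' @param te_class_mix named probabilities over LINE, SINE, LTR, DNA.
#' @param te_mean_len named mean TE insert lengths (bp) per class.
#' @param flank_len flank window the generator plants into (bp).
#' @param n_go_terms,go_annotation_fraction,planted_term_specificity,planted_term_background
#'   GO layer: number of terms, fraction of genes annotated, probability
#'   an annotated labile-family gene carries the planted term, same for
#'   other genes.
#' @param subtelomere_bias "none", "enriched" or "depleted" placement of
#'   labile genes relative to the terminal 10% of each chromosome.
#' @param n_samples haploid genomes in the simulated population.
#' @param n_te_variants,n_snvs variant counts.
#' @param afs_skew mixture weight of the high-frequency allele component
#'   for TE variants in labile-gene flanks (0 = neutral).
#' @param selection_base_pos,selection_effect,selection_base_con,constraint_effect
#'   expected per-site rates of P(positive) > 0.95 (base and labile
#'   excess) and of P(constraint) > 0.95.
#' @param sites_per_family codon sites simulated per family.
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 5L, chrom_length = 4e7, n_genes = 1000L,
                              gene_length = 2000L,
                              n_families = 400L, family_exponent = 2,
                              frac_labile = 0.05,
                              te_rate_background = 0.05, te_rate_labile = 0.5,
                              te_class_mix = c(LINE = 0.4, SINE = 0.2,
                                               LTR = 0.25, DNA = 0.15),
                              te_mean_len = c(LINE = 800, SINE = 300,
                                              LTR = 600, DNA = 400),
                              flank_len = 50000L,
                              n_go_terms = 50L, go_annotation_fraction = 0.6,
                              planted_term_specificity = 0.9,
                              planted_term_background = 0.02,
                              subtelomere_bias = c("none", "enriched", "depleted"),
                              n_samples = 50L,
                              n_te_variants = 1000L, n_snvs = 1000L,
                              afs_skew = 0.3,
                              selection_base_pos = 0.01, selection_effect = 0.04,
                              selection_base_con = 0.2, constraint_effect = 0.01,
                              sites_per_family = 200L) {
  subtelomere_bias <- match.arg(subtelomere_bias)
  cfg <- as.list(environment())
  fracs <- c(frac_labile, go_annotation_fraction, planted_term_specificity,
             planted_term_background, afs_skew, selection_base_pos,
             selection_effect, selection_base_con, constraint_effect)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (te_rate_labile < te_rate_background)
    stop("te_rate_labile must be >= te_rate_background")
  if (abs(sum(te_class_mix) - 1) > 1e-8) stop("te_class_mix must sum to 1")
  if (!setequal(names(te_class_mix), TE_CLASSES) ||
      !setequal(names(te_mean_len), TE_CLASSES))
    stop("te_class_mix / te_mean_len must be named over ", paste(TE_CLASSES, collapse = ", "))
  if (n_samples < 4) stop("n_samples must be >= 4")
  structure(cfg, class = "sim_config")
}

# Stage-specific child seeds so each generator is independently
# reproducible from one top-level seed.
child_seed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

# Non-overlapping uniform starts for n spans of width w in [0, L):
# draw order statistics on the shrunk line then re-inflate.
place_nonoverlapping <- function(n, w, L) {
  if (n * w > L) stop("infeasible packing: ", n, " genes of ", w, " bp exceed ", L, " bp")
  if (n == 0) return(integer(0))
  starts <- sort(sample.int(L - n * w + 1L, n, replace = TRUE) - 1L)
  starts + (seq_len(n) - 1L) * w
}

draw_family_sizes <- function(n_families, exponent, n_genes, max_size = 30L) {
  sizes <- sample(max_size, n_families, replace = TRUE,
                  prob = (1:max_size)^(-exponent))
  # scale the family count so total membership covers the gene set
  while (sum(sizes) < n_genes)
    sizes <- c(sizes, sample(max_size, 50, replace = TRUE,
                             prob = (1:max_size)^(-exponent)))
  cum <- cumsum(sizes)
  k <- which(cum >= n_genes)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (cum[k] - n_genes)
  sizes[sizes > 0]
}

#' Simulate one annotated species
#'
#' Places non-overlapping genes uniformly (optionally biasing labile
#' genes toward or away from the terminal 10% of each chromosome), builds
#' a three-exon CDS structure per gene, assigns genes to power-law-sized
#' families, marks labile families (size-weighted) until `frac_labile` of
#' genes are labile, plants TE insertions in every gene's flanks as a
#' Poisson number of exponential-length intervals with expected coverage
#' `te_rate_background` (or `te_rate_labile`), and attaches GO terms with
#' the planted term concentrated on labile families.
#'
#' @param config a [simulation_config()].
#' @return list with `ann` ([genome_annotation()]), `repeats`, `go_map`,
#'   `family_map`, and `truth` (labile_gene_ids, labile_family_ids,
#'   planted_go_term).
#' @export
simulate_species <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 0L))
  n_chroms <- config$n_chroms
  L <- as.integer(config$chrom_length)
  chroms <- chromosome_spec(paste0("chr", seq_len(n_chroms)), rep(L, n_chroms))

  # genes per chromosome (as even as possible), placed uniformly with a
  # guard band of one flank length on each side so one gene's planted
  # flank never reaches into a neighbour's flank
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = n_chroms + 1)))
  w_eff <- as.integer(config$gene_length + 2L * config$flank_len)
  gene_rows <- list()
  for (ci in seq_len(n_chroms)) {
    st <- place_nonoverlapping(per_chrom[ci], w_eff, L) + as.integer(config$flank_len)
    gene_rows[[ci]] <- data.frame(chrom = chroms$name[ci], start = st,
                                  end = st + as.integer(config$gene_length),
                                  stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)

  # families and labile labels
  sizes <- draw_family_sizes(config$n_families, config$family_exponent,
                             nrow(genes))
  family_ids <- sprintf("FAM%04d", seq_along(sizes))
  membership <- sample(rep(family_ids, sizes))   # scatter members genome-wide
  # fill the labile gene quota from a size-weighted family order: take
  # families that fit, then close the gap with the best-fitting leftover
  # so the realized labile gene count stays within ~1 of the target
  target_labile <- round(config$frac_labile * nrow(genes))
  labile_families <- character(0)
  if (target_labile > 0) {
    ord <- sample(seq_along(sizes), prob = sizes)   # size-weighted order
    sel <- logical(length(sizes))
    cum <- 0L
    for (i in ord) {
      if (cum + sizes[i] <= target_labile) {
        sel[i] <- TRUE
        cum <- cum + sizes[i]
      }
      if (cum >= target_labile) break
    }
    if (cum < target_labile) {
      rem <- ord[!sel[ord]]
      best <- rem[which.min(abs(cum + sizes[rem] - target_labile))]
      sel[best] <- TRUE
    }
    labile_families <- family_ids[sel]
  }
  is_labile_gene <- membership %in% labile_families

  # subtelomere bias: permute the family labels over the fixed gene
  # positions so labile genes land in (or avoid) terminal regions
  mid <- (genes$start + genes$end) / 2
  terminal <- mid < 0.1 * L | mid >= 0.9 * L
  if (config$subtelomere_bias != "none" && any(is_labile_gene)) {
    pref <- if (config$subtelomere_bias == "enriched") terminal else !terminal
    ord_pos <- order(!pref, sample.int(nrow(genes)))   # preferred slots first
    perm <- integer(nrow(genes))
    perm[ord_pos] <- order(!is_labile_gene, sample.int(nrow(genes)))
    membership <- membership[perm]
    is_labile_gene <- is_labile_gene[perm]
  }

  genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes$family_id <- membership
  genes <- genes[, c("gene_id", "chrom", "start", "end", "strand", "family_id")]

  # three-exon CDS: fixed fractions of the gene span
  gl <- config$gene_length
  rel <- rbind(c(0, 0.2), c(0.4, 0.6), c(0.8, 1.0))
  cds <- do.call(rbind, lapply(seq_len(3), function(k)
    data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
               start = genes$start + as.integer(rel[k, 1] * gl),
               end = genes$start + as.integer(rel[k, 2] * gl),
               stringsAsFactors = FALSE)))
  ann <- genome_annotation(chroms, genes, cds)

  repeats <- simulate_repeats(ann, is_labile_gene, config)

  # GO layer
  terms <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  planted <- terms[1]
  annotated <- runif(nrow(genes)) < config$go_annotation_fraction
  go_rows <- list()
  for (i in which(annotated)) {
    k <- 1L + rpois(1, 1)
    tm <- sample(terms[-1], min(k, length(terms) - 1L))
    p_plant <- if (is_labile_gene[i]) config$planted_term_specificity
               else config$planted_term_background
    if (runif(1) < p_plant) tm <- c(planted, tm)
    go_rows[[length(go_rows) + 1L]] <-
      data.frame(gene_id = genes$gene_id[i], term = tm, stringsAsFactors = FALSE)
  }
  go_map <- if (length(go_rows)) do.call(rbind, go_rows) else
    data.frame(gene_id = character(), term = character(), stringsAsFactors = FALSE)

  list(ann = ann,
       repeats = repeats,
       go_map = go_map,
       family_map = data.frame(gene_id = genes$gene_id,
                               family_id = genes$family_id,
                               stringsAsFactors = FALSE),
       truth = list(labile_gene_ids = genes$gene_id[is_labile_gene],
                    labile_family_ids = sort(unique(labile_families)),
                    planted_go_term = planted))
}

simulate_repeats <- function(ann, is_labile_gene, config) {
  genes <- ann$genes
  L <- config$chrom_length
  mix <- config$te_class_mix[TE_CLASSES]
  mlen <- config$te_mean_len[TE_CLASSES]
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    rate <- if (is_labile_gene[i]) config$te_rate_labile else config$te_rate_background
    if (rate == 0) next
    wins <- rbind(c(max(0, genes$start[i] - config$flank_len), genes$start[i]),
                  c(genes$end[i], min(L, genes$end[i] + config$flank_len)))
    for (w in seq_len(2)) {
      width <- wins[w, 2] - wins[w, 1]
      if (width <= 0) next
      # Poisson number of inserts per class, exponential fragment
      # lengths, placed without overlap (order-statistics on the line
      # shrunk by the total insert length) so realized flank coverage
      # has expectation rate * width
      cls <- character(0); len <- integer(0)
      for (cl in TE_CLASSES) {
        n_ins <- rpois(1, rate * mix[[cl]] * width / mlen[[cl]])
        if (n_ins == 0) next
        cls <- c(cls, rep(cl, n_ins))
        len <- c(len, pmax(50L, as.integer(round(rexp(n_ins, 1 / mlen[[cl]])))))
      }
      if (!length(cls)) next
      ord <- sample(length(cls))
      cls <- cls[ord]; len <- len[ord]
      drop <- cumsum(as.numeric(len)) > 0.9 * width   # overfull flank guard
      cls <- cls[!drop]; len <- len[!drop]
      n <- length(cls)
      if (!n) next
      slack <- as.integer(width - sum(len))
      u <- sort(sample.int(slack + 1L, n, replace = TRUE) - 1L)
      st <- as.integer(wins[w, 1]) + u + c(0L, cumsum(len)[-n])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = genes$chrom[i], start = st, end = st + len,
        family_name = paste0(cls, "-fam", sample(20, n, replace = TRUE)),
        score = sample(100:5000, n, replace = TRUE),
        strand = sample(c("+", "-"), n, replace = TRUE),
        te_class = cls, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               family_name = character(), score = numeric(),
               strand = character(), te_class = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Draw biallelic alt-allele counts with an optional high-frequency skew
#'
#' Neutral-like counts follow P(i) proportional to 1/i over 1..n-1 (the
#' standard neutral SFS shape); with probability `skew` a count is drawn
#' uniformly from the high-frequency range (counts above n/2) instead.
#' This is the allele-count engine behind [simulate_population()],
#' exposed for calibration and power studies of the spectrum comparison.
#'
#' @param n_var number of variants.
#' @param n_samples haploid sample count.
#' @param skew high-frequency mixture weight in `[0, 1]`.
#' @return integer vector of alt counts in 1..(n_samples - 1).
#' @export
simulate_alt_counts <- function(n_var, n_samples, skew = 0) {
  i <- seq_len(n_samples - 1L)
  neutral <- sample(i, n_var, replace = TRUE, prob = 1 / i)
  if (skew <= 0) return(neutral)
  # counts just above n/2: high minor-allele frequency after folding
  hi_range <- seq.int(floor(n_samples / 2) + 1L,
                      min(n_samples - 1L, ceiling(3 * n_samples / 4)))
  hi <- sample(hi_range, n_var, replace = TRUE)
  ifelse(runif(n_var) < skew, hi, neutral)
}

#' Simulate a polymorphic population over a synthetic species
#'
#' TE structural variants are dropped uniformly into noncoding gene
#' flanks with neutral-like allele counts; flanks of labile genes receive
#' an `afs_skew`-weighted admixture of high-frequency alleles.
#' Synonymous and nonsynonymous SNVs are placed in CDS with neutral-like
#' counts in both groups.
#'
#' @param sim output of [simulate_species()].
#' @param config the same [simulation_config()].
#' @return data.frame of variant records (see [read_variants()]).
#' @export
simulate_population <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 1000003L))
  n <- config$n_samples
  flanks <- noncoding_flank_table(sim$ann, config$flank_len)
  labile <- flanks$gene_id %in% sim$truth$labile_gene_ids
  rows <- list()
  if (config$n_te_variants > 0 && nrow(flanks) > 0) {
    # split TE variants between labile and other flanks in proportion to
    # their counts of target genes, then sample an interval and position
    pick <- sample(nrow(flanks), config$n_te_variants, replace = TRUE)
    w <- flanks$end[pick] - flanks$start[pick]
    pos <- as.integer(flanks$start[pick] + floor(runif(length(pick)) * w))
    skew <- ifelse(labile[pick], config$afs_skew, 0)
    ac <- integer(length(pick))
    ac[skew > 0] <- simulate_alt_counts(sum(skew > 0), n, config$afs_skew)
    ac[skew == 0] <- simulate_alt_counts(sum(skew == 0), n, 0)
    rows$te <- data.frame(
      variant_id = sprintf("tesv%05d", seq_along(pick)),
      chrom = flanks$chrom[pick], pos = pos,
      vtype = sample(c("TE_SV_INS", "TE_SV_DEL"), length(pick),
                     replace = TRUE, prob = c(0.8, 0.2)),
      length = 100L + as.integer(round(rexp(length(pick), 1 / 1000))),
      te_coverage = round(runif(length(pick), 0.5, 1), 4),
      alt_count = ac, n_samples = n, stringsAsFactors = FALSE)
  }
  if (config$n_snvs > 0 && nrow(sim$ann$cds) > 0) {
    cds <- sim$ann$cds
    pick <- sample(nrow(cds), config$n_snvs, replace = TRUE)
    pos <- as.integer(cds$start[pick] +
                        floor(runif(length(pick)) * (cds$end[pick] - cds$start[pick])))
    rows$snv <- data.frame(
      variant_id = sprintf("snv%05d", seq_along(pick)),
      chrom = cds$chrom[pick], pos = pos,
      vtype = sample(c("SNV_SYN", "SNV_NONSYN"), length(pick), replace = TRUE),
      length = NA_integer_, te_coverage = NA_real_,
      alt_count = simulate_alt_counts(length(pick), n, 0),
      n_samples = n, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_variant_table()
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate per-site selection posteriors
#'
#' For every family, `sites_per_family` codon sites are drawn; each site
#' is positively selected with probability `selection_base_pos`
#' (+`selection_effect` for labile families), constrained with
#' probability `selection_base_con` (+`constraint_effect` for labile
#' families), else neutral. Posteriors are drawn above 0.95 for the
#' selected category and below 0.95 otherwise, so a site never exceeds
#' the cutoff in both columns.
#'
#' @param sim output of [simulate_species()] (uses `family_map`, `truth`).
#' @param config the same [simulation_config()].
#' @param species_id label for the output table.
#' @return data.frame with columns species_id, family_id, site, prob_pos,
#'   prob_neg.
#' @export
simulate_site_posteriors <- function(sim, config, species_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 2000003L))
  fams <- sort(unique(sim$family_map$family_id))
  if (!length(fams))
    return(data.frame(species_id = character(), family_id = character(),
                      site = integer(), prob_pos = numeric(),
                      prob_neg = numeric(), stringsAsFactors = FALSE))
  m <- config$sites_per_family
  labile <- fams %in% sim$truth$labile_family_ids
  p_pos <- config$selection_base_pos + ifelse(labile, config$selection_effect, 0)
  p_con <- config$selection_base_con + ifelse(labile, config$constraint_effect, 0)
  res <- lapply(seq_along(fams), function(k) {
    u <- runif(m)
    cat_pos <- u < p_pos[k]
    cat_con <- !cat_pos & u < p_pos[k] + p_con[k]
    prob_pos <- ifelse(cat_pos, runif(m, 0.951, 1), runif(m, 0, 0.5))
    prob_neg <- ifelse(cat_con, runif(m, 0.951, 1), runif(m, 0, 0.5))
    data.frame(species_id = species_id, family_id = fams[k], site = seq_len(m),
               prob_pos = round(prob_pos, 6), prob_neg = round(prob_neg, 6),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write a full synthetic fixture set to a directory
#'
#' Emits chromosomes.tsv, genes.gff3, repeats.bed, go_map.tsv,
#' families.tsv, variants.vcf, posteriors.tsv and ground_truth.tsv, all
#' plain text, re-readable with this package's readers.
#'
#' @param sim output of [simulate_species()].
#' @param outdir directory (created if needed).
#' @param variants optional output of [simulate_population()].
#' @param posteriors optional output of [simulate_site_posteriors()].
#' @return named vector of written paths, invisibly.
#' @export
write_species_fixtures <- function(sim, outdir, variants = NULL,
                                   posteriors = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_chromosomes(sim$ann$chroms, p("chromosomes.tsv"))
  write_genes(sim$ann, p("genes.gff3"))
  write_repeats(sim$repeats, p("repeats.bed"))
  write_go_map(sim$go_map, p("go_map.tsv"))
  write_family_map(sim$family_map, p("families.tsv"))
  truth <- data.frame(gene_id = sim$ann$genes$gene_id,
                      labile = sim$ann$genes$gene_id %in% sim$truth$labile_gene_ids,
                      planted_go_term = sim$truth$planted_go_term,
                      stringsAsFactors = FALSE)
  write.table(truth, p("ground_truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(chromosomes = p("chromosomes.tsv"), genes = p("genes.gff3"),
             repeats = p("repeats.bed"), go_map = p("go_map.tsv"),
             families = p("families.tsv"), truth = p("ground_truth.tsv"))
  if (!is.null(variants)) {
    write_variants(variants, p("variants.vcf"))
    paths["variants"] <- p("variants.vcf")
  }
  if (!is.null(posteriors)) {
    write_site_posteriors(posteriors, p("posteriors.tsv"))
    paths["posteriors"] <- p("posteriors.tsv")
  }
  invisible(paths)
}
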