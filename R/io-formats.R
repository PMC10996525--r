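# I/O for every external format the pipeline touches. One fixed internal
# convention: 0-based half-open intervals on named chromosomes. Converters
# to each standard's native convention live only in this file.

#' Chromosome table
#'
#' @param name character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bp (>= 1).
#' @return A data.frame with columns `name`, `length`.
#' @export
chromosome_spec <- function(name, length) {
  chroms <- data.frame(name = as.character(name), length = as.integer(length),
                       stringsAsFactors = FALSE)
  validate_chromosomes(chroms)
  chroms
}

validate_chromosomes <- function(chroms) {
  stopifnot(is.data.frame(chroms), all(c("name", "length") %in% names(chroms)))
  if (anyDuplicated(chroms$name))
    stop("duplicate chromosome names: ",
         paste(unique(chroms$name[duplicated(chroms$name)]), collapse = ", "))
  if (any(chroms$length < 1)) stop("chromosome lengths must be >= 1")
  invisible(chroms)
}

#' Bundle chromosomes, genes and CDS into a genome annotation
#'
#' The gene table carries one row per gene; CDS intervals live in a
#' separate table keyed by `gene_id` (relational layout, like a TxDb).
#' All coordinates are 0-based half-open.
#'
#' @param chroms data.frame from [chromosome_spec()].
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and optionally `family_id`.
#' @param cds data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(chroms, genes, cds) {
  validate_chromosomes(chroms)
  genes$family_id <- if (is.null(genes$family_id)) NA_character_ else as.character(genes$family_id)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  cds <- cds[order(cds$chrom, cds$start), , drop = FALSE]
  rownames(cds) <- NULL
  ann <- structure(list(chroms = chroms, genes = genes, cds = cds),
                   class = "genome_annotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  genes <- ann$genes
  chroms <- ann$chroms
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1])
  bad <- !genes$chrom %in% chroms$name
  if (any(bad))
    stop("gene ", genes$gene_id[bad][1], " on unknown chromosome ", genes$chrom[bad][1])
  len <- chroms$length[match(genes$chrom, chroms$name)]
  if (any(genes$start < 0) || any(genes$start >= genes$end) || any(genes$end > len))
    stop("gene coordinates out of range (0-based half-open, within chromosome)")
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  cds <- ann$cds
  if (nrow(cds)) {
    i <- match(cds$gene_id, genes$gene_id)
    if (anyNA(i)) stop("CDS for unknown gene ", cds$gene_id[which(is.na(i))[1]])
    out <- cds$start < genes$start[i] | cds$end > genes$end[i] | cds$start >= cds$end
    if (any(out))
      stop("CDS outside gene span for gene ", cds$gene_id[out][1])
    by_gene <- split(cds[, c("start", "end")], cds$gene_id)
    for (g in names(by_gene)) {
      b <- by_gene[[g]][order(by_gene[[g]]$start), ]
      if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
        stop("overlapping CDS intervals within gene ", g)
    }
  }
  invisible(ann)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$chroms), "chromosomes,",
      nrow(x$genes), "genes,", nrow(x$cds), "CDS intervals\n")
  invisible(x)
}

#' Read gene and CDS annotations from GFF3
#'
#' Accepts the usual gene/CDS dialect where CDS features point at their
#' gene via `Parent`. GFF3 1-based inclusive coordinates are converted to
#' the internal 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @param chroms data.frame from [chromosome_spec()].
#' @return A [genome_annotation()] object (genes sorted by chrom, start).
#' @export
read_genes <- function(path, chroms) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  gn <- gr[type == "gene"]
  cd <- gr[type == "CDS"]
  if (length(gn) == 0) {
    return(genome_annotation(chroms,
      data.frame(gene_id = character(), chrom = character(), start = integer(),
                 end = integer(), strand = character(), stringsAsFactors = FALSE),
      data.frame(gene_id = character(), chrom = character(), start = integer(),
                 end = integer(), stringsAsFactors = FALSE)))
  }
  genes <- data.frame(
    gene_id = as.character(gn$ID),
    chrom = as.character(GenomicRanges::seqnames(gn)),
    start = GenomicRanges::start(gn) - 1L,
    end = GenomicRanges::end(gn),
    strand = as.character(GenomicRanges::strand(gn)),
    stringsAsFactors = FALSE)
  if (!is.null(gn$family_id)) genes$family_id <- as.character(gn$family_id)
  parent <- vapply(as.list(cd$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  cds <- data.frame(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(cd)),
    start = GenomicRanges::start(cd) - 1L,
    end = GenomicRanges::end(cd),
    stringsAsFactors = FALSE)
  genome_annotation(chroms, genes, cds)
}

#' Write a genome annotation as GFF3
#'
#' @param ann a [genome_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genes <- function(ann, path) {
  genes <- ann$genes
  cds <- ann$cds
  n_g <- nrow(genes)
  n_c <- nrow(cds)
  gr <- GenomicRanges::GRanges(
    seqnames = c(genes$chrom, cds$chrom),
    ranges = IRanges::IRanges(start = c(genes$start, cds$start) + 1L,
                              end = c(genes$end, cds$end)),
    strand = c(genes$strand, genes$strand[match(cds$gene_id, genes$gene_id)]))
  gr$type <- c(rep("gene", n_g), rep("CDS", n_c))
  cds_ids <- if (n_c) paste0(cds$gene_id, ".cds", sequence(rle(cds$gene_id)$lengths)) else character(0)
  gr$ID <- c(genes$gene_id, cds_ids)
  gr$Parent <- S4Vectors::SimpleList(c(replicate(n_g, character(0), simplify = FALSE),
                                       as.list(cds$gene_id)))
  gr$phase <- c(rep(NA_integer_, n_g), rep(0L, n_c))
  if (!all(is.na(genes$family_id)))
    gr$family_id <- c(genes$family_id, rep(NA_character_, n_c))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Normalize a RepeatMasker-style class label to the closed vocabulary
#'
#' Slash-qualified labels are reduced to their prefix ("LINE/L1" ->
#' "LINE"); simple repeats and low-complexity map to "Simple"; anything
#' unrecognized maps to "Other".
#'
#' @param x character vector of raw class labels.
#' @return character vector over LINE, SINE, LTR, DNA, Simple, Other.
#' @export
normalize_te_class <- function(x) {
  pre <- sub("/.*$", "", x)
  out <- ifelse(pre %in% TE_CLASSES, pre,
         ifelse(pre %in% c("Simple_repeat", "Low_complexity", "Simple"), "Simple",
                "Other"))
  out
}

#' Read repeat annotations from a BED6+1 file
#'
#' RM2Bed-style dialect: tab-separated chrom, start, end, family_name,
#' score, strand, te_class; no header. Class labels are normalized with
#' [normalize_te_class()].
#'
#' @param path BED6+1 file.
#' @return data.frame with columns chrom, start, end, family_name, score,
#'   strand, te_class (sorted by chrom, start).
#' @export
read_repeats <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      family_name = character(), score = numeric(),
                      strand = character(), te_class = character(),
                      stringsAsFactors = FALSE))
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 7) stop("expected 7 columns (BED6 + te_class), got ", ncol(x))
  rep <- data.frame(chrom = as.character(x[[1]]), start = as.integer(x[[2]]),
                    end = as.integer(x[[3]]), family_name = as.character(x[[4]]),
                    score = as.numeric(x[[5]]), strand = as.character(x[[6]]),
                    te_class = normalize_te_class(as.character(x[[7]])),
                    stringsAsFactors = FALSE)
  if (any(rep$start < 0) || any(rep$start >= rep$end))
    stop("invalid repeat interval (negative coordinate or start >= end)")
  rep <- rep[order(rep$chrom, rep$start), , drop = FALSE]
  rownames(rep) <- NULL
  rep
}

#' Write repeat annotations as BED6+1
#'
#' @param repeats data.frame as returned by [read_repeats()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_repeats <- function(repeats, path) {
  write.table(repeats[, c("chrom", "start", "end", "family_name", "score",
                          "strand", "te_class")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# ---- VCF ----

parse_info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  out <- rep(NA_character_, length(info))
  hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0
  out[hit] <- sub(paste0(".*", key, "="), "", m)
  out
}

#' Read population variants from a VCF
#'
#' Expects haploid GT columns. Structural variants are recognised by the
#' INFO keys SVTYPE (INS/DEL), SVLEN and TECOV (fraction of the SV
#' sequence covered by a TE); SNVs by the annotation key EFF with values
#' `synonymous` / `missense`. Multi-allelic sites are dropped; sites with
#' missing genotypes are skipped with a warning. VCF 1-based positions
#' become 0-based.
#'
#' @param path VCF file (plain text or gzipped).
#' @return data.frame with columns variant_id, chrom, pos, vtype, length,
#'   te_coverage, alt_count, n_samples.
#' @export
read_variants <- function(path) {
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) return(empty_variant_table())
  gt <- vcfR::extract.gt(v)
  keep <- !grepl(",", fix[, "ALT"])        # biallelic only
  miss <- rowSums(is.na(gt) | gt == ".") > 0
  if (any(miss & keep))
    warning(sum(miss & keep), " site(s) skipped for missing genotypes")
  keep <- keep & !miss
  if (!any(keep)) return(empty_variant_table())
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  info <- fix[, "INFO"]
  svtype <- parse_info_field(info, "SVTYPE")
  svlen <- suppressWarnings(as.integer(parse_info_field(info, "SVLEN")))
  tecov <- suppressWarnings(as.numeric(parse_info_field(info, "TECOV")))
  eff <- parse_info_field(info, "EFF")
  vtype <- rep("OTHER", nrow(fix))
  vtype[svtype %in% "INS"] <- "TE_SV_INS"
  vtype[svtype %in% "DEL"] <- "TE_SV_DEL"
  vtype[eff %in% "synonymous"] <- "SNV_SYN"
  vtype[eff %in% "missense"] <- "SNV_NONSYN"
  data.frame(
    variant_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                        paste0("var", seq_len(nrow(fix))), fix[, "ID"]),
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]) - 1L,
    vtype = vtype,
    length = abs(svlen),
    te_coverage = tecov,
    alt_count = as.integer(rowSums(gt == "1")),
    n_samples = ncol(gt),
    stringsAsFactors = FALSE, row.names = NULL)
}

empty_variant_table <- function() {
  data.frame(variant_id = character(), chrom = character(), pos = integer(),
             vtype = character(), length = integer(), te_coverage = numeric(),
             alt_count = integer(), n_samples = integer(),
             stringsAsFactors = FALSE)
}

#' Write a variant table as VCF 4.2
#'
#' Emits this package's dialect (INFO keys SVTYPE/SVLEN/TECOV for SVs and
#' EFF for SNVs) with haploid GT columns. Genotypes are reconstructed from
#' `alt_count` deterministically (the first `alt_count` samples carry the
#' alternate allele): the table does not track which genome carried which
#' allele, only the count.
#'
#' @param variants data.frame as returned by [read_variants()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  n <- if (nrow(variants)) max(variants$n_samples) else 0L
  samples <- sprintf("S%03d", seq_len(n))
  hdr <- c("##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=TECOV,Number=1,Type=Float,Description=\"Fraction of SV covered by a TE\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Coding effect\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    is_sv <- v$vtype %in% c("TE_SV_INS", "TE_SV_DEL")
    info <- if (is_sv) {
      sprintf("SVTYPE=%s;SVLEN=%d;TECOV=%s",
              if (v$vtype == "TE_SV_INS") "INS" else "DEL",
              if (v$vtype == "TE_SV_DEL") -v$length else v$length,
              format(v$te_coverage, digits = 6))
    } else if (v$vtype == "SNV_SYN") "EFF=synonymous"
      else if (v$vtype == "SNV_NONSYN") "EFF=missense"
      else "."
    alt <- if (is_sv) sprintf("<%s>", if (v$vtype == "TE_SV_INS") "INS" else "DEL") else "G"
    gts <- c(rep("1", v$alt_count), rep("0", v$n_samples - v$alt_count))
    paste(c(v$chrom, v$pos + 1L, v$variant_id, "N", alt, ".", "PASS", info,
            "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# ---- plain TSV tables ----

read_two_col_tsv <- function(path, names) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0)
    return(setNames(data.frame(character(), character(), stringsAsFactors = FALSE), names))
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  setNames(x[, 1:2], names)
}

#' Read / write a gene-to-GO association table (two-column TSV)
#' @param path TSV with one gene_id / term pair per line, no header.
#' @return data.frame with columns gene_id, term.
#' @export
read_go_map <- function(path) read_two_col_tsv(path, c("gene_id", "term"))

#' @rdname read_go_map
#' @param go_map data.frame with columns gene_id, term.
#' @export
write_go_map <- function(go_map, path) {
  write.table(go_map[, c("gene_id", "term")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a gene-to-family assignment table (two-column TSV)
#' @param path TSV with one gene_id / family_id pair per line, no header.
#' @return data.frame with columns gene_id, family_id.
#' @export
read_family_map <- function(path) read_two_col_tsv(path, c("gene_id", "family_id"))

#' @rdname read_family_map
#' @param family_map data.frame with columns gene_id, family_id.
#' @export
write_family_map <- function(family_map, path) {
  write.table(family_map[, c("gene_id", "family_id")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a bedGraph track (GC content, recombination rate)
#' @param path bedGraph file.
#' @return data.frame with columns chrom, start, end, value (0-based
#'   half-open).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = gr$score, stringsAsFactors = FALSE)
}

#' @rdname read_bedgraph
#' @param track data.frame with columns chrom, start, end, value.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$chrom,
    IRanges::IRanges(start = track$start + 1L, end = track$end),
    score = track$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read / write per-site selection posterior tables
#'
#' FUBAR-style per-site posteriors, one row per codon site: species_id,
#' family_id, site, prob_pos (posterior probability of positive
#' selection), prob_neg (posterior probability of constraint).
#'
#' @param path TSV with header.
#' @return data.frame with those five columns.
#' @export
read_site_posteriors <- function(path) {
  x <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("species_id", "family_id", "site", "prob_pos", "prob_neg")
  if (!all(need %in% names(x))) stop("posterior table must have columns: ",
                                     paste(need, collapse = ", "))
  if (any(x$prob_pos < 0 | x$prob_pos > 1 | x$prob_neg < 0 | x$prob_neg > 1))
    stop("posteriors must lie in [0, 1]")
  x[, need]
}

#' @rdname read_site_posteriors
#' @param posteriors data.frame with columns species_id, family_id, site,
#'   prob_pos, prob_neg.
#' @export
write_site_posteriors <- function(posteriors, path) {
  write.table(posteriors, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a chromosome table (name, length TSV with header)
#' @param path TSV file.
#' @return data.frame with columns name, length.
#' @export
read_chromosomes <- function(path) {
  x <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  chromosome_spec(x$name, x$length)
}

#' @rdname read_chromosomes
#' @param chroms data.frame from [chromosome_spec()].
#' @export
write_chromosomes <- function(chroms, path) {
  write.table(chroms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
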