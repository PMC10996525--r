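# Aggregation of per-site selection posteriors (FUBAR-style) into
# group-level proportions, and the cross-species sign test.

#' Summarize selection posteriors by compartment group
#'
#' Families are labelled "called" if at least one member gene is
#' compartmentalized (`family_rule = "any"`, the default) or if more than
#' half are (`"majority"`). Families below `min_family` genes are
#' excluded. Sites are pooled within each group; a site counts as
#' positively selected when `prob_pos > cutoff` and as constrained when
#' `prob_neg > cutoff` (FUBAR semantics forbid both; violated input is a
#' hard error).
#'
#' @param posteriors data.frame from [read_site_posteriors()] /
#'   [simulate_site_posteriors()].
#' @param calls a [call_compartmentalized()] result.
#' @param family_map gene-to-family table.
#' @param min_family minimum family size tested (default 10).
#' @param cutoff posterior cutoff (default 0.95).
#' @param family_rule "any" or "majority".
#' @return data.frame with one row per group: group, n_families,
#'   n_sites, n_pos_sites, n_con_sites, prop_pos, prop_con.
#' @export
summarize_selection <- function(posteriors, calls, family_map,
                                min_family = 10, cutoff = 0.95,
                                family_rule = c("any", "majority")) {
  family_rule <- match.arg(family_rule)
  sizes <- table(family_map$family_id)
  eligible <- names(sizes)[sizes >= min_family]
  called_frac <- tapply(family_map$gene_id %in% calls$called_gene_ids,
                        family_map$family_id, mean)
  called_fams <- names(called_frac)[if (family_rule == "any")
    called_frac > 0 else called_frac > 0.5]
  po <- posteriors[posteriors$family_id %in% eligible, , drop = FALSE]
  if (any(po$prob_pos > cutoff & po$prob_neg > cutoff))
    stop("site with both posteriors above the cutoff: not FUBAR-like input")
  po$group <- ifelse(po$family_id %in% called_fams, "called_families",
                     "other_families")
  if (length(unique(po$group)) < 2)
    stop("species skipped: need at least one eligible family in each group")
  rows <- lapply(split(po, po$group), function(g) {
    data.frame(group = g$group[1],
               n_families = length(unique(g$family_id)),
               n_sites = nrow(g),
               n_pos_sites = sum(g$prob_pos > cutoff),
               n_con_sites = sum(g$prob_neg > cutoff),
               prop_pos = mean(g$prob_pos > cutoff),
               prop_con = mean(g$prob_neg > cutoff),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}

#' Cross-species sign test on selection proportions
#'
#' For each species, the sign of (called-group proportion minus
#' other-group proportion) of sites above the posterior cutoff is taken,
#' separately for positive selection and constraint; each sign vector is
#' tested against Binomial(n, 0.5) two-sided (zeros dropped).
#'
#' @param summaries named list of [summarize_selection()] results.
#' @return list with p_pos, p_con (NA when every species ties on that
#'   component), n_species, signs_pos, signs_con.
#' @export
cross_species_selection_test <- function(summaries) {
  if (!length(summaries)) stop("need at least one species")
  get_sign <- function(s, col) {
    called <- s[s$group == "called_families", col]
    other <- s[s$group == "other_families", col]
    sign(called - other)
  }
  signs_pos <- vapply(summaries, get_sign, numeric(1), col = "prop_pos")
  signs_con <- vapply(summaries, get_sign, numeric(1), col = "prop_con")
  p_of <- function(signs) if (all(signs == 0)) NA_real_ else
    cross_species_binomial(signs)$p
  p_pos <- p_of(signs_pos)
  p_con <- p_of(signs_con)
  if (is.na(p_pos) && is.na(p_con))
    stop("all species tie in both components: test undefined")
  list(p_pos = p_pos, p_con = p_con, n_species = length(summaries),
       signs_pos = signs_pos, signs_con = signs_con)
}
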