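# Presence/absence (deletion) hotspot detection from panel missingness,
# and coding-variant class summaries in an ecotype subset.

#' Remove NPs missing in more than half of all accessions
#'
#' The panel-wide pre-filter: an NP missing in strictly more than 50% of
#' all accessions (both ecotypes pooled) is removed; exactly 50% is kept.
#'
#' @param panel list with `geno` (sites x accessions matrix, NA = missing),
#'   `ecotype`, `sites` as returned by [simulate_panel()] or
#'   [read_panel_tsv()].
#' @param max_missing_fraction removal threshold (default 0.5).
#' @return filtered panel (same structure).
#' @export
prefilter_panel <- function(panel, max_missing_fraction = 0.5) {
  frac <- rowMeans(is.na(panel$geno))
  keep <- frac <= max_missing_fraction
  panel$geno <- panel$geno[keep, , drop = FALSE]
  panel$sites <- panel$sites[keep, , drop = FALSE]
  panel
}

#' Per-window ecotype missing-NP percentages and hotspot calls
#'
#' Bins NP sites into fixed half-open windows `[k*w, (k+1)*w)` anchored at
#' coordinate 0. Within each ecotype, an NP counts as *absent* when it is
#' missing in at least 50% of that ecotype's accessions; the window
#' statistic is the percentage of its NPs that are absent, and a window is
#' a deletion hotspot for the ecotype when that percentage reaches 50%.
#' Windows with no NPs give `NA` and no flag.
#'
#' @param panel (pre-filtered) panel list.
#' @param window_bp window width in bp (default 10000).
#' @param absent_fraction per-ecotype missing fraction at which an NP
#'   counts as absent (default 0.5, inclusive).
#' @param hotspot_percent window percentage at which the flag is set
#'   (default 50, inclusive).
#' @return data.frame per chromosome window: chrom, start, end, n_nps,
#'   pct_missing_lowland, pct_missing_upland, hotspot_lowland,
#'   hotspot_upland.
#' @export
window_missing <- function(panel, window_bp = 10000,
                           absent_fraction = 0.5, hotspot_percent = 50) {
  eco <- panel$ecotype
  miss <- is.na(panel$geno)
  abs_low <- rowMeans(miss[, eco == "lowland", drop = FALSE]) >=
    absent_fraction
  abs_upl <- rowMeans(miss[, eco == "upland", drop = FALSE]) >=
    absent_fraction
  out <- list()
  for (chr in unique(panel$sites$chrom)) {
    ii <- panel$sites$chrom == chr
    k <- floor(panel$sites$pos_bp[ii] / window_bp)
    kk <- seq(0, max(k))
    n <- tabulate(k + 1L, nbins = length(kk))
    nl <- vapply(kk, function(w) sum(abs_low[ii][k == w]), numeric(1))
    nu <- vapply(kk, function(w) sum(abs_upl[ii][k == w]), numeric(1))
    pl <- ifelse(n > 0, 100 * nl / n, NA_real_)
    pu <- ifelse(n > 0, 100 * nu / n, NA_real_)
    out[[chr]] <- data.frame(
      chrom = chr, start = kk * window_bp, end = (kk + 1) * window_bp,
      n_nps = n, pct_missing_lowland = pl, pct_missing_upland = pu,
      hotspot_lowland = !is.na(pl) & pl >= hotspot_percent,
      hotspot_upland = !is.na(pu) & pu >= hotspot_percent,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-gene coding-variant class counts in an ecotype subset
#'
#' Restricts NPs to the chosen ecotype's accessions, computes the minor
#' allele frequency on non-missing calls within that subset, applies the
#' MAF and missingness filters, and tallies effect classes per gene.
#'
#' @param panel panel list (geno, ecotype, sites).
#' @param genes gene-model data.frame (gene_id, chrom, start, end).
#' @param effect_annotations data.frame(site_id, gene, effect) with effect
#'   in {synonymous, missense, nonsense, splice}; site ids match
#'   `rownames(panel$geno)`.
#' @param ecotype subset to analyse (default "lowland").
#' @param maf_min minimum minor allele frequency (default 0.05,
#'   inclusive).
#' @param max_missing maximum missing fraction within the subset
#'   (default 0.30, inclusive).
#' @return data.frame per gene: gene_id, synonymous, missense, nonsense,
#'   splice (genes with no passing NPs get all-zero rows).
#' @export
subset_variant_summary <- function(panel, genes, effect_annotations,
                                   ecotype = "lowland", maf_min = 0.05,
                                   max_missing = 0.30) {
  sub <- panel$geno[, panel$ecotype == ecotype, drop = FALSE]
  n_acc <- ncol(sub)
  miss_frac <- rowMeans(is.na(sub))
  af <- rowMeans(sub, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  pass <- miss_frac <= max_missing & maf >= maf_min
  passing_sites <- rownames(sub)[pass]
  classes <- c("synonymous", "missense", "nonsense", "splice")
  ann <- effect_annotations[effect_annotations$site_id %in% passing_sites &
                              effect_annotations$effect %in% classes, ]
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (cl in classes)
    out[[cl]] <- vapply(genes$gene_id, function(g)
      sum(ann$gene == g & ann$effect == cl), numeric(1))
  rownames(out) <- NULL
  out
}

#' Jaccard overlap between flagged hotspot windows and true blocks
#'
#' Utility for validating hotspot calls against planted deletion blocks:
#' base-pair Jaccard index between the union of flagged windows and the
#' union of true blocks.
#'
#' @param windows result of [window_missing()].
#' @param blocks data.frame(chrom, start_bp, end_bp) of true deletions.
#' @param ecotype which ecotype's flags to use.
#' @return Jaccard index in [0, 1].
#' @export
hotspot_jaccard <- function(windows, blocks, ecotype = "upland") {
  flag <- if (ecotype == "upland") windows$hotspot_upland else
    windows$hotspot_lowland
  w <- windows[flag, , drop = FALSE]
  cover <- function() {
    # bp covered on a common grid per chromosome
    tot <- 0; inter <- 0
    for (chr in unique(c(w$chrom, blocks$chrom))) {
      a <- w[w$chrom == chr, ]
      b <- blocks[blocks$chrom == chr, ]
      pts <- sort(unique(c(a$start, a$end, b$start_bp, b$end_bp)))
      if (length(pts) < 2) next
      mid <- (pts[-1] + pts[-length(pts)]) / 2
      len <- diff(pts)
      in_a <- vapply(mid, function(m) any(a$start <= m & m < a$end),
                     logical(1))
      in_b <- vapply(mid, function(m)
        any(b$start_bp <= m & m < b$end_bp), logical(1))
      inter <- inter + sum(len[in_a & in_b])
      tot <- tot + sum(len[in_a | in_b])
    }
    c(inter, tot)
  }
  v <- cover()
  if (v[2] == 0) return(NA_real_)
  v[1] / v[2]
}
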