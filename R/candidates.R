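# QTL-interval candidate-gene prioritization by multi-evidence
# intersection: differential expression, variant impact, GO keywords,
# parental coverage absence.

#' Convert a cM interval to physical coordinates
#'
#' Linearly interpolates between the nearest flanking bp-anchored markers
#' of the linkage group; bounds beyond the outermost anchors clamp to the
#' chromosome ends (or extrapolate to the anchor's bp when no chromosome
#' length is given).
#'
#' @param map a `genetic_map` whose `info` carries `pos_bp` anchors.
#' @param group linkage group id.
#' @param lo_cm,hi_cm interval bounds in cM (lo <= hi).
#' @param chrom_length_bp optional physical chromosome length for clamping.
#' @return list(chrom=, start_bp=, end_bp=).
#' @export
interval_to_physical <- function(map, group, lo_cm, hi_cm,
                                 chrom_length_bp = NULL) {
  if (lo_cm > hi_cm) stopf("interval bounds must be ordered")
  mi <- map$info[map$info$group == group & !is.na(map$info$pos_bp), ]
  if (!nrow(mi)) stopf("no bp-anchored markers in group %s", group)
  mi <- mi[order(mi$pos_cm), ]
  interp <- function(p) {
    if (p <= mi$pos_cm[1]) return(mi$pos_bp[1])
    if (p >= mi$pos_cm[nrow(mi)]) return(mi$pos_bp[nrow(mi)])
    k <- max(which(mi$pos_cm <= p))
    k2 <- min(which(mi$pos_cm > p))
    w <- (p - mi$pos_cm[k]) / (mi$pos_cm[k2] - mi$pos_cm[k])
    mi$pos_bp[k] + w * (mi$pos_bp[k2] - mi$pos_bp[k])
  }
  lo_bp <- interp(lo_cm); hi_bp <- interp(hi_cm)
  if (lo_cm <= mi$pos_cm[1]) lo_bp <- 1
  if (!is.null(chrom_length_bp)) {
    if (hi_cm >= mi$pos_cm[nrow(mi)]) hi_bp <- chrom_length_bp
    hi_bp <- min(hi_bp, chrom_length_bp)
  }
  list(chrom = group, start_bp = as.numeric(lo_bp),
       end_bp = as.numeric(hi_bp))
}

#' Candidate-evidence thresholds
#'
#' @param padj_max adjusted-p cutoff for differential expression
#'   (default 0.01).
#' @param min_abs_log2fc fold-change cutoff, |log2FC| strictly greater
#'   (default 1, i.e. > twofold).
#' @param impact_levels variant-impact classes conferring evidence.
#' @param go_keywords case-insensitive substrings matched against GO term
#'   names (wax-synthesis related by default).
#' @param low_cov,high_cov parental CDS coverage cutoffs for the
#'   absence flag: < `low_cov` in one parent and >= `high_cov` in the
#'   other.
#' @param feature_scope "CDS" restricts impact evidence to CDS variants
#'   when the effect table carries a `feature` column; "any" uses all rows.
#' @return an `evidence_config` list.
#' @export
evidence_config <- function(padj_max = 0.01, min_abs_log2fc = 1,
                            impact_levels = c("HIGH", "MODERATE"),
                            go_keywords = c("fatty acid biosynthetic process",
                                            "lipid metabolic process"),
                            low_cov = 1, high_cov = 5,
                            feature_scope = c("any", "CDS")) {
  structure(list(padj_max = padj_max, min_abs_log2fc = min_abs_log2fc,
                 impact_levels = impact_levels, go_keywords = go_keywords,
                 low_cov = low_cov, high_cov = high_cov,
                 feature_scope = match.arg(feature_scope)),
            class = "evidence_config")
}

is_hom <- function(gt) gt %in% c("0/0", "1/1", "0|0", "1|1", "AA", "BB")

#' Evaluate candidate-gene evidence inside a QTL interval
#'
#' Flags each gene for: differential expression (padj < `padj_max` and
#' |log2FC| > `min_abs_log2fc`); variant impact (at least one
#' HIGH/MODERATE variant with both parents homozygous for different
#' alleles); GO keyword (case-insensitive substring match of the term
#' name); and expression/coverage absence (mean CDS coverage below
#' `low_cov` in one parent and at least `high_cov` in the other). Genes
#' missing from a table get a FALSE flag. Rank orders by descending
#' evidence count, then ascending padj, then gene id.
#'
#' @param genes gene-model data.frame (gene_id, chrom, start, end).
#' @param interval list(chrom=, start_bp=, end_bp=) from
#'   [interval_to_physical()].
#' @param de data.frame(gene, log2fc, padj).
#' @param effects data.frame(gene, impact, parent1_gt, parent2_gt).
#' @param go data.frame(gene, go_name).
#' @param coverage data.frame(gene, parent1_cov, parent2_cov); optional
#'   (NULL drops the absence flag).
#' @param cfg an [evidence_config()].
#' @return data.frame: gene, in_interval, de_flag, de_direction,
#'   impact_flag, go_flag, absence_flag, evidence_count, padj, rank --
#'   restricted to interval genes, ordered by rank.
#' @export
evaluate_evidence <- function(genes, interval, de, effects, go,
                              coverage = NULL, cfg = evidence_config()) {
  gid <- genes$gene_id
  in_int <- genes$chrom == interval$chrom &
    genes$start >= interval$start_bp & genes$start <= interval$end_bp

  de_i <- match(gid, de$gene)
  padj <- de$padj[de_i]
  l2fc <- de$log2fc[de_i]
  de_flag <- !is.na(padj) & padj < cfg$padj_max &
    abs(l2fc) > cfg$min_abs_log2fc
  de_dir <- ifelse(de_flag, ifelse(l2fc > 0, "up", "down"), NA)

  eff <- effects
  if (cfg$feature_scope == "CDS" && "feature" %in% names(eff))
    eff <- eff[eff$feature == "CDS", , drop = FALSE]
  eff_ok <- eff$impact %in% cfg$impact_levels &
    is_hom(eff$parent1_gt) & is_hom(eff$parent2_gt) &
    eff$parent1_gt != eff$parent2_gt
  impact_flag <- gid %in% eff$gene[eff_ok]

  kw <- tolower(cfg$go_keywords)
  go_genes <- unique(go$gene[vapply(tolower(go$go_name), function(nm)
    any(vapply(kw, grepl, logical(1), x = nm, fixed = TRUE)),
    logical(1))])
  go_flag <- gid %in% go_genes

  if (!is.null(coverage)) {
    cv_i <- match(gid, coverage$gene)
    c1 <- coverage$parent1_cov[cv_i]; c2 <- coverage$parent2_cov[cv_i]
    absence_flag <- !is.na(c1) & !is.na(c2) &
      ((c1 < cfg$low_cov & c2 >= cfg$high_cov) |
         (c2 < cfg$low_cov & c1 >= cfg$high_cov))
  } else absence_flag <- rep(FALSE, length(gid))

  out <- data.frame(gene = gid, in_interval = in_int,
                    de_flag = de_flag, de_direction = de_dir,
                    impact_flag = impact_flag, go_flag = go_flag,
                    absence_flag = absence_flag,
                    padj = padj, stringsAsFactors = FALSE)
  out <- out[out$in_interval, , drop = FALSE]
  out$evidence_count <- out$de_flag + out$impact_flag + out$go_flag +
    out$absence_flag
  o <- order(-out$evidence_count, out$padj, out$gene,
             na.last = TRUE, method = "radix")
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Summarize evidence classes inside the interval
#'
#' @param evidence result of [evaluate_evidence()].
#' @return list with class sizes (`n_interval`, `n_impact`, `n_de`,
#'   `n_both`, `n_go_shortlist`, `n_all_evidence`) and the member gene ids
#'   (`impact_class`, `de_class`, `both_classes`, `go_shortlist`,
#'   `all_evidence`).
#' @export
summarize_classes <- function(evidence) {
  imp <- evidence$gene[evidence$impact_flag]
  de <- evidence$gene[evidence$de_flag]
  both <- intersect(imp, de)
  go_short <- evidence$gene[evidence$de_flag & evidence$go_flag]
  full <- evidence$gene[evidence$evidence_count == 4]
  list(n_interval = nrow(evidence), n_impact = length(imp),
       n_de = length(de), n_both = length(both),
       n_go_shortlist = length(go_short), n_all_evidence = length(full),
       impact_class = imp, de_class = de, both_classes = both,
       go_shortlist = go_short, all_evidence = full)
}

#' Totals of a differential-expression partition
#'
#' Sums up- and down-regulated gene counts into a total, the bookkeeping
#' check used when a DE table is split by expression direction between
#' ecotypes.
#'
#' @param n_up,n_down counts of genes upregulated in each direction.
#' @return list(total=, n_up=, n_down=).
#' @export
de_partition_total <- function(n_up, n_down) {
  list(total = n_up + n_down, n_up = n_up, n_down = n_down)
}
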