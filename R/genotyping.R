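# Site filtering and conversion of allele read counts into the A/B/H/C/D
# genotype score alphabet, consolidation of nearby sites, and cosegregation
# grouping.

SCORE_LEVELS <- c("A", "B", "H", "C", "D", "-")

# score -> set-of-possible-genotypes semantics used for reconciliation and
# compatibility: D = "A or H", C = "B or H", "-" = unknown
score_sets <- list(A = "A", B = "B", H = "H",
                   C = c("B", "H"), D = c("A", "H"),
                   "-" = c("A", "B", "H"))

set_to_score <- function(s) {
  if (length(s) == 0) return("-")
  if (length(s) == 1) return(s)
  if (setequal(s, c("A", "H"))) return("D")
  if (setequal(s, c("B", "H"))) return("C")
  "-"
}

#' Genotyping thresholds and consolidation parameters
#'
#' @param min_depth sites with read depth below this in a sample are scored
#'   missing (default 8).
#' @param hom_max_minor_fraction minor-allele read fraction at or below
#'   which a call is homozygous (default 0.05).
#' @param het_min_minor_fraction minor-allele read fraction at or above
#'   which a call is heterozygous (default 0.2); the band between the two
#'   fractions yields the ambiguous codes D ("A or H") and C ("B or H").
#' @param min_qd sites with quality-by-depth below this are removed
#'   (default 10; QD of exactly 10 is retained).
#' @param allele_freq_bounds pooled alt-read frequency bounds outside which
#'   a site is removed (default c(0.10, 0.90), inclusive bounds retained).
#' @param max_missing_fraction markers missing in more than this fraction of
#'   progeny are dropped (default 0.30).
#' @param consolidation_window_bp sites within this distance of a cluster's
#'   first site are consolidated into one marker (default 1000).
#' @param coseg_min_overlap minimum number of progeny informative in both
#'   markers for a cosegregation comparison (default 20).
#' @return a `genotyping_config` list.
#' @export
genotyping_config <- function(min_depth = 8, hom_max_minor_fraction = 0.05,
                              het_min_minor_fraction = 0.2, min_qd = 10,
                              allele_freq_bounds = c(0.10, 0.90),
                              max_missing_fraction = 0.30,
                              consolidation_window_bp = 1000,
                              coseg_min_overlap = 20) {
  if (hom_max_minor_fraction < 0 ||
      hom_max_minor_fraction >= het_min_minor_fraction ||
      het_min_minor_fraction > 0.5)
    stopf("need 0 <= hom_max_minor_fraction < het_min_minor_fraction <= 0.5")
  structure(list(min_depth = min_depth,
                 hom_max_minor_fraction = hom_max_minor_fraction,
                 het_min_minor_fraction = het_min_minor_fraction,
                 min_qd = min_qd, allele_freq_bounds = allele_freq_bounds,
                 max_missing_fraction = max_missing_fraction,
                 consolidation_window_bp = consolidation_window_bp,
                 coseg_min_overlap = coseg_min_overlap),
            class = "genotyping_config")
}

#' Filter variant sites before genotype scoring
#'
#' Retains biallelic sites with QD >= `min_qd` and pooled alt-read
#' frequency inside `allele_freq_bounds` (inclusive). Filters are applied
#' in a fixed order -- allele count, then QD, then frequency -- and each
#' removed site is counted against the first rule it fails, so the
#' rejection tallies partition the removed set. A site with no QD value is
#' treated as failing the QD filter.
#'
#' @param sites data.frame with columns `n_alleles`, `qd`,
#'   `pooled_alt_freq` (plus any identifier columns, carried through).
#' @param cfg a [genotyping_config()].
#' @return list with `retained` (subset of `sites`) and `rejected` (named
#'   integer vector: n_alleles, qd, freq).
#' @export
filter_sites <- function(sites, cfg = genotyping_config()) {
  fail_alleles <- sites$n_alleles != 2L
  fail_qd <- !fail_alleles & (is.na(sites$qd) | sites$qd < cfg$min_qd)
  fail_freq <- !fail_alleles & !fail_qd &
    (sites$pooled_alt_freq < cfg$allele_freq_bounds[1] |
       sites$pooled_alt_freq > cfg$allele_freq_bounds[2])
  keep <- !(fail_alleles | fail_qd | fail_freq)
  list(retained = sites[keep, , drop = FALSE],
       rejected = c(n_alleles = sum(fail_alleles), qd = sum(fail_qd),
                    freq = sum(fail_freq)))
}

#' Score a genotype from allele read counts
#'
#' Converts reference/alternate read counts to the five-letter score
#' alphabet: A (homozygous parent 1), B (homozygous parent 2), H
#' (heterozygous), D ("A or H") and C ("B or H"), with `-` for missing.
#' Depth below `min_depth` is missing. Otherwise, with minor-allele read
#' fraction f: f >= `het_min_minor_fraction` is H; f <=
#' `hom_max_minor_fraction` is homozygous for the major allele (A or B
#' depending on which allele is the parent-1 allele); the band between
#' gives the ambiguous code on the major allele's side (D when the major
#' allele is the A allele, C when it is the B allele).
#'
#' @param ref,alt non-negative read counts (vectors recycle together).
#' @param orientation `"ref"` if the reference allele is the parent-1 (A)
#'   allele, `"alt"` otherwise. Recycled across sites.
#' @param cfg a [genotyping_config()].
#' @return character vector of scores over `A B H C D -`.
#' @export
score_genotype <- function(ref, alt, orientation = "ref",
                           cfg = genotyping_config()) {
  if (any(ref < 0) || any(alt < 0)) stopf("negative read counts")
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  orientation <- rep_len(orientation, n)
  depth <- ref + alt
  out <- rep("-", n)
  ok <- depth >= cfg$min_depth
  f <- ifelse(ok, pmin(ref, alt) / depth, NA_real_)
  major_is_ref <- ref >= alt
  # major allele expressed on the A/B axis
  major_is_A <- (major_is_ref & orientation == "ref") |
    (!major_is_ref & orientation == "alt")
  het <- ok & f >= cfg$het_min_minor_fraction
  hom <- ok & f <= cfg$hom_max_minor_fraction
  band <- ok & !het & !hom
  out[het] <- "H"
  out[hom & major_is_A] <- "A"
  out[hom & !major_is_A] <- "B"
  out[band & major_is_A] <- "D"
  out[band & !major_is_A] <- "C"
  out
}

#' Score a full read-count matrix
#'
#' Applies [score_genotype()] across a sites x samples pair of count
#' matrices.
#'
#' @param ref,alt sites x samples count matrices.
#' @param orientation per-site orientation vector ("ref"/"alt").
#' @param cfg a [genotyping_config()].
#' @return character matrix of scores, same shape and dimnames.
#' @export
score_matrix <- function(ref, alt, orientation = "ref",
                         cfg = genotyping_config()) {
  stopifnot(all(dim(ref) == dim(alt)))
  orientation <- rep_len(orientation, nrow(ref))
  out <- score_genotype(as.vector(ref), as.vector(alt),
                        rep(orientation, times = ncol(ref)), cfg)
  matrix(out, nrow(ref), ncol(ref), dimnames = dimnames(ref))
}

# consensus of a set of scores for one progeny: intersect the possibility
# sets; empty intersection (conflicting concrete scores) or all-missing -> "-"
reconcile_scores <- function(scores) {
  scores <- scores[scores != "-"]
  if (length(scores) == 0) return("-")
  s <- score_sets[[scores[1]]]
  for (sc in scores[-1]) s <- intersect(s, score_sets[[sc]])
  set_to_score(s)
}

#' Consolidate nearby scored sites into representative markers
#'
#' Left-to-right clustering: walking along each chromosome in position
#' order, a site joins the open cluster iff it lies within
#' `consolidation_window_bp` of the cluster's *first* site; otherwise it
#' starts a new cluster. Per progeny, the consolidated score is the
#' consensus of the member scores under set semantics (identical concrete
#' scores kept; D reconciles with A or H, C with B or H, to the concrete
#' score; conflicting concrete scores give missing; all missing gives
#' missing). The representative position is the first member site.
#'
#' @param sites data.frame sorted by (chrom, pos_bp) with columns
#'   `site_id`, `chrom`, `pos_bp`.
#' @param scores sites x samples character score matrix (rows align with
#'   `sites`).
#' @param parents length-2 character vector naming the two parental columns
#'   of `scores`; all other columns are progeny.
#' @param cfg a [genotyping_config()].
#' @return a `marker_table`: list with `info` (data.frame marker_id, chrom,
#'   pos_bp, parent1, parent2, n_missing, n_ambiguous, members) and
#'   `scores` (markers x progeny matrix).
#' @export
consolidate <- function(sites, scores, parents,
                        cfg = genotyping_config()) {
  stopifnot(nrow(sites) == nrow(scores), length(parents) == 2,
            all(parents %in% colnames(scores)))
  o <- order(sites$chrom, sites$pos_bp)
  if (any(o != seq_len(nrow(sites))))
    stopf("sites must be sorted by (chrom, pos_bp)")
  cluster <- integer(nrow(sites))
  cur <- 0L; cur_chrom <- ""; cur_start <- -Inf
  for (i in seq_len(nrow(sites))) {
    if (sites$chrom[i] != cur_chrom ||
        sites$pos_bp[i] - cur_start > cfg$consolidation_window_bp) {
      cur <- cur + 1L
      cur_chrom <- sites$chrom[i]
      cur_start <- sites$pos_bp[i]
    }
    cluster[i] <- cur
  }
  prog_cols <- setdiff(colnames(scores), parents)
  idx <- split(seq_len(nrow(sites)), cluster)
  n_mark <- length(idx)
  mscores <- matrix("-", n_mark, length(prog_cols),
                    dimnames = list(NULL, prog_cols))
  info <- data.frame(marker_id = sprintf("M%05d", seq_len(n_mark)),
                     chrom = NA_character_, pos_bp = NA_integer_,
                     parent1 = NA_character_, parent2 = NA_character_,
                     n_missing = NA_integer_, n_ambiguous = NA_integer_,
                     members = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_len(n_mark)) {
    ii <- idx[[k]]
    info$chrom[k] <- sites$chrom[ii[1]]
    info$pos_bp[k] <- sites$pos_bp[ii[1]]
    info$members[k] <- paste(sites$site_id[ii], collapse = ",")
    sub <- scores[ii, , drop = FALSE]
    mscores[k, ] <- apply(sub[, prog_cols, drop = FALSE], 2,
                          reconcile_scores)
    info$parent1[k] <- reconcile_scores(sub[, parents[1]])
    info$parent2[k] <- reconcile_scores(sub[, parents[2]])
  }
  info$n_missing <- rowSums(mscores == "-")
  info$n_ambiguous <- rowSums(mscores == "C" | mscores == "D")
  rownames(mscores) <- info$marker_id
  structure(list(info = info, scores = mscores), class = "marker_table")
}

#' Drop markers with excessive missing data
#'
#' Removes markers whose missing fraction across progeny exceeds
#' `max_missing_fraction` (strictly greater; exactly at the bound is kept).
#' Only `-` counts as missing; the ambiguous codes C and D do not.
#'
#' @param markers a `marker_table` from [consolidate()].
#' @param cfg a [genotyping_config()].
#' @return filtered `marker_table`.
#' @export
drop_high_missing <- function(markers, cfg = genotyping_config()) {
  frac <- markers$info$n_missing / ncol(markers$scores)
  keep <- frac <= cfg$max_missing_fraction
  structure(list(info = markers$info[keep, , drop = FALSE],
                 scores = markers$scores[keep, , drop = FALSE]),
            class = "marker_table")
}

# TRUE iff two score vectors are compatible: >= min_overlap progeny
# non-missing in both, and every such pair has intersecting possibility sets
scores_compatible <- function(s1, s2, min_overlap) {
  both <- s1 != "-" & s2 != "-"
  if (sum(both) < min_overlap) return(FALSE)
  a <- s1[both]; b <- s2[both]
  same <- a == b
  if (all(same)) return(TRUE)
  for (i in which(!same)) {
    if (length(intersect(score_sets[[a[i]]], score_sets[[b[i]]])) == 0)
      return(FALSE)
  }
  TRUE
}

#' Group cosegregating markers and pick representatives
#'
#' Two markers cosegregate when they share at least `coseg_min_overlap`
#' progeny scored in both, every shared progeny is score-compatible (equal
#' concrete scores, or an ambiguous code covering the other's score), and
#' the markers belong to the same segregation category. Grouping is
#' seeded-greedy: markers are ordered by (n_missing + n_ambiguous
#' ascending, then position), the best unassigned marker seeds a group and
#' absorbs all markers compatible with it, and the seed -- the member with
#' the fewest missing-or-ambiguous scores -- is the group's representative.
#'
#' @param markers a `marker_table`.
#' @param cfg a [genotyping_config()].
#' @return `marker_table` whose `info` gains `coseg_group` (integer) and
#'   `representative` (logical) columns.
#' @export
cosegregation_groups <- function(markers, cfg = genotyping_config()) {
  info <- markers$info
  n <- nrow(info)
  cat <- vapply(seq_len(n), function(i)
    classify_marker(info$parent1[i], info$parent2[i]), character(1))
  ord <- order(info$n_missing + info$n_ambiguous, info$chrom, info$pos_bp)
  group <- rep(NA_integer_, n)
  rep_flag <- rep(FALSE, n)
  g <- 0L
  for (i in ord) {
    if (!is.na(group[i])) next
    g <- g + 1L
    group[i] <- g
    rep_flag[i] <- TRUE
    seed <- markers$scores[i, ]
    for (j in ord) {
      if (!is.na(group[j]) || cat[j] != cat[i]) next
      if (scores_compatible(seed, markers$scores[j, ],
                            cfg$coseg_min_overlap))
        group[j] <- g
    }
  }
  info$coseg_group <- group
  info$representative <- rep_flag
  structure(list(info = info, scores = markers$scores),
            class = "marker_table")
}

#' Keep only cosegregation-group representatives
#'
#' @param markers a `marker_table` with cosegregation groups assigned.
#' @return `marker_table` restricted to representatives.
#' @export
representatives <- function(markers) {
  if (is.null(markers$info$representative))
    stopf("run cosegregation_groups() first")
  keep <- markers$info$representative
  structure(list(info = markers$info[keep, , drop = FALSE],
                 scores = markers$scores[keep, , drop = FALSE]),
            class = "marker_table")
}

#' @exportS3Method base::print
print.marker_table <- function(x, ...) {
  cat(sprintf("marker_table: %d markers x %d progeny\n",
              nrow(x$info), ncol(x$scores)))
  invisible(x)
}
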