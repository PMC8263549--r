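# Segregation-category classification (HH / AH / HA), chi-square
# distortion testing, and dataset partitioning.

#' Classify a marker by its parental scores
#'
#' In an F1 x F1 cross, markers heterozygous in both parents segregate
#' A:H:B 1:2:1 (HH dataset); markers homozygous in parent 1 and
#' heterozygous in parent 2 segregate 1:1 and form the paternal (AH)
#' dataset; the reverse forms the maternal (HA) dataset. Any other parental
#' combination (missing or ambiguous parent, both parents homozygous) is
#' unclassifiable and dropped from mapping.
#'
#' @param parent1,parent2 parental score codes (A/B/H/C/D/-).
#' @return one of "HH", "AH", "HA", "unclassifiable".
#' @export
classify_marker <- function(parent1, parent2) {
  hom <- c("A", "B")
  if (parent1 == "H" && parent2 == "H") return("HH")
  if (parent1 %in% hom && parent2 == "H") return("AH")
  if (parent1 == "H" && parent2 %in% hom) return("HA")
  "unclassifiable"
}

#' Chi-square segregation test for one marker
#'
#' Tests the observed concrete score counts against the Mendelian
#' expectation for the marker's category: 1:2:1 over (A, H, B) with 2
#' degrees of freedom for HH markers, 1:1 over (A, H) with 1 degree of
#' freedom for AH/HA markers (after B-to-A recoding). Missing and
#' ambiguous (C/D) scores are excluded from the counts. Markers with
#' p-value <= `p_cut` are flagged as highly distorted.
#'
#' @param scores character vector of progeny scores for the marker.
#' @param category "HH", "AH" or "HA".
#' @param p_cut distortion threshold (default 1e-10).
#' @return list with `observed`, `expected`, `chi_square`, `p_value`,
#'   `distorted`, `df`; or `NULL` when every score is excluded (test
#'   undefined).
#' @export
segregation_test <- function(scores, category, p_cut = 1e-10) {
  if (!category %in% c("HH", "AH", "HA"))
    stopf("category must be HH, AH or HA")
  if (category == "HH") {
    obs <- c(A = sum(scores == "A"), H = sum(scores == "H"),
             B = sum(scores == "B"))
    ratio <- c(1, 2, 1) / 4
  } else {
    # AH/HA scores are recoded so only A and H remain
    obs <- c(A = sum(scores %in% c("A", "B")), H = sum(scores == "H"))
    ratio <- c(1, 1) / 2
  }
  n <- sum(obs)
  if (n == 0) return(NULL)
  expd <- n * ratio
  chi <- sum((obs - expd)^2 / expd)
  df <- length(obs) - 1L
  p <- stats::pchisq(chi, df = df, lower.tail = FALSE)
  list(observed = obs, expected = expd, chi_square = chi, p_value = p,
       distorted = p <= p_cut, df = df)
}

#' Partition markers into HH, AH and HA datasets
#'
#' Classifies each marker from its parental scores, applies the chi-square
#' distortion filter, recodes B progeny scores to A in the AH and HA
#' datasets (turning them into backcross-coded 1:1 data), and returns the
#' three datasets with a partition report. Every surviving marker appears
#' in exactly one dataset.
#'
#' @param markers a `marker_table` (see [consolidate()]).
#' @param p_cut distortion p-value threshold (default 1e-10).
#' @return list with `HH`, `AH`, `HA` (marker_tables), and `report`
#'   (data.frame of per-category counts and percentages plus dropped
#'   tallies).
#' @export
build_datasets <- function(markers, p_cut = 1e-10) {
  info <- markers$info
  n <- nrow(info)
  cat <- if (n) vapply(seq_len(n), function(i)
    classify_marker(info$parent1[i], info$parent2[i]), character(1))
    else character(0)
  distorted <- rep(FALSE, n)
  undef <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (cat[i] == "unclassifiable") next
    st <- segregation_test(markers$scores[i, ], cat[i], p_cut)
    if (is.null(st)) undef[i] <- TRUE else distorted[i] <- st$distorted
  }
  keep <- cat != "unclassifiable" & !distorted & !undef
  subset_mt <- function(sel, recode) {
    sc <- markers$scores[sel, , drop = FALSE]
    if (recode) {
      sc[sc == "B"] <- "A"
      sc[sc == "C"] <- "D"  # "B or H" becomes "A or H" after recoding
    }
    structure(list(info = info[sel, , drop = FALSE], scores = sc),
              class = "marker_table")
  }
  out <- list(HH = subset_mt(keep & cat == "HH", FALSE),
              AH = subset_mt(keep & cat == "AH", TRUE),
              HA = subset_mt(keep & cat == "HA", TRUE))
  counts <- vapply(out, function(m) nrow(m$info), integer(1))
  report <- data.frame(category = names(counts), n = as.integer(counts),
                       percent = if (sum(counts)) 100 * counts / sum(counts)
                                 else rep(0, 3))
  attr(report, "dropped") <- c(unclassifiable = sum(cat == "unclassifiable"),
                               distorted = sum(distorted),
                               undefined_test = sum(undef))
  out$report <- report
  out
}

#' Summarize marker-category partitions across populations
#'
#' Given per-population HH/AH/HA marker counts, returns each population's
#' filtered-marker total and the per-population and mean category
#' percentages -- the summary used to describe how much of a map is built
#' from intercross versus backcross-coded markers.
#'
#' @param counts data.frame with columns `population`, `HH`, `AH`, `HA`.
#' @return list with `totals` (named per-population totals) and
#'   `mean_percent` (named mean of per-population percentages for HH, AH,
#'   HA).
#' @export
partition_totals <- function(counts) {
  stopifnot(all(c("population", "HH", "AH", "HA") %in% names(counts)))
  mat <- as.matrix(counts[, c("HH", "AH", "HA")])
  totals <- rowSums(mat)
  names(totals) <- counts$population
  pct <- 100 * mat / totals
  list(totals = totals, mean_percent = colMeans(pct))
}
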