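# Independent brute-force oracles shared across test files. These are
# deliberately naive re-derivations from first principles, kept separate
# from the package's own code paths.

# possibility sets of the score alphabet (D = "A or H", C = "B or H")
oracle_sets <- list(A = "A", B = "B", H = "H",
                    C = c("B", "H"), D = c("A", "H"),
                    "-" = c("A", "B", "H"))

# consensus of member scores by set intersection
oracle_consensus <- function(scores) {
  scores <- scores[scores != "-"]
  if (!length(scores)) return("-")
  s <- Reduce(intersect, lapply(scores, function(x) oracle_sets[[x]]))
  if (!length(s)) "-"
  else if (length(s) == 1) s
  else if (setequal(s, c("A", "H"))) "D"
  else if (setequal(s, c("B", "H"))) "C"
  else "-"
}

oracle_compatible_pair <- function(a, b) {
  length(intersect(oracle_sets[[a]], oracle_sets[[b]])) > 0
}

# all-pairs greedy cosegregation grouping with the package's seeding order,
# written straight from the definition
oracle_coseg <- function(scores, info, min_overlap, categories) {
  n <- nrow(scores)
  comp <- function(i, j) {
    if (categories[i] != categories[j]) return(FALSE)
    s1 <- scores[i, ]; s2 <- scores[j, ]
    both <- which(s1 != "-" & s2 != "-")
    if (length(both) < min_overlap) return(FALSE)
    all(vapply(both, function(k) oracle_compatible_pair(s1[k], s2[k]),
               logical(1)))
  }
  ord <- order(info$n_missing + info$n_ambiguous, info$chrom, info$pos_bp)
  group <- rep(NA_integer_, n); repr <- rep(FALSE, n); g <- 0L
  for (i in ord) {
    if (!is.na(group[i])) next
    g <- g + 1L; group[i] <- g; repr[i] <- TRUE
    for (j in ord) {
      if (!is.na(group[j])) next
      if (comp(i, j)) group[j] <- g
    }
  }
  list(group = group, representative = repr)
}

# two-locus F2 genotype cell probabilities by direct gamete enumeration
oracle_f2_cells <- function(r) {
  haps <- list(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  hp <- c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2)
  cells <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4) {
    g1 <- haps[[i]][1] + haps[[j]][1]
    g2 <- haps[[i]][2] + haps[[j]][2]
    cells[g1 + 1, g2 + 1] <- cells[g1 + 1, g2 + 1] + hp[i] * hp[j]
  }
  cells
}

# grid-search maximum-likelihood rf from a 3x3 table
oracle_grid_ml_rf <- function(tab, step = 1e-4) {
  rs <- seq(step, 0.5 - step, by = step)
  ll <- vapply(rs, function(r) {
    p <- oracle_f2_cells(r)
    sum(tab * log(pmax(p, 1e-300)))
  }, numeric(1))
  rs[which.max(ll)]
}

# conditional genotype distribution at a middle locus given flanking
# genotypes, by full enumeration of ordered three-locus gamete haplotypes
oracle_cond_mid <- function(gl, gr, r1, r2) {
  p_hap <- function(h) {
    p <- 0.5
    p <- p * (if (h[1] == h[2]) 1 - r1 else r1)
    p * (if (h[2] == h[3]) 1 - r2 else r2)
  }
  haps <- expand.grid(a = 0:1, q = 0:1, b = 0:1)
  hp <- apply(haps, 1, p_hap)
  out <- numeric(3)
  for (i in seq_len(8)) for (j in seq_len(8)) {
    if (haps$a[i] + haps$a[j] != gl) next
    if (haps$b[i] + haps$b[j] != gr) next
    q <- haps$q[i] + haps$q[j]
    out[q + 1] <- out[q + 1] + hp[i] * hp[j]
  }
  out / sum(out)
}

# paralog call by filter-then-argmin, written straight from the rule
oracle_paralog <- function(gene, hits, homoeolog_map) {
  h <- hits[hits$query == gene & hits$subject != gene, , drop = FALSE]
  if (!nrow(h)) return(NA_character_)
  h <- h[order(h$evalue, -h$psim, h$subject, method = "radix"), ]
  top <- h[1, ]
  hm <- homoeolog_map[gene]
  if (!is.na(hm) && unname(hm) == top$subject) return(NA_character_)
  if (top$evalue > 1e-5) return(NA_character_)
  if (top$alnlen < 0.7 * top$qlen) return(NA_character_)
  if (top$psim < 80) return(NA_character_)
  top$subject
}

# standard small F2 toy: scored marker table built directly from a
# simulated cross at high depth (used by several files)
make_toy_marker_table <- function(n_progeny = 120, sites = 40,
                                  len_cm = 80, seed = 42,
                                  mean_depth = 40) {
  cc <- cross_config(n_chromosomes = 1, chrom_length_cm = len_cm,
                     sites_per_chrom = sites, n_progeny = n_progeny,
                     seed = seed)
  cr <- simulate_cross(cc)
  rd <- simulate_reads(cr$geno, gbs_config(mean_depth = mean_depth,
                                           seed = seed + 1))
  f1r <- simulate_reads(cr$f1_geno, gbs_config(mean_depth = mean_depth,
                                               seed = seed + 2))
  sc <- score_matrix(cbind(rd$ref, f1r$ref), cbind(rd$alt, f1r$alt))
  mk <- consolidate(cr$sites[, c("site_id", "chrom", "pos_bp")], sc,
                    parents = c("F1a", "F1b"))
  list(cross = cr, markers = mk)
}
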