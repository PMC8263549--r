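# Genetic-map construction from pairwise recombination fractions and
# Haley-Knott interval-mapping / composite-interval-mapping QTL scans with
# permutation LOD thresholds.

CONCRETE_F2 <- c("A", "H", "B")
CONCRETE_BC <- c("A", "H")

# two-locus F2 gamete machinery: gametes carry haplotypes (0,0),(1,1) with
# prob (1-r)/2 each and (0,1),(1,0) with prob r/2 each; an F2 genotype pair
# is the dosage sum of two independent gametes.
f2_cell_probs <- function(r) {
  hap <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  hp <- c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2)
  rec <- c(0, 0, 1, 1)
  cells <- matrix(0, 3, 3)      # dosage at locus1 x locus2 (0,1,2)
  krec <- matrix(0, 3, 3)       # expected recombinant gametes x prob
  for (i in 1:4) for (j in 1:4) {
    g1 <- hap[i, 1] + hap[j, 1]
    g2 <- hap[i, 2] + hap[j, 2]
    p <- hp[i] * hp[j]
    cells[g1 + 1, g2 + 1] <- cells[g1 + 1, g2 + 1] + p
    krec[g1 + 1, g2 + 1] <- krec[g1 + 1, g2 + 1] + p * (rec[i] + rec[j])
  }
  list(cells = cells, krec = krec)
}

# EM maximum-likelihood rf from a 3x3 F2 genotype count table
em_rf_f2 <- function(tab, init = 0.25, tol = 1e-8, max_iter = 200L) {
  n <- sum(tab)
  r <- init
  for (it in seq_len(max_iter)) {
    cp <- f2_cell_probs(r)
    ek <- cp$krec / pmax(cp$cells, 1e-300)  # E[recombinant gametes | cell]
    r_new <- sum(tab * ek) / (2 * n)
    if (abs(r_new - r) < tol) { r <- r_new; break }
    r <- r_new
  }
  r
}

#' Estimate the recombination fraction between two markers
#'
#' AH/HA (backcross-coded) markers: the direct count estimate,
#' recombinants over doubly-concrete progeny. HH (F2 codominant) markers:
#' maximum likelihood via EM on the 3x3 genotype table (initial value
#' 0.25, tolerance 1e-8, at most 200 iterations). Only progeny with
#' concrete scores at both loci are used; the estimate is clamped to
#' [0, 0.4999].
#'
#' @param s1,s2 score vectors for the two markers over the same progeny.
#' @param category "HH" for F2 codominant, "AH" or "HA" for
#'   backcross-coded.
#' @param min_overlap minimum doubly-concrete progeny required
#'   (default 20); below it the estimate is undefined (`NA`).
#' @return recombination fraction in [0, 0.4999], or `NA` if undefined.
#' @export
estimate_rf <- function(s1, s2, category = "HH", min_overlap = 20) {
  if (category == "HH") {
    ok <- s1 %in% CONCRETE_F2 & s2 %in% CONCRETE_F2
    if (sum(ok) < min_overlap) return(NA_real_)
    d1 <- match(s1[ok], CONCRETE_F2) - 1L  # A=0, H=1, B=2 dosage of allele B
    d2 <- match(s2[ok], CONCRETE_F2) - 1L
    if (all(d1 == d2)) return(0)
    tab <- matrix(0, 3, 3)
    for (i in seq_along(d1)) tab[d1[i] + 1, d2[i] + 1] <-
        tab[d1[i] + 1, d2[i] + 1] + 1
    r <- em_rf_f2(tab)
  } else {
    ok <- s1 %in% CONCRETE_BC & s2 %in% CONCRETE_BC
    if (sum(ok) < min_overlap) return(NA_real_)
    r <- mean(s1[ok] != s2[ok])
  }
  min(max(r, 0), 0.4999)
}

#' Scan and map configuration
#'
#' @param walk_speed_cm grid step of the genome scan in cM (default 0.5).
#' @param n_permutations permutations for the LOD threshold (default 1000).
#' @param alpha genome-wide significance level (default 0.05).
#' @param model "CIM" (composite interval mapping) or "IM".
#' @param n_cofactors maximum background cofactor markers for CIM
#'   (default 5), chosen by forward stepwise regression with entry
#'   p < 0.01.
#' @param exclusion_window_cm cofactors within this distance of the test
#'   position are dropped (default 10).
#' @param mapping_function "haldane" (default) or "kosambi".
#' @param min_overlap doubly-informative progeny required per marker pair.
#' @param seed RNG seed for permutations.
#' @return a `scan_config` list.
#' @export
scan_config <- function(walk_speed_cm = 0.5, n_permutations = 1000,
                        alpha = 0.05, model = c("CIM", "IM"),
                        n_cofactors = 5, exclusion_window_cm = 10,
                        mapping_function = c("haldane", "kosambi"),
                        min_overlap = 20, seed = NULL) {
  if (walk_speed_cm <= 0) stopf("walk_speed_cm must be positive")
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  structure(list(walk_speed_cm = walk_speed_cm,
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, model = match.arg(model),
                 n_cofactors = n_cofactors,
                 exclusion_window_cm = exclusion_window_cm,
                 mapping_function = match.arg(mapping_function),
                 min_overlap = min_overlap, seed = seed),
            class = "scan_config")
}

map_fun <- function(cfg) {
  if (cfg$mapping_function == "kosambi")
    list(cm = kosambi_cm, rf = kosambi_rf)
  else list(cm = haldane_cm, rf = haldane_rf)
}

#' Build a genetic map from ordered markers
#'
#' Computes cM positions per linkage group (one group per chromosome) as
#' the cumulative sum of adjacent-pair map distances, with marker order
#' taken from reference physical coordinates by default (a user-supplied
#' order may be given). Adjacent pairs with an undefined recombination
#' fraction inherit the position of the nearest preceding anchored marker
#' and are flagged as gaps.
#'
#' @param markers a `marker_table` from one segregation dataset.
#' @param category "HH", "AH" or "HA" (population type F2 intercross vs
#'   backcross-coded).
#' @param cfg a [scan_config()].
#' @param order optional integer permutation of markers overriding
#'   physical order.
#' @return a `genetic_map`: list with `info` (data.frame marker_id, group,
#'   pos_cm, pos_bp, gap), `scores` matrix, `category`.
#' @export
map_from_order <- function(markers, category = "HH", cfg = scan_config(),
                           order = NULL) {
  info <- markers$info
  sc <- markers$scores
  if (!is.null(order)) { info <- info[order, ]; sc <- sc[order, , drop = FALSE] }
  o <- order(info$chrom, info$pos_bp)
  info <- info[o, ]; sc <- sc[o, , drop = FALSE]
  fun <- map_fun(cfg)
  pos_cm <- numeric(nrow(info))
  gap <- logical(nrow(info))
  for (grp in unique(info$chrom)) {
    ii <- which(info$chrom == grp)
    pos <- numeric(length(ii))
    anchor <- 1L
    for (k in seq_along(ii)[-1]) {
      r <- estimate_rf(sc[ii[anchor], ], sc[ii[k], ], category,
                       cfg$min_overlap)
      if (is.na(r)) {
        pos[k] <- pos[anchor]
        gap[ii[k]] <- TRUE
      } else {
        pos[k] <- pos[anchor] + fun$cm(min(r, 0.4999))
        anchor <- k
      }
    }
    pos_cm[ii] <- pos
  }
  structure(list(info = data.frame(marker_id = info$marker_id,
                                   group = info$chrom,
                                   pos_cm = pos_cm, pos_bp = info$pos_bp,
                                   gap = gap, stringsAsFactors = FALSE),
                 scores = sc, category = category),
            class = "genetic_map")
}

#' @exportS3Method base::print
print.genetic_map <- function(x, ...) {
  len <- tapply(x$info$pos_cm, x$info$group, max)
  cat(sprintf("genetic_map (%s): %d markers, %d groups, total %.1f cM\n",
              x$category, nrow(x$info), length(len), sum(len)))
  invisible(x)
}

# conditional genotype distribution at a query locus given concrete flank
# genotypes, by enumeration over ordered gamete allele configurations.
# gl/gr are dosages (0/1/2 F2; 0=A,1=H backcross) or NA when absent;
# r1 = rf(left, query), r2 = rf(query, right).
cond_geno_dist <- function(gl, gr, r1, r2, f2 = TRUE) {
  if (!f2) {
    # backcross: genotype follows the single segregating gamete's 2-state
    # chain directly
    p <- c(0.5, 0.5)
    if (!is.na(gl)) {
      p <- if (gl == 0) c(1 - r1, r1) else c(r1, 1 - r1)
    }
    if (!is.na(gr)) {
      lik <- if (gr == 0) c(1 - r2, r2) else c(r2, 1 - r2)
      p <- p * lik
    }
    return(p / sum(p))
  }
  trans <- function(a, b, r) if (a == b) 1 - r else r
  ordered <- function(g) switch(g + 1L,
                                list(c(0L, 0L)),
                                list(c(0L, 1L), c(1L, 0L)),
                                list(c(1L, 1L)))
  confL <- if (is.na(gl)) list(NULL) else ordered(gl)
  confR <- if (is.na(gr)) list(NULL) else ordered(gr)
  out <- numeric(3)
  for (cl in confL) for (cr in confR) {
    w <- 1
    qdist <- vector("list", 2)
    for (gam in 1:2) {
      a <- if (is.null(cl)) NA else cl[gam]
      b <- if (is.null(cr)) NA else cr[gam]
      # per-gamete distribution over allele {0,1} at the query locus
      pq <- c(0.5, 0.5)
      if (!is.na(a)) pq <- c(trans(a, 0L, r1), trans(a, 1L, r1))
      if (!is.na(b)) pq <- pq * c(trans(0L, b, r2), trans(1L, b, r2))
      if (!is.na(a) && !is.na(b)) w <- w * trans(a, b, min(r1 + r2 -
                                                            2 * r1 * r2, 0.5))
      # w uses P(b|a) under no interference: r13 = r1 + r2 - 2 r1 r2
      qdist[[gam]] <- pq
    }
    z1 <- sum(qdist[[1]]); z2 <- sum(qdist[[2]])
    p1 <- qdist[[1]] / z1; p2 <- qdist[[2]] / z2
    contrib <- w * outer(p1, p2)
    out[1] <- out[1] + contrib[1, 1]
    out[2] <- out[2] + contrib[1, 2] + contrib[2, 1]
    out[3] <- out[3] + contrib[2, 2]
  }
  out / sum(out)
}

#' Genotype probabilities at an arbitrary map position
#'
#' For each progeny, computes the conditional distribution over {A, H, B}
#' (F2) or {A, H} (backcross-coded) at a query position from the nearest
#' flanking concrete markers, using no-interference (Haldane) transition
#' probabilities; missing or ambiguous flanks fall back to the nearest
#' concrete markers further out. With no informative flank the prior
#' (1/4, 1/2, 1/4) or (1/2, 1/2) is returned.
#'
#' @param map a `genetic_map`.
#' @param group linkage group id.
#' @param pos_cm query position in cM.
#' @return progeny x genotype probability matrix (rows sum to 1).
#' @export
genotype_probabilities <- function(map, group, pos_cm) {
  pg <- precompute_flanks(map, group)
  f2 <- map$category == "HH"
  t(vapply(seq_len(pg$n_prog), function(j) {
    fl <- flanks_for(pg, j, pos_cm)
    cond_geno_dist(fl$gl, fl$gr, fl$r1, fl$r2, f2)
  }, numeric(if (f2) 3 else 2)))
}

# per-progeny informative-marker index for one linkage group
precompute_flanks <- function(map, group) {
  ii <- which(map$info$group == group)
  if (!length(ii)) stopf("unknown linkage group %s", group)
  sc <- map$scores[ii, , drop = FALSE]
  pos <- map$info$pos_cm[ii]
  f2 <- map$category == "HH"
  conc <- if (f2) CONCRETE_F2 else CONCRETE_BC
  dos <- matrix(match(sc, conc) - 1L, nrow(sc), ncol(sc))
  inf_idx <- lapply(seq_len(ncol(sc)), function(j) which(!is.na(dos[, j])))
  list(pos = pos, dos = dos, inf_idx = inf_idx, n_prog = ncol(sc),
       f2 = f2)
}

flanks_for <- function(pg, j, p) {
  idx <- pg$inf_idx[[j]]
  if (!length(idx)) return(list(gl = NA, gr = NA, r1 = NA, r2 = NA))
  ip <- pg$pos[idx]
  k <- findInterval(p, ip)
  gl <- if (k >= 1) pg$dos[idx[k], j] else NA
  r1 <- if (k >= 1) haldane_rf(p - ip[k]) else NA
  gr <- if (k < length(idx)) pg$dos[idx[k + 1], j] else NA
  r2 <- if (k < length(idx)) haldane_rf(ip[k + 1] - p) else NA
  list(gl = gl, gr = gr, r1 = r1, r2 = r2)
}

# expected additive dosage and dominance indicator at every grid position:
# returns list(x, z) matrices progeny x positions; z is NULL for backcross
expected_dosages <- function(map, group, grid) {
  pg <- precompute_flanks(map, group)
  n <- pg$n_prog
  X <- matrix(0, n, length(grid))
  Z <- if (pg$f2) matrix(0, n, length(grid)) else NULL
  cache <- new.env(hash = TRUE, parent = emptyenv())
  for (j in seq_len(n)) {
    idx <- pg$inf_idx[[j]]
    ip <- pg$pos[idx]
    kk <- findInterval(grid, ip)
    for (g in seq_along(grid)) {
      k <- kk[g]
      gl <- if (k >= 1) pg$dos[idx[k], j] else NA
      gr <- if (k < length(idx)) pg$dos[idx[k + 1], j] else NA
      dl <- if (k >= 1) grid[g] - ip[k] else NA
      dr <- if (k < length(idx)) ip[k + 1] - grid[g] else NA
      key <- paste(gl, gr, round(dl, 6), round(dr, 6), sep = "|")
      pr <- cache[[key]]
      if (is.null(pr)) {
        pr <- cond_geno_dist(gl, gr,
                             if (is.na(dl)) NA else haldane_rf(dl),
                             if (is.na(dr)) NA else haldane_rf(dr),
                             pg$f2)
        cache[[key]] <- pr
      }
      if (pg$f2) {
        X[j, g] <- pr[1] - pr[3]   # +1 for A, -1 for B
        Z[j, g] <- pr[2]
      } else {
        X[j, g] <- pr[1]           # P(A)
      }
    }
  }
  list(x = X, z = Z)
}

# numeric additive coding of marker scores for cofactor regression;
# ambiguous/missing scores imputed at the column mean
marker_numeric <- function(map) {
  f2 <- map$category == "HH"
  sc <- map$scores
  num <- matrix(NA_real_, nrow(sc), ncol(sc))
  num[sc == "A"] <- 1
  num[sc == "H"] <- 0
  if (f2) num[sc == "B"] <- -1
  X <- t(num)
  for (k in seq_len(ncol(X))) {
    mu <- mean(X[, k], na.rm = TRUE)
    X[is.na(X[, k]), k] <- if (is.finite(mu)) mu else 0
  }
  colnames(X) <- map$info$marker_id
  X
}

# forward stepwise cofactor selection: marker columns entering at p < p_enter
select_cofactors <- function(Xm, y, max_cof = 5, p_enter = 0.01) {
  chosen <- integer(0)
  avail <- which(apply(Xm, 2, stats::sd) > 0)
  while (length(chosen) < max_cof && length(avail)) {
    base <- cbind(1, Xm[, chosen, drop = FALSE])
    qb <- qr(base)
    ry <- stats::resid(stats::lm.fit(base, y))
    best_p <- 1; best_j <- NA
    for (j in avail) {
      rx <- stats::resid(stats::lm.fit(base, Xm[, j]))
      sxx <- sum(rx^2)
      if (sxx < 1e-10) next
      bhat <- sum(rx * ry) / sxx
      df <- length(y) - qb$rank - 1
      if (df <= 0) next
      s2 <- (sum(ry^2) - bhat^2 * sxx) / df
      if (s2 <= 0) { pj <- 0 } else {
        tj <- bhat / sqrt(s2 / sxx)
        pj <- 2 * stats::pt(-abs(tj), df)
      }
      if (pj < best_p) { best_p <- pj; best_j <- j }
    }
    if (is.na(best_j) || best_p >= p_enter) break
    chosen <- c(chosen, best_j)
    avail <- setdiff(avail, best_j)
  }
  chosen
}

rss_of <- function(X, Y) {
  # residual sum of squares of each column of Y on design X
  q <- qr(X)
  qty <- qr.qty(q, Y)
  keep <- seq_len(q$rank)
  colSums(Y^2) - colSums(qty[keep, , drop = FALSE]^2)
}

#' Genome scan for QTL by Haley-Knott regression
#'
#' At each grid position (step `walk_speed_cm`) the phenotype is regressed
#' on the expected additive dosage -- plus a dominance indicator for F2
#' (intercross "SF2" model); backcross-coded AH/HA maps use a single
#' effect ("B2" model) -- computed from flanking-marker genotype
#' probabilities. Under CIM, background cofactor markers (forward stepwise,
#' entry p < 0.01, at most `n_cofactors`) are included, dropping any
#' cofactor within `exclusion_window_cm` of the test position;
#' `LOD = (n/2) log10(RSS0/RSS1)` compares the models with and without the
#' QTL terms, and R^2 = 1 - RSS1/RSS0 is reported at the peak of the
#' single-position model.
#'
#' @param map a `genetic_map`.
#' @param phenotype numeric vector aligned with the map's progeny columns.
#' @param cfg a [scan_config()].
#' @return a `qtl_scan`: list with `grid` (data.frame group, pos_cm, lod,
#'   a, d, r2), `peaks` (per-group peak summary with 1-LOD support
#'   interval), `cofactors` (marker ids), `model`, `category`.
#' @export
qtl_scan <- function(map, phenotype, cfg = scan_config()) {
  stopifnot(length(phenotype) == ncol(map$scores))
  y <- as.numeric(phenotype)
  n <- length(y)
  f2 <- map$category == "HH"
  Xm <- marker_numeric(map)
  cof <- integer(0)
  if (cfg$model == "CIM" && cfg$n_cofactors > 0 && stats::sd(y) > 0)
    cof <- select_cofactors(Xm, y, cfg$n_cofactors)
  cof_ids <- colnames(Xm)[cof]
  cof_group <- map$info$group[cof]
  cof_pos <- map$info$pos_cm[cof]

  grids <- list()
  for (grp in unique(map$info$group)) {
    pos <- map$info$pos_cm[map$info$group == grp]
    grid <- seq(0, max(pos), by = cfg$walk_speed_cm)
    ed <- expected_dosages(map, grp, grid)
    lod <- a <- d <- r2 <- numeric(length(grid))
    for (g in seq_along(grid)) {
      active <- cof[!(cof_group == grp &
                        abs(cof_pos - grid[g]) < cfg$exclusion_window_cm)]
      X0 <- cbind(1, Xm[, active, drop = FALSE])
      qtl_terms <- if (f2) cbind(ed$x[, g], ed$z[, g]) else
        cbind(ed$x[, g])
      X1 <- cbind(X0, qtl_terms)
      rss0 <- rss_of(X0, matrix(y))
      rss1 <- rss_of(X1, matrix(y))
      rss1 <- min(rss1, rss0)
      lod[g] <- if (rss1 <= 0 || rss0 <= 0) 0 else
        max(0, n / 2 * log10(rss0 / rss1))
      fit <- stats::lm.fit(X1, y)
      cf <- fit$coefficients
      nq <- ncol(qtl_terms)
      qcoef <- cf[(length(cf) - nq + 1):length(cf)]
      a[g] <- if (is.na(qcoef[1])) 0 else qcoef[1]
      d[g] <- if (f2 && length(qcoef) > 1 && !is.na(qcoef[2])) qcoef[2] else 0
      r2[g] <- if (rss0 <= 0) 0 else 1 - rss1 / rss0
    }
    grids[[grp]] <- data.frame(group = grp, pos_cm = grid, lod = lod,
                               a = a, d = d, r2 = r2,
                               stringsAsFactors = FALSE)
  }
  grid_df <- do.call(rbind, c(grids, list(make.row.names = FALSE)))

  peaks <- do.call(rbind, lapply(split(grid_df, grid_df$group), function(gd) {
    i <- which.max(gd$lod)
    # 1-LOD support interval around the peak (convention for interval ends)
    thr <- gd$lod[i] - 1
    lo <- i; while (lo > 1 && gd$lod[lo - 1] >= thr) lo <- lo - 1
    hi <- i; while (hi < nrow(gd) && gd$lod[hi + 1] >= thr) hi <- hi + 1
    mi <- map$info[map$info$group == gd$group[1], ]
    nearest <- function(p) mi$marker_id[which.min(abs(mi$pos_cm - p))]
    data.frame(group = gd$group[1], pos_cm = gd$pos_cm[i], lod = gd$lod[i],
               a = gd$a[i], d = gd$d[i], r2 = gd$r2[i],
               ci_lo_cm = gd$pos_cm[lo], ci_hi_cm = gd$pos_cm[hi],
               peak_marker = nearest(gd$pos_cm[i]),
               left_marker = nearest(gd$pos_cm[lo]),
               right_marker = nearest(gd$pos_cm[hi]),
               stringsAsFactors = FALSE)
  }))
  rownames(peaks) <- NULL
  structure(list(grid = grid_df, peaks = peaks, cofactors = cof_ids,
                 model = cfg$model, category = map$category),
            class = "qtl_scan")
}

#' @exportS3Method base::print
print.qtl_scan <- function(x, ...) {
  cat(sprintf("qtl_scan (%s, %s): max LOD %.2f\n", x$model, x$category,
              max(x$grid$lod)))
  print(x$peaks[which.max(x$peaks$lod), ])
  invisible(x)
}

#' Permutation LOD significance threshold
#'
#' Permutes the phenotype across progeny `n_permutations` times, rescans
#' the genome for each permutation, and returns the empirical
#' `1 - alpha` quantile of the genome-wide maximum LOD. Cofactors (CIM)
#' are held at the set selected on the observed phenotype. The permuted
#' rescans reuse the fixed per-position design matrices, so the cost is
#' one QR decomposition per position plus matrix products.
#'
#' @param map a `genetic_map`.
#' @param phenotype numeric phenotype vector.
#' @param cfg a [scan_config()] (uses `n_permutations`, `alpha`, `seed`).
#' @return list with `threshold` (LOD at `1 - alpha`) and `max_lod`
#'   (per-permutation genome-wide maxima).
#' @export
permutation_threshold <- function(map, phenotype, cfg = scan_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  y <- as.numeric(phenotype)
  n <- length(y)
  nperm <- cfg$n_permutations
  Y <- vapply(seq_len(nperm), function(i) y[sample.int(n)], numeric(n))
  f2 <- map$category == "HH"
  Xm <- marker_numeric(map)
  cof <- integer(0)
  if (cfg$model == "CIM" && cfg$n_cofactors > 0 && stats::sd(y) > 0)
    cof <- select_cofactors(Xm, y, cfg$n_cofactors)
  cof_group <- map$info$group[cof]
  cof_pos <- map$info$pos_cm[cof]
  maxlod <- rep(0, nperm)
  for (grp in unique(map$info$group)) {
    pos <- map$info$pos_cm[map$info$group == grp]
    grid <- seq(0, max(pos), by = cfg$walk_speed_cm)
    ed <- expected_dosages(map, grp, grid)
    for (g in seq_along(grid)) {
      active <- cof[!(cof_group == grp &
                        abs(cof_pos - grid[g]) < cfg$exclusion_window_cm)]
      X0 <- cbind(1, Xm[, active, drop = FALSE])
      X1 <- if (f2) cbind(X0, ed$x[, g], ed$z[, g]) else
        cbind(X0, ed$x[, g])
      rss0 <- rss_of(X0, Y)
      rss1 <- pmin(rss_of(X1, Y), rss0)
      lod <- ifelse(rss1 <= 0 | rss0 <= 0, 0,
                    pmax(0, n / 2 * log10(rss0 / rss1)))
      maxlod <- pmax(maxlod, lod)
    }
  }
  list(threshold = as.numeric(stats::quantile(maxlod, 1 - cfg$alpha)),
       max_lod = maxlod)
}
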