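# Synthetic-data generation: every input the pipeline consumes, with planted
# truth records, from seeded configuration lists.

#' Configuration for a simulated outbred F1 x F1 -> F2 cross
#'
#' Describes a cross between two heterozygous founders whose F1 progeny are
#' intercrossed to produce an F2 population segregating for founder alleles,
#' the design used for switchgrass upland x lowland mapping populations.
#' Crossovers follow a Poisson count with independent uniform placement
#' (Haldane model, no interference) and inheritance is disomic.
#'
#' @param n_chromosomes number of chromosomes (default 2; scale up to 18 for
#'   a genome-sized simulation).
#' @param chrom_length_cm map length per chromosome in centimorgans. May be 0
#'   for the no-recombination (single-locus) limit; negative lengths are
#'   rejected.
#' @param sites_per_chrom number of variant sites per chromosome, evenly
#'   spaced along the map.
#' @param founder_heterozygosity probability that a founder is heterozygous
#'   at a site. At 0, founder 1 is fixed for allele 0 and founder 2 for
#'   allele 1 at every site, so both F1s are heterozygous everywhere.
#' @param n_progeny number of F2 individuals.
#' @param cm_per_mb scale linking genetic and physical coordinates
#'   (default 1 cM per Mb). Physical positions are assigned deterministically
#'   from cM positions.
#' @param suppressed_region optional list(chrom=, start_cm=, end_cm=,
#'   bp_factor=) emulating a proximal low-recombination region: physical
#'   spacing within the region is inflated by `bp_factor` while genetic
#'   spacing is unchanged.
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return a `cross_config` list.
#' @export
cross_config <- function(n_chromosomes = 2, chrom_length_cm = 100,
                         sites_per_chrom = 100, founder_heterozygosity = 0,
                         n_progeny = 200, cm_per_mb = 1,
                         suppressed_region = NULL, seed = NULL) {
  assert_count(n_chromosomes, "n_chromosomes")
  assert_count(sites_per_chrom, "sites_per_chrom")
  assert_count(n_progeny, "n_progeny")
  if (!is.numeric(chrom_length_cm) || any(chrom_length_cm < 0))
    stopf("chrom_length_cm must be non-negative")
  assert_prob(founder_heterozygosity, "founder_heterozygosity")
  if (cm_per_mb <= 0) stopf("cm_per_mb must be positive")
  chrom_length_cm <- rep_len(chrom_length_cm, n_chromosomes)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_cm = chrom_length_cm,
                 sites_per_chrom = as.integer(sites_per_chrom),
                 founder_heterozygosity = founder_heterozygosity,
                 n_progeny = as.integer(n_progeny),
                 cm_per_mb = cm_per_mb,
                 suppressed_region = suppressed_region,
                 seed = seed),
            class = "cross_config")
}

# one gamete from a phased diploid: hap1/hap2 are allele vectors over sites
# at positions pos_cm on a chromosome of length len_cm
sim_gamete <- function(hap1, hap2, pos_cm, len_cm) {
  n_co <- stats::rpois(1L, len_cm / 100)
  phase <- stats::rbinom(1L, 1L, 0.5)  # 0 -> start on hap1
  if (n_co == 0L || len_cm == 0) {
    return(if (phase == 0L) hap1 else hap2)
  }
  xo <- sort(stats::runif(n_co, 0, len_cm))
  # phase at a site flips once per crossover to its left
  flips <- findInterval(pos_cm, xo)
  use2 <- (phase + flips) %% 2L == 1L
  out <- hap1
  out[use2] <- hap2[use2]
  out
}

#' Simulate an outbred F1 x F1 -> F2 cross
#'
#' Generates founder haplotypes, two F1 individuals, and an F2 population.
#' Alleles are labelled 0 (founder-1 default allele) and 1 (founder-2
#' default allele); the true F2 genotype at each site is the alt-allele
#' dosage 0/1/2, equivalently A/H/B relative to the founder labels.
#'
#' @param cfg a [cross_config()].
#' @return list with elements `sites` (data.frame: site_id, chrom, pos_cm,
#'   pos_bp), `founders` (list of two haplotype-pair matrices), `f1` (list of
#'   two phased F1 individuals, each a list(hap_m, hap_p)), `geno`
#'   (sites x progeny integer matrix of alt dosages), `f1_geno` (sites x 2
#'   dosage matrix), and `phase` (list of per-progeny gamete origin records).
#' @export
simulate_cross <- function(cfg) {
  stopifnot(inherits(cfg, "cross_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  m <- cfg$sites_per_chrom
  sites_list <- vector("list", cfg$n_chromosomes)
  for (cc in seq_len(cfg$n_chromosomes)) {
    len <- cfg$chrom_length_cm[cc]
    pos_cm <- if (m == 1L) 0 else seq(0, len, length.out = m)
    pos_bp <- cm_to_bp(pos_cm, cfg, cc)
    sites_list[[cc]] <- data.frame(
      site_id = sprintf("S%02d_%04d", cc, seq_len(m)),
      chrom = sprintf("Chr%02d", cc),
      pos_cm = pos_cm, pos_bp = pos_bp,
      stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, sites_list)
  n_sites <- nrow(sites)

  # founder haplotypes: default allele 0 for founder 1, 1 for founder 2;
  # a founder is heterozygous at a site with prob founder_heterozygosity
  founder_haps <- function(default_allele) {
    het <- stats::runif(n_sites) < cfg$founder_heterozygosity
    h1 <- rep(default_allele, n_sites)
    h2 <- rep(default_allele, n_sites)
    other <- 1L - default_allele
    swap <- stats::rbinom(sum(het), 1L, 0.5) == 1L
    h1[het][swap] <- other
    h2[het][!swap] <- other
    list(h1 = h1, h2 = h2)
  }
  fd1 <- founder_haps(0L)
  fd2 <- founder_haps(1L)

  chrom_idx <- split(seq_len(n_sites), sites$chrom)
  gamete_of <- function(ind) {
    g <- integer(n_sites)
    for (cc in seq_len(cfg$n_chromosomes)) {
      ii <- chrom_idx[[sprintf("Chr%02d", cc)]]
      g[ii] <- sim_gamete(ind$h1[ii], ind$h2[ii], sites$pos_cm[ii],
                          cfg$chrom_length_cm[cc])
    }
    g
  }

  # F1s: maternal gamete from founder 1, paternal from founder 2
  f1a <- list(h1 = gamete_of(fd1), h2 = gamete_of(fd2))
  f1b <- list(h1 = gamete_of(fd1), h2 = gamete_of(fd2))

  geno <- matrix(0L, n_sites, cfg$n_progeny,
                 dimnames = list(sites$site_id,
                                 sprintf("F2_%03d", seq_len(cfg$n_progeny))))
  phase <- vector("list", cfg$n_progeny)
  for (p in seq_len(cfg$n_progeny)) {
    gm <- gamete_of(f1a)
    gp <- gamete_of(f1b)
    geno[, p] <- gm + gp
    phase[[p]] <- cbind(maternal = gm, paternal = gp)
  }
  f1_geno <- cbind(F1a = f1a$h1 + f1a$h2, F1b = f1b$h1 + f1b$h2)
  rownames(f1_geno) <- sites$site_id
  list(sites = sites, founders = list(fd1, fd2), f1 = list(f1a, f1b),
       f1_geno = f1_geno, geno = geno, phase = phase, config = cfg)
}

# deterministic cM -> bp under the configured scale, with optional
# suppressed-recombination inflation
cm_to_bp <- function(pos_cm, cfg, chrom_i) {
  bp <- pos_cm * 1e6 / cfg$cm_per_mb
  sr <- cfg$suppressed_region
  if (!is.null(sr) && identical(sr$chrom, sprintf("Chr%02d", chrom_i))) {
    lo <- sr$start_cm * 1e6 / cfg$cm_per_mb
    span <- (pmin(pos_cm, sr$end_cm) - pmin(pos_cm, sr$start_cm)) *
      1e6 / cfg$cm_per_mb
    bp <- bp + span * (sr$bp_factor - 1)
  }
  as.integer(round(bp)) + 1L
}

#' GBS read-depth configuration
#'
#' @param mean_depth mean per-sample per-site read depth (negative binomial).
#' @param depth_dispersion negative-binomial size parameter; depth variance
#'   is `mu + mu^2/size`.
#' @param error_rate per-read allele miscall probability.
#' @param seed integer RNG seed.
#' @return a `gbs_config` list.
#' @export
gbs_config <- function(mean_depth = 20, depth_dispersion = 5,
                       error_rate = 0.005, seed = NULL) {
  if (mean_depth < 0) stopf("mean_depth must be non-negative")
  if (error_rate < 0 || error_rate >= 0.5)
    stopf("error_rate must be in [0, 0.5)")
  if (depth_dispersion <= 0) stopf("depth_dispersion must be positive")
  structure(list(mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 error_rate = error_rate, seed = seed),
            class = "gbs_config")
}

#' Simulate GBS allele read counts from true genotypes
#'
#' Per sample and site, total depth is negative binomial and the reference
#' (allele-0) read count is binomial with success probability `1 - e`, `0.5`
#' or `e` for the allele-0 homozygote, heterozygote and allele-1 homozygote,
#' where `e` is the per-read miscall rate. A site-level quality-by-depth
#' (QD) score is emitted as a saturating deterministic function of mean site
#' depth plus Gaussian noise, truncated at 0: only its threshold behaviour
#' matters downstream.
#'
#' @param geno sites x samples integer matrix of alt-allele dosages (0/1/2).
#' @param cfg a [gbs_config()].
#' @return list with `ref` and `alt` count matrices (sites x samples) and
#'   `qd` numeric vector per site.
#' @export
simulate_reads <- function(geno, cfg) {
  stopifnot(inherits(cfg, "gbs_config"), is.matrix(geno))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- length(geno)
  depth <- if (cfg$mean_depth == 0) integer(n) else
    stats::rnbinom(n, size = cfg$depth_dispersion, mu = cfg$mean_depth)
  p_ref <- c(1 - cfg$error_rate, 0.5, cfg$error_rate)[geno + 1L]
  ref <- stats::rbinom(n, depth, p_ref)
  ref <- matrix(ref, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  alt <- matrix(depth, nrow(geno), ncol(geno), dimnames = dimnames(geno)) - ref
  mean_site_depth <- rowMeans(ref + alt)
  qd <- pmax(0, 30 * mean_site_depth / (mean_site_depth + 5) +
               stats::rnorm(nrow(geno), 0, 2))
  list(ref = ref, alt = alt, qd = qd)
}

#' Planted-QTL description
#'
#' Parameters of a single additive/dominance QTL used to simulate a
#' phenotype: `y = mu + a*x + d*z + N(0, sigma^2)` with `x = +1/0/-1` for
#' the A/H/B genotype at the site nearest the QTL position and `z = 1` for
#' heterozygotes.
#'
#' @param chrom chromosome id (as in the simulated cross, e.g. "Chr01").
#' @param pos_cm QTL position in centimorgans.
#' @param a additive effect in trait units.
#' @param d dominance effect in trait units.
#' @param sigma residual standard deviation (>= 0).
#' @param mu baseline trait value.
#' @param seed integer RNG seed.
#' @return a `qtl_truth` list.
#' @export
qtl_truth <- function(chrom = "Chr01", pos_cm = 50, a = 1, d = 0,
                      sigma = 1, mu = 0, seed = NULL) {
  if (sigma < 0) stopf("sigma must be non-negative")
  structure(list(chrom = chrom, pos_cm = pos_cm, a = a, d = d,
                 sigma = sigma, mu = mu, seed = seed),
            class = "qtl_truth")
}

#' Residual SD giving a target QTL heritability
#'
#' For an additive QTL at 1:2:1 genotype frequencies, `var(x) = 1/2` and
#' `var(z) = 1/4`, so the residual variance achieving model R^2 = `r2` is
#' `(a^2/2 + d^2/4) * (1 - r2) / r2` (the additive/dominance codes are
#' uncorrelated at 1:2:1).
#'
#' @param a,d QTL effects.
#' @param r2 target fraction of phenotypic variance explained, in (0, 1).
#' @return residual standard deviation.
#' @export
sigma_for_r2 <- function(a, d = 0, r2) {
  if (r2 <= 0 || r2 >= 1) stopf("r2 must be in (0, 1)")
  vg <- a^2 / 2 + d^2 / 4
  sqrt(vg * (1 - r2) / r2)
}

#' Simulate a phenotype from true genotypes and a planted QTL
#'
#' @param cross result of [simulate_cross()].
#' @param truth a [qtl_truth()].
#' @return numeric phenotype vector, one value per F2 individual.
#' @export
simulate_phenotype <- function(cross, truth) {
  stopifnot(inherits(truth, "qtl_truth"))
  if (!is.null(truth$seed)) set.seed(truth$seed)
  on_chr <- cross$sites$chrom == truth$chrom
  if (!any(on_chr)) stopf("QTL chromosome %s not in cross", truth$chrom)
  pos <- cross$sites$pos_cm[on_chr]
  if (truth$pos_cm < min(pos) - 1e-9 || truth$pos_cm > max(pos) + 1e-9)
    stopf("QTL position outside chromosome span")
  site <- which(on_chr)[which.min(abs(pos - truth$pos_cm))]
  g <- cross$geno[site, ]
  x <- c(1, 0, -1)[g + 1L]   # +1 for A (dosage 0), -1 for B
  z <- as.numeric(g == 1L)
  truth$mu + truth$a * x + truth$d * z +
    stats::rnorm(length(g), 0, truth$sigma)
}

#' Accession-panel configuration with planted deletion blocks
#'
#' Emulates a diversity panel of lowland and upland accessions genotyped at
#' nucleotide-polymorphism (NP) sites, where ecotype-specific chromosomal
#' deletions manifest as blocks of missing calls in carrier accessions.
#'
#' @param n_lowland,n_upland accession counts per ecotype.
#' @param deletion_blocks data.frame with columns chrom, start_bp, end_bp,
#'   ecotype, carrier_frequency; may be empty/NULL. Blocks overlapping on
#'   the same ecotype are rejected.
#' @param missing_rate_in_deletion per-NP missing probability for a carrier
#'   inside its block.
#' @param background_missing_rate per-NP missing probability elsewhere.
#' @param seed integer RNG seed.
#' @return a `panel_config` list.
#' @export
panel_config <- function(n_lowland = 95, n_upland = 65,
                         deletion_blocks = NULL,
                         missing_rate_in_deletion = 0.9,
                         background_missing_rate = 0.05, seed = NULL) {
  assert_count(n_lowland, "n_lowland"); assert_count(n_upland, "n_upland")
  assert_prob(missing_rate_in_deletion, "missing_rate_in_deletion")
  assert_prob(background_missing_rate, "background_missing_rate")
  if (!is.null(deletion_blocks) && nrow(deletion_blocks)) {
    assert_prob(deletion_blocks$carrier_frequency, "carrier_frequency")
    sp <- split(deletion_blocks, deletion_blocks[, c("ecotype", "chrom")],
                drop = TRUE)
    for (blk in sp) {
      blk <- blk[order(blk$start_bp), ]
      if (nrow(blk) > 1 && any(blk$start_bp[-1] <= blk$end_bp[-nrow(blk)]))
        stopf("overlapping deletion blocks on the same ecotype")
    }
  }
  structure(list(n_lowland = as.integer(n_lowland),
                 n_upland = as.integer(n_upland),
                 deletion_blocks = deletion_blocks,
                 missing_rate_in_deletion = missing_rate_in_deletion,
                 background_missing_rate = background_missing_rate,
                 seed = seed),
            class = "panel_config")
}

#' Simulate an accession-panel genotype matrix with deletion blocks
#'
#' @param cfg a [panel_config()].
#' @param sites data.frame with columns chrom and pos_bp giving NP sites.
#' @return list with `geno` (sites x accessions matrix of 0/1/2 dosages,
#'   NA = missing call), `ecotype` (factor per accession), and `truth`
#'   (carrier assignment per block).
#' @export
simulate_panel <- function(cfg, sites) {
  stopifnot(inherits(cfg, "panel_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_acc <- cfg$n_lowland + cfg$n_upland
  ecotype <- factor(rep(c("lowland", "upland"),
                        c(cfg$n_lowland, cfg$n_upland)))
  acc <- sprintf("%s_%03d", ifelse(ecotype == "lowland", "LOW", "UPL"),
                 unlist(lapply(c(cfg$n_lowland, cfg$n_upland), seq_len)))
  n_sites <- nrow(sites)
  maf <- stats::runif(n_sites, 0.05, 0.5)
  geno <- matrix(stats::rbinom(n_sites * n_acc, 2L, rep(maf, n_acc)),
                 n_sites, n_acc,
                 dimnames = list(sprintf("NP_%05d", seq_len(n_sites)), acc))
  miss <- matrix(stats::runif(n_sites * n_acc) <
                   cfg$background_missing_rate, n_sites, n_acc)
  carriers <- list()
  blocks <- cfg$deletion_blocks
  if (!is.null(blocks) && nrow(blocks)) {
    for (b in seq_len(nrow(blocks))) {
      in_blk <- sites$chrom == blocks$chrom[b] &
        sites$pos_bp >= blocks$start_bp[b] & sites$pos_bp <= blocks$end_bp[b]
      aff <- which(ecotype == blocks$ecotype[b])
      is_car <- stats::runif(length(aff)) < blocks$carrier_frequency[b]
      carriers[[b]] <- acc[aff][is_car]
      for (j in aff[is_car]) {
        miss[in_blk, j] <- stats::runif(sum(in_blk)) <
          cfg$missing_rate_in_deletion
      }
    }
  }
  geno[miss] <- NA_integer_
  list(geno = geno, ecotype = ecotype, sites = sites,
       truth = list(blocks = blocks, carriers = carriers))
}

#' Simulate gene models and candidate-gene evidence tables
#'
#' Places genes inside and outside a physical interval and emits the four
#' evidence tables the candidate-prioritization module consumes:
#' differential expression (gene, log2fc, padj), variant effects (gene,
#' impact, parental genotypes), a GO term map, and parental CDS coverage.
#' Planted full candidates carry all four lines of evidence (padj < 0.01,
#' |log2FC| > 1, HIGH/MODERATE impact with parents homozygous for different
#' alleles, a wax-related GO term, and near-zero coverage in one parent);
#' background classes carry the configured subsets.
#'
#' @param interval list(chrom=, start_bp=, end_bp=).
#' @param n_background number of interval genes with no planted evidence.
#' @param n_full number of planted full-evidence candidates.
#' @param n_impact_only,n_de_only,n_both extra interval genes planted with
#'   impact evidence only, DE evidence only, or both (without GO/absence).
#' @param n_outside genes placed outside the interval (never candidates).
#' @param seed integer RNG seed.
#' @return list with `genes` (data.frame gene model table), `de`, `effects`,
#'   `go`, `coverage` (evidence tables) and `truth` (planted gene ids per
#'   class).
#' @export
simulate_gene_evidence <- function(interval, n_background = 50, n_full = 3,
                                   n_impact_only = 0, n_de_only = 0,
                                   n_both = 0, n_outside = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_in <- n_background + n_full + n_impact_only + n_de_only + n_both
  classes <- rep(c("background", "full", "impact", "de", "both"),
                 c(n_background, n_full, n_impact_only, n_de_only, n_both))
  classes <- sample(classes)
  width <- 3000L
  span <- interval$end_bp - interval$start_bp - width
  start_in <- sort(interval$start_bp +
                     floor(stats::runif(n_in, 0, max(1, span))))
  start_out <- interval$end_bp + 50000L +
    sort(floor(stats::runif(n_outside, 0, 1e6)))
  genes <- data.frame(
    gene_id = sprintf("Gene%04d", seq_len(n_in + n_outside)),
    chrom = interval$chrom,
    start = c(start_in, start_out),
    end = c(start_in, start_out) + width,
    strand = sample(c("+", "-"), n_in + n_outside, replace = TRUE),
    stringsAsFactors = FALSE)
  gid_in <- genes$gene_id[seq_len(n_in)]

  has_de <- classes %in% c("full", "de", "both")
  has_imp <- classes %in% c("full", "impact", "both")
  # DE rows for every gene; only planted ones pass padj/fold-change cuts
  de <- data.frame(
    gene = genes$gene_id,
    log2fc = stats::rnorm(n_in + n_outside, 0, 0.3),
    padj = stats::runif(n_in + n_outside, 0.2, 1),
    stringsAsFactors = FALSE)
  planted_de <- c(gid_in[has_de])
  de$log2fc[de$gene %in% planted_de] <-
    sample(c(-1, 1), length(planted_de), TRUE) *
    stats::runif(length(planted_de), 2, 10)
  de$padj[de$gene %in% planted_de] <- 10^stats::runif(length(planted_de), -15, -3)

  eff_rows <- function(gene, impact) {
    data.frame(gene = gene, impact = rep_len(impact, length(gene)),
               parent1_gt = rep_len("0/0", length(gene)),
               parent2_gt = rep_len("1/1", length(gene)),
               stringsAsFactors = FALSE)
  }
  effects <- rbind(
    eff_rows(gid_in[has_imp], sample(c("HIGH", "MODERATE"),
                                     sum(has_imp), TRUE)),
    # background LOW-impact rows and het-parent rows never confer evidence
    data.frame(gene = sample(genes$gene_id, 10, TRUE), impact = "LOW",
               parent1_gt = "0/0", parent2_gt = "1/1",
               stringsAsFactors = FALSE),
    data.frame(gene = sample(genes$gene_id, 5, TRUE), impact = "HIGH",
               parent1_gt = "0/1", parent2_gt = "1/1",
               stringsAsFactors = FALSE))

  go <- data.frame(gene = genes$gene_id,
                   go_name = "cellular process",
                   stringsAsFactors = FALSE)
  full_ids <- gid_in[classes == "full"]
  go$go_name[go$gene %in% full_ids] <-
    sample(c("fatty acid biosynthetic process", "lipid metabolic process"),
           length(full_ids), TRUE)

  coverage <- data.frame(gene = genes$gene_id,
                         parent1_cov = stats::runif(n_in + n_outside, 5, 30),
                         parent2_cov = stats::runif(n_in + n_outside, 5, 30),
                         stringsAsFactors = FALSE)
  coverage$parent2_cov[coverage$gene %in% full_ids] <-
    stats::runif(length(full_ids), 0, 0.5)

  list(genes = genes, de = de, effects = effects, go = go,
       coverage = coverage,
       truth = list(full = full_ids,
                    de_class = gid_in[has_de],
                    impact_class = gid_in[has_imp]))
}

#' Plant a collinear two-chromosome gene layout with paralogs
#'
#' Builds gene models on two homoeologous chromosomes where a configurable
#' fraction of chromosome-A genes retain a collinear partner at the same
#' rank on chromosome B, plus dispersed paralogs elsewhere.
#'
#' @param n_genes genes per chromosome.
#' @param collinear_fraction fraction of A genes with a collinear B partner.
#' @param n_paralogs number of A genes additionally given a dispersed
#'   paralog on a third chromosome.
#' @param gene_spacing_bp physical spacing between gene starts.
#' @param retained_by_region optional function(rank) -> retention
#'   probability, overriding `collinear_fraction` per gene (used to plant
#'   proximal/distal retention contrasts).
#' @param seed integer RNG seed.
#' @return list with `genes` (gene model table for chromosomes A, B and P),
#'   and `truth` (`ortholog_pairs`, `paralog_pairs` data.frames).
#' @export
simulate_synteny_truth <- function(n_genes = 100, collinear_fraction = 0.8,
                                   n_paralogs = 10, gene_spacing_bp = 20000L,
                                   retained_by_region = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mk <- function(chrom, n) data.frame(
    gene_id = sprintf("%s.G%04d", chrom, seq_len(n)),
    chrom = chrom,
    start = seq_len(n) * gene_spacing_bp,
    end = seq_len(n) * gene_spacing_bp + 2000L,
    strand = "+", stringsAsFactors = FALSE)
  ga <- mk("ChrA", n_genes); gb <- mk("ChrB", n_genes)
  gp <- mk("ChrP", max(n_paralogs, 1L))
  p_ret <- if (is.null(retained_by_region)) rep(collinear_fraction, n_genes)
           else vapply(seq_len(n_genes), retained_by_region, numeric(1))
  retained <- stats::runif(n_genes) < p_ret
  ortho <- data.frame(gene_a = ga$gene_id[retained],
                      gene_b = gb$gene_id[retained],
                      stringsAsFactors = FALSE)
  par_idx <- sample(seq_len(n_genes), min(n_paralogs, n_genes))
  paralog <- if (n_paralogs > 0) data.frame(
    gene = ga$gene_id[par_idx],
    paralog = gp$gene_id[seq_along(par_idx)],
    percent_similarity = stats::runif(length(par_idx), 85, 99),
    coverage_fraction = stats::runif(length(par_idx), 0.75, 1),
    stringsAsFactors = FALSE)
  else data.frame(gene = character(), paralog = character(),
                  percent_similarity = numeric(),
                  coverage_fraction = numeric())
  list(genes = rbind(ga, gb, gp),
       truth = list(ortholog_pairs = ortho, paralog_pairs = paralog))
}

#' Emit a protein hit table from planted synteny truth
#'
#' Collinear ortholog pairs appear as strong reciprocal hits
#' (e-value <= 1e-10, high similarity, near-full coverage); planted
#' paralogs appear with their configured similarity and coverage; optional
#' noise hits have e-value above the downstream threshold. Self hits can be
#' included to exercise their exclusion downstream.
#'
#' @param st result of [simulate_synteny_truth()].
#' @param query_length protein length assumed for every query, residues.
#' @param n_noise number of random weak hits (e-value > 1e-5).
#' @param include_self_hits also emit an exact self hit for every gene.
#' @param seed integer RNG seed.
#' @return data.frame with columns query, subject, pident, psim, alnlen,
#'   evalue, qlen (BLAST outfmt-6-like plus query length and % similarity).
#' @export
simulate_hit_table <- function(st, query_length = 400L, n_noise = 0,
                               include_self_hits = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ortho <- st$truth$ortholog_pairs
  par <- st$truth$paralog_pairs
  hit <- function(q, s, pid, psim, aln, ev) data.frame(
    query = q, subject = s, pident = pid, psim = psim,
    alnlen = as.integer(aln), evalue = ev, qlen = query_length,
    stringsAsFactors = FALSE)
  out <- list()
  if (nrow(ortho)) {
    psim <- stats::runif(nrow(ortho), 90, 99)
    ev <- 10^stats::runif(nrow(ortho), -180, -20)
    aln <- round(query_length * stats::runif(nrow(ortho), 0.9, 1))
    out$fwd <- hit(ortho$gene_a, ortho$gene_b, psim - 3, psim, aln, ev)
    out$rev <- hit(ortho$gene_b, ortho$gene_a, psim - 3, psim, aln, ev)
  }
  if (nrow(par)) {
    out$par <- hit(par$gene, par$paralog,
                   par$percent_similarity - 3, par$percent_similarity,
                   round(query_length * par$coverage_fraction),
                   10^stats::runif(nrow(par), -60, -8))
  }
  genes <- st$genes$gene_id
  if (n_noise > 0) {
    q <- sample(genes, n_noise, TRUE)
    s <- sample(genes, n_noise, TRUE)
    keep <- q != s
    out$noise <- hit(q[keep], s[keep],
                     stats::runif(sum(keep), 20, 40),
                     stats::runif(sum(keep), 30, 50),
                     round(query_length * stats::runif(sum(keep), 0.1, 0.4)),
                     10^stats::runif(sum(keep), -4, 1))
  }
  if (include_self_hits) {
    out$self <- hit(genes, genes, 100, 100, query_length, 0)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
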