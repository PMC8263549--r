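# Synthetic cross, read, phenotype, panel and evidence generators

test_that("identical seeds give bit-identical crosses, different seeds differ", {
  cc <- cross_config(sites_per_chrom = 30, n_progeny = 40, seed = 7)
  a <- simulate_cross(cc)
  b <- simulate_cross(cc)
  expect_identical(a$geno, b$geno)
  expect_identical(a$f1_geno, b$f1_geno)
  cc2 <- cross_config(sites_per_chrom = 30, n_progeny = 40, seed = 8)
  expect_false(identical(simulate_cross(cc2)$geno, a$geno))
})

test_that("fixed opposite founders force heterozygous F1s and 1:2:1 F2", {
  cc <- cross_config(n_chromosomes = 1, chrom_length_cm = 50,
                     sites_per_chrom = 3, founder_heterozygosity = 0,
                     n_progeny = 10000, seed = 21)
  cr <- simulate_cross(cc)
  expect_true(all(cr$f1_geno == 1L))
  for (i in seq_len(nrow(cr$geno))) {
    tab <- tabulate(cr$geno[i, ] + 1L, 3)
    p <- stats::chisq.test(tab, p = c(1, 2, 1) / 4)$p.value
    expect_gt(p, 0.001)
  }
})

test_that("zero map length gives whole-chromosome single-phase gametes", {
  cc <- cross_config(n_chromosomes = 1, chrom_length_cm = 0,
                     sites_per_chrom = 20, n_progeny = 30, seed = 3)
  cr <- simulate_cross(cc)
  for (p in seq_along(cr$phase)) {
    gm <- cr$phase[[p]][, "maternal"]
    expect_true(all(gm == gm[1]))
  }
  expect_error(cross_config(chrom_length_cm = -5), "non-negative")
})

test_that("two-point recombinant fraction matches the Haldane closed form", {
  # 10,000 gamete pairs at two loci 20 cM apart; r = (1 - exp(-0.4))/2
  cc <- cross_config(n_chromosomes = 1, chrom_length_cm = 20,
                     sites_per_chrom = 2, n_progeny = 10000, seed = 99)
  cr <- simulate_cross(cc)
  r_true <- (1 - exp(-2 * 0.2)) / 2
  rec <- vapply(cr$phase, function(ph)
    c(ph[1, "maternal"] != ph[2, "maternal"],
      ph[1, "paternal"] != ph[2, "paternal"]), logical(2))
  r_hat <- mean(rec)
  se <- sqrt(r_true * (1 - r_true) / (2 * 10000))
  expect_lt(abs(r_hat - r_true), 3 * se)
})

test_that("Haldane recombinant fractions match across a range of distances", {
  set.seed(5)
  for (d_cm in c(1, 5, 10, 20, 30, 40, 60, 80, 100, 150)) {
    n <- 4000
    cc <- cross_config(n_chromosomes = 1, chrom_length_cm = d_cm,
                       sites_per_chrom = 2, n_progeny = n,
                       seed = 500 + d_cm)
    cr <- simulate_cross(cc)
    rec <- vapply(cr$phase, function(ph)
      c(ph[1, "maternal"] != ph[2, "maternal"],
        ph[1, "paternal"] != ph[2, "paternal"]), logical(2))
    r_true <- (1 - exp(-2 * d_cm / 100)) / 2
    se <- sqrt(r_true * (1 - r_true) / (2 * n))
    expect_lt(abs(mean(rec) - r_true), 3 * se)
  }
})

test_that("read simulation respects depth, error and degenerate settings", {
  g <- matrix(1L, 1, 1000)  # heterozygote
  rd <- simulate_reads(g, gbs_config(mean_depth = 10, error_rate = 0,
                                     seed = 1))
  expect_true(all(rd$ref + rd$alt >= 0))
  expect_equal(mean(rd$ref / pmax(rd$ref + rd$alt, 1)), 0.5,
               tolerance = 0.05)
  # zero depth: all counts zero, downstream scores all missing
  rd0 <- simulate_reads(g, gbs_config(mean_depth = 0, seed = 1))
  expect_true(all(rd0$ref == 0 & rd0$alt == 0))
  expect_true(all(score_matrix(rd0$ref, rd0$alt) == "-"))
  # homozygote minor-allele read fraction has binomial mean error_rate
  gh <- matrix(0L, 1, 10000)
  rdh <- simulate_reads(gh, gbs_config(mean_depth = 30, error_rate = 0.005,
                                       seed = 2))
  tot <- sum(rdh$ref + rdh$alt)
  frac <- sum(rdh$alt) / tot
  se <- sqrt(0.005 * 0.995 / tot)
  expect_lt(abs(frac - 0.005), 3 * se)
  expect_true(all(rd$qd >= 0))
})

test_that("phenotype follows the additive-dominance model", {
  cc <- cross_config(n_chromosomes = 1, chrom_length_cm = 50,
                     sites_per_chrom = 11, n_progeny = 5000, seed = 31)
  cr <- simulate_cross(cc)
  tr0 <- qtl_truth(chrom = "Chr01", pos_cm = 25, a = 1, d = 0, sigma = 0,
                   mu = 10)
  y <- simulate_phenotype(cr, tr0)
  expect_setequal(unique(y), c(11, 10, 9))
  site <- which.min(abs(cr$sites$pos_cm - 25))
  expect_true(all(y[cr$geno[site, ] == 0L] == 11))
  expect_true(all(y[cr$geno[site, ] == 2L] == 9))

  # variance decomposition against the brute-force 1:2:1 oracle
  a <- 1.3; d <- 0.6; s <- 0.8
  tr <- qtl_truth(chrom = "Chr01", pos_cm = 25, a = a, d = d, sigma = s,
                  seed = 32)
  y2 <- simulate_phenotype(cr, tr)
  px <- c(A = 0.25, H = 0.5, B = 0.25)
  xv <- c(1, 0, -1); zv <- c(0, 1, 0)
  ex <- sum(px * xv); ez <- sum(px * zv)
  var_o <- sum(px * (a * xv + d * zv)^2) - (a * ex + d * ez)^2 + s^2
  expect_equal(stats::var(y2), var_o, tolerance = 0.08)
})

test_that("sigma_for_r2 solves the 1:2:1 variance algebra", {
  expect_equal(sigma_for_r2(1, 0, 0.30)^2, 0.5 * (0.70 / 0.30))
  # check by simulation: realized R^2 of the true-genotype model
  cc <- cross_config(n_chromosomes = 1, chrom_length_cm = 10,
                     sites_per_chrom = 3, n_progeny = 8000, seed = 41)
  cr <- simulate_cross(cc)
  tr <- qtl_truth(chrom = "Chr01", pos_cm = 5, a = 1, d = 0,
                  sigma = sigma_for_r2(1, 0, 0.30), seed = 42)
  y <- simulate_phenotype(cr, tr)
  site <- which.min(abs(cr$sites$pos_cm - 5))
  x <- c(1, 0, -1)[cr$geno[site, ] + 1L]
  expect_equal(summary(stats::lm(y ~ x))$r.squared, 0.30, tolerance = 0.03)
})

test_that("panel deletion blocks drive missingness as configured", {
  sites <- data.frame(chrom = "Chr07K",
                      pos_bp = seq(5000, 995000, by = 10000))
  blocks <- data.frame(chrom = "Chr07K", start_bp = 200000, end_bp = 400000,
                       ecotype = "upland", carrier_frequency = 1,
                       stringsAsFactors = FALSE)
  cfg <- panel_config(n_lowland = 20, n_upland = 15,
                      deletion_blocks = blocks,
                      missing_rate_in_deletion = 1,
                      background_missing_rate = 0, seed = 11)
  pan <- simulate_panel(cfg, sites)
  inside <- sites$pos_bp >= 2e5 & sites$pos_bp <= 4e5
  upl <- pan$ecotype == "upland"
  expect_true(all(is.na(pan$geno[inside, upl])))
  expect_true(all(!is.na(pan$geno[!inside, ])))
  expect_true(all(!is.na(pan$geno[, !upl])))

  # overlapping blocks on one ecotype are rejected
  bad <- rbind(blocks, data.frame(chrom = "Chr07K", start_bp = 300000,
                                  end_bp = 500000, ecotype = "upland",
                                  carrier_frequency = 1))
  expect_error(panel_config(deletion_blocks = bad), "overlapping")
})

test_that("partial-carrier missingness matches the binomial-tail oracle", {
  n_upl <- 50; cf <- 0.6; mr <- 0.9
  sites <- data.frame(chrom = "Chr07K", pos_bp = seq_len(2000) * 100)
  blocks <- data.frame(chrom = "Chr07K", start_bp = 1, end_bp = 200001,
                       ecotype = "upland", carrier_frequency = cf,
                       stringsAsFactors = FALSE)
  cfg <- panel_config(n_lowland = 10, n_upland = n_upl,
                      deletion_blocks = blocks,
                      missing_rate_in_deletion = mr,
                      background_missing_rate = 0, seed = 13)
  pan <- simulate_panel(cfg, sites)
  upl <- pan$ecotype == "upland"
  miss_frac <- rowMeans(is.na(pan$geno[, upl]))
  # conditional on the realized carrier count
  n_car <- sum(colnames(pan$geno)[upl] %in% pan$truth$carriers[[1]])
  expect_equal(mean(miss_frac), n_car / n_upl * mr, tolerance = 0.05)
  # fraction of NPs missing in >= 50% of uplands vs exact binomial tail
  p_tail <- stats::pbinom(ceiling(n_upl / 2) - 1, n_car, mr,
                          lower.tail = FALSE)
  obs <- mean(miss_frac >= 0.5)
  se <- sqrt(max(p_tail * (1 - p_tail), 1e-6) / 2000)
  expect_lt(abs(obs - p_tail), max(3 * se, 0.02))
})

test_that("gene-evidence generator plants exactly the configured classes", {
  int <- list(chrom = "Chr07K", start_bp = 1, end_bp = 31e6)
  ev <- simulate_gene_evidence(int, n_background = 500, n_full = 3,
                               seed = 17)
  expect_length(ev$truth$full, 3)
  expect_true(all(ev$de$padj[ev$de$gene %in% ev$truth$full] < 0.01))
  expect_true(all(abs(ev$de$log2fc[ev$de$gene %in% ev$truth$full]) > 1))
  # a background gene with padj 0.5 carries no DE evidence
  bg <- setdiff(ev$genes$gene_id, ev$truth$de_class)[1]
  expect_gt(ev$de$padj[ev$de$gene == bg], 0.01)
})

test_that("hit-table generator emits reciprocal ortholog hits and self hits", {
  st <- simulate_synteny_truth(n_genes = 30, collinear_fraction = 1,
                               n_paralogs = 2, seed = 19)
  ht <- simulate_hit_table(st, include_self_hits = TRUE, seed = 20)
  op <- st$truth$ortholog_pairs
  fwd <- paste(op$gene_a, op$gene_b)
  expect_true(all(fwd %in% paste(ht$query, ht$subject)))
  expect_true(all(paste(op$gene_b, op$gene_a) %in%
                    paste(ht$query, ht$subject)))
  expect_true(any(ht$query == ht$subject))
  expect_true(all(ht$evalue[paste(ht$query, ht$subject) %in% fwd] <= 1e-10))
})
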