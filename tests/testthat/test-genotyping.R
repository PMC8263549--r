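# Site filtering, read-count scoring, consolidation, cosegregation

test_that("site filters apply in order and partition rejections", {
  sites <- data.frame(
    site_id = paste0("s", 1:6),
    n_alleles = c(3L, 2L, 2L, 2L, 2L, 2L),
    qd = c(5, 9.99, 10, NA, 25, 25),
    pooled_alt_freq = c(0.5, 0.5, 0.5, 0.5, 0.05, 0.91))
  fr <- filter_sites(sites)
  expect_equal(fr$retained$site_id, "s3")      # QD exactly 10 retained
  expect_equal(fr$rejected, c(n_alleles = 1L, qd = 2L, freq = 2L))
  expect_equal(sum(fr$rejected) + nrow(fr$retained), nrow(sites))
  # boundary frequencies are retained (bounds inclusive)
  sites2 <- data.frame(site_id = "x", n_alleles = 2L, qd = 20,
                       pooled_alt_freq = 0.10)
  expect_equal(nrow(filter_sites(sites2)$retained), 1L)
})

test_that("score_genotype implements the depth and ratio rules", {
  expect_equal(score_genotype(5, 2), "-")      # depth 7 < 8 -> missing
  expect_equal(score_genotype(12, 0), "A")
  expect_equal(score_genotype(6, 6), "H")
  expect_equal(score_genotype(9, 1), "D")      # f = 0.1, major = A allele
  expect_equal(score_genotype(1, 9), "C")      # major = B allele
  # orientation swaps the homozygote labels
  expect_equal(score_genotype(12, 0, orientation = "alt"), "B")
  expect_equal(score_genotype(9, 1, orientation = "alt"), "C")
  # boundary fractions: f = 0.05 homozygous, f = 0.2 heterozygous
  expect_equal(score_genotype(19, 1), "A")
  expect_equal(score_genotype(16, 4), "H")
  expect_error(score_genotype(-1, 5), "negative")
})

test_that("missing call is exactly depth < 8 over the whole count lattice", {
  for (dp in 0:30) {
    for (ref in 0:dp) {
      s <- score_genotype(ref, dp - ref)
      expect_identical(s == "-", dp < 8)
    }
  }
})

test_that("scoring is deterministic and exhaustive over the alphabet", {
  ref <- rep(0:25, each = 26); alt <- rep(0:25, times = 26)
  s1 <- score_genotype(ref, alt)
  s2 <- score_genotype(ref, alt)
  expect_identical(s1, s2)
  expect_true(all(s1 %in% c("A", "B", "H", "C", "D", "-")))
})

test_that("concrete-call accuracy on default GBS settings is >= 99%", {
  for (seed in 1:3) {
    cc <- cross_config(n_chromosomes = 1, chrom_length_cm = 100,
                       sites_per_chrom = 500, n_progeny = 200, seed = seed)
    cr <- simulate_cross(cc)
    rd <- simulate_reads(cr$geno, gbs_config(mean_depth = 20,
                                             error_rate = 0.005,
                                             seed = seed + 100))
    sc <- score_matrix(rd$ref, rd$alt)
    truth <- c("A", "H", "B")[cr$geno + 1L]
    concrete <- sc %in% c("A", "H", "B")
    acc <- mean(sc[concrete] == truth[concrete])
    expect_gte(acc, 0.99)
  }
})

test_that("consolidation clusters by first-site anchor and reconciles scores", {
  sites <- data.frame(site_id = c("a", "b", "c"), chrom = "Chr01",
                      pos_bp = c(1L, 901L, 1801L))
  sc <- matrix("A", 3, 4, dimnames = list(NULL, c("p1", "p2", "P1", "P2")))
  mk <- consolidate(sites, sc, parents = c("P1", "P2"))
  # 1801 - 1 > 1000: clusters {a, b} and {c}
  expect_equal(nrow(mk$info), 2L)
  expect_equal(mk$info$members, c("a,b", "c"))
  expect_equal(mk$info$pos_bp, c(1L, 1801L))

  # identical vectors 400 bp apart collapse unchanged
  sites2 <- data.frame(site_id = c("a", "b"), chrom = "Chr01",
                       pos_bp = c(100L, 500L))
  v <- c("A", "H", "B", "D", "C", "-")
  sc2 <- rbind(c(v, "H", "H"), c(v, "H", "H"))
  colnames(sc2) <- c(paste0("p", 1:6), "P1", "P2")
  mk2 <- consolidate(sites2, sc2, parents = c("P1", "P2"))
  expect_equal(unname(mk2$scores[1, ]), v)
  expect_error(consolidate(sites2[2:1, ], sc2, parents = c("P1", "P2")),
               "sorted")
})

test_that("score reconciliation equals the set-intersection oracle on all 6x6 pairs", {
  codes <- c("A", "B", "H", "C", "D", "-")
  for (x in codes) for (y in codes) {
    sites <- data.frame(site_id = c("a", "b"), chrom = "Chr01",
                        pos_bp = c(1L, 2L))
    sc <- matrix(c(x, y, "H", "H", "H", "H"), 2, 3,
                 dimnames = list(NULL, c("p1", "P1", "P2")))
    mk <- consolidate(sites, sc, parents = c("P1", "P2"))
    expect_identical(unname(mk$scores[1, "p1"]), oracle_consensus(c(x, y)),
                     label = paste("pair", x, y))
  }
  # spotlit examples: {D, A} -> A, {D, B} -> missing
  expect_identical(oracle_consensus(c("D", "A")), "A")
  expect_identical(oracle_consensus(c("D", "B")), "-")
})

test_that("consolidated concrete scores stay compatible with every member", {
  set.seed(77)
  codes <- c("A", "B", "H", "C", "D", "-")
  for (rep in 1:200) {
    members <- sample(codes, sample(2:5, 1), replace = TRUE)
    cons <- oracle_consensus(members)
    if (cons %in% c("A", "B", "H")) {
      for (m in members[members != "-"])
        expect_true(oracle_compatible_pair(cons, m))
    }
  }
})

test_that("high-missing markers are dropped; ambiguous codes do not count", {
  mkt <- function(n_miss, n_amb, n = 100) {
    sc <- matrix("A", 1, n, dimnames = list("M1", paste0("p", 1:n)))
    if (n_miss) sc[1, seq_len(n_miss)] <- "-"
    if (n_amb) sc[1, n_miss + seq_len(n_amb)] <- "D"
    info <- data.frame(marker_id = "M1", chrom = "Chr01", pos_bp = 1L,
                       parent1 = "H", parent2 = "H",
                       n_missing = n_miss, n_ambiguous = n_amb,
                       members = "s1")
    structure(list(info = info, scores = sc), class = "marker_table")
  }
  expect_equal(nrow(drop_high_missing(mkt(31, 0))$info), 0L)
  expect_equal(nrow(drop_high_missing(mkt(30, 0))$info), 1L)
  expect_equal(nrow(drop_high_missing(mkt(25, 20))$info), 1L)
  expect_equal(nrow(drop_high_missing(mkt(0, 0))$info), 1L)
})

test_that("cosegregation grouping matches the all-pairs brute-force oracle", {
  toy <- make_toy_marker_table(n_progeny = 60, sites = 50, len_cm = 40,
                               seed = 101, mean_depth = 12)
  mk <- toy$markers
  grouped <- cosegregation_groups(mk)
  categories <- vapply(seq_len(nrow(mk$info)), function(i)
    classify_marker(mk$info$parent1[i], mk$info$parent2[i]), character(1))
  oc <- oracle_coseg(mk$scores, mk$info, min_overlap = 20,
                     categories = categories)
  expect_identical(grouped$info$coseg_group, oc$group)
  expect_identical(grouped$info$representative, oc$representative)

  # representative minimizes missing + ambiguous within its group
  info <- grouped$info
  for (g in unique(info$coseg_group)) {
    members <- info[info$coseg_group == g, ]
    rep_row <- members[members$representative, ]
    expect_equal(rep_row$n_missing + rep_row$n_ambiguous,
                 min(members$n_missing + members$n_ambiguous))
  }
})

test_that("identical vectors group together; one concrete conflict separates", {
  n <- 30
  sc <- matrix(rep(c("A", "H", "B"), each = n / 3), 1, n)
  sc <- rbind(sc, sc, sc)
  sc[3, 1] <- "H"  # doubly-concrete disagreement with rows 1-2
  colnames(sc) <- paste0("p", 1:n)
  rownames(sc) <- paste0("M", 1:3)
  info <- data.frame(marker_id = paste0("M", 1:3), chrom = "Chr01",
                     pos_bp = 1:3, parent1 = "H", parent2 = "H",
                     n_missing = 0L, n_ambiguous = 0L, members = "x")
  mk <- structure(list(info = info, scores = sc), class = "marker_table")
  out <- cosegregation_groups(mk)
  expect_equal(out$info$coseg_group[1], out$info$coseg_group[2])
  expect_false(out$info$coseg_group[3] == out$info$coseg_group[1])
})

test_that("every retained site lands in exactly one marker", {
  toy <- make_toy_marker_table(n_progeny = 40, sites = 60, len_cm = 50,
                               seed = 55)
  members <- unlist(strsplit(toy$markers$info$members, ","))
  expect_equal(sort(members), sort(toy$cross$sites$site_id))
  expect_false(anyDuplicated(members) > 0)
})
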