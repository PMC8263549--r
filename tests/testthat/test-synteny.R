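# Collinear-block chaining, homoeolog/paralog classification, windows

mk_ranks <- function(n, chroms = c("ChrA", "ChrB")) {
  do.call(rbind, lapply(chroms, function(ch)
    data.frame(gene_id = sprintf("%s.G%04d", ch, 1:n), chrom = ch,
               rank = 1:n)))
}

mk_hits <- function(q, s, evalue = 1e-20) {
  data.frame(query = q, subject = s, pident = 90, psim = 95,
             alnlen = 380, evalue = evalue, qlen = 400,
             stringsAsFactors = FALSE)
}

test_that("perfect collinear runs chain into one block with the right score", {
  rk <- mk_ranks(10)
  h <- mk_hits(sprintf("ChrA.G%04d", 1:5), sprintf("ChrB.G%04d", 1:5))
  b <- chain_blocks(h, rk, "ChrA", "ChrB")
  expect_equal(length(unique(b$block)), 1)
  expect_equal(nrow(b), 5)
  expect_equal(unique(b$score), 250)   # 50 per pair, no gaps
  expect_equal(unique(b$orientation), "same")

  # two pairs fall short of the minimum match size of 3
  h2 <- mk_hits(sprintf("ChrA.G%04d", 1:2), sprintf("ChrB.G%04d", 1:2))
  expect_equal(nrow(chain_blocks(h2, rk, "ChrA", "ChrB")), 0)
})

test_that("a 26-rank gap splits a chain", {
  rk <- mk_ranks(60)
  qs <- c(1:4, 31:34)   # gap of 27 between rank 4 and 31
  h <- mk_hits(sprintf("ChrA.G%04d", qs), sprintf("ChrB.G%04d", qs))
  b <- chain_blocks(h, rk, "ChrA", "ChrB")
  expect_equal(length(unique(b$block)), 2)
  # a 25-rank gap still chains
  qs2 <- c(1:4, 29:32)  # gap of 25
  h2 <- mk_hits(sprintf("ChrA.G%04d", qs2), sprintf("ChrB.G%04d", qs2))
  b2 <- chain_blocks(h2, rk, "ChrA", "ChrB")
  expect_equal(length(unique(b2$block)), 1)
})

test_that("inverted collinear runs are chained with inverted orientation", {
  rk <- mk_ranks(20)
  h <- mk_hits(sprintf("ChrA.G%04d", 1:5), sprintf("ChrB.G%04d", 10:6))
  b <- chain_blocks(h, rk, "ChrA", "ChrB")
  expect_equal(length(unique(b$block)), 1)
  expect_equal(unique(b$orientation), "inverted")
})

test_that("noise-free planted layout is recovered exactly", {
  st <- simulate_synteny_truth(n_genes = 80, collinear_fraction = 0.85,
                               n_paralogs = 0, seed = 601)
  ht <- simulate_hit_table(st, seed = 602)
  rk <- gene_ranks(st$genes)
  b <- chain_blocks(ht, rk, "ChrA", "ChrB")
  hm <- classify_homoeologs(b)
  truth_pairs <- st$truth$ortholog_pairs
  found <- unname(hm[truth_pairs$gene_a])
  expect_true(mean(found == truth_pairs$gene_b, na.rm = TRUE) > 0.97)
  # homoeolog fraction within 2% of planted truth
  frac_true <- nrow(truth_pairs) / 80
  frac_est <- mean(sprintf("ChrA.G%04d", 1:80) %in% names(hm))
  expect_lt(abs(frac_est - frac_true), 0.02)
  # a gene with no hit has no homoeolog
  lost <- setdiff(st$genes$gene_id[st$genes$chrom == "ChrA"],
                  truth_pairs$gene_a)
  if (length(lost)) expect_false(any(lost %in% names(hm)))
})

test_that("paralog rule honors all four conditions and self-hit exclusion", {
  base <- data.frame(query = "g1", subject = "g2", pident = 85, psim = 85,
                     alnlen = 300, evalue = 1e-10, qlen = 400,
                     stringsAsFactors = FALSE)
  expect_equal(classify_paralog("g1", base), "g2")     # 75% cov, 85% sim
  low_cov <- transform(base, alnlen = 279)             # 69.75% coverage
  expect_true(is.na(classify_paralog("g1", low_cov)))
  low_sim <- transform(base, psim = 79.9)
  expect_true(is.na(classify_paralog("g1", low_sim)))
  weak <- transform(base, evalue = 1e-4)
  expect_true(is.na(classify_paralog("g1", weak)))
  # self hit excluded even though it is the best scoring
  selfh <- rbind(data.frame(query = "g1", subject = "g1", pident = 100,
                            psim = 100, alnlen = 400, evalue = 0,
                            qlen = 400), base)
  expect_equal(classify_paralog("g1", selfh), "g2")
  # the top hit being the syntenic homoeolog blocks the call
  hm <- c(g1 = "g2")
  expect_true(is.na(classify_paralog("g1", base, hm)))
})

test_that("paralog classification agrees with the brute-force oracle on fuzz", {
  set.seed(603)
  genes <- paste0("g", 1:8)
  for (case in 1:1000) {
    n <- sample(1:6, 1)
    hits <- data.frame(
      query = "g1",
      subject = sample(genes, n, TRUE),
      pident = stats::runif(n, 20, 100),
      psim = stats::runif(n, 30, 100),
      alnlen = sample(50:400, n, TRUE),
      evalue = 10^stats::runif(n, -50, 1),
      qlen = 400, stringsAsFactors = FALSE)
    hm <- if (stats::runif(1) < 0.5)
      stats::setNames(sample(genes, 1), "g1") else character(0)
    got <- classify_paralog("g1", hits, hm)
    want <- oracle_paralog("g1", hits, if (length(hm)) hm else
      stats::setNames(NA_character_, "g1"))
    expect_identical(got, want, label = paste("fuzz case", case))
  }
})

test_that("tandem duplicates collapse before chaining", {
  rk <- mk_ranks(30)
  # query 1 hits subjects at ranks 5 and 7 (within the 5-rank window):
  # only one survives, so the three queries still form one clean block
  h <- rbind(
    mk_hits("ChrA.G0001", "ChrB.G0005", 1e-30),
    mk_hits("ChrA.G0001", "ChrB.G0007", 1e-10),
    mk_hits("ChrA.G0002", "ChrB.G0006"),
    mk_hits("ChrA.G0003", "ChrB.G0008"))
  b <- chain_blocks(h, rk, "ChrA", "ChrB")
  expect_equal(length(unique(b$block)), 1)
  expect_equal(sum(b$query == "ChrA.G0001"), 1)
  expect_equal(b$subject[b$query == "ChrA.G0001"], "ChrB.G0005")
})

test_that("window fractions use half-open bins and NA for empty windows", {
  genes <- data.frame(gene_id = paste0("g", 1:6), chrom = "ChrA",
                      start = c(10, 100000, 150000, 199999, 200000, 600000))
  hm <- c(g1 = "x", g2 = "y", g3 = "z")      # 3 of 4 in window 1
  pm <- stats::setNames(c(NA, NA, NA, "p", "q", NA), genes$gene_id)
  w <- windowed_fractions(genes, hm, pm, window_bp = 200000)
  expect_equal(w$pct_homoeolog[1], 75)
  expect_equal(w$pct_paralog[1], 25)
  expect_equal(w$n_genes[2], 1)               # 200000 falls in window 2
  expect_true(is.na(w$pct_homoeolog[2]) == FALSE)
  expect_true(is.na(w$pct_homoeolog[3]))      # empty window -> NA, not 0
  expect_equal(w$n_genes[3], 0)
})

test_that("planted proximal/distal retention contrast is recovered", {
  st <- simulate_synteny_truth(
    n_genes = 400, n_paralogs = 0, gene_spacing_bp = 10000,
    retained_by_region = function(rk) if (rk <= 200) 0.2 else 0.6,
    seed = 604)
  ht <- simulate_hit_table(st, seed = 605)
  rk <- gene_ranks(st$genes)
  hm <- classify_homoeologs(chain_blocks(ht, rk, "ChrA", "ChrB"))
  ga <- st$genes[st$genes$chrom == "ChrA", ]
  pm <- stats::setNames(rep(NA_character_, nrow(ga)), ga$gene_id)
  w <- windowed_fractions(ga, hm, pm, window_bp = 200000)
  # proximal windows cover genes ranked 1..200 (first 2 Mb)
  prox <- w$start < 2e6
  expect_equal(mean(w$pct_homoeolog[prox], na.rm = TRUE), 20,
               tolerance = 0.35)
  expect_equal(mean(w$pct_homoeolog[!prox], na.rm = TRUE), 60,
               tolerance = 0.2)
  expect_true(all(w$pct_homoeolog >= 0 & w$pct_homoeolog <= 100,
                  na.rm = TRUE))
})

test_that("block pairs are disjoint and satisfy size and gap constraints", {
  st <- simulate_synteny_truth(n_genes = 120, collinear_fraction = 0.7,
                               n_paralogs = 5, seed = 606)
  ht <- simulate_hit_table(st, n_noise = 60, include_self_hits = TRUE,
                           seed = 607)
  b <- chain_blocks(ht, gene_ranks(st$genes), "ChrA", "ChrB")
  key <- paste(b$query, b$subject)
  expect_false(anyDuplicated(key) > 0)
  for (blk in split(b, b$block)) {
    expect_gte(nrow(blk), 3)
    if (nrow(blk) > 1) {
      expect_true(all(abs(diff(blk$qrank)) <= 25))
      expect_true(all(abs(diff(blk$srank)) <= 25))
    }
  }
})
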