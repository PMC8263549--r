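# Collinearity-block chaining between homoeologous chromosomes, homoeolog
# and paralog classification from protein hit tables, and per-window
# duplication fractions.

#' Synteny-chaining parameters
#'
#' @param match_score score contributed by each aligned gene pair
#'   (default 50).
#' @param match_size minimum pairs per block (default 3).
#' @param gap_penalty penalty per gapped rank (default 1, subtracted).
#' @param max_gap maximum rank gap on either chromosome between
#'   consecutive pairs of a chain (default 25).
#' @param overlap_window tandem duplicates within this many ranks are
#'   collapsed to one representative before chaining (default 5).
#' @param evalue_max hits above this e-value are ignored (default 1e-5).
#' @return a `synteny_config` list.
#' @export
synteny_config <- function(match_score = 50, match_size = 3,
                           gap_penalty = 1, max_gap = 25,
                           overlap_window = 5, evalue_max = 1e-5) {
  structure(list(match_score = match_score, match_size = match_size,
                 gap_penalty = gap_penalty, max_gap = max_gap,
                 overlap_window = overlap_window, evalue_max = evalue_max),
            class = "synteny_config")
}

#' Rank genes along each chromosome
#'
#' @param genes gene-model data.frame (gene_id, chrom, start).
#' @return data.frame gene_id, chrom, rank (1-based per chromosome in
#'   start order).
#' @export
gene_ranks <- function(genes) {
  o <- order(genes$chrom, genes$start)
  g <- genes[o, ]
  rk <- stats::ave(seq_len(nrow(g)), g$chrom, FUN = seq_along)
  data.frame(gene_id = g$gene_id, chrom = g$chrom, rank = as.integer(rk),
             stringsAsFactors = FALSE)
}

# collapse tandem duplicates: subject genes of the same query within
# overlap_window ranks keep only the best hit
collapse_tandem <- function(pairs, cfg) {
  o <- order(pairs$query, pairs$srank, pairs$evalue)
  p <- pairs[o, ]
  keep <- rep(TRUE, nrow(p))
  last_q <- ""; last_r <- -Inf
  for (i in seq_len(nrow(p))) {
    if (p$query[i] == last_q && p$srank[i] - last_r <= cfg$overlap_window) {
      keep[i] <- FALSE
    } else {
      last_q <- p$query[i]; last_r <- p$srank[i]
    }
  }
  p[keep, , drop = FALSE]
}

#' Chain protein hit pairs into collinear blocks
#'
#' Dynamic-programming chaining of hit pairs sorted by query rank: a pair
#' extends a chain iff both rank gaps are at most `max_gap` and the
#' subject ranks move consistently with the chain's orientation (same or
#' inverted). Chain score is `match_score` per pair minus `gap_penalty`
#' per skipped rank; chains with fewer than `match_size` pairs are
#' discarded, and each pair belongs to at most one block (highest score
#' wins, ties to the leftmost start). Tandem duplicates within
#' `overlap_window` ranks are collapsed to one representative before
#' chaining.
#'
#' @param hits protein hit data.frame (query, subject, evalue, ...).
#' @param ranks output of [gene_ranks()] covering both chromosomes.
#' @param chrom_a,chrom_b the two chromosomes to chain between (query
#'   genes on `chrom_a`, subjects on `chrom_b`).
#' @param cfg a [synteny_config()].
#' @return data.frame of block pairs: block, query, subject, qrank,
#'   srank, orientation, score (block-level score repeated per pair);
#'   zero rows when no block passes.
#' @export
chain_blocks <- function(hits, ranks, chrom_a, chrom_b,
                         cfg = synteny_config()) {
  if (anyDuplicated(ranks[, c("chrom", "rank")]))
    stopf("duplicate gene ranks")
  rk <- stats::setNames(ranks$rank, ranks$gene_id)
  ch <- stats::setNames(ranks$chrom, ranks$gene_id)
  h <- hits[hits$query != hits$subject & hits$evalue <= cfg$evalue_max, ]
  h <- h[!is.na(ch[h$query]) & !is.na(ch[h$subject]) &
           ch[h$query] == chrom_a & ch[h$subject] == chrom_b, ]
  if (!nrow(h)) return(empty_blocks())
  pairs <- data.frame(query = h$query, subject = h$subject,
                      qrank = as.integer(rk[h$query]),
                      srank = as.integer(rk[h$subject]),
                      evalue = h$evalue, stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(pairs[, c("qrank", "srank")]), ]
  pairs <- collapse_tandem(pairs, cfg)
  pairs <- pairs[order(pairs$qrank, pairs$srank), ]
  n <- nrow(pairs)

  chain_dir <- function(sgn) {
    # sgn +1: subject ranks increase; -1: inverted
    score <- rep(cfg$match_score, n)
    prev <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        dq <- pairs$qrank[i] - pairs$qrank[j]
        ds <- sgn * (pairs$srank[i] - pairs$srank[j])
        if (dq < 1 || ds < 1 || dq > cfg$max_gap || ds > cfg$max_gap) next
        cand <- score[j] + cfg$match_score -
          cfg$gap_penalty * ((dq - 1) + (ds - 1))
        if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
      }
    }
    list(score = score, prev = prev)
  }

  assigned <- rep(FALSE, n)
  blocks <- list()
  bid <- 0L
  for (sgn in c(1L, -1L)) {
    dp <- chain_dir(sgn)
    # extract chains best-first: visit each endpoint once; traceback stops
    # at pairs already claimed by a higher-scoring block
    for (i in order(-dp$score, pairs$qrank)) {
      if (assigned[i]) next
      chain <- i
      j <- dp$prev[i]
      while (!is.na(j) && !assigned[j]) { chain <- c(j, chain); j <- dp$prev[j] }
      if (length(chain) < cfg$match_size) next
      bid <- bid + 1L
      sc <- cfg$match_score * length(chain) -
        cfg$gap_penalty * sum(abs(diff(pairs$qrank[chain])) - 1 +
                                abs(diff(pairs$srank[chain])) - 1)
      blocks[[bid]] <- data.frame(
        block = bid, query = pairs$query[chain],
        subject = pairs$subject[chain],
        qrank = pairs$qrank[chain], srank = pairs$srank[chain],
        orientation = if (sgn == 1L) "same" else "inverted",
        score = sc, stringsAsFactors = FALSE)
      assigned[chain] <- TRUE
    }
  }
  if (!length(blocks)) return(empty_blocks())
  do.call(rbind, c(blocks, list(make.row.names = FALSE)))
}

empty_blocks <- function() {
  data.frame(block = integer(), query = character(), subject = character(),
             qrank = integer(), srank = integer(), orientation = character(),
             score = numeric(), stringsAsFactors = FALSE)
}

#' Map genes to homoeologs from collinear blocks
#'
#' Every gene appearing in a block pair is homoeologous with its partner;
#' genes absent from all blocks have no homoeolog.
#'
#' @param blocks result of [chain_blocks()].
#' @return named character vector: gene id -> partner id (covers both
#'   sides of every pair).
#' @export
classify_homoeologs <- function(blocks) {
  if (!nrow(blocks)) return(stats::setNames(character(0), character(0)))
  m <- c(stats::setNames(blocks$subject, blocks$query),
         stats::setNames(blocks$query, blocks$subject))
  m[!duplicated(names(m))]
}

#' Classify a gene's paralog from its hit list
#'
#' Self hits are excluded; the remaining top hit (ascending e-value, ties
#' broken by descending similarity then subject id) is the paralog iff
#' e-value <= `evalue_max`, alignment length >= 70% of the query length,
#' percent similarity >= 80, and the (gene, subject) pair is not in a
#' collinear block (homoeologs are excluded).
#'
#' @param gene query gene id.
#' @param hits hit table rows for this query (query, subject, psim,
#'   alnlen, evalue, qlen).
#' @param homoeolog_map named vector from [classify_homoeologs()].
#' @param min_coverage,min_similarity,evalue_max rule thresholds
#'   (defaults 0.7, 80, 1e-5).
#' @return subject id of the paralog, or `NA_character_`.
#' @export
classify_paralog <- function(gene, hits, homoeolog_map = character(0),
                             min_coverage = 0.7, min_similarity = 80,
                             evalue_max = 1e-5) {
  h <- hits[hits$query == gene & hits$subject != gene, , drop = FALSE]
  if (!nrow(h)) return(NA_character_)
  o <- order(h$evalue, -h$psim, h$subject, method = "radix")
  top <- h[o[1], ]
  syntenic <- !is.na(homoeolog_map[gene]) &&
    identical(unname(homoeolog_map[gene]), top$subject)
  if (top$evalue <= evalue_max &&
      top$alnlen >= min_coverage * top$qlen &&
      top$psim >= min_similarity && !syntenic)
    top$subject
  else NA_character_
}

#' Per-window homoeolog and paralog percentages
#'
#' Bins genes by start coordinate into half-open windows
#' `[k*w, (k+1)*w)` and reports the percentage of genes per window with a
#' homoeolog and with a paralog. Windows containing no genes are `NA`,
#' not 0.
#'
#' @param genes gene-model data.frame (gene_id, chrom, start) for the
#'   chromosome of interest.
#' @param homoeolog_map named vector from [classify_homoeologs()].
#' @param paralog_map named vector gene -> paralog id (NA for none).
#' @param window_bp window width (default 200000).
#' @return data.frame: chrom, start, end, n_genes, pct_homoeolog,
#'   pct_paralog.
#' @export
windowed_fractions <- function(genes, homoeolog_map, paralog_map,
                               window_bp = 200000) {
  k <- floor(genes$start / window_bp)
  kk <- seq(0, max(k))
  has_h <- genes$gene_id %in% names(homoeolog_map)[!is.na(homoeolog_map)]
  has_p <- !is.na(paralog_map[genes$gene_id])
  n <- tabulate(k + 1L, nbins = length(kk))
  nh <- vapply(kk, function(w) sum(has_h[k == w]), numeric(1))
  np <- vapply(kk, function(w) sum(has_p[k == w]), numeric(1))
  data.frame(chrom = genes$chrom[1], start = kk * window_bp,
             end = (kk + 1) * window_bp, n_genes = n,
             pct_homoeolog = ifelse(n > 0, 100 * nh / n, NA_real_),
             pct_paralog = ifelse(n > 0, 100 * np / n, NA_real_))
}
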