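# Duplication and selection-pressure machinery: local similarity search,
# collinear block chaining, tandem/segmental classification, and
# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.

#' Local similarity search between two protein sets
#'
#' Smith-Waterman local alignment score (BLOSUM62, affine gaps) for every
#' query-subject pair; hits below `min_score` are dropped, self-pairs are
#' excluded when the query and subject sets are identical, and only the
#' `top_n` best hits per query are kept (ties broken by subject id).
#' The raw-score threshold plays the role of a BLAST E-value cutoff at
#' desk scale.
#'
#' @param queries,subjects Named character vectors of protein sequences.
#' @param min_score Minimum local score to keep a hit (default 50).
#' @param top_n Hits retained per query (default 5).
#' @param submat,gap_open,gap_extend Scoring scheme (BLOSUM62, 11, 1).
#' @return `data.frame`: `query_id`, `subject_id`, `score`, `rank_in_query`.
#' @export
similarity_search <- function(queries, subjects, min_score = 50, top_n = 5L,
                              submat = NULL, gap_open = 11, gap_extend = 1) {
  stopifnot(length(queries) > 0L, length(subjects) > 0L)
  if (is.null(submat)) submat <- blosum62()
  self_mode <- identical(sort(names(queries)), sort(names(subjects)))
  enc <- function(v) lapply(v, function(s) match(chars(s), rownames(submat)))
  qa <- enc(queries); sb <- enc(subjects)
  if (self_mode && identical(names(queries), names(subjects))) {
    # scores are symmetric: compute each unordered pair once, mirror after
    idx <- which(upper.tri(matrix(0, length(queries), length(queries))),
                 arr.ind = TRUE)
    pairs <- cbind(idx[, 1L], idx[, 2L])
    scores <- .sw_score_pairs_cpp(qa, sb, submat, gap_open, gap_extend, pairs)
    df <- data.frame(
      query_id = names(queries)[c(pairs[, 1L], pairs[, 2L])],
      subject_id = names(subjects)[c(pairs[, 2L], pairs[, 1L])],
      score = c(scores, scores), stringsAsFactors = FALSE)
  } else {
    pairs <- as.matrix(expand.grid(q = seq_along(queries),
                                   s = seq_along(subjects)))
    if (self_mode) {
      same <- names(queries)[pairs[, 1L]] == names(subjects)[pairs[, 2L]]
      pairs <- pairs[!same, , drop = FALSE]
    }
    scores <- .sw_score_pairs_cpp(qa, sb, submat, gap_open, gap_extend, pairs)
    df <- data.frame(query_id = names(queries)[pairs[, 1L]],
                     subject_id = names(subjects)[pairs[, 2L]],
                     score = scores, stringsAsFactors = FALSE)
  }
  df <- df[df$score >= min_score, , drop = FALSE]
  if (!nrow(df)) {
    df$rank_in_query <- integer(0)
    return(df)
  }
  out <- do.call(rbind, lapply(split(df, df$query_id), function(g) {
    g <- g[order(-g$score, g$subject_id), , drop = FALSE]
    g <- head(g, top_n)
    g$rank_in_query <- seq_len(nrow(g))
    g
  }))
  rownames(out) <- NULL
  out
}

#' Chain similarity anchors into collinear blocks
#'
#' Within each chromosome pair, extracts chains of anchors monotone in
#' gene rank on both sides (increasing/increasing = same orientation,
#' increasing/decreasing = inverted) with per-step rank gaps of at most
#' `max_gap` on both sides. Chains are extracted greedily by descending
#' length; chains shorter than `min_anchors` are discarded. The defaults
#' follow common collinearity-chaining conventions (MCScanX-like).
#'
#' @param anchors `data.frame` with columns `chrom_a`, `rank_a`,
#'   `gene_a`, `chrom_b`, `rank_b`, `gene_b` (gene columns optional).
#' @param min_anchors Minimum anchors per block (default 5).
#' @param max_gap Maximum rank gap between consecutive anchors (default 25).
#' @return List of blocks: `list(chrom_a, chrom_b, orientation, anchors)`
#'   where `anchors` is the ordered sub-data.frame.
#' @export
chain_blocks <- function(anchors, min_anchors = 5L, max_gap = 25L) {
  stopifnot(all(c("chrom_a", "rank_a", "chrom_b", "rank_b") %in% names(anchors)))
  blocks <- list()
  if (!nrow(anchors)) return(blocks)
  key <- paste(anchors$chrom_a, anchors$chrom_b, sep = "\r")
  for (grp in split(anchors, key)) {
    pool <- grp[order(grp$rank_a, grp$rank_b), , drop = FALSE]
    repeat {
      if (nrow(pool) < min_anchors) break
      best <- NULL
      for (orient in c("same", "inverted")) {
        ch <- longest_chain(pool$rank_a, pool$rank_b, orient, max_gap)
        if (is.null(best) || length(ch) > length(best$idx))
          best <- list(idx = ch, orientation = orient)
      }
      if (length(best$idx) < min_anchors) break
      blk <- pool[best$idx, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <-
        list(chrom_a = blk$chrom_a[1L], chrom_b = blk$chrom_b[1L],
             orientation = best$orientation, anchors = blk)
      pool <- pool[-best$idx, , drop = FALSE]
    }
  }
  blocks[order(-vapply(blocks, function(b) nrow(b$anchors), numeric(1L)))]
}

# Longest chain (indices into ra/rb, which are sorted by ra then rb):
# strictly monotone in both coordinates with per-step gaps <= max_gap.
longest_chain <- function(ra, rb, orientation, max_gap) {
  n <- length(ra)
  if (!n) return(integer(0))
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)[seq_len(i - 1L) > 0L]) {
      da <- ra[i] - ra[j]
      db <- if (orientation == "same") rb[i] - rb[j] else rb[j] - rb[i]
      if (da > 0L && da <= max_gap && db > 0L && db <= max_gap &&
          len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  end <- which.max(len)
  idx <- integer(0)
  while (end != 0L) { idx <- c(end, idx); end <- prev[end] }
  idx
}

#' Classify duplicate gene pairs as tandem, segmental or dispersed
#'
#' Candidate pairs are reciprocal best hits among family members (from a
#' member-vs-member [similarity_search()]). A pair is tandem iff on the
#' same chromosome with gene-rank gap at most `tandem_max_gap`; else
#' segmental iff it occurs as an anchor inside a collinear block; else
#' dispersed. Tandem takes precedence over segmental.
#'
#' @param members Member table with `gene_id`, `chrom`, `rank` columns.
#' @param hits Member-vs-member hits from [similarity_search()].
#' @param blocks Collinear blocks from [chain_blocks()] whose anchors carry
#'   `gene_a`/`gene_b` columns.
#' @param tandem_max_gap Maximum rank gap for tandem (default 1: adjacent).
#' @return `data.frame`: `gene_a`, `gene_b` (lexically ordered), `dup_type`.
#' @export
classify_duplications <- function(members, hits, blocks, tandem_max_gap = 1L) {
  if (!nrow(hits))
    return(data.frame(gene_a = character(), gene_b = character(),
                      dup_type = character(), stringsAsFactors = FALSE))
  best <- vapply(split(hits, hits$query_id), function(g)
    g$subject_id[order(-g$score, g$subject_id)][1L], character(1L))
  cand <- list()
  for (q in names(best)) {
    s <- best[[q]]
    if (!is.na(best[s]) && identical(best[[s]], q) && q < s)
      cand[[length(cand) + 1L]] <- c(q, s)
  }
  if (!length(cand))
    return(data.frame(gene_a = character(), gene_b = character(),
                      dup_type = character(), stringsAsFactors = FALSE))
  block_pairs <- character(0)
  for (b in blocks) {
    if (all(c("gene_a", "gene_b") %in% names(b$anchors)))
      block_pairs <- c(block_pairs,
                       paste(pmin(b$anchors$gene_a, b$anchors$gene_b),
                             pmax(b$anchors$gene_a, b$anchors$gene_b),
                             sep = "\r"))
  }
  rows <- lapply(cand, function(p) {
    a <- p[1L]; b <- p[2L]
    ga <- members[members$gene_id == a, ]
    gb <- members[members$gene_id == b, ]
    type <- if (nrow(ga) && nrow(gb) && ga$chrom == gb$chrom &&
                abs(ga$rank - gb$rank) <= tandem_max_gap) {
      "tandem"
    } else if (paste(min(a, b), max(a, b), sep = "\r") %in% block_pairs) {
      "segmental"
    } else {
      "dispersed"
    }
    data.frame(gene_a = a, gene_b = b, dup_type = type,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Map a protein alignment of two genes onto their codons
#'
#' Each aligned amino-acid column is mapped to the underlying codon pair.
#' Columns with a gap on either side are dropped, as are codon pairs
#' containing `N` or an internal stop (with the drop count reported in the
#' `"dropped"` attribute).
#'
#' @param cds_a,cds_b CDS strings (terminal stop codons are stripped).
#' @param aligned_a,aligned_b Gapped protein strings whose ungapped
#'   residues must equal the CDS translations.
#' @return 2-column character matrix of codon pairs, attribute `dropped`.
#' @export
codon_align <- function(cds_a, cds_b, aligned_a, aligned_b) {
  strip <- function(s) {
    n <- nchar(s)
    if (n >= 3L && substring(s, n - 2L, n) %in%
        c("TAA", "TAG", "TGA")) substring(s, 1L, n - 3L) else s
  }
  cds_a <- strip(cds_a); cds_b <- strip(cds_b)
  check <- function(cds, aligned, which) {
    prot <- gsub("-", "", aligned, fixed = TRUE)
    tr <- translate_cds(cds)
    if (nchar(tr) != nchar(prot))
      stop("translation length mismatch for sequence ", which, call. = FALSE)
    diff <- which(chars(tr) != chars(prot))
    if (length(diff))
      stop(sprintf("translation mismatch for sequence %s at residue %d",
                   which, diff[1L]), call. = FALSE)
  }
  check(cds_a, aligned_a, "a")
  check(cds_b, aligned_b, "b")
  ca <- chars(aligned_a); cb <- chars(aligned_b)
  stopifnot(length(ca) == length(cb))
  ia <- cumsum(ca != "-"); ib <- cumsum(cb != "-")
  keep <- ca != "-" & cb != "-"
  codon_of <- function(cds, i) substring(cds, 3L * i - 2L, 3L * i)
  pair <- cbind(codon_a = codon_of(cds_a, ia[keep]),
                codon_b = codon_of(cds_b, ib[keep]))
  gap_dropped <- sum(!keep)
  has_n <- grepl("N", pair[, 1L]) | grepl("N", pair[, 2L])
  is_stop <- pair[, 1L] %in% c("TAA", "TAG", "TGA") |
    pair[, 2L] %in% c("TAA", "TAG", "TGA")
  bad <- has_n | is_stop
  out <- pair[!bad, , drop = FALSE]
  attr(out, "dropped") <- sum(bad)
  attr(out, "gap_columns") <- gap_dropped
  out
}

# ---- NG86 lookup tables, built once per session -------------------------

ng86_env <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(ng86_env$S_c)) return(as.list(ng86_env))
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  stops <- codons[code == "*"]
  nt <- DNA_LETTERS
  # per-codon synonymous site count, stop-adjusted denominators
  S_c <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (cd %in% stops) { S_c[cd] <- NA_real_; next }
    s <- 0
    for (p in 1:3) {
      alt <- nt[nt != substring(cd, p, p)]
      variants <- vapply(alt, function(x) {
        v <- cd; substring(v, p, p) <- x; v
      }, character(1L))
      nonstop <- variants[!variants %in% stops]
      if (length(nonstop))
        s <- s + sum(code[nonstop] == code[cd]) / length(nonstop)
    }
    S_c[cd] <- s
  }
  # pairwise (Sd, Nd) with equal-weight pathway averaging,
  # stop-containing pathways excluded
  diffpos <- function(a, b) which(chars(a) != chars(b))
  pair_diff <- function(a, b) {
    dp <- diffpos(a, b)
    k <- length(dp)
    if (k == 0L) return(c(0, 0))
    perms <- if (k == 1L) list(dp)
    else if (k == 2L) list(dp, rev(dp))
    else list(dp[c(1, 2, 3)], dp[c(1, 3, 2)], dp[c(2, 1, 3)],
              dp[c(2, 3, 1)], dp[c(3, 1, 2)], dp[c(3, 2, 1)])
    eval_path <- function(ord, allow_stops) {
      cur <- a; sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur
        substring(nxt, p, p) <- substring(b, p, p)
        if (!allow_stops && code[nxt] == "*") return(NULL)
        if (code[nxt] == code[cur]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- Filter(Negate(is.null), lapply(perms, eval_path, allow_stops = FALSE))
    if (!length(res))  # all pathways pass through a stop: fall back
      res <- lapply(perms, eval_path, allow_stops = TRUE)
    Reduce(`+`, res) / length(res)
  }
  nonstop <- codons[!codons %in% stops]
  Sd <- matrix(0, 64, 64, dimnames = list(codons, codons))
  Nd <- Sd
  for (a in nonstop) for (b in nonstop) {
    if (a < b) {
      v <- pair_diff(a, b)
      Sd[a, b] <- Sd[b, a] <- v[1L]
      Nd[a, b] <- Nd[b, a] <- v[2L]
    }
  }
  ng86_env$S_c <- S_c
  ng86_env$Sd <- Sd
  ng86_env$Nd <- Nd
  as.list(ng86_env)
}

#' Nei-Gojobori (1986) Ka/Ks from aligned codon pairs
#'
#' Synonymous site counts use stop-adjusted denominators (changes to stop
#' codons are excluded from numerator and denominator); `N_c = 3 - S_c`
#' per codon. Differences between codon pairs are averaged with equal
#' weights over all minimal mutational pathways, excluding pathways
#' through stop codons. Proportions are corrected with Jukes-Cantor,
#' `K = -(3/4) ln(1 - (4/3) p)`, undefined (flagged `NA`) when
#' `p >= 3/4`. The ratio is defined iff `Ks > 0`; selection is
#' `"purifying"` for ratio < 1, `"neutral"` at 1 (tolerance 1e-9),
#' `"positive"` above 1 and `"undefined"` otherwise.
#'
#' @param codon_pairs 2-column character matrix of codon pairs, e.g. from
#'   [codon_align()].
#' @return `list(Ka, Ks, ratio, selection, pN, pS, Sd, Nd, S_sites,
#'   N_sites, n_codons_used)` of class `kaks_result`.
#' @export
ng86_kaks <- function(codon_pairs) {
  if (is.null(dim(codon_pairs)) || nrow(codon_pairs) < 1L)
    stop("need at least one codon pair", call. = FALSE)
  tb <- ng86_tables()
  a <- codon_pairs[, 1L]; b <- codon_pairs[, 2L]
  stops <- c("TAA", "TAG", "TGA")
  if (any(a %in% stops) || any(b %in% stops))
    stop("stop codon in codon pairs (strip them with codon_align)", call. = FALSE)
  S_sites <- (sum(tb$S_c[a]) + sum(tb$S_c[b])) / 2
  N_sites <- 3 * length(a) - S_sites
  Sd <- sum(tb$Sd[cbind(a, b)])
  Nd <- sum(tb$Nd[cbind(a, b)])
  pS <- if (S_sites > 0) Sd / S_sites else 0
  pN <- if (N_sites > 0) Nd / N_sites else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(pS); Ka <- jc(pN)
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  selection <- if (is.na(ratio)) "undefined"
  else if (abs(ratio - 1) <= 1e-9) "neutral"
  else if (ratio < 1) "purifying"
  else "positive"
  structure(list(Ka = Ka, Ks = Ks, ratio = ratio, selection = selection,
                 pN = pN, pS = pS, Sd = Sd, Nd = Nd,
                 S_sites = S_sites, N_sites = N_sites,
                 n_codons_used = length(a)),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86: Ka = %.4f, Ks = %.4f, Ka/Ks = %s (%s), %d codons\n",
              x$Ka, x$Ks,
              if (is.na(x$ratio)) "undef" else sprintf("%.4f", x$ratio),
              x$selection, x$n_codons_used))
  invisible(x)
}

#' Ka/Ks for a gene pair from a genome bundle
#'
#' Convenience wrapper: globally aligns the two proteins, maps the
#' alignment onto codons and runs [ng86_kaks()].
#'
#' @param bundle A `genome_bundle`.
#' @param gene_a,gene_b Gene ids present in the bundle's proteome and CDS.
#' @param ... Passed to [global_align()].
#' @return A `kaks_result`.
#' @export
pair_kaks <- function(bundle, gene_a, gene_b, ...) {
  al <- global_align(bundle$proteome[[gene_a]], bundle$proteome[[gene_b]], ...)
  cp <- codon_align(bundle$cds[[gene_a]], bundle$cds[[gene_b]], al$a, al$b)
  ng86_kaks(cp)
}
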