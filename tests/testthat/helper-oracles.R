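# Independent oracles used by the unit and acceptance tests. These share
# no code with the package implementations they check.

# -- exhaustive global alignment score (affine gaps) ----------------------
# Recursion over (position a, position b, previous step type); a gap run
# of length L costs open + L * ext. No DP tables from the package are used.
brute_global_score <- function(a, b, submat, open = 11, ext = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, prev) {
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb))
      best <- max(best, submat[ca[i], cb[j]] + rec(i + 1, j + 1, "m"))
    if (j <= length(cb))  # gap in a
      best <- max(best, -(ext + if (prev == "ga") 0 else open) +
                    rec(i, j + 1, "ga"))
    if (i <= length(ca))  # gap in b
      best <- max(best, -(ext + if (prev == "gb") 0 else open) +
                    rec(i + 1, j, "gb"))
    memo[[key]] <- best
    best
  }
  rec(1, 1, "m")
}

# -- local score via substrings + global alignment ------------------------
brute_local_score <- function(a, b, submat, open = 11, ext = 1) {
  best <- 0
  na <- nchar(a); nb <- nchar(b)
  for (i1 in seq_len(na)) for (i2 in i1:na) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(nb)) for (j2 in j1:nb) {
      al <- famsurvey::global_align(sa, substr(b, j1, j2), submat, open, ext)
      if (al$score > best) best <- al$score
    }
  }
  best
}

# -- exhaustive profile window scan ---------------------------------------
brute_scan <- function(protein, profile) {
  cc <- strsplit(protein, "")[[1]]
  L <- profile$length
  if (length(cc) < L) return(NULL)
  best <- NULL
  for (off in 0:(length(cc) - L)) {
    s <- 0
    for (k in seq_len(L)) {
      aa <- cc[off + k]
      s <- s + if (aa == "X") 0 else unname(profile$scores[k, aa])
    }
    if (is.null(best) || s > best$score + 1e-9)
      best <- list(start = off, score = s)
  }
  best
}

# -- independent NG86 (site counts, pathway enumeration, JC) --------------
ng86_oracle <- function(codon_pairs) {
  code <- Biostrings::GENETIC_CODE
  stops <- names(code)[code == "*"]
  nts <- c("A", "C", "G", "T")
  syn_sites <- function(cd) {
    total <- 0
    for (p in 1:3) {
      nb <- syn <- 0
      for (x in setdiff(nts, substr(cd, p, p))) {
        v <- cd
        substr(v, p, p) <- x
        if (v %in% stops) next
        nb <- nb + 1
        if (code[[v]] == code[[cd]]) syn <- syn + 1
      }
      if (nb > 0) total <- total + syn / nb
    }
    total
  }
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  path_counts <- function(ca, cb) {
    dp <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (!length(dp)) return(c(0, 0))
    walk <- function(ord, allow) {
      cur <- ca; s <- 0; n <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        if (!allow && nxt %in% stops) return(NULL)
        if (code[[nxt]] == code[[cur]]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(s, n)
    }
    res <- Filter(Negate(is.null), lapply(perms_of(dp), walk, allow = FALSE))
    if (!length(res)) res <- lapply(perms_of(dp), walk, allow = TRUE)
    Reduce(`+`, res) / length(res)
  }
  Stot_a <- sum(vapply(codon_pairs[, 1], syn_sites, numeric(1)))
  Stot_b <- sum(vapply(codon_pairs[, 2], syn_sites, numeric(1)))
  S <- (Stot_a + Stot_b) / 2
  N <- 3 * nrow(codon_pairs) - S
  sd_nd <- rowSums(vapply(seq_len(nrow(codon_pairs)), function(i)
    path_counts(codon_pairs[i, 1], codon_pairs[i, 2]), numeric(2)))
  pS <- if (S > 0) sd_nd[1] / S else 0
  pN <- if (N > 0) sd_nd[2] / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(Ka = jc(pN), Ks = jc(pS), S = S, N = N, Sd = sd_nd[1], Nd = sd_nd[2])
}

# random non-stop codon pair list
random_codon_pairs <- function(n, mut = 0.4) {
  code <- Biostrings::GENETIC_CODE
  nonstop <- names(code)[code != "*"]
  a <- sample(nonstop, n, replace = TRUE)
  b <- vapply(a, function(cd) {
    v <- cd
    for (p in 1:3) {
      if (runif(1) < mut) {
        repeat {
          substr(v, p, p) <- sample(c("A", "C", "G", "T"), 1)
          if (!(v %in% c("TAA", "TAG", "TGA"))) break
          v2 <- v
          substr(v2, p, p) <- substr(cd, p, p)
          v <- v2
        }
      }
    }
    v
  }, character(1))
  cbind(codon_a = unname(a), codon_b = unname(b))
}

# -- naive IUPAC consensus matcher ---------------------------------------
iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

naive_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

naive_match_offsets <- function(seq, consensus) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(consensus, "")[[1]]
  L <- length(pc); n <- length(sc)
  if (n < L) return(integer(0))
  hits <- integer(0)
  for (off in 0:(n - L)) {
    ok <- TRUE
    for (k in seq_len(L)) {
      if (!(sc[off + k] %in% iupac_sets[[pc[k]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

naive_scan <- function(seq, table, both_strands = TRUE) {
  out <- list()
  for (i in seq_len(nrow(table))) {
    for (off in naive_match_offsets(seq, table$consensus[i]))
      out[[length(out) + 1]] <- data.frame(element = table$name[i],
                                           offset = off, strand = "+")
    if (both_strands) {
      rc <- naive_revcomp(table$consensus[i])
      for (off in naive_match_offsets(seq, rc))
        out[[length(out) + 1]] <- data.frame(element = table$name[i],
                                             offset = off, strand = "-")
    }
  }
  if (!length(out))
    return(data.frame(element = character(), offset = integer(),
                      strand = character()))
  df <- do.call(rbind, out)
  df[order(df$offset, df$element, df$strand), , drop = FALSE]
}

# -- random additive trees for NJ recovery --------------------------------
# Builds a random binary unrooted tree via ape::rtree (branch lengths
# drawn uniform on [0.1, 1]) and returns its exact leaf distance matrix.
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.1, 1))
  D <- ape::cophenetic.phylo(tr)
  D <- D[sort(rownames(D)), sort(rownames(D))]
  list(tree = tr, D = D)
}

unrooted_splits <- function(tree) {
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  keys <- character(0)
  for (p in parts) {
    side <- labs[p]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2 && length(side) <= n - 2)
      keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  sort(unique(keys))
}

# -- tiny handcrafted genome bundle ---------------------------------------
toy_bundle <- function() {
  chrom <- paste(rep("ACGT", 3000), collapse = "")  # 12 kb
  genes <- data.frame(
    gene_id = c("g1", "g2"), chrom = "c1",
    start = c(1000L, 6000L), end = c(1300L, 6300L),
    strand = c("+", "+"), stringsAsFactors = FALSE)
  cds1 <- substr(chrom, 1001, 1300)
  cds2 <- substr(chrom, 6001, 6300)
  # ensure no stop codon issues: rebuild CDS from non-stop codons
  fix <- function(s) {
    n <- nchar(s) %/% 3
    cods <- substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
    cods[cods %in% c("TAA", "TAG", "TGA")] <- "AAA"
    paste(cods, collapse = "")
  }
  cds1 <- fix(cds1); cds2 <- fix(cds2)
  ch <- chrom
  substr(ch, 1001, 1300) <- cds1
  substr(ch, 6001, 6300) <- cds2
  genes$exons <- list(cbind(1000L, 1300L), cbind(6000L, 6300L))
  genes <- famsurvey:::compute_ranks(genes)
  rownames(genes) <- genes$gene_id
  genome_bundle(chromosomes = c(c1 = ch), genes = genes,
                proteome = setNames(vapply(c(cds1, cds2),
                                           famsurvey:::translate_cds,
                                           character(1)), c("g1", "g2")),
                cds = c(g1 = cds1, g2 = cds2))
}
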