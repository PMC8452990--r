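# Family identification by conserved-domain profile scoring, plus protein
# characterization (molecular weight, isoelectric point).
#
# The identification step scores every gapless window of each protein
# against a log-odds profile built from a seed alignment of the conserved
# domain (Peptidase_S8 for SBTs, with PA and Inhibitor_I9 as architecture
# annotations). Membership requires the best window score to reach a
# configurable fraction of the profile's maximum attainable score.

#' Build a log-odds profile matrix from a seed alignment
#'
#' Columns with more than 50% gaps are dropped. Per column `c` and residue
#' `a`, `score = log2((count[c][a] + pseudocount * background[a]) /
#' (n_c + pseudocount) / background[a])` with `n_c` the non-gap count.
#'
#' @param seed_alignment Character vector of equal-length gapped protein
#'   strings (gap = `-`), length >= 2.
#' @param pseudocount Positive pseudocount (default 1).
#' @param background Background residue frequencies over the 20 amino
#'   acids; default uniform.
#' @param name Profile name (e.g. `"Peptidase_S8"`).
#' @return An object of class `profile_matrix` with fields `name`,
#'   `length`, `scores` (L x 20, bits) and `max_score`.
#' @export
build_profile <- function(seed_alignment, pseudocount = 1,
                          background = rep(1 / 20, 20), name = "domain") {
  if (length(seed_alignment) < 2L)
    stop("seed alignment needs >= 2 sequences", call. = FALSE)
  if (length(unique(nchar(seed_alignment))) != 1L)
    stop("seed alignment rows differ in length", call. = FALSE)
  if (!is_number(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0", call. = FALSE)
  stopifnot(length(background) == 20L, all(background > 0))
  background <- background / sum(background)
  mat <- do.call(rbind, strsplit(seed_alignment, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  mat <- mat[, gap_frac <= 0.5, drop = FALSE]
  if (ncol(mat) == 0L) stop("all columns gap-dominated", call. = FALSE)
  L <- ncol(mat)
  scores <- matrix(0, L, 20L, dimnames = list(NULL, AA_LETTERS))
  for (cidx in seq_len(L)) {
    col <- mat[, cidx]
    col <- col[col != "-"]
    n_c <- length(col)
    counts <- table(factor(col, levels = AA_LETTERS))
    scores[cidx, ] <- log2((as.numeric(counts) + pseudocount * background) /
                             (n_c + pseudocount) / background)
  }
  structure(list(name = name, length = L, scores = scores,
                 max_score = sum(apply(scores, 1L, max))),
            class = "profile_matrix")
}

#' Generate a seed alignment by mutating a consensus
#'
#' Deterministic helper used to instantiate profiles from a single domain
#' consensus string: `n` copies are independently mutated at the given
#' per-site rate and stacked (gapless) into a seed alignment.
#'
#' @param consensus Ungapped protein string.
#' @param n Number of variant rows.
#' @param rate Per-site substitution probability.
#' @param seed Integer seed.
#' @return Character vector usable as `seed_alignment` in [build_profile()].
#' @export
seed_alignment_variants <- function(consensus, n = 6L, rate = 0.05, seed = 1L) {
  vapply(seq_len(n), function(i)
    mutate_sequence(consensus, rate, seed = sub_seed(seed, paste0("seedaln", i))),
    character(1L))
}

#' Scan a protein for the best-scoring gapless profile window
#'
#' Returns the maximum-score window; ties are broken by the smallest start
#' offset. The ambiguity letter `X` scores 0 in any column. Proteins
#' shorter than the profile yield `NULL` with a message.
#'
#' @param protein Protein sequence string.
#' @param profile A `profile_matrix`.
#' @return `list(domain, start, score)` with `start` a 0-based offset, or
#'   `NULL` if the protein is shorter than the profile.
#' @export
scan_domains <- function(protein, profile) {
  stopifnot(inherits(profile, "profile_matrix"))
  L <- profile$length
  n <- nchar(protein)
  if (n < L) {
    message("scan_domains: protein shorter than profile '", profile$name, "'")
    return(NULL)
  }
  ai <- match(chars(protein), AA_LETTERS)  # NA for X
  W <- n - L + 1L
  pos <- outer(seq_len(W) - 1L, seq_len(L), "+")  # W x L positions
  letter <- matrix(ai[pos], W, L)
  colidx <- matrix(rep(seq_len(L), each = W), W, L)
  val <- profile$scores[cbind(as.vector(colidx), as.vector(letter))]
  val[is.na(val)] <- 0  # X is neutral
  win <- rowSums(matrix(val, W, L))
  # smallest start among windows within numerical tolerance of the maximum
  best <- which(win >= max(win) - 1e-9)[1L]
  list(domain = profile$name, start = best - 1L, score = unname(win[best]))
}

#' Amino-acid property table (average masses and pKa values)
#'
#' Loads the packaged EMBOSS-style table of average residue masses and pKa
#' values (terminal groups and the ionizable side chains D, E, C, Y, H, K,
#' R) used by [compute_protein_properties()]. Users may supply their own
#' table with the same columns to swap the constant set.
#'
#' @param path Optional path to a replacement TSV with columns `key`,
#'   `mass`, `pka`, `charge` (`+`, `-` or empty).
#' @return `data.frame` keyed by residue letter plus `NTERM`/`CTERM` rows.
#' @export
aa_property_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aa_properties.tsv", package = "famsurvey")
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("key", "mass", "pka", "charge") %in% names(df)))
  rownames(df) <- df$key
  df
}

#' Molecular weight, isoelectric point and length of a protein
#'
#' MW is the sum of average residue masses plus one water mass. The pI is
#' the pH at which the Henderson-Hasselbalch net charge crosses zero,
#' located by bisection on \[0, 14\] to a tolerance of 1e-3. Positive
#' groups (N-terminus, H, K, R) contribute `+1/(1 + 10^(pH - pKa))`,
#' negative groups (C-terminus, D, E, C, Y) `-1/(1 + 10^(pKa - pH))`.
#'
#' @param protein Protein string over the 20 standard letters (`X` is
#'   rejected: mass and charge are undefined for it).
#' @param table Property table from [aa_property_table()].
#' @return `list(mw, pi, length)`.
#' @export
compute_protein_properties <- function(protein, table = aa_property_table()) {
  if (!nzchar(protein)) stop("empty protein", call. = FALSE)
  cc <- chars(protein)
  if (any(cc == "X"))
    stop("protein contains X: MW/pI undefined", call. = FALSE)
  if (any(!cc %in% AA_LETTERS))
    stop("illegal residue: ", cc[!cc %in% AA_LETTERS][1L], call. = FALSE)
  counts <- table(factor(cc, levels = AA_LETTERS))
  mw <- sum(as.numeric(counts) * table[AA_LETTERS, "mass"]) +
    table["WATER", "mass"]
  pi <- solve_pi(counts, table)
  list(mw = mw, pi = pi, length = nchar(protein))
}

# Net charge of a composition at a given pH; strictly decreasing in pH.
net_charge <- function(counts, table, ph) {
  ion <- table[!is.na(table$pka) & nzchar(table$charge), , drop = FALSE]
  z <- 0
  for (k in rownames(ion)) {
    n <- if (k == "NTERM" || k == "CTERM") 1 else as.numeric(counts[[k]])
    if (is.na(n) || n == 0) next
    z <- z + if (ion[k, "charge"] == "+")
      n / (1 + 10 ^ (ph - ion[k, "pka"]))
    else
      -n / (1 + 10 ^ (ion[k, "pka"] - ph))
  }
  z
}

solve_pi <- function(counts, table, tol = 1e-3) {
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(counts, table, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Identify family members in a proteome by profile scoring
#'
#' A gene is a member iff its best window score against the primary
#' (first) profile reaches `threshold_frac * max_score`. Additional
#' profiles (e.g. PA, Inhibitor_I9) annotate domain architecture by the
#' same rule with their own maxima. Members are sorted by (chrom, start)
#' and carry protein length, MW and pI.
#'
#' @param bundle A `genome_bundle`.
#' @param profiles Named list of `profile_matrix` objects; the first one
#'   defines membership.
#' @param threshold_frac Fraction of `max_score` required (default 0.5).
#' @return `data.frame` of members: `gene_id`, `chrom`, `start`, `strand`,
#'   `rank`, `length_aa`, `mw_da`, `pi`, `<primary>_score`,
#'   `<primary>_start`, and a logical `has_<name>` per extra profile.
#' @export
identify_family <- function(bundle, profiles, threshold_frac = 0.5) {
  stopifnot(inherits(bundle, "genome_bundle"), length(profiles) >= 1L)
  if (!is_number(threshold_frac) || threshold_frac <= 0)
    stop("threshold_frac must be a positive number", call. = FALSE)
  primary <- profiles[[1L]]
  rows <- list()
  for (gid in names(bundle$proteome)) {
    prot <- bundle$proteome[[gid]]
    hit <- if (nchar(prot) >= primary$length)
      scan_domains(prot, primary) else NULL
    if (is.null(hit) || hit$score < threshold_frac * primary$max_score) next
    g <- bundle$genes[gid, ]
    props <- tryCatch(compute_protein_properties(prot),
                      error = function(e) list(mw = NA_real_, pi = NA_real_,
                                               length = nchar(prot)))
    row <- data.frame(gene_id = gid, chrom = g$chrom, start = g$start,
                      strand = g$strand, rank = g$rank,
                      length_aa = props$length, mw_da = props$mw,
                      pi = props$pi, stringsAsFactors = FALSE)
    row[[paste0(primary$name, "_score")]] <- hit$score
    row[[paste0(primary$name, "_start")]] <- hit$start
    for (nm in names(profiles)[-1L]) {
      pr <- profiles[[nm]]
      h <- if (nchar(prot) >= pr$length)
        suppressMessages(scan_domains(prot, pr)) else NULL
      row[[paste0("has_", nm)]] <-
        !is.null(h) && h$score >= threshold_frac * pr$max_score
    }
    rows[[gid]] <- row
  }
  if (!length(rows)) {
    out <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), strand = character(),
                      rank = integer(), length_aa = integer(),
                      mw_da = numeric(), pi = numeric())
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- out$gene_id
  out
}
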