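# Protein alignment, distances, neighbor joining with bootstrap, and
# subfamily assignment against labeled references.
#
# The NJ implementation follows Saitou & Nei's agglomeration with the
# Q-criterion and Studier-Keppler distance updates; ties on minimal Q are
# broken by the lexically lowest pair of cluster labels (a cluster is
# labeled by its smallest leaf id), and negative branch lengths are clamped
# to zero. Trees are returned as ape "phylo" objects so the whole ape
# toolkit (Newick I/O, plotting, patristic distances) applies.

#' Global pairwise alignment with affine gaps (Needleman-Wunsch)
#'
#' A gap run of length L is penalized `gap_open + L * gap_extend`.
#' Traceback tie-breaking prefers match/mismatch over a gap in `a` over a
#' gap in `b`, making the alignment deterministic.
#'
#' @param a,b Ungapped protein strings.
#' @param submat Substitution matrix (default BLOSUM62 from Biostrings).
#' @param gap_open,gap_extend Positive gap penalties (defaults 11 and 1).
#' @return `list(a, b, score)` with `a`/`b` the gapped aligned strings.
#' @export
global_align <- function(a, b, submat = NULL, gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty input sequence", call. = FALSE)
  if (is.null(submat)) submat <- blosum62()
  ca <- chars(a); cb <- chars(b)
  S <- submat[ca, cb, drop = FALSE]
  res <- .nw_affine_cpp(S, gap_open, gap_extend)
  al_a <- ifelse(res$path_a == 0L, "-", ca[pmax(res$path_a, 1L)])
  al_b <- ifelse(res$path_b == 0L, "-", cb[pmax(res$path_b, 1L)])
  list(a = paste(al_a, collapse = ""), b = paste(al_b, collapse = ""),
       score = res$score)
}

# k-mer count cosine distance between ungapped sequences (guide distances)
kmer_cosine_dist <- function(seqs, k = 3L) {
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character()))
    table(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  })
  all_kmers <- unique(unlist(lapply(counts, names)))
  M <- vapply(counts, function(tb) {
    v <- setNames(numeric(length(all_kmers)), all_kmers)
    v[names(tb)] <- as.numeric(tb)
    v
  }, numeric(length(all_kmers)))
  M <- t(M)  # seqs x kmers
  nrm <- sqrt(rowSums(M ^ 2))
  nrm[nrm == 0] <- 1
  sim <- (M %*% t(M)) / outer(nrm, nrm)
  d <- 1 - sim
  d[d < 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

# Column-score matrix between two alignment profiles: mean pairwise
# substitution value over the residue pairs of the two columns; pairs
# involving a gap contribute a flat gap score.
profile_colscores <- function(matA, matB, submat, gap_pair_score = -4) {
  sym <- c(AA_LETTERS, "-")
  S21 <- matrix(gap_pair_score, 21L, 21L, dimnames = list(sym, sym))
  S21[AA_LETTERS, AA_LETTERS] <- submat[AA_LETTERS, AA_LETTERS]
  freq <- function(m) {
    f <- apply(m, 2L, function(col)
      tabulate(match(col, sym), nbins = 21L) / length(col))
    matrix(f, nrow = 21L)
  }
  FA <- freq(matA); FB <- freq(matB)
  t(FA) %*% S21 %*% FB
}

merge_profiles <- function(matA, matB, submat, gap_open, gap_extend) {
  cs <- profile_colscores(matA, matB, submat)
  res <- .nw_affine_cpp(cs, gap_open, gap_extend)
  ncols <- length(res$path_a)
  out <- matrix("-", nrow(matA) + nrow(matB), ncols)
  ia <- res$path_a > 0L
  ib <- res$path_b > 0L
  out[seq_len(nrow(matA)), ia] <- matA[, res$path_a[ia], drop = FALSE]
  out[nrow(matA) + seq_len(nrow(matB)), ib] <- matB[, res$path_b[ib], drop = FALSE]
  rownames(out) <- c(rownames(matA), rownames(matB))
  out
}

#' Progressive multiple alignment of protein sequences
#'
#' Guide tree from 3-mer count cosine distances via neighbor joining;
#' profiles are merged bottom-up by profile-profile Needleman-Wunsch
#' (column score = mean pairwise substitution value; gap pairs score a
#' flat penalty). Input order of ids is preserved in the output.
#'
#' @param seqs Named character vector of >= 1 ungapped protein strings.
#' @param submat,gap_open,gap_extend As in [global_align()].
#' @return Named character vector of equal-length gapped rows.
#' @export
progressive_msa <- function(seqs, submat = NULL, gap_open = 11, gap_extend = 1) {
  if (is.null(submat)) submat <- blosum62()
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names", call. = FALSE)
  if (length(seqs) == 1L) {
    warning("single sequence: returned unaligned")
    return(seqs)
  }
  if (length(seqs) == 2L) {
    al <- global_align(seqs[[1L]], seqs[[2L]], submat, gap_open, gap_extend)
    return(setNames(c(al$a, al$b), names(seqs)))
  }
  D <- kmer_cosine_dist(seqs)
  guide <- nj_core(D)
  align_node <- function(node) {
    if (is.character(node)) {
      m <- matrix(chars(seqs[[node]]), nrow = 1L)
      rownames(m) <- node
      return(m)
    }
    acc <- align_node(node[[1L]])
    for (k in seq_along(node)[-1L])
      acc <- merge_profiles(acc, align_node(node[[k]]), submat,
                            gap_open, gap_extend)
    acc
  }
  m <- align_node(phylo_to_nested(guide))
  m <- m[names(seqs), , drop = FALSE]
  setNames(apply(m, 1L, paste, collapse = ""), names(seqs))
}

# Convert a phylo tree (possibly with a multifurcating root) into nested
# lists of leaf labels, children ordered by smallest descendant label.
phylo_to_nested <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  build <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    ch <- lapply(kids[[as.character(node)]], build)
    first_leaf <- vapply(ch, function(x)
      if (is.character(x)) x else attr(x, "min_leaf"), character(1L))
    ch <- ch[order(first_leaf)]
    structure(ch, min_leaf = min(first_leaf))
  }
  build(n + 1L)
}

#' Pairwise distances from a protein alignment
#'
#' `p` is the mismatch proportion over columns where both rows are
#' non-gap; model `"p"` returns it as-is, model `"poisson"` applies
#' `d = -ln(1 - p)`. Saturated pairs (`p >= 0.99`) are clamped to
#' `-ln(0.01)` with a warning so neighbor joining stays defined.
#'
#' @param alignment Named character vector of equal-length gapped rows.
#' @param model `"poisson"` (default, MEGA-like protein distance) or `"p"`.
#' @param on_empty What to do for a pair with zero shared non-gap columns:
#'   `"error"` (default) or `"clamp"` to the saturation distance (used
#'   during bootstrap resampling).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(alignment, model = c("poisson", "p"),
                            on_empty = c("error", "clamp")) {
  model <- match.arg(model)
  on_empty <- match.arg(on_empty)
  if (length(alignment) < 2L) stop("need >= 2 rows", call. = FALSE)
  if (length(unique(nchar(alignment))) != 1L)
    stop("alignment rows differ in length", call. = FALSE)
  ids <- names(alignment)
  m <- do.call(rbind, strsplit(unname(alignment), "", fixed = TRUE))
  nongap <- m != "-"
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- nongap[i, ] & nongap[j, ]
      ns <- sum(shared)
      if (ns == 0L) {
        if (on_empty == "error")
          stop("no shared non-gap columns between ", ids[i], " and ", ids[j],
               call. = FALSE)
        p <- 0.99
      } else {
        p <- sum(m[i, shared] != m[j, shared]) / ns
      }
      if (p >= 0.99) { p <- 0.99; sat <- TRUE }
      d[i, j] <- d[j, i] <- if (model == "p") p else -log(1 - p)
    }
  }
  if (sat) warning("saturated pair(s) clamped at p = 0.99")
  d
}

# Core Saitou-Nei agglomeration. D: symmetric matrix with dimnames.
# Returns an unrooted phylo (root trifurcation). Deterministic: minimal-Q
# ties resolved by the lexically lowest (label_i, label_j) pair where a
# cluster is labeled by its smallest leaf id.
nj_core <- function(D) {
  labels <- rownames(D)
  n <- length(labels)
  if (n < 3L) stop("neighbor joining needs >= 3 taxa", call. = FALSE)
  # each active cluster: list(rep = smallest leaf label, node = subtree)
  # subtree = list(label=, children=list(list(node, length), ...)) or leaf
  make_leaf <- function(lab) list(leaf = lab)
  active <- lapply(labels, make_leaf)
  reps <- labels
  Dm <- D
  while (length(active) > 3L) {
    r <- length(active)
    rs <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      pr <- sort(c(reps[ij[1L]], reps[ij[2L]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    bi <- Dm[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    bj <- Dm[i, j] - bi
    bi <- max(bi, 0); bj <- max(bj, 0)
    newnode <- list(children = list(list(node = active[[i]], length = bi),
                                    list(node = active[[j]], length = bj)))
    dnew <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2  # Studier-Keppler
    keep <- setdiff(seq_len(r), c(i, j))
    Dm2 <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                 c(dnew[keep], 0))
    newrep <- min(reps[c(i, j)])
    rn <- c(reps[keep], newrep)
    dimnames(Dm2) <- list(rn, rn)
    Dm <- Dm2
    active <- c(active[keep], list(newnode))
    reps <- rn
  }
  # final three-point resolution
  d12 <- Dm[1L, 2L]; d13 <- Dm[1L, 3L]; d23 <- Dm[2L, 3L]
  b1 <- max((d12 + d13 - d23) / 2, 0)
  b2 <- max((d12 + d23 - d13) / 2, 0)
  b3 <- max((d13 + d23 - d12) / 2, 0)
  root <- list(children = list(list(node = active[[1L]], length = b1),
                               list(node = active[[2L]], length = b2),
                               list(node = active[[3L]], length = b3)))
  nested_to_phylo(root, labels)
}

# Build an ape phylo from the nested node structure produced by nj_core.
nested_to_phylo <- function(root, tip_labels) {
  n <- length(tip_labels)
  edges <- list(); elens <- numeric(0)
  n_internal <- 0L
  count_internal <- function(node) {
    if (!is.null(node$leaf)) return(invisible(NULL))
    n_internal <<- n_internal + 1L
    for (ch in node$children) count_internal(ch$node)
  }
  count_internal(root)
  next_internal <- n + 1L
  edge_from <- integer(0); edge_to <- integer(0)
  assign_ids <- function(node) {
    if (!is.null(node$leaf)) return(match(node$leaf, tip_labels))
    id <- next_internal
    next_internal <<- next_internal + 1L
    for (ch in node$children) {
      cid <- assign_ids(ch$node)
      edge_from <<- c(edge_from, id)
      edge_to <<- c(edge_to, cid)
      elens <<- c(elens, ch$length)
    }
    id
  }
  assign_ids(root)
  tree <- list(edge = cbind(edge_from, edge_to), edge.length = elens,
               tip.label = tip_labels, Nnode = n_internal)
  dimnames(tree$edge) <- NULL
  class(tree) <- "phylo"
  ape::reorder.phylo(tree, "cladewise")
}

# Canonical bipartition keys of a phylo's internal edges. Each key is the
# sorted leaf set on the side NOT containing the first tip, collapsed to a
# string.
bipartition_keys <- function(tree) {
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1L]  # orientation anchor, stable across trees
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  keys <- character(0)
  nodes <- integer(0)
  for (k in seq_along(parts)) {
    side <- labs[parts[[k]]]
    if (length(side) %in% c(0L, n)) next
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L || length(side) > n - 2L) next  # trivial split
    keys <- c(keys, paste(sort(side), collapse = "\r"))
    nodes <- c(nodes, n + k)
  }
  list(keys = keys, nodes = nodes)
}

#' Neighbor-joining tree, optionally with bootstrap supports
#'
#' Saitou-Nei agglomeration with Q-criterion and Studier-Keppler updates;
#' minimal-Q ties broken by the lexically lowest cluster-label pair, and
#' negative branch lengths clamped to zero. With `bootstrap`, alignment
#' columns are resampled with replacement per replicate, the distance
#' matrix and tree rebuilt, and each internal edge's support set to the
#' fraction of replicates containing its bipartition.
#'
#' @param D Symmetric distance matrix with dimnames (>= 3 taxa).
#' @param bootstrap Optional `list(alignment =, n_reps =, seed =, model =)`;
#'   `model` defaults to `"poisson"`.
#' @return An unrooted `phylo`; with bootstrap, `node.label` holds supports
#'   in \[0, 1\] for internal nodes (root label empty).
#' @export
nj_tree <- function(D, bootstrap = NULL) {
  if (!isTRUE(all.equal(D, t(D))) || any(diag(D) != 0))
    stop("D must be symmetric with zero diagonal", call. = FALSE)
  tree <- nj_core(D)
  if (!is.null(bootstrap)) {
    aln <- bootstrap$alignment
    n_reps <- bootstrap$n_reps
    model <- if (is.null(bootstrap$model)) "poisson" else bootstrap$model
    stopifnot(!is.null(aln), is_number(n_reps), n_reps >= 1)
    ncols <- unique(nchar(aln))
    stopifnot(length(ncols) == 1L)
    rows <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
    rownames(rows) <- names(aln)
    main <- bipartition_keys(tree)
    hits <- setNames(numeric(length(main$keys)), main$keys)
    with_seed(if (is.null(bootstrap$seed)) 1L else bootstrap$seed, {
      for (b in seq_len(n_reps)) {
        cols <- sample.int(ncols, ncols, replace = TRUE)
        rep_aln <- setNames(apply(rows[, cols, drop = FALSE], 1L,
                                  paste, collapse = ""), names(aln))
        Drep <- suppressWarnings(
          distance_matrix(rep_aln, model = model, on_empty = "clamp"))
        rep_tree <- nj_core(Drep)
        rk <- bipartition_keys(rep_tree)$keys
        found <- main$keys %in% rk
        hits[found] <- hits[found] + 1
      }
    })
    support <- hits / n_reps
    node.label <- rep("", tree$Nnode)
    node.label[main$nodes - length(tree$tip.label)] <-
      format(round(support, 3), trim = TRUE)
    tree$node.label <- node.label
    attr(tree, "support") <- support
  }
  tree
}

#' Assign subfamily groups to member leaves by nearest labeled reference
#'
#' Each non-reference leaf receives the group of its nearest reference
#' leaf by patristic (path-length) distance; ties are resolved by majority
#' group among the equidistant references, then by lexical group order.
#'
#' @param tree A `phylo` containing all reference leaves.
#' @param reference_labels Named character vector `ref_id -> group`.
#' @return `data.frame` (`member`, `group`, `nearest_ref`, `distance`) with
#'   attribute `method = "nearest_reference_patristic"`.
#' @export
assign_subfamilies <- function(tree, reference_labels) {
  refs <- names(reference_labels)
  if (!length(refs)) stop("no references supplied", call. = FALSE)
  missing <- setdiff(refs, tree$tip.label)
  if (length(missing))
    stop("reference not in tree: ", missing[1L], call. = FALSE)
  members <- setdiff(tree$tip.label, refs)
  pd <- ape::cophenetic.phylo(tree)
  out <- lapply(sort(members), function(m) {
    dv <- pd[m, refs]
    dmin <- min(dv)
    tied <- refs[dv <= dmin + 1e-12]
    if (length(tied) == 1L) {
      grp <- reference_labels[[tied]]
      nearest <- tied
    } else {
      tg <- table(unname(reference_labels[tied]))
      winners <- names(tg)[tg == max(tg)]
      grp <- sort(winners)[1L]  # lexical group order on residual ties
      nearest <- sort(tied[reference_labels[tied] == grp])[1L]
    }
    data.frame(member = m, group = grp, nearest_ref = nearest,
               distance = dmin, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "method") <- "nearest_reference_patristic"
  res
}

#' Per-group composition by clade of origin
#'
#' Counts group members partitioned by a clade-of-origin tag (e.g.
#' monocot/dicot) and reports integer-rounded percentages within each
#' group, as used to describe subfamily composition across lineages.
#'
#' @param groups Named character vector `leaf -> group`.
#' @param clades Named character vector `leaf -> clade tag`.
#' @return `data.frame` with `group`, `clade`, `n`, `pct` (integer percent
#'   of the group's total).
#' @export
subfamily_composition <- function(groups, clades) {
  ids <- intersect(names(groups), names(clades))
  if (!length(ids)) stop("no leaves shared between groups and clades", call. = FALSE)
  tb <- table(group = unname(groups[ids]), clade = unname(clades[ids]))
  df <- as.data.frame(tb, stringsAsFactors = FALSE)
  names(df)[3L] <- "n"
  tot <- tapply(df$n, df$group, sum)
  df$pct <- as.integer(round(100 * df$n / as.numeric(tot[df$group])))
  df[order(df$group, df$clade), , drop = FALSE]
}

#' Write a tree to Newick with supports as internal node labels
#'
#' @param tree A `phylo`, e.g. from [nj_tree()].
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
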