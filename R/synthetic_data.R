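# Synthetic survey dataset with planted ground truth.
#
# The generator emulates the statistical structure a genome-wide family
# survey assumes: background genes with random coding sequences, family
# genes carrying a mutated copy of a conserved domain inside group-specific
# protein backbones, a tandem-adjacent duplicate pair and cross-chromosome
# pairs embedded in collinear blocks with controlled synonymous vs
# nonsynonymous divergence, promoters with planted cis-elements (and
# background scrubbed of spurious motif matches so per-gene counts are
# exact), and tissue-specific vs ubiquitous expression profiles. A single
# integer seed drives sub-streams with fixed labels, so outputs are
# byte-identical for identical configs.

#' Built-in synthetic domain consensus strings
#'
#' Fixed invented consensus sequences standing in for the family-defining
#' catalytic domain and the two accessory domains of plant subtilases
#' (Peptidase_S8-like, PA-like, Inhibitor_I9-like). They are synthetic:
#' suitable for benchmarks, not for scanning real proteomes.
#'
#' @return Named list of protein strings `S8` (60 aa), `PA` (40 aa),
#'   `I9` (35 aa).
#' @export
famsurvey_domains <- function() {
  list(
    S8 = paste0("ATGSHGTHVA", "GTIAGLDNGV", "AKKANLIAVK",
                "VLDSSGSGSY", "SDIIAGLEWA", "VQNHMDVISL"),
    PA = paste0("GPNPVNAKFC", "KTAPILSYFS", "SRGPSTLDGR", "HVLKPDITAP"),
    I9 = paste0("YIVYMGSLPS", "GDYSPASHHL", "SMLQEVVGSD", "AAKEA"))
}

#' Configuration for the synthetic survey generator
#'
#' Defaults define the benchmark conditions: 200 background genes and 30
#' family genes over 6 subfamily groups (sizes 10/6/5/4/3/2) on 5
#' chromosomes; one planted tandem pair and four segmental pairs inside
#' 6-anchor collinear blocks; strong synonymous (0.3) versus weak
#' nonsynonymous (0.05) divergence between pair members (purifying
#' regime); a fixed element set planted into every family promoter; 8
#' tissues with 10 tissue-specific and 6 ubiquitous family genes.
#'
#' @param seed Integer master seed.
#' @param n_chromosomes,n_background_genes,n_family_genes Layout sizes.
#' @param domain_consensus Family-defining domain (>= 50 aa).
#' @param per_site_sub_rate Per-site mutation rate of each member's domain
#'   copies (the identification difficulty dial).
#' @param backbone_divergence Per-site mutation rate of the non-domain
#'   backbone relative to the group consensus; well above
#'   `per_site_sub_rate` so planted duplicate partners are always closer
#'   to each other than to other group members.
#' @param n_tandem_pairs,n_segmental_pairs Planted duplicate pairs.
#' @param block_size Genes per planted collinear block (>= 5).
#' @param planted_elements Named integer vector: element name -> copies
#'   planted per family promoter (names must exist in `element_table`).
#' @param element_table Element definitions (default packaged table).
#' @param tissues Tissue labels (>= 2).
#' @param n_specific,n_ubiquitous Family genes with specific / ubiquitous
#'   expression.
#' @param syn_divergence,nonsyn_divergence Substitution probabilities at
#'   4-fold-degenerate vs nondegenerate codon positions of planted pairs.
#' @param group_sizes Members per subfamily group (sums to
#'   `n_family_genes`).
#' @param n_refs_per_group Labeled reference proteins emitted per group.
#' @param family_protein_length,background_protein_codons Protein sizes.
#' @param promoter_length Planted/cleaned promoter window (bp).
#' @param intergenic Gap between consecutive genes (bp); must exceed
#'   twice the promoter length so planted windows never collide.
#' @return A validated object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 5L,
                             n_background_genes = 200L,
                             n_family_genes = 30L,
                             domain_consensus = famsurvey_domains()$S8,
                             per_site_sub_rate = 0.05,
                             backbone_divergence = 0.3,
                             n_tandem_pairs = 1L,
                             n_segmental_pairs = 4L,
                             block_size = 6L,
                             planted_elements = c("Box 4" = 3L, "G-box" = 2L,
                                                  "ABRE" = 2L, "ARE" = 1L,
                                                  "MBS" = 1L,
                                                  "CGTCA-motif" = 1L),
                             element_table = read_element_table(),
                             tissues = c("root", "leaf", "flower", "sepal",
                                         "petal", "stamen", "ovule", "fruit"),
                             n_specific = 10L,
                             n_ubiquitous = 6L,
                             syn_divergence = 0.3,
                             nonsyn_divergence = 0.05,
                             group_sizes = c(10L, 6L, 5L, 4L, 3L, 2L),
                             n_refs_per_group = 2L,
                             family_protein_length = 260L,
                             background_protein_codons = c(120L, 250L),
                             promoter_length = 2000L,
                             intergenic = 4500L) {
  cfg <- as.list(environment())
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (nchar(domain_consensus) < 50L)
      stop("domain_consensus must be >= 50 aa", call. = FALSE)
    if (per_site_sub_rate < 0 || per_site_sub_rate >= 1)
      stop("per_site_sub_rate must lie in [0, 1)", call. = FALSE)
    if (backbone_divergence < 0 || backbone_divergence >= 1)
      stop("backbone_divergence must lie in [0, 1)", call. = FALSE)
    if (syn_divergence < 0 || syn_divergence >= 1 ||
        nonsyn_divergence < 0 || nonsyn_divergence >= 1)
      stop("divergence rates must lie in [0, 1)", call. = FALSE)
    if (block_size < 5L) stop("block_size must be >= 5", call. = FALSE)
    if (n_family_genes < 2L * (n_tandem_pairs + n_segmental_pairs))
      stop("n_family_genes must cover all planted pairs", call. = FALSE)
    if (sum(group_sizes) != n_family_genes)
      stop("group_sizes must sum to n_family_genes", call. = FALSE)
    n_unpaired <- n_family_genes - 2L * (n_tandem_pairs + n_segmental_pairs)
    need_bg <- 2L * n_segmental_pairs * (block_size - 1L) + 2L * n_unpaired
    if (n_background_genes < need_bg)
      stop("n_background_genes too small for layout (need >= ", need_bg, ")",
           call. = FALSE)
    if (n_specific + n_ubiquitous > n_family_genes)
      stop("n_specific + n_ubiquitous exceeds n_family_genes", call. = FALSE)
    if (length(tissues) < 2L) stop("need >= 2 tissues", call. = FALSE)
    if (intergenic < 2L * promoter_length + 100L)
      stop("intergenic must exceed twice the promoter length", call. = FALSE)
    if (n_chromosomes < 2L && n_segmental_pairs > 0L)
      stop("segmental pairs need >= 2 chromosomes", call. = FALSE)
    bad <- setdiff(names(planted_elements), element_table$name)
    if (length(bad))
      stop("planted element not in table: ", bad[1L], call. = FALSE)
  })
  invisible(TRUE)
}

#' Mutate a sequence at a fixed per-site substitution rate
#'
#' Each position is independently substituted with probability `rate` by a
#' uniformly chosen different letter of the sequence's alphabet (DNA if
#' the sequence contains only A/C/G/T, protein otherwise). Deterministic
#' given `seed`; the caller's RNG state is untouched.
#'
#' @param seq Sequence string.
#' @param rate Substitution probability in \[0, 1).
#' @param seed Integer seed.
#' @param alphabet Optional explicit alphabet (character vector).
#' @return Mutated sequence of the same length.
#' @export
mutate_sequence <- function(seq, rate, seed, alphabet = NULL) {
  if (!is_number(rate) || rate < 0 || rate >= 1)
    stop("rate must lie in [0, 1)", call. = FALSE)
  cc <- chars(seq)
  if (is.null(alphabet))
    alphabet <- if (all(cc %in% DNA_LETTERS)) DNA_LETTERS else AA_LETTERS
  with_seed(seed, {
    hit <- runif(length(cc)) < rate
    if (any(hit)) {
      cc[hit] <- vapply(cc[hit], function(x)
        sample(setdiff(alphabet, x), 1L), character(1L))
    }
  })
  paste(cc, collapse = "")
}

# --- small sequence helpers (use the RNG stream in effect) ---------------

random_protein <- function(n) paste(sample(AA_LETTERS, n, TRUE), collapse = "")
random_dna <- function(n) paste(sample(DNA_LETTERS, n, TRUE), collapse = "")

syn_codon_sets <- function() {
  code <- Biostrings::GENETIC_CODE
  split(names(code)[code != "*"], code[code != "*"])
}

reverse_translate <- function(protein) {
  sets <- syn_codon_sets()
  paste(vapply(chars(protein), function(a) {
    s <- sets[[a]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1L)), collapse = "")
}

# Codon degeneracy classes under the standard code.
fourfold_third <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[codon]
  variants <- paste0(substring(codon, 1L, 2L), DNA_LETTERS)
  all(code[variants] == aa)
}

nondegenerate_positions <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[codon]
  which(vapply(1:3, function(p) {
    alt <- DNA_LETTERS[DNA_LETTERS != substring(codon, p, p)]
    vs <- vapply(alt, function(x) {
      v <- codon; substring(v, p, p) <- x; v
    }, character(1L))
    all(code[vs] != aa)  # every change alters the amino acid
  }, logical(1L)))
}

# Derive a duplicate-pair partner CDS: synonymous substitutions at
# 4-fold-degenerate third positions (rate syn_rate), nonsynonymous
# substitutions at nondegenerate positions (rate nonsyn_rate, stops
# rejected), leaving codons in `protect` (e.g. the diagnostic domain)
# free of nonsynonymous edits.
plant_divergence <- function(cds, syn_rate, nonsyn_rate, protect = integer(0)) {
  code <- Biostrings::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  for (i in seq_len(n)) {
    cd <- codons[i]
    if (fourfold_third(cd) && runif(1L) < syn_rate) {
      third <- substring(cd, 3L, 3L)
      substring(cd, 3L, 3L) <- sample(DNA_LETTERS[DNA_LETTERS != third], 1L)
    }
    if (!(i %in% protect)) {
      for (p in nondegenerate_positions(cd)) {
        if (runif(1L) < nonsyn_rate) {
          cur <- substring(cd, p, p)
          cand <- sample(DNA_LETTERS[DNA_LETTERS != cur])
          for (x in cand) {
            v <- cd; substring(v, p, p) <- x
            if (!(v %in% stops) && code[v] != code[cd]) { cd <- v; break }
          }
        }
      }
    }
    codons[i] <- cd
  }
  paste(codons, collapse = "")
}

# Expand an IUPAC consensus into a concrete instance (RNG in effect).
expand_iupac <- function(consensus) {
  paste(vapply(chars(consensus), function(x) {
    opts <- IUPAC_CODES[[x]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1L)), collapse = "")
}

# Build one promoter: random background scrubbed of table matches, with
# the requested element instances planted at spaced offsets. Returns the
# sequence and the exact in-window hit truth (offsets 0-based, promoter
# coordinates).
build_promoter <- function(len, planted_elements, element_table,
                           max_iter = 200L) {
  defs <- setNames(element_table$consensus, element_table$name)
  inst <- list()
  for (nm in names(planted_elements)) {
    for (k in seq_len(planted_elements[[nm]]))
      inst[[length(inst) + 1L]] <- list(name = nm,
                                        seq = expand_iupac(defs[[nm]]))
  }
  n_inst <- length(inst)
  widths <- vapply(inst, function(x) nchar(x$seq), numeric(1L))
  slot <- len %/% max(n_inst, 1L)
  if (n_inst && slot < max(widths) + 20L)
    stop("promoter too short for planted elements", call. = FALSE)
  seq <- random_dna(len)
  windows <- matrix(integer(0), 0L, 2L)
  for (k in seq_len(n_inst)) {
    lo <- (k - 1L) * slot + 5L
    hi <- k * slot - widths[k] - 5L
    off <- lo + floor(runif(1L) * max(hi - lo, 1L))
    substring(seq, off + 1L, off + widths[k]) <- inst[[k]]$seq
    windows <- rbind(windows, c(off, off + widths[k]))
  }
  in_window <- function(o, w)
    any(windows[, 1L] <= o & o + w <= windows[, 2L])
  for (iter in seq_len(max_iter)) {
    hits <- scan_elements(data.frame(gene_id = "p", seq = seq,
                                     stringsAsFactors = FALSE),
                          element_table, both_strands = TRUE)
    if (nrow(hits)) {
      w <- nchar(defs[hits$element])
      spurious <- !mapply(in_window, hits$offset, w)
    } else spurious <- logical(0)
    if (!any(spurious)) {
      truth <- hits[, c("element", "offset", "strand"), drop = FALSE]
      rownames(truth) <- NULL
      return(list(seq = seq, truth = truth))
    }
    bad <- which(spurious)
    for (h in bad) {
      pos <- hits$offset[h] + seq_len(w[h])  # 1-based positions of the hit
      fixable <- pos[!vapply(pos, function(p)
        any(windows[, 1L] < p & p <= windows[, 2L]), logical(1L))]
      if (!length(fixable)) next
      p <- sample(fixable, 1L)
      substring(seq, p, p) <- sample(DNA_LETTERS, 1L)
    }
  }
  stop("promoter cleaning did not converge", call. = FALSE)
}

#' Generate a synthetic survey dataset with ground truth
#'
#' See [synthetic_config()] for the planted structure. The returned truth
#' record is exhaustive: family membership and subfamily groups, duplicate
#' pairs with types, collinear-block anchor pairs, per-promoter element
#' hits, tissue-specific and ubiquitous gene sets, and domain-architecture
#' flags.
#'
#' @param config A `synthetic_config`.
#' @return `list(bundle, expression, element_table, refs, ref_labels,
#'   ref_clades, truth)` of class `survey_dataset`.
#' @export
generate_survey_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  cfg <- config
  seed <- cfg$seed
  domains <- famsurvey_domains()
  n_groups <- length(cfg$group_sizes)

  # --- group backbones -------------------------------------------------
  dom_off <- 60L   # S8 domain offset within every group backbone
  pa_off <- 140L
  i9_off <- 15L
  pa_groups <- seq_len(min(4L, n_groups))
  i9_groups <- seq_len(min(5L, n_groups))
  group_seeds <- with_seed(sub_seed(seed, "group_seeds"), {
    lapply(seq_len(n_groups), function(g) {
      bb <- chars(random_protein(cfg$family_protein_length))
      put <- function(bb, s, off) {
        bb[off + seq_len(nchar(s))] <- chars(s); bb
      }
      bb <- put(bb, cfg$domain_consensus, dom_off)
      if (g %in% i9_groups) bb <- put(bb, domains$I9, i9_off)
      if (g %in% pa_groups) bb <- put(bb, domains$PA, pa_off)
      paste(bb, collapse = "")
    })
  })
  group_names <- paste0("Group_", utils::as.roman(seq_len(n_groups)))

  # --- family gene inventory -------------------------------------------
  fam_ids <- sprintf("FAM%03d", seq_len(cfg$n_family_genes))
  fam_group <- rep(seq_len(n_groups), times = cfg$group_sizes)
  names(fam_group) <- fam_ids

  n_pairs <- cfg$n_tandem_pairs + cfg$n_segmental_pairs
  # pair up consecutive members of the largest groups first so both pair
  # members share a subfamily
  pair_slots <- list(); used <- character(0)
  for (g in order(-cfg$group_sizes)) {
    ids <- fam_ids[fam_group == g]
    while (length(setdiff(ids, used)) >= 2L && length(pair_slots) < n_pairs) {
      free <- setdiff(ids, used)
      pair_slots[[length(pair_slots) + 1L]] <- free[1:2]
      used <- c(used, free[1:2])
    }
    if (length(pair_slots) >= n_pairs) break
  }
  if (length(pair_slots) < n_pairs)
    stop("group sizes cannot host all planted pairs", call. = FALSE)
  tandem_pairs <- pair_slots[seq_len(cfg$n_tandem_pairs)]
  seg_pairs <- pair_slots[cfg$n_tandem_pairs + seq_len(cfg$n_segmental_pairs)]
  paired_ids <- unlist(pair_slots)
  unpaired <- setdiff(fam_ids, paired_ids)

  # --- family proteins and CDS -----------------------------------------
  protect <- (dom_off + 1L):(dom_off + nchar(cfg$domain_consensus))
  # a member: group backbone mutated at backbone_divergence, with fresh
  # domain copies mutated at per_site_sub_rate written over the domain
  # slots (so the diagnostic domains stay close to consensus while
  # same-group members stay far from each other)
  make_member <- function(id, g) {
    bb <- chars(mutate_sequence(group_seeds[[g]], cfg$backbone_divergence,
                                seed = sub_seed(seed, paste0("bb_", id))))
    put <- function(bb, s, off, tag) {
      m <- mutate_sequence(s, cfg$per_site_sub_rate,
                           seed = sub_seed(seed, paste0("dom_", id, tag)))
      bb[off + seq_len(nchar(m))] <- chars(m)
      bb
    }
    bb <- put(bb, cfg$domain_consensus, dom_off, "_s8")
    if (g %in% i9_groups) bb <- put(bb, domains$I9, i9_off, "_i9")
    if (g %in% pa_groups) bb <- put(bb, domains$PA, pa_off, "_pa")
    paste(bb, collapse = "")
  }
  proteome <- character(0); cds <- character(0)
  with_seed(sub_seed(seed, "family_seqs"), {
    for (id in fam_ids) {
      if (id %in% vapply(pair_slots, `[`, character(1L), 2L)) next  # partners later
      prot <- make_member(id, fam_group[[id]])
      proteome[id] <- prot
      cds[id] <- reverse_translate(prot)
    }
    for (pr in pair_slots) {
      a <- pr[1L]; b <- pr[2L]
      cds[b] <- plant_divergence(cds[[a]], cfg$syn_divergence,
                                 cfg$nonsyn_divergence, protect = protect)
      proteome[b] <- translate_cds(cds[[b]])
    }
  })

  # --- background genes, including collinear-block homolog copies ------
  n_anchor_bg <- cfg$n_segmental_pairs * (cfg$block_size - 1L)
  bg_ids <- sprintf("BG%03d", seq_len(cfg$n_background_genes))
  with_seed(sub_seed(seed, "background_seqs"), {
    # first 2*n_anchor_bg ids are block anchors: originals then copies
    for (k in seq_len(n_anchor_bg)) {
      orig <- bg_ids[k]; copy <- bg_ids[n_anchor_bg + k]
      n_cod <- sample(cfg$background_protein_codons[1L]:
                        cfg$background_protein_codons[2L], 1L)
      prot <- random_protein(n_cod)
      proteome[orig] <- prot
      cds[orig] <- reverse_translate(prot)
      prot2 <- mutate_sequence(prot, 0.05,
                               seed = sub_seed(seed, paste0("bgcopy", k)))
      proteome[copy] <- prot2
      cds[copy] <- reverse_translate(prot2)
    }
    for (id in bg_ids[seq(2L * n_anchor_bg + 1L,
                          length.out = cfg$n_background_genes -
                            2L * n_anchor_bg)]) {
      n_cod <- sample(cfg$background_protein_codons[1L]:
                        cfg$background_protein_codons[2L], 1L)
      prot <- random_protein(n_cod)
      proteome[id] <- prot
      cds[id] <- reverse_translate(prot)
    }
  })

  # --- chromosome layout (ordered gene lists = rank order) -------------
  chrom_names <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  lists <- setNames(vector("list", cfg$n_chromosomes), chrom_names)
  block_truth <- list()
  copy_of <- setNames(bg_ids[n_anchor_bg + seq_len(n_anchor_bg)],
                      bg_ids[seq_len(n_anchor_bg)])
  bg_cursor <- 2L * n_anchor_bg  # anchors consumed; remainder free
  take_bg <- function(n) {
    ids <- bg_ids[bg_cursor + seq_len(n)]
    bg_cursor <<- bg_cursor + n
    ids
  }
  mid <- ceiling(cfg$block_size / 2)
  for (k in seq_along(seg_pairs)) {
    A <- ((k - 1L) %% cfg$n_chromosomes) + 1L
    B <- (k %% cfg$n_chromosomes) + 1L
    anchors_a <- bg_ids[(k - 1L) * (cfg$block_size - 1L) +
                          seq_len(cfg$block_size - 1L)]
    run_a <- append(anchors_a, seg_pairs[[k]][1L], after = mid - 1L)
    run_b <- ifelse(run_a == seg_pairs[[k]][1L], seg_pairs[[k]][2L],
                    copy_of[run_a])
    lists[[A]] <- c(lists[[A]], unname(run_a))
    lists[[B]] <- c(lists[[B]], unname(run_b))
    block_truth[[k]] <- list(chrom_a = chrom_names[A], chrom_b = chrom_names[B],
                             genes_a = run_a, genes_b = unname(run_b))
  }
  for (k in seq_along(tandem_pairs)) {
    ch <- ((k - 1L) %% cfg$n_chromosomes) + 1L
    lists[[ch]] <- c(lists[[ch]], take_bg(1L), tandem_pairs[[k]], take_bg(1L))
  }
  ch <- 0L
  for (id in unpaired) {
    ch <- (ch %% cfg$n_chromosomes) + 1L
    lists[[ch]] <- c(lists[[ch]], take_bg(1L), id, take_bg(1L))
  }
  remaining <- bg_ids[seq(bg_cursor + 1L, length.out =
                            cfg$n_background_genes - bg_cursor)]
  ch <- 0L
  for (id in remaining) {
    ch <- (ch %% cfg$n_chromosomes) + 1L
    lists[[ch]] <- c(lists[[ch]], id)
  }

  # --- gene models and chromosome sequences ----------------------------
  genes <- list()
  chrom_seq_parts <- list()
  strand_pick <- with_seed(sub_seed(seed, "strands"),
                           setNames(sample(c("+", "-"), length(proteome),
                                           replace = TRUE), names(proteome)))
  exon_plan <- with_seed(sub_seed(seed, "exons"), {
    lapply(setNames(names(cds), names(cds)), function(id) {
      n_ex <- sample(1:4, 1L)
      lens <- nchar(cds[[id]])
      if (n_ex == 1L) return(list(ex = lens, intron = integer(0)))
      cuts <- sort(sample(seq_len(lens - 1L), n_ex - 1L))
      list(ex = diff(c(0L, cuts, lens)), intron = sample(150:300, n_ex - 1L,
                                                         replace = TRUE))
    })
  })
  chromosomes <- setNames(character(cfg$n_chromosomes), chrom_names)
  with_seed(sub_seed(seed, "genome_seq"), {
    for (cn in chrom_names) {
      ids <- lists[[cn]]
      pos <- cfg$intergenic  # leading gap
      parts <- list(random_dna(cfg$intergenic))
      for (id in ids) {
        plan <- exon_plan[[id]]
        glen <- sum(plan$ex) + sum(plan$intron)
        body_cds <- if (strand_pick[[id]] == "+") cds[[id]] else revcomp(cds[[id]])
        exlens <- if (strand_pick[[id]] == "+") plan$ex else rev(plan$ex)
        introns <- plan$intron
        segs <- character(0); exon_iv <- matrix(integer(0), 0L, 2L)
        cur <- pos; cds_pos <- 0L
        for (e in seq_along(exlens)) {
          exseq <- substring(body_cds, cds_pos + 1L, cds_pos + exlens[e])
          cds_pos <- cds_pos + exlens[e]
          segs <- c(segs, exseq)
          exon_iv <- rbind(exon_iv, c(cur, cur + exlens[e]))
          cur <- cur + exlens[e]
          if (e < length(exlens)) {
            segs <- c(segs, random_dna(introns[e]))
            cur <- cur + introns[e]
          }
        }
        genes[[id]] <- list(gene_id = id, chrom = cn, start = pos,
                            end = pos + glen, strand = strand_pick[[id]],
                            exons = exon_iv)
        parts <- c(parts, paste(segs, collapse = ""),
                   random_dna(cfg$intergenic))
        pos <- pos + glen + cfg$intergenic
      }
      chromosomes[[cn]] <- paste(unlist(parts), collapse = "")
    }
  })

  # --- planted promoters for family genes ------------------------------
  element_truth <- list()
  with_seed(sub_seed(seed, "promoters"), {
    for (id in fam_ids) {
      g <- genes[[id]]
      pr <- build_promoter(cfg$promoter_length, cfg$planted_elements,
                           cfg$element_table)
      if (g$strand == "+") {
        at <- g$start - cfg$promoter_length
        substring(chromosomes[[g$chrom]], at + 1L, g$start) <- pr$seq
      } else {
        substring(chromosomes[[g$chrom]], g$end + 1L,
                  g$end + cfg$promoter_length) <- revcomp(pr$seq)
      }
      tr <- pr$truth
      tr$gene_id <- id
      element_truth[[id]] <- tr[, c("gene_id", "element", "offset", "strand")]
    }
  })
  element_truth <- do.call(rbind, element_truth)
  rownames(element_truth) <- NULL

  # --- expression matrix ------------------------------------------------
  all_ids <- unlist(lists, use.names = FALSE)
  n_t <- length(cfg$tissues)
  with_seed(sub_seed(seed, "expression"), {
    expr <- matrix(runif(length(all_ids) * n_t, 0, 1),
                   length(all_ids), n_t,
                   dimnames = list(all_ids, cfg$tissues))
    chosen <- sample(fam_ids, cfg$n_specific + cfg$n_ubiquitous)
    specific_ids <- chosen[seq_len(cfg$n_specific)]
    ubiq_ids <- chosen[cfg$n_specific + seq_len(cfg$n_ubiquitous)]
    specific_map <- setNames(cfg$tissues[(seq_along(specific_ids) - 1L) %%
                                           n_t + 1L], specific_ids)
    for (id in specific_ids) {
      expr[id, ] <- runif(n_t, 0, 0.5)
      expr[id, specific_map[[id]]] <- runif(1L, 50, 100)
    }
    for (id in ubiq_ids) expr[id, ] <- runif(n_t, 5, 50)
  })

  # --- labeled references ----------------------------------------------
  refs <- character(0)
  with_seed(sub_seed(seed, "refs"), {
    for (g in seq_len(n_groups)) {
      for (r in seq_len(cfg$n_refs_per_group)) {
        rid <- sprintf("REF_G%d_%d", g, r)
        refs[rid] <- make_member(rid, g)
      }
    }
  })
  ref_labels <- setNames(group_names[rep(seq_len(n_groups),
                                         each = cfg$n_refs_per_group)],
                         names(refs))
  ref_clades <- setNames(rep(c("monocot", "dicot"),
                             length.out = length(refs)), names(refs))

  # --- assemble ---------------------------------------------------------
  gene_df <- data.frame(
    gene_id = vapply(genes, `[[`, character(1L), "gene_id"),
    chrom = vapply(genes, `[[`, character(1L), "chrom"),
    start = vapply(genes, `[[`, integer(1L), "start"),
    end = vapply(genes, `[[`, integer(1L), "end"),
    strand = vapply(genes, `[[`, character(1L), "strand"),
    stringsAsFactors = FALSE)
  gene_df$exons <- lapply(genes, `[[`, "exons")
  gene_df <- compute_ranks(gene_df)
  rownames(gene_df) <- gene_df$gene_id

  bundle <- genome_bundle(chromosomes, gene_df, proteome, cds)

  pairs_df <- data.frame(
    gene_a = vapply(c(tandem_pairs, seg_pairs), min, character(1L)),
    gene_b = vapply(c(tandem_pairs, seg_pairs), max, character(1L)),
    dup_type = c(rep("tandem", length(tandem_pairs)),
                 rep("segmental", length(seg_pairs))),
    stringsAsFactors = FALSE)

  truth <- structure(list(
    family_ids = fam_ids,
    groups = setNames(group_names[fam_group], fam_ids),
    pairs = pairs_df,
    blocks = block_truth,
    element_hits = element_truth,
    specific_map = specific_map,
    ubiquitous_ids = ubiq_ids,
    domain_offset = dom_off,
    has_pa = setNames(fam_group %in% pa_groups, fam_ids),
    has_i9 = setNames(fam_group %in% i9_groups, fam_ids)),
    class = "survey_truth")

  structure(list(bundle = bundle, expression = expr,
                 element_table = cfg$element_table,
                 refs = refs, ref_labels = ref_labels,
                 ref_clades = ref_clades, truth = truth, config = cfg),
            class = "survey_dataset")
}

#' Write a synthetic survey dataset to a directory
#'
#' Emits `genome.fna`, `genes.gff3`, `proteome.faa`, `cds.fna`,
#' `expression.tsv`, `elements.tsv`, `refs.faa`, `ref_labels.tsv` and
#' `truth.json`. Identical datasets produce byte-identical files.
#'
#' @param ds A `survey_dataset` from [generate_survey_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "survey_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fasta(ds$bundle$chromosomes, p("genome.fna"))
  write_gff3(ds$bundle$genes, p("genes.gff3"))
  write_fasta(ds$bundle$proteome, p("proteome.faa"))
  write_fasta(ds$bundle$cds, p("cds.fna"))
  write_expression_tsv(ds$expression, p("expression.tsv"))
  write.table(ds$element_table, p("elements.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_fasta(ds$refs, p("refs.faa"))
  write.table(data.frame(ref_id = names(ds$ref_labels),
                         group = unname(ds$ref_labels),
                         clade = unname(ds$ref_clades[names(ds$ref_labels)])),
              p("ref_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- ds$truth
  truth_json <- list(
    family_ids = truth$family_ids,
    groups = as.list(truth$groups),
    pairs = truth$pairs,
    element_hits = truth$element_hits,
    specific_map = as.list(truth$specific_map),
    ubiquitous_ids = truth$ubiquitous_ids,
    domain_offset = truth$domain_offset,
    has_pa = as.list(truth$has_pa),
    has_i9 = as.list(truth$has_i9))
  jsonlite::write_json(truth_json, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
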