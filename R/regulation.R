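# Promoter extraction and cis-regulatory element census.
#
# Promoters are the <= 2,000-bp regions immediately upstream of each gene,
# clipped at the chromosome boundary and (optionally) at the span of the
# nearest upstream gene, mirroring the practice of deleting overlapped
# regions before element scanning. Elements are defined by IUPAC consensus
# strings in a user-editable packaged table and matched exactly (every
# offset, both strands, overlapping matches all reported).

#' Read a cis-element definition table
#'
#' The packaged default covers commonly published consensus motifs for the
#' three standard categories (growth/development, stress, phytohormone).
#' Consensus strings are validated against the IUPAC nucleotide alphabet
#' at load time.
#'
#' @param path Optional path to a replacement TSV with columns `name`,
#'   `consensus`, `category`.
#' @return `data.frame` with one row per element.
#' @export
read_element_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cis_elements.tsv", package = "famsurvey")
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "consensus", "category") %in% names(df)))
  df$consensus <- toupper(df$consensus)
  ok_cat <- c("growth_development", "stress", "phytohormone")
  bad <- setdiff(df$category, ok_cat)
  if (length(bad))
    stop("unknown element category: ", bad[1L], call. = FALSE)
  for (i in seq_len(nrow(df))) {
    cc <- chars(df$consensus[i])
    illegal <- setdiff(cc, names(IUPAC_CODES))
    if (length(illegal))
      stop("invalid IUPAC code '", illegal[1L], "' in element ",
           df$name[i], call. = FALSE)
  }
  if (anyDuplicated(df$name)) stop("duplicate element name", call. = FALSE)
  df
}

#' Extract promoter sequences for a set of genes
#'
#' For a plus-strand gene at `[s, e)` the promoter is the genomic interval
#' `[max(0, s - length), s)` taken as-is; for a minus-strand gene it is
#' `[e, min(chrom_end, e + length))` reverse-complemented, so the returned
#' sequence always reads 5' to 3' towards the gene. With
#' `truncate_overlap`, the interval is further clipped to exclude bases
#' inside the span of the nearest upstream gene (any strand). Genes whose
#' promoter clips to zero length are excluded with a message.
#'
#' @param bundle A `genome_bundle`.
#' @param gene_ids Genes to extract (default: all genes in the bundle).
#' @param length Maximum promoter length in bp (default 2000).
#' @param truncate_overlap Clip at upstream-gene overlap (default TRUE).
#' @return `data.frame`: `gene_id`, `seq`, `chrom`, `start`, `end`,
#'   `strand`, `truncated` (`start`/`end` genomic, 0-based half-open).
#' @export
extract_promoters <- function(bundle, gene_ids = NULL, length = 2000L,
                              truncate_overlap = TRUE) {
  stopifnot(inherits(bundle, "genome_bundle"))
  genes <- bundle$genes
  if (is.null(gene_ids)) gene_ids <- genes$gene_id
  missing <- setdiff(gene_ids, genes$gene_id)
  if (length(missing) > 0L)
    stop("gene absent from annotation: ", missing[1L], call. = FALSE)
  rows <- list()
  for (gid in gene_ids) {
    g <- genes[genes$gene_id == gid, ]
    chrom_len <- nchar(bundle$chromosomes[[g$chrom]])
    others <- genes[genes$chrom == g$chrom & genes$gene_id != gid, ,
                    drop = FALSE]
    truncated <- FALSE
    if (g$strand == "+") {
      p_start <- g$start - length
      if (p_start < 0L) { p_start <- 0L; truncated <- TRUE }
      p_end <- g$start
      if (truncate_overlap && nrow(others)) {
        up <- others[others$start < g$start, , drop = FALSE]
        if (nrow(up)) {
          lim <- min(max(up$end), g$start)
          if (lim > p_start) { p_start <- lim; truncated <- TRUE }
        }
      }
      if (p_end <= p_start) {
        message("extract_promoters: ", gid,
                " fully overlapped by upstream gene; excluded")
        next
      }
      seq <- substring(bundle$chromosomes[[g$chrom]], p_start + 1L, p_end)
    } else {
      p_start <- g$end
      p_end <- g$end + length
      if (p_end > chrom_len) { p_end <- chrom_len; truncated <- TRUE }
      if (truncate_overlap && nrow(others)) {
        dn <- others[others$end > g$end, , drop = FALSE]
        if (nrow(dn)) {
          lim <- max(min(dn$start), g$end)
          if (lim < p_end) { p_end <- lim; truncated <- TRUE }
        }
      }
      if (p_end <= p_start) {
        message("extract_promoters: ", gid,
                " fully overlapped by upstream gene; excluded")
        next
      }
      seq <- revcomp(substring(bundle$chromosomes[[g$chrom]],
                               p_start + 1L, p_end))
    }
    rows[[gid]] <- data.frame(gene_id = gid, seq = seq, chrom = g$chrom,
                              start = p_start, end = p_end,
                              strand = g$strand, truncated = truncated,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan promoter sequences for IUPAC consensus elements
#'
#' Every offset where a consensus matches is reported, on the forward
#' strand and (by default) the reverse complement; overlapping matches are
#' all kept. Matching uses Biostrings' IUPAC-aware pattern matching with a
#' literal subject. Offsets are 0-based on the promoter's own 5'->3'
#' coordinates; a minus-strand hit at offset `o` means the reverse
#' complement of the consensus occurs at `o`.
#'
#' @param promoters `data.frame` from [extract_promoters()], or any frame
#'   with `gene_id` and `seq` columns.
#' @param table Element definitions from [read_element_table()].
#' @param both_strands Also scan the reverse complement (default TRUE).
#' @return `data.frame`: `gene_id`, `element`, `offset`, `strand`, ordered
#'   by (gene, offset, element, strand).
#' @export
scan_elements <- function(promoters, table, both_strands = TRUE) {
  stopifnot(nrow(table) > 0L, all(c("gene_id", "seq") %in% names(promoters)))
  hits <- list()
  for (i in seq_len(nrow(promoters))) {
    subject <- Biostrings::DNAString(promoters$seq[i])
    for (k in seq_len(nrow(table))) {
      pat <- Biostrings::DNAString(table$consensus[k])
      fwd <- Biostrings::matchPattern(pat, subject, fixed = "subject")
      if (length(fwd))
        hits[[length(hits) + 1L]] <- data.frame(
          gene_id = promoters$gene_id[i], element = table$name[k],
          offset = BiocGenerics::start(fwd) - 1L, strand = "+",
          stringsAsFactors = FALSE)
      if (both_strands) {
        rev <- Biostrings::matchPattern(
          Biostrings::reverseComplement(pat), subject, fixed = "subject")
        if (length(rev))
          hits[[length(hits) + 1L]] <- data.frame(
            gene_id = promoters$gene_id[i], element = table$name[k],
            offset = BiocGenerics::start(rev) - 1L, strand = "-",
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(gene_id = character(), element = character(),
                      offset = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$gene_id, out$offset, out$element, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize element hits into a category census
#'
#' Produces the grand total, the number of distinct element types
#' observed, per-category totals with percentages of the grand total,
#' within-category per-element percentages, and the gene-by-element count
#' matrix.
#'
#' @param hits Hit table from [scan_elements()].
#' @param table Element definitions (supplies the element -> category map).
#' @return An object of class `element_census`: `list(total, n_types,
#'   by_category, by_element, per_gene)`. With zero hits all counts are 0
#'   and `empty = TRUE` is flagged.
#' @export
summarize_categories <- function(hits, table) {
  cat_of <- setNames(table$category, table$name)
  total <- nrow(hits)
  if (total == 0L) {
    by_category <- data.frame(category = sort(unique(table$category)),
                              n = 0L, pct = 0, stringsAsFactors = FALSE)
    return(structure(list(total = 0L, n_types = 0L, by_category = by_category,
                          by_element = data.frame(), per_gene = matrix(0, 0, 0),
                          empty = TRUE),
                     class = "element_census"))
  }
  unknown <- setdiff(unique(hits$element), names(cat_of))
  if (length(unknown))
    stop("hit for element not in table: ", unknown[1L], call. = FALSE)
  hits$category <- unname(cat_of[hits$element])
  cat_tab <- table(hits$category)
  by_category <- data.frame(category = names(cat_tab),
                            n = as.integer(cat_tab),
                            pct = 100 * as.integer(cat_tab) / total,
                            stringsAsFactors = FALSE)
  el_tab <- table(hits$element)
  by_element <- data.frame(element = names(el_tab),
                           category = unname(cat_of[names(el_tab)]),
                           n = as.integer(el_tab), stringsAsFactors = FALSE)
  cat_totals <- setNames(by_category$n, by_category$category)
  by_element$pct_within_category <-
    100 * by_element$n / as.numeric(cat_totals[by_element$category])
  by_element <- by_element[order(by_element$category, -by_element$n,
                                 by_element$element), , drop = FALSE]
  rownames(by_element) <- NULL
  per_gene <- table(factor(hits$gene_id), factor(hits$element))
  per_gene <- matrix(as.integer(per_gene), nrow(per_gene), ncol(per_gene),
                     dimnames = dimnames(per_gene))
  structure(list(total = total,
                 n_types = length(unique(hits$element)),
                 by_category = by_category, by_element = by_element,
                 per_gene = per_gene, empty = FALSE),
            class = "element_census")
}

#' @export
print.element_census <- function(x, ...) {
  cat("element census:", x$total, "hit(s) of", x$n_types, "type(s)\n")
  if (!x$empty) print(x$by_category)
  invisible(x)
}
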